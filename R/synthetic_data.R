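#' Configuration for the synthetic oocyte-study generator
#'
#' Describes a clustered single-cell heteroplasmy study: mothers
#' (individuals) of several ages, each with her own founder heteroplasmy,
#' contributing a clutch of oocytes. Defaults emulate a desk-scale version
#' of a mouse oocyte study: 40 mothers split over 4 age groups spanning
#' young to aged animals, 30 oocytes per mother, founder heteroplasmies
#' uniform in (0.2, 0.8), and the neutral division + turnover +
#' reamplification truth with bottleneck copy number 670 and ageing
#' turnover 1.4e-4 per day.
#'
#' @param n_individuals number of mothers.
#' @param oocytes_per_individual oocytes per mother.
#' @param ages_days age groups in days; mothers are distributed across them
#'   in rotation.
#' @param h0_range uniform bounds for the per-mother founder heteroplasmy.
#' @param truth named list of generative parameters: `b`, `nu_f_over_n`,
#'   `rho`, `n_d`.
#' @param backend `"gaussian_transformed"` (draw transformed heteroplasmy
#'   from its Gaussian model) or `"full_ssa"` (run each oocyte through the
#'   stochastic developmental cascade and a Gillespie ageing epoch).
#' @param seed RNG seed recorded with the dataset.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_individuals = 40,
                             oocytes_per_individual = 30,
                             ages_days = c(60, 150, 250, 365),
                             h0_range = c(0.2, 0.8),
                             truth = list(b = 670, nu_f_over_n = 1.4e-4,
                                          rho = 0, n_d = 1),
                             backend = c("gaussian_transformed", "full_ssa"),
                             seed = 1) {
  backend <- match.arg(backend)
  stopifnot(n_individuals >= 1, oocytes_per_individual >= 1,
            length(ages_days) >= 1, all(ages_days >= 0),
            h0_range[1] > 0, h0_range[2] < 1, h0_range[1] < h0_range[2])
  truth <- utils::modifyList(list(b = 670, nu_f_over_n = 1.4e-4, rho = 0,
                                  n_d = 1), truth)
  structure(list(n_individuals = n_individuals,
                 oocytes_per_individual = oocytes_per_individual,
                 ages_days = ages_days, h0_range = h0_range,
                 truth = truth, backend = backend, seed = seed),
            class = "generator_config")
}

#' Generate a synthetic single-cell heteroplasmy dataset
#'
#' With the `gaussian_transformed` backend, each oocyte's transformed
#' heteroplasmy is drawn from the model the inference assumes:
#' `z ~ Normal(rho * age, V'(age) / (E (1 - E)))` with
#' `V'(age)` from the truth schedule and `E = selection_mean(rho, age,
#' h0)`, then mapped back with the inverse transform (so `h` always lies
#' in (0, 1)).
#'
#' With the `full_ssa` backend, each oocyte's molecule counts are run
#' through the developmental cascade by exact sampling -- hypergeometric
#' halving at each division and Polya-urn (beta-binomial) regrowth along
#' the geometric copy-number profile, plus the final reamplification --
#' and the ageing turnover epoch is then simulated with the Gillespie core
#' at a reduced surrogate copy number (1000) with the degradation rate
#' matched so that nu*f/n equals the truth compound (the V'(h) accrual
#' depends on nu f t / n only). Oocytes fixated at h = 0 or 1 are retained
#' in the returned records but flagged, mirroring the inference exclusion
#' policy.
#'
#' @param config a [generator_config()].
#' @return a [heteroplasmy_dataset()] with attributes `truth` and `seed`;
#'   `attr(, "raw_records")` holds all generated rows including fixated
#'   ones.
#' @export
generate_heteroplasmy <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  tr <- config$truth
  sch <- mouse_schedule(b = tr$b, nu_f_over_n = tr$nu_f_over_n,
                        n_d = tr$n_d,
                        model_tag = if (tr$rho != 0) "with_selection"
                                    else "div_turnover_amp",
                        rho = tr$rho)
  ages <- rep(config$ages_days, length.out = config$n_individuals)
  rows <- vector("list", config$n_individuals)
  for (i in seq_len(config$n_individuals)) {
    h0 <- runif(1, config$h0_range[1], config$h0_range[2])
    age <- ages[i]
    nv <- predict_norm_var(sch, age)$norm_var
    k <- config$oocytes_per_individual
    if (config$backend == "gaussian_transformed") {
      Eh <- selection_mean(tr$rho, age, h0)
      z <- stats::rnorm(k, mean = tr$rho * age,
                        sd = sqrt(nv / (Eh * (1 - Eh))))
      h <- inverse_transform_heteroplasmy(z, h0)
    } else {
      h <- vapply(seq_len(k), function(j)
        ssa_oocyte(h0, sch, age, tr), numeric(1))
    }
    rows[[i]] <- data.frame(individual_id = sprintf("m%03d", i),
                            age_days = age, h0 = h0, h = h)
  }
  raw <- do.call(rbind, rows)
  out <- heteroplasmy_dataset(raw, label = sprintf("synthetic (%s)",
                                                   config$backend))
  attr(out, "truth") <- tr
  attr(out, "seed") <- config$seed
  attr(out, "raw_records") <- raw
  out
}

# one oocyte through the stochastic developmental cascade + ageing epoch
ssa_oocyte <- function(h0, schedule, age_days, truth) {
  n0 <- 1e5
  m <- round(n0 * h0)
  w <- n0 - m
  for (p in schedule$phases) {
    a <- 2 * (p$copy_end / p$copy_start)^(1 / p$n_divisions)
    n <- p$copy_start
    for (i in seq_len(p$n_divisions)) {
      half <- floor((w + m) / 2)
      m <- rhyper(1, m, w, half)        # keep one daughter
      w <- half - m
      ntarget <- round(n * a / 2)
      amp <- polya_amplify(odna_pool(w, m), max(ntarget, w + m))
      w <- amp$n_wild; m <- amp$n_mut
      n <- ntarget
    }
  }
  fa <- schedule$final_amplification
  amp <- polya_amplify(odna_pool(w, m), fa[2])
  w <- amp$n_wild; m <- amp$n_mut
  h <- m / (w + m)
  if (h <= 0 || h >= 1 || age_days == 0) return(h)
  # ageing turnover at a dynamically equivalent surrogate copy number
  n_sim <- 1000L
  m_sim <- round(n_sim * h)
  if (m_sim == 0 || m_sim == n_sim) return(m_sim / n_sim)
  nuf_sim <- truth$nu_f_over_n * n_sim
  par <- sim_params(lam = 2 * nuf_sim, nu = nuf_sim, alpha = 1 / n_sim,
                    kappa = 0, n_d = truth$n_d)
  tr <- ssa_run_cpp(c(0L, n_sim - m_sim, 0L, m_sim), unclass(par),
                    age_days)
  tot <- sum(tr[1, ])
  if (tot == 0) return(NA_real_)
  (tr[1, 3] + tr[1, 4]) / tot
}

#' Parameter-recovery experiment
#'
#' Generates `n_datasets` synthetic datasets at a fixed truth, fits the
#' requested model(s) to each, and tabulates bias, relative error, RMSE
#' and (optionally) bootstrap confidence-interval coverage per parameter,
#' plus model-selection accuracy when both a neutral and a selection model
#' are requested.
#'
#' @param config a [generator_config()]; its seed seeds dataset `i` as
#'   `seed + i`.
#' @param model_tags models to fit; the first is the estimation model.
#' @param n_datasets number of replicate datasets (>= 2).
#' @param n_boot bootstrap resamples per dataset for coverage (0 disables
#'   coverage assessment).
#' @return list with `fits` (per-dataset estimate table), `summary`
#'   (median relative error, RMSE, coverage per parameter) and
#'   `model_selection` (delta-AIC table) when two models were requested.
#' @export
recovery_experiment <- function(config,
                                model_tags = "div_turnover_amp",
                                n_datasets = 20, n_boot = 0) {
  stopifnot(inherits(config, "generator_config"), n_datasets >= 2)
  tr <- config$truth
  est_tag <- model_tags[1]
  pn <- theta_names(est_tag)
  truth_vec <- c(b = tr$b, nu_f_over_n = tr$nu_f_over_n, rho = tr$rho,
                 n2_subsample = NA, n_c = NA)[pn]
  rows <- vector("list", n_datasets)
  cover <- matrix(NA, n_datasets, length(pn), dimnames = list(NULL, pn))
  daic <- rep(NA_real_, n_datasets)
  for (i in seq_len(n_datasets)) {
    cfg <- config
    cfg$seed <- config$seed + i
    dat <- generate_heteroplasmy(cfg)
    fit <- fit_ml(dat, est_tag)
    rows[[i]] <- fit$point_estimates
    if (n_boot >= 100) {
      bf <- suppressWarnings(
        bootstrap_fit(dat, fit, n_boot = n_boot, seed = cfg$seed))
      ci <- bf$bootstrap_intervals
      for (nm in pn)
        if (!is.na(truth_vec[nm]))
          cover[i, nm] <- truth_vec[nm] >= ci[nm, "lo"] &&
            truth_vec[nm] <= ci[nm, "hi"]
    }
    if (length(model_tags) >= 2) {
      cmp <- compare_models(dat, model_tags)
      # delta-AIC of the second model relative to the first
      daic[i] <- cmp$aic[cmp$model_tag == model_tags[2]] -
        cmp$aic[cmp$model_tag == model_tags[1]]
    }
  }
  est <- do.call(rbind, rows)
  summ <- lapply(pn, function(nm) {
    e <- est[, nm]
    tv <- truth_vec[nm]
    data.frame(parameter = nm, truth = tv,
               median_estimate = stats::median(e),
               median_rel_error = if (!is.na(tv) && tv != 0)
                 stats::median((e - tv) / abs(tv)) else NA_real_,
               rmse = if (!is.na(tv)) sqrt(mean((e - tv)^2)) else NA_real_,
               coverage = mean(cover[, nm]))
  })
  list(fits = as.data.frame(est),
       summary = do.call(rbind, summ),
       model_selection = if (length(model_tags) >= 2)
         data.frame(dataset = seq_len(n_datasets), delta_aic = daic)
       else NULL,
       truth = truth_vec,
       n_datasets = n_datasets)
}
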