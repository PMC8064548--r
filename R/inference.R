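#' Single-cell heteroplasmy dataset
#'
#' Validates a table of single-cell heteroplasmy measurements: one row per
#' cell with the individual (mother) identifier, the individual's age in
#' days, the founder heteroplasmy `h0` and the measured heteroplasmy `h`.
#' Rows with `h` at exactly 0 or 1 are fixated: they have no finite
#' transform and are flagged and excluded from the fittable records (their
#' count is kept in the `n_fixated` attribute).
#'
#' @param records data frame with columns `individual_id`, `age_days`,
#'   `h0`, `h`.
#' @param label optional text label.
#' @return an object of class `heteroplasmy_dataset` (a data frame).
#' @export
heteroplasmy_dataset <- function(records, label = "") {
  required <- c("individual_id", "age_days", "h0", "h")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)[required]
  bad <- which(!is.finite(records$age_days) | records$age_days < 0)
  if (length(bad))
    stop("invalid age_days in row(s): ", paste(head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(records$h0) | records$h0 <= 0 | records$h0 >= 1)
  if (length(bad))
    stop("h0 must lie strictly in (0, 1); offending row(s): ",
         paste(head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(records$h) | records$h < 0 | records$h > 1)
  if (length(bad))
    stop("h must lie in [0, 1]; offending row(s): ",
         paste(head(bad, 5), collapse = ", "))
  fixated <- records$h <= 0 | records$h >= 1
  out <- records[!fixated, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_fixated = sum(fixated), label = label,
            class = c("heteroplasmy_dataset", "data.frame"))
}

#' Read a heteroplasmy dataset from delimited text
#'
#' Reads CSV or TSV (by extension, or `sep`) with header columns
#' `individual_id`, `age_days`, `h0`, `h` and validates it.
#'
#' @param path file path.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return a [heteroplasmy_dataset()].
#' @export
read_heteroplasmy <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  heteroplasmy_dataset(df, label = basename(path))
}

#' Gaussian log-likelihood of a germline model on the transformed scale
#'
#' Each record contributes the Gaussian log-density of its transformed
#' heteroplasmy `z = logit(h) - logit(h0)` with mean `rho * age` (0 for
#' neutral models) and delta-method variance
#' `Var(z) = V'(age) / (E(h) (1 - E(h)))`, where `V'(age)` is the
#' schedule's predicted normalised variance at that age and
#' `E(h) = selection_mean(rho, age, h0)`.
#'
#' @param data a [heteroplasmy_dataset()].
#' @param schedule a [mouse_schedule()]; its `rho` supplies the selection
#'   coefficient.
#' @return the summed log-likelihood (`-Inf` when any model variance is
#'   nonpositive).
#' @export
log_likelihood <- function(data, schedule) {
  stopifnot(inherits(data, "heteroplasmy_dataset"),
            inherits(schedule, "germline_schedule"))
  v0 <- developmental_norm_var(schedule)
  rho <- schedule$rho
  nv <- v0 + (1 + schedule$n_d) * schedule$ageing_turnover * data$age_days
  Eh <- selection_mean(rho, data$age_days, data$h0)
  var_z <- nv / (Eh * (1 - Eh))
  if (any(!is.finite(var_z)) || any(var_z <= 0)) return(-Inf)
  z <- transform_heteroplasmy(data$h, data$h0)
  sum(dnorm(z, mean = rho * data$age_days, sd = sqrt(var_z), log = TRUE))
}

model_k <- function(model_tag) {
  switch(model_tag, with_selection = 3L, 2L)
}

theta_to_schedule <- function(theta, model_tag) {
  switch(model_tag,
    div_turnover_amp = mouse_schedule(b = exp(theta[1]),
                                      nu_f_over_n = exp(theta[2]),
                                      model_tag = "div_turnover_amp"),
    subsample_amp = mouse_schedule(nu_f_over_n = exp(theta[2]),
                                   model_tag = "subsample_amp",
                                   n2_subsample = exp(theta[1])),
    clustered = mouse_schedule(nu_f_over_n = exp(theta[2]),
                               n_c = exp(theta[1]),
                               model_tag = "clustered"),
    with_selection = mouse_schedule(b = exp(theta[1]),
                                    nu_f_over_n = exp(theta[2]),
                                    model_tag = "with_selection",
                                    rho = theta[3]))
}

theta_names <- function(model_tag) {
  switch(model_tag,
    div_turnover_amp = c("b", "nu_f_over_n"),
    subsample_amp = c("n2_subsample", "nu_f_over_n"),
    clustered = c("n_c", "nu_f_over_n"),
    with_selection = c("b", "nu_f_over_n", "rho"))
}

theta_default_init <- function(model_tag) {
  switch(model_tag,
    div_turnover_amp = c(log(1000), log(1e-4)),
    subsample_amp = c(log(1000), log(1e-4)),
    clustered = c(log(5), log(1e-4)),
    with_selection = c(log(1000), log(1e-4), 0))
}

theta_to_estimates <- function(theta, model_tag) {
  est <- c(exp(theta[1]), exp(theta[2]))
  if (model_tag == "with_selection") est <- c(est, theta[3])
  setNames(est, theta_names(model_tag))
}

neg_loglik <- function(theta, data, model_tag) {
  sch <- tryCatch(theta_to_schedule(theta, model_tag),
                  error = function(e) NULL)
  if (is.null(sch)) return(1e12)
  ll <- log_likelihood(data, sch)
  if (!is.finite(ll)) return(1e12)
  -ll
}

#' Maximum-likelihood fit of a germline model
#'
#' Maximises [log_likelihood()] with derivative-free Nelder-Mead simplex
#' search (`optim`). Scale parameters (`b`, `nu*f/n`, `n2`, `n_c`) are
#' optimised on the log scale to enforce positivity; the selection
#' coefficient `rho` is unconstrained. The fit is deterministic for a
#' fixed starting point.
#'
#' @param data a [heteroplasmy_dataset()].
#' @param model_tag one of `"div_turnover_amp"`, `"subsample_amp"`,
#'   `"clustered"`, `"with_selection"`.
#' @param init optional starting values on the optimiser scale
#'   (log scale for positive parameters).
#' @param control passed to [stats::optim()].
#' @return an object of class `fit_result` with elements `model_tag`,
#'   `point_estimates` (natural scale), `loglik`, `aic`, `r_squared`,
#'   `converged`, `theta` (optimiser scale), `n_records`.
#' @export
fit_ml <- function(data, model_tag = "div_turnover_amp", init = NULL,
                   control = list(maxit = 500, reltol = 1e-10)) {
  stopifnot(inherits(data, "heteroplasmy_dataset"))
  model_tag <- match.arg(model_tag, c("div_turnover_amp", "subsample_amp",
                                      "clustered", "with_selection"))
  if (length(unique(data$age_days)) < 2)
    warning("fewer than 2 distinct ages: the ageing-turnover rate is not ",
            "identifiable from this design")
  if (is.null(init)) init <- theta_default_init(model_tag)
  opt <- optim(init, neg_loglik, data = data, model_tag = model_tag,
               method = "Nelder-Mead", control = control)
  k <- model_k(model_tag)
  est <- theta_to_estimates(opt$par, model_tag)
  res <- structure(list(model_tag = model_tag,
                        point_estimates = est,
                        theta = opt$par,
                        loglik = -opt$value,
                        aic = 2 * k - 2 * (-opt$value),
                        k = k,
                        converged = opt$convergence == 0,
                        n_records = nrow(data)),
                   class = "fit_result")
  res$r_squared <- fit_r_squared(data, res)
  if (!res$converged)
    warning("Nelder-Mead did not report convergence (code ",
            opt$convergence, ")")
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("ML fit [%s]: loglik = %.2f, AIC = %.2f, R^2 = %.3f (n = %d)\n",
              x$model_tag, x$loglik, x$aic, x$r_squared, x$n_records))
  est <- x$point_estimates
  for (nm in names(est)) cat(sprintf("  %-12s %.6g", nm, est[[nm]]),
                             if (!is.null(x$bootstrap_intervals) &&
                                 nm %in% rownames(x$bootstrap_intervals))
                               sprintf("  [%.6g, %.6g]",
                                       x$bootstrap_intervals[nm, 1],
                                       x$bootstrap_intervals[nm, 2]) else "",
                             "\n")
  invisible(x)
}

fitted_schedule <- function(fit) theta_to_schedule(fit$theta, fit$model_tag)

# R^2 between per-age observed V'(h) (mean of per-mother normalised
# variances) and the model prediction
fit_r_squared <- function(data, fit) {
  obs <- empirical_norm_var(data)
  byage <- aggregate(norm_var ~ age_days, data = obs, FUN = mean)
  sch <- fitted_schedule(fit)
  pred <- predict_norm_var(sch, byage$age_days)$norm_var
  sstot <- sum((byage$norm_var - mean(byage$norm_var))^2)
  ssres <- sum((byage$norm_var - pred)^2)
  if (sstot <= 0) return(NA_real_)
  1 - ssres / sstot
}

#' Bootstrap confidence intervals for a fitted germline model
#'
#' Nonparametric bootstrap of the records: by default each individual's
#' records are resampled with replacement within that individual
#' (stratified resampling, preserving the per-mother founder-heteroplasmy
#' design); alternatively whole individuals are resampled. Each resample is
#' refitted from the original point estimate and percentile 95% intervals
#' are reported. Resamples whose refit fails or does not converge are
#' dropped; a warning is issued if more than 10% fail.
#'
#' @param data a [heteroplasmy_dataset()].
#' @param fit a [fit_ml()] result (supplies model and starting point).
#' @param n_boot number of bootstrap resamples (>= 100; the conventional
#'   default is 1000).
#' @param unit `"record"` (stratified within individual) or
#'   `"individual"` (resample whole mothers).
#' @param seed optional RNG seed.
#' @param level confidence level.
#' @return the `fit_result` with `bootstrap_intervals` (matrix with
#'   columns `lo`, `hi`), `n_boot`, `boot_failures` and `seed` added.
#' @export
bootstrap_fit <- function(data, fit, n_boot = 1000,
                          unit = c("record", "individual"), seed = NULL,
                          level = 0.95) {
  stopifnot(inherits(data, "heteroplasmy_dataset"),
            inherits(fit, "fit_result"))
  if (n_boot < 100) stop("n_boot must be at least 100")
  unit <- match.arg(unit)
  if (!is.null(seed)) set.seed(seed)
  ids <- data$individual_id
  uid <- unique(ids)
  idx_by_id <- split(seq_len(nrow(data)), ids)
  p <- length(fit$theta)
  draws <- matrix(NA_real_, n_boot, p)
  failures <- 0L
  for (bi in seq_len(n_boot)) {
    if (unit == "record") {
      idx <- unlist(lapply(idx_by_id, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
    } else {
      take <- sample(uid, length(uid), replace = TRUE)
      idx <- unlist(idx_by_id[as.character(take)], use.names = FALSE)
    }
    bd <- data[idx, , drop = FALSE]
    class(bd) <- class(data)
    opt <- tryCatch(
      optim(fit$theta, neg_loglik, data = bd, model_tag = fit$model_tag,
            method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(opt) || opt$convergence != 0 || opt$value >= 1e12) {
      failures <- failures + 1L
    } else {
      draws[bi, ] <- opt$par
    }
  }
  if (failures > 0.1 * n_boot)
    warning(sprintf("%d of %d bootstrap refits failed", failures, n_boot))
  ok <- stats::complete.cases(draws)
  alpha <- (1 - level) / 2
  ci <- t(apply(draws[ok, , drop = FALSE], 2, quantile,
                probs = c(alpha, 1 - alpha), names = FALSE))
  # back to natural scale
  nat <- ci
  nat[1:2, ] <- exp(ci[1:2, ])
  rownames(nat) <- theta_names(fit$model_tag)
  colnames(nat) <- c("lo", "hi")
  fit$bootstrap_intervals <- nat
  fit$n_boot <- n_boot
  fit$boot_failures <- failures
  fit$boot_unit <- unit
  fit$seed <- seed
  fit
}

#' Compare germline mechanism models by AIC
#'
#' Fits each requested model and tabulates log-likelihood, AIC, delta-AIC
#' (relative to the best model) and R^2 between per-age observed and
#' predicted V'(h).
#'
#' @param data a [heteroplasmy_dataset()].
#' @param model_tags character vector of model tags (>= 2 entries, or one
#'   repeated to check determinism).
#' @param ... passed to [fit_ml()].
#' @return data frame ranked by AIC, with attribute `fits` holding the
#'   individual `fit_result` objects.
#' @export
compare_models <- function(data, model_tags = c("div_turnover_amp",
                                                "with_selection"), ...) {
  stopifnot(length(model_tags) >= 2)
  fits <- lapply(model_tags, function(tag) fit_ml(data, tag, ...))
  tab <- data.frame(model_tag = model_tags,
                    k = vapply(fits, `[[`, integer(1), "k"),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    aic = vapply(fits, `[[`, numeric(1), "aic"),
                    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"))
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- setNames(fits, model_tags)
  tab
}

#' Empirical normalised heteroplasmy variance by group
#'
#' Sample mean, unbiased variance, normalised variance V'(h), bottleneck
#' size N_b and the standard error `V' * sqrt(2 / (m - 1))` per group of
#' measurements. By default cells are grouped by individual and age so the
#' variance reflects within-mother segregation rather than between-mother
#' founder differences; set `by = "age_days"` to pool an age group.
#' Groups with fewer than 2 records are dropped with a warning; groups of
#' identical measurements have V' = 0 and N_b reported as missing.
#'
#' @param data a [heteroplasmy_dataset()].
#' @param by grouping columns, default `c("individual_id", "age_days")`.
#' @return data frame with one row per retained group: the grouping
#'   columns, `n_cells`, `mean_h`, `var_h`, `norm_var`, `norm_var_se`,
#'   `bottleneck_size`.
#' @export
empirical_norm_var <- function(data, by = c("individual_id", "age_days")) {
  stopifnot(inherits(data, "heteroplasmy_dataset"),
            all(by %in% names(data)))
  key <- interaction(data[by], drop = TRUE)
  groups <- split(seq_len(nrow(data)), key)
  small <- vapply(groups, length, integer(1)) < 2
  if (any(small)) {
    warning(sum(small), " group(s) with a single record dropped")
    groups <- groups[!small]
  }
  rows <- lapply(groups, function(ix) {
    h <- data$h[ix]
    m <- length(h)
    mh <- mean(h)
    vh <- var(h)
    nv <- if (mh > 0 && mh < 1) vh / (mh * (1 - mh)) else NA_real_
    cbind(data[ix[1], by, drop = FALSE],
          data.frame(n_cells = m, mean_h = mh, var_h = vh, norm_var = nv,
                     norm_var_se = nv * sqrt(2 / (m - 1)),
                     bottleneck_size = if (!is.na(nv) && nv > 0) 1 / nv
                                       else NA_real_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
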