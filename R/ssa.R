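#' Stochastic simulation parameters
#'
#' Rates and structural parameters of the cellular oDNA model. Defaults are
#' the standard illustrative parameterisation: baseline replication
#' `lam = 2`/day, turnover `nu = 1`/day, copy-number control
#' `alpha = 1/1000` (target copy number 1000), gene conversion
#' `kappa = 0.002`/day and single-molecule autophagy `n_d = 1`.
#'
#' The per-molecule replication rate follows the relaxed-replication
#' feedback law `r(N) = max(0, nu + (lam - nu) (1 - alpha N))`, which equals
#' `lam` at N = 0 and exactly balances degradation (rate `nu`) at the target
#' copy number N = 1/alpha, so the population is regulated around 1/alpha.
#' Mutant molecules replicate at `r(N) (1 + delta)`. Gene conversion acts
#' on discordant pairs in the fused pool at total rate
#' `kappa * W_f * M_f` in each direction, weighted `(1 + eps)` towards
#' mutant conversion and `(1 - eps)` towards wild-type; `eps > 0` therefore
#' favours the mutant type. Autophagy removes `n_d` same-type singleton
#' molecules per event at event rate `nu * pool / n_d` (per-molecule rate
#' `nu`). Fission and fusion switch molecules between the fused and
#' singleton pools at per-molecule rates `rate_fission` and `rate_fusion`,
#' giving equilibrium fragmentation fraction
#' `f = rate_fission / (rate_fission + rate_fusion)`.
#'
#' @param lam baseline per-molecule replication rate, per day.
#' @param nu per-molecule degradation rate of the fragmented pool, per day.
#' @param alpha inverse target copy number.
#' @param kappa gene conversion rate per discordant fused pair, per day.
#' @param delta mutant replicative advantage (dimensionless).
#' @param eps gene-conversion bias in `[-1, 1]`; positive favours mutant.
#' @param n_d molecules destroyed per autophagy event.
#' @param rate_fission per-molecule fused-to-singleton rate, per day.
#' @param rate_fusion per-molecule singleton-to-fused rate, per day.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(lam = 2, nu = 1, alpha = 1 / 1000, kappa = 0.002,
                       delta = 0, eps = 0, n_d = 1,
                       rate_fission = 0, rate_fusion = 0) {
  stopifnot(lam >= 0, nu >= 0, alpha >= 0, kappa >= 0,
            eps >= -1, eps <= 1, n_d >= 1, n_d == round(n_d),
            rate_fission >= 0, rate_fusion >= 0)
  structure(list(lam = lam, nu = nu, alpha = alpha, kappa = kappa,
                 delta = delta, eps = eps, n_d = as.integer(n_d),
                 rate_fission = rate_fission, rate_fusion = rate_fusion),
            class = "sim_params")
}

#' Cell state: oDNA copy numbers by type and organelle state
#'
#' @param w_fused,w_single wild-type molecules in fused / singleton
#'   organelles.
#' @param m_fused,m_single mutant molecules in fused / singleton organelles.
#' @param time_days simulation time attached to the state.
#' @return an object of class `cell_state` with derived quantities `n`
#'   (total copy number), `h` (heteroplasmy, NA when N = 0) and `f`
#'   (fragmentation fraction).
#' @export
cell_state <- function(w_fused = 0, w_single = 0, m_fused = 0, m_single = 0,
                       time_days = 0) {
  counts <- c(w_fused, w_single, m_fused, m_single)
  stopifnot(all(counts >= 0), all(counts == round(counts)), time_days >= 0)
  n <- sum(counts)
  structure(list(w_fused = as.integer(w_fused),
                 w_single = as.integer(w_single),
                 m_fused = as.integer(m_fused),
                 m_single = as.integer(m_single),
                 time_days = time_days,
                 n = n,
                 h = if (n > 0) (m_fused + m_single) / n else NA_real_,
                 f = if (n > 0) (w_single + m_single) / n else NA_real_),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf(
    "cell state t = %.3g d: W = (%d fused, %d single), M = (%d fused, %d single); N = %d, h = %s, f = %s\n",
    x$time_days, x$w_fused, x$w_single, x$m_fused, x$m_single, x$n,
    if (is.na(x$h)) "NA" else sprintf("%.4g", x$h),
    if (is.na(x$f)) "NA" else sprintf("%.4g", x$f)))
  invisible(x)
}

state_vec <- function(state) {
  c(state$w_fused, state$w_single, state$m_fused, state$m_single)
}

#' Reaction propensities of the cell model
#'
#' Labelled vector of instantaneous event rates for a cell state under a
#' parameter set; the reference definition of the simulator's rate laws
#' (the compiled Gillespie core implements the same vector).
#'
#' @param state a [cell_state()].
#' @param params a [sim_params()].
#' @return named nonnegative numeric vector of event rates; empty when the
#'   population is extinct (N = 0 is absorbing).
#' @export
propensities <- function(state, params) {
  stopifnot(inherits(state, "cell_state"), inherits(params, "sim_params"))
  if (state$n == 0) return(setNames(numeric(0), character(0)))
  r <- max(0, params$nu + (params$lam - params$nu) *
             (1 - params$alpha * state$n))
  with(c(state, params), c(
    rep_w_fused = r * w_fused,
    rep_w_single = r * w_single,
    rep_m_fused = r * (1 + delta) * m_fused,
    rep_m_single = r * (1 + delta) * m_single,
    autophagy_w = nu * w_single / n_d,
    autophagy_m = nu * m_single / n_d,
    conv_to_mut = kappa * (1 + eps) * w_fused * m_fused,
    conv_to_wild = kappa * (1 - eps) * w_fused * m_fused,
    fission_w = rate_fission * w_fused,
    fission_m = rate_fission * m_fused,
    fusion_w = rate_fusion * w_single,
    fusion_m = rate_fusion * m_single))
}

#' Simulate one exact trajectory
#'
#' Runs Gillespie's stochastic simulation algorithm (exponential waiting
#' times, categorical event choice) from an initial state, recording the
#' state at the requested times. The trajectory is bitwise reproducible
#' for a fixed seed. Extinction (N = 0) is absorbing; the remaining record
#' times repeat the absorbed state and the result is flagged.
#'
#' @param initial a [cell_state()].
#' @param params a [sim_params()].
#' @param t_max end time in days.
#' @param record_times times at which to record the state; defaults to 101
#'   evenly spaced points on `[0, t_max]`.
#' @param seed optional RNG seed.
#' @return data frame with columns `time_days`, `w_fused`, `w_single`,
#'   `m_fused`, `m_single`, `n`, `h`, `f`; attribute `extinct` flags
#'   whether the population was absorbed at 0.
#' @export
run_trajectory <- function(initial, params, t_max, record_times = NULL,
                           seed = NULL) {
  stopifnot(inherits(initial, "cell_state"), inherits(params, "sim_params"),
            t_max > 0)
  if (is.null(record_times))
    record_times <- seq(0, t_max, length.out = 101)
  record_times <- sort(record_times)
  stopifnot(all(record_times >= 0), all(record_times <= t_max))
  if (!is.null(seed)) set.seed(seed)
  m <- ssa_run_cpp(state_vec(initial), unclass(params), record_times)
  n <- rowSums(m)
  out <- data.frame(time_days = record_times,
                    w_fused = m[, 1], w_single = m[, 2],
                    m_fused = m[, 3], m_single = m[, 4],
                    n = n,
                    h = ifelse(n > 0, (m[, 3] + m[, 4]) / n, NA_real_),
                    f = ifelse(n > 0, (m[, 2] + m[, 4]) / n, NA_real_))
  attr(out, "extinct") <- any(n == 0)
  out
}

#' Simulate an ensemble of cells
#'
#' Runs `n_reps` independent trajectories and summarises heteroplasmy
#' statistics at each record time: mean, variance, normalised variance
#' V'(h) and its standard error `V' * sqrt(2 / (m - 1))` (m = surviving
#' replicates). Extinct cells have no defined heteroplasmy; they are
#' excluded from the statistics and counted in `extinct_frac`.
#'
#' @inheritParams run_trajectory
#' @param n_reps number of replicate cells (>= 2).
#' @return an `ensemble_result`: data frame with columns `time_days`,
#'   `mean_h`, `var_h`, `norm_var`, `norm_var_se`, `mean_n`,
#'   `extinct_frac`, with `n_reps` and `seed` attributes.
#' @export
run_ensemble <- function(initial, params, t_max, record_times = NULL,
                         n_reps = 1000, seed = NULL) {
  stopifnot(inherits(initial, "cell_state"), inherits(params, "sim_params"),
            n_reps >= 2)
  if (is.null(record_times))
    record_times <- seq(0, t_max, length.out = 21)
  record_times <- sort(record_times)
  if (!is.null(seed)) set.seed(seed)
  res <- ssa_ensemble_cpp(state_vec(initial), unclass(params), record_times,
                          as.integer(n_reps))
  h <- res$h
  nmat <- res$n
  summarise_col <- function(j) {
    hv <- h[, j]
    ok <- !is.na(hv)
    m <- sum(ok)
    if (m < 2) {
      return(c(mean_h = NA, var_h = NA, norm_var = NA, norm_var_se = NA,
               mean_n = mean(nmat[, j]), extinct_frac = 1 - m / n_reps))
    }
    mh <- mean(hv[ok])
    vh <- var(hv[ok])
    nv <- if (mh > 0 && mh < 1) vh / (mh * (1 - mh)) else NA_real_
    c(mean_h = mh, var_h = vh, norm_var = nv,
      norm_var_se = nv * sqrt(2 / (m - 1)),
      mean_n = mean(nmat[, j]), extinct_frac = 1 - m / n_reps)
  }
  s <- t(vapply(seq_along(record_times), summarise_col, numeric(6)))
  out <- data.frame(time_days = record_times, s)
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  class(out) <- c("ensemble_result", "data.frame")
  out
}

#' Divide a simulated cell
#'
#' Partitions a cell's molecules between two daughters, preserving the
#' fused/singleton structure (the four pools are partitioned jointly).
#' This lets Gillespie epochs be interleaved with the instantaneous
#' division, subsampling and amplification events of a schedule.
#'
#' @param state a [cell_state()] with N >= 2.
#' @param mode `"hypergeometric"` (daughter totals exactly N/2, sampled
#'   without replacement), `"perfect"` (each pool halved, remainders by
#'   fair coin) or `"binomial"` (independent assignment).
#' @param n_c homoplasmic cluster size for hypergeometric partitioning
#'   (clusters drawn within genotype across organelle states).
#' @return list of two `cell_state` daughters whose pools sum to the
#'   parent's.
#' @export
apply_division <- function(state, mode = c("hypergeometric", "perfect",
                                           "binomial"), n_c = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "cell_state"))
  if (state$n < 2) stop("cannot divide a cell with fewer than 2 molecules")
  pools <- state_vec(state)
  if (mode == "perfect") {
    d1 <- pools %/% 2 + rbinom(4, pools %% 2, 0.5)
  } else if (mode == "binomial") {
    d1 <- rbinom(4, pools, 0.5)
  } else if (n_c == 1) {
    # multivariate hypergeometric: draw N/2 molecules without replacement,
    # category by category conditional on what remains
    n_take <- floor(state$n / 2)
    d1 <- integer(4)
    remaining <- state$n
    for (i in 1:4) {
      remaining <- remaining - pools[i]
      d1[i] <- rhyper(1, pools[i], remaining, n_take)
      n_take <- n_take - d1[i]
    }
  } else {
    # clustered: partition genotype totals cluster-wise, then distribute
    # each genotype's draw across organelle states hypergeometrically
    pw <- odna_pool(pools[1] + pools[2], pools[3] + pools[4])
    dd <- partition_hypergeometric(pw, floor(state$n / 2), n_c)
    w1 <- rhyper(1, pools[1], pools[2], dd[[1]]$n_wild)
    m1 <- rhyper(1, pools[3], pools[4], dd[[1]]$n_mut)
    d1 <- c(w1, dd[[1]]$n_wild - w1, m1, dd[[1]]$n_mut - m1)
  }
  d2 <- pools - d1
  list(cell_state(d1[1], d1[2], d1[3], d1[4], state$time_days),
       cell_state(d2[1], d2[2], d2[3], d2[4], state$time_days))
}

#' Calibrate the effective selection coefficient of a parameter set
#'
#' Runs an ensemble and fits the logistic selection trajectory to the mean
#' heteroplasmy: on the transformed scale the mean is linear in time with
#' slope rho, so the empirical rho is the zero-intercept regression slope
#' of `logit(E(h)) - logit(h0)` on time. A warning is issued if the
#' transformed means are not close to linear (R^2 < 0.99), indicating
#' non-logistic dynamics.
#'
#' @param initial a [cell_state()] (founder heteroplasmy is taken from it).
#' @param params a [sim_params()] with `delta != 0` (or conversion bias).
#' @param t_grid times at which to record the ensemble mean.
#' @param n_reps ensemble size.
#' @param seed optional RNG seed.
#' @return the empirical rho (per day), with attributes `r_squared` and
#'   `ensemble`.
#' @export
effective_rho <- function(initial, params, t_grid, n_reps = 1000,
                          seed = NULL) {
  stopifnot(length(t_grid) >= 2)
  t_grid <- sort(unique(c(0, t_grid)))
  ens <- run_ensemble(initial, params, max(t_grid), record_times = t_grid,
                      n_reps = n_reps, seed = seed)
  h0 <- initial$h
  stopifnot(h0 > 0, h0 < 1)
  keep <- ens$time_days > 0 & ens$mean_h > 0 & ens$mean_h < 1
  z <- transform_heteroplasmy(ens$mean_h[keep], h0)
  tt <- ens$time_days[keep]
  fit <- lm(z ~ 0 + tt)
  rho <- unname(coef(fit)[1])
  ssres <- sum(residuals(fit)^2)
  sstot <- sum(z^2)
  r2 <- if (sstot > 0) 1 - ssres / sstot else NA_real_
  if (!is.na(r2) && r2 < 0.99)
    warning(sprintf(
      "transformed-mean trajectory is not linear (R^2 = %.3f): logistic selection model may not apply", r2))
  structure(rho, r_squared = r2, ensemble = ens)
}

#' Run a mechanism schedule through the stochastic simulator
#'
#' Executes the events of an [odna_schedule()] on a single cell:
#' instantaneous events (`division`, `subsample`, `amplify`) act on the
#' molecule counts through the corresponding sampling operations (the
#' surviving daughter is kept at a division), and epoch events run the
#' Gillespie core for their duration with the epoch's turnover and
#' conversion rates. At the start of each epoch the fused/singleton split
#' is set to the epoch's fragmentation fraction (rounded) and held there
#' (no fission/fusion during the epoch), matching the assumption that
#' physical dynamics equilibrate faster than genetic dynamics.
#'
#' @param initial a [cell_state()].
#' @param schedule an [odna_schedule()].
#' @param params a [sim_params()] supplying the replication feedback law
#'   for epochs (baseline rates; epoch rates override `nu` and `kappa`,
#'   and `alpha` is reset so the epoch's copy number is the control
#'   target).
#' @param mode partition mode for divisions, see [apply_division()].
#' @param seed optional RNG seed.
#' @return the final [cell_state()].
#' @export
run_schedule <- function(initial, schedule, params = sim_params(),
                         mode = "hypergeometric", seed = NULL) {
  stopifnot(inherits(initial, "cell_state"),
            inherits(schedule, "odna_schedule"))
  if (!is.null(seed)) set.seed(seed)
  st <- initial
  tnow <- st$time_days
  for (ev in schedule$events) {
    w <- st$w_fused + st$w_single
    m <- st$m_fused + st$m_single
    if (ev$kind == "division") {
      st <- apply_division(st, mode = mode, n_c = ev$cluster_size)[[1]]
    } else if (ev$kind == "subsample") {
      keep <- subsample_pool(odna_pool(w, m), round(ev$n2),
                             n_c = ev$cluster_size)
      st <- cell_state(0, keep$n_wild, 0, keep$n_mut, tnow)
    } else if (ev$kind == "amplify") {
      amp <- polya_amplify(odna_pool(w, m), round(ev$n2))
      st <- cell_state(0, amp$n_wild, 0, amp$n_mut, tnow)
    } else {
      # epoch: split pools to the epoch fragmentation fraction and run SSA
      ws <- round(w * ev$frag_fraction); ms <- round(m * ev$frag_fraction)
      ep <- sim_params(lam = params$lam, nu = ev$turnover_rate,
                       alpha = 1 / max(1, w + m),
                       kappa = ev$conversion_rate,
                       delta = params$delta, eps = params$eps,
                       n_d = ev$autophagy_size)
      tr <- ssa_run_cpp(c(w - ws, ws, m - ms, ms), unclass(ep),
                        ev$duration_days)
      tnow <- tnow + ev$duration_days
      st <- cell_state(tr[1, 1], tr[1, 2], tr[1, 3], tr[1, 4], tnow)
    }
    st$time_days <- tnow
  }
  st
}
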