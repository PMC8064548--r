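#' Normalised heteroplasmy variance
#'
#' Converts raw cell-to-cell heteroplasmy variance V(h) into the normalised
#' variance V'(h) = V(h) / (E(h) (1 - E(h))), the drift-scale statistic that
#' measures progress towards fixation: V'(h) = 0 for identical cells and
#' V'(h) = 1 when every cell is homoplasmic.
#'
#' @param var_h nonnegative raw variance of heteroplasmy across cells.
#' @param mean_h mean heteroplasmy, strictly inside (0, 1).
#' @return the normalised variance, a value in `[0, 1]` for any realisable
#'   population.
#' @examples
#' normalise_variance(0.05, 0.5) # 0.2
#' @export
normalise_variance <- function(var_h, mean_h) {
  stopifnot(is.numeric(var_h), is.numeric(mean_h), var_h >= 0)
  if (any(mean_h <= 0 | mean_h >= 1))
    stop("mean_h must lie strictly in (0, 1): variance is undefined at fixation")
  var_h / (mean_h * (1 - mean_h))
}

#' Effective bottleneck size and bottleneck parameter
#'
#' The effective bottleneck size N_b = 1 / V'(h) is the number of segregating
#' units that would produce the observed normalised variance in a single
#' generation of neutral sampling; the bottleneck parameter is b = 1 - V'(h).
#'
#' @param norm_var positive normalised heteroplasmy variance V'(h).
#' @return `bottleneck_size`: N_b = 1/V'; `bottleneck_param`: 1 - V'.
#' @examples
#' bottleneck_size(0.01)  # 100
#' bottleneck_param(0.01) # 0.99
#' @export
bottleneck_size <- function(norm_var) {
  stopifnot(is.numeric(norm_var))
  if (any(norm_var <= 0)) stop("norm_var must be > 0")
  1 / norm_var
}

#' @rdname bottleneck_size
#' @export
bottleneck_param <- function(norm_var) {
  stopifnot(is.numeric(norm_var))
  if (any(norm_var <= 0)) stop("norm_var must be > 0")
  1 - norm_var
}

#' Per-mechanism contributions to normalised heteroplasmy variance
#'
#' Closed-form first-order contributions of each cellular mechanism to
#' V'(h), assuming copy numbers well above 1 and no selective difference:
#'
#' * `division_contribution`: each cell division partitions molecules
#'   without replacement (hypergeometrically) and adds `n_c / n`, where `n`
#'   is copy number before division and `n_c` the homoplasmic cluster size
#'   in which molecules are co-inherited.
#' * `turnover_contribution`: random degradation and compensating
#'   replication over `t` days adds `(1 + n_d) * nu * f * t / n`; only the
#'   fragmented fraction `f` of molecules is exposed to autophagy, which
#'   destroys `n_d` molecules per event.
#' * `conversion_contribution`: recombination-dependent gene conversion at
#'   rate `kappa` adds `2 * kappa * (1 - f)^2 * t`, independent of copy
#'   number; only the fused fraction `(1 - f)` can recombine. In a plastid
#'   picture the pool is split into `n_compartments` organelles that never
#'   mix, rescaling `kappa` by `1 / n_compartments`.
#' * `subsample_contribution`: replicating only `n2` of `n1` molecules (and
#'   letting the rest degrade) adds `n_c * (1/n2 - 1/n1)`; with
#'   `exact = TRUE` the exact hypergeometric form
#'   `n_c * (n1 - n2) / (n2 * (n1 - 1))` is returned.
#' * `amplification_contribution`: regrowing a population from `n1` to `n2`
#'   by random replication (a Polya urn) adds `1/n1 - 1/n2`.
#'
#' @param n,n1,n2 positive integer copy numbers.
#' @param n_c homoplasmic cluster size (molecules inherited as one unit).
#' @param nu per-molecule turnover (degradation) rate, per day.
#' @param f fragmentation fraction: proportion of molecules in singleton
#'   organelles.
#' @param t duration in days.
#' @param n_d molecules destroyed per autophagy event.
#' @param n_compartments number of separate non-mixing organelle
#'   compartments (plastid rescaling); 1 for a mixing chondriome.
#' @param exact use the exact hypergeometric variance rather than the
#'   large-n approximation.
#' @return nonnegative contribution to V'(h).
#' @examples
#' division_contribution(1000)            # 0.001
#' turnover_contribution(1, 1, 1, 1000)   # 0.002
#' conversion_contribution(0.002, 0, 1)   # 0.004
#' subsample_contribution(1000, 100)      # 0.009
#' amplification_contribution(500, 1e5)   # 0.00199
#' @name contributions
NULL

#' @rdname contributions
#' @export
division_contribution <- function(n, n_c = 1) {
  stopifnot(all(n >= 2), all(n_c >= 1))
  if (any(n_c > n)) stop("cluster size n_c cannot exceed copy number n")
  n_c / n
}

#' @rdname contributions
#' @export
turnover_contribution <- function(nu, f, t, n, n_d = 1) {
  stopifnot(nu >= 0, f >= 0, f <= 1, t >= 0, n >= 1, n_d >= 1)
  (1 + n_d) * nu * f * t / n
}

#' @rdname contributions
#' @export
conversion_contribution <- function(kappa, f, t, n_compartments = 1) {
  stopifnot(kappa >= 0, f >= 0, f <= 1, t >= 0, n_compartments >= 1)
  2 * (kappa / n_compartments) * (1 - f)^2 * t
}

#' @rdname contributions
#' @export
subsample_contribution <- function(n1, n2, n_c = 1, exact = FALSE) {
  stopifnot(all(n1 >= 1), all(n2 >= 1), all(n_c >= 1))
  if (any(n2 > n1)) stop("subsampling requires n2 <= n1")
  if (exact) n_c * (n1 - n2) / (n2 * (n1 - 1)) else n_c * (1 / n2 - 1 / n1)
}

#' @rdname contributions
#' @export
amplification_contribution <- function(n1, n2) {
  stopifnot(all(n1 >= 1))
  if (any(n2 < n1)) stop("amplification requires n2 >= n1")
  1 / n1 - 1 / n2
}

#' Construct a mechanism event
#'
#' One variance-generating event in a schedule: an instantaneous sampling
#' event (`division`, `subsample`, `amplify`) or a timed epoch of
#' within-cell-cycle dynamics (`turnover_epoch`, `conversion_epoch`).
#' Copy numbers `n1` (before) and `n2` (after) chain along a schedule.
#'
#' @param kind one of `"division"`, `"turnover_epoch"`, `"conversion_epoch"`,
#'   `"subsample"`, `"amplify"`.
#' @param n1 copy number before the event.
#' @param n2 copy number after the event; defaults to `n1 / 2` for a
#'   division and `n1` for epochs.
#' @param duration_days epoch length in days (0 for instantaneous kinds).
#' @param turnover_rate degradation rate nu (per day), turnover epochs only.
#' @param conversion_rate gene conversion rate kappa (per day), conversion
#'   epochs only.
#' @param frag_fraction fragmentation fraction f in `[0, 1]`.
#' @param cluster_size homoplasmic cluster size n_c.
#' @param autophagy_size molecules destroyed per autophagy event, n_d.
#' @param n_compartments separated-organelle divisor for conversion.
#' @return an object of class `mechanism_event`.
#' @export
mechanism_event <- function(kind, n1, n2 = NULL, duration_days = 0,
                            turnover_rate = 0, conversion_rate = 0,
                            frag_fraction = 1, cluster_size = 1,
                            autophagy_size = 1, n_compartments = 1) {
  kind <- match.arg(kind, c("division", "turnover_epoch", "conversion_epoch",
                            "subsample", "amplify"))
  stopifnot(n1 >= 1, duration_days >= 0, turnover_rate >= 0,
            conversion_rate >= 0, frag_fraction >= 0, frag_fraction <= 1,
            cluster_size >= 1, autophagy_size >= 1, n_compartments >= 1)
  if (is.null(n2)) {
    n2 <- switch(kind, division = n1 / 2, n1)
  }
  epoch <- kind %in% c("turnover_epoch", "conversion_epoch")
  if (epoch && duration_days <= 0)
    stop("epoch events require duration_days > 0")
  if (!epoch && duration_days != 0)
    stop("instantaneous events must have duration_days = 0")
  if (kind == "subsample" && n2 > n1) stop("subsample requires n2 <= n1")
  if (kind == "amplify" && n2 < n1) stop("amplify requires n2 >= n1")
  structure(list(kind = kind, n1 = n1, n2 = n2,
                 duration_days = duration_days,
                 turnover_rate = turnover_rate,
                 conversion_rate = conversion_rate,
                 frag_fraction = frag_fraction,
                 cluster_size = cluster_size,
                 autophagy_size = autophagy_size,
                 n_compartments = n_compartments),
            class = "mechanism_event")
}

#' Construct an ordered schedule of mechanism events
#'
#' @param events list of [mechanism_event()] objects; copy numbers must
#'   chain (the `n2` of each event equals the `n1` of the next).
#' @param label optional text label.
#' @return an object of class `odna_schedule`.
#' @export
odna_schedule <- function(events = list(), label = "") {
  stopifnot(is.list(events),
            all(vapply(events, inherits, logical(1), "mechanism_event")))
  if (length(events) > 1) {
    for (i in seq_len(length(events) - 1)) {
      if (abs(events[[i]]$n2 - events[[i + 1]]$n1) > 1e-8)
        stop(sprintf(
          "copy numbers do not chain: event %d ends at n2 = %g but event %d starts at n1 = %g",
          i, events[[i]]$n2, i + 1, events[[i + 1]]$n1))
    }
  }
  structure(list(events = events, label = label), class = "odna_schedule")
}

#' @export
print.odna_schedule <- function(x, ...) {
  cat(sprintf("oDNA mechanism schedule%s: %d events, total duration %.3g days\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$events),
              sum(vapply(x$events, `[[`, numeric(1), "duration_days"))))
  invisible(x)
}

event_contribution <- function(ev) {
  switch(ev$kind,
    division = division_contribution(ev$n1, ev$cluster_size),
    turnover_epoch = turnover_contribution(ev$turnover_rate,
                                           ev$frag_fraction,
                                           ev$duration_days, ev$n1,
                                           ev$autophagy_size),
    conversion_epoch = conversion_contribution(ev$conversion_rate,
                                               ev$frag_fraction,
                                               ev$duration_days,
                                               ev$n_compartments),
    subsample = subsample_contribution(ev$n1, ev$n2, ev$cluster_size),
    amplify = amplification_contribution(ev$n1, ev$n2))
}

#' Variance summary for a cell population
#'
#' Bundles the heteroplasmy mean, raw variance, normalised variance V'(h),
#' effective bottleneck size N_b = 1/V' and bottleneck parameter b = 1 - V'.
#'
#' @param mean_h mean heteroplasmy in `[0, 1]`.
#' @param var_h raw variance (nonnegative).
#' @param norm_var optionally, a precomputed V'(h); derived from `var_h` and
#'   `mean_h` when omitted.
#' @return an object of class `variance_summary`.
#' @export
variance_summary <- function(mean_h, var_h = NA_real_, norm_var = NULL) {
  stopifnot(mean_h >= 0, mean_h <= 1)
  if (is.null(norm_var)) norm_var <- normalise_variance(var_h, mean_h)
  if (is.na(var_h)) var_h <- norm_var * mean_h * (1 - mean_h)
  if (norm_var < 0 || norm_var > 1)
    stop("norm_var outside [0, 1]: not a realisable population")
  new_variance_summary(mean_h, var_h, norm_var)
}

new_variance_summary <- function(mean_h, var_h, norm_var) {
  structure(list(mean_h = mean_h, var_h = var_h, norm_var = norm_var,
                 bottleneck_size = if (norm_var > 0) 1 / norm_var else Inf,
                 bottleneck_param = 1 - norm_var),
            class = "variance_summary")
}

#' @export
print.variance_summary <- function(x, ...) {
  cat(sprintf("E(h) = %.4g, V(h) = %.4g, V'(h) = %.4g, N_b = %.4g, b = %.4g\n",
              x$mean_h, x$var_h, x$norm_var, x$bottleneck_size,
              x$bottleneck_param))
  invisible(x)
}

#' Total normalised variance generated by a schedule
#'
#' Sums the per-event first-order contributions to V'(h) along a schedule.
#' The first-order theory is additive; as the total approaches 1 (all cells
#' homoplasmic) the true accumulation slows, so totals above 0.5 are
#' flagged and totals above 1 trigger a strong warning. The reported value
#' is left uncapped so the breakdown remains visible.
#'
#' @param schedule an [odna_schedule()].
#' @param mean_h reference mean heteroplasmy used to fill in the raw
#'   variance of the returned summary (neutral dynamics leave it constant).
#' @return a [variance_summary()]; `attr(, "per_event")` holds the
#'   individual contributions.
#' @export
total_normalised_variance <- function(schedule, mean_h = 0.5) {
  stopifnot(inherits(schedule, "odna_schedule"))
  per <- vapply(schedule$events, event_contribution, numeric(1))
  tot <- sum(per)
  if (tot > 1) {
    warning("total V'(h) exceeds 1: first-order additivity has broken down; ",
            "interpret as complete fixation")
  } else if (tot > 0.5) {
    warning("total V'(h) exceeds 0.5: first-order theory is approaching ",
            "saturation and will overestimate the true variance")
  }
  out <- new_variance_summary(mean_h, tot * mean_h * (1 - mean_h), tot)
  attr(out, "per_event") <- per
  out
}

#' Variance accumulated by a cascade of divisions with regrowth
#'
#' Closed form for the V'(h) generated when copy number changes from `N0`
#' to `Nk` over `k` cell cycles, each cycle consisting of a halving
#' division followed by reamplification, with the cycle-start copy number
#' following the geometric profile `n_i = N0 (a/2)^i`, `a = 2 (Nk/N0)^(1/k)`.
#' Each cycle contributes `n_c / n_i` (division) plus
#' `2/n_i - 1/n_{i+1}` (regrowth from `n_i / 2` to `n_{i+1}`), and the
#' geometric sum gives
#' `V' = (a n_c + 2 (a - 1)) / (a N0) * ((2/a)^k - 1) / ((2/a) - 1)`.
#' At `a = 2` (constant copy number) the ratio is 1 and the sum reduces to
#' `k (n_c + 1) / N0`.
#'
#' @param N0 copy number at the start of the cascade.
#' @param Nk copy number at the end, after `k` cycles.
#' @param k number of cell cycles (>= 1).
#' @param n_c homoplasmic cluster size at divisions.
#' @return the accumulated normalised variance.
#' @examples
#' cascade_variance(1e5, 670, 29)
#' @export
cascade_variance <- function(N0, Nk, k, n_c = 1) {
  stopifnot(N0 >= 2, Nk >= 1, k >= 1, n_c >= 1)
  a <- 2 * (Nk / N0)^(1 / k)
  if (a < 1)
    stop("depletion faster than halving per cycle (Nk/N0 < 2^-k): ",
         "regrowth model does not apply")
  pref <- (a * n_c + 2 * (a - 1)) / (a * N0)
  r <- 2 / a
  s <- if (abs(r - 1) < 1e-9) k else (r^k - 1) / (r - 1)
  pref * s
}

#' Mean heteroplasmy under selection
#'
#' Generalised logistic drift of mean heteroplasmy under a scaled
#' replicative difference `rho` between mutant and wild-type oDNA:
#' `E(h)(t) = h0 e^(rho t) / (1 + h0 (e^(rho t) - 1))`, i.e. the logit of
#' the mean moves linearly, `logit E(h) = logit h0 + rho t`. At `h0 = 1/2`
#' this is `1 / (1 + e^(-rho t))`.
#'
#' @param rho scaled replicative difference, per day; positive favours the
#'   mutant type.
#' @param t time in days.
#' @param h0 founder heteroplasmy, strictly inside (0, 1).
#' @return mean heteroplasmy at time `t`.
#' @export
selection_mean <- function(rho, t, h0 = 0.5) {
  stopifnot(h0 > 0, h0 < 1)
  plogis(qlogis(h0) + rho * t)
}

#' Selection parameters
#'
#' @param rho scaled replicative difference between oDNA types, per day.
#' @param nu turnover (degradation) rate, per day.
#' @param f fragmentation fraction in `[0, 1]`.
#' @param copy_number cellular oDNA copy number N.
#' @param h0 founder heteroplasmy.
#' @return an object of class `selection_params`.
#' @export
selection_params <- function(rho, nu, f = 1, copy_number = 1000, h0 = 0.5) {
  stopifnot(nu >= 0, f >= 0, f <= 1, copy_number >= 1, h0 > 0, h0 < 1)
  structure(list(rho = rho, nu = nu, f = f, copy_number = copy_number,
                 h0 = h0), class = "selection_params")
}

# raw-h variance under selection at reference h0 = 1/2: closed-form
# solution of the linear-noise moment equation
#   dV/dt = 2 rho (1 - 2E) V + 2 nu f E(1-E)/N,  E(t) = 1/(1 + e^{-rho t}),
# integrating factor 16 e^{2s}/(1+e^s)^4 with s = rho t, giving
#   V(t) = (2 nu f / (N rho)) e^{2s} (2s + e^s - e^{-s}) / (1 + e^s)^4.
# Symmetric in the sign of rho and reduces to h0(1-h0) 2 nu f t / N as
# rho -> 0; the variance collapses as the mean approaches fixation.
selection_variance_half <- function(rho, nuf, N, t) {
  s <- rho * t
  (2 * nuf / (N * rho)) * exp(2 * s) *
    (2 * s + exp(s) - exp(-s)) / (1 + exp(s))^4
}

#' Heteroplasmy variance under selection
#'
#' Closed-form cell-to-cell variance V(h) at time `t` under turnover at
#' rate `nu` (fragmented fraction `f`, copy number N) and a scaled
#' replicative difference `rho`: the solution of the drift-diffusion
#' moment equations with logistic mean drift `rho E (1 - E)` and neutral
#' turnover diffusion `2 nu f E (1 - E) / N`, verified against stochastic
#' simulation. At `rho = 0` this reduces to the neutral result
#' `V = h0 (1 - h0) * 2 nu f t / N`; as the mean approaches fixation the
#' variance collapses. The closed form is derived at reference founder
#' heteroplasmy 1/2; for other founders the normalised variance is taken
#' as founder-invariant and the raw variance rescaled by `E(1 - E)` at
#' the actual mean.
#'
#' @param params a [selection_params()] object.
#' @param t time in days.
#' @return V(h) at time `t`.
#' @export
selection_variance <- function(params, t) {
  stopifnot(inherits(params, "selection_params"), t >= 0)
  nuf <- params$nu * params$f
  N <- params$copy_number
  if (t == 0) return(0)
  if (params$rho == 0) {
    E <- params$h0
    return(E * (1 - E) * 2 * nuf * t / N)
  }
  vhalf <- selection_variance_half(params$rho, nuf, N, t)
  if (params$h0 == 0.5) return(vhalf)
  Eh <- selection_mean(params$rho, t, params$h0)
  E2 <- selection_mean(params$rho, t, 0.5)
  Eh * (1 - Eh) * vhalf / (E2 * (1 - E2))
}

#' Heteroplasmy transform and its inverse
#'
#' The founder-referenced logit transform
#' `z = log(h (h0 - 1) / (h0 (h - 1))) = logit(h) - logit(h0)` places
#' measurements from mothers with different founder heteroplasmies on a
#' common scale: under neutral drift the transformed mean is 0, and under
#' selection it is exactly `rho * t`. The inverse maps any real `z` back
#' into (0, 1).
#'
#' @param h heteroplasmy strictly inside (0, 1); values at 0 or 1 are
#'   fixated and have no finite transform.
#' @param z transformed value (any real number).
#' @param h0 founder or reference heteroplasmy, default 1/2.
#' @return `transform_heteroplasmy`: the transformed value;
#'   `inverse_transform_heteroplasmy`: the heteroplasmy in (0, 1).
#' @examples
#' transform_heteroplasmy(0.7, 0.5) # log(7/3)
#' @export
transform_heteroplasmy <- function(h, h0 = 0.5) {
  stopifnot(h0 > 0, h0 < 1)
  if (any(h <= 0 | h >= 1))
    stop("h at 0 or 1 is fixated: transform undefined; treat as censored")
  qlogis(h) - qlogis(h0)
}

#' @rdname transform_heteroplasmy
#' @export
inverse_transform_heteroplasmy <- function(z, h0 = 0.5) {
  stopifnot(h0 > 0, h0 < 1)
  plogis(z + qlogis(h0))
}
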