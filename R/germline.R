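#' Developmental schedule of the mouse female germline
#'
#' Builds the canonical copy-number schedule of mouse germline development:
#' 29 divisions with a 7-hour period during which mtDNA copy number falls
#' geometrically from 1e5 to the minimum `b` (the debated physical
#' bottleneck, always a free parameter here), 7 divisions with a 16-hour
#' period during which copy number regrows to 5,000, and a final
#' reamplification to 1e5 -- 36 divisions in total. Ongoing turnover in the
#' ageing oocyte is parameterised by the compound statistic `nu_f_over_n`
#' (= nu * f / n per day), the only combination identifiable from oocyte
#' data.
#'
#' The reported minimum copy number is the minimum over cycle-boundary
#' values (= `b`); the transient post-division halving within a cycle dips
#' below it.
#'
#' @param b minimum (bottleneck) copy number, 1 < b < 1e5.
#' @param nu_f_over_n compound ageing-turnover statistic, per day.
#' @param n_c homoplasmic cluster size at divisions.
#' @param n_d molecules destroyed per autophagy event (1 for the mouse).
#' @param model_tag which mechanism combination the schedule represents;
#'   see [model_variants()].
#' @param n2_subsample copy number retained by the single oogenesis
#'   subsampling event (used by the `"subsample_amp"` variant).
#' @param rho scaled replicative difference (selection), per day.
#' @return an object of class `germline_schedule`.
#' @export
mouse_schedule <- function(b = 670, nu_f_over_n = 1.4e-4, n_c = 1, n_d = 1,
                           model_tag = c("div_turnover_amp", "subsample_amp",
                                         "clustered", "with_selection"),
                           n2_subsample = 1000, rho = 0) {
  model_tag <- match.arg(model_tag)
  stopifnot(nu_f_over_n >= 0, n_c >= 1, n_d >= 1)
  if (model_tag %in% c("div_turnover_amp", "with_selection") &&
      (b <= 1 || b >= 1e5))
    stop("bottleneck copy number b must satisfy 1 < b < 1e5")
  phases <- switch(model_tag,
    div_turnover_amp = ,
    with_selection = list(
      list(n_divisions = 29L, period_days = 7 / 24,
           copy_start = 1e5, copy_end = b),
      list(n_divisions = 7L, period_days = 16 / 24,
           copy_start = b, copy_end = 5000)),
    clustered = list(
      list(n_divisions = 36L, period_days = 7 / 24,
           copy_start = 1e5, copy_end = 5000)),
    subsample_amp = list())
  structure(list(phases = phases,
                 final_amplification = c(5000, 1e5),
                 n2_subsample = n2_subsample,
                 ageing_turnover = nu_f_over_n,
                 bottleneck_min = switch(model_tag,
                                         subsample_amp = n2_subsample, b),
                 n_c = n_c, n_d = n_d, rho = rho,
                 model_tag = model_tag),
            class = "germline_schedule")
}

#' @export
print.germline_schedule <- function(x, ...) {
  cat(sprintf(
    "mouse germline schedule [%s]: %d divisions, min copy number %g, nu*f/n = %.3g /day%s\n",
    x$model_tag, sum(vapply(x$phases, `[[`, integer(1), "n_divisions")),
    x$bottleneck_min, x$ageing_turnover,
    if (x$rho != 0) sprintf(", rho = %.3g /day", x$rho) else ""))
  cat(sprintf("developmental V'(h) = %.4g (N_b = %.3g)\n",
              developmental_norm_var(x),
              1 / developmental_norm_var(x)))
  invisible(x)
}

#' Developmental normalised variance of a germline schedule
#'
#' The V'(h) accumulated by the end of development (age 0), before any
#' ageing turnover: the cascade contributions of all division/regrowth
#' cycles plus the final reamplification for the division-based variants,
#' or the single subsample plus reamplification for the subsampling
#' variant.
#'
#' @param schedule a [mouse_schedule()].
#' @return nonnegative normalised variance.
#' @export
developmental_norm_var <- function(schedule) {
  stopifnot(inherits(schedule, "germline_schedule"))
  if (schedule$model_tag == "subsample_amp") {
    n2 <- schedule$n2_subsample
    return(subsample_contribution(1e5, n2, schedule$n_c) +
             amplification_contribution(n2, 1e5))
  }
  v <- sum(vapply(schedule$phases, function(p) {
    cascade_variance(p$copy_start, p$copy_end, p$n_divisions, schedule$n_c)
  }, numeric(1)))
  fa <- schedule$final_amplification
  v + amplification_contribution(fa[1], fa[2])
}

#' Expand a germline schedule into an explicit event schedule
#'
#' Unrolls the division/regrowth cascade into the equivalent ordered
#' [odna_schedule()] of division and amplification events (plus the final
#' reamplification), so the germline prediction can be cross-checked
#' against [total_normalised_variance()].
#'
#' @param schedule a division-based [mouse_schedule()].
#' @return an [odna_schedule()].
#' @export
as_event_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "germline_schedule"))
  if (schedule$model_tag == "subsample_amp") {
    n2 <- schedule$n2_subsample
    evs <- list(mechanism_event("subsample", 1e5, n2,
                                cluster_size = schedule$n_c),
                mechanism_event("amplify", n2, 1e5))
    return(odna_schedule(evs, label = "oogenesis subsample + reamplification"))
  }
  evs <- list()
  for (p in schedule$phases) {
    a <- 2 * (p$copy_end / p$copy_start)^(1 / p$n_divisions)
    n <- p$copy_start
    for (i in seq_len(p$n_divisions)) {
      nn <- n * a / 2
      evs <- c(evs, list(
        mechanism_event("division", n, n / 2,
                        cluster_size = schedule$n_c),
        mechanism_event("amplify", n / 2, nn)))
      n <- nn
    }
  }
  fa <- schedule$final_amplification
  evs <- c(evs, list(mechanism_event("amplify", fa[1], fa[2])))
  odna_schedule(evs, label = "mouse germline development")
}

#' Predict heteroplasmy variance versus oocyte age
#'
#' The normalised variance at oocyte age `t` (days) is the developmental
#' contribution V'_0 plus the linearly accruing ageing-turnover
#' contribution `(1 + n_d) * (nu f / n) * t`. The transformed mean is 0
#' under neutrality.
#'
#' @param schedule a [mouse_schedule()].
#' @param ages_days nonnegative oocyte ages in days.
#' @return a `germline_prediction` data frame with columns `age_days`,
#'   `norm_var`, `bottleneck_size`, `transformed_mean`.
#' @export
predict_norm_var <- function(schedule, ages_days) {
  stopifnot(inherits(schedule, "germline_schedule"), all(ages_days >= 0))
  v0 <- developmental_norm_var(schedule)
  nv <- v0 + (1 + schedule$n_d) * schedule$ageing_turnover * ages_days
  out <- data.frame(age_days = ages_days, norm_var = nv,
                    bottleneck_size = 1 / nv,
                    transformed_mean = 0)
  class(out) <- c("germline_prediction", "data.frame")
  out
}

#' Predict variance and transformed mean under germline selection
#'
#' As [predict_norm_var()], but the transformed mean heteroplasmy moves
#' linearly with age at rate `rho` and the prediction carries a 95%
#' interval for single-cell heteroplasmy: on the transformed scale,
#' `rho * t +/- 1.96 * sqrt(V'(t) / (E(1 - E)))`, back-transformed to the
#' heteroplasmy scale. At `rho = 0` this reduces exactly to the neutral
#' prediction.
#'
#' @inheritParams predict_norm_var
#' @param rho scaled replicative difference, per day; defaults to the
#'   schedule's `rho`.
#' @param h0 founder heteroplasmy used for the back-transformed interval.
#' @return a `germline_prediction` data frame with columns `age_days`,
#'   `norm_var`, `bottleneck_size`, `transformed_mean`, `mean_h`,
#'   `h_lo95`, `h_hi95`.
#' @export
predict_with_selection <- function(schedule, rho = schedule$rho, ages_days,
                                   h0 = 0.5) {
  stopifnot(inherits(schedule, "germline_schedule"))
  base <- predict_norm_var(schedule, ages_days)
  Eh <- selection_mean(rho, ages_days, h0)
  var_z <- base$norm_var / (Eh * (1 - Eh))
  zc <- rho * ages_days
  out <- data.frame(age_days = ages_days,
                    norm_var = base$norm_var,
                    bottleneck_size = base$bottleneck_size,
                    transformed_mean = zc,
                    mean_h = Eh,
                    h_lo95 = inverse_transform_heteroplasmy(
                      zc - 1.96 * sqrt(var_z), h0),
                    h_hi95 = inverse_transform_heteroplasmy(
                      zc + 1.96 * sqrt(var_z), h0))
  class(out) <- c("germline_prediction", "data.frame")
  out
}

#' Competing mechanism variants of the germline bottleneck
#'
#' Constructs the comparison set of proposed bottleneck mechanisms:
#' `div_turnover_amp` (divisions + turnover + reamplification),
#' `subsample_amp` (a single oogenesis subsampling event plus
#' reamplification), `clustered` (divisions of homoplasmic mtDNA clusters,
#' n_c > 1, without depletion) and `with_selection` (the division model
#' with a free selection coefficient).
#'
#' @param tags character vector of variant tags.
#' @param b bottleneck copy number for division-based variants.
#' @param nu_f_over_n compound ageing-turnover statistic.
#' @param n_c cluster size for the clustered variant.
#' @param n2_subsample subsample size for the subsampling variant.
#' @param rho selection coefficient for the selection variant.
#' @return named list of [mouse_schedule()] objects.
#' @export
model_variants <- function(tags = c("div_turnover_amp", "subsample_amp",
                                    "clustered", "with_selection"),
                           b = 670, nu_f_over_n = 1.4e-4, n_c = 10,
                           n2_subsample = 1000, rho = 0) {
  known <- c("div_turnover_amp", "subsample_amp", "clustered",
             "with_selection")
  bad <- setdiff(tags, known)
  if (length(bad)) stop("unknown model tag(s): ", paste(bad, collapse = ", "))
  setNames(lapply(tags, function(tag) {
    switch(tag,
      div_turnover_amp = mouse_schedule(b, nu_f_over_n,
                                        model_tag = "div_turnover_amp"),
      subsample_amp = mouse_schedule(b, nu_f_over_n,
                                     model_tag = "subsample_amp",
                                     n2_subsample = n2_subsample),
      clustered = mouse_schedule(b, nu_f_over_n, n_c = n_c,
                                 model_tag = "clustered"),
      with_selection = mouse_schedule(b, nu_f_over_n,
                                      model_tag = "with_selection",
                                      rho = rho))
  }), tags)
}
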