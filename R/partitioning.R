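#' A pool of wild-type and mutant oDNA molecules
#'
#' @param n_wild,n_mut nonnegative integer molecule counts.
#' @return an object of class `odna_pool`.
#' @export
odna_pool <- function(n_wild, n_mut) {
  stopifnot(n_wild >= 0, n_mut >= 0, n_wild == round(n_wild),
            n_mut == round(n_mut))
  structure(list(n_wild = as.integer(n_wild), n_mut = as.integer(n_mut)),
            class = "odna_pool")
}

#' @export
print.odna_pool <- function(x, ...) {
  tot <- x$n_wild + x$n_mut
  cat(sprintf("oDNA pool: %d wild + %d mutant = %d (h = %s)\n",
              x$n_wild, x$n_mut, tot,
              if (tot > 0) sprintf("%.4g", x$n_mut / tot) else "NA"))
  invisible(x)
}

pool_total <- function(pool) pool$n_wild + pool$n_mut

pool_h <- function(pool) {
  tot <- pool_total(pool)
  if (tot == 0) NA_real_ else pool$n_mut / tot
}

#' Partition a pool without replacement (hypergeometric)
#'
#' Samples exactly `n_out` molecules for the first daughter without
#' replacement; the second daughter receives the complement, so molecules
#' are conserved exactly. With `n_c > 1`, molecules are grouped into
#' homoplasmic clusters of `n_c` (remainders stay as singletons) and the
#' clusters are sampled as units; if the last sampled cluster overshoots
#' `n_out` it is split, with the excess returned to the second daughter.
#'
#' @param pool an [odna_pool()].
#' @param n_out number of molecules for the first daughter.
#' @param n_c homoplasmic cluster size.
#' @return list of two `odna_pool` daughters.
#' @export
partition_hypergeometric <- function(pool, n_out, n_c = 1) {
  stopifnot(inherits(pool, "odna_pool"), n_c >= 1)
  tot <- pool_total(pool)
  if (n_out > tot) stop("n_out exceeds pool size")
  if (n_c == 1) {
    w1 <- rhyper(1, pool$n_wild, pool$n_mut, n_out)
    d1 <- odna_pool(w1, n_out - w1)
  } else {
    # unit list: (size, is_mutant); clusters first, remainders as singletons
    wc <- pool$n_wild %/% n_c; wr <- pool$n_wild %% n_c
    mc <- pool$n_mut %/% n_c;  mr <- pool$n_mut %% n_c
    sizes <- c(rep(n_c, wc), rep(1L, wr), rep(n_c, mc), rep(1L, mr))
    muts  <- c(rep(0L, wc + wr), rep(1L, mc + mr))
    ord <- sample.int(length(sizes))
    cum <- cumsum(sizes[ord])
    k <- which(cum >= n_out)[1]
    take <- sizes[ord][seq_len(k)]
    ismut <- muts[ord][seq_len(k)]
    excess <- cum[k] - n_out
    take[k] <- take[k] - excess  # split the overshooting cluster
    m1 <- sum(take * ismut)
    d1 <- odna_pool(n_out - m1, m1)
  }
  d2 <- odna_pool(pool$n_wild - d1$n_wild, pool$n_mut - d1$n_mut)
  list(d1, d2)
}

#' Partition a pool binomially (with-replacement comparison model)
#'
#' The binomial division model: each daughter receives a fixed complement
#' of molecules (`n * p` and `n * (1 - p)`) drawn with replacement from
#' the parent's composition. Provided for comparison with the
#' hypergeometric model: sampling with replacement permits unphysical
#' outcomes (several copies of one molecule inherited by a daughter, or
#' the same molecule by both daughters), and doubles the division term of
#' the variance to 2/n. Daughter totals sum to the parent total by
#' construction, but per-type counts need not, precisely because molecule
#' fates are not exclusive under this model.
#'
#' @param pool an [odna_pool()].
#' @param p fraction of the parent total received by the first daughter.
#' @return list of two `odna_pool` daughters.
#' @export
partition_binomial <- function(pool, p = 0.5) {
  stopifnot(inherits(pool, "odna_pool"), p > 0, p < 1)
  tot <- pool_total(pool)
  h <- pool_h(pool)
  n1 <- round(tot * p)
  m1 <- rbinom(1, n1, h)
  m2 <- rbinom(1, tot - n1, h)
  list(odna_pool(n1 - m1, m1),
       odna_pool(tot - n1 - m2, m2))
}

#' Partition a pool perfectly
#'
#' Splits each type exactly in half, adding no heteroplasmy variance; odd
#' remainders are assigned by a fair coin.
#'
#' @param pool an [odna_pool()].
#' @return list of two `odna_pool` daughters.
#' @export
partition_perfect <- function(pool) {
  stopifnot(inherits(pool, "odna_pool"))
  w1 <- pool$n_wild %/% 2 + rbinom(1, pool$n_wild %% 2, 0.5)
  m1 <- pool$n_mut %/% 2 + rbinom(1, pool$n_mut %% 2, 0.5)
  list(odna_pool(w1, m1),
       odna_pool(pool$n_wild - w1, pool$n_mut - m1))
}

#' Amplify a pool by a Polya urn
#'
#' Grows the pool to `n_target` molecules by repeatedly drawing a molecule
#' with probability proportional to current counts and adding a copy of its
#' type. By exchangeability the number of mutant additions follows a
#' beta-binomial law, which is how the draw is generated (a Beta(m, w)
#' replication propensity followed by a binomial count) -- exactly the
#' urn's marginal distribution. Homoplasmic pools remain homoplasmic.
#'
#' @param pool a nonempty [odna_pool()].
#' @param n_target final copy number, at least the current total.
#' @return the amplified `odna_pool`.
#' @export
polya_amplify <- function(pool, n_target) {
  stopifnot(inherits(pool, "odna_pool"))
  tot <- pool_total(pool)
  if (tot < 1) stop("cannot amplify an empty pool")
  if (n_target < tot) stop("n_target must be >= current pool size")
  k <- n_target - tot
  if (k == 0) return(pool)
  if (pool$n_mut == 0) return(odna_pool(n_target, 0))
  if (pool$n_wild == 0) return(odna_pool(0, n_target))
  p <- rbeta(1, pool$n_mut, pool$n_wild)
  add_m <- rbinom(1, k, p)
  odna_pool(pool$n_wild + (k - add_m), pool$n_mut + add_m)
}

#' Probability mass of Polya-urn amplification
#'
#' Probability that `x` of the `n_add` molecules added by a Polya urn
#' started from `n_wild` wild-type and `n_mut` mutant molecules are mutant:
#' the beta-binomial pmf with shape `(n_mut, n_wild)`.
#'
#' @param x number of mutant additions (vectorised).
#' @param n_add total molecules added.
#' @param n_wild,n_mut starting counts (both positive).
#' @return pmf values.
#' @export
polya_pmf <- function(x, n_add, n_wild, n_mut) {
  stopifnot(n_wild >= 1, n_mut >= 1, n_add >= 0)
  exp(lchoose(n_add, x) + lbeta(n_mut + x, n_wild + n_add - x) -
        lbeta(n_mut, n_wild))
}

#' Subsample a pool
#'
#' Draws `n_out` molecules from the pool, without replacement
#' (hypergeometric, the default) or with replacement (binomial).
#'
#' @param pool an [odna_pool()].
#' @param n_out molecules to draw.
#' @param with_replacement draw with replacement (binomial model).
#' @param n_c homoplasmic cluster size (without-replacement draws only).
#' @return the subsampled `odna_pool`.
#' @export
subsample_pool <- function(pool, n_out, with_replacement = FALSE, n_c = 1) {
  stopifnot(inherits(pool, "odna_pool"), n_out >= 0)
  tot <- pool_total(pool)
  if (with_replacement) {
    h <- pool_h(pool)
    m <- rbinom(1, n_out, h)
    odna_pool(n_out - m, m)
  } else {
    if (n_out > tot) stop("n_out exceeds pool size")
    partition_hypergeometric(pool, n_out, n_c)[[1]]
  }
}

#' Physical partitioning experiment
#'
#' Monte-Carlo study of how the physical arrangement of organelles at
#' division affects daughter statistics. `n_organelles` single-oDNA
#' organelles are placed uniformly at random in the unit square, a
#' fraction `h0` carrying mutant oDNA. With `interaction = "repulsive"`,
#' positions are relaxed by short-range inverse-distance pairwise repulsion
#' (reflecting boundaries) to spread organelles evenly. The cell is then
#' bisected at x = 1/2. Spreading reduces the variance of the daughter
#' copy number below the binomial value n/4, but leaves normalised
#' heteroplasmy variance unchanged, because genotype labels are independent
#' of position.
#'
#' @param n_organelles number of organelles (>= 2).
#' @param h0 mutant fraction; the mutant count is fixed at
#'   `round(n_organelles * h0)`.
#' @param interaction `"none"` or `"repulsive"`.
#' @param n_reps Monte-Carlo replicates.
#' @param seed optional RNG seed.
#' @param step,tol,max_iter,cutoff relaxation controls: initial step size,
#'   displacement stopping tolerance, iteration cap and interaction radius.
#' @return list with `var_N` (variance of daughter-1 copy number), its
#'   standard error `var_N_se`, `mean_h`, `norm_var_h`, `norm_var_h_se`,
#'   and `n_reps`.
#' @export
spatial_partition_experiment <- function(n_organelles, h0 = 0.5,
                                         interaction = c("none", "repulsive"),
                                         n_reps = 1000, seed = NULL,
                                         step = 2e-4, tol = 1e-4,
                                         max_iter = 200, cutoff = 0.4) {
  interaction <- match.arg(interaction)
  stopifnot(n_organelles >= 2, h0 > 0, h0 < 1, n_reps >= 2)
  if (!is.null(seed)) set.seed(seed)
  n_mut <- round(n_organelles * h0)
  N1 <- numeric(n_reps)
  h1 <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    pos <- matrix(runif(2 * n_organelles), ncol = 2)
    if (interaction == "repulsive")
      pos <- spatial_relax_cpp(pos, step, tol, max_iter, cutoff)
    left <- pos[, 1] < 0.5
    # genotype labels are independent of position: first n_mut are mutant
    N1[r] <- sum(left)
    h1[r] <- if (N1[r] > 0) sum(left[seq_len(n_mut)]) / N1[r] else NA_real_
  }
  ok <- !is.na(h1)
  mh <- mean(h1[ok])
  vh <- var(h1[ok])
  nv <- vh / (mh * (1 - mh))
  list(var_N = var(N1),
       var_N_se = var(N1) * sqrt(2 / (n_reps - 1)),
       mean_h = mh,
       norm_var_h = nv,
       norm_var_h_se = nv * sqrt(2 / (sum(ok) - 1)),
       n_reps = n_reps)
}
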