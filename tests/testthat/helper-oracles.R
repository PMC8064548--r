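# Independent brute-force oracles used across the suite.

# Exact hypergeometric pmf by direct enumeration of equally likely subsets:
# probability that a draw of k molecules from w wild + m mutant contains x
# mutant, computed by counting subsets with choose().
hyper_pmf_enum <- function(x, w, m, k) {
  vapply(x, function(xi) {
    if (xi < 0 || xi > m || k - xi < 0 || k - xi > w) return(0)
    choose(m, xi) * choose(w, k - xi) / choose(w + m, k)
  }, numeric(1))
}

# Exact Polya-urn pmf by recursive enumeration of all draw histories:
# probability that x of the n_add added molecules are mutant, starting
# from w wild + m mutant.
polya_pmf_enum <- function(n_add, w, m) {
  probs <- setNames(1, paste(w, m))
  for (step in seq_len(n_add)) {
    nxt <- new.env()
    for (key in names(probs)) {
      cnt <- as.numeric(strsplit(key, " ")[[1]])
      tot <- sum(cnt)
      for (i in 1:2) {
        cnt2 <- cnt
        cnt2[i] <- cnt2[i] + 1
        k2 <- paste(cnt2, collapse = " ")
        prev <- if (!is.null(nxt[[k2]])) nxt[[k2]] else 0
        nxt[[k2]] <- prev + probs[[key]] * cnt[i] / tot
      }
    }
    probs <- unlist(as.list(nxt))
  }
  # reindex by number of mutant additions
  out <- numeric(n_add + 1)
  for (key in names(probs)) {
    cnt <- as.numeric(strsplit(key, " ")[[1]])
    out[cnt[2] - m + 1] <- probs[[key]]
  }
  out
}

# Brute-force cascade: explicit per-cycle sum of division and
# amplification contributions along the geometric copy-number profile.
cascade_brute <- function(N0, Nk, k, n_c = 1) {
  a <- 2 * (Nk / N0)^(1 / k)
  n <- N0
  v <- 0
  for (i in seq_len(k)) {
    v <- v + division_contribution(n, n_c) +
      amplification_contribution(n / 2, n * a / 2)
    n <- n * a / 2
  }
  v
}

# Mean and normalised variance of a distribution over mutant counts.
pmf_norm_var <- function(x, p, n_total) {
  h <- x / n_total
  mh <- sum(p * h)
  vh <- sum(p * (h - mh)^2)
  vh / (mh * (1 - mh))
}

# Monte-Carlo z-score of an estimate against a theory value, using the
# standard error of a variance-type statistic.
nv_z <- function(estimate, theory, se) (estimate - theory) / se

make_test_dataset <- function(seed = 101, n_individuals = 40,
                              oocytes = 30, truth = list()) {
  cfg <- generator_config(n_individuals = n_individuals,
                          oocytes_per_individual = oocytes,
                          truth = truth, seed = seed)
  generate_heteroplasmy(cfg)
}
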