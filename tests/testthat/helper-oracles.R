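# Independent oracles used by the unit and acceptance tests. These never call
# the implementation paths they check.

# exact two-sided sign test by enumerating all 2^n equally likely sign patterns
enum_sign_test <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  k <- sum(d > 0)
  counts <- vapply(0:n, function(j) choose(n, j), 0)
  lower <- sum(counts[seq_len(k + 1L)]) / 2^n
  upper <- sum(counts[(k + 1L):(n + 1L)]) / 2^n
  min(1, 2 * min(lower, upper))
}

# exact two-sided Wilcoxon signed-rank p by full 2^n enumeration (no ties)
enum_wilcoxon <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# hypergeometric upper tail by brute-force enumeration of all C(N, n) draws
enum_hypergeom <- function(N, K, n, h) {
  draws <- utils::combn(N, n)
  inside <- colSums(draws <= K)  # compounds 1..K form the pathway
  mean(inside >= h)
}

# hand step-up BH on a raw p vector
hand_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(1, q)
  out
}

# independent NIPALS PLS1: iterative u-loop, unit-variance scaled X
nipals_pls1_scores <- function(X, y, tol = 1e-12, maxit = 500L) {
  Xs <- scale(X)
  u <- y - mean(y)
  t_old <- rep(Inf, nrow(Xs))
  for (i in seq_len(maxit)) {
    w <- crossprod(Xs, u) / sum(u^2)
    w <- w / sqrt(sum(w^2))
    tt <- Xs %*% w
    if (sqrt(sum((tt - t_old)^2)) < tol) break
    t_old <- tt
    q <- sum((y - mean(y)) * tt) / sum(tt^2)
    u <- (y - mean(y)) * q
  }
  drop(tt)
}

# small deterministic cohort with a hand-set intensity pattern
tiny_cohort <- function(n_pairs = 6L, n_met = 8L, seed = 99L,
                        effects = list(), qc_per_run = 5L, ...) {
  cfg <- cohort_config(
    n_pairs = n_pairs, n_metabolites = n_met, n_internal_standards = 1L,
    n_runs = 1L, pairs_per_full_run = n_pairs, qc_per_run = qc_per_run,
    blanks_per_run = 1L, conditioning_per_run = 1L,
    effect_metabolites = effects, seed = seed, ...
  )
  generate_cohort(cfg)
}

# paired log2-ratio matrix (pairs x metabolites) straight from a cohort
ratio_matrix <- function(cohort, timepoint = "POD2") {
  ser <- paired_series(cohort, timepoint)
  wide <- tidyr::pivot_wider(ser[c("metabolite_id", "pair_id", "log2_ratio")],
                             names_from = "metabolite_id",
                             values_from = "log2_ratio")
  as.matrix(wide[-1L])
}
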