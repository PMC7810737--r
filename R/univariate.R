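#' Per-pair log2 ratios for one timepoint
#'
#' For every metabolite, forms the log2 DEL/CNT ratio within each matched
#' pair at the given timepoint. Pairs with either member missing are dropped
#' pairwise for that metabolite.
#'
#' @param x a preprocessed [metab_cohort()].
#' @param timepoint `"PREOP"` or `"POD2"`.
#' @return tibble: `metabolite_id`, `pair_id`, `del`, `cnt`, `log2_ratio`.
#' @export
paired_series <- function(x, timepoint = c("PREOP", "POD2")) {
  timepoint <- match.arg(timepoint)
  s <- x$samples
  sel <- s$group %in% c("DEL", "CNT") & s$timepoint == timepoint
  cohort_long(cohort_subset(x, samples = which(sel))) |>
    dplyr::select("metabolite_id", "pair_id", "group", "value") |>
    tidyr::pivot_wider(names_from = "group", values_from = "value") |>
    dplyr::rename(del = "DEL", cnt = "CNT") |>
    dplyr::filter(!is.na(.data$del), !is.na(.data$cnt),
                  .data$del > 0, .data$cnt > 0) |>
    dplyr::mutate(log2_ratio = log2(.data$del / .data$cnt))
}

#' Paired t-test on log2 ratios
#'
#' Two-sided one-sample t-test of the per-pair log2 DEL/CNT ratios against 0.
#' With zero variance the p-value is 1 if all ratios are exactly 0 (no
#' evidence either way) and `NA` otherwise (statistic undefined).
#'
#' @param diffs numeric vector of per-pair log2 ratios.
#' @return two-sided p-value.
#' @export
paired_t_test <- function(diffs) {
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 3L) stop("paired t-test needs at least 3 pairs", call. = FALSE)
  if (stats::sd(diffs) == 0) return(if (all(diffs == 0)) 1 else NA_real_)
  stats::t.test(diffs)$p.value
}

#' Wilcoxon signed-rank test on log2 ratios
#'
#' Two-sided; zero ratios are dropped (the signed-rank convention), the
#' exact null distribution is used for n <= 25 without ties, and the normal
#' approximation with tie correction otherwise.
#'
#' @param diffs numeric vector of per-pair log2 ratios.
#' @return two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  diffs <- diffs[is.finite(diffs)]
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n < 3L) stop("Wilcoxon signed-rank needs at least 3 non-zero ratios", call. = FALSE)
  exact <- n <= 25L && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(diffs, mu = 0, exact = exact, correct = !exact)$p.value
  )
}

#' Exact two-sided sign (binomial) test on log2 ratios
#'
#' Counts pairs with DEL above CNT among non-tied pairs and tests against
#' Binomial(n, 1/2). Two-sided by doubling the smaller tail, capped at 1.
#'
#' @param diffs numeric vector of per-pair log2 ratios.
#' @return two-sided p-value.
#' @export
sign_binomial_test <- function(diffs) {
  diffs <- diffs[is.finite(diffs)]
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n < 1L) stop("sign test needs at least 1 non-tied pair", call. = FALSE)
  k <- sum(d > 0)
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, returning q-values in
#' input order; `NA` p-values yield `NA` q-values and do not count towards m.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' One-step Tukey biweight fold change
#'
#' Robust location estimate of the per-pair log2 DEL/CNT ratios: with
#' m = median and s = MAD, u_i = (x_i - m) / (c * s + eps), weights
#' w_i = (1 - u_i^2)^2 for |u_i| < 1 and 0 otherwise, and
#' b = sum(w x) / sum(w). The signed fold change is `2^b` when b >= 0 and
#' `-2^(-b)` otherwise, so FC = -2 means two-fold down in DEL.
#'
#' @param diffs numeric vector of per-pair log2 ratios.
#' @param c biweight tuning constant.
#' @param eps guard added to the scaled MAD so constant vectors keep unit
#'   weights.
#' @return list with `b_log2` (the biweight on the log2 scale) and `fc`
#'   (the signed fold change).
#' @export
tukey_biweight_fc <- function(diffs, c = 5, eps = 1e-4) {
  x <- diffs[is.finite(diffs)]
  if (!length(x)) stop("fold change needs at least one pair", call. = FALSE)
  m <- stats::median(x)
  s <- stats::mad(x)
  u <- (x - m) / (c * s + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  if (sum(w) == 0) stop("all biweight weights vanished", call. = FALSE)
  b <- sum(w * x) / sum(w)
  list(b_log2 = b, fc = if (b >= 0) 2^b else -(2^(-b)))
}

run_three_tests <- function(diffs) {
  c(p_t = tryCatch(paired_t_test(diffs), error = function(e) NA_real_),
    p_wilcoxon = tryCatch(wilcoxon_signed_rank(diffs), error = function(e) NA_real_),
    p_binomial = tryCatch(sign_binomial_test(diffs), error = function(e) NA_real_))
}

#' Consensus univariate table for one timepoint
#'
#' Runs the paired t-test, Wilcoxon signed-rank and sign tests per
#' metabolite on log2 DEL/CNT ratios, adjusts each test across metabolites
#' with Benjamini-Hochberg, applies the consensus rule (significant in at
#' least `min_tests` tests at `alpha`, at the nominal or BH level), and
#' reports the one-step biweight fold change.
#'
#' @param x a preprocessed [metab_cohort()].
#' @param timepoint `"PREOP"` or `"POD2"`.
#' @param level `"nominal"` (raw p) or `"BH"` (adjusted q) for the consensus
#'   cutoff.
#' @param alpha significance cutoff.
#' @param min_tests tests that must pass for consensus.
#' @return tibble (one row per metabolite): p and q per test,
#'   `n_tests_passed`, `consensus`, `AVG_p` (mean raw p of the passing
#'   tests; `NA` without consensus), `b_log2`, `FC`, `n_pairs`.
#' @export
univariate_table <- function(x, timepoint = c("PREOP", "POD2"),
                             level = c("nominal", "BH"), alpha = 0.05,
                             min_tests = 2L) {
  timepoint <- match.arg(timepoint)
  level <- match.arg(level)
  series <- paired_series(x, timepoint)
  analytes <- x$metabolites$metabolite_id[!x$metabolites$is_internal_standard]
  by_met <- split(series, factor(series$metabolite_id, levels = analytes))
  rows <- purrr::map(by_met, function(d) {
    p <- run_three_tests(d$log2_ratio)
    fc <- if (nrow(d)) tukey_biweight_fc(d$log2_ratio) else list(b_log2 = NA_real_, fc = NA_real_)
    tibble::tibble(p_t = p[["p_t"]], p_wilcoxon = p[["p_wilcoxon"]],
                   p_binomial = p[["p_binomial"]],
                   b_log2 = fc$b_log2, FC = fc$fc, n_pairs = nrow(d))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(metabolite_id = analytes, .before = 1L)
  out$q_t <- bh_adjust(out$p_t)
  out$q_wilcoxon <- bh_adjust(out$p_wilcoxon)
  out$q_binomial <- bh_adjust(out$p_binomial)
  consensus_select(out, alpha = alpha, level = level, min_tests = min_tests)
}

#' Apply the consensus rule to a univariate table
#'
#' A metabolite reaches consensus when at least `min_tests` of the three
#' tests fall below `alpha` at the chosen level. `AVG_p` is the mean of the
#' raw p-values of the tests that passed the cutoff.
#'
#' @param table a [univariate_table()]-shaped tibble with `p_*` and `q_*`
#'   columns.
#' @inheritParams univariate_table
#' @return the table with `n_tests_passed`, `consensus` and `AVG_p` updated.
#' @export
consensus_select <- function(table, alpha = 0.05,
                             level = c("nominal", "BH"), min_tests = 2L) {
  level <- match.arg(level)
  pcols <- c("p_t", "p_wilcoxon", "p_binomial")
  crit <- if (level == "nominal") as.matrix(table[pcols])
          else as.matrix(table[c("q_t", "q_wilcoxon", "q_binomial")])
  pass <- !is.na(crit) & crit < alpha
  praw <- as.matrix(table[pcols])
  table$n_tests_passed <- rowSums(pass)
  table$consensus <- table$n_tests_passed >= min_tests
  avg <- rowSums(praw * pass, na.rm = TRUE) / pmax(1L, rowSums(pass))
  table$AVG_p <- ifelse(table$consensus, avg, NA_real_)
  table
}

#' Split-resampling robustness of consensus calls
#'
#' Repeatedly leaves out a fraction of the matched pairs, reruns the three
#' tests (with BH re-adjustment when the criterion works at the BH level) on
#' the retained pairs, and records how often each metabolite still reaches
#' consensus. A metabolite is "robust" when it passes in at least half of
#' the splits.
#'
#' @param x a preprocessed [metab_cohort()].
#' @param timepoint `"PREOP"` or `"POD2"`.
#' @param n_iter number of resampling iterations.
#' @param leave_frac fraction of pairs left out each iteration
#'   (rounded to a whole number of pairs).
#' @inheritParams univariate_table
#' @param seed integer seed for the resampling stream.
#' @return tibble: `metabolite_id`, `robust_fraction`, `robust`.
#' @export
split_robustness <- function(x, timepoint = c("PREOP", "POD2"),
                             n_iter = 10000L, leave_frac = 0.1,
                             level = c("nominal", "BH"), alpha = 0.05,
                             min_tests = 2L, seed = 1L) {
  timepoint <- match.arg(timepoint)
  level <- match.arg(level)
  if (n_iter < 1L) stop("n_iter must be at least 1", call. = FALSE)
  series <- paired_series(x, timepoint)
  analytes <- x$metabolites$metabolite_id[!x$metabolites$is_internal_standard]
  ratio_mat <- series |>
    dplyr::select("metabolite_id", "pair_id", "log2_ratio") |>
    tidyr::pivot_wider(names_from = "metabolite_id", values_from = "log2_ratio")
  pairs <- ratio_mat$pair_id
  rm <- as.matrix(ratio_mat[-1L])
  rm <- rm[, intersect(analytes, colnames(rm)), drop = FALSE]
  n_drop <- round(leave_frac * length(pairs))
  passes <- stats::setNames(numeric(ncol(rm)), colnames(rm))
  restore_rng <- snapshot_rng()
  on.exit(restore_rng(), add = TRUE)
  set.seed(stage_seed(seed, "split-robustness"))
  for (it in seq_len(n_iter)) {
    keep <- sample.int(length(pairs), length(pairs) - n_drop)
    sub <- rm[keep, , drop = FALSE]
    pm <- t(apply(sub, 2L, function(col) run_three_tests(col[is.finite(col)])))
    crit <- if (level == "BH") apply(pm, 2L, bh_adjust) else pm
    npass <- rowSums(!is.na(crit) & crit < alpha)
    passes <- passes + (npass >= min_tests)
  }
  frac <- passes / n_iter
  tibble::tibble(metabolite_id = names(frac),
                 robust_fraction = unname(frac),
                 robust = unname(frac) >= 0.5)
}
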