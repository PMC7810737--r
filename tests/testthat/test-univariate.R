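test_that("paired t-test matches hand computation and guards small n", {
  expect_equal(paired_t_test(c(1, -1, 1, -1)), 1)
  d <- c(0.5, 1.5, 1.0, 1.0)
  tstat <- mean(d) / (stats::sd(d) / 2)
  expect_equal(tstat, 4.898979, tolerance = 1e-6)
  expect_equal(paired_t_test(d), 2 * stats::pt(-tstat, df = 3))
  expect_error(paired_t_test(c(1, 2)), "at least 3")
  expect_equal(paired_t_test(c(0, 0, 0)), 1)
  expect_true(is.na(paired_t_test(c(1, 1, 1))))
})

test_that("Wilcoxon signed-rank agrees with sign-pattern enumeration", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3)), 0.25)
  expect_equal(wilcoxon_signed_rank(c(-3, -1, 1, 3)), 1)
  set.seed(61)
  for (n in c(5L, 8L, 10L)) {
    for (rep in 1:3) {
      d <- stats::rnorm(n) + 0.4
      d <- d[d != 0]
      if (any(duplicated(abs(d)))) next
      expect_equal(wilcoxon_signed_rank(d), enum_wilcoxon(d),
                   tolerance = 1e-12)
    }
  }
  expect_error(wilcoxon_signed_rank(c(-1, 1, 0)), "at least 3 non-zero")
})

test_that("sign test doubles the smaller exact binomial tail", {
  expect_equal(sign_binomial_test(rep(1, 10)), 2 * 0.5^10)
  expect_equal(sign_binomial_test(c(rep(1, 4), rep(-1, 4))), 1)
  d52 <- c(rep(1, 36), rep(-1, 16))
  expect_equal(sign_binomial_test(d52),
               2 * stats::pbinom(35, 52, 0.5, lower.tail = FALSE))
  set.seed(67)
  for (n in c(4L, 7L, 12L)) {
    d <- sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, 0.5, 2)
    expect_equal(sign_binomial_test(d), enum_sign_test(d), tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the hand step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.05, 9)), rep(0.05, 9))
  set.seed(71)
  p <- stats::runif(4)
  expect_equal(bh_adjust(p), hand_bh(p))
})

test_that("consensus rule and AVG_p follow the two-of-three convention", {
  tab <- tibble::tibble(
    metabolite_id = c("a", "b", "c"),
    p_t = c(0.01, 0.04, 0.20), p_wilcoxon = c(0.20, 0.06, 0.30),
    p_binomial = c(0.03, 0.07, 0.40),
    q_t = c(0.04, 0.2, 0.5), q_wilcoxon = c(0.04, 0.3, 0.6),
    q_binomial = c(0.90, 0.3, 0.7)
  )
  nom <- consensus_select(tab, level = "nominal")
  expect_equal(nom$consensus, c(TRUE, FALSE, FALSE))
  expect_equal(nom$AVG_p[1], mean(c(0.01, 0.03)))
  bh <- consensus_select(tab, level = "BH")
  expect_true(bh$consensus[1])  # q = (0.04, 0.04, 0.90)
  expect_equal(bh$AVG_p[1], mean(c(0.01, 0.20)))  # raw p of passing tests
})

test_that("one-step biweight downweights outliers and converges to the mean", {
  expect_equal(tukey_biweight_fc(rep(1, 5))$b_log2, 1)
  expect_equal(tukey_biweight_fc(rep(1, 5))$fc, 2)
  expect_equal(tukey_biweight_fc(c(-1, 0, 1))$b_log2, 0)
  expect_equal(tukey_biweight_fc(c(-1, 0, 1))$fc, 1)
  # MAD = 0 with one gross outlier: eps guard zeroes the outlier's weight
  out <- tukey_biweight_fc(c(0, 0, 0, 0, 10))
  expect_lt(abs(out$b_log2), 1e-6)
  expect_equal(out$fc, 1, tolerance = 1e-6)
  set.seed(73)
  x <- stats::rnorm(30)
  expect_equal(tukey_biweight_fc(x, c = 1e9)$b_log2, mean(x), tolerance = 1e-6)
  # downregulation sign convention
  expect_equal(tukey_biweight_fc(rep(-1, 4))$fc, -2)
})

test_that("swapping DEL and CNT flips FC and preserves p-values", {
  set.seed(79)
  for (rep in 1:10) {
    d <- stats::rnorm(15, mean = stats::runif(1, -1, 1))
    d <- d[d != 0]
    expect_equal(tukey_biweight_fc(-d)$b_log2, -tukey_biweight_fc(d)$b_log2)
    expect_equal(paired_t_test(-d), paired_t_test(d))
    expect_equal(wilcoxon_signed_rank(-d), wilcoxon_signed_rank(d))
    expect_equal(sign_binomial_test(-d), sign_binomial_test(d))
  }
})

test_that("univariate table detects a strong spiked effect end to end", {
  gen <- tiny_cohort(n_pairs = 12L, n_met = 20L, seed = 83L,
                     effects = spike_effects("met_002", 2, "POD2"),
                     mnar_quantile = 0, mcar_rate = 0)
  u <- univariate_table(gen$cohort, "POD2", level = "nominal")
  expect_equal(nrow(u), 19L)  # internal standard excluded
  row <- u[u$metabolite_id == "met_002", ]
  expect_true(row$consensus)
  expect_gt(row$FC, 2)
  others <- u$metabolite_id != "met_002"
  expect_false(any(u$consensus[others] & u$AVG_p[others] < 0.01, na.rm = TRUE))
  # q >= p always
  expect_true(all(u$q_t >= u$p_t, na.rm = TRUE))
})

test_that("split robustness is deterministic and saturates for strong effects", {
  gen <- tiny_cohort(n_pairs = 12L, n_met = 10L, seed = 89L,
                     effects = spike_effects("met_001", 3, "POD2"),
                     mnar_quantile = 0, mcar_rate = 0)
  r1 <- split_robustness(gen$cohort, "POD2", n_iter = 50L, seed = 4L)
  r2 <- split_robustness(gen$cohort, "POD2", n_iter = 50L, seed = 4L)
  expect_identical(r1, r2)
  expect_equal(r1$robust_fraction[r1$metabolite_id == "met_001"], 1)
  expect_true(r1$robust[r1$metabolite_id == "met_001"])
  expect_error(split_robustness(gen$cohort, "POD2", n_iter = 0L), "at least 1")
})
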