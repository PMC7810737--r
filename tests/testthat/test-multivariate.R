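sim_class_data <- function(n = 60L, J = 20L, strength = 1, seed = 1L) {
  set.seed(seed)
  y <- rep(c(-1, 1), each = n / 2)
  X <- matrix(stats::rnorm(n * J), n, J,
              dimnames = list(NULL, paste0("V", seq_len(J))))
  X[, 1] <- X[, 1] + strength * y
  list(X = X, y = y)
}

test_that("a perfect predictor column gives R2Y of one", {
  set.seed(101)
  y <- rep(c(-1, 1), each = 10)
  noise <- matrix(stats::rnorm(20 * 5), 20, 5)
  noise <- apply(noise, 2L, function(z) stats::residuals(stats::lm(z ~ y)))
  X <- cbind(sig = y, noise)  # noise orthogonal to y in-sample
  colnames(X) <- paste0("V", 1:6)
  m <- fit_opls_da(X, y, n_ortho = 0L)
  expect_equal(m$R2Y, 1, tolerance = 1e-9)
})

test_that("one orthogonal component recovers a planted two-latent structure", {
  set.seed(103)
  n <- 40L; J <- 30L
  y <- rep(c(-1, 1), each = n / 2)
  t_o <- stats::rnorm(n)
  t_o <- stats::residuals(stats::lm(t_o ~ y))  # force orthogonality to y
  p_y <- stats::rnorm(J); p_o <- stats::rnorm(J)
  X <- outer(y, p_y) + 3 * outer(t_o, p_o) +
    matrix(stats::rnorm(n * J, 0, 0.01), n, J)
  colnames(X) <- paste0("V", seq_len(J))
  m <- fit_opls_da(X, y, n_ortho = 1L)
  expect_gt(abs(stats::cor(m$scores, y)), 0.999)
})

test_that("OPLS-DA with no orthogonal component equals NIPALS PLS1", {
  d <- sim_class_data(seed = 107)
  m <- fit_opls_da(d$X, d$y, n_ortho = 0L)
  oracle <- nipals_pls1_scores(d$X, d$y)
  sgn <- sign(sum(oracle * m$scores))
  expect_lt(sqrt(sum((m$scores - sgn * oracle)^2)) / sqrt(sum(m$scores^2)),
            1e-8)
})

test_that("VIP normalization and limits hold", {
  d <- sim_class_data(J = 25L, seed = 109)
  m <- fit_opls_da(d$X, d$y, n_ortho = 1L)
  expect_equal(mean(m$VIP^2), 1, tolerance = 1e-6)
  expect_equal(tidy(m)$VIP, unname(m$VIP))
  # one informative variable among J, the rest orthogonal to y in-sample:
  # in the noise -> 0 limit VIP of the informative variable reaches sqrt(J)
  set.seed(113)
  yy <- rep(c(-1, 1), each = 30)
  noise <- matrix(stats::rnorm(60 * 15), 60, 15)
  noise <- apply(noise, 2L, function(z) stats::residuals(stats::lm(z ~ yy)))
  Xv <- cbind(yy, noise)
  colnames(Xv) <- paste0("V", 1:16)
  ms <- fit_opls_da(Xv, yy, n_ortho = 0L)
  expect_equal(ms$VIP[["V1"]], sqrt(16), tolerance = 1e-8)
})

test_that("predictive and orthogonal scores are orthogonal; R2Y grows with
           components while Q2 need not", {
  d <- sim_class_data(J = 40L, strength = 0.4, seed = 127)
  r2 <- q2 <- numeric(3)
  for (k in 0:2) {
    m <- fit_opls_da(d$X, d$y, n_ortho = k)
    if (k > 0) {
      rel <- max(abs(crossprod(m$scores, m$T_o))) / sum(m$scores^2)
      expect_lt(rel, 1e-8)
    }
    r2[k + 1] <- m$R2Y
    q2[k + 1] <- as.numeric(q2_cross_validate(d$X, d$y, k, seed = 5L))
  }
  expect_true(all(diff(r2) > -1e-10))
  expect_false(all(diff(q2) > 0))  # cross-validation punishes overfit
})

test_that("class-coding flips leave R2, Q2, VIP and AUC invariant", {
  d <- sim_class_data(seed = 131)
  m1 <- fit_opls_da(d$X, d$y, n_ortho = 1L)
  m2 <- fit_opls_da(d$X, -d$y, n_ortho = 1L)
  expect_equal(m1$R2Y, m2$R2Y)
  expect_equal(m1$R2X, m2$R2X)
  expect_equal(unname(m1$VIP), unname(m2$VIP))
  expect_equal(m1$scores, -m2$scores, tolerance = 1e-10)
  q1 <- as.numeric(q2_cross_validate(d$X, d$y, 1L, seed = 6L))
  q2v <- as.numeric(q2_cross_validate(d$X, -d$y, 1L, seed = 6L))
  expect_equal(q1, q2v)
  a1 <- svm_panel_auc(d$X, d$y, c("V1", "V2"), seed = 7L)$auc
  a2 <- svm_panel_auc(d$X, -d$y, c("V1", "V2"), seed = 7L)$auc
  expect_equal(a1, a2)
})

test_that("Q2 behaves across signal strengths and fold schemes", {
  # one strong column (signal SD 10x noise) and one pure-noise column
  set.seed(137)
  y137 <- rep(c(-1, 1), each = 30)
  strong <- list(X = cbind(V1 = 10 * y137 + stats::rnorm(60),
                           V2 = stats::rnorm(60)),
                 y = y137)
  expect_gt(as.numeric(q2_cross_validate(strong$X, strong$y, 0L, seed = 8L)),
            0.9)
  loo <- q2_cross_validate(strong$X, strong$y, 0L,
                           folds = nrow(strong$X), seed = 8L)
  expect_true(is.finite(as.numeric(loo)))
  # permuted labels on a multivariate noise matrix: Q2 collapses
  null <- sim_class_data(n = 60L, J = 10L, strength = 0, seed = 139)
  set.seed(139)
  qs <- replicate(20, {
    yp <- sample(null$y)
    as.numeric(q2_cross_validate(null$X, yp, 0L, seed = 9L))
  })
  expect_lte(median(qs), 0)
  expect_error(q2_cross_validate(strong$X, strong$y, 0L, folds = 1L), "folds")
})

test_that("CV-ANOVA tracks predictive power in both limits", {
  strong <- sim_class_data(n = 60L, J = 10L, strength = 10, seed = 149)
  cva <- cv_anova(strong$X, strong$y, 0L, seed = 10L)
  expect_lt(cva$p, 1e-10)
  expect_equal(cva$df1, 1L)
  expect_equal(cva$df2, 58L)
  null <- sim_class_data(n = 40L, J = 60L, strength = 0, seed = 151)
  cva0 <- cv_anova(null$X, null$y, 1L, seed = 11L)
  expect_gt(cva0$p, 0.5)  # overfit null: PRESS >= SS, F clamped at 0
})

test_that("permutation p-values respect their bounds and count the identity", {
  strong <- sim_class_data(n = 40L, J = 8L, strength = 5, seed = 157)
  pv <- permutation_validate(strong$X, strong$y, 0L, n_perm = 19L, seed = 12L)
  expect_equal(pv$pQ2, 1 / 20)  # observed beats every permutation
  expect_gte(pv$pR2Y, 1 / 20)
  # a permutation equal to y itself counts as an exceedance
  tied <- permutation_validate(strong$X, strong$y, 0L, n_perm = 19L,
                               seed = 12L)
  expect_true(all(c(tied$pR2Y, tied$pQ2) >= 1 / 20))
})

test_that("PCA/Mahalanobis screen flags gross outliers at the chi-square cut", {
  set.seed(163)
  X <- matrix(stats::rnorm(100 * 10), 100, 10)
  X[1, ] <- X[1, ] + c(10, rep(0, 9)) * 5
  scr <- pca_outlier_screen(X)
  expect_true(scr$outlier[1])
  # spherical cloud: outlier count near alpha * n
  X0 <- matrix(stats::rnorm(200 * 6), 200, 6)
  scr0 <- pca_outlier_screen(X0, alpha = 0.025)
  expect_lte(sum(scr0$outlier), stats::qbinom(0.999, 200, 0.025))
  expect_error(pca_outlier_screen(X0[1:5, 1:2], n_components = 3L), "rank|few")
})

test_that("SVM panel classification is perfect when separable and honest
           under cross-validation", {
  sep <- sim_class_data(n = 40L, J = 6L, strength = 20, seed = 167)
  pairs <- rep(seq_len(20), 2)
  sv <- svm_panel_auc(sep$X, sep$y, c("V1", "V2"), pairs = pairs, seed = 13L)
  expect_equal(sv$auc, 100)
  expect_equal(sv$scheme, "leave-pair-out CV")
  expect_error(svm_panel_auc(sep$X, sep$y, "nope", seed = 1L), "not in X")
})
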