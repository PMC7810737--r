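make_study_cohort <- function(values, n_per_group = 4L) {
  # minimal balanced design: n_per_group pairs, one timepoint block each
  n <- nrow(values)
  stopifnot(n == 4L * n_per_group)
  grid <- tidyr::expand_grid(pair_id = sprintf("P%02d", seq_len(n_per_group)),
                             timepoint = c("PREOP", "POD2"),
                             group = c("DEL", "CNT"))
  samples <- tibble::tibble(
    sample_id = sprintf("%s_%s_%s", grid$pair_id, grid$group, grid$timepoint),
    subject_id = paste0(grid$pair_id, substr(grid$group, 1, 1)),
    pair_id = grid$pair_id, group = grid$group, timepoint = grid$timepoint,
    run_id = 1L, injection_order = seq_len(n)
  )
  metab_cohort(values, samples)
}

test_that("presence rule is boundary-inclusive per phenotypic group", {
  v <- matrix(1, 16, 3, dimnames = list(NULL, c("m1", "m2", "m3")))
  # m1: measured in 2 of 4 samples of PREOP-CNT only (0.50 >= 0.50)
  x <- make_study_cohort(v)
  pheno <- paste(x$samples$timepoint, x$samples$group, sep = "-")
  g1 <- which(pheno == "PREOP-CNT")
  x$values[setdiff(seq_len(16), g1[1:2]), "m1"] <- NA
  # m2: measured in 1 of 4 in every group
  for (g in unique(pheno)) {
    idx <- which(pheno == g)
    x$values[idx[-1], "m2"] <- NA
  }
  mask <- presence_filter(x, 0.5)
  expect_true(mask$present[mask$metabolite_id == "m1"])
  expect_false(mask$present[mask$metabolite_id == "m2"])
  expect_true(mask$present[mask$metabolite_id == "m3"])
})

test_that("constructed 315-metabolite fixture keeps exactly 245", {
  gen <- generate_cohort(cohort_config(
    n_pairs = 8L, n_runs = 1L, pairs_per_full_run = 8L,
    n_metabolites = 315L, n_internal_standards = 0L,
    mnar_quantile = 0, mcar_rate = 0, seed = 31L
  ))
  x <- gen$cohort
  study <- which(x$samples$group %in% c("DEL", "CNT"))
  x$values[study, 1:70] <- NA  # force 70 below threshold in all groups
  mask <- presence_filter(x)
  expect_equal(sum(mask$present), 245L)
  expect_equal(ncol(cohort_values(apply_presence(x, mask))), 245L)
})

test_that("knn imputation honors twins, equidistant means and identity", {
  v <- matrix(c(1, 2, 3, 4,
                1, 2, 3, 4), 2, 4, byrow = TRUE)
  colnames(v) <- paste0("m", 1:4)
  samples <- tibble::tibble(sample_id = c("a", "b"), subject_id = NA,
                            pair_id = NA, group = "QC", timepoint = NA,
                            run_id = 1L, injection_order = 1:2)
  x <- metab_cohort(v, samples)
  x$values["a", "m4"] <- NA
  imp <- knn_impute(x, k = 1L)
  expect_equal(cohort_values(imp)["a", "m4"], 4)

  # three equidistant (here: identical-profile) neighbours holding {10, 20, 30}
  v2 <- rbind(c(5, 5, NA),
              c(5, 5, 10),
              c(5, 5, 20),
              c(5, 5, 30))
  colnames(v2) <- paste0("m", 1:3)
  s2 <- tibble::tibble(sample_id = letters[1:4], subject_id = NA,
                       pair_id = NA, group = "QC", timepoint = NA,
                       run_id = 1L, injection_order = 1:4)
  x2 <- metab_cohort(v2, s2)
  imp2 <- knn_impute(x2, k = 3L)
  expect_equal(cohort_values(imp2)["a", "m3"], 20)

  x3 <- metab_cohort(v2[, 1:2], s2)  # complete matrix
  expect_identical(cohort_values(knn_impute(x3, 2L)), cohort_values(x3))

  x4 <- x2
  x4$values["a", ] <- NA
  expect_error(knn_impute(x4, 2L), "all values missing")
})

test_that("drift correction is identity on a flat QC series and removes a
           noiseless linear drift", {
  gen <- tiny_cohort(n_pairs = 10L, n_met = 10L, seed = 41L,
                     drift = list(amplitude = 0, shape = "linear"),
                     mnar_quantile = 0, mcar_rate = 0,
                     technical_cv = 0, loading_sd = 0, qc_per_run = 10L)
  x <- gen$cohort
  corr <- qc_drift_correct(x, "spline")
  expect_equal(cohort_values(corr), cohort_values(x), tolerance = 1e-8)

  # impose a noiseless 2x linear drift over injection order
  drifted <- x
  n <- nrow(drifted$values)
  fac <- seq(1, 2, length.out = n)
  drifted$values <- drifted$values * fac
  pre <- compute_rsd(drifted)$rsd_pct
  post <- compute_rsd(qc_drift_correct(drifted, "spline"))$rsd_pct
  expect_true(all(post < 0.1 * pre))
})

test_that("drift correction lowers QC RSD on a drifting synthetic cohort", {
  gen <- tiny_cohort(n_pairs = 10L, n_met = 60L, seed = 43L,
                     drift = list(amplitude = 0.5, shape = "exponential-decay"),
                     mnar_quantile = 0, mcar_rate = 0, qc_per_run = 13L)
  pre <- compute_rsd(gen$cohort)$rsd_pct
  post <- compute_rsd(qc_drift_correct(gen$cohort, "rf", seed = 1L))$rsd_pct
  improved <- sum(post < pre)
  p <- stats::binom.test(improved, length(pre), 0.5,
                         alternative = "greater")$p.value
  expect_lt(p, 0.01)
  expect_true(all(cohort_values(qc_drift_correct(gen$cohort, "spline")) >= 0,
                  na.rm = TRUE))
})

test_that("NOMIS removes a shared loading factor exactly and approximately", {
  # every metabolite = standard * constant: post-normalization variance 0
  n <- 24L
  load_fac <- exp(stats::rnorm(n, 0, 0.3))
  v <- cbind(IS_1 = 100 * load_fac,
             m1 = 5 * 100 * load_fac,
             m2 = 0.2 * 100 * load_fac)
  samples <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                            subject_id = NA, pair_id = NA, group = "QC",
                            timepoint = NA, run_id = 1L,
                            injection_order = 1:n)
  metab <- tibble::tibble(metabolite_id = colnames(v),
                          display_name = colnames(v),
                          is_internal_standard = c(TRUE, FALSE, FALSE))
  x <- metab_cohort(v, samples, metab)
  norm <- nomis_normalize(x)
  expect_equal(ncol(cohort_values(norm)), 2L)  # standard removed
  expect_lt(max(apply(log2(cohort_values(norm)), 2, stats::sd)), 1e-10)

  # independent metabolite: slope shrinks, values re-centered only
  set.seed(7)
  n2 <- 200L
  v2 <- cbind(IS_1 = exp(stats::rnorm(n2, 4, 0.3)),
              m1 = exp(stats::rnorm(n2, 2, 0.3)))
  s2 <- dplyr::mutate(samples[rep(1, n2), ],
                      sample_id = sprintf("t%03d", 1:n2),
                      injection_order = 1:n2)
  m2 <- dplyr::slice(metab, 1:2)
  x2 <- metab_cohort(v2, s2, m2)
  norm2 <- nomis_normalize(x2)
  slope <- stats::coef(stats::lm(log2(cohort_values(norm2)[, 1]) ~
                                   log2(v2[, "IS_1"])))[2]
  expect_lt(abs(slope), 0.05)
})

test_that("NOMIS halves the per-metabolite CV on a loaded cohort", {
  gen <- tiny_cohort(n_pairs = 12L, n_met = 40L, seed = 47L,
                     drift = list(amplitude = 0, shape = "linear"),
                     mnar_quantile = 0, mcar_rate = 0,
                     loading_sd = 0.3, between_subject_sd = 0.05,
                     technical_cv = 0.02)
  cv_of <- function(m) apply(m, 2L, function(z) stats::sd(z) / mean(z))
  raw_cv <- mean(cv_of(cohort_values(gen$cohort)))
  norm_cv <- mean(cv_of(cohort_values(nomis_normalize(gen$cohort))))
  expect_lt(norm_cv, 0.5 * raw_cv)
})

test_that("RSD arithmetic matches hand computation and handles gaps", {
  v <- matrix(c(90, 110, 100, 100, 50, NA), 2, 3)
  colnames(v) <- c("m1", "m2", "m3")
  s <- tibble::tibble(sample_id = c("q1", "q2"), subject_id = NA,
                      pair_id = NA, group = "QC", timepoint = NA,
                      run_id = 1L, injection_order = 1:2)
  x <- metab_cohort(v, s)
  rsd <- compute_rsd(x)
  expect_equal(rsd$rsd_pct[1], 100 * stats::sd(c(90, 110)) / 100)
  expect_equal(round(rsd$rsd_pct[1], 2), 14.14)
  expect_equal(rsd$rsd_pct[2], 0)
  expect_true(is.na(rsd$rsd_pct[3]))
  expect_equal(rsd$n_used, c(2L, 2L, 1L))
})

test_that("preprocessing commutes with sample permutation", {
  gen <- tiny_cohort(n_pairs = 6L, n_met = 15L, seed = 53L)
  perm <- sample(nrow(cohort_values(gen$cohort)))
  a <- preprocess_cohort(gen$cohort, drift_method = "spline", seed = 2L)$cohort
  b <- preprocess_cohort(cohort_subset(gen$cohort, samples = perm),
                         drift_method = "spline", seed = 2L)$cohort
  expect_equal(cohort_values(a)[cohort_samples(b)$sample_id, ],
               cohort_values(b), tolerance = 1e-10)
})
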