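#' Presence filter over phenotypic groups
#'
#' A metabolite is "present" when it was measured (non-missing) in at least
#' `threshold` of the study samples of at least one phenotypic group
#' (PREOP-CNT, PREOP-DEL, POD2-CNT, POD2-DEL). QC, blank and conditioning
#' injections do not enter the fractions. Internal standards are always kept
#' (they are spiked, not biological).
#'
#' @param x a [metab_cohort()].
#' @param threshold measured-fraction cutoff, boundary inclusive.
#' @return tibble with one row per metabolite: per-group measured fractions
#'   and the `present` flag.
#' @export
presence_filter <- function(x, threshold = 0.5) {
  s <- x$samples
  study <- s$group %in% c("DEL", "CNT")
  pheno <- paste(s$timepoint, s$group, sep = "-")
  groups <- sort(unique(pheno[study]))
  fr <- sapply(groups, function(g) {
    rows <- study & pheno == g
    colMeans(!is.na(x$values[rows, , drop = FALSE]))
  })
  out <- tibble::as_tibble(fr) |>
    dplyr::mutate(metabolite_id = x$metabolites$metabolite_id, .before = 1L)
  out$max_fraction <- apply(fr, 1L, max)
  out$present <- out$max_fraction >= threshold |
    x$metabolites$is_internal_standard
  out
}

#' Drop metabolites deemed absent
#'
#' @param x a [metab_cohort()].
#' @param mask output of [presence_filter()].
#' @return a [metab_cohort()] restricted to present metabolites.
#' @export
apply_presence <- function(x, mask) {
  keep <- mask$present[match(x$metabolites$metabolite_id, mask$metabolite_id)]
  cohort_subset(x, metabolites = which(keep))
}

#' k-nearest-neighbour imputation of missing intensities
#'
#' Distances between samples are Euclidean over co-observed metabolites after
#' per-metabolite standardization (mean 0, SD 1 on observed values), scaled
#' by the number of co-observed channels so samples with different
#' missingness patterns are comparable. Each missing cell is replaced by the
#' inverse-distance weighted mean of the k nearest samples that observed that
#' metabolite; zero-distance neighbours (exact twins) take all the weight.
#' Observed cells are never altered.
#'
#' @param x a [metab_cohort()].
#' @param k number of neighbours (must be < number of samples).
#' @return a [metab_cohort()] with no missing cells (provided each
#'   metabolite is observed somewhere).
#' @export
knn_impute <- function(x, k = 10L) {
  v <- x$values
  if (!anyNA(v)) return(x)
  n <- nrow(v)
  if (k >= n) stop("k must be smaller than the number of samples", call. = FALSE)
  if (any(rowSums(!is.na(v)) == 0L)) {
    stop("a sample with all values missing has no neighbours", call. = FALSE)
  }
  mu <- colMeans(v, na.rm = TRUE)
  sdv <- apply(v, 2L, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  z <- sweep(sweep(v, 2L, mu), 2L, sdv, "/")
  obs <- !is.na(z)
  z0 <- z
  z0[!obs] <- 0
  # mean squared difference over co-observed channels, via cross-products
  sq <- z0^2
  co <- tcrossprod(obs * 1)                    # co-observed counts
  ssq <- tcrossprod(sq, obs) + tcrossprod(obs, sq) - 2 * tcrossprod(z0)
  d2 <- ssq / pmax(co, 1L)
  d2[co == 0L] <- Inf
  d2[d2 < 0] <- 0                              # numeric guard
  diag(d2) <- Inf
  out <- v
  eps <- sqrt(.Machine$double.eps)
  for (i in which(rowSums(!obs) > 0L)) {
    for (j in which(!obs[i, ])) {
      cand <- which(obs[, j] & is.finite(d2[i, ]))
      if (!length(cand)) next
      dd <- sqrt(d2[i, cand])
      ord <- order(dd)[seq_len(min(k, length(cand)))]
      dd <- dd[ord]
      vals <- v[cand[ord], j]
      w <- if (any(dd < eps)) as.numeric(dd < eps) else 1 / dd
      out[i, j] <- sum(w * vals) / sum(w)
    }
  }
  x$values <- out
  x
}

#' QC-anchored signal-drift correction
#'
#' For each metabolite a flexible regressor — random-forest regression
#' (the default, after QC-RFSC) or a cubic smoothing spline — is fit to the
#' pooled-QC intensities against the global injection index, jointly across
#' all runs so the QC series bridges them. The correction factor at any
#' injection is the fitted value divided by the median fitted QC value; every
#' sample's intensity is divided by the factor at its own injection index.
#' Metabolites missing in more than half of the QCs are left uncorrected and
#' flagged in the `uncorrected` attribute. Spline fits do not extrapolate:
#' injections outside the QC span use the nearest fitted value.
#'
#' @param x a [metab_cohort()].
#' @param method `"rf"` (random forest, 500 trees) or `"spline"`.
#' @param seed integer seed controlling the forest's bootstrap draws.
#' @return a corrected [metab_cohort()] (attribute `uncorrected` lists any
#'   skipped metabolite ids).
#' @export
qc_drift_correct <- function(x, method = c("rf", "spline"), seed = 1L) {
  method <- match.arg(method)
  v <- x$values
  idx <- global_injection_index(x)
  qc <- x$samples$group == "QC"
  if (sum(qc) < 3L) stop("drift correction needs at least 3 QC samples", call. = FALSE)
  uncorrected <- character(0)
  restore_rng <- snapshot_rng()
  on.exit(restore_rng(), add = TRUE)
  set.seed(stage_seed(seed, "drift-correct"))
  for (j in seq_len(ncol(v))) {
    yq <- v[qc, j]
    ok <- !is.na(yq)
    if (mean(ok) < 0.5 || sum(ok) < 3L) {
      uncorrected <- c(uncorrected, x$metabolites$metabolite_id[j])
      next
    }
    xs <- idx[qc][ok]
    ys <- yq[ok]
    if (stats::sd(ys) == 0) next  # flat QC series: factors are all 1
    fitted_at <- if (method == "rf") {
      fit <- randomForest::randomForest(x = data.frame(order = xs), y = ys,
                                        ntree = 500L)
      function(at) stats::predict(fit, data.frame(order = at))
    } else {
      df_ok <- length(unique(xs)) >= 4L
      if (df_ok) {
        fit <- stats::smooth.spline(xs, ys)
        function(at) stats::predict(fit, pmin(max(xs), pmax(min(xs), at)))$y
      } else {
        fit <- stats::lm(ys ~ xs)
        function(at) {
          at <- pmin(max(xs), pmax(min(xs), at))
          stats::predict(fit, data.frame(xs = at))
        }
      }
    }
    f <- fitted_at(idx) / stats::median(fitted_at(xs))
    f[!is.finite(f) | f <= 0] <- 1
    v[, j] <- v[, j] / f
  }
  x$values <- v
  attr(x, "uncorrected") <- uncorrected
  x
}

#' Internal-standard (NOMIS) normalization
#'
#' Removes per-sample loading variation by regressing, on the log2 scale,
#' each analyte on the centered log2 internal-standard channels across
#' samples (ordinary least squares with intercept). The normalized value is
#' the residual plus the analyte's mean, mapped back to the intensity scale.
#' The standards themselves are removed from the returned analyte set.
#' Collinear standards are dropped (with a warning) via the QR decomposition.
#'
#' @param x a [metab_cohort()] with strictly positive, complete intensities
#'   (run after imputation).
#' @param standards metabolite ids of the internal standards; defaults to
#'   those flagged `is_internal_standard` in the metadata.
#' @return a [metab_cohort()] without the standard channels.
#' @export
nomis_normalize <- function(x, standards = NULL) {
  if (is.null(standards)) {
    standards <- x$metabolites$metabolite_id[x$metabolites$is_internal_standard]
  }
  if (!length(standards)) stop("NOMIS requires at least one internal standard", call. = FALSE)
  si <- match(standards, x$metabolites$metabolite_id)
  if (anyNA(si)) stop("unknown standard id: ", standards[is.na(si)][1], call. = FALSE)
  S <- log2(x$values[, si, drop = FALSE])
  if (anyNA(S)) stop("internal standards must be observed in every sample", call. = FALSE)
  Z <- scale(S, center = TRUE, scale = FALSE)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    drop_idx <- qrz$pivot[-seq_len(qrz$rank)]
    warning("dropping collinear internal standard(s): ",
            paste(standards[drop_idx], collapse = ", "))
    Z <- Z[, qrz$pivot[seq_len(qrz$rank)], drop = FALSE]
  }
  ai <- setdiff(seq_len(ncol(x$values)), si)
  Y <- log2(x$values[, ai, drop = FALSE])
  if (anyNA(Y)) stop("NOMIS requires complete values; impute first", call. = FALSE)
  cm <- colMeans(Y)
  Yc <- sweep(Y, 2L, cm)
  beta <- qr.coef(qr(Z), Yc)
  res <- Yc - Z %*% beta
  x$values[, ai] <- 2^sweep(res, 2L, cm, "+")
  cohort_subset(x, metabolites = ai)
}

#' Pooled-QC relative standard deviation audit
#'
#' RSD% = 100 * SD / mean per metabolite over the selected sample group,
#' using non-missing values only (at least two required). The returned
#' tibble carries the fractions of metabolites below 5%, 10% and 15% RSD
#' as the `summary` attribute.
#'
#' @param x a [metab_cohort()].
#' @param group sample group to audit (default pooled QCs).
#' @return tibble: `metabolite_id`, `n_used`, `rsd_pct`.
#' @export
compute_rsd <- function(x, group = "QC") {
  rows <- x$samples$group == group
  if (sum(rows) < 2L) stop("need at least 2 samples in group ", group, call. = FALSE)
  v <- x$values[rows, , drop = FALSE]
  n_used <- unname(colSums(!is.na(v)))
  m <- unname(colMeans(v, na.rm = TRUE))
  s <- unname(apply(v, 2L, stats::sd, na.rm = TRUE))
  rsd <- ifelse(n_used >= 2L & m != 0, 100 * s / m, NA_real_)
  out <- tibble::tibble(metabolite_id = x$metabolites$metabolite_id,
                        n_used = n_used, rsd_pct = rsd)
  ok <- !is.na(rsd)
  attr(out, "summary") <- tibble::tibble(
    threshold_pct = c(5, 10, 15),
    fraction_below = vapply(c(5, 10, 15),
                            function(t) mean(rsd[ok] < t), 0)
  )
  out
}

#' Full preprocessing chain
#'
#' Runs the canonical stage order: presence filter, QC-anchored drift
#' correction, k-nearest-neighbour imputation, NOMIS normalization — and
#' audits pooled-QC RSD before and after.
#'
#' @param x a raw [metab_cohort()].
#' @param threshold presence-filter cutoff.
#' @param drift_method `"rf"` or `"spline"` (see [qc_drift_correct()]).
#' @param k imputation neighbours.
#' @param impute_first run imputation before drift correction instead of
#'   after (both orders are defensible; the default corrects drift on the
#'   observed values so imputation sees drift-free data).
#' @param seed integer seed for the drift regressor.
#' @return list: `cohort` (preprocessed), `mask` (presence tibble),
#'   `rsd_before`, `rsd_after` (QC audits).
#' @export
preprocess_cohort <- function(x, threshold = 0.5,
                              drift_method = c("rf", "spline"),
                              k = 10L, impute_first = FALSE, seed = 1L) {
  drift_method <- match.arg(drift_method)
  x <- cohort_canonical_order(x)
  mask <- presence_filter(x, threshold)
  y <- apply_presence(x, mask)
  rsd_before <- compute_rsd(y)
  if (impute_first) {
    y <- knn_impute(y, k)
    y <- qc_drift_correct(y, drift_method, seed = seed)
  } else {
    y <- qc_drift_correct(y, drift_method, seed = seed)
    y <- knn_impute(y, k)
  }
  y <- nomis_normalize(y)
  list(cohort = y, mask = mask,
       rsd_before = rsd_before, rsd_after = compute_rsd(y))
}
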