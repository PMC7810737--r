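#' PCA / Mahalanobis outlier screen
#'
#' Samples are projected onto the first `n_components` principal components
#' (unit-variance scaled); the squared Mahalanobis distance of each score
#' vector is compared with the upper chi-square quantile, and flagged
#' samples are intended to be removed before OPLS-DA.
#'
#' @param X complete samples-by-variables matrix.
#' @param n_components principal components to keep.
#' @param alpha upper-tail probability of the chi-square cutoff.
#' @return tibble: `sample`, per-component scores, `mahalanobis_sq`,
#'   `outlier`.
#' @export
pca_outlier_screen <- function(X, n_components = 2L, alpha = 0.025) {
  X <- as.matrix(X)
  if (nrow(X) < n_components + 2L) stop("too few samples for the screen", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  if (n_components > sum(pc$sdev > 1e-10)) {
    stop("n_components exceeds the matrix rank", call. = FALSE)
  }
  sc <- pc$x[, seq_len(n_components), drop = FALSE]
  d2 <- stats::mahalanobis(sc, colMeans(sc), stats::cov(sc))
  cut <- stats::qchisq(1 - alpha, df = n_components)
  out <- tibble::as_tibble(sc)
  out <- dplyr::mutate(out,
                       sample = rownames(X) %||% as.character(seq_len(nrow(X))),
                       .before = 1L)
  out$mahalanobis_sq <- d2
  out$outlier <- d2 > cut
  out
}

# fold assignment: pairs stay together; without pairs, stratified by class
make_folds <- function(y, folds, pairs = NULL) {
  n <- length(y)
  fold_of <- integer(n)
  if (!is.null(pairs)) {
    u <- unique(pairs)
    fu <- rep(seq_len(folds), length.out = length(u))[sample.int(length(u))]
    fold_of <- fu[match(pairs, u)]
  } else {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold_of[idx] <- rep(seq_len(folds), length.out = length(idx))[sample.int(length(idx))]
    }
  }
  fold_of
}

#' Cross-validated predictive ability (Q2)
#'
#' Q2 = 1 - PRESS / SS of the centered class response, with PRESS
#' accumulated over held-out OPLS-DA predictions. Fold assignment keeps the
#' two members of a matched pair together (preventing leakage through
#' pair-level structure) and is otherwise stratified by class.
#'
#' @param X complete samples-by-variables matrix.
#' @param y two-class response.
#' @param n_ortho orthogonal components.
#' @param folds number of folds (default sevenfold; `folds = n` gives
#'   leave-one-out).
#' @param pairs optional pair ids aligned with rows of `X`.
#' @param seed integer seed for the fold assignment.
#' @param scaling passed to [fit_opls_da()].
#' @return Q2 (numeric scalar) with attribute `PRESS`.
#' @export
q2_cross_validate <- function(X, y, n_ortho = 1L, folds = 7L, pairs = NULL,
                              seed = 1L, scaling = "uv") {
  X <- as.matrix(X)
  yc <- code_class(y)
  if (folds < 2L || folds > nrow(X)) stop("folds must be in [2, n]", call. = FALSE)
  fold_of <- with_seed(stage_seed(seed, "cv-folds"),
                       make_folds(yc$y, folds, pairs))
  press <- 0
  yv <- yc$y - mean(yc$y)
  for (f in sort(unique(fold_of))) {
    test <- fold_of == f
    fit <- fit_opls_da(X[!test, , drop = FALSE], yc$y[!test],
                       n_ortho = n_ortho, scaling = scaling)
    pred <- predict(fit, X[test, , drop = FALSE])$yhat
    press <- press + sum((yc$y[test] - pred)^2)
  }
  q2 <- 1 - press / sum(yv^2)
  attr(q2, "PRESS") <- press
  q2
}

#' CV-ANOVA significance of an OPLS-DA model
#'
#' F-test of cross-validated prediction error against the total response
#' variation: F = ((SS_tot - PRESS)/df1) / (PRESS/df2) with df1 = 1 +
#' n_ortho (model components) and df2 = N - 1 - df1; the p-value is the
#' upper tail of the F distribution. The degrees-of-freedom convention is
#' recorded in the output.
#'
#' @inheritParams q2_cross_validate
#' @return one-row tibble: `F`, `df1`, `df2`, `p`, `PRESS`, `SS_tot`,
#'   `convention`.
#' @export
cv_anova <- function(X, y, n_ortho = 1L, folds = 7L, pairs = NULL,
                     seed = 1L, scaling = "uv") {
  yc <- code_class(y)
  q2 <- q2_cross_validate(X, yc$y, n_ortho = n_ortho, folds = folds,
                          pairs = pairs, seed = seed, scaling = scaling)
  press <- attr(q2, "PRESS")
  ss <- sum((yc$y - mean(yc$y))^2)
  df1 <- 1L + n_ortho
  df2 <- length(yc$y) - 1L - df1
  f <- max(0, ((ss - press) / df1) / (press / df2))
  tibble::tibble(F = f, df1 = df1, df2 = df2,
                 p = stats::pf(f, df1, df2, lower.tail = FALSE),
                 PRESS = press, SS_tot = ss,
                 convention = "df1 = 1 + n_ortho; df2 = N - 1 - df1")
}

#' Response-permutation validation of an OPLS-DA model
#'
#' The class labels are permuted `n_perm` times (matched-pair structure
#' deliberately broken), the model is refit each time, and empirical
#' p-values for R2Y and Q2 use the (1 + exceedances) / (1 + n_perm)
#' estimator.
#'
#' @inheritParams q2_cross_validate
#' @param n_perm number of permutations.
#' @return list: `pR2Y`, `pQ2`, `observed` (R2Y, Q2), `permuted`
#'   (tibble of permuted R2Y/Q2), `n_perm`.
#' @export
permutation_validate <- function(X, y, n_ortho = 1L, n_perm = 1000L,
                                 folds = 7L, pairs = NULL, seed = 1L,
                                 scaling = "uv") {
  X <- as.matrix(X)
  yc <- code_class(y)
  obs_fit <- fit_opls_da(X, yc$y, n_ortho = n_ortho, scaling = scaling)
  obs_q2 <- as.numeric(q2_cross_validate(X, yc$y, n_ortho, folds, pairs,
                                         seed = seed, scaling = scaling))
  perm <- with_seed(stage_seed(seed, "permutation"),
    purrr::map_dfr(seq_len(n_perm), function(i) {
      yp <- sample(yc$y)
      fit <- fit_opls_da(X, yp, n_ortho = n_ortho, scaling = scaling)
      q2p <- as.numeric(q2_cross_validate(X, yp, n_ortho, folds, pairs,
                                          seed = seed + i, scaling = scaling))
      tibble::tibble(R2Y = fit$R2Y, Q2 = q2p)
    }))
  list(
    pR2Y = (1 + sum(perm$R2Y >= obs_fit$R2Y)) / (1 + n_perm),
    pQ2 = (1 + sum(perm$Q2 >= obs_q2)) / (1 + n_perm),
    observed = c(R2Y = obs_fit$R2Y, Q2 = obs_q2),
    permuted = perm,
    n_perm = n_perm
  )
}

#' Cross-validated SVM classification of a metabolite panel
#'
#' Fits a linear-kernel support vector machine on the selected panel with
#' leave-pair-out cross-validation by default (features standardized inside
#' each training fold), pools the held-out decision values into a single
#' ROC curve, and reports the trapezoid AUC. Each fold's decision values are
#' oriented by the training data so the positive class scores higher.
#'
#' @param X complete samples-by-variables matrix.
#' @param y two-class response (second factor level / larger numeric value
#'   is the positive class).
#' @param panel variable (column) names to use as predictors.
#' @param pairs optional pair ids; when given, folds are leave-pair-out.
#' @param folds fold count when `pairs` is `NULL`.
#' @param cost SVM regularization constant.
#' @param seed integer seed for fold assignment.
#' @return a `panel_classifier`: list with `panel`, `auc` (0-100 scale),
#'   `roc` (tibble of specificity/sensitivity points), `decision` tibble.
#' @export
svm_panel_auc <- function(X, y, panel, pairs = NULL, folds = 7L,
                          cost = 1, seed = 1L) {
  X <- as.matrix(X)
  miss <- setdiff(panel, colnames(X))
  if (length(miss)) stop("panel variable not in X: ", miss[1], call. = FALSE)
  Xp <- X[, panel, drop = FALSE]
  yc <- code_class(y)
  yf <- factor(yc$y, levels = c(-1, 1))
  fold_of <- with_seed(stage_seed(seed, "svm-folds"),
                       if (!is.null(pairs)) match(pairs, unique(pairs))
                       else make_folds(yc$y, folds))
  dec <- numeric(length(yf))
  for (f in sort(unique(fold_of))) {
    test <- fold_of == f
    fit <- e1071::svm(Xp[!test, , drop = FALSE], yf[!test],
                      kernel = "linear", cost = cost, scale = TRUE)
    dtr <- drop(attr(stats::predict(fit, Xp[!test, , drop = FALSE],
                                    decision.values = TRUE), "decision.values"))
    flip <- mean(dtr[yf[!test] == "1"]) < mean(dtr[yf[!test] == "-1"])
    dte <- drop(attr(stats::predict(fit, Xp[test, , drop = FALSE],
                                    decision.values = TRUE), "decision.values"))
    dec[test] <- if (flip) -dte else dte
  }
  roc <- pROC::roc(response = yf, predictor = dec,
                   levels = c("-1", "1"), direction = "<", quiet = TRUE)
  structure(list(
    panel = panel,
    auc = 100 * as.numeric(pROC::auc(roc)),
    roc = tibble::tibble(specificity = roc$specificities,
                         sensitivity = roc$sensitivities),
    decision = tibble::tibble(class = yc$levels[(yc$y > 0) + 1L],
                              decision_value = dec),
    scheme = if (is.null(pairs)) sprintf("%d-fold CV", folds) else "leave-pair-out CV"
  ), class = "panel_classifier")
}

#' @export
print.panel_classifier <- function(x, ...) {
  cat("<panel_classifier> ", length(x$panel), " predictors, ", x$scheme,
      sprintf(", AUC = %.2f%%\n", x$auc), sep = "")
  invisible(x)
}

#' ROC curve plot for a panel classifier
#'
#' @param object a `panel_classifier` from [svm_panel_auc()].
#' @param ... unused.
#' @return a ggplot ROC curve annotated with the AUC.
#' @method autoplot panel_classifier
#' @export
autoplot.panel_classifier <- function(object, ...) {
  df <- object$roc[order(1 - object$roc$specificity, object$roc$sensitivity), ]
  ggplot2::ggplot(df, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.2f%%", object$auc)) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}
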