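scale_spec <- function(X, scaling = c("uv", "pareto", "center")) {
  scaling <- match.arg(scaling)
  ctr <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  scl <- switch(scaling, uv = sdv, pareto = sqrt(sdv), center = rep(1, ncol(X)))
  keep <- scl > 0 | scaling == "center"
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl, keep = keep, scaling = scaling)
}

apply_scale <- function(X, sp) {
  sweep(sweep(X, 2L, sp$center), 2L, sp$scale, "/")[, sp$keep, drop = FALSE]
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures for a two-class response:
#' variation in X orthogonal to the class axis is estimated and deflated
#' component by component (w proportional to X'y; w_o the part of the X
#' loading orthogonal to w; deflation X <- X - t_o p_o'), after which a
#' single predictive component is extracted from the filtered matrix.
#' X is centered and unit-variance scaled internally by default.
#'
#' @param X numeric samples-by-variables matrix (complete).
#' @param y two-class response: a factor, or numeric +/-1 coding.
#' @param n_ortho number of orthogonal components.
#' @param scaling `"uv"` (unit variance), `"pareto"` or `"center"`.
#' @return an `opls_model` with scores/loadings/weights for the predictive
#'   and orthogonal parts, `R2X`, `R2Y`, and per-variable `VIP`.
#' @export
fit_opls_da <- function(X, y, n_ortho = 1L, scaling = "uv") {
  X <- as.matrix(X)
  yc <- code_class(y)
  if (nrow(X) != length(yc$y)) stop("X rows must match y length", call. = FALSE)
  if (n_ortho >= min(nrow(X), ncol(X)) - 1L) {
    stop("n_ortho too large for the matrix rank", call. = FALSE)
  }
  sp <- scale_spec(X, scaling)
  if (any(!sp$keep)) warning("dropping constant column(s): ",
                             paste(colnames(X)[!sp$keep], collapse = ", "))
  Xs <- apply_scale(X, sp)
  yv <- yc$y - mean(yc$y)
  ssx_tot <- sum(Xs^2)
  ssy_tot <- sum(yv^2)
  J <- ncol(Xs)
  W_o <- P_o <- matrix(0, J, 0)
  T_o <- matrix(0, nrow(Xs), 0)
  Xd <- Xs
  for (i in seq_len(n_ortho)) {
    w <- crossprod(Xd, yv)
    w <- w / sqrt(sum(w^2))
    tt <- Xd %*% w
    p <- crossprod(Xd, tt) / sum(tt^2)
    w_o <- p - as.numeric(crossprod(w, p)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) stop("no orthogonal variation left at component ", i, call. = FALSE)
    w_o <- w_o / nw
    t_o <- Xd %*% w_o
    p_o <- crossprod(Xd, t_o) / sum(t_o^2)
    Xd <- Xd - t_o %*% t(p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
  }
  w <- crossprod(Xd, yv)
  w <- w / sqrt(sum(w^2))
  tt <- Xd %*% w
  p <- crossprod(Xd, tt) / sum(tt^2)
  q <- as.numeric(crossprod(yv, tt) / sum(tt^2))
  r2y <- 1 - sum((yv - tt * q)^2) / ssy_tot
  ss_pred <- sum(tt^2) * sum(p^2)
  ss_orth <- if (ncol(T_o)) sum(colSums(T_o^2) * colSums(P_o^2)) else 0
  model <- structure(list(
    weights = drop(w), loadings = drop(p), q = q, scores = drop(tt),
    W_o = W_o, P_o = P_o, T_o = T_o, n_ortho = n_ortho,
    center = sp$center, scale = sp$scale, keep = sp$keep, scaling = sp$scaling,
    y_mean = mean(yc$y), y = yc$y, levels = yc$levels,
    R2X = (ss_pred + ss_orth) / ssx_tot, R2Y = r2y,
    variable = colnames(Xs) %||% paste0("V", seq_len(J))
  ), class = "opls_model")
  model$VIP <- vip_scores(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

code_class <- function(y) {
  if (is.numeric(y)) {
    u <- sort(unique(y))
    if (!length(u) %in% c(1L, 2L)) stop("y must be two-class", call. = FALSE)
    return(list(y = ifelse(y == max(u), 1, -1),
                levels = as.character(u)))
  }
  f <- factor(y)
  if (nlevels(f) != 2L) stop("y must be two-class", call. = FALSE)
  list(y = ifelse(f == levels(f)[2L], 1, -1), levels = levels(f))
}

#' Predict from an OPLS-DA model
#'
#' New samples are scaled with the training parameters, orthogonal variation
#' is removed component by component, and the predictive score is mapped to
#' the class axis.
#'
#' @param object an `opls_model`.
#' @param newdata samples-by-variables matrix with the training columns.
#' @param ... unused.
#' @return list with `score` (predictive score) and `yhat` (continuous
#'   class-axis prediction; sign separates the classes).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xn <- apply_scale(as.matrix(newdata), object)
  if (ncol(object$W_o)) {
    for (i in seq_len(ncol(object$W_o))) {
      t_o <- Xn %*% object$W_o[, i]
      Xn <- Xn - t_o %*% t(object$P_o[, i])
    }
  }
  score <- drop(Xn %*% object$weights)
  list(score = score, yhat = score * object$q + object$y_mean)
}

#' Variable importance in projection
#'
#' VIP_j = sqrt(J * sum_a(w_ja^2 SSY_a) / sum_a SSY_a) over the predictive
#' component(s); orthogonal components can be included but by default the
#' class-discriminating (predictive) part alone is scored, so mean(VIP^2)
#' is exactly 1.
#'
#' @param model an `opls_model`.
#' @param include_orthogonal also weight the orthogonal components by their
#'   explained X variation.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model, include_orthogonal = FALSE) {
  J <- length(model$weights)
  W <- cbind(model$weights)
  yv <- model$y - model$y_mean
  ssy <- sum((model$scores * model$q)^2)
  ssya <- ssy
  if (include_orthogonal && ncol(model$W_o)) {
    W <- cbind(W, model$W_o)
    ssya <- c(ssya, colSums(model$T_o^2) * 0)  # orthogonal parts carry no Y variance
    ssxa <- c(sum(model$scores^2) * sum(model$loadings^2), colSums(model$T_o^2) * colSums(model$P_o^2))
    ssya <- ssxa  # weight by explained X variation instead
  }
  num <- rowSums(sweep(W^2, 2L, ssya, "*"))
  stats::setNames(sqrt(J * num / sum(ssya)), model$variable)
}

#' @export
print.opls_model <- function(x, ...) {
  cat("<opls_model> 1 predictive + ", x$n_ortho, " orthogonal component(s), ",
      length(x$weights), " variables\n", sep = "")
  cat(sprintf("  R2X = %.3f  R2Y = %.3f\n", x$R2X, x$R2Y))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an OPLS-DA model
#'
#' @param x an `opls_model`.
#' @param ... unused.
#' @return tibble with one row per variable: predictive weight, loading and
#'   VIP score.
#' @method tidy opls_model
#' @export
tidy.opls_model <- function(x, ...) {
  tibble::tibble(variable = x$variable,
                 weight = unname(x$weights),
                 loading = unname(x$loadings),
                 VIP = unname(x$VIP))
}

#' One-row summary of an OPLS-DA model
#'
#' @param x an `opls_model`.
#' @param ... unused.
#' @return tibble: `n_ortho`, `R2X`, `R2Y`, and `Q2` when attached by
#'   [q2_cross_validate()].
#' @method glance opls_model
#' @export
glance.opls_model <- function(x, ...) {
  tibble::tibble(n_ortho = x$n_ortho, R2X = x$R2X, R2Y = x$R2Y,
                 Q2 = attr(x, "Q2") %||% NA_real_)
}

#' Score-plot data / plot for an OPLS-DA model
#'
#' @param object an `opls_model`.
#' @param ... unused.
#' @return a ggplot: predictive score against the first orthogonal score
#'   (or sample index when no orthogonal component exists), colored by class.
#' @method autoplot opls_model
#' @export
autoplot.opls_model <- function(object, ...) {
  df <- tibble::tibble(
    t_pred = object$scores,
    t_ortho = if (ncol(object$T_o)) object$T_o[, 1L] else seq_along(object$scores),
    class = object$levels[(object$y > 0) + 1L]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t_pred, .data$t_ortho,
                                   colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::stat_ellipse() +
    ggplot2::labs(x = "predictive score t[1]",
                  y = if (ncol(object$T_o)) "orthogonal score to[1]" else "sample index",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
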