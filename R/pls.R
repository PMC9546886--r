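#' @name pls
#' @title PLS-DA and OPLS-DA by NIPALS
#'
#' @description
#' `fit_plsda()` fits a partial least squares discriminant model to a binary
#' outcome by NIPALS with deflation (tolerance 1e-10, max 500 iterations).
#' `fit_oplsda()` first extracts `n_orth` components of X variation that are
#' exactly uncorrelated with the class, then fits the single predictive
#' component on the filtered matrix; with `n_orth = 0` it reproduces
#' one-component PLS exactly.  The predictive score is oriented so that its
#' correlation with the class is non-negative.
#'
#' The class vector may be a factor/character (the `"post"` or alphabetically
#' later level is coded +1) or numeric in \{0,1\}/\{-1,+1\}; it is centred
#' internally.  X should already be scaled as appropriate (see
#' [scale_columns()]); it is mean-centred internally and the centring is
#' reapplied on prediction.
NULL

# class vector -> centred numeric +-1, remembering the positive level
code_class <- function(y) {
  if (is.character(y) || is.factor(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2) abort("`y` must contain exactly two classes.")
    pos <- if ("post" %in% lev) "post" else lev[2]
    yy <- ifelse(as.character(y) == pos, 1, -1)
  } else {
    lev <- sort(unique(y))
    if (length(lev) != 2) abort("`y` must contain exactly two classes.")
    pos <- lev[2]
    yy <- ifelse(y == pos, 1, -1)
  }
  list(y = yy, positive = pos)
}

as_x_matrix <- function(x) {
  if (is.data.frame(x)) feature_values(as_feature_table(x)) else {
    m <- as.matrix(x); storage.mode(m) <- "double"; m
  }
}

# core NIPALS PLS on a centred matrix and centred y (single column)
nipals_pls <- function(Xc, yc, ncomp, tol = 1e-10, maxit = 500) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); cvec <- numeric(ncomp)
  ssx0 <- sum(Xc^2); ssy0 <- sum(yc^2)
  X <- Xc; y <- yc
  r2x_comp <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    u <- y
    w_old <- rep(0, p)
    for (it in seq_len(maxit)) {
      w <- crossprod(X, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps) abort("degenerate component: X carries no class-related variation.")
      w <- w / nw
      tt <- as.vector(X %*% w)
      cc <- sum(tt * y) / sum(tt^2)
      u_new <- y * cc  # single-column y: converges immediately
      if (sqrt(sum((w - w_old)^2)) < tol) break
      w_old <- w
      u <- u_new
    }
    if (sum(tt * y) < 0) { w <- -w; tt <- -tt; cc <- -cc }  # orient to class
    pp <- crossprod(X, tt)[, 1] / sum(tt^2)
    X <- X - tcrossprod(tt, pp)
    y <- y - tt * cc
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; cvec[a] <- cc
    r2x_comp[a] <- sum(tcrossprod(tt, pp)^2) / ssx0
  }
  b <- as.vector(W %*% solve(crossprod(P, W), cvec))
  fitted <- as.vector(Xc %*% b)
  list(W = W, P = P, T = Tm, C = cvec, b = b,
       R2X = sum(r2x_comp), R2X_comp = r2x_comp,
       R2Y = 1 - sum((yc - fitted)^2) / ssy0)
}

#' @rdname pls
#' @param x feature tibble (first column `sample`) or numeric matrix, already
#'   scaled; centred internally.
#' @param y binary class vector, one entry per sample.
#' @param n_components number of PLS components.
#' @return `fit_plsda()` returns an object of class `pls_model` with weights
#'   `W`, loadings `P`, scores `T`, y-loadings `C`, coefficients `b`,
#'   `R2X`/`R2Y` and centring information; `fit_oplsda()` an `opls_model`
#'   with predictive (`t_p`, `p_p`, `w_p`) and orthogonal (`T_o`, `P_o`,
#'   `W_o`) parts.
#' @export
fit_plsda <- function(x, y, n_components = 1) {
  X <- as_x_matrix(x)
  n_components <- check_count(n_components, "n_components")
  cls <- code_class(y)
  if (length(cls$y) != nrow(X)) abort("`y` must have one entry per sample.")
  x_means <- colMeans(X)
  Xc <- sweep(X, 2, x_means)
  rk <- qr(Xc)$rank
  if (n_components > rk) abort(sprintf("n_components (%d) exceeds rank(X) = %d.", n_components, rk))
  y_mean <- mean(cls$y)
  fit <- nipals_pls(Xc, cls$y - y_mean, n_components)
  structure(c(fit, list(n_components = n_components, x_means = x_means,
                        y_mean = y_mean, positive = cls$positive,
                        feature_ids = colnames(X))),
            class = "pls_model")
}

#' @rdname pls
#' @param n_orth number of orthogonal components (OPLS).
#' @export
fit_oplsda <- function(x, y, n_orth = 1) {
  X <- as_x_matrix(x)
  n_orth <- check_count(n_orth, "n_orth", min = 0)
  cls <- code_class(y)
  if (length(cls$y) != nrow(X)) abort("`y` must have one entry per sample.")
  x_means <- colMeans(X)
  Xc <- sweep(X, 2, x_means)
  rk <- qr(Xc)$rank
  if (n_orth >= rk) abort(sprintf("n_orth (%d) must be < rank(X) = %d.", n_orth, rk))
  yc <- cls$y - mean(cls$y)
  ssx0 <- sum(Xc^2)

  w <- crossprod(Xc, yc)[, 1] / sum(yc^2)
  w <- w / sqrt(sum(w^2))
  p <- ncol(Xc)
  W_o <- matrix(0, p, n_orth); P_o <- matrix(0, p, n_orth)
  T_o <- matrix(0, nrow(Xc), n_orth)
  r2x_orth <- numeric(n_orth)
  Xf <- Xc
  for (k in seq_len(n_orth)) {
    tt <- as.vector(Xf %*% w)
    pp <- crossprod(Xf, tt)[, 1] / sum(tt^2)
    wo <- pp - sum(w * pp) * w
    nw <- sqrt(sum(wo^2))
    if (nw < 1e-12) abort("no orthogonal variation left to extract.")
    wo <- wo / nw
    to <- as.vector(Xf %*% wo)
    po <- crossprod(Xf, to)[, 1] / sum(to^2)
    Xf <- Xf - tcrossprod(to, po)
    W_o[, k] <- wo; P_o[, k] <- po; T_o[, k] <- to
    r2x_orth[k] <- sum(tcrossprod(to, po)^2) / ssx0
  }
  pred <- nipals_pls(Xf, yc, 1)
  structure(list(
    w_p = pred$W[, 1], p_p = pred$P[, 1], t_p = pred$T[, 1], c_p = pred$C[1],
    b = pred$b, W_o = W_o, P_o = P_o, T_o = T_o, n_orth = n_orth,
    R2X_comp = c(pred = sum(tcrossprod(pred$T[, 1], pred$P[, 1])^2) / ssx0,
                 orth = r2x_orth),
    R2X = sum(tcrossprod(pred$T[, 1], pred$P[, 1])^2) / ssx0 + sum(r2x_orth),
    R2Y = pred$R2Y,
    x_means = x_means, y_mean = mean(cls$y), positive = cls$positive,
    feature_ids = colnames(X)
  ), class = "opls_model")
}

#' Predict scores and class values from a fitted (O)PLS-DA model
#'
#' @param object a `pls_model` or `opls_model`.
#' @param newdata feature tibble or matrix with the model's features.
#' @param ... unused.
#' @return list with `scores` (predictive score(s)) and `y_hat` (continuous
#'   class prediction on the centred +-1 scale plus the training class mean).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as_x_matrix(newdata)
  Xc <- sweep(X, 2, object$x_means)
  list(scores = Xc %*% object$W,
       y_hat = as.vector(Xc %*% object$b) + object$y_mean)
}

#' @rdname predict.pls_model
#' @export
predict.opls_model <- function(object, newdata, ...) {
  X <- as_x_matrix(newdata)
  Xc <- sweep(X, 2, object$x_means)
  for (k in seq_len(object$n_orth)) {
    to <- as.vector(Xc %*% object$W_o[, k])
    Xc <- Xc - tcrossprod(to, object$P_o[, k])
  }
  list(scores = as.vector(Xc %*% object$w_p),
       y_hat = as.vector(Xc %*% object$b) + object$y_mean)
}

# fold assignment: venetian blinds over units (samples, or subjects when
# grouping is supplied); reshuffled with bounded retries if a training fold
# lacks a class.
assign_folds <- function(y, folds, grouping = NULL, seed = NULL, max_retry = 20) {
  n <- length(y)
  grouping <- as.character(grouping %||% seq_len(n))
  units <- unique(grouping)
  if (folds < 2 || folds > length(units)) abort("`folds` must be between 2 and the number of units.")
  ord <- units
  for (retry in 0:max_retry) {
    unit_fold <- stats::setNames(((seq_along(ord) - 1L) %% folds) + 1L, ord)
    fold <- unname(unit_fold[grouping])
    ok <- all(vapply(seq_len(folds), function(f) length(unique(y[fold != f])) == 2, logical(1)))
    if (ok) return(fold)
    if (is.null(seed)) abort("a fold left one class absent; supply `seed` to allow re-stratification.")
    set.seed(seed + retry)
    ord <- sample(units)
  }
  abort("could not build folds with both classes in every training set.")
}

#' Cross-validated predictive ability (Q2Y)
#'
#' Splits units (samples, or whole subjects when `grouping` is given) into
#' `folds` venetian-blind folds, refits the model on each training set and
#' accumulates Q2Y = 1 - PRESS/TSS over held-out predictions.
#'
#' @param x feature tibble or matrix (scaled).
#' @param y binary class vector.
#' @param model_spec list: `method` (`"pls"` or `"opls"`), `n_components`,
#'   `n_orth`.
#' @param folds number of folds (default 7).
#' @param grouping optional subject id per sample; all samples of a subject
#'   share a fold.
#' @param seed used only to reshuffle units if a fold lacks a class.
#' @return object of class `cv_result`: `q2y`, per-fold `press`, `tss`,
#'   `fold` assignment.
#' @export
cross_validate_q2 <- function(x, y, model_spec = list(method = "pls", n_components = 1),
                              folds = 7, grouping = NULL, seed = NULL) {
  X <- as_x_matrix(x)
  cls <- code_class(y)
  yy <- cls$y
  fold <- assign_folds(yy, folds, grouping, seed)
  press <- numeric(folds); tss <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    fit <- if (identical(model_spec$method, "opls")) {
      fit_oplsda(X[tr, , drop = FALSE], yy[tr], n_orth = model_spec$n_orth %||% 1)
    } else {
      fit_plsda(X[tr, , drop = FALSE], yy[tr], n_components = model_spec$n_components %||% 1)
    }
    yhat <- predict(fit, X[te, , drop = FALSE])$y_hat
    press[f] <- sum((yy[te] - yhat)^2)
    tss[f] <- sum((yy[te] - mean(yy[tr]))^2)
  }
  structure(list(q2y = 1 - sum(press) / sum(tss), press = press, tss = tss,
                 fold = fold, folds = folds),
            class = "cv_result")
}

#' Jackknifed coefficient inference for (O)PLS-DA
#'
#' Computes per-feature correlation loadings (Pearson correlation of each
#' feature with the predictive score of the full-data model) and jackknife
#' 95% confidence intervals of the regression coefficients from refits over
#' cross-validation segments.  A feature is selected iff its |correlation
#' loading| exceeds `r_threshold` (strict) *and* its confidence interval
#' excludes zero.
#'
#' @inheritParams cross_validate_q2
#' @param r_threshold correlation-loading threshold (default 0.35, applied to
#'   |r|).
#' @param segments number of jackknife segments (default 7, >= 2).
#' @return tibble: `feature`, `coefficient`, `r`, `lo`, `hi`, `selected`.
#' @export
coefficient_inference <- function(x, y, model_spec = list(method = "opls", n_orth = 1),
                                  r_threshold = 0.35, segments = 7,
                                  grouping = NULL, seed = NULL) {
  if (segments < 2) abort("`segments` must be >= 2.")
  X <- as_x_matrix(x)
  cls <- code_class(y)
  yy <- cls$y
  fit_one <- function(Xs, ys) {
    if (identical(model_spec$method, "opls")) {
      fit_oplsda(Xs, ys, n_orth = model_spec$n_orth %||% 1)
    } else {
      fit_plsda(Xs, ys, n_components = model_spec$n_components %||% 1)
    }
  }
  full <- fit_one(X, yy)
  t_p <- if (inherits(full, "opls_model")) full$t_p else full$T[, 1]
  r <- suppressWarnings(as.vector(stats::cor(X, t_p)))
  r[is.na(r)] <- 0  # constant features carry no loading
  fold <- assign_folds(yy, segments, grouping, seed)
  B <- matrix(0, ncol(X), segments)
  for (f in seq_len(segments)) {
    B[, f] <- fit_one(X[fold != f, , drop = FALSE], yy[fold != f])$b
  }
  bbar <- rowMeans(B)
  se <- sqrt((segments - 1) / segments * rowSums((B - bbar)^2))
  tq <- stats::qt(0.975, segments - 1)
  lo <- full$b - tq * se
  hi <- full$b + tq * se
  tibble(
    feature = colnames(X) %||% paste0("feature", seq_len(ncol(X))),
    coefficient = full$b, r = r, lo = lo, hi = hi,
    selected = abs(r) > r_threshold & (lo > 0 | hi < 0)
  )
}

#' @export
tidy.pls_model <- function(x, ...) {
  tibble(feature = x$feature_ids %||% paste0("feature", seq_along(x$b)),
         coefficient = x$b,
         weight_1 = x$W[, 1], loading_1 = x$P[, 1])
}

#' @export
tidy.opls_model <- function(x, ...) {
  tibble(feature = x$feature_ids %||% paste0("feature", seq_along(x$b)),
         coefficient = x$b, weight_pred = x$w_p, loading_pred = x$p_p)
}

#' @export
glance.pls_model <- function(x, ...) {
  tibble(r2x = x$R2X, r2y = x$R2Y, n_components = x$n_components)
}

#' @export
glance.opls_model <- function(x, ...) {
  tibble(r2x = x$R2X, r2y = x$R2Y, n_orth = x$n_orth)
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble(q2y = x$q2y, folds = x$folds)
}
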