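#' Within-subject (multilevel) transform
#'
#' Replaces each sample row by its deviation from the subject mean row.  For
#' a complete two-timepoint design each subject's pre and post rows become
#' exact negatives of each other, isolating the paired intervention effect.
#' Subjects missing a timepoint are dropped with a warning.  The transform is
#' idempotent.
#'
#' @param table feature tibble.
#' @param design paired design tibble describing every sample.
#' @return list with `table` (transformed feature tibble, complete subjects
#'   only) and `design` (matching design rows).
#' @export
within_subject_transform <- function(table, design) {
  table <- as_feature_table(table)
  design <- validate_design(design, table)
  design <- design[match(table$sample, design$sample), ]
  counts <- table(design$subject)
  complete <- names(counts)[counts == 2]
  dropped <- setdiff(design$subject, complete)
  if (length(dropped)) {
    warn(sprintf("dropping incomplete subject(s): %s", paste(unique(dropped), collapse = ", ")))
  }
  if (!length(complete)) abort("no subject has both timepoints.")
  keep <- design$subject %in% complete
  x <- feature_values(table)[keep, , drop = FALSE]
  design <- design[keep, ]
  subj_means <- rowsum(x, design$subject) / 2
  x <- x - subj_means[design$subject, , drop = FALSE]
  list(table = rebuild_feature_table(x, template = table), design = design)
}

#' Residualise features on covariates
#'
#' Replaces each feature column by its least-squares residual on an intercept
#' plus the supplied covariate columns.
#'
#' @param table feature tibble.
#' @param covariates data frame with a `sample` column and numeric covariate
#'   columns (aligned by sample id), or a numeric matrix in row order.
#' @return the adjusted feature tibble (columns centred by construction).
#' @export
covariate_adjust <- function(table, covariates) {
  table <- as_feature_table(table)
  x <- feature_values(table)
  if (is.data.frame(covariates)) {
    covariates <- as_tibble(covariates)
    if ("sample" %in% names(covariates)) {
      idx <- match(table$sample, covariates$sample)
      if (anyNA(idx)) abort("every sample needs a covariate row.")
      covariates <- covariates[idx, setdiff(names(covariates), "sample"), drop = FALSE]
    }
    covariates <- as.matrix(covariates)
  }
  Z <- cbind(`(Intercept)` = 1, covariates)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    bad <- colnames(Z)[qz$pivot[(qz$rank + 1):ncol(Z)]]
    abort(sprintf("covariate matrix is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  res <- qr.resid(qz, x)
  rebuild_feature_table(res, template = table)
}

# fast one-component PLS on a centred matrix / centred y; returns weights,
# coefficients and fit statistics only (hot loop of the MCCV engine)
pls1_fast <- function(Xc, yc) {
  w <- crossprod(Xc, yc)[, 1]
  nw <- sqrt(sum(w^2))
  if (nw < .Machine$double.eps) return(NULL)
  w <- w / nw
  tt <- as.vector(Xc %*% w)
  stt <- sum(tt^2)
  cc <- sum(tt * yc) / stt
  pp <- crossprod(Xc, tt)[, 1] / stt
  b <- w * (cc / sum(pp * w))
  list(w = w, t = tt, c = cc, p = pp, b = b,
       r2x = sum(tcrossprod(tt, pp)^2) / sum(Xc^2),
       r2y = 1 - sum((yc - tt * cc)^2) / sum(yc^2))
}

#' Repeated-measures Monte-Carlo cross-validated PLS-DA
#'
#' The package's central inference engine for paired designs.  The feature
#' table is within-subject transformed (idempotent, so pre-transformed input
#' is safe), optionally residualised on covariates, then centred and
#' unit-variance scaled.  For each of `n_models` Monte-Carlo iterations,
#' subjects are split into training and test sets (`test_fraction` of
#' subjects held out); a one-predictive-component PLS-DA is fitted on the
#' training samples, oriented so the post-class training score mean is
#' positive, and the held-out samples are projected to accumulate their
#' cross-validated predictive scores (T_pred).  Within each iteration,
#' `n_boot` bootstrap resamples of the training subjects are refitted to
#' collect regression-coefficient draws.  Per-feature p-values come from a
#' two-sided normal tail of mean(beta draws)/sd(beta draws) pooled over all
#' `n_models * n_boot` draws; q-values are Benjamini-Hochberg.
#'
#' @param table feature tibble (raw or already within-subject transformed).
#' @param design paired design; the pre/post timepoint is the class.
#' @param n_models Monte-Carlo iterations (study default 1000).
#' @param n_boot bootstrap resamples per iteration (study default 25).
#' @param test_fraction fraction of subjects held out per iteration, in
#'   (0, 1) (default 0.3).
#' @param q_threshold significance level on q (default 0.01).
#' @param covariate_names optional covariate columns of `design` to
#'   residualise on before modelling.
#' @param seed integer seed; identical seed and inputs give identical
#'   results.
#' @return object of class `rm_mccv`: `$samples` (sample, subject,
#'   timepoint, tpred_mean, tpred_var, inclusions), `$features` (feature,
#'   beta, beta_var, p, q), `$stats` (mean_r2x, mean_q2y over iterations) and
#'   `$params`.
#' @export
run_rm_mccv_plsda <- function(table, design, n_models = 1000, n_boot = 25,
                              test_fraction = 0.3, q_threshold = 0.01,
                              covariate_names = NULL, seed = 1) {
  n_models <- check_count(n_models, "n_models")
  n_boot <- check_count(n_boot, "n_boot")
  if (test_fraction <= 0 || test_fraction >= 1) abort("`test_fraction` must be in (0, 1).")
  ml <- within_subject_transform(table, design)
  design <- ml$design
  if (!is.null(covariate_names)) {
    miss <- setdiff(covariate_names, names(design))
    if (length(miss)) abort(sprintf("unknown covariate(s): %s", paste(miss, collapse = ", ")))
    ml$table <- covariate_adjust(ml$table, design[c("sample", covariate_names)])
  }
  scaled <- scale_columns(ml$table, method = "unit_variance")
  X <- feature_values(scaled)
  yy <- ifelse(design$timepoint == "post", 1, -1)
  subjects <- unique(design$subject)
  ns <- length(subjects)
  if (ns < 6) abort("at least 6 complete subjects are required.")
  n_test <- max(1L, round(test_fraction * ns))
  if (n_test >= ns) n_test <- ns - 1L
  subj_rows <- lapply(subjects, function(s) which(design$subject == s))
  names(subj_rows) <- subjects
  p <- ncol(X)

  tp_sum <- tp_sumsq <- numeric(nrow(X))
  tp_n <- integer(nrow(X))
  beta_sum <- beta_sumsq <- numeric(p)
  n_draws <- 0L
  r2x <- q2y <- numeric(n_models)
  seeds <- split_seed(seed, n_models)

  for (i in seq_len(n_models)) {
    set.seed(seeds[i])
    fit <- NULL
    for (retry in 1:20) {
      test_subj <- sample(subjects, n_test)
      tr <- !(design$subject %in% test_subj)
      ytr <- yy[tr]
      if (length(unique(ytr)) < 2) next
      Xtr <- X[tr, , drop = FALSE]
      mu <- colMeans(Xtr)
      Xtr <- sweep(Xtr, 2, mu)
      ym <- mean(ytr)
      fit <- pls1_fast(Xtr, ytr - ym)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) abort("could not draw a training split with both classes.")
    # orient scores so the post class has positive mean training score
    s <- if (mean(fit$t[ytr > 0]) >= mean(fit$t[ytr < 0])) 1 else -1
    te <- which(!tr)
    Xte <- sweep(X[te, , drop = FALSE], 2, mu)
    t_test <- s * as.vector(Xte %*% fit$w)
    tp_sum[te] <- tp_sum[te] + t_test
    tp_sumsq[te] <- tp_sumsq[te] + t_test^2
    tp_n[te] <- tp_n[te] + 1L
    yhat <- as.vector(Xte %*% fit$b) + ym
    q2y[i] <- 1 - sum((yy[te] - yhat)^2) / sum((yy[te] - ym)^2)
    r2x[i] <- fit$r2x

    tr_subjects <- setdiff(subjects, test_subj)
    for (bdraw in seq_len(n_boot)) {
      bs <- sample(tr_subjects, length(tr_subjects), replace = TRUE)
      rows <- unlist(subj_rows[bs], use.names = FALSE)
      Xb <- X[rows, , drop = FALSE]
      yb <- yy[rows]
      bf <- pls1_fast(sweep(Xb, 2, colMeans(Xb)), yb - mean(yb))
      if (is.null(bf)) next
      beta_sum <- beta_sum + bf$b
      beta_sumsq <- beta_sumsq + bf$b^2
      n_draws <- n_draws + 1L
    }
  }

  beta_mean <- beta_sum / n_draws
  beta_var <- beta_sumsq / n_draws - beta_mean^2
  beta_var[beta_var < 0] <- 0
  zstat <- ifelse(beta_var > 0, beta_mean / sqrt(beta_var), 0)
  pval <- 2 * stats::pnorm(-abs(zstat))
  qval <- benjamini_hochberg(pval)

  tpred_mean <- ifelse(tp_n > 0, tp_sum / tp_n, NA_real_)
  tpred_var <- ifelse(tp_n > 1, (tp_sumsq - tp_sum^2 / tp_n) / (tp_n - 1), NA_real_)
  structure(list(
    samples = tibble(sample = design$sample, subject = design$subject,
                     timepoint = design$timepoint,
                     tpred_mean = tpred_mean, tpred_var = tpred_var,
                     inclusions = tp_n),
    features = tibble(feature = colnames(X), beta = beta_mean,
                      beta_var = beta_var, p = pval, q = qval),
    stats = tibble(mean_r2x = mean(r2x), mean_q2y = mean(q2y)),
    params = list(n_models = n_models, n_boot = n_boot,
                  test_fraction = test_fraction, q_threshold = q_threshold,
                  covariate_names = covariate_names, seed = seed)
  ), class = "rm_mccv")
}

#' @export
tidy.rm_mccv <- function(x, ...) x$features

#' @export
glance.rm_mccv <- function(x, ...) {
  dplyr::bind_cols(x$stats,
                   tibble(n_models = x$params$n_models, n_boot = x$params$n_boot,
                          n_significant = sum(x$features$q <= x$params$q_threshold)))
}

#' Signed Manhattan table of RM-MCCV results
#'
#' Per-feature signed log score: -log10(q) times the sign of the bootstrap
#' mean coefficient, with the significance cut line at -log10(q_threshold).
#' q-values of exactly zero are clamped to the smallest positive double with
#' a warning.
#'
#' @param result an `rm_mccv` object (or tibble with `feature`, `beta`, `q`).
#' @param q_threshold cut level; defaults to the one stored in `result`.
#' @return tibble: `feature`, `beta`, `q`, `score`, `cut`, `significant`.
#' @export
manhattan_table <- function(result, q_threshold = NULL) {
  feats <- if (inherits(result, "rm_mccv")) result$features else as_tibble(result)
  q_threshold <- q_threshold %||%
    (if (inherits(result, "rm_mccv")) result$params$q_threshold else 0.01)
  q <- feats$q
  if (any(q < 0 | q > 1)) abort("q-values must lie in [0, 1].")
  if (any(q == 0)) {
    warn("q-value(s) of 0 clamped to the smallest positive double.")
    q[q == 0] <- .Machine$double.xmin
  }
  tibble(feature = feats$feature, beta = feats$beta, q = q,
         score = -log10(q) * sign(feats$beta),
         cut = -log10(q_threshold),
         significant = q <= q_threshold)
}

#' Per-group Gaussian kernel density of cross-validated scores
#'
#' Gaussian KDE (Silverman's bandwidth) of T_pred per timepoint group on a
#' shared grid; each curve integrates to 1.
#'
#' @param result an `rm_mccv` object.
#' @param n_grid number of grid points (default 512).
#' @return tibble: `group`, `t`, `density`.
#' @export
tpred_density <- function(result, n_grid = 512) {
  smp <- result$samples[!is.na(result$samples$tpred_mean), ]
  groups <- split(smp$tpred_mean, smp$timepoint)
  if (length(groups) < 2 || any(lengths(groups) < 2)) abort("need >= 2 samples per group.")
  bws <- vapply(groups, function(v) {
    if (stats::sd(v) == 0) abort("zero-variance T_pred in a group.")
    stats::bw.nrd0(v)
  }, numeric(1))
  lo <- min(smp$tpred_mean) - 4 * max(bws)
  hi <- max(smp$tpred_mean) + 4 * max(bws)
  purrr::imap_dfr(groups, function(v, g) {
    d <- stats::density(v, bw = stats::bw.nrd0(v), from = lo, to = hi, n = n_grid)
    tibble(group = g, t = d$x, density = d$y)
  })
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment: on the sorted p-values,
#' q_(i) = min over j >= i of p_(j) * m / j, mapped back to input order.
#'
#' @param p vector of p-values in [0, 1].
#' @return q-values in [0, 1], same order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  stats::p.adjust(p, method = "BH")
}
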