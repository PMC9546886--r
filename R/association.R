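#' Univariate feature tests for paired or two-group designs
#'
#' Paired data are tested feature-wise with the two-sided Wilcoxon
#' signed-rank test on post - pre differences; unpaired data with the
#' two-sided Mann-Whitney U test between classes.  Exact null distributions
#' are used for small samples (signed-rank n <= 25; Mann-Whitney
#' min(n1, n2) <= 10) when there are no ties, otherwise the
#' continuity-corrected normal approximation.  Features with all-tied values
#' get p = 1 and a `tied` flag rather than an error.  q-values are
#' Benjamini-Hochberg over the tested family.
#'
#' @param table feature tibble.
#' @param design paired design; `timepoint` defines pairing, `class` (or
#'   `group`) the unpaired comparison.
#' @param paired use the paired signed-rank test (default TRUE).
#' @return tibble: `feature`, `statistic`, `p`, `q`, `direction` (sign of
#'   the median paired/group difference), `tied`.
#' @export
univariate_tests <- function(table, design, paired = TRUE) {
  table <- as_feature_table(table)
  design <- as_tibble(design)
  idx <- match(table$sample, design$sample)
  if (anyNA(idx)) abort("every sample needs a design row.")
  design <- design[idx, ]
  x <- feature_values(table)

  if (paired) {
    design <- validate_design(design)
    counts <- table(design$subject)
    complete <- names(counts)[counts == 2]
    keep <- design$subject %in% complete
    x <- x[keep, , drop = FALSE]; design <- design[keep, ]
    if (!length(complete)) abort("no complete pairs.")
    ord <- order(design$subject, design$timepoint)
    pre <- x[ord, , drop = FALSE][design$timepoint[ord] == "pre", , drop = FALSE]
    post <- x[ord, , drop = FALSE][design$timepoint[ord] == "post", , drop = FALSE]
    pre <- pre[order(design$subject[ord][design$timepoint[ord] == "pre"]), , drop = FALSE]
    post <- post[order(design$subject[ord][design$timepoint[ord] == "post"]), , drop = FALSE]
    n <- nrow(pre)
    res <- purrr::map_dfr(seq_len(ncol(x)), function(j) {
      d <- post[, j] - pre[, j]
      if (all(d == 0)) {
        return(tibble(statistic = NA_real_, p = 1, direction = 0, tied = TRUE))
      }
      wt <- suppressWarnings(stats::wilcox.test(
        post[, j], pre[, j], paired = TRUE,
        exact = n <= 25, correct = TRUE
      ))
      tibble(statistic = unname(wt$statistic), p = wt$p.value,
             direction = sign(stats::median(d)), tied = FALSE)
    })
  } else {
    gcol <- if ("class" %in% names(design)) "class" else "group"
    g <- as.character(design[[gcol]])
    lev <- sort(unique(g))
    if (length(lev) != 2) abort("unpaired tests need exactly two groups.")
    if (any(table(g) < 2)) abort("each group needs >= 2 samples.")
    x1 <- x[g == lev[1], , drop = FALSE]
    x2 <- x[g == lev[2], , drop = FALSE]
    exact <- min(nrow(x1), nrow(x2)) <= 10
    res <- purrr::map_dfr(seq_len(ncol(x)), function(j) {
      a <- x2[, j]; b <- x1[, j]   # direction = later group minus earlier
      if (length(unique(c(a, b))) == 1) {
        return(tibble(statistic = NA_real_, p = 1, direction = 0, tied = TRUE))
      }
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
      tibble(statistic = unname(wt$statistic), p = wt$p.value,
             direction = sign(stats::median(a) - stats::median(b)), tied = FALSE)
    })
  }
  res <- dplyr::bind_cols(tibble(feature = colnames(x)), res)
  res$q <- benjamini_hochberg(res$p)
  res[c("feature", "statistic", "p", "q", "direction", "tied")]
}

# spearman p-value: exact (via cor.test AS89) for small tie-free n,
# t approximation otherwise
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) return(list(rho = NA_real_, p = NA_real_, n = n, flag = "too_few"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, flag = "constant"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n, flag = "ok")
}

#' Spearman correlations between features and target covariates
#'
#' Rank correlations (average ranks for ties) of every feature against every
#' target column, with BH q-values over the whole emitted family.  Constant
#' vectors yield a missing rho with a flag.
#'
#' @param table feature tibble.
#' @param targets data frame with `sample` plus numeric target columns
#'   (e.g. BMI, HbA1c).
#' @return edge tibble: `feature`, `target`, `rho`, `p`, `q`, `n`, `flag`.
#' @export
spearman_matrix <- function(table, targets) {
  table <- as_feature_table(table)
  targets <- as_tibble(targets)
  idx <- match(table$sample, targets$sample)
  if (anyNA(idx)) abort("every sample needs a target row.")
  targets <- targets[idx, setdiff(names(targets), "sample"), drop = FALSE]
  x <- feature_values(table)
  edges <- tidyr::expand_grid(feature = colnames(x), target = names(targets))
  res <- purrr::pmap_dfr(edges, function(feature, target) {
    st <- spearman_test(x[, feature], targets[[target]])
    tibble(feature = feature, target = target, rho = st$rho, p = st$p,
           n = st$n, flag = st$flag)
  })
  res$q <- NA_real_
  ok <- !is.na(res$p)
  res$q[ok] <- benjamini_hochberg(res$p[ok])
  res[c("feature", "target", "rho", "p", "q", "n", "flag")]
}

#' Partial Spearman correlation
#'
#' Pearson correlation of the residuals of rank-transformed `x` and `y` on an
#' intercept plus the rank-transformed control columns `z`; p from a t
#' distribution with n - ncol(z) - 2 degrees of freedom.  With no controls
#' this reduces to the ordinary Spearman correlation.
#'
#' @param x,y numeric vectors.
#' @param z optional data frame/matrix of control covariates.
#' @return tibble: `rho`, `p`, `df`, `n_control`.
#' @export
partial_spearman <- function(x, y, z = NULL) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  if (is.null(z) || NCOL(z) == 0 || (is.data.frame(z) && ncol(z) == 0)) {
    rho <- stats::cor(x, y, method = "spearman")
    k <- 0L
  } else {
    z <- as.matrix(as.data.frame(z))
    if (nrow(z) != n) abort("`z` must have one row per observation.")
    k <- ncol(z)
    if (n <= k + 2) abort("need n > ncol(z) + 2 observations.")
    rz <- apply(z, 2, rank, ties.method = "average")
    Z <- cbind(1, rz)
    if (qr(Z)$rank < ncol(Z)) abort("control matrix is rank deficient.")
    rx <- stats::lm.fit(Z, rank(x, ties.method = "average"))$residuals
    ry <- stats::lm.fit(Z, rank(y, ties.method = "average"))$residuals
    rho <- stats::cor(rx, ry)
  }
  df <- n - k - 2
  tstat <- rho * sqrt(df / (1 - rho^2))
  tibble(rho = rho, p = 2 * stats::pt(-abs(tstat), df), df = df, n_control = k)
}

#' Threshold an edge table into a correlation network
#'
#' Keeps edges with q strictly below the threshold; node degree counts
#' retained incident edges; edge signs are retained.
#'
#' @param edges edge tibble with at least `feature`, `target` (or `node_a`,
#'   `node_b`), `rho`, `q`.
#' @param q_threshold retention threshold (default 0.01).
#' @return list of class `assoc_network`: `edges` (with `sign`), `nodes`
#'   (`node`, `degree`).
#' @export
build_network <- function(edges, q_threshold = 0.01) {
  edges <- as_tibble(edges)
  if (!"q" %in% names(edges)) abort("`edges` must carry a `q` column.")
  ab <- if (all(c("node_a", "node_b") %in% names(edges))) c("node_a", "node_b") else c("feature", "target")
  all_nodes <- unique(c(edges[[ab[1]]], edges[[ab[2]]]))
  kept <- edges[!is.na(edges$q) & edges$q < q_threshold, ]
  kept$sign <- sign(kept$rho)
  deg <- table(factor(c(kept[[ab[1]]], kept[[ab[2]]]), levels = all_nodes))
  structure(list(
    edges = kept,
    nodes = tibble(node = all_nodes, degree = as.integer(deg[all_nodes])),
    q_threshold = q_threshold
  ), class = "assoc_network")
}

#' Hierarchically cluster a correlation matrix
#'
#' Agglomerative (complete-linkage) clustering on Euclidean distances
#' between rows of a square symmetric correlation matrix.  Rows are first
#' put in lexicographic label order so the leaf order is deterministic and
#' independent of input row order.
#'
#' @param rho square symmetric correlation matrix with dimnames.
#' @return list: `order` (leaf labels in dendrogram order), `hclust` (the
#'   stats::hclust object).
#' @export
cluster_correlations <- function(rho) {
  rho <- as.matrix(rho)
  if (nrow(rho) != ncol(rho) || max(abs(rho - t(rho))) > 1e-8) {
    abort("`rho` must be square and symmetric.")
  }
  labs <- rownames(rho) %||% paste0("v", seq_len(nrow(rho)))
  dimnames(rho) <- list(labs, labs)
  ord <- order(labs)
  rho <- rho[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::dist(rho), method = "complete")
  list(order = rownames(rho)[hc$order], hclust = hc)
}

#' Build signed association sets from per-context result tables
#'
#' A metabolite enters a context's set iff its q-value is strictly below
#' `alpha`; its direction sign is stored.  When `merge_concordant` is TRUE,
#' duplicate ids within one context (e.g. the same metabolite in several
#' biofluids) are merged if their directions agree.
#'
#' @param tables named list of tibbles, each with columns `id` (or
#'   `feature`), `q` and `direction`.
#' @param alpha significance threshold (default 0.05, strict <).
#' @param merge_concordant merge same-id entries with agreeing signs.
#' @return object of class `association_sets`: tibble `members` (`context`,
#'   `id`, `direction`) plus the `alpha` used.
#' @export
build_association_sets <- function(tables, alpha = 0.05, merge_concordant = FALSE) {
  if (is.null(names(tables)) || any(names(tables) == "")) abort("`tables` must be a named list.")
  members <- purrr::imap_dfr(tables, function(tab, ctx) {
    tab <- as_tibble(tab)
    idcol <- if ("id" %in% names(tab)) "id" else "feature"
    if (!"q" %in% names(tab)) abort(sprintf("table '%s' has no `q` column.", ctx))
    sig <- tab[!is.na(tab$q) & tab$q < alpha, ]
    tibble(context = ctx, id = as.character(sig[[idcol]]),
           direction = if ("direction" %in% names(sig)) sign(sig$direction) else NA_real_)
  })
  if (isTRUE(merge_concordant) && nrow(members)) {
    members <- members |>
      dplyr::group_by(.data$context, .data$id) |>
      dplyr::summarise(direction = if (dplyr::n_distinct(sign(.data$direction)) == 1)
        .data$direction[1] else NA_real_, .groups = "drop")
  }
  structure(list(members = members, alpha = alpha), class = "association_sets")
}

#' Euler region counts and pairwise commonality of association sets
#'
#' Counts every non-empty Euler region (exact membership pattern over the
#' contexts) and reports, per context pair, the commonality percentage
#' 100 * |A intersect B| / |A union B| and the percent-of-reference share
#' 100 * |A intersect B| / |A|.
#'
#' @param sets an `association_sets` object, or a named list of id vectors.
#' @return object of class `overlap_report`: `regions` (tibble `pattern`,
#'   `contexts`, `count`), `pairs` (tibble `context_a`, `context_b`,
#'   `intersection`, `union`, `commonality`, `share_of_a`), `set_sizes`,
#'   `union_size`.
#' @export
overlap_report <- function(sets) {
  if (inherits(sets, "association_sets")) {
    sets <- split(sets$members$id, sets$members$context)
  }
  sets <- lapply(sets, unique)
  if (length(sets) < 2) abort("need >= 2 sets.")
  ctx <- names(sets)
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(universe))
  pattern <- apply(memb, 1, function(r) paste(ctx[r], collapse = "&"))
  tab <- table(pattern)
  regions <- tibble(pattern = names(tab), count = as.integer(tab)) |>
    dplyr::arrange(dplyr::desc(.data$count))
  pairs <- purrr::map_dfr(utils::combn(ctx, 2, simplify = FALSE), function(pr) {
    a <- sets[[pr[1]]]; b <- sets[[pr[2]]]
    i <- length(intersect(a, b)); u <- length(union(a, b))
    tibble(context_a = pr[1], context_b = pr[2], intersection = i, union = u,
           commonality = if (u > 0) 100 * i / u else NA_real_,
           share_of_a = if (length(a) > 0) 100 * i / length(a) else NA_real_)
  })
  structure(list(regions = regions, pairs = pairs,
                 set_sizes = lengths(sets), union_size = length(universe)),
            class = "overlap_report")
}

#' Balanced error rate of binary predictions
#'
#' Confusion counts plus FPR = FP/(FP+TN), FNR = FN/(FN+TP) and
#' BER = 0.5 * (FPR + FNR): 0 for a perfect classifier, 0.5 for a random
#' one, 1 for systematically inverted predictions.
#'
#' @param truth,predicted equal-length binary label vectors (logical, 0/1,
#'   or two-level factor/character); both classes must occur in `truth`.
#' @return tibble of class `confusion_summary`: `tp`, `fp`, `tn`, `fn`,
#'   `fpr`, `fnr`, `ber`.
#' @export
balanced_error_rate <- function(truth, predicted) {
  if (length(truth) != length(predicted)) abort("label vectors must have equal length.")
  lev <- sort(unique(c(as.character(truth), as.character(predicted))))
  if (length(lev) > 2) abort("labels must be binary.")
  pos <- lev[length(lev)]
  tt <- as.character(truth) == pos
  if (length(unique(tt)) < 2) abort("`truth` must contain both classes.")
  pp <- as.character(predicted) == pos
  tp <- sum(tt & pp); fn <- sum(tt & !pp)
  tn <- sum(!tt & !pp); fp <- sum(!tt & pp)
  fpr <- fp / (fp + tn); fnr <- fn / (fn + tp)
  out <- tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                fpr = fpr, fnr = fnr, ber = 0.5 * (fpr + fnr))
  class(out) <- c("confusion_summary", class(out))
  out
}
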