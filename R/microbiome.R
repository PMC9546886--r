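#' Bray-Curtis dissimilarity matrix
#'
#' d(a, b) = 1 - 2 * sum(min(a_i, b_i)) / (sum(a_i) + sum(b_i)), computed
#' via [vegan::vegdist()] and returned as a full square symmetric matrix
#' with zero diagonal.
#'
#' @param table taxa tibble (counts or relative abundances; no all-zero
#'   sample).
#' @return square symmetric numeric matrix with sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  table <- as_feature_table(table)
  x <- feature_values(table)
  if (any(x < 0)) abort("abundances must be non-negative.")
  zero <- rowSums(x) == 0
  if (any(zero)) abort(sprintf("all-zero sample(s): %s", paste(rownames(x)[zero], collapse = ", ")))
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Eigen-decomposition of the double-centred -0.5 * D^2 matrix (classical
#' MDS).  Axes are ordered by descending eigenvalue; negative eigenvalues
#' are reported but their axes dropped; the variance proportion of each
#' retained axis is relative to the sum of positive eigenvalues.
#'
#' @param d square symmetric dissimilarity matrix (zero diagonal).
#' @return object of class `pcoa_result`: `points` (tibble `sample` +
#'   `Axis1`, `Axis2`, ...), `eigenvalues`, `proportion`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) abort("`d` must be square and symmetric.")
  if (any(abs(diag(d)) > 1e-12)) abort("`d` must have a zero diagonal.")
  n <- nrow(d)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  pts <- fit$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  structure(list(
    points = dplyr::bind_cols(tibble(sample = rownames(d) %||% paste0("s", seq_len(n))),
                              as_tibble(pts)),
    eigenvalues = eig,
    proportion = pmax(eig, 0)[pos] / sum(eig[pos])
  ), class = "pcoa_result")
}

# pseudo-F for a one-way design on a dissimilarity matrix
permanova_f <- function(d2, groups) {
  n <- length(groups)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx, drop = FALSE])]) / length(idx)
  }
  a <- length(unique(groups))
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Pseudo-F from among/within sums of squared dissimilarities, with a
#' permutation p-value.  Without `strata`, group labels are permuted freely
#' (or, with `exhaustive = TRUE` and two groups, every distinct label split
#' is enumerated).  With `strata` (a subject id per sample, the nested /
#' repeated-measures case), labels are permuted only within each stratum —
#' for pre/post pairs this is a within-subject timepoint swap — and
#' `exhaustive = TRUE` enumerates all 2^S swap patterns.
#'
#' Sampled p-values use the +1 convention,
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations); exhaustive
#' p-values count the observed labelling among the enumerated set.
#'
#' @param d square symmetric dissimilarity matrix.
#' @param groups group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_permutations number of random permutations (default 999).
#' @param strata optional subject id per sample; permutations stay within
#'   strata and every stratum must contain >= 2 groups.
#' @param seed integer seed for random permutations.
#' @param exhaustive enumerate the full permutation space instead of
#'   sampling (two-group designs; with strata, all strata of size 2).
#' @return object of class `permanova_result`: `f`, `p`, `n_permutations`,
#'   `df`, `exhaustive`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 999, strata = NULL,
                      seed = 1, exhaustive = FALSE) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) abort("one group label per sample is required.")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("PERMANOVA needs >= 2 groups with >= 2 samples each.")
  }
  if (!is.null(strata)) {
    strata <- as.character(strata)
    ok <- vapply(split(groups, strata), function(g) length(unique(g)) >= 2, logical(1))
    if (!all(ok)) abort("every stratum must contain samples from >= 2 groups.")
  }
  d2 <- d^2
  f_obs <- permanova_f(d2, groups)
  n <- length(groups)

  if (exhaustive) {
    if (is.null(strata)) {
      if (length(tab) != 2) abort("exhaustive mode requires two groups.")
      lev <- names(tab)
      sel <- utils::combn(n, tab[[lev[1]]])
      fs <- apply(sel, 2, function(idx) {
        g <- rep(lev[2], n); g[idx] <- lev[1]
        permanova_f(d2, g)
      })
    } else {
      us <- unique(strata)
      if (any(table(strata) != 2)) abort("exhaustive strata mode needs strata of size 2.")
      S <- length(us)
      if (S > 20) abort("exhaustive strata mode is limited to 20 strata.")
      fs <- vapply(seq_len(2^S) - 1L, function(mask) {
        g <- groups
        for (k in seq_len(S)) {
          if (bitwAnd(mask, bitwShiftL(1L, k - 1L))) {
            idx <- which(strata == us[k])
            g[idx] <- g[rev(idx)]
          }
        }
        permanova_f(d2, g)
      }, numeric(1))
    }
    p <- sum(fs >= f_obs - 1e-12) / length(fs)
    n_permutations <- length(fs)
  } else {
    set.seed(seed)
    count <- 0L
    for (i in seq_len(n_permutations)) {
      g <- if (is.null(strata)) {
        sample(groups)
      } else {
        gp <- groups
        for (u in unique(strata)) {
          idx <- which(strata == u)
          gp[idx] <- gp[idx][sample(length(idx))]
        }
        gp
      }
      if (permanova_f(d2, g) >= f_obs - 1e-12) count <- count + 1L
    }
    p <- (1 + count) / (1 + n_permutations)
  }
  structure(list(f = f_obs, p = p, n_permutations = n_permutations,
                 df = c(among = length(tab) - 1L, within = n - length(tab)),
                 exhaustive = exhaustive, strata = !is.null(strata), seed = seed),
            class = "permanova_result")
}

#' @export
glance.permanova_result <- function(x, ...) {
  tibble(f = x$f, p = x$p, n_permutations = x$n_permutations,
         exhaustive = x$exhaustive, strata = x$strata)
}

#' Metagenomic gene richness by rarefaction
#'
#' Downsamples each sample's reads to a fixed depth without replacement
#' (multivariate hypergeometric, realised as a uniform random permutation of
#' the reads with prefix counting, so richness is monotone in depth for a
#' shared seed) and reports the mean number of distinct genes observed over
#' `n_draws` draws.  Samples with fewer total reads than `depth` are flagged
#' and skipped.
#'
#' @param counts tibble (`sample` + gene count columns) or a named integer
#'   vector for a single sample.
#' @param depth rarefaction depth in reads (study convention 7e6).
#' @param n_draws number of random draws (study convention 30).
#' @param seed integer seed.
#' @return object of class `richness_result`: `samples` (tibble `sample`,
#'   `total_reads`, `mean_richness`, `sd_richness`, `skipped`), `draws`
#'   (matrix sample x draw), `depth`, `n_draws`, `seed`.
#' @export
gene_richness <- function(counts, depth = 7e6, n_draws = 30, seed = 1) {
  if (!is.data.frame(counts)) {
    counts <- as_feature_table(matrix(counts, 1, dimnames = list("sample01", names(counts))))
  }
  counts <- as_feature_table(counts)
  depth <- check_count(depth, "depth")
  n_draws <- check_count(n_draws, "n_draws")
  x <- feature_values(counts)
  if (any(x < 0) || any(x != floor(x))) abort("gene counts must be non-negative integers.")
  totals <- rowSums(x)
  draws <- matrix(NA_real_, nrow(x), n_draws,
                  dimnames = list(rownames(x), NULL))
  seeds <- split_seed(seed, nrow(x))
  skipped <- totals < depth
  if (any(skipped)) {
    warn(sprintf("sample(s) below depth, skipped: %s",
                 paste(rownames(x)[skipped], collapse = ", ")))
  }
  for (i in which(!skipped)) {
    reads <- rep.int(seq_len(ncol(x)), x[i, ])
    set.seed(seeds[i])
    for (b in seq_len(n_draws)) {
      perm <- sample.int(totals[i])
      draws[i, b] <- length(unique(reads[perm[seq_len(depth)]]))
    }
  }
  structure(list(
    samples = tibble(sample = rownames(x), total_reads = unname(totals),
                     mean_richness = unname(rowMeans(draws)),
                     sd_richness = unname(apply(draws, 1, stats::sd)),
                     skipped = unname(skipped)),
    draws = draws, depth = depth, n_draws = n_draws, seed = seed
  ), class = "richness_result")
}

#' @export
tidy.richness_result <- function(x, ...) x$samples

#' Differential taxon abundance between groups or timepoints
#'
#' Converts counts to relative abundance and delegates to
#' [univariate_tests()]; taxa significant at p < 0.05 are flagged, and those
#' surviving BH FDR < 0.05 additionally marked.
#'
#' @param table taxa tibble (ideally pre-filtered with
#'   [filter_low_abundance_taxa()]).
#' @param design design tibble (paired: `subject`/`timepoint`; unpaired:
#'   `class` or `group`).
#' @param paired paired (signed-rank) or two-group (Mann-Whitney) testing.
#' @return the [univariate_tests()] tibble plus `sig_p` (p < 0.05) and
#'   `sig_q` (q < 0.05) flags.
#' @export
differential_abundance <- function(table, design, paired = TRUE) {
  rel <- to_relative_abundance(table)
  res <- univariate_tests(rel, design, paired = paired)
  res$sig_p <- res$p < 0.05
  res$sig_q <- res$q < 0.05
  res
}
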