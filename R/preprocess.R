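#' Median fold change normalisation
#'
#' Corrects per-sample dilution by dividing each sample by the median, over
#' features, of its fold change relative to the median spectrum.  The
#' reference is the feature-wise median across samples; ratios are taken only
#' over features where both the reference and the sample intensity are
#' strictly positive (the fold change is undefined otherwise).
#'
#' @param table feature tibble of non-negative raw intensities (>= 2 samples,
#'   each with at least one positive feature).
#' @return a list of class `mfc_norm`: `normalised` (feature tibble),
#'   `factors` (named per-sample dilution factor) and `reference` (named
#'   per-feature median spectrum).  Re-running on `normalised` yields factors
#'   of 1.
#' @examples
#' sim <- generate_paired_matrix(5, 30, 0, seed = 2)
#' norm <- median_fold_change_normalise(sim$table)
#' head(norm$factors)
#' @export
median_fold_change_normalise <- function(table) {
  table <- as_feature_table(table)
  x <- feature_values(table)
  if (nrow(x) < 2) abort("median fold change normalisation needs >= 2 samples.")
  if (any(x < 0)) abort("raw intensities must be non-negative.")
  zero_rows <- rowSums(x > 0) == 0
  if (any(zero_rows)) {
    abort(sprintf("all-zero sample row(s): %s",
                  paste(rownames(x)[zero_rows], collapse = ", ")))
  }
  # iterate the median-ratio step to its fixed point so that renormalising
  # the output yields unit factors
  factors <- rep(1, nrow(x))
  names(factors) <- rownames(x)
  reference <- apply(x, 2, stats::median)
  for (it in seq_len(1000)) {
    reference <- apply(x, 2, stats::median)
    step <- vapply(seq_len(nrow(x)), function(i) {
      ok <- reference > 0 & x[i, ] > 0
      if (!any(ok)) abort(sprintf("sample %s shares no positive feature with the reference.", rownames(x)[i]))
      stats::median(x[i, ok] / reference[ok])
    }, numeric(1))
    x <- x / step
    factors <- factors * step
    if (max(abs(step - 1)) < 1e-10) break
  }
  structure(list(
    normalised = rebuild_feature_table(x, template = table),
    factors = factors,
    reference = reference
  ), class = "mfc_norm")
}

#' Log-transform feature intensities
#'
#' Natural log of strictly positive intensities (with an optional additive
#' offset for zeros).  Dilution-corrected intensity data are log-normal to a
#' good approximation, so downstream linear modelling — in particular the
#' within-subject transform, which removes multiplicative subject effects
#' only once they are additive — operates on the log scale.
#'
#' @param table feature tibble of non-negative intensities.
#' @param offset added before taking logs (default 0; required > 0 if zeros
#'   are present).
#' @return the log-scale feature tibble.
#' @export
log_transform <- function(table, offset = 0) {
  table <- as_feature_table(table)
  x <- feature_values(table) + offset
  if (any(x <= 0)) abort("non-positive intensities; supply a positive `offset`.")
  rebuild_feature_table(log(x), template = table)
}

#' Column-wise scaling of a feature table
#'
#' Centres by column mean (when `center`) then scales: `"unit_variance"`
#' divides by the column standard deviation, `"pareto"` by its square root,
#' `"none"` leaves values as centred.  Zero-variance columns are left as
#' all-zero (after centring) without error.
#'
#' @param table feature tibble (>= 2 samples).
#' @param method one of `"unit_variance"`, `"pareto"`, `"none"`.
#' @param center centre columns by their mean first (default TRUE).
#' @return the scaled feature tibble.
#' @export
scale_columns <- function(table, method = c("unit_variance", "pareto", "none"),
                          center = TRUE) {
  method <- match.arg(method)
  table <- as_feature_table(table)
  x <- feature_values(table)
  if (nrow(x) < 2) abort("scaling needs >= 2 samples.")
  if (center) x <- sweep(x, 2, colMeans(x))
  if (method != "none") {
    s <- apply(x, 2, stats::sd)
    div <- if (method == "unit_variance") s else sqrt(s)
    div[s == 0] <- 1  # zero-variance columns stay (centred) zero
    x <- sweep(x, 2, div, "/")
  }
  rebuild_feature_table(x, template = table)
}

#' Remove spectral regions by chemical shift
#'
#' Drops feature columns whose ppm coordinate falls inside any closed
#' interval.  With `regions = NULL` the standard exclusion set is used:
#' internal standard (-0.5 to 0.5 ppm) and water (4.6 to 5.0 ppm), plus the
#' urea region (5.4 to 6.3 ppm) when `urea = TRUE`.
#'
#' @param table feature tibble with a ppm axis.
#' @param regions list of length-2 numeric intervals `c(lo, hi)`, or `NULL`
#'   for the defaults; `list()` masks nothing.
#' @param urea also mask the urea region (urine/serum convention).
#' @return the feature tibble with masked features removed (ppm axis
#'   updated).  Warns if every feature is removed.
#' @export
mask_ppm_regions <- function(table, regions = NULL, urea = FALSE) {
  table <- as_feature_table(table)
  ppm <- feature_ppm(table)
  if (is.null(ppm)) abort("`table` has no ppm axis.")
  if (is.null(regions)) {
    regions <- list(c(-0.5, 0.5), c(4.6, 5.0))
    if (urea) regions <- c(regions, list(c(5.4, 6.3)))
  }
  drop <- rep(FALSE, length(ppm))
  for (r in regions) {
    r <- sort(as.numeric(r))
    drop <- drop | (ppm >= r[1] & ppm <= r[2])
  }
  if (all(drop)) warn("masking removed every feature.")
  keep <- which(!drop)
  out <- table[c(1L, keep + 1L)]
  attr(out, "ppm") <- ppm[keep]
  out
}

#' Correct urinary dilution by osmolality or creatinine
#'
#' Divides each sample row by its osmolality (mOsm/kg) or creatinine
#' (mmol/L) measurement.
#'
#' @param table feature tibble of targeted urinary metabolite levels.
#' @param osmolality per-sample osmolality (used when `mode = "osmolality"`).
#' @param creatinine per-sample creatinine (used when `mode = "creatinine"`).
#' @param mode which divisor to use.
#' @return the corrected feature tibble.
#' @export
correct_urinary_dilution <- function(table, osmolality = NULL, creatinine = NULL,
                                     mode = c("osmolality", "creatinine")) {
  mode <- match.arg(mode)
  table <- as_feature_table(table)
  div <- if (mode == "osmolality") osmolality else creatinine
  if (is.null(div)) abort(sprintf("`%s` values are required for mode = \"%s\".", mode, mode))
  if (length(div) != nrow(table)) abort("one divisor per sample is required.")
  bad <- which(!is.finite(div) | div <= 0)
  if (length(bad)) {
    abort(sprintf("non-positive %s for sample(s): %s", mode,
                  paste(table$sample[bad], collapse = ", ")))
  }
  rebuild_feature_table(feature_values(table) / div, template = table)
}

#' Filter low-prevalence taxa
#'
#' A taxon is retained iff its prevalence (fraction of samples with abundance
#' strictly > 0) reaches the threshold in at least one of the two groups;
#' taxa present in fewer than the threshold fraction of *both* subgroups are
#' excluded.
#'
#' @param table taxa tibble (`sample` + taxa columns, counts or relative
#'   abundances).
#' @param groups either a tibble with columns `sample` and `group`, or a
#'   vector of group labels named by sample.  Exactly two non-empty groups.
#' @param prevalence_threshold retention threshold (default 0.30).
#' @return the taxa tibble restricted to retained taxa.
#' @export
filter_low_abundance_taxa <- function(table, groups, prevalence_threshold = 0.30) {
  table <- as_feature_table(table)
  if (is.data.frame(groups)) groups <- stats::setNames(groups$group, groups$sample)
  g <- as.character(groups[table$sample])
  if (anyNA(g)) abort("every sample needs a group label.")
  lev <- unique(g)
  if (length(lev) != 2) abort("exactly two non-empty groups are required.")
  x <- feature_values(table) > 0
  prevA <- colMeans(x[g == lev[1], , drop = FALSE])
  prevB <- colMeans(x[g == lev[2], , drop = FALSE])
  keep <- prevA >= prevalence_threshold | prevB >= prevalence_threshold
  table[c(TRUE, keep)]
}

#' Convert taxa counts to relative abundance
#'
#' @param table taxa tibble of non-negative counts; every sample total > 0.
#' @return taxa tibble whose rows sum to 1.
#' @export
to_relative_abundance <- function(table) {
  table <- as_feature_table(table)
  x <- feature_values(table)
  if (any(x < 0)) abort("counts must be non-negative.")
  tot <- rowSums(x)
  if (any(tot == 0)) {
    abort(sprintf("all-zero sample(s): %s", paste(rownames(x)[tot == 0], collapse = ", ")))
  }
  rebuild_feature_table(x / tot, template = table)
}
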