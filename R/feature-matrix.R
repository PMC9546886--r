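#' Feature tables and paired designs
#'
#' Throughout the package a *feature table* is an ordinary tibble whose first
#' column is `sample` (unique character ids) and whose remaining columns are
#' numeric feature intensities.  Spectral tables additionally carry a `"ppm"`
#' attribute: a numeric vector of chemical-shift coordinates, one per feature
#' column, strictly monotone along the feature order.  A *paired design* is a
#' tibble with columns `sample`, `subject`, `timepoint` (`"pre"`/`"post"`),
#' `class`, plus any number of numeric covariate columns.
#'
#' `as_feature_table()` validates (and converts) an object into this layout;
#' `feature_values()` extracts the numeric matrix (samples in rows);
#' `feature_ppm()` returns the ppm axis or `NULL`.
#'
#' @param x a data frame (first column sample ids) or a numeric matrix with
#'   rownames as sample ids.
#' @param ppm optional numeric ppm axis, one value per feature column.
#' @return `as_feature_table()` returns a tibble; `feature_values()` a numeric
#'   matrix; `feature_ppm()` a numeric vector or `NULL`.
#' @examples
#' m <- matrix(1:6, 2, dimnames = list(c("a", "b"), c("f1", "f2", "f3")))
#' ft <- as_feature_table(m)
#' feature_values(ft)
#' @export
as_feature_table <- function(x, ppm = NULL) {
  if (is.matrix(x)) {
    sample_ids <- rownames(x) %||% paste0("sample", seq_len(nrow(x)))
    feats <- colnames(x) %||% paste0("feature", seq_len(ncol(x)))
    df <- tibble(sample = sample_ids)
    vals <- as_tibble(x, .name_repair = "minimal")
    names(vals) <- feats
    x <- dplyr::bind_cols(df, vals)
  }
  x <- as_tibble(x)
  if (ncol(x) < 2) abort("a feature table needs a sample column plus at least one feature.")
  names(x)[1] <- "sample"
  x$sample <- as.character(x$sample)
  if (anyDuplicated(x$sample)) {
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(x$sample[duplicated(x$sample)]), collapse = ", ")))
  }
  num <- vapply(x[-1], is.numeric, logical(1))
  if (!all(num)) abort(sprintf("non-numeric feature column(s): %s",
                               paste(names(x)[-1][!num], collapse = ", ")))
  if (!is.null(ppm)) {
    if (length(ppm) != ncol(x) - 1) abort("`ppm` must have one value per feature column.")
    d <- diff(ppm)
    if (length(d) && !(all(d > 0) || all(d < 0))) abort("`ppm` must be strictly monotone.")
    attr(x, "ppm") <- as.numeric(ppm)
  }
  x
}

#' @rdname as_feature_table
#' @export
feature_values <- function(x) {
  m <- as.matrix(x[-1])
  storage.mode(m) <- "double"
  rownames(m) <- x$sample
  m
}

#' @rdname as_feature_table
#' @export
feature_ppm <- function(x) attr(x, "ppm", exact = TRUE)

# rebuild a feature table from a matrix, carrying a ppm axis along
rebuild_feature_table <- function(values, template = NULL, ppm = NULL) {
  ft <- as_feature_table(values)
  ppm <- ppm %||% if (!is.null(template)) feature_ppm(template) else NULL
  if (!is.null(ppm)) attr(ft, "ppm") <- as.numeric(ppm)
  ft
}

#' Validate a paired design against a feature table
#'
#' Checks the design tibble layout (columns `sample`, `subject`, `timepoint`,
#' `class`), that no subject has two samples at the same timepoint, and — when
#' a feature table is supplied — that every sample in it is described.
#'
#' @param design a design tibble.
#' @param table optional feature table whose samples must all appear.
#' @return the validated design tibble, invisibly usable in pipes.
#' @export
validate_design <- function(design, table = NULL) {
  design <- as_tibble(design)
  need <- c("sample", "subject", "timepoint")
  miss <- setdiff(need, names(design))
  if (length(miss)) abort(sprintf("design is missing column(s): %s", paste(miss, collapse = ", ")))
  design$sample <- as.character(design$sample)
  if (anyDuplicated(design$sample)) abort("duplicate sample ids in design.")
  dup <- duplicated(design[c("subject", "timepoint")])
  if (any(dup)) {
    abort(sprintf("subject(s) with two samples at one timepoint: %s",
                  paste(unique(design$subject[dup]), collapse = ", ")))
  }
  if (!is.null(table)) {
    missing_samples <- setdiff(table$sample, design$sample)
    if (length(missing_samples)) {
      abort(sprintf("sample(s) in feature table but not in design: %s",
                    paste(missing_samples, collapse = ", ")))
    }
  }
  design
}

# covariate columns = numeric columns that are not structural
design_covariates <- function(design) {
  structural <- c("sample", "subject", "timepoint", "class", "group")
  keep <- setdiff(names(design), structural)
  keep[vapply(design[keep], is.numeric, logical(1))]
}
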