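#' Simulate a paired two-timepoint feature matrix with planted effects
#'
#' Generates log-normal intensities for a repeated-measures (pre/post) design:
#' log-intensity = feature baseline + subject random effect + (post x effect
#' for affected features) + noise, exponentiated and multiplied by a
#' per-sample dilution factor.  Subject effects are drawn per subject and
#' feature, so they survive dilution correction and must be removed by the
#' within-subject transform, as in real paired metabolome data.
#'
#' @param n_subjects number of subjects (each contributes a pre and a post
#'   sample).
#' @param n_features number of features.
#' @param n_affected number of features shifted at the post timepoint.
#' @param effect_size standardised log-scale shift applied to affected
#'   features at `post`.
#' @param subject_sd standard deviation of the per-subject, per-feature random
#'   effect (log scale).
#' @param noise_sd residual log-scale noise standard deviation (must be > 0).
#' @param dilution_range length-2 positive interval; per-sample dilution
#'   factors are drawn uniformly from it.
#' @param seed integer seed; identical seeds give identical output.
#' @return a list with `table` (feature tibble), `design` (paired design
#'   tibble with `bmi`, `hba1c`, `age` covariates) and `truth` (list:
#'   `affected_features` indices, `effect_sizes`, `dilution` named per sample,
#'   `subject_effects` matrix).
#' @examples
#' sim <- generate_paired_matrix(6, 20, 3, effect_size = 2, seed = 1)
#' sim$truth$affected_features
#' @export
generate_paired_matrix <- function(n_subjects, n_features, n_affected,
                                   effect_size = 1.5, subject_sd = 1,
                                   noise_sd = 0.5, dilution_range = c(0.5, 2),
                                   seed = 1) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_features <- check_count(n_features, "n_features")
  n_affected <- check_count(n_affected, "n_affected", min = 0)
  if (n_affected > n_features) abort("`n_affected` must be <= `n_features`.")
  check_positive(noise_sd, "noise_sd")
  if (subject_sd < 0) abort("`subject_sd` must be >= 0.")
  if (length(dilution_range) != 2 || any(dilution_range <= 0) ||
      dilution_range[1] > dilution_range[2]) {
    abort("`dilution_range` must be a positive interval [lo, hi].")
  }

  seeds <- split_seed(seed, 5)
  n_samples <- 2L * n_subjects
  subjects <- sprintf("subj%02d", seq_len(n_subjects))
  samples <- as.vector(t(outer(subjects, c("pre", "post"), paste, sep = "_")))
  timepoint <- rep(c("pre", "post"), n_subjects)

  set.seed(seeds[1])
  baseline <- stats::rnorm(n_features, mean = 2, sd = 1)
  affected <- if (n_affected > 0) sort(sample.int(n_features, n_affected)) else integer(0)

  set.seed(seeds[2])
  subj_eff <- matrix(stats::rnorm(n_subjects * n_features, sd = subject_sd),
                     n_subjects, n_features)
  set.seed(seeds[3])
  noise <- matrix(stats::rnorm(n_samples * n_features, sd = noise_sd),
                  n_samples, n_features)
  set.seed(seeds[4])
  dilution <- stats::runif(n_samples, dilution_range[1], dilution_range[2])
  names(dilution) <- samples

  log_int <- matrix(baseline, n_samples, n_features, byrow = TRUE) +
    subj_eff[rep(seq_len(n_subjects), each = 2), , drop = FALSE] + noise
  if (n_affected > 0) {
    log_int[timepoint == "post", affected] <-
      log_int[timepoint == "post", affected] + effect_size
  }
  values <- exp(log_int) * dilution
  dimnames(values) <- list(samples, sprintf("feat%03d", seq_len(n_features)))

  set.seed(seeds[5])
  covs <- tibble(
    bmi = rep(stats::rnorm(n_subjects, 42, 5), each = 2),
    hba1c = rep(stats::rnorm(n_subjects, 55, 12), each = 2),
    age = rep(round(stats::rnorm(n_subjects, 48, 9)), each = 2)
  )
  design <- dplyr::bind_cols(
    tibble(sample = samples,
           subject = rep(subjects, each = 2),
           timepoint = timepoint,
           class = timepoint),
    covs
  )
  rownames(subj_eff) <- subjects
  list(
    table = as_feature_table(values),
    design = design,
    truth = list(
      affected_features = affected,
      effect_sizes = stats::setNames(rep(effect_size, n_affected),
                                     colnames(values)[affected]),
      dilution = dilution,
      subject_effects = subj_eff,
      baseline = baseline
    )
  )
}

#' Simulate multiplet-structured pseudo-NMR spectra
#'
#' Each molecule contributes Gaussian lines at its multiplet positions
#' (evenly spaced around each peak centre, Pascal's-triangle intensity
#' ratios), scaled by its per-sample concentration, summed over molecules,
#' multiplied by a per-sample dilution factor, with additive detector noise.
#' Before noise, all features of one molecule are exact scalar multiples of
#' each other across samples.
#'
#' @param peaks data frame with columns `molecule`, `centre` (ppm), `width`
#'   (Gaussian sd, ppm), `multiplicity` (number of lines), `amplitude`
#'   (signal per unit concentration); optional `spacing` (line spacing in
#'   ppm, default 0.01).
#' @param concentrations data frame, first column `sample`, one numeric
#'   column per molecule named in `peaks`.
#' @param ppm_axis numeric grid of chemical shifts (strictly monotone).
#' @param dilution per-sample positive factor (default all 1).
#' @param noise_sd additive noise sd (default 0 = noiseless).
#' @param seed integer seed.
#' @return a feature tibble with a `"ppm"` attribute; feature columns are
#'   named after their ppm coordinate.
#' @export
generate_spectra <- function(peaks, concentrations, ppm_axis,
                             dilution = NULL, noise_sd = 0, seed = 1) {
  peaks <- as_tibble(peaks)
  if (nrow(peaks) == 0) abort("`peaks` must contain at least one peak.")
  need <- c("molecule", "centre", "width", "multiplicity", "amplitude")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) abort(sprintf("`peaks` is missing column(s): %s", paste(miss, collapse = ", ")))
  if (!"spacing" %in% names(peaks)) peaks$spacing <- 0.01
  rng <- range(ppm_axis)
  if (any(peaks$centre < rng[1] | peaks$centre > rng[2])) {
    abort("all peak centres must lie within the ppm axis range.")
  }
  concentrations <- as_tibble(concentrations)
  names(concentrations)[1] <- "sample"
  mols <- unique(peaks$molecule)
  miss <- setdiff(mols, names(concentrations))
  if (length(miss)) abort(sprintf("no concentration column for molecule(s): %s", paste(miss, collapse = ", ")))
  conc <- as.matrix(concentrations[mols])
  n <- nrow(conc)
  dilution <- dilution %||% rep(1, n)
  if (length(dilution) != n || any(dilution <= 0)) abort("`dilution` must be positive, one per sample.")

  # per-molecule unit spectrum over the axis
  shape <- matrix(0, length(ppm_axis), length(mols), dimnames = list(NULL, mols))
  for (k in seq_len(nrow(peaks))) {
    pk <- peaks[k, ]
    m <- pk$multiplicity
    offsets <- (seq_len(m) - (m + 1) / 2) * pk$spacing
    wts <- choose(m - 1, seq_len(m) - 1)
    wts <- wts / sum(wts)
    for (j in seq_len(m)) {
      shape[, pk$molecule] <- shape[, pk$molecule] +
        pk$amplitude * wts[j] *
          exp(-(ppm_axis - (pk$centre + offsets[j]))^2 / (2 * pk$width^2))
    }
  }
  spectra <- (conc %*% t(shape)) * dilution
  if (noise_sd > 0) {
    set.seed(seed)
    spectra <- spectra + matrix(stats::rnorm(length(spectra), sd = noise_sd),
                                nrow(spectra), ncol(spectra))
  }
  dimnames(spectra) <- list(concentrations$sample,
                            sprintf("ppm_%.4f", ppm_axis))
  as_feature_table(spectra, ppm = ppm_axis)
}

#' Simulate compositional taxa count tables with group shifts
#'
#' Draws per-sample compositions from a log-normal model (taxon-level means
#' plus per-sample noise), applies a log-fold shift to the named taxa in
#' group B, renormalises, and samples counts multinomially at the requested
#' depth.
#'
#' @param n_per_group samples per group; scalar or length-2 vector (A, B).
#' @param n_taxa number of taxa.
#' @param shifted_taxa integer indices of taxa shifted in group B.
#' @param log_fold_shift natural-log shift applied to `shifted_taxa` in
#'   group B (e.g. `log(10)` for a 10-fold shift).
#' @param depth sequencing depth (reads per sample, >= 1).
#' @param seed integer seed.
#' @return list with `table` (tibble: `sample` + taxa counts), `design`
#'   (tibble: `sample`, `group`), `taxonomy` (named lineage strings) and
#'   `truth` (shifted taxa, shift, group vector).
#' @export
generate_taxa_counts <- function(n_per_group, n_taxa, shifted_taxa = integer(0),
                                 log_fold_shift = 0, depth = 1e4, seed = 1) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  n_per_group <- vapply(n_per_group, check_count, integer(1), name = "n_per_group")
  n_taxa <- check_count(n_taxa, "n_taxa")
  depth <- check_count(depth, "depth")
  shifted_taxa <- as.integer(shifted_taxa)
  if (length(shifted_taxa) && (any(shifted_taxa < 1) || any(shifted_taxa > n_taxa))) {
    abort("`shifted_taxa` indices out of range.")
  }
  seeds <- split_seed(seed, 3)
  set.seed(seeds[1])
  mu <- stats::rnorm(n_taxa, 0, 1.5)    # taxon log-abundance means (heavy spread)
  n <- sum(n_per_group)
  group <- rep(c("A", "B"), n_per_group)
  set.seed(seeds[2])
  loga <- matrix(mu, n, n_taxa, byrow = TRUE) +
    matrix(stats::rnorm(n * n_taxa, sd = 0.5), n, n_taxa)
  if (length(shifted_taxa)) {
    loga[group == "B", shifted_taxa] <- loga[group == "B", shifted_taxa] + log_fold_shift
  }
  comp <- exp(loga)
  comp <- comp / rowSums(comp)
  set.seed(seeds[3])
  counts <- t(apply(comp, 1, function(p) stats::rmultinom(1, depth, p)[, 1]))
  taxa <- sprintf("taxon%03d", seq_len(n_taxa))
  dimnames(counts) <- list(sprintf("%s%02d", tolower(group), stats::ave(seq_len(n), group, FUN = seq_along)), taxa)
  taxonomy <- stats::setNames(
    sprintf("k__Bacteria|p__P%02d|g__G%03d|s__%s", (seq_len(n_taxa) %% 6) + 1, seq_len(n_taxa), taxa),
    taxa
  )
  list(
    table = as_feature_table(counts),
    design = tibble(sample = rownames(counts), group = group),
    taxonomy = taxonomy,
    truth = list(shifted_taxa = shifted_taxa, log_fold_shift = log_fold_shift,
                 group = stats::setNames(group, rownames(counts)),
                 composition = comp)
  )
}

#' Simulate heavy-tailed metagenomic gene read counts
#'
#' Gene abundances follow a Pareto-like power law (abundance of gene g
#' proportional to g^-skew); reads are drawn multinomially so each sample's
#' counts sum exactly to `total_reads`.
#'
#' @param n_genes catalogue size (>= 1).
#' @param abundance_skew power-law exponent (0 = uniform abundances).
#' @param total_reads reads per sample (>= 1).
#' @param n_samples number of samples (default 1).
#' @param seed integer seed.
#' @return tibble: `sample` column + one integer count column per gene.
#' @export
generate_gene_counts <- function(n_genes, abundance_skew = 1, total_reads = 1e5,
                                 n_samples = 1, seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  total_reads <- check_count(total_reads, "total_reads")
  n_samples <- check_count(n_samples, "n_samples")
  if (abundance_skew < 0) abort("`abundance_skew` must be >= 0.")
  p <- seq_len(n_genes)^(-abundance_skew)
  p <- p / sum(p)
  set.seed(seed)
  counts <- t(stats::rmultinom(n_samples, total_reads, p))
  dimnames(counts) <- list(sprintf("sample%02d", seq_len(n_samples)),
                           sprintf("gene%05d", seq_len(n_genes)))
  as_feature_table(counts)
}

#' Plant feature-covariate correlation structure into a design
#'
#' Replaces the named covariates with rho-weighted mixtures of the
#' rank-standardised target feature and independent Gaussian noise, so that
#' the realised Spearman correlation approximates the target rho.
#'
#' @param table feature tibble supplying the anchor features.
#' @param design paired design whose covariates are replaced.
#' @param links data frame with columns `feature`, `covariate`, `rho`
#'   (each |rho| < 1).
#' @param seed integer seed.
#' @return the design tibble with linked covariate columns regenerated.
#' @export
generate_covariate_structure <- function(table, design, links, seed = 1) {
  links <- as_tibble(links)
  if (any(abs(links$rho) >= 1)) abort("every |rho| must be < 1.")
  bad <- setdiff(links$feature, names(table)[-1])
  if (length(bad)) abort(sprintf("unknown feature(s): %s", paste(bad, collapse = ", ")))
  bad <- setdiff(links$covariate, names(design))
  if (length(bad)) abort(sprintf("unknown covariate(s): %s", paste(bad, collapse = ", ")))
  design <- as_tibble(design)
  idx <- match(design$sample, table$sample)
  if (anyNA(idx)) abort("every design sample must appear in the feature table.")
  set.seed(seed)
  n <- nrow(design)
  for (k in seq_len(nrow(links))) {
    f <- table[[links$feature[k]]][idx]
    z <- stats::qnorm(rank(f, ties.method = "average") / (n + 1))  # rank-standardise
    z <- as.vector(scale(z))
    rho <- links$rho[k]
    design[[links$covariate[k]]] <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
  }
  design
}
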