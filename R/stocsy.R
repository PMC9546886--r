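#' Statistical total correlation spectroscopy (STOCSY)
#'
#' Correlates the intensity of one spectral variable (the driver, snapped to
#' the nearest grid point) with every variable across samples.  Resonances
#' belonging to the same molecule share a concentration factor and therefore
#' show correlations near 1, which supports structural assignment.
#'
#' @param spectra feature tibble with a ppm axis (>= 4 spectra).
#' @param driver_ppm chemical shift of the driver peak (within the axis
#'   range; snapped to the nearest grid point, echoed in the result).
#' @return object of class `stocsy_trace`: `trace` (tibble `ppm`, `feature`,
#'   `r`, `covariance`), `driver_ppm` (snapped), `driver_feature`.
#' @export
stocsy_trace <- function(spectra, driver_ppm) {
  spectra <- as_feature_table(spectra)
  ppm <- feature_ppm(spectra)
  if (is.null(ppm)) abort("`spectra` has no ppm axis.")
  x <- feature_values(spectra)
  if (nrow(x) < 4) abort("STOCSY needs >= 4 spectra.")
  rng <- range(ppm)
  if (driver_ppm < rng[1] || driver_ppm > rng[2]) abort("`driver_ppm` outside the axis range.")
  j <- which.min(abs(ppm - driver_ppm))
  drv <- x[, j]
  if (stats::sd(drv) == 0) abort("zero-variance driver peak.")
  r <- suppressWarnings(as.vector(stats::cor(x, drv)))
  cv <- as.vector(stats::cov(x, drv))
  structure(list(
    trace = tibble(ppm = ppm, feature = colnames(x), r = r, covariance = cv),
    driver_ppm = ppm[j], driver_feature = colnames(x)[j]
  ), class = "stocsy_trace")
}

#' @export
tidy.stocsy_trace <- function(x, ...) x$trace

#' Candidate peaks from a STOCSY trace
#'
#' Collapses contiguous runs of features with correlation at or above the
#' threshold to their apex (maximum r), yielding a shortlist of resonances
#' likely to share a molecule with the driver.
#'
#' @param trace a `stocsy_trace`.
#' @param r_threshold correlation threshold in (0, 1].
#' @return tibble: `ppm`, `r` of each candidate apex.
#' @export
stocsy_peak_candidates <- function(trace, r_threshold = 0.8) {
  if (r_threshold <= 0 || r_threshold > 1) abort("`r_threshold` must be in (0, 1].")
  tr <- trace$trace
  above <- !is.na(tr$r) & tr$r >= r_threshold
  if (!any(above)) return(tibble(ppm = numeric(0), r = numeric(0)))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  purrr::map_dfr(which(runs$values), function(k) {
    idx <- starts[k]:ends[k]
    # apex by covariance (intensity-scaled), so tied r values within a run
    # still resolve to the resonance maximum
    apex <- idx[which.max(abs(tr$covariance[idx]))]
    tibble(ppm = tr$ppm[apex], r = tr$r[apex])
  })
}

#' Relative metabolite concentration from a representative peak
#'
#' Per-sample apex (maximum) intensity within a ppm window around a
#' representative spectral peak; with `mode = "integral"` the trapezoidal
#' integral over the window is used instead.
#'
#' @param spectra feature tibble with a ppm axis.
#' @param peak_ppm peak position (within the axis).
#' @param window half-width of the window in ppm (> 0).
#' @param mode `"apex"` (default) or `"integral"`.
#' @return tibble: `sample`, `concentration`.
#' @export
peak_relative_concentration <- function(spectra, peak_ppm, window,
                                        mode = c("apex", "integral")) {
  mode <- match.arg(mode)
  check_positive(window, "window")
  spectra <- as_feature_table(spectra)
  ppm <- feature_ppm(spectra)
  if (is.null(ppm)) abort("`spectra` has no ppm axis.")
  idx <- which(abs(ppm - peak_ppm) <= window)
  if (!length(idx)) abort("the window contains no grid point.")
  x <- feature_values(spectra)[, idx, drop = FALSE]
  conc <- if (mode == "apex" || length(idx) == 1) {
    apply(x, 1, max)
  } else {
    w <- ppm[idx]
    abs(apply(x, 1, function(row) {
      sum(diff(w) * (utils::head(row, -1) + utils::tail(row, -1)) / 2)
    }))
  }
  tibble(sample = spectra$sample, concentration = unname(conc))
}
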