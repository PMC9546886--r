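# shared fixture builders; everything is generated in code at test time

# tiny paired design with post - pre differences fixed per feature
paired_from_diffs <- function(diffs, n_features = length(diffs), base = 10) {
  n <- length(diffs)
  pre <- matrix(base, n, n_features)
  post <- pre + matrix(diffs, n, n_features)
  vals <- rbind(pre, post)
  rownames(vals) <- c(sprintf("s%02d_pre", 1:n), sprintf("s%02d_post", 1:n))
  colnames(vals) <- sprintf("f%02d", seq_len(n_features))
  list(
    table = as_feature_table(vals),
    design = tibble::tibble(
      sample = rownames(vals),
      subject = rep(sprintf("s%02d", 1:n), 2),
      timepoint = rep(c("pre", "post"), each = n),
      class = rep(c("pre", "post"), each = n)
    )
  )
}

# two-molecule reference spectrum set used by several STOCSY tests
two_molecule_peaks <- function() {
  tibble::tibble(
    molecule = c("lactate", "lactate", "citrate"),
    centre = c(1.33, 4.11, 2.55),
    width = c(0.01, 0.01, 0.012),
    multiplicity = c(2, 4, 2),
    amplitude = c(3, 1, 2)
  )
}

default_ppm_axis <- function() seq(0.5, 4.5, by = 0.005)
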