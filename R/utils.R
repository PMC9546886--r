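#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# internal: deterministic expansion of one user seed into per-component seeds.
# set.seed(seed) then draw n integers below 2^31 - 1; documented in the
# methods vignette so that component-level runs can be reproduced in isolation.
split_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d (got %s).", name, min, deparse(x)))
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
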