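#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_area labs theme_minimal
NULL

#' Manhattan plot of RM-MCCV feature significance
#'
#' Signed -log10(q) per feature with dotted lines at the q-threshold cut.
#'
#' @param object an `rm_mccv` fit.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rm_mccv <- function(object, ...) {
  man <- manhattan_table(object)
  man$index <- seq_len(nrow(man))
  ggplot(man, aes(x = .data$index, y = .data$score, colour = .data$significant)) +
    geom_point(size = 0.8) +
    geom_hline(yintercept = c(-man$cut[1], man$cut[1]), linetype = "dotted") +
    labs(x = "feature index", y = expression(-log[10](q) %*% sign(beta)),
         colour = paste0("q ≤ ", object$params$q_threshold)) +
    theme_minimal()
}

#' Cross-validated score densities per group
#'
#' @param result an `rm_mccv` fit.
#' @return a ggplot object of the per-timepoint Gaussian KDEs of T_pred.
#' @export
plot_tpred_density <- function(result) {
  dens <- tpred_density(result)
  ggplot(dens, aes(x = .data$t, y = .data$density, fill = .data$group)) +
    geom_area(alpha = 0.4, position = "identity") +
    labs(x = expression(T[pred]), y = "density") +
    theme_minimal()
}

#' @rdname pcoa
#' @param object a `pcoa_result`.
#' @param colour optional vector of group labels, one per sample.
#' @param ... unused.
#' @export
autoplot.pcoa_result <- function(object, colour = NULL, ...) {
  pts <- object$points
  if (!is.null(colour)) pts$group <- colour
  pr <- round(100 * object$proportion[1:2], 1)
  p <- ggplot(pts, aes(x = .data$Axis1, y = .data$Axis2)) +
    labs(x = sprintf("PCo1 (%.1f%%)", pr[1]), y = sprintf("PCo2 (%.1f%%)", pr[2])) +
    theme_minimal()
  if (is.null(colour)) p + geom_point() else p + geom_point(aes(colour = .data$group))
}

#' @rdname stocsy_trace
#' @param object a `stocsy_trace`.
#' @param ... unused.
#' @export
autoplot.stocsy_trace <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$ppm, y = .data$covariance, colour = abs(.data$r))) +
    geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    labs(x = "chemical shift (ppm)", y = "covariance with driver",
         colour = "|r|",
         title = sprintf("STOCSY, driver %.4g ppm", object$driver_ppm)) +
    theme_minimal()
}
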