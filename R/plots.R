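#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman residual plot
#'
#' Difference against ground truth per measurement, with horizontal lines at
#' the bias (solid) and the 95% limits of agreement (dashed). With jittered
#' repeated measurements all 27 points of a scan share one truth value,
#' producing the characteristic vertical point patterns.
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$truth, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", linewidth = 0.5) +
    ggplot2::labs(x = "True noise (HU)",
                  y = "Measured - true noise (HU)",
                  subtitle = sprintf("bias %.2f HU, LoA distance %.2f HU (n = %d)",
                                     object$bias, object$loa_distance, object$n)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman panels for a noise study
#'
#' One Bland-Altman residual panel per measurement shape (circular ROI,
#' spherical VOI), on a shared difference axis so the narrower limits of
#' agreement of the volume-based method are directly visible.
#'
#' @param object A `noise_study`.
#' @param ... Unused.
#' @return A ggplot with one facet per shape.
#' @method autoplot noise_study
#' @export
autoplot.noise_study <- function(object, ...) {
  refs <- dplyr::bind_rows(lapply(c("circle", "sphere"), function(sh) {
    ba <- object$agreement[[sh]]
    tibble(shape = sh, bias = ba$bias, loa_low = ba$loa_low,
           loa_high = ba$loa_high)
  }))
  kept <- object$measurements[!object$measurements$excluded, ]
  kept$diff <- kept$noise_hu - kept$true_noise_hu
  ggplot2::ggplot(kept, ggplot2::aes(x = .data$true_noise_hu, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.9) +
    ggplot2::geom_hline(data = refs, ggplot2::aes(yintercept = .data$bias),
                        linewidth = 0.6) +
    ggplot2::geom_hline(data = refs, ggplot2::aes(yintercept = .data$loa_low),
                        linetype = "dashed", linewidth = 0.5) +
    ggplot2::geom_hline(data = refs, ggplot2::aes(yintercept = .data$loa_high),
                        linetype = "dashed", linewidth = 0.5) +
    ggplot2::facet_wrap(~shape, labeller = ggplot2::as_labeller(
      c(circle = "Circular ROI", sphere = "Spherical VOI"))) +
    ggplot2::labs(x = "True noise (HU)", y = "Measured - true noise (HU)") +
    ggplot2::theme_minimal()
}
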