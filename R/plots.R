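#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Kaplan-Meier step curves
#'
#' @param object A `km_fit` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot of per-group survival step functions.
#' @export
autoplot.km_fit <- function(object, ...) {
  start <- object |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, surv = 1)
  curves <- dplyr::bind_rows(
    start,
    object[, c("group", "time", "surv")]
  ) |>
    dplyr::arrange(.data$group, .data$time)
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$time, .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability",
                  colour = "Score group") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.signature_survival <- function(object, ...) {
  p <- autoplot(object$km)
  lab <- sprintf("log-rank p = %.3g", object$logrank$p_value)
  p + ggplot2::ggtitle("Target-network signature survival", subtitle = lab)
}

#' Screen classification scatter plot
#'
#' CV against class-vector correlation for every miRNA, coloured by label,
#' with the selection cutoffs drawn as reference lines.
#'
#' @param object A `mirna_screen` tibble from [classify_mirnas()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirna_screen <- function(object, ...) {
  co <- attr(object, "cutoffs")
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$r, .data$cv, colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-co[["corr"]], co[["corr"]]),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = co[["cv"]], linetype = "dashed") +
    ggplot2::labs(x = "Correlation with class vector",
                  y = "Coefficient of variation", colour = "Label") +
    ggplot2::theme_minimal()
}
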