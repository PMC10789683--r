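## Figures mirroring the study's presentation: Bland-Altman panels with
## per-subject markers, and repeated-measures scatter with parallel
## per-subject fits.

#' Bland-Altman plot for one comparison
#'
#' @param report a [run_study()] report.
#' @param comparison one of `"cdcvp_vs_dppl"`, `"pes_vs_dppl"`,
#'   `"pes_vs_cdcvp"`.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(report, comparison = "cdcvp_vs_dppl") {
  stopifnot(inherits(report, "study_report"),
            comparison %in% names(COMPARISONS))
  spec <- COMPARISONS[[comparison]]
  dat <- report$exclusions$sets[[spec$set]]
  ba <- report$agreement
  ba <- ba[ba$comparison == comparison & ba$stratum == "overall", ]
  df <- tibble::tibble(
    avg = (dat[[spec$est]] + dat[[spec$ref]]) / 2,
    diff = dat[[spec$est]] - dat[[spec$ref]],
    subject = factor(dat$subject)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$avg, .data$diff,
                                   shape = .data$subject)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = ba$bias) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::scale_shape_manual(
      values = rep(c(16, 17, 15, 3, 7, 8, 5, 6, 4, 1), length.out =
                     nlevels(df$subject))) +
    ggplot2::labs(
      x = "mean of methods (cmH2O)", y = "difference (cmH2O)",
      title = spec$label,
      subtitle = sprintf("bias %.2f, limits of agreement %.2f to %.2f cmH2O",
                         ba$bias, ba$loa_low, ba$loa_high)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Repeated-measures scatter plot for one comparison
#'
#' One colour per subject with parallel common-slope fits, the graphical
#' counterpart of [rmcorr()].
#'
#' @inheritParams plot_bland_altman
#' @return a ggplot object.
#' @export
plot_rmcorr <- function(report, comparison = "cdcvp_vs_dppl") {
  stopifnot(inherits(report, "study_report"),
            comparison %in% names(COMPARISONS))
  spec <- COMPARISONS[[comparison]]
  dat <- report$exclusions$sets[[spec$set]]
  df <- tibble::tibble(
    x = dat[[spec$ref]], y = dat[[spec$est]], subject = factor(dat$subject)
  )
  xc <- df$x - ave(df$x, df$subject)
  yc <- df$y - ave(df$y, df$subject)
  slope <- sum(xc * yc) / sum(xc^2)
  fits <- dplyr::summarise(
    dplyr::group_by(df, .data$subject),
    intercept = mean(.data$y) - slope * mean(.data$x), .groups = "drop")
  fits$slope <- slope
  r <- report$rmcorr[[comparison]]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$subject)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(
      data = fits,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$subject),
      alpha = 0.6) +
    ggplot2::labs(
      x = "reference swing (cmH2O)", y = "estimated swing (cmH2O)",
      title = spec$label,
      subtitle = if (!is.null(r)) {
        sprintf("rmcorr r = %.3f (df = %d, p = %.2g)", r$r, r$df, r$p)
      } else NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
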