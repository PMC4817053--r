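# ggplot2 visualisations for each result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an extracted ion chromatogram
#'
#' @param object an `"xic"` from [extract_xic()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot xic
#' @export
autoplot.xic <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$scan_time, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Retention time (min)", y = "Intensity",
      title = sprintf("XIC (%d target(s), %.3g ppm)",
                      length(attr(object, "targets")),
                      attr(object, "tolerance_ppm"))) +
    ggplot2::theme_minimal()
}

#' Plot an activity time course
#'
#' -log10 fold change of the phosphorylation level per time window, the
#' conventional display for dephosphorylation progress.
#'
#' @param object an `"activity_timecourse"` from
#'   [activity_fold_change()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot activity_timecourse
#' @export
autoplot.activity_timecourse <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$window_start + df$window_end) / 2
  ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$neg_log10_fold)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)",
                  y = expression(-log[10] ~ "(fold change)"),
                  title = "Phosphatase activity time course") +
    ggplot2::theme_minimal()
}

#' Plot a per-residue discriminability profile
#'
#' @param object a `"discriminability_profile"`.
#' @param ... unused.
#' @return a ggplot with the eta threshold drawn as a dashed line.
#' @method autoplot discriminability_profile
#' @export
autoplot.discriminability_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$residue, .data$eta)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$flagged),
                      show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = attr(object, "eta_crit"),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55",
                                          `TRUE` = "firebrick")) +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = "Residue", y = expression(eta),
                  title = "Per-residue ensemble discriminability") +
    ggplot2::theme_minimal()
}

#' Plot a Michaelis-Menten fit
#'
#' Initial velocities with the fitted saturation curve.
#'
#' @param object an `"mm_fit"`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  s_grid <- seq(0, max(object$data$substrate_mM) * 1.05, length.out = 200)
  curve <- tibble::tibble(
    substrate_mM = s_grid,
    v0 = object$Vmax * s_grid / (object$Km + s_grid))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$substrate_mM, .data$v0)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "[S] (mM)", y = expression(v[0] ~ "(mM/min)"),
                  title = sprintf("Michaelis-Menten fit: Km = %.3g mM, Vmax = %.3g mM/min",
                                  object$Km, object$Vmax)) +
    ggplot2::theme_minimal()
}
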