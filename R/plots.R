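# Publication-style plots: Michaelis-Menten panels, double-reciprocal line
# families, secondary replots. Plots mirror the classical presentation for
# visual comparison; they are never an analysis input.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_bad_arg("plotting requires the ggplot2 package")
}

#' Plot a Michaelis-Menten fit
#'
#' Points with the fitted hyperbola; excluded (windowed-out) points from the
#' full dataset, if supplied, are shown hollow.
#'
#' @param fit An [fit_mm()] result.
#' @param full_data Optional full data frame (`S`, `v`) including excluded
#'   points.
#' @return A ggplot object.
#' @export
plot_mm_fit <- function(fit, full_data = NULL) {
  need_ggplot()
  stopifnot(inherits(fit, "mm_fit"))
  grid <- data.frame(S = seq(0, max(fit$data$S) * 1.05, length.out = 200))
  grid$v <- fit$V * grid$S / (fit$KM + grid$S)
  gg <- ggplot2::ggplot(fit$data, ggplot2::aes(x = .data$S, y = .data$v)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "[S] (mM)", y = "v",
                  title = sprintf("KM = %.3g mM, V = %.3g", fit$KM, fit$V)) +
    ggplot2::theme_classic()
  if (!is.null(full_data)) {
    excl <- full_data[full_data$S > fit$window_max, , drop = FALSE]
    if (nrow(excl))
      gg <- gg + ggplot2::geom_point(data = excl, shape = 1)
  }
  gg
}

#' Plot a double-reciprocal line family
#'
#' @param fam A [primary_reciprocal_fits()] family.
#' @return A ggplot object.
#' @export
plot_double_reciprocal <- function(fam) {
  need_ggplot()
  stopifnot(inherits(fam, "line_family"))
  pts <- attr(fam, "points")
  df <- do.call(rbind, lapply(names(pts), function(nm)
    cbind(pts[[nm]], level = nm)))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$level)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0("1/[", attr(fam, "varied_label"), "] (mM^-1)"),
                  y = "1/v",
                  colour = paste0("[", attr(fam, "fixed_label"), "] (mM)")) +
    ggplot2::theme_classic()
  for (i in seq_len(nrow(fam)))
    gg <- gg + ggplot2::geom_abline(slope = fam$slope[i],
                                    intercept = fam$intercept[i],
                                    linewidth = 0.3, colour = "grey40")
  gg
}

#' Plot a secondary slope replot
#'
#' @param sp A [secondary_slope_replot()] result.
#' @return A ggplot object.
#' @export
plot_secondary <- function(sp) {
  need_ggplot()
  stopifnot(inherits(sp, "secondary_plot"))
  df <- data.frame(x = sp$x, y = sp$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = sp$slope, intercept = sp$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = paste0("1/[", sp$fixed_label, "] (mM^-1)"),
                  y = "primary slope",
                  title = sprintf("intercept = %.3g (origin p = %.3g)",
                                  sp$intercept, sp$origin_p)) +
    ggplot2::theme_classic()
}
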