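# ggplot2 methods for the result types.

#' Plot site-specific cleavage yields
#'
#' Bar chart of per-site c (filled) and y (open) yields with guanosine
#' sites marked by dashed lines.
#'
#' @param object A `cleavage_yields` table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cleavage_yields
#' @export
autoplot.cleavage_yields <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("site", "g_site", "yield_c", "yield_y")],
    cols = c("yield_c", "yield_y"), names_to = "ion", values_to = "yield"
  )
  long$ion <- ifelse(long$ion == "yield_c", "c", "y")
  g_sites <- object$site[object$g_site]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$site, y = .data$yield,
                                     fill = .data$ion)) +
    ggplot2::geom_col(position = "dodge", colour = "black",
                      linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = g_sites, linetype = "dashed",
                        colour = "red3", alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(c = "grey25", y = "white")) +
    ggplot2::labs(x = "cleavage site", y = "yield (% of all c/y)",
                  fill = "ion",
                  title = paste0("Site-specific c/y yields (n = ",
                                 attr(object, "n"), ")")) +
    ggplot2::theme_classic()
}

#' Plot a fold-change correlation
#'
#' Log-log scatter of normalized fragment signals, modified versus
#' reference run, with the identity line; fragments from the site of
#' interest are highlighted.
#'
#' @param object A `fold_change` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fold_change
#' @export
autoplot.fold_change <- function(object, ...) {
  pairs <- object$pairs
  pairs$highlight <- pairs$site == object$site
  pairs <- pairs[pairs$norm_abundance_ref > 0 &
                   pairs$norm_abundance_mod > 0, , drop = FALSE]
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$norm_abundance_ref,
                                      y = .data$norm_abundance_mod,
                                      colour = .data$highlight)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red3")) +
    ggplot2::labs(
      x = "reference signal (normalized)",
      y = "modified signal (normalized)",
      colour = paste("site", object$site),
      title = sprintf("Fold change at site %d: %.1f", object$site,
                      object$fold_change)
    ) +
    ggplot2::theme_classic()
}

#' Plot a peak list as a stick spectrum
#'
#' @param peaks Peak-list tibble.
#' @return A ggplot.
#' @export
plot_spectrum <- function(peaks) {
  ggplot2::ggplot(peaks, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                      y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment() +
    ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_classic()
}

#' Plot hydrolysis site yields over time
#'
#' @param site_yields Output of [hydrolysis_site_yields()].
#' @return A ggplot with one curve per site, guanosine sites coloured.
#' @export
plot_hydrolysis_timecourse <- function(site_yields) {
  ggplot2::ggplot(site_yields,
                  ggplot2::aes(x = .data$time, y = .data$yield,
                               group = .data$site,
                               colour = .data$g_site)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "forestgreen")) +
    ggplot2::labs(x = "time (h)", y = "site yield (%)",
                  colour = "5' of G") +
    ggplot2::theme_classic()
}
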