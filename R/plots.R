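# ggplot2 views of the main result types. Each plot_* function has an
# autoplot() alias on the corresponding class.

#' Plot a conservation profile
#'
#' Per-column information content (bits) with an optional domain strip.
#'
#' @param profile a `conservation_profile`.
#' @return a ggplot.
#' @export
plot_conservation <- function(profile) {
  df <- tibble(column = seq_along(profile$info), information = profile$info,
               domain = profile$domain %||% NA_character_)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$information)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::labs(x = "alignment column", y = "information (bits)") +
    ggplot2::theme_minimal()
  if (any(!is.na(df$domain))) {
    p <- p + ggplot2::geom_tile(
      data = df[!is.na(df$domain), ],
      ggplot2::aes(y = -0.2, fill = .data$domain), height = 0.3) +
      ggplot2::scale_fill_viridis_d(option = "turbo", name = "domain")
  }
  p
}

#' @export
autoplot.conservation_profile <- function(object, ...) plot_conservation(object)

#' Plot a hydropathy profile with transmembrane calls
#'
#' @param tm a `tm_prediction`.
#' @param threshold call threshold to draw.
#' @return a ggplot.
#' @export
plot_hydropathy <- function(tm, threshold = 1.6) {
  df <- tibble(position = seq_along(tm$hydropathy), score = tm$hydropathy)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "red") +
    ggplot2::labs(x = "residue", y = "Kyte-Doolittle hydropathy") +
    ggplot2::theme_minimal()
  if (nrow(tm$segments) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = tm$segments, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.15, fill = "steelblue")
  }
  p
}

#' @export
autoplot.tm_prediction <- function(object, ...) plot_hydropathy(object)

#' Plot per-site selection results
#'
#' -log10 p-value by site, coloured by call.
#'
#' @param results a `site_selection` tibble (from [slac()] or [fel()]).
#' @return a ggplot.
#' @export
plot_site_selection <- function(results) {
  df <- as_tibble(results)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site,
                                   y = -log10(pmax(.data$p_value, 1e-16)),
                                   colour = .data$call)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(positive = "firebrick",
                                            negative = "steelblue",
                                            neutral = "grey60")) +
    ggplot2::labs(x = "codon site", y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.site_selection <- function(object, ...) plot_site_selection(object)

#' Plot a breakpoint scan
#'
#' @param x a `breakpoint_result`.
#' @return a ggplot.
#' @export
plot_breakpoint_scan <- function(x) {
  p <- ggplot2::ggplot(x$scan, ggplot2::aes(x = .data$candidate,
                                            y = .data$improvement)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "candidate breakpoint (codon)",
                  y = "two-tree fit improvement") +
    ggplot2::theme_minimal()
  if (!is.na(x$breakpoint)) {
    p <- p + ggplot2::geom_vline(xintercept = x$breakpoint, colour = "red",
                                 linetype = 2)
  }
  p
}

#' @export
autoplot.breakpoint_result <- function(object, ...) plot_breakpoint_scan(object)
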