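# broom-style tidiers for fitted objects.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tidy.mg94_fit <- function(x, ...) {
  tibble(term = c("omega", "kappa", "scale"),
         estimate = c(x$omega, x$kappa, x$scale),
         conf.low = c(if (is.null(x$ci)) NA_real_ else x$ci[[1]], NA, NA),
         conf.high = c(if (is.null(x$ci)) NA_real_ else x$ci[[2]], NA, NA))
}

#' @export
glance.mg94_fit <- function(x, ...) {
  tibble(logLik = x$loglik, omega = x$omega, kappa = x$kappa,
         sig_diff_from_1 = x$sig_diff_from_1, n_sites = x$n_sites,
         n_taxa = x$n_taxa, converged = x$converged)
}

#' @export
tidy.site_selection <- function(x, ...) as_tibble(x)

#' @export
glance.site_selection <- function(x, ...) {
  tibble(method = unique(x$method),
         n_sites = attr(x, "n_sites") %||% max(x$site),
         n_positive = sum(x$call == "positive"),
         n_negative = sum(x$call == "negative"),
         alpha_level = attr(x, "alpha_level") %||% NA_real_)
}

#' @export
tidy.repertoire_summary <- function(x, ...) x$by_family

#' @export
glance.repertoire_summary <- function(x, ...) {
  tibble(n_genes = x$n_genes, intact = x$totals[["intact"]],
         partial = x$totals[["partial"]],
         pseudogene = x$totals[["pseudogene"]],
         truncated = x$totals[["truncated"]],
         ratio_disrupted_intact = x$ratio_disrupted_intact)
}

#' @export
tidy.breakpoint_result <- function(x, ...) x$scan

#' @export
glance.breakpoint_result <- function(x, ...) {
  tibble(breakpoint = x$breakpoint, improvement = x$improvement,
         p_value = x$p_value, n_partitions = length(x$partitions))
}
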