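#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a REML mixed-model fit
#'
#' `tidy()` returns one row per term: fixed effects (with Wald statistics)
#' and/or variance components; `glance()` returns the one-row model summary.
#'
#' @param x an `mg_lmm` fit.
#' @param effects `"fixed"`, `"varcomp"` or both (default).
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.mg_lmm <- function(x, effects = c("fixed", "varcomp"), ...) {
  effects <- match.arg(effects, several.ok = TRUE)
  out <- list()
  if ("fixed" %in% effects) {
    w <- wald_fixed(x)
    out$fixed <- dplyr::mutate(
      dplyr::rename(w, term = "effect"),
      effect_type = "fixed", .before = 1)
  }
  if ("varcomp" %in% effects) {
    out$varcomp <- dplyr::mutate(
      dplyr::rename(x$varcomp, term2 = "term"),
      effect_type = "varcomp", .before = 1) |>
      dplyr::rename(term = "term2")
  }
  dplyr::bind_rows(out)
}

#' @rdname tidy.mg_lmm
#' @export
glance.mg_lmm <- function(x, ...) {
  tibble(logLik = x$loglik_reml, deviance = x$deviance,
         nobs = x$n_obs, n_fixed = x$n_fixed, n_varcomp = x$n_par,
         converged = x$converged)
}

#' Tidy a selection-response fit
#'
#' One row per cycle contrast (vs the C0 baseline), with the per-cycle
#' genetic variance joined in; `glance()` reports the variance-homogeneity
#' likelihood-ratio test and fit summary.
#'
#' @param x an `mg_selresp` object.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.mg_selresp <- function(x, ...) {
  dplyr::left_join(
    dplyr::mutate(x$cycle_effects, trait = x$trait, .before = 1),
    x$cycle_variances, by = "cycle")
}

#' @rdname tidy.mg_selresp
#' @export
glance.mg_selresp <- function(x, ...) {
  tibble(trait = x$trait, lrt_stat = x$lrt_hom_vs_het$stat,
         lrt_df = x$lrt_hom_vs_het$df, lrt_p = x$lrt_hom_vs_het$p,
         logLik = x$fit$loglik_reml, converged = x$fit$converged)
}

#' Plot a genetic-correlation scan over after-ripening time
#'
#' Recreates the correlation-over-time panel: one facet per malting trait,
#' timepoint on the x axis, genetic correlation with the germination trait
#' on the y axis, one line per allele group, significant correlations
#' (LRT p below the scan's star threshold) marked with an asterisk.
#'
#' @param scan result of [correlation_scan()].
#' @return a ggplot object.
#' @export
plot_correlation_scan <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$timepoint, y = .data$r_g,
                                     colour = .data$group,
                                     group = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_text(data = function(d) d[which(d$star), , drop = FALSE],
                       ggplot2::aes(label = "*"), vjust = -0.4, size = 5,
                       show.legend = FALSE) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "after-ripening timepoint",
                  y = "genetic correlation with germination rate",
                  colour = "HvMKK3 group") +
    ggplot2::theme_minimal()
}

#' Trait-relationship biplot
#'
#' Plots PC1-PC2 loadings of a trait correlation matrix as arrows from the
#' origin; arrows pointing the same way are positively correlated traits.
#'
#' @param decomp result of [biplot_decomposition()].
#' @return a ggplot object.
#' @export
plot_biplot <- function(decomp) {
  lo <- decomp$loadings
  ve <- round(100 * decomp$variance_explained, 1)
  ggplot2::ggplot(lo, ggplot2::aes(x = 0, y = 0, xend = .data$PC1,
                                   yend = .data$PC2)) +
    ggplot2::geom_segment(arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(ggplot2::aes(x = .data$PC1 * 1.08, y = .data$PC2 * 1.08,
                                    label = .data$trait),
                       inherit.aes = FALSE, size = 3) +
    ggplot2::labs(x = paste0("PC1 (", ve[1], "%)"),
                  y = paste0("PC2 (", ve[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Plot the correlated response to selection
#'
#' Each cycle is drawn at its mean PHS score (GI at the first timepoint,
#' lower = more resistant) against the malting-trait mean, with a vertical
#' band of ± 2 genetic standard deviations and the Wald significance stars
#' of the cycle contrasts.
#'
#' @param summary result of [response_summary()] (rows for one or more traits).
#' @return a ggplot object.
#' @export
plot_selection_response <- function(summary) {
  x_col <- if ("phs_mean" %in% names(summary) &&
               !all(is.na(summary$phs_mean))) "phs_mean" else "cycle"
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes(x = .data[[x_col]], y = .data$trait_mean,
                                    colour = .data$cycle)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$star), vjust = -1,
                       show.legend = FALSE) +
    ggplot2::labs(x = if (x_col == "phs_mean")
      "mean PHS score (GI at TP1)" else "selection cycle",
      y = "trait value", colour = "cycle") +
    ggplot2::theme_minimal()
  if ("trait" %in% names(summary) && length(unique(summary$trait)) > 1) {
    p <- p + ggplot2::facet_wrap(~trait, scales = "free_y")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_correlation_scan
#' @param object,... autoplot interface.
#' @export
autoplot.mg_scan <- function(object, ...) plot_correlation_scan(object)
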