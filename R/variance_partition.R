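#' Technical repeatability of a malting assay
#'
#' Fits the plot-replicate model \eqn{Y = \mu + p_i + e} per trait x year x
#' malting timepoint, with a random plot effect, and returns the
#' repeatability \eqn{\sigma^2_{pl} / (\sigma^2_{pl} + \sigma^2_e)} — the
#' "technical heritability" of the assay — together with both components.
#'
#' @param data phenotype records for one trait x year x timepoint (long format
#'   with `plot_id`, `value`; extra rows of other traits may be present if
#'   `trait`/`year`/`timepoint` filters are supplied).
#' @param trait,year,timepoint optional filters applied before fitting.
#' @return tibble with `repeatability`, `sigma2_pl`, `sigma2_e`, `n_plots`,
#'   `n_obs`, `converged`.
#' @export
technical_repeatability <- function(data, trait = NULL, year = NULL,
                                    timepoint = NULL) {
  d <- filter_scope(data, trait, year, timepoint)
  d <- d[!is.na(d$value), , drop = FALSE]
  reps <- table(d$plot_id)
  if (!any(reps >= 2)) {
    abort("technical_repeatability: no plot has >= 2 technical replicates")
  }
  fit <- fit_lmm(d, value ~ 1, random = list(ranef_iid("plot_id")))
  s_pl <- get_varcomp(fit, "plot_id")
  s_e <- get_varcomp(fit, ".residual")
  tibble(repeatability = s_pl / (s_pl + s_e),
         sigma2_pl = s_pl, sigma2_e = s_e,
         n_plots = length(reps), n_obs = nrow(d), converged = fit$converged)
}

#' Within-year line x timepoint variance partition
#'
#' Fits, per trait and year, \eqn{Y = T_i + g_j + g{:}T_{ij} + e} with a
#' fixed timepoint effect and random line and line-by-timepoint effects,
#' returning \eqn{\sigma^2_g}, \eqn{\sigma^2_{g:TP}} and the residual. The
#' line-by-timepoint component confounds genuine after-ripening change with
#' plot-level sampling error; [delta_gtp()] separates the two using the
#' replicated-check estimate from [check_plot_error()].
#'
#' @inheritParams technical_repeatability
#' @return tibble with `sigma2_g`, `sigma2_gTP`, `sigma2_e`, `loglik`,
#'   `n_lines`, `n_obs`, `converged` plus scope columns.
#' @export
within_year_partition <- function(data, trait = NULL, year = NULL) {
  d <- filter_scope(data, trait, year, NULL)
  d <- d[!is.na(d$value), , drop = FALSE]
  if (length(unique(d$timepoint)) < 2) {
    abort(paste0("within_year_partition needs >= 2 timepoints; ",
                 "use technical_repeatability for a single timepoint"))
  }
  fit <- fit_lmm(d, value ~ factor(timepoint),
                 random = list(ranef_iid("line_id"),
                               ranef_iid(c("line_id", "timepoint"))))
  tibble(trait = trait %||% single_or_na(d$trait),
         year = year %||% single_or_na(d$year),
         sigma2_g = get_varcomp(fit, "line_id"),
         sigma2_gTP = get_varcomp(fit, "line_id:timepoint"),
         sigma2_e = get_varcomp(fit, ".residual"),
         loglik = fit$loglik_reml, n_lines = length(unique(d$line_id)),
         n_obs = nrow(d), converged = fit$converged)
}

#' Plot-level error variance from the replicated check
#'
#' The repeated check cultivar (grain from a single lot, replicated every 15
#' samples) carries no genetic variance, so the variance of its per-plot
#' means in excess of the assay error measures the plot-level sampling error
#' \eqn{\sigma^2_{pltE}}: sample variance of check plot means minus
#' `assay_error / mean technical replicates`. A negative estimate is
#' reported as-is and flagged, never truncated. Fewer than 5 check plots is
#' an error; 5–9 produces a wide-uncertainty flag.
#'
#' @param check_values numeric vector of per-plot check means (or a data frame
#'   with `plot_id` and `value` at technical-replicate level, which is
#'   averaged per plot first).
#' @param assay_error assay (extraction) error variance, typically
#'   `sigma2_e` from [technical_repeatability()].
#' @param reps mean number of technical replicates behind each check plot
#'   mean; inferred when a data frame is supplied.
#' @return tibble with `sigma2_pltE`, `n_checks`, `negative`, `low_n` flags.
#' @export
check_plot_error <- function(check_values, assay_error, reps = 1) {
  n_strata <- 1L
  if (is.data.frame(check_values)) {
    d <- check_values[!is.na(check_values$value), , drop = FALSE]
    means <- tapply(d$value, d$plot_id, mean)
    reps <- mean(table(d$plot_id))
    ## fixed year/timepoint shifts are not plot error: centre within stratum
    strata <- intersect(c("year", "timepoint"), names(d))
    if (length(strata)) {
      key <- do.call(paste, d[match(names(means), d$plot_id), strata,
                              drop = FALSE])
      means <- means - stats::ave(means, key)
      n_strata <- length(unique(key))
    }
    check_values <- as.numeric(means)
  }
  n <- length(check_values)
  if (n < 5) abort("check_plot_error: fewer than 5 check plots")
  est <- sum((check_values - mean(check_values))^2) / (n - n_strata) -
    assay_error / reps
  low_n <- n < 10
  if (low_n) warn("check_plot_error: < 10 check plots; estimate has wide uncertainty")
  if (est < 0) warn("check_plot_error: negative plot-error estimate (reported as-is)")
  tibble(sigma2_pltE = est, n_checks = n, mean_reps = reps,
         negative = est < 0, low_n = low_n)
}

#' After-ripening change variance and its diagnostic ratios
#'
#' Decomposes the line-by-timepoint variance as
#' \eqn{\sigma^2_{g:TP} \approx \sigma^2_{\Delta g:TP} + \sigma^2_{pltE}}:
#' the part of the interaction due to genuine change in the trait between
#' malting timepoints versus plot-level sampling error. Returns
#' \eqn{\sigma^2_{\Delta g:TP} = \sigma^2_{g:TP} - \sigma^2_{pltE}} along
#' with ratio1 = \eqn{\sigma^2_{pltE}/\sigma^2_{g:TP}} (how much of the
#' interaction is plot error) and ratio2 =
#' \eqn{\sigma^2_{\Delta g:TP}/\sigma^2_g} (importance of change relative to
#' the line variance). Negative \eqn{\sigma^2_{\Delta g:TP}} — which occurs
#' when the check-based plot error exceeds the interaction variance — is
#' flagged, not clamped.
#'
#' @param vc one row from [within_year_partition()].
#' @param sigma2_pltE plot error variance from [check_plot_error()] (number
#'   or its result row).
#' @return tibble with `sigma2_dgTP`, `ratio1`, `ratio2`, `negative` flag.
#' @export
delta_gtp <- function(vc, sigma2_pltE) {
  if (is.data.frame(sigma2_pltE)) sigma2_pltE <- sigma2_pltE$sigma2_pltE
  stopifnot(is.data.frame(vc), nrow(vc) == 1)
  d <- vc$sigma2_gTP - sigma2_pltE
  ratio1 <- if (vc$sigma2_gTP > 0) sigma2_pltE / vc$sigma2_gTP else NA_real_
  ratio2 <- if (vc$sigma2_g > 0) d / vc$sigma2_g else NA_real_
  if (d < 0) warn("delta_gtp: negative after-ripening change variance (flagged)")
  tibble(trait = vc$trait, year = vc$year,
         sigma2_gTP = vc$sigma2_gTP, sigma2_pltE = sigma2_pltE,
         sigma2_dgTP = d, ratio1 = ratio1, ratio2 = ratio2, negative = d < 0)
}

#' Across-year variance partition
#'
#' Fits, per trait over all years,
#' \eqn{Y = E_y + T_i + E{:}T_{yi} + g_j + g{:}T_{ij} + e} with fixed year,
#' timepoint and year-timepoint effects and random line and
#' line-by-timepoint effects. Data collected without rigid after-ripening
#' control can be merged by assigning it the TP6 label (see
#' [assign_tp6()]); the fit tolerates the resulting unbalanced timepoint
#' structure.
#'
#' @inheritParams technical_repeatability
#' @return tibble like [within_year_partition()], plus `n_years`.
#' @export
across_year_partition <- function(data, trait = NULL) {
  d <- filter_scope(data, trait, NULL, NULL)
  d <- d[!is.na(d$value), , drop = FALSE]
  years <- sort(unique(d$year))
  if (length(years) < 2) abort("across_year_partition needs >= 2 years")
  fit <- fit_lmm(d, value ~ factor(year) * factor(timepoint),
                 random = list(ranef_iid("line_id"),
                               ranef_iid(c("line_id", "timepoint"))))
  tibble(trait = trait %||% single_or_na(d$trait),
         sigma2_g = get_varcomp(fit, "line_id"),
         sigma2_gTP = get_varcomp(fit, "line_id:timepoint"),
         sigma2_e = get_varcomp(fit, ".residual"),
         loglik = fit$loglik_reml, n_lines = length(unique(d$line_id)),
         n_years = length(years), n_obs = nrow(d), converged = fit$converged)
}

#' Broad-sense heritability on a line-mean basis
#'
#' Across years: \eqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{g:TP} +
#' \sigma^2_e / y)} with `y` the number of years. The per-year variant
#' divides by the full residual (`y = 1`); the per-year formula is a labelled
#' assumption of this package, since only the across-year form is standard.
#'
#' @param vc one row from [across_year_partition()] (or
#'   [within_year_partition()] for the per-year variant).
#' @param y number of years entering the line means.
#' @return tibble with `H2`, `y` and the scope columns of `vc`.
#' @export
heritability <- function(vc, y = vc$n_years %||% 1) {
  stopifnot(is.data.frame(vc), nrow(vc) == 1, y >= 1)
  denom <- vc$sigma2_g + vc$sigma2_gTP + vc$sigma2_e / y
  if (denom <= 0) abort("heritability: all variance components are zero")
  tibble(trait = vc$trait, H2 = vc$sigma2_g / denom, y = as.integer(y))
}

#' Relabel uncontrolled-after-ripening records as TP6
#'
#' Material malted late without rigid after-ripening control (e.g. a whole
#' early season) is conventionally merged into across-year analyses under the
#' TP6 label, since trait change beyond ~110 days post PM is below assay
#' resolution.
#'
#' @param data phenotype tibble.
#' @param year the year whose records should be relabelled.
#' @return the tibble with `timepoint` set to `"TP6"` for that year.
#' @export
assign_tp6 <- function(data, year) {
  data$timepoint[data$year %in% year] <- "TP6"
  data
}

single_or_na <- function(x) {
  u <- unique(x)
  if (length(u) == 1) u else vctrs_na(x)
}
vctrs_na <- function(x) if (is.numeric(x)) NA_real_ else NA_character_

filter_scope <- function(data, trait, year, timepoint) {
  d <- as_tibble(data)
  if (!is.null(trait)) d <- d[d$trait %in% trait, , drop = FALSE]
  if (!is.null(year)) d <- d[d$year %in% year, , drop = FALSE]
  if (!is.null(timepoint)) d <- d[d$timepoint %in% timepoint, , drop = FALSE]
  if (!nrow(d)) abort("no phenotype rows left after trait/year/timepoint filters")
  d
}
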