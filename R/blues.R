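#' Line BLUEs per timepoint (cell means)
#'
#' The within-year line-by-timepoint model refit with the line effect fixed
#' reduces, in its cell-means parameterisation, to least-squares line x
#' timepoint cell means over technical replicates; the standard error uses
#' the pooled residual. One row per line x timepoint actually observed — a
#' line absent at a timepoint yields no entry, never an imputation.
#'
#' @param data phenotype records (technical-replicate level) for one trait;
#'   `trait` and `year` filters may be supplied.
#' @param trait,year optional filters.
#' @return tibble `line_id`, `trait`, `label` (the timepoint), `estimate`,
#'   `se`, `n`.
#' @export
blues_per_timepoint <- function(data, trait = NULL, year = NULL) {
  d <- filter_scope(data, trait, year, NULL)
  d <- d[!is.na(d$value), , drop = FALSE]
  cells <- d |>
    dplyr::group_by(.data$line_id, .data$trait, .data$timepoint) |>
    dplyr::summarise(estimate = mean(.data$value), n = dplyr::n(),
                     sse = sum((.data$value - mean(.data$value))^2),
                     .groups = "drop")
  df_res <- sum(cells$n) - nrow(cells)
  s2 <- if (df_res > 0) sum(cells$sse) / df_res else NA_real_
  cells |>
    dplyr::transmute(line_id = .data$line_id, trait = .data$trait,
                     label = as.character(.data$timepoint),
                     estimate = .data$estimate,
                     se = sqrt(s2 / .data$n), n = .data$n)
}

#' Line BLUEs across timepoints within a year
#'
#' Fits \eqn{Y = T_i + G_j + e} with timepoint and line both fixed — i.e.
#' the malting timepoints are treated as replicates — and reports each
#' line's adjusted mean: its effect plus the average of the timepoint
#' effects over the observed timepoint set, so a line seen at only one
#' timepoint is adjusted by the timepoint contrast estimated from the rest
#' of the population. The mean BLUE equals the grand adjusted mean.
#'
#' @inheritParams blues_per_timepoint
#' @param label label recorded for this scheme (default joins the observed
#'   timepoints, e.g. `"TP4/TP6"`).
#' @return tibble `line_id`, `trait`, `label`, `estimate`, `se`.
#' @export
blues_across_timepoints <- function(data, trait = NULL, year = NULL,
                                    label = NULL) {
  d <- filter_scope(data, trait, year, NULL)
  d <- d[!is.na(d$value), , drop = FALSE]
  label <- label %||% paste(sort(unique(as.character(d$timepoint))),
                            collapse = "/")
  adjusted_line_means(d, value ~ factor(timepoint) + line_id,
                      grid_cols = "timepoint", residual = resid_iid(),
                      label = label)
}

#' Line BLUEs across years with per-year residual variance
#'
#' Fits \eqn{Y = E_y + T_i + E{:}T_{yi} + G_j + e} with all terms fixed and
#' a heterogeneous residual variance per year estimated by REML on the
#' residual layer (feasible generalised least squares), so noisier years are
#' down-weighted. If the heterogeneous-weight fit does not converge the
#' function falls back to homogeneous weights with a warning. Supplying a
#' single year reduces to [blues_across_timepoints()].
#'
#' @inheritParams blues_across_timepoints
#' @param years optional subset of years.
#' @param weights `"heterogeneous"` (default) estimates one residual variance
#'   per year; `"homogeneous"` forces equal year weights, under which the
#'   balanced-complete-data fit reduces exactly to simple line means.
#' @return tibble `line_id`, `trait`, `label`, `estimate`, `se`.
#' @export
blues_across_years <- function(data, trait = NULL, years = NULL,
                               label = "Combined",
                               weights = c("heterogeneous", "homogeneous")) {
  weights <- match.arg(weights)
  d <- filter_scope(data, trait, years, NULL)
  d <- d[!is.na(d$value), , drop = FALSE]
  if (length(unique(d$year)) == 1) {
    return(blues_across_timepoints(d, label = label))
  }
  multi_tp <- length(unique(d$timepoint)) > 1
  fml <- if (multi_tp) {
    value ~ factor(year) * factor(timepoint) + line_id
  } else {
    value ~ factor(year) + line_id
  }
  if (weights == "homogeneous") {
    return(adjusted_line_means(d, fml,
                               grid_cols = if (multi_tp) c("year", "timepoint") else "year",
                               residual = resid_iid(), label = label))
  }
  out <- tryCatch(
    adjusted_line_means(d, fml,
                        grid_cols = if (multi_tp) c("year", "timepoint") else "year",
                        residual = resid_diag("year"), label = label),
    error = function(e) NULL)
  fallback <- is.null(out)
  if (!fallback) {
    fit_conv <- attr(out, "converged")
    fallback <- isFALSE(fit_conv)
  }
  if (fallback) {
    warn("blues_across_years: heterogeneous-variance weights did not converge; using homogeneous weights")
    out <- adjusted_line_means(d, fml,
                               grid_cols = if (multi_tp) c("year", "timepoint") else "year",
                               residual = resid_iid(), label = label)
  }
  out
}

## fixed-effect fit through the REML engine's GLS path, then adjusted means:
## for every line the design row is averaged over the observed covariate grid
adjusted_line_means <- function(d, fml, grid_cols, residual, label) {
  d$line_id <- factor(d$line_id)
  fit <- fit_lmm(d, fml, random = list(), residual = residual)
  if (length(fit$aliased)) {
    warn(paste0("aliased fixed-effect levels: ",
                paste(fit$aliased, collapse = ", ")))
  }
  grid <- dplyr::distinct(d[, grid_cols, drop = FALSE])
  lines <- levels(d$line_id)
  newd <- merge(data.frame(line_id = lines), grid)
  newd$line_id <- factor(newd$line_id, levels = lines)
  newd$value <- 0
  Xg <- model.matrix(fml, newd)
  Xg <- Xg[, fit$fixed_labels, drop = FALSE]
  A <- rowsum(Xg, group = newd$line_id) / nrow(grid)
  est <- as.numeric(A %*% fit$beta)
  v <- rowSums((A %*% fit$vcov_beta) * A)
  out <- tibble(line_id = lines,
                trait = single_or_na(d$trait),
                label = label, estimate = est, se = sqrt(pmax(v, 0)))
  ## keep only lines actually observed (no imputation of absent lines)
  out <- out[out$line_id %in% unique(as.character(d$line_id)), , drop = FALSE]
  attr(out, "converged") <- fit$converged
  out
}
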