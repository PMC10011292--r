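#' Correlated response to selection for one trait
#'
#' Fits the across-year selection-cycle model
#' \eqn{Y = E_y + C_c + T_i + E{:}T_{yi} + T{:}C_{ic} + E{:}C_{yc} + g_j + e}
#' with fixed year, cycle, timepoint and interaction effects, a random line
#' effect with a separate genetic variance per selection cycle, and a
#' separate residual variance per year. Cycle effects are contrasts against
#' the base population C0 and are tested with Wald t statistics; the
#' heterogeneous-variance model is compared with its homogeneous counterpart
#' by a likelihood-ratio test on (number of cycles - 1) df. Interaction
#' terms whose cycle x year or cycle x timepoint cells are empty are dropped
#' automatically with a logged note (augmented selection designs are
#' unbalanced by construction). Parent rows are excluded by default.
#'
#' @param data phenotype records for one trait (technical-replicate or plot
#'   level), with `line_id`, `year`, `timepoint`, `value`.
#' @param cycles tibble `line_id`, `cycle`; cycle levels ordered
#'   `C0, C1P, C1G, C2G` where present.
#' @param trait optional filter on `data$trait`.
#' @param include_parents keep `PARENT` rows (default FALSE).
#' @return object of class `mg_selresp`: list with `cycle_effects` (tibble of
#'   contrasts vs C0 with Wald tests), `cycle_variances`,
#'   `lrt_hom_vs_het`, `year_residuals`, `fit`, `trait`.
#' @export
fit_selection_response <- function(data, cycles, trait = NULL,
                                   include_parents = FALSE) {
  d <- filter_scope(data, trait, NULL, NULL)
  d <- d[!is.na(d$value), , drop = FALSE]
  d <- dplyr::inner_join(d, cycles[, c("line_id", "cycle")], by = "line_id")
  if (!include_parents) d <- d[d$cycle != "PARENT", , drop = FALSE]
  cyc_order <- intersect(c("C0", "C1P", "C1G", "C2G"), unique(d$cycle))
  d$cycle <- factor(d$cycle, levels = cyc_order)
  n_per <- table(dplyr::distinct(d, .data$line_id, .data$cycle)$cycle)
  if (sum(n_per >= 20) < 2) {
    abort("fit_selection_response needs >= 2 cycles with >= 20 lines each")
  }
  if (any(n_per < 5)) {
    warn(paste0("cycle(s) with < 5 lines; their variance is unreliable: ",
                paste(names(n_per)[n_per < 5], collapse = ", ")))
  }

  ## drop interaction terms with empty cells (keeps the fit well-posed)
  has_tc <- all(table(d$timepoint, d$cycle) > 0)
  has_ec <- all(table(d$year, d$cycle) > 0)
  multi_tp <- length(unique(d$timepoint)) > 1
  multi_yr <- length(unique(d$year)) > 1
  rhs <- c("factor(year)"[multi_yr], "cycle", "factor(timepoint)"[multi_tp],
           "factor(year):factor(timepoint)"[multi_yr && multi_tp &&
                                              all(table(d$year, d$timepoint) > 0)],
           "factor(timepoint):cycle"[multi_tp && has_tc],
           "factor(year):cycle"[multi_yr && has_ec])
  if ((multi_tp && !has_tc) || (multi_yr && !has_ec)) {
    inform("[selection_response] interaction term(s) with empty cells dropped")
  }
  fml <- stats::reformulate(rhs, response = "value")

  res_struct <- if (multi_yr) resid_diag("year") else resid_iid()
  hom <- fit_lmm(d, fml, random = list(ranef_iid("line_id")),
                 residual = res_struct)
  ## warm-start the heterogeneous fit at the homogeneous optimum
  rvar <- get_varcomp(hom, ".residual")
  r1 <- rvar[1]
  vg <- max(get_varcomp(hom, "line_id"), 1e-8 * r1)
  warm <- c(rep(log(vg / r1), length(cyc_order)), log(rvar[-1] / r1))
  full <- fit_lmm(d, fml,
                  random = list(ranef_diag("line_id", by = "cycle")),
                  residual = res_struct, starts = 2,
                  control = list(extra_starts = list(warm)))
  test <- lrt(full, hom, df = length(cyc_order) - 1)

  wt <- wald_fixed(full)
  ce <- wt[grepl("^cycle", wt$effect), , drop = FALSE]
  ce$cycle <- sub("^cycle", "", ce$effect)
  ce <- ce[, c("cycle", "estimate", "se", "t", "df", "p", "aliased")]

  vc <- full$varcomp
  cyc_var <- vc[vc$term == "line_id|cycle", c("level", "estimate")]
  names(cyc_var) <- c("cycle", "sigma2_g")
  yr_res <- vc[vc$term == ".residual", c("level", "estimate")]
  names(yr_res) <- c("year", "sigma2_e")

  ## adjusted mean of the C0 baseline: prediction averaged over the observed
  ## year x timepoint grid at cycle = C0
  grid <- dplyr::distinct(d[, c("year", "timepoint"), drop = FALSE])
  grid$cycle <- factor(cyc_order[1], levels = cyc_order)
  grid$value <- 0
  Xg <- model.matrix(fml, grid)
  Xg <- Xg[, full$fixed_labels, drop = FALSE]
  baseline_mean <- mean(as.numeric(Xg %*% full$beta))

  structure(list(
    trait = trait %||% single_or_na(d$trait),
    baseline_mean = baseline_mean,
    cycle_effects = as_tibble(ce),
    cycle_variances = as_tibble(cyc_var),
    lrt_hom_vs_het = test,
    year_residuals = as_tibble(yr_res),
    fit = full, fit_hom = hom,
    cycles = cyc_order
  ), class = "mg_selresp")
}

#' @export
print.mg_selresp <- function(x, ...) {
  cat("Correlated response to selection —", x$trait, "\n")
  cat("Cycle contrasts vs C0:\n")
  print(as.data.frame(x$cycle_effects), row.names = FALSE)
  cat("Per-cycle genetic variances:\n")
  print(as.data.frame(x$cycle_variances), row.names = FALSE)
  cat(sprintf("Heterogeneous vs homogeneous variance LRT: stat %.3f, df %d, p %.3g\n",
              x$lrt_hom_vs_het$stat, x$lrt_hom_vs_het$df, x$lrt_hom_vs_het$p))
  invisible(x)
}

#' Significance stars at conventional tiers
#'
#' `""`, `*`, `**`, `***`, `****` at p < 0.05, 0.01, 0.001, 0.0001.
#'
#' @param p numeric vector of p values.
#' @return character vector of stars.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Summarise selection response for plotting
#'
#' Builds the per-cycle summary behind the response-to-selection panels:
#' each cycle's adjusted trait mean (C0 baseline mean plus its contrast),
#' the band mean ± 2 genetic standard deviations (using that cycle's genetic
#' variance), the mean PHS score (GI at the first timepoint) per cycle, and
#' significance stars for the cycle contrasts.
#'
#' @param result `mg_selresp` from [fit_selection_response()].
#' @param phs_means tibble `cycle`, `phs_mean` (mean GI TP1 per cycle).
#' @return tibble, one row per cycle.
#' @export
response_summary <- function(result, phs_means = NULL) {
  stopifnot(inherits(result, "mg_selresp"))
  base_mean <- result$baseline_mean
  ce <- result$cycle_effects
  out <- tibble(cycle = result$cycles) |>
    dplyr::left_join(ce, by = "cycle") |>
    dplyr::left_join(result$cycle_variances, by = "cycle") |>
    dplyr::mutate(
      estimate = ifelse(.data$cycle == result$cycles[1], 0, .data$estimate),
      trait_mean = base_mean + .data$estimate,
      band_halfwidth = 2 * sqrt(pmax(.data$sigma2_g, 0)),
      lower = .data$trait_mean - .data$band_halfwidth,
      upper = .data$trait_mean + .data$band_halfwidth,
      star = significance_stars(.data$p),
      trait = result$trait
    )
  if (!is.null(phs_means)) {
    out <- dplyr::left_join(out, phs_means, by = "cycle")
  }
  out
}
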