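#' Classify HvMKK3 dormancy alleles from two diagnostic markers
#'
#' Three alleles of the dormancy gene HvMKK3 segregate in this germplasm:
#' dormant (D), non-dormant (N) and highly non-dormant (N*, the
#' PHS-susceptible allele carrying the E165Q mutation). The E165Q KASP
#' marker identifies N* directly; among E165Q wild-type lines a linked
#' 50k-chip marker separates N from D. The default mapping is
#' MUT at E165Q -> `Nstar`; WT + linked allele A -> `N`; WT + linked allele
#' B -> `D`; any missing call -> `UNKNOWN` (excluded from within-allele
#' analyses). The 50k-marker allele assignment is configurable because the
#' physical allele coding of the linked marker is array-batch dependent.
#'
#' @param calls tibble with columns `line_id`, `e165q` (`"WT"`, `"MUT"`,
#'   `"MISSING"`) and `linked50k` (`"A"`, `"B"`, `"MISSING"`).
#' @param linked_map named character vector mapping the linked-marker alleles
#'   to HvMKK3 alleles among E165Q wild types; default `c(A = "N", B = "D")`.
#' @return the input with an `allele` column in \{D, N, Nstar, UNKNOWN\}.
#' @export
classify_mkk3 <- function(calls, linked_map = c(A = "N", B = "D")) {
  calls <- as_tibble(calls)
  need <- c("line_id", "e165q", "linked50k")
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    abort(paste0("MKK3 call table missing column(s): ", paste(miss, collapse = ", ")))
  }
  stopifnot(all(c("A", "B") %in% names(linked_map)))
  allele <- dplyr::case_when(
    calls$e165q == "MUT" ~ "Nstar",
    calls$e165q == "WT" & calls$linked50k %in% names(linked_map) ~
      unname(linked_map[calls$linked50k]),
    TRUE ~ "UNKNOWN"
  )
  dplyr::mutate(calls, allele = allele)
}

#' Plot-level trait means
#'
#' Averages technical replicates (and, by default, malting timepoints) per
#' plot, the input granularity for the bivariate genetic-correlation models:
#' plot-level means allow the two traits of a pair to be joined as paired
#' observations on the same experimental unit.
#'
#' @param phenotypes phenotype records (technical-replicate level).
#' @param within_timepoint keep malting timepoints separate (default FALSE:
#'   average across them).
#' @return tibble `line_id`, `year`, `plot_id`(, `timepoint`), `trait`, `value`.
#' @export
plot_trait_means <- function(phenotypes, within_timepoint = FALSE) {
  ph <- as_tibble(phenotypes)
  ph <- ph[!is.na(ph$value), , drop = FALSE]
  keys <- c("line_id", "year", "plot_id",
            if (within_timepoint) "timepoint", "trait")
  ph |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

#' Bivariate REML genetic correlation between two traits
#'
#' Stacks plot-level means of two traits into the two-trait mixed model
#' \eqn{Y = E_{ty} + g_{tj} + e_{tyj}}: fixed trait-by-year cell means, a
#' line effect with an unstructured 2x2 covariance across traits, and a
#' heterogeneous residual per trait x year with zero residual cross-trait
#' covariance (germination and malting are measured on different grain
#' samples from the plot, and with mostly one plot per line a residual
#' covariance is near-unidentifiable). The genetic correlation is
#' \eqn{r_g = \sigma_{AB} / \sqrt{\sigma^2_A \sigma^2_B}}, tested with a
#' likelihood-ratio test (df = 1) against the same model with a diagonal
#' line structure.
#'
#' @param data plot-level means, long format: `line_id`, `year`, `plot_id`,
#'   `trait`, `value`; exactly the two traits of interest after filtering.
#' @param trait_a,trait_b trait names to correlate.
#' @param group label recorded in the result (e.g. an HvMKK3 allele).
#' @param min_lines groups smaller than this are flagged `low_n`
#'   (default 30); the model is still fitted.
#' @return a `GeneticCorrelationResult` tibble: `trait_pair`, `group`,
#'   `r_g`, `var_a`, `var_b`, `cov_ab`, `lrt_stat`, `p`, `n_lines`, flags.
#' @export
genetic_correlation <- function(data, trait_a, trait_b, group = "ALL",
                                min_lines = 30) {
  d <- as_tibble(data)
  d <- d[d$trait %in% c(trait_a, trait_b) & !is.na(d$value), , drop = FALSE]
  ## paired observations: keep line-years where both traits were measured
  wide_n <- d |>
    dplyr::distinct(.data$line_id, .data$year, .data$trait) |>
    dplyr::count(.data$line_id, .data$year) |>
    dplyr::filter(.data$n == 2)
  d <- dplyr::semi_join(d, wide_n, by = c("line_id", "year"))
  n_lines <- length(unique(d$line_id))
  base <- tibble(trait_pair = paste(trait_a, trait_b, sep = ":"),
                 group = group, n_lines = n_lines)
  if (n_lines < 3) {
    return(dplyr::mutate(base, r_g = NA_real_, var_a = NA_real_,
                         var_b = NA_real_, cov_ab = NA_real_,
                         lrt_stat = NA_real_, p = NA_real_,
                         low_n = TRUE, boundary = NA, converged = FALSE))
  }
  d$trait <- factor(d$trait, levels = c(trait_a, trait_b))
  fml <- if (length(unique(d$year)) > 1) {
    value ~ trait * factor(year)
  } else {
    value ~ trait
  }
  res_by <- if (length(unique(d$year)) > 1) c("trait", "year") else "trait"
  reduced <- tryCatch(
    fit_lmm(d, fml,
            random = list(ranef_diag(c("line_id", "trait"), by = "trait")),
            residual = resid_diag(res_by)),
    error = function(e) NULL)
  ## warm-start the unstructured fit at the diagonal optimum (covariance 0)
  ## so the nested likelihoods are directly comparable
  extra <- list()
  if (!is.null(reduced)) {
    rvar <- get_varcomp(reduced, ".residual")
    r1 <- rvar[1]
    vA <- max(get_varcomp(reduced, "line_id:trait|trait", trait_a), 1e-8 * r1)
    vB <- max(get_varcomp(reduced, "line_id:trait|trait", trait_b), 1e-8 * r1)
    extra <- list(c(0.5 * log(vA / r1), 0.5 * log(vB / r1), 0,
                    log(rvar[-1] / r1)))
  }
  full <- tryCatch(
    fit_lmm(d, fml, random = list(ranef_us2("line_id", "trait")),
            residual = resid_diag(res_by),
            starts = if (length(extra)) 2 else 3,
            control = list(extra_starts = extra)),
    error = function(e) NULL)
  if (is.null(full) || is.null(reduced)) {
    return(dplyr::mutate(base, r_g = NA_real_, var_a = NA_real_,
                         var_b = NA_real_, cov_ab = NA_real_,
                         lrt_stat = NA_real_, p = NA_real_,
                         low_n = n_lines < min_lines, boundary = NA,
                         converged = FALSE))
  }
  test <- lrt(full, reduced, df = 1)
  va <- get_varcomp(full, "line_id@trait", trait_a)
  vb <- get_varcomp(full, "line_id@trait", trait_b)
  cab <- get_varcomp(full, "line_id@trait", "cov")
  rg <- get_varcomp(full, "line_id@trait", "cor")
  if (va <= 1e-10 * vb || vb <= 1e-10 * va) {
    warn("genetic_correlation: a trait has (near) zero genetic variance; r_g undefined")
    rg <- NA_real_
  }
  dplyr::mutate(base,
                r_g = rg, var_a = va, var_b = vb, cov_ab = cab,
                lrt_stat = test$stat, p = test$p,
                low_n = n_lines < min_lines,
                boundary = is.finite(rg) && abs(rg) > 0.999,
                converged = full$converged && reduced$converged)
}

#' Genetic-correlation scan over timepoints and allele groups
#'
#' Runs [genetic_correlation()] for each malting trait against the chosen
#' germination trait at each after-ripening timepoint, across all lines and
#' within each HvMKK3 allele group, producing the table behind the
#' correlation-over-time panel (one row per trait x timepoint x group with a
#' significance star at p < 0.01). Missing combinations are gaps, not
#' failures.
#'
#' @param malt_means plot-level malting-trait means: `line_id`, `year`,
#'   `plot_id`, `trait`, `value`.
#' @param germ_means plot-level germination summaries: `line_id`, `year`,
#'   `plot_id`, `timepoint` plus the `germ_trait` column (`GI` or `GE`).
#' @param alleles optional tibble `line_id`, `allele`; when supplied, the
#'   scan runs within each allele group (UNKNOWN excluded) in addition to ALL.
#' @param malt_traits traits to scan (default: all in `malt_means`).
#' @param germ_trait `"GI"` (default) or `"GE"`.
#' @param timepoints germination timepoints to scan (default: all present).
#' @param star_p significance threshold for the star column (default 0.01).
#' @param min_lines passed to [genetic_correlation()].
#' @return tibble with one row per trait x timepoint x group.
#' @export
correlation_scan <- function(malt_means, germ_means, alleles = NULL,
                             malt_traits = NULL, germ_trait = c("GI", "GE"),
                             timepoints = NULL, star_p = 0.01, min_lines = 30) {
  germ_trait <- match.arg(germ_trait)
  malt_means <- as_tibble(malt_means)
  germ_means <- as_tibble(germ_means)
  malt_traits <- malt_traits %||% sort(unique(malt_means$trait))
  timepoints <- timepoints %||% sort(unique(as.character(germ_means$timepoint)))
  groups <- "ALL"
  if (!is.null(alleles)) {
    groups <- c("ALL", setdiff(sort(unique(alleles$allele)), "UNKNOWN"))
  }
  grid <- tidyr::expand_grid(trait = malt_traits, timepoint = timepoints,
                             group = groups)
  out <- purrr::pmap_dfr(grid, function(trait, timepoint, group) {
    g <- germ_means[germ_means$timepoint == timepoint, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    g_long <- tibble(line_id = g$line_id, year = g$year, plot_id = g$plot_id,
                     trait = paste0(germ_trait, "_", timepoint),
                     value = g[[germ_trait]])
    m_long <- malt_means[malt_means$trait == trait,
                         c("line_id", "year", "plot_id", "trait", "value")]
    d <- dplyr::bind_rows(m_long, g_long)
    if (group != "ALL") {
      keep <- alleles$line_id[alleles$allele == group]
      d <- d[d$line_id %in% keep, , drop = FALSE]
    }
    if (!nrow(d)) return(NULL)
    res <- genetic_correlation(d, trait, unique(g_long$trait), group = group,
                               min_lines = min_lines)
    dplyr::mutate(res, trait = trait, timepoint = timepoint,
                  star = !is.na(res$p) & res$p < star_p)
  })
  class(out) <- c("mg_scan", class(out))
  out
}

#' Phenotypic correlation matrix from line BLUEs
#'
#' Pearson correlations between traits over lines, computed on scaled and
#' centred BLUEs with pairwise-complete observations (lines differ in
#' availability across years, and casewise deletion would discard most of
#' them). Traits with zero variance are excluded with a warning.
#'
#' @param blues tibble with `line_id`, `trait`, `estimate` (one value per
#'   line x trait, e.g. the `Combined` BLUE scheme).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
phenotypic_correlation_matrix <- function(blues) {
  wide <- blues |>
    dplyr::select("line_id", "trait", "estimate") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "estimate")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$line_id
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  zero <- is.na(sds) | sds == 0
  if (any(zero)) {
    warn(paste0("phenotypic_correlation_matrix: zero-variance trait(s) excluded: ",
                paste(colnames(m)[zero], collapse = ", ")))
    m <- m[, !zero, drop = FALSE]
  }
  m <- scale(m)
  cc <- stats::cor(m, use = "pairwise.complete.obs")
  diag(cc) <- 1
  cc
}

#' Eigen-decomposition of a trait correlation matrix for biplots
#'
#' Decomposes a (near-)positive-semi-definite correlation matrix into
#' principal components; loadings are eigenvectors scaled by the square root
#' of their eigenvalues, and the variance explained by the first two
#' components is their eigenvalue share of the trace. Small negative
#' eigenvalues (an artefact of pairwise-complete correlation) are clipped at
#' zero with a warning.
#'
#' @param corr_matrix symmetric correlation/covariance matrix.
#' @return list with `loadings` (traits x PC1-PC2 tibble) and
#'   `variance_explained` (length-2 numeric).
#' @export
biplot_decomposition <- function(corr_matrix) {
  if (!isSymmetric(unname(corr_matrix), tol = 1e-8)) {
    abort("biplot_decomposition: matrix is not symmetric")
  }
  e <- eigen((corr_matrix + t(corr_matrix)) / 2, symmetric = TRUE)
  if (any(e$values < -1e-8)) {
    warn("biplot_decomposition: negative eigenvalue(s) clipped at 0")
  }
  vals <- pmax(e$values, 0)
  tr <- sum(vals)
  load <- e$vectors[, 1:2, drop = FALSE] %*% diag(sqrt(vals[1:2]), 2)
  list(
    loadings = tibble(trait = colnames(corr_matrix),
                      PC1 = load[, 1], PC2 = load[, 2]),
    variance_explained = vals[1:2] / tr
  )
}
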