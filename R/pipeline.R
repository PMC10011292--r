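pipeline_stages <- c("simulate", "germination", "variance_partition", "blues",
                     "correlations", "selection_response", "scoring")

#' Run the full analysis pipeline
#'
#' Orchestrates every stage end-to-end on one output directory:
#' simulate (or load) the data, plot-level germination summaries, variance
#' partitioning with the check-based plot-error decomposition and
#' heritability, line BLUEs under the per-timepoint / across-timepoint /
#' across-year labelling schemes, genetic-correlation scan across and within
#' dormancy-allele groups, correlated response to selection, and end-use
#' quality scoring. Every stage reads and writes plain CSV files in
#' `out_dir` so stages are independently inspectable and resumable; a run
#' manifest records the seed, configuration hash and a content hash per
#' output file. A stage failure halts the run with the stage name; outputs
#' of completed stages persist.
#'
#' The default correlation-scan scope (three focal malting traits at the
#' three timepoints carrying three full years of germination data) keeps the
#' default run modest; pass `scan_traits`/`scan_timepoints` to widen it.
#'
#' @param out_dir output directory (created if needed).
#' @param cfg an `mg_sim_config` (used by the simulate stage).
#' @param seed master seed for the whole run.
#' @param stages character vector, subset of
#'   `simulate, germination, variance_partition, blues, correlations,
#'   selection_response, scoring`.
#' @param score_config path to a scoring YAML (defaults to the illustrative
#'   config shipped with the package).
#' @param scan_traits,scan_timepoints correlation-scan scope.
#' @param verbose emit progress messages.
#' @return invisibly, a named list of the result tibbles.
#' @export
run_pipeline <- function(out_dir, cfg = sim_config(), seed = 1,
                         stages = pipeline_stages,
                         score_config = NULL,
                         scan_traits = c("AA", "FAN", "BG"),
                         scan_timepoints = c("TP1", "TP4", "TP6"),
                         verbose = TRUE) {
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", "),
                 "; valid stages are: ", paste(pipeline_stages, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) inform(paste0("[pipeline] ", ...))
  path <- function(f) file.path(out_dir, f)
  results <- list()

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    say("stage: ", name)
    tryCatch(fun(), error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  need_file <- function(f) {
    if (!file.exists(path(f))) {
      abort(paste0("missing input '", path(f),
                   "'; run the simulate stage or provide the file"))
    }
    path(f)
  }

  ## ---- simulate ----
  run_stage("simulate", function() {
    sim <- simulate_study(cfg, seed = seed)
    write_results(sim$phenotypes, path("phenotypes.csv"))
    write_results(sim$plates, path("plates.csv"))
    write_results(sim$line_meta, path("line_meta.csv"))
    write_results(sim$markers, path("markers.csv"))
    write_results(sim$mkk3_calls, path("mkk3_calls.csv"))
    write_results(truth_report(sim$truth), path("truth.csv"))
    results$sim <<- sim
  })

  load_tbl <- function(f) read_results(need_file(f))

  ## ---- germination ----
  run_stage("germination", function() {
    plates <- load_tbl("plates.csv")
    gs <- plot_germination_means(plates)
    write_results(gs, path("germination_summary.csv"))
    results$germination <<- gs
  })

  ## ---- variance partition ----
  run_stage("variance_partition", function() {
    ph <- validate_phenotypes(load_tbl("phenotypes.csv"), "phenotypes.csv")
    meta <- load_tbl("line_meta.csv")
    checks <- meta$line_id[meta$is_check]
    ph_ln <- ph[!ph$line_id %in% checks, , drop = FALSE]
    traits <- sort(unique(ph$trait))
    years <- sort(unique(ph$year))

    rep_rows <- list(); wy_rows <- list(); dg_rows <- list()
    ay_rows <- list(); h2_rows <- list()
    for (trt in traits) {
      for (yr in years) {
        sub <- ph_ln[ph_ln$trait == trt & ph_ln$year == yr, ]
        if (!nrow(sub)) next
        for (tp in unique(sub$timepoint)) {
          rr <- tryCatch(technical_repeatability(sub, timepoint = tp),
                         error = function(e) NULL)
          if (!is.null(rr)) {
            rep_rows[[length(rep_rows) + 1]] <-
              dplyr::mutate(rr, trait = trt, year = yr, timepoint = tp)
          }
        }
        if (length(unique(sub$timepoint)) >= 2) {
          vc <- within_year_partition(sub, trait = trt, year = yr)
          wy_rows[[length(wy_rows) + 1]] <- vc
          chk <- ph[ph$trait == trt & ph$year == yr &
                      ph$line_id %in% checks & !is.na(ph$value), ]
          if (length(unique(chk$plot_id)) >= 5) {
            assay <- rep_rows[[length(rep_rows)]]$sigma2_e
            pe <- suppressWarnings(check_plot_error(chk, assay_error = assay))
            dg_rows[[length(dg_rows) + 1]] <-
              suppressWarnings(delta_gtp(vc, pe))
          }
        }
      }
      if (length(years) >= 2) {
        ay <- across_year_partition(ph_ln, trait = trt)
        ay_rows[[length(ay_rows) + 1]] <- ay
        h2_rows[[length(h2_rows) + 1]] <- heritability(ay, y = ay$n_years)
      }
    }
    vp <- list(repeatability = dplyr::bind_rows(rep_rows),
               within_year = dplyr::bind_rows(wy_rows),
               delta_gtp = dplyr::bind_rows(dg_rows),
               across_year = dplyr::bind_rows(ay_rows),
               heritability = dplyr::bind_rows(h2_rows))
    write_results(vp$repeatability, path("repeatability.csv"))
    write_results(vp$within_year, path("variance_components_within_year.csv"))
    write_results(vp$delta_gtp, path("delta_gtp.csv"))
    write_results(vp$across_year, path("variance_components_across_year.csv"))
    write_results(vp$heritability, path("heritability.csv"))
    results$variance_partition <<- vp
  })

  ## ---- BLUEs ----
  run_stage("blues", function() {
    ph <- load_tbl("phenotypes.csv")
    meta <- load_tbl("line_meta.csv")
    ph <- ph[!ph$line_id %in% meta$line_id[meta$is_check], , drop = FALSE]
    traits <- sort(unique(ph$trait))
    years <- sort(unique(ph$year))
    rows <- list()
    for (trt in traits) {
      for (yr in setdiff(years, min(years))) {
        sub <- ph[ph$trait == trt & ph$year == yr, ]
        if (!nrow(sub)) next
        rows[[length(rows) + 1]] <-
          dplyr::mutate(blues_per_timepoint(sub), year_scope = as.character(yr))
        if (length(unique(sub$timepoint)) >= 2) {
          rows[[length(rows) + 1]] <-
            dplyr::mutate(blues_across_timepoints(sub),
                          year_scope = as.character(yr))
        }
      }
      sub_all <- ph[ph$trait == trt, ]
      if (length(unique(sub_all$year)) >= 2) {
        rows[[length(rows) + 1]] <-
          dplyr::mutate(blues_across_years(sub_all, label = "Combined"),
                        year_scope = paste(years, collapse = "/"))
      }
    }
    bl <- dplyr::bind_rows(rows)
    write_results(bl, path("blues.csv"))
    results$blues <<- bl
  })

  ## ---- correlations ----
  run_stage("correlations", function() {
    gs <- load_tbl("germination_summary.csv")
    ph <- load_tbl("phenotypes.csv")
    meta <- load_tbl("line_meta.csv")
    calls <- load_tbl("mkk3_calls.csv")
    checks <- meta$line_id[meta$is_check]
    gs <- gs[!gs$line_id %in% checks, ]
    malt_means <- plot_trait_means(ph[!ph$line_id %in% checks, ])
    alleles <- classify_mkk3(calls)[, c("line_id", "allele")]
    scan <- correlation_scan(malt_means, gs, alleles = alleles,
                             malt_traits = intersect(scan_traits,
                                                     unique(malt_means$trait)),
                             germ_trait = "GI",
                             timepoints = intersect(scan_timepoints,
                                                    unique(gs$timepoint)))
    write_results(scan, path("correlation_scan.csv"))
    results$correlation_scan <<- scan

    bl <- load_tbl("blues.csv")
    comb <- bl[bl$label == "Combined", ]
    if (nrow(comb)) {
      pc <- phenotypic_correlation_matrix(comb)
      pc_tbl <- as_tibble(pc, rownames = "trait")
      write_results(pc_tbl, path("phenotypic_correlations.csv"))
      bp <- biplot_decomposition(pc)
      write_results(dplyr::mutate(bp$loadings,
                                  var_exp_pc1 = bp$variance_explained[1],
                                  var_exp_pc2 = bp$variance_explained[2]),
                    path("biplot_loadings.csv"))
      results$biplot <<- bp
    }
  })

  ## ---- selection response ----
  run_stage("selection_response", function() {
    ph <- load_tbl("phenotypes.csv")
    meta <- load_tbl("line_meta.csv")
    gs <- load_tbl("germination_summary.csv")
    ph <- ph[!ph$line_id %in% meta$line_id[meta$is_check], , drop = FALSE]
    cyc <- meta[!is.na(meta$cycle), c("line_id", "cycle")]
    tp1 <- sort(unique(gs$timepoint))[1]
    phs <- gs[gs$timepoint == tp1, ] |>
      dplyr::inner_join(cyc, by = "line_id") |>
      dplyr::filter(.data$cycle != "PARENT") |>
      dplyr::group_by(.data$cycle) |>
      dplyr::summarise(phs_mean = mean(.data$GI), .groups = "drop")
    rows <- list()
    for (trt in sort(unique(ph$trait))) {
      sr <- fit_selection_response(ph, cyc, trait = trt)
      rows[[length(rows) + 1]] <- response_summary(sr, phs_means = phs)
    }
    out <- dplyr::bind_rows(rows)
    write_results(out, path("selection_response.csv"))
    results$selection_response <<- out
  })

  ## ---- scoring ----
  run_stage("scoring", function() {
    bl <- load_tbl("blues.csv")
    comb <- bl[bl$label == "Combined", c("line_id", "trait", "estimate")]
    if (!nrow(comb)) abort("scoring requires 'Combined' BLUEs in blues.csv")
    names(comb)[3] <- "value"
    sc_path <- score_config %||%
      system.file("extdata", "score_config.yaml", package = "maltgerm")
    cfg_sc <- read_score_config(sc_path)
    sc <- suppressWarnings(score_lines(comb, cfg_sc))
    write_results(sc, path("quality_scores.csv"))
    results$scores <<- sc
  })

  ## ---- manifest ----
  files <- sort(list.files(out_dir, pattern = "\\.csv$"))
  manifest <- c(
    paste0("package=maltgerm ", as.character(utils::packageVersion("maltgerm"))),
    paste0("seed=", seed),
    paste0("config_hash=", rlang::hash(cfg)),
    paste0("stages=", paste(stages, collapse = ",")),
    vapply(files, function(f)
      paste0(f, "=", rlang::hash(readLines(path(f), warn = FALSE))), "")
  )
  writeLines(manifest, path("manifest.txt"))
  say("done: ", length(files), " output files")
  invisible(results)
}
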