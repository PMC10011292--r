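#' Read and validate an end-use scoring configuration
#'
#' Malt-house scoring ranks each line for two end uses — adjunct and
#' all-malt brewing — by awarding points per trait according to which band
#' of the trait scale its value falls in, then summing the points over
#' traits; separately, an acceptance interval per trait and end use defines
#' whether a line falls inside the published breeding-target ranges. The
#' band tables and target intervals are deliberately config-driven: the
#' shipped `inst/extdata/score_config.yaml` is an illustrative synthetic
#' configuration for tests and examples, not a published scoring table.
#'
#' The YAML layout is, per end use (`adjunct`, `all_malt`):
#' `bands: {TRAIT: [{min, max, points}, ...]}` and
#' `range: {TRAIT: {min, max}}`. Band intervals are half-open `[min, max)`,
#' must not overlap within a trait, and any value outside every band scores
#' 0 (implicit catch-all). `min`/`max` may be `-Inf`/`.inf`/`Inf`.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return validated `mg_score_config` object.
#' @export
read_score_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  for (use in c("adjunct", "all_malt")) {
    if (is.null(cfg[[use]])) abort(paste0("score config missing end use '", use, "'"))
    bands <- cfg[[use]]$bands
    for (tr in names(bands)) {
      b <- dplyr::bind_rows(lapply(bands[[tr]], as_tibble))
      b$min <- as.numeric(b$min); b$max <- as.numeric(b$max)
      if (any(b$points < 0)) abort(paste0("negative points for ", use, "/", tr))
      if (any(b$min >= b$max)) abort(paste0("empty band for ", use, "/", tr))
      b <- b[order(b$min), , drop = FALSE]
      if (nrow(b) > 1 && any(b$min[-1] < b$max[-nrow(b)])) {
        abort(paste0("overlapping score bands for ", use, "/", tr))
      }
      cfg[[use]]$bands[[tr]] <- b
    }
    rng <- cfg[[use]]$range
    for (tr in names(rng)) {
      r <- rng[[tr]]
      if (is.null(r$min) || is.null(r$max) ||
          as.numeric(r$min) >= as.numeric(r$max)) {
        abort(paste0("invalid acceptance range for ", use, "/", tr))
      }
      cfg[[use]]$range[[tr]] <- list(min = as.numeric(r$min),
                                     max = as.numeric(r$max))
    }
  }
  structure(cfg, class = "mg_score_config")
}

score_one_use <- function(traits, bands) {
  total <- 0
  skipped <- character(0)
  for (tr in names(bands)) {
    v <- traits[[tr]]
    if (is.null(v) || is.na(v)) {
      skipped <- c(skipped, tr)
      next
    }
    b <- bands[[tr]]
    hit <- which(v >= b$min & v < b$max)
    total <- total + if (length(hit)) b$points[hit[1]] else 0
  }
  list(points = total, skipped = skipped)
}

in_ranges <- function(traits, rng) {
  for (tr in names(rng)) {
    v <- traits[[tr]]
    if (is.null(v) || is.na(v)) return(NA)
    if (v < rng[[tr]]$min || v > rng[[tr]]$max) return(FALSE)
  }
  TRUE
}

#' Score lines for adjunct and all-malt end use
#'
#' Applies a scoring configuration to per-line trait values, returning the
#' two total scores (`ccru_adj`, `ccru_allmalt`), a breeding-target range
#' class per line (`ALL_MALT`, `ADJUNCT`, `BOTH`, `NEITHER`) and a
#' completeness flag when any configured trait was missing for the line
#' (missing traits are skipped with a warning, not imputed as zero-band).
#'
#' @param line_traits tibble with `line_id` and one column per trait (wide),
#'   or long format with `line_id`, `trait`, `value`.
#' @param cfg an `mg_score_config` from [read_score_config()].
#' @return tibble `line_id`, `ccru_adj`, `ccru_allmalt`, `range_class`,
#'   `complete`.
#' @export
score_lines <- function(line_traits, cfg) {
  stopifnot(inherits(cfg, "mg_score_config"))
  wide <- as_tibble(line_traits)
  if (all(c("trait", "value") %in% names(wide))) {
    wide <- tidyr::pivot_wider(wide[, c("line_id", "trait", "value")],
                               names_from = "trait", values_from = "value")
  }
  any_skip <- FALSE
  out <- purrr::map_dfr(seq_len(nrow(wide)), function(i) {
    tr <- as.list(wide[i, , drop = FALSE])
    adj <- score_one_use(tr, cfg$adjunct$bands)
    am <- score_one_use(tr, cfg$all_malt$bands)
    if (length(adj$skipped) || length(am$skipped)) any_skip <<- TRUE
    tibble(line_id = wide$line_id[i],
           ccru_adj = adj$points, ccru_allmalt = am$points,
           range_class = classify_ranges(tr, cfg),
           complete = !length(adj$skipped) && !length(am$skipped))
  })
  if (any_skip) warn("score_lines: some lines missing configured trait(s); scored on the remainder")
  out
}

#' Classify a line against the breeding-target ranges
#'
#' `ALL_MALT` when every configured trait lies inside the all-malt
#' acceptance interval, `ADJUNCT` analogously, `BOTH` when inside the
#' intersection of the two target regions, else `NEITHER`. A missing trait
#' makes the corresponding classification indeterminate, which resolves to
#' `NEITHER` with the line flagged incomplete by [score_lines()].
#'
#' @param traits named list/one-row data of trait values.
#' @param cfg an `mg_score_config`.
#' @return one of `"ALL_MALT"`, `"ADJUNCT"`, `"BOTH"`, `"NEITHER"`.
#' @export
classify_ranges <- function(traits, cfg) {
  stopifnot(inherits(cfg, "mg_score_config"))
  traits <- as.list(traits)
  am <- isTRUE(in_ranges(traits, cfg$all_malt$range))
  ad <- isTRUE(in_ranges(traits, cfg$adjunct$range))
  if (am && ad) "BOTH" else if (am) "ALL_MALT" else if (ad) "ADJUNCT" else "NEITHER"
}
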