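#' After-ripening timepoint map
#'
#' Germination assays are run at seven after-ripening timepoints labelled
#' TP1..TP7, at 6, 20, 34, 48, 69, 110 and 160 days post physiological
#' maturity (PM). Malting is performed at TP4 (48 d) and TP6 (110 d);
#' less tightly controlled material malted between 150 and 200 days post PM
#' is conventionally assigned the TP6 label before across-year analyses.
#'
#' @return named integer vector, days post PM per timepoint label.
#' @export
timepoint_days <- function() {
  c(TP1 = 6L, TP2 = 20L, TP3 = 34L, TP4 = 48L, TP5 = 69L, TP6 = 110L, TP7 = 160L)
}

phenotype_cols <- c("plot_id", "line_id", "year", "location", "block",
                    "trait", "timepoint", "tech_rep", "value")

#' Read a long-format plot-level phenotype table
#'
#' The canonical phenotype layout is one row per technical replicate of one
#' trait on one plot at one timepoint, with columns `plot_id`, `line_id`,
#' `year`, `location`, `block`, `trait`, `timepoint`, `tech_rep`, `value`.
#' Rows with a missing `value` are kept and flagged (`missing_value` column),
#' not dropped, so each downstream model can decide its own subset; the read
#' is logged to stderr with row and missing counts.
#'
#' @param path CSV file path.
#' @return validated tibble of phenotype records.
#' @export
read_phenotypes <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_phenotypes(tab, context = path)
}

#' @rdname read_phenotypes
#' @param tab in-memory data frame to validate against the phenotype schema.
#' @param context label used in messages.
#' @export
validate_phenotypes <- function(tab, context = "phenotypes") {
  tab <- as_tibble(tab)
  miss <- setdiff(phenotype_cols, names(tab))
  if (length(miss)) {
    abort(paste0("phenotype table '", context, "' is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  key <- paste(tab$plot_id, tab$trait, tab$timepoint, tab$tech_rep, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab[duplicated(key), c("plot_id", "trait", "timepoint", "tech_rep")]
    abort(paste0("phenotype table '", context, "' has ", nrow(dup),
                 " duplicated (plot_id, trait, timepoint, tech_rep) key(s), e.g. ",
                 paste(unlist(dup[1, ]), collapse = "/")))
  }
  plmap <- dplyr::distinct(tab, .data$plot_id, .data$line_id, .data$year)
  if (anyDuplicated(plmap$plot_id)) {
    abort(paste0("phenotype table '", context,
                 "': some plot_id map to more than one line_id/year"))
  }
  tab$missing_value <- is.na(tab$value)
  inform(paste0("[io] ", context, ": ", nrow(tab), " rows, ",
                sum(tab$missing_value), " with missing value"))
  tab
}

#' Marker quality control
#'
#' Filters a long-format marker table (one row per line x marker, genotype in
#' \{A, B, HET, MISSING\}) on per-marker heterozygosity and minor allele
#' frequency. MAF is computed from non-missing calls with heterozygotes
#' counted as half a dose of each allele. The boundary is retained on both
#' filters: markers are removed when heterozygosity exceeds `max_het`
#' (strictly) or MAF falls below `min_maf` (strictly), so het = `max_het`
#' and MAF = `min_maf` survive. Markers with every call missing are dropped
#' with a warning.
#'
#' @param markers tibble with columns `line_id`, `marker_id`, `genotype`.
#' @param max_het maximum tolerated heterozygosity (default 0.10).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @return the filtered marker tibble (same columns, fewer markers).
#' @export
qc_markers <- function(markers, max_het = 0.10, min_maf = 0.05) {
  stopifnot(max_het >= 0, max_het <= 0.5, min_maf >= 0, min_maf <= 0.5)
  markers <- as_tibble(markers)
  need <- c("line_id", "marker_id", "genotype")
  miss <- setdiff(need, names(markers))
  if (length(miss)) {
    abort(paste0("marker table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(markers$genotype), c("A", "B", "HET", "MISSING"))
  if (length(bad)) {
    abort(paste0("marker genotypes outside {A, B, HET, MISSING}: ",
                 paste(bad, collapse = ", ")))
  }
  stats <- markers |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(
      n_called = sum(.data$genotype != "MISSING"),
      het = ifelse(n_called == 0, NA_real_,
                   sum(.data$genotype == "HET") / n_called),
      p_a = ifelse(n_called == 0, NA_real_,
                   (sum(.data$genotype == "A") + 0.5 * sum(.data$genotype == "HET")) /
                     n_called),
      maf = pmin(p_a, 1 - p_a),
      .groups = "drop")
  all_missing <- stats$marker_id[stats$n_called == 0]
  if (length(all_missing)) {
    warn(paste0("qc_markers: ", length(all_missing),
                " marker(s) with no non-missing calls excluded: ",
                paste(head(all_missing, 5), collapse = ", ")))
  }
  keep <- stats$marker_id[!is.na(stats$het) &
                            stats$het <= max_het & stats$maf >= min_maf]
  dplyr::filter(markers, .data$marker_id %in% keep)
}

#' Write and re-read result tables
#'
#' All result types in this package are plain tibbles; `write_results()`
#' serialises them as RFC-4180 CSV with deterministic column order and full
#' float precision so that `read_results()` round-trips exactly (identifiers)
#' or to ~1e-15 relative (doubles).
#'
#' @param obj a data frame (any result table).
#' @param path output CSV path.
#' @return `path`, invisibly (for `write_results`); a tibble for `read_results`.
#' @export
write_results <- function(obj, path) {
  stopifnot(is.data.frame(obj))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(obj), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
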