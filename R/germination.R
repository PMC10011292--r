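#' Germination percentage from a plate count record
#'
#' A germination assay plates `n_plated` kernels (30 by default) in a petri
#' dish and counts newly germinated kernels at 24, 48 and 72 h. The
#' germination percentage GE is the proportion of plated kernels that
#' germinated within 72 h:
#' \deqn{GE = (n_{24} + n_{48} + n_{72}) / n_{plated}.}
#'
#' @param plates data frame with integer columns `n24`, `n48`, `n72` and
#'   optionally `n_plated` (default 30); any other columns pass through.
#' @return the input as a tibble with a `GE` column appended.
#' @export
germination_percentage <- function(plates) {
  plates <- validate_plates(plates)
  dplyr::mutate(plates, GE = (.data$n24 + .data$n48 + .data$n72) / .data$n_plated)
}

#' Germination index (rate) from a plate count record
#'
#' GI is an inverse-mean-germination-time index scaled to lie in \[0, 10\]:
#' \deqn{GI = 10 (n_{24}+n_{48}+n_{72}) \cdot GE /
#'   (1 n_{24} + 2 n_{48} + 3 n_{72}).}
#' A fully dormant plate (no kernel germinated) is assigned GI = 0, the
#' dormant extreme of the scale; GI = 10 is attained only when every plated
#' kernel germinates within the first 24 h. GI at the first after-ripening
#' timepoint (6 days post physiological maturity) serves as the measure of
#' preharvest-sprouting resistance and is exposed under the alias
#' [phs_score()].
#'
#' @inheritParams germination_percentage
#' @return the input as a tibble with `GE` and `GI` columns appended.
#' @export
germination_index <- function(plates) {
  plates <- germination_percentage(plates)
  tot <- plates$n24 + plates$n48 + plates$n72
  days <- 1 * plates$n24 + 2 * plates$n48 + 3 * plates$n72
  gi <- ifelse(tot == 0, 0, 10 * tot * plates$GE / days)
  dplyr::mutate(plates, GI = gi)
}

#' @rdname germination_index
#' @export
phs_score <- function(plates) {
  out <- germination_index(plates)
  dplyr::rename(out, phs_score = "GI")
}

validate_plates <- function(plates) {
  plates <- as_tibble(plates)
  need <- c("n24", "n48", "n72")
  miss <- setdiff(need, names(plates))
  if (length(miss)) {
    abort(paste0("plate table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"n_plated" %in% names(plates)) plates$n_plated <- 30L
  counts <- plates[c(need, "n_plated")]
  if (any(vapply(counts, function(x) any(x < 0 | x != floor(x)), TRUE))) {
    abort("plate counts must be non-negative integers")
  }
  if (any(plates$n_plated <= 0)) abort("n_plated must be positive")
  over <- plates$n24 + plates$n48 + plates$n72 > plates$n_plated
  if (any(over)) {
    abort(paste0(sum(over), " plate(s) have more germinated kernels than were plated"))
  }
  plates
}

#' Plot-level germination summaries
#'
#' Computes GE and GI per plate, then averages the technical plate replicates
#' (two per experimental plot by design) within each plot x timepoint cell.
#' Averaging is per-plate-then-mean, matching how technical replicates are
#' handled throughout: the index is computed on each plate and the plate
#' values averaged, not pooled counts.
#'
#' @param plates data frame with `plot_id`, `timepoint`, plate counts and any
#'   identifying columns (`line_id`, `year`, ... are carried through when
#'   constant within plot x timepoint).
#' @return tibble with one row per plot x timepoint: `GE`, `GI`, `n_plates`.
#' @export
plot_germination_means <- function(plates) {
  plates <- germination_index(plates)
  need <- c("plot_id", "timepoint")
  miss <- setdiff(need, names(plates))
  if (length(miss)) {
    abort(paste0("plate table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  carry <- intersect(c("line_id", "year", "location", "cycle"), names(plates))
  plates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(need, carry)))) |>
    dplyr::summarise(GE = mean(.data$GE), GI = mean(.data$GI),
                     n_plates = dplyr::n(), .groups = "drop")
}
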