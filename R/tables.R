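#' Read a specimen classifier table
#'
#' The classifier CSV assigns each specimen to its species, locality, sex and
#' individual. (In this design specimen and individual usually coincide; the
#' `individual` column exists so that multiple preparations of one animal can
#' be tied together.)
#'
#' @param path CSV file with a header containing at least `specimen_id`,
#'   `species`, `locality`, `sex`, `individual`.
#' @return A tibble with those columns as factors (specimen_id, individual as
#'   character).
#' @export
read_classifier_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("specimen_id", "species", "locality", "sex", "individual")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    abort(paste0("classifier table missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tab$specimen_id)) {
    abort("duplicate specimen_id in classifier table")
  }
  if (anyNA(tab$species) || anyNA(tab$sex)) {
    abort("species and sex must be non-missing for every specimen")
  }
  dplyr::mutate(tab,
                specimen_id = as.character(.data$specimen_id),
                individual = as.character(.data$individual),
                dplyr::across(c("species", "locality", "sex"), as.factor))
}

#' Read a covariate (count) table
#'
#' Per-specimen named non-negative integer counts, e.g. spinule counts per
#' row (alpha..delta on the antennal basis, epsilon/zeta on the fourth leg,
#' La on the labrum).
#'
#' @param path CSV file with a header containing `specimen_id` plus one
#'   numeric column per count.
#' @return A tibble.
#' @export
read_covariate_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"specimen_id" %in% names(tab)) abort("covariate table missing column: specimen_id")
  counts <- dplyr::select(tab, -"specimen_id")
  if (any(vapply(counts, function(x) any(x < 0, na.rm = TRUE), logical(1)))) {
    abort("covariate counts must be non-negative")
  }
  dplyr::mutate(tab, specimen_id = as.character(.data$specimen_id))
}

#' Check a landmark dataset for completeness
#'
#' Real landmark datasets are rarely complete: specimens can lack one side or
#' a replicate because of damage or abnormalities. This reports, per specimen,
#' which side/replicate cells are present, and applies the analysis policy:
#' specimens with incomplete side sets are dropped from matching-symmetry
#' asymmetry analyses but retained wherever only per-individual means are
#' needed (PCA, regressions, group means).
#'
#' The operation only reports; it never mutates its inputs, and running it on
#' its own retained subset returns the same subset.
#'
#' @param configs Configuration tibble ([read_tps()] format).
#' @param classifiers Classifier tibble ([read_classifier_table()] format).
#' @param scheme The [landmark_scheme] the configurations follow.
#' @return An object of class `validation_report`: a list with `specimens`
#'   (tibble: specimen, n_configs, n_sides, complete_sides, in_classifier),
#'   `retained_asymmetry`, `retained_means` (character vectors of specimen
#'   IDs) and `counts`.
#' @export
validate_dataset <- function(configs, classifiers, scheme) {
  needs_sides <- scheme$symmetry == "matching"
  per <- configs |>
    dplyr::group_by(.data$specimen) |>
    dplyr::summarise(
      n_configs = dplyr::n(),
      n_sides = dplyr::n_distinct(.data$side),
      complete_sides = if (needs_sides) all(c("left", "right") %in% .data$side) else TRUE,
      .groups = "drop"
    ) |>
    dplyr::mutate(in_classifier = .data$specimen %in% classifiers$specimen_id)
  retained_asym <- per$specimen[per$complete_sides & per$in_classifier]
  retained_means <- per$specimen[per$in_classifier]
  out <- list(
    specimens = per,
    retained_asymmetry = retained_asym,
    retained_means = retained_means,
    counts = c(total = nrow(per),
               retained_asymmetry = length(retained_asym),
               dropped_asymmetry = nrow(per) - length(retained_asym),
               retained_means = length(retained_means))
  )
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(x$counts)
  invisible(x)
}
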