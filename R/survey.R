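#' Household survey datasets
#'
#' A `survey_dataset` holds one row per household: `household_id`, `unit_id`
#' (the agroecosystem the household belongs to), response columns (categorical
#' labels or numbers) and livestock head counts in `livestock.<species>`
#' columns. A derived `tlu` response (tropical livestock units, the
#' species-weighted herd size) is computed automatically from the livestock
#' columns when present.
#'
#' @name survey_dataset
NULL

#' Default tropical livestock unit conversion factors
#'
#' The standard TLU weights for East African herds (one TLU is a 250 kg
#' animal): camel 1.0, cattle 0.7, horse 0.8, mule 0.7, donkey 0.5, sheep 0.1,
#' goat 0.1, pig 0.2, chicken 0.01. Override by passing a named vector to
#' [compute_tlu()] or [survey_dataset()].
#'
#' @return named numeric vector of TLU per head by species.
#' @export
default_tlu_factors <- function() {
  c(camel = 1.0, cattle = 0.7, horse = 0.8, mule = 0.7, donkey = 0.5,
    sheep = 0.1, goat = 0.1, pig = 0.2, chicken = 0.01)
}

#' Convert livestock head counts to tropical livestock units
#'
#' @param livestock named numeric vector or one-row list, species -> head
#'   count (non-negative).
#' @param factors named numeric vector, species -> TLU weight per head.
#' @return scalar TLU value (0 for an empty herd).
#' @export
#' @examples
#' compute_tlu(c(cattle = 2, sheep = 2)) # 2*0.7 + 2*0.1 = 1.6
compute_tlu <- function(livestock, factors = default_tlu_factors()) {
  livestock <- unlist(livestock)
  if (length(livestock) == 0) return(0)
  if (any(livestock < 0, na.rm = TRUE)) stop_named("negative livestock count")
  unknown <- setdiff(names(livestock), names(factors))
  if (length(unknown))
    stop_named("unknown livestock species: %s (no TLU factor)",
               paste(unknown, collapse = ", "))
  sum(livestock * factors[names(livestock)], na.rm = TRUE)
}

#' Build a survey dataset from a household-level data.frame
#'
#' @param records data.frame with `household_id`, `unit_id`, response columns
#'   and optional `livestock.<species>` columns. Missing responses are `NA`
#'   (empty cells in CSV input).
#' @param units optional ordered character vector of unit ids; defaults to
#'   order of first appearance.
#' @param tlu_factors species weights used to derive the `tlu` column.
#' @return a `survey_dataset`: list with `records` (data.frame), `units`
#'   (ordered ids) and `n` (named per-unit household counts).
#' @export
survey_dataset <- function(records, units = NULL,
                           tlu_factors = default_tlu_factors()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("household_id", "unit_id"))
    if (is.null(records[[col]])) stop_named("records missing column: %s", col)
  if (any(is.na(records$unit_id) | !nzchar(records$unit_id)))
    stop_named("empty unit_id in records")
  units <- units %||% unique(records$unit_id)
  stray <- setdiff(unique(records$unit_id), units)
  if (length(stray))
    stop_named("records reference units not in unit list: %s",
               paste(stray, collapse = ", "))
  ls_cols <- grep("^livestock\\.", names(records), value = TRUE)
  if (length(ls_cols) && is.null(records$tlu)) {
    species <- sub("^livestock\\.", "", ls_cols)
    counts <- as.matrix(records[ls_cols])
    counts[is.na(counts)] <- 0
    weights <- vapply(species, function(s) {
      if (!s %in% names(tlu_factors))
        stop_named("unknown livestock species: %s (no TLU factor)", s)
      tlu_factors[[s]]
    }, numeric(1))
    records$tlu <- as.numeric(counts %*% weights)
  }
  n <- table(factor(records$unit_id, levels = units))
  structure(list(records = records, units = units,
                 n = stats::setNames(as.integer(n), units)),
            class = "survey_dataset")
}

#' Read a survey dataset from delimited text
#'
#' Expects a header row with `household_id`, `unit_id`, response columns and
#' `livestock.<species>` columns; empty cells are missing.
#'
#' @param path CSV file path.
#' @inheritParams survey_dataset
#' @return a `survey_dataset`.
#' @export
read_survey <- function(path, units = NULL, tlu_factors = default_tlu_factors()) {
  if (!file.exists(path)) stop_named("survey file not found: %s", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = "")
  survey_dataset(rec, units = units, tlu_factors = tlu_factors)
}

#' Write a survey dataset to CSV
#' @param ds a `survey_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(ds, path) {
  utils::write.csv(ds$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("<survey_dataset> %d households in %d units (%s)\n",
              nrow(x$records), length(x$units),
              paste(sprintf("%s: %d", x$units, x$n), collapse = ", ")))
  invisible(x)
}
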