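#' Aggregate one indicator to per-unit raw values
#'
#' Turns household responses into the unit-level raw value the index
#' standardization consumes. Proportion indicators return
#' `100 * matches / non-missing responses` in the unit (missing responses are
#' excluded from the denominator, not treated as non-matches); `mean` and
#' `sum` aggregate non-missing numeric responses. Units with zero non-missing
#' responses get a flagged-missing (`NA`) cell with a warning.
#'
#' @param ds a [survey_dataset()].
#' @param ind one-row data.frame (or list) with `id`, `aggregator`,
#'   `source_field`, `target_category` as in an `lvi_framework` indicator.
#' @return list with `values` (named per-unit vector; percent for
#'   proportions) and `n_eff` (named per-unit non-missing response counts).
#' @export
aggregate_indicator <- function(ds, ind) {
  agg <- ind$aggregator
  if (agg == "precomputed")
    stop_named("indicator '%s' is precomputed at unit level; supply its values via the precomputed table",
               ind$id)
  field <- ind$source_field
  if (is.null(ds$records[[field]]))
    stop_named("indicator '%s': source field '%s' not present in survey records",
               ind$id, field)
  x <- ds$records[[field]]
  unit <- factor(ds$records$unit_id, levels = ds$units)
  per_unit <- function(fun) vapply(split(x, unit), fun, numeric(1))
  n_eff <- vapply(split(x, unit), function(v) sum(!is.na(v)), numeric(1))
  values <- switch(agg,
    proportion = per_unit(function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) return(NA_real_)
      100 * sum(v == ind$target_category) / length(v)
    }),
    mean = per_unit(function(v) {
      v <- as.numeric(v); v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else mean(v)
    }),
    sum = per_unit(function(v) {
      v <- as.numeric(v); v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else sum(v)
    }),
    stop_named("indicator '%s': unknown aggregator '%s'", ind$id, agg))
  if (anyNA(values))
    warning(sprintf("indicator '%s': no non-missing responses in unit(s) %s; cell flagged missing",
                    ind$id, paste(ds$units[is.na(values)], collapse = ", ")),
            call. = FALSE)
  list(values = values, n_eff = stats::setNames(as.numeric(n_eff), ds$units))
}

#' Assemble the unit x indicator raw-value table
#'
#' Survey-aggregatable indicators are computed from `ds`; `precomputed`
#' indicators (and any survey indicator also present in `precomputed`) are
#' taken from the supplied unit-level table. Each cell records its provenance.
#'
#' @param ds a [survey_dataset()].
#' @param fw an `lvi_framework`.
#' @param precomputed data.frame with columns `unit_id`, `indicator_id`,
#'   `value`, or a path to such a CSV, or `NULL`.
#' @return an `aes_indicator_table`: list with `values` (units x indicators
#'   numeric matrix of raw values), `n` (per-unit sample sizes), `n_eff`
#'   (units x indicators effective response counts; `NA` for precomputed
#'   cells) and `provenance` ("survey" or "precomputed" per cell).
#' @export
build_indicator_table <- function(ds, fw, precomputed = NULL) {
  if (is.character(precomputed)) {
    if (!file.exists(precomputed))
      stop_named("precomputed table not found: %s", precomputed)
    precomputed <- utils::read.csv(precomputed, stringsAsFactors = FALSE)
  }
  units <- ds$units
  ids <- fw$indicators$id
  values <- matrix(NA_real_, length(units), length(ids),
                   dimnames = list(units, ids))
  n_eff <- values
  prov <- matrix(NA_character_, length(units), length(ids),
                 dimnames = list(units, ids))
  for (k in seq_along(ids)) {
    ind <- fw$indicators[k, ]
    pre <- NULL
    if (!is.null(precomputed))
      pre <- precomputed[precomputed$indicator_id == ind$id, , drop = FALSE]
    if (!is.null(pre) && nrow(pre) > 0) {
      m <- match(units, pre$unit_id)
      if (anyNA(m))
        stop_named("indicator '%s': precomputed values missing for unit(s) %s",
                   ind$id, paste(units[is.na(m)], collapse = ", "))
      values[, k] <- pre$value[m]
      prov[, k] <- "precomputed"
    } else if (ind$aggregator == "precomputed") {
      stop_named("indicator '%s' is precomputed but absent from the precomputed table",
                 ind$id)
    } else {
      agg <- aggregate_indicator(ds, ind)
      values[, k] <- agg$values
      n_eff[, k] <- agg$n_eff
      prov[, k] <- "survey"
    }
  }
  structure(list(values = values, n = ds$n, n_eff = n_eff, provenance = prov,
                 units = units, indicators = ids),
            class = "aes_indicator_table")
}

#' "All households" summary of a per-unit row
#'
#' Collapses one indicator's per-unit values to a single whole-sample figure,
#' either as the plain mean of unit values (`unweighted`) or as the
#' sample-size-weighted mean `sum(n_i v_i) / sum(n_i)` (`weighted`). Published
#' LVI survey tables mix both conventions row by row, so reports carry the two
#' side by side rather than guessing one.
#'
#' @param values per-unit numeric vector.
#' @param n per-unit sample sizes (required for `weighted`).
#' @param mode `"unweighted"` or `"weighted"`.
#' @return scalar summary.
#' @export
all_units_summary <- function(values, n = NULL, mode = c("unweighted", "weighted")) {
  mode <- match.arg(mode)
  if (length(values) == 0) stop_named("empty value row")
  keep <- !is.na(values)
  if (mode == "unweighted") return(mean(values[keep]))
  if (is.null(n) || length(n) != length(values))
    stop_named("weighted summary requires per-unit n of matching length")
  if (any(n[keep] <= 0)) stop_named("weighted summary requires n > 0")
  sum(n[keep] * values[keep]) / sum(n[keep])
}

#' @export
print.aes_indicator_table <- function(x, ...) {
  cat(sprintf("<aes_indicator_table> %d units x %d indicators (%d missing cells)\n",
              length(x$units), length(x$indicators), sum(is.na(x$values))))
  invisible(x)
}
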