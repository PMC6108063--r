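#' Report formatting and pipeline orchestration
#'
#' `format_table()` renders a scores table in one of two styles: `"paper"`
#' mirrors published index tables (one row per unit plus an `Average` row of
#' unweighted column means, indices rounded half-up to 2 decimals) and
#' `"tidy"` is a lossless long format for downstream tools. `run_pipeline()`
#' executes the whole analysis from file inputs and writes the standard
#' output bundle.
#'
#' @name cli_reporting
NULL

#' Format a unit-by-scores table for reporting
#'
#' @param scores data.frame with a `unit` column and numeric score columns
#'   (e.g. the `scores` element of [compute_lvi()]), plus optionally `class`.
#' @param style `"paper"` (wide, 2-decimal half-up rounding, appended
#'   `Average` row = unweighted column means of the unit rows) or `"tidy"`
#'   (long `unit, variable, value` at full precision; re-parses losslessly).
#' @param digits decimal places for `"paper"` style.
#' @return a data.frame in the requested layout. The `"paper"` layout carries
#'   a `footnote` attribute noting that the LVI-IPCC column is recomputed
#'   from its own E/S/A columns via (E - A) * S, which published tables do
#'   not always satisfy.
#' @export
format_table <- function(scores, style = c("paper", "tidy"), digits = 2) {
  style <- match.arg(style)
  num_cols <- names(scores)[vapply(scores, is.numeric, logical(1))]
  if (style == "tidy") {
    long <- do.call(rbind, lapply(num_cols, function(cl)
      data.frame(unit = scores$unit, variable = cl, value = scores[[cl]],
                 stringsAsFactors = FALSE)))
    return(long)
  }
  avg <- scores[1, , drop = FALSE]
  avg$unit <- "Average"
  for (cl in setdiff(names(scores), c("unit", num_cols))) avg[[cl]] <- ""
  for (cl in num_cols) avg[[cl]] <- mean(scores[[cl]])
  out <- rbind(scores, avg)
  for (cl in num_cols) out[[cl]] <- round_half_up(out[[cl]], digits)
  rownames(out) <- NULL
  attr(out, "footnote") <-
    "LVI-IPCC computed as (E - A) * S from this table's own columns; published index tables do not always satisfy that identity."
  out
}

#' Run the full LVI pipeline from file inputs
#'
#' Reads the survey, framework, precomputed unit-level cells, optional
#' climate series and unit areas; computes the indicator table, the
#' standardization/profile/factor/index chain, pairwise comparisons for every
#' survey proportion indicator, climate trend tests and land-area class
#' shares; and writes `indicator_table.csv`, `standardized.csv`,
#' `profiles.csv`, `factors.csv`, `lvi.csv`, `comparisons.csv`,
#' `trends.csv`, `area_shares.csv` and a `manifest.json` into `out_dir`.
#' Rerunning with the same config and seed reproduces the outputs
#' byte-identically.
#'
#' @param survey path to the survey CSV, or a [survey_dataset()].
#' @param framework path to a framework config, or an `lvi_framework`.
#' @param precomputed path to the unit-level precomputed cells CSV (or
#'   data.frame, or `NULL`).
#' @param areas path to a `unit_id, area_km2` CSV (or named vector, or
#'   `NULL` to skip area shares).
#' @param climate path to a `station_id, year[, month], value` CSV (or named
#'   list of `climate_series`, or `NULL` to skip trends).
#' @param out_dir output directory (created if needed).
#' @param alpha significance level for comparisons and trend masks.
#' @param thresholds LVI-IPCC classification thresholds.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the survey input was generated).
#' @return invisibly, a list with the in-memory results (`table`, `result`,
#'   `comparisons`, `trends`, `area_shares`, `paths`).
#' @export
run_pipeline <- function(survey, framework = default_framework_path(),
                         precomputed = NULL, areas = NULL, climate = NULL,
                         out_dir = ".", alpha = 0.05, thresholds = c(0, 0.45),
                         seed = NA_integer_) {
  fw <- if (inherits(framework, "lvi_framework")) framework else load_framework(framework)
  ds <- if (inherits(survey, "survey_dataset")) survey else read_survey(survey)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tab <- build_indicator_table(ds, fw, precomputed)
  res <- compute_lvi(tab, fw, thresholds = thresholds)

  prop_inds <- fw$indicators[fw$indicators$aggregator == "proportion", , drop = FALSE]
  comparisons <- do.call(rbind, lapply(seq_len(nrow(prop_inds)), function(k) {
    cm <- pairwise_significance(ds, prop_inds$source_field[k],
                                prop_inds$target_category[k], alpha = alpha)
    cbind(indicator = prop_inds$id[k], cm$pairs)
  }))

  trends <- NULL
  if (!is.null(climate)) {
    series <- if (is.character(climate)) read_climate(climate) else climate
    trends <- do.call(rbind, lapply(series, function(s) {
      tr <- linear_trend_test(compute_anomaly(s))
      data.frame(station = tr$id, slope = tr$slope, t_stat = tr$t_stat,
                 df = tr$df, p_value = tr$p_value,
                 significant_05 = tr$significant_05,
                 significant_10 = tr$significant_10)
    }))
  }

  area_shares <- NULL
  if (!is.null(areas)) {
    if (is.character(areas)) {
      a <- utils::read.csv(areas, stringsAsFactors = FALSE)
      areas <- stats::setNames(a$area_km2, a$unit_id)
    }
    cls <- stats::setNames(res$scores$class, res$scores$unit)
    area_shares <- area_share_by_class(areas, cls)
  }

  w <- function(x, f) utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  w(data.frame(unit = rownames(tab$values), tab$values, check.names = FALSE),
    "indicator_table.csv")
  w(data.frame(unit = rownames(res$standardized$values), res$standardized$values,
               check.names = FALSE), "standardized.csv")
  w(data.frame(unit = rownames(res$profiles$values), res$profiles$values,
               check.names = FALSE), "profiles.csv")
  w(data.frame(unit = rownames(res$factors$values), res$factors$values,
               check.names = FALSE), "factors.csv")
  w(format_table(res$scores, "paper"), "lvi.csv")
  w(comparisons, "comparisons.csv")
  if (!is.null(trends)) w(trends, "trends.csv")
  if (!is.null(area_shares))
    w(data.frame(class = names(area_shares), percent = as.numeric(area_shares)),
      "area_shares.csv")
  jsonlite::write_json(
    list(seed = seed, alpha = alpha, thresholds = thresholds,
         units = ds$units, n = as.list(ds$n),
         n_indicators = length(tab$indicators),
         package_version = as.character(utils::packageVersion("lviaes"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(list(table = tab, result = res, comparisons = comparisons,
                 trends = trends, area_shares = area_shares,
                 paths = file.path(out_dir,
                   c("indicator_table.csv", "standardized.csv", "profiles.csv",
                     "factors.csv", "lvi.csv", "comparisons.csv",
                     "manifest.json"))))
}
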