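#' Indicator frameworks: profiles, indicators and IPCC factor mapping
#'
#' An `lvi_framework` encodes which survey indicator feeds which vulnerability
#' profile and which profile feeds which IPCC contributing factor (exposure,
#' sensitivity, adaptive capacity). The packaged default
#' (`system.file("extdata", "framework_choke_table1.json", package =
#' "lviaes")`) carries 8 profiles and 39 indicators for a mixed crop-livestock
#' highland survey: climate (exposure); ecosystem and agriculture
#' (sensitivity); wealth, technology, infrastructure, community and social
#' (adaptive capacity).
#'
#' Each indicator carries an explicit `orientation`: `factor_increasing` if a
#' larger raw value increases the profile's contributing factor,
#' `factor_decreasing` otherwise (e.g. more suitable land lowers sensitivity;
#' longer walking distance to market lowers adaptive capacity). Making the
#' hypothesized direction data rather than convention prevents silent sign
#' errors during standardization.
#'
#' @name lvi_framework
NULL

FACTORS <- c("exposure", "sensitivity", "adaptive_capacity")
CAPITALS <- c("none", "natural", "financial", "physical", "human", "social")
ORIENTATIONS <- c("factor_increasing", "factor_decreasing")
AGGREGATORS <- c("proportion", "mean", "sum", "precomputed")

#' Construct an indicator framework
#'
#' @param profiles data.frame with columns `id`, `name`, `factor`, `capital`.
#' @param indicators data.frame with columns `id`, `label`, `profile_id`,
#'   `unit`, `orientation`, `aggregator`, `source_field`, `target_category`
#'   (the last two may be `NA` for precomputed indicators).
#' @param metadata free-text description.
#' @param schema_version integer config schema version.
#' @return an object of class `lvi_framework`.
#' @export
new_framework <- function(profiles, indicators, metadata = "", schema_version = 1L) {
  fw <- structure(
    list(profiles = as.data.frame(profiles, stringsAsFactors = FALSE),
         indicators = as.data.frame(indicators, stringsAsFactors = FALSE),
         metadata = metadata, schema_version = schema_version),
    class = "lvi_framework")
  diags <- validate_framework(fw)
  errs <- diags[vapply(diags, function(d) d$severity == "error", logical(1))]
  if (length(errs) > 0)
    stop_named("invalid framework: %s",
               paste(vapply(errs, function(d) paste0(d$location, ": ", d$message),
                            character(1)), collapse = "; "))
  fw
}

#' Validate a framework, returning diagnostics rather than raising
#'
#' Checks referential integrity (every indicator's `profile_id` resolves,
#' unique ids, legal factor/orientation/aggregator vocabularies, at least one
#' profile per factor, proportion indicators carry a source field and target
#' category). An empty list means the framework satisfies every invariant.
#'
#' @param fw a list shaped like an `lvi_framework` (possibly broken).
#' @return list of diagnostics, each a list with `severity` ("error" or
#'   "warning"), `location` (key path) and `message`.
#' @export
validate_framework <- function(fw) {
  diags <- list()
  add <- function(severity, location, message)
    diags[[length(diags) + 1L]] <<- list(severity = severity, location = location,
                                         message = message)
  pr <- fw$profiles; ind <- fw$indicators
  if (anyDuplicated(pr$id))
    add("error", "profiles.id", paste("duplicate profile id:",
        paste(unique(pr$id[duplicated(pr$id)]), collapse = ", ")))
  if (anyDuplicated(ind$id))
    add("error", "indicators.id", paste("duplicate indicator id:",
        paste(unique(ind$id[duplicated(ind$id)]), collapse = ", ")))
  bad_factor <- setdiff(unique(pr$factor), FACTORS)
  if (length(bad_factor))
    add("error", "profiles.factor", paste("unknown factor:",
        paste(bad_factor, collapse = ", ")))
  dangling <- setdiff(unique(ind$profile_id), pr$id)
  if (length(dangling))
    add("error", "indicators.profile_id", paste("dangling profile_id:",
        paste(dangling, collapse = ", ")))
  bad_orient <- setdiff(unique(ind$orientation), ORIENTATIONS)
  if (length(bad_orient))
    add("error", "indicators.orientation", paste("unknown orientation:",
        paste(bad_orient, collapse = ", ")))
  bad_agg <- setdiff(unique(ind$aggregator), AGGREGATORS)
  if (length(bad_agg))
    add("error", "indicators.aggregator", paste("unknown aggregator:",
        paste(bad_agg, collapse = ", ")))
  # a narrowed framework (e.g. exposure-only) is constructible; factors with
  # no profiles only fail at contributing_factors() time
  for (f in setdiff(FACTORS, unique(pr$factor)))
    add("warning", "profiles.factor", paste("factor has zero profiles:", f))
  empty <- setdiff(pr$id, unique(ind$profile_id))
  if (length(empty))
    add("error", "profiles", paste("profile has zero indicators:",
        paste(empty, collapse = ", ")))
  prop <- ind[!is.na(ind$aggregator) & ind$aggregator == "proportion", , drop = FALSE]
  bad_prop <- prop$id[is.na(prop$source_field) | is.na(prop$target_category)]
  if (length(bad_prop))
    add("error", "indicators.target_category",
        paste("proportion indicator missing source field or target category:",
              paste(bad_prop, collapse = ", ")))
  svy <- ind[!is.na(ind$aggregator) & ind$aggregator != "precomputed", , drop = FALSE]
  bad_src <- svy$id[is.na(svy$source_field) | !nzchar(svy$source_field)]
  if (length(bad_src))
    add("error", "indicators.source_field",
        paste("survey indicator missing source field:",
              paste(bad_src, collapse = ", ")))
  diags
}

#' Load a framework from a JSON config document
#'
#' The config is a flat JSON object with `schema_version`, `metadata`, a
#' `profiles` array (`id`, `name`, `factor`, `capital`) and an `indicators`
#' array (`id`, `label`, `profile_id`, `unit`, `orientation`, `aggregator`,
#' `source_field`, `target_category`). Parse errors and invariant violations
#' are raised naming the offending key path.
#'
#' @param path path to a JSON framework config; defaults to the packaged
#'   framework reproducing the published 8-profile / 39-indicator table.
#' @return an `lvi_framework`.
#' @export
load_framework <- function(path = default_framework_path()) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e) stop_named("framework config parse failure (%s): %s",
                                                 path, conditionMessage(e)))
  for (key in c("profiles", "indicators"))
    if (is.null(doc[[key]])) stop_named("framework config missing key: %s", key)
  ind <- doc$indicators
  for (col in c("source_field", "target_category"))
    if (is.null(ind[[col]])) ind[[col]] <- NA_character_
  new_framework(doc$profiles, ind,
                metadata = doc$metadata %||% "",
                schema_version = as.integer(doc$schema_version %||% 1L))
}

#' @rdname load_framework
#' @export
default_framework_path <- function()
  system.file("extdata", "framework_choke_table1.json", package = "lviaes",
              mustWork = TRUE)

#' Serialize a framework back to its JSON config form
#'
#' `load_framework(write_framework(fw, path))` round-trips to an identical
#' framework.
#'
#' @param fw an `lvi_framework`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_framework <- function(fw, path) {
  jsonlite::write_json(
    list(schema_version = fw$schema_version, metadata = fw$metadata,
         profiles = fw$profiles, indicators = fw$indicators),
    path, auto_unbox = TRUE, na = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' Per-profile indicator counts (the N_p weights)
#'
#' @param fw an `lvi_framework`.
#' @return named integer vector, one entry per profile in framework order.
#' @export
profile_sizes <- function(fw) {
  np <- table(factor(fw$indicators$profile_id, levels = fw$profiles$id))
  stats::setNames(as.integer(np), fw$profiles$id)
}

#' @export
print.lvi_framework <- function(x, ...) {
  np <- profile_sizes(x)
  cat(sprintf("<lvi_framework> %d profiles, %d indicators\n",
              nrow(x$profiles), nrow(x$indicators)))
  for (i in seq_len(nrow(x$profiles)))
    cat(sprintf("  %-15s -> %-17s (%d indicators)\n", x$profiles$id[i],
                x$profiles$factor[i], np[[x$profiles$id[i]]]))
  invisible(x)
}
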