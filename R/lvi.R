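#' The LVI calculation chain
#'
#' The index is a balanced weighted average: every indicator is first
#' standardized to a common 0-1 scale by min-max across units,
#' `I_v = (I_a - I_min) / (I_max - I_min)`; each profile score `P_a` is the
#' plain mean of its standardized indicators; the composite LVI and the IPCC
#' contributing factors weight profile scores by their indicator counts `N_p`,
#' so each indicator contributes equally overall; and the IPCC-framework score
#' is `LVI-IPCC = (E - A) * S`, running from -1 (least vulnerable) to +1
#' (most vulnerable).
#'
#' Indicators whose larger raw values lower their contributing factor
#' (orientation `factor_decreasing`) are flipped (`1 - I_v`) after
#' standardization, so every profile score is oriented "higher = more of the
#' factor" — the sign convention the `(E - A) * S` form requires for adaptive
#' capacity to offset exposure.
#'
#' @name lvi_chain
NULL

#' Min-max standardize an indicator table across units
#'
#' @param table an `aes_indicator_table` from [build_indicator_table()], or a
#'   plain units x indicators numeric matrix.
#' @param fw an `lvi_framework` supplying per-indicator orientation.
#' @return a `standardized_table`: list with `values` (units x indicators in
#'   0-1, orientation applied), `i_min`, `i_max` (per-indicator bounds used),
#'   and `flipped` (logical per indicator). Indicators constant across units
#'   carry no information and standardize to 0 everywhere, with a warning.
#' @export
standardize <- function(table, fw) {
  raw <- if (inherits(table, "aes_indicator_table")) table$values else as.matrix(table)
  if (nrow(raw) < 2)
    stop_named("standardization needs >= 2 units (min = max everywhere); supply precomputed bounds or more units")
  ids <- colnames(raw)
  orient <- fw$indicators$orientation[match(ids, fw$indicators$id)]
  if (anyNA(orient))
    stop_named("indicators absent from framework: %s",
               paste(ids[is.na(orient)], collapse = ", "))
  i_min <- apply(raw, 2, min, na.rm = TRUE)
  i_max <- apply(raw, 2, max, na.rm = TRUE)
  rng <- i_max - i_min
  constant <- rng == 0
  if (any(constant)) {
    warning(sprintf("constant indicator(s) across units standardized to 0: %s",
                    paste(ids[constant], collapse = ", ")), call. = FALSE)
    rng[constant] <- 1  # avoid 0/0; numerator is 0 for these columns
  }
  std <- sweep(sweep(raw, 2, i_min, "-"), 2, rng, "/")
  flipped <- orient == "factor_decreasing"
  std[, flipped] <- 1 - std[, flipped, drop = FALSE]
  std[, constant] <- ifelse(is.na(raw[, constant, drop = FALSE]), NA_real_, 0)
  structure(list(values = std, i_min = i_min, i_max = i_max, flipped = flipped),
            class = "standardized_table")
}

#' Profile scores: per-unit means of standardized indicators
#'
#' @param st a `standardized_table`.
#' @param fw an `lvi_framework`.
#' @return a `profile_scores`: list with `values` (units x profiles matrix of
#'   `P_a` in 0-1), `n_p` (framework indicator count per profile) and `n_used`
#'   (units x profiles count actually averaged; missing cells reduce it).
#' @export
profile_scores <- function(st, fw) {
  std <- st$values
  units <- rownames(std)
  pids <- fw$profiles$id
  values <- matrix(NA_real_, length(units), length(pids),
                   dimnames = list(units, pids))
  n_used <- values
  for (p in pids) {
    cols <- fw$indicators$id[fw$indicators$profile_id == p]
    sub <- std[, cols, drop = FALSE]
    n_used[, p] <- rowSums(!is.na(sub))
    values[, p] <- rowMeans(sub, na.rm = TRUE)
  }
  if (any(n_used == 0))
    stop_named("profile(s) with all indicators missing in some unit: %s",
               paste(pids[colSums(n_used == 0) > 0], collapse = ", "))
  structure(list(values = values, n_p = profile_sizes(fw), n_used = n_used),
            class = "profile_scores")
}

#' Composite LVI: indicator-count-weighted mean of profile scores
#'
#' Weighting each profile by the number of indicators it actually contributed
#' makes the composite algebraically identical to the flat mean of all the
#' unit's standardized indicators.
#'
#' @param ps a `profile_scores`.
#' @return named per-unit LVI vector in 0-1.
#' @export
composite_lvi <- function(ps) {
  w <- ps$n_used  # per-unit effective weights; equal n_p when nothing missing
  rowSums(w * ps$values) / rowSums(w)
}

#' IPCC contributing factors from profile scores
#'
#' Within each factor (exposure, sensitivity, adaptive capacity), profile
#' scores are combined with the same indicator-count weights as the composite
#' index. Under the default framework exposure equals the climate profile
#' score, being the factor's only profile.
#'
#' @param ps a `profile_scores`.
#' @param fw an `lvi_framework`.
#' @return a `factor_scores`: list with `values` (units x 3 matrix, columns
#'   `exposure`, `sensitivity`, `adaptive_capacity`) and `n_f` (indicator
#'   totals per factor).
#' @export
contributing_factors <- function(ps, fw) {
  values <- matrix(NA_real_, nrow(ps$values), length(FACTORS),
                   dimnames = list(rownames(ps$values), FACTORS))
  n_f <- stats::setNames(numeric(length(FACTORS)), FACTORS)
  for (f in FACTORS) {
    pids <- fw$profiles$id[fw$profiles$factor == f]
    if (length(pids) == 0) stop_named("factor '%s' has zero profiles", f)
    w <- ps$n_used[, pids, drop = FALSE]
    values[, f] <- rowSums(w * ps$values[, pids, drop = FALSE]) / rowSums(w)
    n_f[f] <- sum(ps$n_p[pids])
  }
  structure(list(values = values, n_f = n_f), class = "factor_scores")
}

#' LVI-IPCC score: (exposure - adaptive capacity) * sensitivity
#'
#' @param fs a `factor_scores` (or a list/data.frame with `exposure`,
#'   `sensitivity`, `adaptive_capacity` vectors).
#' @return named per-unit score in -1..1 when factors are in 0-1.
#' @export
lvi_ipcc <- function(fs) {
  v <- if (inherits(fs, "factor_scores")) fs$values else
    cbind(exposure = fs$exposure, sensitivity = fs$sensitivity,
          adaptive_capacity = fs$adaptive_capacity)
  (v[, "exposure"] - v[, "adaptive_capacity"]) * v[, "sensitivity"]
}

#' Classify LVI-IPCC scores into vulnerability classes
#'
#' Negative scores (adaptive capacity exceeding exposure) are `low`; positive
#' scores are vulnerable, split at `t_high` into `moderate` ("positive but
#' close to zero") and `high`. Intervals are left-closed: a score exactly at a
#' threshold takes the upper class.
#'
#' @param scores named per-unit LVI-IPCC vector.
#' @param thresholds length-2 numeric `(t_low, t_high)`, `t_low < t_high`.
#'   Defaults `(0, 0.45)`.
#' @return named character vector in `{low, moderate, high}`.
#' @export
classify_vulnerability <- function(scores, thresholds = c(0, 0.45)) {
  if (length(thresholds) != 2 || thresholds[1] >= thresholds[2])
    stop_named("thresholds must be (t_low, t_high) with t_low < t_high")
  cls <- ifelse(scores < thresholds[1], "low",
                ifelse(scores < thresholds[2], "moderate", "high"))
  stats::setNames(cls, names(scores))
}

#' Land-area share per vulnerability class
#'
#' The denominator is the sum of all supplied unit areas, so units present in
#' `areas` but absent from `classes` (e.g. an uninhabited summit unit) count
#' toward the total land mass without being classified, and class shares sum
#' to at most 100.
#'
#' @param areas named numeric vector, unit -> area (km^2), all > 0.
#' @param classes named character vector, unit -> class (a subset of
#'   `names(areas)`).
#' @return named numeric vector of unrounded percent shares, one entry per
#'   class present.
#' @export
area_share_by_class <- function(areas, classes) {
  if (length(areas) == 0) stop_named("empty area set")
  if (any(areas <= 0)) stop_named("areas must be > 0")
  missing_units <- setdiff(names(classes), names(areas))
  if (length(missing_units))
    stop_named("classified unit(s) without area: %s",
               paste(missing_units, collapse = ", "))
  total <- sum(areas)
  shares <- tapply(areas[names(classes)], classes, sum) / total * 100
  stats::setNames(as.numeric(shares), names(shares))
}

#' Run the full index chain on an indicator table
#'
#' Convenience wrapper: standardize, profile scores, contributing factors,
#' composite LVI, LVI-IPCC and classes in one call.
#'
#' @param table an `aes_indicator_table` or units x indicators matrix.
#' @param fw an `lvi_framework`.
#' @param thresholds classification thresholds, see
#'   [classify_vulnerability()].
#' @return a `vulnerability_result`: list with `standardized`, `profiles`,
#'   `factors`, and `scores` (data.frame with unit, E, S, A, LVI, LVI_IPCC,
#'   class) plus the threshold set used.
#' @export
compute_lvi <- function(table, fw, thresholds = c(0, 0.45)) {
  st <- standardize(table, fw)
  ps <- profile_scores(st, fw)
  fs <- contributing_factors(ps, fw)
  ipcc <- lvi_ipcc(fs)
  scores <- data.frame(
    unit = rownames(fs$values),
    exposure = fs$values[, "exposure"],
    sensitivity = fs$values[, "sensitivity"],
    adaptive_capacity = fs$values[, "adaptive_capacity"],
    LVI = composite_lvi(ps),
    LVI_IPCC = ipcc,
    class = classify_vulnerability(ipcc, thresholds),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(standardized = st, profiles = ps, factors = fs,
                 scores = scores, thresholds = thresholds),
            class = "vulnerability_result")
}

#' @export
print.vulnerability_result <- function(x, ...) {
  cat("<vulnerability_result>\n")
  print(format_table(x$scores, style = "paper"))
  invisible(x)
}
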