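#' Pooled two-sample z-test for proportions
#'
#' Inter-unit comparison of a survey proportion (e.g. "% perceiving increasing
#' temperature"), using the pooled standard error under the null of equal
#' proportions. The squared statistic equals the 2x2 Pearson chi-square on the
#' implied counts (no continuity correction).
#'
#' @param p1,p2 group proportions, in percent (0-100).
#' @param n1,n2 group sample sizes (>= 1).
#' @return list with `statistic` (z), `p_value` (two-tailed, standard
#'   normal). A degenerate pooled proportion (0 or 100) has zero variance:
#'   equal inputs give p = 1, differing inputs are an error (impossible
#'   counts).
#' @export
two_proportion_test <- function(p1, n1, p2, n2) {
  if (any(c(p1, p2) < 0 | c(p1, p2) > 100)) stop_named("proportions must be in [0, 100]")
  if (any(c(n1, n2) < 1)) stop_named("sample sizes must be >= 1")
  q1 <- p1 / 100; q2 <- p2 / 100
  pool <- (q1 * n1 + q2 * n2) / (n1 + n2)
  if (pool == 0 || pool == 1) {
    if (q1 == q2) return(list(statistic = 0, p_value = 1))
    stop_named("degenerate pooled proportion with differing group proportions")
  }
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- (q1 - q2) / se
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Welch two-sample t-test from summary statistics
#'
#' Mean comparison with unequal variances (Welch-Satterthwaite degrees of
#' freedom), usable when only group means, standard deviations and sizes are
#' published.
#'
#' @param mean1,mean2 group means.
#' @param sd1,sd2 group standard deviations (>= 0).
#' @param n1,n2 group sizes (>= 2).
#' @return list with `statistic` (t), `df`, `p_value` (two-tailed). Both
#'   groups degenerate (sd = 0): p = 1 if means equal, else p = 0.
#' @export
two_sample_mean_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(c(sd1, sd2) < 0)) stop_named("standard deviations must be >= 0")
  if (any(c(n1, n2) < 2)) stop_named("sample sizes must be >= 2")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  if (v1 + v2 == 0) {
    equal <- isTRUE(all.equal(mean1, mean2))
    return(list(statistic = if (equal) 0 else Inf * sign(mean1 - mean2),
                df = n1 + n2 - 2, p_value = if (equal) 1 else 0))
  }
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Pairwise inter-unit significance tests for one survey field
#'
#' Reproduces the "significantly different (95% level) from unit ..." rows of
#' stratified survey reports: every unit pair is tested, categorical fields
#' with the pooled two-proportion z on the target-category share, numeric
#' fields with Welch's t on the raw responses. No multiplicity correction by
#' default; pass `adjust` for Bonferroni/Holm.
#'
#' @param ds a [survey_dataset()].
#' @param field response column to test.
#' @param target_category category defining the proportion (categorical
#'   fields); `NULL` treats the field as numeric.
#' @param alpha significance level for the flags.
#' @param adjust p-value adjustment method (`"none"`, `"holm"`,
#'   `"bonferroni"`; any method of [stats::p.adjust()]).
#' @return a `comparison_matrix`: list with `field`, `pairs` (data.frame:
#'   unit_a, unit_b, statistic, df, p_value, significant) and `different_from`
#'   (per-unit character vector listing the units it differs from at `alpha`,
#'   formatted like the published table rows).
#' @export
pairwise_significance <- function(ds, field, target_category = NULL,
                                  alpha = 0.05, adjust = "none") {
  units <- ds$units
  if (length(units) < 2) stop_named("need >= 2 units")
  x <- ds$records[[field]]
  if (is.null(x)) stop_named("field '%s' not present in survey records", field)
  unit <- factor(ds$records$unit_id, levels = units)
  groups <- split(x, unit)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  empty <- names(groups)[vapply(groups, length, integer(1)) == 0]
  if (length(empty))
    stop_named("unit(s) with no non-missing responses for '%s': %s", field,
               paste(empty, collapse = ", "))
  combs <- utils::combn(units, 2)
  res <- lapply(seq_len(ncol(combs)), function(j) {
    a <- groups[[combs[1, j]]]; b <- groups[[combs[2, j]]]
    if (!is.null(target_category)) {
      tst <- two_proportion_test(100 * mean(a == target_category), length(a),
                                 100 * mean(b == target_category), length(b))
      data.frame(unit_a = combs[1, j], unit_b = combs[2, j],
                 statistic = tst$statistic, df = NA_real_,
                 p_value = tst$p_value)
    } else {
      a <- as.numeric(a); b <- as.numeric(b)
      tst <- two_sample_mean_test(mean(a), stats::sd(a), length(a),
                                  mean(b), stats::sd(b), length(b))
      data.frame(unit_a = combs[1, j], unit_b = combs[2, j],
                 statistic = tst$statistic, df = tst$df, p_value = tst$p_value)
    }
  })
  pairs <- do.call(rbind, res)
  pairs$p_value <- stats::p.adjust(pairs$p_value, method = adjust)
  pairs$significant <- pairs$p_value < alpha
  diff_from <- stats::setNames(vector("list", length(units)), units)
  for (j in seq_len(nrow(pairs))) {
    if (pairs$significant[j]) {
      diff_from[[pairs$unit_a[j]]] <- c(diff_from[[pairs$unit_a[j]]], pairs$unit_b[j])
      diff_from[[pairs$unit_b[j]]] <- c(diff_from[[pairs$unit_b[j]]], pairs$unit_a[j])
    }
  }
  structure(list(field = field, target_category = target_category,
                 alpha = alpha, pairs = pairs,
                 different_from = lapply(diff_from, function(v) sort(unique(v)))),
            class = "comparison_matrix")
}

#' Pairwise tests from published summary rows
#'
#' Summary-statistic entry point for when raw responses are not available:
#' proportions with per-unit n, or means with per-unit sd and n.
#'
#' @param values named per-unit proportions (percent) or means.
#' @param n named per-unit sample sizes.
#' @param sd named per-unit standard deviations; `NULL` means `values` are
#'   proportions.
#' @inheritParams pairwise_significance
#' @return a `comparison_matrix` (see [pairwise_significance()]).
#' @export
pairwise_significance_summary <- function(values, n, sd = NULL, alpha = 0.05,
                                          adjust = "none") {
  units <- names(values)
  if (length(units) < 2) stop_named("need >= 2 units")
  combs <- utils::combn(units, 2)
  res <- lapply(seq_len(ncol(combs)), function(j) {
    a <- combs[1, j]; b <- combs[2, j]
    if (is.null(sd)) {
      tst <- two_proportion_test(values[[a]], n[[a]], values[[b]], n[[b]])
      data.frame(unit_a = a, unit_b = b, statistic = tst$statistic,
                 df = NA_real_, p_value = tst$p_value)
    } else {
      tst <- two_sample_mean_test(values[[a]], sd[[a]], n[[a]],
                                  values[[b]], sd[[b]], n[[b]])
      data.frame(unit_a = a, unit_b = b, statistic = tst$statistic,
                 df = tst$df, p_value = tst$p_value)
    }
  })
  pairs <- do.call(rbind, res)
  pairs$p_value <- stats::p.adjust(pairs$p_value, method = adjust)
  pairs$significant <- pairs$p_value < alpha
  diff_from <- stats::setNames(vector("list", length(units)), units)
  for (j in seq_len(nrow(pairs))) {
    if (pairs$significant[j]) {
      diff_from[[pairs$unit_a[j]]] <- c(diff_from[[pairs$unit_a[j]]], pairs$unit_b[j])
      diff_from[[pairs$unit_b[j]]] <- c(diff_from[[pairs$unit_b[j]]], pairs$unit_a[j])
    }
  }
  structure(list(field = NA_character_, target_category = NA_character_,
                 alpha = alpha, pairs = pairs,
                 different_from = lapply(diff_from, function(v) sort(unique(v)))),
            class = "comparison_matrix")
}

#' Pearson correlation with two-tailed t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r`, `p_value`, `df` (n - 2).
#' @export
correlation <- function(x, y) {
  if (length(x) != length(y)) stop_named("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_named("need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_named("constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(sprintf("<comparison_matrix> field '%s', alpha = %g\n", x$field, x$alpha))
  for (u in names(x$different_from)) {
    d <- x$different_from[[u]]
    cat(sprintf("  %s: significantly different from %s\n", u,
                if (length(d)) paste(d, collapse = ", ") else "none"))
  }
  invisible(x)
}
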