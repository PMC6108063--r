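fw5 <- function() {
  # one increasing exposure indicator for hand checks
  new_framework(
    data.frame(id = c("c", "a"), name = c("c", "a"),
               factor = c("exposure", "adaptive_capacity"), capital = "none"),
    data.frame(id = c("x", "y"), label = "x", profile_id = c("c", "a"),
               unit = "x",
               orientation = c("factor_increasing", "factor_decreasing"),
               aggregator = "precomputed", source_field = NA_character_,
               target_category = NA_character_))
}

test_that("standardize implements min-max with orientation flip", {
  fw <- fw5()
  m <- cbind(x = c(0.78, 0.30, 0.30, 0.60, 0.76),
             y = c(0.2, 0.8, 0.5, 0.5, 0.5))
  rownames(m) <- paste0("u", 1:5)
  st <- standardize(m, fw)
  expect_equal(unname(st$values[, "x"]),
               c(1.0, 0.0, 0.0, 0.625, 0.9583333), tolerance = 1e-6)
  # factor_decreasing flipped after min-max: (0.2, 0.8) -> (1, 0)
  expect_equal(unname(st$values[1:2, "y"]), c(1.0, 0.0))
  # endpoints: min -> 0 (or 1 flipped), max -> 1 (or 0 flipped)
  expect_equal(min(st$values[, "x"]), 0)
  expect_equal(max(st$values[, "x"]), 1)
  expect_true(all(st$values >= 0 & st$values <= 1))
  expect_equal(st$flipped, c(FALSE, TRUE))
})

test_that("constant indicators standardize to 0 with a warning; single unit errors", {
  fw <- fw5()
  m <- cbind(x = c(1, 1, 1), y = c(0, 1, 2))
  rownames(m) <- paste0("u", 1:3)
  expect_warning(st <- standardize(m, fw), "constant")
  expect_equal(unname(st$values[, "x"]), c(0, 0, 0))
  expect_error(standardize(m[1, , drop = FALSE], fw), "2 units")
})

test_that("standardization attains both 0 and 1 for non-constant indicators (property)", {
  for (seed in 1:5) {
    rtf <- random_table_framework(n_units = 6, seed = seed)
    st <- standardize(rtf$values * 10 - 3, rtf$fw)
    expect_true(all(st$values >= 0 & st$values <= 1))
    expect_true(all(abs(apply(st$values, 2, min)) < 1e-12))
    expect_true(all(abs(apply(st$values, 2, max) - 1) < 1e-12))
  }
})

test_that("profile scores are plain means of the profile's standardized indicators", {
  rtf <- random_table_framework(seed = 3)
  st <- standardize(rtf$values, rtf$fw)
  ps <- profile_scores(st, rtf$fw)
  for (p in rtf$fw$profiles$id) {
    cols <- rtf$fw$indicators$id[rtf$fw$indicators$profile_id == p]
    expect_equal(unname(ps$values[, p]),
                 unname(rowMeans(st$values[, cols, drop = FALSE])))
  }
  expect_equal(mean(c(0.2, 0.4, 0.9)), 0.5)  # the hand case the mean reduces to
  expect_true(all(ps$values >= 0 & ps$values <= 1))
})

test_that("composite LVI is the N_p-weighted profile mean and equals the flat indicator mean (oracle)", {
  # hand case: two profiles, N = (3, 5), P = (0.2, 0.6) -> 0.45
  ps <- structure(list(
    values = matrix(c(0.2, 0.6), 1, dimnames = list("u", c("p1", "p2"))),
    n_p = c(p1 = 3L, p2 = 5L),
    n_used = matrix(c(3, 5), 1, dimnames = list("u", c("p1", "p2")))),
    class = "profile_scores")
  expect_equal(unname(composite_lvi(ps)), 0.45)
  # algebraic oracle on random tables: Eq 2-3 chain == flat mean over indicators
  for (seed in 1:20) {
    rtf <- random_table_framework(n_units = 4, n_profiles = 5, seed = seed)
    st <- standardize(rtf$values, rtf$fw)
    ps <- profile_scores(st, rtf$fw)
    expect_equal(unname(composite_lvi(ps)), unname(rowMeans(st$values)),
                 tolerance = 1e-12)
  }
})

test_that("contributing factors weight profiles by indicator count within each factor (oracle)", {
  # hand case: sensitivity from N=5 @ 0.4 and N=3 @ 0.8 -> 0.55
  expect_equal((5 * 0.4 + 3 * 0.8) / 8, 0.55)
  for (seed in 1:20) {
    rtf <- random_table_framework(n_units = 4, n_profiles = 6, seed = seed)
    st <- standardize(rtf$values, rtf$fw)
    ps <- profile_scores(st, rtf$fw)
    fs <- contributing_factors(ps, rtf$fw)
    for (f in c("exposure", "sensitivity", "adaptive_capacity")) {
      pids <- rtf$fw$profiles$id[rtf$fw$profiles$factor == f]
      cols <- rtf$fw$indicators$id[rtf$fw$indicators$profile_id %in% pids]
      # brute-force flat mean over the factor's standardized indicators
      expect_equal(unname(fs$values[, f]),
                   unname(rowMeans(st$values[, cols, drop = FALSE])),
                   tolerance = 1e-12)
    }
    expect_true(all(fs$values >= 0 & fs$values <= 1))
  }
})

test_that("exposure equals the climate profile score under the default framework", {
  fw <- load_framework()
  ds <- generate_survey(default_choke_spec(), seed = 11)
  tab <- build_indicator_table(
    ds, fw, system.file("extdata", "precomputed_choke_synthetic.csv",
                        package = "lviaes"))
  st <- standardize(tab, fw)
  ps <- profile_scores(st, fw)
  fs <- contributing_factors(ps, fw)
  expect_equal(unname(fs$values[, "exposure"]), unname(ps$values[, "climate"]))
})

test_that("lvi_ipcc is (E - A) * S with its symmetry and range", {
  expect_equal(unname(lvi_ipcc(list(exposure = 0.5, sensitivity = 0.9,
                                    adaptive_capacity = 0.5))), 0)
  expect_equal(unname(lvi_ipcc(list(exposure = 0.78, sensitivity = 0.30,
                                    adaptive_capacity = 0.21))), 0.171)
  expect_equal(unname(lvi_ipcc(list(exposure = 0.30, sensitivity = 1.26,
                                    adaptive_capacity = 0.73))), -0.5418)
  set.seed(1)
  e <- runif(100); s <- runif(100); a <- runif(100)
  v <- lvi_ipcc(list(exposure = e, sensitivity = s, adaptive_capacity = a))
  expect_true(all(v >= -1 & v <= 1))
})

test_that("classification is left-closed on the published-score pattern", {
  scores <- c(AES1 = 0.72, AES2 = -0.62, AES3 = -0.72, AES4 = 0.18,
              AES5 = 0.71)
  expect_equal(unname(classify_vulnerability(scores)),
               c("high", "low", "low", "moderate", "high"))
  expect_equal(unname(classify_vulnerability(c(x = 0))), "moderate")
  expect_equal(unname(classify_vulnerability(c(x = 0.45))), "high")
  expect_equal(unname(classify_vulnerability(c(a = -1, b = -0.001))),
               c("low", "low"))
  expect_error(classify_vulnerability(scores, thresholds = c(1, 0)), "t_low")
})

test_that("area shares use all supplied areas as denominator", {
  areas <- c(AES1 = 7200, AES2 = 3200, AES3 = 1600, AES4 = 1300,
             AES5 = 2400, AES6 = 250)
  classes <- c(AES1 = "high", AES2 = "low", AES3 = "low", AES4 = "moderate",
               AES5 = "high")
  sh <- area_share_by_class(areas, classes)
  expect_equal(unname(sh["low"]), 100 * 4800 / 15950, tolerance = 1e-12)
  expect_equal(unname(sh["moderate"]), 100 * 1300 / 15950, tolerance = 1e-12)
  expect_true(sum(sh) < 100)  # AES6 unclassified but in the denominator
  expect_equal(unname(area_share_by_class(c(u = 5), c(u = "low"))), 100)
  expect_error(area_share_by_class(numeric(0), classes), "empty")
  expect_error(area_share_by_class(c(u = -1), c(u = "low")), "> 0")
})

test_that("monotonicity: raising an exposure indicator never lowers LVI-IPCC, raising adaptive capacity never raises it", {
  fw <- load_framework()
  ds <- generate_survey(default_choke_spec(), seed = 5)
  tab <- build_indicator_table(
    ds, fw, system.file("extdata", "precomputed_choke_synthetic.csv",
                        package = "lviaes"))
  base <- compute_lvi(tab, fw)$scores
  bump <- function(ind_id, unit, delta) {
    t2 <- tab
    # keep bounds fixed by staying inside the column range
    rng <- range(t2$values[, ind_id])
    t2$values[unit, ind_id] <- min(max(t2$values[unit, ind_id] + delta,
                                       rng[1]), rng[2])
    compute_lvi(t2, fw)$scores
  }
  # temp_change is factor_increasing on exposure; pick a unit strictly inside
  # the column range so the perturbation is real
  mid <- names(sort(tab$values[, "temp_change"]))[3]
  up <- bump("temp_change", mid, 2)
  expect_gte(up$LVI_IPCC[up$unit == mid], base$LVI_IPCC[base$unit == mid])
  # savings is factor_increasing on adaptive capacity
  mid2 <- names(sort(tab$values[, "savings"]))[3]
  up2 <- bump("savings", mid2, 200)
  expect_lte(up2$LVI_IPCC[up2$unit == mid2], base$LVI_IPCC[base$unit == mid2])
})

test_that("permuting unit order permutes outputs identically", {
  rtf <- random_table_framework(n_units = 5, seed = 9)
  fw <- rtf$fw
  perm <- c(3, 1, 5, 2, 4)
  r1 <- compute_lvi(rtf$values, fw)$scores
  r2 <- compute_lvi(rtf$values[perm, ], fw)$scores
  r2 <- r2[match(r1$unit, r2$unit), ]
  rownames(r2) <- NULL
  expect_equal(r2, r1)
})

test_that("missing cells reduce the profile N and the composite weights", {
  rtf <- random_table_framework(n_units = 4, n_profiles = 3, seed = 2)
  vals <- rtf$values
  # knock out one indicator cell in a multi-indicator profile
  sizes <- table(rtf$fw$indicators$profile_id)
  bigp <- names(sizes)[sizes >= 2][1]
  expect_false(is.na(bigp))  # seed fixed: a multi-indicator profile exists
  col <- rtf$fw$indicators$id[rtf$fw$indicators$profile_id == bigp][1]
  vals[2, col] <- NA
  st <- standardize(vals, rtf$fw)
  ps <- profile_scores(st, rtf$fw)
  expect_equal(unname(ps$n_used[2, bigp]), sum(sizes[bigp]) - 1)
  # composite equals flat mean over the unit's non-missing indicators
  expect_equal(unname(composite_lvi(ps))[2],
               mean(st$values[2, ], na.rm = TRUE), tolerance = 1e-12)
})
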