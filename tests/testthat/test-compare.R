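test_that("two_proportion_test matches the pooled z hand derivation and the chi-square identity (oracle)", {
  tst <- two_proportion_test(95.2, 87, 78.3, 183)
  expect_equal(tst$statistic, 3.518, tolerance = 1e-3)
  expect_lt(tst$p_value, 0.05)
  # z^2 equals the 2x2 Pearson chi-square without continuity correction
  set.seed(10)
  for (rep in 1:20) {
    n1 <- sample(20:300, 1); n2 <- sample(20:300, 1)
    x1 <- rbinom(1, n1, runif(1, 0.1, 0.9)); x2 <- rbinom(1, n2, runif(1, 0.1, 0.9))
    z <- two_proportion_test(100 * x1 / n1, n1, 100 * x2 / n2, n2)
    pt <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                                            correct = FALSE))
    expect_equal(z$statistic^2, unname(pt$statistic), tolerance = 1e-10)
    expect_equal(z$p_value, pt$p.value, tolerance = 1e-10)
  }
  # symmetry up to sign
  a <- two_proportion_test(40, 50, 60, 80)
  b <- two_proportion_test(60, 80, 40, 50)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  # degenerate cases
  expect_equal(two_proportion_test(50, 10, 50, 10)$statistic, 0)
  expect_equal(two_proportion_test(0, 10, 0, 20)$p_value, 1)
  expect_equal(two_proportion_test(100, 10, 100, 5)$p_value, 1)
  # a 0%-vs-nonzero comparison pools to a non-degenerate proportion
  expect_lt(two_proportion_test(0, 10, 50, 10)$statistic, 0)
  expect_error(two_proportion_test(120, 10, 50, 10), "0, 100")
})

test_that("two_sample_mean_test is Welch's t, agreeing with t.test on raw samples (oracle)", {
  set.seed(4)
  for (rep in 1:20) {
    a <- rnorm(sample(5:40, 1), runif(1, -2, 2), runif(1, 0.5, 2))
    b <- rnorm(sample(5:40, 1), runif(1, -2, 2), runif(1, 0.5, 2))
    ours <- two_sample_mean_test(mean(a), sd(a), length(a),
                                 mean(b), sd(b), length(b))
    ref <- stats::t.test(a, b)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  # frozen hand case (correct Welch arithmetic for the published-style inputs)
  t <- two_sample_mean_test(2.16, 1, 284, 1.26, 1, 87)
  expect_equal(t$statistic, 0.9 / sqrt(1 / 284 + 1 / 87), tolerance = 1e-12)
  expect_equal(t$statistic, 7.344, tolerance = 1e-3)
  # identical groups; equal n and sd reduce df to 2n - 2
  expect_equal(two_sample_mean_test(1, 1, 10, 1, 1, 10)$p_value, 1)
  expect_equal(two_sample_mean_test(1, 2, 15, 3, 2, 15)$df, 28)
  expect_equal(two_sample_mean_test(1, 0, 5, 1, 0, 5)$p_value, 1)
  expect_equal(two_sample_mean_test(2, 0, 5, 1, 0, 5)$p_value, 0)
})

test_that("pairwise_significance builds symmetric 'different from' sets", {
  rec <- data.frame(
    household_id = as.character(1:300),
    unit_id = rep(c("a", "b", "c"), each = 100),
    f = c(rep(c("yes", "no"), c(90, 10)),   # a: 90%
          rep(c("yes", "no"), c(50, 50)),   # b: 50%
          rep(c("yes", "no"), c(88, 12))),  # c: 88%
    v = c(rnorm(100, 0), rnorm(100, 3), rnorm(100, 0.1)))
  ds <- survey_dataset(rec)
  cm <- pairwise_significance(ds, "f", "yes")
  expect_equal(cm$different_from$a, "b")
  expect_equal(cm$different_from$b, c("a", "c"))
  expect_equal(cm$different_from$c, "b")
  expect_equal(nrow(cm$pairs), 3)
  expect_true(all(cm$pairs$p_value >= 0 & cm$pairs$p_value <= 1))
  # numeric field via Welch
  cmn <- pairwise_significance(ds, "v")
  expect_equal(cmn$different_from$b, c("a", "c"))
  # identical units -> empty sets
  rec2 <- rec; rec2$f <- rep(rep(c("yes", "no"), 50), 3)
  cm2 <- pairwise_significance(survey_dataset(rec2), "f", "yes")
  expect_equal(unname(lengths(cm2$different_from)), c(0L, 0L, 0L))
  # Bonferroni can only lose significance
  cmb <- pairwise_significance(ds, "f", "yes", adjust = "bonferroni")
  expect_true(all(cmb$pairs$p_value >= cm$pairs$p_value))
  expect_error(pairwise_significance(ds, "missing_field", "yes"), "missing_field")
})

test_that("per-pair type-I error of pairwise proportion tests is ~ alpha under the null", {
  # identical true proportions in all units; fraction of significant pairs
  # over replicates should be near alpha (per-pair, not family-wise)
  set.seed(2026)
  n <- 200; reps <- 200; units <- 3
  sig <- 0
  for (r in seq_len(reps)) {
    rec <- data.frame(household_id = as.character(seq_len(n * units)),
                      unit_id = rep(paste0("u", 1:units), each = n),
                      f = sample(c("yes", "no"), n * units, TRUE, c(0.4, 0.6)))
    cm <- pairwise_significance(survey_dataset(rec), "f", "yes")
    sig <- sig + sum(cm$pairs$significant)
  }
  rate <- sig / (reps * 3)
  se <- sqrt(0.05 * 0.95 / (reps * 3))
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("published temperature row pattern: unit 1 differs from 2, 4, 5 but not 3", {
  vals <- c(AES1 = 95.2, AES2 = 78.3, AES3 = 94.6, AES4 = 79.6, AES5 = 80.2)
  n <- c(AES1 = 87, AES2 = 183, AES3 = 148, AES4 = 284, AES5 = 91)
  cm <- pairwise_significance_summary(vals, n)
  expect_equal(cm$different_from$AES1, c("AES2", "AES4", "AES5"))
})

test_that("correlation is Pearson r with a t-based two-tailed p", {
  expect_equal(correlation(1:10, 1:10)$r, 1)
  expect_equal(correlation(1:10, -(1:10))$r, -1)
  expect_equal(correlation(c(1, 2, 3), c(2, 1, 3))$r, 0.5)
  set.seed(8)
  x <- rnorm(50); y <- 0.3 * x + rnorm(50)
  ours <- correlation(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(ours$r, unname(ref$estimate))
  expect_equal(ours$p_value, ref$p.value)
  expect_equal(ours$df, 48)
  expect_error(correlation(rep(1, 5), rnorm(5)), "constant")
  expect_error(correlation(1:2, 1:2), ">= 3")
})
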