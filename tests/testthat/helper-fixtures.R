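# Small builders shared across test files. All fixtures are constructed in
# code; nothing is read from disk except the packaged default config.

toy_framework <- function() {
  profiles <- data.frame(
    id = c("climate", "eco", "wealth"),
    name = c("climate", "eco", "wealth"),
    factor = c("exposure", "sensitivity", "adaptive_capacity"),
    capital = c("none", "natural", "financial"))
  indicators <- data.frame(
    id = c("heat", "rain", "forest", "land", "cash"),
    label = c("heat", "rain", "forest", "land", "cash"),
    profile_id = c("climate", "climate", "eco", "wealth", "wealth"),
    unit = "x",
    orientation = c("factor_increasing", "factor_increasing",
                    "factor_decreasing", "factor_increasing",
                    "factor_increasing"),
    aggregator = c("proportion", "proportion", "precomputed", "mean", "mean"),
    source_field = c("hot", "wet", NA, "ha", "birr"),
    target_category = c("yes", "yes", NA, NA, NA))
  new_framework(profiles, indicators, metadata = "toy")
}

toy_survey <- function() {
  records <- data.frame(
    household_id = sprintf("h%02d", 1:6),
    unit_id = c("u1", "u1", "u1", "u2", "u2", "u2"),
    hot = c("yes", "yes", "no", "no", "no", "yes"),
    wet = c("yes", NA, "no", "yes", "yes", "yes"),
    ha = c(1.0, 1.2, 1.4, 2.0, 2.2, 2.4),
    birr = c(10, 20, 30, 40, 50, 60),
    livestock.cattle = c(2, 0, 1, 3, 0, 1),
    livestock.sheep = c(2, 0, 0, 5, 1, 0))
  survey_dataset(records)
}

# random units x indicators matrix plus a matching one-profile-per-factor-ish
# framework, for property tests
random_table_framework <- function(n_units = 5, n_profiles = 4, seed = 1) {
  set.seed(seed)
  sizes <- sample(1:4, n_profiles, replace = TRUE)
  pid <- paste0("p", seq_len(n_profiles))
  profiles <- data.frame(
    id = pid, name = pid,
    factor = c("exposure", "sensitivity", "adaptive_capacity",
               sample(c("exposure", "sensitivity", "adaptive_capacity"),
                      max(0, n_profiles - 3), replace = TRUE)),
    capital = "none")
  ind <- data.frame(
    id = paste0("i", seq_len(sum(sizes))),
    label = "x",
    profile_id = rep(pid, sizes),
    unit = "x",
    orientation = sample(c("factor_increasing", "factor_decreasing"),
                         sum(sizes), replace = TRUE),
    aggregator = "precomputed",
    source_field = NA_character_, target_category = NA_character_)
  fw <- new_framework(profiles, ind)
  values <- matrix(runif(n_units * sum(sizes)), n_units,
                   dimnames = list(paste0("u", seq_len(n_units)), ind$id))
  list(fw = fw, values = values)
}
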