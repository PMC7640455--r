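# Shared fixtures built in code at test time.

# Small codebook with mixed category counts, used by property-style tests.
tiny_codebook <- function() {
  codebook(list(
    area = c("urban", "rural"),
    educ = c("none", "primary", "secondary"),
    wealth = c("q1", "q2", "q3", "q4")
  ))
}

# Random household table over tiny_codebook(); unit or gamma weights.
random_table <- function(n = 200, seed = 1, gamma_weights = FALSE) {
  set.seed(seed)
  df <- data.frame(
    id = as.character(seq_len(n)),
    weight = if (gamma_weights) rgamma(n, 4, 4) else rep(1, n),
    area = sample(0:1, n, replace = TRUE),
    educ = sample(0:2, n, replace = TRUE),
    wealth = sample(0:3, n, replace = TRUE),
    diet_class = rbinom(n, 1, 0.6),
    stunting = rbinom(n, 1, 0.25),
    child_age_months = sample(6:25, n, replace = TRUE),
    interview_day = sample(1:150, n, replace = TRUE),
    stringsAsFactors = FALSE)
  df$adequate <- 1L - df$diet_class
  household_table(df, tiny_codebook())
}

# Randomized-treatment design with a constant planted effect tau on the
# stunting probability; outcome risk varies with wealth so matching has
# something to balance.
randomized_config <- function(n, seed, tau) {
  synthetic_config(
    n = n, seed = seed,
    covariates = list(
      wealth = list(labels = paste0("q", 1:5), p = rep(0.2, 5)),
      area = list(labels = c("urban", "rural"), p = c(0.4, 0.6))),
    treatment = list(intercept = 0.25,
                     coef = list(wealth = rep(0, 5), area = c(0, 0))),
    outcome = list(baseline = 0.15,
                   coef = list(wealth = c(0.05, 0.02, 0, -0.03, -0.05)),
                   effects = if (tau != 0)
                     list(list(profile = profile(character(0), integer(0)),
                               tau = tau))
                   else list()))
}

# Mildly confounded design with a planted effect map over the 8 categories
# of a "region" covariate; taus named by region code.
region_config <- function(n, seed, taus,
                          treat_coef = c(0, 0.15, -0.1, 0.1, -0.15, 0, 0.05,
                                         -0.05)) {
  effects <- lapply(seq_along(taus), function(i) {
    list(profile = profile("region", i - 1L), tau = taus[i])
  })
  effects <- effects[taus != 0]
  synthetic_config(
    n = n, seed = seed,
    covariates = list(
      region = list(labels = paste0("r", 1:8), p = rep(0.125, 8)),
      wealth = list(labels = paste0("q", 1:3), p = rep(1 / 3, 3))),
    treatment = list(intercept = 0.3,
                     coef = list(region = treat_coef,
                                 wealth = c(0.15, 0, -0.15))),
    outcome = list(baseline = 0.18,
                   coef = list(wealth = c(0.02, 0, -0.02)),
                   effects = effects))
}

expect_quiet_equal <- function(object, expected, tol = 1e-12) {
  expect_equal(object, expected, tolerance = tol)
}

toy_expectations <- function() {
  jsonlite::read_json(system.file("extdata", "toy_expected.json",
                                  package = "pollmatch"),
                      simplifyVector = TRUE)
}
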