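#' Configuration for the synthetic household-survey generator
#'
#' Describes a DHS-like cross-section with a known treatment-assignment
#' model and a known outcome model, so every stage of the pipeline can be
#' validated against planted truth.  The default configuration mimics the
#' scale of the motivating survey: roughly 1600 households with children
#' aged 6--25 months, a treated (inadequate diet diversity) share around
#' 0.7, a stunting base rate around 0.2, ten integer-coded covariates with
#' education, wealth and urban gradients lowering the probability of
#' inadequate diversity.  These defaults are approximations of the study
#' conditions, not fitting targets.
#'
#' @param n Number of households (default 1613).
#' @param seed Random seed (default 20151104).
#' @param covariates Named list: per variable, `labels` (category labels)
#'   and `p` (marginal probabilities summing to 1).  Defaults to the ten
#'   study covariates.
#' @param treatment List with `intercept` and `coef` (named list of
#'   per-category probit coefficients, one numeric vector per covariate;
#'   omitted variables contribute 0).  Treatment is
#'   \eqn{1\{\beta_0 + \sum_r \beta_{r,c_r} + \mathrm{trend} + \epsilon > 0\}}
#'   with standard normal \eqn{\epsilon}.
#' @param outcome List with `baseline` (stunting probability), `coef`
#'   (optional named list of additive per-category risk shifts) and
#'   `effects` (list of `list(profile =, tau =)` entries planting a
#'   treatment effect `tau` on the probability scale inside each profile;
#'   overlapping profiles add).
#' @param interview List with `days` (fieldwork length, default 150) and
#'   `trend` (latent-scale linear day coefficient applied over the
#'   fieldwork window, default 0).
#' @param weights List with `type` (`"unit"` or `"gamma"`) and `shape`
#'   (gamma shape, mean fixed at 1).
#' @param age_range Two integers, inclusive age window in months for the
#'   two age bands (default `c(6, 25)` split at 12 months).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 1613L, seed = 20151104L,
                             covariates = NULL, treatment = NULL,
                             outcome = NULL, interview = NULL,
                             weights = NULL, age_range = c(6L, 25L)) {
  if (is.null(covariates)) covariates <- default_covariate_spec()
  for (v in names(covariates)) {
    sp <- covariates[[v]]
    if (abs(sum(sp$p) - 1) > 1e-8)
      stop("marginal probabilities of '", v, "' must sum to 1")
    if (length(sp$p) != length(sp$labels))
      stop("labels/p length mismatch for '", v, "'")
  }
  if (is.null(treatment)) treatment <- default_treatment_spec()
  if (is.null(outcome))
    outcome <- list(baseline = 0.20, coef = default_outcome_coef(),
                    effects = list())
  if (is.null(outcome$effects)) outcome$effects <- list()
  if (is.null(interview)) interview <- list(days = 150L, trend = 0)
  if (is.null(weights)) weights <- list(type = "unit", shape = 4)
  if (n <= 0) stop("n must be positive")
  for (ef in outcome$effects) {
    p <- ef$profile
    if (!inherits(p, "profile")) stop("each effect needs a profile")
    for (i in seq_along(p$variables)) {
      v <- p$variables[i]
      if (is.null(covariates[[v]]) ||
          !(p$values[i] %in% (seq_along(covariates[[v]]$labels) - 1L)))
        stop("effect profile invalid under covariate spec: ", profile_key(p))
    }
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 covariates = covariates, treatment = treatment,
                 outcome = outcome, interview = interview,
                 weights = weights, age_range = as.integer(age_range)),
            class = "synthetic_config")
}

default_covariate_spec <- function() {
  list(
    age_band = list(labels = c("6-12m", "13-25m"), p = c(0.37, 0.63)),
    sibling = list(labels = c("no", "yes"), p = c(0.55, 0.45)),
    mother_working = list(labels = c("no", "yes"), p = c(0.60, 0.40)),
    mother_education = list(labels = c("none", "primary", "secondary",
                                       "tertiary"),
                            p = c(0.08, 0.50, 0.38, 0.04)),
    wealth = list(labels = c("q1", "q2", "q3", "q4", "q5"),
                  p = rep(0.2, 5)),
    area = list(labels = c("urban", "rural"), p = c(0.30, 0.70)),
    land_use = list(labels = c("cultivated_gt50", "forest_barren",
                               "grass_wood", "built_up", "associations"),
                    p = c(0.25, 0.20, 0.30, 0.10, 0.15)),
    growing_period = list(labels = c("0-75d", "76-120d", "121-180d",
                                     "gt180d"),
                          p = c(0.15, 0.30, 0.40, 0.15)),
    farming_system = list(labels = c("highland_temperate", "root_cereal",
                                     "maize_mixed", "commercial_pastoral",
                                     "agropastoral"),
                          p = c(0.10, 0.15, 0.45, 0.15, 0.15)),
    slope = list(labels = c("0-8deg", "8-30deg", "gt30deg"),
                 p = c(0.50, 0.35, 0.15))
  )
}

default_treatment_spec <- function() {
  list(intercept = 2.05,
       coef = list(
         age_band = c(0.35, 0),
         sibling = c(0, 0.15),
         mother_working = c(0, -0.25),
         mother_education = c(0, -0.70, -0.75, -0.95),
         wealth = c(0, -0.17, -0.29, -0.50, -0.47),
         area = c(-0.32, 0),
         land_use = c(0, -0.75, -0.60, -0.72, -0.75),
         growing_period = c(0, -0.09, -0.12, 0.06),
         farming_system = c(0, 0.40, 0.03, 0.63, 0.15),
         slope = c(0, -0.06, -0.23)))
}

default_outcome_coef <- function() {
  list(wealth = c(0.05, 0.02, 0, -0.03, -0.05),
       mother_education = c(0.06, 0.02, -0.02, -0.05),
       age_band = c(-0.02, 0.02))
}

#' Generate a synthetic household table
#'
#' Covariates are drawn independently from their marginals; treatment
#' (inadequate diet diversity) follows the probit assignment model;
#' stunting is Bernoulli with probability `baseline` plus any covariate
#' risk shifts plus the planted effect \eqn{\tau_x} for treated members of
#' each effect profile (probabilities clipped to `[0, 1]` with a logged
#' clip count; more than 5% clipped is an error).  Food-item recall flags
#' are generated consistently with the assigned diet class, so rescoring
#' the table through the CDDS builder reproduces `diet_class` exactly.
#' Fully reproducible given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A [household_table] with covariates, item flags, `cdds`,
#'   `adequate`, `diet_class`, `stunting`, `child_age_months`,
#'   `interview_day` and `weight` columns.
#' @export
generate_households <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n
  cov <- config$covariates

  df <- data.frame(id = sprintf("hh%06d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (v in names(cov))
    df[[v]] <- sample.int(length(cov[[v]]$p), n, replace = TRUE,
                          prob = cov[[v]]$p) - 1L

  # child age consistent with the age band (split at 12 months)
  lo <- config$age_range[1L]; hi <- config$age_range[2L]
  split <- min(12L, hi)
  df$child_age_months <- if (is.null(df$age_band)) {
    sample(lo:hi, n, replace = TRUE)
  } else {
    ifelse(df$age_band == 0L, sample(lo:split, n, replace = TRUE),
           sample((split + 1L):hi, n, replace = TRUE))
  }
  df$interview_day <- sample.int(config$interview$days, n, replace = TRUE)

  df$weight <- switch(config$weights$type,
                      unit = rep(1, n),
                      gamma = stats::rgamma(n, shape = config$weights$shape,
                                            rate = config$weights$shape),
                      stop("unknown weight type: ", config$weights$type))

  # probit treatment assignment
  latent <- rep(config$treatment$intercept, n)
  for (v in names(config$treatment$coef)) {
    b <- config$treatment$coef[[v]]
    if (length(b) != length(cov[[v]]$labels))
      stop("treatment coefficient length mismatch for '", v, "'")
    latent <- latent + b[df[[v]] + 1L]
  }
  if (config$interview$trend != 0)
    latent <- latent + config$interview$trend *
      (df$interview_day / config$interview$days - 0.5)
  df$diet_class <- as.integer(latent + stats::rnorm(n) > 0)
  df$adequate <- 1L - df$diet_class

  # stunting outcome: baseline + covariate shifts + planted tau for treated
  pr <- rep(config$outcome$baseline, n)
  for (v in names(config$outcome$coef))
    pr <- pr + config$outcome$coef[[v]][df[[v]] + 1L]
  for (ef in config$outcome$effects) {
    m <- rep(TRUE, n)
    for (i in seq_along(ef$profile$variables))
      m <- m & df[[ef$profile$variables[i]]] == ef$profile$values[i]
    pr <- pr + ef$tau * m * df$diet_class
  }
  clipped <- pr < 0 | pr > 1
  if (mean(clipped) > 0.05)
    stop(sprintf(
      "outcome model pushes %.1f%% of probabilities outside [0, 1]; re-specify",
      100 * mean(clipped)))
  if (any(clipped)) {
    message(sum(clipped), " outcome probabilities clipped to [0, 1]")
    pr <- pmin(pmax(pr, 0), 1)
  }
  df$stunting <- as.integer(stats::runif(n) < pr)

  df <- cbind(df, synth_item_flags(df$diet_class))
  df$cdds <- NULL  # recomputed below through the scoring path

  cb_spec <- lapply(cov, function(sp) list(labels = sp$labels,
                                           role = "covariate"))
  for (it in names(cdds_mapping()))
    cb_spec[[it]] <- list(labels = c("no", "yes"), role = "item-flag")
  tab <- household_table(df, codebook(cb_spec))
  score_cdds(tab)
}

# Item flags realizing a random CDDS consistent with the diet class:
# inadequate -> 0..3 groups, adequate -> 4..7 groups; one representative
# item per selected group.
synth_item_flags <- function(diet_class) {
  map <- cdds_mapping()
  items <- names(map)
  rep_item <- vapply(1:7, function(g) items[which(unclass(map) == g)[1L]],
                     character(1))
  n <- length(diet_class)
  target <- ifelse(diet_class == 1L,
                   sample(0:3, n, replace = TRUE,
                          prob = c(0.15, 0.35, 0.30, 0.20)),
                   sample(4:7, n, replace = TRUE,
                          prob = c(0.50, 0.30, 0.15, 0.05)))
  flags <- matrix(0L, n, length(items), dimnames = list(NULL, items))
  for (i in seq_len(n)) {
    if (target[i] > 0L) {
      g <- sample.int(7L, target[i])
      flags[i, rep_item[g]] <- 1L
    }
  }
  as.data.frame(flags)
}

#' Deterministic 12-record toy table with hand-computable metrics
#'
#' A fixed table of 12 households over two binary covariates (`area`,
#' `educ`) with varied weights, built entirely in code with no randomness.
#' Its polling and impact metrics were worked out by hand (exact
#' fractions) and shipped in `inst/extdata/toy_expected.json`; the unit
#' and acceptance suites compare the package's computations against them.
#' All records share the propensity score 0.5, so the kernel
#' counterfactual reduces to the mass-weighted comparison mean.
#'
#' @return A [household_table] of 12 records, total mass 14.
#' @export
toy_fixture <- function() {
  df <- data.frame(
    id = as.character(1:12),
    weight = c(1, 2, 1, 1, 1, 2, 1, 1, 1, 1, 1, 1),
    area   = c(1L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L, 1L, 0L),
    educ   = c(0L, 0L, 1L, 0L, 1L, 0L, 0L, 1L, 1L, 0L, 1L, 1L),
    diet_class = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L, 1L, 0L),
    stunting   = c(1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L),
    child_age_months = c(6L, 8L, 10L, 12L, 14L, 16L, 18L, 20L, 22L, 24L,
                         7L, 9L),
    interview_day = 1:12,
    stringsAsFactors = FALSE)
  df$adequate <- 1L - df$diet_class
  cb <- codebook(list(
    area = list(labels = c("urban", "rural"), role = "covariate"),
    educ = list(labels = c("none", "primary"), role = "covariate")))
  household_table(df, cb)
}
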