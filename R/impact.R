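#' ATT within a single profile, reusing globally fitted scores
#'
#' Restricts both the treated and the comparison group to the members of a
#' profile, re-checks common support within the profile, and computes the
#' Epanechnikov kernel ATT using the propensity scores fitted once on the
#' full sample (the scores are never re-estimated per subgroup).
#'
#' @param p A [profile].
#' @param table A [household_table].
#' @param scores Full-sample propensity scores (a numeric vector or a
#'   `propensity_model`).
#' @param outcome Outcome column name (default `"stunting"`).
#' @param bandwidth Kernel bandwidth (default 0.06).
#' @return An `att_estimate`, or `NULL` (with attribute-free invisibility)
#'   when the profile has no treated or no comparison members — such
#'   profiles are inestimable and excluded from ranking.
#' @export
profile_att <- function(p, table, scores, outcome = "stunting",
                        bandwidth = 0.06) {
  stopifnot(inherits(p, "profile"), inherits(table, "household_table"))
  if (inherits(scores, "propensity_model")) scores <- scores$scores
  inside <- profile_members(p, table)
  if (!any(inside)) return(NULL)
  sub <- table[inside, , drop = FALSE]
  sub <- structure(sub, codebook = attr(table, "codebook"),
                   class = c("household_table", "data.frame"))
  s <- scores[inside]
  if (!any(sub$diet_class == 1L) || !any(sub$diet_class == 0L)) return(NULL)
  sup <- tryCatch(common_support(s, sub$diet_class), error = function(e) NULL)
  if (is.null(sup)) return(NULL)
  tryCatch(kernel_att(sub, s, support = sup, outcome = outcome,
                      bandwidth = bandwidth),
           error = function(e) NULL)
}

#' Impact of fixing diet diversity within a profile
#'
#' The expected population-level gain from treating profile `x`:
#' \deqn{\mathrm{impact}(x) = ATT(x) \times
#'   \Pr[\mathrm{treated} \mid x] \times \Pr[x].}
#' Scaling the ATT by the treated share alone gives the profile's average
#' treatment effect, \eqn{ATE(x) = ATT(x)\,\Pr[\mathrm{treated} \mid x]}.
#'
#' @param att Profile ATT.
#' @param pr_treated_given_x Treated (inadequate-diversity) mass share
#'   within the profile, in `[0, 1]`.
#' @param pr_x Profile mass share of the population, in `[0, 1]`.
#' @return A list with `impact` and `ate_x`.
#' @export
impact <- function(att, pr_treated_given_x, pr_x) {
  if (any(pr_treated_given_x < 0 | pr_treated_given_x > 1) ||
      any(pr_x < 0 | pr_x > 1))
    stop("probabilities must lie in [0, 1]")
  list(impact = att * pr_treated_given_x * pr_x,
       ate_x = att * pr_treated_given_x)
}

#' Per-profile impact metrics over an exhaustive profile universe
#'
#' Enumerates every value profile of every size-`k` subset of `variables`,
#' computes each profile's mass shares and — where estimable — its kernel
#' ATT (treated and comparison restricted to the profile, global scores
#' reused), and assembles the impact metrics: \eqn{\Pr[x]},
#' \eqn{\Pr[\mathrm{treated}\mid x]}, \eqn{ATE(x)}, and the impact.
#' Inclusion error \eqn{\mu_{impact} = 1 - \Pr[\mathrm{treated}\mid x]} is
#' attached immediately; impact coverage and the exclusion error require a
#' universe-level denominator and are added by [impact_coverage()].
#'
#' @inheritParams polling_analysis
#' @param scores Full-sample propensity scores (vector or
#'   `propensity_model`).
#' @param outcome Outcome column (default `"stunting"`).
#' @param bandwidth Kernel bandwidth (default 0.06).
#' @param min_treated Minimum treated members a profile needs before its
#'   ATT is computed (default 1; raising it skips hopeless tiny profiles
#'   and speeds up large universes).
#' @return A data.frame with one row per profile: `profile_key`,
#'   `subset_id`, `n_members`, `n_treated`, `n_comparison`, `pr_x`,
#'   `pr_treated_given_x`, `mu_impact`, `att`, `se`, `t`,
#'   `n_treated_matched`, `ate_x`, `impact`, `estimable`.
#' @export
impact_analysis <- function(table, variables, k, scores,
                            outcome = "stunting", bandwidth = 0.06,
                            min_treated = 1L, group = 1L) {
  stopifnot(inherits(table, "household_table"))
  if (inherits(scores, "propensity_model")) scores <- scores$scores
  base <- polling_analysis(table, variables, k, group = group)
  tm <- total_mass(table)
  out <- data.frame(
    profile_key = base$profile_key, subset_id = base$subset_id,
    n_members = base$n_members, n_treated = base$n_group_members,
    n_comparison = base$n_members - base$n_group_members,
    pr_x = base$profile_mass / tm,
    pr_treated_given_x = ifelse(base$profile_mass > 0,
                                base$mass / base$profile_mass, NA_real_),
    stringsAsFactors = FALSE)
  out$mu_impact <- 1 - out$pr_treated_given_x
  out$att <- out$se <- out$t <- NA_real_
  out$n_treated_matched <- NA_integer_

  todo <- which(out$n_treated >= max(1L, min_treated) & out$n_comparison >= 1L)
  for (i in todo) {
    est <- profile_att(profile_from_key(out$profile_key[i]), table, scores,
                       outcome = outcome, bandwidth = bandwidth)
    if (is.null(est)) next
    out$att[i] <- est$att
    out$se[i] <- est$se
    out$t[i] <- est$t
    out$n_treated_matched[i] <- est$n_treated
  }
  imp <- impact(out$att, pmin(pmax(out$pr_treated_given_x, 0), 1), out$pr_x)
  out$ate_x <- imp$ate_x
  out$impact <- imp$impact
  out$estimable <- !is.na(out$att)
  attr(out, "group") <- group
  attr(out, "n_subsets") <- attr(base, "n_subsets")
  out
}

#' Impact coverage and exclusion error over a profile universe
#'
#' Impact coverage of a profile is its impact divided by the total impact
#' across all profiles of the universe.  When profiles overlap (a
#' household can belong to several), summing plain impacts double-counts
#' households; with `overlap_adjust = TRUE` each household's weight in the
#' denominator is divided by the number of universe profiles containing it
#' (its overlap count), replacing \eqn{\Pr[x']} with
#' \eqn{\bar{\Pr}[x'] = \sum_{s \in S_{x'}} w_s / c_s}.  For pairwise
#' disjoint universes the two denominators coincide.  The exclusion error
#' is the complement: \eqn{\lambda_{impact} = 1 - \mathrm{impact\ coverage}}.
#'
#' @param metrics An [impact_analysis()] data.frame; rows with `NA` impact
#'   are excluded from the universe.
#' @param table The [household_table] the metrics were computed on
#'   (needed to count overlaps).
#' @param overlap_adjust Use the overlap-adjusted denominator (default
#'   `TRUE`).
#' @return `metrics` with columns `impact_coverage` and `lambda_impact`
#'   added, and attributes `impact_total` (the denominator) and
#'   `overlap_adjust`.  Zero total impact leaves the coverages `NA` with a
#'   warning.
#' @export
impact_coverage <- function(metrics, table, overlap_adjust = TRUE) {
  stopifnot(is.data.frame(metrics), inherits(table, "household_table"))
  est <- which(!is.na(metrics$impact))
  if (!length(est)) stop("no estimable profile in the universe")
  tm <- total_mass(table)

  if (overlap_adjust) {
    members <- lapply(metrics$profile_key[est], function(k)
      profile_members(profile_from_key(k), table))
    count <- Reduce(`+`, lapply(members, as.integer), integer(nrow(table)))
    denom <- 0
    for (j in seq_along(est)) {
      i <- est[j]
      m <- members[[j]]
      pr_bar <- sum(table$weight[m] / count[m]) / tm
      denom <- denom +
        metrics$att[i] * metrics$pr_treated_given_x[i] * pr_bar
    }
  } else {
    denom <- sum(metrics$impact[est])
  }

  metrics$impact_coverage <- NA_real_
  metrics$lambda_impact <- NA_real_
  if (denom == 0) {
    warning("zero total impact; impact coverages undefined")
  } else {
    metrics$impact_coverage[est] <- metrics$impact[est] / denom
    metrics$lambda_impact[est] <- 1 - metrics$impact_coverage[est]
  }
  attr(metrics, "impact_total") <- denom
  attr(metrics, "overlap_adjust") <- overlap_adjust
  metrics
}

#' Winning impact profiles across the error-weight grid
#'
#' Per \eqn{\alpha}, the winner minimizes
#' \eqn{\psi_{impact} = \lambda_{impact}^{\alpha}\mu_{impact}^{1-\alpha}};
#' ties are handled as in [winning_profiles()].
#'
#' @param metrics An [impact_coverage()]-augmented metrics data.frame.
#' @inheritParams winning_profiles
#' @return A data.frame as in [winning_profiles()].
#' @export
winning_impact_profiles <- function(metrics, alpha_grid = seq(0, 1, by = 0.1),
                                    min_members = 0L) {
  if (is.null(metrics$lambda_impact))
    stop("run impact_coverage() first to obtain lambda_impact")
  m <- metrics
  m$lambda <- m$lambda_impact
  m$mu <- m$mu_impact
  winning_profiles(m, alpha_grid = alpha_grid, min_members = min_members)
}

#' Profile-ATT distributions by minimum treated sample size
#'
#' Summarizes the distribution of estimated profile ATTs over profiles
#' with strictly more than each threshold of treated observations.  Under
#' a global null the distributions should be centered at zero at every
#' threshold; a genuine positive effect shows up as right skew and a
#' shrinking share of negative estimates as the threshold rises.
#'
#' @param metrics An [impact_analysis()] data.frame.
#' @param thresholds Minimum treated-count thresholds (default
#'   `c(50, 75, 100, 125, 150)`).
#' @return A data.frame with one row per threshold: `min_n`, `n_profiles`,
#'   `mean`, `median`, `sd`, `skewness`, `share_negative`; the per-profile
#'   ATT vectors are attached as the `att_values` attribute (a named
#'   list), ready for density plots.  Thresholds leaving no profile yield
#'   an `NA` row.
#' @export
att_distribution_by_min_n <- function(metrics,
                                      thresholds = c(50, 75, 100, 125, 150)) {
  stopifnot(is.data.frame(metrics))
  atts <- list()
  rows <- lapply(thresholds, function(th) {
    a <- metrics$att[!is.na(metrics$att) & metrics$n_treated > th]
    atts[[as.character(th)]] <<- a
    if (!length(a))
      return(data.frame(min_n = th, n_profiles = 0L, mean = NA_real_,
                        median = NA_real_, sd = NA_real_,
                        skewness = NA_real_, share_negative = NA_real_))
    s <- stats::sd(a)
    sk <- if (length(a) > 2L && s > 0) mean(((a - mean(a)) / s)^3) else NA_real_
    data.frame(min_n = th, n_profiles = length(a), mean = mean(a),
               median = stats::median(a), sd = s, skewness = sk,
               share_negative = mean(a < 0))
  })
  out <- do.call(rbind, rows)
  attr(out, "att_values") <- atts
  out
}

#' False-discovery-rate trade-off over sample-size and t thresholds
#'
#' A profile is "discovered" when its estimated ATT is positive with a
#' one-sided t-statistic at or above the threshold and at least the
#' minimum number of treated observations.  The FDR of each
#' (minimum n, t) cell is estimated by a permutation null: treatment
#' labels are permuted, the propensity model re-fitted, all profile ATTs
#' recomputed, and the expected null discovery count (averaged over
#' replicates) is divided by the observed discovery count.
#'
#' @param table A [household_table].
#' @param variables Covariate names defining the profile universe.
#' @param k Profile size.
#' @param regressors Regressors of the propensity model (default:
#'   `variables`).
#' @param metrics Optional precomputed [impact_analysis()] table for the
#'   observed data (saves refitting).
#' @param n_grid Minimum treated-count thresholds (default
#'   `c(50, 75, 100, 125, 150)`).
#' @param t_grid One-sided t thresholds (default `c(1.0, 1.645, 2.0)`).
#' @param null_replicates Number of label permutations (default 20).
#' @param seed Random seed (default 20151104).
#' @param method `"permutation"` (default) or `"bh"`, which instead
#'   reports per cell the Benjamini–Hochberg adjusted share of discoveries
#'   surviving at level `0.05` (no permutations).
#' @inheritParams impact_analysis
#' @return An object of class `fdr_tradeoff`: a data.frame grid with
#'   columns `min_n`, `t_threshold`, `n_discoveries`, `null_mean`
#'   (permutation method only), `fdr` (NA where nothing was discovered).
#' @export
fdr_tradeoff <- function(table, variables, k, regressors = variables,
                         metrics = NULL,
                         n_grid = c(50, 75, 100, 125, 150),
                         t_grid = c(1.0, 1.645, 2.0),
                         null_replicates = 20L, seed = 20151104,
                         bandwidth = 0.06, outcome = "stunting",
                         method = c("permutation", "bh")) {
  stopifnot(inherits(table, "household_table"))
  method <- match.arg(method)
  if (is.null(metrics)) {
    ps <- fit_propensity(table, regressors)
    metrics <- impact_analysis(table, variables, k, ps, outcome = outcome,
                               bandwidth = bandwidth,
                               min_treated = max(1L, min(n_grid)))
  }
  grid <- expand.grid(min_n = n_grid, t_threshold = t_grid,
                      KEEP.OUT.ATTRS = FALSE)
  count_disc <- function(m, n0, t0)
    sum(!is.na(m$att) & m$att > 0 & m$t >= t0 & m$n_treated >= n0)
  grid$n_discoveries <- mapply(function(n0, t0)
    count_disc(metrics, n0, t0), grid$min_n, grid$t_threshold)

  if (method == "bh") {
    grid$fdr <- NA_real_
    for (r in seq_len(nrow(grid))) {
      sel <- !is.na(metrics$att) & metrics$n_treated >= grid$min_n[r]
      if (!any(sel)) next
      p1 <- stats::pnorm(-metrics$t[sel])         # one-sided, positive effects
      padj <- stats::p.adjust(p1, method = "BH")
      disc <- metrics$att[sel] > 0 &
        metrics$t[sel] >= grid$t_threshold[r]
      if (any(disc)) grid$fdr[r] <- mean(padj[disc] > 0.05)
    }
    return(structure(grid, class = c("fdr_tradeoff", "data.frame"),
                     method = method))
  }

  null_counts <- matrix(0, nrow = nrow(grid), ncol = null_replicates)
  set.seed(seed)
  for (b in seq_len(null_replicates)) {
    perm <- table
    perm$diet_class <- sample(table$diet_class)
    perm <- structure(perm, codebook = attr(table, "codebook"),
                      class = c("household_table", "data.frame"))
    ps_b <- fit_propensity(perm, regressors)
    m_b <- impact_analysis(perm, variables, k, ps_b, outcome = outcome,
                           bandwidth = bandwidth,
                           min_treated = max(1L, min(n_grid)))
    null_counts[, b] <- mapply(function(n0, t0) count_disc(m_b, n0, t0),
                               grid$min_n, grid$t_threshold)
  }
  grid$null_mean <- rowMeans(null_counts)
  grid$fdr <- ifelse(grid$n_discoveries > 0,
                     pmin(1, grid$null_mean / grid$n_discoveries), NA_real_)
  structure(grid, class = c("fdr_tradeoff", "data.frame"), method = method)
}

#' @export
print.fdr_tradeoff <- function(x, ...) {
  cat(sprintf("<fdr_tradeoff> method %s\n", attr(x, "method")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Need versus impact: do the neediest profiles gain the most?
#'
#' Pairs each qualifying profile's polling coverage (its share of the
#' needy population) with its impact coverage (its share of the total
#' achievable impact) and reports the Pearson correlation.  A correlation
#' near 1 means targeting the neediest also targets the largest gains;
#' a low correlation means need and impact diverge.
#'
#' @param polling An [polling_analysis()] data.frame.
#' @param impact An [impact_coverage()]-augmented impact metrics
#'   data.frame on the same profile universe.
#' @param t_min Minimum one-sided t for a profile to qualify (default
#'   1.645); set `-Inf` to keep all estimable profiles.
#' @param min_treated Minimum treated observations (default 100).
#' @param positive_only Keep only positive estimated ATTs (default
#'   `TRUE`).
#' @return A list of class `need_vs_impact`: `data` (profile_key,
#'   coverage, impact_coverage, att, t, n_treated), `correlation`
#'   (Pearson; `NA` with a warning when fewer than 3 profiles qualify),
#'   `n_profiles`.
#' @export
need_vs_impact <- function(polling, impact, t_min = 1.645,
                           min_treated = 100L, positive_only = TRUE) {
  stopifnot(is.data.frame(polling), is.data.frame(impact))
  if (is.null(impact$impact_coverage))
    stop("run impact_coverage() first")
  keep <- !is.na(impact$att) & !is.na(impact$impact_coverage) &
    impact$t >= t_min & impact$n_treated >= min_treated
  if (positive_only) keep <- keep & impact$att > 0
  sel <- impact[keep, , drop = FALSE]
  m <- match(sel$profile_key, polling$profile_key)
  if (anyNA(m)) stop("impact and polling metrics cover different universes")
  df <- data.frame(profile_key = sel$profile_key,
                   coverage = polling$coverage[m],
                   impact_coverage = sel$impact_coverage,
                   att = sel$att, t = sel$t, n_treated = sel$n_treated,
                   stringsAsFactors = FALSE)
  r <- if (nrow(df) >= 3L) stats::cor(df$coverage, df$impact_coverage)
  else {
    warning("fewer than 3 qualifying profiles; correlation undefined")
    NA_real_
  }
  structure(list(data = df, correlation = r, n_profiles = nrow(df)),
            class = "need_vs_impact")
}

#' @export
print.need_vs_impact <- function(x, ...) {
  cat(sprintf(
    "<need_vs_impact> %d qualifying profiles; Pearson correlation %s\n",
    x$n_profiles,
    if (is.na(x$correlation)) "NA" else sprintf("%.3f", x$correlation)))
  invisible(x)
}

#' Frequency of characteristics across significant profiles
#'
#' For each (variable, value) pair, the share of qualifying profiles that
#' fix it — the standard summary of which characteristics dominate the
#' significant impact profiles.
#'
#' @inheritParams need_vs_impact
#' @param cb The [codebook] (for labels).
#' @return A data.frame with `variable`, `value`, `label`,
#'   `share_of_profiles`, sorted decreasing.
#' @export
profile_characteristics <- function(impact, cb, t_min = 1.645,
                                    min_treated = 100L,
                                    positive_only = TRUE) {
  keep <- !is.na(impact$att) & impact$t >= t_min &
    impact$n_treated >= min_treated
  if (positive_only) keep <- keep & impact$att > 0
  keys <- impact$profile_key[keep]
  if (!length(keys))
    return(data.frame(variable = character(0), value = integer(0),
                      label = character(0), share_of_profiles = numeric(0)))
  pairs <- unlist(strsplit(keys, "|", fixed = TRUE))
  tab <- table(pairs) / length(keys)
  kv <- strsplit(names(tab), "=", fixed = TRUE)
  vars <- vapply(kv, `[`, "", 1L)
  vals <- as.integer(vapply(kv, `[`, "", 2L))
  labs <- mapply(function(v, c) {
    if (!is.null(cb[[v]])) cb[[v]]$labels[c + 1L] else as.character(c)
  }, vars, vals)
  out <- data.frame(variable = vars, value = vals, label = labs,
                    share_of_profiles = as.numeric(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$share_of_profiles, out$variable), ]
}
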