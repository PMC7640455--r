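#' Common-support restriction on the propensity score
#'
#' Treated records whose score falls outside the `[min, max]` range of the
#' comparison group's scores have no credible counterfactual and are
#' flagged off support; the ATT is estimated on the remaining treated.
#' Comparison records are always retained (they can only ever contribute
#' through kernel windows around on-support treated scores).
#'
#' @param scores Numeric propensity scores, one per record.
#' @param treat Binary treatment indicator, one per record.
#' @return An object of class `support_mask`: `on_support` (logical per
#'   record), `share_treated_off`, `n_treated_off`, `range` (the
#'   comparison-group score range).
#' @export
common_support <- function(scores, treat) {
  treat <- as.integer(treat)
  if (length(scores) != length(treat))
    stop("scores and treat must have equal length")
  if (!any(treat == 1L) || !any(treat == 0L))
    stop("both treated and comparison records are required")
  rng <- range(scores[treat == 0L])
  off <- treat == 1L & (scores < rng[1L] | scores > rng[2L])
  if (all(off[treat == 1L]))
    stop("all treated records fall outside the comparison support")
  structure(list(on_support = !off,
                 share_treated_off = sum(off) / sum(treat == 1L),
                 n_treated_off = sum(off),
                 range = rng),
            class = "support_mask")
}

#' @export
print.support_mask <- function(x, ...) {
  cat(sprintf(
    "<support_mask> comparison score range [%.4f, %.4f]; %d treated off support (%.2f%%)\n",
    x$range[1], x$range[2], x$n_treated_off, 100 * x$share_treated_off))
  invisible(x)
}

#' Epanechnikov kernel ATT on the common support
#'
#' For each on-support treated record \eqn{i}, the counterfactual outcome
#' is the kernel-weighted mean of comparison outcomes,
#' \deqn{\hat y_i^0 = \sum_j K\!\left(\frac{p_j - p_i}{h}\right) w_j y_j
#'   \Big/ \sum_j K\!\left(\frac{p_j - p_i}{h}\right) w_j,}
#' with \eqn{K(u) = 0.75\,(1 - u^2)} on \eqn{|u| < 1} and comparison
#' observation masses \eqn{w_j} entering multiplicatively.  The ATT is the
#' mass-weighted mean of \eqn{y_i - \hat y_i^0} over treated records.
#' Treated records with no comparison inside the bandwidth window are
#' dropped with a logged count.
#'
#' The standard error assumes independent observations, fixed matching
#' weights, homoscedastic outcomes within the treated and within the
#' comparison group, and outcome variance unrelated to the score:
#' \eqn{\mathrm{Var} = s_T^2 \sum_i a_i^2 + s_C^2 \sum_j \omega_j^2}, where
#' \eqn{a_i} are the normalized treated masses and
#' \eqn{\omega_j = \sum_i a_i K_{ij} w_j / \sum_{j'} K_{ij'} w_{j'}} the
#' aggregated comparison weights.
#'
#' @param table A [household_table].
#' @param scores Propensity scores, one per record of `table`.
#' @param support A `support_mask` from [common_support()], or `NULL` to
#'   compute one.
#' @param outcome Name of the binary outcome column (default
#'   `"stunting"`).
#' @param bandwidth Kernel bandwidth \eqn{h} on the score scale; default
#'   0.06.
#' @param method `"exact"` evaluates every treated-comparison kernel pair;
#'   `"fast"` computes the same sums through sorted prefix sums in
#'   O(n log n), at the cost of a little floating-point cancellation when
#'   the bandwidth is very small relative to the score spread.  `"auto"`
#'   (default) picks `"fast"` for large problems with a non-tiny
#'   bandwidth and `"exact"` otherwise.
#' @return An object of class `att_estimate` with fields `att`, `se`, `t`,
#'   `mean_treated`, `mean_matched_comparison`, `n_treated`,
#'   `n_comparison`, `n_dropped_nomatch`, `unmatched_diff`,
#'   `unmatched_se`, `unmatched_t`, and (for diagnostics) `matched_w`
#'   (aggregated comparison weights \eqn{\omega_j}), `treated_idx`,
#'   `comparison_idx`, `treated_scores`, `treated_diff` (per-treated
#'   \eqn{y_i - \hat y_i^0}).
#' @export
kernel_att <- function(table, scores, support = NULL, outcome = "stunting",
                       bandwidth = 0.06,
                       method = c("auto", "exact", "fast")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "household_table"))
  if (bandwidth <= 0) stop("bandwidth must be positive")
  y <- table[[outcome]]
  if (is.null(y)) stop("outcome column not in table: ", outcome)
  treat <- table$diet_class
  w <- table$weight
  if (length(scores) != nrow(table))
    stop("scores must have one entry per record")
  if (is.null(support)) support <- common_support(scores, treat)

  idx_t <- which(treat == 1L & support$on_support)
  idx_c <- which(treat == 0L)
  if (!length(idx_t) || !length(idx_c))
    stop("need on-support treated and comparison records")

  p_t <- scores[idx_t]; y_t <- y[idx_t]; w_t <- w[idx_t]
  p_c <- scores[idx_c]; y_c <- y[idx_c]; w_c <- w[idx_c]

  n_t <- length(idx_t); n_c <- length(idx_c)
  em <- epa_match(p_t, w_t, p_c, w_c, y_c, bandwidth, method = method)
  cf <- em$cf
  has_match <- em$has_match
  omega_raw <- em$omega_raw   # sum_i w_i K_ij w_j / denom_i, original order
  n_dropped <- sum(!has_match)
  if (n_dropped > 0)
    message(n_dropped,
            " treated record(s) without comparison inside the bandwidth window dropped")
  if (!any(has_match))
    stop("no treated record has a comparison inside the bandwidth window")

  keep <- which(has_match)
  a <- w_t[keep] / sum(w_t[keep])
  diff_i <- y_t[keep] - cf[keep]
  att <- sum(a * diff_i)
  mean_treated <- sum(a * y_t[keep])
  mean_cf <- sum(a * cf[keep])
  omega <- omega_raw / sum(w_t[keep])   # sums to 1 over comparisons

  s2_t <- if (length(keep) > 1L) stats::var(y_t[keep]) else 0
  s2_c <- if (n_c > 1L) stats::var(y_c) else 0
  v <- s2_t * sum(a^2) + s2_c * sum(omega^2)
  se <- sqrt(v)

  # raw (unmatched) difference on the full sample, mass-weighted
  all_t <- treat == 1L; all_c <- treat == 0L
  b_t <- w[all_t] / sum(w[all_t]); b_c <- w[all_c] / sum(w[all_c])
  um_diff <- sum(b_t * y[all_t]) - sum(b_c * y[all_c])
  um_v <- stats::var(y[all_t]) * sum(b_t^2) + stats::var(y[all_c]) * sum(b_c^2)
  um_se <- sqrt(um_v)

  structure(list(att = att, se = se, t = if (se > 0) att / se else NA_real_,
                 mean_treated = mean_treated,
                 mean_matched_comparison = mean_cf,
                 n_treated = length(keep), n_comparison = n_c,
                 n_dropped_nomatch = n_dropped,
                 unmatched_diff = um_diff, unmatched_se = um_se,
                 unmatched_t = if (um_se > 0) um_diff / um_se else NA_real_,
                 bandwidth = bandwidth, outcome = outcome,
                 matched_w = omega,
                 treated_idx = idx_t[keep], comparison_idx = idx_c,
                 treated_scores = p_t[keep], treated_diff = diff_i),
            class = "att_estimate")
}

# Epanechnikov kernel sums: per-treated counterfactual and kernel mass,
# plus the aggregated comparison weights omega_raw_j = sum_i w_i K_ij w_j /
# denom_i (over treated with a non-empty window), in the original
# comparison order.  Two algebraically identical routes:
#   exact — chunked dense evaluation of all treated x comparison pairs;
#   fast  — K(u) expanded into a quadratic in p_j, window sums via prefix
#           sums over score-sorted comparisons and omega via difference
#           arrays (O(n log n)).  The expansion subtracts large partial
#           sums, so "auto" only uses it when the pair count is large and
#           the bandwidth is not tiny relative to the score scale.
epa_match <- function(p_t, w_t, p_c, w_c, y_c, h,
                      method = c("auto", "exact", "fast")) {
  method <- match.arg(method)
  n_t <- length(p_t); n_c <- length(p_c)
  if (method == "auto")
    method <- if (as.double(n_t) * n_c > 4e6 && h >= 0.005) "fast" else "exact"

  if (method == "exact") {
    cf <- numeric(n_t)
    has_match <- logical(n_t)
    omega_raw <- numeric(n_c)
    chunk <- max(1L, floor(2e6 / max(1L, n_c)))
    for (s in seq(1L, n_t, by = chunk)) {
      ii <- s:min(s + chunk - 1L, n_t)
      U <- outer(p_c, p_t[ii], "-") / h          # n_c x |ii|
      K <- 0.75 * (1 - U * U)
      K[abs(U) >= 1] <- 0
      Kw <- K * w_c
      denom <- colSums(Kw)
      ok <- denom > 0
      has_match[ii] <- ok
      cf[ii][ok] <- (colSums(Kw * y_c) / denom)[ok]
      scale <- ifelse(ok, w_t[ii] / pmax(denom, 1e-300), 0)
      omega_raw <- omega_raw + as.vector(Kw %*% scale)
    }
    return(list(cf = cf, has_match = has_match, omega_raw = omega_raw))
  }

  ord <- order(p_c)
  pc <- p_c[ord]; wc <- w_c[ord]; yc <- y_c[ord]
  # prefix sums of w, w*p, w*p^2 and the y-weighted versions
  W0 <- c(0, cumsum(wc)); W1 <- c(0, cumsum(wc * pc))
  W2 <- c(0, cumsum(wc * pc * pc))
  Y0 <- c(0, cumsum(wc * yc)); Y1 <- c(0, cumsum(wc * yc * pc))
  Y2 <- c(0, cumsum(wc * yc * pc * pc))
  lo <- findInterval(p_t - h, pc) + 1L   # first j with pc_j > p_t - h (ties: K=0)
  hi <- findInterval(p_t + h, pc)        # last j with pc_j <= p_t + h
  win <- function(S) S[hi + 1L] - S[lo]
  # sum_j w_j K_ij = 0.75 * [ (1 - p_i^2/h^2) S_w0 + (2 p_i/h^2) S_w1 - S_w2/h^2 ]
  cA <- 1 - p_t * p_t / h^2
  cB <- 2 * p_t / h^2
  denom <- 0.75 * (cA * win(W0) + cB * win(W1) - win(W2) / h^2)
  num <- 0.75 * (cA * win(Y0) + cB * win(Y1) - win(Y2) / h^2)
  has_match <- !is.na(denom) & denom > 0 & lo <= hi
  cf <- numeric(n_t)
  cf[has_match] <- num[has_match] / denom[has_match]

  # omega_j = w_cj * sum_{i: j in win_i} w_i 0.75 (A_i + B_i p_j + C_i p_j^2)/denom_i
  ret <- which(has_match)
  fac <- 0.75 * w_t[ret] / denom[ret]
  accum <- function(vals) {
    acc <- numeric(n_c + 1L)
    if (length(ret)) {
      up <- rowsum(vals, lo[ret], reorder = FALSE)
      acc[as.integer(rownames(up))] <- acc[as.integer(rownames(up))] + up[, 1L]
      dn <- rowsum(vals, hi[ret] + 1L, reorder = FALSE)
      acc[as.integer(rownames(dn))] <- acc[as.integer(rownames(dn))] - dn[, 1L]
    }
    cumsum(acc)[seq_len(n_c)]
  }
  pA <- accum(fac * (1 - p_t[ret]^2 / h^2))
  pB <- accum(fac * 2 * p_t[ret] / h^2)
  pC <- accum(-fac / h^2)
  omega_sorted <- wc * (pA + pB * pc + pC * pc * pc)
  omega_raw <- numeric(n_c)
  omega_raw[ord] <- pmax(omega_sorted, 0)   # clip tiny negative round-off
  list(cf = cf, has_match = has_match, omega_raw = omega_raw)
}

#' @export
print.att_estimate <- function(x, ...) {
  cat(sprintf("<att_estimate> outcome '%s', bandwidth %.3g\n",
              x$outcome, x$bandwidth))
  tab <- data.frame(
    row.names = c("Unmatched", "ATT"),
    Treated = c(NA, x$mean_treated),
    Comparison = c(NA, x$mean_matched_comparison),
    Difference = c(x$unmatched_diff, x$att),
    s.e. = c(x$unmatched_se, x$se),
    t = c(x$unmatched_t, x$t), check.names = FALSE)
  print(round(tab, 3))
  cat(sprintf("n treated %d (dropped without match: %d), n comparison %d\n",
              x$n_treated, x$n_dropped_nomatch, x$n_comparison))
  invisible(x)
}

#' Covariate balance before and after matching
#'
#' Standardized differences and variance ratios of every propensity-model
#' regressor column, before matching (treated vs. comparison, observation
#' masses as weights) and after matching (on-support treated vs. the
#' kernel-matched comparison sample weighted by the aggregated weights
#' \eqn{\omega_j}).  The standardized-difference denominator is fixed at
#' the before-matching pooled standard deviation so the two rows are
#' comparable; a covariate constant in both groups scores 0.
#'
#' @param model A `propensity_model` (supplies the design matrix).
#' @param table The [household_table] the model was fitted on.
#' @param att An `att_estimate` from [kernel_att()].
#' @return An object of class `balance_report`: `balance` (data.frame with
#'   columns term, std_diff_before, std_diff_after, var_ratio_before,
#'   var_ratio_after) and `density_data` (long data.frame of
#'   score/child-age/interview-day values with group and matching weights,
#'   for before/after density plots).
#' @export
balance_report <- function(model, table, att) {
  stopifnot(inherits(model, "propensity_model"),
            inherits(att, "att_estimate"))
  X <- model$X
  slopes <- setdiff(colnames(X), "(Intercept)")
  treat <- model$treat
  w <- table$weight

  idx_t0 <- which(treat == 1L); idx_c0 <- which(treat == 0L)
  wt0 <- w[idx_t0] / sum(w[idx_t0]); wc0 <- w[idx_c0] / sum(w[idx_c0])
  idx_t1 <- att$treated_idx; idx_c1 <- att$comparison_idx
  wt1 <- w[idx_t1] / sum(w[idx_t1])
  wc1 <- att$matched_w / sum(att$matched_w)

  bal <- lapply(slopes, function(j) {
    x <- X[, j]
    mt0 <- sum(wt0 * x[idx_t0]); mc0 <- sum(wc0 * x[idx_c0])
    vt0 <- wvar(x[idx_t0], wt0); vc0 <- wvar(x[idx_c0], wc0)
    mt1 <- sum(wt1 * x[idx_t1]); mc1 <- sum(wc1 * x[idx_c1])
    vt1 <- wvar(x[idx_t1], wt1); vc1 <- wvar(x[idx_c1], wc1)
    pooled <- sqrt((vt0 + vc0) / 2)
    data.frame(term = j,
               std_diff_before = if (pooled > 0) (mt0 - mc0) / pooled else 0,
               std_diff_after = if (pooled > 0) (mt1 - mc1) / pooled else 0,
               var_ratio_before = if (vc0 > 0) vt0 / vc0 else NA_real_,
               var_ratio_after = if (vc1 > 0) vt1 / vc1 else NA_real_,
               stringsAsFactors = FALSE)
  })
  dens <- density_export(table, model$scores, treat, idx_t1, idx_c1, wc1)
  structure(list(balance = do.call(rbind, bal), density_data = dens),
            class = "balance_report")
}

wvar <- function(x, w) {
  m <- sum(w * x)
  sum(w * (x - m)^2) / max(1e-300, (1 - sum(w^2)))
}

density_export <- function(table, scores, treat, idx_t1, idx_c1, wc1) {
  vars <- intersect(c("child_age_months", "interview_day"), names(table))
  pieces <- list()
  add <- function(var, vals, grp, stage, wt) {
    data.frame(variable = var, group = grp, stage = stage, value = vals,
               weight = wt / sum(wt), stringsAsFactors = FALSE)
  }
  for (v in c("score", vars)) {
    vals <- if (v == "score") scores else as.numeric(table[[v]])
    it <- which(treat == 1L); ic <- which(treat == 0L)
    pieces[[length(pieces) + 1L]] <-
      add(v, vals[it], "treated", "before", table$weight[it])
    pieces[[length(pieces) + 1L]] <-
      add(v, vals[ic], "comparison", "before", table$weight[ic])
    pieces[[length(pieces) + 1L]] <-
      add(v, vals[idx_t1], "treated", "after", table$weight[idx_t1])
    pieces[[length(pieces) + 1L]] <-
      add(v, vals[idx_c1], "comparison", "after", wc1)
  }
  do.call(rbind, pieces)
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report>\n")
  b <- x$balance
  b[-1L] <- lapply(b[-1L], round, 3)
  print(b, row.names = FALSE)
  invisible(x)
}

#' Local regression of the treatment effect on the propensity score
#'
#' Smooths the per-treated difference between the observed outcome and its
#' kernel-matched counterfactual against the treated record's propensity
#' score, using locally weighted scatterplot smoothing.  An upward slope
#' would indicate that impact rises with the likelihood of treatment
#' (targeting on need also targets impact); a falling curve indicates the
#' opposite.
#'
#' @param att An `att_estimate` from [kernel_att()].
#' @param span Smoother span passed to [stats::lowess()] (default 2/3).
#' @return A data.frame with columns `score` and `local_att` (fitted
#'   values, one per treated record, ordered by score).  When the treated
#'   scores are all identical a single-row table is returned with a
#'   warning.
#' @export
att_by_pscore_curve <- function(att, span = 2/3) {
  stopifnot(inherits(att, "att_estimate"))
  p <- att$treated_scores
  d <- att$treated_diff
  if (length(p) < 10L) stop("fewer than 10 treated records")
  if (length(unique(p)) == 1L) {
    warning("treated scores show no variation; returning a single point")
    return(data.frame(score = p[1L], local_att = mean(d)))
  }
  # iter = 0: the per-treated differences are bimodal (binary outcome minus
  # a smooth counterfactual), so robustness reweighting would chase the
  # majority mode instead of the conditional mean
  fit <- stats::lowess(p, d, f = span, iter = 0)
  data.frame(score = fit$x, local_att = fit$y)
}
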