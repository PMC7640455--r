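#' Weighted geometric mean of exclusion and inclusion errors
#'
#' \eqn{\psi = \lambda^{\alpha} \mu^{1-\alpha}} with
#' \eqn{0 \le \alpha \le 1}.  \eqn{\alpha} weights the exclusion error
#' relative to the inclusion error; \eqn{0^0} is taken as 1 so that a
#' perfect profile scores 0 at the boundary values of \eqn{\alpha}.
#'
#' @param lambda Exclusion error(s) in `[0, 1]`.
#' @param mu Inclusion error(s) in `[0, 1]`.
#' @param alpha Weight(s) in `[0, 1]`.
#' @return `lambda^alpha * mu^(1 - alpha)`, vectorized.
#' @export
psi <- function(lambda, mu, alpha) {
  if (any(lambda < 0 | lambda > 1, na.rm = TRUE) ||
      any(mu < 0 | mu > 1, na.rm = TRUE) ||
      any(alpha < 0 | alpha > 1, na.rm = TRUE))
    stop("psi arguments must lie in [0, 1]")
  lambda^alpha * mu^(1 - alpha)  # R's 0^0 == 1, as required
}

#' Polling metrics for one profile
#'
#' For the relevant group \eqn{g} (by default the households with
#' inadequate diet diversity, `diet_class == 1`):
#' coverage is the mass of group members inside the profile over the total
#' group mass \eqn{m_{gc} / \sum_c m_{gc}}; the exclusion error
#' \eqn{\lambda} is one minus the coverage; the inclusion error \eqn{\mu}
#' is the share of the profile's mass that lies outside the group,
#' \eqn{1 - m_{gc} / \sum_g m_{gc}}.
#'
#' @param p A [profile].
#' @param table A [household_table] with a `diet_class` column.
#' @param group The relevant value of `diet_class` (default 1, inadequate).
#' @return A list of class `polling_metrics`: `profile`, `mass` (m_gc),
#'   `group_mass`, `profile_mass`, `coverage`, `lambda`, `mu` (`NA` with
#'   `zero_mass = TRUE` when the profile holds no mass).
#' @export
polling_metrics <- function(p, table, group = 1L) {
  stopifnot(inherits(p, "profile"), inherits(table, "household_table"))
  if (is.null(table$diet_class)) stop("table has no 'diet_class' column")
  in_group <- table$diet_class == group
  group_mass <- sum(table$weight[in_group])
  if (group_mass <= 0) stop("the relevant group has no mass")
  inside <- profile_members(p, table)
  mass <- sum(table$weight[inside & in_group])
  profile_mass <- sum(table$weight[inside])
  coverage <- mass / group_mass
  mu <- if (profile_mass > 0) 1 - mass / profile_mass else NA_real_
  structure(list(profile = p, mass = mass, group_mass = group_mass,
                 profile_mass = profile_mass, coverage = coverage,
                 lambda = 1 - coverage, mu = mu,
                 zero_mass = profile_mass <= 0),
            class = "polling_metrics")
}

#' @export
print.polling_metrics <- function(x, ...) {
  cat(sprintf("<polling_metrics> %s\n  coverage %.4f  lambda %.4f  mu %s\n",
              profile_key(x$profile), x$coverage, x$lambda,
              if (is.na(x$mu)) "NA (zero mass)" else sprintf("%.4f", x$mu)))
  invisible(x)
}

#' Polling metrics for every profile over k-subsets of covariates
#'
#' Exhaustively enumerates all value assignments of every size-`k` subset
#' of `variables` (see [enumerate_profiles()]) and computes the Box-1
#' polling metrics for each.  Masses are tabulated per variable subset, so
#' the full enumeration stays fast even for tens of thousands of profiles.
#'
#' @inheritParams polling_metrics
#' @param table A [household_table].
#' @param variables Covariate names to combine.
#' @param k Profile size.
#' @return A data.frame with one row per profile: `profile_key`,
#'   `subset_id`, `n_vars`, `mass`, `profile_mass`, `n_members`,
#'   `n_group_members`, `coverage`, `lambda`, `mu` (`NA` for zero-mass
#'   profiles).  Attributes: `group_mass`, `n_subsets`, `group`.
#' @export
polling_analysis <- function(table, variables, k, group = 1L) {
  stopifnot(inherits(table, "household_table"))
  cb <- attr(table, "codebook")
  if (is.null(table$diet_class)) stop("table has no 'diet_class' column")
  if (k <= 0) stop("k must be positive")
  variables <- as.character(variables)
  if (k > length(variables)) stop("k exceeds the number of variables")

  w <- table$weight
  in_group <- table$diet_class == group
  group_mass <- sum(w[in_group])
  if (group_mass <= 0) stop("the relevant group has no mass")

  subs <- utils::combn(variables, k, simplify = FALSE)
  res <- vector("list", length(subs))
  for (si in seq_along(subs)) {
    vars <- subs[[si]]
    sizes <- vapply(vars, function(v) length(cb[[v]]$codes), integer(1))
    ncells <- prod(sizes)
    # mixed-radix cell index, first variable fastest (expand.grid order)
    cell <- rep(1L, nrow(table))
    mult <- 1L
    for (j in seq_along(vars)) {
      cell <- cell + table[[vars[j]]] * mult
      mult <- mult * sizes[j]
    }
    m_all <- cell_mass(cell, w, ncells)
    m_grp <- cell_mass(cell[in_group], w[in_group], ncells)
    n_all <- cell_mass(cell, rep(1, nrow(table)), ncells)
    n_grp <- cell_mass(cell[in_group], rep(1, sum(in_group)), ncells)

    grid <- expand.grid(lapply(vars, function(v) cb[[v]]$codes),
                        KEEP.OUT.ATTRS = FALSE)
    key <- profile_grid_keys(vars, grid)
    res[[si]] <- data.frame(
      profile_key = key, subset_id = si, n_vars = k,
      mass = m_grp, profile_mass = m_all,
      n_members = n_all, n_group_members = n_grp,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$coverage <- out$mass / group_mass
  out$lambda <- 1 - out$coverage
  out$mu <- ifelse(out$profile_mass > 0, 1 - out$mass / out$profile_mass,
                   NA_real_)
  attr(out, "group_mass") <- group_mass
  attr(out, "n_subsets") <- length(subs)
  attr(out, "group") <- group
  out
}

# Aggregate weights into 1..ncells (cells with no rows get 0).
cell_mass <- function(cell, w, ncells) {
  m <- numeric(ncells)
  if (length(cell)) {
    agg <- rowsum(w, cell)
    m[as.integer(rownames(agg))] <- agg[, 1L]
  }
  m
}

# Canonical keys for all rows of an expand.grid over `vars`.
profile_grid_keys <- function(vars, grid) {
  o <- order(vars)
  cols <- lapply(o, function(j) sprintf("%s=%d", vars[j], grid[[j]]))
  do.call(paste, c(cols, sep = "|"))
}

#' Winning profiles across a grid of error weights
#'
#' For each \eqn{\alpha} in the grid, the winning profile minimizes
#' \eqn{\psi = \lambda^{\alpha}\mu^{1-\alpha}} over all profiles with a
#' defined inclusion error.  Ties are reported, with the lexicographically
#' smallest profile key as the deterministic primary pick.
#'
#' @param metrics A data.frame with `profile_key`, `lambda` and `mu`
#'   columns, as returned by [polling_analysis()] (or by
#'   [impact_analysis()] via its `lambda_impact`/`mu_impact` columns — see
#'   [winning_impact_profiles()]).
#' @param alpha_grid Numeric vector of weights; default `seq(0, 1, 0.1)`.
#' @param min_members Optional minimum number of profile members; profiles
#'   below it are excluded before ranking (default 0: keep all).
#' @return A data.frame with one row per alpha: `alpha`, `profile_key`,
#'   `lambda`, `mu`, `psi`, `n_ties`, `ties` (all tied keys, `;`-joined).
#' @export
winning_profiles <- function(metrics, alpha_grid = seq(0, 1, by = 0.1),
                             min_members = 0L) {
  stopifnot(is.data.frame(metrics),
            all(c("profile_key", "lambda", "mu") %in% names(metrics)))
  # profiles with errors outside [0, 1] (possible for impact metrics when
  # profile impacts have mixed signs) cannot enter the geometric mean and
  # are excluded from the ranking
  ok <- !is.na(metrics$mu) & !is.na(metrics$lambda) &
    metrics$mu >= 0 & metrics$mu <= 1 &
    metrics$lambda >= 0 & metrics$lambda <= 1
  if (min_members > 0 && "n_members" %in% names(metrics))
    ok <- ok & metrics$n_members >= min_members
  m <- metrics[ok, , drop = FALSE]
  if (nrow(m) == 0L) stop("no profile with defined errors to rank")
  rows <- lapply(alpha_grid, function(a) {
    p <- psi(m$lambda, m$mu, a)
    best <- min(p)
    tied <- which(p == best)
    keys <- sort(m$profile_key[tied])
    i <- tied[order(m$profile_key[tied])][1L]
    data.frame(alpha = a, profile_key = keys[1L],
               lambda = m$lambda[i], mu = m$mu[i], psi = best,
               n_ties = length(tied),
               ties = paste(keys, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
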