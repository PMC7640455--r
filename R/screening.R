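#' Univariate screening of candidate profiling variables
#'
#' Regresses the binary outcome (by default adequate diet diversity) on
#' each candidate variable separately — a probit on the variable's
#' category indicators — and ranks candidates by the p-value of the joint
#' Wald test across the variable's categories.  The top `k` variables by
#' ascending p-value are returned, ties broken lexicographically by
#' variable name.
#'
#' Candidates with a single observed category are assigned p = 1 with a
#' warning.  When the probit shows signs of complete separation the
#' p-value is recomputed from a ridge-penalized probit and the result is
#' flagged.
#'
#' @param table A [household_table].
#' @param candidates Character vector of candidate covariate names.
#' @param outcome Binary outcome column name (default `"adequate"`).
#' @param k Number of variables to keep (default 10).
#' @return A data.frame of class `screen_result` with one row per selected
#'   variable: `variable`, `statistic` (Wald chi-squared), `df`,
#'   `p_value`, `rank`, `flag` (`""`, `"single-category"` or
#'   `"separation-penalized"`), sorted by rank.
#' @export
univariate_screen <- function(table, candidates, outcome = "adequate",
                              k = 10L) {
  stopifnot(inherits(table, "household_table"))
  candidates <- sort(as.character(candidates))
  if (k > length(candidates)) stop("k exceeds the number of candidates")
  y <- table[[outcome]]
  if (is.null(y)) stop("outcome column not in table: ", outcome)
  if (any(!y %in% c(0L, 1L))) stop("outcome must be binary")
  cb <- attr(table, "codebook")

  rows <- lapply(candidates, function(v) {
    col <- table[[v]]
    if (is.null(col)) stop("candidate not in table: ", v)
    if (length(unique(col)) < 2L) {
      warning("candidate '", v, "' has a single observed category; p = 1")
      return(data.frame(variable = v, statistic = 0, df = 0L, p_value = 1,
                        flag = "single-category", stringsAsFactors = FALSE))
    }
    f <- if (!is.null(cb[[v]]) && cb[[v]]$role == "covariate")
      droplevels(factor(col, levels = cb[[v]]$codes, labels = cb[[v]]$labels))
    else factor(col)
    wald_probit(y, f, v)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$variable), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out <- out[out$rank <= k, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

# Joint Wald test of all category indicators of one candidate.
wald_probit <- function(y, f, name) {
  warn <- character(0)
  fit <- withCallingHandlers(
    stats::glm(y ~ f, family = stats::binomial(link = "probit")),
    warning = function(cnd) {
      warn <<- c(warn, conditionMessage(cnd))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  sep <- any(grepl("fitted probabilities numerically 0 or 1", warn)) ||
    !fit$converged || anyNA(beta) || any(abs(beta[-1L]) > 8)
  if (sep) {
    X <- stats::model.matrix(~f)
    pen <- probit_ridge(X, y, lambda = 1e-2)
    b <- pen$beta[-1L]
    V <- pen$vcov[-1L, -1L, drop = FALSE]
    stat <- drop(t(b) %*% solve(V, b))
    df <- length(b)
    return(data.frame(variable = name, statistic = stat, df = df,
                      p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                      flag = "separation-penalized",
                      stringsAsFactors = FALSE))
  }
  b <- beta[-1L]
  V <- stats::vcov(fit)[-1L, -1L, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  df <- length(b)
  data.frame(variable = name, statistic = stat, df = df,
             p_value = stats::pchisq(stat, df, lower.tail = FALSE),
             flag = "", stringsAsFactors = FALSE)
}

# Ridge-penalized probit by Newton-Raphson; keeps coefficients finite
# under complete separation.  Penalty excludes the intercept.
probit_ridge <- function(X, y, lambda = 1e-2, maxit = 50L, tol = 1e-8) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    Phi <- stats::pnorm(eta)
    phi <- stats::dnorm(eta)
    Phi <- pmin(pmax(Phi, 1e-10), 1 - 1e-10)
    score <- drop(t(X) %*% (phi * (y - Phi) / (Phi * (1 - Phi)))) - pen %*% beta
    W <- phi^2 / (Phi * (1 - Phi))
    H <- t(X) %*% (X * W) + pen
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = drop(beta), vcov = solve(H))
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> top %d variables by joint probit Wald p-value\n",
              nrow(x)))
  df <- as.data.frame(x)
  df$statistic <- signif(df$statistic, 4)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
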