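#' Probit propensity-score model for inadequate diet diversity
#'
#' Fits a maximum-likelihood probit of the treatment indicator
#' (`diet_class`, 1 = inadequate diet diversity) on category indicators of
#' the chosen covariates: \eqn{\Pr[\mathrm{treated} \mid x] = \Phi(x'\beta)}.
#' Codebook covariates enter as factors with their first category omitted;
#' numeric columns not in the codebook (e.g. an age-in-years term) enter
#' linearly.  Marginal effects are evaluated at the means of the
#' regressors, with discrete 0/1 changes for indicator columns and
#' delta-method standard errors.
#'
#' @param table A [household_table] with a `diet_class` column.
#' @param regressors Character vector of covariate names (codebook
#'   covariates and/or numeric columns of the table).
#' @param weights Logical; if `TRUE` the observation weights enter the
#'   probit likelihood.  Default `FALSE` (unweighted fit).
#' @param control Passed to [stats::glm.control()]; defaults to
#'   `epsilon = 1e-8, maxit = 100`.
#' @return An object of class `propensity_model`: `fit` (the glm),
#'   `coefficients`, `vcov`, `marginal_effects` (data.frame with estimate,
#'   SE, z, p, significance stars at 1/5/10%), `scores` (fitted
#'   \eqn{\Phi(x'\beta)}, clamped strictly inside (0, 1)), `X` (model
#'   matrix), `treat`, `converged`.
#' @export
fit_propensity <- function(table, regressors, weights = FALSE,
                           control = stats::glm.control(epsilon = 1e-8,
                                                        maxit = 100)) {
  stopifnot(inherits(table, "household_table"))
  if (is.null(table$diet_class)) stop("table has no 'diet_class' column")
  treat <- table$diet_class
  if (all(treat == 1L) || all(treat == 0L))
    stop("both treated and untreated records are required")
  cb <- attr(table, "codebook")

  dat <- data.frame(.treat = treat)
  for (v in regressors) {
    col <- table[[v]]
    if (is.null(col)) stop("regressor not in table: ", v)
    if (!is.null(cb[[v]]) && cb[[v]]$role == "covariate") {
      dat[[v]] <- factor(col, levels = cb[[v]]$codes,
                         labels = cb[[v]]$labels)
    } else {
      dat[[v]] <- as.numeric(col)
    }
  }
  # drop unused factor levels so the design matrix has full rank
  single <- vapply(dat[-1L], function(x) length(unique(x)) < 2L, logical(1))
  if (any(single))
    stop("regressor(s) with a single observed value: ",
         paste(regressors[single], collapse = ", "))
  dat <- droplevels(dat)

  form <- stats::as.formula(paste(".treat ~", paste(sprintf("`%s`", regressors),
                                                    collapse = " + ")))
  w <- if (isTRUE(weights)) table$weight else NULL
  warn <- character(0)
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(link = "probit"),
               data = dat, weights = w, control = control),
    warning = function(cnd) {
      warn <<- c(warn, conditionMessage(cnd))
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("probit did not converge after ", control$maxit, " iterations",
         "; deviance trace: ", paste(signif(fit$deviance, 6), collapse = " "))
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("collinear regressors: ", paste(names(beta)[is.na(beta)],
                                         collapse = ", "))
  if (any(grepl("fitted probabilities numerically 0 or 1", warn)) &&
      any(abs(beta) > 8)) {
    worst <- names(beta)[which.max(abs(beta))]
    stop("perfect separation detected; separating term: ", worst)
  }

  X <- stats::model.matrix(fit)
  V <- stats::vcov(fit)
  me <- marginal_effects_at_means(beta, V, X)
  eps <- 1e-12
  scores <- pmin(pmax(stats::fitted(fit), eps), 1 - eps)

  structure(list(fit = fit, coefficients = beta, vcov = V,
                 marginal_effects = me, scores = scores, X = X,
                 treat = treat, regressors = regressors,
                 weighted = isTRUE(weights), converged = fit$converged),
            class = "propensity_model")
}

# Marginal effects of a probit at the regressor means.  Indicator columns
# get the discrete change Phi(x1'b) - Phi(x0'b); continuous columns get
# phi(xbar'b) * b_j.  SEs by the delta method.
marginal_effects_at_means <- function(beta, V, X) {
  xbar <- colMeans(X)
  slopes <- setdiff(names(beta), "(Intercept)")
  est <- se <- numeric(length(slopes))
  for (i in seq_along(slopes)) {
    j <- slopes[i]
    xj <- X[, j]
    if (all(xj %in% c(0, 1))) {
      x1 <- x0 <- xbar
      x1[j] <- 1; x0[j] <- 0
      l1 <- sum(x1 * beta); l0 <- sum(x0 * beta)
      est[i] <- stats::pnorm(l1) - stats::pnorm(l0)
      grad <- stats::dnorm(l1) * x1 - stats::dnorm(l0) * x0
    } else {
      l <- sum(xbar * beta)
      est[i] <- stats::dnorm(l) * beta[j]
      grad <- -l * stats::dnorm(l) * xbar * beta[j]
      grad[j] <- grad[j] + stats::dnorm(l)
    }
    se[i] <- sqrt(drop(t(grad) %*% V %*% grad))
  }
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(term = slopes, estimate = est, se = se, z = z, p = p,
             stars = significance_stars(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

significance_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.10, "*", "")))
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("<propensity_model> probit, %d obs (%d treated), %s\n",
              length(x$scores), sum(x$treat),
              if (x$weighted) "weighted" else "unweighted"))
  cat("Marginal effects at means:\n")
  me <- x$marginal_effects
  me$estimate <- signif(me$estimate, 3)
  me$se <- signif(me$se, 3)
  print(me[, c("term", "estimate", "se", "stars")], row.names = FALSE)
  invisible(x)
}
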