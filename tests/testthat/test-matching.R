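# Weighted stratified difference-of-means oracle over a discrete covariate.
strat_oracle <- function(tab, var, outcome = "stunting") {
  vals <- sort(unique(tab[[var]]))
  num <- 0; den <- 0
  for (v in vals) {
    st <- tab[[var]] == v & tab$diet_class == 1L
    sc <- tab[[var]] == v & tab$diet_class == 0L
    if (!any(st) || !any(sc)) next
    d <- weighted.mean(tab[[outcome]][st], tab$weight[st]) -
      weighted.mean(tab[[outcome]][sc], tab$weight[sc])
    num <- num + sum(tab$weight[st]) * d
    den <- den + sum(tab$weight[st])
  }
  num / den
}

test_that("probit recovers a known assignment model within its own SEs", {
  # single 5-category covariate with known coefficients
  true_b <- c(0, -0.3, -0.6, 0.4, 0.2)
  hits <- 0L
  reps <- 60L
  for (r in seq_len(reps)) {
    tab <- generate_households(synthetic_config(
      n = 4000, seed = 5000 + r,
      covariates = list(wealth = list(labels = paste0("q", 1:5),
                                      p = rep(0.2, 5))),
      treatment = list(intercept = 0.2, coef = list(wealth = true_b)),
      outcome = list(baseline = 0.2, coef = list(), effects = list())))
    m <- fit_propensity(tab, "wealth")
    est <- m$coefficients[-1]              # category contrasts vs q1
    se <- sqrt(diag(m$vcov))[-1]
    hits <- hits + as.integer(all(abs(est - true_b[-1]) <= 2 * se))
  }
  expect_gte(hits / reps, 0.80)  # joint 4-coefficient coverage at +/-2 SE
})

test_that("null regressors give marginal effects within 2 SE of zero", {
  tab <- generate_households(synthetic_config(
    n = 8000, seed = 77,
    covariates = list(wealth = list(labels = paste0("q", 1:5),
                                    p = rep(0.2, 5)),
                      area = list(labels = c("urban", "rural"),
                                  p = c(0.4, 0.6))),
    treatment = list(intercept = 0.4,
                     coef = list(wealth = rep(0, 5), area = c(0, 0))),
    outcome = list(baseline = 0.2, coef = list(), effects = list())))
  m <- fit_propensity(tab, c("wealth", "area"))
  me <- m$marginal_effects
  expect_true(all(abs(me$estimate) <= 2.5 * me$se))
  expect_true(all(m$scores > 0 & m$scores < 1))
})

test_that("degenerate propensity inputs error", {
  tab <- random_table(50, seed = 51)
  tab$diet_class <- 1L
  expect_error(fit_propensity(tab, "area"), "both treated")
  tab2 <- random_table(50, seed = 52)
  tab2$area <- 0L
  expect_error(fit_propensity(tab2, "area"), "single observed")
})

test_that("common support drops exactly the out-of-range treated", {
  # treated inside comparison range: nothing dropped
  s <- c(0.4, 0.5, 0.2, 0.8)
  tr <- c(1L, 1L, 0L, 0L)
  m <- common_support(s, tr)
  expect_equal(m$n_treated_off, 0L)
  expect_true(all(m$on_support))
  # one treated above the comparison maximum
  s2 <- c(0.99, 0.5, 0.2, 0.90)
  m2 <- common_support(s2, tr)
  expect_equal(m2$n_treated_off, 1L)
  expect_equal(m2$share_treated_off, 1 / 2)
  expect_false(m2$on_support[1])
  # simulated disjoint upper tail vs brute-force count
  set.seed(53)
  sc <- runif(500, 0.1, 0.7)
  st <- c(runif(400, 0.2, 0.9), sc)
  tr3 <- c(rep(1L, 400), rep(0L, 500))
  m3 <- common_support(c(st[1:400], sc), tr3)
  brute <- sum(st[1:400] > max(sc) | st[1:400] < min(sc))
  expect_equal(m3$n_treated_off, brute)
  expect_error(common_support(c(0.9, 0.95, 0.1, 0.2), c(1L, 1L, 0L, 0L)),
               "outside the comparison support")
})

test_that("identical outcomes at every score give a zero ATT", {
  tab <- random_table(400, seed = 54)
  tab$stunting <- 1L
  a <- kernel_att(tab, runif(400, 0.2, 0.8))
  expect_equal(a$att, 0)
  expect_equal(a$se, 0)
})

test_that("kernel weights normalize and shift-invariance holds", {
  tab <- random_table(500, seed = 55, gamma_weights = TRUE)
  s <- runif(500, 0.1, 0.9)
  a <- kernel_att(tab, s)
  expect_equal(sum(a$matched_w), 1, tolerance = 1e-10)
  # shifting the outcome leaves the ATT unchanged
  tab2 <- tab
  tab2$shifted <- tab$stunting + 5
  a2 <- kernel_att(tab2, s, outcome = "shifted")
  expect_equal(a2$att, a$att, tolerance = 1e-10)
  expect_gt(a$se, 0)  # outcomes vary within groups
})

test_that("an infinite-bandwidth counterfactual is the comparison mean", {
  tab <- random_table(600, seed = 56, gamma_weights = TRUE)
  s <- runif(600, 0.3, 0.7)
  a <- kernel_att(tab, s, bandwidth = 10)
  cmean <- weighted.mean(tab$stunting[tab$diet_class == 0L],
                         tab$weight[tab$diet_class == 0L])
  expect_equal(a$mean_matched_comparison, cmean, tolerance = 1e-3)
})

test_that("kernel ATT equals the stratified oracle on a discrete covariate", {
  cfg <- synthetic_config(
    n = 3000, seed = 57,
    covariates = list(area = list(labels = c("urban", "rural"),
                                  p = c(0.4, 0.6))),
    treatment = list(intercept = 0.3, coef = list(area = c(-0.5, 0.4))),
    outcome = list(baseline = 0.2, coef = list(area = c(0, 0.1)),
                   effects = list()))
  tab <- generate_households(cfg)
  m <- fit_propensity(tab, "area")
  h <- min(diff(sort(unique(m$scores)))) / 2  # isolates each score value
  a <- kernel_att(tab, m$scores, bandwidth = h)
  expect_equal(a$att, strat_oracle(tab, "area"), tolerance = 1e-10)
})

test_that("fast and exact kernel paths agree", {
  for (seed in 1:3) {
    tab <- random_table(800, seed = 60 + seed, gamma_weights = TRUE)
    s <- runif(800, 0.05, 0.95)
    for (h in c(0.03, 0.06, 0.15)) {
      ae <- kernel_att(tab, s, bandwidth = h, method = "exact")
      af <- kernel_att(tab, s, bandwidth = h, method = "fast")
      expect_equal(af$att, ae$att, tolerance = 1e-10)
      expect_equal(af$se, ae$se, tolerance = 1e-10)
      expect_equal(af$matched_w, ae$matched_w, tolerance = 1e-10)
      expect_equal(af$n_treated, ae$n_treated)
    }
  }
})

test_that("randomized treatment with a constant effect is recovered", {
  reps <- 30L
  atts <- vapply(seq_len(reps), function(r) {
    tab <- generate_households(randomized_config(4000, 6000 + r, tau = 0.10))
    m <- fit_propensity(tab, c("wealth", "area"))
    kernel_att(tab, m$scores)$att
  }, numeric(1))
  mc_se <- sd(atts) / sqrt(reps)
  expect_lt(abs(mean(atts) - 0.10), 2 * mc_se)
})

test_that("treated without in-window comparisons are dropped and counted", {
  cb <- codebook(list(area = c("urban", "rural")))
  df <- data.frame(id = as.character(1:6), weight = 1,
                   area = 0L, diet_class = c(1L, 1L, 1L, 0L, 0L, 0L),
                   stunting = c(1L, 0L, 1L, 0L, 1L, 0L))
  tab <- household_table(df, cb)
  s <- c(0.30, 0.31, 0.70, 0.29, 0.33, 0.71)
  expect_no_message(a <- kernel_att(tab, s, bandwidth = 0.05))
  expect_equal(a$n_dropped_nomatch, 0L)  # 0.70 has 0.71 in window
  s2 <- c(0.30, 0.31, 0.50, 0.29, 0.33, 0.70)
  expect_message(a2 <- kernel_att(tab, s2, bandwidth = 0.05), "1 treated")
  expect_equal(a2$n_dropped_nomatch, 1L)
  expect_equal(a2$n_treated, 2L)
})

test_that("balance improves after matching in a confounded design", {
  better <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    tab <- generate_households(synthetic_config(
      n = 4000, seed = 700 + r,
      covariates = list(wealth = list(labels = paste0("q", 1:5),
                                      p = rep(0.2, 5)),
                        area = list(labels = c("urban", "rural"),
                                    p = c(0.4, 0.6))),
      treatment = list(intercept = 0.6,
                       coef = list(wealth = c(0, -0.3, -0.6, -0.9, -1.2),
                                   area = c(-0.4, 0))),
      outcome = list(baseline = 0.2,
                     coef = list(wealth = c(0.06, 0.03, 0, -0.03, -0.06)),
                     effects = list())))
    m <- fit_propensity(tab, c("wealth", "area"))
    sup <- common_support(m$scores, tab$diet_class)
    a <- suppressMessages(kernel_att(tab, m$scores, sup))
    b <- balance_report(m, tab, a)$balance
    before <- mean(abs(b$std_diff_before))
    after <- mean(abs(b$std_diff_after))
    if (after < before) better <- better + 1L
  }
  expect_gte(better / reps, 0.9)
})

test_that("randomized designs start nearly balanced; constants score zero", {
  tab <- generate_households(randomized_config(8000, seed = 71, tau = 0))
  m <- fit_propensity(tab, c("wealth", "area"))
  a <- kernel_att(tab, m$scores)
  b <- balance_report(m, tab, a)$balance
  expect_true(all(abs(b$std_diff_before) < 0.1))
  # a covariate constant in both groups has zero standardized difference
  tb2 <- random_table(200, seed = 72)
  tb2$wealth <- 2L
  m2 <- fit_propensity(tb2, c("area", "educ"))
  a2 <- kernel_att(tb2, m2$scores)
  X <- cbind(m2$X, const = 1)
  m2$X <- X
  b2 <- balance_report(m2, tb2, a2)$balance
  expect_equal(b2$std_diff_before[b2$term == "const"], 0)
  expect_equal(b2$std_diff_after[b2$term == "const"], 0)
})

test_that("the local effect-by-score curve tracks a constant effect", {
  tab <- generate_households(randomized_config(6000, seed = 73, tau = 0.12))
  m <- fit_propensity(tab, c("wealth", "area"))
  a <- kernel_att(tab, m$scores)
  cur <- att_by_pscore_curve(a)
  expect_true(all(abs(cur$local_att - 0.12) < 0.08))
  expect_equal(nrow(cur), a$n_treated)
})

test_that("an effect declining in the score yields a falling curve", {
  neg <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    set.seed(800 + r)
    n <- 3000
    df <- data.frame(id = as.character(seq_len(n)), weight = 1,
                     area = sample(0:1, n, TRUE))
    p <- runif(n, 0.2, 0.8)
    df$diet_class <- rbinom(n, 1, p)
    tau <- 0.3 * (0.8 - p)  # effect falls with the score
    df$stunting <- rbinom(n, 1, 0.2 + tau * df$diet_class)
    tab <- household_table(df, codebook(list(area = c("urban", "rural"))))
    a <- kernel_att(tab, p)
    cur <- att_by_pscore_curve(a)
    sl <- coef(lm(local_att ~ score, data = cur))[2]
    if (sl < 0) neg <- neg + 1L
  }
  expect_gte(neg / reps, 0.95)
})

test_that("degenerate curve inputs are handled", {
  tab <- random_table(40, seed = 74)
  s <- rep(0.5, 40)
  a <- kernel_att(tab, s)
  expect_warning(cur <- att_by_pscore_curve(a), "no variation")
  expect_equal(nrow(cur), 1L)
  tab2 <- random_table(30, seed = 75)
  tab2 <- tab2[1:12, ]
  class(tab2) <- c("household_table", "data.frame")
  a2 <- kernel_att(tab2, runif(12, 0.3, 0.7), bandwidth = 1)
  expect_error(att_by_pscore_curve(a2), "fewer than 10")
})
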