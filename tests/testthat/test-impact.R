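test_that("restricting the ATT to the whole sample is the identity", {
  tab <- generate_households(randomized_config(2000, seed = 81, tau = 0.1))
  m <- fit_propensity(tab, c("wealth", "area"))
  everyone <- profile(character(0), integer(0))
  a_all <- profile_att(everyone, tab, m)
  a_glob <- kernel_att(tab, m$scores)
  expect_equal(a_all$att, a_glob$att, tolerance = 1e-12)
  expect_equal(a_all$se, a_glob$se, tolerance = 1e-12)
})

test_that("profiles without treated or comparison members are inestimable", {
  tab <- toy_fixture()
  tab$diet_class[tab$area == 0L] <- 0L  # no treated urban households
  s <- rep(0.5, nrow(tab))
  expect_null(profile_att(profile("area", 0L), tab, s))
  im <- impact_analysis(tab, c("area", "educ"), 1L, s)
  expect_false(im$estimable[im$profile_key == "area=0"])
  expect_true(is.na(im$att[im$profile_key == "area=0"]))
})

test_that("the impact product behaves at its boundaries", {
  expect_equal(impact(0, 0.5, 0.3)$impact, 0)
  expect_equal(impact(0.1, 0.5, 0.2)$impact, 0.01)
  expect_equal(impact(0.1, 0.5, 0.2)$ate_x, 0.05)
  z <- impact(0.25, 0.6, 1)
  expect_equal(z$impact, z$ate_x)  # whole population: impact = ATE(x)
  expect_error(impact(0.1, 1.5, 0.2), "\\[0, 1\\]")
})

test_that("disjoint exhaustive universes: Eq-2 and Eq-3 denominators agree", {
  tab <- toy_fixture()
  s <- rep(0.5, nrow(tab))
  im <- impact_analysis(tab, c("area", "educ"), 1L, s)
  area <- im[im$profile_key %in% c("area=0", "area=1"), ]
  plain <- impact_coverage(area, tab, overlap_adjust = FALSE)
  adj <- impact_coverage(area, tab, overlap_adjust = TRUE)
  expect_equal(attr(plain, "impact_total"), attr(adj, "impact_total"),
               tolerance = 1e-12)
  expect_equal(plain$impact_coverage, adj$impact_coverage, tolerance = 1e-12)
  expect_equal(sum(adj$impact_coverage), 1, tolerance = 1e-12)
  expect_equal(adj$lambda_impact, 1 - adj$impact_coverage)
})

test_that("a duplicated profile halves its members' adjusted masses", {
  tab <- toy_fixture()
  s <- rep(0.5, nrow(tab))
  im <- impact_analysis(tab, c("area", "educ"), 1L, s)
  one <- im[im$profile_key == "area=1", ]
  dup <- rbind(one, one)
  single <- impact_coverage(one, tab, overlap_adjust = TRUE)
  doubled <- impact_coverage(dup, tab, overlap_adjust = TRUE)
  expect_equal(attr(doubled, "impact_total"), attr(single, "impact_total"),
               tolerance = 1e-12)
})

test_that("a single-profile universe has coverage one", {
  tab <- toy_fixture()
  s <- rep(0.5, nrow(tab))
  im <- impact_analysis(tab, c("area", "educ"), 1L, s)
  one <- impact_coverage(im[im$profile_key == "area=1", ], tab)
  expect_equal(one$impact_coverage, 1, tolerance = 1e-12)
  expect_equal(one$lambda_impact, 0, tolerance = 1e-12)
})

test_that("impact metrics satisfy their algebraic identities", {
  tab <- random_table(400, seed = 82, gamma_weights = TRUE)
  s <- runif(400, 0.2, 0.8)
  im <- impact_analysis(tab, names(tiny_codebook()), 2L, s)
  est <- !is.na(im$att)
  expect_true(any(est))
  expect_equal(im$mu_impact, 1 - im$pr_treated_given_x, tolerance = 1e-12)
  expect_equal(im$impact[est],
               im$att[est] * im$pr_treated_given_x[est] * im$pr_x[est],
               tolerance = 1e-12)
  expect_true(all(abs(im$impact[est]) <= abs(im$att[est]) * im$pr_x[est] + 1e-12))
  expect_true(all(sign(im$impact[est, drop = TRUE]) == sign(im$att[est]) |
                    im$impact[est] == 0))
})

test_that("winning impact profiles match an exhaustive scan", {
  set.seed(83)
  grid <- seq(0, 1, by = 0.1)
  for (r in 1:10) {
    n <- 100
    mets <- data.frame(
      profile_key = sprintf("p=%03d", sample(500, n)),
      lambda_impact = runif(n), mu_impact = runif(n),
      stringsAsFactors = FALSE)
    w <- winning_impact_profiles(mets, grid)
    for (i in seq_along(grid)) {
      ps <- mets$lambda_impact^grid[i] * mets$mu_impact^(1 - grid[i])
      expect_equal(w$psi[i], min(ps))
    }
  }
  # alpha = 0 winner maximizes the treated share (psi reduces to mu)
  w0 <- winning_impact_profiles(
    data.frame(profile_key = c("a=1", "b=1", "c=1"),
               lambda_impact = c(0.9, 0.2, 0.5),
               mu_impact = c(0.1, 0.6, 0.4)), alpha_grid = 0)
  expect_equal(w0$profile_key, "a=1")
  # perfect profile dominates everywhere
  wd <- winning_impact_profiles(
    data.frame(profile_key = c("a=1", "b=1"),
               lambda_impact = c(0, 0.3), mu_impact = c(0, 0.2)))
  expect_true(all(wd$profile_key == "a=1" & wd$psi == 0))
})

test_that("ATT distributions are summarized per minimum-n threshold", {
  set.seed(84)
  mets <- data.frame(profile_key = sprintf("p=%d", 1:300),
                     att = rnorm(300, 0.05, 0.1),
                     n_treated = sample(10:300, 300, TRUE))
  d <- att_distribution_by_min_n(mets)
  expect_equal(nrow(d), 5L)
  expect_equal(d$min_n, c(50, 75, 100, 125, 150))
  expect_true(all(diff(d$n_profiles) <= 0))  # eligibility shrinks with n
  brute <- sum(mets$att < 0 & mets$n_treated > 100) /
    sum(mets$n_treated > 100)
  expect_equal(d$share_negative[d$min_n == 100], brute)
  empty <- att_distribution_by_min_n(mets, thresholds = 1000)
  expect_equal(empty$n_profiles, 0L)
  expect_true(is.na(empty$mean))
})

test_that("planted positive effects shrink the negative share with n", {
  # profiles over region; large regions carry tau = 0.15, small ones 0
  ok <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    taus <- c(0.15, 0.15, 0, 0, 0.15, 0, 0.15, 0)
    tab <- generate_households(region_config(6000, 900 + r, taus))
    m <- fit_propensity(tab, c("region", "wealth"))
    im <- impact_analysis(tab, "region", 1L, m)
    d <- att_distribution_by_min_n(im, thresholds = c(0, 200))
    sn <- d$share_negative
    if (!anyNA(sn) && sn[2] <= sn[1]) ok <- ok + 1L
  }
  expect_gte(ok / reps, 0.7)
})

test_that("the FDR grid is monotone in eligibility and sanely bounded", {
  tab <- generate_households(randomized_config(1500, seed = 85, tau = 0))
  m <- fit_propensity(tab, c("wealth", "area"))
  im <- impact_analysis(tab, c("wealth", "area"), 1L, m)
  fdr <- fdr_tradeoff(tab, c("wealth", "area"), 1L,
                      regressors = c("wealth", "area"), metrics = im,
                      n_grid = c(20, 100), t_grid = c(1.0, 1.645),
                      null_replicates = 4L, seed = 86)
  expect_s3_class(fdr, "fdr_tradeoff")
  expect_equal(nrow(fdr), 4L)
  for (t0 in unique(fdr$t_threshold)) {
    sub <- fdr[fdr$t_threshold == t0, ]
    expect_true(all(diff(sub$n_discoveries[order(sub$min_n)]) <= 0))
  }
  expect_true(all(is.na(fdr$fdr) | (fdr$fdr >= 0 & fdr$fdr <= 1)))
  bh <- fdr_tradeoff(tab, c("wealth", "area"), 1L, metrics = im,
                     n_grid = 20, t_grid = 1.645, method = "bh")
  expect_true(all(is.na(bh$fdr) | (bh$fdr >= 0 & bh$fdr <= 1)))
})

test_that("need and impact coverage correlate when effect tracks need", {
  # effect proportional to the treated share across regions
  taus <- seq(0.02, 0.3, length.out = 8)
  treat_coef <- seq(-0.6, 0.8, length.out = 8)  # need rises with tau
  tab <- generate_households(region_config(20000, seed = 87,
                                           taus = taus,
                                           treat_coef = treat_coef))
  m <- fit_propensity(tab, c("region", "wealth"))
  pm <- polling_analysis(tab, "region", 1L)
  im <- impact_analysis(tab, "region", 1L, m)
  im <- impact_coverage(im, tab)
  nvi <- need_vs_impact(pm, im, t_min = -Inf, min_treated = 1L,
                        positive_only = FALSE)
  expect_gt(nvi$correlation, 0.7)
})

test_that("identical coverage vectors correlate exactly; tiny sets flag NA", {
  pm <- data.frame(profile_key = c("a=1", "b=1", "c=1"),
                   coverage = c(0.2, 0.5, 0.8))
  im <- data.frame(profile_key = c("a=1", "b=1", "c=1"),
                   impact_coverage = c(0.2, 0.5, 0.8),
                   att = c(0.1, 0.1, 0.1), t = c(2, 2, 2),
                   n_treated = c(200, 200, 200))
  nvi <- need_vs_impact(pm, im, t_min = 1.645, min_treated = 100)
  expect_equal(nvi$correlation, 1)
  expect_warning(
    nvi2 <- need_vs_impact(pm, im, t_min = 1.645, min_treated = 1000),
    "fewer than 3")
  expect_true(is.na(nvi2$correlation))
})

test_that("characteristic frequencies count variable-value pairs", {
  im <- data.frame(
    profile_key = c("area=1|educ=0", "area=1|educ=1", "area=0|educ=0"),
    att = c(0.2, 0.3, 0.1), t = c(2, 2, 2), n_treated = c(150, 150, 150))
  cb <- codebook(list(area = c("urban", "rural"),
                      educ = c("none", "primary")))
  ch <- profile_characteristics(im, cb, t_min = 1.645, min_treated = 100)
  expect_equal(ch$share_of_profiles[ch$variable == "area" & ch$value == 1],
               2 / 3)
  expect_equal(ch$label[ch$variable == "educ" & ch$value == 0][1], "none")
})
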