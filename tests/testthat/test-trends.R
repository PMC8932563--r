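test_that("NB trend fit handles flat, short and shifted series", {
  flat <- count_series("X", 2014:2017, rep(1000, 4))
  f <- fit_nb_glm(flat)
  expect_equal(f$beta_year, 0, tolerance = 1e-8)
  expect_equal(f$dev_exp, 0, tolerance = 1e-6)

  # exclusion rule: fewer than 3 points is not fitted
  short <- count_series("X", c(2013, 2017), c(100, 200))
  expect_equal(fit_nb_glm(short)$status, "insufficient_data")
  one_year <- data.frame(colony_id = "X", season_year = c(2017, 2017, 2017),
                         count = c(1, 2, 3))
  expect_equal(fit_nb_glm(one_year)$status, "insufficient_data")

  # slope invariant to shifting all years by a constant
  set.seed(83)
  y <- rnbinom(8, mu = 500 * exp(0.1 * (0:7)), size = 20)
  f1 <- fit_nb_glm(count_series("X", 2000:2007, y))
  f2 <- fit_nb_glm(count_series("X", 2100:2107, y))
  expect_equal(f1$beta_year, f2$beta_year, tolerance = 1e-6)
  expect_equal(f1$dev_exp, f2$dev_exp, tolerance = 1e-6)
})

test_that("NB fit agrees with a Poisson oracle when data are Poisson-like", {
  set.seed(89)
  years <- 2005:2016
  y <- rpois(length(years), 800 * exp(0.08 * (years - 2005)))
  nb <- fit_nb_glm(count_series("X", years, y))
  pois <- stats::glm(y ~ years, family = stats::poisson())
  expect_equal(nb$beta_year, unname(coef(pois)["years"]), tolerance = 1e-4)
  expect_gt(nb$theta, 100)  # dispersion pushed towards the Poisson limit
})

test_that("NB fit recovers a generative slope and self-covers near its nominal rate", {
  # independent oracle run (3000 reps) puts the true Wald self-coverage of
  # this 6-point design at 0.823 +/- 0.007: small-sample undercoverage, so
  # the frozen band is [0.77, 0.88] around the oracle value, not the nominal
  # 0.95.
  set.seed(97)
  res <- replicate(200, {
    cs <- simulate_metapopulation(
      data.frame(colony_id = "X", initial_abundance = 200,
                 log_growth_rate = 0.11, theta = 50),
      years = 2012:2017)[[1]]
    f <- fit_nb_glm(cs)
    c(err = f$beta_year - 0.11,
      hit = isTRUE(f$ci[1] <= 0.11 && 0.11 <= f$ci[2]))
  })
  expect_lt(abs(median(res["err", ])), 0.02)
  expect_gt(mean(res["hit", ]), 0.77)
  expect_lt(mean(res["hit", ]), 0.88)
})

test_that("deviance explained is non-negative and grows with a nested quadratic term", {
  # nested comparison at fixed dispersion (same theta for both fits): with
  # theta re-estimated per model the null deviances differ and monotonicity
  # is not a theorem
  set.seed(101)
  for (i in 1:10) {
    years <- 2000:2009
    y <- rnbinom(10, mu = 700 * exp(0.05 * (years - 2000)), size = 10)
    dat <- data.frame(year = years - 2004.5, count = y)
    lin <- stats::glm(count ~ year, family = MASS::negative.binomial(10),
                      data = dat)
    quad <- stats::glm(count ~ year + I(year^2),
                       family = MASS::negative.binomial(10), data = dat)
    de_lin <- 100 * (1 - lin$deviance / lin$null.deviance)
    de_quad <- 100 * (1 - quad$deviance / quad$null.deviance)
    expect_gte(de_lin, 0)
    expect_gte(de_quad, de_lin - 1e-8)
  }
  # and the package fit reports dev_exp in [0, 100] on these fixtures
  f <- fit_nb_glm(count_series("X", 2000:2009,
                               rnbinom(10, mu = 500, size = 10)))
  expect_gte(f$dev_exp, 0)
  expect_lte(f$dev_exp, 100)
})

test_that("reliability classification reproduces the published spot cases", {
  mk <- function(p, dev, th) {
    structure(list(colony_id = "X", n_obs = 8L, df = 6L, beta_year = 0.1,
                   intercept = 0, se_beta = 0.01, z = 1, p_value = p,
                   ci = c(0, 0.2), dev_exp = dev, theta = th,
                   theta_initial = th, converged = TRUE,
                   status = "converged"),
              class = "trend_fit")
  }
  # Seal Rocks analogue: p = 0.69
  expect_equal(classify_reliability(mk(0.69, 1.9, 24.2)), "not_significant")
  # Wright Rocks analogue: p < 0.10, dev 87.9, theta 2.0 - both modes agree
  expect_equal(classify_reliability(mk(0.001, 87.9, 2.0), "caption_or"),
               "reliable")
  expect_equal(classify_reliability(mk(0.001, 87.9, 2.0), "strict_and"),
               "reliable")
  # Deen Maar analogue: dev 67.6, theta 28.8 - mode-dependent
  expect_equal(classify_reliability(mk(0.001, 67.6, 28.8), "caption_or"),
               "reliable")
  expect_equal(classify_reliability(mk(0.001, 67.6, 28.8), "strict_and"),
               "significant_unreliable")
  # non-fit statuses pass through
  expect_equal(classify_reliability(fit_nb_glm(
    count_series("X", c(2013, 2017), c(1, 2)))), "insufficient_data")
})

test_that("cubic fits interpolate exact cubics and reject flat noise", {
  years <- 2000:2009
  cy <- years - mean(years)
  exact <- 500 + 10 * cy - 2 * cy^2 + 0.5 * cy^3
  # summary.lm warns about the (intentionally) perfect fit
  f <- suppressWarnings(fit_cubic(count_series("X", years, pmax(exact, 0))))
  expect_equal(f$r_squared, 1, tolerance = 1e-8)
  expect_true(f$good_fit)
  expect_equal(unname(f$coefficients["I(cy^3)"]), 0.5, tolerance = 1e-6)

  expect_equal(fit_cubic(count_series("X", 2014:2017, rep(5, 4)))$status,
               "insufficient_data")

  # flat noisy data: good-fit rate stays low (oracle run: ~0.065)
  set.seed(9)
  gf <- replicate(200, fit_cubic(count_series(
    "X", 2000:2009, pmax(0, round(rnorm(10, 500, 50)))))$good_fit)
  expect_lte(mean(gf), 0.15)
})

test_that("rise-peak-decline series favour the cubic over the log-linear GLM", {
  set.seed(11)
  years <- c(1990, 1995, 2000, 2002, 2007, 2013, 2017)
  mu <- 3000 + 1500 * sin((years - 1990) / 27 * pi)  # growth then decline
  wins <- replicate(50, {
    cs <- count_series("SRlike", years, rnbinom(length(years), mu = mu, size = 50))
    fit_cubic(cs)$r_squared > fit_nb_glm(cs)$dev_exp / 100
  })
  expect_gt(mean(wins), 0.9)
})

test_that("OLS regression matches closed forms and permutation behaviour", {
  x <- 1:10
  f <- suppressWarnings(ols_regression(x, 2 * x + 1))  # perfect-fit warning
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_error(ols_regression(rep(1, 5), 1:5), class = "pc_usage_error")
  expect_error(ols_regression(1:2, 1:2), class = "pc_usage_error")

  # permuted responses: r2 distribution centred near 1/(n-1)
  set.seed(5)
  y <- 2 * (1:12) + rnorm(12)
  r2 <- replicate(1000, ols_regression(1:12, sample(y))$r_squared)
  expect_lt(abs(mean(r2) - 1 / 11), 0.01)
})

test_that("growth rate vs abundance regression recovers known structure", {
  # degenerate response: all slopes zero
  fits <- data.frame(colony_id = c("A", "B", "C"), beta_year = c(0, 0, 0))
  ab <- data.frame(colony_id = c("A", "B", "C"), season_year = 2017,
                   estimate = c(100, 1000, 5000))
  expect_equal(rate_vs_abundance(fits, ab)$slope, 0, tolerance = 1e-12)

  # published configuration: 18 colonies, most recent abundance
  reg <- rate_vs_abundance(afs_trend_results(), afs_abundance_history())
  expect_equal(nrow(reg$data), 18)
  expect_lt(reg$slope, 0)
  expect_equal(reg$r_squared, 0.308, tolerance = 0.02)
  expect_lt(reg$p_value, 0.05)
  # fallback rows use the latest available estimate
  expect_equal(reg$data$abundance[reg$data$colony_id == "WM"], 256)

  # synthetic metapopulation: large colonies decline, small grow
  set.seed(103)
  colonies <- data.frame(
    colony_id = paste0("C", 1:12),
    initial_abundance = c(rep(4000, 6), rep(150, 6)),
    log_growth_rate = c(rep(-0.03, 6), rep(0.10, 6)),
    theta = 50)
  series <- simulate_metapopulation(colonies, 2002:2017, seed = 7)
  fits2 <- trend_table(lapply(series, fit_nb_glm))
  ab2 <- do.call(rbind, lapply(series, function(s) {
    data.frame(colony_id = s$colony_id[1], season_year = 2017,
               estimate = s$count[s$season_year == 2017])
  }))
  expect_lt(rate_vs_abundance(fits2, ab2)$slope, 0)
})

test_that("category change trends pool consecutive changes by size class", {
  # all-constant histories: every change 0, slopes 0
  hist_const <- do.call(rbind, lapply(c("A", "B", "C"), function(id) {
    data.frame(colony_id = id, season_year = c(2007, 2013, 2017),
               count = 2000)
  }))
  ref <- data.frame(colony_id = c("A", "B", "C"), estimate = c(2000, 1800, 100))
  out <- suppressWarnings(category_change_trend(hist_const, ref))
  expect_equal(out$large$slope, 0, tolerance = 1e-12)
  expect_true(all(out$large$data$change == 0))

  # synthetic: large sites at -3%/yr, small at +10%/yr
  set.seed(107)
  years <- seq(2002, 2017, by = 5)
  mk_hist <- function(id, n0, rate) {
    data.frame(colony_id = id, season_year = years,
               count = round(n0 * (1 + rate)^(years - 2002) *
                               exp(rnorm(length(years), 0, 0.02))))
  }
  hist2 <- rbind(mk_hist("L1", 5000, -0.03), mk_hist("L2", 4000, -0.03),
                 mk_hist("L3", 3500, -0.03),
                 mk_hist("S1", 100, 0.10), mk_hist("S2", 150, 0.10),
                 mk_hist("S3", 200, 0.10))
  ref2 <- data.frame(colony_id = c("L1", "L2", "L3", "S1", "S2", "S3"),
                     estimate = c(3000, 2500, 2200, 300, 450, 500))
  out2 <- category_change_trend(hist2, ref2)
  expect_lt(mean(out2$large$data$change), 0)
  expect_gt(mean(out2$small$data$change), 0)

  # single-site category carries a df warning (one per degenerate category)
  suppressWarnings(expect_warning(
    category_change_trend(
      rbind(mk_hist("L1", 5000, -0.03), mk_hist("M1", 800, 0)),
      data.frame(colony_id = c("L1", "M1"), estimate = c(3000, 800))),
    class = "pc_df_warning"))
})
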