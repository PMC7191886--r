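test_that("a noiseless line is recovered exactly", {
  x <- seq(-2, 2, length.out = 50)
  fit <- fit_loglog(data.frame(ln_ci = x, ln_cr = 0.7 * x - 1))
  expect_equal(fit$k, 0.7)
  expect_equal(fit$C0, -1)
  expect_equal(fit$R, 1)
  expect_equal(fit$s_resid, 0)
  expect_true(is.na(fit$dw))
  # zero-width confidence band
  band <- confidence_band(fit, c(-1, 0, 1))
  expect_equal(band$lower, band$upper)
})

test_that("OLS matches the hand-evaluated normal equations on the 5-point set", {
  x <- c(0, 1, 2, 3, 4)
  y <- c(-1, -0.2, 0.3, 1.2, 1.7)
  fit <- fit_loglog(data.frame(ln_ci = x, ln_cr = y))
  expect_equal(fit$k, 0.68)   # frozen from the normal-equation solution
  expect_equal(fit$C0, -0.96)
  o <- ols_oracle(x, y)
  expect_sig(fit$k, o$k)
  expect_sig(fit$C0, o$C0)
  expect_sig(fit$se_k, o$se_k)
  expect_sig(fit$se_C0, o$se_C0)
})

test_that("OLS equals the closed form across sizes up to 1e5", {
  set.seed(404)
  for (n in c(10, 250, 5000, 1e5)) {
    x <- rnorm(n, 0, 2)
    y <- 0.6 * x - 1 + rnorm(n, 0, 1.1)
    fit <- fit_loglog(data.frame(ln_ci = x, ln_cr = y))
    o <- ols_oracle(x, y)
    expect_sig(fit$k, o$k, 10)
    expect_sig(fit$C0, o$C0, 10)
    expect_sig(fit$se_k, o$se_k, 10)
    expect_sig(fit$se_C0, o$se_C0, 10)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_loglog(data.frame(ln_ci = c(0, 1), ln_cr = c(0, 1))),
               "at least 3")
  expect_error(fit_loglog(data.frame(ln_ci = rep(1, 5), ln_cr = rnorm(5))),
               "degenerate predictor")
})

test_that("adjusted R^2 reproduces the printed whole-dataset value", {
  expect_equal(round(adjusted_r2(0.765^2, 15120), 3), 0.585)
  expect_equal(adjusted_r2(1, 100), 1)
  expect_equal(adjusted_r2(0.5, 12), 0.45)
  expect_error(adjusted_r2(0.5, 2), "n > m")
  expect_error(adjusted_r2(1.2, 100), "\\[0, 1\\]")
})

test_that("the confidence band is narrowest at the predictor mean", {
  set.seed(11)
  x <- rnorm(200)
  fit <- fit_loglog(data.frame(ln_ci = x, ln_cr = 0.6 * x - 1 + rnorm(200, 0, 0.5)))
  at_mean <- confidence_band(fit, fit$x_mean)
  expect_equal(at_mean$upper - at_mean$lower, 2 * 1.96 * fit$s_fit_min)
  extreme <- fit$x_range[which.max(abs(fit$x_range - fit$x_mean))]
  at_ext <- confidence_band(fit, extreme)
  expect_equal(at_ext$upper - at_ext$lower, 2 * 1.96 * fit$s_fit_max)
  grid <- confidence_band(fit, seq(-2, 2, length.out = 101))
  expect_true(all(grid$upper - grid$lower >= at_mean$upper - at_mean$lower - 1e-12))
  expect_error(confidence_band(fit, 0, level = 1.2), "level")
})

test_that("the Durbin-Watson statistic matches closed forms", {
  expect_equal(durbin_watson(c(1, 2, 3)), 2 / 14)
  alt <- rep(c(1, -1), 50)
  expect_equal(durbin_watson(alt), 4 * 99 / 100) # 3.96 for n = 100
  set.seed(8)
  iid <- rnorm(4000)
  expect_lt(abs(durbin_watson(iid) - 2), 0.15)
  expect_error(durbin_watson(rep(0, 10)), "undefined")
  expect_error(durbin_watson(1), "at least 2")
})

test_that("the Lilliefors test has power and is location/scale invariant", {
  set.seed(19)
  x_exp <- rexp(500)
  null500 <- lilliefors_null_stats(500, n_mc = 2000, seed = 77)
  expect_lt(lilliefors_normality(x_exp, null_stats = null500), 0.001)
  x_norm <- rnorm(500, 3, 2)
  p <- lilliefors_normality(x_norm, null_stats = null500)
  expect_gt(p, 0.01)
  # estimating mean/sd removes location and scale entirely
  expect_equal(lilliefors_normality(x_norm + 100, null_stats = null500), p)
  expect_equal(lilliefors_normality(x_norm * 3, null_stats = null500), p)
  expect_error(lilliefors_normality(rnorm(4), seed = 1), "at least 5")
  expect_error(lilliefors_null_stats(10, 100), "seed is mandatory")
})

test_that("the Monte-Carlo Lilliefors p agrees with the tabulated test", {
  skip_if_not_installed("nortest")
  set.seed(23)
  for (i in 1:3) {
    x <- rnorm(200)
    p_mc <- lilliefors_normality(x, n_mc = 4000, seed = 50 + i)
    p_tab <- nortest::lillie.test(x)$p.value
    expect_lt(abs(p_mc - min(p_tab, 1)) , 0.1)
  }
})

test_that("fits are equivariant under rescaling of concentrations", {
  set.seed(3)
  x <- rnorm(300)
  y <- 0.6 * x - 1 + rnorm(300, 0, 0.4)
  base <- fit_loglog(data.frame(ln_ci = x, ln_cr = y))
  lambda <- 2.5
  # multiplying all c_I by lambda shifts ln_ci by ln(lambda)
  shifted <- fit_loglog(data.frame(ln_ci = x + log(lambda), ln_cr = y))
  expect_sig(shifted$k, base$k, 10)
  expect_sig(shifted$C0, base$C0 - base$k * log(lambda), 10)
  # multiplying all c_R by a constant leaves the slope untouched
  scaled <- fit_loglog(data.frame(ln_ci = x, ln_cr = y + log(lambda)))
  expect_sig(scaled$k, base$k, 10)
})

test_that("coefficients are recovered within their estimated uncertainty", {
  reg <- load_registry()
  sc <- scenario_from_registry(reg, "gamma", match_design = TRUE)
  hits <- 0L
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    pairs <- generate_pairs(sc, seed = 9000 + r, enforce_cr_le_ci = FALSE,
                            apply_cutoffs = FALSE)
    fit <- fit_loglog(pairs)
    ok <- abs(fit$k - sc$k_true) <= 3 * fit$se_k &&
      abs(fit$C0 - sc$C0_true) <= 3 * fit$se_C0
    hits <- hits + ok
  }
  expect_gte(hits, n_rep - 1)
})

test_that("fit_by_group mirrors the per-group fits", {
  tax <- load_taxonomy()
  pairs <- rbind(
    generate_pairs(group_scenario("gamma", 0.8, -0.6, 0.3, n_pairs = 50), seed = 1),
    generate_pairs(group_scenario("eta", 0.7, -1.0, 0.3, n_pairs = 40), seed = 2)
  )
  pairs <- assign_groups(pairs, tax)
  tab <- fit_by_group(pairs, level = "heuristic")
  expect_setequal(tab$group, c("gamma", "eta"))
  direct <- fit_loglog(pairs[pairs$heuristic_group == "eta", ])
  expect_equal(tab$k[tab$group == "eta"], direct$k)
  expect_equal(tab$adj_R2[tab$group == "eta"], direct$adj_R2)
})
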