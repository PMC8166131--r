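# Weight derivation, weighted regression, multimodel averaging, paired
# tests and the scenario / scaling arithmetic.

test_that("empirical weighting reacts to heteroscedasticity and not to its absence", {
  set.seed(21)
  n <- 120
  d <- data.frame(length_y = stats::runif(n, 2, 12),
                  area_ha = stats::runif(n, 0.2, 1.1))
  # homoscedastic: the unweighted candidate is selected or indistinguishable
  d$y <- stats::rnorm(n)
  w0 <- derive_weights(d, "y")
  base_sc <- local({  # score of the unweighted candidate
    r2 <- stats::residuals(stats::lm(y ~ 1, data = d))^2
    max(abs(stats::cor(r2, d$length_y, method = "spearman")),
        abs(stats::cor(r2, d$area_ha, method = "spearman")))
  })
  expect_lte(w0$score, base_sc + 1e-12)
  # variance proportional to 1/length: a nonzero length exponent is chosen
  d$y <- stats::rnorm(n, 0, 1 / sqrt(d$length_y))
  w1 <- derive_weights(d, "y")
  expect_gt(w1$p_length, 0)
  # constant effort -> weight 1 with a note
  d2 <- d; d2$length_y <- 5; d2$area_ha <- 1
  expect_match(derive_weights(d2, "y")$note, "constant")
  # stored defaults reproduce the study's selections
  cfg <- default_weight_config()
  expect_equal(cfg$p_length[cfg$response == "d_gains"], 1/4)
  expect_equal(cfg$p_length[cfg$response == "d_losses"], 1/3)
  expect_equal(cfg$p_length[cfg$response == "d_net"], 1/6)
  expect_equal(cfg$q_area[cfg$response == "d_net"], 1/8)
  expect_equal(cfg$p_length[cfg$response == "d_stem_recruitment"], 0)
})

test_that("weighted regression reduces to OLS under equal weights and recovers slopes", {
  set.seed(31)
  d <- data.frame(x = stats::rnorm(100))
  d$y <- -0.003 * d$x * 100 + stats::rnorm(100, 0, 0.5)
  wr <- weighted_regression(d, "y", "x", weights = rep(2, 100))
  ols <- stats::lm(y ~ x, data = d)
  expect_equal(wr$slope, stats::coef(ols)[["x"]], tolerance = 1e-12)
  expect_equal(wr$ci, unname(stats::confint(ols)["x", ]), tolerance = 1e-12)
  expect_error(weighted_regression(d[1:2, ], "y", "x"), ">= 3")
  # CI coverage of the generating slope over seeds
  hits <- vapply(1:60, function(s) {
    set.seed(s)
    x <- stats::rnorm(100) * 60
    y <- -0.003 * x + stats::rnorm(100, 0, 1.5)
    wr <- weighted_regression(data.frame(x = x, y = y), "y", "x")
    wr$ci[1] <= -0.003 && -0.003 <= wr$ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("two-model averaging matches the hand enumeration", {
  set.seed(41)
  d <- data.frame(x = stats::rnorm(50))
  d$y <- 0.4 * d$x + stats::rnorm(50, 0, 1)
  a <- multimodel_average(d, "y", terms = "x", level = 1)  # keep both models
  f1 <- stats::lm(y ~ 1, data = d)
  z <- (d$x - mean(d$x)) / stats::sd(d$x)
  f2 <- stats::lm(d$y ~ z)
  aic <- c(stats::AIC(f1), stats::AIC(f2))
  w <- exp(-(aic - min(aic)) / 2); w <- w / sum(w)
  expect_equal(sum(a$models$weight), 1)
  expect_equal(sort(a$models$weight), sort(w), tolerance = 1e-9)
  # full average: weight of the x-model times its coefficient
  expect_equal(a$coefficients$estimate[a$coefficients$term == "x"],
               w[2] * stats::coef(f2)[[2]], tolerance = 1e-9)
})

test_that("multimodel averaging ranks a strong drought effect above a null temperature one", {
  set.seed(51)
  n <- 100
  d <- data.frame(d_tas = stats::rnorm(n, 0.3, 0.15),
                  d_mcwd = stats::rnorm(n, 97, 60),
                  pre_tas = stats::rnorm(n, 24.8, 0.5),
                  pre_mcwd = stats::rnorm(n, -250, 40))
  d$d_net <- -0.003 * d$d_mcwd + stats::rnorm(n, 0, 0.3)
  a <- multimodel_average(d, "d_net",
                          terms = c("d_tas", "d_mcwd", "pre_tas", "pre_mcwd"),
                          interactions = c("d_tas:d_mcwd"))
  ct <- a$coefficients
  expect_gt(abs(ct$estimate[ct$term == "d_mcwd"]),
            5 * abs(ct$estimate[ct$term == "d_tas"]))
  # Akaike weights normalize and the confidence set is the smallest >= 0.95
  expect_equal(sum(a$models$weight), 1, tolerance = 1e-12)
  win <- a$models$weight[a$models$in_set]
  expect_gte(sum(win), 0.95)
  expect_lt(sum(win) - min(win), 0.95)
  # standardization is invertible: the full model refit on raw scales
  # matches the standardized coefficients divided by the predictor SDs
  full_std <- stats::lm(d_net ~ scale(d_tas) + scale(d_mcwd) + scale(pre_tas) +
                          scale(pre_mcwd), data = d)
  full_raw <- stats::lm(d_net ~ d_tas + d_mcwd + pre_tas + pre_mcwd, data = d)
  expect_equal(stats::coef(full_std)[[3]] / stats::sd(d$d_mcwd),
               stats::coef(full_raw)[["d_mcwd"]], tolerance = 1e-9)
  expect_error(multimodel_average(d[1:4, ], "d_net",
                                  terms = c("d_tas", "d_mcwd", "pre_tas", "pre_mcwd")),
               "more candidate terms")
})

test_that("interaction terms only enter with both main effects", {
  models <- forestflux:::enumerate_models(c("a", "b", "c"),
                                          c("a:b", "a:c"))
  for (m in models) {
    if ("a:b" %in% m) expect_true(all(c("a", "b") %in% m))
    if ("a:c" %in% m) expect_true(all(c("a", "c") %in% m))
  }
  # 4 subsets without admissible interactions, {ab} and {ac} branch once,
  # {abc} branches over both: 4*1 + 1 + 1 + 2 + 2 + 4 = 13
  expect_equal(length(models), 13L)
})

test_that("paired comparisons handle identity, shifts and degeneracy", {
  x <- c(1, 2, 3, 4)
  p0 <- paired_comparison(x, x)
  expect_equal(p0$mean_diff, 0)
  expect_true(is.na(p0$t))
  p1 <- paired_comparison(x, x + 0.5)
  expect_equal(p1$mean_diff, 0.5)
  expect_true(is.na(p1$p))        # constant shift: zero difference variance
  set.seed(61)
  pre <- stats::rnorm(100); dur <- pre + 0.3 + stats::rnorm(100, 0, 0.1)
  p2 <- paired_comparison(pre, dur)
  expect_lt(p2$p, 1e-6)
  expect_equal(p2$mean_diff, mean(dur - pre))
})

test_that("scenario, scaling and percent-of-stock arithmetic match frozen values", {
  # counterfactual event-window rate from the printed inputs
  expect_equal(scenario_partition(2.7, 1.0, 0.80, 0.51), 0.017, tolerance = 1e-12)
  expect_equal(scenario_partition(2.7, 1.0, 0.8, 0.8), 0.8)
  expect_equal(scenario_partition(2, 2 - 1e-9, 0.8, 0.5), 0.5, tolerance = 1e-5)
  expect_error(scenario_partition(2.7, 2.7, 0.8, 0.5), "shorter")
  # regional scaling
  expect_equal(regional_scaling(0.46, 0.80, 0.51), 0.29325, tolerance = 1e-12)
  expect_equal(regional_scaling(0.46, 0.8, 0.8), 0.46)
  expect_equal(regional_scaling(0.46, 0.8, 0), 0)
  expect_error(regional_scaling(0.46, 0, 0.5), "nonzero")
  # percent of stock
  expect_equal(percent_of_stock(0.29, 164), 0.1768293, tolerance = 1e-6)
  expect_equal(percent_of_stock(0, 164), 0)
  expect_error(percent_of_stock(0.29, 0), "stock")
})
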