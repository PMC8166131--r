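# Observed fluxes, census-interval correction, pre-event means, deltas and
# size-class summaries.

carbonize <- function(cen) stem_carbon(cen, tiny_wd_table(), tiny_height_model())

test_that("observed fluxes follow the hand-computed cases", {
  # one surviving stem gaining carbon over T = 2 y in a 1-ha plot
  cen <- carbonize(toy_census(c(A = 200), c(A = 220)))
  c0 <- cen$carbon_kg[cen$census_date == 2010] / 1000
  c1 <- cen$carbon_kg[cen$census_date == 2012] / 1000
  f <- observed_fluxes(cen, 1)
  expect_equal(f$gains, (c1 - c0) / 2)
  expect_equal(f$losses, 0)
  expect_equal(f$net, f$gains)
  # identical censuses -> all fluxes zero
  cen <- carbonize(toy_census(c(A = 200, B = 300), c(A = 200, B = 300)))
  f <- observed_fluxes(cen, 1)
  expect_equal(f$gains, 0); expect_equal(f$losses, 0); expect_equal(f$net, 0)
  # one death, nothing else changes
  cen <- carbonize(toy_census(c(A = 200, B = 300), c(A = 200, B = NA)))
  cB <- cen$carbon_kg[cen$stem_id == "B" & cen$census_date == 2010] / 1000
  f <- observed_fluxes(cen, 0.5)
  expect_equal(f$losses, cB / (0.5 * 2))
  expect_equal(f$gains, 0)
  expect_equal(f$net, -f$losses)
  expect_error(observed_fluxes(cen, -1), "area")
})

test_that("net = gains - losses holds to machine precision for carbon, stems and basal area", {
  cfg <- sim_config(n_plots = 3, n_clusters = 2, stems_per_ha = 200, seed = 9)
  net <- generate_plot_network(cfg)
  cen <- stem_carbon(net$census, net$wd_table, tiny_height_model())
  for (pid in unique(cen$plot_id)) {
    pc <- cen[cen$plot_id == pid, ]
    area <- net$plots$area_ha[net$plots$plot_id == pid]
    for (val in c("carbon_kg", "ba_cm2")) {
      f <- observed_fluxes(pc, area, value = val)
      expect_equal(f$net, f$gains - f$losses, tolerance = 1e-12)
      expect_equal(f$stem_net, f$stem_recruitment - f$stem_mortality, tolerance = 1e-12)
      fc <- census_interval_correction(f)
      expect_equal(fc$net, fc$gains - fc$losses, tolerance = 1e-12)
      # net fluxes are invariant under the correction
      expect_equal(fc$net, f$net, tolerance = 1e-12)
    }
  }
})

test_that("census-interval correction is bounded below by observed and vanishes with no deaths", {
  # no deaths: corrected recruitment equals observed recruitment
  sim <- local({ set.seed(5); simulate_bdg(n0 = 100, m = 0, b_rate = 3, Tlen = 5) })
  fc <- census_interval_correction(sim$fluxes)
  expect_equal(fc$stem_recruitment, sim$fluxes$stem_recruitment)
  expect_equal(fc$gains, sim$fluxes$gains)
  # with mortality, corrections only increase gains/losses/rates
  set.seed(6)
  sim <- simulate_bdg(n0 = 300, m = 0.03, b_rate = 9, Tlen = 8)
  fc <- census_interval_correction(sim$fluxes)
  expect_gte(fc$gains, sim$fluxes$gains)
  expect_gte(fc$losses, sim$fluxes$losses)
  expect_gte(fc$stem_recruitment, sim$fluxes$stem_recruitment)
  expect_gte(fc$stem_mortality, sim$fluxes$stem_mortality)
  # corrections shrink as T -> 0 (relative adjustment of mortality)
  rel_adj <- function(Tlen) {
    set.seed(7)
    s <- simulate_bdg(n0 = 4000, m = 0.02, b_rate = 80, Tlen = Tlen)
    fc <- census_interval_correction(s$fluxes)
    fc$stem_mortality / s$fluxes$stem_mortality - 1
  }
  expect_lt(rel_adj(0.5), rel_adj(10))
  expect_lt(rel_adj(0.5), 0.01)
  # all stems died -> degenerate interval keeps observed values
  f <- local({ set.seed(8); simulate_bdg(n0 = 5, m = 10, b_rate = 0, Tlen = 5)$fluxes })
  expect_equal(f$S, 0)
  fc <- census_interval_correction(f)
  expect_true(fc$degenerate)
  expect_equal(fc$gains, f$gains)
})

test_that("corrected fluxes match the continuous-time oracle where observed are biased", {
  set.seed(11)
  nrep <- 120
  bias <- replicate(nrep, {
    s <- simulate_bdg(n0 = 250, m = 0.025, b_rate = 6.25, Tlen = 8)
    fc <- census_interval_correction(s$fluxes)
    c(corr = fc$gains - s$true_gains, obs = s$fluxes$gains - s$true_gains,
      corr_l = fc$losses - s$true_losses, obs_l = s$fluxes$losses - s$true_losses)
  })
  # observed gains and losses are biased low; corrected bias is an order
  # of magnitude smaller
  expect_lt(mean(bias["obs", ]), -3 * stats::sd(bias["obs", ]) / sqrt(nrep))
  expect_lt(mean(bias["obs_l", ]), -3 * stats::sd(bias["obs_l", ]) / sqrt(nrep))
  expect_lt(abs(mean(bias["corr", ])), abs(mean(bias["obs", ])) / 5)
  expect_lt(abs(mean(bias["corr_l", ])), abs(mean(bias["obs_l", ])) / 5)
})

test_that("pre-event means are time weighted and deltas signed event minus pre", {
  f <- data.frame(t0 = c(2000, 2002), t1 = c(2002, 2008), T = c(2, 6),
                  gains = c(1, 3), losses = c(0.5, 0.5), net = c(0.5, 2.5),
                  stem_recruitment = c(1, 3), stem_mortality = 0, stem_net = c(1, 3),
                  mortality_pct = 0, stock0 = 100)
  pm <- pre_event_mean(f)
  expect_equal(pm$gains, 2.5)          # (2*1 + 6*3)/8, not the simple mean 2
  expect_equal(pm$T, 8)
  # single interval -> identity; equal lengths -> simple mean
  expect_equal(pre_event_mean(f[1, ])$gains, 1)
  f2 <- f; f2$T <- c(3, 3)
  expect_equal(pre_event_mean(f2)$gains, 2)
  # delta convention: event minus pre (gains 2.59 -> 2.48 gives -0.11)
  pre <- pm; pre$gains <- 2.59; ev <- f[1, ]; ev$gains <- 2.48
  d <- delta_metrics(pre, ev)
  expect_equal(d$d_gains, -0.11)
  # higher event losses -> positive delta losses
  pre$losses <- 1.79; ev$losses <- 1.97
  expect_equal(delta_metrics(pre, ev)$d_losses, 0.18)
  # identical periods -> all deltas zero
  z <- delta_metrics(pre, pre)
  expect_true(all(abs(as.numeric(z)) < 1e-12))
})

test_that("size-class summaries report medians per class and react to size-biased death", {
  d0 <- c(A = 150, B = 160, C = 170, D = 250, E = 300, F = 500)
  d1 <- d0 + c(1, 2, 3, 4, 5, 6)
  names(d1) <- names(d0)
  cen <- toy_census(d0, d1)
  cen$wd_g_cm3 <- 0.6
  s <- size_class_summaries(cen, data.frame(plot_id = "P1", t0 = 2010, t1 = 2012))
  small <- s$classes[s$classes$class == "100-199", ]
  expect_equal(small$median_growth_mm_yr, stats::median(c(1, 2, 3)) / 2)
  expect_equal(s$classes$mortality_pct_yr, rep(0, 3))
  expect_false("400+" %in% s$classes$class[s$classes$n0 == 0])   # empty classes absent
  # killing only small stems lowers the dying median below the surviving one
  d1b <- d1; d1b[c("A", "B")] <- NA
  cenb <- toy_census(d0, d1b); cenb$wd_g_cm3 <- 0.6
  sb <- size_class_summaries(cenb, data.frame(plot_id = "P1", t0 = 2010, t1 = 2012))
  allstems <- sb$classes
  dying <- stats::median(c(150, 160)); surviving <- stats::median(c(170, 250, 300, 500))
  expect_lt(dying, surviving)
  expect_gt(allstems$mortality_pct_yr[allstems$class == "100-199"], 0)
  expect_equal(allstems$mortality_pct_yr[allstems$class == "400+"], 0)
})
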