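# Harmonization, downscaling, MCWD and anomaly summaries.

flat_record <- function(years, tas = 25, pr = 100) {
  g <- expand.grid(month = 1:12, year = years[1]:years[2])
  data.frame(year = g$year, month = g$month, tas_C = tas, pr_mm = pr)
}

test_that("harmonization recovers identity and affine relations exactly", {
  ref <- flat_record(c(1990, 2010), tas = 25)
  ref$tas_C <- 25 + 0.5 * sin(2 * pi * ref$month / 12) + 0.01 * (ref$year - 1990)
  aux <- ref; aux$year <- aux$year  # identical on overlap
  aux_pre <- flat_record(c(1970, 1989)); aux_pre$tas_C <- 24
  h <- harmonize(ref, rbind(aux_pre, aux), value = "tas_C")
  expect_equal(h$model$slope, rep(1, 12), tolerance = 1e-9)
  expect_equal(h$model$intercept, rep(0, 12), tolerance = 1e-9)
  expect_equal(nrow(h$merged), (2010 - 1970 + 1) * 12)
  expect_true(all(h$merged$provenance[h$merged$year < 1990] == "adjusted-auxiliary"))
  # pure offset: auxiliary = reference - 2 reproduces the reference exactly
  aux2 <- rbind(aux_pre, aux); aux2$tas_C <- aux2$tas_C - 2
  h2 <- harmonize(ref, aux2, value = "tas_C")
  merged_overlap <- h2$merged[h2$merged$year >= 1990, ]
  expect_equal(merged_overlap$tas_C, ref$tas_C[order(ref$year, ref$month)],
               tolerance = 1e-9)
  # adjusted auxiliary is mapped back onto the reference scale (24 - 2 + 2)
  expect_equal(h2$merged$tas_C[h2$merged$year == 1980 & h2$merged$month == 1],
               24, tolerance = 1e-9)
})

test_that("harmonization slope estimate is consistent with the OLS sampling law", {
  set.seed(3)
  ref <- flat_record(c(1990, 2009))
  ref$tas_C <- 25 + stats::rnorm(nrow(ref), 0, 1)
  aux <- ref
  aux$tas_C <- 0.9 * ref$tas_C + stats::rnorm(nrow(ref), 0, 0.1)
  h <- harmonize(ref, aux, value = "tas_C")
  # regressing reference on auxiliary: slope ~ 1/0.9 per month, n = 20 y
  expect_equal(mean(h$model$slope), 1 / 0.9, tolerance = 0.02)
  expect_error(harmonize(ref[ref$year < 1991, ], aux, value = "tas_C"), "overlap")
})

test_that("temperature downscaling applies T_diff and the lapse rate", {
  rec <- flat_record(c(1970, 2010))
  rec$tas_C <- 24 + 0.3 * sin(2 * pi * rec$month / 12)
  base <- rec[rec$year <= 2000, ]
  clim <- as.numeric(tapply(base$tas_C, base$month, mean))
  # climatology equals the baseline mean and equal altitudes -> identity
  out <- downscale_temperature(rec, clim, a_cell = 400, a_plot = 400)
  expect_equal(out$tas_C, rec$tas_C, tolerance = 1e-12)
  # 200 m altitude difference -> +1.0 deg C everywhere
  out2 <- downscale_temperature(rec, clim, a_cell = 600, a_plot = 400)
  expect_equal(out2$tas_C, rec$tas_C + 1.0, tolerance = 1e-12)
  # climatology 1 deg cooler than the baseline mean -> record shifted down 1
  out3 <- downscale_temperature(rec, clim - 1, a_cell = 0, a_plot = 0)
  expect_equal(out3$tas_C, rec$tas_C - 1, tolerance = 1e-12)
  expect_error(downscale_temperature(rec, clim[1:11], 0, 0), "12")
  # anomaly preservation: event-minus-baseline differences survive the shift
  d_raw <- mean(rec$tas_C[rec$year == 2010]) - mean(rec$tas_C[rec$year <= 2000])
  d_dn <- mean(out3$tas_C[out3$year == 2010]) - mean(out3$tas_C[out3$year <= 2000])
  expect_equal(d_raw, d_dn, tolerance = 1e-12)
})

test_that("precipitation downscaling is a per-calendar-month ratio", {
  rec <- flat_record(c(1970, 2010))
  rec$pr_mm <- 80 + 10 * rec$month
  base <- rec[rec$year <= 2000, ]
  clim <- as.numeric(tapply(base$pr_mm, base$month, mean))
  expect_equal(downscale_precipitation(rec, clim)$pr_mm, rec$pr_mm, tolerance = 1e-12)
  expect_equal(downscale_precipitation(rec, 2 * clim)$pr_mm, rec$pr_mm / 2,
               tolerance = 1e-12)
  # month-specific routing: only January rescaled when only its climatology changes
  clim2 <- clim; clim2[1] <- clim[1] / 1.2; clim2[7] <- clim[7] / 0.8
  out <- downscale_precipitation(rec, clim2)
  expect_equal(out$pr_mm[out$month == 1], rec$pr_mm[rec$month == 1] * 1.2,
               tolerance = 1e-12)
  expect_equal(out$pr_mm[out$month == 7], rec$pr_mm[rec$month == 7] * 0.8,
               tolerance = 1e-12)
  expect_equal(out$pr_mm[out$month == 3], rec$pr_mm[rec$month == 3], tolerance = 1e-12)
  # zero/zero months get ratio 1; zero climatology with rain is an error
  rec0 <- rec; rec0$pr_mm[rec0$month == 2] <- 0
  clim0 <- as.numeric(tapply(rec0$pr_mm[rec0$year <= 2000], base$month, mean))
  expect_equal(downscale_precipitation(rec0, clim0)$pr_mm[rec0$month == 2],
               rep(0, 41))
  climbad <- clim; climbad[3] <- 0
  expect_error(downscale_precipitation(rec, climbad), "month")
})

test_that("the water-deficit recursion reproduces hand-computed MCWD", {
  # supply matches demand every month -> no deficit
  rec <- flat_record(c(2000, 2002), pr = 100)
  expect_equal(mcwd(rec)$mcwd_mm, rep(0, 2))   # two complete May-April years
  # a rainless year accumulates -1200
  rec0 <- flat_record(c(2000, 2002), pr = 0)
  expect_equal(mcwd(rec0)$mcwd_mm, rep(-1200, 2))
  # ten wet months then 40, 40 -> deficits -60, -120 -> MCWD -120
  rec2 <- flat_record(c(2000, 2001), pr = 100)
  rec2$pr_mm[rec2$year == 2000 & rec2$month %in% c(6, 7)] <- 40
  m <- mcwd(rec2, year_start_month = 5)
  expect_equal(m$mcwd_mm[m$climate_year == 2000], -120)
  # calendar-year convention is switchable
  m2 <- mcwd(rec2, year_start_month = 1)
  expect_equal(m2$mcwd_mm[m2$climate_year == 2000], -120)
  expect_equal(m2$mcwd_mm[m2$climate_year == 2001], 0)
  expect_error(mcwd(rec2[-5, ]), "gaps")
})

test_that("MCWD is translation-covariant and ET providers compose", {
  set.seed(4)
  rec <- flat_record(c(2000, 2005))
  rec$pr_mm <- stats::runif(nrow(rec), 20, 180)
  m1 <- mcwd(rec)
  rec2 <- rec; rec2$pr_mm <- rec$pr_mm + 30
  expect_true(all(mcwd(rec2)$mcwd_mm >= m1$mcwd_mm))
  # a variable-ET provider returning the constant reproduces fixed ET exactly
  m3 <- mcwd(rec, et_provider = function(tas, pr) rep(100, length(pr)))
  expect_identical(m1$mcwd_mm, m3$mcwd_mm)
  expect_identical(mcwd(rec, et_provider = et_constant(100))$mcwd_mm, m1$mcwd_mm)
})

test_that("event summaries take the most negative annual MCWD and dilute anomalies", {
  rec <- flat_record(c(2000, 2017), pr = 100)
  rec$tas_C <- 24
  # one droughted climate-year (2015: May onward short by 25 mm/mo -> -300)
  dr <- rec$year == 2015 & rec$month >= 5 | rec$year == 2016 & rec$month <= 4
  rec$pr_mm[dr] <- 75
  ann <- mcwd(rec)
  s <- event_and_pre_summaries(rec, ann, pre_interval = c(2005, 2014),
                               event_interval = c(2014.5, 2017.2))
  expect_equal(s$mcwd_mm[s$period == "event"], -300)
  expect_equal(s$mcwd_mm[s$period == "pre"], 0)
  # +0.6 deg C only in the event year is diluted over a longer interval
  rec$tas_C[dr] <- 24.6
  s2 <- event_and_pre_summaries(rec, ann, c(2005, 2014), c(2014.5, 2017.2))
  dT <- s2$mean_tas_C[s2$period == "event"] - s2$mean_tas_C[s2$period == "pre"]
  expect_gt(dT, 0.1); expect_lt(dT, 0.6)
  # hand weighting: 12 anomalous months out of the interval's months
  months_in <- sum(month_grid(2014, 2017)$year + (month_grid(2014, 2017)$month - 0.5) / 12 >= 2014.5 &
                   month_grid(2014, 2017)$year + (month_grid(2014, 2017)$month - 0.5) / 12 <= 2017.2)
  expect_equal(dT, 0.6 * 12 / months_in, tolerance = 1e-9)
  expect_error(event_and_pre_summaries(rec, ann, c(1950, 2014), c(2014.5, 2017.2)),
               "span")
})

test_that("regional anomalies recover an injected event signal with 1/sqrt(n) CIs", {
  mk_cell <- function(seed, anom = 0) {
    set.seed(seed)
    rec <- flat_record(c(1970, 2017))
    rec$tas_C <- 24 + stats::rnorm(nrow(rec), 0, 0.3)
    rec$pr_mm <- stats::runif(nrow(rec), 60, 160)
    ev <- rec$year == 2015 & rec$month >= 5 | rec$year == 2016 & rec$month <= 4
    rec$tas_C[ev] <- rec$tas_C[ev] + anom
    rec
  }
  # stationary climate: anomalies straddle zero
  cells0 <- lapply(1:12, mk_cell)
  a0 <- regional_anomalies(cells0, event_year = 2015)
  tas0 <- a0$summary[a0$summary$variable == "tas", ]
  expect_lt(abs(tas0$anomaly_decade), 3 * tas0$anomaly_decade_ci)
  # injected +0.57 deg C recovered
  cells <- lapply(1:12, mk_cell, anom = 0.57)
  a <- regional_anomalies(cells, event_year = 2015)
  tas <- a$summary[a$summary$variable == "tas", ]
  expect_equal(tas$anomaly_decade, 0.57, tolerance = 0.1)
  # CI halves when cell count quadruples (up to sampling noise)
  cells4 <- lapply(1:48, mk_cell, anom = 0.57)
  a4 <- regional_anomalies(cells4, event_year = 2015)
  tas4 <- a4$summary[a4$summary$variable == "tas", ]
  expect_lt(tas4$anomaly_decade_ci, tas$anomaly_decade_ci)
})
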