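# Plot-level climate reconstruction: harmonization of two partially
# overlapping monthly datasets, climatology-based downscaling with a
# lapse-rate altitude adjustment, the maximum cumulative water deficit
# (MCWD), and event / pre-event summaries.
#
# A climate record is a long-format data.frame with columns year, month and
# a value column (tas_C for temperature, pr_mm for precipitation), one row
# per month with no gaps inside its span.

record_span <- function(rec) range(month_to_decimal(rec$year, rec$month))

check_record <- function(rec, value) {
  need <- c("year", "month", value)
  if (!all(need %in% names(rec)))
    stopf("climate record must have columns %s", paste(need, collapse = ", "))
  rec <- rec[order(rec$year, rec$month), ]
  idx <- rec$year * 12L + rec$month
  if (any(diff(idx) != 1L)) stopf("climate record has gaps or duplicates")
  rec
}

#' Harmonize an auxiliary climate dataset against a reference
#'
#' Per calendar month, ordinary least squares of the reference on the
#' auxiliary over their overlap; the fitted coefficients are used to adjust
#' auxiliary values from before the reference span, which are then
#' concatenated with the reference to form one continuous record.
#'
#' @param reference,auxiliary long-format records sharing a value column.
#' @param value name of the value column (`"tas_C"` or `"pr_mm"`).
#' @return list with `model` (data.frame month, slope, intercept, n, r2),
#'   `merged` (continuous record with a `provenance` column:
#'   `"reference"` or `"adjusted-auxiliary"`).
#' @export
harmonize <- function(reference, auxiliary, value = "tas_C") {
  reference <- check_record(reference, value)
  auxiliary <- check_record(auxiliary, value)
  key <- function(r) paste(r$year, r$month)
  ov <- intersect(key(reference), key(auxiliary))
  model <- do.call(rbind, lapply(1:12, function(m) {
    rm_ <- reference[paste(reference$year, reference$month) %in% ov & reference$month == m, ]
    am_ <- auxiliary[paste(auxiliary$year, auxiliary$month) %in% ov & auxiliary$month == m, ]
    if (nrow(rm_) < 2L)
      stopf("harmonization needs >= 2 overlap years for calendar month %d, got %d", m, nrow(rm_))
    am_ <- am_[match(paste(rm_$year, rm_$month), paste(am_$year, am_$month)), ]
    x <- am_[[value]]; y <- rm_[[value]]
    if (stats::var(x) == 0) {            # degenerate: pure offset
      sl <- 1; ic <- mean(y) - mean(x); r2 <- 1
    } else {
      f <- stats::lm(y ~ x)
      sl <- stats::coef(f)[[2]]; ic <- stats::coef(f)[[1]]
      # summary() warns on an essentially perfect fit; that is a valid case here
      r2 <- suppressWarnings(summary(f)$r.squared)
    }
    data.frame(month = m, slope = sl, intercept = ic, n = nrow(rm_), r2 = r2)
  }))
  ref_start <- min(month_to_decimal(reference$year, reference$month))
  pre <- auxiliary[month_to_decimal(auxiliary$year, auxiliary$month) < ref_start, ]
  i <- match(pre$month, model$month)
  pre[[value]] <- model$intercept[i] + model$slope[i] * pre[[value]]
  if (value == "pr_mm") pre[[value]] <- pmax(0, pre[[value]])  # physical floor
  pre$provenance <- rep("adjusted-auxiliary", nrow(pre))
  ref <- reference
  ref$provenance <- "reference"
  merged <- rbind(pre[, c("year", "month", value, "provenance")],
                  ref[, c("year", "month", value, "provenance")])
  merged <- merged[order(merged$year, merged$month), ]
  rownames(merged) <- NULL
  list(model = model, merged = merged)
}

#' Downscale a temperature record to a plot location
#'
#' Per calendar month, the difference between the record's baseline-period
#' mean and the static climatology (T_diff = T_mu - T_clim) is removed from
#' the whole record (T_plot = T - T_diff); the result is then adjusted for
#' the altitude difference between the grid cell used for the climatology
#' interpolation and the plot with a constant lapse rate:
#' T_plotalt = T_plot + lapse * (A_cell - A_plot).
#'
#' @param record continuous temperature record (tas_C).
#' @param climatology numeric vector of 12 monthly climatology means (deg C).
#' @param a_cell,a_plot altitudes (m a.s.l.) of the climatology cell and the
#'   plot.
#' @param baseline two-element year range over which T_mu is computed
#'   (default 1970-2000, the climatology's epoch).
#' @param lapse lapse rate in deg C per m (default 0.005).
#' @return record with tas_C replaced by the plot-level series.
#' @export
downscale_temperature <- function(record, climatology, a_cell, a_plot,
                                  baseline = c(1970, 2000), lapse = 0.005) {
  record <- check_record(record, "tas_C")
  if (length(climatology) != 12L || anyNA(climatology))
    stopf("climatology must supply 12 monthly values")
  base <- record[record$year >= baseline[1] & record$year <= baseline[2], ]
  if (nrow(base) == 0L) stopf("record does not cover the baseline period")
  t_mu <- tapply(base$tas_C, base$month, mean)
  t_diff <- as.numeric(t_mu[as.character(1:12)]) - climatology
  record$tas_C <- record$tas_C - t_diff[record$month] + lapse * (a_cell - a_plot)
  record
}

#' Downscale a precipitation record to a plot location
#'
#' Per calendar month, the ratio of the record's baseline-period mean to the
#' static climatology (P_ratio = P_mu / P_clim) rescales the whole record:
#' P_plot = P * P_ratio.  A month where both the climatology and the
#' baseline mean are zero gets ratio 1; a zero climatology against a nonzero
#' baseline mean is an error.
#'
#' @inheritParams downscale_temperature
#' @param climatology 12 monthly climatology precipitation means (mm/mo).
#' @export
downscale_precipitation <- function(record, climatology, baseline = c(1970, 2000)) {
  record <- check_record(record, "pr_mm")
  if (length(climatology) != 12L || anyNA(climatology))
    stopf("climatology must supply 12 monthly values")
  base <- record[record$year >= baseline[1] & record$year <= baseline[2], ]
  if (nrow(base) == 0L) stopf("record does not cover the baseline period")
  p_mu <- as.numeric(tapply(base$pr_mm, base$month, mean)[as.character(1:12)])
  ratio <- rep(1, 12)
  nz <- climatology > 0
  ratio[nz] <- p_mu[nz] / climatology[nz]
  if (any(!nz & p_mu > 0))
    stopf("zero climatology against nonzero baseline precipitation in month(s) %s",
          paste(which(!nz & p_mu > 0), collapse = ", "))
  record$pr_mm <- record$pr_mm * ratio[record$month]
  record
}

#' Constant monthly evapotranspiration provider
#'
#' @param value mm per month (default 100).
#' @return function `(tas_C, pr_mm) -> mm/mo`, vectorized over months.
#' @export
et_constant <- function(value = 100) {
  force(value)
  function(tas_C = NULL, pr_mm = NULL) {
    n <- max(length(tas_C), length(pr_mm), 1L)
    rep(value, n)
  }
}

#' Temperature-dependent evapotranspiration provider
#'
#' A simple bulk linear formula ET = base + sens * (T - t_ref), clamped at
#' zero.  With the defaults and a record averaging ~0.5 deg C above t_ref it
#' yields a plot-mean ET of about 101 mm/mo, the calibration target for the
#' variable-ET robustness check.
#'
#' @param base mm/mo at the reference temperature.
#' @param sens mm/mo per deg C.
#' @param t_ref reference temperature, deg C.
#' @export
et_temperature <- function(base = 100, sens = 2, t_ref = 24.5) {
  function(tas_C, pr_mm = NULL) pmax(0, base + sens * (tas_C - t_ref))
}

#' Maximum cumulative water deficit by climate-year
#'
#' Runs the water-deficit recursion WD_n = min(0, WD_{n-1} - ET_n + P_n)
#' through each climate-year (default May to April), resetting WD to zero at
#' each year start.  The annual MCWD is the most negative WD within the
#' year; it is always <= 0.
#'
#' @param record continuous record with pr_mm (and tas_C if the ET provider
#'   uses it).
#' @param et_provider function `(tas_C, pr_mm) -> mm/mo`; default constant
#'   100 mm/mo, keeping MCWD temperature independent.
#' @param year_start_month first month of the climate-year (default 5, May).
#' @return data.frame with `climate_year` (the year in which the
#'   climate-year starts) and `mcwd_mm`; only complete 12-month years are
#'   returned.
#' @export
mcwd <- function(record, et_provider = et_constant(100), year_start_month = 5) {
  record <- check_record(record, "pr_mm")
  if (any(record$pr_mm < 0)) stopf("negative precipitation")
  et <- et_provider(record$tas_C %||% rep(NA_real_, nrow(record)), record$pr_mm)
  et <- rep_len(et, nrow(record))
  # climate-year label: months before the start month belong to the previous year
  cy <- ifelse(record$month >= year_start_month, record$year, record$year - 1L)
  out <- lapply(split(seq_len(nrow(record)), cy), function(idx) {
    if (length(idx) != 12L) return(NULL)
    wd <- 0; worst <- 0
    for (i in idx) {
      wd <- wd - et[i] + record$pr_mm[i]
      if (wd >= 0) wd <- 0
      if (wd < worst) worst <- wd
    }
    data.frame(climate_year = cy[idx[1L]], mcwd_mm = worst)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Event and pre-event climate summaries for a plot
#'
#' Pre-event monitoring period: the mean of the annual MCWD values and the
#' mean monthly temperature over the span from the first to the last
#' pre-event census.  Event interval: the single most negative annual MCWD
#' and the mean monthly temperature across the interval (the most extreme
#' conditions the plot experienced while being monitored through the event).
#'
#' @param record plot-level continuous record with tas_C and pr_mm.
#' @param annual_mcwd output of [mcwd()] on the same record.
#' @param pre_interval,event_interval two-element decimal-year vectors
#'   (census dates bounding each period).
#' @return data.frame with one row per period (`"pre"`, `"event"`) and
#'   columns `mean_tas_C`, `mcwd_mm`.
#' @export
event_and_pre_summaries <- function(record, annual_mcwd, pre_interval, event_interval) {
  record <- check_record(record, "pr_mm")
  span <- record_span(record)
  if (pre_interval[1] < span[1] - 1/12 || event_interval[2] > span[2] + 1/12)
    stopf("census dates fall outside the climate record span")
  dec <- month_to_decimal(record$year, record$month)
  mean_t <- function(iv) mean(record$tas_C[dec >= iv[1] & dec <= iv[2]])
  # climate-years whose start falls inside the interval
  yrs_in <- function(iv) annual_mcwd$climate_year >= floor(iv[1]) &
    annual_mcwd$climate_year <= ceiling(iv[2]) - 1L
  pre_m <- mean(annual_mcwd$mcwd_mm[yrs_in(pre_interval)])
  ev <- annual_mcwd$mcwd_mm[yrs_in(event_interval)]
  if (length(ev) == 0L) stopf("no complete climate-year inside the event interval")
  data.frame(period = c("pre", "event"),
             mean_tas_C = c(mean_t(pre_interval), mean_t(event_interval)),
             mcwd_mm = c(pre_m, min(ev)))
}

#' Regional event anomalies across grid cells
#'
#' For each cell: the event climate-year mean temperature, total
#' precipitation and MCWD, compared both with the mean of the prior decade
#' and with a fixed baseline period; region-level means with 95% CIs across
#' cells.
#'
#' @param records named list of cell records (tas_C and pr_mm columns).
#' @param event_year climate-year (start year) of the event.
#' @param baseline_fixed two-element fixed baseline year range
#'   (default 1980-2010).
#' @param year_start_month see [mcwd()].
#' @return list with `cells` (per-cell table) and `summary` (variable,
#'   event mean, decade anomaly, fixed-baseline anomaly, each with 95% CI
#'   half-widths).
#' @export
regional_anomalies <- function(records, event_year, baseline_fixed = c(1980, 2010),
                               year_start_month = 5) {
  per_cell <- lapply(records, function(rec) {
    rec <- check_record(rec, "pr_mm")
    cy <- ifelse(rec$month >= year_start_month, rec$year, rec$year - 1L)
    ann <- data.frame(
      climate_year = as.integer(names(split(rec$tas_C, cy))),
      tas = as.numeric(tapply(rec$tas_C, cy, mean)),
      pr = as.numeric(tapply(rec$pr_mm, cy, sum)),
      n = as.numeric(tapply(rec$pr_mm, cy, length)))
    ann <- ann[ann$n == 12, ]
    ann <- merge(ann, mcwd(rec, year_start_month = year_start_month),
                 by = "climate_year")
    dec <- ann[ann$climate_year >= event_year - 10 & ann$climate_year < event_year, ]
    if (nrow(dec) < 10L) stopf("fewer than 10 complete years in the prior decade")
    fix <- ann[ann$climate_year >= baseline_fixed[1] & ann$climate_year <= baseline_fixed[2], ]
    ev <- ann[ann$climate_year == event_year, ]
    if (nrow(ev) != 1L) stopf("event climate-year %d not covered", event_year)
    data.frame(
      tas_event = ev$tas, tas_dec = ev$tas - mean(dec$tas), tas_fix = ev$tas - mean(fix$tas),
      pr_event = ev$pr, pr_dec = ev$pr - mean(dec$pr), pr_fix = ev$pr - mean(fix$pr),
      mcwd_event = ev$mcwd_mm, mcwd_dec = ev$mcwd_mm - mean(dec$mcwd_mm),
      mcwd_fix = ev$mcwd_mm - mean(fix$mcwd_mm))
  })
  cells <- do.call(rbind, per_cell)
  ci <- function(x) if (length(x) > 1L)
    stats::qt(0.975, length(x) - 1L) * stats::sd(x) / sqrt(length(x)) else NA_real_
  summ <- do.call(rbind, lapply(c("tas", "pr", "mcwd"), function(v) {
    data.frame(variable = v,
               event_mean = mean(cells[[paste0(v, "_event")]]),
               event_ci = ci(cells[[paste0(v, "_event")]]),
               anomaly_decade = mean(cells[[paste0(v, "_dec")]]),
               anomaly_decade_ci = ci(cells[[paste0(v, "_dec")]]),
               anomaly_fixed = mean(cells[[paste0(v, "_fix")]]),
               anomaly_fixed_ci = ci(cells[[paste0(v, "_fix")]]))
  }))
  list(cells = cells, summary = summ)
}
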