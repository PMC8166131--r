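# Demography: per-interval observed and census-interval-bias-corrected
# carbon / basal-area / stem fluxes, time-weighted pre-event summaries,
# delta metrics and size-class breakdowns.

#' Attach allometric quantities to a census table
#'
#' Adds wood density (with taxonomic fallback), modelled height, AGB,
#' carbon and basal area to every measured stem row.  Diameters are stored
#' in mm in census tables and converted to cm for the allometric equations.
#' Modelled heights are used for all stems (measured heights, where they
#' exist, only calibrate the height model).
#'
#' @param census census table with columns diameter_mm, species, genus,
#'   family (per stem).
#' @param wd_table a [wood_density_table()].
#' @param height_model a [fit_height_model()] result.
#' @param carbon_fraction carbon fraction of dry mass (default 0.456).
#' @param palm_fn optional palm allometry hook passed to [stem_agb()].
#' @return census table with columns wd_g_cm3, wd_provenance, height_m,
#'   agb_kg, carbon_kg, ba_cm2.
#' @export
stem_carbon <- function(census, wd_table, height_model,
                        carbon_fraction = 0.456, palm_fn = NULL) {
  # one density per stem, from its (constant) taxonomy
  first <- census[!duplicated(census$stem_id), ]
  wd <- assign_wood_density(first$species, first$genus, first$family, wd_table)
  i <- match(census$stem_id, first$stem_id)
  census$wd_g_cm3 <- wd$wd_g_cm3[i]
  census$wd_provenance <- wd$wd_provenance[i]
  d_cm <- census$diameter_mm / 10
  has <- !is.na(d_cm)
  census$height_m <- NA_real_
  census$height_m[has] <- estimate_height(d_cm[has], height_model)
  census$agb_kg <- NA_real_
  is_palm <- if ("is_palm" %in% names(census)) isTRUE(census$is_palm) else FALSE
  census$agb_kg[has] <- stem_agb(census$wd_g_cm3[has], d_cm[has],
                                 census$height_m[has],
                                 is_palm = if (length(is_palm) > 1) is_palm[has] else is_palm,
                                 palm_fn = palm_fn)
  census$carbon_kg <- to_carbon(census$agb_kg, carbon_fraction)
  census$ba_cm2 <- NA_real_
  census$ba_cm2[has] <- basal_area(d_cm[has])
  census
}

is_alive <- function(status) status %in% c("alive", "recruit")

#' Observed per-interval fluxes for one plot
#'
#' For each pair of consecutive censuses: carbon (or basal-area) gains from
#' survivor growth plus newly recruited stems valued at the closing census,
#' losses as the opening-census value of stems that died, and the stem-count
#' analogues.  `net = gains - losses` holds exactly and equals the rate of
#' change of the live stock.
#'
#' @param census single-plot census table with the value column present.
#' @param area_ha plot area (ha).
#' @param value column to aggregate: `"carbon_kg"` (default) or `"ba_cm2"`.
#' @param scale multiplies the summed value: default 1/1000 turns kg into
#'   Mg; use 1e-4 with `"ba_cm2"` for m^2.
#' @return data.frame of class `interval_fluxes`, one row per interval, with
#'   columns t0, t1, T, N0, NT, S, R_obs, D_obs, gains, losses, net (per ha
#'   per y), stem_recruitment, stem_mortality (stems/ha/y), mortality_pct
#'   (%/y), g_surv (per-survivor annual value growth), c_recruit (mean
#'   per-recruit value at t1) and corrected = FALSE.
#' @export
observed_fluxes <- function(census, area_ha, value = "carbon_kg", scale = 1/1000) {
  check_pos(area_ha, "area_ha")
  dates <- sort(unique(census$census_date))
  if (length(dates) < 2L) stopf("need >= 2 censuses")
  recs <- classify_recruits(census)
  out <- vector("list", length(dates) - 1L)
  for (k in seq_len(length(dates) - 1L)) {
    t0 <- dates[k]; t1 <- dates[k + 1L]
    Tlen <- t1 - t0
    if (Tlen <= 0) stopf("non-positive interval length at censuses %.2f -> %.2f", t0, t1)
    c0 <- census[census$census_date == t0 & is_alive(census$status), ]
    c1 <- census[census$census_date == t1, ]
    alive1 <- c1[is_alive(c1$status), ]
    rec_ids <- recs$stem_id[recs$interval == k]
    init0 <- c0[!c0$stem_id %in% rec_ids, ]            # at-risk initial cohort
    surv <- intersect(init0$stem_id, alive1$stem_id)
    dead <- setdiff(init0$stem_id, alive1$stem_id)
    new1 <- alive1[alive1$stem_id %in% rec_ids, ]
    v0 <- stats::setNames(init0[[value]], init0$stem_id)
    v1 <- stats::setNames(alive1[[value]], alive1$stem_id)
    grow <- sum(v1[surv] - v0[surv]) * scale
    rec_val <- sum(v1[new1$stem_id]) * scale
    loss <- sum(v0[dead]) * scale
    N0 <- nrow(init0); S <- length(surv)
    R_obs <- nrow(new1); D_obs <- length(dead)
    NT <- S + R_obs
    out[[k]] <- data.frame(
      t0 = t0, t1 = t1, T = Tlen, area_ha = area_ha,
      N0 = N0, NT = NT, S = S, R_obs = R_obs, D_obs = D_obs,
      gains = (grow + rec_val) / (area_ha * Tlen),
      losses = loss / (area_ha * Tlen),
      net = (grow + rec_val - loss) / (area_ha * Tlen),
      stock0 = sum(v0) * scale / area_ha,
      stem_recruitment = R_obs / (area_ha * Tlen),
      stem_mortality = D_obs / (area_ha * Tlen),
      stem_net = (R_obs - D_obs) / (area_ha * Tlen),
      mortality_pct = if (N0 > 0 && S > 0) 100 * (1 - (S / N0)^(1 / Tlen))
                      else if (N0 == 0) NA_real_ else 100,
      g_surv = if (S > 0) sum(v1[surv] - v0[surv]) * scale / (S * Tlen) else 0,
      c_recruit = if (R_obs > 0) mean(v1[new1$stem_id]) * scale else 0,
      corrected = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("interval_fluxes", class(res))
  res
}

# helper: (exp(x) - 1)/x with the x -> 0 limit
expm1_over <- function(x) ifelse(abs(x) < 1e-8, 1 + x / 2, expm1(x) / x)

#' Census-interval bias correction of fluxes
#'
#' Under a constant-instantaneous-rates model within each interval
#' (per-capita mortality m = ln(N0/S)/T, per-capita recruitment
#' r = ln(NT/S)/T), accounts for the unobserved events between censuses:
#' stems that recruited and then died (unobserved recruitment and their
#' deaths), and the growth of dying stems prior to death (added to gains,
#' and to losses since it is lost with the stem).  Dying stems of the
#' initial cohort are assigned the truncated-exponential expected death time
#' 1/m - T e^(-mT)/(1 - e^(-mT)); within-interval recruit-deaths are valued
#' at the mean observed recruit value net of the growth difference between
#' surviving and dying recruits (c_recruit - g T/6 to first order).
#' Corrections
#' vanish as T -> 0 or m -> 0, corrected gains/losses/recruitment/mortality
#' are never below observed, and net fluxes are unchanged (the added growth
#' is both produced and lost inside the interval).
#'
#' @param fluxes an [observed_fluxes()] table.
#' @return the table with gains, losses, stem_recruitment and
#'   stem_mortality corrected and `corrected = TRUE`; degenerate intervals
#'   (no survivors) keep observed values and are flagged in the `degenerate`
#'   column.
#' @export
census_interval_correction <- function(fluxes) {
  f <- fluxes
  f$degenerate <- FALSE
  for (k in seq_len(nrow(f))) {
    N0 <- f$N0[k]; S <- f$S[k]; NT <- f$NT[k]
    Tlen <- f$T[k]; A <- f$area_ha[k]
    if (N0 <= 0 || Tlen <= 0) { f$degenerate[k] <- TRUE; next }
    if (S == 0) { f$degenerate[k] <- TRUE; next }   # rates unidentifiable
    m <- log(N0 / S) / Tlen
    r <- log(NT / S) / Tlen
    # total recruits under influx proportional to N(t) = N0 exp((r-m) t)
    R_tot <- if (r <= 0) f$R_obs[k] else
      r * N0 * Tlen * expm1_over((r - m) * Tlen)
    U <- max(0, R_tot - f$R_obs[k])                 # recruited then died
    # expected death time of initial-cohort deaths (truncated exponential)
    tbar <- if (m < 1e-10) Tlen / 2 else
      1 / m - Tlen * exp(-m * Tlen) / (1 - exp(-m * Tlen))
    grow_dying <- f$D_obs[k] * f$g_surv[k] * tbar
    # an observed recruit's census value embeds ~T/2 of post-recruitment
    # growth (uniform entry); a recruit that died inside the interval
    # produced its threshold value plus ~T/3 of growth, hence c_rec - g T/6
    u_val <- U * max(0, f$c_recruit[k] - f$g_surv[k] * Tlen / 6)
    add <- (grow_dying + u_val) / (A * Tlen)
    f$gains[k] <- f$gains[k] + add
    f$losses[k] <- f$losses[k] + add
    f$stem_recruitment[k] <- (f$R_obs[k] + U) / (A * Tlen)
    f$stem_mortality[k] <- (f$D_obs[k] + U) / (A * Tlen)
  }
  f$net <- f$gains - f$losses
  f$stem_net <- f$stem_recruitment - f$stem_mortality
  f$corrected <- !f$degenerate
  f
}

flux_vars <- c("gains", "losses", "net", "stem_recruitment", "stem_mortality",
               "stem_net", "mortality_pct", "stock0")

#' Time-weighted mean of pre-event interval fluxes
#'
#' Each flux variable is averaged over intervals with weights proportional
#' to the interval lengths.
#'
#' @param fluxes interval-flux table (one plot's pre-event intervals).
#' @return one-row data.frame with the weighted means, `T` = total span and
#'   `n_intervals`.
#' @export
pre_event_mean <- function(fluxes) {
  if (nrow(fluxes) == 0L) stopf("no pre-event intervals")
  w <- fluxes$T / sum(fluxes$T)
  out <- as.data.frame(lapply(fluxes[flux_vars], function(x) sum(w * x)))
  out$T <- sum(fluxes$T)
  out$n_intervals <- nrow(fluxes)
  out
}

#' Event-minus-pre delta metrics for one plot
#'
#' @param pre one-row summary from [pre_event_mean()].
#' @param event one-row interval-flux table for the event interval.
#' @return one-row data.frame of differences `d_<var> = event - pre`.
#' @export
delta_metrics <- function(pre, event) {
  out <- as.data.frame(lapply(flux_vars, function(v) event[[v]][1] - pre[[v]][1]))
  names(out) <- paste0("d_", flux_vars)
  out
}

#' Size-class growth, mortality and composition summaries
#'
#' Pools all consecutive census pairs inside a period window across plots.
#' Stems are classified by diameter at the interval start.  Reports, per
#' class: the median annualized survivor growth rate, the annual mortality
#' percentage (from pooled survival over the exposure-weighted mean interval
#' length), and the median diameter and wood density of dying and surviving
#' stems; plus the median wood density of recruiting stems over the whole
#' period (recruits enter at the threshold and are not classed).
#'
#' @param census multi-plot census table (wood density column `wd_g_cm3`
#'   optional; composition medians are NA without it).
#' @param periods data.frame with columns plot_id, t0, t1 delimiting the
#'   period on each plot.
#' @return list with `classes` (per-class table; empty classes are absent
#'   rows) and `recruit_wd_median`.
#' @export
size_class_summaries <- function(census, periods) {
  rows <- list(); rec_wd <- numeric(0)
  for (p in seq_len(nrow(periods))) {
    pc <- census[census$plot_id == periods$plot_id[p], ]
    dates <- sort(unique(pc$census_date))
    dates <- dates[dates >= periods$t0[p] - 1e-9 & dates <= periods$t1[p] + 1e-9]
    if (length(dates) < 2L) next
    recs <- classify_recruits(pc)
    all_dates <- sort(unique(pc$census_date))
    for (k in seq_len(length(dates) - 1L)) {
      t0 <- dates[k]; t1 <- dates[k + 1L]; Tlen <- t1 - t0
      c0 <- pc[pc$census_date == t0 & is_alive(pc$status), ]
      c1 <- pc[pc$census_date == t1, ]
      alive1 <- c1[is_alive(c1$status), ]
      ival <- match(t1, all_dates) - 1L
      rid <- recs$stem_id[recs$interval == ival]
      init <- c0[!c0$stem_id %in% rid, ]
      surv <- init$stem_id %in% alive1$stem_id
      d1 <- alive1$diameter_mm[match(init$stem_id, alive1$stem_id)]
      rows[[length(rows) + 1L]] <- data.frame(
        class = as.character(diameter_class(init$diameter_mm)),
        d0 = init$diameter_mm, surv = surv, Tlen = Tlen,
        rate = (d1 - init$diameter_mm) / Tlen,
        wd = if ("wd_g_cm3" %in% names(init)) init$wd_g_cm3 else NA_real_)
      if ("wd_g_cm3" %in% names(alive1))
        rec_wd <- c(rec_wd, alive1$wd_g_cm3[alive1$stem_id %in% rid])
    }
  }
  if (length(rows) == 0L) stopf("no census pairs inside the requested periods")
  d <- do.call(rbind, rows)
  d <- d[!is.na(d$class), ]
  cls <- do.call(rbind, lapply(c("100-199", "200-399", "400+"), function(cl) {
    x <- d[d$class == cl, ]
    if (nrow(x) == 0L) return(NULL)
    Tbar <- sum(x$Tlen) / nrow(x)
    sfrac <- mean(x$surv)
    data.frame(class = cl, n0 = nrow(x), deaths = sum(!x$surv),
               median_growth_mm_yr = stats::median(x$rate[x$surv], na.rm = TRUE),
               mortality_pct_yr = 100 * (1 - sfrac^(1 / Tbar)),
               median_d_dying = stats::median(x$d0[!x$surv]),
               median_d_surviving = stats::median(x$d0[x$surv]),
               median_wd_dying = stats::median(x$wd[!x$surv]),
               median_wd_surviving = stats::median(x$wd[x$surv]))
  }))
  list(classes = cls,
       recruit_wd_median = if (length(rec_wd)) stats::median(rec_wd) else NA_real_)
}
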