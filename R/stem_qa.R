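# Stem-census quality control: screening of anomalous diameter trajectories,
# interpolation/extrapolation of rejected measurements, single-measurement
# imputation from size-class growth rates, point-of-measurement (POM) changes
# and recruit classification.
#
# A "stem series" is a data.frame with one row per census for one stem,
# sorted by date, with columns census_date (decimal year), diameter_mm,
# pom_m, status and (optionally) provenance.  Census tables (all stems of a
# plot) hold the same columns plus plot_id, stem_id and taxonomy.

GROWTH_MM_YR_MAX <- 40   # annualized increment screen, mm / y (strict >)
SHRINK_MM_MAX <- 5       # per-interval total shrinkage screen, mm (strict >)

#' Diameter size class
#'
#' @param d_mm diameter in mm.
#' @return factor with levels `"100-199"`, `"200-399"`, `"400+"` (NA below
#'   100 mm).
#' @export
diameter_class <- function(d_mm) {
  cut(d_mm, breaks = c(100, 200, 400, Inf), right = FALSE,
      labels = c("100-199", "200-399", "400+"))
}

#' Screen a stem series for anomalous growth or shrinkage
#'
#' An interval is flagged iff its annualized increment exceeds 40 mm/y or
#' its total shrinkage exceeds 5 mm.  Boundary values are not flagged.  When
#' a data-entry error makes an interval satisfy both rules the growth rule
#' is recorded (checked first, for deterministic output).
#'
#' @param series stem series data.frame (>= 2 dated measurements).
#' @return data.frame with columns `from`, `to` (row indices of the interval
#'   endpoints), `rule` (`"growth_gt_40mm_yr"` or `"shrink_gt_5mm"`); zero
#'   rows when nothing is anomalous.
#' @export
flag_anomalous_growth <- function(series) {
  d <- series$diameter_mm
  t <- series$census_date
  meas <- which(!is.na(d))
  if (length(meas) < 2L) return(data.frame(from = integer(0), to = integer(0),
                                           rule = character(0)))
  out <- list()
  for (k in seq_len(length(meas) - 1L)) {
    i <- meas[k]; j <- meas[k + 1L]
    dt <- t[j] - t[i]
    if (dt <= 0)
      stopf("non-positive interval between censuses %.2f and %.2f", t[i], t[j])
    inc <- d[j] - d[i]
    if (inc / dt > GROWTH_MM_YR_MAX) {
      out[[length(out) + 1L]] <- data.frame(from = i, to = j, rule = "growth_gt_40mm_yr")
    } else if (-inc > SHRINK_MM_MAX) {
      out[[length(out) + 1L]] <- data.frame(from = i, to = j, rule = "shrink_gt_5mm")
    }
  }
  if (length(out) == 0L)
    return(data.frame(from = integer(0), to = integer(0), rule = character(0)))
  do.call(rbind, out)
}

# Decide which measurements a set of interval flags indicts.  A measurement
# that closes one flagged interval and opens the next is a spike and is the
# sole suspect for both; an isolated flagged interval indicts its closing
# measurement.
suspect_measurements <- function(series, flags) {
  if (nrow(flags) == 0L) return(integer(0))
  suspects <- integer(0)
  spike <- intersect(flags$to, flags$from)
  suspects <- c(suspects, spike)
  for (k in seq_len(nrow(flags))) {
    if (flags$to[k] %in% spike || flags$from[k] %in% spike) next
    suspects <- c(suspects, flags$to[k])
  }
  sort(unique(suspects))
}

#' Replace flagged diameters by interpolation or extrapolation
#'
#' Flagged measurements are replaced by linear interpolation in time between
#' the nearest accepted measurements, or linear extrapolation from the two
#' nearest accepted measurements at the series ends.  Unflagged values are
#' untouched; provenance is updated.
#'
#' @param series stem series data.frame.
#' @param flags output of [flag_anomalous_growth()].
#' @return corrected stem series with a `provenance` column
#'   (`"measured"`, `"interpolated"` or `"extrapolated"`).
#' @export
correct_flagged <- function(series, flags) {
  if (!"provenance" %in% names(series))
    series$provenance <- ifelse(is.na(series$diameter_mm), NA, "measured")
  if (nrow(flags) == 0L) return(series)
  sus <- suspect_measurements(series, flags)
  meas <- which(!is.na(series$diameter_mm))
  good <- setdiff(meas, sus)
  if (length(good) == 0L)
    stop(structure(class = c("all_flagged", "error", "condition"),
                   list(message = "all measurements flagged; route stem to impute_single_measurement",
                        call = NULL)))
  t <- series$census_date
  d <- series$diameter_mm
  for (i in sus) {
    lo <- good[good < i]; hi <- good[good > i]
    if (length(lo) && length(hi)) {           # interior: interpolate
      a <- max(lo); b <- min(hi)
      d[i] <- d[a] + (d[b] - d[a]) * (t[i] - t[a]) / (t[b] - t[a])
      series$provenance[i] <- "interpolated"
    } else {                                   # end: extrapolate from nearest two
      src <- if (length(lo)) utils::tail(lo, 2L) else utils::head(hi, 2L)
      if (length(src) == 1L) {                 # single good value: carry rate 0
        d[i] <- d[src]
      } else {
        rate <- (d[src[2L]] - d[src[1L]]) / (t[src[2L]] - t[src[1L]])
        anchor <- if (length(lo)) src[2L] else src[1L]
        d[i] <- d[anchor] + rate * (t[i] - t[anchor])
      }
      series$provenance[i] <- "extrapolated"
    }
  }
  series$diameter_mm <- d
  series
}

#' Plot-population growth rates by size class
#'
#' Mean annualized increment for the 100-199 and 200-399 mm classes and the
#' median for the 400+ mm class (few stems), computed over all intervals of
#' all stems with at least two measurements, classified by diameter at the
#' interval start.
#'
#' @param census census table for one plot (or several).
#' @return data.frame with columns `class`, `rate_mm_yr`, `n`.
#' @export
size_class_rates <- function(census) {
  cc <- census[!is.na(census$diameter_mm), ]
  ord <- order(cc$stem_id, cc$census_date)
  sid <- cc$stem_id[ord]; d <- cc$diameter_mm[ord]; t <- cc$census_date[ord]
  same <- which(sid[-1L] == sid[-length(sid)])
  inc <- data.frame(d0 = d[same],
                    rate = (d[same + 1L] - d[same]) / (t[same + 1L] - t[same]))
  if (nrow(inc) == 0L) stopf("no growth intervals available for class rates")
  inc$class <- diameter_class(inc$d0)
  inc <- inc[!is.na(inc$class), ]
  out <- do.call(rbind, lapply(levels(inc$class), function(cl) {
    r <- inc$rate[inc$class == cl]
    if (length(r) == 0L) return(NULL)
    stat <- if (cl == "400+") stats::median(r) else mean(r)
    data.frame(class = cl, rate_mm_yr = stat, n = length(r))
  }))
  out
}

#' Reconstruct a trajectory from a single accurate measurement
#'
#' Applies the plot-population growth rate of the stem's size class (mean
#' rate for 100-199 and 200-399 mm, median for 400+ mm) forwards and
#' backwards in time from the one accepted measurement.
#'
#' @param series stem series with exactly one accepted measurement
#'   (non-NA diameter, or all others flagged).
#' @param class_rates output of [size_class_rates()].
#' @param valid_index row index of the accepted measurement; defaults to the
#'   single non-NA diameter.
#' @return stem series with imputed diameters (provenance `"imputed"`).
#' @export
impute_single_measurement <- function(series, class_rates, valid_index = NULL) {
  if (is.null(class_rates) || nrow(class_rates) == 0L)
    stopf("empty size-class rate summary")
  if (is.null(valid_index)) {
    valid_index <- which(!is.na(series$diameter_mm))
    if (length(valid_index) != 1L)
      stopf("impute_single_measurement expects exactly one accepted measurement, found %d",
            length(valid_index))
  }
  d0 <- series$diameter_mm[valid_index]
  cl <- as.character(diameter_class(d0))
  rate <- class_rates$rate_mm_yr[match(cl, class_rates$class)]
  if (is.na(rate)) stopf("no class rate available for class %s", cl)
  t0 <- series$census_date[valid_index]
  if (!"provenance" %in% names(series)) series$provenance <- "measured"
  idx <- setdiff(seq_len(nrow(series)), valid_index)
  series$diameter_mm[idx] <- d0 + rate * (series$census_date[idx] - t0)
  series$provenance[idx] <- "imputed"
  series$provenance[valid_index] <- "measured"
  series
}

#' Splice a stem series across a point-of-measurement change
#'
#' When the POM moves, growth across the change is represented by a single
#' common annualized rate (the mean of the pre-change and post-change
#' segment rates; the one available rate when a segment is degenerate).
#' Post-change diameters are kept on the new-POM scale and pre-change
#' censuses are re-expressed on that scale by back-projecting from the first
#' post-change measurement at the common rate, so stock differences never
#' register a spurious step.
#'
#' @param series stem series with a `pom_m` column.
#' @return series on a continuous (new-POM) diameter scale; attribute
#'   `common_rate_mm_yr` records the spliced rate (NA when no change).
#' @export
resolve_pom_change <- function(series) {
  pom <- series$pom_m
  n <- nrow(series)
  attr(series, "common_rate_mm_yr") <- NA_real_
  if (n < 2L || length(unique(pom[!is.na(pom)])) <= 1L) return(series)
  chg <- which(diff(pom) != 0) + 1L   # first census measured at the new POM
  if (length(chg) == 0L) return(series)
  k <- chg[1L]
  if (k == 1L) {
    warnf("POM change recorded at the first census; treated as an ordinary measurement")
    return(series)
  }
  t <- series$census_date; d <- series$diameter_mm
  seg_rate <- function(idx) {
    idx <- idx[!is.na(d[idx])]
    if (length(idx) < 2L) return(NA_real_)
    (d[idx[length(idx)]] - d[idx[1L]]) / (t[idx[length(idx)]] - t[idx[1L]])
  }
  r_pre <- seg_rate(seq_len(k - 1L))
  r_post <- seg_rate(k:n)
  common <- mean(c(r_pre, r_post), na.rm = TRUE)
  if (is.nan(common)) common <- 0
  # back-project the pre-change censuses on the new-POM scale
  series$diameter_mm[seq_len(k - 1L)] <- d[k] - common * (t[k] - t[seq_len(k - 1L)])
  series$pom_m <- pom[k]
  attr(series, "common_rate_mm_yr") <- common
  series
}

#' Classify recruits per census interval
#'
#' A stem is a recruit in the first interval at whose closing census its
#' diameter is >= 100 mm having been absent or < 100 mm before.  Stems at or
#' above 100 mm at the first census belong to the initial population.
#'
#' @param census census table for one plot (columns stem_id, census_date,
#'   diameter_mm, status).
#' @return data.frame with columns `stem_id`, `interval` (index, closing at
#'   census interval+1) and `census_date` of the closing census.
#' @export
classify_recruits <- function(census) {
  dates <- sort(unique(census$census_date))
  if (length(dates) < 2L) stopf("need >= 2 censuses to classify recruits")
  over <- !is.na(census$diameter_mm) & census$diameter_mm >= 100
  if (!any(over))
    return(data.frame(stem_id = character(0), interval = integer(0),
                      census_date = numeric(0)))
  first_over <- tapply(census$census_date[over], census$stem_id[over], min)
  ci <- match(as.numeric(first_over), dates)
  rec <- !is.na(ci) & ci > 1L
  data.frame(stem_id = names(first_over)[rec], interval = ci[rec] - 1L,
             census_date = as.numeric(first_over)[rec],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full QC pipeline over a census table
#'
#' Per stem: POM changes are resolved first, the growth/shrinkage screens
#' are applied, flagged measurements are interpolated/extrapolated, and
#' stems left with a single accepted measurement are imputed from the plot's
#' size-class growth rates.
#'
#' @param census census table (one or more plots).
#' @param class_rates optional [size_class_rates()] table; computed from the
#'   data when NULL.
#' @return list with `census` (corrected table, with `provenance`) and `log`
#'   (QA log: stem_id, census_date, rule, old, new).
#' @export
qc_census <- function(census, class_rates = NULL) {
  census$provenance <- ifelse(is.na(census$diameter_mm), NA, "measured")
  logs <- list()
  # vectorized pre-screen: only stems with a suspicious interval, a POM
  # change, or an unmeasured-alive census need the per-stem machinery
  ord <- order(census$stem_id, census$census_date)
  sid <- census$stem_id[ord]
  d <- census$diameter_mm[ord]; t <- census$census_date[ord]
  pom <- if ("pom_m" %in% names(census)) census$pom_m[ord] else rep(1.3, length(d))
  same <- sid[-1L] == sid[-length(sid)]
  inc <- (d[-1L] - d[-length(d)])
  dt <- (t[-1L] - t[-length(t)])
  anom <- same & !is.na(inc) &
    (inc / dt > GROWTH_MM_YR_MAX | -inc > SHRINK_MM_MAX)
  pomchg <- same & !is.na(pom[-1L]) & !is.na(pom[-length(pom)]) &
    pom[-1L] != pom[-length(pom)]
  flagged_ids <- unique(sid[c(which(anom), which(anom) + 1L,
                              which(pomchg), which(pomchg) + 1L)])
  alive_na <- is.na(d) & census$status[ord] %in% "alive"
  flagged_ids <- unique(c(flagged_ids, sid[alive_na]))
  if (length(flagged_ids) == 0L) {
    return(list(census = census,
                log = data.frame(stem_id = character(0), census_date = numeric(0),
                                 rule = character(0), old = numeric(0), new = numeric(0)),
                corrected_fraction = 0))
  }
  if (is.null(class_rates)) class_rates <- size_class_rates(census)
  keep <- !census$stem_id %in% flagged_ids
  pieces <- split(census[!keep, ], census$stem_id[!keep])
  for (nm in names(pieces)) {
    s <- pieces[[nm]][order(pieces[[nm]]$census_date), ]
    if (sum(!is.na(s$diameter_mm)) >= 2L) {
      s <- resolve_pom_change(s)
      flags <- flag_anomalous_growth(s)
      if (nrow(flags) > 0L) {
        old <- s$diameter_mm
        s2 <- tryCatch(correct_flagged(s, flags), all_flagged = function(e) NULL)
        if (is.null(s2)) {
          # every measurement rejected: keep the first and impute the rest
          keep <- which(!is.na(s$diameter_mm))[1L]
          s$diameter_mm[setdiff(which(!is.na(s$diameter_mm)), keep)] <- NA
          s <- impute_single_measurement(s, class_rates, valid_index = keep)
        } else s <- s2
        ch <- which(!is.na(old) & !is.na(s$diameter_mm) & old != s$diameter_mm)
        for (i in ch)
          logs[[length(logs) + 1L]] <- data.frame(
            stem_id = nm, census_date = s$census_date[i],
            rule = flags$rule[1L], old = old[i], new = s$diameter_mm[i])
      }
    } else if (sum(!is.na(s$diameter_mm)) == 1L && nrow(s) > 1L &&
               any(is.na(s$diameter_mm) & s$status %in% "alive")) {
      s <- impute_single_measurement(s, class_rates)
    }
    pieces[[nm]] <- s
  }
  out <- rbind(census[keep, ], do.call(rbind, pieces))
  rownames(out) <- NULL
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(stem_id = character(0), census_date = numeric(0),
               rule = character(0), old = numeric(0), new = numeric(0))
  list(census = out, log = log,
       corrected_fraction = if (sum(!is.na(census$diameter_mm)) > 0)
         nrow(log) / sum(!is.na(census$diameter_mm)) else 0)
}
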