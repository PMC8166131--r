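# Shared fixtures: stem-series builders and the continuous-time
# birth-death-growth simulator used as the independent oracle for the
# census-interval correction.

stem_series <- function(dates, d_mm, pom = 1.3, status = "alive") {
  data.frame(stem_id = "S1", plot_id = "P1",
             census_date = dates, diameter_mm = d_mm,
             pom_m = rep_len(pom, length(dates)),
             status = rep_len(status, length(dates)))
}

# tiny two-census plot: named diameter vectors at t0 and t1 (NA = dead),
# extra stems only in d1 are recruits
toy_census <- function(d0, d1, t0 = 2010, t1 = 2012) {
  ids <- union(names(d0), names(d1))
  rows <- list()
  for (id in names(d0))
    rows[[length(rows) + 1L]] <- data.frame(
      plot_id = "P1", stem_id = id, census_date = t0, diameter_mm = d0[[id]],
      pom_m = 1.3, species = "Gen01 sp001", genus = "Gen01", family = "Fam01",
      status = "alive")
  for (id in ids) {
    v <- if (id %in% names(d1)) d1[[id]] else NA_real_
    st <- if (is.na(v)) "dead" else if (id %in% names(d0)) "alive" else "recruit"
    rows[[length(rows) + 1L]] <- data.frame(
      plot_id = "P1", stem_id = id, census_date = t1, diameter_mm = v,
      pom_m = 1.3, species = "Gen01 sp001", genus = "Gen01", family = "Fam01",
      status = st)
  }
  do.call(rbind, rows)
}

tiny_wd_table <- function() {
  wood_density_table(data.frame(
    taxon = c("Gen01 sp001", "Gen01", "Fam01"),
    rank = c("species", "genus", "family"),
    wd_g_cm3 = c(0.6, 0.58, 0.55)))
}

tiny_height_model <- function() {
  structure(list(a = 45, b = 0.03, c = 0.9, region = "synthetic",
                 rss = 0, n = 0), class = "height_model")
}

# Continuous-time birth-death-growth simulator (independent oracle).
# Initial cohort of n0 stems with per-stem carbon c0, linear growth g
# (carbon/y), exponential deaths at rate m; recruits as a Poisson process
# of rate b_rate entering at carbon c_rec, growing and dying identically.
# Returns the exact integrated fluxes over [0, T] and the two-census
# observed summaries the package sees.
simulate_bdg <- function(n0 = 200, m = 0.02, b_rate = 4, Tlen = 5,
                         g = 0.005, c0 = 0.4, c_rec = 0.06, area = 1) {
  td <- if (m > 0) stats::rexp(n0, m) else rep(Inf, n0)   # death times
  surv <- td > Tlen
  # recruits
  nr <- stats::rpois(1, b_rate * Tlen)
  te <- sort(stats::runif(nr, 0, Tlen))
  tdr <- te + (if (m > 0) stats::rexp(nr, m) else rep(Inf, nr))
  rec_surv <- tdr > Tlen
  # true integrated fluxes
  life0 <- pmin(td, Tlen)
  life_r <- pmin(tdr, Tlen) - te
  true_gains <- sum(g * life0) + sum(c_rec + g * life_r)
  true_losses <- sum((c0 + g * td[!surv])) +
    sum(c_rec + g * (tdr[!rec_surv] - te[!rec_surv]))
  # observed two-census summaries
  S <- sum(surv); D_obs <- n0 - S
  R_obs <- sum(rec_surv)
  obs_gains <- sum(g * Tlen * surv) + sum((c_rec + g * (Tlen - te))[rec_surv])
  obs_losses <- D_obs * c0
  g_surv <- if (S > 0) g else 0                     # survivor growth rate per stem
  c_recruit <- if (R_obs > 0) mean((c_rec + g * (Tlen - te))[rec_surv]) else 0
  fl <- data.frame(
    t0 = 0, t1 = Tlen, T = Tlen, area_ha = area,
    N0 = n0, NT = S + R_obs, S = S, R_obs = R_obs, D_obs = D_obs,
    gains = obs_gains / (area * Tlen), losses = obs_losses / (area * Tlen),
    net = (obs_gains - obs_losses) / (area * Tlen),
    stock0 = n0 * c0 / area,
    stem_recruitment = R_obs / (area * Tlen),
    stem_mortality = D_obs / (area * Tlen),
    stem_net = (R_obs - D_obs) / (area * Tlen),
    mortality_pct = 100 * (1 - (S / n0)^(1 / Tlen)),
    g_surv = g_surv, c_recruit = c_recruit, corrected = FALSE)
  class(fl) <- c("interval_fluxes", class(fl))
  list(fluxes = fl,
       true_gains = true_gains / (area * Tlen),
       true_losses = true_losses / (area * Tlen),
       true_recruits = nr / (area * Tlen),
       true_deaths = (sum(!surv) + sum(!rec_surv)) / (area * Tlen))
}
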