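# Synthetic study generator: a clustered plot network with stem dynamics
# and paired climate records carrying known ground truth, emulating a
# 100-plot African long-term inventory design monitored through the
# 2015-2016 El Nino (two pre-event censuses plus one event census per plot,
# ~425 stems/ha at >= 100 mm, median plot 1 ha in 26 clusters).
#
# Sign convention: the generator's per-plot drought anomaly `d_mcwd` is the
# intensification of the water deficit in mm, positive when the event
# interval is drier than the pre-event mean (d_mcwd = MCWD_pre - MCWD_event,
# both <= 0).  With beta_mcwd = -0.003 Mg C / ha / y per mm a 100-mm deficit
# intensification removes 0.3 Mg C / ha / y from the net flux.

#' Synthetic study configuration
#'
#' Defaults are the emulated study design: 100 plots in 26 clusters,
#' ~425 stems/ha, censuses around 2008.4 / 2014.3 / 2017.1, the El Nino
#' window May 2015 to April 2016, size-class median growth 0.83 / 1.64 /
#' 2.86 mm/y, 1.2 %/y stem mortality, 6.4 recruits/ha/y, event temperature
#' anomaly +0.28 deg C and deficit intensification 97 mm at plot level (the
#' diluted census-interval anomalies), and effects
#' beta_mcwd = -0.003 Mg C/ha/y per mm, beta_temp = 0.
#'
#' @param n_plots,n_clusters network size; `n_plots >= n_clusters >= 1`.
#' @param stems_per_ha expected stem density at >= 100 mm.
#' @param census_years baseline census dates (decimal years, strictly
#'   increasing; jittered per plot); the last is the post-event census.
#' @param event_window two decimal years delimiting the event climate-year.
#' @param baseline_growth named increments mm/y by size class.
#' @param growth_sdlog lognormal sdlog of stem-level growth noise (the
#'   study reports no stem-level growth variance; free parameter).
#' @param baseline_mortality annual instantaneous per-capita mortality.
#' @param baseline_recruitment recruits per ha per y.
#' @param beta_mcwd,beta_temp effects of the drought intensification (mm)
#'   and temperature anomaly (deg C) on the event-interval net carbon flux
#'   (Mg C/ha/y per unit).
#' @param noise_sd residual plot-level spread of the injected effect.
#' @param d_mcwd_mean,d_mcwd_sd,d_tas_mean,d_tas_sd distribution of the
#'   plot-level anomalies (half the variance at cluster level).
#' @param event_mortality_factor multiplier on mortality during the event
#'   interval (default 1: effects enter through the growth channel).
#' @param measurement_error_rate fraction of diameter measurements hit by a
#'   gross field error (default 0: clean data).
#' @param diameter_exp_mean mean of the shifted-exponential initial diameter
#'   distribution, mm above the 100-mm threshold; the default 165 gives a
#'   standing stock of ~164 Mg C/ha at 425 stems/ha, the large-tree-dominated
#'   structure the network emulates.
#' @param n_species species-pool size; `wd_mean`, `wd_sd` its wood-density
#'   spread (g cm^-3).
#' @param seed integer seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_plots = 100, n_clusters = 26,
                       stems_per_ha = 425,
                       census_years = c(2008.4, 2014.3, 2017.1),
                       event_window = c(2015 + 4/12, 2016 + 4/12),
                       baseline_growth = c("100-199" = 0.83, "200-399" = 1.64,
                                           "400+" = 2.86),
                       growth_sdlog = 0.5,
                       baseline_mortality = 0.012,
                       baseline_recruitment = 6.4,
                       beta_mcwd = -0.003, beta_temp = 0,
                       noise_sd = 0.25,
                       d_mcwd_mean = 97, d_mcwd_sd = 60,
                       d_tas_mean = 0.28, d_tas_sd = 0.15,
                       event_mortality_factor = 1,
                       measurement_error_rate = 0,
                       diameter_exp_mean = 165,
                       n_species = 60, wd_mean = 0.63, wd_sd = 0.12,
                       seed = 1L) {
  if (n_plots < 1) stopf("n_plots must be >= 1")
  if (n_clusters < 1 || n_clusters > n_plots)
    stopf("n_clusters must satisfy n_plots >= n_clusters >= 1")
  if (length(census_years) < 3)
    stopf("census_years must hold >= 3 dates (two pre-event censuses and one after)")
  if (any(diff(census_years) <= 0)) stopf("census_years must be strictly increasing")
  for (nm in c("stems_per_ha", "growth_sdlog"))
    check_pos(get(nm), nm)
  for (nm in c("baseline_mortality", "baseline_recruitment",
               "event_mortality_factor", "measurement_error_rate"))
    if (get(nm) < 0) stopf("'%s' must be >= 0", nm)
  if (any(baseline_growth < 0)) stopf("'baseline_growth' rates must be >= 0")
  structure(as.list(environment()), class = "sim_config")
}

plot_seed <- function(config, j, purpose = 0L) {
  (config$seed * 10007L + j * 7919L + purpose * 104729L) %% 2147483647L
}

# true generating allometry used internally for effect calibration
true_height <- function(d_cm) 45 * (1 - exp(-0.03 * d_cm^0.9))
true_carbon_kg <- function(d_mm, rho) {
  d_cm <- d_mm / 10
  0.456 * 0.0673 * (rho * d_cm^2 * true_height(d_cm))^0.976
}

make_species_pool <- function(config) {
  n_fam <- max(3L, config$n_species %/% 8L)
  n_gen <- max(n_fam, config$n_species %/% 3L)
  fam <- sprintf("Fam%02d", seq_len(n_fam))
  gen_fam <- sample(fam, n_gen, replace = TRUE)
  gen <- sprintf("Gen%02d", seq_len(n_gen))
  sp_gen <- sample(seq_len(n_gen), config$n_species, replace = TRUE)
  fam_eff <- stats::rnorm(n_fam, 0, config$wd_sd * 0.5)
  gen_eff <- stats::rnorm(n_gen, 0, config$wd_sd * 0.6)
  sp_eff <- stats::rnorm(config$n_species, 0, config$wd_sd * 0.6)
  wd <- config$wd_mean + fam_eff[match(gen_fam[sp_gen], fam)] +
    gen_eff[sp_gen] + sp_eff
  wd <- pmin(1.2, pmax(0.2, wd))
  data.frame(species = sprintf("Gen%02d sp%03d", sp_gen, seq_len(config$n_species)),
             genus = gen[sp_gen], family = gen_fam[sp_gen], wd_g_cm3 = wd)
}

pool_to_wd_table <- function(pool, drop_species_frac = 0.15) {
  # some species lack species-level entries so the genus/family fallback is
  # exercised on realistic data
  keep <- seq_len(nrow(pool)) > ceiling(drop_species_frac * nrow(pool))
  sp <- data.frame(taxon = pool$species[keep], rank = "species",
                   wd_g_cm3 = pool$wd_g_cm3[keep])
  ge <- stats::aggregate(wd_g_cm3 ~ genus, pool, mean)
  fa <- stats::aggregate(wd_g_cm3 ~ family, pool, mean)
  wood_density_table(rbind(
    sp,
    data.frame(taxon = ge$genus, rank = "genus", wd_g_cm3 = ge$wd_g_cm3),
    data.frame(taxon = fa$family, rank = "family", wd_g_cm3 = fa$wd_g_cm3)))
}

grow_increment <- function(config, d_mm, Tlen, factor = 1) {
  cl <- as.character(diameter_class(d_mm))
  rate <- config$baseline_growth[cl]
  rate[is.na(rate)] <- config$baseline_growth[["100-199"]]
  mult <- stats::rlnorm(length(d_mm), -config$growth_sdlog^2 / 2, config$growth_sdlog)
  pmax(0, rate * mult * Tlen * factor)
}

#' Generate a synthetic plot network with known ground truth
#'
#' Simulates every plot's stem trajectories across its censuses: size-class
#' growth with lognormal stem noise, binomial survival and Poisson
#' recruitment from the configured annual instantaneous rates, and an
#' event-interval perturbation whose expected change in the net carbon flux
#' is beta_mcwd * d_mcwd + beta_temp * d_tas + noise, injected through the
#' growth channel (see the methods vignette).
#'
#' @param config a [sim_config()].
#' @param plots optional externally supplied plot metadata (advanced).
#' @return list with `census` (all plots, census CSV dialect columns),
#'   `plots` (metadata: plot_id, cluster, area_ha, altitude_m,
#'   cell_altitude_m, census dates), `wd_table`, `species_pool`,
#'   `height_pairs` (D_cm, H_m calibration sample from the true Weibull
#'   law), and `truth` (per-plot d_mcwd, d_tas, delta_true, pre-event
#'   climate, plus the generating betas).
#' @export
generate_plot_network <- function(config, plots = NULL) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  set.seed(config$seed)
  pool <- make_species_pool(config)
  wd_table <- pool_to_wd_table(pool)
  # height calibration sample from the generating law
  Dh <- stats::runif(500, 10, 150)
  height_pairs <- data.frame(D_cm = Dh,
                             H_m = pmax(2, true_height(Dh) + stats::rnorm(500, 0, 2)))
  ncl <- config$n_clusters
  clus <- data.frame(
    cluster = seq_len(ncl),
    dmcwd = config$d_mcwd_mean + stats::rnorm(ncl, 0, config$d_mcwd_sd * sqrt(0.5)),
    dtas = config$d_tas_mean + stats::rnorm(ncl, 0, config$d_tas_sd * sqrt(0.5)),
    pre_tas = stats::rnorm(ncl, 24.8, 0.6),
    pre_mcwd = -250 + stats::rnorm(ncl, 0, 40),
    altitude = stats::runif(ncl, 100, 700))
  census_list <- vector("list", config$n_plots)
  plot_rows <- vector("list", config$n_plots)
  truth_rows <- vector("list", config$n_plots)
  for (j in seq_len(config$n_plots)) {
    set.seed(plot_seed(config, j))
    cl <- ((j - 1L) %% ncl) + 1L
    area <- if (stats::runif(1) < 0.55) 1.0 else round(stats::runif(1, 0.2, 1.1), 2)
    dates <- config$census_years + stats::rnorm(length(config$census_years), 0, 0.15)
    dates <- sort(dates)
    # keep the last pre-event census before, and the final census after, the window
    dates[length(dates) - 1L] <- min(dates[length(dates) - 1L], config$event_window[1] - 0.1)
    dates[length(dates)] <- max(dates[length(dates)], config$event_window[2] + 0.1)
    d_mcwd <- clus$dmcwd[cl] + stats::rnorm(1, 0, config$d_mcwd_sd * sqrt(0.5))
    d_tas <- clus$dtas[cl] + stats::rnorm(1, 0, config$d_tas_sd * sqrt(0.5))
    delta_true <- config$beta_mcwd * d_mcwd + config$beta_temp * d_tas +
      stats::rnorm(1, 0, config$noise_sd)
    n0 <- stats::rpois(1, area * config$stems_per_ha)
    # stem state as parallel vectors (ids are integers until assembly)
    s_sp <- sample.int(nrow(pool), n0, replace = TRUE)
    s_d <- 100 + pmin(1400, stats::rexp(n0, 1 / config$diameter_exp_mean))
    s_alive <- rep(TRUE, n0)
    next_id <- n0 + 1L
    # census-row accumulators
    r_id <- list(seq_len(n0)); r_date <- list(rep(dates[1L], n0))
    r_d <- list(s_d); r_status <- list(rep("alive", n0))
    n_int <- length(dates) - 1L
    for (k in seq_len(n_int)) {
      Tlen <- dates[k + 1L] - dates[k]
      is_event <- (k == n_int)
      m <- config$baseline_mortality *
        (if (is_event) config$event_mortality_factor else 1)
      f_growth <- 1
      if (is_event && delta_true != 0) {
        # calibrate the growth multiplier so the expected change in the
        # plot's carbon-gain rate equals delta_true: solve
        # E[gains(f)] - E[gains(1)] = delta_true, with survivor weighting
        dl <- s_d[s_alive]; wl <- pool$wd_g_cm3[s_sp[s_alive]]
        base_inc <- config$baseline_growth[as.character(diameter_class(dl))]
        base_inc[is.na(base_inc)] <- config$baseline_growth[["100-199"]]
        c0 <- true_carbon_kg(dl, wl)
        surv_w <- exp(-m * Tlen)
        # average over the lognormal stem-noise multiplier (carbon is convex
        # in the increment) with a deterministic quantile midpoint rule
        qm <- stats::qlnorm(seq(0.05, 0.95, by = 0.1),
                            -config$growth_sdlog^2 / 2, config$growth_sdlog)
        gains_at <- function(f) {
          tot <- 0
          for (mu in qm)
            tot <- tot + sum(true_carbon_kg(dl + f * mu * base_inc * Tlen, wl) - c0)
          surv_w * tot / length(qm) / 1000 / (area * Tlen)
        }
        target <- gains_at(1) + delta_true
        if (gains_at(0.01) < target && target < gains_at(5)) {
          f_growth <- stats::uniroot(function(f) gains_at(f) - target,
                                     c(0.01, 5), tol = 1e-6)$root
        } else f_growth <- if (target <= gains_at(0.01)) 0.01 else 5
      }
      # survival and growth of the standing cohort
      live_idx <- which(s_alive)
      survives <- stats::runif(length(live_idx)) < exp(-m * Tlen)
      inc <- grow_increment(config, s_d[live_idx], Tlen, f_growth)
      s_d[live_idx[survives]] <- s_d[live_idx[survives]] + inc[survives]
      s_alive[live_idx[!survives]] <- FALSE
      dead_idx <- live_idx[!survives]
      # recruitment: uniform entry times, exponential survival to the census
      nr <- stats::rpois(1, config$baseline_recruitment * area * Tlen)
      rec_ids <- integer(0)
      if (nr > 0) {
        entry <- stats::runif(nr, 0, Tlen)
        keep <- stats::runif(nr) < exp(-m * (Tlen - entry))
        nk <- sum(keep)
        if (nk > 0) {
          dt_rec <- Tlen - entry[keep]
          dr <- 100 + grow_increment(config, rep(100, nk), dt_rec, f_growth)
          rec_ids <- seq.int(next_id, next_id + nk - 1L)
          next_id <- next_id + nk
          s_sp <- c(s_sp, sample.int(nrow(pool), nk, replace = TRUE))
          s_d <- c(s_d, dr)
          s_alive <- c(s_alive, rep(TRUE, nk))
        }
      }
      surv_idx <- live_idx[survives]
      ids_k <- c(surv_idx, dead_idx, rec_ids)
      r_id[[k + 1L]] <- ids_k
      r_date[[k + 1L]] <- rep(dates[k + 1L], length(ids_k))
      r_d[[k + 1L]] <- c(s_d[surv_idx], rep(NA_real_, length(dead_idx)), s_d[rec_ids])
      r_status[[k + 1L]] <- c(rep("alive", length(surv_idx)),
                              rep("dead", length(dead_idx)),
                              rep("recruit", length(rec_ids)))
    }
    ids <- unlist(r_id)
    spv <- s_sp[ids]
    census <- data.frame(
      plot_id = sprintf("P%03d", j),
      stem_id = sprintf("P%03d-S%05d", j, ids),
      census_date = unlist(r_date), diameter_mm = unlist(r_d), pom_m = 1.3,
      species = pool$species[spv], genus = pool$genus[spv],
      family = pool$family[spv], status = unlist(r_status),
      stringsAsFactors = FALSE)
    if (config$measurement_error_rate > 0) {
      meas <- which(!is.na(census$diameter_mm))
      hit <- meas[stats::runif(length(meas)) < config$measurement_error_rate]
      census$diameter_mm[hit] <- census$diameter_mm[hit] +
        sample(c(-1, 1), length(hit), TRUE) * stats::runif(length(hit), 60, 200)
    }
    census_list[[j]] <- census
    plot_rows[[j]] <- data.frame(
      plot_id = sprintf("P%03d", j), cluster = cl, area_ha = area,
      altitude_m = clus$altitude[cl] + stats::rnorm(1, 0, 30),
      cell_altitude_m = clus$altitude[cl],
      census_dates = I(list(dates)))
    truth_rows[[j]] <- data.frame(
      plot_id = sprintf("P%03d", j), cluster = cl,
      d_mcwd = d_mcwd, d_tas = d_tas, delta_true = delta_true,
      pre_tas = clus$pre_tas[cl], pre_mcwd = clus$pre_mcwd[cl])
  }
  truth <- do.call(rbind, truth_rows)
  truth$beta_mcwd <- config$beta_mcwd
  truth$beta_temp <- config$beta_temp
  list(census = do.call(rbind, census_list),
       plots = do.call(rbind, plot_rows),
       wd_table = wd_table, species_pool = pool,
       height_pairs = height_pairs,
       truth = truth, config = config)
}

#' Generate paired synthetic climate records with known truth
#'
#' One grid cell per cluster.  The monthly truth (1970-2017) carries a
#' bimodal seasonal precipitation cycle, a warming trend, and the
#' configured event-window anomalies (additive on temperature,
#' multiplicative fractional reduction on precipitation).  Two datasets are
#' derived per cell and variable: the reference covers the later span and
#' the auxiliary the full early span, related to the truth by a known
#' per-month affine map plus noise.  The static climatology is the
#' 1970-2000 monthly mean of the truth plus a known plot-level offset.
#'
#' @param config a [sim_config()].
#' @param plots optional plot metadata from [generate_plot_network()]
#'   (generated afresh when NULL) used for plot-level climatology offsets.
#' @param event_tas_anomaly,event_pr_reduction event-window anomalies for
#'   the May-April event year (deg C added; fraction of precipitation
#'   removed).
#' @param affine known per-dataset relationship `list(slope, intercept,
#'   noise_sd)` of the auxiliary to the truth.
#' @return list with `cells` (per cluster: `truth`, `reference`,
#'   `auxiliary` records for tas and pr), `climatology` (per plot: 12
#'   monthly tas/pr values), `plot_truth` (configured anomalies and
#'   offsets) and spans.
#' @export
generate_climate <- function(config, plots = NULL,
                             event_tas_anomaly = 0.6, event_pr_reduction = 0.18,
                             affine = list(tas = list(slope = 0.95, intercept = 1.2, noise_sd = 0.15),
                                           pr = list(slope = 1.1, intercept = -5, noise_sd = 8))) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  set.seed(plot_seed(config, 0L, purpose = 3L))
  if (is.null(plots)) plots <- generate_plot_network(config)$plots
  span <- c(1970L, 2017L)
  ev <- config$event_window
  if (ev[1] < span[1] || ev[2] > span[2] + 1) stopf("event window outside the record span")
  seas_p <- c(50, 55, 80, 140, 160, 70, 40, 55, 130, 180, 160, 80) * 1.25
  grid <- month_grid(span[1], span[2])
  dec <- month_to_decimal(grid$year, grid$month)
  in_event <- dec >= ev[1] & dec <= ev[2]
  cells <- lapply(seq_len(config$n_clusters), function(cl) {
    set.seed(plot_seed(config, cl, purpose = 4L))
    t_base <- 24.0 + stats::rnorm(1, 0, 0.5)
    tas <- t_base + 1.2 * sin(2 * pi * (grid$month - 3) / 12) +
      0.015 * (grid$year - 1970) + stats::rnorm(nrow(grid), 0, 0.25)
    tas[in_event] <- tas[in_event] + event_tas_anomaly
    pr <- pmax(0, seas_p[grid$month] * stats::rlnorm(nrow(grid), -0.02, 0.2))
    pr[in_event] <- pr[in_event] * (1 - event_pr_reduction)
    truth <- data.frame(cell_id = cl, year = grid$year, month = grid$month,
                        tas_C = tas, pr_mm = pr)
    mk <- function(value, spn, aff) {
      r <- truth[truth$year >= spn[1] & truth$year <= spn[2],
                 c("cell_id", "year", "month", value)]
      r
    }
    ref_t <- mk("tas_C", c(1979, 2017))
    aux_t <- mk("tas_C", c(1970, 2016))
    aux_t$tas_C <- (aux_t$tas_C - affine$tas$intercept) / affine$tas$slope +
      stats::rnorm(nrow(aux_t), 0, affine$tas$noise_sd)
    ref_p <- mk("pr_mm", c(1998, 2017))
    aux_p <- mk("pr_mm", c(1970, 2003))
    aux_p$pr_mm <- pmax(0, (aux_p$pr_mm - affine$pr$intercept) / affine$pr$slope +
                          stats::rnorm(nrow(aux_p), 0, affine$pr$noise_sd))
    list(truth = truth, reference_tas = ref_t, auxiliary_tas = aux_t,
         reference_pr = ref_p, auxiliary_pr = aux_p)
  })
  names(cells) <- as.character(seq_len(config$n_clusters))
  # plot climatology: 1970-2000 truth mean + known plot offset
  set.seed(plot_seed(config, 0L, purpose = 5L))
  plot_truth <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
    cl <- plots$cluster[i]
    tr <- cells[[cl]]$truth
    base <- tr[tr$year >= 1970 & tr$year <= 2000, ]
    t_off <- stats::rnorm(1, 0, 0.4)
    p_fac <- exp(stats::rnorm(1, 0, 0.05))
    data.frame(plot_id = plots$plot_id[i], cluster = cl,
               tas_offset = t_off, pr_factor = p_fac,
               event_tas_anomaly = event_tas_anomaly,
               event_pr_reduction = event_pr_reduction)
  }))
  climatology <- lapply(seq_len(nrow(plots)), function(i) {
    cl <- plots$cluster[i]
    tr <- cells[[cl]]$truth
    base <- tr[tr$year >= 1970 & tr$year <= 2000, ]
    list(tas = as.numeric(tapply(base$tas_C, base$month, mean)) -
           plot_truth$tas_offset[i],
         pr = as.numeric(tapply(base$pr_mm, base$month, mean)) /
           plot_truth$pr_factor[i])
  })
  names(climatology) <- plots$plot_id
  list(cells = cells, climatology = climatology, plot_truth = plot_truth,
       span = span, event_window = ev)
}
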