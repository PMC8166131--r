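# End-to-end orchestration: synthetic network -> QC -> allometry ->
# fluxes -> deltas -> attribution -> paired comparisons, plus the
# sensitivity harness over the study's methodological variants.

attribution_terms <- function() {
  list(main = c("d_tas", "d_mcwd", "pre_tas", "pre_mcwd"),
       interactions = c("d_tas:d_mcwd", "d_tas:pre_tas", "d_mcwd:pre_mcwd"))
}

delta_responses <- c("d_net", "d_gains", "d_losses",
                     "d_stem_net", "d_stem_recruitment", "d_stem_mortality")

weights_for_response <- function(obs, response, weighting) {
  if (identical(weighting, "none")) return(rep(1, nrow(obs)))
  if (identical(weighting, "derive"))
    return(derive_weights(obs, response)$weights)
  cfg <- default_weight_config()
  i <- match(response, cfg$response)
  if (is.na(i)) return(rep(1, nrow(obs)))
  weight_values(obs$length_y, obs$area_ha, cfg$p_length[i], cfg$q_area[i])
}

#' Build the plot-level observation table of a study
#'
#' One row per plot: delta fluxes (event interval minus time-weighted
#' pre-event mean), the climate anomalies, pre-event climate, plot area and
#' pre-event monitoring length.
#'
#' @param fluxes named list (by plot) with elements `pre` (one-row
#'   [pre_event_mean()]) and `event` (one-row event interval fluxes).
#' @param climate data.frame with plot_id, d_tas, d_mcwd, pre_tas, pre_mcwd.
#' @param plots plot metadata (plot_id, area_ha).
#' @export
plot_observations <- function(fluxes, climate, plots) {
  rows <- lapply(names(fluxes), function(pid) {
    f <- fluxes[[pid]]
    d <- delta_metrics(f$pre, f$event)
    cbind(data.frame(plot_id = pid,
                     length_y = f$pre$T,
                     area_ha = plots$area_ha[match(pid, plots$plot_id)],
                     pre_net = f$pre$net, pre_gains = f$pre$gains,
                     pre_losses = f$pre$losses, stock0 = f$pre$stock0,
                     event_net = f$event$net, event_gains = f$event$gains,
                     event_losses = f$event$losses,
                     event_T = f$event$T,
                     pre_stem_recruitment = f$pre$stem_recruitment,
                     pre_stem_mortality = f$pre$stem_mortality,
                     pre_stem_net = f$pre$stem_net,
                     event_stem_recruitment = f$event$stem_recruitment,
                     event_stem_mortality = f$event$stem_mortality,
                     event_stem_net = f$event$stem_net),
          d)
  })
  obs <- do.call(rbind, rows)
  merge(obs, climate, by = "plot_id", sort = TRUE)
}

#' Run the complete synthetic El Nino study
#'
#' Generates the network, optionally runs census QC, fits the
#' height-diameter model from the calibration pairs, values every stem,
#' computes observed and census-interval-corrected fluxes per plot, builds
#' the plot-level delta observations (climate anomalies from the
#' generator's recorded truth), runs multimodel attribution for the
#' requested responses, and the paired pre/during comparisons.
#'
#' @param config a [sim_config()].
#' @param qc run the census QC stage (identity on clean data).
#' @param metric `"carbon"` (Mg C) or `"ba"` (basal area, m^2).
#' @param corrected use census-interval-corrected fluxes (default TRUE).
#' @param weighting `"stored"` (the default per-response configuration),
#'   `"derive"` (empirical search) or `"none"`.
#' @param responses responses to attribute (default all six).
#' @param exclude_clusters cluster ids dropped before attribution.
#' @return object of class `enso_study`.
#' @export
run_enso_study <- function(config = sim_config(), qc = TRUE,
                           metric = c("carbon", "ba"),
                           corrected = TRUE,
                           weighting = c("stored", "derive", "none"),
                           responses = delta_responses,
                           exclude_clusters = NULL) {
  metric <- match.arg(metric)
  weighting <- match.arg(weighting)
  net <- generate_plot_network(config)
  census <- net$census
  qa_log <- NULL
  if (qc) {
    q <- qc_census(census)
    census <- q$census
    qa_log <- q$log
  }
  hm <- fit_height_model(net$height_pairs$D_cm, net$height_pairs$H_m)
  census <- stem_carbon(census, net$wd_table, hm)
  value <- if (metric == "carbon") "carbon_kg" else "ba_cm2"
  scale <- if (metric == "carbon") 1 / 1000 else 1e-4
  by_plot <- split(census, census$plot_id)
  fluxes <- lapply(names(by_plot), function(pid) {
    area <- net$plots$area_ha[match(pid, net$plots$plot_id)]
    obs <- observed_fluxes(by_plot[[pid]], area, value = value, scale = scale)
    if (corrected) obs <- census_interval_correction(obs)
    n <- nrow(obs)
    list(all = obs, pre = pre_event_mean(obs[-n, , drop = FALSE]),
         event = obs[n, , drop = FALSE])
  })
  names(fluxes) <- names(by_plot)
  climate <- net$truth[, c("plot_id", "d_tas", "d_mcwd", "pre_tas", "pre_mcwd")]
  obs <- plot_observations(fluxes, climate, net$plots)
  obs$cluster <- net$plots$cluster[match(obs$plot_id, net$plots$plot_id)]
  if (!is.null(exclude_clusters)) obs <- obs[!obs$cluster %in% exclude_clusters, ]
  tm <- attribution_terms()
  attribution <- lapply(responses, function(rsp) {
    w <- weights_for_response(obs, rsp, weighting)
    multimodel_average(obs, rsp, tm$main, tm$interactions, weights = w)
  })
  names(attribution) <- responses
  paired <- list(
    net = paired_comparison(obs$pre_net, obs$event_net),
    gains = paired_comparison(obs$pre_gains, obs$event_gains),
    losses = paired_comparison(obs$pre_losses, obs$event_losses),
    stem_recruitment = paired_comparison(obs$pre_stem_recruitment,
                                         obs$event_stem_recruitment),
    stem_mortality = paired_comparison(obs$pre_stem_mortality,
                                       obs$event_stem_mortality),
    stem_net = paired_comparison(obs$pre_stem_net, obs$event_stem_net))
  structure(list(network = net, census = census, qa_log = qa_log,
                 height_model = hm, fluxes = fluxes, observations = obs,
                 attribution = attribution, paired = paired,
                 metric = metric, weighting = weighting,
                 corrected = corrected, config = config),
            class = "enso_study")
}

#' @export
print.enso_study <- function(x, ...) {
  obs <- x$observations
  cat(sprintf("Synthetic El Nino study: %d plots, metric = %s, %s fluxes\n",
              nrow(obs), x$metric, if (x$corrected) "corrected" else "observed"))
  cat(sprintf("  pre net %6.3f -> event net %6.3f (per ha per y)\n",
              mean(obs$pre_net), mean(obs$event_net)))
  cat(sprintf("  mean anomalies: d_tas %+.2f degC, d_mcwd %+.0f mm\n",
              mean(obs$d_tas), mean(obs$d_mcwd)))
  for (nm in names(x$attribution)) {
    ct <- x$attribution[[nm]]$coefficients
    i <- match("d_mcwd", ct$term)
    cat(sprintf("  %s ~ d_mcwd: %+0.4f [%+0.4f, %+0.4f] (standardized)\n",
                nm, ct$estimate[i], ct$ci_low[i], ct$ci_high[i]))
  }
  invisible(x)
}

#' Sensitivity harness over methodological variants
#'
#' Re-runs attribution for a fitted study under the study's robustness
#' variants: unweighted plots, basal-area metric, observed (uncorrected)
#' fluxes, an alternative drought anomaly (e.g. variable-ET MCWD), and the
#' exclusion of a designated cluster.  Reports the standardized
#' model-averaged coefficients per variant so sign stability can be
#' checked.
#'
#' @param study an [run_enso_study()] result.
#' @param response response to attribute (default `"d_net"`).
#' @param d_mcwd_alt optional replacement for the d_mcwd column (same plot
#'   order as `study$observations`), e.g. recomputed with a variable-ET
#'   MCWD.
#' @param exclude_cluster cluster id for the exclusion variant (default:
#'   the cluster with the most negative mean d_tas, the "cooled" cluster).
#' @return data.frame: variant x term matrix of standardized estimates.
#' @export
sensitivity_harness <- function(study, response = "d_net",
                                d_mcwd_alt = NULL, exclude_cluster = NULL) {
  obs <- study$observations
  tm <- attribution_terms()
  fit <- function(o, w) {
    a <- multimodel_average(o, response, tm$main, tm$interactions, weights = w)
    stats::setNames(a$coefficients$estimate, a$coefficients$term)
  }
  w_std <- weights_for_response(obs, response, "stored")
  out <- list(baseline = fit(obs, w_std))
  out$unweighted <- fit(obs, rep(1, nrow(obs)))
  if (is.null(exclude_cluster)) {
    mt <- tapply(obs$d_tas, obs$cluster, mean)
    exclude_cluster <- as.integer(names(which.min(mt)))
  }
  keep <- obs$cluster != exclude_cluster
  out$exclude_cooled <- fit(obs[keep, ], w_std[keep])
  if (!is.null(d_mcwd_alt)) {
    o2 <- obs; o2$d_mcwd <- d_mcwd_alt
    out$variable_et <- fit(o2, w_std)
  }
  ba <- run_enso_study(study$config, qc = FALSE, metric = "ba",
                       corrected = study$corrected,
                       weighting = study$weighting, responses = response)
  out$basal_area <- stats::setNames(
    ba$attribution[[response]]$coefficients$estimate,
    ba$attribution[[response]]$coefficients$term)
  as.data.frame(do.call(rbind, out))
}
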