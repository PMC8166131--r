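# Report assembly: pre vs during summary tables with paired-test
# annotations, percent-change lines, and deterministic CSV/markdown output.

stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p <= 0.05) "*" else ""
}

#' Percent change between a pre and a during value
#'
#' @param pre,during values on the same scale; `pre` must be nonzero.
#' @return 100 * (during - pre) / pre.
#' @export
percent_change <- function(pre, during) {
  if (any(pre == 0)) stopf("pre value must be nonzero")
  100 * (during - pre) / pre
}

#' Assemble the study summary report
#'
#' Builds the pre/during flux table (means, 95% CIs, paired-test p values
#' and significance stars, percent change), appends the attribution
#' coefficient tables and any regional anomaly summary, and optionally
#' writes deterministic CSVs plus a markdown digest.  Percent changes are
#' rounded half-even to one decimal for display; raw values are retained in
#' the CSV.
#'
#' @param study an [run_enso_study()] result.
#' @param anomalies optional [regional_anomalies()] summary.
#' @param dir optional output directory for CSV/markdown files.
#' @return list with `fluxes` (summary table), `attribution`, `anomalies`,
#'   `manifest`.
#' @export
build_report <- function(study, anomalies = NULL, dir = NULL) {
  if (!inherits(study, "enso_study")) stopf("missing upstream stage: 'study' must be an enso_study")
  obs <- study$observations
  ci95 <- function(x) stats::qt(0.975, length(x) - 1) * stats::sd(x) / sqrt(length(x))
  vars <- data.frame(
    variable = c("net_carbon", "carbon_gains", "carbon_losses",
                 "net_stems", "stem_recruitment", "stem_mortality"),
    pre = c("pre_net", "pre_gains", "pre_losses",
            "pre_stem_net", "pre_stem_recruitment", "pre_stem_mortality"),
    during = c("event_net", "event_gains", "event_losses",
               "event_stem_net", "event_stem_recruitment", "event_stem_mortality"),
    paired = c("net", "gains", "losses", "stem_net",
               "stem_recruitment", "stem_mortality"))
  tab <- do.call(rbind, lapply(seq_len(nrow(vars)), function(i) {
    pre <- obs[[vars$pre[i]]]; dur <- obs[[vars$during[i]]]
    p <- study$paired[[vars$paired[i]]]$p
    data.frame(variable = vars$variable[i],
               pre_mean = mean(pre), pre_ci = ci95(pre),
               during_mean = mean(dur), during_ci = ci95(dur),
               pct_change = percent_change(mean(pre), mean(dur)),
               p = p, signif = stars(p))
  }))
  att <- do.call(rbind, lapply(names(study$attribution), function(nm) {
    ct <- study$attribution[[nm]]$coefficients
    cbind(response = nm, ct)
  }))
  manifest <- run_manifest(study$config,
                           outputs = list(fluxes = "fluxes.csv",
                                          attribution = "attribution.csv"))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(dir, "fluxes.csv"), row.names = FALSE)
    utils::write.csv(att, file.path(dir, "attribution.csv"), row.names = FALSE)
    if (!is.null(anomalies))
      utils::write.csv(anomalies$summary, file.path(dir, "anomalies.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    md <- c("# Study summary", "",
            sprintf("- %s: %.2f to %.2f (%+.1f%%)%s",
                    tab$variable, tab$pre_mean, tab$during_mean,
                    round(tab$pct_change, 1), tab$signif))
    writeLines(md, file.path(dir, "report.md"))
  }
  list(fluxes = tab, attribution = att, anomalies = anomalies,
       manifest = manifest)
}
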