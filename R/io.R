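# Plain-text interchange: the census CSV dialect, wood-density CSV,
# long-format climate CSV and the JSON run manifest.

#' Write / read a census table CSV
#'
#' Dialect columns: plot_id, stem_id, census_date, diameter_mm, pom_m,
#' taxon (the species binomial), genus, family, status (alive | dead |
#' recruit | prior).
#'
#' @param census census table.
#' @param path file path.
#' @export
write_census_csv <- function(census, path) {
  out <- data.frame(plot_id = census$plot_id, stem_id = census$stem_id,
                    census_date = census$census_date,
                    diameter_mm = census$diameter_mm, pom_m = census$pom_m,
                    taxon = census$species, genus = census$genus,
                    family = census$family, status = census$status)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_census_csv
#' @export
read_census_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(x)[names(x) == "taxon"] <- "species"
  x
}

#' Write / read a wood-density CSV (taxon, level, wd_g_cm3)
#' @param table a [wood_density_table()].
#' @param path file path.
#' @export
write_wd_csv <- function(table, path) {
  out <- data.frame(taxon = table$entries$taxon, level = table$entries$rank,
                    wd_g_cm3 = table$entries$wd_g_cm3)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_wd_csv
#' @export
read_wd_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  wood_density_table(data.frame(taxon = x$taxon, rank = x$level,
                                wd_g_cm3 = x$wd_g_cm3))
}

#' Write / read a long-format climate CSV (cell_id, year, month, tas_C, pr_mm)
#' @param record long-format climate data.frame.
#' @param path file path.
#' @export
write_climate_csv <- function(record, path) {
  utils::write.csv(record, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' JSON run manifest
#'
#' Records the configuration, seed and an inventory of outputs so a report
#' can be regenerated bit-identically.
#'
#' @param config a [sim_config()].
#' @param outputs named list/character of output descriptions or paths.
#' @param path optional path to write JSON to.
#' @export
run_manifest <- function(config, outputs = list(), path = NULL) {
  cfg <- unclass(config)
  cfg <- lapply(cfg, function(x) if (is.numeric(x)) unname(x) else x)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  man <- list(config = cfg,
              config_md5 = unname(tools::md5sum(tmp)),
              seed = config$seed,
              package_version = as.character(utils::packageVersion("forestflux")),
              outputs = outputs)
  if (!is.null(path))
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  man
}
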