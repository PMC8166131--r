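# Allometry: wood density assignment, height-diameter Weibull models,
# per-stem aboveground biomass, carbon and basal area.
#
# Units are fixed package-wide: diameter D in cm for allometric equations
# (census tables store mm and are converted at the module boundary), height H
# in m, wood density rho in g cm^-3, per-stem AGB in kg dry mass; plot-level
# sums are converted to Mg.

#' Build a wood-density lookup table
#'
#' @param entries data.frame with columns `taxon`, `rank`
#'   (one of `"species"`, `"genus"`, `"family"`) and `wd_g_cm3`.
#'   Duplicate taxon entries are averaged (species values are means over
#'   sources).
#' @param synonyms optional data.frame with columns `from`, `to` mapping
#'   synonymous taxon names onto the accepted name used in `entries`.
#' @return object of class `wd_table`.
#' @export
wood_density_table <- function(entries, synonyms = NULL) {
  need <- c("taxon", "rank", "wd_g_cm3")
  if (!all(need %in% names(entries)))
    stopf("entries must have columns %s", paste(need, collapse = ", "))
  bad <- !entries$rank %in% c("species", "genus", "family")
  if (any(bad)) stopf("unknown rank(s): %s", paste(unique(entries$rank[bad]), collapse = ", "))
  if (any(!is.finite(entries$wd_g_cm3) | entries$wd_g_cm3 <= 0.05 |
          entries$wd_g_cm3 >= 1.5))
    stopf("wood densities must lie in (0.05, 1.5) g cm^-3")
  agg <- stats::aggregate(wd_g_cm3 ~ taxon + rank, data = entries, FUN = mean)
  syn <- if (is.null(synonyms)) character(0) else stats::setNames(synonyms$to, synonyms$from)
  structure(list(entries = agg, synonyms = syn), class = "wd_table")
}

#' @export
print.wd_table <- function(x, ...) {
  cat("Wood-density table:", nrow(x$entries), "taxa (",
      sum(x$entries$rank == "species"), "species,",
      sum(x$entries$rank == "genus"), "genus,",
      sum(x$entries$rank == "family"), "family ),",
      length(x$synonyms), "synonyms\n")
  invisible(x)
}

# resolve a taxon name through the synonym map
resolve_synonym <- function(name, table) {
  hit <- !is.na(name) & name %in% names(table$synonyms)
  name[hit] <- unname(table$synonyms[name[hit]])
  name
}

#' Assign wood density to stems with taxonomic fallback
#'
#' Species mean if available, else genus mean, else family mean, else the
#' unweighted mean wood density of all individual stems in the plot that did
#' receive a taxonomic match.
#'
#' @param species,genus,family character vectors (NA or "" where unknown),
#'   recycled to a common length.
#' @param table a [wood_density_table()].
#' @return data.frame with columns `wd_g_cm3` and
#'   `wd_provenance` (`"species"`, `"genus"`, `"family"` or `"plot_mean"`).
#' @export
assign_wood_density <- function(species, genus, family, table) {
  if (!inherits(table, "wd_table")) stopf("'table' must be a wd_table")
  if (nrow(table$entries) == 0L) stopf("wood-density table is empty")
  n <- max(length(species), length(genus), length(family))
  species <- rep_len(as.character(species), n)
  genus   <- rep_len(as.character(genus), n)
  family  <- rep_len(as.character(family), n)
  blank <- function(x) is.na(x) | x == ""
  lut <- function(rank) {
    e <- table$entries[table$entries$rank == rank, ]
    stats::setNames(e$wd_g_cm3, e$taxon)
  }
  sp <- lut("species"); ge <- lut("genus"); fa <- lut("family")
  species <- resolve_synonym(species, table)
  genus <- resolve_synonym(genus, table)
  rho <- rep(NA_real_, n)
  prov <- rep(NA_character_, n)
  i <- !blank(species) & species %in% names(sp)
  rho[i] <- sp[species[i]]; prov[i] <- "species"
  j <- is.na(rho) & !blank(genus) & genus %in% names(ge)
  rho[j] <- ge[genus[j]]; prov[j] <- "genus"
  k <- is.na(rho) & !blank(family) & family %in% names(fa)
  rho[k] <- fa[family[k]]; prov[k] <- "family"
  if (anyNA(rho)) {
    matched <- rho[!is.na(rho)]
    if (length(matched) == 0L)
      stopf("no stem in the plot has a taxonomic wood-density match; cannot form a plot mean")
    rho[is.na(rho)] <- mean(matched)   # unweighted stem mean
    prov[is.na(prov)] <- "plot_mean"
  }
  data.frame(wd_g_cm3 = rho, wd_provenance = prov, stringsAsFactors = FALSE)
}

#' Fit a three-parameter Weibull height-diameter model
#'
#' Fits H = a (1 - exp(-b D^c)) by Levenberg-Marquardt nonlinear least
#' squares.  `D` in cm, `H` in m.
#'
#' @param D,H numeric vectors of paired diameter (cm) and height (m)
#'   calibration measurements.
#' @param region label carried on the model (e.g. `"West Africa"`).
#' @param start optional named list of starting values `a`, `b`, `c`.
#' @return object of class `height_model` with elements `a`, `b`, `c`,
#'   `region`, `fit` (the nls object) and `rss`.
#' @export
fit_height_model <- function(D, H, region = "synthetic", start = NULL) {
  ok <- is.finite(D) & is.finite(H) & D > 0 & H > 0
  D <- D[ok]; H <- H[ok]
  if (length(unique(D)) < 9L)
    stopf("height-diameter fit needs >= 9 distinct diameters (3 x 3 parameters); got %d",
          length(unique(D)))
  if (is.null(start)) {
    a0 <- max(H) * 1.1
    # linearize: -log(1 - H/a0) = b D^c
    y <- -log(pmax(1e-6, 1 - H / a0))
    lf <- stats::lm(log(y) ~ log(D))
    start <- list(a = a0, b = exp(stats::coef(lf)[[1]]), c = stats::coef(lf)[[2]])
    if (!is.finite(start$b) || start$b <= 0) start$b <- 0.03
    if (!is.finite(start$c) || start$c <= 0) start$c <- 0.9
  }
  fit <- try(minpack.lm::nlsLM(H ~ a * (1 - exp(-b * D^c)),
                               data = data.frame(D = D, H = H),
                               start = start,
                               lower = c(a = 1e-3, b = 1e-8, c = 1e-3),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stopf("height model did not converge: %s", attr(fit, "condition")$message %||% "unknown")
  cf <- stats::coef(fit)
  structure(list(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
                 region = region, fit = fit,
                 rss = sum(stats::residuals(fit)^2), n = length(D)),
            class = "height_model")
}

#' @export
print.height_model <- function(x, ...) {
  cat(sprintf("Weibull height model [%s]: H = %.3f (1 - exp(-%.5f D^%.4f)), n = %d, RSS = %.4g\n",
              x$region, x$a, x$b, x$c, x$n, x$rss))
  invisible(x)
}

#' Predict stem height from diameter
#'
#' @param D diameter in cm (vectorized).
#' @param model a [fit_height_model()] result, or a list with `a`, `b`, `c`.
#' @return heights in m; always `< a`.
#' @export
estimate_height <- function(D, model) {
  if (any(D <= 0, na.rm = TRUE)) stopf("diameters must be positive")
  model$a * (1 - exp(-model$b * D^model$c))
}

#' Per-stem aboveground biomass (kg dry mass)
#'
#' Moist-forest allometry AGB = 0.0673 (rho D^2 H)^0.976 with rho in
#' g cm^-3, D in cm, H in m.  Palms are not covered by this equation; a
#' pluggable `palm_fn(rho, D, H)` may be supplied, and the default treats
#' palms as dicots with a one-time warning.
#'
#' @param rho wood density g cm^-3.
#' @param D diameter cm.
#' @param H height m.
#' @param is_palm logical vector marking palm stems.
#' @param palm_fn optional function `(rho, D, H) -> kg` for palms.
#' @return AGB in kg (vector).
#' @export
stem_agb <- function(rho, D, H, is_palm = FALSE, palm_fn = NULL) {
  if (any(rho <= 0 | D <= 0 | H <= 0, na.rm = TRUE))
    stopf("rho, D and H must all be positive")
  agb <- 0.0673 * (rho * D^2 * H)^0.976
  is_palm <- rep_len(is_palm, length(agb))
  if (any(is_palm)) {
    if (is.null(palm_fn)) {
      warnf("%d palm stem(s) valued with the dicot allometry (no palm allometry supplied)",
            sum(is_palm))
    } else {
      agb[is_palm] <- palm_fn(rho[is_palm], D[is_palm], H[is_palm])
    }
  }
  agb
}

#' Convert aboveground dry mass to carbon
#'
#' @param agb biomass (any mass unit).
#' @param fraction carbon fraction of dry mass; default 0.456, the mean for
#'   tropical angiosperms.
#' @export
to_carbon <- function(agb, fraction = 0.456) {
  if (any(agb < 0, na.rm = TRUE)) stopf("AGB must be non-negative")
  fraction * agb
}

#' Stem basal area
#'
#' @param D diameter (cm).
#' @return cross-sectional area pi (D/2)^2 in cm^2.
#' @export
basal_area <- function(D) {
  if (any(D <= 0, na.rm = TRUE)) stopf("diameters must be positive")
  pi * (D / 2)^2
}
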