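# Attribution of flux changes to climate anomalies: empirical plot
# weighting, weighted regression, all-subsets AIC multimodel averaging with
# a 95% confidence set and full (shrinkage) model averaging, paired pre /
# during comparisons, and the scenario / scaling arithmetic.

#' Default empirical weightings per response
#'
#' The stored default configuration maps each delta response to the
#' sampling-effort weighting that removes residual patterns in the study
#' design this package emulates: d_net = length^(1/6) + area^(1/8) - 1;
#' d_gains = length^(1/4); d_losses = length^(1/3);
#' d_stem_net = length^(1/2) + area^(1/4) - 1; recruitment and stem
#' mortality unweighted.
#'
#' @export
default_weight_config <- function() {
  data.frame(
    response = c("d_net", "d_gains", "d_losses", "d_stem_net",
                 "d_stem_recruitment", "d_stem_mortality"),
    p_length = c(1/6, 1/4, 1/3, 1/2, 0, 0),
    q_area   = c(1/8, 0,   0,   1/4, 0, 0))
}

# evaluate one candidate weighting on effort variables
weight_values <- function(length_y, area_ha, p, q) {
  if (p > 0 && q > 0) length_y^p + area_ha^q - 1   # minus 1: avoid double counting
  else if (p > 0) length_y^p
  else if (q > 0) area_ha^q
  else rep(1, length(length_y))
}

#' Derive an empirical optimum weighting
#'
#' Searches candidate exponents for monitoring length and plot area
#' (weight = length^p + area^q - 1, dropping the -1 and the absent term
#' when an exponent is zero).  Each candidate's weighted intercept-only
#' model is fitted and the candidate minimizing the maximum absolute
#' Spearman rank correlation between squared residuals and the two
#' sampling-effort variables is selected; ties break toward smaller
#' exponents.
#'
#' @param data data.frame with the response, `length_y` (pre-event
#'   monitoring length) and `area_ha`.
#' @param response response column name.
#' @param exponents candidate exponents (default {0, 1/8, 1/6, 1/4, 1/3,
#'   1/2, 1}).
#' @return list with `p_length`, `q_area`, `weights`, `score` and `note`.
#' @export
derive_weights <- function(data, response,
                           exponents = c(0, 1/8, 1/6, 1/4, 1/3, 1/2, 1)) {
  if (nrow(data) < 10L) stopf("need >= 10 plots to derive weights")
  y <- data[[response]]
  L <- data$length_y; A <- data$area_ha
  if (stats::sd(L) == 0 && stats::sd(A) == 0)
    return(list(p_length = 0, q_area = 0, weights = rep(1, length(y)),
                score = NA_real_, note = "constant effort variables; weight 1"))
  grid <- expand.grid(p = exponents, q = exponents)
  grid <- grid[order(grid$p + grid$q, grid$p, grid$q), ]
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    w <- weight_values(L, A, grid$p[i], grid$q[i])
    if (any(w <= 0)) next
    fit <- stats::lm(y ~ 1, weights = w)
    r2 <- stats::residuals(fit)^2 * w    # weighted squared residuals
    sc <- max(if (stats::sd(L) > 0) abs(stats::cor(r2, L, method = "spearman")) else 0,
              if (stats::sd(A) > 0) abs(stats::cor(r2, A, method = "spearman")) else 0)
    if (is.null(best) || sc < best$score - 1e-12)
      best <- list(p_length = grid$p[i], q_area = grid$q[i], weights = w,
                   score = sc, note = "selected by residual-pattern criterion")
  }
  best
}

#' Weighted least-squares regression of a delta response on one predictor
#'
#' @param data data.frame holding response and predictor columns.
#' @param response,predictor column names.
#' @param weights observation weights (default equal, reducing to OLS).
#' @return list with slope, intercept, ci (95%), p, n and the lm fit.
#' @export
weighted_regression <- function(data, response, predictor, weights = NULL) {
  if (nrow(data) < 3L) stopf("need >= 3 plots for regression")
  if (is.null(weights)) weights <- rep(1, nrow(data))
  df <- data.frame(y = data[[response]], x = data[[predictor]], w = weights)
  fit <- stats::lm(y ~ x, data = df, weights = w)
  sm <- summary(fit)
  ci <- stats::confint(fit)["x", ]
  list(slope = stats::coef(fit)[["x"]], intercept = stats::coef(fit)[["(Intercept)"]],
       ci = unname(ci), p = sm$coefficients["x", "Pr(>|t|)"],
       n = nrow(df), fit = fit)
}

# Model-averaged tail-area (MATA-Wald) interval for an averaged coefficient.
# b, se, w: estimates, standard errors and (confidence-set) weights of the
# models CONTAINING the term; the remaining mass 1 - sum(w) sits as a point
# mass at zero (the term's full-average shrinkage).  Endpoints solve
# sum_i w_i Phi((theta - b_i)/se_i) + w0 1{theta >= 0} = alpha/2, 1 - alpha/2.
mata_interval <- function(b, se, w, alpha = 0.05) {
  w0 <- max(0, 1 - sum(w))
  Fc <- function(theta)
    if (length(b) == 0L) 0 else
      sum(w * ifelse(se > 0, stats::pnorm((theta - b) / se), as.numeric(theta >= b)))
  solve_tail <- function(tau) {
    F0 <- Fc(0)
    if (F0 >= tau) {                       # endpoint on the continuous part
      lo <- min(b - 10 * pmax(se, 1e-12), -1e-12)
      stats::uniroot(function(th) Fc(th) - tau, c(lo, 0))$root
    } else if (F0 + w0 >= tau) {
      0
    } else {
      hi <- max(b + 10 * pmax(se, 1e-12), 1e-12)
      stats::uniroot(function(th) Fc(th) + w0 - tau, c(0, hi))$root
    }
  }
  c(solve_tail(alpha / 2), solve_tail(1 - alpha / 2))
}

# enumerate admissible term subsets: interactions (a:b) only when both main
# effects are present
enumerate_models <- function(main, interactions) {
  subsets <- list(character(0))
  for (t in main) subsets <- c(subsets, lapply(subsets, c, t))
  out <- list()
  for (s in subsets) {
    adm <- interactions[vapply(strsplit(interactions, ":", fixed = TRUE),
                               function(p) all(p %in% s), logical(1))]
    isubs <- list(character(0))
    for (t in adm) isubs <- c(isubs, lapply(isubs, c, t))
    for (is_ in isubs) out[[length(out) + 1L]] <- c(s, is_)
  }
  out
}

#' All-subsets AIC multimodel averaging of climate effects
#'
#' Standardizes the predictors to zero mean and unit SD, enumerates every
#' admissible combination of main effects and interactions (an interaction
#' enters only with both its main effects), fits each by weighted least
#' squares, computes Akaike weights, restricts to the smallest set of top
#' models whose weights sum to at least `level` (the 95% confidence set),
#' and reports full model-averaged coefficients (a term absent from a model
#' contributes zero, so weakly supported terms shrink toward zero) with
#' unconditional 95% CIs.
#'
#' @param data plot-level observation table.
#' @param response response column name (e.g. `"d_net"`).
#' @param terms main-effect column names (standardized internally).
#' @param interactions character vector like `"d_tas:d_mcwd"` (optional).
#' @param weights observation weights.
#' @param level confidence-set mass (default 0.95).
#' @param aicc use small-sample AICc instead of AIC.
#' @return object of class `enso_attribution`: coefficient table
#'   (standardized and raw scales), model table with AIC weights and
#'   confidence-set membership, and the variance explained by the
#'   best model.
#' @export
multimodel_average <- function(data, response, terms,
                               interactions = character(0),
                               weights = NULL, level = 0.95, aicc = FALSE) {
  n <- nrow(data)
  if (length(terms) + length(interactions) >= n)
    stopf("more candidate terms than plots")
  if (is.null(weights)) weights <- rep(1, n)
  y <- data[[response]]
  sds <- vapply(terms, function(t) stats::sd(data[[t]]), numeric(1))
  mus <- vapply(terms, function(t) mean(data[[t]]), numeric(1))
  Z <- as.data.frame(lapply(terms, function(t) (data[[t]] - mean(data[[t]])) / stats::sd(data[[t]])))
  names(Z) <- terms
  for (ia in interactions) {
    p <- strsplit(ia, ":", fixed = TRUE)[[1]]
    Z[[ia]] <- Z[[p[1]]] * Z[[p[2]]]
  }
  Z$.y <- y; Z$.w <- weights
  models <- enumerate_models(terms, interactions)
  fits <- lapply(models, function(tm) {
    rhs <- if (length(tm) == 0L) "1" else
      paste(sprintf("`%s`", tm), collapse = " + ")
    stats::lm(stats::as.formula(paste(".y ~", rhs)), data = Z, weights = .w)
  })
  ic <- vapply(fits, stats::AIC, numeric(1))
  if (aicc) {
    k <- vapply(fits, function(f) length(stats::coef(f)) + 1, numeric(1))
    ic <- ic + 2 * k * (k + 1) / pmax(1, n - k - 1)
  }
  delta <- ic - min(ic)
  w_ak <- exp(-delta / 2); w_ak <- w_ak / sum(w_ak)
  ord <- order(w_ak, decreasing = TRUE)
  cum <- cumsum(w_ak[ord])
  keep_n <- which(cum >= level)[1]
  in_set <- logical(length(fits)); in_set[ord[seq_len(keep_n)]] <- TRUE
  w_set <- w_ak * in_set / sum(w_ak[in_set])
  all_terms <- c(terms, interactions)
  coefs <- vapply(all_terms, function(tm) {
    b <- se <- numeric(length(fits))
    present <- logical(length(fits))
    for (i in seq_along(fits)) {
      cf <- stats::coef(fits[[i]])
      names(cf) <- gsub("`", "", names(cf), fixed = TRUE)
      if (tm %in% names(cf)) {
        present[i] <- TRUE
        b[i] <- cf[[tm]]
        v <- sqrt(diag(stats::vcov(fits[[i]])))
        names(v) <- gsub("`", "", names(v), fixed = TRUE)
        se[i] <- v[[tm]]
      }
    }
    bbar <- sum(w_set * b)
    # adjusted SE (model-selection variance included)
    sebar <- sum(w_set * sqrt(se^2 + (b - bbar)^2))
    ci <- mata_interval(b[present & in_set], se[present & in_set],
                        w_set[present & in_set], alpha = 0.05)
    c(est = bbar, se = sebar, lo = ci[1], hi = ci[2])
  }, numeric(4))
  est <- coefs["est", ]; se <- coefs["se", ]
  ctab <- data.frame(
    term = all_terms,
    estimate = est, se = se,
    ci_low = coefs["lo", ], ci_high = coefs["hi", ],
    weight = vapply(all_terms, function(tm)
      sum(w_ak[vapply(models, function(m) tm %in% m, logical(1))]), numeric(1)),
    row.names = NULL)
  # raw-scale slopes for the main effects (standardization back-transform)
  ctab$estimate_raw <- NA_real_
  ctab$ci_low_raw <- NA_real_
  ctab$ci_high_raw <- NA_real_
  i <- match(terms, ctab$term)
  ctab$estimate_raw[i] <- est[seq_along(terms)] / sds
  ctab$ci_low_raw[i] <- ctab$ci_low[i] / sds
  ctab$ci_high_raw[i] <- ctab$ci_high[i] / sds
  mtab <- data.frame(
    model = vapply(models, function(m) if (length(m)) paste(m, collapse = " + ") else "(null)",
                   character(1)),
    k = vapply(fits, function(f) length(stats::coef(f)), numeric(1)),
    aic = ic, delta = delta, weight = w_ak, in_set = in_set)
  mtab <- mtab[order(mtab$aic), ]
  best <- fits[[which.min(ic)]]
  structure(list(response = response, coefficients = ctab, models = mtab,
                 r2_best = summary(best)$r.squared,
                 level = level, n = n,
                 standardization = data.frame(term = terms, mean = mus, sd = sds)),
            class = "enso_attribution")
}

#' @export
print.enso_attribution <- function(x, ...) {
  cat(sprintf("Multimodel-averaged attribution for %s (n = %d plots)\n",
              x$response, x$n))
  cat(sprintf("  %d candidate models; %d in the %.0f%% confidence set; best-model R2 = %.3f\n",
              nrow(x$models), sum(x$models$in_set), 100 * x$level, x$r2_best))
  ct <- x$coefficients
  for (i in seq_len(nrow(ct)))
    cat(sprintf("  %-24s %+.4f  [%+.4f, %+.4f]  (Akaike weight %.2f)\n",
                ct$term[i], ct$estimate[i], ct$ci_low[i], ct$ci_high[i], ct$weight[i]))
  invisible(x)
}

#' @export
summary.enso_attribution <- function(object, ...) {
  object$coefficients
}

#' @export
coef.enso_attribution <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Paired pre / during comparison
#'
#' Two-sided paired t test on plot-level values.  With zero difference
#' variance the exact equality is reported and no test statistic is
#' computed.
#'
#' @param pre,during numeric vectors paired by plot.
#' @return list with mean_diff, ci, t, p, n (t, p, ci NA when degenerate).
#' @export
paired_comparison <- function(pre, during) {
  if (length(pre) != length(during)) stopf("pre and during must pair by plot")
  if (length(pre) < 2L) stopf("need >= 2 plots")
  d <- during - pre
  if (stats::sd(d) == 0)
    return(list(mean_diff = mean(d), ci = c(mean(d), mean(d)),
                t = NA_real_, p = NA_real_, n = length(d),
                note = "zero difference variance: exact equality"))
  tt <- stats::t.test(during, pre, paired = TRUE)
  list(mean_diff = unname(tt$estimate), ci = unname(tt$conf.int),
       t = unname(tt$statistic), p = tt$p.value, n = length(d))
}

#' Counterfactual event-window rate
#'
#' Solves overall_rate * total = pre_rate * (total - window) + x * window
#' for the rate x that must have prevailed during the event window if the
#' pre-event rate held at all other times.
#'
#' @param total_interval_y,event_window_y interval lengths (y), with
#'   0 < window < total.
#' @param pre_rate,overall_rate rates over the pre period and the whole
#'   interval.
#' @export
scenario_partition <- function(total_interval_y, event_window_y, pre_rate, overall_rate) {
  if (event_window_y >= total_interval_y || event_window_y <= 0)
    stopf("event window must be positive and shorter than the interval")
  (overall_rate * total_interval_y -
     pre_rate * (total_interval_y - event_window_y)) / event_window_y
}

#' Scale a regional sink by the event / pre rate ratio
#'
#' @param baseline_sink regional baseline sink (e.g. Pg C / y).
#' @param pre_rate,event_rate per-area rates (same units).
#' @export
regional_scaling <- function(baseline_sink, pre_rate, event_rate) {
  if (pre_rate == 0) stopf("pre-event rate must be nonzero")
  baseline_sink * (event_rate / pre_rate)
}

#' Flux change as a percentage of standing stock
#'
#' @param flux_change per-area flux change (e.g. Mg C / ha / y).
#' @param stock standing stock in the same mass-per-area units.
#' @return percentage (100 * flux_change / stock).
#' @export
percent_of_stock <- function(flux_change, stock) {
  check_pos(stock, "stock")
  100 * flux_change / stock
}
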