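# Integrated exposure-response (IER) relative risks and population
# attributable fractions for the complete-traffic-removal counterfactual.
#
# RR(pm) = 1 + theta * (1 - exp(-omega * z^delta)), z = max(0, pm - x):
# no excess risk below the counterfactual threshold x, a saturating rise
# above it, asymptote 1 + theta. PAF = 1 - RR(pm_cf) / RR(pm_baseline)
# compares the counterfactual concentration (baseline minus the traffic
# contribution, both posterior means) with the baseline. Parameter
# uncertainty is propagated by averaging PAF over a table of (theta,
# omega, delta, x) draws.

#' IER relative risk
#'
#' @param pm Ambient PM2.5 concentration(s), ug/m^3, non-negative.
#' @param theta,omega,delta Positive IER curve parameters (vectors are
#'   recycled against `pm`).
#' @param x Counterfactual threshold(s), ug/m^3.
#' @return Relative risk(s), always >= 1; exactly 1 when `pm <= x`.
#' @export
relative_risk <- function(pm, theta, omega, delta, x) {
  if (any(!is.finite(pm)) || any(pm < 0)) {
    pm_stop("pm must be non-negative", "pm_input_error")
  }
  if (any(theta <= 0) || any(omega <= 0) || any(delta <= 0)) {
    pm_stop("IER parameters theta, omega, delta must be positive",
            "pm_input_error")
  }
  z <- pmax(0, pm - x)
  1 + theta * (1 - exp(-omega * z^delta))
}

#' Baseline / counterfactual concentration pair for one city
#'
#' The baseline is the posterior mean of the overall concentration; the
#' counterfactual (all traffic emissions removed) subtracts the posterior
#' mean of the traffic-related concentration. A negative difference is
#' floored at zero with a warning.
#'
#' @param city_draws A `pm_city_draws` from [predict_city()].
#' @return Object of class `pm_cf_pair`: list with `city`, `pm_baseline`,
#'   `pm_cf` (ug/m^3) and a `floored` flag.
#' @export
counterfactual_pair <- function(city_draws) {
  stopifnot(inherits(city_draws, "pm_city_draws"))
  if (length(city_draws$overall) == 0L) pm_stop("empty draws", "pm_input_error")
  pm_b <- mean(city_draws$overall)
  pm_cf <- pm_b - mean(city_draws$traffic)
  floored <- pm_cf < 0
  if (floored) {
    warning("counterfactual concentration below zero; floored at 0")
    pm_cf <- 0
  }
  structure(list(city = city_draws$city, pm_baseline = pm_b,
                 pm_cf = pm_cf, floored = floored),
            class = "pm_cf_pair")
}

#' Population attributable fraction for one parameter draw
#'
#' `PAF = 1 - RR(pm_cf) / RR(pm_baseline)`; zero when the two
#' concentrations coincide or both lie below the counterfactual
#' threshold.
#'
#' @param pair A `pm_cf_pair` from [counterfactual_pair()], or any list
#'   with `pm_baseline` and `pm_cf`.
#' @param theta,omega,delta,x IER parameters (vectors allowed).
#' @return PAF fraction(s) in \[0, 1).
#' @export
paf <- function(pair, theta, omega, delta, x) {
  rr_b <- relative_risk(pair$pm_baseline, theta, omega, delta, x)
  rr_cf <- relative_risk(pair$pm_cf, theta, omega, delta, x)
  1 - rr_cf / rr_b
}

#' Monte-Carlo mean PAF for one city and endpoint
#'
#' Averages the PAF over a table of IER parameter draws (typically 1000)
#' for a single endpoint, reporting the mean as a percentage.
#'
#' @param pair A `pm_cf_pair`.
#' @param ier_draws data.frame with columns endpoint, age_group, theta,
#'   omega, delta, x; must contain a single endpoint/age-group
#'   combination.
#' @param keep_draws Retain the per-draw PAF values as an attribute?
#' @return data.frame with city, endpoint, age_group, mean_paf_pct,
#'   n_draws (and attribute `"paf_draws"` when requested).
#' @export
city_paf_mc <- function(pair, ier_draws, keep_draws = FALSE) {
  if (nrow(ier_draws) < 1L) pm_stop("need at least one IER draw", "pm_input_error")
  key <- unique(ier_draws[, intersect(c("endpoint", "age_group"), names(ier_draws)),
                          drop = FALSE])
  if (nrow(key) > 1L) {
    pm_stop("ier_draws must contain a single endpoint/age-group per call",
            "pm_input_error")
  }
  vals <- paf(pair, ier_draws$theta, ier_draws$omega, ier_draws$delta,
              ier_draws$x)
  out <- data.frame(
    city = pair$city %||% NA_character_,
    endpoint = key$endpoint %||% NA_character_,
    age_group = if ("age_group" %in% names(key)) key$age_group else NA_character_,
    mean_paf_pct = round(100 * mean(vals), 2),
    n_draws = length(vals),
    stringsAsFactors = FALSE
  )
  if (keep_draws) attr(out, "paf_draws") <- vals
  out
}

#' City-by-endpoint mortality-reduction table
#'
#' Mean percent reduction in mortality (the Monte-Carlo mean PAF) for
#' every city and endpoint, against the city's baseline concentration —
#' the table behind a percent-reduction-versus-pollution-level plot.
#'
#' @param pairs List of `pm_cf_pair` objects (one per city).
#' @param ier_draws data.frame of IER draws covering one or more
#'   endpoints.
#' @return data.frame with city, pm_baseline, pm_cf, endpoint, age_group,
#'   pct_reduction, sorted by endpoint then baseline concentration.
#' @export
benefit_curve <- function(pairs, ier_draws) {
  if (!length(pairs) || nrow(ier_draws) < 1L) {
    pm_stop("need at least one city pair and one IER draw", "pm_input_error")
  }
  if (inherits(pairs, "pm_cf_pair")) pairs <- list(pairs)
  groups <- split(ier_draws, ier_draws$endpoint)
  rows <- lapply(pairs, function(pr) {
    do.call(rbind, lapply(groups, function(g) {
      res <- city_paf_mc(pr, g)
      data.frame(city = res$city, pm_baseline = pr$pm_baseline,
                 pm_cf = pr$pm_cf, endpoint = res$endpoint,
                 age_group = res$age_group,
                 pct_reduction = res$mean_paf_pct,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$endpoint, out$pm_baseline), , drop = FALSE]
  rownames(out) <- NULL
  out
}
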