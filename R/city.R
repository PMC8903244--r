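# Per-city posterior concentrations and guideline exceedance.
#
# A city profile is a covariate vector; pushing it through every retained
# posterior draw gives per-draw expected log concentrations for both
# outcomes, hence natural-scale traffic, overall and non-traffic PM2.5
# distributions, and the probability that the non-traffic concentration
# would still meet or exceed a guideline if all traffic emissions were
# removed.

#' Build per-city covariate profiles
#'
#' Collapses curated records to one covariate row per city. With
#' `aggregate = "most-recent"` (default) the covariates of the city's
#' most recently published record are used; with `"mean-of-records"`
#' numeric covariates are averaged and categorical ones taken by
#' majority.
#'
#' @param curated Curated records from [curate_records()].
#' @param aggregate `"most-recent"` or `"mean-of-records"`.
#' @return data.frame with one row per city: city, ln_population, lat10,
#'   sea_salt_reported, post2005, loc_cat, plus the observed mean overall
#'   concentration of the city's records.
#' @export
city_profiles <- function(curated, aggregate = c("most-recent", "mean-of-records")) {
  aggregate <- match.arg(aggregate)
  split_idx <- split(seq_len(nrow(curated)), curated$city)
  rows <- lapply(split_idx, function(ix) {
    sub <- curated[ix, , drop = FALSE]
    if (aggregate == "most-recent") {
      pick <- sub[which.max(sub$pub_year), , drop = FALSE]
      prof <- pick[, c("city", "ln_population", "lat10", "sea_salt_reported",
                       "post2005", "loc_cat")]
    } else {
      mode_of <- function(x) names(sort(table(x), decreasing = TRUE))[1L]
      prof <- data.frame(
        city = sub$city[1L],
        ln_population = mean(sub$ln_population),
        lat10 = mean(sub$lat10),
        sea_salt_reported = mean(as.numeric(sub$sea_salt_reported)) >= 0.5,
        post2005 = as.integer(mean(sub$post2005) >= 0.5),
        loc_cat = factor(mode_of(sub$loc_cat), levels = pm_loc_levels())
      )
    }
    prof$observed_overall_pm25 <- mean(sub$overall_pm25)
    prof
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Covariate row of one profile in the column order of one fitted equation.
#' @noRd
profile_row <- function(profile, columns) {
  regressors <- setdiff(columns, "(Intercept)")
  base_field <- ifelse(startsWith(regressors, "loc_"), "loc_cat", regressors)
  absent <- !(base_field %in% names(profile))
  if (any(absent)) {
    pm_stop(sprintf("city profile is missing covariate(s): %s",
                    paste(regressors[absent], collapse = ", ")),
            "pm_prediction_error")
  }
  cov <- expand_covariates(profile)
  c(1, as.numeric(cov[1L, regressors]))
}

#' Per-draw city concentrations on the natural scale
#'
#' Evaluates mu_k = eta_k + gamma_k' X_c for every posterior draw and
#' back-transforms: `"median"` uses exp(mu) (the lognormal median),
#' `"lognormal_mean"` uses exp(mu + Sigma_kk / 2). The non-traffic
#' concentration is overall minus traffic per draw; draws where traffic
#' exceeds overall keep their negative non-traffic value (they count as
#' below any positive threshold) and are tallied in `negative_nontraffic`.
#'
#' @param fit A `pm_posterior` from [fit_joint_model()].
#' @param profile One-row data.frame from [city_profiles()] (or any frame
#'   with the same covariate columns).
#' @param transform `"median"` or `"lognormal_mean"`.
#' @return Object of class `pm_city_draws`: list with `city`, vectors
#'   `traffic`, `overall`, `nontraffic` (ug/m^3, one element per draw),
#'   the transform used and the negative-non-traffic tally.
#' @export
predict_city <- function(fit, profile,
                         transform = c("median", "lognormal_mean")) {
  stopifnot(inherits(fit, "pm_posterior"))
  transform <- match.arg(transform)
  if (nrow(fit$beta) == 0L) pm_stop("empty posterior draws", "pm_prediction_error")
  if (is.list(profile) && !is.data.frame(profile)) {
    profile <- as.data.frame(profile, stringsAsFactors = FALSE)
  }
  stopifnot(nrow(profile) == 1L)
  x1 <- profile_row(profile, fit$meta$columns$traffic)
  x2 <- profile_row(profile, fit$meta$columns$overall)
  p1 <- fit$meta$p1
  mu1 <- as.numeric(fit$beta[, seq_len(p1), drop = FALSE] %*% x1)
  mu2 <- as.numeric(fit$beta[, p1 + seq_len(fit$meta$p2), drop = FALSE] %*% x2)
  if (transform == "lognormal_mean") {
    mu1 <- mu1 + fit$sigma[1, 1, ] / 2
    mu2 <- mu2 + fit$sigma[2, 2, ] / 2
  }
  traffic <- exp(mu1)
  overall <- exp(mu2)
  nontraffic <- overall - traffic
  structure(
    list(
      city = if ("city" %in% names(profile)) as.character(profile$city) else NA_character_,
      traffic = traffic, overall = overall, nontraffic = nontraffic,
      transform = transform,
      negative_nontraffic = sum(nontraffic < 0)
    ),
    class = "pm_city_draws"
  )
}

#' @export
print.pm_city_draws <- function(x, ...) {
  cat(sprintf("City %s: %d posterior draws (%s transform)\n",
              x$city, length(x$overall), x$transform))
  cat(sprintf("  mean overall %.2f, traffic %.2f, non-traffic %.2f ug/m^3\n",
              mean(x$overall), mean(x$traffic), mean(x$nontraffic)))
  invisible(x)
}

#' Probability that non-traffic PM2.5 meets or exceeds a threshold
#'
#' The fraction of posterior draws in which the expected non-traffic
#' concentration is at or above the guideline (indicator >= 1 at the
#' threshold itself).
#'
#' @param city_draws A `pm_city_draws` from [predict_city()].
#' @param threshold Guideline concentration in ug/m^3; default 5, the
#'   WHO annual guideline.
#' @return Probability in \[0, 1\].
#' @export
exceedance_probability <- function(city_draws, threshold = 5) {
  stopifnot(inherits(city_draws, "pm_city_draws"))
  if (!is.numeric(threshold) || threshold <= 0) {
    pm_stop("threshold must be a positive concentration", "pm_config_error")
  }
  if (length(city_draws$nontraffic) == 0L) {
    pm_stop("empty draws", "pm_prediction_error")
  }
  mean(city_draws$nontraffic >= threshold)
}

#' Exceedance probabilities for a set of cities
#'
#' One row per city with posterior mean concentrations, 95% intervals and
#' the exceedance probability, sorted by mean overall concentration (the
#' layout used to plot probability against overall pollution level).
#'
#' @param fit A `pm_posterior`.
#' @param profiles data.frame of city profiles from [city_profiles()].
#' @param threshold Guideline in ug/m^3 (default 5).
#' @param transform Back-transform passed to [predict_city()].
#' @return data.frame sorted by `mean_overall`.
#' @export
exceedance_curve <- function(fit, profiles, threshold = 5,
                             transform = "median") {
  stopifnot(nrow(profiles) >= 1L)
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    cd <- predict_city(fit, profiles[i, , drop = FALSE], transform = transform)
    q <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
    qo <- q(cd$overall); qt <- q(cd$traffic); qn <- q(cd$nontraffic)
    data.frame(
      city = cd$city,
      mean_traffic = mean(cd$traffic),
      traffic_lower = qt[1L], traffic_upper = qt[2L],
      mean_overall = mean(cd$overall),
      overall_lower = qo[1L], overall_upper = qo[2L],
      mean_nontraffic = mean(cd$nontraffic),
      nontraffic_lower = qn[1L], nontraffic_upper = qn[2L],
      exceedance_probability = exceedance_probability(cd, threshold),
      negative_nontraffic_draws = cd$negative_nontraffic
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_overall), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}
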