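# Shared builders for small in-memory fixtures.

# A hand-written record data.frame; defaults satisfy all invariants.
make_records <- function(n = 3L,
                         city = sprintf("City_%02d", seq_len(n)),
                         region = rep("North America", n),
                         country = rep("United States", n),
                         pub_year = rep(2010L, n),
                         population = rep(2e6, n),
                         latitude = rep(40, n),
                         site_type = rep("urban", n),
                         overall_pm25 = rep(20, n),
                         traffic_share_pct = rep(25, n),
                         sea_salt_reported = rep(FALSE, n)) {
  data.frame(
    study_id = sprintf("S%02d", seq_len(n)),
    city = city, country = country, region = region,
    pub_year = pub_year, population = population,
    latitude = latitude, longitude = rep(0, n),
    site_type = site_type, overall_pm25 = overall_pm25,
    traffic_share_pct = traffic_share_pct,
    sea_salt_reported = sea_salt_reported,
    method = rep("PMF", n),
    stringsAsFactors = FALSE
  )
}

write_records_csv <- function(records, path = tempfile(fileext = ".csv")) {
  utils::write.csv(records, path, row.names = FALSE)
  path
}

# Minimal posterior object for operations that only consume draws.
make_fake_posterior <- function(beta, sigma, chain = rep(1L, nrow(beta)),
                                columns = NULL, sigma_fixed = FALSE) {
  p <- ncol(beta)
  if (is.null(columns)) {
    columns <- list(traffic = colnames(beta)[seq_len(p / 2)],
                    overall = colnames(beta)[p / 2 + seq_len(p / 2)])
  }
  p1 <- length(columns$traffic); p2 <- length(columns$overall)
  structure(
    list(
      eta = beta[, c(1L, p1 + 1L), drop = FALSE],
      gamma1 = beta[, seq.int(2L, length.out = p1 - 1L), drop = FALSE],
      gamma2 = beta[, seq.int(p1 + 2L, length.out = p2 - 1L), drop = FALSE],
      beta = beta, sigma = sigma, chain = chain,
      iter = seq_len(nrow(beta)),
      meta = list(columns = columns, n_obs = NA_integer_, p1 = p1, p2 = p2,
                  pd_retries = 0L, sigma_fixed = sigma_fixed)
    ),
    class = "pm_posterior"
  )
}

# Intercept-only posterior: every draw predicts exp(eta) for both outcomes.
make_intercept_posterior <- function(eta1, eta2, n_draws = length(eta1),
                                     sigma = array(0, c(2, 2, n_draws))) {
  beta <- cbind(rep_len(eta1, n_draws), rep_len(eta2, n_draws))
  colnames(beta) <- c("traffic:(Intercept)", "overall:(Intercept)")
  make_fake_posterior(beta, sigma,
                      columns = list(traffic = "(Intercept)",
                                     overall = "(Intercept)"),
                      sigma_fixed = TRUE)
}

# City-draws object built directly from a non-traffic vector.
make_city_draws <- function(nontraffic, overall = nontraffic + 5,
                            traffic = overall - nontraffic) {
  structure(
    list(city = "TestCity", traffic = traffic, overall = overall,
         nontraffic = nontraffic, transform = "median",
         negative_nontraffic = sum(nontraffic < 0)),
    class = "pm_city_draws"
  )
}

# One-row covariate profile with all model covariates zero (reference
# categories, equator, one-million population).
zero_profile <- function() {
  data.frame(
    city = "ZeroCity", ln_population = 0, lat10 = 0,
    sea_salt_reported = FALSE, post2005 = 0L,
    loc_cat = factor("rest_of_world", levels = pm_loc_levels()),
    stringsAsFactors = FALSE
  )
}

# Point-mass IER draw table.
make_ier_draws <- function(n = 10L, endpoint = "COPD", theta = 0.5,
                           omega = 0.05, delta = 1, x = 4,
                           age_group = NA_character_) {
  data.frame(endpoint = endpoint, age_group = age_group, draw = seq_len(n),
              theta = theta, omega = omega, delta = delta, x = x,
              stringsAsFactors = FALSE)
}

# Access to the internal all-parameters draws matrix.
draws_matrix_for_test <- function(fit) trafficpm:::draws_matrix(fit)
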