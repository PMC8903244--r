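# Synthetic-data generator.
#
# Reads the joint lognormal meta-regression model forward: covariates are
# drawn from a configurable per-covariate law, the pair (log traffic PM2.5,
# log overall PM2.5) from a bivariate normal around the linear predictors,
# and rows whose simulated traffic exceeds the overall concentration are
# redrawn so the reported traffic share stays within (0, 100]. The returned
# truth ledger carries every generating parameter and per-row latent mean,
# which is what parameter-recovery tests score against.

#' Default covariate law
#'
#' Independent marginal distributions whose moments mirror the urban
#' subset of the WHO source-apportionment database: normal log city
#' population (millions) with mean -0.13 and sd 1.68; normal signed
#' latitude with mean 30.97 and sd 23.61 (clamped to \[-90, 90\]);
#' Bernoulli(0.5) sea-salt reporting; Bernoulli(0.742) post-2005
#' publication; categorical region with the database's observed
#' frequencies. `site_type_prob` and `share_missing_prob` allow tests to
#' inject non-urban contamination or missing traffic shares; both default
#' to clean data.
#'
#' @return Named list of distribution specifications.
#' @export
default_covariate_law <- function() {
  counts <- pm_region_counts()
  list(
    ln_population = list(mean = -0.13, sd = 1.68),
    latitude = list(mean = 30.97, sd = 23.61),
    sea_salt = list(prob = 0.5),
    post2005 = list(prob = 0.742),
    region = list(levels = names(counts), prob = as.numeric(counts) / sum(counts)),
    site_type = list(levels = c("urban", "industrial", "rural"),
                     prob = c(1, 0, 0)),
    share_missing_prob = 0,
    year_range = c(1987L, 2014L)
  )
}

#' Generator configuration
#'
#' Defines the generating model for [simulate_dataset()]: the true
#' intercepts, coefficient vectors and residual covariance of the joint
#' log-concentration model, plus the covariate law. The default truth sets
#' the intercepts and coefficients to values representative of a global
#' urban sample (traffic equation intercept 2.54; overall equation
#' intercept 3.63) and a residual covariance with log-scale standard
#' deviations 0.5 and 0.4 and correlation 0.6.
#'
#' @param n_obs Number of measurement rows.
#' @param n_cities Number of distinct cities (`<= n_obs`); cities beyond
#'   the first appearance are reused for repeat measurements.
#' @param true_eta Length-2 intercepts (traffic, overall).
#' @param true_gamma1 Coefficients of the traffic equation, in the order
#'   of `default_regressors()$traffic`.
#' @param true_gamma2 Coefficients of the overall equation, in the order
#'   of `default_regressors()$overall`.
#' @param true_sigma 2x2 symmetric positive-definite residual covariance
#'   of (log traffic, log overall).
#' @param covariate_law Per-covariate distribution list; see
#'   [default_covariate_law()].
#' @param seed Master integer seed; split internally into covariate and
#'   outcome substreams.
#' @return Object of class `pm_generator_config`.
#' @export
generator_config <- function(n_obs = 182L,
                             n_cities = 117L,
                             true_eta = c(2.54, 3.63),
                             true_gamma1 = c(0.21, 0.06, -0.29, -0.36, -1.25, -1.69),
                             true_gamma2 = c(0.08, 0.13, -0.33, -1.11, -1.49, -0.41),
                             true_sigma = matrix(c(0.25, 0.12, 0.12, 0.16), 2, 2),
                             covariate_law = default_covariate_law(),
                             seed = 1L) {
  if (n_cities > n_obs) {
    pm_stop("n_cities must not exceed n_obs", "pm_config_error")
  }
  if (!isTRUE(all.equal(true_sigma, t(true_sigma))) ||
      any(eigen(true_sigma, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    pm_stop("true_sigma must be symmetric positive definite", "pm_config_error")
  }
  prob <- covariate_law$region$prob
  if (abs(sum(prob) - 1) > 1e-8) {
    pm_stop("region probabilities must sum to 1", "pm_config_error")
  }
  structure(
    list(
      n_obs = as.integer(n_obs), n_cities = as.integer(n_cities),
      true_eta = true_eta, true_gamma1 = true_gamma1,
      true_gamma2 = true_gamma2, true_sigma = true_sigma,
      covariate_law = covariate_law, seed = as.integer(seed)
    ),
    class = "pm_generator_config"
  )
}

#' Simulate a source-apportionment dataset with known truth
#'
#' Draws city-level covariates (population, latitude, region, country),
#' per-observation covariates (publication year, sea-salt reporting,
#' estimation method), then the bivariate log-concentration outcomes from
#' the generating model. Rows where the simulated traffic concentration
#' exceeds the overall concentration are rejection-resampled (outcome pair
#' only, covariates kept) so that the implied traffic share lies in
#' (0, 100]; the number of redraws is recorded in the truth ledger.
#'
#' @param cfg A [generator_config()].
#' @return List of class `pm_simulation` with elements `records` (a
#'   data.frame round-trippable through [read_records()]) and `truth`
#'   (parameters, per-row latent means, substream seeds, rejection count).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "pm_generator_config"))
  law <- cfg$covariate_law
  seeds <- pm_sub_seeds(cfg$seed, 2L)

  set.seed(seeds[1L])  # covariate substream
  n <- cfg$n_obs
  nc <- cfg$n_cities
  countries <- pm_region_countries()
  city_region <- sample(law$region$levels, nc, replace = TRUE, prob = law$region$prob)
  city_country <- vapply(city_region, function(r) sample(countries[[r]], 1L), "")
  city_pop <- exp(stats::rnorm(nc, law$ln_population$mean, law$ln_population$sd)) * 1e6
  city_lat <- pmin(90, pmax(-90, stats::rnorm(nc, law$latitude$mean, law$latitude$sd)))
  city_lon <- stats::runif(nc, -180, 180)
  city_name <- sprintf("City_%03d", seq_len(nc))

  idx <- c(seq_len(nc), if (n > nc) sample.int(nc, n - nc, replace = TRUE))
  post <- stats::rbinom(n, 1L, law$post2005$prob)
  yr <- law$year_range
  pub_year <- ifelse(post == 1L,
                     sample(seq(max(2006L, yr[1L]), max(yr[2L], 2006L)), n, replace = TRUE),
                     sample(seq(yr[1L], 2005L), n, replace = TRUE))
  sea_salt <- stats::rbinom(n, 1L, law$sea_salt$prob) == 1L
  site_type <- sample(law$site_type$levels, n, replace = TRUE, prob = law$site_type$prob)
  method <- sample(c("PMF", "CMB", "PCA"), n, replace = TRUE)

  records <- data.frame(
    study_id = sprintf("S%03d", seq_len(n)),
    city = city_name[idx],
    country = city_country[idx],
    region = city_region[idx],
    pub_year = pub_year,
    population = city_pop[idx],
    latitude = city_lat[idx],
    longitude = city_lon[idx],
    site_type = site_type,
    overall_pm25 = NA_real_,
    traffic_share_pct = NA_real_,
    sea_salt_reported = sea_salt,
    method = method,
    stringsAsFactors = FALSE
  )

  # Linear predictors from the same covariate coding the fit will use.
  tmp <- records
  tmp$traffic_pm25 <- 1  # placeholder, not used by expand_covariates
  tmp$ln_population <- log(tmp$population / 1e6)
  tmp$lat10 <- tmp$latitude / 10
  tmp$post2005 <- as.integer(tmp$pub_year > 2005)
  tmp$loc_cat <- region_to_loc_cat(tmp$region)
  cov <- expand_covariates(tmp)
  reg <- default_regressors()
  mu1 <- cfg$true_eta[1L] +
    as.matrix(cov[, reg$traffic]) %*% cfg$true_gamma1
  mu2 <- cfg$true_eta[2L] +
    as.matrix(cov[, reg$overall]) %*% cfg$true_gamma2

  set.seed(seeds[2L])  # outcome substream
  L <- chol(cfg$true_sigma)
  draw_pairs <- function(m) matrix(stats::rnorm(2L * m), m, 2L) %*% L
  y <- cbind(mu1, mu2) + draw_pairs(n)
  rejections <- 0L
  for (round in seq_len(1000L)) {
    bad <- which(y[, 1L] > y[, 2L])
    if (!length(bad)) break
    rejections <- rejections + length(bad)
    y[bad, ] <- cbind(mu1[bad], mu2[bad]) + draw_pairs(length(bad))
  }
  if (any(y[, 1L] > y[, 2L])) {
    pm_stop("share-cap rejection sampling did not terminate", "pm_config_error")
  }

  records$overall_pm25 <- exp(y[, 2L])
  records$traffic_share_pct <- 100 * exp(y[, 1L] - y[, 2L])
  if (law$share_missing_prob > 0) {
    drop <- stats::runif(n) < law$share_missing_prob
    records$traffic_share_pct[drop] <- NA_real_
  }

  truth <- list(
    eta = cfg$true_eta,
    gamma1 = stats::setNames(cfg$true_gamma1, reg$traffic),
    gamma2 = stats::setNames(cfg$true_gamma2, reg$overall),
    sigma = cfg$true_sigma,
    rho = cfg$true_sigma[1L, 2L] / sqrt(prod(diag(cfg$true_sigma))),
    mu1 = as.numeric(mu1),
    mu2 = as.numeric(mu2),
    master_seed = cfg$seed,
    substream_seeds = list(covariates = seeds[1L], outcomes = seeds[2L]),
    rejection_redraws = rejections,
    n_obs = n,
    n_cities = nc
  )
  structure(list(records = records, truth = truth), class = "pm_simulation")
}

#' Default synthetic IER parameter law for one endpoint
#'
#' Synthetic placeholder distributions for the integrated
#' exposure-response parameters (theta, omega, delta) of the six disease
#' endpoints. These are NOT the Global Burden of Disease / Burnett draws;
#' they are invented values whose curve shapes reproduce the qualitative
#' behaviour of the published functions (shallow saturation for ischemic
#' heart disease and stroke, steeper sustained rise for COPD, lung cancer
#' and lower respiratory infections, and a diabetes curve that is
#' essentially flat above roughly 20 ug/m^3). Real draw tables can be
#' supplied as CSV wherever IER draws are accepted.
#'
#' @param endpoint One of `"IHD"`, `"stroke"`, `"COPD"`, `"lung_cancer"`,
#'   `"LRI"`, `"diabetes"`.
#' @return List of lognormal (meanlog/sdlog) specs for theta, omega,
#'   delta, a uniform range for the counterfactual threshold x, and the
#'   default age-group label (IHD and stroke only).
#' @export
default_ier_law <- function(endpoint) {
  base <- list(
    IHD         = list(theta = 0.90, omega = 0.070, delta = 0.60, age_group = "55-60"),
    stroke      = list(theta = 0.60, omega = 0.060, delta = 0.60, age_group = "55-60"),
    COPD        = list(theta = 0.35, omega = 0.015, delta = 1.10, age_group = NA_character_),
    lung_cancer = list(theta = 0.40, omega = 0.010, delta = 1.20, age_group = NA_character_),
    LRI         = list(theta = 0.50, omega = 0.020, delta = 1.10, age_group = NA_character_),
    diabetes    = list(theta = 0.30, omega = 0.100, delta = 1.20, age_group = NA_character_)
  )
  if (!endpoint %in% names(base)) {
    pm_stop(sprintf("unknown endpoint: %s", endpoint), "pm_config_error")
  }
  p <- base[[endpoint]]
  list(
    theta = list(meanlog = log(p$theta), sdlog = 0.10),
    omega = list(meanlog = log(p$omega), sdlog = 0.10),
    delta = list(meanlog = log(p$delta), sdlog = 0.05),
    x = list(min = 2.4, max = 5.9),
    age_group = p$age_group
  )
}

#' Simulate IER parameter draws for one endpoint
#'
#' Draws `n_draws` quadruples (theta, omega, delta, x): the three curve
#' parameters from the endpoint's lognormal law (point masses when sdlog
#' is 0) and the counterfactual threshold x independently from
#' Uniform(2.4, 5.9).
#'
#' @param endpoint Disease endpoint label; see [default_ier_law()].
#' @param n_draws Number of draws (default 1000).
#' @param law Parameter law; defaults to [default_ier_law()] for the
#'   endpoint.
#' @param seed Integer seed.
#' @return data.frame with columns endpoint, age_group, draw, theta,
#'   omega, delta, x.
#' @export
simulate_ier_draws <- function(endpoint, n_draws = 1000L,
                               law = default_ier_law(endpoint), seed = 1L) {
  for (nm in c("theta", "omega", "delta")) {
    if (law[[nm]]$sdlog < 0 || !is.finite(law[[nm]]$meanlog)) {
      pm_stop(sprintf("IER parameter %s must have positive support", nm),
              "pm_config_error")
    }
  }
  set.seed(as.integer(seed))
  rl <- function(spec, n) {
    if (spec$sdlog == 0) rep(exp(spec$meanlog), n)
    else stats::rlnorm(n, spec$meanlog, spec$sdlog)
  }
  data.frame(
    endpoint = endpoint,
    age_group = law$age_group %||% NA_character_,
    draw = seq_len(n_draws),
    theta = rl(law$theta, n_draws),
    omega = rl(law$omega, n_draws),
    delta = rl(law$delta, n_draws),
    x = stats::runif(n_draws, law$x$min, law$x$max),
    stringsAsFactors = FALSE
  )
}

PM_ENDPOINTS <- c("IHD", "stroke", "COPD", "lung_cancer", "LRI", "diabetes")

#' Write a named synthetic fixture to disk
#'
#' Generates a deterministic dataset plus its truth ledger and a synthetic
#' IER draw table for all six endpoints, and writes them as plain-text
#' files (`records.csv`, `truth.json`, `ier_draws.csv`). Two fixtures are
#' packaged: `"small"` (50 observations, 30 cities; fast end-to-end runs)
#' and `"paper_scale"` (182 observations, 117 cities, the size of the
#' urban subset of the WHO database). Regenerating a fixture is
#' byte-identical because all seeds are fixed constants.
#'
#' @param name `"small"` or `"paper_scale"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of file paths written.
#' @export
make_fixture <- function(name, dir) {
  specs <- list(
    small = list(n_obs = 50L, n_cities = 30L, seed = 11001L, ier_seed = 21001L),
    paper_scale = list(n_obs = 182L, n_cities = 117L, seed = 11002L, ier_seed = 21002L)
  )
  if (!name %in% names(specs)) {
    pm_stop(sprintf("unknown fixture name: %s", name), "pm_config_error")
  }
  sp <- specs[[name]]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(generator_config(
    n_obs = sp$n_obs, n_cities = sp$n_cities, seed = sp$seed
  ))
  ier <- do.call(rbind, lapply(seq_along(PM_ENDPOINTS), function(i) {
    simulate_ier_draws(PM_ENDPOINTS[i], n_draws = 1000L,
                       seed = sp$ier_seed + i)
  }))
  paths <- c(
    records = file.path(dir, sprintf("%s_records.csv", name)),
    truth = file.path(dir, sprintf("%s_truth.json", name)),
    ier = file.path(dir, sprintf("%s_ier_draws.csv", name))
  )
  utils::write.csv(sim$records, paths[["records"]], row.names = FALSE)
  jsonlite::write_json(sim$truth, paths[["truth"]], digits = NA, auto_unbox = TRUE)
  utils::write.csv(ier, paths[["ier"]], row.names = FALSE)
  invisible(paths)
}
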