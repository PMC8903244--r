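# Reading, filtering, curation and design construction.

test_that("read_records parses a well-formed CSV and round-trips the generator", {
  path <- write_records_csv(make_records(3L))
  recs <- read_records(path)
  expect_equal(nrow(recs), 3L)
  expect_setequal(names(recs), names(default_dialect()))

  sim <- simulate_dataset(generator_config(n_obs = 182L, n_cities = 117L, seed = 42L))
  p2 <- write_records_csv(sim$records)
  expect_equal(nrow(read_records(p2)), 182L)
})

test_that("read_records reports invalid rows by number instead of dropping them", {
  bad <- make_records(3L)
  bad$overall_pm25[2L] <- -4
  path <- write_records_csv(bad)
  err <- expect_error(read_records(path), class = "pm_validation_error")
  expect_match(conditionMessage(err), "row 2")

  bad2 <- make_records(2L)
  bad2$latitude[1L] <- 95
  expect_error(read_records(write_records_csv(bad2)), class = "pm_validation_error")
  bad3 <- make_records(2L)
  bad3$traffic_share_pct[2L] <- 101
  expect_error(read_records(write_records_csv(bad3)), class = "pm_validation_error")
})

test_that("read_records flags configuration and data errors", {
  recs <- make_records(2L)
  recs$overall_pm25 <- NULL
  path <- write_records_csv(recs)
  expect_error(read_records(path), class = "pm_config_error")

  empty <- tempfile(fileext = ".csv")
  writeLines(paste(default_dialect(), collapse = ","), empty)
  expect_error(read_records(empty), class = "pm_data_error")
  expect_error(read_records(tempfile()), class = "pm_config_error")
})

test_that("read_records honours a custom column dialect", {
  recs <- make_records(2L)
  names(recs)[names(recs) == "overall_pm25"] <- "PM25_total"
  path <- write_records_csv(recs)
  dialect <- default_dialect()
  dialect["overall_pm25"] <- "PM25_total"
  got <- read_records(path, dialect)
  expect_equal(got$overall_pm25, c(20, 20))
})

test_that("filter_records keeps urban records with a traffic share and logs removals", {
  recs <- make_records(3L,
                       site_type = c("urban", "industrial", "urban"),
                       traffic_share_pct = c(25, 25, NA))
  kept <- filter_records(recs)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$study_id, "S01")
  log <- attr(kept, "retention_log")
  expect_equal(log$removed_non_urban, 1L)
  expect_equal(log$removed_missing_traffic_share, 1L)

  clean <- make_records(4L)
  expect_equal(filter_records(clean)[, names(clean)], clean)

  all_bad <- make_records(2L, site_type = c("rural", "industrial"))
  expect_error(filter_records(all_bad), class = "pm_data_error")
})

test_that("filter_records is idempotent and matches a brute-force recount", {
  law <- default_covariate_law()
  law$site_type$prob <- c(0.8, 0.1, 0.1)
  law$share_missing_prob <- 0.1
  sim <- simulate_dataset(generator_config(n_obs = 200L, n_cities = 150L,
                                           covariate_law = law, seed = 99L))
  once <- filter_records(sim$records)
  twice <- filter_records(once)
  expect_equal(nrow(once), nrow(twice))
  expect_equal(once$study_id, twice$study_id)
  # independent recount straight off the raw labels
  expect_equal(nrow(once),
               sum(sim$records$site_type == "urban" &
                     !is.na(sim$records$traffic_share_pct)))
})

test_that("curate_records derives analysis variables correctly", {
  recs <- make_records(2L, overall_pm25 = c(20, 40),
                       traffic_share_pct = c(25, 50),
                       population = c(1e6, 5e6), latitude = c(30, -41.27),
                       pub_year = c(2005L, 2006L))
  cur <- curate_records(recs)
  expect_equal(cur$traffic_pm25, c(5, 20))
  expect_equal(cur$ln_population, c(0, log(5)))
  expect_equal(cur$lat10, c(3, -4.127))
  expect_equal(cur$post2005, c(0L, 1L))  # strictly after the cut year
})

test_that("a Japanese city falls in the North America/Oceania/Japan category", {
  recs <- make_records(1L, country = "Japan", region = "Oceania/Japan")
  cur <- curate_records(recs)
  expect_equal(as.character(cur$loc_cat), "NA_Oceania_Japan")
})

test_that("curate_records rejects undefined inputs and logs exclusions", {
  bad_pop <- make_records(2L, population = c(2e6, -1))
  expect_error(curate_records(bad_pop), class = "pm_validation_error")

  recs <- make_records(3L)
  recs$traffic_share_pct[2L] <- 0      # log-traffic undefined
  recs$latitude[3L] <- NA              # incomplete covariates
  cur <- curate_records(recs)
  expect_equal(nrow(cur), 1L)
  log <- attr(cur, "curation_log")
  expect_equal(log$rejected_zero_traffic_share, 2L)
  expect_equal(log$excluded_incomplete_covariates, 3L)
})

test_that("curated records satisfy the traffic <= overall invariant", {
  sim <- simulate_dataset(generator_config(n_obs = 300L, n_cities = 200L, seed = 7L))
  cur <- curate_records(filter_records(sim$records))
  expect_true(all(cur$traffic_pm25 > 0))
  expect_true(all(cur$traffic_pm25 <= cur$overall_pm25 + 1e-12))
})

test_that("build_design produces the default regressor sets and log outcomes", {
  sim <- simulate_dataset(generator_config(n_obs = 40L, n_cities = 30L, seed = 12L))
  cur <- curate_records(filter_records(sim$records))
  dm <- build_design(cur)
  expect_equal(ncol(dm$X1), 6L)
  expect_equal(ncol(dm$X2), 6L)
  expect_equal(colnames(dm$X1), default_regressors()$traffic)
  expect_equal(colnames(dm$X2), default_regressors()$overall)
  expect_equal(dm$y1, log(cur$traffic_pm25))
  expect_equal(dm$y2, log(cur$overall_pm25))
  # mutually exclusive location dummies
  loc_cols <- grep("^loc_", colnames(dm$X2))
  expect_true(all(rowSums(dm$X2[, loc_cols]) <= 1))

  single <- curate_records(make_records(1L, latitude = 30))
  expect_equal(unname(build_design(single)$X1[1L, "lat10"]), 3)

  expect_error(build_design(cur, list(traffic = "no_such", overall = "lat10")),
               class = "pm_config_error")
})

test_that("permuting input rows permutes design rows identically", {
  sim <- simulate_dataset(generator_config(n_obs = 25L, n_cities = 20L, seed = 3L))
  cur <- curate_records(filter_records(sim$records))
  dm <- build_design(cur)
  perm <- sample(nrow(cur))
  dmp <- build_design(cur[perm, , drop = FALSE])
  expect_equal(dmp$y1, dm$y1[perm])
  expect_equal(unname(dmp$X2), unname(dm$X2[perm, , drop = FALSE]))
})

test_that("descriptive_summary matches an independent pass over the rows", {
  two <- curate_records(make_records(2L, overall_pm25 = c(10, 30)))
  s <- descriptive_summary(two)
  conc <- s$concentrations[s$concentrations$outcome == "overall_pm25", ]
  expect_equal(conc$mean, 20)
  expect_equal(conc$min, 10)
  expect_equal(conc$max, 30)
  expect_equal(s$regions$percent[s$regions$region == "North America"], 100)

  sim <- simulate_dataset(generator_config(n_obs = 120L, n_cities = 80L, seed = 5L))
  cur <- curate_records(filter_records(sim$records))
  s2 <- descriptive_summary(cur)
  expect_equal(s2$covariates$mean[s2$covariates$variable == "ln_population"],
               sum(log(cur$population / 1e6)) / nrow(cur))
  expect_equal(s2$concentrations$sd[1L], stats::sd(cur$overall_pm25))
  expect_equal(sum(s2$regions$percent), 100, tolerance = 0.01)
})
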