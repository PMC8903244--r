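# End-to-end orchestration: curate -> fit -> predict -> exceedance ->
# health impact, with a JSON run manifest that records the configuration,
# seed, per-stage row counts and warning counters needed to re-execute
# the run exactly.

#' Default pipeline configuration
#'
#' Every analysis default mirrors the protocol of the published WHO
#' database analysis: normal(0, 100) coefficient priors, Wishart(K = 2,
#' R = diag(0.01)) precision prior, two chains of 15,000 iterations with
#' 5,000 burn-in, guideline threshold 5 ug/m^3, 1000 IER draws and all
#' six disease endpoints.
#'
#' @param records Path to the records CSV.
#' @param ier_draws Optional path to an IER draw CSV (columns endpoint,
#'   age_group, draw, theta, omega, delta, x); when `NULL`, synthetic
#'   draws are generated from [default_ier_law()].
#' @param out_dir Output directory for all artifacts.
#' @param seed Master seed (substreams derived internally).
#' @return Nested configuration list.
#' @export
default_run_config <- function(records = NULL, ier_draws = NULL,
                               out_dir = NULL, seed = 1L) {
  list(
    paths = list(records = records, ier_draws = ier_draws, out_dir = out_dir),
    dialect = as.list(default_dialect()),
    regressors = default_regressors(),
    priors = list(coef_mean = 0, coef_var = 100, wishart_df = 2,
                  wishart_scale_diag = 0.01),
    mcmc = list(n_chains = 2L, n_iter = 15000L, n_burn = 5000L,
                init_dispersion = 2.5),
    transform = "median",
    threshold = 5,
    aggregate = "most-recent",
    endpoints = PM_ENDPOINTS,
    n_ier_draws = 1000L,
    year_cut = 2005L,
    seed = as.integer(seed)
  )
}

#' @noRd
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      pm_stop(sprintf("config file not found: %s", config), "pm_config_error")
    }
    user <- yaml::read_yaml(config)
  } else if (is.list(config)) {
    user <- config
  } else {
    pm_stop("config must be a path to a YAML file or a list", "pm_config_error")
  }
  base <- default_run_config()
  merge_cfg <- function(base, user) {
    for (nm in names(user)) {
      if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
          !is.null(names(base[[nm]]))) {
        base[[nm]] <- merge_cfg(base[[nm]], user[[nm]])
      } else {
        base[[nm]] <- user[[nm]]
      }
    }
    base
  }
  merge_cfg(base, user)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: read and validate records, apply the urban /
#' traffic-share filter, curate, build the design matrices, fit the joint
#' model, run convergence diagnostics, build city profiles, compute the
#' exceedance table, and compute the city-by-endpoint PAF table. Any
#' stage failure halts with the stage name in the error message. All
#' artifacts (curated CSV, tidy posterior-draw CSV, diagnostics CSV, city
#' table CSV, PAF table CSV, JSON manifest) are written to the output
#' directory.
#'
#' @param config A configuration list (see [default_run_config()]) or a
#'   path to a YAML file of overrides.
#' @param through Last stage to execute: one of `"curate"`, `"fit"`,
#'   `"predict"`, `"exceedance"`, `"health_impact"` (default, the full
#'   pipeline).
#' @return Invisibly, the run manifest list.
#' @export
run_pipeline <- function(config, through = "health_impact") {
  cfg <- load_run_config(config)
  stages <- c("curate", "fit", "predict", "exceedance", "health_impact")
  through <- match.arg(through, stages)
  stage_rank <- match(through, stages)
  out_dir <- cfg$paths$out_dir
  if (is.null(out_dir)) pm_stop("config must set paths$out_dir", "pm_config_error")
  if (is.null(cfg$paths$records)) {
    pm_stop("config must set paths$records", "pm_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- pm_sub_seeds(cfg$seed, 2L)  # fit, IER
  manifest <- list(
    package_version = as.character(utils::packageVersion("trafficpm")),
    config = cfg, stages = list(), warnings = list()
  )
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      pm_stop(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)),
              "pm_pipeline_error")
    })
  }

  # -- curate ---------------------------------------------------------
  curated <- run_stage("curate", {
    recs <- read_records(cfg$paths$records,
                         dialect = unlist(cfg$dialect)[PM_RECORD_FIELDS])
    kept <- filter_records(recs)
    cur <- curate_records(kept, year_cut = cfg$year_cut)
    retention <- attr(kept, "retention_log")
    curation <- attr(cur, "curation_log")
    jsonlite::write_json(
      list(retention = retention, curation = curation),
      file.path(out_dir, "retention_log.json"),
      auto_unbox = TRUE, digits = NA
    )
    utils::write.csv(cur, file.path(out_dir, "curated.csv"), row.names = FALSE)
    manifest$stages$curate <- list(
      n_read = retention$n_input, n_filtered = retention$n_retained,
      n_curated = nrow(cur)
    )
    cur
  })
  if (stage_rank == 1L) return(finish_manifest(manifest, out_dir))

  # -- fit ------------------------------------------------------------
  fit <- run_stage("fit", {
    dm <- build_design(curated, formula_cfg = cfg$regressors)
    priors <- pm_priors(
      coef_mean = cfg$priors$coef_mean, coef_var = cfg$priors$coef_var,
      wishart_df = cfg$priors$wishart_df,
      wishart_scale = diag(cfg$priors$wishart_scale_diag, 2)
    )
    mc <- mcmc_config(
      n_chains = cfg$mcmc$n_chains, n_iter = cfg$mcmc$n_iter,
      n_burn = cfg$mcmc$n_burn, seed = seeds[1L],
      init_dispersion = cfg$mcmc$init_dispersion
    )
    f <- fit_joint_model(dm, priors, mc)
    write_draws_csv(f, file.path(out_dir, "posterior_draws.csv"))
    diag_tab <- if (cfg$mcmc$n_chains >= 2L) gelman_rubin(f) else NULL
    if (!is.null(diag_tab)) {
      utils::write.csv(diag_tab, file.path(out_dir, "diagnostics.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(posterior_summary(f),
                     file.path(out_dir, "posterior_summary.csv"),
                     row.names = FALSE)
    rho <- posterior_correlation(f)
    manifest$stages$fit <- list(
      n_draws = nrow(f$beta), n_chains = cfg$mcmc$n_chains,
      pd_retries = f$meta$pd_retries,
      max_rhat = if (!is.null(diag_tab)) max(diag_tab$rhat) else NA_real_,
      n_flagged = if (!is.null(diag_tab)) sum(diag_tab$flagged) else NA_integer_,
      correlation_mean = rho$mean, correlation_sd = rho$sd
    )
    f
  })
  if (stage_rank == 2L) return(finish_manifest(manifest, out_dir))

  # -- predict --------------------------------------------------------
  profiles <- run_stage("predict", {
    prof <- city_profiles(curated, aggregate = cfg$aggregate)
    utils::write.csv(prof, file.path(out_dir, "city_profiles.csv"),
                     row.names = FALSE)
    manifest$stages$predict <- list(n_cities = nrow(prof),
                                    aggregate = cfg$aggregate)
    prof
  })
  if (stage_rank == 3L) return(finish_manifest(manifest, out_dir))

  # -- exceedance -----------------------------------------------------
  city_tab <- run_stage("exceedance", {
    tab <- exceedance_curve(fit, profiles, threshold = cfg$threshold,
                            transform = cfg$transform)
    utils::write.csv(tab, file.path(out_dir, "city_table.csv"), row.names = FALSE)
    manifest$stages$exceedance <- list(
      n_cities = nrow(tab), threshold = cfg$threshold,
      transform = cfg$transform,
      negative_nontraffic_draws = sum(tab$negative_nontraffic_draws)
    )
    tab
  })
  if (stage_rank <= 4L) return(finish_manifest(manifest, out_dir))

  # -- health impact --------------------------------------------------
  run_stage("health_impact", {
    ier <- if (!is.null(cfg$paths$ier_draws)) {
      utils::read.csv(cfg$paths$ier_draws, stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(seq_along(cfg$endpoints), function(i) {
        simulate_ier_draws(cfg$endpoints[i], n_draws = cfg$n_ier_draws,
                           seed = seeds[2L] %% 2000000000L + i)
      }))
    }
    ier <- ier[ier$endpoint %in% cfg$endpoints, , drop = FALSE]
    pairs <- lapply(seq_len(nrow(profiles)), function(i) {
      cd <- predict_city(fit, profiles[i, , drop = FALSE],
                         transform = cfg$transform)
      counterfactual_pair(cd)
    })
    paf_tab <- benefit_curve(pairs, ier)
    utils::write.csv(paf_tab, file.path(out_dir, "paf_table.csv"),
                     row.names = FALSE)
    manifest$stages$health_impact <- list(
      n_rows = nrow(paf_tab), endpoints = unique(paf_tab$endpoint),
      n_ier_draws_per_endpoint = nrow(ier) / length(unique(ier$endpoint)),
      n_floored_counterfactuals = sum(vapply(pairs, `[[`, TRUE, "floored"))
    )
    paf_tab
  })
  finish_manifest(manifest, out_dir)
}

#' @noRd
finish_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}

# Tidy persistence of the posterior: one row per chain x iteration x
# scalar parameter.
#' @noRd
write_draws_csv <- function(fit, path) {
  dm <- draws_matrix(fit)
  tidy <- data.frame(
    chain = rep(fit$chain, times = ncol(dm)),
    iter = rep(fit$iter, times = ncol(dm)),
    parameter = rep(colnames(dm), each = nrow(dm)),
    value = as.numeric(dm)
  )
  utils::write.csv(tidy, path, row.names = FALSE)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a named synthetic fixture), `curate`,
#' `fit`, `predict`, `exceedance`, `health-impact` (run the pipeline up
#' to the named stage) and `run-all` (the full pipeline). All
#' pipeline subcommands take `--config <yaml>` plus optional overrides
#' `--records`, `--ier-draws`, `--out`, `--seed`; `simulate` takes
#' `--name` and `--dir`. Errors print a one-line cause to stderr.
#'
#' @param args Character vector of command-line tokens (defaults to the
#'   process arguments).
#' @return Integer exit status, invisibly: 0 on success, 1 on failure,
#'   2 on usage error.
#' @export
pm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: trafficpm <subcommand> [options]",
    "  simulate       --name <small|paper_scale> --dir <path>",
    "  curate         --config <yaml> | --records <csv> --out <dir> [--seed <int>]",
    "  fit            (same options; runs through model fitting)",
    "  predict        (same options; runs through city prediction)",
    "  exceedance     (same options; runs through the exceedance table)",
    "  health-impact  (same options; full pipeline)",
    "  run-all        (same options; full pipeline)",
    sep = "\n"
  )
  if (length(args) == 0L) {
    message(usage)
    return(invisible(2L))
  }
  sub <- args[[1L]]
  opts <- parse_cli_flags(args[-1L])
  if (is.character(opts$error)) {
    message(opts$error, "\n", usage)
    return(invisible(2L))
  }
  status <- tryCatch({
    if (sub == "simulate") {
      if (is.null(opts$name) || is.null(opts$dir)) {
        message("simulate requires --name and --dir\n", usage)
        return(invisible(2L))
      }
      paths <- make_fixture(opts$name, opts$dir)
      message(sprintf("wrote fixture '%s': %s", opts$name,
                      paste(paths, collapse = ", ")))
      0L
    } else if (sub %in% c("curate", "fit", "predict", "exceedance",
                          "health-impact", "run-all")) {
      through <- switch(sub,
        "curate" = "curate", "fit" = "fit", "predict" = "predict",
        "exceedance" = "exceedance",
        "health-impact" = , "run-all" = "health_impact"
      )
      cfg <- if (!is.null(opts$config)) load_run_config(opts$config)
             else default_run_config()
      if (!is.null(opts$records)) cfg$paths$records <- opts$records
      if (!is.null(opts$`ier-draws`)) cfg$paths$ier_draws <- opts$`ier-draws`
      if (!is.null(opts$out)) cfg$paths$out_dir <- opts$out
      if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
      manifest <- run_pipeline(cfg, through = through)
      message(sprintf("pipeline complete through '%s'; artifacts in %s",
                      through, cfg$paths$out_dir))
      0L
    } else {
      message(sprintf("unknown subcommand: %s\n%s", sub, usage))
      2L
    }
  }, error = function(e) {
    message(sprintf("error: %s", conditionMessage(e)))
    1L
  })
  invisible(status)
}

#' @noRd
parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) {
      return(list(error = sprintf("unexpected token: %s", a)))
    }
    key <- substring(a, 3L)
    if (i == length(args)) {
      return(list(error = sprintf("flag --%s needs a value", key)))
    }
    opts[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  known <- c("name", "dir", "config", "records", "ier-draws", "out", "seed")
  bad <- setdiff(names(opts), known)
  if (length(bad)) {
    return(list(error = sprintf("unknown flag(s): %s",
                                paste0("--", bad, collapse = ", "))))
  }
  opts
}
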