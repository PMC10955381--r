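#' Pipeline configuration
#'
#' Assembles and validates the settings of an end-to-end run. Either an
#' input CSV (`input`) or generator parameters (`simulate = TRUE`, with
#' `scm`) must be given. The seed is mandatory: every stochastic stage
#' derives from it.
#'
#' @param output_dir writable output directory (created if absent).
#' @param seed integer seed.
#' @param input path to a survey CSV (optional if simulating).
#' @param simulate generate data with [simulate_population()] instead of
#'   reading `input`.
#' @param scm an [scm_params()] (used when `simulate = TRUE`).
#' @param outcomes outcome columns to fit.
#' @param exposures exposures to g-compute.
#' @param chains,iter_warmup,iter_sampling sampler size.
#' @param education_levels counterfactual education grid.
#' @param strata_path optional stratum-weight CSV for poststratification.
#' @param dag_path optional DAG edge-list path (default: the built-in
#'   study DAG).
#' @param rhat_gate abort when any monitored R-hat exceeds this (set
#'   `Inf` to override).
#' @param max_gcomp_draws thin the posterior to at most this many draws
#'   for g-computation (memory guard).
#' @param adapt_delta sampler target acceptance.
#' @param verbose print progress.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, seed, input = NULL, simulate = is.null(input),
                            scm = scm_params(seed = seed),
                            outcomes = c("think_freq", "ritual_freq"),
                            exposures = c("food_insecure", "education"),
                            chains = 4L, iter_warmup = 1000L,
                            iter_sampling = 1000L,
                            education_levels = seq(0, 30, 5),
                            strata_path = NULL, dag_path = NULL,
                            rhat_gate = 1.01, max_gcomp_draws = 1000L,
                            adapt_delta = 0.8, verbose = TRUE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (!simulate && is.null(input)) {
    stop("either input or simulate = TRUE is required", call. = FALSE)
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("input not readable: ", input, call. = FALSE)
  }
  stopifnot(all(outcomes %in% c("think_freq", "ritual_freq")),
            all(exposures %in% c("food_insecure", "education")))
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 input = input, simulate = simulate, scm = scm,
                 outcomes = outcomes, exposures = exposures,
                 chains = as.integer(chains),
                 iter_warmup = as.integer(iter_warmup),
                 iter_sampling = as.integer(iter_sampling),
                 education_levels = education_levels,
                 strata_path = strata_path, dag_path = dag_path,
                 rhat_gate = rhat_gate,
                 max_gcomp_draws = as.integer(max_gcomp_draws),
                 adapt_delta = adapt_delta, verbose = verbose),
            class = "pipeline_config")
}

config_hash <- function(config) {
  flat <- config
  # the hash identifies the analysis, not where it is written or how loud
  flat$verbose <- NULL
  flat$output_dir <- NULL
  txt <- paste(utils::capture.output(utils::str(flat, digits.d = 12)),
               collapse = "\n")
  md5_of_text(txt)
}

#' Read a pipeline config from a flat key-value file
#'
#' Lines `key: value`; list-valued keys comma-separated; `scm.*` keys are
#' forwarded to [scm_params()]. Keys mirror the arguments of
#' [pipeline_config()].
#'
#' @param path config file path.
#' @param ... overrides applied after the file (flag-style overrides).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  kv <- read_keyvalue(path)
  scm_keys <- grep("^scm\\.", names(kv), value = TRUE)
  args <- list()
  for (k in setdiff(names(kv), scm_keys)) {
    v <- kv[[k]]
    args[[k]] <- switch(k,
      outcomes = , exposures = strsplit(v, ",\\s*")[[1]],
      education_levels = as.numeric(strsplit(v, ",")[[1]]),
      input = , output_dir = , strata_path = , dag_path = v,
      simulate = , verbose = as.logical(v),
      as.numeric(v))
  }
  if (length(scm_keys)) {
    scm_args <- lapply(kv[scm_keys], function(v) as.numeric(strsplit(v, ",")[[1]]))
    names(scm_args) <- sub("^scm\\.", "", scm_keys)
    args$scm <- do.call(scm_params, scm_args)
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}

pipeline_log <- function(lines, con, verbose) {
  writeLines(lines, con)
  if (verbose) message(paste(lines, collapse = "\n"))
}

#' Run the full pipeline
#'
#' Orchestrates the analysis end to end: DAG identification checks, data
#' read or simulation, schema validation and complete-case filtering, one
#' multilevel ordered-logit fit per outcome, a convergence gate (abort on
#' R-hat above `rhat_gate`), g-computation over every requested exposure,
#' optional poststratification, and tidy CSV outputs. Every output embeds
#' the config hash and seed; reruns with the same config are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the fits, summaries, contrasts, file
#'   paths and the log path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  logpath <- file.path(config$output_dir, "run_log.txt")
  logcon <- file(logpath, "w")
  on.exit(close(logcon))
  log <- function(...) pipeline_log(sprintf(...), logcon, config$verbose)
  log("ordgcomp pipeline | config_hash: %s | seed: %d", hash, config$seed)
  log("package version: %s | R: %s",
      as.character(utils::packageVersion("ordgcomp")),
      paste(R.version$major, R.version$minor, sep = "."))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log("stage %s FAILED: %s", name, conditionMessage(e))
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- identification ---
  stage("validate-dag", {
    dag <- if (is.null(config$dag_path)) build_study_dag() else
      read_dag(config$dag_path)
    adj <- c("Sex", "Age", "Education", "Children")
    adj <- intersect(adj, dag$nodes)
    ok_m <- backdoor_valid(dag, "FoodInsecurity", "Religiosity", adj)
    ok_e <- backdoor_valid(dag, "Education", "Religiosity",
                           intersect(c("Sex", "Age"), dag$nodes))
    log("dag: %d nodes, %d edges; backdoor ok (food insecurity): %s; (education): %s",
        length(dag$nodes), nrow(dag$edges), ok_m, ok_e)
    if (!ok_m || !ok_e) {
      stop("adjustment sets invalid for the supplied DAG", call. = FALSE)
    }
  })

  # --- data ---
  tab <- stage("data", {
    if (config$simulate) {
      scm <- config$scm
      log("simulating: %d sites x %d (seed %d)", scm$n_sites, scm$n_per_site,
          scm$seed)
      simulate_population(scm)
    } else {
      t <- read_survey_csv(config$input)
      inv <- attr(t, "invalid")
      log("read %s: %d rows, %d invalid cells flagged", config$input, nrow(t),
          nrow(inv))
      if (nrow(inv)) t <- t[-unique(inv$row), , drop = FALSE]
      t
    }
  })
  n_input <- nrow(tab)

  results <- list(config = config, hash = hash, files = character(0))
  strata <- if (!is.null(config$strata_path)) {
    stage("strata", read_strata_csv(config$strata_path))
  } else NULL

  for (outcome in config$outcomes) {
    vars <- c("site", "sex", "age", "education", "children", "food_insecure",
              outcome)
    cc <- stage("complete-cases", complete_cases(tab, vars, quiet = TRUE))
    log("outcome %s: input %d = used %d + dropped %d (complete-case)",
        outcome, n_input, nrow(cc), attr(cc, "dropped"))
    spec <- model_spec_from_data(cc, outcome = outcome)
    fit <- stage("fit", {
      log("fitting %s: %d chains x (%d + %d)", outcome, config$chains,
          config$iter_warmup, config$iter_sampling)
      fit_ordinal(cc, spec, chains = config$chains,
                  iter_warmup = config$iter_warmup,
                  iter_sampling = config$iter_sampling,
                  seed = config$seed, adapt_delta = config$adapt_delta)
    })
    diag <- stage("diagnostics", fit_diagnostics(fit))
    log("diagnostics %s: max R-hat %.4f, divergences %d", outcome,
        diag$max_rhat, diag$divergences)
    if (is.finite(config$rhat_gate) && !is.na(diag$max_rhat) &&
        diag$max_rhat > config$rhat_gate) {
      log("non-convergence: R-hat gate %.3f exceeded", config$rhat_gate)
      stop("[diagnostics] non-convergence: max R-hat ",
           sprintf("%.4f", diag$max_rhat), " exceeds gate ", config$rhat_gate,
           call. = FALSE)
    }
    dpath <- file.path(config$output_dir, paste0("draws_", outcome, ".csv"))
    write_draws_csv(fit, dpath)
    results$files <- c(results$files, dpath)
    results[[paste0("fit_", outcome)]] <- fit
    results[[paste0("diagnostics_", outcome)]] <- diag

    draw_ids <- thin_draw_ids(n_draws(fit), config$max_gcomp_draws)
    for (exposure in config$exposures) {
      grid <- if (exposure == "education") {
        exposure_grid("education", config$education_levels)
      } else exposure_grid("food_insecure")
      po <- stage("gcomp", impute_potential_outcomes(fit, cc, grid, draw_ids))
      summ <- marginalize(po)
      meta <- c(config_hash = hash, seed = as.character(config$seed),
                outcome = outcome, exposure = exposure)
      spath <- file.path(config$output_dir,
                         sprintf("gcomp_%s_%s.csv", outcome, exposure))
      write_summary_csv(summ, spath, meta)
      results$files <- c(results$files, spath)
      ctr <- contrast_levels(po, min(grid$levels), max(grid$levels))
      cpath <- file.path(config$output_dir,
                         sprintf("contrast_%s_%s.csv", outcome, exposure))
      write_summary_csv(ctr, cpath, meta)
      results$files <- c(results$files, cpath)
      results[[sprintf("summary_%s_%s", outcome, exposure)]] <- summ
      results[[sprintf("contrast_%s_%s", outcome, exposure)]] <- ctr
      log("gcomp %s/%s: %d levels, %d draws", outcome, exposure,
          length(grid$levels), length(draw_ids))
      if (!is.null(strata)) {
        ps <- stage("poststratify", poststratify(po, strata, cc))
        ppath <- file.path(config$output_dir,
                           sprintf("poststrat_%s_%s.csv", outcome, exposure))
        write_summary_csv(ps, ppath, meta)
        results$files <- c(results$files, ppath)
        results[[sprintf("poststrat_%s_%s", outcome, exposure)]] <- ps
      }
    }
  }
  log("done: %d output files", length(results$files))
  results$log <- logpath
  invisible(results)
}

# Evenly spaced draw thinning (deterministic).
thin_draw_ids <- function(n, max_n) {
  if (n <= max_n) return(seq_len(n))
  unique(round(seq(1L, n, length.out = max_n)))
}
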