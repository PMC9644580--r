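#' Analysis configuration
#'
#' Collects everything a full run needs: where to write outputs, the
#' engine settings, the synthetic-cohort settings used by the `simulate`
#' stage, the PSA size, and the population-scaling assumption. Can be
#' populated from a YAML/JSON file with [read_analysis_config()].
#'
#' @param output_dir directory for the report bundle (created if absent).
#' @param engine a [engine_config()].
#' @param truth a [ground_truth()] driving the synthetic `simulate` stage;
#'   set to `NULL` when `histories_file` points at existing records.
#' @param histories_file optional CSV of existing state histories
#'   (`patient_id,cycle,state`); overrides simulation.
#' @param strategies named list of [strategy_mix()] objects.
#' @param n_draws PSA draws.
#' @param patients_per_year annual treated patients for population
#'   scaling.
#' @param base_strategy comparison base for the strategy table.
#' @param seed top-level seed; stage seeds are expanded from it and
#'   recorded in the manifest.
#' @param verbose print stage progress to stderr.
#' @return object of class `cad_analysis_config`.
#' @export
analysis_config <- function(output_dir,
                            engine = engine_config(),
                            truth = default_ground_truth(),
                            histories_file = NULL,
                            strategies = default_strategies(),
                            n_draws = 1000L,
                            patients_per_year = 6000,
                            base_strategy = "current_practice",
                            seed = 1L,
                            verbose = FALSE) {
  if (!is.null(histories_file) && !file.exists(histories_file)) {
    stop("histories_file does not exist: ", histories_file)
  }
  structure(
    list(output_dir = output_dir, engine = engine, truth = truth,
         histories_file = histories_file, strategies = strategies,
         n_draws = as.integer(n_draws),
         patients_per_year = patients_per_year,
         base_strategy = base_strategy, seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "cad_analysis_config"
  )
}

#' Read an analysis configuration from YAML or JSON
#'
#' Recognised top-level keys: `output_dir`, `seed`, `n_draws`,
#' `patients_per_year`, `base_strategy`, `histories_file`, `engine`
#' (fields of [engine_config()]), `cohort` (fields `n_patients`,
#' `n_cycles` of the default ground truth), and `strategies` (name ->
#' map of arm weights). Unspecified values fall back to the package
#' defaults.
#'
#' @param path YAML or JSON file.
#' @return a [analysis_config()] object.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  eng <- do.call(engine_config, as.list(raw$engine %||% list()))
  seed <- raw$seed %||% 1L
  cohort <- raw$cohort %||% list()
  truth <- default_ground_truth(
    n_patients = cohort$n_patients %||% 10000L,
    n_cycles = cohort$n_cycles %||% 20L,
    seed = seed
  )
  strategies <- if (is.null(raw$strategies)) default_strategies() else {
    out <- lapply(names(raw$strategies), function(nm) {
      strategy_mix(nm, unlist(raw$strategies[[nm]]))
    })
    stats::setNames(out, names(raw$strategies))
  }
  analysis_config(
    output_dir = raw$output_dir %||% ".",
    engine = eng, truth = truth,
    histories_file = raw$histories_file,
    strategies = strategies,
    n_draws = raw$n_draws %||% 1000L,
    patients_per_year = raw$patients_per_year %||% 6000,
    base_strategy = raw$base_strategy %||% "current_practice",
    seed = seed, verbose = isTRUE(raw$verbose)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, config, code) {
  if (config$verbose) message(sprintf("[cadcea] stage %s ...", name))
  tryCatch(force(code), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: `simulate` (synthetic histories and billing, unless
#' a histories file is supplied), `estimate` (transition matrix and
#' medication cost groups from the records), `build` (model assembly),
#' `run` (deterministic cohort trace per arm), `psa`, `cea` (strategy
#' comparison table, acceptability curves, cost-effectiveness plane,
#' population scaling) and `summarize` (baseline-characteristics table).
#' Every stage writes plain CSV, and a JSON manifest records the seeds,
#' configuration hash and package version so each emitted number is
#' reproducible from the manifest alone. Display rounding never feeds
#' back into computation.
#'
#' @param config a [analysis_config()] (or a path readable by
#'   [read_analysis_config()]).
#' @return invisibly, a list with the in-memory results (`model`, `psa`,
#'   `comparison`, `ceac`, `scaling`, `manifest`, and the output file
#'   paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "cad_analysis_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(config$output_dir, f)
  manifest <- list(
    package = "cadcea",
    version = as.character(utils::packageVersion("cadcea")),
    seed = config$seed,
    stage_seeds = list(simulate = config$seed,
                       billing = config$seed + 1L,
                       psa = config$seed + 2L),
    files = character(), partial = TRUE
  )

  histories <- stage("simulate", config, {
    if (!is.null(config$histories_file)) {
      read_records_csv(config$histories_file, "histories")
    } else {
      truth <- config$truth
      truth$seed <- manifest$stage_seeds$simulate
      h <- generate_histories(truth)
      write_records_csv(h, out_path("histories.csv"))
      b <- generate_billing(h, truth$cost_params,
                            seed = manifest$stage_seeds$billing)
      write_records_csv(b, out_path("billing.csv"))
      h
    }
  })

  est <- stage("estimate", config, {
    states <- if (!is.null(config$truth)) config$truth$states else {
      model_state_names()
    }
    estimate_transition_matrix(histories, states)
  })

  model <- stage("build", config, {
    # states with no observed successor pairs keep the default row
    probs <- est$probabilities
    na_rows <- rownames(probs)[apply(is.na(probs), 1, any)]
    if (length(na_rows)) {
      probs[na_rows, ] <- default_transition_matrix()[na_rows, ]
      est$probabilities <- probs
    }
    build_model(default_model_structure(), default_parameters(est))
  })

  traces <- stage("run", config, {
    arms <- names(model$arms)
    res <- lapply(arms, function(a) evaluate_arm(model, a, config$engine))
    names(res) <- arms
    tr <- do.call(rbind, lapply(arms, function(a) {
      occ <- res[[a]]$trace$occupancy
      data.frame(arm = a,
                 cycle = rep(as.integer(rownames(occ)), ncol(occ)),
                 state = rep(colnames(occ), each = nrow(occ)),
                 count = as.numeric(occ), stringsAsFactors = FALSE)
    }))
    utils::write.csv(tr, out_path("trace.csv"), row.names = FALSE)
    totals <- data.frame(
      arm = arms,
      cost = vapply(res, `[[`, numeric(1), "total_cost"),
      qaly = vapply(res, `[[`, numeric(1), "total_qaly"))
    utils::write.csv(totals, out_path("arm_totals.csv"), row.names = FALSE)
    res
  })

  psa <- stage("psa", config, {
    eng <- config$engine
    eng$seed <- manifest$stage_seeds$psa
    p <- run_psa(model, config$strategies, eng, n_draws = config$n_draws)
    utils::write.csv(p$draws, out_path("psa_draws.csv"), row.names = FALSE)
    p
  })

  cea_out <- stage("cea", config, {
    comparison <- comparison_table(psa, base = config$base_strategy)
    utils::write.csv(comparison, out_path("strategy_comparison.csv"),
                     row.names = FALSE)
    curves <- do.call(rbind, lapply(comparison$strategy, function(s) {
      cbind(strategy = s, ceac(psa, s, config$base_strategy))
    }))
    utils::write.csv(curves, out_path("ceac.csv"), row.names = FALSE)
    plane <- ce_plane(psa, base = config$base_strategy)
    utils::write.csv(plane, out_path("ce_plane.csv"), row.names = FALSE)
    rec <- comparison[comparison$strategy == "recommended", , drop = FALSE]
    scaling <- if (nrow(rec)) {
      sc <- population_scale(
        list(delta_cost = rec$delta_cost, delta_qaly = rec$delta_qaly),
        config$patients_per_year, config$engine$wtp_threshold)
      df <- data.frame(quantity = names(sc), value = as.numeric(sc))
      utils::write.csv(df, out_path("population_scaling.csv"),
                       row.names = FALSE)
      sc
    }
    list(comparison = comparison, ceac = curves, plane = plane,
         scaling = scaling)
  })

  stage("summarize", config, {
    n <- length(unique(histories$patient_id))
    baseline <- generate_baseline(n, seed = config$seed)
    summ <- cohort_summary(baseline[, setdiff(names(baseline), "arm")])
    utils::write.csv(summ, out_path("cohort_summary.csv"), row.names = FALSE)
  })

  cfg_json <- out_path("config.json")
  jsonlite::write_json(
    list(seed = config$seed, n_draws = config$n_draws,
         engine = unclass(config$engine),
         base_strategy = config$base_strategy,
         patients_per_year = config$patients_per_year,
         strategies = lapply(config$strategies, function(s) as.list(s$weights))),
    cfg_json, auto_unbox = TRUE, digits = NA)
  manifest$files <- list.files(config$output_dir)
  manifest$config_hash <- unname(tools::md5sum(cfg_json))
  manifest$partial <- FALSE
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(model = model, psa = psa,
                 comparison = cea_out$comparison, ceac = cea_out$ceac,
                 scaling = cea_out$scaling, manifest = manifest,
                 output_dir = config$output_dir))
}
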