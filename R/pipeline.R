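#' Assemble a full run configuration
#'
#' Collects every knob of the pipeline -- task design, cohort generator,
#' priors, MCMC settings, analysis toggles -- and derives all module seeds
#' deterministically from one master seed. `path` may point to a flat YAML
#' file whose keys override the defaults (seeds included).
#'
#' @param path Optional YAML file of overrides.
#' @param ... Named overrides applied after the file (e.g. `n_subjects`,
#'   `master_seed`, `models`, `chains`, `iter_warmup`, `iter_draws`).
#' @return List of class `"run_config"` with `session` (a
#'   [session_config()]), `cohort` (a [cohort_spec()]), `priors`, `mcmc`,
#'   `analysis` and `master_seed`.
#' @export
run_config <- function(path = NULL, ...) {
  ov <- list()
  if (!is.null(path)) ov <- yaml::read_yaml(path)
  dots <- list(...)
  ov[names(dots)] <- dots
  master_seed <- as.integer(ov$master_seed %||% 1L)
  seeds <- derive_seeds(master_seed, 4L)
  take <- function(name, default) ov[[name]] %||% default
  session <- session_config(
    n_blocks = take("n_blocks", 6L),
    trials_per_block = take("trials_per_block", 40L),
    reps_per_trial_type = take("reps_per_trial_type", 30L),
    congruence_prob = take("congruence_prob", 0.8),
    shock_positions = take("shock_positions", c(12L, 28L)),
    response_window = take("response_window", 1500),
    threat_block_first = take("threat_block_first", FALSE),
    seed = seeds[1])
  cohort <- cohort_spec(
    n_subjects = take("n_subjects", 59L),
    model_id = take("sim_model", "m4"),
    rt_meanlog = take("rt_meanlog", log(600)),
    rt_sdlog = take("rt_sdlog", 0.25),
    rt_block_speedup = take("rt_block_speedup", 0.97),
    seed = seeds[2])
  cfg <- list(
    master_seed = master_seed,
    session = session,
    cohort = cohort,
    priors = prior_spec(
      mean_loc = take("prior_mean_loc", 0),
      mean_scale = take("prior_mean_scale", 1),
      sd_scale = take("prior_sd_scale", 0.2)),
    mcmc = list(chains = take("chains", 4L),
                iter_warmup = take("iter_warmup", 1000L),
                iter_draws = take("iter_draws", 500L),
                thin = take("thin", 2L),
                seed = seeds[3]),
    analysis = list(models = take("models", c("m1", "m2", "m3", "m4")),
                    hdi_mass = take("hdi_mass", 0.95),
                    power_dz = take("power_dz", 0.4),
                    power_alpha = take("power_alpha", 0.05),
                    power_target = take("power_target", 0.80),
                    seed = seeds[4]))
  class(cfg) <- "run_config"
  cfg
}

ensure_outdir <- function(out_dir, overwrite, files) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  existing <- files[file.exists(file.path(out_dir, files))]
  if (length(existing) && !overwrite)
    stop("refusing to overwrite existing file(s) in ", out_dir, ": ",
         paste(existing, collapse = ", "),
         " (use overwrite = TRUE)", call. = FALSE)
  invisible(out_dir)
}

#' Simulate a cohort and write the dataset and truth tables
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (`dataset.csv`, `truth.csv`).
#' @param overwrite Allow overwriting existing outputs (default `FALSE`).
#' @return Named paths, invisibly.
#' @export
cmd_simulate <- function(config = run_config(), out_dir,
                         overwrite = FALSE) {
  ensure_outdir(out_dir, overwrite, c("dataset.csv", "truth.csv"))
  sim <- simulate_cohort(config$cohort, config$session)
  ds <- file.path(out_dir, "dataset.csv")
  tru <- file.path(out_dir, "truth.csv")
  write_dataset(sim$trials, ds)
  utils::write.csv(sim$truth, tru, row.names = FALSE)
  message("simulated ", config$cohort$n_subjects, " subjects x ",
          nrow(sim$trials) / config$cohort$n_subjects,
          " trials (master seed ", config$master_seed, ")")
  invisible(c(dataset = ds, truth = tru))
}

#' Fit the model family to each task condition
#'
#' Runs [fit_hierarchical()] for every requested model on each of the four
#' condition datasets, writes group-level draws as columnar CSV and a JSON
#' summary (LOOIC table, Rhat extremes) into `out_dir`, and returns the
#' fits.
#'
#' @param config A [run_config()].
#' @param dataset Path to a dataset file, or a trial table.
#' @param out_dir Output directory.
#' @param overwrite Allow overwriting existing outputs.
#' @return Invisible list of `"gng_fit"` objects named `model.condition`.
#' @export
cmd_fit <- function(config = run_config(), dataset, out_dir,
                    overwrite = FALSE) {
  trials <- if (is.character(dataset)) read_dataset(dataset) else
    validate_trials(dataset)
  ensure_outdir(out_dir, overwrite, "fit_summary.json")
  conds <- condition_datasets(trials)
  models <- config$analysis$models
  fit_seeds <- derive_seeds(config$mcmc$seed,
                            length(models) * length(conds))
  fits <- list()
  k <- 0L
  for (m in models) for (cond in names(conds)) {
    k <- k + 1L
    f <- fit_hierarchical(conds[[cond]], m, config$priors,
                          chains = config$mcmc$chains,
                          iter_warmup = config$mcmc$iter_warmup,
                          iter_draws = config$mcmc$iter_draws,
                          thin = config$mcmc$thin, seed = fit_seeds[k])
    fits[[paste(m, cond, sep = ".")]] <- f
    mu <- apply(f$draws$mu, 3, as.vector)
    sg <- apply(f$draws$sigma, 3, as.vector)
    colnames(sg) <- paste0("sigma_", colnames(sg))
    utils::write.csv(cbind(mu, sg),
                     file.path(out_dir,
                               paste0("draws_", m, "_", cond, ".csv")),
                     row.names = FALSE)
    message("fit ", m, " / ", cond, ": LOOIC ", round(f$looic, 1),
            ", max Rhat ", round(max(f$rhat), 3))
  }
  sel <- select_model(fits)
  summary <- list(
    master_seed = config$master_seed,
    models = models,
    looic = sel$table,
    winner = sel$winner,
    tie = sel$tie,
    rhat_max = vapply(fits, function(f)
      max(c(f$rhat, f$rhat_theta), na.rm = TRUE), numeric(1)),
    rhat_flagged = names(fits)[!vapply(fits, `[[`, logical(1),
                                       "converged")])
  jsonlite::write_json(summary,
                       file.path(out_dir, "fit_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fits)
}

#' Produce the end-to-end analysis report
#'
#' Model selection over the fitted family, HDI inference on the winning
#' model's hyperparameters (the four simple effects and the
#' condition-by-action interaction score per parameter), both
#' repeated-measures ANOVAs (TOS- and block-factorized) on accuracy plus
#' the block ANOVA on latency, the FDR-corrected valence simple-effect
#' contrasts, an optional manipulation check, and the a-priori power note.
#' Writes `report.json` (machine-readable) and `report.txt`.
#'
#' @param config A [run_config()].
#' @param fits List of fits from [cmd_fit()] (or a fit directory is
#'   re-fit from the dataset when `NULL`).
#' @param dataset Path to the dataset file, or a trial table.
#' @param out_dir Output directory.
#' @param ratings Optional ratings table for [manipulation_check()].
#' @param overwrite Allow overwriting existing outputs.
#' @return Invisible report list.
#' @export
cmd_report <- function(config = run_config(), fits, dataset, out_dir,
                       ratings = NULL, overwrite = FALSE) {
  trials <- if (is.character(dataset)) read_dataset(dataset) else
    validate_trials(dataset)
  ensure_outdir(out_dir, overwrite, c("report.json", "report.txt"))
  sel <- select_model(fits)
  win <- sel$winner
  win_fits <- fits[paste(win, condition_labels(), sep = ".")]
  names(win_fits) <- condition_labels()
  hdi_seed <- config$analysis$seed
  hdis <- lapply(model_param_names(win), function(p)
    interaction_difference(win_fits, p, mass = config$analysis$hdi_mass,
                           seed = hdi_seed))
  names(hdis) <- model_param_names(win)
  acc_tos <- accuracy_table(trials, "tos")
  acc_block <- accuracy_table(trials, "block")
  an_tos <- rm_anova(acc_tos, "accuracy",
                     c("tos", "action", "instruction", "valence"))
  an_block <- rm_anova(acc_block, "accuracy",
                       c("block", "action", "instruction", "valence"))
  # latency over blocks, aggregated at the block level so sparse
  # trial-type cells do not force listwise deletion
  rt_cells <- stats::aggregate(
    rt_ms ~ subject_id + block_index,
    data = trials[trials$chosen_go & !is.na(trials$rt_ms), ], FUN = mean)
  names(rt_cells)[names(rt_cells) == "block_index"] <- "block"
  an_rt <- tryCatch(rm_anova(rt_cells, "rt_ms", "block"),
                    error = function(e) NULL)
  contrasts <- paired_contrasts(acc_tos, list(
    c("threat.press.go.win", "threat.press.go.avoid"),
    c("threat.lift.go.win", "threat.lift.go.avoid"),
    c("safe.press.go.win", "safe.press.go.avoid"),
    c("safe.lift.go.win", "safe.lift.go.avoid")))
  power_n <- power_paired_t(config$analysis$power_dz,
                            config$analysis$power_alpha,
                            config$analysis$power_target)
  manip <- if (!is.null(ratings)) manipulation_check(ratings) else NULL
  report <- list(
    master_seed = config$master_seed,
    seeds = list(hdi = hdi_seed, mcmc = config$mcmc$seed,
                 cohort = config$cohort$seed,
                 session = config$session$seed),
    model_selection = list(table = sel$table, winner = win,
                           tie = sel$tie),
    hdi = lapply(hdis, function(h) list(
      interaction = h$interaction[c("parameter", "lower", "upper",
                                    "mass", "credible", "median")],
      simple_effects = lapply(h$simple_effects, function(s)
        s[c("parameter", "lower", "upper", "mass", "credible",
            "median")]))),
    anova_accuracy_tos = as.data.frame(an_tos),
    anova_accuracy_block = as.data.frame(an_block),
    anova_rt_block = if (is.null(an_rt)) NULL else as.data.frame(an_rt),
    contrasts_valence_simple_effects = contrasts,
    manipulation_check = manip,
    power = list(dz = config$analysis$power_dz,
                 alpha = config$analysis$power_alpha,
                 target_power = config$analysis$power_target,
                 required_n = power_n))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(
    "Go/No-Go under threat of shock: analysis report",
    sprintf("master seed: %d", config$master_seed),
    "",
    sprintf("Winning model (summed LOOIC over 4 conditions): %s%s",
            win, if (sel$tie) " [tie]" else ""),
    utils::capture.output(print(sel$table, row.names = FALSE)),
    "",
    sprintf("A-priori power: dz=%.2f, alpha=%.2f, power=%.2f -> N = %d",
            config$analysis$power_dz, config$analysis$power_alpha,
            config$analysis$power_target, power_n),
    "",
    "Accuracy ANOVA (TOS x Action x Instruction x Valence):",
    utils::capture.output(print(as.data.frame(
      an_tos[, c("effect", "df1", "df2", "F", "p_corrected", "pes")]),
      row.names = FALSE)),
    "",
    "Hyperparameter interaction scores ((TP-SP)-(TL-SL)):",
    vapply(names(hdis), function(p) {
      h <- hdis[[p]]$interaction
      sprintf("  %s: [%.3f, %.3f]%s", p, h$lower, h$upper,
              if (h$credible) " *credible*" else "")
    }, character(1)))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(report)
}
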