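#' Cohort specification for the synthetic study
#'
#' Group-level generating distributions for one model, per task condition.
#' Subject parameters live on the sampling scale (real line) and are pushed
#' through the model links (unit-interval parameters via the standard-normal
#' CDF, sensitivities via `exp`, biases identity), exactly mirroring the
#' hierarchical model fitted later.
#'
#' The default emulates a healthy-adult cohort with moderate learning,
#' positive Pavlovian bias and no true condition differences: `xi ~ 0.1`,
#' `ep ~ 0.2`, `b = 0.3`, `pi = 0.5`, `rhoRew = rhoPun ~ 4` on the natural
#' scale, identical across the four conditions.
#'
#' @param n_subjects Number of subjects (default 59, the study sample).
#' @param model_id Generating model, `"m1"`..`"m4"` (default `"m4"`).
#' @param group_mean Named list: one numeric vector of sampling-scale group
#'   means per condition (`threat_press`, `threat_lift`, `safe_press`,
#'   `safe_lift`), each named by [model_param_names()]. If a single vector is
#'   supplied it is recycled to all four conditions.
#' @param group_sd Same shape as `group_mean`; nonnegative sampling-scale
#'   spreads (default 0.4 for every parameter).
#' @param rt_meanlog,rt_sdlog Location/scale of the lognormal latency
#'   generator in log-ms (defaults `log(600)`, 0.25).
#' @param rt_block_speedup Multiplicative per-block latency factor (default
#'   0.97, i.e. responses get ~3% faster each block).
#' @param seed Integer master seed for the cohort.
#' @return A validated list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 59L,
                        model_id = "m4",
                        group_mean = NULL,
                        group_sd = NULL,
                        rt_meanlog = log(600),
                        rt_sdlog = 0.25,
                        rt_block_speedup = 0.97,
                        seed = 1L) {
  model_id <- match.arg(model_id, c("m1", "m2", "m3", "m4"))
  pn <- model_param_names(model_id)
  conds <- condition_labels()
  default_mean <- c(xi = stats::qnorm(0.1), ep = stats::qnorm(0.2),
                    b = 0.3, pi = 0.5,
                    rho = log(4), rhoRew = log(4), rhoPun = log(4))[pn]
  default_sd <- stats::setNames(rep(0.4, length(pn)), pn)
  norm_cond <- function(x, default) {
    if (is.null(x)) x <- default
    if (is.numeric(x)) x <- stats::setNames(rep(list(x[pn]), 4), conds)
    stopifnot(all(conds %in% names(x)))
    lapply(x[conds], function(v) {
      stopifnot(all(pn %in% names(v)))
      v[pn]
    })
  }
  spec <- list(n_subjects = as.integer(n_subjects), model_id = model_id,
               group_mean = norm_cond(group_mean, default_mean),
               group_sd = norm_cond(group_sd, default_sd),
               rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
               rt_block_speedup = rt_block_speedup,
               seed = as.integer(seed))
  if (any(unlist(spec$group_sd) < 0))
    stop("group_sd entries must be nonnegative", call. = FALSE)
  class(spec) <- "cohort_spec"
  spec
}

#' The four task conditions
#' @return Character vector `threat_press`, `threat_lift`, `safe_press`,
#'   `safe_lift`.
#' @export
condition_labels <- function() {
  c("threat_press", "threat_lift", "safe_press", "safe_lift")
}

condition_of <- function(block_threat, action_context) {
  paste(block_threat, action_context, sep = "_")
}

# within-condition stimulus renumbering: the four instruction x valence types
condition_stim_index <- function(instruction, valence) {
  1L + 2L * (instruction != "go") + (valence != "win")
}

#' Draw one subject's per-condition parameters from the group distributions
#' @param spec A [cohort_spec()].
#' @return Named list (by condition) of [agent_params()]; draws use the
#'   current RNG stream.
#' @keywords internal
draw_subject_params <- function(spec) {
  pn <- model_param_names(spec$model_id)
  out <- lapply(condition_labels(), function(cond) {
    z <- stats::rnorm(length(pn), spec$group_mean[[cond]],
                      spec$group_sd[[cond]])
    names(z) <- pn
    nat <- transform_params(z, pn)
    do.call(agent_params, c(list(model_id = spec$model_id), as.list(nat)))
  })
  stats::setNames(out, condition_labels())
}

#' Map sampling-scale values to the natural parameter scale
#'
#' Unit-interval parameters (`xi`, `ep`) through the standard-normal CDF,
#' sensitivities (`rho`, `rhoRew`, `rhoPun`) through `exp`, biases (`b`,
#' `pi`) identity.
#'
#' @param z Numeric vector on the sampling scale.
#' @param names Parameter names aligned with `z`.
#' @return Natural-scale values, same names.
#' @export
transform_params <- function(z, names = base::names(z)) {
  stopifnot(length(z) == length(names))
  out <- numeric(length(z))
  for (i in seq_along(z)) {
    out[i] <- switch(link_of(names[i]),
                     probit = stats::pnorm(z[i]),
                     log = exp(z[i]),
                     identity = z[i])
  }
  stats::setNames(out, names)
}

link_of <- function(name) {
  switch(name,
         xi = , ep = "probit",
         rho = , rhoRew = , rhoPun = "log",
         b = , pi = "identity",
         stop("unknown parameter: ", name, call. = FALSE))
}

#' Simulate a full synthetic cohort
#'
#' Every subject receives a seeded schedule (subject-specific stimulus
#' permutation, trial order, shock placement and counterbalanced block
#' order), and four independent model agents -- one per task condition, each
#' with its own parameters and latent state over its four stimuli -- emit
#' the choices. Latencies on go choices come from a lognormal generator with
#' a multiplicative per-block speed-up.
#'
#' @param spec A [cohort_spec()].
#' @param config A [session_config()].
#' @return List with `trials` (one row per subject x trial, the dataset
#'   schema of [write_dataset()]) and `truth` (one row per subject x
#'   condition x parameter, the generating values on both scales).
#' @export
simulate_cohort <- function(spec = cohort_spec(), config = session_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_session_config(config)
  pn <- model_param_names(spec$model_id)
  seeds <- derive_seeds(spec$seed, spec$n_subjects * 2L + 1L)
  all_trials <- vector("list", spec$n_subjects)
  truth <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    sub_cfg <- config
    sub_cfg$seed <- seeds[2L * i - 1L]
    sub_cfg$threat_block_first <- (i %% 2L == 0L)
    sched <- make_schedule(sub_cfg)
    sub <- with_seed(seeds[2L * i], {
      params <- draw_subject_params(spec)
      sim_subject(sched, params, spec, config)
    })
    sub$trials$subject_id <- sprintf("s%03d", i)
    all_trials[[i]] <- sub$trials
    tr <- do.call(rbind, lapply(condition_labels(), function(cond) {
      p <- params_to_truth_row(sub$params[[cond]], pn)
      data.frame(subject_id = sprintf("s%03d", i), condition = cond,
                 parameter = pn, value = p, row.names = NULL)
    }))
    truth[[i]] <- tr
  }
  trials <- do.call(rbind, all_trials)
  cols <- c("subject_id", "block_index", "block_threat", "trial_in_block",
            "stimulus_id", "action_context", "instruction", "valence",
            "required_go", "chosen_go", "correct", "outcome_points", "rt_ms",
            "shock_event")
  trials <- trials[, cols]
  rownames(trials) <- NULL
  list(trials = trials, truth = do.call(rbind, truth))
}

params_to_truth_row <- function(params, pn) {
  unlist(params[pn])
}

# simulate one subject given a schedule and per-condition agent params;
# uses the current RNG stream
sim_subject <- function(sched, params, spec, config) {
  sched$condition <- condition_of(sched$block_threat, sched$action_context)
  sched$stim <- condition_stim_index(sched$instruction, sched$valence)
  sched$chosen_go <- NA
  sched$outcome_points <- NA_integer_
  for (cond in condition_labels()) {
    idx <- which(sched$condition == cond)
    if (!length(idx)) next
    res <- simulate_agent(sched[idx, c("stim", "required_go", "valence")],
                          params[[cond]], seed = NULL,
                          congruence_prob = config$congruence_prob)
    sched$chosen_go[idx] <- res$chosen_go
    sched$outcome_points[idx] <- res$outcome
  }
  sched$chosen_go <- as.logical(sched$chosen_go)
  sched$correct <- sched$chosen_go == sched$required_go
  sched$rt_ms <- NA_real_
  ngo <- sum(sched$chosen_go)
  if (ngo > 0) {
    rt <- stats::rlnorm(ngo, spec$rt_meanlog, spec$rt_sdlog) *
      spec$rt_block_speedup^(sched$block_index[sched$chosen_go] - 1L)
    sched$rt_ms[sched$chosen_go] <- rt
  }
  list(trials = sched, params = params)
}
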