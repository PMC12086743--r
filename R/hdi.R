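#' Highest density interval of a draw set
#'
#' The shortest interval containing the stated posterior mass, computed
#' from the sorted draws (every window of `floor(mass * n)` consecutive
#' order statistics is a candidate; the narrowest wins).
#'
#' @param draws Numeric vector of posterior draws.
#' @param mass Interval mass (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass < 1, length(draws) >= 2)
  x <- sort(draws)
  n <- length(x)
  m <- max(2L, floor(mass * n))
  k <- n - m + 1L
  widths <- x[m:n] - x[1:k]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1L])
}

new_hdi_result <- function(parameter, draws, mass, extra = list()) {
  iv <- hdi(draws, mass)
  structure(c(list(parameter = parameter,
                   lower = unname(iv[1]), upper = unname(iv[2]),
                   mass = mass,
                   credible = iv[1] > 0 || iv[2] < 0,
                   median = stats::median(draws)),
              extra),
            class = "hdi_result")
}

#' @export
print.hdi_result <- function(x, ...) {
  cat(sprintf("<hdi_result> %s: %.0f%% HDI [%.4g, %.4g]%s\n",
              x$parameter, 100 * x$mass, x$lower, x$upper,
              if (x$credible) " (credible: excludes 0)" else ""))
  invisible(x)
}

# pair two independent draw vectors by index after a seeded shuffle
paired_difference_draws <- function(a, b, seed = 1L) {
  n <- min(length(a), length(b))
  with_seed(seed, {
    a <- sample(a)[seq_len(n)]
    b <- sample(b)[seq_len(n)]
  })
  a - b
}

#' HDI of a group-level hyperparameter difference between two fits
#'
#' Condition fits are independent, so difference draws are formed by
#' pairing the two posterior draw vectors after a seeded shuffle. The
#' difference is taken on the sampling scale, where the group normal lives;
#' the natural-scale difference is reported alongside for interpretation.
#'
#' @param fitA,fitB `"gng_fit"` objects exposing the parameter.
#' @param parameter Parameter name.
#' @param mass HDI mass (default 0.95).
#' @param seed Seed for the pairing shuffle.
#' @return An `"hdi_result"` for A - B (with `natural`, the same contrast
#'   on natural-scale draws).
#' @export
hdi_difference <- function(fitA, fitB, parameter, mass = 0.95, seed = 1L) {
  d <- paired_difference_draws(group_mean_draws(fitA, parameter),
                               group_mean_draws(fitB, parameter), seed)
  dn <- paired_difference_draws(
    group_mean_draws(fitA, parameter, natural = TRUE),
    group_mean_draws(fitB, parameter, natural = TRUE), seed)
  lab <- paste0(parameter, ": ", fitA$condition, " - ", fitB$condition)
  new_hdi_result(lab, d, mass,
                 extra = list(natural = hdi(dn, mass), draws = d))
}

#' Condition-by-action interaction score on a hyperparameter
#'
#' The double difference ((threat press - safe press) - (threat lift -
#' safe lift)) of group-level mean draws, plus the four pairwise simple
#' effects (threat press - safe press, threat lift - safe lift, threat
#' press - threat lift, safe press - safe lift).
#'
#' @param fits Named list of four `"gng_fit"`s (`threat_press`,
#'   `threat_lift`, `safe_press`, `safe_lift`).
#' @param parameter Parameter name present in all four fits.
#' @param mass HDI mass (default 0.95).
#' @param seed Seed for the pairing shuffles.
#' @return List with `interaction` (an `"hdi_result"`) and
#'   `simple_effects` (named list of `"hdi_result"`s).
#' @export
interaction_difference <- function(fits, parameter, mass = 0.95, seed = 1L) {
  stopifnot(all(condition_labels() %in% names(fits)))
  dr <- lapply(fits[condition_labels()], function(f)
    group_mean_draws(f, parameter))
  n <- min(lengths(dr))
  sh <- with_seed(seed, lapply(dr, function(x) sample(x)[seq_len(n)]))
  dd <- (sh$threat_press - sh$safe_press) -
        (sh$threat_lift - sh$safe_lift)
  inter <- new_hdi_result(
    paste0(parameter, ": (threat_press - safe_press) - ",
           "(threat_lift - safe_lift)"), dd, mass,
    extra = list(draws = dd))
  pairs <- list(
    threat_press_vs_safe_press = c("threat_press", "safe_press"),
    threat_lift_vs_safe_lift = c("threat_lift", "safe_lift"),
    threat_press_vs_threat_lift = c("threat_press", "threat_lift"),
    safe_press_vs_safe_lift = c("safe_press", "safe_lift"))
  simple <- lapply(pairs, function(pr)
    hdi_difference(fits[[pr[1]]], fits[[pr[2]]], parameter, mass, seed))
  list(interaction = inter, simple_effects = simple)
}

#' Posterior predictive check against observed per-type accuracy
#'
#' For each subject, task performance is re-simulated from posterior draws
#' of that subject's own parameters on a schedule matched to the data (by
#' default, the subject's observed stimulus sequence), and the observed
#' accuracy per trial type is compared with the predictive interval.
#'
#' @param fit A converged `"gng_fit"`.
#' @param schedules Optional named list (by subject) of schedule
#'   data.frames (`stim`, `required_go`, `valence`); defaults to each
#'   subject's observed sequence from the fitted dataset.
#' @param n_draws Number of posterior draws to simulate per subject
#'   (default 100; must be >= 1).
#' @param mass Predictive interval mass (default 0.95).
#' @param congruence_prob Outcome congruence probability used in the
#'   re-simulation (default 0.8).
#' @param seed Integer seed.
#' @return Data.frame: subject_id, stim type, observed accuracy, predictive
#'   mean and interval, and an `inside` flag.
#' @export
posterior_predictive <- function(fit, schedules = NULL, n_draws = 100L,
                                 mass = 0.95, congruence_prob = 0.8,
                                 seed = 1L) {
  stopifnot(inherits(fit, "gng_fit"))
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  tr <- fit$data$trials
  P <- length(fit$parameters)
  if (is.null(schedules)) {
    schedules <- split(tr[, c("stim", "required_go", "valence")],
                       tr$subject_id)[fit$subjects]
  } else {
    miss <- setdiff(fit$subjects, names(schedules))
    if (length(miss))
      stop("schedules missing for subject(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    bad <- vapply(schedules, function(s)
      !all(c("stim", "required_go", "valence") %in% names(s)), logical(1))
    if (any(bad)) stop("schedule columns must be stim, required_go, valence",
                       call. = FALSE)
  }
  draws_total <- dim(fit$draws$theta)[1] * dim(fit$draws$theta)[2]
  theta_flat <- matrix(fit$draws$theta, nrow = draws_total)
  seeds <- derive_seeds(seed, 1L + fit$n_subjects)
  pick <- with_seed(seeds[1],
                    sample.int(draws_total, n_draws,
                               replace = n_draws > draws_total))
  alpha <- (1 - mass) / 2
  out <- vector("list", fit$n_subjects)
  for (i in seq_len(fit$n_subjects)) {
    sid <- fit$subjects[i]
    sched <- schedules[[sid]]
    obs <- tr[tr$subject_id == sid, ]
    acc_mat <- matrix(NA_real_, n_draws, 4)
    with_seed(seeds[1L + i], {
      for (d in seq_len(n_draws)) {
        nat <- theta_flat[pick[d], ((i - 1L) * P + 1L):(i * P)]
        names(nat) <- fit$parameters
        pars <- do.call(agent_params,
                        c(list(model_id = fit$model_id), as.list(nat)))
        sim <- simulate_agent(sched, pars, seed = NULL,
                              congruence_prob = congruence_prob)
        acc_mat[d, ] <- vapply(1:4, function(s) {
          sel <- sim$stim == s
          if (!any(sel)) NA_real_ else mean(sim$correct[sel])
        }, numeric(1))
      }
    })
    obs_acc <- vapply(1:4, function(s) {
      sel <- obs$stim == s
      if (!any(sel)) NA_real_
      else mean(obs$chosen_go[sel] == obs$required_go[sel])
    }, numeric(1))
    out[[i]] <- data.frame(
      subject_id = sid, stim = 1:4,
      observed = obs_acc,
      predicted_mean = colMeans(acc_mat, na.rm = TRUE),
      predicted_lower = apply(acc_mat, 2, stats::quantile,
                              probs = alpha, na.rm = TRUE),
      predicted_upper = apply(acc_mat, 2, stats::quantile,
                              probs = 1 - alpha, na.rm = TRUE),
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  res$inside <- res$observed >= res$predicted_lower &
    res$observed <= res$predicted_upper
  res
}
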