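#' Parameters of one Go/No-Go learning agent
#'
#' The nested Rescorla-Wagner family: every model has a lapse rate `xi`, a
#' learning rate `ep` and outcome sensitivity; m2 adds a constant go bias
#' `b`, m3 adds a Pavlovian bias `pi` coupling stimulus value to the go
#' weight, and m4 splits sensitivity into `rhoRew` (outcomes >= 0) and
#' `rhoPun` (outcomes < 0). Parameters absent from a model are fixed at
#' their null value (`b = 0`, `pi = 0`, `rhoRew = rhoPun = rho`).
#'
#' @param model_id One of `"m1"`, `"m2"`, `"m3"`, `"m4"`.
#' @param xi Lapse probability in `[0, 1]`.
#' @param ep Learning rate in `[0, 1]`.
#' @param rho Outcome sensitivity (> 0), models m1-m3.
#' @param rhoRew,rhoPun Reward / punishment sensitivities (> 0), model m4.
#' @param b Go bias (real), models m2-m4.
#' @param pi Pavlovian bias (real), models m3-m4.
#' @return A validated list of class `"agent_params"` with canonical fields
#'   `xi, ep, b, pi, rhoRew, rhoPun` (plus `rho` for m1-m3).
#' @export
agent_params <- function(model_id, xi, ep, rho = NULL,
                         rhoRew = NULL, rhoPun = NULL, b = 0, pi = 0) {
  model_id <- match.arg(model_id, c("m1", "m2", "m3", "m4"))
  if (model_id == "m4") {
    if (is.null(rhoRew) || is.null(rhoPun))
      stop("m4 requires rhoRew and rhoPun", call. = FALSE)
  } else {
    if (is.null(rho)) stop(model_id, " requires rho", call. = FALSE)
    rhoRew <- rhoPun <- rho
  }
  if (model_id == "m1") b <- 0
  if (model_id %in% c("m1", "m2")) pi <- 0
  p <- list(model_id = model_id, xi = xi, ep = ep, b = b, pi = pi,
            rhoRew = rhoRew, rhoPun = rhoPun)
  if (model_id != "m4") p$rho <- rho
  stopifnot(xi >= 0, xi <= 1, ep >= 0, ep <= 1,
            p$rhoRew > 0, p$rhoPun > 0,
            is.finite(b), is.finite(pi))
  class(p) <- "agent_params"
  p
}

#' @export
print.agent_params <- function(x, ...) {
  cat("<agent_params ", x$model_id, "> ", sep = "")
  flds <- model_param_names(x$model_id)
  vals <- unlist(x[flds])
  cat(paste(flds, signif(vals, 4), sep = "="), sep = "  ")
  cat("\n")
  invisible(x)
}

#' Free parameter names of each model
#' @param model_id Model identifier `"m1"`..`"m4"`.
#' @return Character vector of free parameter names, in canonical order.
#' @export
model_param_names <- function(model_id) {
  switch(match.arg(model_id, c("m1", "m2", "m3", "m4")),
         m1 = c("xi", "ep", "rho"),
         m2 = c("xi", "ep", "b", "rho"),
         m3 = c("xi", "ep", "b", "pi", "rho"),
         m4 = c("xi", "ep", "b", "pi", "rhoRew", "rhoPun"))
}

#' Fresh latent state over the four in-condition stimuli
#'
#' Instrumental action values `q_go`, `q_nogo` and Pavlovian stimulus value
#' `v`, all initialized at zero.
#'
#' @param n_stim Number of stimuli (default 4).
#' @return List of class `"latent_state"`.
#' @export
latent_state <- function(n_stim = 4L) {
  st <- list(q_go = numeric(n_stim), q_nogo = numeric(n_stim),
             v = numeric(n_stim))
  class(st) <- "latent_state"
  st
}

#' Action weights for one stimulus
#'
#' The go weight adds the go bias and the Pavlovian term `pi * v(s)` to the
#' instrumental go value; the no-go weight is the instrumental no-go value.
#'
#' @param state A [latent_state()].
#' @param s Stimulus index (1-based).
#' @param params An [agent_params()].
#' @return Named numeric vector `c(w_go, w_nogo)`.
#' @export
action_weights <- function(state, s, params) {
  c(w_go = state$q_go[s] + params$b + params$pi * state$v[s],
    w_nogo = state$q_nogo[s])
}

#' Choice probability of go
#'
#' Squashed softmax: a logistic choice between the two action weights mixed
#' with a value-independent lapse, so the probability always lies in
#' `[xi/2, 1 - xi/2]`.
#'
#' @param w_go,w_nogo Action weights.
#' @param xi Lapse probability in `[0, 1]`.
#' @return Probability of emitting go.
#' @export
p_go <- function(w_go, w_nogo, xi) {
  stopifnot(xi >= 0, xi <= 1)
  (1 - xi) * stats::plogis(w_go - w_nogo) + xi / 2
}

#' Rescorla-Wagner state update after one trial
#'
#' The outcome is scaled by the sensitivity (for m4, `rhoRew` when the
#' outcome is >= 0 and `rhoPun` otherwise); the stimulus value `v(s)` and the
#' chosen action's instrumental value move a fraction `ep` toward the scaled
#' outcome. The unchosen action and all other stimuli are untouched.
#'
#' @param state A [latent_state()].
#' @param s Stimulus index.
#' @param chosen_go Logical; was go chosen.
#' @param outcome Outcome in `{-1, 0, +1}`.
#' @param params An [agent_params()].
#' @return The updated state.
#' @export
update_state <- function(state, s, chosen_go, outcome, params) {
  if (!outcome %in% c(-1L, 0L, 1L))
    stop("outcome must be one of -1, 0, +1", call. = FALSE)
  sr <- if (outcome >= 0) params$rhoRew else params$rhoPun
  target <- sr * outcome
  state$v[s] <- state$v[s] + params$ep * (target - state$v[s])
  if (isTRUE(chosen_go)) {
    state$q_go[s] <- state$q_go[s] + params$ep * (target - state$q_go[s])
  } else {
    state$q_nogo[s] <- state$q_nogo[s] + params$ep * (target - state$q_nogo[s])
  }
  state
}

params_to_canonical <- function(params) {
  c(params$xi, params$ep, params$b, params$pi, params$rhoRew, params$rhoPun)
}

#' Log-likelihood of a choice sequence
#'
#' Forward pass from the zero state: each trial contributes
#' `log P(chosen_go | state)` under the squashed-softmax rule, and the state
#' is then updated with the observed outcome.
#'
#' @param seq A data.frame with columns `stim` (1..4), `chosen_go` (logical
#'   or 0/1) and `outcome` (-1/0/+1), in trial order.
#' @param params An [agent_params()].
#' @return List with `total` (sum) and `pointwise` (per-trial log
#'   probabilities).
#' @export
sequence_loglik <- function(seq, params) {
  stopifnot(all(c("stim", "chosen_go", "outcome") %in% names(seq)))
  res <- gng_seq_loglik(as.integer(seq$stim), as.integer(seq$chosen_go),
                        as.integer(seq$outcome), params_to_canonical(params))
  list(total = res$total, pointwise = res$pointwise)
}

#' Simulate one agent on a condition schedule
#'
#' The exact generative mirror of [sequence_loglik()]: choices are sampled
#' from the model's go probability and outcomes delivered through
#' [deliver_outcome()], updating the latent state trial by trial.
#'
#' @param schedule Data.frame with columns `stim` (1..4), `required_go`
#'   (logical) and `valence` (`"win"`/`"avoid"`), in trial order.
#' @param params An [agent_params()].
#' @param seed Integer seed (or `NULL` to use the current RNG stream).
#' @param congruence_prob Probability of the expected outcome (default 0.8).
#' @return `schedule` with added columns `chosen_go`, `correct`, `outcome`.
#' @export
simulate_agent <- function(schedule, params, seed = NULL,
                           congruence_prob = 0.8) {
  stopifnot(all(c("stim", "required_go", "valence") %in% names(schedule)))
  with_seed(seed, {
    n <- nrow(schedule)
    u_choice <- stats::runif(n)
    u_cong <- stats::runif(n)
    res <- gng_simulate_agent(as.integer(schedule$stim),
                              as.integer(schedule$required_go),
                              as.integer(schedule$valence == "win"),
                              params_to_canonical(params),
                              u_choice, u_cong, congruence_prob)
    schedule$chosen_go <- as.logical(res$chosen_go)
    schedule$correct <- schedule$chosen_go == schedule$required_go
    schedule$outcome <- as.integer(res$outcome)
    schedule
  })
}
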