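#' Task session configuration
#'
#' Describes one session of the approach-withdrawal Go/No-Go task: alternating
#' safe and threat-of-shock blocks, eight trial types (press/lift crossed with
#' go/no-go and win/avoid), probabilistic outcome delivery, and one shock per
#' threat block at a fixed within-block ordinal position.
#'
#' @param n_blocks Number of blocks (must be even so safe and threat
#'   alternate in equal numbers). Default 6.
#' @param trials_per_block Trials per block (must be a multiple of 8 so each
#'   trial type is balanced within block). Default 40.
#' @param reps_per_trial_type Total repetitions of each of the 8 trial types.
#'   Default 30. Must satisfy `n_blocks * trials_per_block == 8 * reps`.
#' @param congruence_prob Probability that the expected (action-congruent)
#'   outcome is delivered; must lie in (0.5, 1]. Default 0.8.
#' @param shock_positions Within-block 1-based trial positions at which the
#'   single shock of a threat block may occur (chosen uniformly). Default
#'   `c(12, 28)`.
#' @param response_window Response window in ms (metadata only). Default 1500.
#' @param threat_block_first Logical; if `TRUE` the first block is a threat
#'   block (counterbalancing flag). Default `FALSE`.
#' @param seed Integer seed driving schedule randomization.
#' @return A validated list of class `"session_config"`.
#' @export
session_config <- function(n_blocks = 6L,
                           trials_per_block = 40L,
                           reps_per_trial_type = 30L,
                           congruence_prob = 0.8,
                           shock_positions = c(12L, 28L),
                           response_window = 1500,
                           threat_block_first = FALSE,
                           seed = 1L) {
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    reps_per_trial_type = as.integer(reps_per_trial_type),
    congruence_prob = congruence_prob,
    shock_positions = as.integer(shock_positions),
    response_window = response_window,
    threat_block_first = isTRUE(threat_block_first),
    seed = as.integer(seed)
  )
  class(cfg) <- "session_config"
  validate_session_config(cfg)
  cfg
}

validate_session_config <- function(cfg) {
  with(cfg, {
    if (n_blocks * trials_per_block != 8L * reps_per_trial_type)
      stop("invalid session_config: n_blocks * trials_per_block (",
           n_blocks * trials_per_block, ") must equal 8 * reps_per_trial_type (",
           8L * reps_per_trial_type, ")", call. = FALSE)
    if (n_blocks %% 2L != 0L)
      stop("invalid session_config: n_blocks must be even so safe and threat ",
           "blocks alternate in equal numbers", call. = FALSE)
    if (trials_per_block %% 8L != 0L)
      stop("invalid session_config: trials_per_block must be a multiple of 8 ",
           "so trial types are balanced within block", call. = FALSE)
    if (!(congruence_prob > 0.5 && congruence_prob <= 1))
      stop("invalid session_config: congruence_prob must lie in (0.5, 1]",
           call. = FALSE)
    if (any(shock_positions < 1L | shock_positions > trials_per_block))
      stop("invalid session_config: shock_positions must lie in [1, ",
           trials_per_block, "]", call. = FALSE)
  })
  invisible(cfg)
}

#' The eight trial types of the orthogonalized task
#'
#' Action context (press vs lift) crossed with instruction (go vs no-go) and
#' valence (win vs avoid). `required_go` encodes the correct binary choice
#' within the trial's action context.
#'
#' @return A data.frame with 8 rows and columns `type_id`, `action_context`,
#'   `instruction`, `valence`, `required_go`.
#' @export
trial_types <- function() {
  tt <- expand.grid(
    valence = c("win", "avoid"),
    instruction = c("go", "nogo"),
    action_context = c("press", "lift"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("action_context", "instruction", "valence")]
  tt$type_id <- seq_len(8L)
  tt$required_go <- tt$instruction == "go"
  tt[, c("type_id", "action_context", "instruction", "valence", "required_go")]
}

#' Build one session schedule
#'
#' Lays out all trials of a session: blocks strictly alternate safe/threat,
#' each trial type appears equally often in every block (hence 15 times per
#' threat level under the default design), stimulus identities 1..8 are a
#' seeded permutation of the trial types, the within-block trial order is a
#' seeded shuffle, and each threat block carries exactly one shock at a
#' position drawn uniformly from `shock_positions`.
#'
#' @param config A [session_config()].
#' @return A data.frame with one row per trial: `block_index`, `block_threat`,
#'   `trial_in_block`, `stimulus_id`, `action_context`, `instruction`,
#'   `valence`, `required_go`, `shock_event`.
#' @export
make_schedule <- function(config = session_config()) {
  validate_session_config(config)
  tt <- trial_types()
  with_seed(config$seed, {
    # stimulus_id[k] is the stimulus shape assigned to trial type k
    stim_of_type <- sample.int(8L)
    per_block <- config$trials_per_block %/% 8L
    first <- if (config$threat_block_first) "threat" else "safe"
    second <- if (config$threat_block_first) "safe" else "threat"
    threat_of_block <- rep(c(first, second), length.out = config$n_blocks)
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      types <- sample(rep(seq_len(8L), per_block))
      out <- tt[types, ]
      out$block_index <- b
      out$block_threat <- threat_of_block[b]
      out$trial_in_block <- seq_len(config$trials_per_block)
      out$stimulus_id <- stim_of_type[types]
      out$shock_event <- FALSE
      if (threat_of_block[b] == "threat") {
        pos <- if (length(config$shock_positions) == 1L) config$shock_positions
               else sample(config$shock_positions, 1L)
        out$shock_event[pos] <- TRUE
      }
      out
    })
    sched <- do.call(rbind, blocks)
    rownames(sched) <- NULL
    sched[, c("block_index", "block_threat", "trial_in_block", "stimulus_id",
              "action_context", "instruction", "valence", "required_go",
              "shock_event")]
  })
}

#' Deliver a probabilistic trial outcome
#'
#' With probability `congruence_prob` the expected outcome of the chosen
#' action is delivered (win trials: +1 point if the choice was correct, else
#' 0; avoid trials: 0 if correct, else -1); otherwise the opposite member of
#' the valence's outcome pair is delivered.
#'
#' All arguments are vectorized.
#'
#' @param correct Logical; was the emitted choice the required one.
#' @param valence `"win"` or `"avoid"`.
#' @param congruence_draw Uniform draw(s) in `[0, 1)` deciding congruence.
#' @param congruence_prob Probability of the expected outcome (default 0.8).
#' @return Integer outcome(s) in `{-1, 0, +1}`.
#' @export
deliver_outcome <- function(correct, valence, congruence_draw,
                            congruence_prob = 0.8) {
  stopifnot(all(valence %in% c("win", "avoid")))
  n <- max(length(correct), length(valence), length(congruence_draw))
  correct <- rep_len(as.logical(correct), n)
  valence <- rep_len(valence, n)
  congruence_draw <- rep_len(congruence_draw, n)
  congruent <- congruence_draw < congruence_prob
  expected <- ifelse(valence == "win",
                     ifelse(correct, 1L, 0L),
                     ifelse(correct, 0L, -1L))
  other <- ifelse(valence == "win",
                  ifelse(expected == 1L, 0L, 1L),
                  ifelse(expected == 0L, -1L, 0L))
  as.integer(ifelse(congruent, expected, other))
}
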