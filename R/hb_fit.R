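#' Prior specification for hierarchical fitting
#'
#' Group-level priors live on the sampling scale of each parameter: the
#' group mean is Normal(location, scale) and the group spread half-Normal.
#' Links to the natural scale are fixed by parameter (see
#' [transform_params()]).
#'
#' @param mean_loc,mean_scale Location and scale of the group-mean prior
#'   (defaults 0 and 1, shared by all parameters).
#' @param sd_scale Scale of the half-normal group-spread prior (default
#'   0.2).
#' @return List of class `"prior_spec"`.
#' @export
prior_spec <- function(mean_loc = 0, mean_scale = 1, sd_scale = 0.2) {
  stopifnot(mean_scale > 0, sd_scale > 0)
  structure(list(mean_loc = mean_loc, mean_scale = mean_scale,
                 sd_scale = sd_scale), class = "prior_spec")
}

#' Fit one model to one condition dataset, hierarchically
#'
#' Subjects share a group normal per free parameter on the sampling scale;
#' the per-subject likelihood is the forward-pass sequence likelihood of the
#' chosen model ([sequence_loglik()]). Sampling is adaptive
#' Metropolis-within-Gibbs: conjugate Gibbs updates for group means, an
#' exact conditional independence proposal for group spreads, per-subject
#' adaptive random-walk updates, and interweaved translation/rescaling
#' moves of each group parameter together with its subject-level values
#' (which remove the usual funnel coupling), run as independent chains.
#' Convergence is summarized by
#' split-Rhat; any quantity with Rhat > 1.1 attaches a warning flag to the
#' result.
#'
#' @param data A `"condition_dataset"` (see [condition_datasets()]).
#' @param model_id `"m1"`..`"m4"`.
#' @param priors A [prior_spec()].
#' @param chains Number of chains (default 4).
#' @param iter_warmup,iter_draws Warmup and retained iterations per chain
#'   (defaults 1000 / 500).
#' @param thin Thinning interval (default 2).
#' @param seed Integer seed; chain seeds are derived from it.
#' @param store_loglik Keep the pointwise log-likelihood matrix needed for
#'   PSIS-LOO (default `TRUE`).
#' @return Object of class `"gng_fit"`: posterior draws of group means and
#'   spreads (`mu`, `sigma`, chains x draws x parameter, sampling scale),
#'   subject-level natural-scale draws (`theta`), the pointwise
#'   log-likelihood matrix (`log_lik`), `rhat`, `looic` and metadata.
#' @export
fit_hierarchical <- function(data, model_id, priors = prior_spec(),
                             chains = 4L, iter_warmup = 1000L,
                             iter_draws = 500L, thin = 2L, seed = 1L,
                             store_loglik = TRUE) {
  stopifnot(inherits(data, "condition_dataset"))
  model_id <- match.arg(model_id, c("m1", "m2", "m3", "m4"))
  model_num <- as.integer(substring(model_id, 2))
  pn <- model_param_names(model_id)
  P <- length(pn)
  tr <- data$trials
  if (!nrow(tr)) stop("empty condition dataset", call. = FALSE)
  subjects <- unique(tr$subject_id)
  N <- length(subjects)
  tr <- tr[order(match(tr$subject_id, subjects)), ]
  subj_len <- as.integer(table(factor(tr$subject_id, levels = subjects)))
  if (any(subj_len < 1L))
    stop("every subject needs at least one trial", call. = FALSE)
  subj_start <- c(0L, cumsum(subj_len)[-N])
  chain_seeds <- derive_seeds(seed, chains)
  runs <- lapply(seq_len(chains), function(ch) {
    with_seed(chain_seeds[ch],
      gng_mcmc_chain(as.integer(tr$stim), as.integer(tr$chosen_go),
                     as.integer(tr$outcome), subj_start, subj_len,
                     model_num, as.integer(iter_warmup),
                     as.integer(iter_draws), as.integer(thin),
                     rep(priors$mean_loc, P), rep(priors$mean_scale, P),
                     rep(priors$sd_scale, P), store_loglik))
  })
  S <- iter_draws
  arr <- function(field, ncols, cnames) {
    a <- array(NA_real_, c(chains, S, ncols))
    for (ch in seq_len(chains)) a[ch, , ] <- runs[[ch]][[field]]
    dimnames(a) <- list(NULL, NULL, cnames)
    a
  }
  mu <- arr("mu", P, pn)
  sg <- arr("sigma", P, pn)
  theta <- arr("theta", N * P,
               paste(rep(subjects, each = P), rep(pn, N), sep = "."))
  log_lik <- if (store_loglik)
    do.call(rbind, lapply(runs, `[[`, "log_lik")) else NULL
  rhat <- c(apply(mu, 3, split_rhat), apply(sg, 3, split_rhat))
  names(rhat) <- c(paste0("mu.", pn), paste0("sigma.", pn))
  rhat_theta <- apply(theta, 3, split_rhat)
  fit <- structure(list(
    model_id = model_id, condition = data$condition,
    parameters = pn, subjects = subjects,
    n_subjects = N, n_trials = nrow(tr),
    draws = list(mu = mu, sigma = sg, theta = theta),
    log_lik = log_lik,
    rhat = rhat, rhat_theta = rhat_theta,
    converged = max(c(rhat, rhat_theta), na.rm = TRUE) <= 1.1,
    data = data, priors = priors,
    mcmc = list(chains = chains, iter_warmup = iter_warmup,
                iter_draws = iter_draws, thin = thin, seed = seed),
    looic = NA_real_), class = "gng_fit")
  if (!fit$converged)
    warning("Rhat > 1.1 for ", sum(c(rhat, rhat_theta) > 1.1, na.rm = TRUE),
            " quantities in ", model_id, " / ", data$condition, call. = FALSE)
  if (store_loglik) {
    loo <- compute_loo(fit)
    fit$looic <- loo$looic
    fit$loo <- loo
  }
  fit
}

#' @export
print.gng_fit <- function(x, ...) {
  cat("<gng_fit> model ", x$model_id, ", condition ", x$condition, "\n",
      "  ", x$n_subjects, " subjects, ", x$n_trials, " trials, ",
      x$mcmc$chains, " chains x ", x$mcmc$iter_draws, " draws\n",
      "  max Rhat (group) ", round(max(x$rhat), 3),
      if (!is.na(x$looic)) paste0(", LOOIC ", round(x$looic, 1)), "\n",
      sep = "")
  invisible(x)
}

#' Posterior draws of a group-level mean
#'
#' @param fit A `"gng_fit"`.
#' @param parameter Parameter name.
#' @param natural If `TRUE`, return draws pushed through the parameter's
#'   link to the natural scale; default `FALSE` (sampling scale, where the
#'   group normal lives).
#' @return Numeric vector of pooled draws (all chains).
#' @export
group_mean_draws <- function(fit, parameter, natural = FALSE) {
  stopifnot(inherits(fit, "gng_fit"))
  if (!parameter %in% fit$parameters)
    stop("parameter '", parameter, "' not in model ", fit$model_id,
         call. = FALSE)
  d <- as.vector(fit$draws$mu[, , parameter])
  if (natural) transform_scalar(d, parameter) else d
}

transform_scalar <- function(x, name) {
  switch(link_of(name), probit = stats::pnorm(x), log = exp(x),
         identity = x)
}

#' Posterior means of subject-level parameters (natural scale)
#' @param fit A `"gng_fit"`.
#' @return Data.frame subject_id x parameter with posterior-mean values.
#' @export
subject_posterior_means <- function(fit) {
  m <- apply(fit$draws$theta, 3, mean)
  P <- length(fit$parameters)
  out <- data.frame(subject_id = rep(fit$subjects, each = P),
                    parameter = rep(fit$parameters, fit$n_subjects),
                    estimate = as.vector(m), row.names = NULL)
  out
}

#' Split-Rhat convergence diagnostic
#'
#' Each chain is split in half and the standard potential-scale-reduction
#' statistic computed over the resulting sequences.
#'
#' @param x Matrix chains x draws (or vector for a single chain).
#' @return Rhat (>= 1; `NA` if fewer than 4 draws).
#' @export
split_rhat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (n < 4) return(NA_real_)
  half <- n %/% 2
  sub <- rbind(x[, seq_len(half), drop = FALSE],
               x[, (n - half + 1):n, drop = FALSE])
  m <- nrow(sub); nn <- ncol(sub)
  means <- rowMeans(sub)
  vars <- apply(sub, 1, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
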