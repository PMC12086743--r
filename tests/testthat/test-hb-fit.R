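# reduced-scale fits keep this file fast; the full-scale recovery runs
# live in the acceptance suite
small_cohort <- function(n_subjects, seed, model_id = "m4",
                         group_mean = NULL, group_sd = 0.3,
                         config = session_config()) {
  pn <- model_param_names(model_id)
  gs <- stats::setNames(rep(group_sd, length(pn)), pn)
  spec <- cohort_spec(n_subjects = n_subjects, model_id = model_id,
                      group_mean = group_mean, group_sd = gs, seed = seed)
  simulate_cohort(spec, config)
}

quick_fit <- function(ds, model_id, seed, chains = 2, warmup = 400,
                      draws = 250, thin = 2) {
  suppressWarnings(fit_hierarchical(ds, model_id, chains = chains,
                                    iter_warmup = warmup,
                                    iter_draws = draws, thin = thin,
                                    seed = seed))
}

test_that("prior draws land in each parameter's support through the links", {
  set.seed(1)
  z <- rnorm(1e5, 0, 1)
  expect_true(all(transform_params(z, rep("xi", 1e5)) >= 0 &
                  transform_params(z, rep("xi", 1e5)) <= 1))
  expect_true(all(transform_params(z, rep("rhoRew", 1e5)) > 0))
  expect_equal(transform_params(c(b = 0.7)), c(b = 0.7))
  expect_error(transform_params(c(zeta = 1)), "unknown parameter")
})

test_that("a pure-noise cohort is recognized by a high lapse posterior", {
  sim <- small_cohort(20, seed = 31, model_id = "m1",
                      group_mean = c(xi = 3, ep = stats::qnorm(0.2),
                                     rho = log(2)),
                      group_sd = 0.1,
                      config = session_config(n_blocks = 8,
                                              trials_per_block = 80,
                                              reps_per_trial_type = 80))
  cds <- condition_datasets(sim$trials)
  f <- quick_fit(cds$safe_press, "m1", seed = 77)
  expect_gt(mean(group_mean_draws(f, "xi", natural = TRUE)), 0.6)
})

test_that("hierarchical fits converge on a default-design condition", {
  sim <- small_cohort(15, seed = 41)
  cds <- condition_datasets(sim$trials)
  f <- fit_hierarchical(cds$threat_press, "m4", chains = 4, thin = 4,
                        seed = 19)
  expect_s3_class(f, "gng_fit")
  expect_true(all(is.finite(unlist(f$draws))))
  expect_true(all(f$rhat <= 1.1))
  expect_true(all(f$rhat_theta <= 1.1))
  expect_true(f$converged)
  expect_named(f$rhat, c(paste0("mu.", f$parameters),
                         paste0("sigma.", f$parameters)))
  expect_equal(f$n_trials, 15 * 60)
  expect_equal(dim(f$log_lik), c(4 * 500, 15 * 60))
  # LOOIC identity with its own pointwise diagnostics
  expect_equal(f$looic, -2 * f$loo$elpd_loo)
  expect_equal(f$looic, -2 * sum(f$loo$pointwise))
})

test_that("more trials per subject sharpen the learning-rate posterior", {
  base <- session_config(n_blocks = 4, trials_per_block = 40,
                         reps_per_trial_type = 20)
  dbl <- session_config(n_blocks = 8, trials_per_block = 40,
                        reps_per_trial_type = 40)
  sim1 <- small_cohort(15, seed = 61, config = base)
  sim2 <- small_cohort(15, seed = 61, config = dbl)
  f1 <- quick_fit(condition_datasets(sim1$trials)$safe_press, "m4",
                  seed = 3)
  f2 <- quick_fit(condition_datasets(sim2$trials)$safe_press, "m4",
                  seed = 3)
  expect_lt(sd(group_mean_draws(f2, "ep")),
            sd(group_mean_draws(f1, "ep")))
})

test_that("unknown models and malformed data are rejected", {
  sim <- small_cohort(3, seed = 2)
  cds <- condition_datasets(sim$trials)
  expect_error(fit_hierarchical(cds$safe_press, "m9"))
  expect_error(fit_hierarchical(sim$trials, "m1"),
               "condition_dataset")
})

test_that("PSIS-LOO reduces to -2 sum(pointwise) for a degenerate posterior", {
  ll <- matrix(rep(log(runif(30, 0.2, 0.9)), each = 50), nrow = 50)
  loo <- compute_loo(ll)
  expect_equal(loo$looic, -2 * sum(ll[1, ]), tolerance = 1e-10)
  expect_equal(loo$p_loo, 0, tolerance = 1e-8)
  expect_error(compute_loo(structure(list(log_lik = NULL),
                                     class = "gng_fit")),
               "pointwise")
})

test_that("LOOIC prefers the generating model over a lapse-only account", {
  sim <- small_cohort(12, seed = 51, model_id = "m4",
                      group_mean = c(xi = stats::qnorm(0.05),
                                     ep = stats::qnorm(0.3),
                                     b = 0.3, pi = 0.5,
                                     rhoRew = log(4), rhoPun = log(4)))
  cds <- condition_datasets(sim$trials)
  f_gen <- quick_fit(cds$safe_press, "m4", seed = 5)
  noise_ll <- matrix(log(0.5), nrow(f_gen$log_lik), ncol(f_gen$log_lik))
  expect_lt(f_gen$looic, compute_loo(noise_ll)$looic)
})

test_that("model selection sums LOOIC across conditions and flags ties", {
  tab <- data.frame(
    model = rep(c("m1", "m4"), each = 4),
    condition = rep(condition_labels(), 2),
    looic = c(100, 100, 100, 100, 90, 110, 95, 95))
  sel <- select_model(tab)
  expect_equal(sel$winner, "m4")
  expect_false(sel$tie)
  expect_equal(sel$table$total, c(400, 390))
  tie_tab <- tab
  tie_tab$looic <- rep(100, 8)
  sel2 <- select_model(tie_tab)
  expect_true(sel2$tie)
  expect_equal(sel2$winner, "m1")
  expect_setequal(sel2$tied_models, c("m1", "m4"))
  expect_error(select_model(tab[-1, ]), "missing condition")
})

test_that("the HDI equals the sorted-draw shortest-interval oracle", {
  set.seed(9)
  for (i in 1:20) {
    x <- switch(1 + i %% 3,
                rnorm(sample(50:2000, 1)),
                rexp(sample(50:2000, 1)),
                c(rnorm(500), rnorm(200, 6)))
    mass <- sample(c(0.5, 0.8, 0.9, 0.95), 1)
    expect_equal(unname(hdi(x, mass)), oracle_hdi(x, mass))
  }
  # uniform draws: 95% HDI width is ~0.95
  u <- with_seed_test(4, runif(1e6))
  iv <- hdi(u, 0.95)
  expect_lt(abs((iv[2] - iv[1]) - 0.95), 0.01)
})

test_that("hyperparameter differences behave under construction and identity", {
  sim <- small_cohort(8, seed = 71)
  cds <- condition_datasets(sim$trials)
  f <- quick_fit(cds$safe_press, "m4", seed = 7, draws = 150)
  # identical fits: difference contains zero, not credible
  d0 <- hdi_difference(f, f, "ep")
  expect_lte(d0$lower, 0)
  expect_gte(d0$upper, 0)
  expect_false(d0$credible)
  expect_error(hdi_difference(f, f, "nonexistent"), "not in model")
  # tight synthetic normal difference: interval ~ [0.98, 1.02]
  dd <- with_seed_test(12, rnorm(1e5, 1, 0.01))
  iv <- hdi(dd, 0.95)
  expect_equal(unname(iv), c(0.98, 1.02), tolerance = 2e-3)
})

test_that("the interaction score cancels shared threat shifts", {
  sim <- small_cohort(8, seed = 81)
  cds <- condition_datasets(sim$trials)
  f <- quick_fit(cds$safe_press, "m4", seed = 11, draws = 150)
  fits <- list(threat_press = f, threat_lift = f, safe_press = f,
               safe_lift = f)
  res <- interaction_difference(fits, "b")
  expect_lte(res$interaction$lower, 0)
  expect_gte(res$interaction$upper, 0)
  expect_named(res$simple_effects,
               c("threat_press_vs_safe_press", "threat_lift_vs_safe_lift",
                 "threat_press_vs_threat_lift", "safe_press_vs_safe_lift"))
  # shift threat_press draws by +1: interaction becomes credible
  f_up <- f
  f_up$draws$mu[, , "b"] <- f$draws$mu[, , "b"] + 1
  res_up <- interaction_difference(
    list(threat_press = f_up, threat_lift = f, safe_press = f,
         safe_lift = f), "b")
  expect_true(res_up$interaction$credible)
  # shifting both threat conditions cancels in the double difference
  res_both <- interaction_difference(
    list(threat_press = f_up, threat_lift = f_up, safe_press = f,
         safe_lift = f), "b")
  expect_lte(res_both$interaction$lower, 0)
  expect_gte(res_both$interaction$upper, 0)
  expect_true(res_both$simple_effects$threat_press_vs_safe_press$credible)
})

test_that("posterior predictive checks calibrate on the generating model", {
  sim <- small_cohort(10, seed = 91)
  cds <- condition_datasets(sim$trials)
  f <- quick_fit(cds$threat_press, "m4", seed = 13)
  pp <- posterior_predictive(f, n_draws = 80, seed = 17)
  expect_equal(nrow(pp), 10 * 4)
  expect_true(all(pp$predicted_lower <= pp$predicted_upper))
  expect_gte(mean(pp$inside), 0.9)
  expect_error(posterior_predictive(f, n_draws = 0), "n_draws")
})

test_that("a lapse-dominated posterior predicts chance accuracy on go types", {
  sim <- small_cohort(8, seed = 93, model_id = "m1",
                      group_mean = c(xi = 3, ep = stats::qnorm(0.2),
                                     rho = log(2)), group_sd = 0.05)
  cds <- condition_datasets(sim$trials)
  f <- quick_fit(cds$safe_lift, "m1", seed = 23, draws = 150)
  pp <- posterior_predictive(f, n_draws = 60, seed = 29)
  expect_true(all(abs(pp$predicted_mean - 0.5) < 0.15))
})
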