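test_that("cell aggregation matches hand counts on a toy table", {
  sim <- simulate_cohort(cohort_spec(n_subjects = 2, seed = 3),
                         session_config())
  tab <- accuracy_table(sim$trials)
  expect_equal(nrow(tab), 2 * 16)
  expect_true(all(tab$n_trials == 15))
  # hand-recount one cell
  tr <- sim$trials
  cell <- tr[tr$subject_id == "s001" & tr$block_threat == "threat" &
             tr$action_context == "press" & tr$instruction == "go" &
             tr$valence == "win", ]
  got <- tab[tab$subject_id == "s001" & tab$tos == "threat" &
             tab$action == "press" & tab$instruction == "go" &
             tab$valence == "win", ]
  expect_equal(got$accuracy, mean(cell$correct))
  expect_equal(got$rt_ms, mean(cell$rt_ms[cell$chosen_go]))
  # all-correct data gives accuracy 1 everywhere
  tr2 <- tr
  tr2$chosen_go <- tr2$required_go
  tr2$correct <- TRUE
  tr2$rt_ms <- ifelse(tr2$chosen_go, 500, NA_real_)
  expect_true(all(accuracy_table(tr2)$accuracy == 1))
  # block factorization has 6 x 8 cells per subject
  tb <- accuracy_table(sim$trials, "block")
  expect_equal(nrow(tb), 2 * 6 * 8)
})

test_that("a coin-flip chooser sits near one half in every cell", {
  m <- c(xi = 10, ep = stats::qnorm(0.2), b = 0, pi = 0,
         rhoRew = log(4), rhoPun = log(4))
  sim <- simulate_cohort(
    cohort_spec(n_subjects = 30, group_mean = m,
                group_sd = stats::setNames(rep(0, 6), names(m)),
                seed = 17),
    session_config())
  tab <- accuracy_table(sim$trials)
  cellmeans <- tapply(tab$accuracy, tab$cell, mean)
  expect_true(all(abs(cellmeans - 0.5) < 0.06))
})

test_that("rm_anova agrees with brute-force sums of squares and aov", {
  set.seed(23)
  for (rep in 1:5) {
    nf <- sample(2:3, 1)
    factors <- stats::setNames(
      lapply(seq_len(nf), function(k) paste0("l", seq_len(sample(2:3, 1)))),
      paste0("f", seq_len(nf)))
    cells <- toy_cells(n_subj = sample(5:8, 1), factors, seed = rep)
    got <- rm_anova(cells, "y", names(factors))
    ss <- oracle_rm_ss(cells, "y", names(factors), "subject_id")
    ao <- oracle_rm_aov(cells, "y", names(factors), "subject_id")
    for (i in seq_len(nrow(got))) {
      eff <- got$effect[i]
      key <- paste(sort(strsplit(eff, ":")[[1]]), collapse = ":")
      j <- match(key, vapply(strsplit(ss$effect, ":"),
                             function(x) paste(sort(x), collapse = ":"),
                             character(1)))
      expect_equal(got$ss_effect[i], ss$ss_effect[j], tolerance = 1e-8)
      expect_equal(got$ss_error[i], ss$ss_error[j], tolerance = 1e-8)
      expect_equal(got$F[i], ss$F[j], tolerance = 1e-8)
      k <- match(key, ao$effect)
      expect_equal(got$F[i], ao$F[k], tolerance = 1e-8)
      expect_equal(got$df1[i], ao$df1[k])
      expect_equal(got$df2[i], ao$df2[k])
      expect_equal(got$p[i], ao$p[k], tolerance = 1e-8)
    }
  }
})

test_that("two-level effects have epsilon exactly one", {
  cells <- toy_cells(6, list(a = c("x", "y"), b = c("u", "v")), seed = 5)
  an <- rm_anova(cells, "y", c("a", "b"))
  expect_true(all(an$gg_epsilon == 1))
  expect_equal(an$p_corrected, an$p)
  expect_false(any(an$gg_applied))
})

test_that("epsilon and partial eta squared respect their analytic bounds", {
  set.seed(31)
  for (rep in 1:5) {
    cells <- toy_cells(8, list(f = paste0("l", 1:4),
                               g = c("x", "y")), seed = rep + 40)
    an <- rm_anova(cells, "y", c("f", "g"))
    k4 <- an[an$effect == "f", ]
    expect_gt(k4$gg_epsilon, 1 / 3)   # lower bound 1/(k-1)
    expect_lte(k4$gg_epsilon, 1 + 1e-12)
    expect_true(all(an$pes >= 0 & an$pes <= 1))
    expect_true(all(an$F >= 0))
  }
})

test_that("a constructed main effect is detected with the right F", {
  cells <- toy_cells(6, list(a = c("lo", "hi"), b = c("u", "v")),
                     seed = 9, effect = function(d) 2 * (d$a == "hi"))
  an <- rm_anova(cells, "y", c("a", "b"))
  expect_lt(an$p[an$effect == "a"], 0.01)
  ss <- oracle_rm_ss(cells, "y", c("a", "b"), "subject_id")
  expect_equal(an$F[an$effect == "a"], ss$F[ss$effect == "a"],
               tolerance = 1e-8)
})

test_that("anova rejects degenerate inputs and drops incomplete subjects", {
  cells <- toy_cells(4, list(a = c("x", "y")), seed = 2)
  expect_error(rm_anova(cells[cells$subject_id == "s01", ], "y", "a"),
               "at least 2 subjects")
  holed <- cells[-1, ]
  expect_message(an <- rm_anova(holed, "y", "a"), "dropped listwise")
  expect_equal(attr(an, "n_subjects"), 3)
})

test_that("type-I error of the highest-order interaction is calibrated", {
  set.seed(47)
  n_reps <- 500
  p_int <- numeric(n_reps)
  factors <- list(tos = c("safe", "threat"), action = c("press", "lift"),
                  instruction = c("go", "nogo"), valence = c("win", "avoid"))
  grid <- expand.grid(factors, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  for (r in seq_len(n_reps)) {
    cells <- do.call(rbind, lapply(1:12, function(i) {
      g <- grid
      g$subject_id <- sprintf("s%02d", i)
      g$y <- rnorm(nrow(g)) + rnorm(1)  # null: subject shifts only
      g
    }))
    an <- rm_anova(cells, "y", names(factors))
    p_int[r] <- an$p_corrected[an$effect ==
                                 "tos:action:instruction:valence"]
  }
  rate <- mean(p_int < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("paired contrasts reproduce hand-computed statistics", {
  cells <- data.frame(
    subject_id = rep(c("a", "b", "c"), 2),
    cell = rep(c("c1", "c2"), each = 3),
    accuracy = c(1, 2, 3, 1, 1, 1))
  res <- paired_contrasts(cells, list(c("c1", "c2")))
  # differences {0, 1, 2}: mean 1, sd 1, dz 1, t = sqrt(3), df 2
  expect_equal(res$mean_diff, 1)
  expect_equal(res$dz, 1)
  expect_equal(res$t, sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-sqrt(3), 2), tolerance = 1e-12)
  expect_equal(res$ci_lower, 1 - qt(0.975, 2) / sqrt(3), tolerance = 1e-10)
  # identical cells: t = 0; zero-variance flagged
  same <- cells
  same$accuracy <- rep(c(1, 2, 3), 2)
  r2 <- paired_contrasts(same, list(c("c1", "c2")))
  expect_equal(r2$t, 0)
  expect_equal(r2$dz, 0)
  const <- cells
  const$accuracy <- rep(c(2, 1), each = 3)  # constant nonzero difference
  r3 <- paired_contrasts(const, list(c("c1", "c2")))
  expect_true(is.na(r3$t))
  expect_match(r3$note, "zero variance")
})

test_that("FDR adjustment matches the step-up oracle and its invariances", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_equal(fdr_adjust(c(0.005, 0.04, 0.1)), c(0.015, 0.06, 0.1))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(fdr_adjust(c(0.2, 1.4)), "0, 1")
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))^2
    adj <- fdr_adjust(p)
    expect_equal(adj, oracle_bh(p))
    # order invariance and monotonicity in rank
    perm <- sample(seq_along(p))
    expect_equal(fdr_adjust(p[perm]), adj[perm])
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_true(all(adj <= 1))
  }
})

test_that("the contrast family correction is applied within the family", {
  cells <- toy_cells(8, list(a = c("w", "x", "y", "z")), seed = 3,
                     effect = function(d) 0.8 * (d$a == "w"))
  cells$cell <- cells$a
  pairs <- list(c("w", "x"), c("w", "y"), c("w", "z"), c("x", "y"))
  res <- paired_contrasts(cells, pairs, dv = "y")
  expect_equal(res$p_fdr, fdr_adjust(res$p))
  expect_true(all(res$p_fdr >= res$p))
})

test_that("the manipulation check recovers hand-computed paired statistics", {
  ratings <- data.frame(subject_id = 1:4,
                        safe_anxiety = c(1, 2, 1, 2),
                        threat_anxiety = c(3, 3, 4, 4),
                        safe_stress = c(1, 1, 1, 1),
                        threat_stress = c(1, 1, 1, 1))
  mc <- manipulation_check(ratings)
  anx <- mc$tests[mc$tests$rating == "anxiety", ]
  d <- c(2, 1, 3, 2)
  expect_equal(anx$mean_diff, 2)
  expect_equal(anx$t, mean(d) / (sd(d) / 2), tolerance = 1e-12)
  expect_equal(anx$df, 3)
  expect_equal(anx$ci_lower, mean(d) - qt(0.975, 3) * sd(d) / 2,
               tolerance = 1e-12)
  strs <- mc$tests[mc$tests$rating == "stress", ]
  expect_equal(strs$t, 0)
  # constant trait vector: undefined correlation, warned, NA
  ratings$trait_anxiety <- rep(5, 4)
  # both rating changes trigger the undefined-correlation warning
  expect_warning(expect_warning(mc2 <- manipulation_check(ratings),
                                "undefined"), "undefined")
  expect_true(any(is.na(mc2$trait_correlations$r)))
  expect_error(manipulation_check(ratings[, -2]), "missing column")
})

test_that("paired t power analysis reproduces the planned sample size", {
  expect_equal(power_paired_t(0.4, 0.05, 0.80, tails = 2), 52)
  expect_lt(paired_t_power(51, 0.4), 0.80)
  expect_gte(paired_t_power(52, 0.4), 0.80)
  # agreement with the stats package at several effect sizes
  for (dz in c(0.25, 0.5, 0.8)) {
    n_ref <- ceiling(stats::power.t.test(delta = dz, sd = 1, power = 0.8,
                                         type = "paired")$n)
    expect_lte(abs(power_paired_t(dz) - n_ref), 1)
  }
  # monotonicity: larger effects never need more subjects
  ns <- vapply(seq(0.2, 1.2, by = 0.05), power_paired_t, numeric(1))
  expect_true(all(diff(ns) <= 0))
  # round trip of the companion power function
  for (dz in c(0.3, 0.4, 0.6)) {
    n <- power_paired_t(dz)
    expect_gte(paired_t_power(n, dz), 0.80)
    expect_lt(paired_t_power(n - 1, dz), 0.80)
  }
})
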