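# Independent reference implementations used as oracles. These are coded
# step by step from the model definitions, deliberately sharing no code
# with the package internals.

# forward-pass log-likelihood, plain R, one scalar at a time
oracle_loglik <- function(stim, chosen_go, outcome, xi, ep, b, pi,
                          rhoRew, rhoPun) {
  q_go <- q_nogo <- v <- rep(0, 4)
  pw <- numeric(length(stim))
  for (t in seq_along(stim)) {
    s <- stim[t]
    w_go <- q_go[s] + b + pi * v[s]
    w_nogo <- q_nogo[s]
    p <- (1 - xi) * (1 / (1 + exp(-(w_go - w_nogo)))) + xi / 2
    pw[t] <- if (chosen_go[t]) log(p) else log(1 - p)
    rho <- if (outcome[t] >= 0) rhoRew else rhoPun
    tgt <- rho * outcome[t]
    v[s] <- v[s] + ep * (tgt - v[s])
    if (chosen_go[t]) q_go[s] <- q_go[s] + ep * (tgt - q_go[s])
    else q_nogo[s] <- q_nogo[s] + ep * (tgt - q_nogo[s])
  }
  list(total = sum(pw), pointwise = pw)
}

random_params <- function(model_id) {
  xi <- runif(1, 0.01, 0.5)
  ep <- runif(1, 0.05, 0.8)
  b <- runif(1, -1, 1)
  pi <- runif(1, -1, 1.5)
  r1 <- runif(1, 0.5, 6)
  r2 <- runif(1, 0.5, 6)
  switch(model_id,
         m1 = agent_params("m1", xi = xi, ep = ep, rho = r1),
         m2 = agent_params("m2", xi = xi, ep = ep, rho = r1, b = b),
         m3 = agent_params("m3", xi = xi, ep = ep, rho = r1, b = b,
                           pi = pi),
         m4 = agent_params("m4", xi = xi, ep = ep, rhoRew = r1,
                           rhoPun = r2, b = b, pi = pi))
}

random_sequence <- function(n = 60) {
  stim <- sample(1:4, n, replace = TRUE)
  valence <- ifelse(stim %in% c(1, 3), "win", "avoid")
  chosen <- sample(c(TRUE, FALSE), n, replace = TRUE)
  outcome <- ifelse(valence == "win", sample(0:1, n, replace = TRUE),
                    sample(c(-1L, 0L), n, replace = TRUE))
  data.frame(stim = stim, chosen_go = chosen, outcome = as.integer(outcome))
}

# repeated-measures F/df oracle via base aov() error strata, which carries
# out the full sums-of-squares decomposition independently of rm_anova()
oracle_rm_aov <- function(data, dv, within, subject) {
  d <- data
  d$.y <- d[[dv]]
  d$.s <- factor(d[[subject]])
  for (f in within) d[[f]] <- factor(d[[f]])
  rhs <- paste(within, collapse = " * ")
  form <- stats::as.formula(paste0(".y ~ ", rhs, " + Error(.s/(", rhs, "))"))
  fit <- summary(stats::aov(form, data = d))
  rows <- list()
  for (stratum in fit) {
    tab <- stratum[[1]]
    for (r in rownames(tab)) {
      nm <- trimws(r)
      if (nm == "Residuals") next
      eff <- paste(sort(strsplit(nm, ":")[[1]]), collapse = ":")
      rows[[eff]] <- data.frame(
        effect = eff,
        df1 = tab[r, "Df"],
        df2 = tab["Residuals", "Df"],
        F = tab[r, "F value"],
        p = tab[r, "Pr(>F)"],
        ss_effect = tab[r, "Sum Sq"],
        ss_error = tab["Residuals", "Sum Sq"])
    }
  }
  do.call(rbind, rows)
}

# brute-force sums of squares from one big fully crossed linear model
# (subject x all factors); in this balanced design each within-effect is
# tested against its interaction with subject
oracle_rm_ss <- function(data, dv, within, subject) {
  d <- data
  d$.y <- d[[dv]]
  d$.s <- factor(d[[subject]])
  for (f in within) d[[f]] <- factor(d[[f]])
  rhs <- paste(c(".s", within), collapse = " * ")
  # saturated model: residual df is 0 by design, silence the F-test warning
  an <- suppressWarnings(
    anova(stats::lm(stats::as.formula(paste0(".y ~ ", rhs)), data = d)))
  norm_name <- function(x) paste(sort(strsplit(x, ":")[[1]]), collapse = ":")
  rn <- vapply(rownames(an), norm_name, character(1))
  get_ss <- function(eff) {
    eff_key <- norm_name(paste(eff, collapse = ":"))
    err_key <- norm_name(paste(c(".s", eff), collapse = ":"))
    c(ss_effect = an[match(eff_key, rn), "Sum Sq"],
      df1 = an[match(eff_key, rn), "Df"],
      ss_error = an[match(err_key, rn), "Sum Sq"],
      df2 = an[match(err_key, rn), "Df"])
  }
  effs <- unlist(lapply(seq_along(within), function(k)
    combn(within, k, simplify = FALSE)), recursive = FALSE)
  out <- do.call(rbind, lapply(effs, function(e) {
    v <- get_ss(e)
    data.frame(effect = paste(e, collapse = ":"),
               df1 = v["df1"], df2 = v["df2"],
               ss_effect = v["ss_effect"], ss_error = v["ss_error"],
               F = (v["ss_effect"] / v["df1"]) / (v["ss_error"] / v["df2"]),
               row.names = NULL)
  }))
  out
}

# Benjamini-Hochberg step-up, coded directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# shortest interval containing ceiling/floor(mass*n) sorted draws, by loop
oracle_hdi <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(2, floor(mass * n))
  best <- c(-Inf, Inf)
  for (i in 1:(n - m + 1)) {
    lo <- x[i]; hi <- x[i + m - 1]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# small balanced cell table for ANOVA tests
toy_cells <- function(n_subj = 6, factors, seed = 1, effect = NULL) {
  set.seed(seed)
  grid <- expand.grid(factors, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(n_subj), function(i) {
    g <- grid
    g$subject_id <- sprintf("s%02d", i)
    g$y <- rnorm(nrow(g)) + rnorm(1)
    g
  }))
  if (!is.null(effect)) out$y <- out$y + effect(out)
  out
}
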