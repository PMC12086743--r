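#' Per-subject factorial cell means of accuracy and latency
#'
#' Aggregates trials into the subject x cell table the repeated-measures
#' ANOVAs consume. The main factorization crosses TOS (safe/threat), Action
#' (press/lift), Instruction (go/no-go) and Valence (win/avoid); the
#' alternative replaces TOS with Block (1..n) to expose learning effects.
#' Latency means use go-response trials only (no latency exists for a
#' withheld response); cells with no qualifying trials are `NA`, never
#' zero-filled.
#'
#' @param trials A validated trial table.
#' @param time_factor `"tos"` (default) or `"block"`.
#' @return Data.frame with one row per subject x cell: the factor columns,
#'   `n_trials`, `accuracy`, `rt_ms`, and a `cell` label.
#' @export
accuracy_table <- function(trials, time_factor = c("tos", "block")) {
  trials <- validate_trials(trials)
  time_factor <- match.arg(time_factor)
  tcol <- if (time_factor == "tos") "block_threat" else "block_index"
  fac <- list(subject_id = trials$subject_id,
              time = trials[[tcol]],
              action = trials$action_context,
              instruction = trials$instruction,
              valence = trials$valence)
  acc <- stats::aggregate(trials$correct, fac, FUN = mean)
  cnt <- stats::aggregate(trials$correct, fac, FUN = length)
  go_rt <- ifelse(trials$chosen_go, trials$rt_ms, NA_real_)
  rt <- stats::aggregate(go_rt, fac, FUN = function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  out <- acc
  names(out)[names(out) == "x"] <- "accuracy"
  names(out)[names(out) == "time"] <- time_factor
  out$n_trials <- cnt$x
  out$rt_ms <- rt$x
  out$cell <- interaction(out[[time_factor]], out$action, out$instruction,
                          out$valence, sep = ".", drop = TRUE)
  empty <- sum(is.na(out$accuracy))
  if (empty > 0)
    warning(empty, " subject cells have no qualifying trials", call. = FALSE)
  out[order(out$subject_id, out[[time_factor]], out$action,
            out$instruction, out$valence), ]
}

# orthonormal contrast basis (l x (l-1)) and unit vector for a factor
orthonorm_contrasts <- function(l) {
  C <- stats::contr.helmert(l)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Within-subject full-factorial repeated-measures ANOVA
#'
#' Classical univariate decomposition for a fully crossed within-subject
#' design with one observation per subject x cell: every effect is tested
#' against its own subject-by-effect interaction. Computed from orthonormal
#' polynomial-free (Helmert) contrasts, which also yield the
#' Greenhouse-Geisser epsilon and Mauchly sphericity test per effect.
#' Sphericity is evaluated only for effects with >= 3 levels (epsilon is 1
#' exactly for 2-level effects); the GG-corrected p is adopted when the
#' Mauchly test rejects at 0.05. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`. Subjects with any missing cell are
#' removed listwise with a message.
#'
#' @param cells Long data.frame of cell means (e.g. [accuracy_table()]).
#' @param dv Name of the response column.
#' @param within Character vector of within-subject factor columns.
#' @param subject Name of the subject column (default `"subject_id"`).
#' @return Data.frame of class `"anova_table"`: one row per effect with
#'   `df1`, `df2`, `F`, `p`, `gg_epsilon`, `mauchly_p`, `p_gg`,
#'   `p_corrected` (GG-corrected where sphericity was rejected), `pes`.
#' @export
rm_anova <- function(cells, dv, within, subject = "subject_id") {
  stopifnot(all(c(dv, within, subject) %in% names(cells)))
  d <- cells[, c(subject, within, dv)]
  names(d) <- c(".subj", within, ".y")
  for (f in within) d[[f]] <- factor(d[[f]])
  levs <- lapply(d[within], levels)
  nlev <- vapply(levs, length, integer(1))
  # wide matrix, cells ordered so the *last* factor varies fastest,
  # matching the kronecker construction of the contrast bases
  d$.cell <- do.call(paste, c(d[within], sep = "\r"))
  cell_grid <- expand.grid(rev(levs), KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)[, rev(seq_along(within)),
                                                     drop = FALSE]
  names(cell_grid) <- within
  cell_order <- do.call(paste, c(cell_grid, sep = "\r"))
  subjects <- unique(d$.subj)
  Y <- matrix(NA_real_, length(subjects), length(cell_order),
              dimnames = list(subjects, cell_order))
  idx <- cbind(match(d$.subj, subjects), match(d$.cell, cell_order))
  if (anyNA(idx[, 2])) stop("unbalanced cell structure", call. = FALSE)
  Y[idx] <- d$.y
  complete <- stats::complete.cases(Y)
  if (sum(!complete) > 0)
    message(sum(!complete), " subject(s) dropped listwise (missing cells)")
  Y <- Y[complete, , drop = FALSE]
  n <- nrow(Y)
  if (n < 2) stop("need at least 2 subjects with complete data",
                  call. = FALSE)
  bases <- lapply(nlev, orthonorm_contrasts)
  units <- lapply(nlev, function(l) matrix(1 / sqrt(l), l, 1))
  effects <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(effects, function(eff) {
    M <- matrix(1, 1, 1)
    for (f in within)
      M <- kronecker(M, if (f %in% eff) bases[[f]] else units[[f]])
    Z <- Y %*% M
    zbar <- colMeans(Z)
    d1 <- ncol(M)
    ss_eff <- n * sum(zbar^2)
    ss_err <- sum(sweep(Z, 2, zbar)^2)
    d2 <- (n - 1) * d1
    Fv <- (ss_eff / d1) / (ss_err / d2)
    p <- stats::pf(Fv, d1, d2, lower.tail = FALSE)
    if (d1 >= 2 && n > d1) {
      S <- stats::cov(Z)
      eig <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      eps <- sum(eig)^2 / (d1 * sum(eig^2))
      detS <- prod(eig)
      W <- if (detS > 0) detS / (mean(eig))^d1 else 0
      if (W > 0) {
        fcorr <- 1 - (2 * d1^2 + d1 + 2) / (6 * d1 * (n - 1))
        X2 <- -(n - 1) * fcorr * log(W)
        mau_p <- stats::pchisq(X2, d1 * (d1 + 1) / 2 - 1,
                               lower.tail = FALSE)
      } else mau_p <- 0
    } else {
      eps <- 1
      mau_p <- NA_real_
    }
    p_gg <- stats::pf(Fv, eps * d1, eps * d2, lower.tail = FALSE)
    apply_gg <- d1 >= 2 && !is.na(mau_p) && mau_p < 0.05
    data.frame(effect = paste(eff, collapse = ":"),
               df1 = d1, df2 = d2, F = Fv, p = p,
               gg_epsilon = eps, mauchly_p = mau_p, p_gg = p_gg,
               p_corrected = if (apply_gg) p_gg else p,
               gg_applied = apply_gg,
               pes = ss_eff / (ss_eff + ss_err),
               ss_effect = ss_eff, ss_error = ss_err,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_subjects") <- n
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Paired contrasts between factorial cells, FDR-corrected
#'
#' Paired t tests across subjects for each requested pair of cells, with
#' Cohen's dz (mean difference over SD of differences), 95% confidence
#' interval of the mean difference, and Benjamini-Hochberg adjustment
#' across the supplied family.
#'
#' @param cells Long cell table (e.g. [accuracy_table()]) with a `cell`
#'   label column.
#' @param pairs List of length-2 character vectors of cell labels.
#' @param dv Response column (default `"accuracy"`).
#' @param subject Subject column (default `"subject_id"`).
#' @param cell Cell-label column (default `"cell"`).
#' @return Data.frame: contrast, n, mean_diff, t, df, p, p_fdr, dz,
#'   ci_lower, ci_upper, note (flags degenerate contrasts).
#' @export
paired_contrasts <- function(cells, pairs, dv = "accuracy",
                             subject = "subject_id", cell = "cell") {
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2)
    a <- cells[cells[[cell]] == pr[1], c(subject, dv)]
    b <- cells[cells[[cell]] == pr[2], c(subject, dv)]
    m <- merge(a, b, by = subject, suffixes = c(".a", ".b"))
    m <- m[stats::complete.cases(m), ]
    dif <- m[[paste0(dv, ".a")]] - m[[paste0(dv, ".b")]]
    n <- length(dif)
    lab <- paste(pr[1], "-", pr[2])
    if (n < 2)
      return(data.frame(contrast = lab, n = n, mean_diff = NA_real_,
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        dz = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, note = "too few pairs"))
    sdd <- stats::sd(dif)
    if (sdd == 0) {
      if (mean(dif) == 0)   # identical cells: a true zero effect
        return(data.frame(contrast = lab, n = n, mean_diff = 0,
                          t = 0, df = n - 1, p = 1, dz = 0,
                          ci_lower = 0, ci_upper = 0, note = ""))
      return(data.frame(contrast = lab, n = n, mean_diff = mean(dif),
                        t = NA_real_, df = n - 1, p = NA_real_,
                        dz = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_,
                        note = "zero variance of differences"))
    }
    se <- sdd / sqrt(n)
    tt <- mean(dif) / se
    ci <- mean(dif) + c(-1, 1) * stats::qt(0.975, n - 1) * se
    data.frame(contrast = lab, n = n, mean_diff = mean(dif), t = tt,
               df = n - 1, p = 2 * stats::pt(-abs(tt), n - 1),
               dz = mean(dif) / sdd, ci_lower = ci[1], ci_upper = ci[2],
               note = "")
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$p_fdr[ok] <- fdr_adjust(out$p[ok])
  out[, c("contrast", "n", "mean_diff", "t", "df", "p", "p_fdr", "dz",
          "ci_lower", "ci_upper", "note")]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values, capped at 1 and monotone in rank.
#'
#' @param pvalues Numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values in the input order.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Manipulation check on post-task ratings
#'
#' Paired t tests (with 95% CIs of the mean difference) of threat vs safe
#' anxiety and stress ratings, plus Pearson correlations of each rating
#' change with the trait-anxiety score when one is supplied. A constant
#' trait vector yields an `NA` correlation with a warning.
#'
#' @param ratings Data.frame with columns `subject_id`, `safe_anxiety`,
#'   `threat_anxiety`, `safe_stress`, `threat_stress` and optionally
#'   `trait_anxiety`.
#' @return List with `tests` (per rating type: mean_diff, t, df, p,
#'   ci_lower, ci_upper) and `trait_correlations` (or `NULL`).
#' @export
manipulation_check <- function(ratings) {
  need <- c("subject_id", "safe_anxiety", "threat_anxiety",
            "safe_stress", "threat_stress")
  miss <- setdiff(need, names(ratings))
  if (length(miss))
    stop("ratings missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(ratings[, need]))
    stop("ratings must be complete and paired", call. = FALSE)
  one <- function(type) {
    dif <- ratings[[paste0("threat_", type)]] -
      ratings[[paste0("safe_", type)]]
    n <- length(dif)
    sdd <- stats::sd(dif)
    se <- sdd / sqrt(n)
    tt <- if (sdd == 0) 0 else mean(dif) / se
    ci <- if (sdd == 0) c(mean(dif), mean(dif))
          else mean(dif) + c(-1, 1) * stats::qt(0.975, n - 1) * se
    data.frame(rating = type, n = n, mean_diff = mean(dif), t = tt,
               df = n - 1,
               p = if (sdd == 0 && mean(dif) == 0) 1
                   else 2 * stats::pt(-abs(tt), n - 1),
               ci_lower = ci[1], ci_upper = ci[2])
  }
  tests <- rbind(one("anxiety"), one("stress"))
  trait_cor <- NULL
  if ("trait_anxiety" %in% names(ratings)) {
    tr <- ratings$trait_anxiety
    cor_one <- function(x, lab) {
      if (stats::sd(tr) == 0 || stats::sd(x) == 0) {
        warning("correlation with trait anxiety undefined for ", lab,
                " (constant vector)", call. = FALSE)
        data.frame(rating = lab, r = NA_real_, p = NA_real_)
      } else {
        ct <- stats::cor.test(x, tr)
        data.frame(rating = lab, r = unname(ct$estimate), p = ct$p.value)
      }
    }
    trait_cor <- rbind(
      cor_one(ratings$threat_anxiety - ratings$safe_anxiety,
              "anxiety_change"),
      cor_one(ratings$threat_stress - ratings$safe_stress,
              "stress_change"))
  }
  list(tests = tests, trait_correlations = trait_cor)
}

#' Power of a paired t test at sample size n
#'
#' Exact noncentral-t power: noncentrality `dz * sqrt(n)` with `n - 1`
#' degrees of freedom.
#'
#' @param n Sample size (pairs).
#' @param dz Cohen's dz effect size (> 0).
#' @param alpha Significance level (default 0.05).
#' @param tails 1 or 2 (default 2).
#' @return Power in `[0, 1]`.
#' @export
paired_t_power <- function(n, dz, alpha = 0.05, tails = 2) {
  stopifnot(dz > 0, alpha > 0, alpha < 1, tails %in% c(1, 2), n >= 2)
  df <- n - 1
  ncp <- dz * sqrt(n)
  if (tails == 2) {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp)
  } else {
    crit <- stats::qt(1 - alpha, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE)
  }
}

#' Minimal sample size for a paired t test
#'
#' Smallest n whose noncentral-t power reaches the request.
#'
#' @param dz Cohen's dz effect size (> 0).
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param tails 1 or 2 (default 2).
#' @return Integer minimal n.
#' @export
power_paired_t <- function(dz, alpha = 0.05, power = 0.80, tails = 2) {
  stopifnot(dz > 0, power > 0, power < 1)
  n <- 2L
  while (paired_t_power(n, dz, alpha, tails) < power) {
    n <- n + 1L
    if (n > 1e6) stop("requested power unreachable with n <= 1e6",
                      call. = FALSE)
  }
  n
}
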