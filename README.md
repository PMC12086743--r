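# gngtos

Simulation and analysis tools for an **orthogonalized Go/No-Go task under
threat of shock** — the paradigm used to ask whether induced anxiety
promotes *passive* avoidance (withholding a button press to avoid loss)
and/or *active* avoidance (lifting a held button to avoid loss).

The package is aimed at computational-psychiatry researchers who want a
tested, reproducible reimplementation of this analysis pipeline: a
generative simulator of the task and of model-driven cohorts, the nested
Rescorla–Wagner model family with Pavlovian bias, hierarchical Bayesian
fitting with LOOIC model comparison and HDI inference, and the behavioral
repeated-measures statistics.

## The task

Eight trial types cross **Action context** (press vs lift), **Instruction**
(go vs no-go) and **Valence** (win vs avoid losing). A session is 240
trials — 30 of each type — in 6 blocks of 40 that strictly alternate safe
and threat-of-shock; each threat block delivers exactly one
performance-independent shock at the 12th or 28th trial (50/50). Correct
choices earn the expected outcome only 80% of the time (win trials pay
+1/0 points, avoid trials 0/−1).

## The model family

Choice behavior (go vs no-go over the four stimuli of one TOS × Action
condition) is modeled with nested Rescorla–Wagner learners. On each trial
with stimulus *s*:

    w_go(s)   = q_go(s) + b + pi * v(s)
    w_nogo(s) = q_nogo(s)
    P(go)     = (1 − xi) * logistic(w_go − w_nogo) + xi/2

and after observing outcome *r* ∈ {−1, 0, +1}:

    v(s)      ← v(s)      + ep * (rho(r) * r − v(s))
    q_chosen  ← q_chosen  + ep * (rho(r) * r − q_chosen)

* **m1**: lapse `xi`, learning rate `ep`, sensitivity `rho`
* **m2**: + go bias `b`
* **m3**: + Pavlovian bias `pi` (stimulus value promotes action)
* **m4**: separate `rhoRew` (r ≥ 0) and `rhoPun` (r < 0)

Each model is fit hierarchically (subjects share group normals on a
transformed scale) to each of the four conditions separately; the overall
winner minimizes LOOIC summed across conditions; condition contrasts use
95% highest-density intervals of group-mean differences, including the
((threat press − safe press) − (threat lift − safe lift)) interaction
score.

## Worked example

```r
library(gngtos)

## one session schedule: 240 trials, 6 alternating blocks, 3 shocks
s <- make_schedule(session_config(seed = 1))
table(s$block_threat)
#>   safe threat
#>    120    120
s[s$shock_event, c("block_index", "trial_in_block")]
#> blocks 2, 4, 6 at trials 28, 12, 12

## simulate a 12-subject cohort from the m4 generator and split it into
## the four fitting conditions
sim <- simulate_cohort(cohort_spec(n_subjects = 12, seed = 1),
                       session_config())
cds <- condition_datasets(sim$trials)
cds$threat_press
#> <condition_dataset threat_press> 12 subjects, 720 trials

## hierarchical fit of m4 to the threat-press condition
f <- fit_hierarchical(cds$threat_press, "m4",
                      chains = 2, iter_warmup = 600, iter_draws = 300,
                      seed = 2)
f
#> <gng_fit> model m4, condition threat_press
#>   12 subjects, 720 trials, 2 chains x 300 draws
#>   max Rhat (group) 1.107, LOOIC 830.2
mean(group_mean_draws(f, "ep", natural = TRUE))
#> [1] 0.266        # group learning rate (generator: 0.2)

## behavioral layer: 4-factor repeated-measures ANOVA on accuracy
tab <- accuracy_table(sim$trials)
an <- rm_anova(tab, "accuracy", c("tos", "action", "instruction", "valence"))
an[an$effect == "instruction:valence",
   c("effect", "df1", "df2", "F", "p_corrected", "pes")]
#>                effect df1 df2    F p_corrected   pes
#>   instruction:valence   1  11 35.3    9.66e-05 0.763
```

The large Instruction × Valence interaction is the Pavlovian-bias
signature the generator builds in (`pi > 0`): going for reward is easy,
going to avoid loss is hard.

The a-priori power analysis that sized the study is one call:

```r
power_paired_t(dz = 0.4, alpha = 0.05, power = 0.80)
#> [1] 52
```

A full simulate → fit → compare → report run is available
programmatically (`cmd_simulate()`, `cmd_fit()`, `cmd_report()`) or from
the shell via `inst/cli/gngtos.R`:

```sh
Rscript inst/cli/gngtos.R simulate --out study --seed 1
Rscript inst/cli/gngtos.R report --data study/dataset.csv --out study --seed 1
```

Real datasets in the same trial-level CSV schema (see `?write_dataset`)
can be fed to `cmd_fit`/`cmd_report` directly in place of the simulated
cohort; the public deposit of the original study (OSF `wc3mu`) can be
reshaped to this schema as an optional exercise.

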