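# mcimarkov

Multistate Markov modelling of cognitive-state transitions in
longitudinal aging cohorts, for biostatisticians and epidemiologists
studying mild cognitive impairment (MCI): who enters test-based or
clinically diagnosed MCI, who reverts to normal, and who progresses to
dementia or death — and which risk factors drive each move.

## The model

Annual assessments classify each subject-visit into one of six states:
`NORMAL`, test-based amnestic MCI (`AMCI_TB`), test-based mixed MCI
(`MMCI_TB`), clinical-consensus MCI (`MCI_CC`, quasi-absorbing), and the
absorbing competing states `DEMENTIA` and `DEATH`.  Test-based states
come from age-adjusted neuropsychological norms: a *poor score* lies at
least 1.5 residual SD below (or, for error counts and timed tests,
above) the age-adjusted mean.

Adjacent assessment pairs follow a first-order Markov chain modelled by
shared-random-effect polytomous logistic regression against a base state
*b* (normal cognition before `MCI_CC` entry, `MCI_CC` afterwards):

    log[ P(s_t = k | s_{t-1}) / P(s_t = base) ]
        = alpha_k^(b) + x' beta_k^(b) + u_i,     u_i ~ N(0, sigma_u^2)

with covariates x = (age − 78, female, family history, APOE-4, ≤12 y
education, baseline hypertension, and prior-state indicators under the
normal base).  The subject effect u_i is shared across all of a
subject's transitions; the marginal likelihood integrates it by adaptive
Gauss–Hermite quadrature (one point — the Laplace approximation — by
default) and is maximised by quasi-Newton ascent with analytic
gradients.  `relative_risks()` reports exp(beta) with Wald 95%
intervals.

A calibrated synthetic-cohort generator (`simulate_cohort()`) emulates a
554-subject cohort (entry age 72.7 ± 7.8, 64.3% female, 30% APOE-4,
10.8 ± 4.5 annual visits) so the entire pipeline — classification,
cleaning, tabulation, estimation, recovery studies — runs without access
to restricted cohort data.

## Worked example

```r
library(mcimarkov)

spec    <- cohort_spec(n_subjects = 554, seed = 1)
visits  <- emit_raw_scores(simulate_cohort(spec))     # states + raw scores
class   <- classify_visits(visits, true_norms(spec))  # per-visit states
cleaned <- clean_trajectories(class)                  # quasi-absorbing MCI_CC
pairs   <- build_pairs(cleaned$data)

transition_table(pairs)
#>          current
#> prior     NORMAL      AMCI_TB    MMCI_TB    MCI_CC     DEMENTIA  DEATH
#>   NORMAL  1945 (68.3) 418 (14.7) 333 (11.7) 47 (1.7)   23 (0.8)  80 (2.8)
#>   AMCI_TB 324 (59.2)  119 (21.8) 70 (12.8)  17 (3.1)   7 (1.3)   10 (1.8)
#>   MMCI_TB 208 (33.8)  56 (9.1)   270 (43.8) 23 (3.7)   14 (2.3)  45 (7.3)
#>   MCI_CC  .           .          .          140 (68.6) 44 (21.6) 20 (9.8)

fit <- fit_transitions(pairs)   # Laplace marginal likelihood, BFGS
fit
#> Shared-random-effect polytomous transition model
#>   subjects: 554   pairs: 4213
#>   log-likelihood: -4252.799
#>   converged: TRUE  (max |gradient| = 0.000755 )
#>   sigma_u: 0.5157 (SE 0.0671 )  quadrature: 1 point(s), adaptive
#>
#> Relative risks (base NORMAL):
#>            AMCI_TB           MMCI_TB           MCI_CC
#> age_c      1.01 (1.00-1.03)  1.08 (1.06-1.09)* 1.13 (1.09-1.17)*
#> ...
#> prior_mmci 1.00 (0.72-1.40)  4.78 (3.76-6.09)* 2.49 (1.45-4.26)*
```

Each row of the matrix counts one-step transitions out of a prior state
(row percentages in parentheses); the dots are structural zeros — no
return from clinical MCI to transient states.  The fitted table reads
like a published risk-factor table: e.g. a prior mixed-MCI
classification multiplies the odds of *remaining* mixed MCI (versus
returning to normal) by 4.78, and `sigma_u` ≈ 0.52 reflects the
within-subject correlation the cohort was simulated with (0.5).

A thin command-line wrapper with `simulate`, `classify`, `clean`, `fit`
and `report` subcommands is installed at `inst/cli/mcimarkov`.

## Further reading

The methods vignette (`vignettes/mci-transition-modeling.Rmd`) documents
the model and its assumptions, the cleaning rules, quadrature and
optimizer choices, what the synthetic generator does and does not
emulate, and known limitations.
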