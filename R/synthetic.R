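#' True parameter values for the default simulation scenario
#'
#' Effect sizes (log relative risks) follow the published risk-factor
#' tables for this model: e.g. under the normal base state, age RR 1.12
#' per year and prior mixed-MCI RR 4.80 for entry into clinical MCI; under
#' the `MCI_CC` base state, baseline-hypertension RR 0.30 for progression
#' to dementia.  Baseline intercepts are not published anywhere, so the
#' defaults below were calibrated with [calibrate_intercepts()] so that a
#' simulated cohort with the default demographic mix reproduces the
#' published one-step transition-matrix row percentages for the two
#' calibrated rows (normal base and `MCI_CC` base); they are approximations
#' to the unobservable cohort baseline hazards, not published values.
#'
#' @param sigma_u SD of the shared subject random effect (default 0.5).
#' @return [mci_params()] object.
#' @export
default_true_params <- function(sigma_u = 0.5) {
  rr_normal <- rbind(
    AMCI_TB  = c(1.02, 0.77, 0.81, 1.04, 1.24, 0.95, 1.15, 0.76),
    MMCI_TB  = c(1.07, 1.01, 0.76, 1.12, 1.79, 1.04, 1.00, 4.51),
    MCI_CC   = c(1.12, 0.71, 1.04, 1.89, 2.20, 0.79, 2.28, 4.80),
    DEMENTIA = c(1.19, 1.87, 1.66, 2.33, 0.75, 0.79, 1.85, 4.90),
    DEATH    = c(1.18, 0.68, 0.82, 0.97, 1.33, 1.49, 0.64, 2.67)
  )
  rr_cc <- rbind(
    DEMENTIA = c(1.05, 1.75, 2.88, 0.69, 0.97, 0.30),
    DEATH    = c(1.03, 1.15, 0.68, 2.33, 0.55, 0.70)
  )
  ## intercepts from calibrate_intercepts() under cohort_spec() defaults
  int_normal <- c(AMCI_TB = -1.1740, MMCI_TB = -1.5373, MCI_CC = -4.0044,
                  DEMENTIA = -5.6962, DEATH = -2.9499)
  int_cc <- c(DEMENTIA = -1.6831, DEATH = -2.2030)
  mci_params(
    beta_normal = cbind(int_normal, log(rr_normal)),
    beta_cc = cbind(int_cc, log(rr_cc)),
    sigma_u = sigma_u
  )
}

#' Default generative score models for the test battery
#'
#' Per-test score distributions used when emitting raw scores: an
#' age-linear mean, a residual SD, and the direction flag from the
#' battery.  Accuracy-type scores decline with age; error counts and
#' completion times increase.
#'
#' @param battery Test battery (see [default_battery()]).
#' @return Data frame with columns `test`, `domain`, `direction`,
#'   `mean75` (mean at age 75), `slope` (per year of age), `sd`.
#' @export
default_score_models <- function(battery = default_battery()) {
  battery <- check_battery(battery)
  hb <- battery$direction == "higher_better"
  data.frame(
    battery,
    mean75 = ifelse(hb, 50, 6),
    slope = ifelse(hb, -0.3, 0.15),
    sd = ifelse(hb, 6, 2.5),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic longitudinal cohort
#'
#' Defaults emulate the cohort profile the model was developed on: 554
#' initially normal volunteers aged 72.7 +/- 7.8 at entry, 64.3% female,
#' 41.3% with a family history of dementia, 30.0% APOE-4 carriers, 11.9%
#' with at most 12 years of education, 36.6% with baseline hypertension,
#' about 10.8 +/- 4.5 annual assessments per subject and 1.1 +/- 0.4 years
#' between assessments (truncated below at 0.5 years).
#'
#' @param n_subjects Number of subjects.
#' @param seed Mandatory RNG seed; every source of randomness in the
#'   simulator flows from it.
#' @param params True transition-model parameters ([mci_params()]).
#' @param age_mean,age_sd Age-at-entry distribution (years).
#' @param p_female,p_famhx,p_apoe4,p_low_educ,p_htn Covariate prevalences.
#' @param visits_mean,visits_sd Number-of-assessments distribution
#'   (rounded normal, clipped to `[2, max_visits]`).
#' @param max_visits Upper clip for the visit count.
#' @param interval_mean,interval_sd,interval_min Assessment-interval
#'   distribution in years (normal truncated below at `interval_min`).
#' @param score_models Generative score models for [emit_raw_scores()].
#' @return Object of class `cohort_spec` (a list).
#' @export
cohort_spec <- function(n_subjects = 554, seed,
                        params = default_true_params(),
                        age_mean = 72.7, age_sd = 7.8,
                        p_female = 0.643, p_famhx = 0.413, p_apoe4 = 0.300,
                        p_low_educ = 0.119, p_htn = 0.366,
                        visits_mean = 10.8, visits_sd = 4.5,
                        max_visits = 30,
                        interval_mean = 1.1, interval_sd = 0.4,
                        interval_min = 0.5,
                        score_models = default_score_models()) {
  if (missing(seed)) stop("cohort_spec requires an explicit seed",
                          call. = FALSE)
  prev <- c(p_female, p_famhx, p_apoe4, p_low_educ, p_htn)
  stopifnot(inherits(params, "mci_params"),
            n_subjects >= 1, all(prev >= 0 & prev <= 1),
            interval_mean > 0, interval_min > 0, visits_mean >= 2)
  structure(as.list(environment()), class = "cohort_spec")
}

## truncated-normal draw by inversion
rtnorm_min <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

#' Simulate a longitudinal cohort under the transition model
#'
#' Each subject draws entry covariates and a shared random effect
#' `u ~ N(0, sigma_u^2)`, starts in normal cognition, and at every
#' assessment step moves to a next state drawn from the model's transition
#' probabilities given the current base/prior state, with age advanced by
#' the drawn inter-assessment interval.  Follow-up ends at dementia, death
#' or the drawn number of assessments.  Death is recorded at the next
#' scheduled assessment slot, as in the discrete-time chain.  Output is
#' byte-identical across runs with the same spec.
#'
#' @param spec A [cohort_spec()].
#' @return Long-format data frame with columns `subject`, `visit`, `time`
#'   (years from entry), `age`, `state` and the covariate indicators.
#'   The per-subject random effects are attached as attribute `u`, and
#'   `spec` as attribute `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  params <- spec$params

  age0 <- stats::rnorm(n, spec$age_mean, spec$age_sd)
  female <- stats::rbinom(n, 1, spec$p_female)
  famhx <- stats::rbinom(n, 1, spec$p_famhx)
  apoe4 <- stats::rbinom(n, 1, spec$p_apoe4)
  low_educ <- stats::rbinom(n, 1, spec$p_low_educ)
  htn <- stats::rbinom(n, 1, spec$p_htn)
  n_visits <- pmin(pmax(round(stats::rnorm(n, spec$visits_mean,
                                           spec$visits_sd)), 2),
                   spec$max_visits)
  u <- stats::rnorm(n, 0, params$sigma_u)

  state <- rep("NORMAL", n)
  time <- numeric(n)
  active <- rep(TRUE, n)
  out <- vector("list", spec$max_visits)
  out[[1L]] <- data.frame(
    subject = seq_len(n), visit = 1L, time = 0, age = age0,
    state = state, female = female, famhx = famhx, apoe4 = apoe4,
    low_educ = low_educ, htn = htn, stringsAsFactors = FALSE
  )

  outcomesN <- c("NORMAL", ml_outcomes_normal())
  outcomesC <- c("MCI_CC", ml_outcomes_cc())
  for (t in seq_len(spec$max_visits - 1L)) {
    idx <- which(active & n_visits > t)
    if (!length(idx)) break
    iv <- rtnorm_min(length(idx), spec$interval_mean, spec$interval_sd,
                     spec$interval_min)
    draw <- stats::runif(length(idx))
    newstate <- character(length(idx))
    isC <- state[idx] == "MCI_CC"
    for (blk in c("N", "C")) {
      sel <- if (blk == "N") which(!isC) else which(isC)
      if (!length(sel)) next
      ii <- idx[sel]
      if (blk == "N") {
        X <- cbind(1, age0[ii] + time[ii] - 78, female[ii], famhx[ii],
                   apoe4[ii], low_educ[ii], htn[ii],
                   as.numeric(state[ii] == "AMCI_TB"),
                   as.numeric(state[ii] == "MMCI_TB"))
        B <- params$beta_normal
        outs <- outcomesN
      } else {
        X <- cbind(1, age0[ii] + time[ii] - 78, female[ii], famhx[ii],
                   apoe4[ii], low_educ[ii], htn[ii])
        B <- params$beta_cc
        outs <- outcomesC
      }
      eta <- cbind(0, X %*% t(B) + u[ii])  # base category first
      m <- apply(eta, 1, max)
      P <- exp(eta - m)
      P[is.na(P)] <- 0
      P <- P / rowSums(P)
      cp <- t(apply(P, 1, cumsum))
      pick <- rowSums(draw[sel] > cp) + 1L
      newstate[sel] <- outs[pick]
    }
    time[idx] <- time[idx] + iv
    state[idx] <- newstate
    out[[t + 1L]] <- data.frame(
      subject = idx, visit = t + 1L, time = time[idx],
      age = age0[idx] + time[idx], state = newstate,
      female = female[idx], famhx = famhx[idx], apoe4 = apoe4[idx],
      low_educ = low_educ[idx], htn = htn[idx], stringsAsFactors = FALSE
    )
    active[idx[newstate[seq_along(idx)] %in% absorbing_states()]] <- FALSE
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  res <- res[order(res$subject, res$visit), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "u") <- u
  attr(res, "spec") <- spec
  res
}

#' Generative norms implied by a cohort specification
#'
#' Returns the exact age-adjusted norms of the score models used by
#' [emit_raw_scores()], as an `mci_norms` object, so that classification
#' can be checked against the simulated truth without refitting norms.
#'
#' @param spec A [cohort_spec()] (only `score_models` is used).
#' @return `mci_norms` object.
#' @export
true_norms <- function(spec) {
  sm <- spec$score_models
  tab <- data.frame(
    test = sm$test, domain = sm$domain, direction = sm$direction,
    intercept = sm$mean75 - 75 * sm$slope, slope = sm$slope, sd = sm$sd,
    n = NA_integer_, stringsAsFactors = FALSE
  )
  structure(list(table = tab, method = "linear", band_width = NA,
                 bands = list()),
            class = "mci_norms")
}

#' Emit raw test scores consistent with simulated states
#'
#' Adds per-test score columns and clinical-flag columns to a simulated
#' visit table so the classification stage can be exercised end to end.
#' Scores are planted relative to the generative norms: visits in a
#' test-based MCI state receive at least one defining poor score (at or
#' beyond 1.6 SD in the impaired direction) in the defining domain, while
#' scores that must stay in the normal range are kept inside 1.4 SD, so
#' classification against [true_norms()] recovers the simulated state.
#' Clinical states carry their flags (and mildly to clearly impaired
#' scores); death visits carry no scores.
#'
#' @param visits Simulated visit table from [simulate_cohort()].
#' @param spec The generating [cohort_spec()]; defaults to the spec
#'   attached to `visits`.
#' @return `visits` with score and flag columns appended.
#' @export
emit_raw_scores <- function(visits, spec = attr(visits, "spec")) {
  stopifnot(is.data.frame(visits), !is.null(spec))
  set.seed(spec$seed + 1L)  # scores form their own reproducible stream
  sm <- spec$score_models
  n <- nrow(visits)
  st <- as_state(visits$state)

  ## draw "badness" w per visit x test: poor means w >= 1.5 truth-side
  w_ok <- function(n) stats::qnorm(stats::runif(n, 0, stats::pnorm(1.4)))
  w_poor <- function(n) 1.6 + abs(stats::rnorm(n, 0, 0.5))

  score_cols <- matrix(NA_real_, n, nrow(sm),
                       dimnames = list(NULL, sm$test))
  mem <- which(sm$domain == "memory")
  nonmem <- which(sm$domain == "nonmemory")
  for (i in seq_len(n)) {
    s <- st[i]
    if (s == "DEATH") next
    w <- numeric(nrow(sm))
    if (s == "NORMAL") {
      w <- w_ok(nrow(sm))
    } else if (s == "AMCI_TB") {
      w <- w_ok(nrow(sm))
      w[sample(mem, 1L)] <- w_poor(1L)
    } else if (s == "MMCI_TB") {
      w[mem] <- stats::rnorm(length(mem))
      w[nonmem] <- w_ok(length(nonmem))
      w[sample(nonmem, 1L)] <- w_poor(1L)
    } else if (s == "MCI_CC") {
      w <- stats::rnorm(nrow(sm)) + 0.5
    } else {  # DEMENTIA
      w <- stats::rnorm(nrow(sm)) + 1.5
    }
    mu <- sm$mean75 + sm$slope * (visits$age[i] - 75)
    score_cols[i, ] <- ifelse(sm$direction == "higher_better",
                              mu - w * sm$sd, mu + w * sm$sd)
  }
  out <- cbind(visits, as.data.frame(score_cols))
  out$mci_cc <- st == "MCI_CC"
  out$dementia <- st == "DEMENTIA"
  out$death <- st == "DEATH"
  attr(out, "u") <- attr(visits, "u")
  attr(out, "spec") <- spec
  out
}

#' Calibrate baseline intercepts to target transition rates
#'
#' Baseline transition intensities are not recoverable from the published
#' effect sizes alone.  This routine tunes the intercepts of a parameter
#' set so that the simulated one-step row percentages of the two calibrated
#' rows — prior state normal, and prior state `MCI_CC` — match the target
#' row percentages, by iterated log-odds adjustment against a large
#' simulated cohort.  Rows with a transient MCI prior state are implied by
#' the additive prior-state indicator effects and are not separately
#' calibrated.
#'
#' @param params Starting [mci_params()].
#' @param targets List with elements `normal` (named length-5 vector of
#'   target percentages for `AMCI_TB`, `MMCI_TB`, `MCI_CC`, `DEMENTIA`,
#'   `DEATH` from the normal row) and `cc` (named length-2 vector for
#'   `DEMENTIA`, `DEATH` from the `MCI_CC` row).  Defaults are the
#'   published row percentages.
#' @param n_subjects Simulated cohort size per iteration.
#' @param seed RNG seed for the calibration cohorts.
#' @param max_iter,tol Iteration control: stop when the largest intercept
#'   adjustment (log-odds) falls below `tol`.
#' @param ... Further arguments to [cohort_spec()] (demographics).
#' @return `mci_params` with calibrated intercepts.
#' @export
calibrate_intercepts <- function(params = default_true_params(),
                                 targets = list(
                                   normal = c(AMCI_TB = 14.9, MMCI_TB = 12.0,
                                              MCI_CC = 1.1, DEMENTIA = 0.6,
                                              DEATH = 3.1),
                                   cc = c(DEMENTIA = 22.5, DEATH = 10.6)
                                 ),
                                 n_subjects = 30000, seed = 1,
                                 max_iter = 30, tol = 0.002, ...) {
  tn <- targets$normal / 100
  tc <- targets$cc / 100
  odds_n <- log(tn / (1 - sum(tn)))
  odds_c <- log(tc / (1 - sum(tc)))
  for (it in seq_len(max_iter)) {
    spec <- cohort_spec(n_subjects = n_subjects, seed = seed + it,
                        params = params, ...)
    sim <- simulate_cohort(spec)
    tab <- transition_table(build_pairs(sim, validate = FALSE))
    cn <- tab$counts["NORMAL", ]
    ccrow <- tab$counts["MCI_CC", ]
    obs_n <- log(pmax(cn[names(tn)], 0.5) / max(cn["NORMAL"], 0.5))
    obs_c <- log(pmax(ccrow[names(tc)], 0.5) / max(ccrow["MCI_CC"], 0.5))
    adj_n <- odds_n - obs_n
    adj_c <- odds_c - obs_c
    params$beta_normal[names(tn), "(Intercept)"] <-
      params$beta_normal[names(tn), "(Intercept)"] + adj_n
    params$beta_cc[names(tc), "(Intercept)"] <-
      params$beta_cc[names(tc), "(Intercept)"] + adj_c
    if (max(abs(c(adj_n, adj_c))) < tol) break
  }
  params
}

#' Parameter-recovery study by repeated simulation and refitting
#'
#' Simulates `n_replicates` cohorts from `spec`, refits the transition
#' model to each, and summarises, per parameter: mean estimate, bias,
#' Monte-Carlo standard error of the bias, RMSE, and empirical coverage of
#' the Wald confidence interval.  Per-replicate seeds are spawned
#' deterministically from the spec's master seed.
#'
#' @param spec A [cohort_spec()]; its `params` are the truth.
#' @param n_replicates Number of replicates (>= 2).
#' @param fit_args List of arguments passed on to [fit_transitions()].
#' @param level Nominal CI level for the coverage column.
#' @return Object of class `mci_recovery`: data frame with one row per
#'   parameter (`parameter`, `true`, `mean_est`, `bias`, `mc_se`, `rmse`,
#'   `coverage`), with attributes `n_replicates`, `n_failed` and
#'   `n_nonconverged`.
#' @export
recovery_study <- function(spec, n_replicates, fit_args = list(),
                           level = 0.95) {
  stopifnot(inherits(spec, "cohort_spec"), n_replicates >= 2)
  seeds <- with_preserved_seed(spec$seed,
                               sample.int(2^31 - 2, n_replicates))
  z <- stats::qnorm(1 - (1 - level) / 2)
  truth <- c(pack_true(spec$params),
             log_sigma_u = log(spec$params$sigma_u))

  est <- se <- matrix(NA_real_, n_replicates, length(truth),
                      dimnames = list(NULL, names(truth)))
  n_failed <- 0L
  n_nonconv <- 0L
  for (r in seq_len(n_replicates)) {
    spec_r <- spec
    spec_r$seed <- seeds[r]
    fit <- tryCatch({
      sim <- simulate_cohort(spec_r)
      pr <- build_pairs(sim, validate = FALSE)
      suppressWarnings(do.call(fit_transitions, c(list(pr), fit_args)))
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    if (!fit$convergence$converged) n_nonconv <- n_nonconv + 1L
    th <- fit$theta
    common <- intersect(names(truth), names(th))
    est[r, common] <- th[common]
    if (!is.null(fit$theta_se)) se[r, common] <- fit$theta_se[common]
  }

  ok <- colSums(!is.na(est)) > 0
  summ <- lapply(names(truth)[ok], function(p) {
    e <- est[, p]
    s <- se[, p]
    use <- !is.na(e)
    cover <- mean((e[use] - z * s[use] <= truth[p]) &
                    (truth[p] <= e[use] + z * s[use]), na.rm = TRUE)
    data.frame(
      parameter = p, true = unname(truth[p]),
      mean_est = mean(e[use]),
      bias = mean(e[use]) - unname(truth[p]),
      mc_se = stats::sd(e[use]) / sqrt(sum(use)),
      rmse = sqrt(mean((e[use] - truth[p])^2)),
      coverage = cover, n_used = sum(use),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, summ)
  rownames(out) <- NULL
  structure(out, class = c("mci_recovery", "data.frame"),
            n_replicates = n_replicates, n_failed = n_failed,
            n_nonconverged = n_nonconv, seeds = seeds)
}

## flatten true betas with the theta naming used by fit_transitions
pack_true <- function(params) {
  nmN <- as.vector(outer(rownames(params$beta_normal),
                         colnames(params$beta_normal),
                         function(o, cv) paste("NORMAL", o, cv, sep = ":")))
  nmC <- as.vector(outer(rownames(params$beta_cc),
                         colnames(params$beta_cc),
                         function(o, cv) paste("MCI_CC", o, cv, sep = ":")))
  stats::setNames(c(as.vector(params$beta_normal),
                    as.vector(params$beta_cc)), c(nmN, nmC))
}

#' @export
print.mci_recovery <- function(x, ...) {
  cat("Parameter recovery over", attr(x, "n_replicates"),
      "replicates (", attr(x, "n_failed"), "failed,",
      attr(x, "n_nonconverged"), "non-converged )\n")
  print.data.frame(cbind(x["parameter"],
                         round(x[, -1, drop = FALSE], 4)),
                   row.names = FALSE)
  invisible(x)
}
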