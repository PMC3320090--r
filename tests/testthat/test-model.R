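zero_params <- function(sigma = 0) {
  mci_params(matrix(0, 5, 9), matrix(0, 2, 7), sigma_u = sigma)
}

one_pair <- function(current = "AMCI_TB", base = "NORMAL",
                     subject = "s1", ...) {
  x <- list(age_c = 0, female = 0, famhx = 0, apoe4 = 0, low_educ = 0,
            htn = 0, prior_amci = 0, prior_mmci = 0)
  x <- utils::modifyList(x, list(...))
  data.frame(subject = subject, base = base,
             prior_state = if (base == "NORMAL") "NORMAL" else "MCI_CC",
             current_state = current, as.data.frame(x),
             stringsAsFactors = FALSE)
}

test_that("linear predictors follow the additive log-odds structure", {
  p <- zero_params()
  eta <- linear_predictors(c(age_c = 0), "NORMAL", p)
  expect_equal(unname(eta), rep(0, 6))
  expect_identical(names(eta)[1], "NORMAL")

  ## one year of age multiplies the odds of clinical MCI by 1.12
  p2 <- zero_params()
  p2$beta_normal["MCI_CC", "age_c"] <- log(1.12)
  eta2 <- linear_predictors(c(age_c = 1), "NORMAL", p2)
  expect_equal(unname(eta2["MCI_CC"]), log(1.12))
  expect_equal(unname(eta2["AMCI_TB"]), 0)

  ## the shared effect shifts every non-reference logit equally
  eta3 <- linear_predictors(c(age_c = 1), "NORMAL", p2, u = 0.7)
  expect_equal(unname(eta3[-1] - eta2[-1]), rep(0.7, 5))
  expect_equal(unname(eta3[1]), 0)

  ## MCI_CC base drops the prior-state indicators
  eta4 <- linear_predictors(c(age_c = 0), "MCI_CC", p)
  expect_identical(names(eta4), c("MCI_CC", "DEMENTIA", "DEATH"))
  expect_error(linear_predictors(c(prior_amci = 1), "MCI_CC", p),
               "unknown covariate")
})

test_that("transition probabilities are a softmax with structural zeros", {
  p <- zero_params()
  pr <- transition_probs(c(age_c = 0), "NORMAL", p)
  expect_equal(unname(pr), rep(1 / 6, 6))

  ## hand-computed softmax: logits (0, 0, ln 2) for (base, DEM, DEATH)
  p2 <- zero_params()
  p2$beta_cc["DEATH", "(Intercept)"] <- log(2)
  pr2 <- transition_probs(c(age_c = 0), "MCI_CC", p2)
  oracle <- c(1, 1, 2) / sum(c(1, 1, 2))
  expect_equal(unname(pr2[c("MCI_CC", "DEMENTIA", "DEATH")]), oracle)
  ## transient states unreachable from the quasi-absorbing base
  expect_equal(unname(pr2[transient_states()]), rep(0, 3))

  ## shift invariance: adding a constant to every logit changes nothing
  p3 <- zero_params()
  p3$beta_normal[, "(Intercept)"] <- 1:5
  pr3 <- transition_probs(c(age_c = 0), "NORMAL", p3, u = 0)
  pr3_shift <- transition_probs(c(age_c = 0), "NORMAL", p3, u = 500)
  ## u shifts non-reference logits only, so compare against direct softmax
  eta <- c(0, 1:5)
  expect_equal(unname(pr3), exp(eta) / sum(exp(eta)))
  expect_equal(sum(pr3_shift), 1, tolerance = 1e-12)

  ## probability conservation over random parameter draws
  set.seed(3)
  for (i in 1:20) {
    pp <- mci_params(matrix(rnorm(45, 0, 2), 5, 9),
                     matrix(rnorm(14, 0, 2), 2, 7))
    x <- c(age_c = rnorm(1, 0, 5), female = rbinom(1, 1, 0.5))
    expect_equal(sum(transition_probs(x, "NORMAL", pp, u = rnorm(1))), 1,
                 tolerance = 1e-12)
    expect_equal(sum(transition_probs(x, "MCI_CC", pp, u = rnorm(1))), 1,
                 tolerance = 1e-12)
  }
})

test_that("subject log-likelihood factorises over pairs (Markov property)", {
  p <- zero_params()
  expect_equal(subject_loglik(one_pair(), p), log(1 / 6))
  two <- rbind(one_pair("AMCI_TB"), one_pair("DEATH"))
  expect_equal(subject_loglik(two, p),
               subject_loglik(two[1, ], p) + subject_loglik(two[2, ], p))

  ## 10-pair trajectory against an explicit product of pair probabilities
  set.seed(5)
  pp <- mci_params(matrix(rnorm(45, 0, 0.5), 5, 9),
                   matrix(rnorm(14, 0, 0.5), 2, 7))
  pairs <- do.call(rbind, lapply(1:10, function(i) {
    one_pair(sample(c("NORMAL", "AMCI_TB", "MMCI_TB"), 1),
             age_c = rnorm(1, 0, 4), female = rbinom(1, 1, 0.5),
             prior_amci = as.integer(i %% 3 == 0))
  }))
  u <- 0.4
  oracle <- sum(vapply(seq_len(10), function(i) {
    x <- unlist(pairs[i, c("age_c", "female", "famhx", "apoe4", "low_educ",
                           "htn", "prior_amci", "prior_mmci")])
    log(transition_probs(x, "NORMAL", pp, u)[[pairs$current_state[i]]])
  }, numeric(1)))
  expect_equal(subject_loglik(pairs, pp, u), oracle, tolerance = 1e-12)

  ## structurally impossible pair errors
  expect_error(subject_loglik(one_pair("NORMAL", base = "MCI_CC"), p),
               "structurally impossible")
  expect_error(subject_loglik(rbind(one_pair(subject = "a"),
                                    one_pair(subject = "b")), p),
               "single subject")
})

test_that("sigma = 0 collapses the marginal to the fixed-effects likelihood", {
  pairs <- sim_pairs(40, 13, default_true_params(sigma_u = 0))
  p <- default_true_params(sigma_u = 0)
  ref <- sum(vapply(unique(pairs$subject), function(id) {
    subject_loglik(pairs[pairs$subject == id, ], p, u = 0)
  }, numeric(1)))
  for (rule in list(quad_rule(1, TRUE), quad_rule(7, TRUE),
                    quad_rule(15, FALSE))) {
    expect_equal(marginal_loglik(pairs, p, rule), ref, tolerance = 1e-12)
  }
})

test_that("quadrature matches dense numerical integration on a toy set", {
  sp <- cohort_spec(n_subjects = 3, seed = 77)
  pairs <- build_pairs(simulate_cohort(sp))
  p <- default_true_params(sigma_u = 0.7)

  ## oracle: per-subject trapezoid integration on a dense grid
  ids <- unique(pairs$subject)
  ug <- seq(-8 * 0.7, 8 * 0.7, length.out = 10000)
  dense <- sum(vapply(ids, function(id) {
    one <- pairs[pairs$subject == id, ]
    lg <- vapply(ug, function(uu) subject_loglik(one, p, uu), numeric(1)) +
      dnorm(ug, 0, 0.7, log = TRUE)
    m <- max(lg)
    m + log(pracma::trapz(ug, exp(lg - m)))
  }, numeric(1)))

  expect_equal(marginal_loglik(pairs, p, quad_rule(20, adaptive = FALSE)),
               dense, tolerance = 1e-6)
  expect_equal(marginal_loglik(pairs, p, quad_rule(20, adaptive = TRUE)),
               dense, tolerance = 1e-6)

  ## the rule converges in the number of points (Cauchy by Q = 30)
  lls <- vapply(c(2, 5, 10, 20, 30), function(Q) {
    marginal_loglik(pairs, p, quad_rule(Q, adaptive = FALSE))
  }, numeric(1))
  deltas <- abs(diff(lls))
  expect_lt(deltas[length(deltas)], 1e-6)
})

test_that("the one-point adaptive rule is a close Laplace approximation", {
  pairs <- sim_pairs(200, 8)
  p <- default_true_params(sigma_u = 0.5)
  l1 <- marginal_loglik(pairs, p, quad_rule(1, TRUE))
  l20 <- marginal_loglik(pairs, p, quad_rule(20, TRUE))
  expect_lt(abs(l1 - l20) / abs(l20), 0.005)
})

test_that("analytic gradients agree with finite differences", {
  pairs <- sim_pairs(50, 11)
  dat <- mcimarkov:::make_ml_data(pairs)
  p <- default_true_params()
  th <- c(as.vector(p$beta_normal), as.vector(p$beta_cc), log(0.5))

  f_lap <- function(t) {
    q <- mcimarkov:::unpack_theta(t, dat, TRUE)
    mcimarkov:::ml_value(dat, q$BN, q$BC, q$sigma, quad_rule(1, TRUE))
  }
  q <- mcimarkov:::unpack_theta(th, dat, TRUE)
  expect_equal(mcimarkov:::laplace_grad(dat, q$BN, q$BC, q$sigma),
               num_grad(f_lap, th), tolerance = 1e-5)

  thf <- th[-length(th)]
  f_fe <- function(t) {
    q <- mcimarkov:::unpack_theta(t, dat, FALSE)
    sum(mcimarkov:::cond_loglik(dat, q$BN, q$BC, numeric(dat$S))$cl)
  }
  expect_equal(mcimarkov:::fe_grad(dat, q$BN, q$BC),
               num_grad(f_fe, thf), tolerance = 1e-5)

  rule <- quad_rule(9, adaptive = FALSE)
  f_gh <- function(t) {
    q <- mcimarkov:::unpack_theta(t, dat, TRUE)
    mcimarkov:::ml_value(dat, q$BN, q$BC, q$sigma, rule)
  }
  expect_equal(mcimarkov:::quad_grad(dat, q$BN, q$BC, q$sigma, rule),
               num_grad(f_gh, th), tolerance = 1e-5)
})

test_that("intercept-only fits hit the closed-form log-odds of frequencies", {
  freqN <- c(NORMAL = 30, AMCI_TB = 10, MMCI_TB = 8, MCI_CC = 5,
             DEMENTIA = 3, DEATH = 6)
  freqC <- c(MCI_CC = 12, DEMENTIA = 4, DEATH = 2)
  pairs <- rbind(
    do.call(rbind, lapply(names(freqN), function(s) {
      do.call(rbind, replicate(freqN[[s]], one_pair(s), simplify = FALSE))
    })),
    do.call(rbind, lapply(names(freqC), function(s) {
      do.call(rbind, replicate(freqC[[s]], one_pair(s, base = "MCI_CC"),
                               simplify = FALSE))
    }))
  )
  pairs$subject <- paste0("s", seq_len(nrow(pairs)))  # independent pairs
  fit <- fit_transitions(pairs, random_effect = FALSE,
                         covariates = character(0))
  expect_equal(unname(fit$params$beta_normal[, "(Intercept)"]),
               unname(log(freqN[-1] / freqN[["NORMAL"]])), tolerance = 1e-6)
  expect_equal(unname(fit$params$beta_cc[, "(Intercept)"]),
               unname(log(freqC[-1] / freqC[["MCI_CC"]])), tolerance = 1e-6)
  expect_true(fit$convergence$converged)
})

test_that("categories with no observed transitions are refused by name", {
  pairs <- rbind(one_pair("NORMAL"), one_pair("AMCI_TB"),
                 one_pair("MMCI_TB"), one_pair("MCI_CC"),
                 one_pair("DEMENTIA"))
  expect_error(fit_transitions(pairs, random_effect = FALSE), "DEATH")
})

test_that("covariate effects are additive across prior transient states", {
  ## the log odds-ratio for any covariate is identical whether the prior
  ## state is normal, amnestic or mixed MCI: one coefficient per covariate
  p <- default_true_params()
  for (prior in c("NORMAL", "AMCI_TB", "MMCI_TB")) {
    x0 <- build_covariates(80, 0, 0, 0, 0, 0, prior_state = prior)
    x1 <- build_covariates(80, 0, 0, 1, 0, 0, prior_state = prior)  # APOE-4
    pr0 <- transition_probs(x0, "NORMAL", p)
    pr1 <- transition_probs(x1, "NORMAL", p)
    or <- (pr1["MCI_CC"] / pr1["NORMAL"]) / (pr0["MCI_CC"] / pr0["NORMAL"])
    expect_equal(unname(or), 1.89, tolerance = 1e-12)
  }
})

test_that("covariate codings follow the reference definitions", {
  x <- build_covariates(age = 78, female = 1, famhx = 0, apoe4 = 1,
                        htn = 0, education_years = 12,
                        prior_state = "NORMAL")
  expect_equal(x[["age_c"]], 0)
  expect_equal(x[["low_educ"]], 1)
  expect_equal(x[["prior_amci"]], 0)
  expect_equal(x[["prior_mmci"]], 0)
  x2 <- build_covariates(age = 83, female = 0, famhx = 1, apoe4 = 0,
                         htn = 1, education_years = 16,
                         prior_state = "MMCI_TB")
  expect_equal(x2[["age_c"]], 5)
  expect_equal(x2[["low_educ"]], 0)
  expect_equal(x2[["prior_mmci"]], 1)
  expect_error(build_covariates(78, 2, 0, 0, 0, 0), "0/1")
})

test_that("relative risks exponentiate coefficients with Wald intervals", {
  ## closed form: beta 0, SE 0.1 -> RR 1, CI exp(+/- 1.959964 * 0.1)
  se_bn <- matrix(NA_real_, 5, 9)
  se_bn[1, 2] <- 0.1
  fake <- structure(list(
    params = zero_params(),
    se = list(beta_normal = se_bn, beta_cc = matrix(NA_real_, 2, 7),
              sigma_u = NA_real_),
    covariates = list(normal = mcimarkov:::ml_covs_normal(),
                      cc = mcimarkov:::ml_covs_cc())
  ), class = "mci_fit")
  dimnames(fake$se$beta_normal) <- dimnames(fake$params$beta_normal)
  dimnames(fake$se$beta_cc) <- dimnames(fake$params$beta_cc)
  rr <- relative_risks(fake)
  row <- rr[rr$outcome == "AMCI_TB" & rr$term == "age_c", ]
  expect_equal(row$rr, 1)
  expect_equal(row$lower, exp(-qnorm(0.975) * 0.1), tolerance = 1e-12)
  expect_equal(row$upper, exp(qnorm(0.975) * 0.1), tolerance = 1e-12)
  expect_false(row$significant)

  ## monotone transform: the interval brackets the point estimate
  fake$params$beta_normal["MCI_CC", "age_c"] <- log(1.12)
  se_bn[3, 2] <- 0.013
  fake$se$beta_normal["MCI_CC", "age_c"] <- 0.013
  rr2 <- relative_risks(fake)
  row2 <- rr2[rr2$outcome == "MCI_CC" & rr2$term == "age_c", ]
  expect_equal(row2$rr, 1.12)
  expect_true(row2$lower < 1.12 && 1.12 < row2$upper)
  expect_true(row2$significant)

  ## base-NORMAL block has 8 covariate rows for each MCI outcome column
  block <- rr[rr$base == "NORMAL" &
                rr$outcome %in% c("AMCI_TB", "MMCI_TB", "MCI_CC"), ]
  expect_identical(nrow(block), 24L)
  expect_identical(unique(table(block$outcome)), 8L)
})
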