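#' Model parameters for the shared-random-effect transition model
#'
#' Bundles the regression coefficients of the two polytomous logistic
#' blocks and the SD of the shared subject effect.  Under the normal base
#' state the five modelled outcome categories (`AMCI_TB`, `MMCI_TB`,
#' `MCI_CC`, `DEMENTIA`, `DEATH`) each carry an intercept and eight
#' covariate coefficients; under the `MCI_CC` base state the two modelled
#' categories (`DEMENTIA`, `DEATH`) carry an intercept and six (the
#' prior-state indicators are undefined once the base is `MCI_CC`).  The
#' base category of each block has all-zero coefficients by construction.
#'
#' @param beta_normal 5 x 9 numeric matrix, rows `AMCI_TB`, `MMCI_TB`,
#'   `MCI_CC`, `DEMENTIA`, `DEATH`; columns `(Intercept)`, `age_c`,
#'   `female`, `famhx`, `apoe4`, `low_educ`, `htn`, `prior_amci`,
#'   `prior_mmci`.  `-Inf` entries are allowed (a forbidden transition);
#'   `+Inf` is rejected.
#' @param beta_cc 2 x 7 numeric matrix, rows `DEMENTIA`, `DEATH`; columns
#'   as above without the prior-state indicators.
#' @param sigma_u Non-negative SD of the shared subject random effect.
#' @return Object of class `mci_params`.
#' @export
mci_params <- function(beta_normal, beta_cc, sigma_u = 0) {
  cn <- c("(Intercept)", ml_covs_normal())
  cc <- c("(Intercept)", ml_covs_cc())
  beta_normal <- as.matrix(beta_normal)
  beta_cc <- as.matrix(beta_cc)
  stopifnot(nrow(beta_normal) == 5, ncol(beta_normal) == 9,
            nrow(beta_cc) == 2, ncol(beta_cc) == 7,
            length(sigma_u) == 1, sigma_u >= 0)
  dimnames(beta_normal) <- list(ml_outcomes_normal(), cn)
  dimnames(beta_cc) <- list(ml_outcomes_cc(), cc)
  if (any(beta_normal == Inf) || any(beta_cc == Inf)) {
    stop("+Inf coefficients imply certain immediate absorption; not allowed",
         call. = FALSE)
  }
  structure(list(beta_normal = beta_normal, beta_cc = beta_cc,
                 sigma_u = as.numeric(sigma_u)),
            class = "mci_params")
}

#' @export
print.mci_params <- function(x, digits = 3, ...) {
  cat("Transition-model parameters\n\nBase state NORMAL (log-odds):\n")
  print(round(x$beta_normal, digits))
  cat("\nBase state MCI_CC (log-odds):\n")
  print(round(x$beta_cc, digits))
  cat("\nShared random-effect SD (sigma_u):", format(x$sigma_u), "\n")
  invisible(x)
}

#' Gauss-Hermite quadrature rule for the random-effect integral
#'
#' The marginal likelihood integrates the shared subject effect against
#' its normal density.  `adaptive = TRUE` recentres and rescales the nodes
#' at each subject's posterior mode; with a single point this is the
#' Laplace approximation, the package default.
#'
#' @param points Number of quadrature points (>= 1).
#' @param adaptive Recenter/rescale per subject?
#' @return Object of class `quad_rule` with nodes `x` and weights `w`.
#' @export
quad_rule <- function(points = 1L, adaptive = TRUE) {
  points <- as.integer(points)
  stopifnot(points >= 1L)
  if (points == 1L) {
    x <- 0
    w <- sqrt(pi)
  } else {
    gh <- pracma::gaussHermite(points)
    x <- gh$x
    w <- gh$w
  }
  structure(list(points = points, adaptive = isTRUE(adaptive), x = x, w = w),
            class = "quad_rule")
}

#' Build the covariate vector for one transition pair
#'
#' Applies the model's covariate codings: age at the prior assessment
#' centred at 78 years; indicators for female sex, family history of
#' dementia, any APOE-4 allele, at most 12 years of education, and
#' baseline hypertension; and, under the normal base state only,
#' indicators for a prior state of `AMCI_TB` or `MMCI_TB` (normal
#' cognition is the reference).
#'
#' @param age Age in years at the prior visit.
#' @param female,famhx,apoe4,low_educ,htn 0/1 indicators.
#' @param prior_state State at the prior visit.
#' @param base Base state of the pair (`"NORMAL"` or `"MCI_CC"`).
#' @param age_center Centering age (default 78).
#' @param education_years Optional years of education; when given,
#'   `low_educ` is derived as `education_years <= 12`.
#' @return Named numeric covariate vector (without intercept); 8 elements
#'   for the normal base state, 6 for `MCI_CC`.
#' @export
#' @examples
#' build_covariates(age = 78, female = 1, famhx = 0, apoe4 = 1,
#'                  low_educ = 0, htn = 0, prior_state = "AMCI_TB")
build_covariates <- function(age, female, famhx, apoe4, low_educ, htn,
                             prior_state = "NORMAL", base = "NORMAL",
                             age_center = 78, education_years = NULL) {
  stopifnot(base %in% c("NORMAL", "MCI_CC"))
  if (!is.null(education_years)) {
    if (!missing(low_educ)) {
      stop("give either low_educ or education_years, not both", call. = FALSE)
    }
    low_educ <- as.numeric(education_years <= 12)
  }
  prior_state <- as_state(prior_state)
  ind <- c(female, famhx, apoe4, low_educ, htn)
  if (!all(ind %in% c(0, 1))) {
    stop("indicator covariates must be coded 0/1", call. = FALSE)
  }
  x <- c(age_c = age - age_center, female = female, famhx = famhx,
         apoe4 = apoe4, low_educ = low_educ, htn = htn)
  if (base == "NORMAL") {
    x <- c(x, prior_amci = as.numeric(prior_state == "AMCI_TB"),
           prior_mmci = as.numeric(prior_state == "MMCI_TB"))
  }
  x
}

## internal: full-length covariate row from a possibly shorter named vector
expand_x <- function(x, covs) {
  out <- numeric(length(covs))
  names(out) <- covs
  known <- intersect(names(x), covs)
  bad <- setdiff(names(x), covs)
  if (length(bad)) {
    stop("unknown covariate(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out[known] <- x[known]
  out
}

#' Linear predictors (logits) for one transition
#'
#' Returns the log-odds of each outcome category versus the base state:
#' zero for the base category, and `intercept + x'beta + u` for every
#' modelled category, where `u` is the shared subject effect.
#'
#' @param x Named covariate vector as from [build_covariates()].
#' @param base Base state (`"NORMAL"` or `"MCI_CC"`).
#' @param params [mci_params()] object.
#' @param u Subject random effect (default 0).
#' @return Named numeric vector of logits over the block's categories,
#'   base first.
#' @export
linear_predictors <- function(x, base, params, u = 0) {
  stopifnot(inherits(params, "mci_params"), base %in% c("NORMAL", "MCI_CC"))
  if (base == "NORMAL") {
    B <- params$beta_normal
    covs <- ml_covs_normal()
    ref <- "NORMAL"
  } else {
    B <- params$beta_cc
    covs <- ml_covs_cc()
    ref <- "MCI_CC"
  }
  xv <- expand_x(x, covs)
  eta <- as.vector(B %*% c(1, xv)) + u
  names(eta) <- rownames(B)
  c(stats::setNames(0, ref), eta)
}

#' Transition probabilities for one pair
#'
#' Multinomial-logit (softmax) transform of [linear_predictors()].  The
#' probabilities are returned over all six states; categories that are
#' structurally excluded under the given base state (transient states from
#' `MCI_CC`) have probability 0.
#'
#' @inheritParams linear_predictors
#' @return Named probability vector over [mci_states()], summing to 1.
#' @export
transition_probs <- function(x, base, params, u = 0) {
  eta <- linear_predictors(x, base, params, u)
  m <- max(eta)
  p <- exp(eta - m)
  p <- p / sum(p)
  out <- stats::setNames(numeric(6), mci_states())
  out[names(p)] <- p
  out
}

#' Conditional log-likelihood of one subject's transition pairs
#'
#' Sum over the subject's pairs of the log transition probability of the
#' observed current state, conditional on the subject effect `u`.  The
#' Markov property makes this a simple sum: each pair depends only on its
#' prior state.
#'
#' @param pairs Transition pairs of a single subject (see [build_pairs()]).
#' @param params [mci_params()] object.
#' @param u Subject random effect.
#' @return Scalar log-likelihood (can be `-Inf` if a forbidden transition
#'   has been given probability zero).
#' @export
subject_loglik <- function(pairs, params, u = 0) {
  stopifnot(inherits(params, "mci_params"))
  if (length(unique(pairs$subject)) > 1L) {
    stop("subject_loglik expects the pairs of a single subject", call. = FALSE)
  }
  dat <- make_ml_data(pairs)
  sum(cond_loglik(dat, params$beta_normal, params$beta_cc,
                  rep(u, dat$S))$cl)
}

#' Marginal log-likelihood over the shared random effect
#'
#' For each subject the conditional likelihood is integrated against the
#' normal density of the shared effect, `N(0, sigma_u^2)`, using the given
#' quadrature rule; subjects' contributions are summed.  With
#' `sigma_u = 0` the integral collapses to the fixed-effects likelihood
#' for any rule.
#'
#' @param pairs Transition pairs (all subjects).
#' @param params [mci_params()] object.
#' @param rule [quad_rule()]; default 1-point adaptive (Laplace).
#' @return Scalar marginal log-likelihood.
#' @export
marginal_loglik <- function(pairs, params, rule = quad_rule(1, TRUE)) {
  stopifnot(inherits(params, "mci_params"), inherits(rule, "quad_rule"))
  dat <- make_ml_data(pairs)
  val <- ml_value(dat, params$beta_normal, params$beta_cc,
                  params$sigma_u, rule)
  if (!is.finite(val)) {
    bad <- find_nonfinite_subject(dat, params, rule)
    stop("non-finite likelihood contribution (subject ", bad, ")",
         call. = FALSE)
  }
  val
}

find_nonfinite_subject <- function(dat, params, rule) {
  cl <- cond_loglik(dat, params$beta_normal, params$beta_cc,
                    numeric(dat$S))$cl
  i <- which(!is.finite(cl))
  if (length(i)) dat$subjects[i[1L]] else "<unknown>"
}

## ---- fitting ---------------------------------------------------------

pack_theta <- function(BN, BC, log_sigma = NULL) {
  c(as.vector(BN), as.vector(BC), log_sigma)
}

unpack_theta <- function(theta, dat, random_effect) {
  pN <- ncol(dat$XN)
  pC <- ncol(dat$XC)
  nN <- dat$KN * pN
  nC <- dat$KC * pC
  BN <- matrix(theta[seq_len(nN)], dat$KN, pN,
               dimnames = list(ml_outcomes_normal(), colnames(dat$XN)))
  BC <- matrix(theta[nN + seq_len(nC)], dat$KC, pC,
               dimnames = list(ml_outcomes_cc(), colnames(dat$XC)))
  list(BN = BN, BC = BC,
       sigma = if (random_effect) exp(theta[nN + nC + 1L]) else 0)
}

theta_names <- function(dat, random_effect) {
  nm <- c(
    as.vector(outer(ml_outcomes_normal(), colnames(dat$XN),
                    function(o, cv) paste("NORMAL", o, cv, sep = ":"))),
    as.vector(outer(ml_outcomes_cc(), colnames(dat$XC),
                    function(o, cv) paste("MCI_CC", o, cv, sep = ":")))
  )
  if (random_effect) nm <- c(nm, "log_sigma_u")
  nm
}

## run a block of code with the global RNG stream preserved
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Fit the shared-random-effect polytomous transition model
#'
#' Maximum-likelihood estimation of the two-block polytomous logistic
#' Markov model by quasi-Newton (BFGS) ascent.  The marginal likelihood
#' over the shared subject effect is computed with the configured
#' quadrature rule (default: adaptive with one point, i.e. the Laplace
#' approximation).  `sigma_u` is estimated on the log scale to enforce
#' positivity; analytic gradients are used for the fixed-effects,
#' Laplace and non-adaptive rules.  Standard errors come from the inverse
#' of the numerically differenced observed information at the optimum.
#'
#' The additive structure of the model means a single normal-base block
#' with prior-state indicator covariates subsumes the three transient
#' prior states, and one joint likelihood (required for a shared random
#' effect) covers both base states.
#'
#' @param pairs Transition pairs from [build_pairs()] (or compatible data
#'   frame).
#' @param random_effect Estimate the shared subject effect?  `FALSE` fits
#'   the fixed-effects model (`sigma_u = 0`).
#' @param quadrature [quad_rule()] used when `random_effect = TRUE`.
#' @param covariates Character vector of covariates to include (default:
#'   the full set; `character(0)` fits an intercept-only model).
#' @param start Optional start values (an `mci_params` object).  By
#'   default a fixed-effects prefit provides the coefficient start.
#' @param start_sigma Starting value for `sigma_u` (default 0.5).
#' @param n_starts Number of optimizer starts; starts beyond the first are
#'   jittered with deterministic seeds and the best optimum is kept.
#' @param jitter_sd SD of the start jitter.
#' @param control Passed to [stats::optim()] (defaults: `maxit = 500`,
#'   `reltol = 1e-10`).
#' @param hessian Compute the observed information (needed for standard
#'   errors)?
#' @param separation_threshold Absolute coefficient size above which a
#'   separation warning is issued.
#' @return Object of class `mci_fit`: estimates (`params`), standard
#'   errors (`se`), covariance matrix, log-likelihood, convergence
#'   metadata, and data summaries.
#' @export
fit_transitions <- function(pairs, random_effect = TRUE,
                            quadrature = quad_rule(1, TRUE),
                            covariates = ml_covs_normal(),
                            start = NULL, start_sigma = 0.5,
                            n_starts = 1L, jitter_sd = 0.2,
                            control = list(), hessian = TRUE,
                            grad_tol = 1e-6,
                            separation_threshold = 10) {
  dat <- make_ml_data(pairs, covariates)
  check_estimable(dat)
  control <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)

  nll_fe <- function(theta) {
    p <- unpack_theta(theta, dat, FALSE)
    -sum(cond_loglik(dat, p$BN, p$BC, numeric(dat$S))$cl)
  }
  gr_fe <- function(theta) {
    p <- unpack_theta(theta, dat, FALSE)
    -fe_grad(dat, p$BN, p$BC)
  }

  n_fe <- dat$KN * ncol(dat$XN) + dat$KC * ncol(dat$XC)
  theta_fe0 <- if (!is.null(start)) {
    pack_start(start, dat)
  } else {
    numeric(n_fe)
  }
  fe <- stats::optim(theta_fe0, nll_fe, gr_fe, method = "BFGS",
                     control = control)
  fe <- newton_polish(fe, nll_fe, gr_fe, grad_tol)

  if (!random_effect) {
    return(finish_fit(fe, dat, pairs, random_effect = FALSE,
                      quadrature = NULL, nll = nll_fe, gr = gr_fe,
                      hessian = hessian, grad_tol = grad_tol,
                      separation_threshold = separation_threshold))
  }

  nll <- function(theta) {
    p <- unpack_theta(theta, dat, TRUE)
    v <- ml_value(dat, p$BN, p$BC, p$sigma, quadrature)
    if (!is.finite(v)) return(1e10)
    -v
  }
  gr <- if (quadrature$adaptive && quadrature$points == 1L) {
    function(theta) {
      p <- unpack_theta(theta, dat, TRUE)
      -laplace_grad(dat, p$BN, p$BC, p$sigma)
    }
  } else {
    function(theta) {
      p <- unpack_theta(theta, dat, TRUE)
      -quad_grad(dat, p$BN, p$BC, p$sigma, quadrature)
    }
  }

  theta0 <- c(fe$par, log(start_sigma))
  best <- NULL
  for (k in seq_len(max(1L, n_starts))) {
    th <- if (k == 1L) {
      theta0
    } else {
      with_preserved_seed(1000L + k, theta0 + stats::rnorm(length(theta0),
                                                           0, jitter_sd))
    }
    opt <- stats::optim(th, nll, gr, method = "BFGS", control = control)
    opt <- newton_polish(opt, nll, gr, grad_tol)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  finish_fit(best, dat, pairs, random_effect = TRUE,
             quadrature = quadrature, nll = nll, gr = gr, hessian = hessian,
             grad_tol = grad_tol,
             separation_threshold = separation_threshold)
}

check_estimable <- function(dat) {
  missN <- setdiff(seq_len(dat$KN), unique(dat$yN[dat$yN > 0L]))
  if (length(missN)) {
    stop("no observed transitions into category: ",
         paste(ml_outcomes_normal()[missN], collapse = ", "),
         " (base NORMAL); coefficients are inestimable", call. = FALSE)
  }
  if (length(dat$yC)) {
    missC <- setdiff(seq_len(dat$KC), unique(dat$yC[dat$yC > 0L]))
    if (length(missC)) {
      stop("no observed transitions into category: ",
           paste(ml_outcomes_cc()[missC], collapse = ", "),
           " (base MCI_CC); coefficients are inestimable", call. = FALSE)
    }
  }
  invisible(TRUE)
}

pack_start <- function(start, dat) {
  stopifnot(inherits(start, "mci_params"))
  BN <- start$beta_normal[, colnames(dat$XN), drop = FALSE]
  BC <- start$beta_cc[, colnames(dat$XC), drop = FALSE]
  pack_theta(BN, BC)
}

## Newton refinement of a quasi-Newton optimum: near the maximum the
## BFGS line search can stall on a flat plateau; a few damped Newton steps
## using the numerically differenced Hessian of the analytic gradient
## drive the gradient norm down to tolerance.
newton_polish <- function(opt, nll, gr, grad_tol, max_steps = 3L) {
  g <- gr(opt$par)
  tol <- grad_tol * (1 + abs(opt$value))
  for (k in seq_len(max_steps)) {
    if (max(abs(g)) <= tol) break
    H <- stats::optimHess(opt$par, nll, gr)
    dir <- tryCatch(solve((H + t(H)) / 2, g), error = function(e) NULL)
    if (is.null(dir) || any(!is.finite(dir))) break
    improved <- FALSE
    for (step in 2^-(0:6)) {
      cand <- opt$par - step * dir
      v <- nll(cand)
      if (!is.finite(v)) next
      gc_ <- gr(cand)
      if (v <= opt$value + 1e-8 * (1 + abs(opt$value)) &&
          max(abs(gc_)) < max(abs(g))) {
        opt$par <- cand
        opt$value <- v
        g <- gc_
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  opt
}

finish_fit <- function(opt, dat, pairs, random_effect, quadrature, nll, gr,
                       hessian, grad_tol, separation_threshold) {
  p <- unpack_theta(opt$par, dat, random_effect)
  nm <- theta_names(dat, random_effect)
  grad <- gr(opt$par)
  grad_norm <- max(abs(grad))
  ## gradient-norm criterion, scaled by the log-likelihood magnitude
  converged <- opt$convergence == 0L &&
    grad_norm <= grad_tol * (1 + abs(opt$value))

  vcov <- se_theta <- NULL
  if (hessian) {
    Hn <- stats::optimHess(opt$par, nll, gr)
    Hn <- (Hn + t(Hn)) / 2
    vcov <- tryCatch(solve(Hn), error = function(e) NULL)
    if (is.null(vcov) || any(!is.finite(vcov)) || any(diag(vcov) < 0)) {
      warning("observed information is singular or not positive definite; ",
              "standard errors use a pseudo-inverse", call. = FALSE)
      sv <- svd(Hn)
      pos <- sv$d > max(sv$d) * 1e-10
      vcov <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
      vcov <- (vcov + t(vcov)) / 2
      diag(vcov)[diag(vcov) < 0] <- NA_real_
    }
    dimnames(vcov) <- list(nm, nm)
    se_theta <- sqrt(pmax(diag(vcov), 0))
  }

  ## expand to full parameter shapes (zero for excluded covariates)
  full_bn <- matrix(0, 5, 9, dimnames = list(
    ml_outcomes_normal(), c("(Intercept)", ml_covs_normal())))
  full_bc <- matrix(0, 2, 7, dimnames = list(
    ml_outcomes_cc(), c("(Intercept)", ml_covs_cc())))
  full_bn[, colnames(dat$XN)] <- p$BN
  full_bc[, colnames(dat$XC)] <- p$BC
  params <- mci_params(full_bn, full_bc, sigma_u = p$sigma)

  se <- NULL
  if (!is.null(se_theta)) {
    sp <- unpack_theta(se_theta, dat, random_effect)
    se_bn <- matrix(NA_real_, 5, 9, dimnames = dimnames(full_bn))
    se_bc <- matrix(NA_real_, 2, 7, dimnames = dimnames(full_bc))
    se_bn[, colnames(dat$XN)] <- sp$BN
    se_bc[, colnames(dat$XC)] <- sp$BC
    se <- list(beta_normal = se_bn, beta_cc = se_bc,
               sigma_u = if (random_effect) {
                 p$sigma * se_theta[length(se_theta)]
               } else {
                 NA_real_
               })
  }

  big <- c(abs(p$BN[is.finite(p$BN)]), abs(p$BC[is.finite(p$BC)]))
  if (any(big > separation_threshold)) {
    warning("possible separation: |coefficient| > ", separation_threshold,
            call. = FALSE)
  }
  if (!converged) {
    warning("optimizer did not converge (code ", opt$convergence, ")",
            call. = FALSE)
  }

  structure(list(
    params = params, se = se, vcov = vcov,
    logLik = -opt$value,
    convergence = list(converged = converged, code = opt$convergence,
                       grad_norm = grad_norm, counts = opt$counts,
                       message = opt$message),
    n_pairs = nrow(pairs),
    n_subjects = dat$S,
    random_effect = random_effect,
    quadrature = quadrature,
    covariates = list(normal = dat$covsN, cc = dat$covsC),
    theta = stats::setNames(opt$par, nm),
    theta_se = if (!is.null(se_theta)) stats::setNames(se_theta, nm)
  ), class = "mci_fit")
}

#' @export
print.mci_fit <- function(x, ...) {
  cat("Shared-random-effect polytomous transition model\n")
  cat("  subjects:", x$n_subjects, "  pairs:", x$n_pairs, "\n")
  cat("  log-likelihood:", format(x$logLik), "\n")
  cat("  converged:", x$convergence$converged,
      " (max |gradient| =", format(x$convergence$grad_norm, digits = 3),
      ")\n")
  if (x$random_effect) {
    cat("  sigma_u:", format(x$params$sigma_u, digits = 4))
    if (!is.null(x$se)) cat(" (SE", format(x$se$sigma_u, digits = 3), ")")
    cat("  quadrature:", x$quadrature$points, "point(s),",
        if (x$quadrature$adaptive) "adaptive" else "non-adaptive", "\n")
  } else {
    cat("  fixed-effects model (sigma_u = 0)\n")
  }
  cat("\nRelative risks (base NORMAL):\n")
  rr <- relative_risks(x)
  print(format_rr_block(rr[rr$base == "NORMAL", ]), quote = FALSE)
  if (any(rr$base == "MCI_CC")) {
    cat("\nRelative risks (base MCI_CC):\n")
    print(format_rr_block(rr[rr$base == "MCI_CC", ]), quote = FALSE)
  }
  invisible(x)
}

#' @export
logLik.mci_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$theta), class = "logLik")
}

#' @export
vcov.mci_fit <- function(object, ...) object$vcov

#' @export
coef.mci_fit <- function(object, ...) object$theta

#' Relative risks with Wald confidence intervals
#'
#' Exponentiates the fitted log-odds coefficients into the relative-risk
#' style quantities reported for this model (strictly, odds-ratio-type
#' contrasts from the polytomous logistic link), with symmetric Wald
#' intervals on the log scale: `exp(beta +/- z * SE)`.
#'
#' @param fit An `mci_fit` from [fit_transitions()].
#' @param level Confidence level (default 0.95).
#' @param include_intercept Include intercept rows (default `FALSE`)?
#' @return Data frame with columns `base`, `outcome`, `term`, `beta`,
#'   `se`, `rr`, `lower`, `upper`, `significant` (CI excludes 1).
#' @export
relative_risks <- function(fit, level = 0.95, include_intercept = FALSE) {
  stopifnot(inherits(fit, "mci_fit"), level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  blocks <- list(
    NORMAL = list(b = fit$params$beta_normal, s = fit$se$beta_normal,
                  covs = fit$covariates$normal),
    MCI_CC = list(b = fit$params$beta_cc, s = fit$se$beta_cc,
                  covs = fit$covariates$cc)
  )
  rows <- list()
  for (base in names(blocks)) {
    bl <- blocks[[base]]
    terms <- c(if (include_intercept) "(Intercept)", bl$covs)
    for (o in rownames(bl$b)) {
      for (tm in terms) {
        beta <- bl$b[o, tm]
        se <- if (!is.null(bl$s)) bl$s[o, tm] else NA_real_
        lo <- exp(beta - z * se)
        hi <- exp(beta + z * se)
        rows[[length(rows) + 1L]] <- data.frame(
          base = base, outcome = o, term = tm, beta = beta, se = se,
          rr = exp(beta), lower = lo, upper = hi,
          significant = is.finite(lo) & is.finite(hi) & (lo > 1 | hi < 1),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## wide covariate x outcome layout used by print methods
format_rr_block <- function(rr) {
  terms <- unique(rr$term)
  outs <- unique(rr$outcome)
  m <- matrix("", length(terms), length(outs),
              dimnames = list(terms, outs))
  for (i in seq_len(nrow(rr))) {
    m[rr$term[i], rr$outcome[i]] <- sprintf(
      "%.2f (%.2f-%.2f)%s", rr$rr[i], rr$lower[i], rr$upper[i],
      if (isTRUE(rr$significant[i])) "*" else ""
    )
  }
  m
}

#' Serialize a fit to JSON
#'
#' @param fit An `mci_fit`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "mci_fit"))
  out <- list(
    logLik = fit$logLik,
    converged = fit$convergence$converged,
    grad_norm = fit$convergence$grad_norm,
    n_pairs = fit$n_pairs,
    n_subjects = fit$n_subjects,
    sigma_u = fit$params$sigma_u,
    sigma_u_se = if (!is.null(fit$se)) fit$se$sigma_u,
    beta_normal = fit$params$beta_normal,
    beta_cc = fit$params$beta_cc,
    se_beta_normal = if (!is.null(fit$se)) fit$se$beta_normal,
    se_beta_cc = if (!is.null(fit$se)) fit$se$beta_cc,
    relative_risks = relative_risks(fit)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}
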