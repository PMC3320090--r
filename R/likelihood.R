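## Internal likelihood engine for the shared-random-effect polytomous
## logistic Markov model.
##
## Data layout: transition pairs are split into two blocks by base state.
## Under the normal base state the outcome has six categories (reference
## NORMAL plus five modelled categories); under the MCI_CC base state it
## has three (reference MCI_CC plus dementia and death).  A scalar subject
## effect u enters every non-reference logit of both blocks with loading 1.
## All computations are vectorised over pairs; per-subject reductions use
## rowsum().

ml_outcomes_normal <- function() c("AMCI_TB", "MMCI_TB", "MCI_CC",
                                   "DEMENTIA", "DEATH")
ml_outcomes_cc <- function() c("DEMENTIA", "DEATH")
ml_covs_normal <- function() c("age_c", "female", "famhx", "apoe4",
                               "low_educ", "htn", "prior_amci", "prior_mmci")
ml_covs_cc <- function() ml_covs_normal()[1:6]

## build per-block design matrices and outcome indices
make_ml_data <- function(pairs, covariates = ml_covs_normal()) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0,
            all(c("subject", "base", "current_state") %in% names(pairs)))
  covsN <- intersect(ml_covs_normal(), covariates)
  covsC <- intersect(ml_covs_cc(), covariates)
  missing_cols <- setdiff(covsN, names(pairs))
  if (length(missing_cols)) {
    stop("pairs lack covariate column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  base <- as.character(pairs$base)
  if (!all(base %in% c("NORMAL", "MCI_CC"))) {
    stop("base state must be NORMAL or MCI_CC", call. = FALSE)
  }
  cur <- as_state(pairs$current_state)
  subj <- factor(pairs$subject, levels = unique(pairs$subject))
  isN <- base == "NORMAL"

  design <- function(rows, covs) {
    X <- matrix(1, sum(rows), 1L + length(covs))
    if (length(covs)) {
      X[, -1L] <- as.matrix(
        as.data.frame(lapply(pairs[rows, covs, drop = FALSE], as.numeric))
      )
    }
    colnames(X) <- c("(Intercept)", covs)
    X
  }
  yN <- ifelse(cur[isN] == "NORMAL", 0L,
               match(cur[isN], ml_outcomes_normal()))
  curC <- cur[!isN]
  yC <- ifelse(curC == "MCI_CC", 0L, match(curC, ml_outcomes_cc()))
  if (anyNA(yC)) {
    stop("structurally impossible transition: MCI_CC base to ",
         paste(unique(curC[is.na(yC)]), collapse = ", "), call. = FALSE)
  }
  list(
    XN = design(isN, covsN), yN = as.integer(yN),
    XC = design(!isN, covsC), yC = as.integer(yC),
    sN = as.integer(subj)[isN], sC = as.integer(subj)[!isN],
    S = nlevels(subj), subjects = levels(subj),
    covsN = covsN, covsC = covsC,
    KN = length(ml_outcomes_normal()), KC = length(ml_outcomes_cc())
  )
}

## per-subject sum of a per-pair vector
by_subject <- function(x, idx, S) {
  out <- numeric(S)
  if (length(idx)) {
    t <- rowsum(x, idx)
    out[as.integer(rownames(t))] <- t
  }
  out
}

## multinomial-logit statistics for one block at given per-pair effects u
block_stats <- function(X, B, upair, y) {
  n <- nrow(X)
  K <- nrow(B)
  if (n == 0L) {
    return(list(n = 0L, P = matrix(0, 0, K), s = numeric(0),
                logp = numeric(0), d = numeric(0)))
  }
  eta <- X %*% t(B)
  if (length(upair)) eta <- eta + upair
  m <- rep(0, n)
  for (j in seq_len(K)) m <- pmax(m, eta[, j])
  E <- exp(eta - m)
  E[is.na(E)] <- 0  # -Inf - Inf guards; impossible categories contribute 0
  rs <- rowSums(E)
  denom <- exp(-m) + rs
  logdenom <- m + log(denom)
  P <- E / denom
  s <- rs / denom
  lp <- numeric(n)
  pick <- y > 0L
  if (any(pick)) lp[pick] <- eta[cbind(which(pick), y[pick])]
  list(n = n, P = P, s = s, logp = lp - logdenom, d = as.numeric(pick) - s)
}

## conditional per-subject log-likelihood at subject effects u (length S)
cond_loglik <- function(dat, BN, BC, u) {
  bsN <- block_stats(dat$XN, BN, u[dat$sN], dat$yN)
  bsC <- block_stats(dat$XC, BC, u[dat$sC], dat$yC)
  cl <- by_subject(bsN$logp, dat$sN, dat$S) +
    by_subject(bsC$logp, dat$sC, dat$S)
  list(cl = cl, bsN = bsN, bsC = bsC)
}

## Newton mode-finding for the per-subject posterior of u.  The integrand
## is strictly log-concave in u, so undamped Newton with step clipping
## converges from u = 0.
find_modes <- function(dat, BN, BC, sigma, tol = 1e-10, maxit = 100L) {
  sig2 <- sigma^2
  u <- numeric(dat$S)
  for (it in seq_len(maxit)) {
    cs <- cond_loglik(dat, BN, BC, u)
    gu <- by_subject(cs$bsN$d, dat$sN, dat$S) +
      by_subject(cs$bsC$d, dat$sC, dat$S) - u / sig2
    W <- by_subject(cs$bsN$s * (1 - cs$bsN$s), dat$sN, dat$S) +
      by_subject(cs$bsC$s * (1 - cs$bsC$s), dat$sC, dat$S)
    H <- W + 1 / sig2
    step <- pmin(pmax(gu / H, -4), 4)
    u <- u + step
    if (max(abs(step)) < tol) break
  }
  cs <- cond_loglik(dat, BN, BC, u)
  W <- by_subject(cs$bsN$s * (1 - cs$bsN$s), dat$sN, dat$S) +
    by_subject(cs$bsC$s * (1 - cs$bsC$s), dat$sC, dat$S)
  list(u = u, H = W + 1 / sig2, cs = cs)
}

## marginal log-likelihood given blocks, sigma and a quadrature rule.
## sigma = 0 collapses to the fixed-effects likelihood for any rule.
ml_value <- function(dat, BN, BC, sigma, rule) {
  if (sigma < 1e-12) {
    return(sum(cond_loglik(dat, BN, BC, numeric(dat$S))$cl))
  }
  if (rule$adaptive) {
    md <- find_modes(dat, BN, BC, sigma)
    g <- md$cs$cl + stats::dnorm(md$u, 0, sigma, log = TRUE)
    if (rule$points == 1L) {
      return(sum(g + 0.5 * log(2 * pi) - 0.5 * log(md$H)))
    }
    sig_hat <- 1 / sqrt(md$H)
    L <- matrix(0, dat$S, rule$points)
    for (j in seq_len(rule$points)) {
      uj <- md$u + sqrt(2) * sig_hat * rule$x[j]
      clj <- cond_loglik(dat, BN, BC, uj)$cl
      L[, j] <- log(rule$w[j]) + rule$x[j]^2 + clj +
        stats::dnorm(uj, 0, sigma, log = TRUE)
    }
    M <- apply(L, 1, max)
    sum(log(sqrt(2) * sig_hat) + M + log(rowSums(exp(L - M))))
  } else {
    L <- matrix(0, dat$S, rule$points)
    for (j in seq_len(rule$points)) {
      uj <- rep(sqrt(2) * sigma * rule$x[j], dat$S)
      L[, j] <- log(rule$w[j]) - 0.5 * log(pi) +
        cond_loglik(dat, BN, BC, uj)$cl
    }
    M <- apply(L, 1, max)
    sum(M + log(rowSums(exp(L - M))))
  }
}

## gradient of the fixed-effects (sigma = 0) log-likelihood
fe_grad <- function(dat, BN, BC) {
  cs <- cond_loglik(dat, BN, BC, numeric(dat$S))
  gN <- block_score(dat$XN, dat$yN, cs$bsN, dat$KN)
  gC <- block_score(dat$XC, dat$yC, cs$bsC, dat$KC)
  c(as.vector(gN), as.vector(gC))
}

## K x p score matrix Sum_t x_t (1[y=k] - pi_k), optionally pair-weighted
block_score <- function(X, y, bs, K, wpair = NULL) {
  if (bs$n == 0L) return(matrix(0, K, ncol(X)))
  Y <- matrix(0, bs$n, K)
  pick <- y > 0L
  if (any(pick)) Y[cbind(which(pick), y[pick])] <- 1
  R <- Y - bs$P
  if (!is.null(wpair)) R <- R * wpair
  crossprod(R, X)
}

## exact gradient of the Laplace (1-point adaptive) marginal log-likelihood,
## including the dependence of the per-subject mode and curvature on the
## parameters
laplace_grad <- function(dat, BN, BC, sigma) {
  md <- find_modes(dat, BN, BC, sigma)
  u <- md$u
  H <- md$H
  sig2 <- sigma^2
  bsN <- md$cs$bsN
  bsC <- md$cs$bsC
  Hu <- by_subject((1 - 2 * bsN$s) * bsN$s * (1 - bsN$s), dat$sN, dat$S) +
    by_subject((1 - 2 * bsC$s) * bsC$s * (1 - bsC$s), dat$sC, dat$S)
  a <- 1 / (2 * H)
  b <- Hu / (2 * H^2)

  block_grad <- function(X, y, bs, K, sidx) {
    if (bs$n == 0L) return(matrix(0, K, ncol(X)))
    g1 <- block_score(X, y, bs, K)
    wA <- (1 - 2 * bs$s) * (1 - bs$s) * a[sidx]
    wB <- (1 - bs$s) * b[sidx]
    g1 - crossprod(bs$P * wA, X) + crossprod(bs$P * wB, X)
  }
  gN <- block_grad(dat$XN, dat$yN, bsN, dat$KN, dat$sN)
  gC <- block_grad(dat$XC, dat$yC, bsC, dat$KC, dat$sC)
  gs <- sum(-1 + u^2 / sig2 + 2 * a / sig2 - 2 * b * u / sig2)
  c(as.vector(gN), as.vector(gC), gs)
}

## gradient of the quadrature marginal log-likelihood.  For non-adaptive
## Gauss-Hermite rules this is exact; for adaptive rules with several
## points the per-subject recentring is held fixed, which is accurate
## whenever the rule itself is (the value is then insensitive to small node
## shifts).
quad_grad <- function(dat, BN, BC, sigma, rule) {
  sig2 <- sigma^2
  Q <- rule$points
  if (rule$adaptive) {
    md <- find_modes(dat, BN, BC, sigma)
    sig_hat <- 1 / sqrt(md$H)
    U <- outer(md$u, rep(1, Q)) + sqrt(2) * sig_hat %o% rule$x
  } else {
    U <- matrix(sqrt(2) * sigma * rule$x, dat$S, Q, byrow = TRUE)
  }
  L <- matrix(0, dat$S, Q)
  css <- vector("list", Q)
  for (j in seq_len(Q)) {
    css[[j]] <- cond_loglik(dat, BN, BC, U[, j])
    L[, j] <- log(rule$w[j]) + css[[j]]$cl +
      if (rule$adaptive) {
        rule$x[j]^2 + stats::dnorm(U[, j], 0, sigma, log = TRUE)
      } else {
        -0.5 * log(pi)
      }
  }
  M <- apply(L, 1, max)
  Pn <- exp(L - M)
  Pn <- Pn / rowSums(Pn)  # per-subject posterior node weights
  gN <- matrix(0, dat$KN, ncol(dat$XN))
  gC <- matrix(0, dat$KC, ncol(dat$XC))
  gs <- 0
  for (j in seq_len(Q)) {
    cs <- css[[j]]
    gN <- gN + block_score(dat$XN, dat$yN, cs$bsN, dat$KN,
                           Pn[dat$sN, j])
    gC <- gC + block_score(dat$XC, dat$yC, cs$bsC, dat$KC,
                           Pn[dat$sC, j])
    if (rule$adaptive) {
      gs <- gs + sum(Pn[, j] * (-1 + U[, j]^2 / sig2))
    } else {
      clprime <- by_subject(cs$bsN$d, dat$sN, dat$S) +
        by_subject(cs$bsC$d, dat$sC, dat$S)
      gs <- gs + sum(Pn[, j] * clprime * U[, j])
    }
  }
  c(as.vector(gN), as.vector(gC), gs)
}
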