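# Shared fixtures, all built in code.

## compact battery: two memory tests (one error-count), two nonmemory
small_battery <- function() {
  data.frame(
    test = c("recall", "errors", "fluency", "trails"),
    domain = c("memory", "memory", "nonmemory", "nonmemory"),
    direction = c("higher_better", "higher_worse",
                  "higher_better", "higher_worse"),
    stringsAsFactors = FALSE
  )
}

## exact norms object (no fitting noise): mean 50 (or 10 for error counts),
## flat in age, SD 5 (or 2)
small_norms <- function() {
  b <- small_battery()
  hb <- b$direction == "higher_better"
  tab <- data.frame(
    b,
    intercept = ifelse(hb, 50, 10),
    slope = 0,
    sd = ifelse(hb, 5, 2),
    n = 100L,
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, method = "linear", band_width = NA,
                 bands = list()),
            class = "mci_norms")
}

## a full score panel at the age-adjusted mean
mean_panel <- function(norms = small_norms()) {
  stats::setNames(norms$table$intercept, norms$table$test)
}

## build a trajectory table from a vector of states (one subject)
traj <- function(states, subject = "s1", state_tb = NULL,
                 with_covariates = FALSE) {
  k <- length(states)
  out <- data.frame(
    subject = subject, visit = seq_len(k), time = seq_len(k) - 1,
    age = 70 + seq_len(k) - 1, state = states,
    stringsAsFactors = FALSE
  )
  if (!is.null(state_tb)) out$state_tb <- state_tb
  if (with_covariates) {
    out$female <- 1; out$famhx <- 0; out$apoe4 <- 0
    out$low_educ <- 0; out$htn <- 0
  }
  out
}

## bind several single-subject trajectories
traj_cohort <- function(...) do.call(rbind, list(...))

## the 19-subject back-transition fixture: nine subjects whose reversion is
## followed by another clinical-MCI diagnosis (three of whom later become
## demented), six with an isolated mid-series diagnosis, and four whose
## only diagnosis is at the initial evaluation
back_transition_fixture <- function() {
  N <- "NORMAL"; A <- "AMCI_TB"; M <- "MMCI_TB"; C <- "MCI_CC"
  D <- "DEMENTIA"
  lst <- list()
  ## pattern A: reconversion to MCI_CC after reversion
  for (i in 1:6) {
    lst[[length(lst) + 1L]] <- traj(c(N, C, N, C, C), paste0("A", i),
                                    state_tb = c(N, N, N, N, N))
  }
  ## ... three of whom eventually become demented
  for (i in 7:9) {
    lst[[length(lst) + 1L]] <- traj(c(N, C, M, C, D), paste0("A", i),
                                    state_tb = c(N, N, M, M, NA))
  }
  ## pattern B, mid-series: one isolated diagnosis between normal visits;
  ## test-based classification at that visit varies
  tb_mid <- list(c(N, N, N, N), c(N, N, A, N), c(N, N, M, N),
                 c(N, N, N, N), c(N, N, N, N), c(N, N, A, N))
  for (i in 1:6) {
    lst[[length(lst) + 1L]] <- traj(c(N, N, C, N), paste0("Bm", i),
                                    state_tb = tb_mid[[i]])
  }
  ## pattern B, initial: diagnosis only at the first evaluation
  for (i in 1:4) {
    lst[[length(lst) + 1L]] <- traj(c(C, N, N, N), paste0("Bi", i),
                                    state_tb = c(N, N, N, N))
  }
  do.call(rbind, lst)
}

## age-adjusted mean of a test under flat small_norms()
norm_mean_for <- function(nm, test) {
  nm$table$intercept[match(test, nm$table$test)]
}

## central finite-difference gradient for gradient checks
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

## small simulated pair set, cached per session
sim_pairs <- local({
  cache <- list()
  function(n_subjects, seed, params = default_true_params()) {
    key <- paste(n_subjects, seed, signif(params$sigma_u, 6), sep = "_")
    if (is.null(cache[[key]])) {
      sp <- cohort_spec(n_subjects = n_subjects, seed = seed,
                        params = params)
      cache[[key]] <<- build_pairs(simulate_cohort(sp), validate = FALSE)
    }
    cache[[key]]
  }
})
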