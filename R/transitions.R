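#' Build one-step transition pairs from cleaned trajectories
#'
#' Each temporally adjacent visit couple of a subject contributes one pair
#' (prior state, current state).  The model conditions on a *base state*:
#' normal cognition while the prior state is transient, and `MCI_CC` once
#' the quasi-absorbing clinical diagnosis has occurred.  Absorbing states
#' terminate a subject's contribution, so a subject with `k` visits and no
#' absorbing end contributes `k - 1` pairs.
#'
#' Covariates are taken at the prior visit of the pair: centred age
#' (`age_c = age - 78`) from the prior assessment, the fixed baseline
#' indicators (`female`, `famhx`, `apoe4`, `low_educ`, `htn`), and the
#' prior-state indicators `prior_amci` / `prior_mmci` (defined only under
#' the normal base state, with normal cognition as the reference).  Pairs
#' with missing covariates are dropped complete-case with a logged count.
#'
#' @param visits Cleaned long-format data frame with columns `subject`,
#'   `visit`, `state`, `age`, the baseline indicator columns, and
#'   optionally `time` (years from entry; defaults to the visit index).
#' @param age_center Centering age in years (78, the reference median).
#' @param validate Check the quasi-absorbing invariant first (default
#'   `TRUE`); uncleaned input is an error.
#' @return Data frame of class `mci_pairs`: one row per transition with
#'   columns `subject`, `prior_state`, `current_state`, `base`, `interval`
#'   and the model covariates.  The number of excluded incomplete pairs is
#'   attached as attribute `n_excluded`.
#' @export
build_pairs <- function(visits, age_center = 78, validate = TRUE) {
  stopifnot(is.data.frame(visits),
            all(c("subject", "visit", "state", "age") %in% names(visits)))
  covs <- c("female", "famhx", "apoe4", "low_educ", "htn")
  missing_covs <- setdiff(covs, names(visits))
  if (length(missing_covs)) {
    stop("visit table lacks covariate column(s): ",
         paste(missing_covs, collapse = ", "), call. = FALSE)
  }
  if (validate) {
    v <- validate_trajectories(visits)
    if (attr(v, "total") > 0) {
      stop("input trajectories violate invariants (run clean_trajectories ",
           "first):\n", paste(capture_validation(v), collapse = "\n"),
           call. = FALSE)
    }
  }
  visits <- visits[order(visits$subject, visits$visit), , drop = FALSE]
  st <- as_state(visits$state)
  tm <- if ("time" %in% names(visits)) visits$time else visits$visit

  ## adjacent rows of the same subject form the candidate pairs
  n <- nrow(visits)
  prior <- which(visits$subject[-n] == visits$subject[-1L] &
                   !(st[-n] %in% absorbing_states()))
  if (!length(prior)) stop("no transition pairs could be built",
                           call. = FALSE)
  curr <- prior + 1L
  base <- ifelse(st[prior] == "MCI_CC", "MCI_CC", "NORMAL")
  pairs <- data.frame(
    subject = visits$subject[prior],
    prior_state = st[prior],
    current_state = st[curr],
    base = base,
    interval = tm[curr] - tm[prior],
    age_c = visits$age[prior] - age_center,
    female = visits$female[prior],
    famhx = visits$famhx[prior],
    apoe4 = visits$apoe4[prior],
    low_educ = visits$low_educ[prior],
    htn = visits$htn[prior],
    prior_amci = as.integer(base == "NORMAL" & st[prior] == "AMCI_TB"),
    prior_mmci = as.integer(base == "NORMAL" & st[prior] == "MMCI_TB"),
    stringsAsFactors = FALSE
  )
  ## structural check (redundant after validation, cheap insurance)
  bad <- pairs$base == "MCI_CC" &
    !(pairs$current_state %in% c("MCI_CC", "DEMENTIA", "DEATH"))
  if (any(bad)) {
    stop("back-transition from MCI_CC in input; clean trajectories first",
         call. = FALSE)
  }
  complete <- stats::complete.cases(
    pairs[c("age_c", "female", "famhx", "apoe4", "low_educ", "htn")]
  )
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message("build_pairs: excluded ", n_excluded,
            " pair(s) with missing covariates")
  }
  pairs <- pairs[complete, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, class = c("mci_pairs", "data.frame"),
            n_excluded = n_excluded)
}

capture_validation <- function(v) {
  paste0("  ", v$violation, ": ", v$count)
}

#' One-step transition matrix
#'
#' `transition_table()` tabulates transition pairs into the observed
#' one-step transition matrix: four prior-state rows (`NORMAL`, `AMCI_TB`,
#' `MMCI_TB`, `MCI_CC`) by six current-state columns, with row percentages
#' reported to one decimal (half-up rounding, matching published
#' formatting).  Cells that are structurally impossible — transient
#' current states from the quasi-absorbing `MCI_CC` row — are `NA`.
#'
#' `as_transition_table()` builds the same object directly from a matrix
#' of counts (e.g. a published table), so summary quantities can be
#' recomputed from printed counts.
#'
#' @param pairs Transition pairs from [build_pairs()], or any data frame
#'   with `prior_state` and `current_state` columns.
#' @return Object of class `mci_transition_table` with elements `counts`,
#'   `percent` (row percentages, 1 decimal) and `row_totals`.
#' @export
#' @examples
#' counts <- rbind(NORMAL = c(2192, 478, 385, 34, 19, 100))
#' colnames(counts) <- mci_states()
#' as_transition_table(counts)
transition_table <- function(pairs) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0,
            all(c("prior_state", "current_state") %in% names(pairs)))
  prior_levels <- c("NORMAL", "AMCI_TB", "MMCI_TB", "MCI_CC")
  p <- factor(as_state(pairs$prior_state), levels = prior_levels)
  cc <- factor(as_state(pairs$current_state), levels = mci_states())
  counts <- table(p, cc)
  counts <- matrix(as.integer(counts), nrow = 4,
                   dimnames = list(prior = prior_levels,
                                   current = mci_states()))
  as_transition_table(counts)
}

#' @rdname transition_table
#' @param counts Integer matrix of transition counts; rows named by prior
#'   state (any subset of the four prior states, in canonical order),
#'   columns named by current state.
#' @export
as_transition_table <- function(counts) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  prior_levels <- c("NORMAL", "AMCI_TB", "MMCI_TB", "MCI_CC")
  rn <- as_state(rownames(counts))
  cn <- as_state(colnames(counts))
  if (any(!rn %in% prior_levels)) {
    stop("prior rows must be among: ", paste(prior_levels, collapse = ", "),
         call. = FALSE)
  }
  full <- matrix(0L, length(rn), 6,
                 dimnames = list(prior = rn, current = mci_states()))
  full[, cn] <- as.integer(round(counts))
  if (any(full < 0)) stop("negative transition counts", call. = FALSE)
  ## structural zeros in the quasi-absorbing row
  if ("MCI_CC" %in% rn) {
    tr <- transient_states()
    if (any(full["MCI_CC", tr] > 0)) {
      stop("counts place transitions from MCI_CC into transient states",
           call. = FALSE)
    }
    full["MCI_CC", tr] <- NA_integer_
  }
  row_totals <- rowSums(full, na.rm = TRUE)
  percent <- round_half_up(100 * sweep(full, 1, row_totals, "/"), 1)
  structure(list(counts = full, percent = percent, row_totals = row_totals),
            class = "mci_transition_table")
}

#' @export
print.mci_transition_table <- function(x, ...) {
  cat("One-step transition matrix: count (% of prior-state row)\n\n")
  fmt <- matrix("", nrow(x$counts), ncol(x$counts),
                dimnames = dimnames(x$counts))
  for (i in seq_len(nrow(fmt))) {
    for (j in seq_len(ncol(fmt))) {
      fmt[i, j] <- if (is.na(x$counts[i, j])) {
        "."
      } else {
        sprintf("%d (%.1f)", x$counts[i, j], x$percent[i, j])
      }
    }
  }
  print(fmt, quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.mci_transition_table <- function(x, ...) {
  as.data.frame(x$counts, ...)
}

#' Write a transition matrix as CSV
#'
#' @param x `mci_transition_table`.
#' @param path File path; counts and percentages are interleaved as
#'   `<state>_n`, `<state>_pct` columns.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(x, path) {
  stopifnot(inherits(x, "mci_transition_table"))
  out <- data.frame(prior = rownames(x$counts))
  for (j in colnames(x$counts)) {
    out[[paste0(j, "_n")]] <- x$counts[, j]
    out[[paste0(j, "_pct")]] <- x$percent[, j]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Pooled transition rates over groups of current states
#'
#' Computes, within a prior-state row, the percentage of transitions into
#' an arbitrary union of current states — e.g. the progression rate from a
#' test-based MCI state into clinical MCI or dementia.
#'
#' @param x An `mci_transition_table` (or transition pairs, which are
#'   tabulated first).
#' @param groupings A list of groupings, each a list with elements `prior`
#'   (one prior state) and `current` (character vector of current states).
#' @param digits Decimal places of the reported percentage (half-up).
#' @return Data frame with columns `prior`, `current`, `count`, `total`,
#'   `percent`.
#' @export
#' @examples
#' counts <- rbind(AMCI_TB = c(448, 148, 108, 23, 10, 18))
#' colnames(counts) <- mci_states()
#' tab <- as_transition_table(counts)
#' aggregate_rates(tab, list(list(prior = "AMCI_TB",
#'                                current = c("MCI_CC", "DEMENTIA"))))
aggregate_rates <- function(x, groupings, digits = 1) {
  if (!inherits(x, "mci_transition_table")) x <- transition_table(x)
  rows <- lapply(groupings, function(g) {
    prior <- as_state(g$prior)
    current <- as_state(g$current)
    stopifnot(length(prior) == 1L)
    if (!prior %in% rownames(x$counts)) {
      stop("prior state ", prior, " not present in table", call. = FALSE)
    }
    cnt <- sum(x$counts[prior, current], na.rm = TRUE)
    tot <- x$row_totals[[prior]]
    data.frame(prior = prior, current = paste(current, collapse = "+"),
               count = cnt, total = tot,
               percent = round_half_up(100 * cnt / tot, digits),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
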