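#' Enforce the quasi-absorbing structure of clinical-consensus MCI
#'
#' The transition model treats `MCI_CC` as quasi-absorbing: once diagnosed,
#' a subject may progress to dementia or death but never return to a
#' transient state.  Observed trajectories, however, can contain apparent
#' back transitions.  `clean_trajectories()` resolves them with two
#' deterministic patterns:
#'
#' * **Pattern A** — the reversion is followed later by another `MCI_CC`
#'   visit or by dementia.  The diagnosis is taken as genuine from its first
#'   occurrence, and every subsequent transient visit is reclassified as
#'   `MCI_CC` (intervening test-based MCI visits are overwritten too, and
#'   flagged in the audit).
#' * **Pattern B** — the `MCI_CC` visits are followed only by transient
#'   states to the end of follow-up.  The diagnosis is treated as spurious
#'   and those visits are demoted to their test-based classification (the
#'   `state_tb` column when present, else `NORMAL`), so a demoted visit may
#'   still be `AMCI_TB` or `MMCI_TB`.  The audit labels the pattern
#'   `B-initial` when the spurious run starts at the first visit and
#'   `B-mid` otherwise.
#'
#' Back transitions among the transient states themselves are legitimate
#' and untouched, as are dementia and death visits.  Cleaning is
#' idempotent, never changes visit counts or times, and its output passes
#' [validate_trajectories()] with zero violations.
#'
#' Because the real-world analogue of this step is a medical-record review,
#' per-visit manual overrides can be supplied (a data frame or YAML file
#' with `subject`, `visit`, `state`); they are applied before the pattern
#' rules and recorded in the audit as pattern `"manual"`.
#'
#' @param visits Long-format data frame with columns `subject`, `visit`,
#'   `state`, optionally `state_tb`, ordered or orderable by
#'   (`subject`, `visit`).
#' @param overrides Optional manual edits: data frame with columns
#'   `subject`, `visit`, `state`, or path to a YAML file with a list of
#'   such records.
#' @return List with elements `data` (the cleaned table) and `audit`
#'   (data frame `subject`, `visit`, `old_state`, `new_state`, `pattern`).
#' @export
clean_trajectories <- function(visits, overrides = NULL) {
  stopifnot(is.data.frame(visits),
            all(c("subject", "visit", "state") %in% names(visits)))
  visits <- visits[order(visits$subject, visits$visit), , drop = FALSE]
  visits$state <- as_state(visits$state)
  audit <- list()

  if (!is.null(overrides)) {
    ov <- read_overrides(overrides)
    for (i in seq_len(nrow(ov))) {
      j <- which(visits$subject == ov$subject[i] & visits$visit == ov$visit[i])
      if (length(j) != 1L) {
        stop("override targets unknown visit: subject ", ov$subject[i],
             " visit ", ov$visit[i], call. = FALSE)
      }
      if (visits$state[j] != ov$state[i]) {
        audit[[length(audit) + 1L]] <- data.frame(
          subject = ov$subject[i], visit = ov$visit[i],
          old_state = visits$state[j], new_state = as_state(ov$state[i]),
          pattern = "manual", stringsAsFactors = FALSE
        )
        visits$state[j] <- as_state(ov$state[i])
      }
    }
  }

  transient <- transient_states()
  idx_by_subject <- split(seq_len(nrow(visits)), visits$subject)
  idx_by_subject <- idx_by_subject[unique(as.character(visits$subject))]
  for (id in names(idx_by_subject)) {
    idx <- idx_by_subject[[id]]
    s <- visits$state[idx]
    check_absorbing_order(s, id)
    cc <- which(s == "MCI_CC")
    if (!length(cc)) next
    first <- cc[1L]
    rev_after <- which(seq_along(s) > first & s %in% transient)
    if (!length(rev_after)) next  # already quasi-absorbing
    later_support <- any(seq_along(s) > rev_after[1L] &
                           s %in% c("MCI_CC", "DEMENTIA"))
    if (later_support) {
      ## Pattern A: diagnosis genuine from first occurrence onward
      change <- which(seq_along(s) > first & s %in% transient)
      for (j in change) {
        audit[[length(audit) + 1L]] <- data.frame(
          subject = id, visit = visits$visit[idx[j]],
          old_state = s[j], new_state = "MCI_CC", pattern = "A",
          stringsAsFactors = FALSE
        )
      }
      s[change] <- "MCI_CC"
    } else {
      ## Pattern B: spurious diagnosis, demote to test-based state
      pat <- if (first == 1L) "B-initial" else "B-mid"
      tb <- if ("state_tb" %in% names(visits)) {
        visits$state_tb[idx]
      } else {
        rep(NA_character_, length(s))
      }
      for (j in cc) {
        new <- tb[j]
        if (is.na(new) || !(new %in% transient)) new <- "NORMAL"
        audit[[length(audit) + 1L]] <- data.frame(
          subject = id, visit = visits$visit[idx[j]],
          old_state = s[j], new_state = new, pattern = pat,
          stringsAsFactors = FALSE
        )
        s[j] <- new
      }
    }
    visits$state[idx] <- s
  }

  audit <- if (length(audit)) {
    do.call(rbind, audit)
  } else {
    data.frame(subject = character(), visit = integer(),
               old_state = character(), new_state = character(),
               pattern = character(), stringsAsFactors = FALSE)
  }
  list(data = visits, audit = audit)
}

## internal: states recorded after an absorbing state are a hard error
check_absorbing_order <- function(s, id) {
  abs_idx <- which(s %in% absorbing_states())
  if (length(abs_idx) && abs_idx[1L] < length(s)) {
    stop("subject ", id, " has visits recorded after an absorbing state",
         call. = FALSE)
  }
  if (sum(s == "DEATH") > 1L) {
    stop("subject ", id, " has more than one death", call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate trajectory invariants
#'
#' Reports (never mutates) counts of structural violations in a cohort of
#' state trajectories: visits after an absorbing state, multiple deaths,
#' back transitions from `MCI_CC` to a transient state, and non-increasing
#' visit times within subject.  A cleaned cohort reports zero violations.
#'
#' @param visits Long-format data frame with `subject`, `visit`, `state`
#'   and optionally `time` columns.
#' @return An object of class `mci_validation`: data frame of violation
#'   types and counts, with a `total` attribute.
#' @export
validate_trajectories <- function(visits) {
  stopifnot(is.data.frame(visits),
            all(c("subject", "visit", "state") %in% names(visits)))
  visits <- visits[order(visits$subject, visits$visit), , drop = FALSE]
  st <- as_state(visits$state)
  n <- nrow(visits)
  same <- if (n > 1L) visits$subject[-n] == visits$subject[-1L] else logical(0)
  prior <- st[-n][same]
  curr <- st[-1L][same]
  counts <- c(
    "state after absorbing" = sum(prior %in% absorbing_states()),
    "multiple deaths" = sum(tapply(st == "DEATH", visits$subject, sum) > 1L),
    "back-transition from MCI_CC" =
      sum(prior == "MCI_CC" & curr %in% transient_states()),
    "non-increasing times" = if ("time" %in% names(visits)) {
      sum((visits$time[-1L] - visits$time[-n])[same] <= 0)
    } else {
      0L
    }
  )
  out <- data.frame(violation = names(counts), count = as.integer(counts),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("mci_validation", "data.frame"),
            total = sum(counts))
}

#' @export
print.mci_validation <- function(x, ...) {
  total <- attr(x, "total")
  cat("Trajectory validation:", total, "violation(s)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

## internal: overrides from data frame or YAML file
read_overrides <- function(overrides) {
  if (is.character(overrides) && length(overrides) == 1L) {
    raw <- yaml::read_yaml(overrides)
    overrides <- do.call(rbind, lapply(raw, function(r) {
      data.frame(subject = as.character(r$subject),
                 visit = as.integer(r$visit),
                 state = as.character(r$state), stringsAsFactors = FALSE)
    }))
  }
  stopifnot(is.data.frame(overrides),
            all(c("subject", "visit", "state") %in% names(overrides)))
  overrides$state <- as_state(overrides$state)
  overrides
}

#' Write a cleaning audit trail to CSV
#'
#' @param audit Audit data frame from [clean_trajectories()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_audit <- function(audit, path) {
  utils::write.csv(audit, path, row.names = FALSE)
  invisible(path)
}
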