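#' Default neuropsychological test battery
#'
#' Describes the cognitive tests used for state classification: the episodic
#' memory battery that defines test-based amnestic MCI and the
#' language/executive battery that defines test-based mixed MCI.  Each test
#' carries a direction flag: `"higher_better"` for accuracy-type scores and
#' `"higher_worse"` for error counts or completion times (e.g. figure-recall
#' errors, trail-making seconds), for which impairment lies in the upper
#' tail.
#'
#' Users with different instruments can supply their own battery as a data
#' frame with columns `test`, `domain` (`"memory"` or `"nonmemory"`) and
#' `direction`.
#'
#' @return Data frame with columns `test`, `domain`, `direction`.
#' @export
#' @examples
#' default_battery()
default_battery <- function() {
  data.frame(
    test = c(
      "logical_memory", "benton_correct", "benton_errors",
      "wordlist_learning", "wordlist_recall", "wordlist_savings",
      "wordlist_drop",
      "fluency_phonemic", "fluency_category", "boston_naming",
      "trails_a", "trails_b"
    ),
    domain = c(rep("memory", 7), rep("nonmemory", 5)),
    direction = c(
      "higher_better", "higher_better", "higher_worse",
      "higher_better", "higher_better", "higher_better",
      "higher_worse",
      "higher_better", "higher_better", "higher_better",
      "higher_worse", "higher_worse"
    ),
    stringsAsFactors = FALSE
  )
}

check_battery <- function(battery) {
  stopifnot(
    is.data.frame(battery),
    all(c("test", "domain", "direction") %in% names(battery)),
    !anyDuplicated(battery$test)
  )
  if (!all(battery$domain %in% c("memory", "nonmemory"))) {
    stop("battery domains must be 'memory' or 'nonmemory'", call. = FALSE)
  }
  if (!all(battery$direction %in% c("higher_better", "higher_worse"))) {
    stop("battery directions must be 'higher_better' or 'higher_worse'",
         call. = FALSE)
  }
  battery
}

#' Fit age-adjusted normative values for a test battery
#'
#' Derives, for every test in the battery, an age-conditional mean and a
#' residual standard deviation from the baseline visits of a cognitively
#' normal cohort.  These norms define the "poor score" threshold (at least
#' `threshold` residual SDs worse than the age-adjusted mean) used by
#' [classify_visit()].  Norms are frozen once fitted; classification never
#' refits them.
#'
#' Two adjustment forms are available: `"linear"` regresses each baseline
#' score on age and uses the residual SD (the default), and `"age_band"`
#' uses means within 5-year age bands with a pooled within-band SD.  If all
#' baseline subjects share one age the linear form degrades gracefully to a
#' zero slope with the sample mean and SD.
#'
#' @param baseline Data frame of baseline visits with an `age` column and
#'   one column per test score (missing scores allowed).
#' @param battery Test battery, as from [default_battery()].
#' @param method `"linear"` or `"age_band"`.
#' @param band_width Width in years of the age bands (only for
#'   `"age_band"`).
#' @return An object of class `mci_norms`: a data frame with one row per
#'   test (`test`, `domain`, `direction`, `intercept`, `slope`, `sd`, `n`),
#'   plus band tables when `method = "age_band"`.
#' @export
fit_norms <- function(baseline, battery = default_battery(),
                      method = c("linear", "age_band"), band_width = 5) {
  method <- match.arg(method)
  battery <- check_battery(battery)
  stopifnot(is.data.frame(baseline), "age" %in% names(baseline))
  missing_cols <- setdiff(battery$test, names(baseline))
  if (length(missing_cols)) {
    stop("baseline table lacks score column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  rows <- vector("list", nrow(battery))
  bands <- list()
  for (i in seq_len(nrow(battery))) {
    test <- battery$test[i]
    ok <- !is.na(baseline[[test]]) & !is.na(baseline$age)
    score <- baseline[[test]][ok]
    age <- baseline$age[ok]
    if (length(score) < 3L) {
      stop("test '", test, "' has fewer than 3 non-missing baseline scores",
           call. = FALSE)
    }
    if (method == "linear") {
      if (length(unique(age)) < 2L) {
        intercept <- mean(score)
        slope <- 0
        sdres <- stats::sd(score)
      } else {
        fit <- stats::lm(score ~ age)
        intercept <- unname(stats::coef(fit)[1])
        slope <- unname(stats::coef(fit)[2])
        ## residual SD computed directly (summary.lm warns on exact fits)
        sdres <- sqrt(sum(stats::residuals(fit)^2) / (length(score) - 2L))
      }
    } else {
      band <- floor(age / band_width) * band_width
      mu <- tapply(score, band, mean)
      dev <- score - mu[as.character(band)]
      nb <- length(mu)
      sdres <- if (length(score) > nb) {
        sqrt(sum(dev^2) / (length(score) - nb))
      } else {
        0
      }
      bands[[test]] <- data.frame(
        band = as.numeric(names(mu)), mean = as.numeric(mu),
        row.names = NULL
      )
      intercept <- NA_real_
      slope <- NA_real_
    }
    if (!is.na(sdres) && sdres < sqrt(.Machine$double.eps)) {
      stop("degenerate norms for test '", test,
           "': residual variance is zero", call. = FALSE)
    }
    rows[[i]] <- data.frame(
      test = test, domain = battery$domain[i],
      direction = battery$direction[i],
      intercept = intercept, slope = slope, sd = sdres,
      n = length(score), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  structure(
    list(table = out, method = method, band_width = band_width,
         bands = bands),
    class = "mci_norms"
  )
}

#' @export
print.mci_norms <- function(x, ...) {
  cat("Age-adjusted cognitive norms (", x$method, " adjustment, ",
      nrow(x$table), " tests)\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

## internal: age-adjusted mean for given test rows and ages
norm_mean <- function(norms, test, age) {
  tab <- norms$table
  i <- match(test, tab$test)
  if (anyNA(i)) {
    stop("unknown test(s): ", paste(unique(test[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  if (norms$method == "linear") {
    tab$intercept[i] + tab$slope[i] * age
  } else {
    vapply(seq_along(test), function(k) {
      b <- norms$bands[[test[k]]]
      band <- floor(age[k] / norms$band_width) * norms$band_width
      j <- which(b$band == band)
      if (!length(j)) j <- which.min(abs(b$band - band))  # nearest band
      b$mean[j]
    }, numeric(1))
  }
}

#' Is a score "poor" relative to the age-adjusted norms?
#'
#' A poor score lies at least `threshold` (default 1.5) residual SDs on the
#' impaired side of the age-adjusted mean, with the boundary itself counted
#' as poor.  The impaired side respects the test's direction flag: low
#' scores for accuracy-type tests, high scores for error counts and timed
#' tests.
#'
#' @param score Numeric score(s); `NA` is never poor.
#' @param test Test name(s), matched against the norms.
#' @param age Age(s) in years at assessment.
#' @param norms Norms from [fit_norms()].
#' @param threshold SD multiple defining impairment (default 1.5).
#' @return Logical vector.
#' @export
#' @examples
#' base <- data.frame(age = rep(70:80, 10),
#'                    recall = rnorm(110, 50, 5))
#' battery <- data.frame(test = "recall", domain = "memory",
#'                       direction = "higher_better")
#' nm <- fit_norms(base, battery)
#' poor_score(30, "recall", 75, nm)
poor_score <- function(score, test, age, norms, threshold = 1.5) {
  stopifnot(inherits(norms, "mci_norms"), threshold > 0)
  n <- max(length(score), length(test), length(age))
  score <- rep_len(score, n)
  test <- rep_len(test, n)
  age <- rep_len(age, n)
  mu <- norm_mean(norms, test, age)
  i <- match(test, norms$table$test)
  sdv <- norms$table$sd[i]
  worse_high <- norms$table$direction[i] == "higher_worse"
  out <- ifelse(worse_high,
                score >= mu + threshold * sdv,
                score <= mu - threshold * sdv)
  out[is.na(score)] <- FALSE  # missing evidence never creates impairment
  out
}

#' Classify a single visit into a cognitive state
#'
#' Applies the state hierarchy: death supersedes dementia supersedes a
#' clinical-consensus MCI diagnosis, and any clinical state supersedes the
#' test-based classification.  Among test-based states, a poor score on any
#' language/executive measure gives mixed MCI (`MMCI_TB`) regardless of the
#' memory scores; otherwise a poor score on any episodic-memory measure
#' gives amnestic MCI (`AMCI_TB`); otherwise the visit is `NORMAL`.
#'
#' Missing scores are skipped: classification uses the available evidence,
#' and a visit with no scores at all and no clinical flag is an error
#' rather than `NORMAL`.
#'
#' @param scores Named numeric vector of test scores (`NA` allowed).
#' @param flags List or vector with logical elements `mci_cc`, `dementia`,
#'   `death` (absent treated as `FALSE`).
#' @param age Age in years at the visit.
#' @param norms Norms from [fit_norms()].
#' @param threshold Poor-score SD multiple (default 1.5).
#' @return A single state code (see [mci_states()]).
#' @export
classify_visit <- function(scores, flags = list(), age, norms,
                           threshold = 1.5) {
  get_flag <- function(nm) isTRUE(as.logical(flags[[nm]]))
  death <- get_flag("death")
  dementia <- get_flag("dementia")
  mci_cc <- get_flag("mci_cc")
  if (death && dementia) {
    stop("inconsistent clinical flags: dementia and death at one visit",
         call. = FALSE)
  }
  if (death) return("DEATH")
  if (dementia) return("DEMENTIA")
  tb <- classify_test_based(scores, age, norms, threshold,
                            require_scores = !mci_cc)
  if (mci_cc) return("MCI_CC")
  tb
}

## internal: test-based classification from scores alone
classify_test_based <- function(scores, age, norms, threshold = 1.5,
                                require_scores = TRUE) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) {
    if (require_scores) {
      stop("no usable test scores and no clinical flag at this visit",
           call. = FALSE)
    }
    return(NA_character_)
  }
  tests <- names(scores)
  unknown <- setdiff(tests, norms$table$test)
  if (length(unknown)) {
    stop("unknown test(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  poor <- poor_score(unname(scores), tests, age, norms, threshold)
  domain <- norms$table$domain[match(tests, norms$table$test)]
  if (any(poor & domain == "nonmemory")) return("MMCI_TB")
  if (any(poor & domain == "memory")) return("AMCI_TB")
  "NORMAL"
}

#' Classify every visit of a long-format table
#'
#' Vectorised driver for [classify_visit()]: appends a `state` column, and a
#' `state_tb` column holding the purely test-based classification (used by
#' the trajectory cleaner when demoting spurious clinical-MCI visits).
#' Rows flagged as deaths need no scores.
#'
#' @param visits Data frame with an `age` column, one column per battery
#'   test, and optional logical columns `mci_cc`, `dementia`, `death`.
#' @param norms Norms from [fit_norms()].
#' @param battery Test battery; defaults to the tests present in `norms`.
#' @param threshold Poor-score SD multiple.
#' @return `visits` with `state` and `state_tb` columns appended.
#' @export
classify_visits <- function(visits, norms, battery = NULL, threshold = 1.5) {
  stopifnot(is.data.frame(visits), "age" %in% names(visits))
  tests <- if (is.null(battery)) {
    intersect(norms$table$test, names(visits))
  } else {
    check_battery(battery)$test
  }
  if (!length(tests)) stop("no battery score columns found", call. = FALSE)
  n <- nrow(visits)
  flag <- function(nm) {
    if (nm %in% names(visits)) {
      v <- as.logical(visits[[nm]])
      v[is.na(v)] <- FALSE
      v
    } else {
      rep(FALSE, n)
    }
  }
  fl <- data.frame(mci_cc = flag("mci_cc"), dementia = flag("dementia"),
                   death = flag("death"))
  score_mat <- as.matrix(visits[tests])
  state <- character(n)
  state_tb <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    sc <- score_mat[i, ]
    names(sc) <- tests
    state[i] <- classify_visit(sc, fl[i, ], visits$age[i], norms, threshold)
    if (!fl$death[i]) {
      state_tb[i] <- classify_test_based(sc, visits$age[i], norms, threshold,
                                         require_scores = FALSE)
    }
  }
  visits$state <- state
  visits$state_tb <- state_tb
  visits
}

#' Read and write norms as plain CSV
#'
#' Norms are exchangeable as a flat CSV table so that a battery normed on
#' one cohort can classify another.  Only linear-adjustment norms
#' round-trip through CSV; banded norms carry their band tables and should
#' be kept in R.
#'
#' @param norms Norms from [fit_norms()].
#' @param path File path.
#' @return `read_norms()` returns an `mci_norms` object;
#'   `write_norms()` returns `path` invisibly.
#' @export
write_norms <- function(norms, path) {
  stopifnot(inherits(norms, "mci_norms"))
  if (norms$method != "linear") {
    stop("only linear-adjustment norms can be written to CSV", call. = FALSE)
  }
  utils::write.csv(norms$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_norms
#' @export
read_norms <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("test", "domain", "direction", "intercept", "slope", "sd")
  if (!all(needed %in% names(tab))) {
    stop("norms CSV must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$sd <= 0)) stop("norms CSV contains non-positive SDs",
                             call. = FALSE)
  structure(list(table = tab, method = "linear", band_width = NA,
                 bands = list()),
            class = "mci_norms")
}
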