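#' Read a long-format visit table with a YAML column mapping
#'
#' Cohort extracts rarely share column names, so the reader takes a YAML
#' configuration mapping columns to roles.  The configuration has up to
#' four sections:
#'
#' ```yaml
#' columns:            # role: source column
#'   subject: id
#'   visit: visit_no
#'   age: age_years
#'   time: years_in    # optional
#' flags:              # optional clinical flags
#'   mci_cc: mci_dx
#'   dementia: dem_dx
#'   death: died
#' covariates:         # optional model covariates
#'   female: sex_f
#'   apoe4: apoe_any4
#' tests:              # cognitive battery
#'   - column: lm_raw
#'     test: logical_memory
#'     domain: memory
#'     direction: higher_better
#' ```
#'
#' @param csv Path to the delimited file (one row per subject-visit).
#' @param config Path to the YAML mapping, or an equivalent list.
#' @param sep Field separator (default comma).
#' @return List with `visits` (standardised data frame: `subject`,
#'   `visit`, `age`, optional `time`, flags, covariates, one column per
#'   test) and `battery` (data frame usable with [fit_norms()]).
#' @export
read_visit_table <- function(csv, config, sep = ",") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  raw <- utils::read.table(csv, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  cols <- cfg$columns
  for (role in c("subject", "visit", "age")) {
    if (is.null(cols[[role]])) {
      stop("config must map a column for role '", role, "'", call. = FALSE)
    }
  }
  pick <- function(col) {
    if (!col %in% names(raw)) {
      stop("column '", col, "' not found in ", csv, call. = FALSE)
    }
    raw[[col]]
  }
  out <- data.frame(subject = pick(cols$subject),
                    visit = as.integer(pick(cols$visit)),
                    age = as.numeric(pick(cols$age)),
                    stringsAsFactors = FALSE)
  if (!is.null(cols$time)) out$time <- as.numeric(pick(cols$time))
  for (fl in names(cfg$flags)) {
    out[[fl]] <- as.logical(pick(cfg$flags[[fl]]))
  }
  for (cv in names(cfg$covariates)) {
    out[[cv]] <- as.numeric(pick(cfg$covariates[[cv]]))
  }
  battery <- NULL
  if (length(cfg$tests)) {
    battery <- do.call(rbind, lapply(cfg$tests, function(ts) {
      nm <- if (is.null(ts$test)) ts$column else ts$test
      data.frame(test = nm, domain = ts$domain, direction = ts$direction,
                 stringsAsFactors = FALSE)
    }))
    battery <- check_battery(battery)
    for (ts in cfg$tests) {
      nm <- if (is.null(ts$test)) ts$column else ts$test
      out[[nm]] <- as.numeric(pick(ts$column))
    }
  }
  list(visits = out, battery = battery)
}
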