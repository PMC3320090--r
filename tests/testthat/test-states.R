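test_that("fit_norms recovers an age-linear score model", {
  set.seed(42)
  gen <- function(n) {
    age <- runif(n, 65, 90)
    data.frame(age = age, recall = 50 - 0.5 * (age - 75) + rnorm(n, 0, 4))
  }
  battery <- data.frame(test = "recall", domain = "memory",
                        direction = "higher_better")
  base <- gen(200)
  nm <- fit_norms(base, battery)
  expect_equal(nm$table$slope, -0.5, tolerance = 0.1)
  expect_equal(nm$table$sd, 4, tolerance = 0.5)

  ## independent ordinary-least-squares refit at 10x the sample size
  big <- gen(2000)
  oracle <- lm(recall ~ age, data = big)
  nm_big <- fit_norms(big, battery)
  expect_equal(nm_big$table$slope, unname(coef(oracle)[2]), tolerance = 1e-10)
  expect_equal(nm_big$table$sd, summary(oracle)$sigma, tolerance = 1e-10)
})

test_that("degenerate and single-age baselines are handled", {
  battery <- data.frame(test = "recall", domain = "memory",
                        direction = "higher_better")
  ## perfectly collinear scores: zero residual variance must error by name
  collinear <- data.frame(age = c(70, 75, 80), recall = c(70, 80, 90))
  expect_error(fit_norms(collinear, battery), "recall")

  ## all subjects the same age: slope 0, sample mean and SD
  same_age <- data.frame(age = rep(75, 20),
                         recall = c(rep(48, 10), rep(52, 10)))
  nm <- fit_norms(same_age, battery)
  expect_equal(nm$table$slope, 0)
  expect_equal(nm$table$intercept, 50)
  expect_equal(nm$table$sd, sd(same_age$recall))

  ## too few scores
  expect_error(fit_norms(data.frame(age = 1:2, recall = 1:2), battery),
               "fewer than 3")
})

test_that("poor_score applies the inclusive 1.5 SD rule and directions", {
  nm <- small_norms()  # recall: mean 50 sd 5; errors: mean 10 sd 2

  ## boundary is inclusive ("at least 1.5 SD")
  expect_true(poor_score(50 - 1.5 * 5, "recall", 75, nm))
  expect_false(poor_score(50 - 1.5 * 5 + 1e-9, "recall", 75, nm))
  expect_false(poor_score(50, "recall", 75, nm))

  ## error-count test: impairment is the upper tail
  expect_true(poor_score(10 + 1.6 * 2, "errors", 75, nm))
  expect_false(poor_score(10 - 1.6 * 2, "errors", 75, nm))

  ## missing never poor; unknown test errors; threshold configurable
  expect_false(poor_score(NA_real_, "recall", 75, nm))
  expect_error(poor_score(30, "nosuch", 75, nm), "nosuch")
  expect_true(poor_score(50 - 1.1 * 5, "recall", 75, nm, threshold = 1))

  ## age adjustment shifts the cutoff
  aged <- small_norms()
  aged$table$slope[aged$table$test == "recall"] <- -0.4
  aged$table$intercept[aged$table$test == "recall"] <- 50 + 0.4 * 75
  expect_true(poor_score(50 - 0.4 * 5 - 7.5, "recall", 80, aged))
  expect_false(poor_score(50 - 7.5, "recall", 80, aged))
})

test_that("classify_visit applies clinical precedence and domain rules", {
  nm <- small_norms()
  panel <- mean_panel(nm)

  ## clinical flags supersede test-based states, death > dementia > MCI_CC
  expect_identical(classify_visit(panel, list(mci_cc = TRUE), 75, nm),
                   "MCI_CC")
  expect_identical(classify_visit(panel, list(dementia = TRUE), 75, nm),
                   "DEMENTIA")
  expect_identical(
    classify_visit(setNames(rep(NA_real_, 4), names(panel)),
                   list(death = TRUE), 75, nm),
    "DEATH"
  )
  expect_error(classify_visit(panel, list(dementia = TRUE, death = TRUE),
                              75, nm), "inconsistent")

  ## mixed MCI takes precedence over amnestic even with poor memory score
  p <- panel
  p["recall"] <- 50 - 10   # poor memory
  p["fluency"] <- 50 - 10  # poor language/executive
  expect_identical(classify_visit(p, list(), 75, nm), "MMCI_TB")

  p <- panel
  p["recall"] <- 50 - 10
  expect_identical(classify_visit(p, list(), 75, nm), "AMCI_TB")
  expect_identical(classify_visit(panel, list(), 75, nm), "NORMAL")

  ## missing scores: skipped, never impairing; all-missing errors
  p <- panel
  p["recall"] <- NA
  expect_identical(classify_visit(p, list(), 75, nm), "NORMAL")
  expect_error(
    classify_visit(setNames(rep(NA_real_, 4), names(panel)), list(), 75, nm),
    "no usable test scores"
  )
})

test_that("classification is monotone in performance", {
  nm <- small_norms()
  badness <- c(NORMAL = 0, AMCI_TB = 1, MMCI_TB = 2)
  set.seed(7)
  for (i in 1:25) {
    panel <- mean_panel(nm) + rnorm(4, 0, 8) *
      ifelse(nm$table$direction == "higher_better", 1, -1) * sample(c(1, -1), 4, TRUE)
    s0 <- classify_visit(panel, list(), 75, nm)
    ## improve every score by 10 SD in the better direction
    improved <- panel + 10 * nm$table$sd *
      ifelse(nm$table$direction == "higher_better", 1, -1)
    s1 <- classify_visit(improved, list(), 75, nm)
    expect_lte(badness[[s1]], badness[[s0]])
  }
})

test_that("exactly the planted subjects classify as amnestic MCI", {
  nm <- small_norms()
  N <- 40; k <- 9
  visits <- data.frame(age = rep(75, N))
  for (t in nm$table$test) visits[[t]] <- norm_mean_for(nm, t)
  visits$recall[seq_len(k)] <- 50 - 2 * 5  # one memory score at -2 SD
  out <- classify_visits(visits, nm)
  expect_identical(sum(out$state == "AMCI_TB"), as.integer(k))
  expect_identical(sum(out$state == "NORMAL"), as.integer(N - k))
  expect_identical(out$state_tb, out$state)  # no clinical flags anywhere
})

test_that("age-banded norms classify against band means", {
  set.seed(11)
  base <- data.frame(age = rep(c(67, 72, 77, 82), each = 30))
  base$recall <- 60 - 2 * floor(base$age / 5) + rnorm(120, 0, 3)
  battery <- data.frame(test = "recall", domain = "memory",
                        direction = "higher_better")
  nm <- fit_norms(base, battery, method = "age_band")
  ## cutoffs follow the band mean, so the same raw score can flip by age
  young_mean <- nm$bands$recall$mean[nm$bands$recall$band == 65]
  old_mean <- nm$bands$recall$mean[nm$bands$recall$band == 80]
  expect_gt(young_mean, old_mean)
  score <- old_mean - 1.0 * nm$table$sd
  expect_false(poor_score(score, "recall", 81, nm))
  expect_true(poor_score(score, "recall", 66, nm))
})

test_that("norms round-trip through CSV", {
  nm <- small_norms()
  path <- withr::local_tempfile(fileext = ".csv")
  write_norms(nm, path)
  nm2 <- read_norms(path)
  expect_equal(nm2$table$intercept, nm$table$intercept)
  expect_equal(nm2$table$sd, nm$table$sd)
  expect_identical(classify_visit(mean_panel(nm), list(), 75, nm2), "NORMAL")
})

test_that("a visit table reads through a YAML column mapping", {
  csv <- withr::local_tempfile(fileext = ".csv")
  cfg <- withr::local_tempfile(fileext = ".yaml")
  write.csv(data.frame(
    pid = c("p1", "p1"), vno = 1:2, age_years = c(70, 71),
    dem_dx = c(0, 1), rec_raw = c(50, NA), flu_raw = c(49, NA),
    sex_f = c(1, 1)
  ), csv, row.names = FALSE)
  writeLines(c(
    "columns:", "  subject: pid", "  visit: vno", "  age: age_years",
    "flags:", "  dementia: dem_dx",
    "covariates:", "  female: sex_f",
    "tests:",
    "  - column: rec_raw", "    test: recall", "    domain: memory",
    "    direction: higher_better",
    "  - column: flu_raw", "    test: fluency", "    domain: nonmemory",
    "    direction: higher_better"
  ), cfg)
  got <- read_visit_table(csv, cfg)
  expect_identical(names(got$visits),
                   c("subject", "visit", "age", "dementia", "female",
                     "recall", "fluency"))
  expect_identical(got$battery$test, c("recall", "fluency"))
  out <- classify_visits(got$visits, small_norms(), got$battery)
  expect_identical(out$state, c("NORMAL", "DEMENTIA"))
})
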