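test_that("BP summarization takes the mean of the last two readings", {
  expect_equal(summarize_bp(150, 140, 138), 139)
  expect_equal(summarize_bp(120, 118, 122), 120)
  expect_equal(summarize_bp(135, 135, 135), 135)
  # vectorized
  expect_equal(summarize_bp(c(150, 120), c(140, 118), c(138, 122)),
               c(139, 120))
  # fallback to the last two usable readings, NA when fewer than two
  expect_equal(suppressMessages(summarize_bp(150, 140, NA)), 145)
  expect_true(is.na(suppressMessages(summarize_bp(150, NA, NA))))
  expect_message(summarize_bp(150, NA, NA), "fewer than two")
})

test_that("medication amendment adds 10/5 mmHg only for users", {
  expect_equal(adjust_bp_for_medication(130, 85, 1), list(sbp = 140, dbp = 90))
  expect_equal(adjust_bp_for_medication(130, 85, 0), list(sbp = 130, dbp = 85))
  expect_equal(adjust_bp_for_medication(140, 90, 1), list(sbp = 150, dbp = 95))
})

test_that("hypertension coding uses the 140/90/medication rule", {
  expect_equal(define_hypertension(139, 89, 0), 0L)
  expect_equal(define_hypertension(140, 85, 0), 1L)
  expect_equal(define_hypertension(120, 70, 1), 1L)
  expect_equal(define_hypertension(120, 90, 0), 1L)

  # order safety: medication implies hypertensive whether or not the
  # amendment has been applied first
  sbp <- runif(200, 100, 180); dbp <- runif(200, 60, 110)
  med <- rbinom(200, 1, 0.5)
  am <- adjust_bp_for_medication(sbp, dbp, med)
  h_raw <- define_hypertension(sbp, dbp, med)
  h_am <- define_hypertension(am$sbp, am$dbp, med)
  expect_true(all(h_raw[med == 1] == 1L))
  expect_true(all(h_am[med == 1] == 1L))
})

test_that("season standardization removes the cosinor and preserves the mean", {
  d <- seq(5, 360, by = 12)

  # constant series unchanged
  expect_equal(season_standardize(rep(42, length(d)), d), rep(42, length(d)))

  # model-matched pure cosine collapses to a constant annual average
  # (equal to the sample mean, since the sampled days need not average
  # the cosine to zero)
  v <- 50 + 20 * cos(2 * pi * d / 365.25)
  out_cos <- season_standardize(v, d)
  expect_lt(diff(range(out_cos)), 1e-9)
  expect_equal(out_cos, rep(mean(v), length(d)), tolerance = 1e-9)

  # noisy cosinor: refit on the output has (numerically) zero seasonal terms,
  # the grand mean is preserved, and the operation is idempotent
  set.seed(4)
  v2 <- 50 + 15 * cos(2 * pi * (d - 30) / 365.25) + rnorm(length(d), 0, 5)
  out <- season_standardize(v2, d)
  refit <- lm(out ~ cos(2 * pi * d / 365.25) + sin(2 * pi * d / 365.25))
  expect_lt(max(abs(coef(refit)[2:3])), 1e-8)
  expect_equal(mean(out), mean(v2), tolerance = 1e-9)
  expect_equal(season_standardize(out, d), out, tolerance = 1e-9)

  # missing values pass through
  v3 <- v2; v3[4] <- NA
  out3 <- season_standardize(v3, d)
  expect_true(is.na(out3[4]))

  # error contracts
  expect_error(season_standardize(rep(1, 10), seq_len(10)), ">= 20")
  expect_error(season_standardize(rnorm(25, 50), rep(15, 25) + seq_len(25)),
               "seasonal spread")
})

test_that("25(OH)D categories use half-open bins with total coverage", {
  expect_equal(as.character(categorize_vitd(29.9)), "lt30")
  expect_equal(as.character(categorize_vitd(30)), "30to49.9")
  expect_equal(as.character(categorize_vitd(49.9)), "30to49.9")
  expect_equal(as.character(categorize_vitd(50)), "50to74.9")
  expect_equal(as.character(categorize_vitd(74.9)), "50to74.9")
  expect_equal(as.character(categorize_vitd(75)), "ge75")
  expect_error(categorize_vitd(-1), "negative")

  # total and mutually exclusive over a dense grid
  grid <- seq(0, 400, by = 0.5)
  cats <- categorize_vitd(grid)
  expect_false(anyNA(cats))
  expect_setequal(levels(cats), c("lt30", "30to49.9", "50to74.9", "ge75"))
})

test_that("covariate encoding bins BMI and handles unknown levels", {
  tab <- data.frame(age = c(40, 50, 60), sex = c(0, 1, 0),
                    bmi = c(26.3, 24.9, 31),
                    smoking = c("never", NA, "current"))
  X <- encode_covariates(tab)
  expect_equal(unname(X[, "bmi_cat25to29.9"]), c(1, 0, 0))
  expect_equal(unname(X[, "bmi_catge30"]), c(0, 0, 1))
  expect_equal(unname(X[, "smokingunknown"]), c(0, 1, 0))
  # never-smoker is the reference: all smoking dummies zero
  expect_true(all(X[1, grep("smoking", colnames(X))] == 0))

  tab$smoking <- c("never", "sometimes", "current")
  expect_error(encode_covariates(tab), "sometimes")
})

test_that("prospective sample selection drops baseline hypertensives", {
  p <- toy_participants(
    sbp1 = c(150, 120, 118, 130, 125),
    dbp1 = c(95, 80, 75, 85, 92),
    med1 = c(0, 0, 0, 0, 0),
    followed = rep(TRUE, 5)
  )
  kept <- suppressMessages(select_prospective_sample(p))
  expect_equal(nrow(kept), 3)          # rows 1 and 5 are hypertensive
  expect_setequal(kept$id, c(2, 3, 4))

  # all normotensive: identity on the followed set
  p2 <- toy_participants(rep(120, 4), rep(75, 4), rep(0, 4), rep(TRUE, 4))
  expect_equal(nrow(suppressMessages(select_prospective_sample(p2))), 4)

  # conservation: retained + excluded = followed total
  co <- quick_cohort(n = 800, seed = 6)
  pp <- suppressMessages(process_phenotypes(co$participants))
  kept3 <- suppressMessages(select_prospective_sample(pp))
  followed <- sum(pp$followed_w2)
  excluded <- sum(pp$hyper_w1[pp$followed_w2] == 1L)
  expect_equal(nrow(kept3) + excluded, followed)

  p3 <- toy_participants(rep(120, 4), rep(75, 4), rep(0, 4), rep(FALSE, 4))
  expect_error(suppressMessages(select_prospective_sample(p3)), "wave-2")
})
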