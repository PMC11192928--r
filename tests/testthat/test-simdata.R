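test_that("genotype simulation follows the HWE sampling model", {
  panel <- tiny_panel(3)

  # degenerate frequency: nearly all dosages are 2
  pe <- panel
  pe$eaf <- rep(1 - 1e-9, 3)
  g <- simulate_genotypes(pe, 10, seed = 1)
  expect_true(all(g == 2))

  # binomial mean at eaf = 0.3, n = 10,000: mean within 0.6 +/- 3*sqrt(0.42/n)
  p3 <- snp_panel("rs1", "A", "G", 0.3, 1)
  g3 <- simulate_genotypes(p3, 10000, seed = 2)
  expect_lt(abs(mean(g3) - 0.6), 3 * sqrt(0.42 / 10000))

  # determinism
  expect_identical(simulate_genotypes(panel, 50, seed = 9),
                   simulate_genotypes(panel, 50, seed = 9))

  # invalid eaf rejected by panel validation
  expect_error(snp_panel("rs1", "A", "G", 1.2, 1), "eaf")
  expect_error(simulate_genotypes(panel, 0), "n must be")
})

test_that("genotype column means track 2*eaf within binomial error", {
  panel <- default_vitd_panel()
  g <- simulate_genotypes(panel, 20000, seed = 3)
  se <- sqrt(2 * panel$eaf * (1 - panel$eaf) / 20000)
  expect_true(all(abs(colMeans(g) - 2 * panel$eaf) < 4 * se))
})

test_that("simulate_cohort is reproducible and respects its contracts", {
  cfg <- sim_config(n_total = 400, n_subcohort = 100, seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$genotypes, c2$genotypes)

  # sub-cohort rows carry the biomarker, others are missing
  expect_true(all(is.finite(c1$participants$vitd_raw[c1$participants$in_subcohort])))
  expect_true(all(is.na(c1$participants$vitd_raw[!c1$participants$in_subcohort])))

  # assay range respected
  expect_true(all(c1$participants$vitd_raw >= 10, na.rm = TRUE))
  expect_true(all(c1$participants$vitd_raw <= 375, na.rm = TRUE))

  expect_error(sim_config(n_total = 10, n_subcohort = 11), "n_subcohort")
})

test_that("seasonal amplitude zero removes the day-of-year association", {
  co <- quick_cohort(n = 3000, seed = 5, seasonal_amplitude = 0)
  p <- co$participants
  fit <- lm(vitd_raw ~ cos(2 * pi * day_of_year / 365.25) +
              sin(2 * pi * day_of_year / 365.25), data = p)
  expect_gt(anova(fit)[["Pr(>F)"]][1], 0.01)
})

test_that("noiseless confounder-free cohort is exactly linear in Xbar", {
  co <- quick_cohort(
    n = 500, seed = 21, theta_sbp = -0.07, theta_dbp = -0.07,
    confounder_effects = zero_confounders(),
    noise_sd_exposure = 0, noise_sd_sbp = 0, noise_sd_dbp = 0,
    reading_sd = 0, seasonal_amplitude = 0
  )
  xbar <- co$truth$xbar
  y <- co$truth$latent_sbp_w1
  fit <- lm(y ~ xbar)
  expect_equal(unname(coef(fit)[2]), -0.07, tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("null cohort shows confounded observational but clean genetic signal", {
  # theta = 0 with confounding on: the exposure-outcome correlation is
  # non-zero while the GRS stays independent of the confounders.
  reps <- 30
  r_obs <- numeric(reps)
  r_u <- numeric(reps)
  for (i in seq_len(reps)) {
    co <- quick_cohort(n = 1500, seed = 100 + i)
    p <- suppressMessages(process_phenotypes(co$participants))
    grs <- compute_grs(co$genotypes, co$panel)$score
    r_obs[i] <- cor(p$vitd_std, p$sbp_w1)
    r_u[i] <- cor(grs, p$bmi)
  }
  # confounding induces a clearly non-zero marginal correlation
  expect_lt(mean(r_obs), -0.03)
  expect_gt(abs(mean(r_obs)), 5 * sd(r_obs) / sqrt(reps))
  expect_lt(abs(mean(r_u)), 3 * sd(r_u) / sqrt(reps))  # GRS unconfounded
})

test_that("make_summary_stats recovers per-SNP weights and flags degeneracies", {
  co <- quick_cohort(
    n = 4000, seed = 31, confounder_effects = zero_confounders(),
    noise_sd_exposure = 0, seasonal_amplitude = 0
  )
  ss <- suppressMessages(make_summary_stats(co))
  expect_s3_class(ss, "summary_stats")
  # noiseless, confounder-free: beta_x is w_j up to finite-sample
  # cross-SNP correlation captured by the reported SE
  expect_true(all(abs(ss$beta_exposure - co$panel$weight) < 5 * ss$se_exposure))

  # monomorphic SNP excluded with a warning
  co$genotypes[, 3] <- 0L
  expect_warning(ss2 <- make_summary_stats(co), "monomorphic")
  expect_false(co$panel$rsid[3] %in% ss2$rsid)
  expect_equal(nrow(ss2), nrow(co$panel) - 1)
})

test_that("null no-pleiotropy outcome effects are jointly consistent with zero", {
  co <- quick_cohort(n = 8000, n_sub = 2000, seed = 41,
                     confounder_effects = zero_confounders())
  ss <- suppressMessages(make_summary_stats(co))
  chi2 <- sum((ss$beta_outcome / ss$se_outcome)^2)
  expect_gt(pchisq(chi2, nrow(ss), lower.tail = FALSE), 0.001)
})

test_that("plant_outlier shifts one SNP and composes additively", {
  ss <- gen_sumstats(m = 6, seed = 2)
  expect_identical(plant_outlier(ss, 3, 0), ss)
  s1 <- plant_outlier(ss, 3, 0.5)
  expect_equal(s1$beta_outcome[3], ss$beta_outcome[3] + 0.5)
  expect_equal(s1$beta_outcome[-3], ss$beta_outcome[-3])
  s2 <- plant_outlier(plant_outlier(ss, 3, 0.2), 3, 0.3)
  expect_equal(s2, s1)
  expect_error(plant_outlier(ss, 7, 1), "out of range")
})

test_that("cohort files round-trip through the TSV writers", {
  co <- quick_cohort(n = 60, n_sub = 30, seed = 8)
  dir <- tempfile()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("genotypes.tsv",
                                               "phenotypes.tsv",
                                               "panel.tsv")))))
  panel2 <- read_snp_panel(file.path(dir, "panel.tsv"))
  expect_equal(panel2$weight, co$panel$weight)
  g2 <- as.matrix(read.delim(file.path(dir, "genotypes.tsv"),
                             check.names = FALSE))
  expect_equal(unname(g2), unname(co$genotypes))
})
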