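make_stats <- function(bx, by, sx = rep(0.05, length(bx)),
                       sy = rep(0.05, length(by))) {
  m <- length(bx)
  summary_stats(paste0("rs", seq_len(m)), rep("A", m), rep("G", m),
                rep(0.3, m), bx, sx, by, sy)
}

test_that("harmonization aligns alleles, flips betas and drops ambiguity", {
  exp_set <- data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    effect_allele = c("A", "A", "A", "C", "A"),
    other_allele = c("G", "G", "T", "G", "C"),
    eaf = c(0.3, 0.3, 0.50, 0.3, 0.3),
    beta = rep(0.5, 5), se = rep(0.05, 5)
  )
  out_set <- data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    effect_allele = c("A", "G", "A", "C", "A"),
    other_allele = c("G", "A", "T", "G", "T"),
    eaf = c(0.3, 0.7, 0.5, 0.3, 0.3),
    beta = c(0.2, 0.2, 0.2, 0.2, 0.2), se = rep(0.04, 5)
  )
  expect_warning(h <- harmonize(exp_set, out_set), "dropped")
  log <- attr(h, "harmonization_log")

  expect_equal(h$beta_outcome[h$rsid == "rs1"], 0.2)    # identity
  expect_equal(h$beta_outcome[h$rsid == "rs2"], -0.2)   # swapped -> negated
  expect_false("rs3" %in% h$rsid)    # palindromic A/T with eaf 0.5 dropped
  expect_false("rs5" %in% h$rsid)    # irreconcilable alleles dropped
  expect_match(log$action[log$rsid == "rs3"], "palindromic")

  # palindromic outside the frequency window, aligned by frequency
  exp2 <- exp_set[3, ]; exp2$eaf <- 0.2
  out2 <- out_set[3, ]; out2$eaf <- 0.8
  exp2 <- rbind(exp2, exp_set[1, ])
  out2 <- rbind(out2, out_set[1, ])
  h2 <- harmonize(exp2, out2)
  expect_equal(h2$beta_outcome[h2$rsid == "rs3"], -0.2)

  # strand flip with same orientation keeps the sign
  exp3 <- data.frame(rsid = c("a", "b"), effect_allele = c("A", "C"),
                     other_allele = c("G", "T"), eaf = c(0.3, 0.4),
                     beta = c(1, 1), se = c(0.1, 0.1))
  out3 <- data.frame(rsid = c("a", "b"), effect_allele = c("T", "G"),
                     other_allele = c("C", "A"), eaf = c(0.3, 0.4),
                     beta = c(0.3, 0.3), se = c(0.1, 0.1))
  h3 <- harmonize(exp3, out3)
  expect_equal(h3$beta_outcome, c(0.3, 0.3))

  expect_error(harmonize(exp_set[1, ], out_set[2, ]), "overlapping")
})

test_that("IVW matches its closed form, the WLS oracle and the Wald identity", {
  # single SNP: identical to the Wald ratio
  s1 <- make_stats(0.5, 0.1)
  expect_warning(r1 <- mr_ivw(s1), "single SNP")
  expect_equal(r1$beta, 0.2)

  # shared exact ratio: estimate is that ratio and Q = 0
  bx <- c(0.4, 0.8, 1.2, 1.6)
  s2 <- make_stats(bx, 0.3 * bx)
  r2 <- mr_ivw(s2)
  expect_equal(r2$beta, 0.3, tolerance = 1e-12)
  expect_equal(r2$q_stat, 0, tolerance = 1e-20)

  # random 5-SNP instance: matches the normal-equation oracle to 1e-10
  set.seed(21)
  s3 <- make_stats(runif(5, 0.3, 2), rnorm(5, 0.2, 0.3),
                   sy = runif(5, 0.02, 0.2))
  r3 <- mr_ivw(s3)
  expect_equal(r3$beta,
               oracle_wls_origin(s3$beta_exposure, s3$beta_outcome,
                                 1 / s3$se_outcome^2),
               tolerance = 1e-10)

  # fixed-effects SE never exceeds multiplicative-random SE
  for (i in 1:10) {
    si <- gen_sumstats(m = 8, theta = 0.1, pleio_sd = 0.05, seed = 100 + i)
    expect_lte(mr_ivw(si, "fixed")$se, mr_ivw(si, "random")$se + 1e-15)
  }
})

test_that("MR-Egger recovers slope and intercept and matches its oracle", {
  bx <- c(0.5, 0.9, 1.4, 2.0, 2.4)

  # exact line through the origin: zero intercept, slope recovered
  e1 <- mr_egger(make_stats(bx, 0.25 * bx))
  expect_equal(e1$beta, 0.25, tolerance = 1e-12)
  expect_equal(e1$intercept, 0, tolerance = 1e-12)

  # constant offset in every beta_y moves the intercept, not the slope
  e2 <- mr_egger(make_stats(bx, 0.25 * bx + 0.07))
  expect_equal(e2$beta, 0.25, tolerance = 1e-12)
  expect_equal(e2$intercept, 0.07, tolerance = 1e-12)

  # random instance matches the weighted normal-equation oracle to 1e-10
  set.seed(22)
  s3 <- make_stats(runif(6, 0.3, 2), rnorm(6, 0.3, 0.2),
                   sy = runif(6, 0.02, 0.2))
  e3 <- mr_egger(s3)
  oc <- oracle_wls_intercept(s3$beta_exposure, s3$beta_outcome,
                             1 / s3$se_outcome^2)
  expect_equal(e3$intercept, unname(oc[1]), tolerance = 1e-10)
  expect_equal(e3$beta, unname(oc[2]), tolerance = 1e-10)

  expect_error(mr_egger(make_stats(c(1, 2), c(1, 2))), "at least 3")
})

test_that("weighted median interpolates the cumulative weight function", {
  # three equal-weight ratios
  s1 <- make_stats(c(1, 1, 1), c(1, 2, 3))
  expect_equal(mr_weighted_median(s1, n_boot = 50)$beta, 2)

  # SNP holding 60% of the weight (middle of the ratio order) wins
  s2 <- summary_stats(paste0("rs", 1:3), rep("A", 3), rep("G", 3),
                      rep(0.3, 3),
                      beta_exposure = c(1, sqrt(3), 1),
                      se_exposure = rep(0.01, 3),
                      beta_outcome = c(1, 2 * sqrt(3), 3),
                      se_outcome = rep(1, 3))
  # weights (bx/sy)^2 = (1, 3, 1)/5: middle ratio (=2) holds 60%
  expect_equal(mr_weighted_median(s2, n_boot = 50)$beta, 2)

  # unequal weights match the enumeration oracle
  set.seed(23)
  s3 <- make_stats(runif(5, 0.3, 2), rnorm(5, 0.2, 0.4),
                   sy = runif(5, 0.02, 0.3))
  wm <- mr_weighted_median(s3, n_boot = 50)
  expect_equal(wm$beta,
               oracle_weighted_median(s3$beta_outcome / s3$beta_exposure,
                                      (s3$beta_exposure / s3$se_outcome)^2))

  # bootstrap SE is seed-reproducible
  expect_equal(mr_weighted_median(s3, n_boot = 200, seed = 9)$se,
               mr_weighted_median(s3, n_boot = 200, seed = 9)$se)
  expect_error(mr_weighted_median(s1[1:2, ]), "at least 3")
})

test_that("Cochran's Q matches hand algebra", {
  bx <- c(1, 1, 1)
  q0 <- cochran_q(make_stats(bx, 0.4 * bx))
  expect_equal(q0$q, 0, tolerance = 1e-20)
  expect_equal(q0$p, 1)

  # two SNPs, equal first-order SEs sigma, ratios differing by d
  sigma <- 0.05; d <- 0.12
  s2 <- make_stats(c(1, 1), c(0.3, 0.3 + d), sy = c(sigma, sigma))
  q2 <- cochran_q(s2)
  expect_equal(q2$q, d^2 / (2 * sigma^2), tolerance = 1e-10)
  expect_equal(q2$df, 1L)
})

test_that("MR-PRESSO flags planted outliers and corrects exactly via IVW", {
  # data on the IVW line: no outliers, global test quiet
  set.seed(24)
  bx <- runif(10, 0.5, 2)
  s0 <- make_stats(bx, 0.2 * bx + rnorm(10, 0, 0.01), sy = rep(0.05, 10))
  r0 <- mr_presso(s0, n_sim = 500, seed = 1)
  expect_length(r0$outliers, 0)
  expect_gt(r0$global_p, 0.3)
  expect_equal(r0$beta, mr_ivw(s0)$beta)

  # planted 10*se outlier is flagged and correction equals IVW on the rest
  s1 <- plant_outlier(s0, 4, 10 * s0$se_outcome[4])
  r1 <- mr_presso(s1, n_sim = 500, seed = 2)
  expect_true(s1$rsid[4] %in% r1$outliers)
  expect_lt(r1$global_p, 0.05)
  kept <- !(s1$rsid %in% r1$outliers)
  expect_identical(r1$beta, mr_ivw(s1[kept, ])$beta)
  expect_identical(r1$se, mr_ivw(s1[kept, ])$se)

  expect_error(mr_presso(s0[1:3, ]), "at least 4")
  expect_error(mr_presso(s0, n_sim = 50), "n_sim")
})

test_that("estimators are invariant to SNP order and joint sign flips", {
  set.seed(25)
  s <- gen_sumstats(m = 9, theta = 0.15, pleio_sd = 0.03, seed = 25)
  perm <- sample(9)
  sp <- s[perm, ]
  flip <- s
  flip$beta_exposure[3] <- -flip$beta_exposure[3]
  flip$beta_outcome[3] <- -flip$beta_outcome[3]

  for (f in list(function(z) mr_ivw(z)$beta,
                 function(z) mr_egger(z)$beta,
                 function(z) mr_weighted_median(z, n_boot = 50, seed = 1)$beta)) {
    expect_equal(f(sp), f(s), tolerance = 1e-12)
    expect_equal(f(flip), f(s), tolerance = 1e-12)
  }
})

test_that("summary statistics round-trip through TSV", {
  s <- gen_sumstats(m = 5, seed = 26)
  path <- tempfile(fileext = ".tsv")
  write_summary_stats(s, path)
  s2 <- read_summary_stats(path)
  expect_equal(s2$beta_exposure, s$beta_exposure, tolerance = 1e-12)
  expect_equal(s2$rsid, s$rsid)
})
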