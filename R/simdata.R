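# Synthetic cohort generator. Emulates the statistical structure the
# downstream stages assume: HWE genotypes for independent instrument SNPs,
# an exposure with additive genetic effects plus a one-harmonic seasonal
# component within the assay range 10-375 nmol/L, shared confounders acting
# on both exposure and blood pressure, two survey waves with three BP
# readings each, and antihypertensive medication use.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Simulation configuration
#'
#' Defaults encode the emulated study: a total cohort of 86,324 with a
#' 5,854-person sub-cohort carrying biomarker measurements, a null causal
#' effect of annual-mean 25(OH)D on blood pressure, and confounding
#' calibrated so that the covariate-adjusted cross-sectional association is
#' near -1.7 mmHg SBP per 25 nmol/L despite the null causal effect. Means
#' and dispersions follow the emulated population (exposure 51 +/- 17
#' nmol/L; SBP 133.8 +/- 22.0; DBP 77.0 +/- 12.4 mmHg).
#'
#' @param n_total total-cohort size.
#' @param n_subcohort sub-cohort size (rows with a measured biomarker);
#'   must not exceed `n_total`.
#' @param theta_sbp,theta_dbp true causal effect of annual-mean 25(OH)D on
#'   SBP/DBP, mmHg per nmol/L. Default 0 (null).
#' @param effect_shape `"linear"` or `"jshape"`. Under `"jshape"` the causal
#'   dose-response is quadratic with vertex at `jshape_center`, so the local
#'   slope changes sign across the exposure range.
#' @param jshape_curvature,jshape_center quadratic curvature (mmHg per
#'   (nmol/L)^2) and vertex (nmol/L) of the J-shaped dose-response.
#' @param confounder_effects named list; each element is a numeric vector
#'   `c(exposure =, sbp =, dbp =)` giving the confounder's effect on the
#'   exposure (nmol/L per unit) and on each outcome (mmHg per unit).
#'   Recognized names: `age`, `sex`, `bmi`, `smoking_current`, `u` (a latent
#'   standard-normal confounder that is never observed, carrying the
#'   residual confounding).
#' @param seasonal_amplitude,seasonal_phase cosinor amplitude (nmol/L) and
#'   peak day-of-year of the seasonal exposure component.
#' @param noise_sd_exposure,noise_sd_sbp,noise_sd_dbp residual SDs.
#' @param reading_sd within-visit SD of individual BP readings (mmHg).
#' @param bp_drift_sbp,bp_drift_dbp mean latent BP change from wave 1 to
#'   wave 2 (mmHg); `bp_innovation_sd_sbp`, `bp_innovation_sd_dbp` the SD of
#'   the person-level change.
#' @param followup_rate probability a participant attends wave 2.
#' @param med_model coefficients of the medication-use logit:
#'   `c(intercept =, sbp =, age =)` applied to latent SBP and age.
#' @param pleiotropy `c(frac =, mean =, sd =)`: fraction of SNPs with a
#'   direct (non-exposure-mediated) effect on both BP outcomes, and the
#'   normal distribution its per-allele effect is drawn from.
#' @param mean_exposure,mean_sbp,mean_dbp population means.
#' @param seed integer seed; fixing it makes the cohort reproducible
#'   bit-for-bit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_total = 86324L,
                       n_subcohort = 5854L,
                       theta_sbp = 0,
                       theta_dbp = 0,
                       effect_shape = c("linear", "jshape"),
                       jshape_curvature = 0.004,
                       jshape_center = 50,
                       confounder_effects = default_confounder_effects(),
                       seasonal_amplitude = 15,
                       seasonal_phase = 200,
                       noise_sd_exposure = 15.3,
                       noise_sd_sbp = 19.3,
                       noise_sd_dbp = 11.5,
                       reading_sd = 3,
                       bp_drift_sbp = 4,
                       bp_drift_dbp = 1,
                       bp_innovation_sd_sbp = 8,
                       bp_innovation_sd_dbp = 5,
                       followup_rate = 0.61,
                       med_model = c(intercept = -18, sbp = 0.09, age = 0.04),
                       pleiotropy = c(frac = 0, mean = 0, sd = 0),
                       mean_exposure = 51,
                       mean_sbp = 133.8,
                       mean_dbp = 77,
                       seed = 1L) {
  effect_shape <- match.arg(effect_shape)
  cfg <- as.list(environment())
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_confounder_effects <- function() {
  list(
    age = c(exposure = 0.05, sbp = 0.55, dbp = 0.20),
    sex = c(exposure = 1.0, sbp = -6.0, dbp = -3.0),
    bmi = c(exposure = -0.5, sbp = 0.80, dbp = 0.50),
    smoking_current = c(exposure = -2.0, sbp = 1.0, dbp = 0.5),
    u = c(exposure = -6.0, sbp = 2.62, dbp = 1.36)
  )
}

validate_sim_config <- function(cfg) {
  if (cfg$n_subcohort > cfg$n_total) {
    stop("sim_config: n_subcohort exceeds n_total", call. = FALSE)
  }
  if (cfg$n_total < 1) stop("sim_config: n_total must be >= 1", call. = FALSE)
  sds <- c(cfg$noise_sd_exposure, cfg$noise_sd_sbp, cfg$noise_sd_dbp,
           cfg$reading_sd, cfg$bp_innovation_sd_sbp, cfg$bp_innovation_sd_dbp,
           cfg$seasonal_amplitude)
  if (any(sds < 0)) stop("sim_config: dispersions must be >= 0", call. = FALSE)
  if (cfg$followup_rate < 0 || cfg$followup_rate > 1) {
    stop("sim_config: followup_rate must be in [0, 1]", call. = FALSE)
  }
  for (nm in names(cfg$confounder_effects)) {
    eff <- cfg$confounder_effects[[nm]]
    if (!all(c("exposure", "sbp", "dbp") %in% names(eff))) {
      stop("sim_config: confounder effect '", nm,
           "' must name exposure, sbp and dbp components", call. = FALSE)
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each dosage is the sum of two independent Bernoulli(eaf) allele draws,
#' giving 0/1/2 counts of the effect allele. SNPs are simulated independent
#' (no linkage disequilibrium).
#'
#' @param panel a [snp_panel].
#' @param n number of participants.
#' @param seed optional integer seed.
#' @return An `n x nrow(panel)` integer matrix with columns named by rsid.
#' @export
simulate_genotypes <- function(panel, n, seed = NULL) {
  panel <- validate_snp_panel(panel)
  if (n < 1) stop("simulate_genotypes: n must be >= 1", call. = FALSE)
  with_seed(seed, {
    m <- nrow(panel)
    g <- matrix(stats::rbinom(n * m, size = 2L,
                              prob = rep(panel$eaf, each = n)),
                nrow = n, ncol = m, dimnames = list(NULL, panel$rsid))
    g
  })
}

season_term <- function(day, amplitude, phase) {
  amplitude * cos(2 * pi * (day - phase) / 365.25)
}

# Causal dose-response f(xbar) on the outcome scale.
dose_response <- function(xbar, theta, cfg) {
  if (cfg$effect_shape == "jshape") {
    cfg$jshape_curvature * (xbar - cfg$jshape_center)^2
  } else {
    theta * xbar
  }
}

#' Simulate a full two-wave cohort
#'
#' Generates genotypes, confounders, a seasonal exposure, latent blood
#' pressures at two waves with three readings each, medication use, and a
#' sub-cohort flag. The measured biomarker follows
#' \deqn{X_i = \mu + \sum_j w_j g_{ij} + \sum_c \gamma_c C_{ic} +
#'       A\cos(2\pi(d_i-\phi)/365.25) + \epsilon_i,}
#' truncated to the assay range 10-375 nmol/L, and the annual-mean exposure
#' (X without the seasonal term, before truncation) drives the outcomes.
#' The biomarker is observed (non-missing) only in the sub-cohort, mirroring
#' a 10% measured random sample.
#'
#' @param config a [sim_config].
#' @param panel a [snp_panel]; defaults to the built-in synthetic panel.
#' @return A list of class `sim_cohort` with elements `participants`
#'   (data.frame), `genotypes` (dosage matrix), `panel`, and `truth` (the
#'   generating parameters plus per-person latent values).
#' @export
simulate_cohort <- function(config = sim_config(), panel = default_vitd_panel()) {
  config <- validate_sim_config(unclass(config))
  panel <- validate_snp_panel(panel)
  n <- config$n_total
  ce <- config$confounder_effects
  with_seed(config$seed, {
    g <- simulate_genotypes(panel, n)
    genetic <- as.numeric(g %*% panel$weight)

    age <- stats::runif(n, 20, 80)
    sex <- stats::rbinom(n, 1L, 0.53)           # 1 = female
    bmi <- stats::rnorm(n, 26.9, 4.4)
    smoking <- sample(c("never", "former", "current", "unknown"), n,
                      replace = TRUE, prob = c(0.44, 0.22, 0.22, 0.12))
    u <- stats::rnorm(n)

    # Non-confounding lifestyle covariates, present so covariate encoding is
    # exercised; marginals loosely follow the emulated population.
    alcohol <- sample(c("never", "1-4", "ge5", "unknown"), n,
                      replace = TRUE, prob = c(0.24, 0.58, 0.12, 0.06))
    activity <- sample(c("inactive", "low", "moderate", "high", "unknown"), n,
                       replace = TRUE, prob = c(0.19, 0.20, 0.20, 0.11, 0.30))
    education <- sample(c("lt10", "10to12", "ge13", "unknown"), n,
                        replace = TRUE, prob = c(0.33, 0.33, 0.29, 0.05))
    econ <- sample(c("no", "yes", "unknown"), n,
                   replace = TRUE, prob = c(0.51, 0.21, 0.28))

    conf_x <- ce$age["exposure"] * (age - 50) +
      ce$sex["exposure"] * (sex - 0.53) +
      ce$bmi["exposure"] * (bmi - 26.9) +
      ce$smoking_current["exposure"] * (smoking == "current") +
      ce$u["exposure"] * u
    mu <- config$mean_exposure - sum(panel$weight * 2 * panel$eaf)
    xbar <- mu + genetic + conf_x +
      stats::rnorm(n, 0, config$noise_sd_exposure)

    day <- sample.int(365L, n, replace = TRUE)
    x_raw <- xbar + season_term(day, config$seasonal_amplitude,
                                config$seasonal_phase)
    x_raw <- pmin(pmax(x_raw, 10), 375)

    # Optional per-SNP direct (pleiotropic) effects on both BP outcomes.
    pl <- config$pleiotropy
    alpha <- numeric(nrow(panel))
    if (pl[["frac"]] > 0) {
      hit <- stats::runif(nrow(panel)) < pl[["frac"]]
      alpha[hit] <- stats::rnorm(sum(hit), pl[["mean"]], pl[["sd"]])
    }
    direct <- as.numeric(g %*% alpha)

    conf_sbp <- ce$age["sbp"] * (age - 50) + ce$sex["sbp"] * (sex - 0.53) +
      ce$bmi["sbp"] * (bmi - 26.9) +
      ce$smoking_current["sbp"] * (smoking == "current") + ce$u["sbp"] * u
    conf_dbp <- ce$age["dbp"] * (age - 50) + ce$sex["dbp"] * (sex - 0.53) +
      ce$bmi["dbp"] * (bmi - 26.9) +
      ce$smoking_current["dbp"] * (smoking == "current") + ce$u["dbp"] * u

    f_sbp <- dose_response(xbar, config$theta_sbp, config)
    f_dbp <- dose_response(xbar, config$theta_dbp, config)
    b0_sbp <- config$mean_sbp -
      mean_dose_response(config$theta_sbp, config, config$mean_exposure)
    b0_dbp <- config$mean_dbp -
      mean_dose_response(config$theta_dbp, config, config$mean_exposure)
    sbp1 <- b0_sbp + f_sbp + conf_sbp + direct +
      stats::rnorm(n, 0, config$noise_sd_sbp)
    dbp1 <- b0_dbp + f_dbp + conf_dbp + direct +
      stats::rnorm(n, 0, config$noise_sd_dbp)

    sbp2 <- sbp1 + config$bp_drift_sbp +
      stats::rnorm(n, 0, config$bp_innovation_sd_sbp)
    dbp2 <- dbp1 + config$bp_drift_dbp +
      stats::rnorm(n, 0, config$bp_innovation_sd_dbp)

    mm <- config$med_model
    med1 <- stats::rbinom(n, 1L, stats::plogis(
      mm[["intercept"]] + mm[["sbp"]] * sbp1 + mm[["age"]] * age))
    med2 <- stats::rbinom(n, 1L, stats::plogis(
      mm[["intercept"]] + mm[["sbp"]] * sbp2 + mm[["age"]] * (age + 11)))
    med2 <- pmax(med1, med2)  # medication, once started, is not dropped

    readings <- function(latent) {
      sapply(1:3, function(k) latent + stats::rnorm(n, 0, config$reading_sd))
    }
    s1 <- readings(sbp1); d1 <- readings(dbp1)
    s2 <- readings(sbp2); d2 <- readings(dbp2)

    followed <- stats::rbinom(n, 1L, config$followup_rate) == 1L
    sub <- sample.int(n, config$n_subcohort)
    in_sub <- seq_len(n) %in% sub

    batch <- sample(c("b1", "b2", "b3"), n, replace = TRUE)
    pcs <- matrix(stats::rnorm(n * 20), n, 20,
                  dimnames = list(NULL, paste0("PC", 1:20)))

    participants <- data.frame(
      id = seq_len(n), age = age, sex = sex, bmi = bmi,
      smoking = smoking, alcohol = alcohol, activity = activity,
      education = education, econ_difficulty = econ,
      day_of_year = day,
      vitd_raw = ifelse(in_sub, x_raw, NA_real_),
      sbp1_w1 = s1[, 1], sbp2_w1 = s1[, 2], sbp3_w1 = s1[, 3],
      dbp1_w1 = d1[, 1], dbp2_w1 = d1[, 2], dbp3_w1 = d1[, 3],
      med_w1 = med1,
      followed_w2 = followed,
      sbp1_w2 = ifelse(followed, s2[, 1], NA_real_),
      sbp2_w2 = ifelse(followed, s2[, 2], NA_real_),
      sbp3_w2 = ifelse(followed, s2[, 3], NA_real_),
      dbp1_w2 = ifelse(followed, d2[, 1], NA_real_),
      dbp2_w2 = ifelse(followed, d2[, 2], NA_real_),
      dbp3_w2 = ifelse(followed, d2[, 3], NA_real_),
      med_w2 = ifelse(followed, med2, NA_integer_),
      batch = batch,
      in_subcohort = in_sub,
      stringsAsFactors = FALSE
    )
    participants <- cbind(participants, as.data.frame(pcs))

    truth <- list(config = config, alpha = alpha, xbar = xbar,
                  latent_sbp_w1 = sbp1, latent_dbp_w1 = dbp1,
                  latent_sbp_w2 = sbp2, latent_dbp_w2 = dbp2)
    structure(list(participants = participants, genotypes = g,
                   panel = panel, truth = truth),
              class = "sim_cohort")
  })
}

# E[f(X)] used to centre the outcome intercept; under the linear shape this
# is theta * mean_exposure, under the J shape the quadratic's mean is
# absorbed only approximately (exact centring is not needed).
mean_dose_response <- function(theta, cfg, mean_exposure) {
  if (cfg$effect_shape == "jshape") {
    cfg$jshape_curvature * ((mean_exposure - cfg$jshape_center)^2 + 17^2)
  } else {
    theta * mean_exposure
  }
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort: n =", nrow(x$participants),
      "(sub-cohort", sum(x$participants$in_subcohort), "),",
      ncol(x$genotypes), "SNPs\n")
  invisible(x)
}

# Per-SNP simple regression of y on each dosage column, vectorized.
snp_regressions <- function(y, g) {
  keep <- is.finite(y)
  y <- y[keep]; g <- g[keep, , drop = FALSE]
  n <- length(y)
  gc <- sweep(g, 2, colMeans(g))
  yc <- y - mean(y)
  sgg <- colSums(gc^2)
  beta <- colSums(gc * yc) / sgg
  rss <- sum(yc^2) - beta^2 * sgg
  se <- sqrt(pmax(rss, 0) / (n - 2) / sgg)
  list(beta = beta, se = se, n = n)
}

#' Build a summary-statistic set from a simulated cohort
#'
#' Per-SNP exposure effects are estimated by simple regression of the
#' season-standardized biomarker on dosage within the sub-cohort; per-SNP
#' outcome effects by regression of the amended wave-1 blood pressure on
#' dosage within the total cohort. This produces the two-sample MR input
#' that public GWAS summary data would provide.
#'
#' @param cohort a `sim_cohort`.
#' @param panel the panel used to simulate (alleles/eaf are copied from it).
#' @param outcome `"sbp"` or `"dbp"`.
#' @return A `summary_stats` data.frame (see [summary_stats]).
#' @export
make_summary_stats <- function(cohort, panel = cohort$panel,
                               outcome = c("sbp", "dbp")) {
  outcome <- match.arg(outcome)
  if (nrow(panel) < 2) {
    stop("make_summary_stats: need at least 2 SNPs", call. = FALSE)
  }
  p <- cohort$participants
  g <- cohort$genotypes

  mono <- apply(g, 2, function(col) stats::var(col) == 0)
  if (any(mono)) {
    warning("make_summary_stats: dropping monomorphic SNPs: ",
            paste(colnames(g)[mono], collapse = ", "), call. = FALSE)
    g <- g[, !mono, drop = FALSE]
    panel <- panel[!mono, , drop = FALSE]
  }

  sub <- p$in_subcohort
  x_std <- season_standardize(p$vitd_raw[sub], p$day_of_year[sub])
  fx <- snp_regressions(x_std, g[sub, , drop = FALSE])

  pre <- if (outcome == "sbp") "sbp" else "dbp"
  bp <- summarize_bp(p[[paste0(pre, "1_w1")]], p[[paste0(pre, "2_w1")]],
                     p[[paste0(pre, "3_w1")]])
  amended <- adjust_bp_for_medication(bp, bp, p$med_w1)
  y <- if (outcome == "sbp") amended$sbp else amended$dbp
  fy <- snp_regressions(y, g)

  summary_stats(
    rsid = panel$rsid,
    effect_allele = panel$effect_allele,
    other_allele = panel$other_allele,
    eaf = panel$eaf,
    beta_exposure = unname(fx$beta), se_exposure = unname(fx$se),
    beta_outcome = unname(fy$beta), se_outcome = unname(fy$se)
  )
}

#' Plant an outlier SNP in a summary-statistic set
#'
#' Shifts the outcome effect of one SNP by a fixed offset, leaving all other
#' entries untouched. Used to exercise outlier-detection machinery
#' (MR-PRESSO). Successive plants compose additively.
#'
#' @param stats a `summary_stats` set.
#' @param index row position of the SNP to perturb.
#' @param offset shift added to `beta_outcome[index]` (effect units).
#' @return The modified `summary_stats`.
#' @export
plant_outlier <- function(stats, index, offset) {
  if (length(index) != 1L || is.na(index) || index < 1 ||
      index > nrow(stats)) {
    stop("plant_outlier: index out of range", call. = FALSE)
  }
  stats$beta_outcome[index] <- stats$beta_outcome[index] + offset
  stats
}

#' Write simulated cohort files as plain text
#'
#' Writes `genotypes.tsv` (dosage matrix, header = rsids),
#' `phenotypes.tsv` and `panel.tsv` into `dir`.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$genotypes, file.path(dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$participants, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_snp_panel(cohort$panel, file.path(dir, "panel.tsv"))
  invisible(dir)
}
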