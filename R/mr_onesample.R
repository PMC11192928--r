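# Split-sample one-sample Mendelian randomization: the GRS-exposure
# coefficient is estimated in the measured sub-cohort, the GRS-outcome
# coefficients in the total cohort, and their ratio is the Wald IV
# estimate with a second-order delta-method standard error.

mr_adjustment_matrix <- function(data) {
  pcs <- as.matrix(data[, grep("^PC", names(data)), drop = FALSE])
  b <- stats::model.matrix(~ factor(batch), data = data)[, -1, drop = FALSE]
  cbind(age = data$age, sex = data$sex, b, pcs)
}

#' GRS-exposure association (first stage)
#'
#' Linear regression of the season-standardized biomarker on the score in
#' the sub-cohort, adjusted for age, sex, genotyping batch and 20 ancestry
#' principal components.
#'
#' @param data processed participant table restricted to the sub-cohort.
#' @param grs a `grs_vector` (or numeric score) aligned with `data` rows.
#' @return One-row `assoc_result` for the score coefficient.
#' @export
grs_exposure_assoc <- function(data, grs) {
  s <- grs_score(grs)
  if (stats::var(s, na.rm = TRUE) == 0) {
    stop("grs_exposure_assoc: zero-variance GRS", call. = FALSE)
  }
  xmat <- cbind(grs = s, mr_adjustment_matrix(data))
  r <- fit_linear(data$vitd_std, xmat)
  r[r$term == "grs", ]
}

#' GRS-outcome association (reduced form)
#'
#' Regression of the outcome on the score in the total cohort with the same
#' adjustment set as the first stage: linear for SBP/DBP (amended wave-1
#' values), logistic for hypertension.
#'
#' @param data processed participant table (total cohort).
#' @param grs a `grs_vector` (or numeric score) aligned with `data` rows.
#' @param outcome `"sbp"`, `"dbp"` or `"hypertension"`.
#' @return One-row `assoc_result` for the score coefficient.
#' @export
grs_outcome_assoc <- function(data, grs, outcome = c("sbp", "dbp",
                                                     "hypertension")) {
  outcome <- match.arg(outcome)
  s <- grs_score(grs)
  if (stats::var(s, na.rm = TRUE) == 0) {
    stop("grs_outcome_assoc: zero-variance GRS", call. = FALSE)
  }
  xmat <- cbind(grs = s, mr_adjustment_matrix(data))
  r <- if (outcome == "hypertension") {
    fit_logistic(data$hyper_w1, xmat)
  } else {
    fit_linear(data[[paste0(outcome, "_w1")]], xmat)
  }
  r[r$term == "grs", ]
}

#' Wald-ratio IV estimate
#'
#' The causal effect is the ratio of the reduced-form to the first-stage
#' coefficient, \eqn{\hat\theta = \beta_y / \beta_x}, with the second-order
#' delta-method variance
#' \eqn{se_y^2/\beta_x^2 + \beta_y^2 se_x^2/\beta_x^4}
#' (treating the two coefficient estimates as independent, as in a split
#' sample). With `scale = 25` the estimate, SE and CI are reported per 25
#' units of exposure; for a log-odds numerator the odds ratio
#' `exp(scale * ratio)` is attached.
#'
#' @param assoc_y GRS-outcome `assoc_result` (one row).
#' @param assoc_x GRS-exposure `assoc_result` (one row).
#' @param scale exposure-unit multiple for reporting (default 25 nmol/L).
#' @return A list of class `wald_estimate`: `ratio`, `se`, `ci_low`,
#'   `ci_high`, `p`, `or_scale` (odds-ratio triple when the numerator is a
#'   log-odds), `scale`, `components`.
#' @export
wald_ratio <- function(assoc_y, assoc_x, scale = 25) {
  by <- assoc_y$beta; sy <- assoc_y$se
  bx <- assoc_x$beta; sx <- assoc_x$se
  if (!is.finite(bx) || bx == 0) {
    stop("wald_ratio: weak/degenerate first stage (beta_x = 0)",
         call. = FALSE)
  }
  if (abs(bx) / sx < 1) {
    warning("wald_ratio: first-stage |beta_x|/se_x < 1; ",
            "ratio estimate is unreliable", call. = FALSE)
  }
  ratio <- by / bx
  se <- sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  est <- ratio * scale
  se_s <- se * scale
  out <- list(
    ratio = est, se = se_s,
    ci_low = est - z975 * se_s, ci_high = est + z975 * se_s,
    p = 2 * stats::pnorm(-abs(ratio / se)),
    scale = scale,
    components = c(beta_y = by, se_y = sy, beta_x = bx, se_x = sx)
  )
  if (identical(assoc_y$scale, "log-odds")) {
    out$or_scale <- exp(c(or = est, ci_low = out$ci_low,
                          ci_high = out$ci_high))
  }
  class(out) <- "wald_estimate"
  out
}

#' @export
print.wald_estimate <- function(x, ...) {
  cat(sprintf("Wald ratio: %.3f (95%% CI %.3f to %.3f), p = %.3g, per %g units\n",
              x$ratio, x$ci_low, x$ci_high, x$p, x$scale))
  if (!is.null(x$or_scale)) {
    cat(sprintf("  OR %.3f (95%% CI %.3f to %.3f)\n", x$or_scale[1],
                x$or_scale[2], x$or_scale[3]))
  }
  invisible(x)
}

#' One-sample MR for all three outcomes
#'
#' Convenience wrapper: computes the GRS, runs the first stage in the
#' sub-cohort and the reduced form in the total cohort, and returns
#' per-25-nmol/L Wald estimates for SBP, DBP and hypertension together with
#' instrument diagnostics and the confounder-balance table.
#'
#' @param cohort a `sim_cohort` (or list with `participants`, `genotypes`,
#'   `panel`).
#' @param scale exposure-unit multiple for reporting.
#' @return List with `estimates` (named list of `wald_estimate`),
#'   `diagnostics`, `balance`, `first_stage`, `grs`.
#' @export
mr_onesample <- function(cohort, scale = 25) {
  p <- cohort$participants
  if (!"vitd_std" %in% names(p)) p <- process_phenotypes(p)
  grs <- compute_grs(cohort$genotypes, cohort$panel)
  sub <- p$in_subcohort
  sub_grs <- structure(list(score = grs$score[sub],
                            n_snps_used = grs$n_snps_used,
                            missing_imputed = grs$missing_imputed),
                       class = "grs_vector")
  psub <- p[sub, , drop = FALSE]
  bx <- grs_exposure_assoc(psub, sub_grs)
  diag <- instrument_strength(sub_grs, psub$vitd_std)
  bal <- confounder_balance(sub_grs, data.frame(
    age = psub$age, sex = psub$sex, bmi = psub$bmi,
    smoking = factor(psub$smoking)))
  ests <- list(
    sbp = wald_ratio(grs_outcome_assoc(p, grs, "sbp"), bx, scale),
    dbp = wald_ratio(grs_outcome_assoc(p, grs, "dbp"), bx, scale),
    hypertension = wald_ratio(grs_outcome_assoc(p, grs, "hypertension"),
                              bx, scale)
  )
  list(estimates = ests, diagnostics = diag, balance = bal,
       first_stage = bx, grs = grs)
}
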