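# Observational stages: adjusted linear and logistic regression with Wald
# inference, cross-sectional and prospective result tables in the
# conventional per-25-nmol/L and four-category codings, and a
# restricted-cubic-spline test of non-linearity.

z975 <- stats::qnorm(0.975)

#' Construct an association result
#'
#' A single regression coefficient with its Wald standard error, 95% CI,
#' two-sided p-value and sample size. `scale` records the reporting unit
#' (`"per-unit"`, `"per-25-nmol/L"` or `"log-odds"`).
#'
#' @param beta,se coefficient and standard error.
#' @param n sample size.
#' @param scale reporting-unit label.
#' @param term coefficient name.
#' @return A one-row data.frame of class `assoc_result`.
#' @export
assoc_result <- function(beta, se, n, scale = "per-unit", term = "x") {
  stopifnot(se >= 0)
  out <- data.frame(
    term = term, beta = beta, se = se,
    ci_low = beta - z975 * se, ci_high = beta + z975 * se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    n = n, scale = scale, stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Ordinary least squares with Wald inference
#'
#' Fits OLS of `outcome` on `predictors` (an intercept is added). Collinear
#' columns are dropped with a warning. Returns one association row per
#' retained predictor.
#'
#' @param outcome numeric response.
#' @param predictors numeric design matrix (no intercept column needed).
#' @param scale reporting-unit label attached to the results.
#' @return An `assoc_result` data.frame, one row per predictor.
#' @export
fit_linear <- function(outcome, predictors, scale = "per-unit") {
  predictors <- as.matrix(predictors)
  ok <- is.finite(outcome) & apply(is.finite(predictors), 1, all)
  y <- outcome[ok]
  x <- predictors[ok, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(x) + 1) stop("fit_linear: n too small", call. = FALSE)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    dropped <- sub("^x", "", names(cf)[is.na(cf)])
    warning("fit_linear: dropped collinear column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  keep <- rownames(sm) != "(Intercept)"
  res <- do.call(rbind, lapply(which(keep), function(i) {
    assoc_result(sm[i, 1], sm[i, 2], n, scale,
                 term = sub("^x", "", rownames(sm)[i]))
  }))
  res
}

#' Logistic regression with Wald inference
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`). Coefficients are log-odds; `exp(beta)` is the odds
#' ratio. Complete or quasi-complete separation (diverging coefficients or
#' non-convergence) raises an error.
#'
#' @inheritParams fit_linear
#' @return An `assoc_result` data.frame (scale `"log-odds"`).
#' @export
fit_logistic <- function(outcome, predictors) {
  predictors <- as.matrix(predictors)
  ok <- !is.na(outcome) & apply(is.finite(predictors), 1, all)
  y <- as.integer(outcome[ok])
  x <- predictors[ok, , drop = FALSE]
  n <- length(y)
  if (length(unique(y)) < 2) {
    stop("fit_logistic: outcome has a single class", call. = FALSE)
  }
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  cf <- stats::coef(fit)
  if (!fit$converged || any(abs(cf[-1]) > 15, na.rm = TRUE)) {
    stop("fit_logistic: separation detected (diverging coefficients)",
         call. = FALSE)
  }
  if (anyNA(cf)) {
    warning("fit_logistic: dropped collinear column(s): ",
            paste(sub("^x", "", names(cf)[is.na(cf)]), collapse = ", "),
            call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  keep <- rownames(sm) != "(Intercept)"
  do.call(rbind, lapply(which(keep), function(i) {
    assoc_result(sm[i, 1], sm[i, 2], n, "log-odds",
                 term = sub("^x", "", rownames(sm)[i]))
  }))
}

# Default observational adjustment set.
obs_covariates <- function(data) {
  encode_covariates(data)
}

scale_per25 <- function(row) {
  row$beta <- row$beta * 25
  row$se <- row$se * 25
  row$ci_low <- row$ci_low * 25
  row$ci_high <- row$ci_high * 25
  row$scale <- "per-25-nmol/L"
  row
}

result_row <- function(outcome, exposure, r, or = FALSE, n_override = NULL,
                       reference = FALSE) {
  if (reference) {
    return(data.frame(outcome = outcome, exposure = exposure,
                      n = n_override, estimate = if (or) 1 else 0,
                      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                      scale = if (or) "OR" else "mmHg",
                      reference = TRUE, stringsAsFactors = FALSE))
  }
  est <- if (or) exp(c(r$beta, r$ci_low, r$ci_high)) else
    c(r$beta, r$ci_low, r$ci_high)
  data.frame(outcome = outcome, exposure = exposure,
             n = if (is.null(n_override)) r$n else n_override,
             estimate = est[1], ci_low = est[2], ci_high = est[3], p = r$p,
             scale = if (or) "OR" else "mmHg",
             reference = FALSE, stringsAsFactors = FALSE)
}

run_exposure_models <- function(data, outcome_col, logistic, covars, label) {
  y <- data[[outcome_col]]
  rows <- list()
  # continuous, per 25 nmol/L
  xmat <- cbind(vitd = data$vitd_std, covars)
  r <- if (logistic) fit_logistic(y, xmat) else fit_linear(y, xmat)
  r <- r[r$term == "vitd", ]
  r <- scale_per25(r)
  rows[[1]] <- result_row(label, "per25", r, or = logistic)
  # categorical against the 50-74.9 reference
  vc <- stats::relevel(factor(data$vitd_cat, levels = vitd_levels),
                       ref = "50to74.9")
  cmat <- stats::model.matrix(~ vc)[, -1, drop = FALSE]
  colnames(cmat) <- sub("^vc", "cat_", colnames(cmat))
  rc <- if (logistic) fit_logistic(y, cbind(cmat, covars)) else
    fit_linear(y, cbind(cmat, covars))
  lev_n <- table(vc[!is.na(y)])
  for (lev in vitd_levels) {
    if (lev == "50to74.9") {
      rows[[length(rows) + 1L]] <- result_row(
        label, lev, NULL, or = logistic,
        n_override = unname(lev_n[lev]), reference = TRUE)
    } else {
      ri <- rc[rc$term == paste0("cat_", lev), ]
      if (nrow(ri) == 0) next  # empty category dropped upstream
      rows[[length(rows) + 1L]] <- result_row(
        label, lev, ri, or = logistic, n_override = unname(lev_n[lev]))
    }
  }
  do.call(rbind, rows)
}

#' Cross-sectional observational analysis
#'
#' For SBP and DBP (linear) and hypertension (logistic) in the measured
#' sub-cohort: a continuous per-25-nmol/L estimate and four-category
#' estimates against the 50.0-74.9 nmol/L reference, all adjusted for age,
#' sex, binned BMI, smoking, alcohol, physical activity, education and
#' economic difficulty (with explicit unknown levels).
#'
#' @param data processed participant table restricted to rows with a
#'   measured biomarker (`vitd_std` present).
#' @return Data.frame: `outcome`, `exposure`, `n`, `estimate`, `ci_low`,
#'   `ci_high`, `p`, `scale`, `reference`.
#' @export
cross_sectional_analysis <- function(data) {
  data <- data[is.finite(data$vitd_std), , drop = FALSE]
  covars <- obs_covariates(data)
  rbind(
    run_exposure_models(data, "sbp_w1", FALSE, covars, "SBP"),
    run_exposure_models(data, "dbp_w1", FALSE, covars, "DBP"),
    run_exposure_models(data, "hyper_w1", TRUE, covars, "hypertension")
  )
}

#' Prospective observational analysis
#'
#' Wave-2 outcomes regressed on wave-1 exposure among followed-up
#' participants. The BP models additionally adjust for the baseline
#' (wave-1) value of the same pressure; the hypertension model is incident:
#' restricted to baseline normotensives (see
#' [select_prospective_sample]).
#'
#' @param data processed participant table (both waves).
#' @return Result table in the same layout as [cross_sectional_analysis].
#' @export
prospective_analysis <- function(data) {
  data <- data[is.finite(data$vitd_std), , drop = FALSE]
  followed <- data[data$followed_w2 %in% TRUE, , drop = FALSE]
  if (nrow(followed) == 0) {
    stop("prospective_analysis: no wave-2 data", call. = FALSE)
  }
  covars_f <- obs_covariates(followed)
  out <- list()
  for (bp in c("sbp", "dbp")) {
    followed2 <- followed
    covb <- cbind(covars_f, baseline = followed[[paste0(bp, "_w1")]])
    y <- followed[[paste0(bp, "_w2")]]
    lab <- toupper(bp)
    rows <- run_exposure_models_custom(followed2, y, FALSE, covb, lab)
    out[[bp]] <- rows
  }
  normo <- suppressMessages(select_prospective_sample(data))
  covn <- obs_covariates(normo)
  out$hyp <- run_exposure_models_custom(normo, normo$hyper_w2, TRUE, covn,
                                        "hypertension")
  do.call(rbind, out)
}

# Same as run_exposure_models but with an explicit outcome vector (used for
# the baseline-adjusted prospective models).
run_exposure_models_custom <- function(data, y, logistic, covars, label) {
  data$.tmp_out <- y
  run_exposure_models(data, ".tmp_out", logistic, covars, label)
}

#' Restricted cubic spline basis
#'
#' Harrell-style natural cubic spline basis: the linear term plus
#' `length(knots) - 2` non-linear terms, each normalized by the squared
#' knot span so coefficients stay on the scale of the linear term.
#'
#' @param x numeric vector.
#' @param knots knot locations (ascending).
#' @return Matrix with `length(knots) - 1` columns; column 1 is `x`.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  stopifnot(k >= 3)
  tk <- knots[k]; tk1 <- knots[k - 1]
  norm <- (knots[k] - knots[1])^2
  pp <- function(u) pmax(u, 0)^3
  nl <- sapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (pp(x - tj) - pp(x - tk1) * (tk - tj) / (tk - tk1) +
       pp(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  })
  cbind(x, nl)
}

rcs_default_quantiles <- list(
  `3` = c(0.10, 0.50, 0.90),
  `4` = c(0.05, 0.35, 0.65, 0.95),
  `5` = c(0.05, 0.275, 0.50, 0.725, 0.95)
)

#' Restricted-cubic-spline non-linearity test
#'
#' Fits the outcome on an RCS expansion of the exposure plus covariates and
#' Wald-tests the joint nullity of the non-linear spline terms. Knots are
#' placed at conventional quantiles (4 knots: 5/35/65/95 percentiles).
#'
#' @param outcome numeric (linear) or 0/1 (logistic) response.
#' @param exposure continuous exposure.
#' @param covariates optional design matrix of adjustment covariates.
#' @param n_knots 3, 4 or 5.
#' @param logistic fit a logistic model instead of OLS.
#' @return The two-sided p-value of the joint Wald test (chi-square with
#'   `n_knots - 2` df).
#' @export
rcs_nonlinearity_test <- function(outcome, exposure, covariates = NULL,
                                  n_knots = 4, logistic = FALSE) {
  if (!n_knots %in% 3:5) {
    stop("rcs_nonlinearity_test: n_knots must be 3, 4 or 5", call. = FALSE)
  }
  ok <- is.finite(exposure) & !is.na(outcome)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & apply(is.finite(covariates), 1, all)
  }
  x <- exposure[ok]; y <- outcome[ok]
  if (length(unique(x)) < 3 * n_knots) {
    stop("rcs_nonlinearity_test: too few unique exposure values",
         call. = FALSE)
  }
  knots <- unname(stats::quantile(x, rcs_default_quantiles[[as.character(n_knots)]]))
  basis <- rcs_basis(x, knots)
  colnames(basis) <- c("lin", paste0("nl", seq_len(ncol(basis) - 1)))
  xmat <- if (is.null(covariates)) basis else
    cbind(basis, covariates[ok, , drop = FALSE])
  fit <- if (logistic) {
    stats::glm(y ~ xmat, family = stats::binomial())
  } else {
    stats::lm(y ~ xmat)
  }
  idx <- grep("nl", names(stats::coef(fit)))
  b <- stats::coef(fit)[idx]
  V <- stats::vcov(fit)[idx, idx, drop = FALSE]
  W <- drop(t(b) %*% solve(V, b))
  stats::pchisq(W, df = length(idx), lower.tail = FALSE)
}
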