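# Non-linear Mendelian randomization: residual and doubly-ranked
# stratification of the sample, stratum-specific Wald IV estimates, and
# heterogeneity/trend tests of non-linearity across strata.

# Equal-size bin assignment from a rank order: lower strata absorb the
# remainder, so sizes differ by at most one.
rank_bins <- function(ord, k) {
  n <- length(ord)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  assignment <- integer(n)
  assignment[ord] <- rep(seq_len(k), sizes)
  assignment
}

#' Residual-method stratification
#'
#' Regresses the exposure on the instrument, and stratifies on the
#' residual exposure (the part not explained by the instrument) into `k`
#' equal-size quantile bins. Valid under the assumption of a constant
#' genetic effect on the exposure within each stratum.
#'
#' @param iv instrument values (a `grs_vector` or numeric).
#' @param exposure exposure series.
#' @param k number of strata (>= 2).
#' @return Integer vector of stratum indices `1..k` (1 = lowest residual).
#' @export
residual_stratify <- function(iv, exposure, k) {
  s <- grs_score(iv)
  n <- length(s)
  if (k < 2) stop("residual_stratify: k must be >= 2", call. = FALSE)
  if (n < 10 * k) {
    stop("residual_stratify: need n >= 10 * k", call. = FALSE)
  }
  if (stats::var(s) == 0) {
    stop("residual_stratify: zero IV variance", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, s), exposure)
  resid <- exposure - cbind(1, s) %*% fit$coefficients
  ord <- order(resid)                      # stable for ties
  rank_bins(ord, k)
}

#' Doubly-ranked stratification
#'
#' Non-parametric stratification that is less sensitive to the
#' constant-genetic-effect assumption: participants are ranked by the
#' instrument and grouped into consecutive pre-strata of size `k`; within
#' each pre-stratum they are ranked by exposure, and the `j`-th
#' exposure-ranked member of every pre-stratum joins stratum `j`. Members
#' of a final partial pre-stratum (when `n mod k != 0`) are assigned to
#' strata `1, 2, ...` in exposure-rank order. IV ties are broken by
#' original order.
#'
#' @inheritParams residual_stratify
#' @return Integer vector of stratum indices `1..k`.
#' @export
doubly_ranked_stratify <- function(iv, exposure, k) {
  s <- grs_score(iv)
  n <- length(s)
  if (k < 1) stop("doubly_ranked_stratify: k must be >= 1", call. = FALSE)
  if (k == 1) return(rep(1L, n))
  if (n < k^2) {
    warning("doubly_ranked_stratify: n < k^2, strata may be unstable",
            call. = FALSE)
  }
  iv_ord <- order(s)                       # stable: ties by original order
  assignment <- integer(n)
  n_pre <- ceiling(n / k)
  for (b in seq_len(n_pre)) {
    idx <- iv_ord[((b - 1) * k + 1):min(b * k, n)]
    strata <- order(exposure[idx])
    assignment[idx[strata]] <- seq_along(idx)
  }
  assignment
}

#' Per-stratum Wald IV estimates
#'
#' Within each stratum, runs the GRS-exposure and GRS-outcome regressions
#' (adjusted for age and sex) and forms the stratum Wald ratio with the
#' same delta-method SE as the global one-sample MR.
#'
#' @param assignment stratum index per participant (from
#'   [residual_stratify] or [doubly_ranked_stratify]).
#' @param data processed participant table aligned with `assignment`
#'   (needs `vitd_std`, the outcome column, `age`, `sex`).
#' @param grs instrument values aligned with `data` rows.
#' @param outcome `"sbp"`, `"dbp"` or `"hypertension"`.
#' @param scale exposure-unit multiple for reporting (default 25).
#' @param min_size smallest admissible stratum (default 20).
#' @return Data.frame of class `stratum_estimates`: one row per stratum
#'   with `stratum`, `n`, `exposure_mean`, `exposure_lo`, `exposure_hi`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `p`, `f_stat`, `ok`.
#' @export
stratum_estimates <- function(assignment, data, grs,
                              outcome = c("sbp", "dbp", "hypertension"),
                              scale = 25, min_size = 20) {
  outcome <- match.arg(outcome)
  s <- grs_score(grs)
  ycol <- if (outcome == "hypertension") "hyper_w1" else
    paste0(outcome, "_w1")
  rows <- lapply(sort(unique(assignment)), function(st) {
    in_st <- assignment == st
    n_st <- sum(in_st)
    if (n_st < min_size) {
      stop("stratum_estimates: stratum ", st, " has fewer than ", min_size,
           " members", call. = FALSE)
    }
    d <- data[in_st, , drop = FALSE]
    sv <- s[in_st]
    base <- data.frame(stratum = st, n = n_st,
                       exposure_mean = mean(d$vitd_std, na.rm = TRUE),
                       exposure_lo = min(d$vitd_std, na.rm = TRUE),
                       exposure_hi = max(d$vitd_std, na.rm = TRUE))
    if (stats::var(sv) == 0) {
      warning("stratum_estimates: zero IV variance in stratum ", st,
              "; estimate withheld", call. = FALSE)
      return(cbind(base, beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, p = NA_real_, f_stat = NA_real_,
                   ok = FALSE))
    }
    adj <- cbind(age = d$age, sex = d$sex)
    bx <- fit_linear(d$vitd_std, cbind(grs = sv, adj))
    bx <- bx[bx$term == "grs", ]
    by <- if (outcome == "hypertension") {
      fit_logistic(d[[ycol]], cbind(grs = sv, adj))
    } else {
      fit_linear(d[[ycol]], cbind(grs = sv, adj))
    }
    by <- by[by$term == "grs", ]
    f <- instrument_strength(sv, d$vitd_std)
    wr <- tryCatch(suppressWarnings(wald_ratio(by, bx, scale = scale)),
                   error = function(e) NULL)
    if (is.null(wr)) {
      warning("stratum_estimates: degenerate first stage in stratum ", st,
              "; estimate withheld", call. = FALSE)
      return(cbind(base, beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, p = NA_real_, f_stat = f$f_stat,
                   ok = FALSE))
    }
    cbind(base, beta = wr$ratio, se = wr$se, ci_low = wr$ci_low,
          ci_high = wr$ci_high, p = wr$p, f_stat = f$f_stat, ok = TRUE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stratum_estimates", "data.frame")
  out
}

#' Non-linearity tests across stratum estimates
#'
#' Two complementary statistics: Cochran's Q over the stratum IV estimates
#' (heterogeneity of any form) and an inverse-variance-weighted
#' meta-regression of the stratum estimates on the stratum exposure means
#' (a monotone trend in the causal effect). Both p-values are uniform when
#' the causal dose-response is linear.
#'
#' @param estimates a `stratum_estimates` table with at least 3 usable
#'   strata.
#' @return List `(q_stat, q_p, trend_beta, trend_se, trend_p)`.
#' @export
stratum_nonlinearity_test <- function(estimates) {
  e <- estimates[estimates$ok %in% TRUE & is.finite(estimates$se), ,
                 drop = FALSE]
  k <- nrow(e)
  if (k < 3) {
    stop("stratum_nonlinearity_test: need >= 3 usable strata", call. = FALSE)
  }
  w <- 1 / e$se^2
  pooled <- sum(w * e$beta) / sum(w)
  q <- sum(w * (e$beta - pooled)^2)
  q_p <- stats::pchisq(q, k - 1, lower.tail = FALSE)

  # IVW meta-regression of stratum estimate on stratum exposure mean.
  x <- e$exposure_mean
  xw <- sum(w * x) / sum(w)
  sxx <- sum(w * (x - xw)^2)
  slope <- sum(w * (x - xw) * e$beta) / sxx
  slope_se <- sqrt(1 / sxx)
  trend_p <- 2 * stats::pnorm(-abs(slope / slope_se))
  list(q_stat = q, q_p = q_p, trend_beta = slope, trend_se = slope_se,
       trend_p = trend_p)
}

#' Non-linear one-sample MR for a cohort
#'
#' Stratifies the measured sub-cohort by the chosen method, computes
#' per-stratum Wald estimates and the non-linearity tests.
#'
#' @param cohort a `sim_cohort`.
#' @param method `"residual"` or `"doubly-ranked"`.
#' @param k number of strata (default 4).
#' @param outcome `"sbp"`, `"dbp"` or `"hypertension"`.
#' @param scale exposure-unit multiple for reporting.
#' @return List with `estimates` (a `stratum_estimates` table), `tests`
#'   (from [stratum_nonlinearity_test]), `method`, `k`.
#' @export
nlmr_onesample <- function(cohort, method = c("residual", "doubly-ranked"),
                           k = 4, outcome = "sbp", scale = 25) {
  method <- match.arg(method)
  p <- cohort$participants
  if (!"vitd_std" %in% names(p)) p <- process_phenotypes(p)
  sub <- which(p$in_subcohort & is.finite(p$vitd_std))
  d <- p[sub, , drop = FALSE]
  grs <- compute_grs(cohort$genotypes[sub, , drop = FALSE], cohort$panel)
  assignment <- if (method == "residual") {
    residual_stratify(grs, d$vitd_std, k)
  } else {
    doubly_ranked_stratify(grs, d$vitd_std, k)
  }
  est <- stratum_estimates(assignment, d, grs, outcome = outcome,
                           scale = scale)
  list(estimates = est, tests = stratum_nonlinearity_test(est),
       method = method, k = k)
}
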