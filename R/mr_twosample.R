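# Summary-statistics two-sample Mendelian randomization, implemented from
# first principles: allele harmonization, inverse-variance weighted (IVW)
# estimation, MR-Egger regression, the weighted median estimator,
# Cochran's Q heterogeneity test, and MR-PRESSO outlier detection.

#' Construct a per-SNP summary-statistic set
#'
#' One row per SNP with exposure and outcome effect estimates on the same
#' effect allele. rsids must be unique and all standard errors positive.
#'
#' @param rsid,effect_allele,other_allele,eaf SNP metadata.
#' @param beta_exposure,se_exposure per-allele exposure effect and SE.
#' @param beta_outcome,se_outcome per-allele outcome effect and SE.
#' @return Data.frame of class `summary_stats`.
#' @export
summary_stats <- function(rsid, effect_allele, other_allele, eaf,
                          beta_exposure, se_exposure,
                          beta_outcome, se_outcome) {
  out <- data.frame(rsid = as.character(rsid),
                    effect_allele = toupper(effect_allele),
                    other_allele = toupper(other_allele),
                    eaf = eaf,
                    beta_exposure = beta_exposure,
                    se_exposure = se_exposure,
                    beta_outcome = beta_outcome,
                    se_outcome = se_outcome,
                    stringsAsFactors = FALSE)
  validate_summary_stats(out)
}

validate_summary_stats <- function(stats) {
  if (anyDuplicated(stats$rsid)) {
    stop("summary_stats: duplicate rsids", call. = FALSE)
  }
  if (any(stats$se_exposure <= 0) || any(stats$se_outcome <= 0)) {
    stop("summary_stats: all standard errors must be > 0", call. = FALSE)
  }
  class(stats) <- c("summary_stats", "data.frame")
  stats
}

#' Read / write summary statistics as TSV
#' @param path file path.
#' @return `read_summary_stats` returns a `summary_stats` data.frame.
#' @export
read_summary_stats <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  do.call(summary_stats, tab[c("rsid", "effect_allele", "other_allele",
                               "eaf", "beta_exposure", "se_exposure",
                               "beta_outcome", "se_outcome")])
}

#' @rdname read_summary_stats
#' @param stats a `summary_stats` data.frame.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

flip_allele <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]

is_palindromic <- function(ea, oa) flip_allele(ea) == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects two per-SNP tables on rsid and aligns the outcome effects to
#' the exposure effect allele: swapped alleles flip the outcome beta sign
#' and frequency; strand flips are recognized via allele complements;
#' palindromic SNPs (A/T, C/G) are dropped when the effect-allele frequency
#' is in `[0.42, 0.58]` (strand unresolvable) and otherwise aligned by
#' frequency; irreconcilable allele pairs are dropped. Every action is
#' recorded in the `harmonization_log` attribute.
#'
#' @param exposure data.frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, `eaf` and `beta`/`se` (or
#'   `beta_exposure`/`se_exposure`).
#' @param outcome same layout for the outcome GWAS (`beta`/`se` or
#'   `beta_outcome`/`se_outcome`).
#' @param palindromic_window frequency window within which palindromic SNPs
#'   are dropped.
#' @return A `summary_stats` set aligned to the exposure effect alleles.
#' @export
harmonize <- function(exposure, outcome, palindromic_window = c(0.42, 0.58)) {
  get_cols <- function(d, which) {
    b <- if ("beta" %in% names(d)) d$beta else d[[paste0("beta_", which)]]
    s <- if ("se" %in% names(d)) d$se else d[[paste0("se_", which)]]
    data.frame(rsid = d$rsid, effect_allele = toupper(d$effect_allele),
               other_allele = toupper(d$other_allele), eaf = d$eaf,
               beta = b, se = s, stringsAsFactors = FALSE)
  }
  ex <- get_cols(exposure, "exposure")
  ou <- get_cols(outcome, "outcome")
  common <- intersect(ex$rsid, ou$rsid)
  if (length(common) < 2) {
    stop("harmonize: fewer than 2 overlapping rsids", call. = FALSE)
  }
  ex <- ex[match(common, ex$rsid), ]
  ou <- ou[match(common, ou$rsid), ]

  log <- character(length(common))
  keep <- rep(TRUE, length(common))
  beta_y <- ou$beta

  for (i in seq_along(common)) {
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    yea <- ou$effect_allele[i]; yoa <- ou$other_allele[i]
    if (is_palindromic(ea, oa)) {
      if (!(yea %in% c(ea, oa)) || !(yoa %in% c(ea, oa))) {
        keep[i] <- FALSE; log[i] <- "dropped: allele mismatch"
        next
      }
      if (ex$eaf[i] >= palindromic_window[1] &&
          ex$eaf[i] <= palindromic_window[2]) {
        keep[i] <- FALSE
        log[i] <- "dropped: palindromic with ambiguous frequency"
        next
      }
      # Align by frequency: same side of 0.5 means same allele is measured.
      same_side <- (ex$eaf[i] - 0.5) * (ou$eaf[i] - 0.5) >= 0
      if (!same_side) {
        beta_y[i] <- -beta_y[i]
        log[i] <- "palindromic: flipped by frequency"
      } else {
        log[i] <- "palindromic: aligned by frequency"
      }
    } else if (yea == ea && yoa == oa) {
      log[i] <- "aligned"
    } else if (yea == oa && yoa == ea) {
      beta_y[i] <- -beta_y[i]
      log[i] <- "flipped: swapped alleles"
    } else if (yea == flip_allele(ea) && yoa == flip_allele(oa)) {
      log[i] <- "aligned: strand flip"
    } else if (yea == flip_allele(oa) && yoa == flip_allele(ea)) {
      beta_y[i] <- -beta_y[i]
      log[i] <- "flipped: strand flip + swapped alleles"
    } else {
      keep[i] <- FALSE
      log[i] <- "dropped: allele mismatch"
    }
  }
  if (any(!keep)) {
    warning("harmonize: dropped ", sum(!keep), " SNP(s): ",
            paste(common[!keep], collapse = ", "), call. = FALSE)
  }
  if (!any(keep)) stop("harmonize: no SNPs survive harmonization",
                       call. = FALSE)
  out <- summary_stats(ex$rsid[keep], ex$effect_allele[keep],
                       ex$other_allele[keep], ex$eaf[keep],
                       ex$beta[keep], ex$se[keep],
                       beta_y[keep], ou$se[keep])
  attr(out, "harmonization_log") <-
    data.frame(rsid = common, action = log, kept = keep,
               stringsAsFactors = FALSE)
  out
}

two_sample_result <- function(method, beta, se, n_snps, p = NULL, ...) {
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(beta / se))
  structure(c(list(method = method, beta = beta, se = se,
                   ci_low = beta - z975 * se, ci_high = beta + z975 * se,
                   p = p, n_snps = n_snps), list(...)),
            class = "two_sample_result")
}

#' @export
print.two_sample_result <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (95%% CI %.4f to %.4f), p = %.3g, %d SNPs\n",
              x$method, x$beta, x$ci_low, x$ci_high, x$p, x$n_snps))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4f, p = %.3g\n", x$intercept, x$intercept_p))
  }
  if (!is.null(x$q_stat)) {
    cat(sprintf("  Cochran's Q = %.2f (df %d), p = %.3g\n", x$q_stat,
                x$q_df, x$q_p))
  }
  if (!is.null(x$outliers)) {
    cat("  outliers:", if (length(x$outliers)) paste(x$outliers, collapse = ", ")
        else "none", "\n")
  }
  invisible(x)
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of the outcome effects on the exposure effects
#' through the origin with weights \eqn{1/se_y^2}:
#' \eqn{\hat\beta = \sum w \beta_x \beta_y / \sum w \beta_x^2}. Under the
#' multiplicative random-effects model (default) the SE is inflated by
#' \eqn{\max(1, \sqrt{Q/(m-1)})}. Cochran's Q against the IVW estimate is
#' attached. A single SNP falls back to its Wald ratio with a warning.
#'
#' @param stats a `summary_stats` set.
#' @param model `"random"` (multiplicative random effects) or `"fixed"`.
#' @return A `two_sample_result` with fields `q_stat`, `q_df`, `q_p`.
#' @export
mr_ivw <- function(stats, model = c("random", "fixed")) {
  model <- match.arg(model)
  stats <- validate_summary_stats(stats)
  m <- nrow(stats)
  if (m < 1) stop("mr_ivw: empty summary set", call. = FALSE)
  bx <- stats$beta_exposure; by <- stats$beta_outcome
  w <- 1 / stats$se_outcome^2
  if (m == 1) {
    warning("mr_ivw: single SNP, falling back to the Wald ratio",
            call. = FALSE)
    beta <- by / bx
    se <- stats$se_outcome / abs(bx)
    return(two_sample_result("IVW (Wald ratio)", beta, se, 1L))
  }
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  q <- sum(w * (by - beta * bx)^2)
  se <- if (model == "random") {
    se_fixed * max(1, sqrt(q / (m - 1)))
  } else {
    se_fixed
  }
  two_sample_result(paste0("IVW (", model, ")"), beta, se, m,
                    q_stat = q, q_df = m - 1L,
                    q_p = stats::pchisq(q, m - 1, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of the outcome effects on the exposure effects with
#' an intercept, after orienting all exposure effects positive. The slope
#' is the causal estimate under the InSIDE assumption; a non-zero intercept
#' indicates directional pleiotropy. Standard errors use the multiplicative
#' overdispersion factor `max(1, sigma)` and t inference with `m - 2` df.
#'
#' @param stats a `summary_stats` set with at least 3 SNPs.
#' @return A `two_sample_result` with fields `intercept`, `intercept_se`,
#'   `intercept_p`.
#' @export
mr_egger <- function(stats) {
  stats <- validate_summary_stats(stats)
  m <- nrow(stats)
  if (m < 3) stop("mr_egger: need at least 3 SNPs", call. = FALSE)
  flip <- sign(stats$beta_exposure)
  flip[flip == 0] <- 1
  bx <- stats$beta_exposure * flip
  by <- stats$beta_outcome * flip
  w <- 1 / stats$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  infl <- max(1, sm$sigma)
  cf <- sm$coefficients
  slope <- cf["bx", 1]
  slope_se <- cf["bx", 2] / sm$sigma * infl
  int <- cf["(Intercept)", 1]
  int_se <- cf["(Intercept)", 2] / sm$sigma * infl
  p_t <- function(b, s) 2 * stats::pt(-abs(b / s), df = m - 2)
  two_sample_result("MR-Egger", slope, slope_se, m, p = p_t(slope, slope_se),
                    intercept = int, intercept_se = int_se,
                    intercept_p = p_t(int, int_se))
}

# Weighted median of ratios r with normalized weights w, by interpolation
# of the mid-cumulative weights across sorted ratios.
weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  j <- max(which(s < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted median estimator
#'
#' Per-SNP Wald ratios \eqn{r_j = \beta_y/\beta_x} with inverse-variance
#' weights \eqn{w_j = (\beta_x/se_y)^2}; the estimate is the weighted
#' median obtained by interpolating the cumulative weight function at 0.5.
#' Consistent when at least half the total weight comes from valid
#' instruments. The SE comes from a seeded parametric bootstrap over the
#' summary-statistic sampling errors.
#'
#' @param stats a `summary_stats` set with at least 3 SNPs.
#' @param n_boot bootstrap draws for the SE (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return A `two_sample_result`.
#' @export
mr_weighted_median <- function(stats, n_boot = 1000, seed = 42L) {
  stats <- validate_summary_stats(stats)
  m <- nrow(stats)
  if (m < 3) stop("mr_weighted_median: need at least 3 SNPs", call. = FALSE)
  r <- stats$beta_outcome / stats$beta_exposure
  w <- (stats$beta_exposure / stats$se_outcome)^2
  beta <- weighted_median_point(r, w)
  se <- with_seed(seed, {
    draws <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(m, stats$beta_exposure, stats$se_exposure)
      by <- stats::rnorm(m, stats$beta_outcome, stats$se_outcome)
      weighted_median_point(by / bx, (bx / stats$se_outcome)^2)
    }, numeric(1))
    stats::sd(draws)
  })
  two_sample_result("Weighted median", beta, se, m)
}

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_j w_j (r_j - \hat\beta)^2} over per-SNP Wald ratios with
#' first-order weights \eqn{w_j = \beta_x^2 / se_y^2}, referred to a
#' chi-square distribution with `m - 1` degrees of freedom.
#'
#' @param stats a `summary_stats` set with at least 2 SNPs.
#' @param estimate the causal estimate the ratios are compared against
#'   (default: the fixed-effects IVW estimate).
#' @return List `(q, df, p)`.
#' @export
cochran_q <- function(stats, estimate = NULL) {
  stats <- validate_summary_stats(stats)
  m <- nrow(stats)
  if (m < 2) stop("cochran_q: need at least 2 SNPs", call. = FALSE)
  if (is.null(estimate)) estimate <- mr_ivw(stats, model = "fixed")$beta
  r <- stats$beta_outcome / stats$beta_exposure
  w <- stats$beta_exposure^2 / stats$se_outcome^2
  q <- sum(w * (r - estimate)^2)
  list(q = q, df = m - 1L,
       p = stats::pchisq(q, m - 1, lower.tail = FALSE))
}

ivw_point <- function(bx, by, w) sum(w * bx * by) / sum(w * bx^2)

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Global test: the observed weighted residual sum of squares of
#' leave-one-out IVW predictions is compared with its parametric-bootstrap
#' null (SNP effects redrawn from their sampling distributions around the
#' leave-one-out fitted line). Outlier test: each SNP's observed weighted
#' squared residual is compared with its simulated distribution, with
#' Bonferroni correction across SNPs. The outlier-corrected estimate is the
#' IVW estimate on the non-outlying SNPs; the distortion test compares the
#' observed raw-vs-corrected shift against shifts from removing random SNP
#' subsets of the same size.
#'
#' @param stats a `summary_stats` set with at least 4 SNPs.
#' @param n_sim parametric simulations (>= 100; default 1000).
#' @param seed integer seed.
#' @param alpha outlier significance level after Bonferroni correction.
#' @param model IVW model used for raw/corrected estimates.
#' @return A `two_sample_result` for the outlier-corrected estimate, with
#'   fields `global_rss`, `global_p`, `outliers`, `outlier_p` (named,
#'   Bonferroni-adjusted), `distortion_p`, `raw` (the all-SNP IVW result).
#' @export
mr_presso <- function(stats, n_sim = 1000, seed = 7L, alpha = 0.05,
                      model = "random") {
  stats <- validate_summary_stats(stats)
  m <- nrow(stats)
  if (m < 4) stop("mr_presso: need at least 4 SNPs", call. = FALSE)
  if (n_sim < 100) stop("mr_presso: n_sim must be >= 100", call. = FALSE)
  bx <- stats$beta_exposure; by <- stats$beta_outcome
  sx <- stats$se_exposure; sy <- stats$se_outcome
  w <- 1 / sy^2

  loo <- function(bx, by, w) {
    s1 <- sum(w * bx * by); s2 <- sum(w * bx^2)
    (s1 - w * bx * by) / (s2 - w * bx^2)
  }
  b_loo <- loo(bx, by, w)
  res2_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(res2_obs)

  sim <- with_seed(seed, {
    res2_sim <- matrix(NA_real_, n_sim, m)
    for (i in seq_len(n_sim)) {
      bxs <- stats::rnorm(m, bx, sx)
      bys <- stats::rnorm(m, b_loo * bx, sy)
      bls <- loo(bxs, bys, w)
      res2_sim[i, ] <- w * (bys - bls * bxs)^2
    }
    res2_sim
  })
  rss_sim <- rowSums(sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  outlier_p_raw <- (1 + colSums(sweep(sim, 2, res2_obs, `>=`))) / (n_sim + 1)
  outlier_p <- pmin(1, outlier_p_raw * m)
  names(outlier_p) <- stats$rsid
  is_out <- outlier_p < alpha
  outliers <- stats$rsid[is_out]

  raw <- mr_ivw(stats, model = model)
  corrected <- if (any(is_out)) {
    mr_ivw(stats[!is_out, , drop = FALSE], model = model)
  } else {
    raw
  }

  distortion_p <- NA_real_
  if (any(is_out) && sum(!is_out) >= 2) {
    d_obs <- (raw$beta - corrected$beta) / abs(corrected$beta)
    d_sim <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(i) {
        drop_idx <- sample.int(m, sum(is_out))
        b_s <- ivw_point(bx[-drop_idx], by[-drop_idx], w[-drop_idx])
        (raw$beta - b_s) / abs(b_s)
      }, numeric(1))
    })
    distortion_p <- mean(abs(d_sim) >= abs(d_obs))
  }

  res <- unclass(corrected)
  res$method <- "MR-PRESSO (outlier-corrected)"
  res$global_rss <- rss_obs
  res$global_p <- global_p
  res$outliers <- outliers
  res$outlier_p <- outlier_p
  res$distortion_p <- distortion_p
  res$raw <- raw
  structure(res, class = "two_sample_result")
}

#' Run all two-sample MR estimators
#'
#' @param stats a harmonized `summary_stats` set.
#' @param ivw_model `"random"` or `"fixed"`.
#' @param n_boot weighted-median bootstrap draws.
#' @param presso_sims MR-PRESSO simulations.
#' @param seed integer seed for the stochastic components.
#' @return Named list of `two_sample_result` objects
#'   (`ivw`, `egger`, `weighted_median`, `presso` when >= 4 SNPs).
#' @export
mr_twosample_all <- function(stats, ivw_model = "random", n_boot = 1000,
                             presso_sims = 1000, seed = 42L) {
  out <- list(
    ivw = mr_ivw(stats, model = ivw_model),
    egger = mr_egger(stats),
    weighted_median = mr_weighted_median(stats, n_boot = n_boot, seed = seed)
  )
  if (nrow(stats) >= 4) {
    out$presso <- mr_presso(stats, n_sim = presso_sims, seed = seed + 1L)
  }
  out
}
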