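# Externally weighted genetic risk score and instrument diagnostics
# (relevance and independence assumption checks).

#' Compute the externally weighted genetic risk score
#'
#' The score is the weighted sum of effect-allele dosages,
#' \eqn{G_i = \sum_j w_j g_{ij}}, with external weights taken from the
#' panel. Panel SNPs absent from the genotype matrix are dropped with a
#' warning (weights are not rescaled); missing dosages are imputed by their
#' Hardy-Weinberg expectation `2 * eaf`.
#'
#' @param genotypes dosage matrix with columns named by rsid, entries in
#'   `[0, 2]` or `NA`.
#' @param panel a [snp_panel].
#' @return A list of class `grs_vector`: `score` (numeric per participant),
#'   `n_snps_used`, `missing_imputed`.
#' @export
compute_grs <- function(genotypes, panel) {
  panel <- validate_snp_panel(panel)
  present <- panel$rsid %in% colnames(genotypes)
  if (!any(present)) {
    stop("compute_grs: no panel SNP present in genotypes", call. = FALSE)
  }
  if (any(!present)) {
    warning("compute_grs: ", sum(!present), " panel SNP(s) absent from ",
            "genotypes, dropped: ",
            paste(panel$rsid[!present], collapse = ", "), call. = FALSE)
    panel <- panel[present, , drop = FALSE]
  }
  g <- genotypes[, panel$rsid, drop = FALSE]
  obs <- g[!is.na(g)]
  if (length(obs) && (min(obs) < 0 || max(obs) > 2)) {
    stop("compute_grs: dosages outside [0, 2]", call. = FALSE)
  }
  n_imputed <- sum(is.na(g))
  if (n_imputed > 0) {
    for (j in seq_len(ncol(g))) {
      miss <- is.na(g[, j])
      if (any(miss)) g[miss, j] <- 2 * panel$eaf[j]
    }
  }
  structure(list(score = as.numeric(g %*% panel$weight),
                 n_snps_used = nrow(panel),
                 missing_imputed = n_imputed),
            class = "grs_vector")
}

grs_score <- function(grs) {
  if (inherits(grs, "grs_vector")) grs$score else as.numeric(grs)
}

#' Instrument strength diagnostics (relevance assumption)
#'
#' Simple linear regression of the exposure on the score yields the
#' variance explained \eqn{R^2} and the first-stage
#' \eqn{F = (n-2) R^2 / (1 - R^2)}. An F statistic above 10 is the
#' conventional threshold for an adequate instrument; `weak = TRUE` flags
#' scores at or below it.
#'
#' @param grs a `grs_vector` (or numeric score).
#' @param exposure biomarker series (nmol/L); pairs with missing values are
#'   dropped.
#' @return A list of class `instrument_diagnostics`: `f_stat`, `r2`, `n`,
#'   `weak`.
#' @export
instrument_strength <- function(grs, exposure) {
  s <- grs_score(grs)
  ok <- is.finite(s) & is.finite(exposure)
  s <- s[ok]; x <- exposure[ok]
  n <- length(s)
  if (n < 10) stop("instrument_strength: need n >= 10", call. = FALSE)
  if (stats::var(s) == 0) {
    stop("instrument_strength: zero score variance", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("instrument_strength: zero exposure variance", call. = FALSE)
  }
  r2 <- stats::cor(s, x)^2
  f <- (n - 2) * r2 / (1 - r2)
  structure(list(f_stat = f, r2 = r2, n = n, weak = f <= 10),
            class = "instrument_diagnostics")
}

#' @export
print.instrument_diagnostics <- function(x, ...) {
  cat(sprintf("First-stage F = %.1f, R^2 = %.4f, n = %d%s\n", x$f_stat,
              x$r2, x$n, if (x$weak) "  [WEAK: F <= 10]" else ""))
  invisible(x)
}

#' GRS-confounder balance table (independence assumption)
#'
#' Regresses each available confounder on the score: linear regression for
#' continuous confounders, logistic for binary ones, and one-vs-rest
#' logistic per level for categorical ones. Under a valid instrument the
#' resulting p-values are uniform.
#'
#' @param grs a `grs_vector` (or numeric score).
#' @param covariates data.frame of confounders (numeric, binary or factor
#'   columns).
#' @return Data.frame with one row per tested confounder (or level):
#'   `confounder`, `beta`, `se`, `p`, `n`, `type`.
#' @export
confounder_balance <- function(grs, covariates) {
  s <- grs_score(grs)
  if (stats::var(s, na.rm = TRUE) == 0) {
    stop("confounder_balance: zero-variance GRS", call. = FALSE)
  }
  rows <- list()
  add_row <- function(name, fit_beta, fit_se, n, type) {
    z <- fit_beta / fit_se
    rows[[length(rows) + 1L]] <<- data.frame(
      confounder = name, beta = fit_beta, se = fit_se,
      p = 2 * stats::pnorm(-abs(z)), n = n, type = type,
      stringsAsFactors = FALSE)
  }
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    ok <- is.finite(s) & !is.na(v)
    if (length(unique(v[ok])) < 2) {
      warning("confounder_balance: '", nm, "' is constant, skipped",
              call. = FALSE)
      next
    }
    if (is.numeric(v) && length(unique(v[ok])) > 2) {
      fit <- stats::lm(v[ok] ~ s[ok])
      cf <- summary(fit)$coefficients
      add_row(nm, cf[2, 1], cf[2, 2], sum(ok), "linear")
    } else if (is.numeric(v) || is.logical(v)) {
      fit <- stats::glm(as.integer(v[ok]) ~ s[ok], family = stats::binomial())
      cf <- summary(fit)$coefficients
      add_row(nm, cf[2, 1], cf[2, 2], sum(ok), "logistic")
    } else {
      f <- factor(v[ok])
      for (lev in levels(f)) {
        fit <- stats::glm(I(f == lev) ~ s[ok], family = stats::binomial())
        cf <- summary(fit)$coefficients
        add_row(paste0(nm, ":", lev), cf[2, 1], cf[2, 2], sum(ok),
                "logistic-ovr")
      }
    }
  }
  do.call(rbind, rows)
}
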