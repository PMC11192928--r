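# Independent oracles and small fixtures used across the suite. The
# oracles deliberately re-derive each estimator from its definition
# (normal equations, cumulative-weight enumeration, brute-force
# likelihood) rather than reusing package code paths.

# Weighted least squares through the origin, by normal equations.
oracle_wls_origin <- function(bx, by, w) {
  X <- matrix(bx, ncol = 1)
  W <- diag(w)
  solve(t(X) %*% W %*% X, t(X) %*% W %*% by)[1, 1]
}

# Weighted least squares with intercept, by normal equations.
oracle_wls_intercept <- function(bx, by, w) {
  X <- cbind(1, bx)
  W <- diag(w)
  drop(solve(t(X) %*% W %*% X, t(X) %*% W %*% by))
}

# Weighted median by explicit enumeration of the mid-cumulative weight
# function and linear interpolation at 0.5.
oracle_weighted_median <- function(r, w) {
  o <- order(r)
  rs <- r[o]
  ws <- w[o] / sum(w)
  p <- numeric(length(ws))
  acc <- 0
  for (i in seq_along(ws)) {
    p[i] <- acc + ws[i] / 2
    acc <- acc + ws[i]
  }
  if (p[1] >= 0.5) return(rs[1])
  if (p[length(p)] <= 0.5) return(rs[length(rs)])
  j <- max(which(p < 0.5))
  rs[j] + (rs[j + 1] - rs[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

# OLS by explicit normal equations (used against fit_linear).
oracle_ols <- function(y, X) {
  X1 <- cbind(1, X)
  drop(solve(t(X1) %*% X1, t(X1) %*% y))
}

# Logistic log-likelihood maximized by general-purpose optimization
# (used against the IRLS fit).
oracle_logistic <- function(y, X) {
  X1 <- cbind(1, X)
  nll <- function(b) {
    eta <- drop(X1 %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  stats::optim(rep(0, ncol(X1)), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))$par
}

# Tiny panel for unit tests.
tiny_panel <- function(m = 5, seed = 1) {
  set.seed(seed)
  snp_panel(
    rsid = paste0("rs", seq_len(m)),
    effect_allele = rep(c("A", "C", "G", "T", "A"), length.out = m),
    other_allele = rep(c("G", "T", "C", "A", "C"), length.out = m),
    eaf = round(runif(m, 0.15, 0.85), 2),
    weight = round(runif(m, 0.5, 2), 2)
  )
}

# Summary statistics drawn directly from the two-sample MR sampling model:
# beta_x ~ N(w, se_x), beta_y ~ N(theta * w + alpha, se_y) with optional
# balanced pleiotropy alpha ~ N(0, pleio_sd).
gen_sumstats <- function(m = 19, theta = 0, se_x = 0.02, se_y = 0.05,
                         pleio_sd = 0, seed = 1) {
  set.seed(seed)
  w <- runif(m, 0.5, 2.5)
  alpha <- if (pleio_sd > 0) rnorm(m, 0, pleio_sd) else numeric(m)
  summary_stats(
    rsid = paste0("rs", seq_len(m)),
    effect_allele = "A", other_allele = "G",
    eaf = runif(m, 0.2, 0.8),
    beta_exposure = rnorm(m, w, se_x), se_exposure = rep(se_x, m),
    beta_outcome = rnorm(m, theta * w + alpha, se_y), se_outcome = rep(se_y, m)
  )
}

# A small fully measured cohort for stage tests.
quick_cohort <- function(n = 2000, n_sub = n, seed = 1, ...) {
  simulate_cohort(sim_config(n_total = n, n_subcohort = n_sub, seed = seed,
                             ...))
}

zero_confounders <- function() {
  lapply(default_confounder_effects(), function(x) x * 0)
}

# Minimal hand-built participant table with wave-1/wave-2 readings.
toy_participants <- function(sbp1, dbp1, med1, followed, sbp2 = sbp1,
                             dbp2 = dbp1, med2 = med1) {
  n <- length(sbp1)
  data.frame(
    id = seq_len(n), age = 50, sex = rep(c(0, 1), length.out = n),
    bmi = 25, day_of_year = seq(10, 350, length.out = n),
    sbp1_w1 = sbp1, sbp2_w1 = sbp1, sbp3_w1 = sbp1,
    dbp1_w1 = dbp1, dbp2_w1 = dbp1, dbp3_w1 = dbp1,
    med_w1 = med1, followed_w2 = followed,
    sbp1_w2 = sbp2, sbp2_w2 = sbp2, sbp3_w2 = sbp2,
    dbp1_w2 = dbp2, dbp2_w2 = dbp2, dbp3_w2 = dbp2,
    med_w2 = med2
  )
}
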