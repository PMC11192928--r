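# Phenotype processing: blood-pressure summarization and medication
# amendment, hypertension coding, cosinor seasonal standardization of the
# biomarker, covariate encoding with explicit "unknown" levels, and
# selection of the prospective (baseline-normotensive, followed-up) sample.

#' Summarize three blood-pressure readings
#'
#' The working value for each visit is the arithmetic mean of the last two
#' readings. If either of the last two is missing, the mean of the last two
#' non-missing readings is used; participants with fewer than two usable
#' readings get a missing value (a message reports how many).
#'
#' @param r1,r2,r3 first, second and third readings (mmHg), vectorized.
#' @return Numeric vector of summarized BP, mmHg.
#' @export
summarize_bp <- function(r1, r2, r3) {
  m <- cbind(r1, r2, r3)
  out <- rowMeans(m[, 2:3, drop = FALSE])
  fix <- which(!is.finite(out) & rowSums(is.finite(m)) >= 2)
  for (i in fix) {
    avail <- m[i, is.finite(m[i, ])]
    out[i] <- if (length(avail) >= 2) {
      mean(utils::tail(avail, 2))
    } else NA_real_
  }
  n_bad <- sum(!is.finite(out))
  if (n_bad > 0) {
    message("summarize_bp: ", n_bad,
            " participant(s) with fewer than two usable readings set to NA")
  }
  unname(out)
}

#' Amend blood pressure for antihypertensive medication use
#'
#' Adds 10 mmHg to SBP and 5 mmHg to DBP for participants reporting
#' antihypertensive medication use, to correct the treatment-induced
#' downward bias of measured pressures.
#'
#' @param sbp,dbp measured pressures (mmHg).
#' @param med_use binary medication indicator.
#' @return List with amended `sbp` and `dbp`.
#' @export
adjust_bp_for_medication <- function(sbp, dbp, med_use) {
  med <- as.integer(med_use) == 1L
  med[is.na(med)] <- FALSE
  list(sbp = sbp + 10 * med, dbp = dbp + 5 * med)
}

#' Hypertension coding
#'
#' Hypertensive iff measured SBP >= 140 mmHg, or measured DBP >= 90 mmHg,
#' or self-reported antihypertensive medication use. Uses measured
#' (unamended) pressures; for medicated participants the medication
#' criterion makes the amendment question moot.
#'
#' @param sbp_measured,dbp_measured measured pressures (mmHg).
#' @param med_use binary medication indicator.
#' @return Integer 0/1 vector.
#' @export
define_hypertension <- function(sbp_measured, dbp_measured, med_use) {
  med <- as.integer(med_use) == 1L
  med[is.na(med)] <- FALSE
  as.integer(sbp_measured >= 140 | dbp_measured >= 90 | med)
}

#' Seasonal standardization of a biomarker by cosinor regression
#'
#' Fits \eqn{v_i = m + a\cos(2\pi d_i/365.25) + b\sin(2\pi d_i/365.25)} by
#' least squares and subtracts each participant's mean-centred fitted
#' seasonal deviation, returning the annual-average value. The output mean
#' equals the input mean, and the operation is idempotent: re-standardizing
#' leaves the values unchanged (the refitted seasonal coefficients are
#' exactly zero).
#'
#' @param values biomarker series (nmol/L); missing values pass through.
#' @param day_of_year draw day-of-year, 1-366.
#' @return Standardized series, same length as `values`.
#' @export
season_standardize <- function(values, day_of_year) {
  if (length(values) != length(day_of_year)) {
    stop("season_standardize: values and day_of_year differ in length",
         call. = FALSE)
  }
  ok <- is.finite(values) & is.finite(day_of_year)
  if (sum(ok) < 20) {
    stop("season_standardize: need >= 20 non-missing value/day pairs",
         call. = FALSE)
  }
  d <- day_of_year[ok]
  if (length(unique(ceiling(d / 91.3125))) < 2) {
    stop("season_standardize: insufficient seasonal spread ",
         "(all draws fall in a single season)", call. = FALSE)
  }
  cosd <- cos(2 * pi * d / 365.25)
  sind <- sin(2 * pi * d / 365.25)
  fit <- stats::lm.fit(cbind(1, cosd, sind), values[ok])
  seas <- cosd * fit$coefficients[2] + sind * fit$coefficients[3]
  out <- values
  out[ok] <- values[ok] - (seas - mean(seas))
  out
}

vitd_levels <- c("lt30", "30to49.9", "50to74.9", "ge75")

#' Categorize 25(OH)D into the four conventional bins
#'
#' Half-open bins `[0, 30)`, `[30, 50)`, `[50, 75)`, `[75, Inf)`, labelled
#' `"lt30"`, `"30to49.9"`, `"50to74.9"`, `"ge75"`. The `50to74.9` bin is the
#' conventional reference level in regression models.
#'
#' @param value 25(OH)D in nmol/L; missing passes through as NA.
#' @return Factor with the four levels above.
#' @export
categorize_vitd <- function(value) {
  if (any(value < 0, na.rm = TRUE)) {
    stop("categorize_vitd: negative 25(OH)D value", call. = FALSE)
  }
  cut(value, breaks = c(0, 30, 50, 75, Inf), right = FALSE,
      labels = vitd_levels, include.lowest = TRUE)
}

covariate_levels <- list(
  bmi_cat = c("lt25", "25to29.9", "ge30", "unknown"),
  smoking = c("never", "former", "former_lt10", "former_10to20",
              "former_gt20", "current", "current_lt10", "current_10to20",
              "current_gt20", "unknown"),
  alcohol = c("never", "1-4", "ge5", "unknown"),
  activity = c("inactive", "low", "moderate", "high", "unknown"),
  education = c("lt10", "10to12", "ge13", "unknown"),
  econ_difficulty = c("no", "yes", "unknown")
)

#' Encode the adjustment covariates as a design matrix
#'
#' Continuous age and binary sex enter as-is; BMI is binned `<25`,
#' `25-29.9`, `>=30`; the lifestyle covariates enter as treatment-coded
#' dummies with the first canonical level as reference and missing values
#' mapped to an explicit `"unknown"` level (which stays in the model, it is
#' never dropped). Unrecognized category labels raise an error listing the
#' offending values.
#'
#' @param table a participant data.frame with columns `age`, `sex`, `bmi`
#'   and any of `smoking`, `alcohol`, `activity`, `education`,
#'   `econ_difficulty`.
#' @return Numeric design matrix (no intercept column).
#' @export
encode_covariates <- function(table) {
  df <- data.frame(age = table$age, sex = table$sex)
  if ("bmi" %in% names(table)) {
    bc <- cut(table$bmi, c(-Inf, 25, 30, Inf), right = FALSE,
              labels = c("lt25", "25to29.9", "ge30"))
    bc <- as.character(bc)
    bc[is.na(bc)] <- "unknown"
    df$bmi_cat <- factor(bc, levels = intersect(covariate_levels$bmi_cat,
                                                unique(bc)))
  }
  for (v in c("smoking", "alcohol", "activity", "education",
              "econ_difficulty")) {
    if (!v %in% names(table)) next
    x <- as.character(table[[v]])
    x[is.na(x)] <- "unknown"
    bad <- setdiff(unique(x), covariate_levels[[v]])
    if (length(bad)) {
      stop("encode_covariates: unrecognized ", v, " level(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    df[[v]] <- factor(x, levels = intersect(covariate_levels[[v]], unique(x)))
  }
  stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
}

#' Derive per-wave processed phenotypes for a participant table
#'
#' Applies the deterministic phenotype rules in order: summarize the three
#' readings, code hypertension from the measured values plus medication,
#' amend for medication, and (for wave 1) season-standardize and categorize
#' the biomarker within the measured sub-cohort.
#'
#' @param participants a participant data.frame as produced by
#'   [simulate_cohort] (wave-suffixed reading columns).
#' @return The input with added columns `sbp_w1`, `dbp_w1`, `hyper_w1`,
#'   `vitd_std`, `vitd_cat` and, where wave 2 exists, `sbp_w2`, `dbp_w2`,
#'   `hyper_w2`.
#' @export
process_phenotypes <- function(participants) {
  p <- participants
  for (w in c("w1", "w2")) {
    if (!paste0("sbp1_", w) %in% names(p)) next
    s <- summarize_bp(p[[paste0("sbp1_", w)]], p[[paste0("sbp2_", w)]],
                      p[[paste0("sbp3_", w)]])
    d <- summarize_bp(p[[paste0("dbp1_", w)]], p[[paste0("dbp2_", w)]],
                      p[[paste0("dbp3_", w)]])
    med <- p[[paste0("med_", w)]]
    p[[paste0("hyper_", w)]] <- define_hypertension(s, d, med)
    am <- adjust_bp_for_medication(s, d, med)
    p[[paste0("sbp_", w)]] <- am$sbp
    p[[paste0("dbp_", w)]] <- am$dbp
    p[[paste0("sbp_meas_", w)]] <- s
    p[[paste0("dbp_meas_", w)]] <- d
  }
  if ("vitd_raw" %in% names(p)) {
    # The cosinor shift can push assay-floor values marginally below zero;
    # annual averages are non-negative by construction, so floor at 0.
    p$vitd_std <- pmax(season_standardize(p$vitd_raw, p$day_of_year), 0)
    p$vitd_cat <- categorize_vitd(p$vitd_std)
  }
  p
}

#' Select the prospective analysis sample
#'
#' Keeps participants who were followed up at wave 2 and were not
#' hypertensive at wave 1 (using measured BP plus the medication
#' criterion). Exclusion counts are reported via `message()`.
#'
#' @param table a processed participant table (see [process_phenotypes]);
#'   must contain wave-2 data.
#' @return The filtered table.
#' @export
select_prospective_sample <- function(table) {
  if (!"hyper_w1" %in% names(table)) {
    table <- process_phenotypes(table)
  }
  has_w2 <- if ("followed_w2" %in% names(table)) {
    table$followed_w2 %in% TRUE
  } else if ("sbp_w2" %in% names(table)) {
    is.finite(table$sbp_w2)
  } else {
    stop("select_prospective_sample: no wave-2 data present", call. = FALSE)
  }
  if (!any(has_w2)) {
    stop("select_prospective_sample: no wave-2 data present", call. = FALSE)
  }
  followed <- table[has_w2, , drop = FALSE]
  keep <- followed$hyper_w1 == 0L
  message("select_prospective_sample: ", sum(!has_w2),
          " not followed at wave 2; ", sum(!keep),
          " baseline hypertensives excluded; ", sum(keep), " retained")
  followed[keep, , drop = FALSE]
}
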