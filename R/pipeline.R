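# Orchestration: run the full triangulation (observational, one-sample MR,
# two-sample MR, non-linear MR) from one configuration and write a
# reproducible report bundle.

# Deterministic per-stage child seeds from one parent seed; kept below 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, obs = 23L, mr1 = 37L, mr2s = 53L, nlmr = 71L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% 2147483647L
}

#' Pipeline run configuration
#'
#' Exactly one of `sim` (a [sim_config]) or `input_dir` (a directory with
#' `genotypes.tsv`, `phenotypes.tsv`, `panel.tsv` as written by
#' [write_cohort]) must be supplied.
#'
#' @param sim a [sim_config], or NULL when reading files.
#' @param input_dir directory of input files, or NULL when simulating.
#' @param out_dir output directory for the report bundle.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param scale exposure-unit reporting multiple (default 25 nmol/L).
#' @param ivw_model `"random"` or `"fixed"`.
#' @param presso_sims MR-PRESSO simulation count.
#' @param strata_k non-linear MR stratum count.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       out_dir = tempfile("vitdmr_run_"), seed = 1L,
                       scale = 25, ivw_model = "random",
                       presso_sims = 1000, strata_k = 4) {
  if (is.null(sim) == is.null(input_dir)) {
    stop("run_config: supply exactly one of sim or input_dir", call. = FALSE)
  }
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 seed = as.integer(seed), scale = scale,
                 ivw_model = ivw_model, presso_sims = presso_sims,
                 strata_k = strata_k),
            class = "run_config")
}

read_cohort <- function(dir) {
  for (f in c("genotypes.tsv", "phenotypes.tsv", "panel.tsv")) {
    if (!file.exists(file.path(dir, f))) {
      stop("read_cohort: missing input file ", file.path(dir, f),
           call. = FALSE)
    }
  }
  g <- as.matrix(utils::read.delim(file.path(dir, "genotypes.tsv"),
                                   check.names = FALSE))
  p <- utils::read.delim(file.path(dir, "phenotypes.tsv"),
                         stringsAsFactors = FALSE)
  panel <- read_snp_panel(file.path(dir, "panel.tsv"))
  structure(list(participants = p, genotypes = g, panel = panel,
                 truth = NULL), class = "sim_cohort")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

two_sample_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$method, beta = r$beta, se = r$se,
               ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
               n_snps = r$n_snps,
               intercept = if (is.null(r$intercept)) NA_real_ else r$intercept,
               intercept_p = if (is.null(r$intercept_p)) NA_real_ else
                 r$intercept_p,
               q_stat = if (is.null(r$q_stat)) NA_real_ else r$q_stat,
               q_p = if (is.null(r$q_p)) NA_real_ else r$q_p,
               global_p = if (is.null(r$global_p)) NA_real_ else r$global_p,
               outliers = if (is.null(r$outliers)) "" else
                 paste(r$outliers, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

wald_row <- function(outcome, w) {
  data.frame(outcome = outcome, estimate = w$ratio, ci_low = w$ci_low,
             ci_high = w$ci_high, p = w$p,
             or = if (is.null(w$or_scale)) NA_real_ else w$or_scale[[1]],
             stringsAsFactors = FALSE)
}

#' Run the full triangulation pipeline
#'
#' Simulates (or reads) a cohort, processes phenotypes, and runs the
#' cross-sectional, prospective, one-sample MR, two-sample MR and
#' non-linear MR stages. Per-stage TSV tables, a combined comparison table
#' and a JSON metadata record (seed, settings, package version, stage
#' errors) are written into the output directory. A stage failure is
#' recorded and the remaining stages still run.
#'
#' @param config a [run_config].
#' @return List of class `vitdmr_report` with elements `cross_sectional`,
#'   `prospective`, `mr_onesample`, `mr_twosample`, `nlmr`, `summary`,
#'   `errors`, `out_dir`. `errors` is an empty list on a clean run.
#' @export
run_all <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  errors <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  cohort <- if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir)
  } else {
    cfg <- config$sim
    cfg$seed <- derive_seed(config$seed, "simulate")
    simulate_cohort(validate_sim_config(unclass(cfg)))
  }
  p <- suppressMessages(process_phenotypes(cohort$participants))
  cohort$participants <- p
  sub <- p[p$in_subcohort & is.finite(p$vitd_std), , drop = FALSE]

  cs <- run_stage("cross_sectional", cross_sectional_analysis(sub))
  pr <- run_stage("prospective",
                  suppressMessages(prospective_analysis(sub)))
  mr1 <- run_stage("mr_onesample",
                   suppressWarnings(mr_onesample(cohort,
                                                 scale = config$scale)))
  mr2 <- run_stage("mr_twosample", {
    ss <- suppressWarnings(make_summary_stats(cohort, outcome = "sbp"))
    mr_twosample_all(ss, ivw_model = config$ivw_model,
                     presso_sims = config$presso_sims,
                     seed = derive_seed(config$seed, "mr2s"))
  })
  nl <- run_stage("nlmr", {
    lapply(c(residual = "residual", doubly_ranked = "doubly-ranked"),
           function(mm) {
             suppressWarnings(nlmr_onesample(cohort, method = mm,
                                             k = config$strata_k))
           })
  })

  if (!is.null(cs)) write_tsv(cs, file.path(config$out_dir,
                                            "cross_sectional.tsv"))
  if (!is.null(pr)) write_tsv(pr, file.path(config$out_dir,
                                            "prospective.tsv"))
  if (!is.null(mr1)) {
    write_tsv(do.call(rbind, Map(wald_row, names(mr1$estimates),
                                 mr1$estimates)),
              file.path(config$out_dir, "mr_onesample.tsv"))
  }
  if (!is.null(mr2)) {
    write_tsv(two_sample_table(mr2), file.path(config$out_dir,
                                               "mr_twosample.tsv"))
  }
  if (!is.null(nl)) {
    for (mm in names(nl)) {
      write_tsv(nl[[mm]]$estimates,
                file.path(config$out_dir, paste0("nlmr_", mm, ".tsv")))
    }
  }

  # Combined forest-style comparison: per outcome, one row per stage.
  summary_tab <- NULL
  if (!is.null(cs) && !is.null(pr) && !is.null(mr1)) {
    pick <- function(tab, stage) {
      r <- tab[tab$exposure == "per25", ]
      data.frame(stage = stage, outcome = r$outcome, estimate = r$estimate,
                 ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
                 stringsAsFactors = FALSE)
    }
    mr1_tab <- do.call(rbind, Map(function(nm, w) {
      data.frame(stage = "one_sample_mr", outcome = toupper(nm),
                 estimate = if (is.null(w$or_scale)) w$ratio else
                   w$or_scale[[1]],
                 ci_low = if (is.null(w$or_scale)) w$ci_low else
                   w$or_scale[[2]],
                 ci_high = if (is.null(w$or_scale)) w$ci_high else
                   w$or_scale[[3]],
                 p = w$p, stringsAsFactors = FALSE)
    }, names(mr1$estimates), mr1$estimates))
    summary_tab <- rbind(pick(cs, "cross_sectional"),
                         pick(pr, "prospective"), mr1_tab)
    if (!is.null(mr2)) {
      t2 <- two_sample_table(mr2)
      summary_tab <- rbind(summary_tab, data.frame(
        stage = "two_sample_mr", outcome = paste0("SBP:", t2$method),
        estimate = t2$beta, ci_low = t2$ci_low, ci_high = t2$ci_high,
        p = t2$p, stringsAsFactors = FALSE))
    }
    write_tsv(summary_tab, file.path(config$out_dir, "summary.tsv"))
  }

  meta <- list(
    seed = config$seed,
    stage_seeds = sapply(c("simulate", "obs", "mr1", "mr2s", "nlmr"),
                         function(s) derive_seed(config$seed, s)),
    scale = config$scale, ivw_model = config$ivw_model,
    presso_sims = config$presso_sims, strata_k = config$strata_k,
    package_version = as.character(utils::packageVersion("vitdmr")),
    r_version = as.character(getRversion()),
    errors = errors
  )
  jsonlite::write_json(meta, file.path(config$out_dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  structure(list(cross_sectional = cs, prospective = pr,
                 mr_onesample = mr1, mr_twosample = mr2, nlmr = nl,
                 summary = summary_tab, errors = errors,
                 out_dir = config$out_dir),
            class = "vitdmr_report")
}

#' @export
print.vitdmr_report <- function(x, ...) {
  cat("vitdmr triangulation report ->", x$out_dir, "\n")
  if (length(x$errors)) {
    cat("Stage errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ":", x$errors[[nm]], "\n")
  } else if (!is.null(x$summary)) {
    print(x$summary, row.names = FALSE)
  }
  invisible(x)
}
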