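# End-to-end analysis orchestration: exclusions, PRS construction, moment
# estimation, model fitting and comparison, psychometric summaries, and the
# sensitivity variants.

#' Remove children with exclusion-condition flags
#'
#' Drops children flagged for cerebral palsy, Down syndrome, brain injury, or
#' chromosomal abnormality. Each child is removed (and counted) once, under
#' the first flag set, in that order; the per-reason tally is attached as
#' attribute `"removals"`.
#'
#' @param cohort A cohort table with logical `excl_*` columns.
#' @return The filtered cohort with a `removals` attribute.
#' @export
apply_exclusions <- function(cohort) {
  flags <- c("excl_cerebral_palsy", "excl_down_syndrome",
             "excl_brain_injury", "excl_chromosomal")
  miss <- setdiff(flags, names(cohort))
  if (length(miss)) {
    abort(paste0("Missing exclusion flag column(s): ", paste(miss, collapse = ", ")))
  }
  reason <- rep(NA_character_, nrow(cohort))
  for (f in flags) {
    reason[is.na(reason) & as.logical(cohort[[f]])] <- f
  }
  out <- cohort[is.na(reason), , drop = FALSE]
  tally <- unname(vapply(flags, function(r) sum(reason == r, na.rm = TRUE), 0L))
  attr(out, "removals") <- tibble(reason = flags, n = tally)
  out
}

#' Analysis configuration
#'
#' Bundles the measurement design and the PRS construction settings for a
#' full pipeline run.
#'
#' @param factors Named list factor -> item columns (exactly one
#'   internalizing design per run; see [atac_design()],
#'   [smfq_scared_design()], or the synthetic default).
#' @param covariates Covariate columns (default PRS + sex + age + six PCs).
#' @param thresholds PRS p-value thresholds (default [prs_thresholds()]).
#' @param main_threshold Threshold used for the main-model PRS (default 0.5).
#' @param maf_min,info_min,r2_max,window_kb QC and clumping settings.
#' @param min_pair_n Minimum pairwise n for moment estimation.
#' @param max_item_missing Children missing more than this fraction of the
#'   design's items are dropped from the run (default 0.2).
#' @param seed Seed for seeded pipeline choices (e.g. which MZ twin is
#'   dropped in the deduplication variant).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(factors,
                            covariates = c("prs", "sex", "age", paste0("pc", 1:6)),
                            thresholds = prs_thresholds(),
                            main_threshold = 0.5,
                            maf_min = 0.05, info_min = 0.8,
                            r2_max = 0.1, window_kb = 1000,
                            min_pair_n = 50,
                            max_item_missing = 0.2,
                            seed = 1L) {
  if (!is.list(factors) || is.null(names(factors))) {
    abort("factors must be a named list of item columns.")
  }
  if (!main_threshold %in% thresholds) {
    abort("main_threshold must be one of the configured thresholds.")
  }
  structure(
    list(
      factors = factors, covariates = covariates, thresholds = thresholds,
      main_threshold = main_threshold, maf_min = maf_min, info_min = info_min,
      r2_max = r2_max, window_kb = window_kb, min_pair_n = min_pair_n,
      max_item_missing = max_item_missing, seed = as.integer(seed)
    ),
    class = "analysis_config"
  )
}

config_hash <- function(config, seed = NULL) {
  rlang::hash(list(config = unclass(config), seed = seed))
}

#' Run the full PRS-to-general-factor analysis
#'
#' Applies exclusions, builds PRS (filter, standardize, clump on the target
#' panel, score, z-standardize at the main threshold), estimates the mixed
#' correlation matrix over items and covariates, fits the correlated-factors
#' and general-factor models with family-cluster sandwich standard errors,
#' runs the scaled difference test, and computes loading/regression tables,
#' ECV and domain loading summaries.
#'
#' @param cohort Cohort table (one row per child).
#' @param panel `genotype_panel` covering the cohort's children.
#' @param sumstats Discovery summary statistics.
#' @param config An [analysis_config()].
#' @return An object of class `gf_analysis`: list with `fits` (correlated,
#'   general), `difftest`, `loadings`, `betas`, `ecv`, `loading_summary`,
#'   `prs` (all thresholds), `n`, `config_hash`.
#' @export
run_analysis <- function(cohort, panel, sumstats, config) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  cohort <- stage("exclusions", apply_exclusions(cohort))

  prs_tbl <- stage("prs", {
    ss <- filter_variants(sumstats, maf_min = config$maf_min, info_min = config$info_min)
    ss <- add_standardized_beta(ss)
    ss <- clump_variants(ss, panel, r2_max = config$r2_max, window_kb = config$window_kb)
    score_prs(panel, ss, thresholds = config$thresholds)
  })
  items <- unlist(config$factors, use.names = FALSE)
  cohort <- stage("merge", {
    main <- prs_tbl %>%
      filter(.data$threshold == config$main_threshold) %>%
      select(child_id = "sample_id", prs = "std")
    merged <- left_join(cohort, main, by = "child_id")
    if (anyNA(merged$prs)) abort("Children without PRS after merge.")
    frac_missing <- rowMeans(is.na(merged[, items, drop = FALSE]))
    merged[frac_missing <= config$max_item_missing, , drop = FALSE]
  })

  mc <- stage("moments", {
    mixed_cor(cohort, items = items, covariates = config$covariates,
              min_n = config$min_pair_n)
  })
  fit_c <- stage("correlated_fit", {
    fit_gsem(mc, gf_model(config$factors, general = FALSE,
                          covariates = config$covariates),
             clusters = cohort$family_id)
  })
  fit_g <- stage("general_fit", {
    fit_gsem(mc, gf_model(config$factors, general = TRUE,
                          covariates = config$covariates),
             clusters = cohort$family_id)
  })
  dt <- stage("difftest", nested_difference_test(fit_c, fit_g))

  lt <- loading_table(fit_g) %>%
    mutate(scale = .data$factor) %>%
    left_join(
      loading_table(fit_c) %>% select("item", correlated = "specific"),
      by = "item"
    )
  betas <- bind_rows(
    latent_regressions(fit_c) %>% mutate(model = "correlated"),
    latent_regressions(fit_g) %>% mutate(model = "general")
  )
  dmap <- default_domain_map()
  ls <- if (all(unique(lt$scale) %in% names(dmap))) {
    loading_summary(lt, dmap)
  } else {
    NULL
  }

  structure(
    list(
      fits = list(correlated = fit_c, general = fit_g),
      difftest = dt,
      loadings = lt,
      betas = betas,
      ecv = ecv(lt),
      loading_summary = ls,
      prs = prs_tbl,
      n = nrow(cohort),
      seed = config$seed,
      config_hash = config_hash(config)
    ),
    class = "gf_analysis"
  )
}

#' @export
print.gf_analysis <- function(x, ...) {
  cat("<gf_analysis> n = ", x$n, ", ECV = ", round(x$ecv, 1), "%\n", sep = "")
  print(x$difftest)
  prs_beta <- x$betas %>% filter(.data$covariate == "prs", .data$model == "general")
  cat("PRS paths (general-factor model):\n")
  print(as.data.frame(prs_beta[, c("factor", "beta", "se", "p_value", "r2_pct")]),
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Sensitivity analyses
#'
#' Re-runs the pipeline under the standard robustness variants:
#' `no_adhd` drops children with an ADHD diagnosis flag or at least
#' `adhd_symptom_cutoff` endorsed symptoms on either ADHD dimension;
#' `one_mz_per_pair` drops one (seeded, uniformly chosen) twin per
#' monozygotic pair; `sex_stratified` refits the models within each sex
#' (sex removed from the covariates); `threshold_sweep` re-estimates the
#' latent regressions on the PRS at every configured p-value threshold.
#' Variants that would empty a required group are skipped with a warning.
#'
#' @param cohort,panel,sumstats,config As for [run_analysis()].
#' @param variants Subset of variants to run.
#' @param adhd_symptom_cutoff Symptom-count cutoff for the case definition
#'   (default 8).
#' @return A list of results: each element either a `gf_analysis`, a named
#'   list of them (sex strata), or a tibble (`threshold_sweep`: one row per
#'   threshold x factor x model with beta, se, p).
#' @export
sensitivity_suite <- function(cohort, panel, sumstats, config,
                              variants = c("no_adhd", "one_mz_per_pair",
                                           "sex_stratified", "threshold_sweep"),
                              adhd_symptom_cutoff = 8L) {
  stopifnot(inherits(config, "analysis_config"))
  out <- list()

  if ("no_adhd" %in% variants) {
    sub <- cohort[!adhd_case_filter(cohort, adhd_symptom_cutoff), , drop = FALSE]
    out$no_adhd <- if (nrow(sub) == 0) {
      warn("Variant 'no_adhd' removes every child; skipped.")
      NULL
    } else {
      run_analysis(sub, panel, sumstats, config)
    }
  }

  if ("one_mz_per_pair" %in% variants) {
    sub <- withr::with_seed(config$seed, drop_one_mz_twin(cohort))
    out$one_mz_per_pair <- run_analysis(sub, panel, sumstats, config)
  }

  if ("sex_stratified" %in% variants) {
    cfg_s <- config
    cfg_s$covariates <- setdiff(config$covariates, "sex")
    strata <- list()
    for (sx in sort(unique(cohort$sex))) {
      sub <- cohort[cohort$sex == sx, , drop = FALSE]
      lab <- paste0("sex_", sx)
      strata[[lab]] <- tryCatch(
        run_analysis(sub, panel, sumstats, cfg_s),
        error = function(e) {
          warn(paste0("Sex stratum ", sx, " skipped: ", conditionMessage(e)))
          NULL
        }
      )
    }
    out$sex_stratified <- strata
  }

  if ("threshold_sweep" %in% variants) {
    base <- run_analysis(cohort, panel, sumstats, config)
    sweep <- purrr::map_dfr(config$thresholds, function(thr) {
      cfg_t <- config
      cfg_t$main_threshold <- thr
      res <- tryCatch(run_analysis(cohort, panel, sumstats, cfg_t),
                      error = function(e) NULL)
      if (is.null(res)) {
        warn(paste0("Threshold ", thr, " skipped (no scored variants)."))
        return(tibble())
      }
      res$betas %>%
        filter(.data$covariate == "prs") %>%
        mutate(threshold = thr) %>%
        select("threshold", "model", "factor", "beta", "se", "p_value", "r2_pct")
    })
    class(sweep) <- c("prs_sweep", class(sweep))
    out$threshold_sweep <- sweep
    out$base <- base
  }

  out
}

#' ADHD case definition
#'
#' A child is a case when the register (ICD-like) diagnosis flag is set or at
#' least `cutoff` symptoms are endorsed on either DSM dimension (inattention
#' or hyperactivity/impulsivity).
#'
#' @param cohort Cohort table with `adhd_icd`, `dsm_ia_count`,
#'   `dsm_hi_count`.
#' @param cutoff Symptom-count cutoff per dimension (default 8).
#' @return Logical vector, `TRUE` for cases.
#' @export
adhd_case_filter <- function(cohort, cutoff = 8L) {
  as.logical(cohort$adhd_icd) |
    cohort$dsm_ia_count >= cutoff |
    cohort$dsm_hi_count >= cutoff
}

#' Drop one (seeded, uniformly chosen) twin per monozygotic pair
#'
#' @param cohort Cohort table.
#' @return The cohort without one member of each complete MZ pair; cohorts
#'   without MZ pairs are returned unchanged.
#' @export
drop_one_mz_twin <- function(cohort) {
  mz <- cohort$zygosity == "MZ"
  if (!any(mz)) {
    return(cohort)
  }
  fams <- unique(cohort$family_id[mz])
  drop_ids <- vapply(fams, function(f) {
    ids <- cohort$child_id[cohort$family_id == f & mz]
    if (length(ids) < 2) return(NA_character_)
    sample(ids, 1L)
  }, "")
  cohort[!(cohort$child_id %in% drop_ids), , drop = FALSE]
}
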