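# Polygenic risk scoring from GWAS summary statistics with PLINK-equivalent
# semantics: standardized betas, MAF/INFO/allele-type filters, greedy LD
# clumping, and no-mean-imputation dosage scoring across p-value thresholds.

#' The default p-value threshold grid
#'
#' Seven thresholds spanning 0.00001 to 1; the 0.5 threshold is the
#' conventional main-analysis score.
#' @return Numeric vector of length 7.
#' @export
prs_thresholds <- function() {
  c(1e-5, 1e-4, 1e-3, 0.01, 0.1, 0.5, 1)
}

#' Standardized per-genotype-SD effect from a GWAS z-score
#'
#' Converts a z-score to a standardized beta using the effective sample size
#' and the effect-allele frequency:
#' \deqn{\beta_{std} = z / \sqrt{2 p (1 - p) (n_{eff} + z^2)}.}
#'
#' @param z Z-score(s).
#' @param n_eff Effective sample size(s), positive.
#' @param allele_freq Effect-allele frequency in (0, 1).
#' @param variant_id Optional ids used in error messages.
#' @return Numeric vector of standardized betas (same sign as `z`).
#' @examples
#' standardize_beta(5, 50000, 0.5)  # ~0.0316
#' @export
standardize_beta <- function(z, n_eff, allele_freq, variant_id = NULL) {
  bad_p <- !is.finite(allele_freq) | allele_freq <= 0 | allele_freq >= 1
  bad_n <- !is.finite(n_eff) | n_eff <= 0
  if (any(bad_p | bad_n)) {
    idx <- which(bad_p | bad_n)[1]
    id <- if (!is.null(variant_id)) variant_id[idx] else paste0("#", idx)
    abort(paste0("Variant ", id, ": allele frequency must lie strictly in (0, 1) ",
                 "and n_eff must be positive."))
  }
  z / sqrt(2 * allele_freq * (1 - allele_freq) * (n_eff + z^2))
}

#' Add standardized betas to a summary-statistics table
#'
#' @param sumstats Tibble with `z`, `n_eff`, `allele_freq` (and `variant_id`).
#' @return The input with a `beta_std` column appended.
#' @export
add_standardized_beta <- function(sumstats) {
  sumstats$beta_std <- standardize_beta(
    sumstats$z, sumstats$n_eff, sumstats$allele_freq, sumstats$variant_id
  )
  sumstats
}

#' Filter summary-statistic records on MAF, INFO, and allele type
#'
#' Retains biallelic SNPs with minor allele frequency
#' `min(p, 1 - p) >= maf_min`, imputation quality `info >= info_min`, and no
#' indel / multiallelic / strand-ambiguous flag. Order is preserved. A
#' per-reason removal tally (first matching reason per variant, in the order
#' indel, multiallelic, ambiguous, maf, info) is attached as attribute
#' `"removals"`.
#'
#' @param records Summary-statistics tibble (see
#'   [simulate_discovery_sumstats()] for the columns).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param info_min Minimum INFO score (default 0.8).
#' @return Filtered tibble with a `removals` attribute.
#' @export
filter_variants <- function(records, maf_min = 0.05, info_min = 0.8) {
  if (nrow(records) == 0) {
    out <- records
    attr(out, "removals") <- tibble(
      reason = c("indel", "multiallelic", "ambiguous", "maf", "info"),
      n = 0L
    )
    return(out)
  }
  maf <- pmin(records$allele_freq, 1 - records$allele_freq)
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(reason) & records$is_indel] <- "indel"
  reason[is.na(reason) & records$is_multiallelic] <- "multiallelic"
  reason[is.na(reason) & records$is_ambiguous] <- "ambiguous"
  reason[is.na(reason) & maf < maf_min] <- "maf"
  reason[is.na(reason) & records$info < info_min] <- "info"
  out <- records[is.na(reason), , drop = FALSE]
  reasons <- c("indel", "multiallelic", "ambiguous", "maf", "info")
  tally <- unname(vapply(reasons, function(r) sum(reason == r, na.rm = TRUE), 0L))
  attr(out, "removals") <- tibble(reason = reasons, n = tally)
  out
}

# squared dosage correlation between one variant and a set of variants,
# computed on a genotype panel (pairwise complete)
panel_r2 <- function(panel, id_a, ids_b) {
  da <- panel$dosage[, id_a]
  db <- panel$dosage[, ids_b, drop = FALSE]
  suppressWarnings(as.numeric(cor(da, db, use = "pairwise.complete.obs"))^2)
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the smallest-p unassigned variant as an index variant and
#' removes all unassigned variants on the same chromosome within
#' `window_kb` kilobases whose squared correlation with the index exceeds
#' `r2_max`. Ties in p are broken by chromosome, position, then id, so the
#' result is deterministic.
#'
#' @param records Summary-statistics tibble (`variant_id`, `chromosome`,
#'   `position`, `p_value`).
#' @param ld Either a `genotype_panel` (dosage correlations are computed on
#'   it; every record must be present) or a lookup tibble with columns
#'   `var_a`, `var_b`, `r2` (unlisted pairs are taken as r2 = 0).
#' @param r2_max LD threshold (default 0.1: variants with r2 > 0.1 are
#'   clumped).
#' @param window_kb Window half-width in kb (default 1000).
#' @return Tibble of index-variant records (subset of `records`, smallest-p
#'   first), with a `clumps` attribute mapping each index variant to its
#'   clumped members.
#' @export
clump_variants <- function(records, ld, r2_max = 0.1, window_kb = 1000) {
  if (nrow(records) == 0) {
    attr(records, "clumps") <- tibble(index = character(0), member = character(0))
    return(records)
  }
  use_panel <- inherits(ld, "genotype_panel")
  if (use_panel) {
    missing_ids <- setdiff(records$variant_id, colnames(ld$dosage))
    if (length(missing_ids)) {
      abort(paste0("Variants absent from the LD panel: ",
                   paste(missing_ids, collapse = ", ")))
    }
  } else {
    ld <- as_tibble(ld)
    if (!all(c("var_a", "var_b", "r2") %in% names(ld))) {
      abort("LD lookup must have columns var_a, var_b, r2.")
    }
    ld_key <- c(
      setNames(ld$r2, paste(ld$var_a, ld$var_b)),
      setNames(ld$r2, paste(ld$var_b, ld$var_a))
    )
  }
  ord <- order(records$p_value, records$chromosome, records$position, records$variant_id)
  rec <- records[ord, , drop = FALSE]
  assigned <- rep(FALSE, nrow(rec))
  index_rows <- integer(0)
  clump_index <- character(0)
  clump_member <- character(0)
  for (i in seq_len(nrow(rec))) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    index_rows <- c(index_rows, i)
    cand <- which(!assigned &
                    rec$chromosome == rec$chromosome[i] &
                    abs(rec$position - rec$position[i]) <= window_kb * 1000)
    if (length(cand)) {
      if (use_panel) {
        r2 <- panel_r2(ld, rec$variant_id[i], rec$variant_id[cand])
        r2[is.na(r2)] <- 0
      } else {
        r2 <- unname(ld_key[paste(rec$variant_id[i], rec$variant_id[cand])])
        r2[is.na(r2)] <- 0
      }
      drop <- cand[r2 > r2_max]
      if (length(drop)) {
        assigned[drop] <- TRUE
        clump_index <- c(clump_index, rep(rec$variant_id[i], length(drop)))
        clump_member <- c(clump_member, rec$variant_id[drop])
      }
    }
  }
  out <- rec[index_rows, , drop = FALSE]
  attr(out, "clumps") <- tibble(index = clump_index, member = clump_member)
  out
}

#' Score polygenic risk profiles across p-value thresholds
#'
#' For each threshold, the raw score of a sample is
#' \eqn{\sum_j d_j \beta_j / (2 m)} over included variants with
#' `p_value <= threshold`, where `m` counts the sample's non-missing included
#' variants: missing genotypes contribute to neither numerator nor
#' denominator (PLINK `--score` with `no-mean-imputation`). A z-standardized
#' copy (cohort mean 0, SD 1 per threshold) is returned alongside. Thresholds
#' at which no variant passes yield `NA` scores.
#'
#' @param panel A `genotype_panel`.
#' @param effects Tibble with `variant_id`, `beta_std`, `p_value` (typically
#'   filtered, clumped summary statistics run through
#'   [add_standardized_beta()]).
#' @param thresholds P-value thresholds (default [prs_thresholds()]).
#' @return A tibble with one row per sample x threshold: `sample_id`,
#'   `threshold`, `n_used` (non-missing included variants), `raw`, `std`.
#' @export
score_prs <- function(panel, effects, thresholds = prs_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!all(c("variant_id", "beta_std", "p_value") %in% names(effects))) {
    abort("effects must carry variant_id, beta_std, p_value.")
  }
  missing_ids <- setdiff(effects$variant_id, colnames(panel$dosage))
  if (length(missing_ids)) {
    abort(paste0("Effect variants absent from panel: ",
                 paste(missing_ids, collapse = ", ")))
  }
  res <- purrr::map_dfr(sort(thresholds), function(thr) {
    inc <- effects$variant_id[effects$p_value <= thr]
    if (!length(inc)) {
      return(tibble(
        sample_id = panel$samples$sample_id, threshold = thr,
        n_used = 0L, raw = NA_real_, std = NA_real_
      ))
    }
    D <- panel$dosage[, inc, drop = FALSE]
    beta <- effects$beta_std[match(inc, effects$variant_id)]
    miss <- is.na(D)
    D0 <- D
    D0[miss] <- 0
    num <- as.numeric(D0 %*% beta)
    m_used <- unname(length(inc) - rowSums(miss))
    raw <- ifelse(m_used > 0, num / (2 * m_used), NA_real_)
    std <- if (sum(!is.na(raw)) > 1 && sd(raw, na.rm = TRUE) > 0) {
      as.numeric(scale(raw))
    } else {
      raw * NA_real_
    }
    tibble(
      sample_id = panel$samples$sample_id, threshold = thr,
      n_used = as.integer(m_used), raw = raw, std = std
    )
  })
  class(res) <- c("prs_profile", class(res))
  res
}

#' Impute MZ co-twin genotypes by copying
#'
#' Adds ungenotyped monozygotic twins to a panel by copying the dosage vector
#' of the genotyped co-twin verbatim; provenance is recorded in the
#' `imputed_from` column of the sample table.
#'
#' @param panel A `genotype_panel`.
#' @param pairs Tibble with `sample_id` (new, ungenotyped twin) and `co_twin`
#'   (existing sample to copy from).
#' @return The extended panel.
#' @export
impute_mz_genotypes <- function(panel, pairs) {
  stopifnot(inherits(panel, "genotype_panel"))
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    return(panel)
  }
  if (!all(c("sample_id", "co_twin") %in% names(pairs))) {
    abort("pairs must carry sample_id and co_twin.")
  }
  absent <- setdiff(pairs$co_twin, panel$samples$sample_id)
  if (length(absent)) {
    bad <- pairs[pairs$co_twin %in% absent, ]
    abort(paste0("Co-twin(s) absent from panel: ",
                 paste(paste0(bad$sample_id, " <- ", bad$co_twin), collapse = ", ")))
  }
  src_rows <- match(pairs$co_twin, panel$samples$sample_id)
  new_dosage <- panel$dosage[src_rows, , drop = FALSE]
  rownames(new_dosage) <- pairs$sample_id
  src <- panel$samples[src_rows, ]
  new_samples <- tibble(
    sample_id = pairs$sample_id,
    family_id = src$family_id,
    zygosity = "MZ",
    member = src$member + 1L,
    imputed_from = pairs$co_twin
  )
  panel$samples <- bind_rows(panel$samples, new_samples)
  panel$dosage <- rbind(panel$dosage, new_dosage)
  panel
}
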