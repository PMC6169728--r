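# Readers and writers for the pipeline's external formats: summary-statistics
# TSV, cohort CSV, genotypes as PLINK-style .traw text or VCF, per-threshold
# PRS TSV, truth records and fitted results as JSON.

SUMSTATS_COLS <- c(
  "variant_id", "chromosome", "position", "effect_allele", "other_allele",
  "z", "p_value", "allele_freq", "n_eff", "info",
  "is_indel", "is_multiallelic", "is_ambiguous"
)

#' Write / read GWAS summary statistics (TSV)
#'
#' Tab-separated with a fixed documented header (schema v1):
#' `variant_id chromosome position effect_allele other_allele z p_value
#' allele_freq n_eff info is_indel is_multiallelic is_ambiguous`.
#' Simulation-truth columns (e.g. `beta_true`) are not written.
#'
#' @param sumstats Summary-statistics tibble.
#' @param path File path.
#' @return `write_sumstats` returns `path` invisibly; `read_sumstats` a
#'   tibble.
#' @export
write_sumstats <- function(sumstats, path) {
  readr::write_tsv(sumstats[, intersect(SUMSTATS_COLS, names(sumstats))], path)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(SUMSTATS_COLS, names(out))
  if (length(miss)) {
    abort(paste0("Summary-statistics file lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad <- which(is.finite(out$z) &
                 abs(out$p_value - 2 * pnorm(-abs(out$z))) > 1e-6)
  if (length(bad)) {
    abort(paste0("p_value inconsistent with z (two-sided normal) for: ",
                 paste(head(out$variant_id[bad], 5), collapse = ", ")))
  }
  out
}

#' Write / read a cohort table (CSV)
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read genotypes as PLINK-style .traw text
#'
#' One row per variant: `CHR SNP (C)M POS COUNTED ALT` then one dosage column
#' per sample (counted allele = effect allele; missing as NA).
#'
#' @param panel A `genotype_panel`.
#' @param path File path.
#' @export
write_traw <- function(panel, path) {
  v <- panel$variants
  df <- data.frame(
    CHR = v$chromosome, SNP = v$variant_id, CM = 0, POS = v$position,
    COUNTED = v$effect_allele, ALT = v$other_allele,
    check.names = FALSE
  )
  dos <- t(panel$dosage)
  colnames(dos) <- panel$samples$sample_id
  readr::write_tsv(cbind(df, as.data.frame(dos)), path)
  invisible(path)
}

#' @rdname write_traw
#' @export
read_traw <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta_cols <- c("CHR", "SNP", "CM", "POS", "COUNTED", "ALT")
  miss <- setdiff(meta_cols, names(raw))
  if (length(miss)) {
    abort(paste0(".traw file lacks column(s): ", paste(miss, collapse = ", ")))
  }
  sample_ids <- setdiff(names(raw), meta_cols)
  dosage <- t(as.matrix(raw[, sample_ids]))
  rownames(dosage) <- sample_ids
  colnames(dosage) <- raw$SNP
  structure(
    list(
      samples = tibble(
        sample_id = sample_ids,
        family_id = sub("_[0-9]+$", "", sample_ids),
        zygosity = NA_character_, member = NA_integer_,
        imputed_from = NA_character_
      ),
      variants = tibble(
        variant_id = raw$SNP, chromosome = raw$CHR, position = raw$POS,
        effect_allele = raw$COUNTED, other_allele = raw$ALT
      ),
      dosage = dosage
    ),
    class = "genotype_panel"
  )
}

#' Write genotypes as a (plain-text) VCF
#'
#' Hard-call dosages are emitted as GT fields (0/0, 0/1, 1/1 counting the
#' effect allele as ALT); missing dosages become `./.`.
#'
#' @param panel A `genotype_panel`.
#' @param path File path (uncompressed `.vcf`).
#' @export
write_genotype_vcf <- function(panel, path) {
  v <- panel$variants
  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(v), nrow(panel$samples))
  d <- t(panel$dosage)
  ok <- !is.na(d)
  gt[ok] <- gt_map[round(d[ok]) + 1L]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=genfactor",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample_id), collapse = "\t"),
    paste(
      v$chromosome, v$position, v$variant_id, v$other_allele, v$effect_allele,
      ".", "PASS", ".", "GT",
      apply(gt, 1, paste, collapse = "\t"),
      sep = "\t"
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses GT fields into effect-allele (ALT) dosages via the vcfR package.
#'
#' @param path VCF file path.
#' @return A `genotype_panel`.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Reading VCF requires the vcfR package.")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|."), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(z) sum(z == "1"), 0L))
  }
  dosage <- t(apply(gt, 2, function(col) count_alt(col)))
  dosage <- matrix(as.numeric(dosage), ncol = nrow(vcf@fix),
                   dimnames = list(colnames(gt), vcf@fix[, "ID"]))
  structure(
    list(
      samples = tibble(
        sample_id = colnames(gt),
        family_id = sub("_[0-9]+$", "", colnames(gt)),
        zygosity = NA_character_, member = NA_integer_,
        imputed_from = NA_character_
      ),
      variants = tibble(
        variant_id = vcf@fix[, "ID"],
        chromosome = as.integer(vcf@fix[, "CHROM"]),
        position = as.integer(vcf@fix[, "POS"]),
        effect_allele = vcf@fix[, "ALT"],
        other_allele = vcf@fix[, "REF"]
      ),
      dosage = dosage
    ),
    class = "genotype_panel"
  )
}

#' Write / read a PRS profile table (TSV)
#'
#' Columns: `sample_id`, `threshold`, `n_used`, `raw`, `std`.
#'
#' @param prs A PRS tibble from [score_prs()].
#' @param path File path.
#' @export
write_prs <- function(prs, path) {
  readr::write_tsv(prs, path)
  invisible(path)
}

#' @rdname write_prs
#' @export
read_prs <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("prs_profile", class(out))
  out
}

#' Write / read a simulation truth record (JSON)
#'
#' Lossless round-trip of the generating parameters of a synthetic cohort.
#'
#' @param truth A `truth_record`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$loading_plan <- as_tibble(raw$loading_plan)
  raw$threshold_plan <- as_tibble(raw$threshold_plan)
  raw$variant_effects <- as_tibble(raw$variant_effects)
  raw$covariate_effects <- lapply(raw$covariate_effects, unlist)
  raw$factor_cov_gp <- unlist(raw$factor_cov_gp)
  structure(raw, class = "truth_record")
}

#' Write fitted-model results
#'
#' `write_beta_table` emits the latent-regression table (TSV); `write_fit_json`
#' the parameter estimates and fit indices as JSON, stamped with a config
#' hash and seed when provided.
#'
#' @param fit A `gsem_fit`.
#' @param path File path.
#' @param config_hash,seed Optional provenance stamps.
#' @export
write_beta_table <- function(fit, path) {
  readr::write_tsv(latent_regressions(fit), path)
  invisible(path)
}

#' @rdname write_beta_table
#' @export
write_fit_json <- function(fit, path, config_hash = NULL, seed = NULL) {
  out <- list(
    schema_version = 1L,
    config_hash = config_hash, seed = seed,
    parameters = fit$par[, c("label", "type", "estimate", "se", "p_value", "free")],
    fit = as.list(fit_measures(fit))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
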