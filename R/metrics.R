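# Psychometric summaries of bifactor loading tables: explained common
# variance, variance explained by a regression path, and domain-wise loading
# summaries.

#' Explained common variance (ECV) of the general factor
#'
#' The share of common variance attributable to the general factor:
#' \deqn{ECV = 100 \cdot \sum_i \lambda_{g,i}^2 /
#'   (\sum_i \lambda_{g,i}^2 + \sum_i \lambda_{s,i}^2).}
#'
#' @param loadings A data frame with columns `general` and `specific` (one
#'   row per item), e.g. from [loading_table()] or [example_loadings()].
#' @return ECV in percent.
#' @examples
#' ecv(example_loadings("atac"))  # ~56
#' @export
ecv <- function(loadings) {
  if (!all(c("general", "specific") %in% names(loadings))) {
    abort("loadings needs columns 'general' and 'specific'.")
  }
  g2 <- sum(loadings$general^2)
  s2 <- sum(loadings$specific^2)
  if (g2 + s2 == 0) {
    abort("All loadings are zero; explained common variance is undefined.")
  }
  100 * g2 / (g2 + s2)
}

#' Variance explained by a standardized regression coefficient
#'
#' \eqn{R^2 = 100 \beta^2} (percent), the convention for reporting the
#' variance in a latent factor explained by a standardized PRS path.
#'
#' @param beta Standardized coefficient(s), `|beta| <= 1`.
#' @return Percentage(s).
#' @examples
#' r2_from_beta(0.13)  # 1.69
#' @export
r2_from_beta <- function(beta) {
  if (any(!is.finite(beta)) || any(abs(beta) > 1)) {
    abort("Standardized beta must be finite with |beta| <= 1.")
  }
  100 * beta^2
}

#' Default mapping of symptom scales to broad domains
#'
#' Neurodevelopmental: inattention, hyperactivity/impulsivity, autism
#' spectrum, learning. Externalizing: oppositional-defiant, conduct.
#' Internalizing: depression (A-TAC or SMFQ) and all anxiety scales.
#'
#' @return Named character vector scale -> domain.
#' @export
default_domain_map <- function() {
  c(
    ia = "neurodevelopmental", hi = "neurodevelopmental",
    asd = "neurodevelopmental", ld = "neurodevelopmental",
    odd = "externalizing", cd = "externalizing",
    dep = "internalizing", anx = "internalizing", smfq = "internalizing",
    pd = "internalizing", gad = "internalizing", sad = "internalizing",
    sa = "internalizing", sp = "internalizing"
  )
}

#' Summarise general-factor loadings by domain
#'
#' Arithmetic mean and range of the general-factor loadings within each
#' domain group.
#'
#' @param loadings Data frame with columns `general` and either `domain` or
#'   `scale` (mapped through `domain_map`).
#' @param domain_map Named vector scale -> domain used when no `domain`
#'   column is present (default [default_domain_map()]).
#' @return A tibble with `domain`, `n_items`, `mean`, `min`, `max`.
#' @export
loading_summary <- function(loadings, domain_map = default_domain_map()) {
  if (!"general" %in% names(loadings)) {
    abort("loadings needs a 'general' column.")
  }
  if (!"domain" %in% names(loadings)) {
    if (!"scale" %in% names(loadings)) {
      abort("loadings needs a 'domain' or 'scale' column.")
    }
    unknown <- setdiff(unique(loadings$scale), names(domain_map))
    if (length(unknown)) {
      abort(paste0("Unknown domain label for scale(s): ",
                   paste(unknown, collapse = ", ")))
    }
    loadings$domain <- unname(domain_map[loadings$scale])
  }
  if (nrow(loadings) == 0) abort("Empty loading table.")
  loadings %>%
    group_by(.data$domain) %>%
    summarise(
      n_items = dplyr::n(),
      mean = mean(.data$general),
      min = min(.data$general),
      max = max(.data$general),
      .groups = "drop"
    )
}

#' Published bifactor loadings for the two questionnaire designs
#'
#' Standardized item loadings reported by a published bifactor analysis of
#' parent-rated childhood psychopathology in a large Swedish child-twin
#' cohort, for the two internalizing-assessment designs: 62 A-TAC items
#' (`"atac"`) or 99 items with SMFQ depression and the five SCARED anxiety
#' subscales (`"smfq_scared"`). Columns: `scale`, `domain`, `item`,
#' `correlated` (loading in the correlated-factors model), `specific` and
#' `general` (loadings in the general-factor model).
#'
#' @param design `"atac"` or `"smfq_scared"`.
#' @return A tibble with one row per item.
#' @export
example_loadings <- function(design = c("atac", "smfq_scared")) {
  design <- match.arg(design)
  path <- system.file("extdata", paste0(design, "_loadings.csv"),
                      package = "genfactor", mustWork = TRUE)
  read_loading_table(path)
}

#' Read / write a loading table CSV
#'
#' The layout mirrors published loading tables (one item per row, scale and
#' domain labels, correlated-model and general-factor-model loadings), so
#' printed tables can be fed to [ecv()] and [loading_summary()] directly.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_loading_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_loading_table
#' @param loadings Loading table to write.
#' @export
write_loading_table <- function(loadings, path) {
  readr::write_csv(loadings, path)
  invisible(path)
}
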