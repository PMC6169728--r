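# Model specification for correlated-factors and general-factor (bifactor)
# structural models on ordinal items with latent regressions on covariates.
#
# Conventions (fixed so degree-of-freedom arithmetic is reproducible):
# every latent factor has unit total variance; residual correlations between
# the general factor and specific factors are fixed at zero while
# specific-specific residual correlations are free; every latent factor is
# regressed on every covariate; sample moments are the correlations among
# items and covariates except the covariate-covariate block, which is fixed
# at its sample values; thresholds are margin-fixed and not counted.

#' Specify a correlated-factors or general-factor measurement model
#'
#' @param factors Named list mapping each specific latent trait factor to the
#'   character vector of its items (each item belongs to exactly one specific
#'   factor; at least 2 items per factor).
#' @param general Include a general factor on which every item loads
#'   (bifactor structure)? Default `TRUE`. With `general = FALSE` this is the
#'   correlated-factors model, which is nested in the general-factor model.
#' @param covariates Character vector of observed covariates (e.g. PRS, sex,
#'   age, principal components) on which all latent factors are regressed.
#' @return An object of class `gf_model` with the enumerated free-parameter
#'   template (`$par`).
#' @examples
#' m <- gf_model(list(f1 = c("a", "b", "c"), f2 = c("d", "e", "f")),
#'               general = FALSE)
#' count_free_parameters(m)
#' @export
gf_model <- function(factors, general = TRUE, covariates = character()) {
  if (!is.list(factors) || is.null(names(factors)) || any(names(factors) == "")) {
    abort("factors must be a named list: factor name -> item ids.")
  }
  fnames <- names(factors)
  if (anyDuplicated(fnames)) abort("Factor names must be unique.")
  if ("g" %in% fnames) abort("'g' is reserved for the general factor.")
  items <- unlist(factors, use.names = FALSE)
  if (anyDuplicated(items)) {
    dup <- items[duplicated(items)][1]
    abort(paste0("Item '", dup, "' is assigned to more than one specific factor."))
  }
  n_per <- lengths(factors)
  if (any(n_per < 2)) {
    abort(paste0("Factor '", fnames[which(n_per < 2)[1]], "' has fewer than 2 items."))
  }
  item_factor <- rep(fnames, n_per)
  factors_all <- c(if (general) "g", fnames)

  par <- list(
    tibble(
      label = paste0("lambda_s[", items, "]"), type = "loading_s",
      item = items, factor = item_factor, covariate = NA_character_,
      start = 0.5, lower = -0.995, upper = 0.995
    )
  )
  if (general) {
    par <- c(par, list(tibble(
      label = paste0("lambda_g[", items, "]"), type = "loading_g",
      item = items, factor = "g", covariate = NA_character_,
      start = 0.5, lower = -0.995, upper = 0.995
    )))
  }
  if (length(covariates)) {
    grid <- expand.grid(covariate = covariates, factor = factors_all,
                        stringsAsFactors = FALSE)
    par <- c(par, list(tibble(
      label = paste0("beta[", grid$factor, ",", grid$covariate, "]"),
      type = "regression", item = NA_character_,
      factor = grid$factor, covariate = grid$covariate,
      start = 0, lower = -0.99, upper = 0.99
    )))
  }
  if (length(fnames) >= 2) {
    pr <- utils::combn(fnames, 2)
    par <- c(par, list(tibble(
      label = paste0("phi[", pr[1, ], ",", pr[2, ], "]"), type = "factor_cor",
      item = NA_character_, factor = paste0(pr[1, ], ",", pr[2, ]),
      covariate = NA_character_,
      start = 0.2, lower = -0.95, upper = 0.95
    )))
  }

  structure(
    list(
      factors = factors, items = items, item_factor = item_factor,
      general = general, covariates = covariates,
      par = bind_rows(par)
    ),
    class = "gf_model"
  )
}

#' Free parameters and model degrees of freedom
#'
#' The degrees of freedom are the number of modelled sample moments (all
#' correlations among items and covariates except the fixed
#' covariate-covariate block) minus the number of free parameters.
#'
#' @param model A [gf_model()].
#' @param fixed Optional named vector of parameters held fixed (excluded from
#'   the free count), as accepted by [fit_gsem()].
#' @return A list with `n_free`, `n_moments`, `df`.
#' @export
count_free_parameters <- function(model, fixed = NULL) {
  stopifnot(inherits(model, "gf_model"))
  labs <- model$par$label
  if (!is.null(fixed)) {
    unknown <- setdiff(names(fixed), labs)
    if (length(unknown)) {
      abort(paste0("Unknown fixed parameter(s): ", paste(unknown, collapse = ", ")))
    }
    labs <- setdiff(labs, names(fixed))
  }
  p <- length(model$items)
  q <- length(model$covariates)
  n_moments <- choose(p + q, 2) - choose(q, 2)
  df <- n_moments - length(labs)
  if (df < 0) {
    abort(paste0("Model is under-identified: ", length(labs), " free parameters for ",
                 n_moments, " moments (df = ", df, ")."))
  }
  list(n_free = length(labs), n_moments = n_moments, df = df)
}

#' @export
print.gf_model <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.gf_model <- function(x, ...) {
  cnt <- count_free_parameters(x)
  c(
    paste0("model: ", if (x$general) "general-factor (bifactor)" else "correlated-factors"),
    vapply(names(x$factors), function(f) {
      paste0("factor ", f, ": ", paste(x$factors[[f]], collapse = " "))
    }, ""),
    if (x$general) "general g: all items",
    paste0("covariates: ", if (length(x$covariates)) paste(x$covariates, collapse = " ") else "(none)"),
    "constraints: latent variances fixed at 1; general-specific residual correlations fixed at 0; specific-specific residual correlations free",
    paste0("free parameters: ", cnt$n_free, "; moments: ", cnt$n_moments, "; df: ", cnt$df)
  )
}

#' Write / read a model specification as a human-readable text block
#'
#' @param model A [gf_model()].
#' @param path File path.
#' @return `write_model_spec` returns `path` invisibly; `read_model_spec`
#'   returns a `gf_model`.
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "gf_model"))
  lines <- c(
    paste0("general: ", if (model$general) "yes" else "no"),
    vapply(names(model$factors), function(f) {
      paste0("factor ", f, ": ", paste(model$factors[[f]], collapse = " "))
    }, ""),
    paste0("covariates: ", paste(model$covariates, collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  lines <- readLines(path)
  general <- grepl("yes", lines[grepl("^general:", lines)][1])
  flines <- lines[grepl("^factor ", lines)]
  factors <- list()
  for (l in flines) {
    nm <- sub("^factor ([^:]+):.*$", "\\1", l)
    its <- strsplit(trimws(sub("^factor [^:]+:", "", l)), "\\s+")[[1]]
    factors[[nm]] <- its
  }
  cl <- lines[grepl("^covariates:", lines)][1]
  covs <- strsplit(trimws(sub("^covariates:", "", cl)), "\\s+")[[1]]
  covs <- covs[nzchar(covs)]
  gf_model(factors, general = general, covariates = covs)
}

#' Full-scale questionnaire designs
#'
#' Factor-to-item maps matching the two subsample designs used for
#' parent-rated childhood symptoms: `atac_design()` has 8 latent trait
#' factors over 62 A-TAC items (inattention 9, hyperactivity/impulsivity 10,
#' autism spectrum 17, learning 3, oppositional-defiant 5, conduct 5,
#' depression 5, anxiety 8); `smfq_scared_design()` has 12 factors over 99
#' items, replacing the internalizing scales with SMFQ depression (13) and
#' the five SCARED anxiety subscales (9, 9, 8, 4, 7).
#'
#' @return A named list suitable for [gf_model()].
#' @export
atac_design <- function() {
  n <- c(ia = 9, hi = 10, asd = 17, ld = 3, odd = 5, cd = 5, dep = 5, anx = 8)
  lapply(setNames(names(n), names(n)), function(s) paste0(s, "_", seq_len(n[[s]])))
}

#' @rdname atac_design
#' @export
smfq_scared_design <- function() {
  n <- c(ia = 9, hi = 10, asd = 17, ld = 3, odd = 5, cd = 5,
         smfq = 13, pd = 9, gad = 9, sad = 8, sa = 4, sp = 7)
  lapply(setNames(names(n), names(n)), function(s) paste0(s, "_", seq_len(n[[s]])))
}
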