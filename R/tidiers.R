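# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a fitted latent factor model
#'
#' @param x A `gsem_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `type`, `factor`, `item`,
#'   `covariate`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.gsem_fit <- function(x, ...) {
  x$par %>%
    mutate(term = .data$label, std.error = .data$se, p.value = .data$p_value) %>%
    select("term", "type", "factor", "item", "covariate",
           "estimate", "std.error", "statistic", "p.value")
}

#' Glance at a fitted latent factor model
#'
#' @param x A `gsem_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit indices, convergence information, and
#'   sample size.
#' @export
glance.gsem_fit <- function(x, ...) {
  fit_measures(x) %>%
    mutate(
      n_free = sum(x$par$free),
      converged = x$convergence$info %in% 1:4,
      iterations = x$convergence$iterations
    )
}

#' Plot standardized loadings of a fitted model
#'
#' Dot plot of specific (and, for bifactor models, general) loadings per
#' item, grouped by factor, with approximate 95% intervals.
#'
#' @param object A `gsem_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsem_fit <- function(object, ...) {
  lt <- loading_table(object)
  long <- tidyr::pivot_longer(
    lt,
    cols = dplyr::any_of(c("specific", "general")),
    names_to = "loading_type", values_to = "loading"
  )
  se_cols <- tidyr::pivot_longer(
    lt,
    cols = dplyr::any_of(c("specific_se", "general_se")),
    names_to = "se_type", values_to = "se"
  )
  long$se <- se_cols$se
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$loading, y = .data$item, colour = .data$loading_type
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$loading - 1.96 * .data$se,
      xmax = .data$loading + 1.96 * .data$se
    ), position = ggplot2::position_dodge(width = 0.5), size = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$factor),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "standardized loading", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot PRS associations across p-value thresholds
#'
#' @param object A `prs_sweep` tibble from [sensitivity_suite()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prs_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$threshold), y = .data$beta, colour = .data$model,
    group = .data$model
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$beta - 1.96 * .data$se,
      ymax = .data$beta + 1.96 * .data$se
    ), position = ggplot2::position_dodge(width = 0.4), size = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$factor)) +
    ggplot2::labs(x = "PRS p-value threshold", y = "standardized beta",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a mixed correlation matrix
#'
#' @param object A [mixed_cor()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixed_cor <- function(object, ...) {
  vars <- rownames(object$R)
  df <- as_tibble(as.data.frame.table(object$R, stringsAsFactors = FALSE)) %>%
    rename(var1 = "Var1", var2 = "Var2", r = "Freq") %>%
    mutate(var1 = factor(.data$var1, levels = vars),
           var2 = factor(.data$var2, levels = rev(vars)))
  ggplot2::ggplot(df, ggplot2::aes(.data$var1, .data$var2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
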