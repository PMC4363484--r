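#' Broom-style and plotting methods for fitted objects
#'
#' `tidy()` returns the coefficient-level table, `glance()` the one-row
#' model-level summary, and `autoplot()` a ggplot of the result, for
#' `model_fit` (single OLS fits), `avg_model` (delta-AIC averaged models)
#' and `path_fit` (saturated path models).
#'
#' @name methods
NULL

#' @rdname methods
#' @param x,object A fitted object.
#' @param ... Unused.
#' @export
tidy.model_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname methods
#' @export
glance.model_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
    loglik = x$loglik, k = x$k, aic = x$aic, n = x$n
  )
}

#' @rdname methods
#' @export
print.model_fit <- function(x, ...) {
  cat("OLS fit:", x$response, "~",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1", "\n")
  cat(sprintf("n = %d, k = %d, logLik = %.3f, AIC = %.3f\n",
              x$n, x$k, x$loglik, x$aic))
  print(x$coefficients)
  invisible(x)
}

#' @rdname methods
#' @export
tidy.avg_model <- function(x, ...) {
  x$coefficients
}

#' @rdname methods
#' @export
glance.avg_model <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$candidates),
    n_component = nrow(x$component),
    delta_cut = x$delta_cut,
    best_aic = x$candidates$aic[1],
    n = x$n
  )
}

#' @rdname methods
#' @export
print.avg_model <- function(x, ...) {
  cat("Model-averaged fit (delta-AIC <", x$delta_cut, "):",
      nrow(x$component), "of", nrow(x$candidates), "candidate models\n\n")
  cat("Component models:\n")
  print(x$component[, c("label", "k", "aic", "delta", "weight")])
  cat("\nAveraged coefficients (conditional):\n")
  print(x$coefficients)
  cat("\nRelative variable importance:\n")
  print(x$importance)
  invisible(x)
}

#' @rdname methods
#' @export
tidy.path_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(
      dplyr::rename(x$paths, from = "term", coefficient = "estimate"),
      to = x$fit$response, kind = "path", .before = 1
    ),
    tibble::tibble(kind = "correlation", to = x$correlations$var2,
                   from = x$correlations$var1,
                   coefficient = x$correlations$r, p = x$correlations$p)
  )
}

#' @rdname methods
#' @export
glance.path_fit <- function(x, ...) {
  tibble::tibble(n = x$n, saturated = TRUE,
                 r_squared = summary(x$fit$fit)$r.squared)
}

#' @rdname methods
#' @export
print.path_fit <- function(x, ...) {
  cat("Saturated path model (species-mean-centered), n =", x$n, "\n\n")
  cat("Regression paths on", x$fit$response, ":\n")
  print(x$paths)
  cat("\nPredictor correlations:\n")
  print(x$correlations)
  invisible(x)
}

#' @rdname methods
#' @export
autoplot.avg_model <- function(object, ...) {
  cf <- object$coefficients
  cf <- cf[cf$term != "(Intercept)", ]
  cf$term <- stats::reorder(cf$term, abs(cf$estimate))
  ggplot2::ggplot(cf, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se_adj,
                   xmax = .data$estimate + 1.96 * .data$se_adj),
      height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$importance)) +
    ggplot2::scale_size_continuous(limits = c(0, 1), range = c(1, 4)) +
    ggplot2::labs(x = "standardized coefficient (conditional average)",
                  y = NULL, size = "importance") +
    ggplot2::theme_minimal()
}

#' @rdname methods
#' @export
autoplot.path_fit <- function(object, ...) {
  td <- tidy(object)
  td$edge <- paste(td$from, "→", td$to)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$coefficient, y = .data$edge,
                                   fill = .data$p < 0.05)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$kind), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "coefficient / correlation", y = NULL,
                  fill = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' Scatter plots of growth against each trait
#'
#' One panel per predictor trait, growth on a log axis, colored by
#' species — the standard exploratory view of the trait-growth relations.
#'
#' @param traits A trait table.
#' @param predictors Trait columns to plot against `agr`.
#' @return A ggplot.
#' @export
plot_trait_growth <- function(traits,
                              predictors = c("height", "sa", "tla", "sla",
                                             "n_leaf", "n_sapw")) {
  long <- tidyr::pivot_longer(
    traits[, c("species", "agr", intersect(predictors, names(traits)))],
    -c("species", "agr"), names_to = "trait", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$agr,
                                     colour = .data$species)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$trait), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "absolute biomass growth (kg / yr)") +
    ggplot2::theme_minimal()
}
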