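#' Trait-based growth inference
#'
#' The statistical stage of the pipeline: transform-and-scale design
#' construction, ordinary least squares with AIC bookkeeping, Cook's
#' distance diagnostics, species-by-trait interaction screening,
#' all-subsets regression, Akaike weights, delta-AIC < 2 model averaging
#' with adjusted standard errors and Akaike-weight variable importance,
#' regression imputation of sapwood area, the full sapwood-area model, the
#' saturated path model on species-centered variables, and the trait
#' summary table.
#'
#' @name inference
NULL

default_transforms <- c(
  agr = "log", ba = "log", sa = "log", tla = "sqrt",
  sla = "none", n_leaf = "none", n_sapw = "none", height = "none",
  sapwood_growth = "none", sapwood_lifespan = "none"
)

growth_predictors <- c("sa", "tla", "sla", "n_sapw", "height", "n_leaf")

apply_transform <- function(x, transform, var = "variable") {
  switch(transform,
    none = x,
    log = {
      if (any(x <= 0, na.rm = TRUE)) {
        stop("non-positive value under log transform of ", var, call. = FALSE)
      }
      log(x)
    },
    sqrt = {
      if (any(x < 0, na.rm = TRUE)) {
        stop("negative value under sqrt transform of ", var, call. = FALSE)
      }
      sqrt(x)
    },
    stop("unknown transform ", transform, call. = FALSE)
  )
}

transformed_name <- function(var, transform) {
  if (transform == "none") var else paste0(transform, "_", var)
}

#' Build a transformed, standardized design table from a trait table
#'
#' Applies the variable transforms (log for growth, basal area and sapwood
#' area; square root for total leaf area), then centers and SD-scales every
#' numeric column, and encodes species as a factor with *Sweetia* as the
#' reference level. The scaling metadata (per-column transform, center and
#' scale) is retained so results can be mapped back to natural units.
#'
#' @param traits A trait table (one row per tree) as returned by
#'   [derive_traits()] or [simulate_traits()].
#' @param response Trait used as response (default `"agr"`).
#' @param predictors Character vector of predictor traits.
#' @param transforms Named character vector (values `"log"`, `"sqrt"`,
#'   `"none"`) overriding the default transform per trait.
#' @param scale If `TRUE` (default) center and SD-scale all numeric
#'   columns.
#' @return A list of class `trait_design` with elements `data` (tibble:
#'   `tree_id`, `species` factor, scaled response and predictors),
#'   `response`, `predictors` (transformed column names) and `scaling`
#'   (tibble of transform/center/scale per column).
#' @export
trait_design <- function(traits, response = "agr",
                         predictors = growth_predictors,
                         transforms = default_transforms,
                         scale = TRUE) {
  transforms <- utils::modifyList(as.list(default_transforms),
                                  as.list(transforms))
  vars <- c(response, predictors)
  missing_vars <- setdiff(vars, names(traits))
  if (length(missing_vars) > 0) {
    stop("trait_design: trait table lacks column(s) ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }

  scaling <- purrr::map_dfr(vars, function(v) {
    tr <- transforms[[v]] %||% "none"
    x <- apply_transform(traits[[v]], tr, v)
    tibble::tibble(
      variable = v,
      column = transformed_name(v, tr),
      transform = tr,
      center = if (scale) mean(x, na.rm = TRUE) else 0,
      scale = if (scale) stats::sd(x, na.rm = TRUE) else 1
    )
  })

  data <- tibble::tibble(tree_id = as.character(traits$tree_id))
  if ("species" %in% names(traits)) {
    lev <- intersect(species_reference()$species, unique(traits$species))
    lev <- c(intersect("Sweetia", lev), setdiff(lev, "Sweetia"))
    data$species <- factor(traits$species, levels = lev)
  }
  for (i in seq_len(nrow(scaling))) {
    x <- apply_transform(traits[[scaling$variable[i]]], scaling$transform[i],
                         scaling$variable[i])
    data[[scaling$column[i]]] <- (x - scaling$center[i]) / scaling$scale[i]
  }

  structure(
    list(
      data = data,
      response = scaling$column[1],
      predictors = scaling$column[-1],
      scaling = scaling
    ),
    class = "trait_design"
  )
}

#' Ordinary least squares fit with AIC bookkeeping
#'
#' Fits `response ~ terms` by OLS on a design table and records the
#' quantities model selection needs: per-coefficient estimates, standard
#' errors, two-sided t-based p-values, the Gaussian log-likelihood with
#' maximum-likelihood residual variance, the parameter count `k` (the
#' residual variance counts as one parameter), and `aic = 2k - 2 logLik`.
#'
#' @param data Design tibble (e.g. `trait_design(...)$data`).
#' @param response Name of the response column.
#' @param terms Character vector of model terms (may be empty for the
#'   intercept-only model; may contain `species` and interaction terms like
#'   `"species:log_sa"`).
#' @param aicc If `TRUE` use the small-sample corrected criterion
#'   `AICc = AIC + 2k(k+1)/(n-k-1)` in the `aic` field.
#' @return A list of class `model_fit`: `fit` (the `lm` object),
#'   `terms`, `coefficients` (tibble term/estimate/se/t/p), `loglik`, `k`,
#'   `aic`, `n`, `response`.
#' @export
fit_ols <- function(data, response, terms = character(), aicc = FALSE) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = data)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("fit_ols: rank-deficient design; aliased term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  n <- length(stats::residuals(fit))
  k <- length(cf) + 1L # + residual variance
  if (n <= k - 1L) {
    stop("fit_ols: need n > number of coefficients", call. = FALSE)
  }
  ll <- as.numeric(stats::logLik(fit))
  aic <- 2 * k - 2 * ll
  if (aicc) {
    if (n - k - 1 <= 0) {
      stop("fit_ols: n too small for AICc with k = ", k, call. = FALSE)
    }
    aic <- aic + 2 * k * (k + 1) / (n - k - 1)
  }
  sm <- summary(fit)$coefficients
  structure(
    list(
      fit = fit,
      terms = terms,
      coefficients = tibble::tibble(
        term = rownames(sm),
        estimate = sm[, "Estimate"],
        se = sm[, "Std. Error"],
        t = sm[, "t value"],
        p = sm[, "Pr(>|t|)"]
      ),
      loglik = ll, k = k, aic = aic, n = n, response = response
    ),
    class = "model_fit"
  )
}

#' Cook's distance diagnostics for a fitted model
#'
#' Standard Cook's distance per observation with a `4/n` flag threshold.
#' Flagged observations are reported, never removed automatically.
#'
#' @param fit A `model_fit` from [fit_ols()] (or an `lm`).
#' @param threshold Flag threshold; default `4/n`.
#' @return A tibble with columns `obs`, `cooks_d`, `flagged`.
#' @export
cooks_flags <- function(fit, threshold = NULL) {
  lmfit <- if (inherits(fit, "model_fit")) fit$fit else fit
  d <- as.numeric(stats::cooks.distance(lmfit))
  n <- length(d)
  # an (essentially) exact fit has no residual scale: all distances are 0
  scale_ref <- mean(stats::fitted(lmfit)^2) + 1
  if (sum(stats::residuals(lmfit)^2) < 1e-20 * scale_ref) d <- rep(0, n)
  if (is.null(threshold)) threshold <- 4 / n
  tibble::tibble(obs = seq_len(n), cooks_d = d, flagged = d > threshold)
}

#' Screen species-by-trait interactions
#'
#' For each trait, compares the additive model (all traits + species) with
#' the model adding the species-by-trait interaction by a partial F-test,
#' and retains the interaction when `p < alpha`. Interactions lacking
#' residual degrees of freedom are skipped with a warning.
#'
#' @param design A `trait_design`.
#' @param alpha Retention level (default 0.05).
#' @return A tibble with columns `trait`, `df`, `f`, `p`, `retained`; the
#'   retained interaction term labels are in `attr(x, "retained")`.
#' @export
screen_interactions <- function(design, alpha = 0.05) {
  data <- design$data
  preds <- design$predictors
  if (!("species" %in% names(data)) || nlevels(data$species) < 2) {
    out <- tibble::tibble(trait = character(), df = integer(),
                          f = numeric(), p = numeric(), retained = logical())
    attr(out, "retained") <- character(0)
    return(out)
  }
  base_terms <- c(preds, "species")
  base <- fit_ols(data, design$response, base_terms)
  rows <- purrr::map_dfr(preds, function(tr) {
    int <- paste0("species:", tr)
    extra_df <- nlevels(data$species) - 1L
    if (base$n - (base$k - 1L) - extra_df < 1L) {
      warning("insufficient residual df for interaction ", int, "; skipped",
              call. = FALSE)
      return(tibble::tibble(trait = tr, df = NA_integer_, f = NA_real_,
                            p = NA_real_, retained = FALSE))
    }
    full <- fit_ols(data, design$response, c(base_terms, int))
    an <- stats::anova(base$fit, full$fit)
    tibble::tibble(trait = tr, df = as.integer(an$Df[2]), f = an$F[2],
                   p = an$`Pr(>F)`[2],
                   retained = !is.na(an$`Pr(>F)`[2]) && an$`Pr(>F)`[2] < alpha)
  })
  kept <- rows$trait[rows$retained & !is.na(rows$retained)]
  attr(rows, "retained") <- if (length(kept) == 0) character(0) else
    paste0("species:", kept)
  rows
}

#' All-subsets regression ranked by AIC
#'
#' Fits every admissible subset of the candidate terms (the species factor
#' enters or leaves as one block; an interaction is only admissible
#' together with both its main effects — the marginality constraint) and
#' returns all fits sorted by ascending AIC with ties kept in enumeration
#' order. The intercept-only model is always among the candidates.
#'
#' @param design A `trait_design`.
#' @param terms Candidate terms; defaults to the design's predictors plus
#'   `species` when present.
#' @param interactions Interaction terms (e.g. from
#'   [screen_interactions()]).
#' @param aicc Use AICc instead of AIC.
#' @param max_terms Combinatorial guard: refuse more than this many
#'   candidate terms (default 15).
#' @return A tibble of class `subset_models` with columns `model_id`,
#'   `terms` (list), `label`, `k`, `loglik`, `aic`, `delta`, `weight`
#'   (Akaike weights over all candidates) and `fit` (list of `model_fit`),
#'   sorted by `aic`.
#' @export
all_subsets <- function(design, terms = NULL, interactions = character(),
                        aicc = FALSE, max_terms = 15L) {
  data <- design$data
  if (is.null(terms)) {
    terms <- design$predictors
    if ("species" %in% names(data)) terms <- c(terms, "species")
  }
  terms <- c(terms, interactions)
  if (length(terms) > max_terms) {
    stop("all_subsets: ", length(terms), " candidate terms exceed the guard of ",
         max_terms, call. = FALSE)
  }

  requires <- function(term) {
    if (!grepl(":", term)) return(character(0))
    strsplit(term, ":", fixed = TRUE)[[1]]
  }

  n_terms <- length(terms)
  subsets <- purrr::map(seq_len(2^n_terms) - 1L, function(mask) {
    terms[bitwAnd(mask, bitwShiftL(1L, seq_len(n_terms) - 1L)) > 0L]
  })
  admissible <- purrr::map_lgl(subsets, function(s) {
    all(purrr::map_lgl(s, ~ all(requires(.x) %in% s)))
  })
  subsets <- subsets[admissible]

  fits <- purrr::map(subsets, ~ fit_ols(data, design$response, .x, aicc = aicc))
  out <- tibble::tibble(
    model_id = seq_along(fits),
    terms = subsets,
    label = purrr::map_chr(subsets, ~ if (length(.x) == 0) "(intercept)" else
      paste(.x, collapse = " + ")),
    k = purrr::map_int(fits, "k"),
    loglik = purrr::map_dbl(fits, "loglik"),
    aic = purrr::map_dbl(fits, "aic"),
    fit = fits
  )
  out <- out[order(out$aic), ]
  out$delta <- out$aic - out$aic[1]
  out$weight <- akaike_weights(out$aic)
  class(out) <- c("subset_models", class(tibble::tibble()))
  out[, c("model_id", "terms", "label", "k", "loglik", "aic", "delta",
          "weight", "fit")]
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AIC_i - min(AIC)`.
#'
#' @param aic Numeric vector of AIC values.
#' @return Weights summing to one.
#' @examples
#' akaike_weights(c(10, 12)) # ~0.731, 0.269
#' @export
akaike_weights <- function(aic) {
  if (length(aic) == 0) stop("akaike_weights: no models", call. = FALSE)
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w / sum(w)
}

term_variable <- function(coef_name) {
  # map a coefficient name back to its model term: factor-level suffixes on
  # the species dummies collapse onto the species block
  sub("^species[^:]*", "species", coef_name)
}

#' Average the models within a delta-AIC window
#'
#' Selects the models whose AIC differs from the best by less than
#' `delta_cut` (the best model is always selected), renormalizes Akaike
#' weights within that set, and averages coefficients across the selected
#' models. The primary report is the conditional (subset) average — each
#' coefficient averaged only over the models that contain it, with
#' adjusted standard error
#' `SE_adj = sum_i w_i * sqrt(SE_i^2 + (b_i - b_bar)^2)`
#' (weights renormalized over the containing models) and a normal
#' approximation for p-values. The full (zero-substitution) average is
#' reported alongside. Variable importance is the sum of selected-set
#' weights of the models containing the variable; a variable in every
#' selected model has importance exactly 1.
#'
#' @param candidates A `subset_models` table from [all_subsets()].
#' @param delta_cut Width of the selection window (default 2 AIC units).
#' @return An object of class `avg_model`: `component` (selected-model
#'   table with renormalized `weight`), `coefficients` (term, conditional
#'   `estimate`, `se_adj`, `z`, `p`, `estimate_full`, `importance`),
#'   `importance` (per variable), `best` (the best `model_fit`),
#'   `candidates`, `delta_cut`, `n`.
#' @export
average_models <- function(candidates, delta_cut = 2) {
  sel <- candidates[candidates$delta < delta_cut, ]
  if (nrow(sel) == 0) sel <- candidates[1, ]
  w <- akaike_weights(sel$aic)

  # variable-level importance (species block counts as one variable)
  vars <- unique(unlist(sel$terms))
  importance <- tibble::tibble(
    variable = vars,
    importance = purrr::map_dbl(vars, function(v) {
      sum(w[purrr::map_lgl(sel$terms, ~ v %in% .x)])
    })
  )
  importance <- importance[order(-importance$importance), ]

  # coefficient-level averaging
  coef_tables <- purrr::map2(sel$fit, w, function(f, wi) {
    dplyr::mutate(f$coefficients, w = wi,
                  model_terms = list(f$terms))
  })
  all_coefs <- dplyr::bind_rows(coef_tables)
  coef_names <- unique(all_coefs$term)

  coefficients <- purrr::map_dfr(coef_names, function(cn) {
    rows <- all_coefs[all_coefs$term == cn, ]
    wc <- rows$w / sum(rows$w)
    est <- sum(wc * rows$estimate)
    se_adj <- sum(wc * sqrt(rows$se^2 + (rows$estimate - est)^2))
    est_full <- sum(rows$w * rows$estimate) # absent models contribute 0
    z <- est / se_adj
    var <- if (cn == "(Intercept)") "(Intercept)" else term_variable(cn)
    imp <- if (var %in% importance$variable) {
      importance$importance[importance$variable == var]
    } else NA_real_
    tibble::tibble(term = cn, estimate = est, se_adj = se_adj,
                   z = z, p = 2 * stats::pnorm(-abs(z)),
                   estimate_full = est_full, importance = imp)
  })

  component <- sel
  component$weight <- w
  component$fit <- NULL

  structure(
    list(
      component = component,
      coefficients = coefficients,
      importance = importance,
      best = candidates$fit[[1]],
      candidates = candidates,
      delta_cut = delta_cut,
      n = candidates$fit[[1]]$n
    ),
    class = "avg_model"
  )
}

#' Fit the averaged growth model
#'
#' End-to-end inference for absolute biomass growth: builds the
#' transformed/scaled design (`log(agr)` on log sapwood area, sqrt total
#' leaf area, specific leaf area, sapwood and leaf nitrogen, and height,
#' with species as a factor), screens species-by-trait interactions,
#' enumerates all admissible subsets, and averages the models within
#' `delta_cut` AIC units of the best.
#'
#' @param traits A trait table. Rows with missing values in the model
#'   variables are dropped (impute first, see [impute_missing_sa()]).
#' @param response Response trait, `"agr"` (default) or any trait column
#'   (e.g. `"sapwood_growth"` for the basal-area-growth variant).
#' @param delta_cut,aicc,alpha See [average_models()], [fit_ols()],
#'   [screen_interactions()].
#' @param screen Screen species-by-trait interactions first (default
#'   `TRUE`).
#' @return An `avg_model` (see [average_models()]), with the design stored
#'   in `$design` and the interaction screen in `$interactions`.
#' @export
fit_growth_model <- function(traits, response = "agr", delta_cut = 2,
                             aicc = FALSE, screen = TRUE, alpha = 0.05) {
  vars <- c(response, growth_predictors)
  complete <- stats::complete.cases(traits[, vars])
  design <- trait_design(traits[complete, ], response = response)
  inter <- if (screen) screen_interactions(design, alpha = alpha) else NULL
  retained <- if (is.null(inter)) character(0) else attr(inter, "retained")
  cand <- all_subsets(design, interactions = retained, aicc = aicc)
  avg <- average_models(cand, delta_cut = delta_cut)
  avg$design <- design
  avg$interactions <- inter
  avg
}

#' Impute sapwood area for trees without a visible sapwood boundary
#'
#' Fits `log(sa)` on all other traits and `log(ba)` over the trees with
#' observed sapwood area (log growth, height, sqrt total leaf area,
#' specific leaf area, leaf and sapwood nitrogen, log basal area and
#' sapwood growth — sapwood lifespan is excluded because it is unobserved
#' exactly where sapwood area is), predicts the missing values, and flags
#' them with `sa_imputed = TRUE`. Observed rows are untouched.
#'
#' @param traits A trait table with possibly missing `sa`.
#' @return The trait table with `sa` filled and `sa_imputed` set.
#' @export
impute_missing_sa <- function(traits) {
  miss <- is.na(traits$sa)
  if (!any(miss)) return(traits)
  if (all(miss)) stop("impute_missing_sa: no observed sapwood area", call. = FALSE)
  if (dplyr::n_distinct(traits$species[!miss]) < 2) {
    stop("impute_missing_sa: need at least two species with observed sapwood area",
         call. = FALSE)
  }
  preds <- c("agr", "height", "tla", "sla", "n_leaf", "n_sapw", "ba",
             "sapwood_growth")
  design <- trait_design(traits, response = "sa", predictors = preds,
                         scale = FALSE)
  data <- design$data
  obs <- data[!miss, ]
  fit <- fit_ols(obs, design$response, design$predictors)
  pred_log_sa <- as.numeric(stats::predict(fit$fit, newdata = data[miss, ]))
  out <- traits
  out$sa[miss] <- exp(pred_log_sa)
  out$sa_imputed <- miss
  out
}

#' Fit the full sapwood-area model
#'
#' The determinants-of-sapwood-area model: scaled `log(sa)` on scaled
#' sapwood growth, sapwood lifespan and `log(ba)` plus species, fitted as
#' a single full model (no subset selection or averaging), reporting
#' standardized coefficients. Trees with missing or imputed sapwood area
#' are excluded.
#'
#' @param traits A trait table.
#' @return A `model_fit` (see [fit_ols()]) with the design in
#'   `attr(x, "design")`.
#' @export
fit_sa_model <- function(traits) {
  keep <- !is.na(traits$sa)
  if ("sa_imputed" %in% names(traits)) keep <- keep & !traits$sa_imputed
  sub <- traits[keep, ]
  design <- trait_design(sub, response = "sa",
                         predictors = c("sapwood_growth", "sapwood_lifespan", "ba"))
  terms <- design$predictors
  if ("species" %in% names(design$data) && nlevels(design$data$species) > 1) {
    terms <- c(terms, "species")
  }
  fit <- fit_ols(design$data, design$response, terms)
  attr(fit, "design") <- design
  fit
}

#' Saturated path model on species-centered variables
#'
#' Species-mean-centers `log(agr)`, `height`, `log(sa)` and `sqrt(tla)`
#' (removing the species intercept differences found in the averaged
#' model), regresses centered growth on the three centered predictors, and
#' reports the pairwise Pearson correlations among the predictors with
#' t-based p-values. The model is saturated (every path drawn), so path
#' coefficients coincide with the multiple-regression estimates and no
#' overall fit statistic exists.
#'
#' @param traits A trait table; rows with missing values in the four
#'   variables are dropped.
#' @return An object of class `path_fit`: `paths` (term, estimate, se, t,
#'   p), `correlations` (var1, var2, r, p), `n`, and the centered data in
#'   `$data`.
#' @export
path_analysis <- function(traits) {
  vars <- c("agr", "height", "sa", "tla")
  complete <- stats::complete.cases(traits[, vars])
  sub <- traits[complete, ]
  design <- trait_design(sub, response = "agr",
                         predictors = c("height", "sa", "tla"), scale = FALSE)
  data <- design$data
  singletons <- names(which(table(sub$species) == 1))
  if (length(singletons) > 0) {
    warning("species with a single tree (centered values are 0): ",
            paste(singletons, collapse = ", "), call. = FALSE)
  }
  cols <- c(design$response, design$predictors)
  for (cl in cols) {
    data[[cl]] <- data[[cl]] - stats::ave(data[[cl]], data$species)
  }
  fit <- fit_ols(data, design$response, design$predictors)
  paths <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]

  pairs <- utils::combn(design$predictors, 2)
  correlations <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    ct <- stats::cor.test(data[[pairs[1, j]]], data[[pairs[2, j]]])
    tibble::tibble(var1 = pairs[1, j], var2 = pairs[2, j],
                   r = unname(ct$estimate), p = ct$p.value)
  })

  structure(
    list(paths = paths, correlations = correlations, n = nrow(data),
         data = data, fit = fit),
    class = "path_fit"
  )
}

#' Summary statistics of the trait table
#'
#' Per trait: mean, minimum, maximum, sample SD (denominator n - 1) and
#' coefficient of variation `cv = sd / mean`.
#'
#' @param traits A trait table.
#' @param variables Trait columns to summarize; defaults to the ten
#'   standard trait variables present in the table.
#' @return A tibble with columns `variable`, `mean`, `min`, `max`, `sd`,
#'   `cv`.
#' @export
summarize_traits <- function(traits,
                             variables = c("agr", "height", "tla", "sa",
                                           "sla", "n_leaf", "n_sapw", "ba",
                                           "sapwood_lifespan",
                                           "sapwood_growth")) {
  variables <- intersect(variables, names(traits))
  if (nrow(traits) < 2) {
    stop("summarize_traits: need at least two trees", call. = FALSE)
  }
  purrr::map_dfr(variables, function(v) {
    x <- traits[[v]]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      warning("summarize_traits: all values missing for ", v, call. = FALSE)
      return(tibble::tibble(variable = v, mean = NA_real_, min = NA_real_,
                            max = NA_real_, sd = NA_real_, cv = NA_real_))
    }
    m <- mean(x)
    s <- stats::sd(x)
    tibble::tibble(variable = v, mean = m, min = min(x), max = max(x),
                   sd = s, cv = s / m)
  })
}
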