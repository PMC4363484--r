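sim_traits_430 <- local({
  tr <- NULL
  function() {
    if (is.null(tr)) tr <<- sapgrow::simulate_traits(test_config(), seed = 7,
                                                     n_scale = 10L)
    tr
  }
})

test_that("the design matrix is transformed, scaled and reference-coded", {
  tr <- simulate_traits(test_config(), seed = 2)
  d <- trait_design(attr(tr, "ground_truth"))
  for (col in c(d$response, d$predictors)) {
    expect_equal(mean(d$data[[col]]), 0, tolerance = 1e-12)
    expect_equal(sd(d$data[[col]]), 1, tolerance = 1e-12)
  }
  expect_identical(levels(d$data$species)[1], "Sweetia")
  expect_identical(d$response, "log_agr")
  expect_setequal(d$predictors, c("log_sa", "sqrt_tla", "sla", "n_sapw",
                                  "height", "n_leaf"))
  # scaling commutes with relabeling (row permutation) of trees
  gt <- attr(tr, "ground_truth")
  perm <- sample(nrow(gt))
  d2 <- trait_design(gt[perm, ])
  expect_equal(d2$data$log_sa, d$data$log_sa[perm])
  # non-positive values under log are refused
  bad <- gt
  bad$sa[3] <- -1
  expect_error(trait_design(bad), "non-positive value under log")
})

test_that("OLS matches an independent normal-equations solve", {
  set.seed(42)
  n <- 20
  data <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  data$y <- 1 + 2 * data$x1 - data$x2 + rnorm(n)
  fit <- fit_ols(data, "y", c("x1", "x2", "x3"))
  X <- cbind(1, data$x1, data$x2, data$x3)
  beta <- solve(crossprod(X), crossprod(X, data$y)) # the oracle
  expect_equal(unname(fit$coefficients$estimate), as.numeric(beta),
               tolerance = 1e-10)
  # noiseless data is reproduced exactly
  data$y0 <- 2 * data$x1 - data$x2
  fit0 <- suppressWarnings(fit_ols(data, "y0", c("x1", "x2")))
  expect_equal(unname(fit0$coefficients$estimate), c(0, 2, -1),
               tolerance = 1e-10)
  expect_lt(sum(residuals(fit0$fit)^2), 1e-20)
})

test_that("the information criterion identity holds for every fit", {
  d <- trait_design(attr(sim_traits_430(), "ground_truth"))
  cand <- all_subsets(d, terms = c("log_sa", "sqrt_tla", "species"))
  expect_equal(cand$aic, 2 * cand$k - 2 * cand$loglik, tolerance = 1e-10)
  # AICc adds the small-sample correction
  f <- fit_ols(d$data, d$response, "log_sa", aicc = TRUE)
  f0 <- fit_ols(d$data, d$response, "log_sa")
  k <- f0$k; n <- f0$n
  expect_equal(f$aic, f0$aic + 2 * k * (k + 1) / (n - k - 1))
  # rank deficiency is an error naming the aliased term
  dd <- d$data
  dd$dup <- dd$log_sa
  expect_error(fit_ols(dd, d$response, c("log_sa", "dup")), "dup")
})

test_that("Cook's distance equals the leave-one-out definition", {
  set.seed(7)
  n <- 10
  data <- tibble::tibble(x = rnorm(n))
  data$y <- 1 + data$x + rnorm(n)
  fit <- fit_ols(data, "y", "x")
  cd <- cooks_flags(fit)
  # brute-force leave-one-out oracle
  p <- 2
  s2 <- sum(residuals(fit$fit)^2) / (n - p)
  d_loo <- vapply(seq_len(n), function(i) {
    f_i <- lm(y ~ x, data = data[-i, ])
    yh <- predict(fit$fit, newdata = data)
    yh_i <- predict(f_i, newdata = data)
    sum((yh - yh_i)^2) / (p * s2)
  }, numeric(1))
  expect_equal(cd$cooks_d, d_loo, tolerance = 1e-10)

  # an exact fit has zero distances everywhere
  data$y2 <- 2 + 3 * data$x
  cd0 <- cooks_flags(suppressWarnings(fit_ols(data, "y2", "x")))
  expect_equal(cd0$cooks_d, rep(0, n), tolerance = 1e-20)

  # a gross y-outlier carries the largest distance and is flagged
  data$y3 <- data$y
  data$y3[4] <- data$y3[4] + 50
  cd3 <- cooks_flags(fit_ols(data, "y3", "x"))
  expect_identical(which.max(cd3$cooks_d), 4L)
  expect_true(cd3$flagged[4])
})

test_that("Akaike weights follow the exponential delta rule", {
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  expect_equal(akaike_weights(c(10, 12)),
               c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(akaike_weights(c(10, 12)), 4), c(0.7311, 0.2689))
  set.seed(3)
  for (i in 1:5) expect_equal(sum(akaike_weights(runif(7, 0, 50))), 1)
})

test_that("all-subsets enumeration is complete, sorted and marginal", {
  d <- trait_design(attr(sim_traits_430(), "ground_truth"))
  cand <- all_subsets(d, terms = c("log_sa", "sqrt_tla", "sla", "species"))
  expect_identical(nrow(cand), 16L) # 2^4
  expect_true(any(purrr::map_int(cand$terms, length) == 0)) # intercept-only
  expect_true(!is.unsorted(cand$aic))
  expect_equal(cand$delta, cand$aic - min(cand$aic))

  # independent exhaustive oracle: refit every subset directly with lm
  terms <- c("log_sa", "sqrt_tla", "sla", "species")
  oracle_aic <- purrr::map_dbl(0:15, function(mask) {
    sub <- terms[bitwAnd(mask, 2^(0:3)) > 0]
    rhs <- if (length(sub) == 0) "1" else paste(sub, collapse = "+")
    f <- lm(as.formula(paste("log_agr ~", rhs)), data = d$data)
    2 * (length(coef(f)) + 1) - 2 * as.numeric(logLik(f))
  })
  expect_equal(min(cand$aic), min(oracle_aic), tolerance = 1e-10)
  expect_equal(sort(cand$aic), sort(oracle_aic), tolerance = 1e-10)

  # marginality: an interaction never appears without both main effects
  cand_i <- all_subsets(d, terms = c("log_sa", "species"),
                        interactions = "species:log_sa")
  has <- function(s, t) purrr::map_lgl(cand_i$terms, ~ t %in% .x)
  bad <- has(cand_i, "species:log_sa") &
    !(has(cand_i, "species") & has(cand_i, "log_sa"))
  expect_false(any(bad))
  expect_identical(nrow(cand_i), 5L) # {}, {sa}, {sp}, {sa,sp}, {sa,sp,int}

  expect_error(all_subsets(d, terms = paste0("t", 1:16)), "exceed the guard")
})

test_that("model averaging follows the conditional Burnham-Anderson rules", {
  # hand-built candidate set: two models with equal AIC, beta 0.5 and 0.7
  mk_fit <- function(terms, beta, se, aic) {
    structure(list(terms = terms,
                   coefficients = tibble::tibble(
                     term = c("(Intercept)", terms),
                     estimate = c(0, beta), se = c(0.1, se),
                     t = 0, p = 0.5),
                   loglik = -aic / 2 + 3, k = 3, aic = aic, n = 43,
                   response = "y"), class = "model_fit")
  }
  cand <- tibble::tibble(
    model_id = 1:3,
    terms = list(c("x1"), c("x1"), c("x1", "x2")),
    label = c("a", "b", "c"),
    k = 3L, loglik = 0,
    aic = c(100, 100, 104),
    fit = list(mk_fit("x1", 0.5, 0.2, 100), mk_fit("x1", 0.7, 0.2, 100),
               mk_fit(c("x1", "x2"), c(0.6, 0.1), c(0.2, 0.1), 104))
  )
  cand <- cand[order(cand$aic), ]
  cand$delta <- cand$aic - min(cand$aic)
  cand$weight <- akaike_weights(cand$aic)
  avg <- average_models(cand, delta_cut = 2)

  expect_identical(nrow(avg$component), 2L)
  expect_equal(avg$component$weight, c(0.5, 0.5))
  b <- avg$coefficients
  expect_equal(b$estimate[b$term == "x1"], 0.6)
  # SE_adj = sum w_i sqrt(se^2 + (b_i - bbar)^2)
  expect_equal(b$se_adj[b$term == "x1"],
               0.5 * sqrt(0.04 + 0.01) + 0.5 * sqrt(0.04 + 0.01))
  expect_equal(avg$importance$importance[avg$importance$variable == "x1"], 1)
  # full (zero-substitution) average equals the conditional one here
  expect_equal(b$estimate_full[b$term == "x1"], 0.6)

  # a single model within the cut reproduces that model
  cand1 <- cand
  cand1$aic <- c(100, 104, 108)
  cand1$delta <- cand1$aic - 100
  cand1$weight <- akaike_weights(cand1$aic)
  avg1 <- average_models(cand1, delta_cut = 2)
  expect_identical(nrow(avg1$component), 1L)
  expect_equal(avg1$coefficients$estimate[avg1$coefficients$term == "x1"], 0.5)
  expect_true(all(avg1$importance$importance == 1))
})

test_that("averaged coefficients stay within the component-model range", {
  gt <- attr(sim_traits_430(), "ground_truth")
  g <- fit_growth_model(gt, delta_cut = 6) # widen the set to force mixing
  sel <- g$candidates[g$candidates$delta < 6, ]
  for (cn in g$coefficients$term) {
    ests <- purrr::map_dbl(sel$fit, function(f) {
      e <- f$coefficients$estimate[f$coefficients$term == cn]
      if (length(e) == 0) NA_real_ else e
    })
    rng <- range(ests, na.rm = TRUE)
    est <- g$coefficients$estimate[g$coefficients$term == cn]
    expect_gte(est, rng[1] - 1e-12)
    expect_lte(est, rng[2] + 1e-12)
  }
})

test_that("interaction screening has power and respects the null", {
  cfg <- test_config()
  # no interactions in the generator: retention should be near alpha
  set.seed(11)
  retained <- 0L
  tested <- 0L
  for (i in 1:60) {
    tr <- simulate_traits(cfg, seed = 3000 + i, n_scale = 10L)
    si <- screen_interactions(trait_design(attr(tr, "ground_truth")))
    retained <- retained + sum(si$retained, na.rm = TRUE)
    tested <- tested + sum(!is.na(si$p))
  }
  rate <- retained / tested
  # 360 tests at alpha 0.05: binomial 99% CI is about (0.022, 0.083)
  expect_gt(rate, 0.015)
  expect_lt(rate, 0.09)

  # a strong species-by-SA slope difference is detected
  gt <- attr(simulate_traits(cfg, seed = 99, n_scale = 10L), "ground_truth")
  gt$agr <- gt$agr * exp(0.8 * (gt$species == "Hura") * scale(log(gt$sa))[, 1])
  si <- screen_interactions(trait_design(gt))
  expect_true(si$retained[si$trait == "log_sa"])

  # single-species data: nothing testable
  one <- gt[gt$species == "Hura", ]
  si1 <- screen_interactions(trait_design(one))
  expect_identical(attr(si1, "retained"), character(0))
})

test_that("sapwood-area imputation recovers the hidden values", {
  cfg <- test_config()
  tr <- simulate_traits(cfg, seed = 5)
  full <- attr(tr, "ground_truth")
  # no missing values: table comes back unchanged
  expect_identical(impute_missing_sa(full)$sa, full$sa)
  # all missing: error
  allna <- tr
  allna$sa <- NA_real_
  expect_error(impute_missing_sa(allna), "no observed sapwood area")

  # imputed values correlate with the masked truth (100 replicates, n = 43;
  # 9 hidden trees per replicate). The achievable correlation is capped by
  # the within-species predictability of sapwood area in the generator,
  # measured at ~0.73 over this harness.
  set.seed(12)
  r <- purrr::map_dbl(1:100, function(i) {
    tri <- simulate_traits(cfg, seed = 5000 + i)
    gti <- attr(tri, "ground_truth")
    imp <- impute_missing_sa(tri)
    idx <- imp$sa_imputed
    cor(log(imp$sa[idx]), log(gti$sa[idx]))
  })
  expect_gt(mean(r), 0.65)
  expect_gt(median(r), 0.65)

  # growth-model conclusions agree with and without the imputed species
  big <- simulate_traits(cfg, seed = 77, n_scale = 10L)
  with_imp <- fit_growth_model(impute_missing_sa(big))
  without <- fit_growth_model(big) # complete cases only
  b1 <- with_imp$coefficients
  b2 <- without$coefficients
  shared <- intersect(b1$term, b2$term)
  shared <- setdiff(shared, "(Intercept)")
  s1 <- sign(b1$estimate[match(shared, b1$term)])
  s2 <- sign(b2$estimate[match(shared, b2$term)])
  expect_gt(mean(s1 == s2), 0.8)
  expect_lt(b1$p[b1$term == "log_sa"], 0.001)
  expect_lt(b2$p[b2$term == "log_sa"], 0.001)
})

test_that("the sapwood-area model reports positive standardized effects", {
  fit <- fit_sa_model(sim_traits_430())
  cf <- fit$coefficients
  for (term in c("sapwood_growth", "sapwood_lifespan", "log_ba")) {
    expect_gt(cf$estimate[cf$term == term], 0)
  }
  # imputed rows are excluded from the fit
  imp <- impute_missing_sa(sim_traits_430())
  fit2 <- fit_sa_model(imp)
  expect_identical(fit2$n, fit$n)
})

test_that("path coefficients equal OLS on species-centered data", {
  tr <- attr(sim_traits_430(), "ground_truth")
  p <- path_analysis(tr)
  # independent oracle: center by species and fit lm directly
  ctr <- function(x, g) x - ave(x, g)
  d <- data.frame(
    y = ctr(log(tr$agr), tr$species), h = ctr(tr$height, tr$species),
    sa = ctr(log(tr$sa), tr$species), tla = ctr(sqrt(tr$tla), tr$species)
  )
  oracle <- coef(lm(y ~ h + sa + tla, d))
  expect_equal(unname(p$paths$estimate), unname(oracle[-1]), tolerance = 1e-10)
  expect_true(all(abs(p$correlations$r) <= 1))
  # correlations are symmetric in their arguments
  expect_equal(p$correlations$r[1], cor(d$h, d$sa), tolerance = 1e-12)

  # a species with a single tree warns (its centered values are all zero)
  small <- tr[c(which(tr$species == "Hura"), which(tr$species == "Sweetia")[1]), ]
  expect_warning(path_analysis(small), "single tree")
})

test_that("path coefficients equal simple slopes for orthogonal predictors", {
  set.seed(21)
  n <- 400
  base <- attr(sim_traits_430(), "ground_truth")[1:n, ]
  # replace the predictors by centered orthogonal columns on the
  # transformed scales (orthogonal to the intercept as well)
  q <- qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)))
  tr <- base
  tr$height <- 25 + q[, 1]
  tr$sa <- exp(-1.8 + q[, 2])
  tr$tla <- (36 + q[, 3])^2
  tr$agr <- exp(4.4 + 0.5 * q[, 1] + 0.3 * q[, 2] + rnorm(n, 0, 0.1))
  tr$species <- "Hura" # one species: centering is plain centering
  suppressWarnings(p <- path_analysis(tr))
  d <- data.frame(y = log(tr$agr) - mean(log(tr$agr)),
                  h = tr$height - mean(tr$height),
                  sa = log(tr$sa) - mean(log(tr$sa)))
  simple_h <- coef(lm(y ~ h, d))[2]
  expect_equal(unname(p$paths$estimate[p$paths$term == "height"]),
               unname(simple_h), tolerance = 1e-6)
})

test_that("trait summaries compute mean, range, SD and CV", {
  # a two-point sample {m - s/sqrt(2), m + s/sqrt(2)} has mean m and SD s
  two_point <- function(m, s) c(m - s / sqrt(2), m + s / sqrt(2))
  tr <- tibble::tibble(agr = two_point(105.43, 80.68),
                       n_sapw = two_point(0.25, 0.09))
  s <- summarize_traits(tr, variables = c("agr", "n_sapw"))
  expect_equal(s$mean, c(105.43, 0.25))
  expect_equal(s$sd, c(80.68, 0.09))
  expect_equal(round(s$cv, 2), c(0.77, 0.36))
  expect_equal(s$cv, s$sd / s$mean)

  cons <- tibble::tibble(sla = rep(100, 5), tla = rep(2, 5))
  s2 <- summarize_traits(cons, variables = c("sla", "tla"))
  expect_equal(s2$sd, c(0, 0))
  expect_equal(s2$cv, c(0, 0))

  tr$sa <- NA_real_
  expect_warning(s3 <- summarize_traits(tr, variables = c("agr", "sa")),
                 "all values missing")
  expect_true(is.na(s3$cv[s3$variable == "sa"]))
  expect_error(summarize_traits(tr[1, ]), "at least two")
})

test_that("the leaf-area to sapwood-area ratio test runs as a derived column", {
  # the whole-tree hydraulic-supply check: growth on the TLA:SA ratio with
  # a species factor, expressed with the existing design tools
  gt <- attr(sim_traits_430(), "ground_truth")
  gt$tla_sa_ratio <- gt$tla / (gt$sa * 1e4)
  d <- trait_design(gt, response = "agr", predictors = "tla_sa_ratio",
                    transforms = c(tla_sa_ratio = "none"))
  fit <- fit_ols(d$data, d$response, c("tla_sa_ratio", "species"))
  row <- fit$coefficients[fit$coefficients$term == "tla_sa_ratio", ]
  expect_true(is.finite(row$t) && is.finite(row$p))
  expect_true(row$p >= 0 && row$p <= 1)
})
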