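#' End-to-end pipeline and reporting
#'
#' [run_pipeline()] chains the stages — simulate (or ingest provided CSV
#' tables), derive disc and tree-level traits, fit the growth and
#' sapwood-area models and the path model — writing every tabular artifact
#' plus a run manifest to an output directory. [render_report()] formats
#' the inference results as a plain-text report mirroring the layout of
#' the published summary and model tables.
#'
#' @name pipeline
NULL

file_digest <- function(path) {
  # small structural digest (no external tooling): size + cheap checksum
  bytes <- readBin(path, "raw", file.info(path)$size)
  sprintf("%d-%08x", length(bytes),
          sum(as.integer(bytes) * (seq_along(bytes) %% 251)) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Stages: `simulate` (skipped when `input_dir` provides raw CSV tables),
#' `derive` (disc derivations and trait table, with validation),
#' `fit` (sapwood-area imputation, averaged growth model, sapwood-area
#' model, path model, trait summary), `report`. Artifacts written to
#' `out_dir`: the six raw tables (when simulated), `derived_discs.csv`,
#' `traits.csv`, `trait_summary.csv`, `growth_model_coefficients.csv`,
#' `growth_model_components.csv`, `growth_model_importance.csv`,
#' `sa_model_coefficients.csv`, `path_model.csv`, `model_report.txt`, and
#' `manifest.json`. Fails at a stage leave earlier artifacts in place and
#' record the failing stage in the manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for simulation.
#' @param cfg A `sim_config`; `default_config()` if omitted.
#' @param input_dir Optional directory of raw CSV tables to ingest instead
#'   of simulating.
#' @param n_scale Species-count multiplier for simulation.
#' @return Invisibly, a list with the fitted objects, the trait table and
#'   the manifest; `$status` is 0 on success, 2 on a validation failure,
#'   3 on an inference failure.
#' @export
run_pipeline <- function(out_dir, seed = 1L, cfg = NULL, input_dir = NULL,
                         n_scale = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg)) cfg <- default_config()
  manifest <- list(
    package_version = as.character(utils::packageVersion("sapgrow")),
    seed = as.integer(seed),
    n_scale = as.integer(n_scale),
    config_hash = structural_key(cfg),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(),
    inputs = list(),
    status = "running"
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  fail <- function(stage, e, status) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    write_manifest()
    warning("pipeline failed at stage '", stage, "': ", conditionMessage(e),
            call. = FALSE)
    list(status = status, manifest = manifest)
  }

  # --- stage: simulate or ingest -------------------------------------
  field <- tryCatch({
    if (is.null(input_dir)) {
      f <- simulate_field_data(cfg, seed = seed, n_scale = n_scale)
      write_field_tables(f, out_dir)
      manifest$stages$simulate <- list(n_trees = nrow(f$trees))
      f
    } else {
      f <- read_field_tables(input_dir)
      manifest$inputs <- purrr::map(
        stats::setNames(names(field_schemas), names(field_schemas)),
        function(nm) file_digest(file.path(input_dir, paste0(nm, ".csv")))
      )
      manifest$stages$ingest <- list(n_trees = nrow(f$trees))
      f
    }
  }, error = function(e) e)
  if (inherits(field, "error")) return(invisible(fail("simulate", field, 2L)))

  # --- stage: derive --------------------------------------------------
  derived <- tryCatch({
    violations <- validate_field_data(field)
    if (nrow(violations) > 0) {
      readr::write_csv(violations, file.path(out_dir, "validation_violations.csv"))
      stop(nrow(violations), " validation violation(s); see validation_violations.csv")
    }
    discs <- derive_discs(field)
    traits <- derive_traits(field)
    readr::write_csv(discs, file.path(out_dir, "derived_discs.csv"))
    readr::write_csv(traits, file.path(out_dir, "traits.csv"))
    manifest$stages$derive <- list(n_discs = nrow(discs),
                                   n_traits = nrow(traits))
    list(discs = discs, traits = traits)
  }, error = function(e) e)
  if (inherits(derived, "error")) return(invisible(fail("derive", derived, 2L)))

  # --- stage: fit -----------------------------------------------------
  fits <- tryCatch({
    traits <- impute_missing_sa(derived$traits)
    growth <- fit_growth_model(traits)
    sa_fit <- fit_sa_model(traits)
    path <- path_analysis(traits)
    summary_tbl <- summarize_traits(derived$traits)
    readr::write_csv(summary_tbl, file.path(out_dir, "trait_summary.csv"))
    readr::write_csv(tidy(growth), file.path(out_dir, "growth_model_coefficients.csv"))
    readr::write_csv(growth$component[, c("label", "k", "aic", "delta", "weight")],
                     file.path(out_dir, "growth_model_components.csv"))
    readr::write_csv(growth$importance, file.path(out_dir, "growth_model_importance.csv"))
    readr::write_csv(tidy(sa_fit), file.path(out_dir, "sa_model_coefficients.csv"))
    readr::write_csv(tidy(path), file.path(out_dir, "path_model.csv"))
    manifest$stages$fit <- list(
      n_growth_candidates = nrow(growth$candidates),
      n_growth_component = nrow(growth$component),
      n_imputed_sa = sum(traits$sa_imputed)
    )
    list(traits = traits, growth = growth, sa = sa_fit, path = path,
         summary = summary_tbl)
  }, error = function(e) e)
  if (inherits(fits, "error")) return(invisible(fail("fit", fits, 3L)))

  # --- stage: report --------------------------------------------------
  report <- tryCatch({
    lines <- render_report(list(summary = fits$summary, growth = fits$growth,
                                sa = fits$sa, path = fits$path))
    writeLines(lines, file.path(out_dir, "model_report.txt"))
    manifest$stages$report <- list(lines = length(lines))
    lines
  }, error = function(e) e)
  if (inherits(report, "error")) return(invisible(fail("report", report, 3L)))

  manifest$status <- "ok"
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_manifest()
  invisible(list(status = 0L, field = field, discs = derived$discs,
                 traits = fits$traits, growth = fits$growth, sa = fits$sa,
                 path = fits$path, summary = fits$summary,
                 manifest = manifest, report = report))
}

fmt_num <- function(x, digits = 3) {
  formatC(x, format = "fg", digits = digits, flag = "#")
}

#' Render a plain-text model report
#'
#' Formats the trait summary (mean / min / max / SD / CV), the averaged
#' growth model (conditional coefficient, adjusted SE, z, P, relative
#' importance, plus the component-model table with delta-AIC and weight),
#' the full sapwood-area model, and the path model.
#'
#' @param results A list with elements `summary` (from
#'   [summarize_traits()]), `growth` (an `avg_model`), `sa` (a
#'   `model_fit`) and `path` (a `path_fit`); any element may be `NULL`.
#' @return A character vector of report lines.
#' @export
render_report <- function(results) {
  out <- c("Sapwood-driven biomass growth: model report",
           strrep("=", 44), "")
  pad <- function(x, w) formatC(x, width = w)

  if (!is.null(results$summary)) {
    s <- results$summary
    out <- c(out, "Trait summary", strrep("-", 13),
             sprintf("%-18s %10s %10s %10s %10s %6s",
                     "variable", "mean", "min", "max", "SD", "CV"),
             sprintf("%-18s %10s %10s %10s %10s %6.2f",
                     s$variable, fmt_num(s$mean, 4), fmt_num(s$min, 4),
                     fmt_num(s$max, 4), fmt_num(s$sd, 4), s$cv),
             "")
  }

  if (!is.null(results$growth)) {
    g <- results$growth
    out <- c(out, "Averaged growth model", strrep("-", 21),
             sprintf("component models (delta-AIC < %g):", g$delta_cut),
             sprintf("  %-60s %7s %6s %6s", "terms", "AIC", "dAIC", "w"),
             sprintf("  %-60s %7.2f %6.2f %6.3f",
                     substr(g$component$label, 1, 60), g$component$aic,
                     g$component$delta, g$component$weight),
             "",
             sprintf("  %-22s %8s %8s %7s %8s %11s",
                     "term", "beta", "SEadj", "z", "P", "importance"),
             sprintf("  %-22s %8.3f %8.3f %7.2f %8.4f %11s",
                     g$coefficients$term, g$coefficients$estimate,
                     g$coefficients$se_adj, g$coefficients$z,
                     g$coefficients$p,
                     ifelse(is.na(g$coefficients$importance), "",
                            sprintf("%.2f", g$coefficients$importance))),
             "")
  }

  if (!is.null(results$sa)) {
    cf <- results$sa$coefficients
    out <- c(out, "Sapwood-area model (full model, no averaging)",
             strrep("-", 45),
             sprintf("  %-22s %8s %8s %7s %8s",
                     "term", "beta", "SE", "t", "P"),
             sprintf("  %-22s %8.3f %8.3f %7.2f %8.4f",
                     cf$term, cf$estimate, cf$se, cf$t, cf$p),
             "")
  }

  if (!is.null(results$path)) {
    p <- results$path
    out <- c(out, "Path model (species-mean-centered, saturated)",
             strrep("-", 45),
             sprintf("  path %-28s %8.3f  (p = %.4f)",
                     paste(p$paths$term, "-> growth"), p$paths$estimate,
                     p$paths$p),
             sprintf("  corr %-28s %8.3f  (p = %.4f)",
                     paste(p$correlations$var1, "~", p$correlations$var2),
                     p$correlations$r, p$correlations$p),
             "")
  }
  out
}
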