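#' Raw field-measurement tables: schemas, I/O and validation
#'
#' A "field dataset" is a named list of five tibbles mirroring the field
#' sheets for felled-tree sampling:
#'
#' * `trees`: one row per tree — `tree_id`, `species`, `total_height_m`,
#'   `stem_height_m` (height to the first major branch),
#'   `pooled_leaf_area_cm2`, `pooled_leaf_dry_mass_g`, `n_leaf_pct`,
#'   `n_sapw_pct`.
#' * `discs`: one row per stem disc (two per tree: ~1 m and just below the
#'   first branch) — `tree_id`, `disc_id`, `height_m`, inside-bark radii
#'   `radius_long_cm`, `radius_short_cm`, `radius_mid_cm`, bark thickness
#'   `bark1_cm`..`bark4_cm`, per-radius sapwood and heartwood radial
#'   lengths `sapwood1_cm`..`sapwood3_cm`, `heartwood1_cm`..`heartwood3_cm`
#'   (NA when no sapwood boundary is visible), `pith_diameter_cm`.
#' * `rings`: long format, 3 radii x 5 years per disc — `tree_id`,
#'   `disc_id`, `radius_index` (1..3), `year_index` (1..5), `width_cm`.
#' * `ring15`: per-radius 15-year mean ring width — `tree_id`, `disc_id`,
#'   `radius_index`, `mean_width_15yr_cm`.
#' * `wood_samples`: radial wood samples per disc — `tree_id`, `disc_id`,
#'   `position_index` (1 = youngest sapwood, at the cambium),
#'   `fresh_volume_cm3`, `dry_mass_g`.
#' * `branches`: 4-5 branches per tree — `tree_id`, `branch_id`, `ba_cm2`
#'   (cross-sectional basal area excluding bark), `n_shoots`,
#'   `leaves_per_shoot_1`..`leaves_per_shoot_5`, `leaf_area_cm2` (pooled
#'   area of the five harvested leaves of that branch).
#'
#' Units are fixed per column (cm for disc geometry, m for heights, cm^2
#' for branch basal area) and converted only inside derivation functions.
#'
#' @name data_model
NULL

field_schemas <- list(
  trees = c("tree_id", "species", "total_height_m", "stem_height_m",
            "pooled_leaf_area_cm2", "pooled_leaf_dry_mass_g",
            "n_leaf_pct", "n_sapw_pct"),
  discs = c("tree_id", "disc_id", "height_m", "radius_long_cm",
            "radius_short_cm", "radius_mid_cm", "bark1_cm", "bark2_cm",
            "bark3_cm", "bark4_cm", "sapwood1_cm", "sapwood2_cm",
            "sapwood3_cm", "heartwood1_cm", "heartwood2_cm", "heartwood3_cm",
            "pith_diameter_cm"),
  rings = c("tree_id", "disc_id", "radius_index", "year_index", "width_cm"),
  ring15 = c("tree_id", "disc_id", "radius_index", "mean_width_15yr_cm"),
  wood_samples = c("tree_id", "disc_id", "position_index",
                   "fresh_volume_cm3", "dry_mass_g"),
  branches = c("tree_id", "branch_id", "ba_cm2", "n_shoots",
               "leaves_per_shoot_1", "leaves_per_shoot_2",
               "leaves_per_shoot_3", "leaves_per_shoot_4",
               "leaves_per_shoot_5", "leaf_area_cm2")
)

#' Reference table for the four study species
#'
#' Species-level properties: family, ecological guild (long-lived pioneer
#' `LLP` or partially shade-tolerant `PST`), maximum tree height (m),
#' average juvenile crown exposure index (1-5), and mean wood density at
#' breast height (g cm^-3).
#'
#' @return A tibble with one row per species.
#' @export
species_reference <- function() {
  tibble::tibble(
    species = c("Schizolobium", "Sweetia", "Hura", "Cariniana"),
    family = c("Fabaceae/Caesalpiniaceae", "Fabaceae/Papillionaceae",
               "Euphorbiaceae", "Lecythidaceae"),
    guild = c("LLP", "LLP", "PST", "PST"),
    max_height_m = c(35, 30, 44, 45),
    ce_juv = c(2.39, 1.91, 1.62, 1.74),
    wd_breast_height = c(0.45, 0.82, 0.37, 0.36)
  )
}

check_schema <- function(df, table) {
  missing <- setdiff(field_schemas[[table]], names(df))
  if (length(missing) > 0) {
    stop("schema error in ", table, ".csv: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[field_schemas[[table]]]
}

#' Read the raw field-measurement CSV tables
#'
#' Reads `trees.csv`, `discs.csv`, `rings.csv`, `ring15.csv`,
#' `wood_samples.csv` and `branches.csv` from a directory, checks each
#' against its documented schema, checks referential integrity (every disc,
#' ring, wood-sample and branch row must point at a known tree; rings,
#' 15-year means and wood samples at a known disc), and canonicalizes
#' species names against [species_reference()] (case-insensitive).
#'
#' @param dir Directory containing the CSV files.
#' @param radii_outside_bark If `TRUE`, the disc radii in `discs.csv` were
#'   measured outside the bark and the mean of the four bark-thickness
#'   measurements is subtracted from each radius on read. Default `FALSE`
#'   (radii inside bark, the storage convention).
#' @return A field dataset (named list of tibbles) of class `field_data`.
#' @export
read_field_tables <- function(dir, radii_outside_bark = FALSE) {
  paths <- file.path(dir, paste0(names(field_schemas), ".csv"))
  names(paths) <- names(field_schemas)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("read_field_tables: missing file(s) ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }
  field <- purrr::imap(paths, function(p, nm) {
    check_schema(readr::read_csv(p, show_col_types = FALSE), nm)
  })

  # case-insensitive species matching against the reference table
  ref <- species_reference()
  idx <- match(tolower(field$trees$species), tolower(ref$species))
  if (anyNA(idx)) {
    stop("read_field_tables: unknown species ",
         paste(unique(field$trees$species[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  field$trees$species <- ref$species[idx]

  if (radii_outside_bark) {
    bark <- (field$discs$bark1_cm + field$discs$bark2_cm +
               field$discs$bark3_cm + field$discs$bark4_cm) / 4
    for (col in c("radius_long_cm", "radius_short_cm", "radius_mid_cm")) {
      field$discs[[col]] <- field$discs[[col]] - bark
    }
  }

  check_integrity(field)
  structure(field, class = c("field_data", "list"))
}

check_integrity <- function(field) {
  tree_ids <- field$trees$tree_id
  disc_keys <- paste(field$discs$tree_id, field$discs$disc_id)
  problems <- character(0)
  orphan <- function(ids, where) {
    if (length(ids) > 0) {
      problems <<- c(problems, paste0(where, " row(s) referencing unknown id: ",
                                      paste(unique(ids), collapse = ", ")))
    }
  }
  orphan(setdiff(field$discs$tree_id, tree_ids), "discs")
  orphan(setdiff(field$branches$tree_id, tree_ids), "branches")
  for (tab in c("rings", "ring15", "wood_samples")) {
    keys <- paste(field[[tab]]$tree_id, field[[tab]]$disc_id)
    orphan(unique(field[[tab]]$disc_id[!(keys %in% disc_keys)]), tab)
  }
  if (length(problems) > 0) {
    stop("integrity error: ", paste(problems, collapse = "; "), call. = FALSE)
  }
  invisible(field)
}

#' Write a field dataset to CSV tables
#'
#' Inverse of [read_field_tables()]: writes the six tables to `dir` with
#' full numeric precision, so that a write/read round trip is lossless to
#' text-representation precision.
#'
#' @param field A field dataset.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_field_tables <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(field_schemas)) {
    readr::write_csv(field[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Validate a field dataset against the measurement invariants
#'
#' Checks every tree, disc, wood sample and branch against the recorded
#' field-measurement invariants and returns the violations as data (a
#' tibble), not as errors:
#'
#' * heights ordered: `0 < stem height < total height`; lower disc below
#'   upper disc, upper disc at or below stem height; exactly two discs.
#' * disc radial consistency: per radius, sapwood + heartwood +
#'   pith_diameter/2 equals the radius within `tolerance` (relative).
#' * all lengths and areas non-negative; ring widths non-negative.
#' * wood samples: positive fresh volume and dry mass; density below
#'   1.5 g cm^-3.
#' * branches: at least one shoot; 4-5 branches per tree.
#'
#' @param field A field dataset.
#' @param tolerance Relative tolerance for the radial-consistency check
#'   (default 0.02, i.e. 2 percent of the radius, reflecting caliper/ruler
#'   measurement error).
#' @return A tibble with columns `tree_id`, `table`, `field`, `rule`,
#'   `detail`; zero rows when the dataset is fully consistent.
#' @export
validate_field_data <- function(field, tolerance = 0.02) {
  v <- list()
  add <- function(tree_id, table, fld, rule, detail = "") {
    v[[length(v) + 1]] <<- tibble::tibble(
      tree_id = as.character(tree_id), table = table, field = fld,
      rule = rule, detail = detail
    )
  }

  tr <- field$trees
  bad <- which(!(tr$stem_height_m > 0 & tr$stem_height_m < tr$total_height_m))
  for (i in bad) add(tr$tree_id[i], "trees", "stem_height_m",
                     "0 < stem height < total height")

  d <- field$discs
  for (i in seq_len(nrow(d))) {
    radii <- c(d$radius_long_cm[i], d$radius_short_cm[i], d$radius_mid_cm[i])
    sap <- c(d$sapwood1_cm[i], d$sapwood2_cm[i], d$sapwood3_cm[i])
    heart <- c(d$heartwood1_cm[i], d$heartwood2_cm[i], d$heartwood3_cm[i])
    lens <- c(radii, d$pith_diameter_cm[i],
              d$bark1_cm[i], d$bark2_cm[i], d$bark3_cm[i], d$bark4_cm[i])
    if (any(lens < 0, na.rm = TRUE)) {
      add(d$tree_id[i], "discs", d$disc_id[i], "all lengths >= 0")
    }
    if (any(c(sap, heart) < 0, na.rm = TRUE)) {
      add(d$tree_id[i], "discs", d$disc_id[i], "all lengths >= 0",
          "sapwood/heartwood")
    }
    if (!anyNA(c(sap, heart))) {
      recon <- sap + heart + d$pith_diameter_cm[i] / 2
      off <- abs(recon - radii) / radii
      if (any(off > tolerance)) {
        add(d$tree_id[i], "discs", d$disc_id[i],
            sprintf("sapwood + heartwood + pith/2 within %g%% of radius",
                    100 * tolerance),
            sprintf("max relative mismatch %.3f", max(off)))
      }
    }
  }

  disc_count <- table(d$tree_id)
  for (id in names(disc_count)[disc_count != 2]) {
    add(id, "discs", "disc_id", "exactly 2 discs per tree",
        sprintf("found %d", disc_count[[id]]))
  }
  per_tree_discs <- split(d$height_m, d$tree_id)
  stem_h <- stats::setNames(tr$stem_height_m, tr$tree_id)
  for (id in names(per_tree_discs)) {
    h <- sort(per_tree_discs[[id]])
    if (length(h) == 2 && !is.na(stem_h[id]) &&
        !(h[1] < h[2] && h[2] <= stem_h[id] + 1e-9)) {
      add(id, "discs", "height_m",
          "lower disc height < upper disc height <= stem height")
    }
  }

  rg <- field$rings
  bad <- which(rg$width_cm < 0)
  for (i in bad) add(rg$tree_id[i], "rings", "width_cm", "ring width >= 0")

  ws <- field$wood_samples
  bad <- which(!(ws$fresh_volume_cm3 > 0 & ws$dry_mass_g > 0))
  for (i in bad) add(ws$tree_id[i], "wood_samples", "fresh_volume_cm3",
                     "fresh volume and dry mass > 0")
  dens_ok <- ws$fresh_volume_cm3 > 0
  bad <- which(dens_ok & ws$dry_mass_g / ws$fresh_volume_cm3 >= 1.5)
  for (i in bad) add(ws$tree_id[i], "wood_samples", "dry_mass_g",
                     "density dry mass / fresh volume < 1.5",
                     sprintf("%.2f g cm^-3",
                             ws$dry_mass_g[i] / ws$fresh_volume_cm3[i]))

  br <- field$branches
  bad <- which(br$n_shoots < 1)
  for (i in bad) add(br$tree_id[i], "branches", "n_shoots", "n_shoots >= 1")
  branch_count <- table(br$tree_id)
  for (id in names(branch_count)[!(branch_count %in% 4:5)]) {
    add(id, "branches", "branch_id", "4-5 branches per tree",
        sprintf("found %d", branch_count[[id]]))
  }

  if (length(v) == 0) {
    tibble::tibble(tree_id = character(), table = character(),
                   field = character(), rule = character(),
                   detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}
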