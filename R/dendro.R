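#' Disc-level dendrometric derivations
#'
#' Functions that turn raw stem-disc measurements (three radii, ring widths,
#' sapwood/heartwood radial lengths, wood samples) into the disc-level
#' quantities the growth reconstruction needs: mean ring width, basal area,
#' annual basal-area growth, the sapwood/heartwood/pith area partition,
#' sapwood lifespan, and wood density. All scalar helpers are vectorized so
#' they can be used directly inside `dplyr::mutate()`.
#'
#' Geometry convention: a disc is modelled as a circle on the arithmetic
#' mean of its three inside-bark radii (the `"mean_radius"` convention),
#' which keeps the sapwood + heartwood + pith partition an exact identity.
#' The alternative `"mean_area"` convention (mean of per-radius circle
#' areas) is available for sensitivity analysis.
#'
#' @name dendro
NULL

#' Mean annual ring width of a disc
#'
#' Arithmetic mean over the ring-width measurements of a disc: three radii
#' times five years (15 values). Growth estimates are based on a 5-year
#' average to damp year-to-year climatic variability.
#'
#' @param widths Numeric vector (or 3x5 matrix) of ring widths in cm per
#'   year; typically 15 values (3 radii x 5 years).
#' @return Mean ring width, cm per year.
#' @examples
#' mean_ring_width(rep(0.4, 15))
#' @export
mean_ring_width <- function(widths) {
  widths <- as.numeric(widths)
  if (anyNA(widths)) {
    stop("mean_ring_width: missing ring width at position(s) ",
         paste(which(is.na(widths)), collapse = ", "), call. = FALSE)
  }
  if (any(widths < 0)) {
    stop("mean_ring_width: negative ring width", call. = FALSE)
  }
  mean(widths)
}

#' Basal area of a disc from its three radii
#'
#' @param radius_long,radius_short,radius_mid Inside-bark radii in cm
#'   (longest, shortest and one intermediate radius). Vectorized.
#' @param convention `"mean_radius"` (default): area of the circle on the
#'   mean radius. `"mean_area"`: mean of the three per-radius circle areas.
#' @return Basal area in cm^2.
#' @examples
#' disc_basal_area(30, 30, 30) # pi * 900
#' @export
disc_basal_area <- function(radius_long, radius_short, radius_mid,
                            convention = c("mean_radius", "mean_area")) {
  convention <- match.arg(convention)
  if (any(c(radius_long, radius_short, radius_mid) <= 0, na.rm = TRUE)) {
    stop("disc_basal_area: non-positive radius", call. = FALSE)
  }
  if (convention == "mean_radius") {
    r <- (radius_long + radius_short + radius_mid) / 3
    pi * r^2
  } else {
    (pi * radius_long^2 + pi * radius_short^2 + pi * radius_mid^2) / 3
  }
}

#' Annual basal-area growth of a disc
#'
#' The outermost annulus of width equal to the mean annual ring width:
#' current basal area minus the basal area one mean ring earlier,
#' `pi * r^2 - pi * (r - w)^2`.
#'
#' @param mean_radius Mean inside-bark radius, cm. Vectorized.
#' @param ring_width Mean annual ring width, cm per year.
#' @return Annual basal-area growth, cm^2 per year.
#' @examples
#' annual_ba_growth(30, 0.5) # pi * (900 - 870.25)
#' @export
annual_ba_growth <- function(mean_radius, ring_width) {
  if (any(ring_width < 0, na.rm = TRUE)) {
    stop("annual_ba_growth: negative ring width", call. = FALSE)
  }
  if (any(ring_width >= mean_radius & ring_width > 0, na.rm = TRUE)) {
    stop("annual_ba_growth: ring width >= radius", call. = FALSE)
  }
  pi * mean_radius^2 - pi * (mean_radius - ring_width)^2
}

#' Wood density of a sample
#'
#' Dry mass divided by fresh (green) volume, the standard basic-density
#' measure from water-displacement volume and oven-dry mass.
#'
#' @param dry_mass Oven-dry mass, g. Vectorized.
#' @param fresh_volume Fresh volume, cm^3.
#' @return Wood density, g per cm^3.
#' @examples
#' wood_density(39.2, 49)
#' @export
wood_density <- function(dry_mass, fresh_volume) {
  if (any(fresh_volume <= 0, na.rm = TRUE)) {
    stop("wood_density: non-positive fresh volume", call. = FALSE)
  }
  dry_mass / fresh_volume
}

#' Concentric sapwood / heartwood / pith partition of a disc
#'
#' Concentric-circle model on the mean radial lengths: pith radius
#' `p = pith_diameter / 2`, heartwood from `p` to `p + h`, sapwood from
#' `p + h` to `p + h + s`. The three areas partition the circle of radius
#' `p + h + s` exactly.
#'
#' @param sapwood Mean sapwood radial length, cm. Vectorized; `NA` allowed
#'   (species without a visible sapwood boundary) and propagates.
#' @param heartwood Mean heartwood radial length, cm.
#' @param pith_diameter Pith diameter, cm.
#' @return A tibble with columns `sapwood_area`, `heartwood_area`,
#'   `pith_area` (cm^2).
#' @examples
#' sapwood_geometry(10, 19, 2) # sapwood area 500 * pi
#' @export
sapwood_geometry <- function(sapwood, heartwood, pith_diameter) {
  if (any(c(sapwood, heartwood, pith_diameter) < 0, na.rm = TRUE)) {
    stop("sapwood_geometry: negative radial length", call. = FALSE)
  }
  p <- pith_diameter / 2
  rh <- p + heartwood
  rs <- rh + sapwood
  tibble::tibble(
    sapwood_area = pi * (rs^2 - rh^2),
    heartwood_area = pi * (rh^2 - p^2),
    pith_area = pi * p^2
  )
}

#' Sapwood lifespan of a disc
#'
#' Estimated age of the sapwood band: sapwood width divided by the mean
#' annual ring width of the last 15 years (averaged over the three radii).
#'
#' @param sapwood_width Mean sapwood radial length, cm. Vectorized; `NA`
#'   propagates.
#' @param ring_width_15yr Mean annual ring width over the last 15 years,
#'   cm per year.
#' @return Sapwood lifespan in years.
#' @examples
#' sapwood_lifespan(10, 0.4) # 25 years
#' @export
sapwood_lifespan <- function(sapwood_width, ring_width_15yr) {
  if (any(ring_width_15yr <= 0, na.rm = TRUE)) {
    stop("sapwood_lifespan: non-positive 15-year ring width", call. = FALSE)
  }
  sapwood_width / ring_width_15yr
}

#' Wood density of the youngest (outermost) sapwood
#'
#' Selects the cambium-side wood sample of a disc and returns its density.
#' Samples are ordered by `position_index` counted from the cambium inward,
#' so the outermost sample has the smallest index. An explicit
#' `is_youngest_sapwood` flag overrides the positional rule (with a warning
#' when the two disagree).
#'
#' @param samples A data frame of wood samples for one disc with columns
#'   `position_index`, `fresh_volume_cm3`, `dry_mass_g` and optionally
#'   `is_youngest`.
#' @return Wood density of the youngest sapwood, g per cm^3.
#' @export
youngest_sapwood_density <- function(samples) {
  if (nrow(samples) == 0) {
    stop("youngest_sapwood_density: no wood samples", call. = FALSE)
  }
  idx <- which.min(samples$position_index)
  flags <- samples[["is_youngest"]]
  if (!is.null(flags) && any(flags %in% TRUE)) {
    flagged <- which(flags %in% TRUE)[1]
    if (flagged != idx) {
      warning("youngest-sapwood flag disagrees with position index; ",
              "using the flagged sample", call. = FALSE)
    }
    idx <- flagged
  }
  wood_density(samples$dry_mass_g[idx], samples$fresh_volume_cm3[idx])
}

#' Derive disc-level quantities for every disc in a field dataset
#'
#' Joins the disc geometry, ring-width and wood-sample tables and computes,
#' per disc: mean radius, basal area, mean ring width (3 radii x 5 years),
#' annual basal-area growth, the sapwood/heartwood/pith area partition,
#' sapwood width and lifespan, youngest-sapwood wood density, and biomass
#' growth per unit tree height.
#'
#' @param field A field dataset as returned by [read_field_tables()] or
#'   [build_field_tables()].
#' @param convention Disc-area convention, see [disc_basal_area()].
#' @return A tibble with one row per disc. Sapwood-dependent columns are
#'   `NA` where the sapwood boundary was not measurable.
#' @export
derive_discs <- function(field, convention = c("mean_radius", "mean_area")) {
  convention <- match.arg(convention)

  ring_means <- field$rings |>
    dplyr::group_by(.data$tree_id, .data$disc_id) |>
    dplyr::summarise(
      mean_ring_width = mean_ring_width(.data$width_cm),
      n_ring = dplyr::n(),
      .groups = "drop"
    )
  if (any(ring_means$n_ring != 15L)) {
    bad <- ring_means$disc_id[ring_means$n_ring != 15L]
    stop("derive_discs: expected 15 ring widths (3 radii x 5 years) per disc; ",
         "discs with other counts: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  ring15 <- field$ring15 |>
    dplyr::group_by(.data$tree_id, .data$disc_id) |>
    dplyr::summarise(
      mean_ring_width_15yr = mean(.data$mean_width_15yr_cm),
      .groups = "drop"
    )

  wd <- field$wood_samples |>
    dplyr::group_by(.data$tree_id, .data$disc_id) |>
    dplyr::group_modify(~ tibble::tibble(wd_youngest = youngest_sapwood_density(.x))) |>
    dplyr::ungroup()

  geom <- field$discs |>
    dplyr::mutate(
      mean_radius = (.data$radius_long_cm + .data$radius_short_cm +
                       .data$radius_mid_cm) / 3,
      basal_area = disc_basal_area(.data$radius_long_cm, .data$radius_short_cm,
                                   .data$radius_mid_cm, convention = convention),
      sapwood_width = (.data$sapwood1_cm + .data$sapwood2_cm + .data$sapwood3_cm) / 3,
      heartwood_width = (.data$heartwood1_cm + .data$heartwood2_cm +
                           .data$heartwood3_cm) / 3
    )

  sw <- sapwood_geometry(geom$sapwood_width, geom$heartwood_width,
                         geom$pith_diameter_cm)

  geom |>
    dplyr::bind_cols(sw) |>
    dplyr::left_join(ring_means, by = c("tree_id", "disc_id")) |>
    dplyr::left_join(ring15, by = c("tree_id", "disc_id")) |>
    dplyr::left_join(wd, by = c("tree_id", "disc_id")) |>
    dplyr::mutate(
      ba_growth = annual_ba_growth(.data$mean_radius, .data$mean_ring_width),
      sapwood_lifespan = sapwood_lifespan(.data$sapwood_width,
                                          .data$mean_ring_width_15yr),
      biomass_growth_per_height = biomass_growth_per_height(.data$wd_youngest,
                                                            .data$ba_growth)
    ) |>
    dplyr::select(
      "tree_id", "disc_id", "height_m", "mean_radius", "basal_area",
      "mean_ring_width", "mean_ring_width_15yr", "ba_growth",
      "sapwood_width", "sapwood_area", "heartwood_area", "pith_area",
      "sapwood_lifespan", "wd_youngest", "biomass_growth_per_height"
    )
}
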