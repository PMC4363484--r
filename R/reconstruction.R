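#' Tree-level trait reconstruction
#'
#' Builds the per-tree trait table from disc-level derivations and branch
#' measurements: absolute aboveground biomass growth (stem + crown, leaves
#' excluded), total leaf area from the branch basal-area:leaf-area ratio,
#' specific leaf area, and tree-level sapwood area, basal area, sapwood
#' growth and sapwood lifespan.
#'
#' @name reconstruction
NULL

#' Biomass growth per unit tree height
#'
#' Wood density of the youngest sapwood multiplied by the annual basal-area
#' growth of the same disc. Units: g cm^-3 x cm^2 yr^-1 = g cm^-1 yr^-1,
#' converted to kg m^-1 yr^-1 by the factor 0.1.
#'
#' @param wd Wood density of the youngest sapwood, g per cm^3. Vectorized.
#' @param ba_growth Annual basal-area growth, cm^2 per year.
#' @return Biomass growth per unit height, kg per m per year.
#' @examples
#' biomass_growth_per_height(0.5, 100) # 5 kg m^-1 yr^-1
#' @export
biomass_growth_per_height <- function(wd, ba_growth) {
  if (anyNA(wd)) {
    stop("biomass_growth_per_height: missing wood density", call. = FALSE)
  }
  wd * ba_growth * 0.1
}

#' Absolute aboveground biomass growth of a tree
#'
#' Stem growth is the mean of the lower- and upper-disc per-height rates
#' multiplied by stem height (taper occurs along the main stem, so the two
#' discs bracket it); crown growth is the upper-disc rate multiplied by
#' crown length (total height minus stem height), assuming no taper within
#' the crown. Leaf mass is excluded. Vectorized over trees.
#'
#' @param rate_lower,rate_upper Biomass growth per unit height at the lower
#'   (~1 m) and upper (below first branch) disc, kg m^-1 yr^-1.
#' @param stem_height Height to the first major branch, m.
#' @param total_height Total tree height, m.
#' @return Absolute aboveground biomass growth, kg per year.
#' @examples
#' tree_biomass_growth(4, 6, 15, 25) # 5*15 + 6*10 = 135
#' @export
tree_biomass_growth <- function(rate_lower, rate_upper, stem_height, total_height) {
  if (any(stem_height >= total_height, na.rm = TRUE)) {
    stop("tree_biomass_growth: stem height must be below total height",
         call. = FALSE)
  }
  if (any(stem_height <= 0, na.rm = TRUE)) {
    stop("tree_biomass_growth: non-positive stem height", call. = FALSE)
  }
  stem <- (rate_lower + rate_upper) / 2 * stem_height
  crown <- rate_upper * (total_height - stem_height)
  stem + crown
}

#' Leaf area of a branch
#'
#' Number of leaf-bearing shoot apices times the average number of leaves
#' per shoot times the tree-level average leaf area (from the 20-25 pooled
#' harvested leaves).
#'
#' @param n_shoots Count of leaf-bearing shoot apices on the branch.
#' @param leaves_per_shoot Numeric vector of leaf counts on up to five
#'   sampled shoots (or a precomputed mean).
#' @param mean_leaf_area Tree-level mean area of a leaf, cm^2.
#' @return Branch leaf area, cm^2.
#' @examples
#' branch_leaf_area(40, rep(8, 5), 120) # 38400
#' @export
branch_leaf_area <- function(n_shoots, leaves_per_shoot, mean_leaf_area) {
  if (any(n_shoots < 1)) {
    stop("branch_leaf_area: branch must have at least one shoot", call. = FALSE)
  }
  n_shoots * mean(leaves_per_shoot, na.rm = TRUE) * mean_leaf_area
}

#' Tree-level basal-area : leaf-area ratio
#'
#' Arithmetic mean of the per-branch ratios of branch cross-sectional basal
#' area to branch leaf area (four to five branches per tree).
#'
#' @param ratios Numeric vector of per-branch BA:LA ratios (dimensionless,
#'   same units top and bottom).
#' @return The tree-level ratio.
#' @export
tree_ba_la_ratio <- function(ratios) {
  if (length(ratios) == 0) {
    stop("tree_ba_la_ratio: no branches", call. = FALSE)
  }
  mean(ratios)
}

#' Total leaf area of a tree
#'
#' Stem basal area just below the first branch divided by the tree-level
#' BA:leaf-area ratio, assuming basal area just below the first branch is
#' proportional to the leaf area it supports.
#'
#' @param ba_below_first_branch Basal area just below the first branch, m^2.
#' @param ratio Tree-level BA:LA ratio (dimensionless). Vectorized.
#' @return Total leaf area, m^2.
#' @examples
#' total_leaf_area(0.20, 1.5e-4) # 1333.33 m^2
#' @export
total_leaf_area <- function(ba_below_first_branch, ratio) {
  if (any(ratio <= 0, na.rm = TRUE)) {
    stop("total_leaf_area: BA:LA ratio must be positive", call. = FALSE)
  }
  ba_below_first_branch / ratio
}

#' Specific leaf area
#'
#' Pooled leaf area divided by pooled leaf dry mass.
#'
#' @param pooled_area Leaf area of the pooled harvested leaves, cm^2.
#' @param pooled_dry_mass Their oven-dry mass, g. Vectorized.
#' @return Specific leaf area, cm^2 per g.
#' @export
specific_leaf_area <- function(pooled_area, pooled_dry_mass) {
  if (any(pooled_dry_mass <= 0, na.rm = TRUE)) {
    stop("specific_leaf_area: non-positive leaf dry mass", call. = FALSE)
  }
  pooled_area / pooled_dry_mass
}

#' Derive the tree-level trait table from a field dataset
#'
#' Runs the full reconstruction: disc derivations ([derive_discs()]),
#' branch leaf areas and the BA:LA ratio, total leaf area, specific leaf
#' area, and absolute aboveground biomass growth, and assembles one trait
#' row per tree (the variables of the trait summary table).
#'
#' Conventions: the trait-table stem basal area `ba` is the lower
#' (~breast-height) disc's basal area; tree-level `sa`, `sapwood_growth`
#' and `sapwood_lifespan` average the two discs (`sapwood_from` switches
#' the latter two to a single disc). Sapwood-dependent traits are `NA`
#' where no sapwood boundary was measurable, and `sa_imputed` is `FALSE`
#' throughout (see [impute_missing_sa()]).
#'
#' @param field A field dataset as returned by [read_field_tables()] or
#'   [build_field_tables()].
#' @param sapwood_from Which disc(s) define tree-level sapwood growth and
#'   lifespan: `"mean"` (default), `"lower"` or `"upper"`.
#' @param convention Disc-area convention, see [disc_basal_area()].
#' @return A tibble with one row per tree and columns `tree_id`, `species`,
#'   `agr` (kg yr^-1), `height` (m), `tla` (m^2), `sa` (m^2), `sla`
#'   (cm^2 g^-1), `n_leaf` (%), `n_sapw` (%), `ba` (m^2),
#'   `sapwood_lifespan` (yr), `sapwood_growth` (cm^2 yr^-1), `sa_imputed`.
#' @export
derive_traits <- function(field, sapwood_from = c("mean", "lower", "upper"),
                          convention = c("mean_radius", "mean_area")) {
  sapwood_from <- match.arg(sapwood_from)
  convention <- match.arg(convention)

  discs <- derive_discs(field, convention = convention)

  pick_disc <- switch(sapwood_from,
    mean = function(lower, upper) (lower + upper) / 2,
    lower = function(lower, upper) lower,
    upper = function(lower, upper) upper
  )

  per_tree <- discs |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::arrange(.data$height_m, .by_group = TRUE) |>
    dplyr::summarise(
      n_discs = dplyr::n(),
      ba = dplyr::first(.data$basal_area) / 1e4,
      ba_upper = dplyr::last(.data$basal_area) / 1e4,
      sa = mean(.data$sapwood_area) / 1e4,
      sapwood_growth = pick_disc(dplyr::first(.data$ba_growth),
                            dplyr::last(.data$ba_growth)),
      sapwood_lifespan = pick_disc(dplyr::first(.data$sapwood_lifespan),
                              dplyr::last(.data$sapwood_lifespan)),
      rate_lower = dplyr::first(.data$biomass_growth_per_height),
      rate_upper = dplyr::last(.data$biomass_growth_per_height),
      height_lower = dplyr::first(.data$height_m),
      height_upper = dplyr::last(.data$height_m),
      .groups = "drop"
    )
  if (any(per_tree$n_discs != 2L)) {
    stop("derive_traits: every tree needs exactly two discs; offending trees: ",
         paste(per_tree$tree_id[per_tree$n_discs != 2L], collapse = ", "),
         call. = FALSE)
  }

  # One leaf is harvested per sampled shoot apex (five per branch), so the
  # tree-level mean leaf area is the pooled harvested area over 5 x branches.
  mean_la <- field$branches |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::summarise(
      mean_leaf_area = sum(.data$leaf_area_cm2) / (5 * dplyr::n()),
      .groups = "drop"
    )

  branches <- field$branches |>
    dplyr::left_join(mean_la, by = "tree_id") |>
    dplyr::rowwise() |>
    dplyr::mutate(
      leaf_area = branch_leaf_area(
        .data$n_shoots,
        c(.data$leaves_per_shoot_1, .data$leaves_per_shoot_2,
          .data$leaves_per_shoot_3, .data$leaves_per_shoot_4,
          .data$leaves_per_shoot_5),
        .data$mean_leaf_area
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(ba_la_ratio = .data$ba_cm2 / .data$leaf_area)

  ratios <- branches |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::summarise(ba_la_ratio = tree_ba_la_ratio(.data$ba_la_ratio),
                     .groups = "drop")

  out <- field$trees |>
    dplyr::left_join(per_tree, by = "tree_id") |>
    dplyr::left_join(ratios, by = "tree_id")

  bad_heights <- out$height_upper > out$stem_height_m + 1e-9 |
    out$height_lower >= out$height_upper
  if (any(bad_heights, na.rm = TRUE)) {
    stop("derive_traits: disc heights inconsistent with stem height for tree(s) ",
         paste(out$tree_id[which(bad_heights)], collapse = ", "), call. = FALSE)
  }

  out |>
    dplyr::mutate(
      agr = tree_biomass_growth(.data$rate_lower, .data$rate_upper,
                                .data$stem_height_m, .data$total_height_m),
      height = .data$total_height_m,
      tla = total_leaf_area(.data$ba_upper, .data$ba_la_ratio),
      sla = specific_leaf_area(.data$pooled_leaf_area_cm2,
                               .data$pooled_leaf_dry_mass_g),
      n_leaf = .data$n_leaf_pct,
      n_sapw = .data$n_sapw_pct,
      sa_imputed = FALSE
    ) |>
    dplyr::select(
      "tree_id", "species", "agr", "height", "tla", "sa", "sla",
      "n_leaf", "n_sapw", "ba", "sapwood_lifespan", "sapwood_growth",
      "sa_imputed"
    )
}
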