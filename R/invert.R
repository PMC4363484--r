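#' Invert trait records to raw field-measurement tables
#'
#' Constructs, for each tree-level trait record, a full set of raw field
#' measurements (two stem discs with radii, ring widths, sapwood/
#' heartwood/pith lengths; wood samples; branches; heights) whose
#' derivation by [derive_traits()] reproduces the traits exactly (to
#' floating-point precision). This closes the generate-invert-derive-fit
#' loop that validates the whole pipeline.
#'
#' Construction outline, per tree: the lower disc's basal area is the
#' trait `ba`; the upper disc tapers by a factor chosen so both discs can
#' carry their share of the sapwood area; the two discs' annual basal-area
#' growth values average to `sapwood_growth` but are split asymmetrically
#' (together with the stem height and the youngest-sapwood wood density)
#' so that the stem + crown biomass-growth sum equals `agr`; ring widths
#' solve the growth annulus; sapwood/heartwood radial lengths solve the
#' concentric partition for the disc's sapwood area, with per-radius
#' values scaled proportionally to the radius so the radial-consistency
#' check holds exactly; 15-year mean ring widths encode the sapwood
#' lifespan; branch shoot counts, leaves per shoot and basal areas encode
#' the total leaf area through the BA:LA ratio; and the pooled leaf area
#' and dry mass encode the specific leaf area. The wood density is kept
#' near the species mean wood density where the growth partition allows.
#'
#' @name invert
NULL

radius_factors <- c(1.04, 0.96, 1.00) # long, short, intermediate
ring_year_pattern <- c(-0.06, -0.03, 0, 0.03, 0.06) # zero-sum over 5 years

name_some <- function(ids) {
  if (length(ids) > 5) {
    paste0(paste(ids[1:5], collapse = ", "), ", ... (", length(ids), " trees)")
  } else {
    paste(ids, collapse = ", ")
  }
}

# vectorized core: solves the growth partition and disc geometry for all
# trees at once; errors name the offending trees and constraint
invert_trees <- function(traits, wd_pref, mask) {
  need <- c("agr", "height", "tla", "sa", "sla", "ba",
            "sapwood_lifespan", "sapwood_growth")
  miss <- !stats::complete.cases(traits[need])
  if (any(miss)) {
    stop("build_field_tables: missing trait value(s) for tree(s) ",
         name_some(traits$tree_id[miss]), call. = FALSE)
  }
  neg <- purrr::reduce(purrr::map(need, ~ traits[[.x]] < 0), `|`)
  if (any(neg)) {
    stop("build_field_tables: negative trait value for tree(s) ",
         name_some(traits$tree_id[neg]), call. = FALSE)
  }
  if (any(traits$sa > traits$ba)) {
    stop("build_field_tables: sa > ba (sapwood area cannot exceed basal ",
         "area) for tree(s) ",
         name_some(traits$tree_id[traits$sa > traits$ba]), call. = FALSE)
  }
  too_full <- traits$sa > 0.96 * traits$ba
  if (any(too_full)) {
    stop("build_field_tables: sa > 0.96 * ba; disc taper cannot accommodate ",
         "the sapwood share for tree(s) ",
         name_some(traits$tree_id[too_full]), call. = FALSE)
  }

  id <- traits$tree_id
  agr <- traits$agr; ht <- traits$height; sg <- traits$sapwood_growth
  hlo <- partition_limits$hs[1]
  hhi <- pmin(partition_limits$hs[2], ht - 4)
  wd_abs <- partition_limits$wd

  deg <- sg <= 1e-12
  if (any(deg & agr > 1e-9)) {
    stop("build_field_tables: agr > 0 with zero sapwood growth for tree(s) ",
         name_some(id[deg & agr > 1e-9]), call. = FALSE)
  }

  # wood-density window of the stem/crown growth partition
  sg_safe <- pmax(sg, 1e-12)
  w_lo <- 10 * agr / (sg_safe * (2 * ht - hlo))
  w_hi <- 10 * agr / (sg_safe * hlo)
  lo <- pmax(w_lo * 1.02, wd_abs[1])
  hi <- pmin(w_hi * 0.98, wd_abs[2])
  bad <- !deg & lo > hi
  if (any(bad)) {
    stop("build_field_tables: growth partition infeasible (required wood ",
         "density outside the plausible range) for tree(s) ",
         name_some(id[bad]), call. = FALSE)
  }
  wd_used <- ifelse(deg, wd_pref, pmin(pmax(wd_pref, lo), hi))
  req <- ifelse(deg, 0, 10 * agr / wd_used)
  hs <- pmin(pmax(0.6 * ht, hlo), hhi,
             ifelse(deg, Inf, req / sg_safe),
             ifelse(deg, Inf, 2 * ht - req / sg_safe))
  x <- ifelse(deg, 0, (req - sg * hs) / (ht - hs))
  x <- pmin(pmax(x, 0), 2 * sg)
  dba <- cbind(2 * sg - x, x) # lower, upper disc annual BA growth (cm^2)

  taper <- pmin(pmax(2 * (traits$sa / traits$ba) / 0.97 - 1, 0.9), 0.98)
  ba_disc <- cbind(traits$ba, traits$ba * taper) * 1e4
  r_bar <- sqrt(ba_disc / pi)
  over <- dba >= 0.98 * ba_disc
  if (any(over)) {
    stop("build_field_tables: annual BA growth exceeds disc area for ",
         "tree(s) ", name_some(id[rowSums(over) > 0]), call. = FALSE)
  }
  ring_w <- r_bar - sqrt(r_bar^2 - dba / pi)

  pith_d <- 1.2
  p <- pith_d / 2
  q <- 2 * (traits$sa / traits$ba) / (1 + taper) # per-disc sapwood share
  sa_disc <- q * ba_disc
  r_heart <- sqrt(r_bar^2 - sa_disc / pi)
  s_bar <- r_bar - r_heart
  h_bar <- r_heart - p
  if (any(h_bar < 0)) {
    stop("build_field_tables: sapwood share leaves no heartwood for ",
         "tree(s) ", name_some(id[rowSums(h_bar < 0) > 0]), call. = FALSE)
  }

  n <- nrow(traits)
  disc_of <- function(i) paste0(id, "-D", i)
  one_disc <- function(i) {
    s_k <- outer(s_bar[, i], radius_factors)
    h_k <- outer(r_bar[, i], radius_factors) - p - s_k
    tibble::tibble(
      tree_id = id, disc_id = disc_of(i),
      height_m = if (i == 1) rep(1, n) else hs,
      radius_long_cm = r_bar[, i] * radius_factors[1],
      radius_short_cm = r_bar[, i] * radius_factors[2],
      radius_mid_cm = r_bar[, i] * radius_factors[3],
      bark1_cm = 1.1, bark2_cm = 1.3, bark3_cm = 0.9, bark4_cm = 1.2,
      sapwood1_cm = ifelse(mask, NA_real_, s_k[, 1]),
      sapwood2_cm = ifelse(mask, NA_real_, s_k[, 2]),
      sapwood3_cm = ifelse(mask, NA_real_, s_k[, 3]),
      heartwood1_cm = ifelse(mask, NA_real_, h_k[, 1]),
      heartwood2_cm = ifelse(mask, NA_real_, h_k[, 2]),
      heartwood3_cm = ifelse(mask, NA_real_, h_k[, 3]),
      pith_diameter_cm = pith_d
    )
  }
  discs <- dplyr::bind_rows(one_disc(1), one_disc(2))

  rings <- purrr::map_dfr(1:2, function(i) {
    tibble::tibble(
      tree_id = rep(id, each = 15),
      disc_id = rep(disc_of(i), each = 15),
      radius_index = rep(rep(1:3, each = 5), n),
      year_index = rep(1:5, 3 * n),
      width_cm = rep(ring_w[, i], each = 15) *
        (1 + ring_year_pattern[rep(1:5, 3 * n)])
    )
  })

  # 15-year mean ring widths encode the sapwood lifespan per radius; when
  # there is no sapwood (degenerate), fall back to the 5-year width
  ring15 <- purrr::map_dfr(1:2, function(i) {
    m15 <- ifelse(traits$sapwood_lifespan > 0 & s_bar[, i] > 0,
                  s_bar[, i] / traits$sapwood_lifespan,
                  pmax(ring_w[, i], 0.05))
    tibble::tibble(
      tree_id = rep(id, each = 3),
      disc_id = rep(disc_of(i), each = 3),
      radius_index = rep(1:3, n),
      mean_width_15yr_cm = rep(m15, each = 3) * radius_factors[rep(1:3, n)]
    )
  })

  wood_samples <- purrr::map_dfr(1:2, function(i) {
    tibble::tibble(
      tree_id = rep(id, each = 2),
      disc_id = rep(disc_of(i), each = 2),
      position_index = rep(1:2, n),
      fresh_volume_cm3 = 216,
      dry_mass_g = 216 * as.numeric(rbind(wd_used, pmin(1.45, wd_used * 1.03)))
    )
  })

  a_leaf <- 0.9 * traits$sla
  ratio <- (ba_disc[, 2] / 1e4) / traits$tla
  branches <- purrr::map_dfr(1:5, function(b) {
    lps <- ((b + 0:4) %% 4) + 6
    la <- (18 + 4 * b) * mean(lps) * a_leaf
    tibble::tibble(
      tree_id = id, branch_id = paste0(id, "-B", b),
      ba_cm2 = ratio * la, n_shoots = 18 + 4 * b,
      leaves_per_shoot_1 = lps[1], leaves_per_shoot_2 = lps[2],
      leaves_per_shoot_3 = lps[3], leaves_per_shoot_4 = lps[4],
      leaves_per_shoot_5 = lps[5],
      leaf_area_cm2 = 5 * a_leaf
    )
  }) |> dplyr::arrange(.data$tree_id, .data$branch_id)

  trees <- tibble::tibble(
    tree_id = id, species = traits$species,
    total_height_m = ht, stem_height_m = hs,
    pooled_leaf_area_cm2 = 25 * a_leaf,
    pooled_leaf_dry_mass_g = 25 * a_leaf / traits$sla,
    n_leaf_pct = traits$n_leaf, n_sapw_pct = traits$n_sapw
  )

  list(tables = list(trees = trees, discs = discs, rings = rings,
                     ring15 = ring15, wood_samples = wood_samples,
                     branches = branches),
       inversion = tibble::tibble(tree_id = id, wd_used = wd_used,
                                  stem_height_m = hs, taper = taper))
}

#' Build raw field-measurement tables from a trait table
#'
#' Inverts every row of a trait table into raw field measurements (see
#' `?invert`). The trait table must have complete sapwood fields — for
#' generated data pass the ground-truth table (or a `sim_traits` object,
#' whose ground truth is used automatically); masking of the
#' sapwood-unobservable species is applied to the *output* tables only.
#'
#' @param traits A trait table (`tree_id`, `species` and the ten trait
#'   columns, sapwood fields complete).
#' @param cfg A `sim_config` (species wood densities, masked species,
#'   measurement noise); `default_config()` if omitted.
#' @param seed Integer seed (wood-density jitter and measurement noise).
#' @return A `field_data` list of the six raw tables, with the per-tree
#'   construction constants in `attr(x, "inversion")`.
#' @export
build_field_tables <- function(traits, cfg = default_config(), seed = 1L) {
  cfg <- ensure_calibrated(cfg)
  truth <- attr(traits, "ground_truth")
  if (!is.null(truth)) traits <- truth
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed) + 7L)

  sp_row <- match(traits$species, cfg$species$species)
  wd_pref <- cfg$species$wd[sp_row] * exp(stats::rnorm(nrow(traits), 0, 0.06))
  if (!("tree_id" %in% names(traits))) {
    traits$tree_id <- sprintf("T%04d", seq_len(nrow(traits)))
  }

  built <- invert_trees(traits, wd_pref,
                        mask = traits$species %in% cfg$mask_species)
  field <- built$tables

  if (cfg$noise_pct > 0) {
    jitter_cols <- list(
      discs = c("radius_long_cm", "radius_short_cm", "radius_mid_cm",
                "sapwood1_cm", "sapwood2_cm", "sapwood3_cm",
                "heartwood1_cm", "heartwood2_cm", "heartwood3_cm"),
      rings = "width_cm",
      ring15 = "mean_width_15yr_cm",
      wood_samples = c("fresh_volume_cm3", "dry_mass_g"),
      branches = c("ba_cm2", "leaf_area_cm2")
    )
    for (tab in names(jitter_cols)) {
      for (cl in jitter_cols[[tab]]) {
        x <- field[[tab]][[cl]]
        field[[tab]][[cl]] <- x *
          (1 + stats::rnorm(length(x), 0, cfg$noise_pct / 100))
      }
    }
  }

  attr(field, "inversion") <- built$inversion
  structure(field, class = c("field_data", "list"))
}

#' Simulate a complete raw field dataset
#'
#' Convenience wrapper: [simulate_traits()] then [build_field_tables()]
#' on the ground truth, with masking applied on output. The generated
#' trait table (masked) and the ground truth travel as attributes.
#'
#' @inheritParams simulate_traits
#' @return A `field_data` list with attributes `traits` (masked trait
#'   table), `ground_truth`, and `config`.
#' @export
simulate_field_data <- function(cfg = default_config(), seed = 1L,
                                n_scale = 1L) {
  traits <- simulate_traits(cfg, seed = seed, n_scale = n_scale)
  field <- build_field_tables(traits, cfg, seed = seed)
  attr(field, "traits") <- traits
  attr(field, "ground_truth") <- attr(traits, "ground_truth")
  attr(field, "config") <- attr(traits, "config")
  field
}
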