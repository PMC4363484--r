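# Shared fixtures: everything is built in code, nothing read from disk.

# calibrated default configuration, built once per test run
test_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- sapgrow::default_config()
    cfg
  }
})

# small simulated field dataset (43 trees) with ground truth attached
test_field <- local({
  fd <- NULL
  function() {
    if (is.null(fd)) fd <<- sapgrow::simulate_field_data(test_config(),
                                                         seed = 101)
    fd
  }
})

# a hand-built, internally consistent single tree (two discs, five
# branches) whose derived traits are known in closed form
make_hand_tree <- function(tree_id = "HT1") {
  ck <- c(1.04, 0.96, 1.00)
  r_bar <- c(30, 28)          # disc mean radii, cm
  s_bar <- c(8, 7.5)          # sapwood radial lengths
  pith <- 1.2
  w <- c(0.5, 0.45)           # mean ring widths
  wd <- 0.6
  heights <- c(1, 14)

  discs <- purrr::map_dfr(1:2, function(i) {
    s_k <- s_bar[i] * ck
    h_k <- r_bar[i] * ck - pith / 2 - s_k
    tibble::tibble(
      tree_id = tree_id, disc_id = paste0(tree_id, "-D", i),
      height_m = heights[i],
      radius_long_cm = r_bar[i] * ck[1], radius_short_cm = r_bar[i] * ck[2],
      radius_mid_cm = r_bar[i] * ck[3],
      bark1_cm = 1, bark2_cm = 1, bark3_cm = 1, bark4_cm = 1,
      sapwood1_cm = s_k[1], sapwood2_cm = s_k[2], sapwood3_cm = s_k[3],
      heartwood1_cm = h_k[1], heartwood2_cm = h_k[2], heartwood3_cm = h_k[3],
      pith_diameter_cm = pith
    )
  })
  rings <- purrr::map_dfr(1:2, function(i) {
    tidyr::expand_grid(radius_index = 1:3, year_index = 1:5) |>
      dplyr::mutate(tree_id = tree_id, disc_id = paste0(tree_id, "-D", i),
                    width_cm = w[i]) |>
      dplyr::select(tree_id, disc_id, radius_index, year_index, width_cm)
  })
  ring15 <- purrr::map_dfr(1:2, function(i) {
    tibble::tibble(tree_id = tree_id, disc_id = paste0(tree_id, "-D", i),
                   radius_index = 1:3, mean_width_15yr_cm = 0.4 * ck)
  })
  wood_samples <- purrr::map_dfr(1:2, function(i) {
    tibble::tibble(tree_id = tree_id, disc_id = paste0(tree_id, "-D", i),
                   position_index = 1:2, fresh_volume_cm3 = 100,
                   dry_mass_g = 100 * c(wd, wd * 1.1))
  })
  branches <- purrr::map_dfr(1:5, function(b) {
    tibble::tibble(tree_id = tree_id, branch_id = paste0(tree_id, "-B", b),
                   ba_cm2 = 20, n_shoots = 30,
                   leaves_per_shoot_1 = 7, leaves_per_shoot_2 = 7,
                   leaves_per_shoot_3 = 7, leaves_per_shoot_4 = 7,
                   leaves_per_shoot_5 = 7, leaf_area_cm2 = 500)
  })
  trees <- tibble::tibble(
    tree_id = tree_id, species = "Hura", total_height_m = 26,
    stem_height_m = 14, pooled_leaf_area_cm2 = 2500,
    pooled_leaf_dry_mass_g = 25, n_leaf_pct = 2.5, n_sapw_pct = 0.25
  )
  structure(list(trees = trees, discs = discs, rings = rings,
                 ring15 = ring15, wood_samples = wood_samples,
                 branches = branches),
            class = c("field_data", "list"))
}
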