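test_that("per-height biomass growth converts units correctly", {
  expect_equal(biomass_growth_per_height(0.5, 100), 5)
  expect_equal(biomass_growth_per_height(0.7, 0), 0)
  # chains the annulus example: WD 1.0 on BA growth pi*(900-870.25)
  expect_equal(biomass_growth_per_height(1, annual_ba_growth(30, 0.5)),
               9.34625, tolerance = 1e-4)
  expect_error(biomass_growth_per_height(NA, 10), "missing")
})

test_that("tree biomass growth sums the stem and crown parts", {
  expect_equal(tree_biomass_growth(4, 6, 15, 25), 5 * 15 + 6 * 10)
  expect_equal(tree_biomass_growth(0, 0, 15, 25), 0)
  expect_error(tree_biomass_growth(4, 6, 25, 25), "below total height")
  # linear in both heights for fixed rates; crown length 0 limit
  r1 <- 4; r2 <- 6
  agr <- function(hs, ht) tree_biomass_growth(r1, r2, hs, ht)
  expect_equal(agr(10, 20) + agr(20, 30) - agr(10, 30),
               mean(c(r1, r2)) * 20 + r2 * 0)
  expect_equal(agr(15, 15 + 1e-9), mean(c(r1, r2)) * 15, tolerance = 1e-6)
})

test_that("branch leaf area multiplies shoots, leaves per shoot and leaf size", {
  expect_equal(branch_leaf_area(40, rep(8, 5), 120), 38400)
  expect_equal(branch_leaf_area(1, 1, 120), 120)
  expect_equal(branch_leaf_area(10, c(6, 10), 100),
               branch_leaf_area(10, 8, 100))
  expect_error(branch_leaf_area(0, 5, 100), "at least one shoot")
})

test_that("tree BA:LA ratio averages branches and TLA inverts it", {
  expect_equal(tree_ba_la_ratio(c(1e-4, 2e-4)), 1.5e-4)
  expect_equal(tree_ba_la_ratio(3e-4), 3e-4)
  expect_equal(tree_ba_la_ratio(c(2e-4, 1e-4, 3e-4)),
               tree_ba_la_ratio(c(3e-4, 2e-4, 1e-4)))
  expect_error(tree_ba_la_ratio(numeric(0)), "no branches")

  expect_equal(total_leaf_area(0.20, 1.5e-4), 1333.333, tolerance = 1e-4)
  expect_equal(total_leaf_area(0.25, 0.25), 1)
  expect_error(total_leaf_area(0.2, 0), "positive")
  # duplicating a branch (same ratio twice) leaves TLA unchanged
  expect_equal(total_leaf_area(0.2, tree_ba_la_ratio(c(1e-4, 2e-4, 2e-4))),
               total_leaf_area(0.2, tree_ba_la_ratio(c(1e-4, 2e-4, 2e-4, 1e-4,
                                                       2e-4, 2e-4))))
})

test_that("specific leaf area is area over mass and scale-free", {
  expect_equal(specific_leaf_area(2000, 20), 100)
  expect_equal(specific_leaf_area(4000, 40), 100)
  expect_error(specific_leaf_area(2000, 0), "non-positive")
})

test_that("derive_traits reproduces hand-computed tree traits", {
  fd <- make_hand_tree()
  tr <- derive_traits(fd)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$ba, pi * 900 / 1e4)          # lower disc, m^2
  expect_equal(tr$height, 26)
  expect_equal(tr$sla, 100)
  # sapwood area: mean of the two concentric partitions
  g1 <- sapwood_geometry(8, 30 - 0.6 - 8, 1.2)$sapwood_area
  g2 <- sapwood_geometry(7.5, 28 - 0.6 - 7.5, 1.2)$sapwood_area
  expect_equal(tr$sa, mean(c(g1, g2)) / 1e4)
  expect_equal(tr$sapwood_lifespan, mean(c(20, 18.75)))
  dba <- annual_ba_growth(c(30, 28), c(0.5, 0.45))
  expect_equal(tr$sapwood_growth, mean(dba))
  rates <- 0.6 * dba * 0.1
  expect_equal(tr$agr, mean(rates) * 14 + rates[2] * 12)
  # TLA: branch leaf area 30 * 7 * mean leaf area; mean leaf = 2500/25
  la <- 30 * 7 * 100
  expect_equal(tr$tla, (pi * 784 / 1e4) / (20 / la))
  expect_false(tr$sa_imputed)
})

test_that("the disc convention switch moves sapwood growth and lifespan", {
  fd <- make_hand_tree()
  lower <- derive_traits(fd, sapwood_from = "lower")
  upper <- derive_traits(fd, sapwood_from = "upper")
  both <- derive_traits(fd)
  expect_equal(lower$sapwood_lifespan, 20)
  expect_equal(upper$sapwood_lifespan, 18.75)
  expect_equal(both$sapwood_growth,
               mean(c(lower$sapwood_growth, upper$sapwood_growth)))
})

test_that("derived traits reproduce generator ground truth exactly", {
  fd <- test_field()
  gt <- attr(fd, "ground_truth")
  out <- derive_traits(fd)
  m <- dplyr::inner_join(gt, out, by = "tree_id", suffix = c("_t", "_d"))
  for (v in c("agr", "ba", "sa", "tla", "sla", "sapwood_growth",
              "sapwood_lifespan")) {
    a <- m[[paste0(v, "_t")]]
    b <- m[[paste0(v, "_d")]]
    keep <- !is.na(b)
    expect_gt(sum(keep), 30)
    expect_equal(b[keep], a[keep], tolerance = 1e-6)
  }
  # the species without a visible sapwood boundary comes out NA, not 0
  masked <- out$species == "Cariniana"
  expect_true(all(is.na(out$sa[masked])))
  expect_true(all(is.na(out$sapwood_lifespan[masked])))
  expect_true(all(!out$sa_imputed))
})

test_that("disc heights inconsistent with stem height are rejected", {
  fd <- make_hand_tree()
  fd$trees$stem_height_m <- 10 # upper disc at 14 m is now above it
  expect_error(derive_traits(fd), "inconsistent with stem height")
})
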