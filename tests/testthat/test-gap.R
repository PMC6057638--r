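# Build a zoning raster and an all-ones feature realizing given per-category
# cell counts (geometry is irrelevant to the category accounting).
zp_from_counts <- function(counts) {
  z <- rep(0:3, times = counts)
  grid_raster(matrix(z, nrow = 1))
}
feature_of <- function(n, id = "f", status = "NE")
  binary_range(grid_raster(matrix(1, nrow = 1, ncol = n)), id,
               status = status)

test_that("category_counts reproduces printed fixture rows", {
  t3 <- table3_fixture()
  chmo <- t3[t3$feature == "CHmo", ]
  cc <- category_counts(feature_of(chmo$total),
                        zp_from_counts(c(2947, 73689, 210830, 5069)))
  expect_equal(unname(cc$counts), c(2947, 73689, 210830, 5069))
  expect_equal(round(cc$percents[["2"]], 1), 72.1)   # national park share
  hedr <- t3[t3$feature == "HEdr", ]
  cc2 <- category_counts(feature_of(hedr$total),
                         zp_from_counts(c(0, 0, 1833, 442)))
  expect_equal(round(cc2$percents[["3"]], 1), 19.4)  # sanctuary share
  expect_equal(cc2$pa_cells, 2275)
  # whole range in one category
  cc3 <- category_counts(feature_of(50), zp_from_counts(c(0, 0, 0, 50)))
  expect_equal(unname(cc3$percents), c(0, 0, 0, 100))
  expect_error(category_counts(
    binary_range(grid_raster(matrix(0, 1, 4)), "e"),
    zp_from_counts(c(1, 1, 1, 1))), "empty")
})

test_that("representation_target interpolates log-linearly with status rules", {
  expect_equal(representation_target(1000, 10, 1000), 10)     # widest -> 10
  expect_equal(representation_target(10, 10, 1000), 100)      # narrowest -> 100
  expect_equal(representation_target(100, 10, 1000), 100 / sqrt(10),
               tolerance = 1e-9)                              # geometric mean
  expect_equal(representation_target(1000, 10, 1000, status = "CR"), 100)
  expect_equal(representation_target(1000, 10, 1000, status = "DD"), 40)
  expect_equal(representation_target(20, 10, 1000, status = "DD"), 100)
  expect_equal(representation_target(3, 10, 1000), 100)       # tiny feature
  # linlog alternative is monotone and hits the endpoints
  expect_equal(representation_target(1000, 10, 1000, scale = "linlog"), 10)
  expect_equal(representation_target(10, 10, 1000, scale = "linlog"), 100)
  expect_error(representation_target(5, 10, 10), "A_max > A_min")
})

test_that("target_achievement reproduces printed fixture rows", {
  # HEgr: full range in PAs, target 90.4 -> 110.6
  cc <- category_counts(feature_of(4623),
                        zp_from_counts(c(0, 0, 2908, 1715)))
  expect_equal(round(target_achievement(cc, 90.4)$achievement, 1), 110.6)
  expect_true(target_achievement(cc, 90.4)$protected)
  # PAbr: 8702 of 9626 in PAs, target 83.6 -> 108.1
  cc2 <- category_counts(feature_of(9626),
                         zp_from_counts(c(924, 5847, 2833, 22)))
  expect_equal(round(target_achievement(cc2, 83.6)$achievement, 1), 108.1)
  # zero PA cells -> 0
  cc3 <- category_counts(feature_of(10), zp_from_counts(c(10, 0, 0, 0)))
  expect_equal(target_achievement(cc3, 50)$achievement, 0)
  expect_false(target_achievement(cc3, 50)$protected)
  # scale-free: multiplying all counts by k changes nothing
  cc4 <- category_counts(feature_of(5 * 9626),
                         zp_from_counts(5 * c(924, 5847, 2833, 22)))
  expect_equal(target_achievement(cc4, 83.6)$achievement,
               target_achievement(cc2, 83.6)$achievement)
})

test_that("richness_gap counts hotspot cells inside protected areas", {
  zp <- zp_from_counts(c(10, 10, 10, 10))
  hot <- grid_raster(matrix(rep(c(1, 0), times = c(20, 20)), nrow = 1))
  rg <- richness_gap(hot, zp)     # 10 of 20 hotspot cells in PAs
  expect_equal(rg$achievement, 50)
  expect_false(rg$meets_target)
  hot2 <- grid_raster(matrix(rep(c(0, 1), times = c(10, 30)), nrow = 1))
  expect_equal(richness_gap(hot2, zp)$achievement, 100)
  expect_true(richness_gap(hot2, zp)$meets_target)
  # oracle by direct counting on a random plan
  set.seed(3)
  z <- sample(0:3, 200, replace = TRUE)
  h <- sample(0:1, 200, replace = TRUE)
  rg3 <- richness_gap(grid_raster(matrix(h, 1)), grid_raster(matrix(z, 1)))
  expect_equal(rg3$achievement, 100 * sum(h == 1 & z > 0) / sum(h == 1))
  expect_error(richness_gap(grid_raster(matrix(0, 1, 4)), zp_from_counts(c(1,1,1,1))),
               "empty hotspot")
})

test_that("compare_in_out recovers simulated Poisson group means", {
  set.seed(5)
  n <- 10000
  zvals <- rep(c(0, 2), each = n)            # outside / inside
  y <- c(rpois(n, 12), rpois(n, 9))
  layer <- structure(list(count = grid_raster(matrix(y, nrow = 100))),
                     class = "richness_layer")
  zp <- grid_raster(matrix(zvals, nrow = 100))
  res <- compare_in_out(layer, zp)
  expect_equal(res$mean[res$group == "outside"], 12, tolerance = 0.05)
  expect_equal(res$mean[res$group == "inside"], 9, tolerance = 0.05)
  expect_lt(attr(res, "p_value"), 1e-4)
  # Wald CI contains the group sample mean
  expect_true(res$ci_lo[1] <= mean(y[1:n]) && mean(y[1:n]) <= res$ci_hi[1])
  # near-identical distributions: no significant contrast, equal means
  y2 <- c(rpois(n, 10), rpois(n, 10))
  layer2 <- structure(list(count = grid_raster(matrix(y2, nrow = 100))),
                      class = "richness_layer")
  res2 <- compare_in_out(layer2, zp)
  expect_gt(attr(res2, "p_value"), 0.001)
  expect_equal(res2$mean[1], res2$mean[2], tolerance = 0.02)
  # zero-variance response errors
  layer3 <- structure(list(count = grid_raster(matrix(5, 100, 200))),
                      class = "richness_layer")
  expect_error(compare_in_out(layer3, zp), "zero-variance")
})
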