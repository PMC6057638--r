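make_gdm <- function(d, lon, lat, lineage = rep(1, length(lon))) {
  structure(list(d = d, coords = data.frame(lon = lon, lat = lat),
                 lineage = lineage), class = "genetic_dist")
}

test_that("empirical_variogram matches hand arithmetic on collinear points", {
  # points at x = 0, 1, 2; pairwise genetic distances set by hand
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 0.2   # h = 1
  d[2, 3] <- d[3, 2] <- 0.4   # h = 1
  d[1, 3] <- d[3, 1] <- 0.6   # h = 2
  gdm <- make_gdm(d, c(0, 1, 2), c(0, 0, 0))
  emp <- empirical_variogram(gdm, n_lags = 2, cutoff = 2.5)
  expect_equal(emp$n, c(2L, 1L))
  expect_equal(emp$gamma[1], (0.2^2 + 0.4^2) / (2 * 2))
  expect_equal(emp$gamma[2], 0.6^2 / 2)
  # doubling genetic distances quadruples gamma-hat
  emp2 <- empirical_variogram(make_gdm(2 * d, c(0, 1, 2), c(0, 0, 0)),
                              n_lags = 2, cutoff = 2.5)
  expect_equal(emp2$gamma, 4 * emp$gamma)
  # all-zero distances -> zero semivariance in occupied bins
  emp0 <- empirical_variogram(make_gdm(d * 0, c(0, 1, 2), c(0, 0, 0)),
                              n_lags = 2, cutoff = 2.5)
  expect_true(all(emp0$gamma[emp0$n > 0] == 0))
  expect_error(empirical_variogram(gdm, cutoff = 0.5), "beyond cutoff")
})

test_that("fit_variogram recovers noiseless spherical parameters within 5%", {
  true <- variogram_model("spherical", nugget = 0.02, sill = 0.3, range = 6)
  h <- seq(0.5, 12, by = 0.5)
  emp <- structure(data.frame(h = h, gamma = variogram_gamma(h, true),
                              n = rep(20L, length(h))),
                   class = c("empirical_variogram", "data.frame"))
  fit <- fit_variogram(emp, "spherical")
  expect_equal(fit$nugget, true$nugget, tolerance = 0.05)
  expect_equal(fit$sill, true$sill, tolerance = 0.05)
  expect_equal(fit$range, true$range, tolerance = 0.05)
  expect_lte(attr(fit, "rss"), attr(fit, "rss_init") + 1e-12)
  # manual mode echoes its inputs
  man <- fit_variogram(emp, "gaussian", mode = "manual",
                       init = list(nugget = 0.1, sill = 0.5, range = 3))
  expect_equal(unclass(man)[c("nugget", "sill", "range")],
               list(nugget = 0.1, sill = 0.5, range = 3))
  expect_error(variogram_model("spherical", -0.1, 1, 1), "nugget")
})

test_that("variogram families are monotone with the stated limits", {
  m <- list(variogram_model("spherical", 0.1, 1, 5),
            variogram_model("exponential", 0.1, 1, 5),
            variogram_model("gaussian", 0.1, 1, 5),
            variogram_model("linear", 0.1, 1, 5))
  h <- seq(0, 30, by = 0.1)
  for (mm in m) {
    g <- variogram_gamma(h, mm)
    expect_equal(g[1], 0.1)
    expect_false(is.unsorted(g))
    expect_lte(max(g), 1 + 1e-9)
    expect_equal(variogram_gamma(30, mm), 1, tolerance = 0.01)
  }
})

test_that("ordinary kriging is exact at sample points with zero nugget", {
  set.seed(3)
  g <- grid_raster(matrix(0, 12, 12))
  n <- 8
  cells <- sample(144, n)
  cc <- cell_centers(g, cells)
  samples <- data.frame(lon = cc$lon, lat = cc$lat)
  lab <- rep(1:2, each = 4)
  vgm <- variogram_model("spherical", nugget = 0, sill = 1, range = 8)
  pr <- krige_indicator(samples, lab, vgm, g)
  pred1 <- pr[["1"]]$values[cells]
  expect_equal(pred1, as.numeric(lab == 1), tolerance = 1e-8)
})

test_that("kriging weights sum to one: constant indicator and cross-lineage sum", {
  set.seed(5)
  g <- grid_raster(matrix(0, 10, 10))
  cells <- sample(100, 9)
  cc <- cell_centers(g, cells)
  samples <- data.frame(lon = cc$lon, lat = cc$lat)
  vgm <- variogram_model("exponential", nugget = 0.05, sill = 1, range = 5)
  # all samples one lineage -> constant surface 1
  one <- krige_indicator(samples, rep(1, 9), vgm, g)
  expect_equal(unname(one[["1"]]$values[valid_cells(g)]), rep(1, 100))
  # three lineages: raw predictions sum to 1 everywhere
  pr <- krige_indicator(samples, rep(1:3, each = 3), vgm, g)
  raw <- Reduce(`+`, lapply(pr, attr, "raw"))
  expect_lt(max(abs(raw - 1)), 1e-6)
  # clipped values stay in [0, 1]
  for (p in pr) expect_true(all(p$values >= 0 & p$values <= 1))
})

test_that("two-sample kriging matches the closed-form hand solution", {
  g <- grid_raster(matrix(0, 1, 5))
  samples <- data.frame(lon = c(0.5, 4.5), lat = c(0.5, 0.5))
  vgm <- variogram_model("exponential", nugget = 0, sill = 1, range = 2)
  pr <- krige_indicator(samples, c(1, 2), vgm, g)
  cov_of <- function(h) (1 - variogram_gamma(h, vgm))
  # ordinary kriging with 2 samples: w1 - w2 = (c01 - c02) / (1 - c12)
  cc <- cell_centers(g)
  for (j in 1:5) {
    c01 <- cov_of(abs(cc$lon[j] - 0.5))
    c02 <- cov_of(abs(cc$lon[j] - 4.5))
    c12 <- cov_of(4)
    w1 <- (1 + (c01 - c02) / (1 - c12)) / 2
    expect_equal(attr(pr[["1"]], "raw")[j], w1, tolerance = 1e-9)
  }
})

test_that("duplicate sample coordinates are averaged, not singular", {
  g <- grid_raster(matrix(0, 6, 6))
  cc <- cell_centers(g, c(1, 1, 20))
  samples <- data.frame(lon = cc$lon, lat = cc$lat)
  vgm <- variogram_model("spherical", nugget = 0, sill = 1, range = 4)
  expect_message(pr <- krige_indicator(samples, c(1, 2, 2), vgm, g),
                 "duplicate")
  # the duplicated site carries indicator 0.5 for each lineage
  expect_equal(pr[["1"]]$values[1], 0.5, tolerance = 1e-8)
})

test_that("segregated lineages are recovered from kriged indicators", {
  st <- gen_landscape(11, 32, 32, 2, autocorr_range = 4)
  tr <- gen_virtual_species(st, response = function(X) rep(1, nrow(X)),
                            n_lineages = 2, seed = 3)
  occ <- sample_occurrences(tr, 40, seed = 4)
  gdm <- gen_genetic_distances(occ, within_rate = 0.005,
                               between_offset = 0.1, noise_sd = 0.002,
                               seed = 5)
  vgm <- fit_variogram(empirical_variogram(gdm), "spherical")
  pr <- krige_indicator(occ, occ$lineage, vgm, st$layers[[1]])
  pred <- ifelse(pr[["1"]]$values >= 0.5, 1L, 2L)
  truth <- tr$domains$values
  cells <- tr$range_cells
  expect_gte(mean(pred[cells] == truth[cells]), 0.9)
})

test_that("lineage_binary thresholds and intersects with the species range", {
  v <- matrix(0, 8, 8); v[1:4, ] <- 1
  sp <- binary_range(grid_raster(v), "sp")
  full <- grid_raster(matrix(1, 8, 8))
  lb <- lineage_binary(full, sp, "sp_1")
  expect_equal(lb$size, sp$size)
  expect_equal(lb$kind, "lineage")
  low <- grid_raster(matrix(0.49, 8, 8))
  expect_equal(lineage_binary(low, sp, "sp_1")$size, 0)
  empty_sp <- binary_range(grid_raster(matrix(0, 8, 8)), "sp")
  expect_equal(lineage_binary(full, empty_sp, "sp_1")$size, 0)
  small <- grid_raster(matrix(1, 4, 4))
  expect_error(lineage_binary(small, sp, "x"), "not on the same grid")
})
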