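test_that("select_variables honours the correlation ceiling and k", {
  st <- gen_landscape(2, 24, 24, 4, autocorr_range = 3)
  st$layers$lv02$values <- st$layers$lv01$values  # perfectly correlated pair
  keep1 <- select_variables(st, 0.75, k = 1)
  expect_length(keep1, 1)
  # independent rough layers: all retained at k = n
  st2 <- gen_landscape(3, 24, 24, 4, autocorr_range = 0)
  expect_length(select_variables(st2, 0.75, 4), 4)
  # larger stack: output satisfies the ceiling
  st14 <- gen_landscape(4, 32, 32, 14, autocorr_range = 5)
  keep <- select_variables(st14, 0.75, 8)
  X <- sapply(keep, function(v) as.vector(st14$layers[[v]]$values))
  R <- abs(cor(X)); diag(R) <- 0
  expect_lte(max(R), 0.75)
  expect_lte(length(keep), 8)
  expect_error(select_variables(st14, 0.75, 20), "exceeds")
})

test_that("thin_occurrences_pca3 keeps records separated in PC space", {
  st <- gen_landscape(5, 24, 24, 4, autocorr_range = 3)
  tr <- gen_virtual_species(st, n_lineages = 1, seed = 1)
  occ <- sample_occurrences(tr, 30, seed = 2)
  expect_identical(thin_occurrences_pca3(occ, st, radius = 0), occ)
  # duplicate records collapse to one survivor per group
  dup <- rbind(occ[1, ], occ[1, ], occ[1, ])
  expect_equal(nrow(thin_occurrences_pca3(dup, st, radius = 0.1)), 1)
  # kept records are pairwise >= radius apart in PC space
  kept <- thin_occurrences_pca3(occ, st, radius = 1.5)
  X <- sapply(st$layers, function(l) l$values[valid_cells(st$layers[[1]])])
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  Xo <- sapply(st$layers, function(l) l$values[kept$cell])
  P <- scale(Xo, pc$center, pc$scale) %*% pc$rotation[, 1:3]
  d <- as.matrix(dist(P)); diag(d) <- Inf
  expect_gte(min(d), 1.5)
})

test_that("fit_maxent: uniform presences shrink to the uniform density", {
  st <- gen_landscape(6, 12, 12, 2, autocorr_range = 2)
  cc <- cell_centers(st$layers[[1]])
  occ <- data.frame(lon = cc$lon, lat = cc$lat)
  m <- fit_maxent(occ, st, names(st$layers))
  expect_true(all(abs(m$beta) < 1e-8))
  expect_equal(sum(m$density), 1, tolerance = 1e-8)
})

test_that("fit_maxent: signal on one variable yields a positive coefficient and monotone objective", {
  st <- gen_landscape(7, 32, 32, 3, autocorr_range = 4)
  tr <- gen_virtual_species(st, n_lineages = 1, seed = 2)  # logistic on lv01
  occ <- sample_occurrences(tr, 50, seed = 3)
  m <- fit_maxent(occ, st, names(st$layers))
  expect_gt(m$beta[["lv01"]], 0)
  expect_false(is.unsorted(rev(m$objective_trace)))
  expect_equal(sum(m$density), 1, tolerance = 1e-8)
  expect_error(fit_maxent(occ[1:2, ], st, names(st$layers)), "at least 3")
})

test_that("replicate_evaluate applies the replicate-count rule", {
  st <- gen_landscape(8, 24, 24, 2, autocorr_range = 3)
  tr <- gen_virtual_species(st, n_lineages = 1, seed = 4)
  occ24 <- sample_occurrences(tr, 24, seed = 5)
  expect_equal(replicate_evaluate(occ24, st, names(st$layers),
                                  seed = 1)$n_rep, 10L)
  expect_equal(replicate_evaluate(occ24[1:12, ], st, names(st$layers),
                                  seed = 1)$n_rep, 8L)
  expect_equal(replicate_evaluate(occ24[1:8, ], st, names(st$layers),
                                  seed = 1)$n_rep, 4L)
  expect_error(replicate_evaluate(occ24[1:5, ], st, names(st$layers)),
               "too few records")
})

test_that("rank AUC of constant scores is 0.5", {
  expect_equal(lineascape:::rank_auc(rep(1, 7), rep(1, 50)), 0.5)
  expect_equal(lineascape:::rank_auc(2, c(1, 1, 3)), 2 / 3)
})

test_that("binarize_mtp uses the minimum training suitability and covers presences", {
  st <- gen_landscape(9, 24, 24, 2, autocorr_range = 3)
  tr <- gen_virtual_species(st, n_lineages = 1, seed = 6)
  occ <- sample_occurrences(tr, 20, seed = 7)
  ev <- replicate_evaluate(occ, st, names(st$layers), seed = 8)
  rng <- binarize_mtp(ev, occ)
  cells <- cell_at(ev$mean_map, occ$lon, occ$lat)
  expect_equal(rng$threshold, min(ev$mean_map$values[cells]))
  expect_true(all(rng$raster$values[cells] == 1))
  # monotone in theta: lower threshold gives a superset
  low <- ev$mean_map$values >= (rng$threshold / 2)
  expect_true(all(low[rng$raster$values == 1]))
  expect_equal(rng$size, sum(rng$raster$values == 1, na.rm = TRUE))
})

test_that("tss reproduces hand arithmetic and the degenerate cases", {
  v <- matrix(0, 10, 10)
  v[1:30] <- 1                         # range = 30 of 100 cells
  rng <- binary_range(grid_raster(v), "f")
  cc <- cell_centers(rng$raster, c(1:9, 31))  # 9 in, 1 out
  pres <- data.frame(lon = cc$lon, lat = cc$lat)
  out <- tss(rng, pres, background_n = 10000, seed = 1)
  expect_equal(out$sensitivity, 0.9)
  expect_equal(out$specificity, 0.7)
  expect_equal(out$tss, 0.9 + 0.7 - 1)
  # range covering everything: sens 1, spec 0, TSS 0
  all1 <- binary_range(grid_raster(matrix(1, 10, 10)), "f")
  expect_equal(tss(all1, pres)$tss, 0)
  # perfect prediction
  perfect <- binary_range(grid_raster(matrix(c(1, rep(0, 99)), 10, 10)), "f")
  cc1 <- cell_centers(perfect$raster, 1)
  expect_equal(tss(perfect, data.frame(lon = cc1$lon, lat = cc1$lat))$tss,
               1 - 1 / 100)
})

test_that("variable contributions are normalized and identify the driver", {
  st <- gen_landscape(1, 48, 48, 4, autocorr_range = 5)
  tr <- gen_virtual_species(st, n_lineages = 2, seed = 2)
  occ <- sample_occurrences(tr, 40, seed = 3)
  m <- fit_maxent(occ, st, names(st$layers))
  contr <- variable_contribution(m, st, occ, seed = 1)
  expect_equal(sum(contr), 100, tolerance = 1e-6)
  expect_equal(names(which.max(contr)), "lv01")
  expect_gt(max(contr), 50)
  # single-variable model: that variable gets 100%
  m1 <- fit_maxent(occ, st, "lv01")
  expect_equal(unname(variable_contribution(m1, st, occ, seed = 1)), 100)
})

test_that("records_to_range maps records to cells exactly once", {
  st <- gen_landscape(2, 16, 16, 2)
  g <- st$layers[[1]]
  cc <- cell_centers(g, c(5, 20, 20, 77))   # one duplicate cell
  occ <- data.frame(lon = cc$lon, lat = cc$lat)
  rng <- records_to_range(occ, st)
  expect_equal(rng$size, 3)
  expect_true(all(rng$raster$values[c(5, 20, 77)] == 1))
  r1 <- records_to_range(occ[1, , drop = FALSE], st)
  expect_equal(r1$size, 1)
  expect_error(records_to_range(occ[rep(1, 6), ], st), "1-5")
})
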