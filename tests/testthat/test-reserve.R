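square_feature <- function(rows, cols, nr = 6, nc = 6, id = "f") {
  v <- matrix(0, nr, nc)
  v[rows, cols] <- 1
  binary_range(grid_raster(v), id)
}

test_that("build_cost applies category costs and buffered surcharges", {
  zp <- grid_raster(matrix(rep(0:3, each = 8), 4, 8, byrow = TRUE))
  cost <- build_cost(zp)
  expect_equal(cost$values[1, 1], 50)    # general use defaults to middle tier
  expect_equal(cost$values[2, 1], 50)    # resource use
  expect_equal(cost$values[3, 1], 25)    # national park
  expect_equal(cost$values[4, 1], 1)     # sanctuary
  # a main road crossing the national-park row: max rule gives 100
  roads <- data.frame(lon = 2.5, lat = 1.5)   # centre of a row-3 cell
  cost2 <- build_cost(zp, roads = roads, road_buffer = 1.2)
  expect_equal(cost2$values[3, 3], 100)
  expect_equal(cost2$values[3, 7], 25)        # beyond the buffer
  # urban raster input with a large buffer floods its surroundings
  urb <- grid_raster(matrix(0, 4, 8)); urb$values[1, 1] <- 1
  cost3 <- build_cost(zp, urban = urb, urban_buffer = 100)
  expect_true(all(cost3$values == 100))
})

test_that("removal_score is monotone in cost and enforces the edge contract", {
  f <- square_feature(2:5, 2:5)
  cost <- grid_raster(matrix(1, 6, 6)); cost$values[1, 3] <- 100
  pr <- prioritization_problem(list(f), 50, cost, blp = 0.4)
  incl <- matrix(TRUE, 6, 6)
  R <- 1
  # cells (1,3) and (6,3): identical geometry, no features, different costs
  s <- removal_score(pr, incl, R, c(13, 18))
  expect_lt(s[1], s[2])   # expensive cell scores lower -> removed earlier
  # interior cell is not on the edge
  expect_error(removal_score(pr, incl, R, cell_at(pr$grid, 2.5, 2.5)),
               "not on the current edge")
})

test_that("rank_cells: tau = 100 keeps the entire feature range", {
  f <- square_feature(2:4, 2:5)
  res <- rank_cells(prioritization_problem(list(f), 100, blp = 0))
  ms <- minimal_set(res)
  expect_equal(ms$size, f$size)
  expect_equal(ms$raster$values, f$raster$values)
})

test_that("rank_cells: 50% target on a 12-cell range keeps exactly half", {
  f <- square_feature(2:4, 2:5)          # 12 cells on a 6x6 grid
  res <- rank_cells(prioritization_problem(list(f), 50, blp = 0))
  ms <- minimal_set(res)
  expect_equal(ms$size, ceiling(0.5 * f$size))
  # ranks are a permutation of valid cells
  rk <- res$rank$values
  expect_setequal(rk[is.finite(rk)], seq_len(36))
  # minimal-set members were removed after every non-member
  expect_gt(min(rk[ms$raster$values == 1]), max(rk[ms$raster$values == 0]))
  # representation trace never dips below target before the frontier
  npre <- sum(res$trace$phase == "target")
  expect_true(all(res$R_trace[seq_len(npre), 1] >= 0.5 - 1e-9))
})

test_that("minimal sets are locally minimal under the edge rule", {
  set.seed(6)
  for (trial in 1:3) {
    v1 <- matrix(as.numeric(runif(16) < 0.6), 4, 4)
    v2 <- matrix(as.numeric(runif(16) < 0.6), 4, 4)
    if (!any(v1 == 1)) v1[1] <- 1
    if (!any(v2 == 1)) v2[1] <- 1
    feats <- list(binary_range(grid_raster(v1), "a"),
                  binary_range(grid_raster(v2), "b"))
    pr <- prioritization_problem(feats, c(50, 50), blp = 0)
    ms <- minimal_set(rank_cells(pr))
    sel <- ms$raster$values == 1
    R <- sapply(feats, function(f) sum(f$raster$values[sel]) / f$size)
    expect_true(all(R >= 0.5 - 1e-9))
    # no single edge cell of the set is removable without violating a target
    edge <- lineascape:::edge_cells(sel)
    for (cell in which(edge)) {
      sel2 <- sel; sel2[cell] <- FALSE
      R2 <- sapply(feats, function(f) sum(f$raster$values[sel2]) / f$size)
      expect_true(any(R2 < 0.5 - 1e-9))
    }
  }
})

test_that("greedy minimal set is within one cell of the brute-force optimum", {
  set.seed(42)
  for (trial in 1:10) {
    nf <- sample(1:3, 1)
    Fl <- lapply(seq_len(nf), function(j) {
      v <- runif(16) < 0.5
      if (!any(v)) v[sample(16, 1)] <- TRUE
      v
    })
    tau <- sample(c(30, 50, 70), nf, replace = TRUE)
    feats <- lapply(seq_along(Fl), function(j)
      binary_range(grid_raster(matrix(as.numeric(Fl[[j]]), 4, 4)),
                   paste0("f", j)))
    ms <- minimal_set(rank_cells(prioritization_problem(feats, tau, blp = 0)))
    opt <- oracle_min_set_size(Fl, tau)
    expect_lte(ms$size, opt + 1)
    # with beta = 0 the set stays inside the union of feature ranges
    union_f <- Reduce(`|`, Fl)
    expect_true(all(union_f[ms$raster$values == 1]))
  }
})

test_that("raising a target never shrinks the minimal set", {
  f <- square_feature(2:5, 2:5)
  sizes <- sapply(c(25, 50, 75, 100), function(tau)
    minimal_set(rank_cells(prioritization_problem(list(f), tau,
                                                  blp = 0)))$size)
  expect_false(is.unsorted(sizes))
})

test_that("boundary length penalty does not worsen aggregation", {
  set.seed(9)
  v <- matrix(as.numeric(runif(100) < 0.7), 10, 10)
  f <- binary_range(grid_raster(v), "f")
  perim_ratio <- function(ms) {
    sel <- ms$raster$values == 1
    per <- sum((4 - lineascape:::incl_nbrs4(sel))[sel])
    per / sum(sel)
  }
  ms0 <- minimal_set(rank_cells(prioritization_problem(list(f), 50, blp = 0)))
  ms4 <- minimal_set(rank_cells(prioritization_problem(list(f), 50,
                                                       blp = 0.4)))
  expect_lte(perim_ratio(ms4), perim_ratio(ms0) + 1e-9)
})

test_that("compare_solutions matches the textbook chi-square", {
  zp <- grid_raster(matrix(rep(0:3, times = c(40, 30, 20, 10)), nrow = 10))
  vA <- matrix(0, 10, 10); vA[1:50] <- 1
  vB <- matrix(0, 10, 10); vB[41:100] <- 1
  A <- binary_range(grid_raster(vA), "A")
  B <- binary_range(grid_raster(vB), "B")
  cmp <- compare_solutions(A, B, zp)
  O <- cmp$table
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(cmp$chi_square, sum((O - E)^2 / E))
  expect_equal(cmp$df, 3L)
  expect_equal(rowSums(cmp$percents), c(A = 100, B = 100))
  # identical solutions: statistic 0
  expect_equal(compare_solutions(A, A, zp)$chi_square, 0)
  empty <- binary_range(grid_raster(matrix(0, 10, 10)), "E")
  expect_error(compare_solutions(A, empty, zp), "empty solution")
})
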