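#' Target-based greedy reserve prioritization
#'
#' Starting from the full landscape, cells are removed one (or `warp`) at a
#' time, always from the edge of the remaining area, never letting any
#' feature's remaining representation `R_f` (fraction of its range still
#' included) drop below its target `tau_f`.  Among feasible edge cells the
#' one with the lowest removal score goes first, where
#' `score = [max_f(p_f / max(R_f - tau_f, eps)) + beta * dL / 4] / cost`:
#' `p_f` is the cell's share of feature `f`'s range, `dL` the change in
#' total 4-neighbourhood boundary length if the cell is removed (so the
#' boundary-length penalty `beta` favours removing protrusions and keeps
#' the solution aggregated), and `cost` the cell's cost.  When no feasible
#' edge cell remains, the cells still included form the minimal set; removal
#' then continues ignoring targets to produce a complete ranking (1 =
#' removed first, highest ranks = most valuable).
#'
#' @name reserve_design
NULL

#' Build a cost raster from the zoning plan and infrastructure
#'
#' Base costs come from the zoning category (defaults: general use 50,
#' resource use 50, national park 25, sanctuary 1; the plan assigns no cost
#' to general-use cells so they default to the resource-use tier).  Cells
#' within `road_buffer` map units of a main road or `urban_buffer` of an
#' urban cell are surcharged to 100; the per-cell cost is the maximum of
#' all applicable rules.
#'
#' @param zp zoning plan `grid_raster` (values 0-3).
#' @param roads,urban optional data frames with `lon`, `lat` of main-road /
#'   urban locations, or 0/1 `grid_raster`s flagging such cells.
#' @param road_buffer,urban_buffer buffer radii in map units (defaults 112
#'   and 1000, matching ~100 m cells).
#' @param category_cost named cost per zoning category.
#' @param infra_cost surcharge cost for buffered road/urban cells.
#' @return a cost `grid_raster`.
#' @export
build_cost <- function(zp, roads = NULL, urban = NULL,
                       road_buffer = 112, urban_buffer = 1000,
                       category_cost = c("0" = 50, "1" = 50, "2" = 25, "3" = 1),
                       infra_cost = 100) {
  cost <- unname(category_cost[as.character(zp$values)])
  cost <- matrix(cost, nrow(zp$values), ncol(zp$values))
  flag_near <- function(src, buffer) {
    pts <- if (inherits(src, "grid_raster")) {
      stop_unless_aligned(src, zp, "infrastructure and zoning rasters")
      cell_centers(src, which(src$values == 1))
    } else src
    if (!nrow(pts)) return(NULL)
    cc <- cell_centers(zp, valid_cells(zp))
    d2min <- rep(Inf, nrow(cc))
    for (i in seq_len(nrow(pts)))
      d2min <- pmin(d2min, (cc$lon - pts$lon[i])^2 + (cc$lat - pts$lat[i])^2)
    cc$cell[d2min <= buffer^2]
  }
  for (src in list(list(roads, road_buffer), list(urban, urban_buffer))) {
    if (is.null(src[[1L]])) next
    hit <- flag_near(src[[1L]], src[[2L]])
    if (length(hit)) cost[hit] <- pmax(cost[hit], infra_cost)
  }
  cost[!is.finite(zp$values)] <- NA_real_
  grid_raster(cost, zp$x0, zp$y0, zp$cellsize)
}

#' Define a prioritization problem
#'
#' @param features list of `binary_range` objects (aligned).
#' @param targets numeric vector of representation targets in percent,
#'   one per feature, each in `(0, 100]`.
#' @param cost cost `grid_raster` (all costs at least 1); `NULL` for
#'   uniform cost 1.
#' @param blp boundary length penalty weight `beta` (default 0.4).
#' @param warp cells removed per iteration (default 1).
#' @return a `prioritization_problem`.
#' @export
prioritization_problem <- function(features, targets, cost = NULL,
                                   blp = 0.4, warp = 1) {
  if (!length(features)) stop("prioritization_problem: no features")
  if (length(targets) != length(features))
    stop("prioritization_problem: one target per feature required")
  if (any(targets <= 0 | targets > 100))
    stop("prioritization_problem: targets must be in (0, 100]")
  g <- features[[1L]]$raster
  if (is.null(cost)) cost <- with_values(g, 1)
  stop_unless_aligned(cost, g, "cost and feature rasters")
  for (f in features) stop_unless_aligned(f$raster, g, "feature rasters")
  F <- vapply(features, function(f) {
    v <- f$raster$values
    v[!is.finite(v)] <- 0
    as.numeric(v)
  }, numeric(length(g$values)))
  tot <- colSums(F)
  if (any(tot == 0)) stop("prioritization_problem: feature with empty range")
  structure(list(grid = g, features = features,
                 ids = vapply(features, `[[`, "", "feature_id"),
                 P = sweep(F, 2L, tot, `/`), tau = targets / 100,
                 cost = cost$values, blp = blp, warp = warp),
            class = "prioritization_problem")
}

## Internal: logical matrix of edge cells (included with >= 1 excluded
## 8-neighbour; the raster border counts as excluded).
edge_cells <- function(incl) {
  nr <- nrow(incl); nc <- ncol(incl)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- incl
  all_in <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    all_in <- all_in & pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  incl & !all_in
}

## Internal: number of included 4-neighbours of every cell.
incl_nbrs4 <- function(incl) {
  nr <- nrow(incl); nc <- ncol(incl)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- incl
  pad[1:nr, 2:(nc + 1L)] + pad[3:(nr + 2L), 2:(nc + 1L)] +
    pad[2:(nr + 1L), 1:nc] + pad[2:(nr + 1L), 3:(nc + 2L)]
}

#' Removal score of edge cells
#'
#' Computes the score of the given (edge) cells under the current inclusion
#' state; lower scores are removed earlier.  Calling it for a cell that is
#' not currently an includable edge cell is a contract violation.
#'
#' @param problem a `prioritization_problem`.
#' @param incl logical inclusion matrix.
#' @param R current per-feature representation fractions.
#' @param cells integer cell indices (column-major).
#' @param eps floor for the target headroom denominator.
#' @return numeric scores.
#' @export
removal_score <- function(problem, incl, R, cells, eps = 1e-9) {
  edge <- edge_cells(incl)
  if (!all(edge[cells]))
    stop("removal_score: cell is not on the current edge")
  den <- pmax(R - problem$tau, eps)
  Pc <- problem$P[cells, , drop = FALSE]
  feat_term <- do.call(pmax, c(lapply(seq_along(den),
                                      function(f) Pc[, f] / den[f]), list(0)))
  dL <- 2 * incl_nbrs4(incl)[cells] - 4
  (feat_term + problem$blp * dL / 4) / problem$cost[cells]
}

#' Rank all cells by greedy target-constrained removal
#'
#' @param problem a `prioritization_problem`.
#' @return a `prioritization_result`: `rank` raster (1 = removed first),
#'   `minimal` logical matrix of the minimal set, `trace` (data frame of
#'   per-removal records), `R_trace` (matrix of per-feature representation
#'   after each removal), `termination`.
#' @export
rank_cells <- function(problem) {
  g <- problem$grid
  incl <- is.finite(g$values)
  R <- rep(1, length(problem$tau))
  bad <- which(R < problem$tau - 1e-12)
  if (length(bad))
    stop("rank_cells: infeasible start; failing features: ",
         paste(problem$ids[bad], collapse = ", "))
  eps <- 1e-9
  nvalid <- sum(incl)
  rank_m <- g$values * NA_real_
  minimal <- NULL
  order_i <- 0L
  trace <- vector("list", nvalid)
  R_trace <- matrix(NA_real_, nvalid, length(problem$tau))
  nr <- nrow(incl)
  repeat {
    if (!any(incl)) break
    edge <- edge_cells(incl)
    cand <- which(edge)
    if (is.null(minimal)) {
      ok <- rep(TRUE, length(cand))
      for (f in seq_along(problem$tau))
        ok <- ok & (problem$P[cand, f] <= R[f] - problem$tau[f] + 1e-12)
      cand <- cand[ok]
      if (!length(cand)) {
        minimal <- incl
        next
      }
    }
    den <- pmax(R - problem$tau, eps)
    Pc <- problem$P[cand, , drop = FALSE]
    feat_term <- do.call(pmax, c(lapply(seq_along(den),
                                        function(f) Pc[, f] / den[f]),
                                 list(rep(0, length(cand)))))
    dL <- 2 * incl_nbrs4(incl)[cand] - 4
    score <- (feat_term + problem$blp * dL / 4) / problem$cost[cand]
    row <- ((cand - 1L) %% nr) + 1L
    col <- ((cand - 1L) %/% nr) + 1L
    take <- cand[order(score, row, col)[seq_len(min(problem$warp,
                                                    length(cand)))]]
    for (cell in take) {
      order_i <- order_i + 1L
      incl[cell] <- FALSE
      R <- R - problem$P[cell, ]
      rank_m[cell] <- order_i
      trace[[order_i]] <- data.frame(
        iteration = order_i, cell = cell,
        score = score[match(cell, cand)],
        phase = if (is.null(minimal)) "target" else "post")
      R_trace[order_i, ] <- R
    }
  }
  if (is.null(minimal)) minimal <- incl  # degenerate: everything removable
  colnames(R_trace) <- problem$ids
  structure(list(rank = grid_raster(rank_m, g$x0, g$y0, g$cellsize),
                 minimal = minimal, trace = do.call(rbind, trace),
                 R_trace = R_trace, problem = problem,
                 termination = "complete"),
            class = "prioritization_result")
}

#' Minimal set of a prioritization result
#'
#' The cells still included when no edge cell could be removed without
#' violating a target; every feature meets its target within the set (this
#' is asserted).
#'
#' @param result a `prioritization_result`.
#' @param feature_id identifier for the returned range.
#' @return a `binary_range`.
#' @export
minimal_set <- function(result, feature_id = "minimal_set") {
  pr <- result$problem
  sel <- as.numeric(result$minimal)
  R <- drop(crossprod(pr$P, sel))
  stopifnot(all(R >= pr$tau - 1e-9))
  g <- pr$grid
  v <- matrix(sel, nrow(g$values), ncol(g$values))
  v[!is.finite(g$values)] <- NA_real_
  binary_range(grid_raster(v, g$x0, g$y0, g$cellsize), feature_id,
               kind = "species")
}

#' Compare two reserve solutions across zoning categories
#'
#' Tabulates each solution's cells over the zoning categories and computes
#' the Pearson chi-square statistic of the 2 x 4 count table (df = 3).
#'
#' @param solA,solB `binary_range` solutions.
#' @param zp zoning plan raster.
#' @return list with `table` (2 x 4 counts), `percents`, `chi_square`,
#'   `df`, `p_value`.
#' @export
compare_solutions <- function(solA, solB, zp) {
  counts <- function(sol) {
    r <- sol$raster
    stop_unless_aligned(r, zp, "solution and zoning rasters")
    cells <- which(r$values == 1)
    if (!length(cells)) stop("compare_solutions: empty solution")
    vapply(0:3, function(k) sum(zp$values[cells] == k, na.rm = TRUE), 0)
  }
  O <- rbind(A = counts(solA), B = counts(solB))
  colnames(O) <- as.character(0:3)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi <- sum((O - E)^2 / E, na.rm = TRUE)
  list(table = O, percents = 100 * sweep(O, 1L, rowSums(O), `/`),
       chi_square = chi, df = 3L,
       p_value = stats::pchisq(chi, df = 3L, lower.tail = FALSE))
}
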