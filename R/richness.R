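#' Species and lineage richness layers
#'
#' Binary ranges are stacked into per-cell counts; relative richness is the
#' count as a percent of the maximum observed cell count (so the richest
#' cell is at 100).  The standard product is six layers: species and lineage
#' richness for all, wide-range, and restricted-range features, where a
#' feature is restricted-range when it occupies less than a cutoff fraction
#' (default 30%) of the island's valid cells.
#'
#' @name richness
NULL

#' Partition features by range breadth
#'
#' @param features list of `binary_range` objects.
#' @param n_island_cells number of valid cells on the island.
#' @param cutoff restricted-range cutoff as a fraction of the island
#'   (default 0.30); a feature is restricted iff its range is strictly
#'   smaller than `cutoff * n_island_cells`.
#' @return list with `wide` and `restricted` (character vectors of feature
#'   ids) and `is_restricted` (named logical).
#' @export
classify_range_breadth <- function(features, n_island_cells, cutoff = 0.30) {
  sizes <- vapply(features, `[[`, 0, "size")
  ids <- vapply(features, `[[`, "", "feature_id")
  restricted <- sizes < cutoff * n_island_cells
  list(wide = ids[!restricted], restricted = ids[restricted],
       is_restricted = stats::setNames(restricted, ids))
}

#' Stack binary ranges into a richness layer
#'
#' @param features nonempty list of aligned `binary_range` objects.
#' @param layer_def label describing the layer (e.g. `"species_all"`).
#' @return a `richness_layer`: `count` and `relative` rasters plus the
#'   definition.
#' @export
stack_richness <- function(features, layer_def = "layer") {
  if (!length(features)) stop("stack_richness: empty feature list")
  g <- features[[1L]]$raster
  for (f in features) stop_unless_aligned(f$raster, g, "feature rasters")
  cnt <- Reduce(`+`, lapply(features, function(f) {
    v <- f$raster$values
    v[!is.finite(v)] <- 0
    v
  }))
  cnt[!is.finite(g$values)] <- NA_real_
  mx <- max(cnt, na.rm = TRUE)
  rel <- if (mx > 0) 100 * cnt / mx else cnt * 0
  structure(list(count = grid_raster(cnt, g$x0, g$y0, g$cellsize),
                 relative = grid_raster(rel, g$x0, g$y0, g$cellsize),
                 layer_def = layer_def, n_features = length(features),
                 max_count = mx),
            class = "richness_layer")
}

#' The six standard richness layers
#'
#' Emits `{species, lineage} x {all, wide, restricted}` in one call.
#'
#' @param features list of `binary_range` objects (mixed kinds).
#' @param n_island_cells number of valid island cells.
#' @param cutoff restricted-range cutoff fraction.
#' @return named list of six `richness_layer`s
#'   (`species_all`, ..., `lineage_restricted`).
#' @export
richness_layers <- function(features, n_island_cells, cutoff = 0.30) {
  kinds <- vapply(features, `[[`, "", "kind")
  br <- classify_range_breadth(features, n_island_cells, cutoff)
  ids <- vapply(features, `[[`, "", "feature_id")
  pick <- function(kind, breadth) {
    sel <- kinds == kind & (breadth == "all" |
      (breadth == "restricted") == br$is_restricted[ids])
    features[sel]
  }
  out <- list()
  for (kind in c("species", "lineage"))
    for (breadth in c("all", "wide", "restricted")) {
      nm <- paste(kind, breadth, sep = "_")
      fs <- pick(kind, breadth)
      out[nm] <- list(if (length(fs)) stack_richness(fs, nm))
    }
  out
}

#' Percent difference between species and lineage richness
#'
#' @param species_layer,lineage_layer `richness_layer`s on the same grid.
#' @return a `grid_raster` of `relative_species - relative_lineage`
#'   (in `[-100, 100]`).
#' @export
difference_map <- function(species_layer, lineage_layer) {
  a <- species_layer$relative; b <- lineage_layer$relative
  stop_unless_aligned(a, b, "richness layers")
  grid_raster(a$values - b$values, a$x0, a$y0, a$cellsize)
}

#' Binarize a richness layer at its upper quartile
#'
#' The threshold is the 75th percentile of valid-cell relative richness by
#' the nearest-rank method; cells at or above the threshold (ties included)
#' are 1.
#'
#' @param layer a `richness_layer`.
#' @return a 0/1 `grid_raster`.
#' @export
top_quartile_binary <- function(layer) {
  r <- layer$relative
  vals <- r$values[valid_cells(r)]
  if (!length(vals)) stop("top_quartile_binary: empty layer")
  srt <- sort(vals)
  thr <- srt[ceiling(0.75 * length(srt))]
  grid_raster((r$values >= thr) * 1, r$x0, r$y0, r$cellsize)
}

#' Correlate a richness layer with landscape variables and coordinates
#'
#' Plain Pearson correlations over valid cells between the layer's counts
#' and each landscape variable plus cell-centre latitude and longitude.
#'
#' @param layer a `richness_layer`.
#' @param stack a `landscape_stack` on the same grid.
#' @return data frame with `variable`, `rho`, `p_value` (a zero-variance
#'   variable gives `NA` with a note).
#' @export
correlate_lv <- function(layer, stack) {
  r <- layer$count
  cells <- valid_cells(r)
  if (length(cells) < 3L) stop("correlate_lv: need at least 3 valid cells")
  y <- r$values[cells]
  cc <- cell_centers(r, cells)
  X <- cbind(stack_matrix(stack, cells), lat = cc$lat, lon = cc$lon)
  out <- lapply(colnames(X), function(v) {
    x <- X[, v]
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
      return(data.frame(variable = v, rho = NA_real_, p_value = NA_real_))
    ct <- stats::cor.test(y, x, method = "pearson")
    data.frame(variable = v, rho = unname(ct$estimate),
               p_value = ct$p.value)
  })
  do.call(rbind, out)
}
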