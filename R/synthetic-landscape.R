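#' Synthetic landscape-variable stacks
#'
#' Generates a stack of spatially autocorrelated Gaussian random fields that
#' stand in for real landscape variables (slope, habitat cover, ...).  Each
#' layer is white noise convolved with an isotropic Gaussian kernel whose
#' standard deviation (`autocorr_range`, in cells) sets the autocorrelation
#' range; the convolution is performed spectrally (circular), which is cheap
#' and exactly reproducible for a fixed seed.  Layers are standardised to
#' zero mean and unit variance over the grid.
#'
#' @param seed integer RNG seed; identical seed + parameters give
#'   bit-identical stacks.
#' @param nrows,ncols grid dimensions, both at least 8.
#' @param n_vars number of layers, at least 2.
#' @param autocorr_range Gaussian kernel standard deviation in cell units;
#'   0 gives independent white noise per cell.
#' @param cellsize,x0,y0 georeference passed to [grid_raster()].
#' @return a `landscape_stack`: list with `layers` (named list of
#'   `grid_raster`) and the generation parameters.
#' @export
gen_landscape <- function(seed, nrows, ncols, n_vars, autocorr_range = 4,
                          cellsize = 1, x0 = 0, y0 = nrows * cellsize) {
  if (nrows < 8 || ncols < 8) stop("gen_landscape: nrows and ncols must be >= 8")
  if (n_vars < 2) stop("gen_landscape: n_vars must be >= 2")
  if (autocorr_range < 0) stop("gen_landscape: autocorr_range must be >= 0")
  set.seed(seed)
  kern_f <- NULL
  if (autocorr_range > 0) {
    ir <- c(0:(nrows %/% 2), -((ceiling(nrows / 2) - 1):1))
    ic <- c(0:(ncols %/% 2), -((ceiling(ncols / 2) - 1):1))
    k <- exp(-outer(ir^2, ic^2, `+`) / (2 * autocorr_range^2))
    kern_f <- stats::fft(k / sum(k))
  }
  layers <- lapply(seq_len(n_vars), function(i) {
    z <- matrix(stats::rnorm(nrows * ncols), nrows, ncols)
    if (!is.null(kern_f))
      z <- Re(stats::fft(stats::fft(z) * kern_f, inverse = TRUE)) / (nrows * ncols)
    z <- (z - mean(z)) / stats::sd(z)
    grid_raster(z, x0 = x0, y0 = y0, cellsize = cellsize)
  })
  names(layers) <- sprintf("lv%02d", seq_len(n_vars))
  structure(list(layers = layers, nrows = nrows, ncols = ncols,
                 seed = seed, autocorr_range = autocorr_range),
            class = "landscape_stack")
}

#' @export
print.landscape_stack <- function(x, ...) {
  cat(sprintf("landscape_stack: %d layers of %d x %d (autocorr range %g)\n",
              length(x$layers), x$nrows, x$ncols, x$autocorr_range))
  invisible(x)
}

## Internal: matrix (valid cells x layers) of layer values.
stack_matrix <- function(stack, cells = valid_cells(stack$layers[[1]])) {
  vapply(stack$layers, function(l) l$values[cells], numeric(length(cells)))
}

#' Virtual species with known suitability and lineage structure
#'
#' Builds ground truth for recovery tests: a suitability surface in `[0, 1]`
#' obtained by applying a response function to the landscape layers, and a
#' partition of the resulting range (cells with suitability at or above
#' `range_cutoff`) into `n_lineages` spatially contiguous domains (Voronoi
#' cells around randomly placed domain seeds, Euclidean distance between
#' cell centres).
#'
#' @param stack a `landscape_stack`.
#' @param response either `NULL` (default logistic response on the first
#'   layer) or a function taking the matrix of layer values (cells x layers)
#'   and returning suitabilities in `[0, 1]`.
#' @param n_lineages number of lineage domains, at least 1.
#' @param seed integer RNG seed.
#' @param range_cutoff suitability defining the species' true range
#'   (default 0.3).
#' @return a `truth_set`: `suitability` raster, `domains` raster (integer
#'   lineage label inside the range, `NA` outside), `n_lineages`,
#'   `range_cells`.
#' @export
gen_virtual_species <- function(stack, response = NULL, n_lineages = 1,
                                seed = 1, range_cutoff = 0.3) {
  if (n_lineages < 1) stop("gen_virtual_species: n_lineages must be >= 1")
  g <- stack$layers[[1]]
  cells <- valid_cells(g)
  X <- stack_matrix(stack, cells)
  if (is.null(response)) response <- function(X) stats::plogis(2 * X[, 1])
  suit <- response(X)
  if (any(suit < -1e-9 | suit > 1 + 1e-9))
    stop("gen_virtual_species: response must map into [0, 1]")
  suit <- pmin(pmax(suit, 0), 1)
  sv <- g$values * NA_real_
  sv[cells] <- suit
  suit_r <- grid_raster(sv, g$x0, g$y0, g$cellsize)
  range_cells <- cells[suit >= range_cutoff]
  if (n_lineages > length(range_cells))
    stop("gen_virtual_species: n_lineages exceeds available range cells")
  set.seed(seed)
  centers <- sample(range_cells, n_lineages)
  cc <- cell_centers(g, range_cells)
  sc <- cell_centers(g, centers)
  d2 <- outer(cc$lon, sc$lon, `-`)^2 + outer(cc$lat, sc$lat, `-`)^2
  lab <- max.col(-d2, ties.method = "first")
  dv <- g$values * NA_real_
  dv[range_cells] <- lab
  structure(list(suitability = suit_r,
                 domains = grid_raster(dv, g$x0, g$y0, g$cellsize),
                 n_lineages = n_lineages, range_cells = range_cells,
                 range_cutoff = range_cutoff, seed = seed),
            class = "truth_set")
}

#' Sample presence records from a virtual species
#'
#' Draws `n` occupied cells without replacement with probability
#' proportional to true suitability, restricted to the species' true range;
#' records take the coordinates of the cell centre and carry the true
#' lineage label of their cell.
#'
#' @param truth a `truth_set`.
#' @param n number of records (at most the number of range cells).
#' @param seed integer RNG seed.
#' @param feature_id identifier copied into the output records.
#' @return data frame with `feature_id`, `lon`, `lat`, `lineage`, `cell`.
#' @export
sample_occurrences <- function(truth, n, seed = 1, feature_id = "sp") {
  if (n < 1) stop("sample_occurrences: n must be >= 1")
  cells <- truth$range_cells
  if (n > length(cells))
    stop("sample_occurrences: n exceeds number of range cells")
  g <- truth$suitability
  set.seed(seed)
  take <- if (length(cells) == 1L) cells else
    sample(cells, n, prob = g$values[cells])
  cc <- cell_centers(g, take)
  data.frame(feature_id = feature_id, lon = cc$lon, lat = cc$lat,
             lineage = truth$domains$values[take], cell = take,
             stringsAsFactors = FALSE)
}

#' Synthetic zoning plan and cost raster
#'
#' Emulates a four-category protection zoning (0 = general use, 1 = resource
#' use, 2 = national park, 3 = sanctuary; categories 1-3 are Protected
#' Areas).  A smoothed random field is cut at the quantiles implied by the
#' requested category fractions, which yields contiguous patches whose areas
#' match the fractions up to ties; lower field values become lower
#' categories.  The cost raster maps each category through `cost_rules`
#' (defaults: general use and resource use 50, national park 25, sanctuary
#' 1; road/urban surcharges are applied later by [build_cost()]).
#'
#' @param stack a `landscape_stack` providing the grid.
#' @param category_fractions length-4 nonnegative vector summing to 1
#'   (fractions of valid cells in categories 0-3).
#' @param cost_rules named numeric vector mapping categories `"0"`-`"3"` to
#'   cell costs.
#' @param seed integer RNG seed.
#' @param autocorr_range kernel range of the patch-forming field, in cells.
#' @return list with `zp` (categorical `grid_raster` with values 0-3) and
#'   `cost` (`grid_raster`).
#' @export
gen_zoning <- function(stack, category_fractions = c(0.3, 0.25, 0.4, 0.05),
                       cost_rules = c("0" = 50, "1" = 50, "2" = 25, "3" = 1),
                       seed = 1, autocorr_range = 6) {
  f <- category_fractions
  if (length(f) != 4L || any(f < 0) || abs(sum(f) - 1) > 1e-8)
    stop("gen_zoning: category_fractions must be 4 nonnegative values summing to 1")
  g <- stack$layers[[1]]
  field <- gen_landscape(seed + 7L, stack$nrows, stack$ncols, 2,
                         autocorr_range = autocorr_range,
                         cellsize = g$cellsize, x0 = g$x0, y0 = g$y0)$layers[[1]]
  cells <- valid_cells(g)
  z <- field$values[cells]
  cuts <- vapply(cumsum(f)[1:3], function(p) {
    if (p <= 0) -Inf
    else if (p >= 1) Inf
    else stats::quantile(z, probs = p, names = FALSE, type = 1)
  }, numeric(1))
  cat_vals <- findInterval(z, cuts, left.open = TRUE)  # 0..3
  zv <- g$values * NA_real_
  zv[cells] <- cat_vals
  zp <- grid_raster(zv, g$x0, g$y0, g$cellsize)
  cost <- with_values(zp, unname(cost_rules[as.character(zp$values)]))
  list(zp = zp, cost = cost)
}
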