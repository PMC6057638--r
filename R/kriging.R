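#' Geostatistical interpolation of lineage occurrence
#'
#' Lineage ranges are interpolated from a genetic distance matrix in three
#' steps: (i) an empirical semivariogram of genetic distance against
#' geographic distance, (ii) a theoretical variogram model fitted by
#' weighted least squares (or set manually), and (iii) ordinary kriging of
#' per-lineage indicator variables using the unit-sill normalized covariance
#' `C(h) = (sill - gamma(h)) / sill`, so that only the correlation structure
#' of the genetic variogram is transferred to the indicators.  Because the
#' kriging weights depend only on the sample geometry, they are shared by
#' all lineage indicators of a species, and the raw per-cell predictions sum
#' to one across lineages; predictions are clipped to `[0, 1]` afterwards.
#'
#' @name lineage_maps
NULL

#' Empirical semivariogram of genetic distance
#'
#' Pairs are binned by geographic (Euclidean) distance into `n_lags`
#' equal-width bins up to `cutoff`; each bin reports
#' `gamma_hat = sum(d_gen^2) / (2 N)` over its pairs.  Empty bins are kept
#' with `n = 0` and `gamma = NA`.
#'
#' @param gdm a `genetic_dist` (matrix `d` plus `coords`).
#' @param n_lags number of bins (default 12).
#' @param cutoff maximum pair distance used; default half the maximum
#'   pairwise geographic distance.
#' @return an `empirical_variogram` data frame with `h` (bin centres),
#'   `gamma` and `n`.
#' @export
empirical_variogram <- function(gdm, n_lags = 12, cutoff = NULL) {
  n <- nrow(gdm$d)
  if (n < 3L) stop("empirical_variogram: need at least 3 samples")
  geo <- as.matrix(stats::dist(cbind(gdm$coords$lon, gdm$coords$lat)))
  ut <- upper.tri(geo)
  gd <- geo[ut]; dg <- gdm$d[ut]
  if (is.null(cutoff)) cutoff <- max(gd) / 2
  if (cutoff <= 0) stop("empirical_variogram: cutoff must be > 0")
  use <- gd <= cutoff
  if (!any(use)) stop("empirical_variogram: all pairs beyond cutoff")
  width <- cutoff / n_lags
  bin <- pmin(floor(gd[use] / width) + 1L, n_lags)
  N <- tabulate(bin, nbins = n_lags)
  ssq <- vapply(seq_len(n_lags), function(b) sum(dg[use][bin == b]^2), 0)
  gamma <- ifelse(N > 0, ssq / (2 * N), NA_real_)
  structure(data.frame(h = (seq_len(n_lags) - 0.5) * width,
                       gamma = gamma, n = N),
            class = c("empirical_variogram", "data.frame"))
}

#' Theoretical variogram models
#'
#' Evaluates `gamma(h)` for the supported families.  All families satisfy
#' `gamma(0) = nugget` and increase monotonically towards `sill` (the linear
#' family is bounded at `sill` beyond `range`).
#'
#' @param h distances (nonnegative).
#' @param model a `variogram_model` (see [fit_variogram()]).
#' @return semivariances.
#' @export
variogram_gamma <- function(h, model) {
  ng <- model$nugget; s <- model$sill; r <- model$range
  part <- s - ng
  f <- switch(model$family,
    spherical = ifelse(h >= r, 1, 1.5 * h / r - 0.5 * (h / r)^3),
    exponential = 1 - exp(-3 * h / r),
    gaussian = 1 - exp(-3 * (h / r)^2),
    linear = pmin(h / r, 1),
    stop("unknown variogram family: ", model$family))
  out <- ng + part * f
  out[h == 0] <- ng
  out
}

#' Construct a variogram model
#'
#' @param family one of `"spherical"`, `"exponential"`, `"gaussian"`,
#'   `"linear"`.
#' @param nugget nonnegative nugget.
#' @param sill sill, at least the nugget.
#' @param range positive range.
#' @return a `variogram_model`.
#' @export
variogram_model <- function(family, nugget, sill, range) {
  if (nugget < 0 || sill < nugget || range <= 0)
    stop("variogram_model: need 0 <= nugget <= sill and range > 0")
  structure(list(family = family, nugget = nugget, sill = sill, range = range),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s (nugget %.4g, sill %.4g, range %.4g)\n",
              x$family, x$nugget, x$sill, x$range))
  invisible(x)
}

#' Fit a variogram model to an empirical variogram
#'
#' Weighted least squares over `(nugget, sill, range)` with bin pair counts
#' as weights; `mode = "manual"` returns the supplied `init` parameters
#' verbatim.
#'
#' @param emp an `empirical_variogram`.
#' @param family model family (default `"spherical"`).
#' @param init optional named list/vector with `nugget`, `sill`, `range`.
#' @param mode `"wls"` (default) or `"manual"`.
#' @return a `variogram_model` with attributes `rss` and `rss_init`.
#' @export
fit_variogram <- function(emp, family = "spherical", init = NULL,
                          mode = c("wls", "manual")) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    if (is.null(init)) stop("fit_variogram: manual mode requires init")
    return(variogram_model(family, init[["nugget"]], init[["sill"]],
                           init[["range"]]))
  }
  ok <- emp$n > 0 & is.finite(emp$gamma)
  if (sum(ok) < 3L) stop("fit_variogram: need at least 3 occupied bins")
  h <- emp$h[ok]; g <- emp$gamma[ok]; w <- emp$n[ok]
  if (is.null(init))
    init <- c(nugget = max(min(g), 0), sill = max(g), range = max(h) * 0.7)
  par0 <- c(init[["nugget"]], init[["sill"]] - init[["nugget"]],
            init[["range"]])
  rss <- function(par) {
    m <- variogram_model(family, par[1L], par[1L] + par[2L], par[3L])
    sum(w * (g - variogram_gamma(h, m))^2)
  }
  opt <- stats::optim(par0, rss, method = "L-BFGS-B",
                      lower = c(0, 1e-12, max(h) * 1e-4),
                      upper = c(max(g) * 2, max(g) * 4, max(h) * 10))
  if (opt$convergence != 0 && opt$value > rss(par0))
    stop("fit_variogram: optimizer failure (best RSS ", format(opt$value), ")")
  m <- variogram_model(family, opt$par[1L], opt$par[1L] + opt$par[2L],
                       opt$par[3L])
  attr(m, "rss") <- opt$value
  attr(m, "rss_init") <- rss(par0)
  m
}

#' Ordinary kriging of lineage indicator variables
#'
#' For each lineage the indicator `z_i = 1` if sample `i` belongs to it,
#' else 0.  Ordinary kriging weights solve `[C w + mu 1 = c0; sum w = 1]`
#' with the unit-sill covariance `C(h) = (sill - gamma(h)) / sill`.  The
#' system is factorized once; the same weights serve every lineage, so raw
#' predictions sum to one across lineages at every cell.  Duplicate sample
#' coordinates are averaged (their indicators become frequencies) before
#' solving.  Predictions are clipped to `[0, 1]`; the unclipped values are
#' kept in the `raw` attribute of each raster.
#'
#' @param samples data frame with `lon`, `lat`.
#' @param lineage_labels vector of lineage ids, one per sample.
#' @param vgm a `variogram_model`.
#' @param grid a `grid_raster` defining the prediction cells (all valid
#'   cells are predicted).
#' @return named list of probability `grid_raster`s, one per lineage level.
#' @export
krige_indicator <- function(samples, lineage_labels, vgm, grid) {
  stopifnot(nrow(samples) == length(lineage_labels))
  if (nrow(samples) < 2L) stop("krige_indicator: need at least 2 samples")
  lev <- sort(unique(lineage_labels))
  Zfull <- vapply(lev, function(L) as.numeric(lineage_labels == L),
                  numeric(nrow(samples)))
  key <- paste(samples$lon, samples$lat)
  if (anyDuplicated(key)) {
    grp <- match(key, unique(key))
    Z <- apply(Zfull, 2L, function(z) tapply(z, grp, mean))
    xy <- cbind(tapply(samples$lon, grp, mean), tapply(samples$lat, grp, mean))
    message("krige_indicator: averaged ", nrow(samples) - nrow(xy) ,
            " duplicate coordinate(s)")
  } else {
    Z <- Zfull
    xy <- cbind(samples$lon, samples$lat)
  }
  Z <- matrix(Z, ncol = length(lev))
  n <- nrow(xy)
  cov_of <- function(h) (vgm$sill - variogram_gamma(h, vgm)) / vgm$sill
  D <- as.matrix(stats::dist(xy))
  A <- rbind(cbind(cov_of(D), 1), c(rep(1, n), 0))
  cells <- valid_cells(grid)
  cc <- cell_centers(grid, cells)
  D0 <- sqrt(outer(xy[, 1L], cc$lon, `-`)^2 + outer(xy[, 2L], cc$lat, `-`)^2)
  B <- rbind(cov_of(D0), 1)
  W <- solve(A, B)[seq_len(n), , drop = FALSE]
  out <- lapply(seq_along(lev), function(j) {
    raw <- drop(crossprod(W, Z[, j]))
    v <- grid$values * NA_real_
    v[cells] <- pmin(pmax(raw, 0), 1)
    r <- grid_raster(v, grid$x0, grid$y0, grid$cellsize)
    attr(r, "raw") <- raw
    r
  })
  names(out) <- as.character(lev)
  out
}

#' Binary lineage range from a kriged probability surface
#'
#' Thresholds the kriged probability at 0.5 and intersects with the parent
#' species' binary range.
#'
#' @param prob_raster probability `grid_raster` from [krige_indicator()].
#' @param species_binary the species `binary_range`.
#' @param feature_id identifier for the lineage feature.
#' @param threshold probability threshold (default 0.5).
#' @return a `binary_range` with `kind = "lineage"`.
#' @export
lineage_binary <- function(prob_raster, species_binary, feature_id = "ln",
                           threshold = 0.5) {
  sp <- species_binary$raster
  stop_unless_aligned(prob_raster, sp, "probability and species rasters")
  v <- (prob_raster$values >= threshold & sp$values == 1) * 1
  v[!is.finite(sp$values)] <- NA_real_
  binary_range(grid_raster(v, sp$x0, sp$y0, sp$cellsize), feature_id,
               kind = "lineage", status = species_binary$status,
               threshold = threshold)
}
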