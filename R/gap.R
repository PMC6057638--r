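#' Gap analysis against a zoning plan
#'
#' Representation of each biodiversity feature within the four zoning-plan
#' categories (0 = general use, 1 = resource use, 2 = national park,
#' 3 = sanctuary; 1-3 are Protected Areas), log-linear representation
#' targets scaled between 10% for the widest range and 100% for the
#' narrowest, and target achievement as the PA share of the range divided by
#' the target.
#'
#' @name gap_analysis
NULL

PA_CATEGORIES <- c(1, 2, 3)

#' Cells of a feature's range in each zoning category
#'
#' @param feature a `binary_range` (or a 0/1 `grid_raster`).
#' @param zp zoning plan `grid_raster` with values 0-3.
#' @return list with `counts` (named, categories 0-3), `percents`
#'   (`100 * count / total`), `total`, `pa_cells`, `pa_percent`.
#' @export
category_counts <- function(feature, zp) {
  r <- if (inherits(feature, "binary_range")) feature$raster else feature
  stop_unless_aligned(r, zp, "feature and zoning rasters")
  inrange <- which(r$values == 1)
  if (!length(inrange)) stop("category_counts: empty feature range")
  cats <- zp$values[inrange]
  counts <- vapply(0:3, function(k) sum(cats == k, na.rm = TRUE), 0)
  names(counts) <- as.character(0:3)
  total <- length(inrange)
  pa <- sum(counts[as.character(PA_CATEGORIES)])
  list(counts = counts, percents = 100 * counts / total, total = total,
       pa_cells = pa, pa_percent = 100 * pa / total)
}

#' Log-linear representation target
#'
#' The default (`scale = "loglog"`) interpolates log target against log
#' range: `ln tau = ln 100 - s ln(A / A_min)` with
#' `s = ln 10 / ln(A_max / A_min)`, so the narrowest modelled range
#' (`A_min`) gets 100% and the widest (`A_max`) gets 10%.
#' `scale = "linlog"` interpolates the target linearly in `ln A` instead.
#' Targets are clamped to `[10, 100]`, then adjusted: Critically Endangered
#' features get 100%; Data Deficient features get +30 percentage points
#' (capped at 100); features too small to model (5 cells or fewer) get 100%.
#'
#' @param range_cells feature range size in cells.
#' @param A_min,A_max interpolation endpoints (narrowest and widest modelled
#'   range, cells); `A_max` must exceed `A_min`.
#' @param status IUCN-like status tag (`"LC"`, `"NT"`, `"CR"`, `"DD"`,
#'   `"NE"`).
#' @param scale `"loglog"` (default) or `"linlog"`.
#' @return target percent in `(0, 100]`.
#' @export
representation_target <- function(range_cells, A_min, A_max, status = "LC",
                                  scale = c("loglog", "linlog")) {
  scale <- match.arg(scale)
  if (A_max <= A_min) stop("representation_target: need A_max > A_min")
  if (A_min <= 0 || range_cells <= 0)
    stop("representation_target: range sizes must be positive")
  if (range_cells <= 5) return(100)
  tau <- if (scale == "loglog") {
    s <- log(10) / log(A_max / A_min)
    exp(log(100) - s * log(range_cells / A_min))
  } else {
    100 + (10 - 100) * log(range_cells / A_min) / log(A_max / A_min)
  }
  tau <- min(max(tau, 10), 100)
  if (status == "CR") tau <- 100
  if (status == "DD") tau <- min(tau + 30, 100)
  tau
}

#' Target achievement of a feature
#'
#' `100 * (PA share of range) / (target / 100)`; values of 100 or more mean
#' the target is met.
#'
#' @param counts output of [category_counts()].
#' @param target representation target percent (> 0).
#' @return list with `achievement` (percent) and `protected` (logical:
#'   PA percent at or above the target).
#' @export
target_achievement <- function(counts, target) {
  if (target <= 0) stop("target_achievement: target must be > 0")
  ach <- 100 * counts$pa_percent / target
  list(achievement = ach, protected = counts$pa_percent >= target)
}

#' Representation of a richness hotspot within Protected Areas
#'
#' The hotspot target is 100% of its cells inside PAs; achievement is the
#' inside-PA percentage and the target fails when below 100.
#'
#' @param hotspot 0/1 `grid_raster` (e.g. from [top_quartile_binary()]).
#' @param zp zoning plan raster.
#' @return list with `achievement`, `inside`, `total`, `meets_target`.
#' @export
richness_gap <- function(hotspot, zp) {
  stop_unless_aligned(hotspot, zp, "hotspot and zoning rasters")
  cells <- which(hotspot$values == 1)
  if (!length(cells)) stop("richness_gap: empty hotspot")
  inside <- sum(zp$values[cells] %in% PA_CATEGORIES)
  ach <- 100 * inside / length(cells)
  list(achievement = ach, inside = inside, total = length(cells),
       meets_target = ach >= 100)
}

#' Compare richness inside versus outside Protected Areas
#'
#' Fits a Poisson GLM with log link of per-cell richness on an inside-PA
#' indicator and reports group means with Wald 95% confidence intervals and
#' the two-sided p-value of the group contrast.
#'
#' @param richness_layer a `richness_layer`.
#' @param zp zoning plan raster.
#' @return data frame with one row per group (`outside`, `inside`): `mean`,
#'   `ci_lo`, `ci_hi`, plus attribute `p_value`.
#' @export
compare_in_out <- function(richness_layer, zp) {
  r <- richness_layer$count
  stop_unless_aligned(r, zp, "richness and zoning rasters")
  cells <- which(is.finite(r$values) & is.finite(zp$values))
  y <- r$values[cells]
  inside <- factor(zp$values[cells] %in% PA_CATEGORIES,
                   levels = c(FALSE, TRUE), labels = c("outside", "inside"))
  if (nlevels(droplevels(inside)) < 2L)
    stop("compare_in_out: both groups must be nonempty")
  if (stats::sd(y) < 1e-12) stop("compare_in_out: zero-variance response")
  fit <- stats::glm(y ~ inside, family = stats::poisson())
  p <- summary(fit)$coefficients[2L, 4L]
  nd <- data.frame(inside = factor(c("outside", "inside"),
                                   levels = levels(inside)))
  pr <- stats::predict(fit, nd, type = "link", se.fit = TRUE)
  out <- data.frame(group = as.character(nd$inside),
                    mean = exp(pr$fit),
                    ci_lo = exp(pr$fit - 1.96 * pr$se.fit),
                    ci_hi = exp(pr$fit + 1.96 * pr$se.fit))
  attr(out, "p_value") <- p
  out
}
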