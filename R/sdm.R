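#' Presence-background maximum-entropy distribution models
#'
#' The model is the Gibbs density `q(x) = exp(beta' f(x)) / Z` over
#' background cells, with features `f` the standardized linear and quadratic
#' terms of the selected landscape variables.  Coefficients minimize the
#' L1-regularized maxent objective
#' `-mean_presences(beta' f) + log sum_background exp(beta' f) +
#'  sum_f r_f |beta_f|` with per-feature penalty
#' `r_f = reg * sd_f / sqrt(n_presences)`, by monotone proximal gradient
#' descent (soft-thresholding with backtracking line search), which is exact
#' for this convex problem.  Suitability is the density rescaled to `[0, 1]`
#' by its maximum, a monotone transform that leaves thresholding unchanged.
#'
#' @name sdm
NULL

#' Select weakly correlated landscape variables
#'
#' Iteratively drops the variable with the highest mean absolute pairwise
#' Pearson correlation until all pairwise `|r| <= max_abs_corr` and at most
#' `k` variables remain; ties are broken by variable name so the result is
#' deterministic.
#'
#' @param stack a `landscape_stack`.
#' @param max_abs_corr pairwise correlation ceiling (default 0.75).
#' @param k maximum number of variables retained.
#' @return character vector of retained layer names, with attribute
#'   `satisfied` indicating whether the correlation constraint was met.
#' @export
select_variables <- function(stack, max_abs_corr = 0.75, k = length(stack$layers)) {
  if (k > length(stack$layers)) stop("select_variables: k exceeds n_vars")
  X <- stack_matrix(stack)
  keep <- sort(names(stack$layers))
  repeat {
    if (length(keep) == 1L) break
    R <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(R) <- 0
    if (max(R) <= max_abs_corr && length(keep) <= k) break
    worst <- which.max(colMeans(R))  # ties: first in (sorted) name order
    keep <- keep[-worst]
  }
  satisfied <- length(keep) == 1L ||
    max(abs(stats::cor(X[, keep, drop = FALSE]))[
      upper.tri(diag(length(keep)))]) <= max_abs_corr
  if (!satisfied)
    warning("select_variables: correlation constraint not attainable; ",
            "returning best effort")
  structure(keep[order(match(keep, names(stack$layers)))],
            satisfied = satisfied)
}

#' Thin occurrences in 3-D principal-component space
#'
#' Projects each record's landscape values onto the first three principal
#' components (computed over all valid cells) and greedily keeps records,
#' discarding any within Euclidean distance `radius` of an already-kept
#' record in PC space; records are considered in input order.
#'
#' @param occ occurrence data frame (`lon`, `lat`, ...).
#' @param stack a `landscape_stack`.
#' @param radius minimum pairwise PC-space distance.
#' @return the thinned occurrence data frame.
#' @export
thin_occurrences_pca3 <- function(occ, stack, radius) {
  if (nrow(occ) < 2L) stop("thin_occurrences_pca3: need at least 2 records")
  g <- stack$layers[[1L]]
  X <- stack_matrix(stack)
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ncomp <- min(3L, ncol(pc$x))
  cells <- cell_at(g, occ$lon, occ$lat)
  Xo <- stack_matrix(stack, cells)
  P <- scale(Xo, center = pc$center, scale = pc$scale) %*%
    pc$rotation[, seq_len(ncomp), drop = FALSE]
  keep <- logical(nrow(occ))
  for (i in seq_len(nrow(occ))) {
    ki <- which(keep)
    if (!length(ki)) { keep[i] <- TRUE; next }
    d2 <- colSums((t(P[ki, , drop = FALSE]) - P[i, ])^2)
    if (all(d2 >= radius^2) || radius == 0) keep[i] <- TRUE
  }
  occ[keep, , drop = FALSE]
}

## Internal: standardized linear + quadratic feature matrix for given cells.
## Centers/scales are estimated over background cells and reused.
maxent_features <- function(stack, vars, cells, centers = NULL, scales = NULL) {
  X <- stack_matrix(stack, cells)[, vars, drop = FALSE]
  F <- cbind(X, X^2)
  colnames(F) <- c(vars, paste0(vars, "^2"))
  if (is.null(centers)) {
    centers <- colMeans(F)
    scales <- apply(F, 2L, stats::sd)
  }
  keep <- scales > 1e-12
  F <- sweep(sweep(F[, keep, drop = FALSE], 2L, centers[keep]), 2L,
             scales[keep], `/`)
  list(F = F, centers = centers, scales = scales, keep = keep)
}

#' Fit a maxent-style presence-background model
#'
#' @param occ_train occurrence data frame (`lon`, `lat`).
#' @param stack a `landscape_stack`.
#' @param vars character vector of layer names to use.
#' @param background_n background size: all valid cells are used when there
#'   are at most 50000, otherwise a seeded uniform sample of `background_n`.
#' @param reg regularization multiplier (default 1).
#' @param seed RNG seed (used only if the background is subsampled).
#' @param maxit,tol optimizer controls.
#' @return an `sdm_model` with coefficients, the background spec, the
#'   objective trace, and the suitability raster (density rescaled by its
#'   maximum).
#' @export
fit_maxent <- function(occ_train, stack, vars, background_n = 10000, reg = 1,
                       seed = 1, maxit = 500, tol = 1e-8) {
  if (nrow(occ_train) < 3L) stop("fit_maxent: need at least 3 presences")
  g <- stack$layers[[1L]]
  all_cells <- valid_cells(g)
  bg <- if (length(all_cells) <= 50000) all_cells else {
    set.seed(seed); sort(sample(all_cells, background_n))
  }
  ft <- maxent_features(stack, vars, bg)
  pres_cells <- cell_at(g, occ_train$lon, occ_train$lat)
  if (anyNA(pres_cells) || !all(is.finite(g$values[pres_cells])))
    stop("fit_maxent: presences outside the landscape mask")
  Fp <- maxent_features(stack, vars, pres_cells, ft$centers, ft$scales)$F
  Fb <- ft$F
  np <- nrow(Fp)
  r <- reg * 1 / sqrt(np)      # features are standardized, sd_f = 1
  mp <- colMeans(Fp)
  beta <- numeric(ncol(Fb))
  smooth <- function(b) {
    eta <- drop(Fb %*% b)
    M <- max(eta)
    -sum(mp * b) + M + log(sum(exp(eta - M)))
  }
  grad <- function(b) {
    eta <- drop(Fb %*% b)
    w <- exp(eta - max(eta)); w <- w / sum(w)
    -mp + drop(crossprod(Fb, w))
  }
  objective <- function(b) smooth(b) + sum(r * abs(b))
  step <- 1
  obj <- objective(beta)
  trace <- obj
  for (it in seq_len(maxit)) {
    gvec <- grad(beta)
    fs <- smooth(beta)
    repeat {                                     # backtracking + soft-threshold
      cand <- beta - step * gvec
      cand <- sign(cand) * pmax(abs(cand) - step * r, 0)
      d <- cand - beta
      if (smooth(cand) <= fs + sum(gvec * d) + sum(d^2) / (2 * step) + 1e-12)
        break
      step <- step / 2
      if (step < 1e-12) break
    }
    new_obj <- objective(cand)
    if (new_obj > obj + 1e-12) break             # safeguard: stay monotone
    delta <- obj - new_obj
    beta <- cand; obj <- new_obj
    trace <- c(trace, obj)
    if (delta < tol * (abs(obj) + 1)) break
    step <- min(step * 1.5, 1e3)
  }
  eta_b <- drop(Fb %*% beta)
  Z <- sum(exp(eta_b))
  ## suitability over all valid cells
  Fa <- maxent_features(stack, vars, all_cells, ft$centers, ft$scales)$F
  dens <- exp(drop(Fa %*% beta))
  suit <- dens / max(dens)
  sv <- g$values * NA_real_
  sv[all_cells] <- suit
  structure(list(vars = vars, beta = stats::setNames(beta, colnames(Fb)),
                 centers = ft$centers, scales = ft$scales, keep = ft$keep,
                 reg = reg, background = bg, Z = Z,
                 density = stats::setNames(exp(eta_b) / Z, NULL),
                 objective_trace = trace,
                 suitability = grid_raster(sv, g$x0, g$y0, g$cellsize)),
            class = "sdm_model")
}

#' Predict model suitability at cells
#'
#' @param object an `sdm_model`.
#' @param stack the `landscape_stack` used to fit.
#' @param cells cell indices (default all valid cells of the suitability map).
#' @param ... unused.
#' @return numeric suitability in `[0, 1]` (rescaled density).
#' @export
predict.sdm_model <- function(object, stack, cells = NULL, ...) {
  g <- stack$layers[[1L]]
  if (is.null(cells)) cells <- valid_cells(g)
  F <- maxent_features(stack, object$vars, cells, object$centers,
                       object$scales)$F
  dens <- exp(drop(F %*% object$beta))
  dens / max(exp(drop(maxent_features(stack, object$vars, valid_cells(g),
                                      object$centers, object$scales)$F %*%
                        object$beta)))
}

## Internal: rank AUC of presence scores against background scores.
rank_auc <- function(pos, bg) {
  r <- rank(c(pos, bg))
  np <- length(pos); nb <- length(bg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Replicate model evaluation with random train/test splits
#'
#' Runs the replicate rule (10 replicates when `N >= 20`, 8 when
#' `10 <= N < 20`, 4 when `N < 10`; at least 6 records are required --
#' use [records_to_range()] for 5 or fewer).  Each replicate draws a random
#' 70/30 train/test split without replacement, fits on the training
#' presences, and scores train and test AUC against the background; the
#' mean and per-cell standard deviation of the replicate suitability maps
#' are returned.
#'
#' @param occ occurrence data frame.
#' @param stack a `landscape_stack`.
#' @param vars layer names to use.
#' @param test_fraction held-out fraction (default 0.3).
#' @param reg,background_n passed to [fit_maxent()].
#' @param seed RNG seed.
#' @return an `sdm_evaluation`: `replicates` (data frame of AUCs),
#'   `mean_map`, `sd_map`, `models`, `occ`.
#' @export
replicate_evaluate <- function(occ, stack, vars, test_fraction = 0.3,
                               reg = 1, background_n = 10000, seed = 1) {
  N <- nrow(occ)
  if (N <= 5L) stop("replicate_evaluate: too few records (N <= 5); ",
                    "use records_to_range()")
  n_rep <- if (N >= 20) 10L else if (N >= 10) 8L else 4L
  g <- stack$layers[[1L]]
  cells <- valid_cells(g)
  set.seed(seed)
  maps <- matrix(NA_real_, length(cells), n_rep)
  reps <- vector("list", n_rep)
  models <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    test_idx <- sample(N, max(1L, round(test_fraction * N)))
    train <- occ[-test_idx, , drop = FALSE]
    test <- occ[test_idx, , drop = FALSE]
    m <- fit_maxent(train, stack, vars, background_n = background_n,
                    reg = reg, seed = seed + i)
    s <- m$suitability$values[cells]
    maps[, i] <- s
    bg_scores <- m$suitability$values[m$background]
    tr_scores <- m$suitability$values[cell_at(g, train$lon, train$lat)]
    te_scores <- m$suitability$values[cell_at(g, test$lon, test$lat)]
    reps[[i]] <- data.frame(replicate = i,
                            auc_train = rank_auc(tr_scores, bg_scores),
                            auc_test = rank_auc(te_scores, bg_scores))
    models[[i]] <- m
  }
  mean_map <- sd_map <- g$values * NA_real_
  mean_map[cells] <- rowMeans(maps)
  sd_map[cells] <- apply(maps, 1L, stats::sd)
  structure(list(replicates = do.call(rbind, reps),
                 mean_map = grid_raster(mean_map, g$x0, g$y0, g$cellsize),
                 sd_map = grid_raster(sd_map, g$x0, g$y0, g$cellsize),
                 models = models, occ = occ, vars = vars, n_rep = n_rep),
            class = "sdm_evaluation")
}

#' Binary range from the minimum-training-presence threshold
#'
#' The threshold is the minimum mean-map suitability over the training
#' presences; the binary range is every cell at or above it, so every
#' training presence cell is inside the range by construction.
#'
#' @param eval an `sdm_evaluation` (or any list with a `mean_map` raster).
#' @param occ_train training occurrence data frame.
#' @param feature_id,status metadata attached to the range.
#' @return a `binary_range`: list with `raster` (0/1 `grid_raster`),
#'   `feature_id`, `kind`, `size`, `status`, `threshold`.
#' @export
binarize_mtp <- function(eval, occ_train, feature_id = "sp", status = "NE") {
  m <- eval$mean_map
  cells <- cell_at(m, occ_train$lon, occ_train$lat)
  theta <- min(m$values[cells])
  bv <- (m$values >= theta) * 1
  binary_range(grid_raster(bv, m$x0, m$y0, m$cellsize), feature_id,
               kind = "species", status = status, threshold = theta)
}

#' Construct a binary range object
#'
#' @param raster 0/1 `grid_raster`.
#' @param feature_id feature identifier.
#' @param kind `"species"` or `"lineage"`.
#' @param status conservation status tag (LC/NT/CR/DD/NE).
#' @param threshold optional binarization threshold.
#' @return a `binary_range`.
#' @export
binary_range <- function(raster, feature_id, kind = "species", status = "NE",
                         threshold = NA_real_) {
  v <- raster$values
  if (!all(v[is.finite(v)] %in% c(0, 1)))
    stop("binary_range: raster values must be 0/1 inside the mask")
  structure(list(raster = raster, feature_id = feature_id, kind = kind,
                 size = sum(v == 1, na.rm = TRUE), status = status,
                 threshold = threshold),
            class = "binary_range")
}

#' @export
print.binary_range <- function(x, ...) {
  cat(sprintf("binary_range '%s' (%s, %s): %d cells\n",
              x$feature_id, x$kind, x$status, x$size))
  invisible(x)
}

#' True skill statistic of a binary range
#'
#' Sensitivity is the fraction of presences falling in the range;
#' specificity is the fraction of a random background sample falling
#' outside; `TSS = sensitivity + specificity - 1`.
#'
#' @param binary a `binary_range`.
#' @param presences occurrence data frame.
#' @param background_n background sample size (default 10000, capped at the
#'   number of valid cells).
#' @param seed RNG seed for the background sample.
#' @return list with `tss`, `sensitivity`, `specificity`.
#' @export
tss <- function(binary, presences, background_n = 10000, seed = 1) {
  g <- binary$raster
  cells <- valid_cells(g)
  set.seed(seed)
  bg <- if (background_n >= length(cells)) cells else
    sample(cells, background_n)
  pres_cells <- cell_at(g, presences$lon, presences$lat)
  sens <- mean(g$values[pres_cells] == 1)
  spec <- mean(g$values[bg] == 0)
  list(tss = sens + spec - 1, sensitivity = sens, specificity = spec)
}

#' Permutation variable contributions
#'
#' Measures the drop in training gain (mean presence log-density above the
#' uniform baseline) when a variable's values are permuted over cells
#' (its linear and quadratic features move together), averaged over
#' `n_perm` permutations and normalized to sum to 100.
#'
#' @param model an `sdm_model`.
#' @param stack the fitting `landscape_stack`.
#' @param occ the training occurrences.
#' @param n_perm permutations per variable (default 5).
#' @param seed RNG seed.
#' @return named numeric vector of percent contributions summing to 100.
#' @export
variable_contribution <- function(model, stack, occ, n_perm = 5, seed = 1) {
  g <- stack$layers[[1L]]
  bg <- model$background
  pres_cells <- cell_at(g, occ$lon, occ$lat)
  gain_from <- function(Xb, Xp) {
    featurize <- function(X) {
      F <- cbind(X, X^2)
      keep <- model$keep
      sweep(sweep(F[, keep, drop = FALSE], 2L, model$centers[keep]), 2L,
            model$scales[keep], `/`)
    }
    eb <- drop(featurize(Xb) %*% model$beta)
    ep <- drop(featurize(Xp) %*% model$beta)
    mean(ep) - log(mean(exp(eb)))
  }
  cells <- valid_cells(g)
  Xall <- stack_matrix(stack, cells)[, model$vars, drop = FALSE]
  ib <- match(bg, cells); ip <- match(pres_cells, cells)
  Xb0 <- Xall[ib, , drop = FALSE]
  Xp0 <- Xall[ip, , drop = FALSE]
  base <- gain_from(Xb0, Xp0)
  set.seed(seed)
  drops <- vapply(seq_along(model$vars), function(v) {
    mean(vapply(seq_len(n_perm), function(j) {
      perm <- sample(Xall[, v])          # permute the layer over all cells
      Xb <- Xb0; Xp <- Xp0
      Xb[, v] <- perm[ib]
      Xp[, v] <- perm[ip]
      base - gain_from(Xb, Xp)
    }, 0))
  }, 0)
  drops <- pmax(drops, 0)
  out <- if (sum(drops) > 0) 100 * drops / sum(drops) else
    rep(100 / length(drops), length(drops))
  stats::setNames(out, model$vars)
}

#' Binary range directly from records (5 or fewer)
#'
#' For features with too few records to model, the range is exactly the set
#' of cells containing records.
#'
#' @param occ occurrence data frame with 1 to 5 records.
#' @param stack a `landscape_stack`.
#' @param feature_id,status metadata attached to the range.
#' @return a `binary_range`.
#' @export
records_to_range <- function(occ, stack, feature_id = "sp", status = "NE") {
  if (nrow(occ) < 1L || nrow(occ) > 5L)
    stop("records_to_range: applies to 1-5 records")
  g <- stack$layers[[1L]]
  cells <- unique(cell_at(g, occ$lon, occ$lat))
  v <- (is.finite(g$values)) * 0
  v[!is.finite(g$values)] <- NA_real_
  v[cells] <- 1
  binary_range(grid_raster(v, g$x0, g$y0, g$cellsize), feature_id,
               kind = "species", status = status)
}
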