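#' General mixed Yule-coalescent (GMYC) lineage delimitation
#'
#' The single-threshold GMYC model locates a time `T` on an ultrametric tree
#' at which the branching pattern shifts from a between-species Yule process
#' (rate `lambda1 * n^p1` with `n` lineages older than `T`) to independent
#' within-species coalescent processes (one per cluster of branches crossing
#' `T`, rate `lambda2 * (n_j (n_j - 1))^p2` for a cluster with `n_j`
#' branches).  Waiting times between branching events are exponential with
#' the sum of the active rates; the likelihood is the product of the
#' interval survival terms and the rate of the process in which each event
#' falls.  Clusters whose stem branch crosses the threshold are the
#' delimited lineages.
#'
#' @name gmyc
NULL

## ---- tree geometry -------------------------------------------------------

## Internal: precompute node heights, parent pointers and events for a
## rooted binary ultrametric tree.
tree_geometry <- function(tree, tol = 1e-8) {
  if (!inherits(tree, "phylo")) stop("expected a 'phylo' tree")
  n <- ape::Ntip(tree)
  if (n < 2L) stop("tree must have at least 2 tips")
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(n)]) - depth
  bad <- which(abs(h[seq_len(n)]) > max(tol, tol * max(h)))
  if (length(bad))
    stop("tree is not ultrametric: tip '", tree$tip.label[bad[1L]],
         "' is at height ", format(h[bad[1L]]))
  h[seq_len(n)] <- 0
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  list(tree = tree, n = n, h = h, parent = parent,
       children = tree$edge[, 2L], root = n + 1L,
       root_height = h[n + 1L],
       events = sort(h[(n + 1L):(n + tree$Nnode)]))
}

#' Branching intervals of an ultrametric tree
#'
#' Orders the internal-node heights from the present backwards and reports
#' the waiting intervals between consecutive branching events together with
#' the number of branches alive in each interval.
#'
#' @param tree an ultrametric `phylo` tree with at least 2 tips.
#' @param tol ultrametricity tolerance on tip heights.
#' @return list with `events` (ascending node heights), `durations`
#'   (interval lengths, first interval starts at the present; they sum to
#'   the root height) and `branches` (branch count in each interval).
#' @export
compute_intervals <- function(tree, tol = 1e-8) {
  geo <- tree_geometry(tree, tol = tol)
  ev <- geo$events
  list(events = ev, durations = diff(c(0, ev)),
       branches = geo$n - seq_along(ev) + 1L)
}

## Internal: cluster id of every tip for threshold T (the subtree whose stem
## branch crosses T); a single cluster if T >= root height.
threshold_clusters <- function(geo, T) {
  n <- geo$n
  if (T >= geo$root_height) return(rep(1L, n))
  stem <- integer(n)
  for (i in seq_len(n)) {
    v <- i
    while (geo$parent[v] != 0L && geo$h[geo$parent[v]] <= T) v <- geo$parent[v]
    stem[i] <- v
  }
  match(stem, unique(stem))
}

## Internal: slice the tree by events and the threshold, and flatten the
## likelihood into sufficient statistics.  Each slice lies entirely on one
## side of T, so its total branching rate involves a single process:
##   yule slices:  census n_s (branches older than T); rate lambda1 * n^p1
##   coal slices:  per-cluster censuses m_j = n_j (n_j - 1) (entries with
##                 m >= 2 kept, singletons contribute 0); total rate
##                 lambda2 * sum_j m_j^p2
## A slice ending in a branching event contributes the log of its *total*
## rate (the waiting-time density of the superposed process), the standard
## GMYC convention.
gmyc_structure <- function(geo, T) {
  n <- geo$n; h <- geo$h
  ntot <- length(h)
  cl_tip <- threshold_clusters(geo, T)
  k <- max(cl_tip)
  ## cluster of every node at or below T (propagate tip labels rootwards)
  cl_node <- integer(ntot)
  cl_node[seq_len(n)] <- cl_tip
  internal <- (n + 1L):ntot
  for (v in internal[order(h[internal])]) {
    if (h[v] > T) break
    kids <- geo$children[geo$tree$edge[, 1L] == v]
    cl_node[v] <- cl_node[kids[1L]]
  }
  ev <- geo$events
  bounds <- sort(unique(c(0, ev, if (T < geo$root_height) T)))
  y_x <- y_n <- numeric(0); y_ev <- numeric(0)
  c_x <- numeric(0); c_m <- numeric(0); c_sid <- integer(0)
  c_ns <- 0L; c_evs <- integer(0)
  child <- geo$children
  hp <- h[geo$tree$edge[, 1L]]; hc <- h[child]
  for (s in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1L]
    x <- t1 - t0; tm <- (t0 + t1) / 2
    alive <- hc < tm & hp > tm
    ends_event <- any(abs(ev - t1) < 1e-12)
    if (tm > T) {                                 # diversification slice
      nd <- sum(alive)
      y_x <- c(y_x, x); y_n <- c(y_n, nd)
      if (ends_event) y_ev <- c(y_ev, nd)
    } else {                                      # coalescent slice
      cls <- cl_node[child[alive]]
      cnt <- tabulate(cls, nbins = k)
      m <- cnt * (cnt - 1)
      keep <- m >= 2
      c_ns <- c_ns + 1L
      if (any(keep)) {
        c_x <- c(c_x, x)                          # one duration per slice
        c_m <- c(c_m, m[keep])
        c_sid <- c(c_sid, rep(length(c_x), sum(keep)))
      }
      if (ends_event) c_evs <- c(c_evs, length(c_x))
    }
  }
  list(k = k, clusters = cl_tip,
       yule = list(x = y_x, n = y_n, ev = y_ev),
       coal = list(x = c_x, m = c_m, sid = c_sid, ev_slices = c_evs))
}

## Internal: per-slice totals sum_j m_j^p for the coalescent part.
coal_slice_totals <- function(co, p) {
  if (!length(co$x)) return(numeric(0))
  tot <- numeric(length(co$x))
  v <- co$m^p
  agg <- rowsum(v, co$sid)
  tot[as.integer(rownames(agg))] <- agg[, 1L]
  tot
}

## Internal: evaluate the GMYC log-likelihood from a flattened structure.
loglik_from_structure <- function(st, lambda1, p1, lambda2, p2) {
  y <- st$yule; co <- st$coal
  ll <- 0
  if (length(y$x)) ll <- ll - lambda1 * sum(y$x * y$n^p1)
  if (length(y$ev)) {
    r <- lambda1 * y$ev^p1
    if (any(r <= 0)) return(-Inf)
    ll <- ll + sum(log(r))
  }
  if (length(co$x)) {
    tot <- coal_slice_totals(co, p2)
    ll <- ll - lambda2 * sum(co$x * tot)
    if (length(co$ev_slices)) {
      r <- lambda2 * tot[co$ev_slices]
      if (any(r <= 0)) return(-Inf)
      ll <- ll + sum(log(r))
    }
  } else if (length(co$ev_slices)) return(-Inf)
  ll
}

#' GMYC log-likelihood at explicit parameters
#'
#' Evaluates the single-threshold GMYC log-likelihood for a given threshold
#' time and process parameters.  An event falling in a process whose rate is
#' zero yields `-Inf` rather than an error.
#'
#' @param tree ultrametric `phylo` tree.
#' @param T threshold time (height above the present).
#' @param lambda1,p1 Yule rate and scaling exponent (rate `lambda1 * n^p1`).
#' @param lambda2,p2 coalescent rate and scaling exponent (per-cluster rate
#'   `lambda2 * (n_j (n_j - 1))^p2`).
#' @return the log-likelihood (possibly `-Inf`).
#' @export
gmyc_loglik <- function(tree, T, lambda1, p1, lambda2, p2) {
  if (lambda1 < 0 || lambda2 < 0) stop("rates must be nonnegative")
  geo <- tree_geometry(tree)
  loglik_from_structure(gmyc_structure(geo, T), lambda1, p1, lambda2, p2)
}

## Internal: maximize a profile objective f(p) over bounded p by a coarse
## grid scan followed by golden-section refinement (deterministic; robust
## to mild multimodality of the coalescent profile).
maximize_profile <- function(f, p_bounds) {
  grid <- seq(p_bounds[1L], p_bounds[2L], length.out = 25L)
  vals <- vapply(grid, f, 0)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  if (opt$objective >= vals[i]) list(p = opt$maximum, ll = opt$objective)
  else list(p = grid[i], ll = vals[i])
}

## Internal: maximized log-likelihood at one threshold; the rate parameters
## are profiled out in closed form (lambda* = E / S(p)), leaving bounded
## one-dimensional maximizations over the scaling exponents.
fit_at_threshold <- function(st, p_bounds) {
  y <- st$yule; co <- st$coal
  E1 <- length(y$ev)
  if (E1 == 0L) {
    yfit <- list(p = p_bounds[1L], ll = 0); l1 <- 0
  } else {
    slog <- sum(log(y$ev))
    f1 <- function(p) {
      S <- sum(y$x * y$n^p)
      if (!is.finite(S) || S <= 0) return(-Inf)
      E1 * log(E1 / S) - E1 + p * slog
    }
    yfit <- maximize_profile(f1, p_bounds)
    l1 <- E1 / sum(y$x * y$n^yfit$p)
  }
  E2 <- length(co$ev_slices)
  if (E2 == 0L) {
    cfit <- list(p = p_bounds[1L], ll = 0); l2 <- 0
  } else {
    f2 <- function(p) {
      tot <- coal_slice_totals(co, p)
      S <- sum(co$x * tot)
      if (!is.finite(S) || S <= 0) return(-Inf)
      E2 * log(E2 / S) - E2 + sum(log(tot[co$ev_slices]))
    }
    cfit <- maximize_profile(f2, p_bounds)
    l2 <- E2 / sum(co$x * coal_slice_totals(co, cfit$p))
  }
  list(loglik = yfit$ll + cfit$ll, lambda1 = l1, p1 = yfit$p,
       lambda2 = l2, p2 = cfit$p)
}

## Internal: candidate thresholds = midpoints between consecutive distinct
## node heights (starting from the present) plus one above the root (the
## single-cluster null).
candidate_thresholds <- function(geo) {
  uh <- unique(geo$events)
  c((c(0, uh[-length(uh)]) + uh) / 2, geo$root_height * 1.05)
}

#' Fit the single-threshold GMYC model by maximum likelihood
#'
#' Scans candidate thresholds placed at midpoints between consecutive
#' distinct node heights (plus one above the root, the one-cluster null) and
#' maximizes the four process parameters at each.  The rate parameters are
#' profiled out in closed form, leaving two bounded one-dimensional
#' maximizations over the scaling exponents per candidate, which is exact
#' for this likelihood and deterministic.
#'
#' @param tree ultrametric `phylo` tree with at least 3 tips.  Trees with
#'   zero-length terminal pairs (identical haplotypes) are rejected;
#'   identical haplotypes must be removed upstream.
#' @param p_bounds bounds for the scaling exponents `p1`, `p2`.
#' @return a `gmyc_model`: threshold, parameters, log-likelihood, number of
#'   clusters `k`, tip assignment, the single-process null log-likelihood,
#'   and the per-candidate profile table.
#' @export
fit_gmyc <- function(tree, p_bounds = c(-2, 3)) {
  geo <- tree_geometry(tree)
  if (geo$n < 3L) stop("fit_gmyc: tree must have at least 3 tips")
  if (min(geo$events) <= 1e-12)
    stop("fit_gmyc: tree contains zero-length terminal pairs; ",
         "remove identical haplotypes upstream")
  cand <- candidate_thresholds(geo)
  fits <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    st <- gmyc_structure(geo, cand[i])
    f <- fit_at_threshold(st, p_bounds)
    f$T <- cand[i]; f$k <- st$k; f$clusters <- st$clusters
    fits[[i]] <- f
  }
  ll <- vapply(fits, `[[`, 0, "loglik")
  best <- fits[[which.max(ll)]]
  null_ll <- fits[[length(fits)]]$loglik  # T above root: pure coalescent
  structure(list(
    threshold = best$T, lambda1 = best$lambda1, p1 = best$p1,
    lambda2 = best$lambda2, p2 = best$p2, loglik = best$loglik,
    k = best$k,
    assignment = data.frame(tip = geo$tree$tip.label, lineage = best$clusters,
                            stringsAsFactors = FALSE),
    null_loglik = null_ll, p_bounds = p_bounds,
    candidates = data.frame(T = cand, loglik = ll,
                            k = vapply(fits, `[[`, 0L, "k"))),
    class = "gmyc_model")
}

#' @export
print.gmyc_model <- function(x, ...) {
  cat(sprintf("GMYC model: %d cluster(s), threshold %.4g, logLik %.4f\n",
              x$k, x$threshold, x$loglik))
  cat(sprintf("  lambda1 %.4g (p1 %.3g)  lambda2 %.4g (p2 %.3g)\n",
              x$lambda1, x$p1, x$lambda2, x$p2))
  invisible(x)
}

#' Likelihood-ratio test of the GMYC model against a single process
#'
#' The null model is the best single-process (pure coalescent, threshold
#' above the root) fit with one rate and one scaling exponent; the
#' alternative is the fitted mixed model.  The statistic `2 (lnL_alt -
#' lnL_null)` is referred to a chi-square distribution with `df` degrees of
#' freedom (default 3, the conventional choice for 5 versus 2 free
#' parameters).
#'
#' @param fit a `gmyc_model` from [fit_gmyc()].
#' @param df chi-square degrees of freedom.
#' @return list with `LR` and `p_value`.
#' @export
lr_test <- function(fit, df = 3) {
  stopifnot(inherits(fit, "gmyc_model"))
  LR <- max(0, 2 * (fit$loglik - fit$null_loglik))
  list(LR = LR, p_value = stats::pchisq(LR, df = df, lower.tail = FALSE))
}
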