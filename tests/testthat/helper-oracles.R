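# Independent oracles used across the suite.  These deliberately avoid the
# package's internal flattened likelihood machinery: the GMYC oracle slices
# the tree directly with its own bookkeeping.

# Direct (brute-force) GMYC log-likelihood: slice by events and threshold,
# total-rate prefactor at events.
oracle_gmyc_loglik <- function(tree, T, l1, p1, l2, p2) {
  n <- ape::Ntip(tree)
  dep <- ape::node.depth.edgelength(tree)
  h <- max(dep[1:n]) - dep
  h[1:n] <- 0
  ev <- sort(h[(n + 1):(n + tree$Nnode)])
  bounds <- sort(unique(c(0, ev, if (T < max(h)) T)))
  par <- integer(n + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  stem <- sapply(1:n, function(i) {
    v <- i
    while (par[v] != 0 && h[par[v]] <= T) v <- par[v]
    v
  })
  cl <- match(stem, unique(stem))
  desc_tip <- function(v) {
    while (v > n) v <- tree$edge[tree$edge[, 1] == v, 2][1]
    v
  }
  ecl <- sapply(tree$edge[, 2], function(c) cl[desc_tip(c)])
  hp <- h[tree$edge[, 1]]; hc <- h[tree$edge[, 2]]
  ll <- 0
  for (s in seq_len(length(bounds) - 1)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1]
    tm <- (t0 + t1) / 2; x <- t1 - t0
    alive <- hc < tm & hp > tm
    b <- if (tm > T) l1 * sum(alive)^p1 else {
      cnt <- tabulate(ecl[alive], nbins = max(cl))
      m <- cnt * (cnt - 1)
      l2 * sum(m[m >= 2]^p2)
    }
    ll <- ll - b * x
    if (any(abs(ev - t1) < 1e-12)) ll <- ll + log(b)
  }
  ll
}

# Closed-form single-process coalescent log-likelihood over the whole tree:
# intervals i = 1..n-1 backwards from the present with n_i = n - i + 1
# branches, census m_i = n_i (n_i - 1), waiting time x_i; the density is the
# product of exponential waiting terms with rate l * m_i^p.
oracle_coalescent_loglik <- function(tree, l, p) {
  n <- ape::Ntip(tree)
  dep <- ape::node.depth.edgelength(tree)
  h <- max(dep[1:n]) - dep
  ev <- sort(h[(n + 1):(n + tree$Nnode)])
  x <- diff(c(0, ev))
  m <- ((n:2) * (n:2 - 1))
  sum(log(l * m^p) - l * m^p * x)
}

# Minimum feasible subset size by exhaustive enumeration (beta = 0, uniform
# cost): Fl is a list of logical vectors over cells, tau in percent.
oracle_min_set_size <- function(Fl, tau) {
  n <- length(Fl[[1]])
  tots <- sapply(Fl, sum)
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(bitwShiftL(1, 0:(n - 1)), mask))
    ok <- all(sapply(seq_along(Fl), function(j)
      sum(Fl[[j]] & sel) / tots[j] >= tau[j] / 100 - 1e-12))
    if (ok && sum(sel) < best) best <- sum(sel)
  }
  best
}

# Small helper: a landscape_stack whose layers are given matrices.
manual_stack <- function(...) {
  mats <- list(...)
  st <- gen_landscape(1, nrow(mats[[1]]), ncol(mats[[1]]),
                      max(2, length(mats)), autocorr_range = 0)
  for (i in seq_along(mats)) st$layers[[i]]$values <- mats[[i]]
  st$layers <- st$layers[seq_along(mats)]
  names(st$layers) <- sprintf("lv%02d", seq_along(mats))
  st
}

# Moran's I (rook neighbours) of a matrix -- oracle for autocorrelation.
morans_i <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z <- m - mean(m)
  num <- 0; W <- 0
  num <- sum(z[, -nc] * z[, -1]) + sum(z[-nr, ] * z[-1, ])
  W <- (nr * (nc - 1) + (nr - 1) * nc)
  (length(m) / (2 * W)) * (2 * num) / sum(z^2)
}
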