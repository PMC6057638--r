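#' Simulate trees with Yule between-cluster / coalescent within-cluster
#' structure
#'
#' Simulates an ultrametric tree whose deep branching follows a Yule (pure
#' birth) process over `n_clusters` cluster stems and whose shallow
#' branching within each cluster follows a neutral Kingman coalescent with
#' timescale `coal_scale` (the expected pairwise coalescence time).  When
#' `coal_scale` is small relative to `1 / yule_rate` the within-cluster
#' nodes sit far below the between-cluster nodes, the regime in which a
#' single time threshold separates the two processes.  If the simulated
#' backbone would be shallower than the deepest cluster subtree, the
#' backbone node heights are shifted up just enough to keep the tree valid
#' (rare when `coal_scale` is small; the shift is recorded in the result).
#'
#' @param n_clusters number of clusters (Yule tips), at least 1.
#' @param tips_per_cluster tips in each cluster's coalescent subtree, at
#'   least 1 (1 gives a pure Yule tree).
#' @param yule_rate per-lineage speciation rate of the backbone.
#' @param coal_scale coalescent timescale within clusters.
#' @param seed integer RNG seed.
#' @return list with `tree` (an [ape::read.tree()] `phylo`, ultrametric,
#'   tips labelled `c<cluster>_t<tip>`), `assignment` (data frame `tip`,
#'   `lineage`), and `backbone_shift`.
#' @export
gen_tree <- function(n_clusters, tips_per_cluster, yule_rate = 1,
                     coal_scale = 0.05, seed = 1) {
  if (n_clusters < 1 || tips_per_cluster < 1)
    stop("gen_tree: n_clusters and tips_per_cluster must be >= 1")
  set.seed(seed)
  clusters <- lapply(seq_len(n_clusters), function(k) {
    labs <- sprintf("c%d_t%d", k, seq_len(tips_per_cluster))
    sim_join_tree(labs, rep(0, tips_per_cluster),
                  coalescent_times(tips_per_cluster, coal_scale))
  })
  sub_nwk <- vapply(clusters, `[[`, "", "newick")
  sub_h <- vapply(clusters, `[[`, 0, "height")
  shift <- 0
  if (n_clusters > 1L) {
    bh <- yule_backbone_heights(n_clusters, yule_rate)
    lo <- max(sub_h) * 1.05 + 1e-8
    if (min(bh) <= lo) {
      shift <- lo - min(bh)
      bh <- bh + shift
    }
    top <- sim_join_tree(sub_nwk, sub_h, sort(bh))
  } else top <- clusters[[1]]
  tree <- ape::read.tree(text = paste0(top$newick, ";"))
  assignment <- data.frame(
    tip = unlist(lapply(seq_len(n_clusters),
                        function(k) sprintf("c%d_t%d", k, seq_len(tips_per_cluster)))),
    lineage = rep(seq_len(n_clusters), each = tips_per_cluster),
    stringsAsFactors = FALSE)
  list(tree = tree, assignment = assignment, backbone_shift = shift)
}

## Internal: Kingman coalescent node heights for m tips (ascending), scaled
## so that the expected pairwise coalescence time equals `scale`.
coalescent_times <- function(m, scale) {
  if (m < 2L) return(numeric(0))
  k <- m:2
  cumsum(stats::rexp(m - 1L, rate = choose(k, 2)) * scale)
}

## Internal: node heights of a Yule tree on n tips, simulated forward
## (waiting time Exp(k * rate) with k extant lineages) plus a terminal
## Exp(n * rate) stretch to the present; returns heights above the tips.
yule_backbone_heights <- function(n, rate) {
  waits <- stats::rexp(n, rate = (1:n) * rate) # n-th is the stretch to present
  total <- sum(waits)
  ev <- cumsum(waits)[1:(n - 1L)]              # forward times of splits
  total - ev                                   # heights, descending
}

## Internal: random-join construction of an ultrametric newick string from
## leaf subtrees with given heights and ascending join heights.
sim_join_tree <- function(labels, heights, join_h) {
  stopifnot(length(labels) == length(heights),
            length(join_h) == length(labels) - 1L)
  nwk <- as.list(labels); h <- heights
  for (jh in join_h) {
    i <- sample.int(length(nwk), 2L)
    a <- i[1L]; b <- i[2L]
    merged <- sprintf("(%s:%.12g,%s:%.12g)", nwk[[a]], jh - h[a],
                      nwk[[b]], jh - h[b])
    nwk[[a]] <- merged; h[a] <- jh
    nwk <- nwk[-b]; h <- h[-b]
  }
  list(newick = nwk[[1L]], height = h[1L])
}

#' Synthetic genetic distance matrices
#'
#' Builds a pairwise genetic distance matrix over georeferenced samples with
#' the structure the kriging stage assumes: distance grows linearly with
#' geographic separation within lineages (`within_rate` per map unit), jumps
#' by `between_offset` across lineages, and carries half-normal noise
#' (`abs(rnorm(sd = noise_sd))`) on the off-diagonal.  The matrix is
#' symmetric, has a zero diagonal and is nonnegative by construction.
#'
#' @param samples data frame with `lon`, `lat`, `lineage` (as from
#'   [sample_occurrences()]).
#' @param within_rate genetic distance accumulated per map unit of
#'   geographic distance.
#' @param between_offset additive offset between samples of different
#'   lineages.
#' @param noise_sd standard deviation of the half-normal noise.
#' @param seed integer RNG seed.
#' @return a `genetic_dist`: list with `d` (matrix), `coords` (data frame
#'   `lon`, `lat`), `lineage`.
#' @export
gen_genetic_distances <- function(samples, within_rate = 0.01,
                                  between_offset = 0.05, noise_sd = 0,
                                  seed = 1) {
  stopifnot(all(c("lon", "lat", "lineage") %in% names(samples)))
  n <- nrow(samples)
  geo <- as.matrix(stats::dist(cbind(samples$lon, samples$lat)))
  diff_lin <- outer(samples$lineage, samples$lineage, `!=`) * 1
  d <- within_rate * geo + between_offset * diff_lin
  if (noise_sd > 0) {
    set.seed(seed)
    eps <- matrix(0, n, n)
    eps[upper.tri(eps)] <- abs(stats::rnorm(n * (n - 1) / 2, sd = noise_sd))
    d <- d + eps + t(eps)
  }
  diag(d) <- 0
  rownames(d) <- colnames(d) <- sprintf("s%03d", seq_len(n))
  structure(list(d = d,
                 coords = data.frame(lon = samples$lon, lat = samples$lat),
                 lineage = samples$lineage),
            class = "genetic_dist")
}
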