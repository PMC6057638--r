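#' Bayesian GMYC by Metropolis-Hastings sampling
#'
#' Samples the posterior of the single-threshold GMYC model over
#' `(lambda1, p1, lambda2, p2, T)` with uniform priors (rates on
#' `(0, lambda_max)`, scaling exponents on `p_bounds`, threshold uniform
#' over the candidate set, which includes the above-root single-cluster
#' configuration).  Continuous parameters take Gaussian random-walk
#' proposals whose scales are auto-tuned during burn-in towards a 20-40%
#' acceptance rate; the threshold takes an independent uniform proposal over
#' candidates.  Runs are pooled over the supplied tree sample so that
#' phylogenetic uncertainty is integrated over, and summarised as a
#' conspecificity matrix `C(i, j)`: the fraction of retained samples in
#' which tips `i` and `j` fall in the same cluster.
#'
#' @param trees a `phylo`, `multiPhylo`, or list of ultrametric trees
#'   sharing the same tip set.
#' @param generations MCMC generations per tree (default 100000).
#' @param burnin generations discarded (default 10000; must be less than
#'   `generations`).
#' @param thinning keep every `thinning`-th post-burn-in generation.
#' @param priors list with `lambda_max` (default 100) and `p_bounds`
#'   (default `c(-2, 3)`).
#' @param seed integer RNG seed; identical inputs and seed give identical
#'   output.
#' @return a `bgmyc_result`: conspecificity matrix `C`, pooled parameter
#'   samples, acceptance rates, and the settings used.
#' @export
bgmyc_sample <- function(trees, generations = 100000, burnin = 10000,
                         thinning = 100,
                         priors = list(lambda_max = 100, p_bounds = c(-2, 3)),
                         seed = 1) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) < 1L) stop("bgmyc_sample: need at least one tree")
  if (generations <= burnin) stop("bgmyc_sample: generations must exceed burnin")
  lam_max <- priors$lambda_max %||% 100
  p_bounds <- priors$p_bounds %||% c(-2, 3)
  set.seed(seed)
  tips <- trees[[1L]]$tip.label
  n <- length(tips)
  C <- matrix(0, n, n, dimnames = list(tips, tips))
  samples <- list()
  acc_tot <- prop_tot <- 0
  for (tr in trees) {
    if (!setequal(tr$tip.label, tips))
      stop("bgmyc_sample: trees must share one tip set")
    geo <- tree_geometry(tr)
    cand <- candidate_thresholds(geo)
    sts <- lapply(cand, function(T) gmyc_structure(geo, T))
    ## partitions aligned to the common tip order
    ord <- match(tips, tr$tip.label)
    parts <- lapply(sts, function(s) s$clusters[ord])
    ## profile fits per candidate: start point and centres of the joint
    ## threshold-move proposal.  Parameters of a process with no events at
    ## a candidate (likelihood-free there) are proposed from the prior so
    ## that prior drift of unidentified parameters cannot trap the chain.
    prof <- lapply(sts, fit_at_threshold, p_bounds = p_bounds)
    prof_mu <- lapply(prof, function(f)
      c(min(max(f$lambda1, 0.05), lam_max - 0.05), f$p1,
        min(max(f$lambda2, 0.05), lam_max - 0.05), f$p2))
    prof_sd <- lapply(prof_mu, function(mu) pmax(0.5 * abs(mu), 0.2))
    informative <- lapply(sts, function(s)
      c(rep(length(s$yule$ev) > 0L, 2L),
        rep(length(s$coal$ev_slices) > 0L, 2L)))
    ti <- which.max(vapply(prof, `[[`, 0, "loglik"))
    init <- prof[[ti]]
    th <- c(max(init$lambda1, 1e-3), init$p1, max(init$lambda2, 1e-3), init$p2)
    lo <- c(0, p_bounds[1L], 0, p_bounds[1L])
    hi <- c(lam_max, p_bounds[2L], lam_max, p_bounds[2L])
    scales <- pmax(abs(th) * 0.5, 0.1)
    ## mixed proposal log-density for candidate i: truncated normal on the
    ## informative block, uniform over the prior box elsewhere
    dprop <- function(th, i) {
      inf <- informative[[i]]
      mu <- prof_mu[[i]]; sd <- prof_sd[[i]]
      d <- ifelse(inf,
                  stats::dnorm(th, mu, sd, log = TRUE) -
                    log(stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd)),
                  -log(hi - lo))
      sum(d)
    }
    rprop <- function(i) {
      inf <- informative[[i]]
      out <- stats::runif(4, lo, hi)
      if (any(inf))
        out[inf] <- stats::rnorm(sum(inf), prof_mu[[i]][inf],
                                 prof_sd[[i]][inf])
      out
    }
    ll <- loglik_from_structure(sts[[ti]], th[1], th[2], th[3], th[4])
    acc <- att <- numeric(5)
    keep_at <- seq(burnin + thinning, generations, by = thinning)
    for (g in seq_len(generations)) {
      for (j in 1:4) {                      # continuous parameters
        prop <- th; prop[j] <- th[j] + stats::rnorm(1, sd = scales[j])
        att[j] <- att[j] + 1
        if (prop[j] <= lo[j] || prop[j] >= hi[j]) next
        ll2 <- loglik_from_structure(sts[[ti]], prop[1], prop[2],
                                     prop[3], prop[4])
        if (is.finite(ll2) && log(stats::runif(1)) < ll2 - ll) {
          th <- prop; ll <- ll2; acc[j] <- acc[j] + 1
        }
      }
      ## joint threshold move: draw a candidate uniformly and fresh
      ## parameters around its profile fit (truncated-normal independence
      ## proposal), so the chain can jump between threshold modes
      ti2 <- sample.int(length(cand), 1L)
      att[5] <- att[5] + 1
      th2 <- rprop(ti2)
      if (all(th2 > lo & th2 < hi)) {
        ll2 <- loglik_from_structure(sts[[ti2]], th2[1], th2[2],
                                     th2[3], th2[4])
        lr <- (ll2 + dprop(th, ti)) - (ll + dprop(th2, ti2))
        if (is.finite(ll2) && log(stats::runif(1)) < lr) {
          ti <- ti2; th <- th2; ll <- ll2; acc[5] <- acc[5] + 1
        }
      }
      if (g <= burnin && g %% 200 == 0) {   # tune towards 20-40% acceptance
        r <- ifelse(att[1:4] > 0, acc[1:4] / att[1:4], 0.3)
        scales <- scales * ifelse(r > 0.4, 1.3, ifelse(r < 0.2, 1 / 1.3, 1))
        acc[1:4] <- att[1:4] <- 0
      }
      if (g %in% keep_at) {
        pa <- parts[[ti]]
        C <- C + outer(pa, pa, `==`)
        samples[[length(samples) + 1L]] <-
          c(lambda1 = th[1], p1 = th[2], lambda2 = th[3], p2 = th[4],
            T = cand[ti], k = max(pa))
      }
    }
    acc_tot <- acc_tot + sum(acc); prop_tot <- prop_tot + sum(att)
  }
  if (acc_tot == 0)
    stop("bgmyc_sample: zero acceptance over the run (", prop_tot,
         " proposals); check proposal scales and priors")
  nret <- length(samples)
  C <- C / max(nret, 1)
  diag(C) <- 1
  structure(list(C = C, samples = do.call(rbind, samples),
                 acceptance = acc_tot / max(prop_tot, 1),
                 settings = list(generations = generations, burnin = burnin,
                                 thinning = thinning, n_trees = length(trees),
                                 priors = list(lambda_max = lam_max,
                                               p_bounds = p_bounds),
                                 seed = seed)),
            class = "bgmyc_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bgmyc_result <- function(x, ...) {
  cat(sprintf("bGMYC: %d retained samples over %d tree(s), acceptance %.2f\n",
              nrow(x$samples), x$settings$n_trees, x$acceptance))
  invisible(x)
}

#' Consensus lineage assignment from a conspecificity matrix
#'
#' Thresholds the conspecificity matrix at `cutoff` and returns the
#' connected components of the resulting graph as lineages.
#'
#' @param C square symmetric conspecificity matrix with unit diagonal.
#' @param cutoff edge threshold in `(0, 1]` (default 0.5).
#' @return list with `assignment` (data frame `tip`, `lineage`) and `k`.
#' @export
consensus_clusters <- function(C, cutoff = 0.5) {
  n <- nrow(C)
  stopifnot(ncol(C) == n)
  adj <- C >= cutoff
  lab <- integer(n); comp <- 0L
  for (i in seq_len(n)) {
    if (lab[i]) next
    comp <- comp + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (lab[v]) next
      lab[v] <- comp
      queue <- c(queue, which(adj[v, ] & lab == 0L))
    }
  }
  tips <- rownames(C) %||% as.character(seq_len(n))
  list(assignment = data.frame(tip = tips, lineage = lab,
                               stringsAsFactors = FALSE), k = comp)
}
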