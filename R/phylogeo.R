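# Fixed-tree discrete-location ancestral reconstruction: a symmetric
# K-state continuous-time Markov model with uniform stationary frequencies
# on a supplied rooted tree, maximum-likelihood rate, and marginal ancestral
# location posteriors via the up-down (outside) algorithm.

#' UPGMA tree from a distance matrix
#'
#' Average-linkage clustering producing an ultrametric rooted tree: the
#' substrate for fixed-tree ancestral location reconstruction.
#'
#' @param d Square symmetric distance matrix with taxon dimnames.
#' @return An \code{ape::phylo} rooted ultrametric tree.
#' @export
upgma_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("upgma_tree requires >= 2 taxa")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}

#' Internal: symmetric K-state transition probability matrix
#' Off-diagonal instantaneous rate = rate/(K-1) to each other state, so
#' P_ii(t) = 1/K + (1-1/K) exp(-K rate t/(K-1)).
#' @noRd
sym_ctmc_P <- function(rate, t, K) {
  e <- exp(-K * rate * t / (K - 1))
  same <- 1 / K + (1 - 1 / K) * e
  diff <- (1 - e) / K
  P <- matrix(diff, K, K)
  diag(P) <- same
  P
}

#' Internal: tip state indicator matrix and tree bookkeeping
#' @noRd
prepare_tree <- function(tree, tip_locations, K, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(tip_locations))
  if (length(levels) > K) stop("more observed locations than K")
  unmapped <- setdiff(tree$tip.label, names(tip_locations))
  if (length(unmapped))
    stop("tip(s) without a location: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  states <- match(tip_locations[tree$tip.label], levels)
  if (anyNA(states)) stop("tip location outside the location levels")
  list(levels = levels, states = states)
}

#' Log-likelihood of tip locations under the symmetric CTMC
#'
#' Felsenstein pruning on a rooted tree; uniform stationary/root frequencies.
#'
#' @param tree A rooted \code{phylo} tree with branch lengths.
#' @param tip_locations Named character vector: tip label -> location.
#' @param rate Overall location-switch rate (> 0, per unit branch length).
#' @param K Number of locations (defaults to the number observed).
#' @param levels Optional explicit location levels (length K).
#' @return The log-likelihood (scalar).
#' @export
location_loglik <- function(tree, tip_locations, rate, K = NULL,
                            levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(tip_locations))
  if (is.null(K)) K <- length(levels)
  pp <- prepare_tree(tree, tip_locations, K, levels)
  down <- pruning_down(tree, pp$states, rate, K)
  root <- ape::Ntip(tree) + 1L
  lik <- sum(down$partial[root, ] / K)
  log(lik) + down$logscale
}

#' Internal: post-order conditional likelihoods with scaling
#' @noRd
pruning_down <- function(tree, tip_states, rate, K) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  partial <- matrix(0, ntip + nnode, K)
  partial[cbind(seq_len(ntip), tip_states)] <- 1
  logscale <- 0
  ord <- ape::reorder.phylo(tree, "postorder")
  edge <- ord$edge
  elen <- ord$edge.length
  # message from child c up its branch: M_c(s) = sum_s' P_{s s'} L_c(s')
  msg <- matrix(0, ntip + nnode, K)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    P <- sym_ctmc_P(rate, elen[e], K)
    msg[ch, ] <- as.numeric(P %*% partial[ch, ])
    if (all(partial[par, ] == 0)) partial[par, ] <- 1
    partial[par, ] <- partial[par, ] * msg[ch, ]
    m <- max(partial[par, ])
    if (m > 0 && m < 1e-100) {
      partial[par, ] <- partial[par, ] / m
      logscale <- logscale + log(m)
    }
  }
  list(partial = partial, msg = msg, edge = edge, elen = elen,
       logscale = logscale)
}

#' Maximum-likelihood location-switch rate
#'
#' One-dimensional bounded optimisation of \code{location_loglik}.
#'
#' @inheritParams location_loglik
#' @param interval Search interval for the rate.
#' @return List with \code{rate} and \code{loglik}.
#' @export
fit_location_rate <- function(tree, tip_locations, K = NULL, levels = NULL,
                              interval = NULL) {
  if (is.null(levels)) levels <- sort(unique(tip_locations))
  if (is.null(K)) K <- length(levels)
  depth <- max(ape::node.depth.edgelength(tree))
  if (is.null(interval)) interval <- c(1e-8, 1e3 / max(depth, 1e-8))
  f <- function(r) location_loglik(tree, tip_locations, r, K, levels)
  # the profile can plateau at high rates; bracket the optimum on a
  # log-spaced grid before the local search
  grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 40))
  ll <- vapply(grid, f, 0)
  if (all(!is.finite(ll)))
    stop("rate optimisation failed: non-finite likelihood ",
         "(interval ", interval[1], "-", interval[2], ")")
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-10)
  if (opt$objective < ll[i]) opt <- list(maximum = grid[i], objective = ll[i])
  list(rate = opt$maximum, loglik = opt$objective)
}

#' Marginal ancestral location posteriors
#'
#' Empirical-Bayes reconstruction: the switch rate is fitted by maximum
#' likelihood (unless supplied), then the marginal posterior distribution
#' over locations is computed for every internal node by the up-down
#' (outside) algorithm under a uniform root prior.
#'
#' @inheritParams location_loglik
#' @param rate Fixed rate; NULL (default) fits it by ML.
#' @return A \code{location_posterior}: matrix (internal node x location)
#'   of posterior probabilities (rows sum to 1), with attributes
#'   \code{rate} and \code{loglik}. Row names are ape node numbers.
#' @export
ancestral_location_posteriors <- function(tree, tip_locations, K = NULL,
                                          levels = NULL, rate = NULL) {
  if (is.null(levels)) levels <- sort(unique(tip_locations))
  if (is.null(K)) K <- length(levels)
  if (is.null(rate)) {
    fit <- fit_location_rate(tree, tip_locations, K, levels)
    rate <- fit$rate
    ll <- fit$loglik
  } else {
    ll <- location_loglik(tree, tip_locations, rate, K, levels)
  }
  pp <- prepare_tree(tree, tip_locations, K, levels)
  down <- pruning_down(tree, pp$states, rate, K)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  nnodes <- ntip + tree$Nnode
  up <- matrix(0, nnodes, K)
  up[root, ] <- 1 / K
  # pre-order: parent before child
  edge <- down$edge[rev(seq_len(nrow(down$edge))), , drop = FALSE]
  elen <- down$elen[rev(seq_len(nrow(down$edge)))]
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    P <- sym_ctmc_P(rate, elen[e], K)
    # outside message excludes the child's own subtree
    sib_prod <- up[par, ] * down$partial[par, ] / down$msg[ch, ]
    sib_prod[!is.finite(sib_prod)] <- 0
    up[ch, ] <- as.numeric(t(P) %*% sib_prod)
  }
  internal <- (ntip + 1L):nnodes
  post <- up[internal, , drop = FALSE] * down$partial[internal, , drop = FALSE]
  post <- post / rowSums(post)
  dimnames(post) <- list(internal, levels)
  structure(post, class = c("location_posterior", "matrix"),
            rate = rate, loglik = ll)
}

#' Posterior location distribution for the MRCA of a haplotype set
#'
#' @param post A \code{location_posterior} from
#'   \code{ancestral_location_posteriors}.
#' @param tree The tree used for the reconstruction.
#' @param tips Character vector of tip labels defining the clade.
#' @return Named numeric vector over locations for the MRCA node.
#' @export
mrca_location <- function(post, tree, tips) {
  node <- ape::getMRCA(tree, tips)
  if (is.null(node)) node <- ape::Ntip(tree) + 1L
  post[as.character(node), ]
}

#' Simulate locations down a tree under the symmetric CTMC
#'
#' @param tree A rooted \code{phylo} tree.
#' @param rate Switch rate.
#' @param K Number of locations.
#' @param levels Location labels (default \code{L1..LK}).
#' @return Named character vector of tip locations.
#' @export
simulate_locations <- function(tree, rate, K, levels = paste0("L", seq_len(K))) {
  ntip <- ape::Ntip(tree)
  nnodes <- ntip + tree$Nnode
  state <- integer(nnodes)
  root <- ntip + 1L
  state[root] <- sample.int(K, 1)
  ord <- ape::reorder.phylo(tree, "postorder")
  edge <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  elen <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  for (e in seq_len(nrow(edge))) {
    P <- sym_ctmc_P(rate, elen[e], K)
    state[edge[e, 2]] <- sample.int(K, 1, prob = P[state[edge[e, 1]], ])
  }
  stats::setNames(levels[state[seq_len(ntip)]], tree$tip.label)
}
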