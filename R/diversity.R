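# Per-population polymorphism and neutrality statistics for aligned haploid
# sequence data. Ambiguous characters (N, -) are excluded pairwise, i.e. a
# site contributes to a pairwise comparison only when both members carry an
# unambiguous base.

#' Internal: integer state matrix (A=1 C=2 G=3 T=4, NA for N/-)
#' @noRd
state_matrix <- function(aln) {
  m <- aln_matrix(aln)
  s <- match(m, c("A", "C", "G", "T"))
  dim(s) <- dim(m)
  rownames(s) <- rownames(m)
  s
}

#' Internal: pairwise difference counts with pairwise deletion
#' Returns list(diff = matrix of differing-site counts,
#'              valid = matrix of jointly unambiguous site counts)
#' @noRd
pairwise_diffs <- function(sm) {
  n <- nrow(sm)
  d <- matrix(0, n, n)
  v <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(sm[i, ]) & !is.na(sm[j, ])
      nd <- sum(sm[i, ok] != sm[j, ok])
      d[i, j] <- d[j, i] <- nd
      v[i, j] <- v[j, i] <- sum(ok)
    }
  }
  list(diff = d, valid = v)
}

#' Number of segregating sites
#'
#' A site segregates when at least two distinct unambiguous bases occur.
#'
#' @param aln A \code{haplo_alignment}.
#' @return Integer count of segregating sites.
#' @export
segregating_sites <- function(aln) {
  sm <- state_matrix(aln)
  sum(apply(sm, 2, function(col) length(unique(col[!is.na(col)])) > 1))
}

#' Nucleotide diversity (pi), per site
#'
#' Average proportion of differing sites over all unordered sequence pairs,
#' with ambiguous positions excluded pairwise.
#'
#' @param aln A \code{haplo_alignment} with at least 2 sequences.
#' @return Per-site nucleotide diversity.
#' @export
nucleotide_diversity <- function(aln) {
  n <- length(aln$ids)
  if (n < 2) stop("nucleotide_diversity requires n >= 2")
  pd <- pairwise_diffs(state_matrix(aln))
  ut <- upper.tri(pd$diff)
  prop <- ifelse(pd$valid[ut] > 0, pd$diff[ut] / pd$valid[ut], 0)
  mean(prop)
}

#' Mean number of pairwise differences (k)
#' @param aln A \code{haplo_alignment} with at least 2 sequences.
#' @return Mean count of differing sites per unordered pair.
#' @export
mean_pairwise_differences <- function(aln) {
  n <- length(aln$ids)
  if (n < 2) stop("requires n >= 2")
  pd <- pairwise_diffs(state_matrix(aln))
  mean(pd$diff[upper.tri(pd$diff)])
}

#' Watterson's theta, per site
#'
#' \eqn{\theta_w = S / (a_1 L)} with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}: the
#' segregating-sites estimator of 2Ne*mu for a haploid uniparental locus.
#'
#' @param aln A \code{haplo_alignment} with at least 2 sequences.
#' @return Per-site Watterson's theta.
#' @export
watterson_theta <- function(aln) {
  n <- length(aln$ids)
  if (n < 2) stop("watterson_theta requires n >= 2")
  S <- segregating_sites(aln)
  a1 <- sum(1 / seq_len(n - 1))
  S / (a1 * aln$L)
}

#' Haplotype (gene) diversity
#'
#' \eqn{Hd = n/(n-1) (1 - \sum p_i^2)} from haplotype frequencies.
#'
#' @param ht A \code{haplotype_table}.
#' @param population Population name (column of the count matrix), or NULL
#'   to pool all samples.
#' @return Haplotype diversity in [0, 1].
#' @export
haplotype_diversity <- function(ht, population = NULL) {
  counts <- if (is.null(population)) rowSums(ht$counts)
            else {
              if (!population %in% colnames(ht$counts))
                stop("unknown population: ", population)
              ht$counts[, population]
            }
  n <- sum(counts)
  if (n < 2) stop("haplotype_diversity requires n >= 2")
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Internal: Tajima (1989) constants
#' @noRd
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D with simulation-based significance
#'
#' \eqn{D = (\bar k - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}}. Significance is
#' assessed two-sided by coalescent simulation conditioned on the sample size
#' with theta set to the Watterson estimate (\code{n_sim} neutral
#' constant-size replicates under the infinite-sites approximation).
#'
#' @param aln A \code{haplo_alignment} with n >= 4.
#' @param n_sim Number of null-coalescent replicates for the p-value
#'   (0 skips the test).
#' @param alpha Significance level for the \code{significant} flag.
#' @return List with \code{D}, \code{p_value}, \code{significant}, \code{S}.
#'   \code{D} is NA (undefined) when S = 0.
#' @export
tajimas_d <- function(aln, n_sim = 1000, alpha = 0.05) {
  n <- length(aln$ids)
  if (n < 4) stop("tajimas_d requires n >= 4")
  S <- segregating_sites(aln)
  if (S == 0)
    return(list(D = NA_real_, p_value = NA_real_, significant = FALSE, S = 0L))
  k <- mean_pairwise_differences(aln)
  cst <- tajima_constants(n)
  D <- (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  p <- NA_real_
  sig <- FALSE
  if (n_sim > 0) {
    theta <- S / cst$a1
    sims <- replicate(n_sim, tajimas_d_from_sim(n, theta))
    sims <- sims[!is.na(sims)]
    if (length(sims)) {
      p <- (sum(abs(sims) >= abs(D)) + 1) / (length(sims) + 1)
      sig <- p <= alpha
    }
  }
  list(D = D, p_value = p, significant = sig, S = as.integer(S))
}

#' Internal: one neutral infinite-sites replicate -> Tajima's D
#' Coalescent times in units of Ne generations (haploid gene copies), theta
#' is the per-locus 2*Ne*mu; mutations are Poisson on total branch length.
#' @noRd
tajimas_d_from_sim <- function(n, theta) {
  sim <- sim_infinite_sites(n, theta)
  S <- ncol(sim)
  if (is.null(S) || S == 0) return(NA_real_)
  k <- mean(stats::dist(sim, method = "manhattan"))
  cst <- tajima_constants(n)
  (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Internal: simulate an infinite-sites sample (0/1 matrix n x S)
#' Standard neutral coalescent: inter-coalescent times Exp(choose(k,2)) in
#' units of Ne; each mutation hits a fresh site on a uniformly chosen branch
#' point (branch chosen proportional to length).
#' @noRd
sim_infinite_sites <- function(n, theta) {
  # genealogy: active lineages hold sets of tip indices
  groups <- as.list(seq_len(n))
  branch_sets <- list()
  branch_lens <- numeric(0)
  k <- n
  while (k > 1) {
    t_k <- stats::rexp(1, rate = choose(k, 2))
    # every active lineage accrues t_k of branch length
    branch_sets <- c(branch_sets, groups)
    branch_lens <- c(branch_lens, rep(t_k, k))
    pick <- sample.int(k, 2)
    merged <- c(groups[[pick[1]]], groups[[pick[2]]])
    groups <- c(groups[-pick], list(merged))
    k <- k - 1
  }
  total <- sum(branch_lens)
  n_mut <- stats::rpois(1, theta / 2 * total)
  if (n_mut == 0) return(matrix(0L, n, 0))
  hit <- sample.int(length(branch_sets), n_mut, replace = TRUE,
                    prob = branch_lens)
  m <- matrix(0L, n, n_mut)
  for (j in seq_len(n_mut)) m[branch_sets[[hit[j]]], j] <- 1L
  m
}

#' Internal: log unsigned Stirling numbers of the first kind, row n
#' Returns log|s(n, k)| for k = 1..n via the recursion
#' |s(n+1,k)| = n|s(n,k)| + |s(n,k-1)| in log space.
#' @noRd
log_stirling_first <- function(n) {
  lse <- function(a, b) {
    if (is.infinite(a) && a < 0) return(b)
    if (is.infinite(b) && b < 0) return(a)
    m <- max(a, b); m + log(exp(a - m) + exp(b - m))
  }
  row <- c(0)  # n = 1: |s(1,1)| = 1
  if (n == 1) return(row)
  for (m in 1:(n - 1)) {
    new <- numeric(m + 1)
    for (k in 1:(m + 1)) {
      t1 <- if (k <= m) log(m) + row[k] else -Inf
      t2 <- if (k >= 2) row[k - 1] else -Inf
      new[k] <- lse(t1, t2)
    }
    row <- new
  }
  row
}

#' Internal: Ewens sampling-formula distribution of the haplotype count K
#' Pr(K = k | n, theta) = |s(n,k)| theta^k / (theta)_n
#' @noRd
ewens_k_distribution <- function(n, theta) {
  ls <- log_stirling_first(n)
  log_rising <- sum(log(theta + 0:(n - 1)))
  lp <- ls + (1:n) * log(theta) - log_rising
  exp(lp)
}

#' Fu's Fs
#'
#' \eqn{F_s = \ln(S'/(1-S'))} with \eqn{S' = \Pr(K \ge k_{obs})} under the
#' Ewens sampling formula at \eqn{\theta = \bar k} (mean pairwise
#' differences); the probability is computed exactly via unsigned Stirling
#' numbers of the first kind. Large negative values indicate haplotype excess
#' (demographic expansion).
#'
#' @param aln A \code{haplo_alignment} with n >= 2 (>= 4 recommended).
#' @return List with \code{Fs}, \code{S_prime}, \code{k_obs},
#'   \code{extreme} (TRUE when S' hit 0 or 1 numerically, Fs is +-Inf).
#' @export
fu_fs <- function(aln) {
  n <- length(aln$ids)
  if (n < 2) stop("fu_fs requires n >= 2")
  theta <- mean_pairwise_differences(aln)
  ht <- collapse_haplotypes(aln)
  k_obs <- length(ht$haplotypes)
  if (theta <= 0)
    return(list(Fs = Inf, S_prime = 1, k_obs = k_obs, extreme = TRUE))
  pk <- ewens_k_distribution(n, theta)
  S_prime <- sum(pk[k_obs:n])
  S_prime <- min(max(S_prime, 0), 1)
  if (S_prime <= 0 || S_prime >= 1)
    return(list(Fs = ifelse(S_prime >= 1, Inf, -Inf), S_prime = S_prime,
                k_obs = k_obs, extreme = TRUE))
  list(Fs = log(S_prime / (1 - S_prime)), S_prime = S_prime,
       k_obs = k_obs, extreme = FALSE)
}

#' Ramos-Onsins and Rozas' R2
#'
#' \eqn{R_2 = \sqrt{(1/n)\sum_i (U_i - \bar k/2)^2} / S}, where \eqn{U_i} is
#' the number of sites at which sequence i carries a base observed in that
#' sequence only (its singleton sites). Small values indicate recent
#' population growth.
#'
#' @param aln A \code{haplo_alignment} with n >= 2 (>= 4 recommended).
#' @return List with \code{R2} (NA when S = 0), \code{S}, \code{U}.
#' @export
r2_statistic <- function(aln) {
  n <- length(aln$ids)
  if (n < 2) stop("r2_statistic requires n >= 2")
  sm <- state_matrix(aln)
  S <- segregating_sites(aln)
  if (S == 0)
    return(list(R2 = NA_real_, S = 0L, U = rep(0L, n)))
  U <- integer(n)
  for (site in seq_len(ncol(sm))) {
    col <- sm[, site]
    tab <- table(col[!is.na(col)])
    if (length(tab) < 2) next
    singles <- as.integer(names(tab)[tab == 1])
    if (length(singles))
      U[which(col %in% singles)] <- U[which(col %in% singles)] + 1L
  }
  k <- mean_pairwise_differences(aln)
  R2 <- sqrt(mean((U - k / 2)^2)) / S
  list(R2 = R2, S = as.integer(S), U = U)
}

#' Per-population diversity summary table
#'
#' Computes, for every population in the map, the polymorphism and
#' neutrality statistics used ahead of demographic inference. Populations
#' with 3 or fewer sequences are listed with statistics reported as missing.
#'
#' @param aln A \code{haplo_alignment}.
#' @param pm A \code{popmap} covering the alignment.
#' @param n_sim Replicates for the Tajima's D significance test
#'   (0 disables it).
#' @param min_n Populations need more than this many sequences (default 3).
#' @return A data.frame with one row per population: n, h, Hd, pi, theta_w,
#'   S, D, D_significant, Fs, R2.
#' @export
diversity_summary <- function(aln, pm, n_sim = 1000, min_n = 3) {
  validate_popmap(aln, pm)
  pops <- unique(pm$population)
  rows <- lapply(pops, function(p) {
    ids <- pm$sample[pm$population == p]
    ids <- intersect(aln$ids, ids)
    n <- length(ids)
    out <- data.frame(population = p, region = pm$region[match(p, pm$population)],
                      n = n, h = NA_integer_, Hd = NA_real_, pi = NA_real_,
                      theta_w = NA_real_, S = NA_integer_, D = NA_real_,
                      D_significant = NA, Fs = NA_real_, R2 = NA_real_,
                      stringsAsFactors = FALSE)
    if (n <= min_n) return(out)
    sub <- subset_alignment(aln, ids)
    ht <- collapse_haplotypes(sub)
    out$h <- length(ht$haplotypes)
    out$Hd <- haplotype_diversity(ht)
    out$pi <- nucleotide_diversity(sub)
    out$theta_w <- watterson_theta(sub)
    out$S <- as.integer(segregating_sites(sub))
    td <- tajimas_d(sub, n_sim = n_sim)
    out$D <- td$D
    out$D_significant <- td$significant
    fs <- fu_fs(sub)
    out$Fs <- fs$Fs
    out$R2 <- r2_statistic(sub)$R2
    out
  })
  do.call(rbind, rows)
}
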