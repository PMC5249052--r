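# Independent brute-force oracles for the diversity and structure
# statistics, written directly from the textbook definitions and kept free
# of any package internals.

# random clean (unambiguous) alignment with realistic shared polymorphism:
# a random root sequence with mutations scattered over a star of lineages
random_alignment <- function(n, L, n_mut = rpois(1, L / 8) + 1) {
  root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- matrix(rep(root, n), nrow = n, byrow = TRUE)
  for (m in seq_len(n_mut)) {
    site <- sample.int(L, 1)
    carriers <- sample.int(n, sample.int(max(n - 1, 1), 1))
    new_base <- sample(setdiff(c("A", "C", "G", "T"), root[site]), 1)
    seqs[carriers, site] <- new_base
  }
  haplo_alignment(paste0("s", seq_len(n)),
                  apply(seqs, 1, paste, collapse = ""))
}

aln_chars <- function(aln) {
  matrix(unlist(strsplit(aln$seqs, "")), nrow = length(aln$ids), byrow = TRUE)
}

# pi: explicit mean over all unordered pairs of per-site difference fractions
oracle_pi <- function(aln) {
  m <- aln_chars(aln)
  n <- nrow(m)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ]) / ncol(m)
  tot / choose(n, 2)
}

oracle_S <- function(aln) {
  m <- aln_chars(aln)
  sum(apply(m, 2, function(col) length(unique(col)) > 1))
}

oracle_theta_w <- function(aln) {
  n <- nrow(aln_chars(aln))
  oracle_S(aln) / (sum(1 / seq_len(n - 1)) * aln$L)
}

oracle_hd <- function(seq_strings) {
  n <- length(seq_strings)
  p <- as.numeric(table(seq_strings)) / n
  n / (n - 1) * (1 - sum(p^2))
}

# Tajima's D rebuilt constant by constant from the 1989 definitions
oracle_tajima_d <- function(aln) {
  m <- aln_chars(aln)
  n <- nrow(m)
  S <- oracle_S(aln)
  if (S == 0) return(NA_real_)
  kbar <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    kbar <- kbar + sum(m[i, ] != m[j, ])
  kbar <- kbar / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# distribution of the haplotype count K under the Ewens sampling formula,
# via the Chinese-restaurant-process recursion (independent of Stirling
# numbers): customer i+1 opens a new table with probability theta/(theta+i)
oracle_ewens_k <- function(n, theta) {
  p <- c(1, rep(0, n - 1))  # after 1 customer, K = 1
  if (n > 1) for (i in 1:(n - 1)) {
    p_new <- theta / (theta + i)
    p <- c(0, p[-n]) * p_new + p * (1 - p_new)
  }
  p
}

oracle_fu_fs <- function(aln) {
  m <- aln_chars(aln)
  n <- nrow(m)
  kbar <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    kbar <- kbar + sum(m[i, ] != m[j, ])
  kbar <- kbar / choose(n, 2)
  if (kbar <= 0) return(Inf)
  k_obs <- length(unique(aln$seqs))
  Sp <- sum(oracle_ewens_k(n, kbar)[k_obs:n])
  log(Sp / (1 - Sp))
}

oracle_r2 <- function(aln) {
  m <- aln_chars(aln)
  n <- nrow(m)
  S <- oracle_S(aln)
  if (S == 0) return(NA_real_)
  U <- numeric(n)
  for (site in seq_len(ncol(m))) {
    tab <- table(m[, site])
    if (length(tab) < 2) next
    for (b in names(tab)[tab == 1]) U[m[, site] == b] <- U[m[, site] == b] + 1
  }
  kbar <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    kbar <- kbar + sum(m[i, ] != m[j, ])
  kbar <- kbar / choose(n, 2)
  sqrt(mean((U - kbar / 2)^2)) / S
}

# AMOVA oracle: one-hot embedding, sums of squares as deviations from
# centroids (SS = 0.5 * sum ||x_i - x_bar||^2 per stratum for 0/1 allele
# identity), and the expected-mean-square equations solved as a linear
# system rather than by sequential substitution.
oracle_amova <- function(seq_strings, pop, grp) {
  haps <- unique(seq_strings)
  X <- t(vapply(seq_strings, function(s) as.numeric(haps == s),
                numeric(length(haps))))
  N <- nrow(X)
  ss_dev <- function(idx) {
    if (length(idx) < 2) return(0)
    xb <- colMeans(X[idx, , drop = FALSE])
    0.5 * sum(sweep(X[idx, , drop = FALSE], 2, xb)^2)
  }
  pops <- unique(pop); grps <- unique(grp)
  P <- length(pops); G <- length(grps)
  ss_total <- ss_dev(1:N)
  ss_wp <- sum(vapply(pops, function(p) ss_dev(which(pop == p)), 0))
  ss_wg <- sum(vapply(grps, function(g) ss_dev(which(grp == g)), 0))
  ssd <- c(ag = ss_total - ss_wg, ap = ss_wg - ss_wp, wp = ss_wp)
  df <- c(ag = G - 1, ap = P - G, wp = N - P)
  n_p <- table(pop)[pops]
  n_g <- table(grp)[grps]
  pop_grp <- vapply(pops, function(p) grp[match(p, pop)], "")
  s1 <- sum(vapply(grps, function(g)
    sum(n_p[pops[pop_grp == g]]^2) / n_g[[g]], 0))
  n1 <- (N - s1) / df[["ap"]]
  n2 <- (s1 - sum(n_p^2) / N) / df[["ag"]]
  n3 <- (N - sum(n_g^2) / N) / df[["ag"]]
  # E[MS] = A %*% sigma, solve for sigma
  A <- rbind(c(n3, n2, 1),   # among groups
             c(0,  n1, 1),   # among pops within groups
             c(0,  0,  1))   # within pops
  ms <- ssd / df
  sigma <- solve(A, ms)
  names(sigma) <- c("a", "b", "c")
  sigma
}

# tiny haplotype_table builder for network tests
make_ht <- function(seqs, counts = rep(1, length(seqs)),
                    ids = paste0("h", seq_along(seqs))) {
  names(seqs) <- ids
  cm <- matrix(counts, ncol = 1, dimnames = list(ids, "all"))
  structure(list(haplotypes = seqs,
                 assignment = stats::setNames(rep(ids, counts),
                                              paste0("s", seq_len(sum(counts)))),
                 counts = cm),
            class = "haplotype_table")
}

# pairwise coalescence time of two tips from a genealogy
coal_time_of_pair <- function(gen, i, j) {
  anc <- function(v) {
    out <- v
    while (!is.na(gen$parent[v])) { v <- gen$parent[v]; out <- c(out, v) }
    out
  }
  common <- intersect(anc(i), anc(j))
  min(gen$time[common])
}

# fast single-population scenario pair with disjoint N_e priors and a
# tightly constrained nuisance prior (shared by several ABC tests)
disjoint_ne_toy <- function(n = 20) {
  list(
    scenarios = list(
      s_low = scenario("s_low", "P", list(P = "N_low"), list(),
                       c(P = n)),
      s_high = scenario("s_high", "P", list(P = "N_high"), list(),
                        c(P = n))),
    priors = prior_spec(list(N_low = c(1e2, 1e3), N_high = c(1e4, 1e5),
                             mu = c(1e-8, 1e-6), kappa = c(0.05, 20),
                             I = c(0, 0.9))))
}
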