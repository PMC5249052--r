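# Hierarchical analysis of molecular variance (AMOVA) on inter-individual
# distance matrices, with the three standard permutation schemes, pairwise
# F_ST matrices and Benjamini-Yekutieli multiple-testing correction.

#' Inter-individual distance matrix for AMOVA
#'
#' @param aln A \code{haplo_alignment}.
#' @param mode \code{"allele_identity"} (0/1 by haplotype identity; gives
#'   conventional F-statistics) or \code{"site_differences"} (counts of
#'   differing sites; gives Phi-statistics).
#' @return Square symmetric matrix over samples with zero diagonal.
#' @export
haplo_distance <- function(aln, mode = c("allele_identity", "site_differences")) {
  mode <- match.arg(mode)
  if (mode == "allele_identity") {
    ht <- collapse_haplotypes(aln)
    hap <- ht$assignment[aln$ids]
    d <- outer(hap, hap, FUN = "!=") * 1
  } else {
    d <- pairwise_diffs(state_matrix(aln))$diff
  }
  dimnames(d) <- list(aln$ids, aln$ids)
  d
}

#' Internal: sum of squared deviations for a set of samples
#' SS(A) = (1/n_A) * sum_{i<j in A} d2[i,j]
#' @noRd
ss_set <- function(d2, idx) {
  if (length(idx) < 2) return(0)
  sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
}

#' Internal: variance components from a distance matrix and grouping
#' @noRd
amova_components <- function(d2, pop, grp) {
  N <- length(pop)
  pops <- unique(pop)
  grps <- unique(grp)
  P <- length(pops)
  G <- length(grps)
  pop_grp <- vapply(pops, function(p) grp[match(p, pop)], "")
  n_p <- vapply(pops, function(p) sum(pop == p), 0)
  names(n_p) <- pops
  n_g <- vapply(grps, function(g) sum(grp == g), 0)
  names(n_g) <- grps

  all_idx <- seq_len(N)
  ss_total <- ss_set(d2, all_idx)
  ss_wp <- sum(vapply(pops, function(p) ss_set(d2, which(pop == p)), 0))
  ss_g <- sum(vapply(grps, function(g) ss_set(d2, which(grp == g)), 0))
  ssd_ap_wg <- ss_g - ss_wp
  ssd_ag <- ss_total - ss_g

  df_ag <- G - 1
  df_ap <- P - G
  df_wp <- N - P

  # unequal-sample-size coefficients (Excoffier-style expected mean squares)
  sum_np2_over_ng <- sum(vapply(grps, function(g) {
    pg <- pops[pop_grp == g]
    sum(n_p[pg]^2) / n_g[g]
  }, 0))
  n1 <- (N - sum_np2_over_ng) / df_ap
  n2 <- (sum_np2_over_ng - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(n_g^2) / N) / df_ag

  sigma_c <- ss_wp / df_wp
  sigma_b <- (ssd_ap_wg / df_ap - sigma_c) / n1
  sigma_a <- (ssd_ag / df_ag - sigma_c - n2 * sigma_b) / n3
  list(ss = c(among_groups = ssd_ag, among_pops_within_groups = ssd_ap_wg,
              within_pops = ss_wp),
       df = c(among_groups = df_ag, among_pops_within_groups = df_ap,
              within_pops = df_wp),
       sigma = c(a = sigma_a, b = sigma_b, c = sigma_c))
}

#' Internal: F-statistics from variance components
#' @noRd
f_from_sigma <- function(sg) {
  tot <- sum(sg)
  c(F_CT = unname(sg["a"] / tot),
    F_SC = unname(sg["b"] / (sg["b"] + sg["c"])),
    F_ST = unname((sg["a"] + sg["b"]) / tot))
}

#' Hierarchical AMOVA with permutation tests
#'
#' Partitions molecular variance among groups (regions), among populations
#' within groups, and within populations, from an inter-individual distance
#' matrix, and tests F_CT, F_SC and F_ST with the three standard permutation
#' schemes: whole populations among groups (F_CT), samples among populations
#' within groups (F_SC), and samples among populations among groups (F_ST).
#'
#' @param d Square distance matrix over samples (allele-identity 0/1 or
#'   site-difference counts); treated as squared distances in the sums of
#'   squares, as is conventional.
#' @param pm A \code{popmap} covering the rows of \code{d}.
#' @param n_perm Number of permutations per scheme (default 1023; the
#'   observed configuration is added, p = (#perm >= obs + 1)/(n_perm + 1)).
#' @param seed Optional RNG seed for the permutations.
#' @return An \code{amova_result}: data.frame \code{table} (df, SS, variance
#'   components, percent of variation), named vector \code{fixation}
#'   (F_CT, F_SC, F_ST), \code{p_values}, and \code{negative_components}
#'   flag (negative components are retained, not truncated).
#' @export
amova <- function(d, pm, n_perm = 1023, seed = NULL) {
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix must have sample rownames")
  pop <- pm$population[match(ids, pm$sample)]
  grp <- pm$region[match(ids, pm$sample)]
  if (anyNA(pop)) stop("samples missing from popmap")
  if (length(unique(grp)) < 2)
    stop("AMOVA needs >= 2 groups (F_CT undefined for a single group)")
  if (length(unique(pop)) < 2) stop("AMOVA needs >= 2 populations")
  if (!is.null(seed)) set.seed(seed)
  d2 <- as.matrix(d)

  obs <- amova_components(d2, pop, grp)
  fst <- f_from_sigma(obs$sigma)
  tot <- sum(obs$sigma)
  pct <- if (tot > 0) 100 * obs$sigma / tot else rep(NA_real_, 3)

  p <- c(F_CT = NA_real_, F_SC = NA_real_, F_ST = NA_real_)
  if (n_perm > 0 && tot > 0) {
    pops <- unique(pop)
    pop_grp <- vapply(pops, function(pn) grp[match(pn, pop)], "")
    count <- c(F_CT = 0, F_SC = 0, F_ST = 0)
    for (b in seq_len(n_perm)) {
      # F_ST: samples among populations among groups
      perm_pop <- sample(pop)
      perm_grp <- vapply(perm_pop, function(pn) pop_grp[match(pn, pops)], "")
      f1 <- f_from_sigma(amova_components(d2, perm_pop, perm_grp)$sigma)
      if (!is.na(f1["F_ST"]) && f1["F_ST"] >= fst["F_ST"] - 1e-12)
        count["F_ST"] <- count["F_ST"] + 1
      # F_SC: samples among populations within groups
      perm_pop2 <- pop
      for (g in unique(grp)) {
        idx <- which(grp == g)
        perm_pop2[idx] <- sample(pop[idx])
      }
      f2 <- f_from_sigma(amova_components(d2, perm_pop2, grp)$sigma)
      if (!is.na(f2["F_SC"]) && f2["F_SC"] >= fst["F_SC"] - 1e-12)
        count["F_SC"] <- count["F_SC"] + 1
      # F_CT: whole populations among groups
      perm_assign <- sample(pop_grp)
      perm_grp3 <- perm_assign[match(pop, pops)]
      f3 <- f_from_sigma(amova_components(d2, pop, perm_grp3)$sigma)
      if (!is.na(f3["F_CT"]) && f3["F_CT"] >= fst["F_CT"] - 1e-12)
        count["F_CT"] <- count["F_CT"] + 1
    }
    p <- (count + 1) / (n_perm + 1)
  }

  tab <- data.frame(
    source = c("Among groups", "Among populations within groups",
               "Within populations"),
    df = unname(obs$df),
    SS = unname(obs$ss),
    variance = unname(obs$sigma),
    percent = unname(pct),
    stringsAsFactors = FALSE)
  structure(list(table = tab, fixation = fst, p_values = p,
                 negative_components = any(obs$sigma < 0),
                 n_perm = n_perm),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA\n")
  print(x$table, row.names = FALSE)
  cat("\nFixation indices:\n")
  fx <- data.frame(index = names(x$fixation),
                   value = round(unname(x$fixation), 5),
                   p = unname(x$p_values[names(x$fixation)]))
  print(fx, row.names = FALSE)
  if (x$negative_components)
    cat("note: negative variance component(s) retained\n")
  invisible(x)
}

#' Internal: two-population F_ST from squared distances
#' @noRd
fst_two_pops <- function(d2, is_pop1) {
  n1 <- sum(is_pop1); n2 <- sum(!is_pop1); N <- n1 + n2
  ss_total <- ss_set(d2, seq_len(N))
  ss_w <- ss_set(d2, which(is_pop1)) + ss_set(d2, which(!is_pop1))
  ss_a <- ss_total - ss_w
  sigma_w <- ss_w / (N - 2)
  n_c <- (N - (n1^2 + n2^2) / N)
  sigma_a <- (ss_a / 1 - sigma_w) / n_c
  sigma_a / (sigma_a + sigma_w)
}

#' Pairwise F_ST matrix with permutation tests
#'
#' Two-population AMOVA F_ST for every population pair, permutation p-values
#' (samples shuffled between the two populations), and Benjamini-Yekutieli
#' adjusted p-values over all pairs.
#'
#' @param d Square distance matrix over samples.
#' @param pm A \code{popmap}.
#' @param n_perm Permutations per pair.
#' @param seed Optional RNG seed.
#' @return A \code{pairwise_fst} object: matrices \code{fst}, \code{p_raw},
#'   \code{p_adj} (population x population, NA diagonal), and the popmap.
#'   Pairs where either population has n < 2 are skipped with a warning.
#' @export
pairwise_fst <- function(d, pm, n_perm = 1023, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- rownames(d)
  pop <- pm$population[match(ids, pm$sample)]
  pops <- unique(pop)
  K <- length(pops)
  fst <- p_raw <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  d2 <- as.matrix(d)
  skipped <- character(0)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      idx <- which(pop %in% pops[c(i, j)])
      if (sum(pop == pops[i]) < 2 || sum(pop == pops[j]) < 2) {
        skipped <- c(skipped, paste(pops[i], pops[j], sep = "~"))
        next
      }
      sub <- d2[idx, idx]
      is1 <- pop[idx] == pops[i]
      obs <- fst_two_pops(sub, is1)
      fst[i, j] <- fst[j, i] <- obs
      if (n_perm > 0) {
        cnt <- 0
        for (b in seq_len(n_perm)) {
          f <- fst_two_pops(sub, sample(is1))
          if (!is.na(f) && f >= obs - 1e-12) cnt <- cnt + 1
        }
        p_raw[i, j] <- p_raw[j, i] <- (cnt + 1) / (n_perm + 1)
      }
    }
  }
  if (length(skipped))
    warning("pairs skipped (n < 2): ", paste(skipped, collapse = ", "))
  ut <- upper.tri(p_raw)
  p_adj <- p_raw
  p_adj[ut] <- benjamini_yekutieli(p_raw[ut])
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  structure(list(fst = fst, p_raw = p_raw, p_adj = p_adj, popmap = pm),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat("pairwise F_ST over", nrow(x$fst), "populations\n")
  print(round(x$fst, 3))
  invisible(x)
}

#' Benjamini-Yekutieli FDR correction
#'
#' Step-up adjustment valid under arbitrary dependence:
#' \eqn{p_{adj(i)} = \min_{j \ge i} \min(1, p_{(j)} m c(m)/j)} with
#' \eqn{c(m) = \sum_{k=1}^m 1/k}; input order preserved. NAs pass through.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
benjamini_yekutieli <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- pvals
  out[ok] <- stats::p.adjust(pvals[ok], method = "BY")
  out
}

#' Region-pair mean pairwise F_ST
#'
#' Arithmetic mean of pairwise F_ST over all population pairs spanning each
#' pair of regions.
#'
#' @param pf A \code{pairwise_fst} object.
#' @param pm Optional popmap (defaults to the one stored in \code{pf}).
#' @return Symmetric region x region matrix of means; NA where no valid
#'   population pair exists.
#' @export
group_mean_fst <- function(pf, pm = NULL) {
  if (is.null(pm)) pm <- pf$popmap
  pops <- rownames(pf$fst)
  reg <- vapply(pops, function(p) pm$region[match(p, pm$population)], "")
  regions <- unique(reg)
  R <- length(regions)
  out <- matrix(NA_real_, R, R, dimnames = list(regions, regions))
  for (i in seq_len(R)) {
    for (j in i:R) {
      if (i == j) {
        vals <- pf$fst[reg == regions[i], reg == regions[j], drop = FALSE]
        vals <- vals[upper.tri(vals)]
      } else {
        vals <- pf$fst[reg == regions[i], reg == regions[j], drop = FALSE]
      }
      vals <- vals[!is.na(vals)]
      if (length(vals)) out[i, j] <- out[j, i] <- mean(vals)
    }
  }
  out
}
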