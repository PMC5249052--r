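test_that("fixed private haplotypes per population give F_ST = 1", {
  ids <- paste0("s", 1:8)
  aln <- haplo_alignment(ids, rep(c("AAAA", "AAAT", "AATT", "ATTT"), each = 2))
  pm <- popmap(ids, rep(paste0("p", 1:4), each = 2), rep(c("g1", "g2"), each = 4))
  am <- amova(haplo_distance(aln), pm, n_perm = 0)
  expect_equal(unname(am$fixation["F_ST"]), 1)
  expect_equal(sum(am$table$percent), 100, tolerance = 1e-6)
})

test_that("all-identical samples give zero components and undefined indices", {
  ids <- paste0("s", 1:8)
  aln <- haplo_alignment(ids, rep("ACGT", 8))
  pm <- popmap(ids, rep(paste0("p", 1:4), each = 2), rep(c("g1", "g2"), each = 4))
  am <- amova(haplo_distance(aln), pm, n_perm = 0)
  expect_equal(sum(abs(am$table$variance)), 0)
  expect_true(all(is.na(am$fixation) | is.nan(am$fixation)))
})

test_that("variance components match the deviation-form algebra oracle", {
  set.seed(41)
  for (r in 1:6) {
    n_pop <- 6
    sizes <- sample(2:6, n_pop, replace = TRUE)
    aln <- random_alignment(sum(sizes), 30)
    pop <- rep(paste0("p", 1:n_pop), sizes)
    grp <- rep(c("g1", "g2", "g3"), each = 0)  # assigned below
    grp_of_pop <- sample(c("g1", "g2", "g3", sample(c("g1", "g2", "g3"),
                                                    n_pop - 3, replace = TRUE)))
    grp <- grp_of_pop[match(pop, paste0("p", 1:n_pop))]
    pm <- popmap(aln$ids, pop, grp)
    am <- amova(haplo_distance(aln), pm, n_perm = 0)
    orc <- oracle_amova(unname(aln$seqs), pop, grp)
    expect_equal(unname(am$table$variance), unname(orc), tolerance = 1e-10)
  }
})

test_that("single group is rejected and negative components are flagged not truncated", {
  ids <- paste0("s", 1:6)
  aln <- haplo_alignment(ids, c("AAAA", "AAAT", "AATT", "AAAA", "AAAT", "AATT"))
  pm1 <- popmap(ids, rep(c("p1", "p2"), 3), rep("g1", 6))
  expect_error(amova(haplo_distance(aln), pm1, n_perm = 0), ">= 2 groups")
  expect_error(popmap(ids, rep(c("p1", "p2"), 3),
                      rep(c("g1", "g2", "g1", "g1", "g2", "g2"), 1)),
               "more than one region")
  # negative components possible on adversarial distances; flagged, kept
  d <- haplo_distance(aln)
  pm3 <- popmap(ids, rep(c("p1", "p2", "p3"), 2),
                c("g1", "g1", "g2", "g1", "g1", "g2"))
  am <- amova(d, pm3, n_perm = 0)
  expect_type(am$negative_components, "logical")
  expect_equal(sum(am$table$df), 5)
})

test_that("Benjamini-Yekutieli matches the hand evaluation", {
  expect_equal(benjamini_yekutieli(0.3), 0.3)
  expect_equal(benjamini_yekutieli(c(0.01, 0.02, 0.04)),
               c(0.055, 0.055, 11 / 150), tolerance = 1e-12)
  expect_equal(benjamini_yekutieli(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_yekutieli(c(0.5, 1.2)), "0, 1")
})

test_that("pairwise F_ST agrees with two-population AMOVA and handles small pops", {
  ids <- paste0("s", 1:9)
  aln <- haplo_alignment(ids, c(rep("AAAA", 3), rep("AATT", 3),
                                c("AAAA", "AATT", "TTTT")))
  pm <- popmap(ids, rep(c("p1", "p2", "p3"), each = 3),
               rep(c("g1", "g2", "g2"), each = 3))
  d <- haplo_distance(aln)
  pf <- pairwise_fst(d, pm, n_perm = 99, seed = 2)
  # monomorphic, fixed different -> 1
  expect_equal(pf$fst["p1", "p2"], 1)
  # internal consistency with amova() restricted to a pair
  sub_ids <- ids[1:6]
  am <- botryphylo:::fst_two_pops(d[sub_ids, sub_ids],
                                  rep(c(TRUE, FALSE), each = 3))
  expect_equal(pf$fst["p1", "p2"], am)
  expect_true(all(pf$p_adj >= pf$p_raw - 1e-12, na.rm = TRUE))
})

test_that("panmictic populations give near-zero pairwise F_ST", {
  set.seed(42)
  fsts <- replicate(30, {
    pool <- random_alignment(16, 60)
    pm <- popmap(pool$ids, sample(rep(c("p1", "p2"), 8)), rep("g", 16))
    pairwise_fst(haplo_distance(pool), pm, n_perm = 0)$fst["p1", "p2"]
  })
  expect_lt(abs(mean(fsts)), 0.08)
})

test_that("permutation p-value distribution does not depend on the seed", {
  set.seed(43)
  pvals <- function(seed_base) {
    vapply(1:25, function(r) {
      set.seed(seed_base + r)
      pool <- random_alignment(12, 40)
      pm <- popmap(pool$ids, sample(rep(c("p1", "p2"), 6)), rep("g", 12))
      pairwise_fst(haplo_distance(pool), pm, n_perm = 1000,
                   seed = seed_base + 1000 + r)$p_raw["p1", "p2"]
    }, 0)
  }
  # same null datasets cannot be reused (seeds differ end to end); compare
  # the two p-value samples distributionally
  ks <- suppressWarnings(ks.test(pvals(50000), pvals(60000)))
  expect_gt(ks$p.value, 0.01)
})

test_that("region-pair mean F_ST averages the spanning population pairs", {
  fst <- matrix(c(NA, 0.2, 0.4, 0.6,
                  0.2, NA, 0.8, 1.0,
                  0.4, 0.8, NA, 0.1,
                  0.6, 1.0, 0.1, NA), 4, 4,
                dimnames = list(paste0("p", 1:4), paste0("p", 1:4)))
  pm <- popmap(paste0("s", 1:4), paste0("p", 1:4),
               c("r1", "r1", "r2", "r2"))
  pf <- structure(list(fst = fst, popmap = pm), class = "pairwise_fst")
  gm <- group_mean_fst(pf)
  expect_equal(gm["r1", "r2"], mean(c(0.4, 0.6, 0.8, 1.0)))
  expect_equal(gm["r1", "r1"], 0.2)
  # permuting population order leaves the means unchanged
  perm <- c(3, 1, 4, 2)
  pf2 <- structure(list(fst = fst[perm, perm], popmap = pm),
                   class = "pairwise_fst")
  gm2 <- group_mean_fst(pf2)
  expect_equal(gm2["r1", "r2"], gm["r1", "r2"])
})
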