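test_that("two haplotypes give a single edge weighted by their distance", {
  ht <- make_ht(c("AAATTT", "AAAAAA"))
  net <- median_joining(ht)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 3)
  expect_equal(sum(!net$nodes$sampled), 0)
  expect_error(median_joining(ht, epsilon = -1), "epsilon")
})

test_that("the equidistant triplet gains exactly one median and length 3", {
  # binary-state analogue of 000/110/101: consensus is the Steiner point
  ht <- make_ht(c("AAA", "TTA", "TAT"))
  net <- median_joining(ht)
  expect_equal(sum(!net$nodes$sampled), 1)
  expect_equal(net$nodes$sequence[!net$nodes$sampled], "TAA")
  expect_equal(net$length, 3)
  expect_equal(sort(net$edges$weight), c(1, 1, 1))
})

test_that("the output is the minimum spanning network over its final nodes", {
  set.seed(51)
  for (r in 1:5) {
    aln <- random_alignment(12, 40)
    ht <- collapse_haplotypes(aln)
    if (length(ht$haplotypes) < 3) next
    net <- median_joining(ht)
    d <- botryphylo:::hamming_matrix(net$nodes$sequence)
    msn <- botryphylo:::eps_msn(d, 0)
    want <- sort(paste(pmin(net$edges$from, net$edges$to),
                       pmax(net$edges$from, net$edges$to), net$edges$weight))
    # edge multiset equals the epsilon=0 MSN: the network contains that MSN
    expect_equal(sort(paste(pmin(net$nodes$id[msn[, "from"]],
                                 net$nodes$id[msn[, "to"]]),
                            pmax(net$nodes$id[msn[, "from"]],
                                 net$nodes$id[msn[, "to"]]),
                            msn[, "weight"])), want)
  }
})

test_that("medians only ever shorten the network below the sampled-node MSN", {
  set.seed(52)
  for (r in 1:5) {
    aln <- random_alignment(15, 50)
    ht <- collapse_haplotypes(aln)
    if (length(ht$haplotypes) < 2) next
    net <- median_joining(ht)
    d <- botryphylo:::hamming_matrix(unname(ht$haplotypes))
    msn0_len <- botryphylo:::msn_total(d, 0)
    expect_lte(net$length, msn0_len)
    # connected, every sampled haplotype present
    gg <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                        vertices = net$nodes$id)
    expect_true(igraph::is_connected(gg))
    expect_true(all(names(ht$haplotypes) %in% net$nodes$id))
  }
})

test_that("network topology is invariant to haplotype input order", {
  set.seed(53)
  aln <- random_alignment(10, 30)
  ht <- collapse_haplotypes(aln)
  net1 <- median_joining(ht)
  perm <- sample(length(ht$haplotypes))
  ht2 <- make_ht(unname(ht$haplotypes)[perm],
                 counts = as.numeric(rowSums(ht$counts))[perm])
  net2 <- median_joining(ht2)
  expect_equal(net2$length, net1$length)
  expect_equal(sum(!net2$nodes$sampled), sum(!net1$nodes$sampled))
  # identical edge multisets on sequence strings
  canon <- function(net) {
    s <- net$nodes$sequence[match(net$edges$from, net$nodes$id)]
    t <- net$nodes$sequence[match(net$edges$to, net$nodes$id)]
    sort(paste(pmin(s, t), pmax(s, t), net$edges$weight))
  }
  expect_equal(canon(net2), canon(net1))
})

test_that("low-mutation genealogies yield edge weights summing to the mutation count", {
  set.seed(54)
  sc <- scenario("low", "P", list(P = 5000), list(), c(P = 12))
  hits <- 0
  for (r in 1:5) {
    g <- simulate_genealogy(sc)
    aln <- simulate_sequences(g, mu = 3e-7, kappa = 1, I = 0, L = 524)
    S <- segregating_sites(aln)
    ht <- collapse_haplotypes(aln)
    if (length(ht$haplotypes) < 2) next
    net <- median_joining(ht)
    # at low mu each mutation hits a fresh site (infinite-sites-like), so
    # the minimum network connecting the haplotypes has one step per site
    expect_equal(net$length, S)
    hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("region annotation tallies the popmap and aggregates schemes", {
  ids <- paste0("s", 1:6)
  aln <- haplo_alignment(ids, c("AAAA", "AAAA", "AATT", "AATT", "TTTT", "TTTT"))
  pm_fine <- popmap(ids, rep(c("p1", "p2", "p3"), each = 2),
                    c("r1", "r1", "r1", "r1", "r2", "r2"))
  ht <- collapse_haplotypes(aln, pm_fine)
  net <- median_joining(ht)
  ann <- annotate_frequencies(net, ht, pm_fine)
  expect_equal(sum(ann$region_counts), 6)
  expect_equal(as.numeric(colSums(ann$region_counts)), c(4, 2))
  # single-region scheme: every node entirely that region
  pm_one <- popmap(ids, rep(c("p1", "p2", "p3"), each = 2), rep("all", 6))
  ann1 <- annotate_frequencies(net, ht, pm_one)
  expect_equal(as.numeric(colSums(ann1$region_counts)), 6)
  # coarser scheme sums finer counts
  expect_equal(as.numeric(rowSums(ann1$region_counts)),
               as.numeric(rowSums(ann$region_counts)))
  pm_bad <- popmap(ids[1:4], rep(c("p1", "p2"), each = 2), rep("r1", 4))
  expect_error(annotate_frequencies(net, ht, pm_bad), "missing population")
})

test_that("haplotype group assignment labels listed nodes and flags overlap", {
  ht <- make_ht(c("AAA", "TTA", "TAT"), ids = c("Bs1", "Bs2", "Bs3"))
  net <- median_joining(ht)
  lab <- assign_haplotype_groups(net, list(G1 = c("Bs1"), G2 = c("Bs2", "Bs3")))
  expect_equal(unname(lab["Bs1"]), "G1")
  expect_equal(sum(lab == "G1", na.rm = TRUE), 1)
  lab2 <- assign_haplotype_groups(net, list())
  expect_true(all(lab2[net$nodes$sampled] == "unassigned"))
  expect_error(assign_haplotype_groups(net, list(A = "Bs1", B = "Bs1")),
               "more than one group")
})
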