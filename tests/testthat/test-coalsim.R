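test_that("prior sampling respects bounds and order constraints", {
  # disjoint bounds satisfy the constraints automatically
  ps_auto <- prior_spec(list(t2 = c(0, 1), t3 = c(2, 3), t4 = c(4, 5)),
                        c("t4>t3", "t4>t2", "t3>=t2"))
  d <- sample_priors(ps_auto)
  expect_true(d[["t4"]] > d[["t3"]] && d[["t3"]] >= d[["t2"]])

  ps_over <- prior_spec(list(t2 = c(0, 1), t3 = c(0, 1), t4 = c(0, 1)),
                        c("t4>t3", "t4>t2", "t3>=t2"))
  set.seed(71)
  draws <- replicate(500, sample_priors(ps_over))
  expect_true(all(draws["t4", ] > draws["t3", ]))
  expect_true(all(draws["t4", ] > draws["t2", ]))
  expect_true(all(draws["t3", ] >= draws["t2", ]))
  expect_error(prior_spec(list(a = c(2, 1))), "min < max")
})

test_that("unconstrained marginals are uniform (KS)", {
  set.seed(72)
  ps <- prior_spec(list(mu = c(1e-8, 1e-6), t2 = c(0, 1), t3 = c(0, 1),
                        t4 = c(0, 1)),
                   c("t4>t3", "t4>t2", "t3>=t2"))
  draws <- replicate(10000, sample_priors(ps))
  ks <- suppressWarnings(
    ks.test(draws["mu", ], "punif", 1e-8, 1e-6))
  expect_gt(ks$p.value, 0.01)
})

test_that("mean pairwise coalescence time equals N_e for gene copies", {
  set.seed(73)
  sc <- scenario("one", "P", list(P = 1000), list(), c(P = 2))
  t2 <- replicate(2000, max(simulate_genealogy(sc)$time))
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 1000), 3 * se)
})

test_that("cross-population coalescences are older than the merge time", {
  set.seed(74)
  sc <- scenario("two", c("A", "B"), list(A = 300, B = 300),
                 list(list(type = "merge", time = 500, from = "B", to = "A")),
                 c(A = 3, B = 3))
  for (r in 1:30) {
    g <- simulate_genealogy(sc)
    a_tips <- which(g$tip_population == "A")
    b_tips <- which(g$tip_population == "B")
    for (i in a_tips) for (j in b_tips)
      expect_gt(coal_time_of_pair(g, i, j), 500)
  }
})

test_that("one lineage per population with merge at 0 is a single-population coalescent", {
  set.seed(75)
  sc <- scenario("deg", c("A", "B"), list(A = 1000, B = 1000),
                 list(list(type = "merge", time = 0, from = "B", to = "A")),
                 c(A = 1, B = 1))
  t2 <- replicate(1000, max(simulate_genealogy(sc)$time))
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 1000), 3 * se)
})

test_that("stranded lineages are a validation error", {
  sc <- scenario("bad", c("A", "B"), list(A = 100, B = 100), list(),
                 c(A = 2, B = 2))
  expect_error(simulate_genealogy(sc), "stranded")
})

test_that("genealogies have the right tip count and increasing node times", {
  set.seed(76)
  sc <- builtin_scenarios("E")$s19
  pri <- priors_for_scenarios(list(sc))
  for (r in 1:10) {
    g <- simulate_genealogy(sc, sample_priors(pri))
    expect_equal(g$n_tips, sum(sc$samples))
    for (v in seq_len(g$n_tips)) {
      path_t <- g$time[v]
      p <- g$parent[v]
      while (!is.na(p)) {
        expect_gt(g$time[p], path_t)
        path_t <- g$time[p]
        p <- g$parent[p]
      }
    }
  }
})

test_that("admixture events route lineages to both sources", {
  set.seed(77)
  sc <- scenario("adm", c("A", "B", "T"), list(A = 500, B = 500, T = 500),
                 list(list(type = "admixture", time = 100, target = "T",
                           source_a = "A", source_b = "B", rate = 0.5),
                      list(type = "merge", time = 5000, from = "B", to = "A")),
                 c(T = 6))
  # all pairs eventually coalesce; some only after the deep merge
  deep <- replicate(50, {
    g <- simulate_genealogy(sc)
    max(g$time) > 5000
  })
  expect_gt(mean(deep), 0.2)
  expect_lt(mean(deep), 0.999)
})

test_that("mu = 0 keeps all sequences identical to the root", {
  set.seed(78)
  sc <- scenario("one", "P", list(P = 500), list(), c(P = 6))
  g <- simulate_genealogy(sc)
  aln <- simulate_sequences(g, mu = 0, kappa = 2, I = 0.1, L = 100)
  expect_equal(length(unique(aln$seqs)), 1)
  expect_error(simulate_sequences(g, 1e-7, 2, 1, 100), "I must")
  expect_error(simulate_sequences(g, 1e-7, -1, 0, 100), "kappa")
})

test_that("kappa = 1 with equal frequencies behaves like JC69 at stationarity", {
  set.seed(79)
  sc <- scenario("one", "P", list(P = 2000), list(), c(P = 4))
  g <- simulate_genealogy(sc)
  aln <- simulate_sequences(g, mu = 5e-6, kappa = 1, I = 0, L = 5000)
  freqs <- table(strsplit(paste(aln$seqs, collapse = ""), "")[[1]])
  props <- as.numeric(freqs) / sum(freqs)
  expect_true(all(abs(props - 0.25) < 0.03))
})

test_that("the transition:transversion ratio rises with kappa", {
  count_ts_tv <- function(kappa, seed) {
    set.seed(seed)
    sc <- scenario("one", "P", list(P = 3000), list(), c(P = 8))
    g <- simulate_genealogy(sc)
    aln <- simulate_sequences(g, mu = 2e-6, kappa = kappa, I = 0, L = 2000)
    m <- botryphylo:::state_matrix(aln)
    ts <- 0; tv <- 0
    for (site in seq_len(ncol(m))) {
      st <- unique(m[, site])
      if (length(st) != 2) next
      if (all(sort(st) == c(1, 3)) || all(sort(st) == c(2, 4))) ts <- ts + 1
      else tv <- tv + 1
    }
    (ts + 1) / (tv + 1)
  }
  r1 <- count_ts_tv(1, 80)
  r4 <- count_ts_tv(4, 80)
  r16 <- count_ts_tv(16, 80)
  expect_lt(r1, r4)
  expect_lt(r4, r16)
})

test_that("identical seeds reproduce identical datasets bit-for-bit", {
  sc <- builtin_scenarios("E")$s19
  pri <- priors_for_scenarios(list(sc))
  run <- function() {
    set.seed(81)
    simulate_dataset(sc, sample_priors(pri), L = 200)
  }
  a <- run(); b <- run()
  expect_identical(a$alignment$seqs, b$alignment$seqs)
  expect_identical(a$draw, b$draw)
})

test_that("segregating sites grow stochastically with mu", {
  set.seed(82)
  mean_S <- vapply(c(1e-7, 1e-6), function(mu) {
    mean(replicate(50, {
      sc <- scenario("one", "P", list(P = 2000), list(), c(P = 8))
      g <- simulate_genealogy(sc)
      segregating_sites(simulate_sequences(g, mu, 2, 0.2, 524))
    }))
  }, 0)
  expect_lt(mean_S[1], mean_S[2])
})

test_that("built-in scenario libraries validate and cover both clades", {
  for (clade in c("A", "E")) {
    lib <- builtin_scenarios(clade)
    expect_gte(length(lib), 4)
    for (sc in lib) {
      pri <- priors_for_scenarios(list(sc))
      g <- simulate_genealogy(sc, sample_priors(pri))
      expect_equal(g$n_tips, sum(sc$samples))
    }
  }
  # scenario 19 topology: 4 sampled populations + 1 ghost
  s19 <- builtin_scenarios("E")$s19
  expect_equal(length(s19$populations), 5)
  expect_true("ghost" %in% s19$populations)
  expect_equal(sort(names(s19$samples)), sort(c("FR", "EN", "BB", "MED")))
  # FR is terminal ancestor: the last merge flows ghost -> FR
  last_ev <- s19$events[[length(s19$events)]]
  expect_equal(last_ev$to, "FR")
  expect_error(builtin_scenarios("Z"))
})
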