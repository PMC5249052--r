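test_that("summary statistics have a fixed layout and match the other modules", {
  ids <- paste0("s", 1:8)
  aln <- haplo_alignment(ids, c(rep("AAAAA", 2), c("AAAAT", "AATAT"),
                                rep("TTTTT", 2), c("TTTTA", "TTATA")))
  pm <- popmap(ids, rep(c("p1", "p2"), each = 4), rep(c("p1", "p2"), each = 4))
  st <- summary_stats(aln, pm)
  p1 <- subset_alignment(aln, ids[1:4])
  expect_equal(unname(st["p1_h"]),
               length(collapse_haplotypes(p1)$haplotypes))
  expect_equal(unname(st["p1_S"]), segregating_sites(p1))
  expect_equal(unname(st["p1_mpd"]), mean_pairwise_differences(p1))
  expect_equal(unname(st["p1_D"]), tajimas_d(p1, n_sim = 0)$D)
  d <- haplo_distance(aln)
  pf <- pairwise_fst(d, pm, n_perm = 0)
  expect_equal(unname(st["p1.p2_fst"]), pf$fst["p1", "p2"])
  # all-identical dataset degenerates cleanly
  mono <- haplo_alignment(ids, rep("AAAAA", 8))
  st0 <- summary_stats(mono, pm)
  expect_equal(unname(st0[c("p1_h", "p1_S", "p1_mpd", "p1_vpd")]),
               c(1, 0, 0, 0))
  expect_equal(unname(st0["p1_D_undef"]), 1)
  # fixed vector length across random datasets under one scheme
  set.seed(91)
  lens <- replicate(4, {
    a <- random_alignment(8, 30)
    length(summary_stats(a, popmap(a$ids, rep(c("p1", "p2"), each = 4),
                                   rep(c("p1", "p2"), each = 4))))
  })
  expect_equal(length(unique(lens)), 1)
})

test_that("private segregating sites count group-exclusive polymorphism", {
  ids <- paste0("s", 1:6)
  #          p1 polymorphic at site 2 only; p2 polymorphic at sites 2 and 4
  aln <- haplo_alignment(ids, c("AAAA", "ATAA", "AAAA",
                                "ATAA", "AAAA", "AAAT"))
  pm <- popmap(ids, rep(c("p1", "p2"), each = 3), rep(c("p1", "p2"), each = 3))
  st <- summary_stats(aln, pm)
  expect_equal(unname(st["p1_Sp"]), 0)  # site 2 also segregates in p2
  expect_equal(unname(st["p2_Sp"]), 1)  # site 4 is private to p2
})

test_that("reference tables are balanced, seeded and prior-consistent", {
  toy <- disjoint_ne_toy(n = 6)
  rt <- build_reference_table(toy$scenarios, toy$priors, 10, L = 60, seed = 5)
  expect_equal(nrow(rt), 20)
  expect_equal(as.numeric(table(rt$scenario)), c(10, 10))
  rt2 <- build_reference_table(toy$scenarios, toy$priors, 10, L = 60, seed = 5)
  expect_identical(rt, rt2)
  # marginals of parameter columns match the priors
  rt3 <- build_reference_table(toy$scenarios["s_low"], toy$priors, 300,
                               L = 30, seed = 6)
  ks <- suppressWarnings(ks.test(rt3$N_low, "punif", 1e2, 1e3))
  expect_gt(ks$p.value, 0.01)
})

test_that("pre-evaluation flags implausible observations and is reproducible", {
  set.seed(92)
  toy <- disjoint_ne_toy(n = 8)
  rt <- build_reference_table(toy$scenarios, toy$priors, 60, L = 100, seed = 7)
  obs_far <- summary_stats(
    haplo_alignment(paste0("P_", 1:8),
                    replicate(8, paste(sample(c("A", "C", "G", "T"), 100,
                                              TRUE), collapse = ""))),
    popmap(paste0("P_", 1:8), rep("P", 8), rep("P", 8)))
  pe <- suppressWarnings(pre_evaluate(rt, obs_far))
  expect_true(any(pe$flags))
  pe2 <- suppressWarnings(pre_evaluate(rt, obs_far))
  expect_identical(pe$pca$scores, pe2$pca$scores)
  # an observation drawn from the same process is rarely flagged
  draw <- sample_priors(toy$priors)
  ds <- simulate_dataset(toy$scenarios$s_low, draw, L = 100)
  obs_ok <- summary_stats(ds$alignment, ds$popmap)
  pe3 <- suppressWarnings(pre_evaluate(rt, obs_ok))
  expect_lte(mean(pe3$flags["s_low", ]), 0.3)
})

test_that("rejection and logistic model choice agree on the disjoint toy", {
  set.seed(93)
  toy <- disjoint_ne_toy(n = 12)
  rt <- build_reference_table(toy$scenarios, toy$priors, 250, L = 200,
                              seed = 8)
  ds <- simulate_dataset(toy$scenarios$s_low,
                         c(N_low = 400, N_high = 5e4, mu = 5e-7,
                           kappa = 2, I = 0.1), L = 200)
  obs <- summary_stats(ds$alignment, ds$popmap)
  mc_l <- suppressWarnings(
    posterior_probabilities(rt, obs, retain_frac = 0.2, n_boot = 50,
                            seed = 9))
  mc_r <- suppressWarnings(
    posterior_probabilities(rt, obs, retain_frac = 0.2, n_boot = 50,
                            seed = 9, method = "rejection"))
  expect_equal(sum(mc_l$posterior$prob), 1, tolerance = 1e-6)
  expect_equal(sum(mc_r$posterior$prob), 1, tolerance = 1e-6)
  expect_equal(order(mc_l$posterior$prob), order(mc_r$posterior$prob))
  expect_equal(mc_l$posterior$scenario[which.max(mc_l$posterior$prob)],
               "s_low")
  # CIs bracket the estimates
  expect_true(all(mc_l$posterior$lo <= mc_l$posterior$prob + 1e-9))
  expect_true(all(mc_l$posterior$hi >= mc_l$posterior$prob - 1e-9))
  # retain_frac -> 1: rejection converges to the balanced table frequencies
  mc_all <- suppressWarnings(
    posterior_probabilities(rt, obs, retain_frac = 1, n_boot = 0,
                            method = "rejection"))
  expect_equal(mc_all$posterior$prob, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("posterior CI widths shrink with reference-table size", {
  set.seed(94)
  # overlapping N_e priors keep the posterior interior so the bootstrap CI
  # has nonzero width at both table sizes
  toy <- list(
    scenarios = list(
      s_low = scenario("s_low", "P", list(P = "N_low"), list(), c(P = 8)),
      s_high = scenario("s_high", "P", list(P = "N_high"), list(), c(P = 8))),
    priors = prior_spec(list(N_low = c(1e2, 1e4), N_high = c(2e3, 2e5),
                             mu = c(1e-8, 1e-6), kappa = c(0.05, 20),
                             I = c(0, 0.9))))
  ds <- simulate_dataset(toy$scenarios$s_low,
                         c(N_low = 3e3, N_high = 5e4, mu = 4e-7,
                           kappa = 2, I = 0.1), L = 150)
  obs <- summary_stats(ds$alignment, ds$popmap)
  width <- function(n_rows) {
    rt <- build_reference_table(toy$scenarios, toy$priors, n_rows, L = 150,
                                seed = 10)
    mc <- suppressWarnings(
      posterior_probabilities(rt, obs, retain_frac = 0.2, n_boot = 100,
                              seed = 11))
    mean(mc$posterior$hi - mc$posterior$lo)
  }
  expect_lt(width(500), width(50))
})

test_that("parameter estimation: degenerate retain-all equals the prior, quantiles ordered", {
  set.seed(95)
  toy <- disjoint_ne_toy(n = 8)
  rt <- build_reference_table(toy$scenarios["s_low"], toy$priors, 400,
                              L = 100, seed = 12)
  obs <- unlist(rt[1, attr(rt, "stat_cols")])
  est_prior <- estimate_parameters(rt, obs, retain_frac = 1, adjust = FALSE,
                                   params = "N_low")
  # retained = everything, no adjustment -> posterior == prior draws
  expect_equal(est_prior$median, median(rt$N_low))
  expect_equal(est_prior$q025, unname(quantile(rt$N_low, 0.025)))
  est <- suppressWarnings(
    estimate_parameters(rt, obs, retain_frac = 0.1, params = "N_low"))
  expect_true(est$q025 <= est$median && est$median <= est$q975)
})

test_that("model checking calibrates on own data and flags gross misfit", {
  set.seed(96)
  toy <- disjoint_ne_toy(n = 8)
  sc <- toy$scenarios$s_low
  # posterior stand-in: tight draws around the generating parameters
  truth <- c(N_low = 400, N_high = 5e4, mu = 4e-7, kappa = 2, I = 0.1)
  draws <- do.call(rbind, replicate(60, truth, simplify = FALSE))
  draws[, "N_low"] <- runif(60, 300, 500)
  ds <- simulate_dataset(sc, truth, L = 150)
  obs <- summary_stats(ds$alignment, ds$popmap)
  chk <- suppressWarnings(model_check(sc, draws, obs, n_ppc = 120, L = 150,
                                      seed = 13))
  expect_lte(mean(chk$flags), 0.35)
  # an observation from a wildly different regime is flagged
  ds_far <- simulate_dataset(toy$scenarios$s_high,
                             c(N_low = 400, N_high = 9e4, mu = 9e-7,
                               kappa = 2, I = 0), L = 150)
  obs_far <- summary_stats(ds_far$alignment, ds_far$popmap)
  names(obs_far) <- sub("^P", "P", names(obs_far))
  chk_far <- suppressWarnings(model_check(sc, draws, obs_far, n_ppc = 120,
                                          L = 150, seed = 13))
  expect_gte(sum(chk_far$flags), 1)
  chk2 <- suppressWarnings(model_check(sc, draws, obs, n_ppc = 120, L = 150,
                                       seed = 13))
  expect_identical(chk$tail_prob, chk2$tail_prob)
})

test_that("the CI-overlap selection rule handles the boundary configurations", {
  single <- data.frame(scenario = "s1", prob = 1, lo = 0.9, hi = 1)
  sel <- select_by_ci_overlap(single)
  expect_equal(sel$winner, "s1")
  # a clean separation
  two <- data.frame(scenario = c("a", "b"), prob = c(0.8, 0.2),
                    lo = c(0.7, 0.1), hi = c(0.9, 0.3))
  expect_equal(select_by_ci_overlap(two)$winner, "a")
  # overlapping top pair, separated from the rest -> escalation set
  three <- data.frame(scenario = c("a", "b", "c"), prob = c(0.5, 0.45, 0.05),
                      lo = c(0.4, 0.38, 0.01), hi = c(0.6, 0.55, 0.09))
  s3 <- select_by_ci_overlap(three)
  expect_setequal(s3$selected, c("a", "b"))
  expect_true(is.na(s3$winner))
  expect_false(s3$flagged)
  # chained overlap (selected overlaps unselected) -> flagged
  chain <- data.frame(scenario = c("a", "b", "c"), prob = c(0.5, 0.35, 0.15),
                      lo = c(0.40, 0.30, 0.25), hi = c(0.6, 0.45, 0.34))
  expect_true(select_by_ci_overlap(chain)$flagged)
})
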