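# Backward-in-time coalescent simulation of demographic scenarios in the
# DIYABC style: sampled and unsampled ("ghost") populations, lineage-merge
# (population divergence) and admixture events, uniform priors with
# time-order constraints, and HKY+I sequence evolution down the genealogy.
#
# Conventions: N_e is the effective number of gene copies of the haploid
# maternal locus, so the expected pairwise coalescence time within a
# population is N_e generations. Times are generations before sampling.

#' Define a demographic scenario
#'
#' @param id Scenario label.
#' @param populations Character vector of population names (sampled and
#'   ghost).
#' @param ne Named vector/list giving, for each population, either a number
#'   (effective gene copies) or a parameter name to be resolved from a
#'   prior draw (e.g. \code{"N1"}).
#' @param events List of events, each a list with \code{type}
#'   (\code{"merge"} or \code{"admixture"}), \code{time} (number or
#'   parameter name), and for merge: \code{from} (daughter), \code{to}
#'   (parent); for admixture: \code{target}, \code{source_a},
#'   \code{source_b}, \code{rate} (probability a lineage traces to
#'   source_a; number or parameter name).
#' @param samples Named integer vector: sampled population -> number of
#'   sequences (taken at time 0).
#' @return A \code{scenario} object.
#' @export
scenario <- function(id, populations, ne, events, samples) {
  stopifnot(all(names(ne) %in% populations),
            all(names(samples) %in% populations))
  sc <- structure(list(id = id, populations = populations, ne = ne,
                       events = events, samples = samples),
                  class = "scenario")
  sc
}

#' @export
print.scenario <- function(x, ...) {
  cat("scenario", x$id, "-", length(x$populations), "populations (",
      sum(names(x$samples) %in% x$populations), "sampled ),",
      length(x$events), "events\n")
  invisible(x)
}

#' Internal: resolve a value or parameter name against a draw
#' @noRd
resolve_param <- function(x, draw) {
  if (is.character(x)) {
    if (!x %in% names(draw)) stop("parameter not in draw: ", x)
    unname(draw[[x]])
  } else as.numeric(x)
}

#' Define uniform priors with order constraints
#'
#' @param bounds Named list of \code{c(min, max)} pairs, one per parameter.
#' @param constraints Character vector of pairwise order constraints in the
#'   form \code{"a>b"} or \code{"a>=b"} (e.g. \code{"t4>t3"}).
#' @return A \code{prior_spec}.
#' @export
prior_spec <- function(bounds, constraints = character(0)) {
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || !(b[1] < b[2]))
      stop("bounds for ", nm, " must satisfy min < max")
  }
  structure(list(bounds = bounds, constraints = constraints),
            class = "prior_spec")
}

#' Default priors for mtCOI scenario analysis
#'
#' Uniform priors: each population's N_e in [10, 2e5] gene copies
#' (\code{ne_max} switches to the alternate 6e5 maximum), event times in
#' [10, 1e5] generations with t4 > t3, t4 > t2, t3 >= t2, admixture rate
#' in [0.001, 0.999], per-site per-generation mutation rate in [1e-8, 1e-6],
#' HKY kappa in [0.05, 20], invariant proportion in [0, 0.9].
#'
#' @param ne_names Names of the N_e parameters (one per population).
#' @param time_names Names of the time parameters (subset of t2, t3, t4).
#' @param with_ra Include an admixture-rate parameter \code{ra}.
#' @param ne_max Upper bound for N_e (default 2e5; the sensitivity
#'   re-analysis uses 6e5).
#' @return A \code{prior_spec}.
#' @export
default_priors <- function(ne_names, time_names = c("t2", "t3", "t4"),
                           with_ra = FALSE, ne_max = 2e5) {
  bounds <- list()
  for (nm in ne_names) bounds[[nm]] <- c(10, ne_max)
  for (nm in time_names) bounds[[nm]] <- c(10, 1e5)
  if (with_ra) bounds$ra <- c(0.001, 0.999)
  bounds$mu <- c(1e-8, 1e-6)
  bounds$kappa <- c(0.05, 20)
  bounds$I <- c(0, 0.9)
  cons <- character(0)
  if (all(c("t3", "t4") %in% time_names)) cons <- c(cons, "t4>t3")
  if (all(c("t2", "t4") %in% time_names)) cons <- c(cons, "t4>t2")
  if (all(c("t2", "t3") %in% time_names)) cons <- c(cons, "t3>=t2")
  prior_spec(bounds, cons)
}

#' Draw a parameter vector from the joint prior
#'
#' Rejection sampling from the product of uniforms until all order
#' constraints hold.
#'
#' @param ps A \code{prior_spec}.
#' @param max_tries Abort (suggesting bound revision) if no accepted draw in
#'   this many attempts, i.e. acceptance < 1/max_tries.
#' @return Named numeric vector (a ParamDraw).
#' @export
sample_priors <- function(ps, max_tries = 1e4) {
  nm <- names(ps$bounds)
  lo <- vapply(ps$bounds, `[`, 0, 1)
  hi <- vapply(ps$bounds, `[`, 0, 2)
  for (i in seq_len(max_tries)) {
    draw <- stats::setNames(stats::runif(length(nm), lo, hi), nm)
    if (satisfies_constraints(draw, ps$constraints)) return(draw)
  }
  stop("prior acceptance rate below ", format(1 / max_tries),
       "; revise the prior bounds or constraints")
}

#' Internal: check "a>b" / "a>=b" constraints against a draw
#' @noRd
satisfies_constraints <- function(draw, constraints) {
  for (cn in constraints) {
    if (grepl(">=", cn, fixed = TRUE)) {
      ab <- strsplit(cn, ">=", fixed = TRUE)[[1]]
      if (!(draw[[trimws(ab[1])]] >= draw[[trimws(ab[2])]])) return(FALSE)
    } else {
      ab <- strsplit(cn, ">", fixed = TRUE)[[1]]
      if (!(draw[[trimws(ab[1])]] > draw[[trimws(ab[2])]])) return(FALSE)
    }
  }
  TRUE
}

#' Simulate a coalescent genealogy under a scenario
#'
#' Backward in time: within each population, pairs coalesce at rate
#' choose(k,2)/N_e per generation (exponential waiting times); at a merge
#' event every lineage in the daughter moves to the parent; at an admixture
#' event each lineage in the target moves to source_a with probability
#' \code{rate}, else to source_b. After the last event all remaining
#' lineages must share one population, where coalescence runs to a single
#' root.
#'
#' @param sc A \code{scenario}.
#' @param draw Named parameter vector resolving any parameter references.
#' @return A \code{genealogy}: \code{parent} (node index, NA at root),
#'   \code{time} (node ages, 0 at tips), \code{tip_labels},
#'   \code{tip_population}, \code{n_tips}.
#' @export
simulate_genealogy <- function(sc, draw = numeric(0)) {
  samples <- sc$samples
  n <- sum(samples)
  if (n < 1) stop("scenario has no samples")
  ne <- vapply(sc$populations, function(p) {
    v <- sc$ne[[p]]
    if (is.null(v)) stop("no N_e for population ", p)
    resolve_param(v, draw)
  }, 0)
  events <- lapply(sc$events, function(ev) {
    ev$t <- resolve_param(ev$time, draw)
    if (ev$type == "admixture") ev$ra <- resolve_param(ev$rate, draw)
    ev
  })
  events <- events[order(vapply(events, `[[`, 0, "t"))]

  tip_pop <- rep(names(samples), samples)
  tip_labels <- paste0(rep(names(samples), samples), "_",
                       unlist(lapply(samples, seq_len)))
  max_nodes <- 2L * n - 1L
  parent <- rep(NA_integer_, max_nodes)
  node_time <- numeric(max_nodes)
  next_node <- n + 1L
  # active lineages per population
  active <- split(seq_len(n), tip_pop)
  for (p in setdiff(sc$populations, names(active))) active[[p]] <- integer(0)
  t_now <- 0

  coalesce_in <- function(pop, t_stop) {
    k <- length(active[[pop]])
    while (k >= 2) {
      wait <- stats::rexp(1, rate = choose(k, 2) / ne[[pop]])
      if (t_now + wait > t_stop) break
      t_now <<- t_now + wait
      pick <- sample(seq_len(k), 2)
      a <- active[[pop]][pick[1]]; b <- active[[pop]][pick[2]]
      parent[a] <<- next_node; parent[b] <<- next_node
      node_time[next_node] <<- t_now
      active[[pop]] <<- c(active[[pop]][-pick], next_node)
      next_node <<- next_node + 1L
      k <- k - 1L
    }
  }

  for (ev in events) {
    for (p in names(active)) {
      t_save <- t_now
      coalesce_in(p, ev$t)
      t_now <- t_save
    }
    t_now <- ev$t
    if (ev$type == "merge") {
      active[[ev$to]] <- c(active[[ev$to]], active[[ev$from]])
      active[[ev$from]] <- integer(0)
    } else if (ev$type == "admixture") {
      lin <- active[[ev$target]]
      if (length(lin)) {
        go_a <- stats::runif(length(lin)) < ev$ra
        active[[ev$source_a]] <- c(active[[ev$source_a]], lin[go_a])
        active[[ev$source_b]] <- c(active[[ev$source_b]], lin[!go_a])
      }
      active[[ev$target]] <- integer(0)
    } else stop("unknown event type: ", ev$type)
  }
  occupied <- names(active)[vapply(active, length, 0L) > 0]
  n_left <- sum(vapply(active, length, 0L))
  if (length(occupied) > 1 && n_left > 1)
    stop("scenario leaves lineages stranded in populations: ",
         paste(occupied, collapse = ", "),
         " (no merge path to a common ancestor)")
  if (n_left > 1) coalesce_in(occupied, Inf)

  structure(list(parent = parent, time = node_time,
                 tip_labels = tip_labels, tip_population = tip_pop,
                 n_tips = n),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat("genealogy:", x$n_tips, "tips, TMRCA",
      round(max(x$time), 1), "generations\n")
  invisible(x)
}

#' Internal: HKY transition probability matrix
#' Q normalised to one expected substitution per unit branch length.
#' @noRd
hky_P <- function(t, kappa, freqs = rep(0.25, 4)) {
  # state order A C G T; transitions: A<->G, C<->T
  Q <- matrix(rep(freqs, each = 4), 4, 4)
  ti <- rbind(c(1, 3), c(3, 1), c(2, 4), c(4, 2))
  Q[ti] <- Q[ti] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  eg <- eigen(Q)
  V <- eg$vectors
  P <- Re(V %*% diag(exp(eg$values * t)) %*% solve(V))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate sequences down a genealogy under HKY+I
#'
#' A fraction \code{I} of sites is flagged invariant (never mutates); the
#' remaining sites evolve under HKY with rate \code{mu/(1-I)} per variable
#' site per generation, so the locus-wide mean rate is \code{mu}.
#'
#' @param gen A \code{genealogy}.
#' @param mu Mean per-site per-generation mutation rate (> 0 allowed 0).
#' @param kappa HKY transition/transversion rate ratio (> 0).
#' @param I Proportion of invariant sites in [0, 1).
#' @param L Alignment length in sites.
#' @param freqs Stationary base frequencies (A, C, G, T).
#' @return A \code{haplo_alignment} of the tip sequences.
#' @export
simulate_sequences <- function(gen, mu, kappa, I, L, freqs = rep(0.25, 4)) {
  if (mu < 0 || kappa <= 0) stop("mu must be >= 0 and kappa > 0")
  if (I < 0 || I >= 1) stop("I must lie in [0, 1)")
  bases <- c("A", "C", "G", "T")
  n_nodes <- 2L * gen$n_tips - 1L
  root <- which(is.na(gen$parent[seq_len(n_nodes)]))
  variable <- stats::runif(L) >= I
  Lv <- sum(variable)
  seqs <- matrix(0L, n_nodes, Lv)
  root_full <- sample.int(4, L, replace = TRUE, prob = freqs)
  seqs[root, ] <- root_full[variable]
  rate <- if (I < 1) mu / (1 - I) else 0

  # children-before-parents in time; traverse parents-first by node time
  ord <- order(gen$time[seq_len(n_nodes)], decreasing = TRUE)
  for (v in ord) {
    if (v == root || Lv == 0) next
    p <- gen$parent[v]
    t_branch <- gen$time[p] - gen$time[v]
    P <- hky_P(rate * t_branch, kappa, freqs)
    s <- seqs[p, ]
    for (st in 1:4) {
      idx <- which(s == st)
      if (!length(idx)) next
      p_stay <- P[st, st]
      n_change <- stats::rbinom(1, length(idx), 1 - p_stay)
      if (n_change > 0) {
        ch <- if (length(idx) == 1) idx else sample(idx, n_change)
        others <- setdiff(1:4, st)
        pr <- P[st, others]
        s[ch] <- others[sample.int(3, n_change, replace = TRUE,
                                   prob = pr / sum(pr))]
      }
    }
    seqs[v, ] <- s
  }
  out <- matrix(rep(bases[root_full], gen$n_tips), nrow = gen$n_tips,
                byrow = TRUE)
  if (Lv > 0)
    out[, variable] <- matrix(bases[t(seqs[seq_len(gen$n_tips), , drop = FALSE])],
                              nrow = gen$n_tips, byrow = TRUE)
  haplo_alignment(gen$tip_labels,
                  apply(out, 1, paste, collapse = ""))
}

#' Simulate a full dataset (alignment + popmap) under a scenario
#'
#' @param sc A \code{scenario}.
#' @param draw Parameter draw (must resolve mu, kappa, I and every
#'   referenced N_e/time).
#' @param L Alignment length.
#' @param freqs Stationary base frequencies.
#' @return List with \code{alignment}, \code{popmap} (population = region =
#'   the scenario's sampled populations), and \code{draw}.
#' @export
simulate_dataset <- function(sc, draw, L = 524, freqs = rep(0.25, 4)) {
  gen <- simulate_genealogy(sc, draw)
  aln <- simulate_sequences(gen, resolve_param(draw[["mu"]], draw),
                            resolve_param(draw[["kappa"]], draw),
                            resolve_param(draw[["I"]], draw), L, freqs)
  pm <- popmap(aln$ids, gen$tip_population, gen$tip_population)
  list(alignment = aln, popmap = pm, draw = draw, scenario_id = sc$id)
}

#' Built-in demographic scenario library
#'
#' Machine-readable encodings of the dispersal scenarios described for each
#' clade. Clade A (regions PAC, MED, NEA, NWA): scenario 21 (an unsampled
#' lineage diverges from the ancestral Pacific lineage; the northwestern and
#' northeastern Atlantic lineages emerge from it and the Mediterranean
#' arises from the northeastern Atlantic), scenario 26 (the Mediterranean
#' lineage descends from the ancestral Pacific lineage early and gives rise
#' to both Atlantic lineages), scenario 48 (northwestern-Atlantic-ancestral
#' placeholder) and scenario 14 (northeastern-Atlantic ancestral). Clade E
#' (regions FR, EN, BB, MED): scenario 19 (ancestral on the French side of
#' the English Channel; an unsampled population diverges from it, gives rise
#' to the English side, which in turn gives rise to the Mediterranean and
#' Bay of Biscay), plus symmetric alternates with the English Channel
#' England (s15) and Mediterranean (s7, s8) ancestral; s8 includes an
#' admixed Bay of Biscay.
#'
#' @param clade \code{"A"} or \code{"E"}.
#' @param n_per_pop Sample size per sampled population (default 10).
#' @return Named list of \code{scenario} objects.
#' @export
builtin_scenarios <- function(clade = c("A", "E"), n_per_pop = 10) {
  clade <- match.arg(clade)
  if (clade == "E") {
    pops <- c("FR", "EN", "BB", "MED", "ghost")
    ne <- list(FR = "N_FR", EN = "N_EN", BB = "N_BB", MED = "N_MED",
               ghost = "N_ghost")
    samp <- c(FR = n_per_pop, EN = n_per_pop, BB = n_per_pop,
              MED = n_per_pop)
    list(
      s19 = scenario("s19", pops, ne, list(
        list(type = "merge", time = "t2", from = "MED", to = "EN"),
        list(type = "merge", time = "t2", from = "BB", to = "EN"),
        list(type = "merge", time = "t3", from = "EN", to = "ghost"),
        list(type = "merge", time = "t4", from = "ghost", to = "FR")),
        samp),
      s15 = scenario("s15", pops, ne, list(
        list(type = "merge", time = "t2", from = "MED", to = "FR"),
        list(type = "merge", time = "t2", from = "BB", to = "FR"),
        list(type = "merge", time = "t3", from = "FR", to = "ghost"),
        list(type = "merge", time = "t4", from = "ghost", to = "EN")),
        samp),
      s7 = scenario("s7", pops[1:4], ne[1:4], list(
        list(type = "merge", time = "t2", from = "BB", to = "FR"),
        list(type = "merge", time = "t3", from = "FR", to = "EN"),
        list(type = "merge", time = "t4", from = "EN", to = "MED")),
        samp),
      s8 = scenario("s8", pops[1:4], ne[1:4], list(
        list(type = "admixture", time = "t2", target = "BB",
             source_a = "FR", source_b = "EN", rate = "ra"),
        list(type = "merge", time = "t3", from = "FR", to = "EN"),
        list(type = "merge", time = "t4", from = "EN", to = "MED")),
        samp))
  } else {
    pops <- c("PAC", "MED", "NEA", "NWA", "ghost")
    ne <- list(PAC = "N_PAC", MED = "N_MED", NEA = "N_NEA", NWA = "N_NWA",
               ghost = "N_ghost")
    samp <- c(PAC = n_per_pop, MED = n_per_pop, NEA = n_per_pop,
              NWA = n_per_pop)
    list(
      s21 = scenario("s21", pops, ne, list(
        list(type = "merge", time = "t2", from = "MED", to = "NEA"),
        list(type = "merge", time = "t3", from = "NEA", to = "ghost"),
        list(type = "merge", time = "t3", from = "NWA", to = "ghost"),
        list(type = "merge", time = "t4", from = "ghost", to = "PAC")),
        samp),
      s26 = scenario("s26", pops[1:4], ne[1:4], list(
        list(type = "merge", time = "t2", from = "NEA", to = "MED"),
        list(type = "merge", time = "t3", from = "NWA", to = "MED"),
        list(type = "merge", time = "t4", from = "MED", to = "PAC")),
        samp),
      s48 = scenario("s48", pops[1:4], ne[1:4], list(
        list(type = "merge", time = "t2", from = "MED", to = "NEA"),
        list(type = "merge", time = "t3", from = "NEA", to = "NWA"),
        list(type = "merge", time = "t4", from = "PAC", to = "NWA")),
        samp),
      s14 = scenario("s14", pops[1:4], ne[1:4], list(
        list(type = "merge", time = "t2", from = "MED", to = "NEA"),
        list(type = "merge", time = "t3", from = "NWA", to = "NEA"),
        list(type = "merge", time = "t4", from = "PAC", to = "NEA")),
        samp))
  }
}

#' Prior specification matching a built-in scenario set
#'
#' @param scenarios A list of \code{scenario} objects (e.g. from
#'   \code{builtin_scenarios}).
#' @param ne_max Upper N_e bound (2e5 default, 6e5 alternate).
#' @return A \code{prior_spec} covering every parameter referenced by the
#'   scenarios.
#' @export
priors_for_scenarios <- function(scenarios, ne_max = 2e5) {
  refs <- unique(unlist(lapply(scenarios, function(sc) {
    c(unlist(sc$ne[vapply(sc$ne, is.character, TRUE)]),
      unlist(lapply(sc$events, function(ev) {
        out <- c()
        if (is.character(ev$time)) out <- c(out, ev$time)
        if (ev$type == "admixture" && is.character(ev$rate))
          out <- c(out, ev$rate)
        out
      })))
  })))
  ne_names <- grep("^N", refs, value = TRUE)
  time_names <- grep("^t", refs, value = TRUE)
  with_ra <- "ra" %in% refs
  default_priors(ne_names, time_names, with_ra, ne_max)
}
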