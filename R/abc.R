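# DIYABC-style approximate Bayesian computation: one-locus sequence summary
# statistics per group and group pair, seeded reference tables, prior- and
# posterior-predictive checking, LDA + multinomial-logistic scenario
# posterior probabilities with bootstrap CIs, local-linear parameter
# estimation, and the two-round CI-overlap scenario tournament.

#' Summary-statistic vector for ABC
#'
#' Per group: haplotype count, segregating sites, private segregating sites
#' (segregating within the group, monomorphic elsewhere), mean and variance
#' of pairwise differences, Tajima's D; per group pair: mean between-group
#' pairwise differences and pairwise F_ST. Undefined statistics (e.g. D when
#' S = 0 or n < 4) are imputed as 0 with a paired indicator entry, keeping
#' the vector length fixed.
#'
#' @param aln A \code{haplo_alignment}.
#' @param pm A \code{popmap}; groups are its populations by default.
#' @param by Grouping column: \code{"population"} or \code{"region"}.
#' @param groups Optional explicit group ordering (defines the fixed
#'   ordering of the vector).
#' @return Named numeric vector with a fixed layout for a given scheme.
#' @export
summary_stats <- function(aln, pm, by = c("population", "region"),
                          groups = NULL) {
  by <- match.arg(by)
  validate_popmap(aln, pm)
  g <- pm[[by]][match(aln$ids, pm$sample)]
  if (is.null(groups)) groups <- sort(unique(g))
  if (!all(g %in% groups)) stop("sample in a group outside 'groups'")
  sm <- state_matrix(aln)
  seg_in <- function(cols) {
    apply(cols, 2, function(col) length(unique(col[!is.na(col)])) > 1)
  }
  out <- c()
  for (gr in groups) {
    idx <- which(g == gr)
    if (!length(idx)) stop("empty group: ", gr)
    sub <- sm[idx, , drop = FALSE]
    seg <- seg_in(sub)
    seg_out <- seg_in(sm[-idx, , drop = FALSE])
    ht <- length(unique(aln$seqs[idx]))
    S <- sum(seg)
    Sp <- sum(seg & !seg_out)
    if (length(idx) >= 2) {
      pd <- pairwise_diffs(sub)
      dv <- pd$diff[upper.tri(pd$diff)]
      mpd <- mean(dv)
      vpd <- if (length(dv) > 1) stats::var(dv) else 0
    } else { mpd <- 0; vpd <- 0 }
    D <- NA_real_
    if (length(idx) >= 4 && S >= 1) {
      cst <- tajima_constants(length(idx))
      denom <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
      if (denom > 0) D <- (mpd - S / cst$a1) / denom
    }
    out <- c(out, stats::setNames(
      c(ht, S, Sp, mpd, vpd, ifelse(is.na(D), 0, D), as.numeric(is.na(D))),
      paste0(gr, "_", c("h", "S", "Sp", "mpd", "vpd", "D", "D_undef"))))
  }
  if (length(groups) > 1) {
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        ii <- which(g == groups[i]); jj <- which(g == groups[j])
        # mean between-group pairwise differences
        tot <- 0; cnt <- 0
        for (a in ii) {
          ok <- !is.na(sm[a, ])
          for (b in jj) {
            both <- ok & !is.na(sm[b, ])
            tot <- tot + sum(sm[a, both] != sm[b, both])
            cnt <- cnt + 1
          }
        }
        between <- tot / cnt
        fst <- NA_real_
        if (length(ii) >= 2 && length(jj) >= 2) {
          idx <- c(ii, jj)
          ht_sub <- aln$seqs[idx]
          dd <- outer(ht_sub, ht_sub, FUN = "!=") * 1
          fst <- fst_two_pops(dd, c(rep(TRUE, length(ii)),
                                    rep(FALSE, length(jj))))
        }
        nm <- paste0(groups[i], ".", groups[j])
        out <- c(out, stats::setNames(
          c(between, ifelse(is.na(fst), 0, fst), as.numeric(is.na(fst))),
          paste0(nm, "_", c("between", "fst", "fst_undef"))))
      }
    }
  }
  out
}

#' Build an ABC reference table
#'
#' For each scenario, draws \code{n_per_scenario} parameter vectors from the
#' prior, simulates a dataset through the coalescent + HKY+I machinery, and
#' records the summary-statistic vector. Fully reproducible from the seed.
#'
#' @param scenarios Named list of \code{scenario} objects.
#' @param priors A \code{prior_spec} covering all referenced parameters.
#' @param n_per_scenario Simulations per scenario.
#' @param L Alignment length (sites).
#' @param seed RNG seed.
#' @param max_fail_frac Abort if more than this fraction of simulations
#'   fails (default 0.01).
#' @return A \code{reference_table}: data.frame with columns
#'   \code{scenario}, the parameter draw columns, and the statistic columns;
#'   attributes record priors, seed and the statistic column names.
#' @export
build_reference_table <- function(scenarios, priors, n_per_scenario,
                                  L = 524, seed = 1,
                                  max_fail_frac = 0.01) {
  set.seed(seed)
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, `[[`, "", "id")
  n_total <- length(scenarios) * n_per_scenario
  rows <- vector("list", n_total)
  scen_col <- character(n_total)
  fails <- 0
  k <- 0
  for (sid in names(scenarios)) {
    sc <- scenarios[[sid]]
    for (r in seq_len(n_per_scenario)) {
      draw <- sample_priors(priors)
      res <- tryCatch({
        ds <- simulate_dataset(sc, draw, L = L)
        st <- summary_stats(ds$alignment, ds$popmap, by = "population")
        c(draw, st)
      }, error = function(e) NULL)
      if (is.null(res)) {
        fails <- fails + 1
        if (fails > max_fail_frac * n_total + 10)
          stop("simulation failure rate exceeded ", max_fail_frac,
               "; last scenario ", sid)
        next
      }
      k <- k + 1
      rows[[k]] <- res
      scen_col[k] <- sid
    }
  }
  num <- do.call(rbind, rows[seq_len(k)])
  df <- data.frame(scenario = scen_col[seq_len(k)],
                   as.data.frame(num), stringsAsFactors = FALSE,
                   check.names = FALSE)
  stat_cols <- setdiff(names(df), c("scenario", names(priors$bounds)))
  structure(df, class = c("reference_table", "data.frame"),
            priors = priors, seed = seed,
            param_cols = names(priors$bounds),
            stat_cols = stat_cols)
}

#' Internal: standardise statistic columns; drop constants
#' @noRd
standardise_stats <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, stats::sd)
  }
  keep <- scale > 1e-12
  Z <- sweep(X[, keep, drop = FALSE], 2, center[keep], "-")
  Z <- sweep(Z, 2, scale[keep], "/")
  list(Z = Z, center = center, scale = scale, keep = keep)
}

#' Prior-predictive pre-evaluation of scenario-prior combinations
#'
#' For every scenario, reports the prior-predictive quantile of each
#' observed summary statistic and flags statistics falling in the 1% tails;
#' also returns the first two principal-component coordinates (PCA fitted on
#' the standardised statistics) of all simulations with the observed point
#' projected in.
#'
#' @param rt A \code{reference_table}.
#' @param observed Summary-statistic vector of the observed data.
#' @return List with \code{quantiles} (scenario x statistic), \code{flags}
#'   (quantile < 0.01 or > 0.99), \code{pca} (scores, observed point,
#'   excluded constant columns).
#' @export
pre_evaluate <- function(rt, observed) {
  stat_cols <- attr(rt, "stat_cols")
  obs <- observed[stat_cols]
  scen <- unique(rt$scenario)
  q <- matrix(NA_real_, length(scen), length(stat_cols),
              dimnames = list(scen, stat_cols))
  for (s in scen) {
    sub <- rt[rt$scenario == s, stat_cols, drop = FALSE]
    for (cc in stat_cols)
      q[s, cc] <- mean(sub[[cc]] <= obs[[cc]])
  }
  flags <- q < 0.01 | q > 0.99
  std <- standardise_stats(rt[, stat_cols, drop = FALSE])
  excluded <- stat_cols[!std$keep]
  if (length(excluded))
    warning("constant statistic column(s) excluded from PCA: ",
            paste(excluded, collapse = ", "))
  pc <- stats::prcomp(std$Z, center = FALSE, scale. = FALSE)
  zobs <- (obs[std$keep] - std$center[std$keep]) / std$scale[std$keep]
  obs_coords <- as.numeric(zobs %*% pc$rotation[, 1:2, drop = FALSE])
  list(quantiles = q, flags = flags,
       pca = list(scores = pc$x[, 1:2, drop = FALSE],
                  observed = obs_coords, excluded = excluded))
}

#' Posterior probabilities of scenarios (LDA + multinomial logistic)
#'
#' Standardises the statistics, fits linear discriminant axes to the
#' scenario labels, retains the \code{retain_frac} simulations closest to
#' the observed point in LDA space (Euclidean), fits a multinomial logistic
#' regression of scenario on the LDA coordinates over the retained set, and
#' evaluates it at the observed point. 95% CIs by bootstrap over the
#' retained set. A \code{"rejection"} method (scenario counts in the
#' retained set) is also available.
#'
#' @param rt A \code{reference_table} with >= 2 scenarios.
#' @param observed Observed summary-statistic vector.
#' @param retain_frac Fraction of simulations retained (default 0.01).
#' @param n_boot Bootstrap resamples for the CI (default 500).
#' @param seed Optional RNG seed.
#' @param method \code{"lda_logistic"} (default) or \code{"rejection"}.
#' @return A \code{model_choice} object: data.frame \code{posterior} with
#'   scenario, prob, lo, hi; plus method and retained count.
#' @export
posterior_probabilities <- function(rt, observed, retain_frac = 0.01,
                                    n_boot = 500, seed = NULL,
                                    method = c("lda_logistic", "rejection")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  stat_cols <- attr(rt, "stat_cols")
  scen_levels <- unique(rt$scenario)
  if (length(scen_levels) < 2) stop("need >= 2 scenarios")
  n_retain <- max(2L, ceiling(retain_frac * nrow(rt)))
  if (n_retain < 50)
    warning("retained set has fewer than 50 simulations (", n_retain, ")")

  std <- standardise_stats(rt[, stat_cols, drop = FALSE])
  zobs <- (observed[stat_cols][std$keep] - std$center[std$keep]) /
    std$scale[std$keep]
  proj <- tryCatch({
    ld <- MASS::lda(std$Z, grouping = factor(rt$scenario,
                                             levels = scen_levels))
    list(sim = std$Z %*% ld$scaling,
         obs = as.numeric(zobs %*% ld$scaling))
  }, error = function(e) {
    warning("singular LDA; using standardised-statistic space")
    list(sim = std$Z, obs = as.numeric(zobs))
  })
  d <- sqrt(colSums((t(proj$sim) - proj$obs)^2))
  keep <- order(d)[seq_len(n_retain)]
  lab <- factor(rt$scenario[keep], levels = scen_levels)
  missing <- scen_levels[!scen_levels %in% unique(as.character(lab))]
  if (length(missing))
    warning("scenario(s) absent from retained set, probability floored: ",
            paste(missing, collapse = ", "))

  if (method == "rejection") {
    est <- as.numeric(table(lab)) / length(lab)
    boot <- if (n_boot > 0) replicate(n_boot, {
      bs <- sample(seq_along(lab), replace = TRUE)
      as.numeric(table(lab[bs])) / length(bs)
    }) else matrix(est, ncol = 1)
  } else {
    Xr <- proj$sim[keep, , drop = FALSE]
    fit_predict <- function(X, y, xobs) {
      if (length(unique(as.character(y))) == 1) {
        p <- as.numeric(scen_levels == unique(as.character(y)))
        return(p)
      }
      df <- data.frame(y = y, X)
      fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 200)
      nd <- as.data.frame(t(xobs))
      colnames(nd) <- colnames(X)
      pr <- stats::predict(fit, newdata = nd, type = "probs")
      if (is.null(dim(pr))) {
        if (length(pr) == 1) pr <- c(1 - pr, pr)  # binomial case
        names(pr) <- fit$lev
      }
      out <- stats::setNames(numeric(length(scen_levels)), scen_levels)
      out[names(pr)] <- pr
      out
    }
    colnames(Xr) <- paste0("ld", seq_len(ncol(Xr)))
    est <- fit_predict(Xr, lab, proj$obs)
    boot <- if (n_boot == 0) matrix(est, ncol = 1) else replicate(n_boot, {
      bs <- sample(seq_len(nrow(Xr)), replace = TRUE)
      tryCatch(fit_predict(Xr[bs, , drop = FALSE], lab[bs], proj$obs),
               error = function(e) rep(NA_real_, length(scen_levels)))
    })
  }
  est <- pmin(pmax(est, 0), 1)
  est <- est / sum(est)
  if (is.null(dim(boot))) boot <- matrix(boot, nrow = length(scen_levels))
  lo <- apply(boot, 1, stats::quantile, probs = 0.025, na.rm = TRUE)
  hi <- apply(boot, 1, stats::quantile, probs = 0.975, na.rm = TRUE)
  posterior <- data.frame(scenario = scen_levels, prob = as.numeric(est),
                          lo = pmin(lo, est), hi = pmax(hi, est),
                          stringsAsFactors = FALSE)
  structure(list(posterior = posterior, method = method,
                 n_retained = n_retain),
            class = "model_choice")
}

#' @export
print.model_choice <- function(x, ...) {
  cat("scenario posterior probabilities (", x$method, ", ",
      x$n_retained, " retained)\n", sep = "")
  df <- x$posterior
  df$prob <- round(df$prob, 4)
  df$ci95 <- sprintf("%.4f-%.4f", df$lo, df$hi)
  print(df[, c("scenario", "prob", "ci95")], row.names = FALSE)
  invisible(x)
}

#' Local-linear ABC parameter estimation
#'
#' Retains the simulations of a single scenario closest to the observed
#' statistics (Euclidean in standardised space) and applies the local-linear
#' regression adjustment: each retained parameter draw is shifted by the
#' fitted linear effect of (statistic - observed). Posterior summaries are
#' quantiles of the adjusted draws.
#'
#' @param rt A \code{reference_table} restricted to (or filtered for) one
#'   scenario.
#' @param observed Observed summary-statistic vector.
#' @param retain_frac Fraction retained (default 0.01).
#' @param params Parameter columns to estimate (default: all).
#' @param adjust Apply the regression adjustment (default TRUE).
#' @return A \code{param_estimate}: data.frame with parameter, median,
#'   q025, q975; the adjusted draws as attribute \code{"draws"}.
#' @export
estimate_parameters <- function(rt, observed, retain_frac = 0.01,
                                params = NULL, adjust = TRUE) {
  if (length(unique(rt$scenario)) > 1)
    rt <- rt[rt$scenario == rt$scenario[1], , drop = FALSE]
  stat_cols <- attr(rt, "stat_cols")
  if (is.null(params)) params <- intersect(attr(rt, "param_cols"), names(rt))
  std <- standardise_stats(rt[, stat_cols, drop = FALSE])
  zobs <- (observed[stat_cols][std$keep] - std$center[std$keep]) /
    std$scale[std$keep]
  d <- sqrt(colSums((t(std$Z) - zobs)^2))
  n_retain <- max(2L, ceiling(retain_frac * nrow(rt)))
  keep <- order(d)[seq_len(n_retain)]
  X <- sweep(std$Z[keep, , drop = FALSE], 2, zobs, "-")
  draws <- as.matrix(rt[keep, params, drop = FALSE])
  if (adjust && n_retain > ncol(X) + 2) {
    for (j in seq_along(params)) {
      fit <- stats::lm.fit(cbind(1, X), draws[, j])
      beta <- fit$coefficients[-1]
      if (anyNA(beta)) {
        # collinear statistics: ridge-regularised fallback
        warning("collinear statistics; ridge-regularised adjustment for ",
                params[j])
        lambda <- 1e-3
        XtX <- crossprod(X) + diag(lambda, ncol(X))
        beta <- solve(XtX, crossprod(X, draws[, j] - mean(draws[, j])))
      }
      draws[, j] <- draws[, j] - as.numeric(X %*% beta)
    }
  }
  qs <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  out <- data.frame(parameter = params, median = qs[, 2],
                    q025 = qs[, 1], q975 = qs[, 3],
                    stringsAsFactors = FALSE)
  structure(out, class = c("param_estimate", "data.frame"), draws = draws)
}

#' Bias, RMSE and coverage of the ABC parameter estimator
#'
#' Treats \code{n_pseudo} rows of the reference table as pseudo-observed
#' datasets with known generating parameters, estimates each from the
#' remaining rows, and tabulates relative bias, relative RMSE and 95%
#' interval coverage per parameter.
#'
#' @param rt Single-scenario \code{reference_table}.
#' @param n_pseudo Number of pseudo-observed rows.
#' @param retain_frac Retention fraction passed through.
#' @param params Parameters to validate (default: all).
#' @param seed Optional RNG seed.
#' @return data.frame: parameter, bias (relative), rmse (relative),
#'   coverage95.
#' @export
estimation_error <- function(rt, n_pseudo = 40, retain_frac = 0.01,
                             params = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) params <- intersect(attr(rt, "param_cols"), names(rt))
  idx <- sample(seq_len(nrow(rt)), min(n_pseudo, nrow(rt)))
  res <- array(NA_real_, c(length(idx), length(params), 3),
               dimnames = list(NULL, params, c("err", "relerr", "cover")))
  stat_cols <- attr(rt, "stat_cols")
  for (i in seq_along(idx)) {
    obs <- unlist(rt[idx[i], stat_cols])
    truth <- unlist(rt[idx[i], params])
    sub <- rt[-idx[i], , drop = FALSE]
    for (a in c("stat_cols", "param_cols", "priors")) attr(sub, a) <- attr(rt, a)
    est <- estimate_parameters(sub, obs, retain_frac, params)
    res[i, , "err"] <- est$median - truth
    res[i, , "relerr"] <- (est$median - truth) / truth
    res[i, , "cover"] <- as.numeric(est$q025 <= truth & truth <= est$q975)
  }
  relerr <- matrix(res[, , "relerr"], ncol = length(params))
  cover <- matrix(res[, , "cover"], ncol = length(params))
  data.frame(parameter = params,
             bias = colMeans(relerr, na.rm = TRUE),
             rmse = sqrt(colMeans(relerr^2, na.rm = TRUE)),
             coverage95 = colMeans(cover, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' Posterior-predictive model checking
#'
#' Simulates \code{n_ppc} datasets from posterior parameter draws of a
#' fitted scenario and reports, per summary statistic, the posterior-
#' predictive tail probability of the observed value (flagged when < 0.01
#' or > 0.99), plus a PCA overlay of simulated and observed statistics.
#'
#' @param sc The fitted \code{scenario}.
#' @param param_draws Matrix/data.frame of posterior parameter draws
#'   (columns named; e.g. \code{attr(estimate_parameters(...), "draws")}).
#' @param observed Observed summary-statistic vector.
#' @param n_ppc Number of posterior-predictive simulations (>= 100
#'   recommended; fewer triggers a warning).
#' @param L Alignment length.
#' @param seed RNG seed.
#' @return List with \code{tail_prob} (named vector), \code{flags},
#'   \code{pca}.
#' @export
model_check <- function(sc, param_draws, observed, n_ppc = 200, L = 524,
                        seed = 1) {
  if (n_ppc < 100) warning("n_ppc < 100: tail probabilities will be coarse")
  set.seed(seed)
  param_draws <- as.matrix(param_draws)
  pick <- sample(seq_len(nrow(param_draws)), n_ppc, replace = TRUE)
  stats_list <- vector("list", n_ppc)
  for (i in seq_len(n_ppc)) {
    draw <- param_draws[pick[i], ]
    ds <- simulate_dataset(sc, draw, L = L)
    stats_list[[i]] <- summary_stats(ds$alignment, ds$popmap,
                                     by = "population")
  }
  sims <- do.call(rbind, stats_list)
  common <- intersect(colnames(sims), names(observed))
  obs <- observed[common]
  tail_prob <- vapply(common, function(cc) mean(sims[, cc] <= obs[[cc]]), 0)
  flags <- tail_prob < 0.01 | tail_prob > 0.99
  std <- standardise_stats(sims[, common, drop = FALSE])
  pc <- stats::prcomp(std$Z, center = FALSE, scale. = FALSE)
  zobs <- (obs[std$keep] - std$center[std$keep]) / std$scale[std$keep]
  list(tail_prob = tail_prob, flags = flags,
       pca = list(scores = pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE],
                  observed = as.numeric(
                    zobs %*% pc$rotation[, seq_len(min(2, ncol(pc$x))),
                                         drop = FALSE])))
}

#' Select scenarios by the 95% CI overlap rule
#'
#' The tournament's selection rule: take the highest-probability scenario
#' plus every scenario whose 95% CI overlaps the top's, provided none of the
#' selected overlap any unselected scenario; otherwise the overlap set is
#' returned flagged as undecidable.
#'
#' @param posterior data.frame with columns \code{scenario}, \code{prob},
#'   \code{lo}, \code{hi} (as in a \code{model_choice}).
#' @return List: \code{selected} (scenario ids), \code{winner} (id when the
#'   selection is a single scenario, else NA), \code{flagged} (TRUE when the
#'   rule could not produce a clean non-overlapping selection).
#' @export
select_by_ci_overlap <- function(posterior) {
  df <- posterior[order(-posterior$prob), , drop = FALSE]
  overlaps <- function(i, j) df$lo[i] <= df$hi[j] & df$lo[j] <= df$hi[i]
  sel <- 1L
  if (nrow(df) > 1) {
    for (i in 2:nrow(df)) if (overlaps(1L, i)) sel <- c(sel, i)
  }
  unsel <- setdiff(seq_len(nrow(df)), sel)
  clean <- TRUE
  for (i in sel) for (j in unsel) if (overlaps(i, j)) clean <- FALSE
  list(selected = df$scenario[sel],
       winner = if (length(sel) == 1 && clean) df$scenario[sel] else NA_character_,
       flagged = !clean)
}

#' Two-round scenario tournament with CI-overlap selection
#'
#' Round 1: for each ancestral set, compute scenario posterior probabilities
#' against its own reference table and select by the CI-overlap rule.
#' Round 2: pool every selected scenario across sets and recompute. If the
#' top CIs still overlap, a third head-to-head round is run among the
#' overlapping top scenarios. The final comparison is repeated under the
#' alternate N_e prior maximum and both results reported.
#'
#' @param ancestral_sets Named list (label -> named list of scenarios).
#' @param observed Observed summary-statistic vector.
#' @param n_per_scenario Reference-table rows per scenario.
#' @param L Alignment length.
#' @param retain_frac,n_boot Passed to \code{posterior_probabilities}.
#' @param seed Master seed.
#' @param ne_max,ne_max_alt Primary and alternate N_e prior maxima.
#' @return A \code{tournament_result}: \code{winner}, \code{winner_alt}
#'   (alternate N_e maximum), \code{rounds} (audit trail of every
#'   \code{model_choice} and selection), \code{flagged}.
#' @export
scenario_tournament <- function(ancestral_sets, observed,
                                n_per_scenario = 500, L = 524,
                                retain_frac = 0.1, n_boot = 100,
                                seed = 1, ne_max = 2e5, ne_max_alt = 6e5) {
  rounds <- list()
  selected <- list()
  for (lbl in names(ancestral_sets)) {
    set <- ancestral_sets[[lbl]]
    if (is.null(names(set)))
      names(set) <- vapply(set, `[[`, "", "id")
    if (length(set) == 1) {
      rounds[[paste0("round1_", lbl)]] <- list(selection = names(set))
      selected[[lbl]] <- set
      next
    }
    pri <- priors_for_scenarios(set, ne_max)
    rt <- build_reference_table(set, pri, n_per_scenario, L,
                                seed = seed + length(rounds))
    mc <- posterior_probabilities(rt, observed, retain_frac, n_boot,
                                  seed = seed + 1000 + length(rounds))
    sel <- select_by_ci_overlap(mc$posterior)
    rounds[[paste0("round1_", lbl)]] <- list(choice = mc, selection = sel)
    selected[[lbl]] <- set[sel$selected]
  }
  pool <- do.call(c, unname(selected))
  names(pool) <- vapply(pool, `[[`, "", "id")

  run_final <- function(scen_set, nemax, tag) {
    if (length(scen_set) == 1) {
      return(list(winner = names(scen_set), flagged = FALSE, choice = NULL,
                  selection = list(selected = names(scen_set),
                                   winner = names(scen_set), flagged = FALSE)))
    }
    pri <- priors_for_scenarios(scen_set, nemax)
    rt <- build_reference_table(scen_set, pri, n_per_scenario, L,
                                seed = seed + 5000 + nchar(tag))
    mc <- posterior_probabilities(rt, observed, retain_frac, n_boot,
                                  seed = seed + 6000 + nchar(tag))
    sel <- select_by_ci_overlap(mc$posterior)
    if (is.na(sel$winner) && length(sel$selected) > 1 &&
        length(sel$selected) < length(scen_set)) {
      # head-to-head third round among the overlapping top scenarios
      sub <- scen_set[sel$selected]
      pri3 <- priors_for_scenarios(sub, nemax)
      rt3 <- build_reference_table(sub, pri3, n_per_scenario, L,
                                   seed = seed + 7000 + nchar(tag))
      mc3 <- posterior_probabilities(rt3, observed, retain_frac, n_boot,
                                     seed = seed + 8000 + nchar(tag))
      sel3 <- select_by_ci_overlap(mc3$posterior)
      win <- if (!is.na(sel3$winner)) sel3$winner
             else mc3$posterior$scenario[which.max(mc3$posterior$prob)]
      return(list(winner = win, flagged = is.na(sel3$winner), choice = mc,
                  choice3 = mc3, selection = sel3))
    }
    win <- if (!is.na(sel$winner)) sel$winner
           else mc$posterior$scenario[which.max(mc$posterior$prob)]
    list(winner = win, flagged = is.na(sel$winner), choice = mc,
         selection = sel)
  }

  fin <- run_final(pool, ne_max, "primary")
  rounds$round2 <- fin
  fin_alt <- run_final(pool, ne_max_alt, "alternate")
  rounds$round2_alt <- fin_alt
  structure(list(winner = fin$winner, winner_alt = fin_alt$winner,
                 flagged = fin$flagged || fin_alt$flagged,
                 rounds = rounds),
            class = "tournament_result")
}

#' @export
print.tournament_result <- function(x, ...) {
  cat("scenario tournament winner:", x$winner,
      "| alternate N_e maximum:", x$winner_alt, "\n")
  if (x$flagged) cat("note: CI-overlap rule could not fully separate the top scenarios\n")
  invisible(x)
}
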