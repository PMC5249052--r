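# One-config orchestration of the full clade analysis: diversity statistics,
# AMOVA/pairwise F_ST, median-joining network, ancestral location
# reconstruction, and the ABC scenario tournament, with per-stage outputs
# and a seeded, hash-stamped manifest.

#' Run the full analysis pipeline from a configuration
#'
#' Stages (each individually toggleable): \code{synth} (generate a synthetic
#' study; otherwise \code{fasta}/\code{popmap} inputs are read),
#' \code{stats}, \code{structure}, \code{network}, \code{phylogeo},
#' \code{abc}. All randomness flows from one master seed through named
#' per-stage substreams. Completed-stage outputs survive a later-stage
#' failure; the manifest records the failure point.
#'
#' @param config Path to a YAML file or an equivalent named list. Keys:
#'   \code{outdir} (required), \code{seed} (default 1), \code{input}
#'   (\code{fasta}, \code{popmap}) or \code{synth} (\code{template},
#'   \code{scenario}), \code{stages} (character vector; default all),
#'   \code{amova_perm}, \code{abc} (\code{clade}, \code{n_per_scenario},
#'   \code{retain_frac}, \code{n_boot}).
#' @return The manifest (list), invisibly; also written as
#'   \code{manifest.json} in \code{outdir}.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$outdir)) stop("config must name an outdir")
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  stages <- cfg$stages
  if (is.null(stages))
    stages <- c("stats", "structure", "network", "phylogeo", "abc")
  manifest <- list(seed = seed, stages = list(), failed = NULL,
                   package_version = as.character(utils::packageVersion("botryphylo")))
  stage_seed <- function(name) seed + utf8ToInt(substr(name, 1, 1))

  record <- function(name, files) {
    manifest$stages[[name]] <<- list(
      files = files,
      md5 = as.list(tools::md5sum(files)))
  }

  # inputs
  if (!is.null(cfg$synth)) {
    set.seed(stage_seed("synth"))
    study <- generate_study(template = cfg$synth$template %||% "cladeE_like",
                            seed = stage_seed("synth"))
    paths <- write_study(study, outdir)
    record("synth", paths)
    aln <- study$alignment; pm <- study$popmap
  } else {
    aln <- read_alignment(cfg$input$fasta)
    pm <- read_popmap(cfg$input$popmap)
  }
  validate_popmap(aln, pm)

  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible(NULL))
    ok <- tryCatch({ fn(); TRUE }, error = function(e) {
      manifest$failed <<- list(stage = name, message = conditionMessage(e))
      FALSE
    })
    if (!ok) {
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop("stage '", name, "' failed: ", manifest$failed$message)
    }
  }

  run_stage("stats", function() {
    set.seed(stage_seed("stats"))
    ds <- diversity_summary(aln, pm, n_sim = cfg$d_sim %||% 200)
    f <- file.path(outdir, "stats.csv")
    utils::write.csv(ds, f, row.names = FALSE)
    record("stats", f)
  })

  run_stage("structure", function() {
    set.seed(stage_seed("structure"))
    keep <- filter_populations(pm, "min_n", min_n = 3)
    aln2 <- subset_alignment(aln, intersect(aln$ids, keep$sample))
    d <- haplo_distance(aln2)
    am <- amova(d, keep, n_perm = cfg$amova_perm %||% 199)
    pf <- pairwise_fst(d, keep, n_perm = cfg$amova_perm %||% 199)
    gm <- group_mean_fst(pf)
    f <- file.path(outdir, c("amova.csv", "pairwise_fst.csv",
                             "group_mean_fst.csv"))
    utils::write.csv(cbind(am$table,
                           fixation = c(names(am$fixation)),
                           value = unname(am$fixation),
                           p = unname(am$p_values)),
                     f[1], row.names = FALSE)
    utils::write.csv(as.data.frame(pf$fst), f[2])
    utils::write.csv(as.data.frame(gm), f[3])
    record("structure", f)
  })

  run_stage("network", function() {
    ht <- collapse_haplotypes(aln, pm)
    net <- median_joining(ht, epsilon = cfg$epsilon %||% 0)
    net <- annotate_frequencies(net, ht, pm)
    paths <- write_network(net, file.path(outdir, "network"))
    record("network", paths)
  })

  run_stage("phylogeo", function() {
    ht <- collapse_haplotypes(aln, pm)
    hseq <- haplo_alignment(names(ht$haplotypes), unname(ht$haplotypes))
    d <- pairwise_diffs(state_matrix(hseq))$diff
    dimnames(d) <- list(hseq$ids, hseq$ids)
    tree <- upgma_tree(d)
    # haplotype location: region with the largest count
    pops <- colnames(ht$counts)
    reg <- vapply(pops, function(p) pm$region[match(p, pm$population)], "")
    regc <- t(apply(ht$counts, 1, function(x) tapply(x, reg, sum)))
    if (is.null(dim(regc))) regc <- matrix(regc, nrow = nrow(ht$counts))
    locs <- stats::setNames(colnames(regc)[max.col(regc, "first")],
                            rownames(ht$counts))
    post <- ancestral_location_posteriors(tree, locs)
    f <- file.path(outdir, c("ancestral_locations.csv", "upgma.nwk"))
    utils::write.csv(data.frame(node = rownames(post),
                                as.data.frame(unclass(post))),
                     f[1], row.names = FALSE)
    ape::write.tree(tree, f[2])
    record("phylogeo", f)
  })

  run_stage("abc", function() {
    acfg <- cfg$abc %||% list()
    clade <- acfg$clade %||% "E"
    scen <- builtin_scenarios(clade)
    set.seed(stage_seed("abc"))
    # condition simulations on the observed per-region sample configuration,
    # subsampled to a desk-scale cap
    cap <- acfg$max_n_per_region %||% 12
    regions <- names(scen[[1]]$samples)
    if (!all(sort(unique(pm$region)) == sort(regions)))
      stop("abc stage: data regions must match the scenario regions (",
           paste(regions, collapse = ", "), ")")
    keep_ids <- unlist(lapply(regions, function(r) {
      ids <- pm$sample[pm$region == r]
      if (length(ids) > cap) sample(ids, cap) else ids
    }))
    sub_aln <- subset_alignment(aln, intersect(aln$ids, keep_ids))
    sub_pm <- pm[pm$sample %in% sub_aln$ids, , drop = FALSE]
    n_obs <- table(factor(sub_pm$region, levels = regions))
    scen <- lapply(scen, function(s) {
      s$samples <- stats::setNames(as.integer(n_obs), regions)
      s
    })
    sets <- lapply(scen, function(s) stats::setNames(list(s), s$id))
    names(sets) <- names(scen)
    obs <- summary_stats(sub_aln, sub_pm, by = "region",
                         groups = sort(regions))
    tourn <- scenario_tournament(
      sets, observed = obs,
      n_per_scenario = acfg$n_per_scenario %||% 300,
      L = aln$L, retain_frac = acfg$retain_frac %||% 0.1,
      n_boot = acfg$n_boot %||% 50, seed = stage_seed("abc"))
    f <- file.path(outdir, "tournament.json")
    jsonlite::write_json(list(winner = tourn$winner,
                              winner_alt = tourn$winner_alt,
                              flagged = tourn$flagged),
                         f, auto_unbox = TRUE, digits = NA)
    record("abc", f)
  })

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Internal: default operator
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
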