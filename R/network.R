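# Median-joining haplotype networks. Sampled haplotypes are augmented with
# inferred unsampled intermediates ("median vectors") whenever doing so
# shortens the epsilon-relaxed minimum spanning network; obsolete medians
# are pruned. Distances are Hamming counts over jointly unambiguous sites.

#' Internal: Hamming distance matrix between sequence strings
#' N and - are treated as missing and excluded pairwise.
#' @noRd
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = n, byrow = TRUE)
  miss <- m == "N" | m == "-"
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !miss[i, ] & !miss[j, ]
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Internal: epsilon-relaxed minimum spanning network edge list
#' A pair (u,v) is linked iff d(u,v) <= lambda(u,v) + eps, where lambda is
#' the minimax (bottleneck) path distance, i.e. the largest edge on the
#' u-v path in a minimum spanning tree. eps = 0 gives the MSN proper.
#' @noRd
eps_msn <- function(d, eps = 0) {
  lambda <- minimax_lambda(d)
  keep <- which(upper.tri(d) & d <= lambda + eps, arr.ind = TRUE)
  cbind(from = keep[, 1], to = keep[, 2], weight = d[keep])
}

#' Internal: minimax (bottleneck) path distances via Prim + merge order
#' Kruskal-style agglomeration over the MST edges: when two components
#' first connect at weight w, every cross pair gets lambda = w.
#' @noRd
minimax_lambda <- function(d) {
  n <- nrow(d)
  lambda <- matrix(0, n, n)
  if (n < 2) return(lambda)
  # Prim's algorithm, O(n^2)
  in_tree <- rep(FALSE, n); in_tree[1] <- TRUE
  best_w <- d[, 1]; best_from <- rep(1L, n)
  mst_e <- matrix(0, n - 1, 3)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_w[cand])]
    mst_e[k, ] <- c(best_from[v], v, best_w[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & d[, v] < best_w
    best_from[upd] <- v
    best_w[upd] <- d[upd, v]
  }
  # agglomerate in increasing weight; cross pairs get the merge weight
  comp <- as.list(seq_len(n))
  comp_of <- seq_len(n)
  for (k in order(mst_e[, 3])) {
    a <- comp_of[mst_e[k, 1]]; b <- comp_of[mst_e[k, 2]]
    if (a == b) next
    lambda[comp[[a]], comp[[b]]] <- mst_e[k, 3]
    lambda[comp[[b]], comp[[a]]] <- mst_e[k, 3]
    comp[[a]] <- c(comp[[a]], comp[[b]])
    comp_of[comp[[b]]] <- a
    comp[[b]] <- integer(0)
  }
  lambda
}

#' Internal: total eps-MSN length for a distance matrix
#' @noRd
msn_total <- function(d, eps = 0) {
  lambda <- minimax_lambda(d)
  sum(d[upper.tri(d) & d <= lambda + eps])
}

#' Internal: consensus (median) sequence of three haplotypes
#' Per-site majority; an unresolved three-way tie takes the candidate state
#' minimising the summed distance to the triple, then lexicographic order.
#' @noRd
triple_median <- function(s1, s2, s3) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]; c_ <- strsplit(s3, "")[[1]]
  a[a == "N" | a == "-"] <- NA; b[b == "N" | b == "-"] <- NA
  c_[c_ == "N" | c_ == "-"] <- NA
  # majority where any two agree; otherwise (all distinct or partly missing)
  # every candidate adds the same length, so take the lexicographic minimum
  out <- pmin(a, b, c_, na.rm = TRUE)
  ab <- !is.na(a) & !is.na(b) & a == b
  ac <- !is.na(a) & !is.na(c_) & a == c_
  bc <- !is.na(b) & !is.na(c_) & b == c_
  out[bc] <- b[bc]
  out[ac] <- a[ac]
  out[ab] <- a[ab]
  out[is.na(out)] <- "N"
  paste(out, collapse = "")
}

#' Median-joining haplotype network
#'
#' Bandelt-style construction: repeatedly build the epsilon-relaxed minimum
#' spanning network over current nodes, propose the per-site consensus
#' (median) of every linked triple of nodes, add the median that most
#' reduces total network length (ties broken lexicographically on the
#' sequence string), prune unsampled nodes of degree <= 1, and stop at a
#' fixpoint.
#'
#' @param ht A \code{haplotype_table} with >= 2 haplotypes.
#' @param epsilon Non-negative integer relaxation of the feasible-link
#'   criterion (0 = PopART-style default).
#' @return A \code{haplotype_network}: \code{nodes} data.frame (id, sequence,
#'   sampled, count), \code{edges} data.frame (from, to, weight in mutational
#'   steps), \code{epsilon}, \code{length} (total network length).
#' @export
median_joining <- function(ht, epsilon = 0) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  seqs <- unname(ht$haplotypes)
  ids <- names(ht$haplotypes)
  if (length(seqs) < 2) stop("median_joining requires >= 2 haplotypes")
  sampled <- rep(TRUE, length(seqs))
  n_median <- 0L

  # character matrix representation; NA for ambiguous positions
  to_row <- function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    v[v == "N" | v == "-"] <- NA
    v
  }
  mat <- t(vapply(seqs, to_row, character(nchar(seqs[1]))))
  dist_to_all <- function(row, m) {
    # Hamming with pairwise exclusion of NAs, vectorised over nodes
    cmp <- sweep(m, 2, row, FUN = "!=")
    rowSums(cmp, na.rm = TRUE)
  }
  d <- hamming_matrix(seqs)

  repeat {
    edges <- eps_msn(d, epsilon)
    total <- sum(edges[, "weight"])

    # linked triples: nodes u,v,w with at least two of the three links present
    adj <- matrix(FALSE, nrow(mat), nrow(mat))
    if (nrow(edges)) adj[edges[, c("from", "to"), drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    cand <- character(0)
    nn <- nrow(mat)
    if (nn >= 3) {
      for (u in seq_len(nn)) {
        nbr <- which(adj[u, ])
        if (length(nbr) < 2) next
        prs <- utils::combn(nbr, 2)
        for (k in seq_len(ncol(prs))) {
          v <- prs[1, k]; w <- prs[2, k]
          cand <- c(cand, triple_median(seqs[u], seqs[v], seqs[w]))
        }
      }
    }
    cand <- setdiff(unique(cand), seqs)
    improved <- FALSE
    if (length(cand)) {
      new_totals <- vapply(cand, function(m) {
        drow <- dist_to_all(to_row(m), mat)
        dd <- rbind(cbind(d, drow), c(drow, 0))
        msn_total(dd, epsilon)
      }, 0)
      best <- min(new_totals)
      if (best < total - 1e-9) {
        pick <- sort(cand[new_totals == best])[1]
        n_median <- n_median + 1L
        prow <- to_row(pick)
        drow <- dist_to_all(prow, mat)
        d <- rbind(cbind(d, drow), c(drow, 0))
        dimnames(d) <- NULL
        mat <- rbind(mat, prow)
        seqs <- c(seqs, pick)
        ids <- c(ids, paste0("mv", n_median))
        sampled <- c(sampled, FALSE)
        improved <- TRUE
      }
    }
    if (!improved) {
      # prune obsolete medians (unsampled, degree <= 1) to a fixpoint
      pruned <- FALSE
      deg <- tabulate(c(edges[, "from"], edges[, "to"]), nbins = nrow(mat))
      drop <- which(!sampled & deg <= 1)
      if (length(drop)) {
        seqs <- seqs[-drop]; ids <- ids[-drop]; sampled <- sampled[-drop]
        mat <- mat[-drop, , drop = FALSE]
        d <- d[-drop, -drop, drop = FALSE]
        pruned <- TRUE
      }
      if (!pruned) break
    }
  }

  edges <- eps_msn(d, epsilon)
  counts <- rowSums(ht$counts)[ids]
  counts[is.na(counts)] <- 0
  nodes <- data.frame(id = ids, sequence = seqs, sampled = sampled,
                      count = unname(counts), stringsAsFactors = FALSE)
  ed <- data.frame(from = ids[edges[, "from"]], to = ids[edges[, "to"]],
                   weight = edges[, "weight"], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = ed, epsilon = epsilon,
                 length = sum(ed$weight)),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", sum(x$nodes$sampled), "sampled haplotypes,",
      sum(!x$nodes$sampled), "median vector(s),",
      nrow(x$edges), "edges, total length", x$length, "\n")
  invisible(x)
}

#' Annotate network nodes with per-region sample counts
#'
#' @param net A \code{haplotype_network} built from \code{ht}.
#' @param ht The \code{haplotype_table} the network was built from (carries
#'   per-population counts).
#' @param pm A \code{popmap} assigning every population of \code{ht} to a
#'   region under the chosen scheme.
#' @return The network with an added \code{region_counts} matrix
#'   (node x region); median vectors carry zero rows.
#' @export
annotate_frequencies <- function(net, ht, pm) {
  pops <- colnames(ht$counts)
  reg <- vapply(pops, function(p) {
    r <- unique(pm$region[pm$population == p])
    if (length(r) != 1) stop("scheme missing population: ", p)
    r
  }, "")
  regions <- unique(reg)
  rc <- matrix(0, nrow(net$nodes), length(regions),
               dimnames = list(net$nodes$id, regions))
  for (r in regions) {
    cols <- pops[reg == r]
    s <- rowSums(ht$counts[, cols, drop = FALSE])
    hit <- intersect(names(s), net$nodes$id)
    rc[hit, r] <- s[hit]
  }
  net$region_counts <- rc
  net
}

#' Assign haplotypes to named haplotype groups
#'
#' @param net A \code{haplotype_network}.
#' @param group_definitions Named list of character vectors of haplotype ids.
#' @return Named character vector: node id -> group label; sampled nodes not
#'   listed in any group are labelled \code{"unassigned"}; median vectors
#'   are labelled \code{NA}.
#' @export
assign_haplotype_groups <- function(net, group_definitions) {
  all_members <- unlist(group_definitions, use.names = FALSE)
  if (anyDuplicated(all_members))
    stop("haplotype assigned to more than one group: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  lab <- rep(NA_character_, nrow(net$nodes))
  names(lab) <- net$nodes$id
  lab[net$nodes$sampled] <- "unassigned"
  for (g in names(group_definitions)) {
    hit <- intersect(group_definitions[[g]], net$nodes$id)
    lab[hit] <- g
  }
  lab
}

#' Export a network as GraphML and edge-list/node-table CSVs
#'
#' @param net A \code{haplotype_network} (annotated or not).
#' @param prefix Output path prefix; writes \code{<prefix>.graphml},
#'   \code{<prefix>_edges.csv}, \code{<prefix>_nodes.csv}.
#' @return The three paths, invisibly.
#' @export
write_network <- function(net, prefix) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  paths <- paste0(prefix, c(".graphml", "_edges.csv", "_nodes.csv"))
  igraph::write_graph(g, paths[1], format = "graphml")
  utils::write.csv(net$edges, paths[2], row.names = FALSE)
  nodes <- net$nodes
  if (!is.null(net$region_counts))
    nodes <- cbind(nodes, as.data.frame(net$region_counts))
  utils::write.csv(nodes, paths[3], row.names = FALSE)
  invisible(paths)
}
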