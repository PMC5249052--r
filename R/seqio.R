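#' Construct a haplotype alignment
#'
#' An alignment of equal-length haploid sequences (e.g. a 524-bp mtCOI
#' fragment), stored as upper-case character strings over \code{A,C,G,T,N,-}
#' with unique sample identifiers.
#'
#' @param ids Character vector of unique sample identifiers.
#' @param seqs Character vector of sequences, same length as \code{ids}.
#' @return An object of class \code{haplo_alignment} with elements
#'   \code{ids}, \code{seqs} (named by id) and \code{L} (alignment length).
#' @export
haplo_alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (length(ids) == 0L) stop("alignment is empty")
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != stats::median(lens)]
    stop("ragged alignment: sequence length differs for ",
         paste(bad, collapse = ", "))
  }
  if (lens[1] < 1L) stop("alignment length must be >= 1")
  ok <- grepl("^[ACGTN-]*$", seqs)
  if (!all(ok))
    stop("invalid characters in sequence(s): ",
         paste(ids[!ok], collapse = ", "))
  names(seqs) <- ids
  structure(list(ids = ids, seqs = seqs, L = lens[1]),
            class = "haplo_alignment")
}

#' @export
print.haplo_alignment <- function(x, ...) {
  cat("haplo_alignment:", length(x$ids), "sequences of", x$L, "bp\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path Path to a FASTA file of aligned sequences.
#' @param expected_length If non-NULL, validate that all sequences have this
#'   length (sites).
#' @return A \code{haplo_alignment}.
#' @export
read_alignment <- function(path, expected_length = NULL) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no FASTA records in ", path)
  ch <- as.character(dna)
  seqs <- vapply(ch, function(s) paste(toupper(s), collapse = ""), "")
  aln <- haplo_alignment(names(dna), seqs)
  if (!is.null(expected_length) && aln$L != expected_length) {
    lens <- nchar(seqs)
    bad <- aln$ids[lens != expected_length]
    stop("expected length ", expected_length, " but got ", aln$L,
         " (records: ", paste(utils::head(bad, 5), collapse = ", "), ")")
  }
  aln
}

#' Write an alignment to FASTA
#'
#' @param aln A \code{haplo_alignment}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "haplo_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$ids)) {
    writeLines(c(paste0(">", aln$ids[i]), aln$seqs[i]), con)
  }
  invisible(path)
}

#' Internal: alignment as a site-by-sample character matrix
#' @noRd
aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(aln$ids), ncol = aln$L, byrow = TRUE)
  rownames(m) <- aln$ids
  m
}

#' Subset an alignment by sample id
#' @param aln A \code{haplo_alignment}.
#' @param ids Sample ids to keep (order preserved).
#' @return A \code{haplo_alignment}.
#' @export
subset_alignment <- function(aln, ids) {
  stopifnot(all(ids %in% aln$ids))
  haplo_alignment(ids, aln$seqs[ids])
}

#' Construct a population map
#'
#' The two-level grouping hierarchy used throughout: each sample belongs to
#' one population, each population to one geographic region per scheme.
#'
#' @param sample,population,region Equal-length character vectors.
#' @return An object of class \code{popmap}: a data.frame with columns
#'   \code{sample}, \code{population}, \code{region}.
#' @export
popmap <- function(sample, population, region) {
  df <- data.frame(sample = as.character(sample),
                   population = as.character(population),
                   region = as.character(region),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample)) stop("duplicate sample(s) in popmap")
  reg_per_pop <- tapply(df$region, df$population,
                        function(r) length(unique(r)))
  if (any(reg_per_pop > 1))
    stop("population assigned to more than one region: ",
         paste(names(reg_per_pop)[reg_per_pop > 1], collapse = ", "))
  class(df) <- c("popmap", "data.frame")
  df
}

#' Read a population map TSV
#'
#' Format: 3 columns \code{sample<TAB>population<TAB>region}, one header line.
#'
#' @param path Path to the TSV file.
#' @return A \code{popmap}.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 3) stop("popmap must have 3 columns: sample, population, region")
  popmap(df[[1]], df[[2]], df[[3]])
}

#' Write a population map TSV
#' @param pm A \code{popmap}.
#' @param path Output path.
#' @export
write_popmap <- function(pm, path) {
  utils::write.table(data.frame(sample = pm$sample, population = pm$population,
                                region = pm$region),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that a population map covers an alignment
#' @param aln A \code{haplo_alignment}.
#' @param pm A \code{popmap}.
#' @return TRUE invisibly; error if any alignment id is unmapped.
#' @export
validate_popmap <- function(aln, pm) {
  missing <- setdiff(aln$ids, pm$sample)
  if (length(missing))
    stop("samples missing from popmap: ",
         paste(utils::head(missing, 5), collapse = ", "))
  invisible(TRUE)
}

#' Collapse an alignment to haplotypes
#'
#' Groups samples with identical sequences into haplotypes. Sequences
#' containing ambiguity (N or -) are kept as distinct haplotypes only if they
#' differ from every other haplotype at an unambiguous site; otherwise they
#' are merged into the (first) matching haplotype, keeping counts stable.
#'
#' @param aln A \code{haplo_alignment}.
#' @param pm Optional \code{popmap}; if given, counts are tabulated per
#'   (haplotype, population).
#' @param merge_ambiguous Merge ambiguous sequences into compatible
#'   unambiguous haplotypes (default TRUE).
#' @return An object of class \code{haplotype_table}: list with
#'   \code{haplotypes} (named character vector id -> sequence),
#'   \code{assignment} (sample -> haplotype id), and \code{counts}
#'   (haplotype x population matrix, single column "all" if no popmap).
#' @export
collapse_haplotypes <- function(aln, pm = NULL, merge_ambiguous = TRUE) {
  if (length(aln$ids) == 0L) stop("empty alignment")
  seqs <- aln$seqs
  ambig <- grepl("[N-]", seqs)
  uniq <- unique(unname(seqs[!ambig]))
  assignment <- rep(NA_integer_, length(seqs))
  assignment[!ambig] <- match(seqs[!ambig], uniq)
  if (any(ambig)) {
    for (i in which(ambig)) {
      s <- seqs[i]
      hit <- NA_integer_
      if (merge_ambiguous && length(uniq)) {
        sv <- strsplit(s, "")[[1]]
        known <- sv != "N" & sv != "-"
        for (j in seq_along(uniq)) {
          uv <- strsplit(uniq[j], "")[[1]]
          if (all(sv[known] == uv[known])) { hit <- j; break }
        }
      }
      if (is.na(hit)) {
        # also compare against previously admitted ambiguous haplotypes
        prev <- match(s, uniq)
        if (!is.na(prev)) hit <- prev else { uniq <- c(uniq, s); hit <- length(uniq) }
      }
      assignment[i] <- hit
    }
  }
  hap_ids <- paste0("H", seq_along(uniq))
  names(uniq) <- hap_ids
  assign_named <- stats::setNames(hap_ids[assignment], aln$ids)
  if (is.null(pm)) {
    pop <- rep("all", length(aln$ids))
  } else {
    validate_popmap(aln, pm)
    pop <- pm$population[match(aln$ids, pm$sample)]
  }
  counts <- table(factor(assign_named, levels = hap_ids),
                  factor(pop, levels = unique(pop)))
  counts <- unclass(as.matrix(counts))
  structure(list(haplotypes = uniq, assignment = assign_named,
                 counts = counts),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$haplotypes), "haplotypes,",
      sum(x$counts), "samples,", ncol(x$counts), "population(s)\n")
  invisible(x)
}

#' Filter populations by study inclusion rules
#'
#' Implements the two population filters used ahead of downstream analyses:
#' keep only populations with more than \code{min_n} sequences, or drop
#' populations whose Tajima's D deviates significantly from zero.
#'
#' @param pm A \code{popmap}.
#' @param rule One of \code{"min_n"} or \code{"exclude_nonzero_D"}.
#' @param min_n For \code{"min_n"}: keep populations with n > \code{min_n}
#'   (default 3).
#' @param d_significant For \code{"exclude_nonzero_D"}: named logical vector,
#'   TRUE for populations whose Tajima's D is significantly non-zero.
#' @return A filtered \code{popmap} with an attribute \code{"excluded"}
#'   listing the dropped populations.
#' @export
filter_populations <- function(pm, rule = c("min_n", "exclude_nonzero_D"),
                               min_n = 3, d_significant = NULL) {
  rule <- match.arg(rule)
  pops <- unique(pm$population)
  if (rule == "min_n") {
    n <- table(pm$population)
    drop <- names(n)[n <= min_n]
  } else {
    if (is.null(d_significant))
      stop("exclude_nonzero_D requires d_significant flags")
    drop <- intersect(names(which(d_significant)), pops)
  }
  keep <- setdiff(pops, drop)
  out <- pm[pm$population %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("popmap", "data.frame")
  if (nrow(out) == 0L)
    warning("no populations pass the '", rule, "' filter")
  attr(out, "excluded") <- drop
  out
}
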