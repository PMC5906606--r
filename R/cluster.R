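#' Pairwise sequence identity by end-gap-free global alignment
#'
#' Dynamic-programming global alignment with free terminal gaps (overlap
#' alignment). Identity is matches over alignment columns of the aligned
#' region (terminal overhangs excluded); coverage is the aligned fraction of
#' the shorter sequence; the longest perfect run is the longest stretch of
#' consecutive matching columns. Default scoring is match +1, mismatch -1,
#' gap -2.
#'
#' @param seq_a,seq_b non-empty ACGT strings.
#' @param match,mismatch,gap alignment scores.
#' @return list with `identity`, `coverage`, `longest_perfect_run`, `score`,
#'   `matches`, `columns`.
#' @details The function is exactly symmetric in its arguments: the pair is
#'   put into canonical (lexicographic) order before alignment, so
#'   tie-breaking among co-optimal alignments cannot depend on argument
#'   order.
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                              gap = -2) {
  check_seq(seq_a); check_seq(seq_b)
  if (seq_a > seq_b) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  cpp_align(seq_a, seq_b, match, mismatch, gap)
}

check_seq <- function(s) {
  if (length(s) != 1 || !nzchar(s)) stop("sequences must be non-empty")
  if (grepl("[^ACGT]", s)) stop("sequences must use only the ACGT alphabet")
  invisible(TRUE)
}

# Collapse reads (list of per-sample character vectors, or a data.frame with
# `sequence` and `sample`) to unique sequences with per-sample counts,
# ordered by decreasing total abundance, ties broken lexicographically.
derep_reads <- function(reads) {
  if (is.data.frame(reads)) {
    seqs <- reads$sequence
    samples <- as.character(reads$sample)
    ids <- reads$read_id %||% NULL
  } else {
    if (is.character(reads)) reads <- list(sample1 = reads)
    seqs <- unlist(reads, use.names = FALSE)
    samples <- rep(names(reads), lengths(reads))
    ids <- unlist(lapply(reads, names), use.names = FALSE)
  }
  seqs <- as.character(seqs %||% character(0))
  if (length(seqs) == 0) {
    return(list(unique = character(0), total = integer(0),
                read_unique = integer(0), sample = character(0),
                read_id = NULL))
  }
  uniq <- unique(seqs)
  ui <- match(seqs, uniq)
  total <- tabulate(ui, nbins = length(uniq))
  ord <- order(-total, uniq)
  rank <- integer(length(uniq)); rank[ord] <- seq_along(ord)
  list(unique = uniq[ord], total = total[ord],
       read_unique = rank[ui], sample = samples, read_id = ids)
}

#' Greedy centroid OTU clustering
#'
#' Reads are dereplicated and processed in decreasing abundance order (ties
#' by lexicographic sequence); each sequence joins the first existing
#' centroid with identity at or above `threshold`, otherwise it founds a new
#' OTU whose centroid it becomes. The clustering is deterministic and
#' invariant to the input read order.
#'
#' @param reads a named list of per-sample character vectors (names are
#'   sample ids, vector names are read ids), a data.frame with `sequence`
#'   and `sample` columns, or a bare character vector (treated as one
#'   sample).
#' @param threshold identity threshold in (0, 1]; 0.99 is the study's
#'   de novo setting.
#' @param method "auto" decides per input: equal-length sequences are
#'   compared by ungapped mismatch counting (exact for substitution-only
#'   divergence at high thresholds, and fast), anything else by the full
#'   gapped alignment. "align" forces the gapped path (use when reads may
#'   contain indels); "hamming" forces the ungapped path.
#' @param keep_members store per-OTU member read ids (requires read ids;
#'   off by default to bound memory on large runs).
#' @param match,mismatch,gap alignment scores for the gapped path.
#' @return An object of class `otu_table`: list with `counts` (integer
#'   matrix, OTUs x samples), `centroids` (named character vector) and,
#'   optionally, `members`.
#' @export
greedy_cluster <- function(reads, threshold = 0.99,
                           method = c("auto", "hamming", "align"),
                           keep_members = FALSE,
                           match = 1, mismatch = -1, gap = -2) {
  method <- match.arg(method)
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  d <- derep_reads(reads)
  if (length(d$unique) == 0) {
    return(structure(list(counts = matrix(0L, 0, 0), centroids = character(0)),
                     class = "otu_table"))
  }
  use_hamming <- switch(method,
    hamming = TRUE,
    align = FALSE,
    auto = length(unique(nchar(d$unique))) == 1L)
  otu_of_unique <- cpp_greedy_cluster(d$unique, threshold, match, mismatch,
                                      gap, use_hamming)
  n_otu <- max(otu_of_unique)
  centroid_idx <- match(seq_len(n_otu), otu_of_unique)
  otu_ids <- sprintf("OTU_%04d", seq_len(n_otu))
  centroids <- d$unique[centroid_idx]
  names(centroids) <- otu_ids
  samples <- sort(unique(d$sample))
  otu_of_read <- otu_of_unique[d$read_unique]
  counts <- table(factor(otu_of_read, levels = seq_len(n_otu)),
                  factor(d$sample, levels = samples))
  counts <- matrix(as.integer(counts), nrow = n_otu,
                   dimnames = list(otu_ids, samples))
  out <- list(counts = counts, centroids = centroids)
  if (keep_members) {
    if (is.null(d$read_id)) stop("keep_members requires named reads")
    out$members <- split(d$read_id, otu_ids[otu_of_read])
  }
  structure(out, class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples, %d reads\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

subset_otus <- function(table, keep) {
  out <- list(counts = table$counts[keep, , drop = FALSE],
              centroids = table$centroids[keep])
  if (!is.null(table$members)) out$members <- table$members[names(out$centroids)]
  structure(out, class = "otu_table")
}

#' Filter OTUs by total abundance and host similarity
#'
#' Applies the study's OTU exclusion rules, in text order: OTUs occurring
#' once in the whole dataset (singletons), OTUs with fewer than
#' `min_total_reads` reads in total (default 9; the singleton rule is
#' subsumed by it but both are applied), OTUs whose centroid equals the host
#' sequence, and fish-lineage OTUs within `host_dissimilarity` (default 0.02)
#' of the host. Fish lineage is established from `otu_class` when supplied
#' (e.g. from an earlier assignment), otherwise by nearest-neighbour lookup
#' against the reference database (class Actinopterygii); with neither, the
#' lineage-conditioned rule is skipped. The input is never mutated;
#' removals are recorded in the `removed` attribute of the result.
#'
#' @param table an `otu_table` from [greedy_cluster()].
#' @param min_total_reads minimum total reads to retain an OTU (>= 1).
#' @param host_sequence the host marker sequence, or NULL to skip host rules.
#' @param host_dissimilarity maximum dissimilarity (1 - identity) to the host
#'   for the fish-OTU exclusion, in [0, 1].
#' @param refdb a [ref_db()] used to decide which OTUs are fish-lineage.
#' @param otu_class optional named character vector (OTU id -> class name)
#'   overriding the nearest-neighbour class lookup.
#' @return A filtered `otu_table` with attribute `removed`, a list of OTU ids
#'   removed per rule (`singleton`, `low_count`, `host`, `host_like_fish`).
#' @export
filter_otus <- function(table, min_total_reads = 9, host_sequence = NULL,
                        host_dissimilarity = 0.02, refdb = NULL,
                        otu_class = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (min_total_reads < 1) stop("min_total_reads must be >= 1")
  if (host_dissimilarity < 0 || host_dissimilarity > 1)
    stop("host_dissimilarity must be in [0, 1]")
  if (nrow(table$counts) == 0) {
    attr(table, "removed") <- list(singleton = character(0),
                                   low_count = character(0),
                                   host = character(0),
                                   host_like_fish = character(0))
    return(table)
  }
  totals <- rowSums(table$counts)
  ids <- rownames(table$counts)
  singleton <- ids[totals == 1]
  low <- setdiff(ids[totals < min_total_reads], singleton)
  host <- character(0); fishy <- character(0)
  if (!is.null(host_sequence)) {
    cand <- setdiff(ids, c(singleton, low))
    host <- cand[table$centroids[cand] == host_sequence]
    cand <- setdiff(cand, host)
    if ((!is.null(refdb) || !is.null(otu_class)) && length(cand)) {
      near <- vapply(table$centroids[cand], function(s)
        pairwise_identity(s, host_sequence)$identity, numeric(1))
      close <- cand[1 - near <= host_dissimilarity]
      if (length(close)) {
        cls <- if (!is.null(otu_class)) unname(otu_class[close])
          else {
            hit <- cpp_assign_best(unname(table$centroids[close]),
                                   unname(refdb$sequences), 0, 1, -1, -2,
                                   FALSE)
            refdb$taxa$class[hit$ref]
          }
        fishy <- close[!is.na(cls) & cls == "Actinopterygii"]
      }
    }
  }
  drop <- c(singleton, low, host, fishy)
  out <- subset_otus(table, setdiff(ids, drop))
  attr(out, "removed") <- list(singleton = singleton, low_count = low,
                               host = host, host_like_fish = fishy)
  out
}

#' Enforce per-sample sequencing depth
#'
#' Samples with fewer than `min_reads` total reads are dropped (the study
#' discarded samples under 1,000 reads); samples above `cap` are subsampled
#' without replacement down to the cap (the study used at most 10,000 reads
#' per sample).
#'
#' @param table an `otu_table` (or `count_matrix`).
#' @param min_reads minimum sample depth; default 1000.
#' @param cap maximum sample depth; default 10000. Must be >= `min_reads`.
#' @param seed integer seed for the subsampling.
#' @return The table with samples dropped/subsampled; dropped sample ids in
#'   attribute `dropped_samples`.
#' @export
enforce_sample_depth <- function(table, min_reads = 1000, cap = 10000,
                                 seed = 1) {
  if (min_reads > cap) stop("min_reads must not exceed cap")
  m <- if (inherits(table, "otu_table")) table$counts else as_count_matrix(table)
  depth <- colSums(m)
  keep <- depth >= min_reads
  dropped <- colnames(m)[!keep]
  m <- m[, keep, drop = FALSE]
  with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      if (sum(m[, j]) > cap) {
        pool <- rep(seq_len(nrow(m)), m[, j])
        kept <- sample(pool, cap)
        m[, j] <- tabulate(kept, nbins = nrow(m))
      }
    }
  })
  if (inherits(table, "otu_table")) {
    out <- structure(list(counts = m, centroids = table$centroids),
                     class = "otu_table")
  } else if (inherits(table, "count_matrix")) {
    out <- structure(list(counts = m,
                          samples = table$samples[keep, , drop = FALSE]),
                     class = "count_matrix")
  } else out <- m
  attr(out, "dropped_samples") <- dropped
  out
}

#' Closed-reference clustering of reads against a reference database
#'
#' Each read is assigned to the highest-identity reference sequence at or
#' above `threshold` (ties to the first reference) or discarded, mirroring
#' closed-reference OTU picking against a curated database at 97% identity.
#' Identity here is global: matches over the aligned columns plus any
#' unaligned extent of the shorter sequence, so short perfect overlaps
#' between unrelated sequences do not qualify.
#'
#' @inheritParams greedy_cluster
#' @param refdb a [ref_db()].
#' @param threshold identity threshold in (0, 1]; default 0.97.
#' @return A `count_matrix` over reference taxa with attribute `discarded`
#'   (reads below threshold per sample).
#' @export
closed_reference_cluster <- function(reads, refdb, threshold = 0.97,
                                     method = c("auto", "align"),
                                     match = 1, mismatch = -1, gap = -2) {
  method <- match.arg(method)
  if (!inherits(refdb, "ref_db") || nrow(refdb$taxa) == 0)
    stop("a non-empty reference database is required")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  if (is.character(reads) && !is.list(reads)) reads <- list(sample1 = reads)
  ref_ids <- refdb$taxa$id
  use_hamming <- method == "auto"
  counts <- matrix(0L, nrow = length(ref_ids), ncol = length(reads),
                   dimnames = list(ref_ids, names(reads)))
  discarded <- integer(length(reads)); names(discarded) <- names(reads)
  for (j in seq_along(reads)) {
    if (length(reads[[j]]) == 0) next
    hit <- cpp_assign_best(unname(reads[[j]]), unname(refdb$sequences),
                           threshold, match, mismatch, gap, use_hamming)
    tab <- tabulate(hit$ref[hit$ref > 0], nbins = length(ref_ids))
    counts[, j] <- tab
    discarded[j] <- sum(hit$ref == 0)
  }
  habitat <- rep(NA_character_, length(reads))
  out <- structure(list(counts = counts,
                        samples = data.frame(sample_id = names(reads),
                                             habitat = habitat)),
                   class = "count_matrix")
  attr(out, "discarded") <- discarded
  out
}

#' Trim reads to a common length
#'
#' Pass-through utility standing in for the read-preparation trim step:
#' sequences longer than `length` are truncated; shorter ones are dropped.
#'
#' @param reads character vector (or list of vectors) of reads.
#' @param length target length in nt.
#' @export
trim_to_length <- function(reads, length) {
  trim1 <- function(v) {
    v <- v[nchar(v) >= length]
    substr(v, 1, length)
  }
  if (is.list(reads)) lapply(reads, trim1) else trim1(reads)
}
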