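#' Hit-acceptance criteria for taxonomy assignment
#'
#' The three BLASTN-style acceptance criteria used by the study, treated as a
#' conjunction: alignment coverage above `min_coverage` (default 0.98),
#' identity above `min_identity` (default 0.95), and a perfect-identity
#' stretch of at least `min_perfect_run` nucleotides (default 100).
#'
#' @param min_coverage minimum aligned fraction of the shorter sequence.
#' @param min_identity minimum identity in [0, 1].
#' @param min_perfect_run minimum length (nt, >= 1) of the longest run of
#'   consecutive matching columns.
#' @return list of class `hit_criteria`.
#' @export
hit_criteria <- function(min_coverage = 0.98, min_identity = 0.95,
                         min_perfect_run = 100) {
  if (min_coverage < 0 || min_coverage > 1 || min_identity < 0 ||
      min_identity > 1) stop("criteria must lie in [0, 1]")
  if (min_perfect_run < 1) stop("min_perfect_run must be >= 1")
  structure(list(min_coverage = min_coverage, min_identity = min_identity,
                 min_perfect_run = min_perfect_run), class = "hit_criteria")
}

#' Score an OTU centroid against every reference sequence
#'
#' Exhaustive pairwise alignment of the query against the reference set,
#' ranked by identity, then coverage, then reference id — a total order, so
#' ties between identical references resolve deterministically.
#'
#' @param otu_sequence non-empty ACGT string.
#' @param refdb a [ref_db()].
#' @param match,mismatch,gap alignment scores, see [pairwise_identity()].
#' @return data.frame with one row per reference: `ref_id`, `identity`,
#'   `coverage`, `longest_perfect_run`, plus the seven lineage ranks.
#' @export
score_hits <- function(otu_sequence, refdb, match = 1, mismatch = -1,
                       gap = -2) {
  check_seq(otu_sequence)
  if (!inherits(refdb, "ref_db") || nrow(refdb$taxa) == 0)
    stop("a non-empty reference set is required")
  rows <- lapply(refdb$sequences, function(r)
    pairwise_identity(otu_sequence, r, match, mismatch, gap))
  hits <- data.frame(ref_id = refdb$taxa$id,
                     identity = vapply(rows, `[[`, numeric(1), "identity"),
                     coverage = vapply(rows, `[[`, numeric(1), "coverage"),
                     longest_perfect_run = vapply(rows, `[[`, integer(1),
                                                  "longest_perfect_run"))
  hits <- cbind(hits, refdb$taxa[, RANKS])
  ord <- order(-hits$identity, -hits$coverage, hits$ref_id)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Resolve a ranked hit list to a taxonomic assignment
#'
#' Hits failing any acceptance criterion are discarded. If no hit survives,
#' a nearest-neighbour fallback applies: when the best hit still covers the
#' query adequately (coverage at or above the criteria's minimum) and its
#' identity is at least `fallback_identity` (default 0.80), its lineage is
#' assigned, truncated to family at the deepest — only the identity and
#' perfect-run criteria are relaxed, so poorly covered hits remain
#' unassigned. Otherwise the OTU is unassigned. If
#' one hit survives at the top score, its full lineage is assigned; if
#' several tie at the top score — identical (identity, coverage) after
#' rounding to 4 decimals — the lowest common ancestor of their lineages is
#' assigned.
#'
#' @param hits data.frame from [score_hits()] (must retain its ordering).
#' @param criteria a [hit_criteria()].
#' @param fallback_identity identity threshold for the nearest-neighbour
#'   fallback; set to a value > 1 to disable it.
#' @return list of class `taxon_assignment` with `lineage` (character vector
#'   of up to 7 ranks; empty when unassigned), `assigned_rank`,
#'   `best_identity`, `best_coverage`, `best_perfect_run`, `n_ties`.
#' @export
assign_taxonomy <- function(hits, criteria = hit_criteria(),
                            fallback_identity = 0.80) {
  stopifnot(is.data.frame(hits), inherits(criteria, "hit_criteria"))
  pass <- hits$coverage >= criteria$min_coverage &
    hits$identity >= criteria$min_identity &
    hits$longest_perfect_run >= criteria$min_perfect_run
  diag0 <- list(best_identity = hits$identity[1] %||% NA_real_,
                best_coverage = hits$coverage[1] %||% NA_real_,
                best_perfect_run = hits$longest_perfect_run[1] %||% NA_integer_)
  if (!any(pass)) {
    if (nrow(hits) > 0 && hits$identity[1] >= fallback_identity &&
        hits$coverage[1] >= criteria$min_coverage) {
      lin <- unlist(hits[1, RANKS], use.names = FALSE)[1:5]
      return(structure(c(list(lineage = lin, assigned_rank = RANKS[5],
                              n_ties = 1L), diag0),
                       class = "taxon_assignment"))
    }
    return(structure(c(list(lineage = character(0),
                            assigned_rank = "unassigned", n_ties = 0L),
                       diag0), class = "taxon_assignment"))
  }
  ph <- hits[pass, , drop = FALSE]
  key <- paste(round(ph$identity, 4), round(ph$coverage, 4))
  top <- ph[key == key[1], , drop = FALSE]
  lineages <- lapply(seq_len(nrow(top)), function(i)
    unlist(top[i, RANKS], use.names = FALSE))
  lin <- lca(lineages)
  rank <- if (length(lin)) RANKS[length(lin)] else "unassigned"
  structure(list(lineage = lin, assigned_rank = rank,
                 best_identity = ph$identity[1],
                 best_coverage = ph$coverage[1],
                 best_perfect_run = ph$longest_perfect_run[1],
                 n_ties = nrow(top)), class = "taxon_assignment")
}

#' Lowest common ancestor of a set of lineages
#'
#' The longest shared rank prefix — the "lowest common taxonomic
#' denominator" used to resolve tied best hits. Associative and invariant to
#' the input order.
#'
#' @param lineages list of character vectors (each the 7 ranks, or an
#'   already-truncated prefix).
#' @return character vector, possibly empty when even the kingdoms differ.
#' @export
lca <- function(lineages) {
  if (length(lineages) == 0) stop("lca needs at least one lineage")
  ref <- lineages[[1]]
  depth <- length(ref)
  for (l in lineages[-1]) {
    depth <- min(depth, length(l))
    while (depth > 0 && !identical(l[seq_len(depth)], ref[seq_len(depth)]))
      depth <- depth - 1
  }
  ref[seq_len(depth)]
}

#' Assign taxonomy to every OTU of a table
#'
#' Convenience wrapper running [score_hits()] and [assign_taxonomy()] on each
#' OTU centroid.
#'
#' @param table an `otu_table`.
#' @param refdb a [ref_db()].
#' @inheritParams assign_taxonomy
#' @return data.frame with one row per OTU: `otu_id`, `assigned_rank`,
#'   `lineage` (semicolon-delimited), `identity`, `coverage`, `perfect_run`,
#'   `n_ties`.
#' @export
assign_all <- function(table, refdb, criteria = hit_criteria(),
                       fallback_identity = 0.80) {
  stopifnot(inherits(table, "otu_table"))
  rows <- lapply(rownames(table$counts), function(id) {
    a <- assign_taxonomy(score_hits(table$centroids[[id]], refdb), criteria,
                         fallback_identity)
    data.frame(otu_id = id, assigned_rank = a$assigned_rank,
               lineage = paste(a$lineage, collapse = ";"),
               identity = a$best_identity, coverage = a$best_coverage,
               perfect_run = a$best_perfect_run, n_ties = a$n_ties)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(otu_id = character(0), assigned_rank = character(0),
                      lineage = character(0), identity = numeric(0),
                      coverage = numeric(0), perfect_run = integer(0),
                      n_ties = integer(0))
  rownames(out) <- NULL
  out
}

#' Aggregate an OTU table to taxonomic-group composition
#'
#' Read counts are summed per group at the requested rank and divided by
#' per-sample totals; OTUs whose assignment is shallower than the requested
#' rank (including unassigned OTUs) are pooled into an explicit
#' "unassigned" group. Rows (samples) sum to 1 for the fraction output.
#'
#' @param table an `otu_table` or `count_matrix`.
#' @param assignments data.frame from [assign_all()] covering every OTU of
#'   the table.
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @param as "fraction" (rows sum to 1) or "count" (summed reads).
#' @return matrix, samples x groups.
#' @export
aggregate_by_rank <- function(table, assignments, rank = "phylum",
                              as = c("fraction", "count")) {
  as <- match.arg(as)
  if (!rank %in% RANKS)
    stop("rank must be one of: ", paste(RANKS, collapse = ", "))
  m <- if (inherits(table, "otu_table")) table$counts else as_count_matrix(table)
  if (!all(rownames(m) %in% assignments$otu_id))
    stop("every OTU in the table needs an assignment")
  depth <- match(rank, RANKS)
  idx <- match(rownames(m), assignments$otu_id)
  lin <- strsplit(assignments$lineage[idx], ";", fixed = TRUE)
  group <- vapply(lin, function(l)
    if (length(l) >= depth) l[depth] else "unassigned", character(1))
  groups <- sort(unique(group))
  agg <- rowsum(m, group = group, reorder = TRUE)
  out <- t(agg)
  if (as == "fraction") {
    tot <- rowSums(out)
    tot[tot == 0] <- 1
    out <- out / tot
  }
  out[, groups, drop = FALSE]
}
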