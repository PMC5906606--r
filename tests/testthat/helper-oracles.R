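# Independent oracles and small fixture builders used across the suite.

# Brute-force optimal score of an end-gap-free (dovetail) global alignment,
# by exhaustive enumeration of all monotone position matchings. A matching
# scores the sum of its pair scores, plus `gap` for every unpaired residue
# strictly between the first and last pair, plus `gap` for the leading and
# trailing overhang of ONE sequence per end (the other end run rides free,
# as in the alignment's free terminal gaps). The empty matching scores 0.
bf_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(A); lb <- length(B)
  s <- function(i, j) if (A[i] == B[j]) match else mismatch
  best <- 0
  ext <- function(fi, fj, li, lj, k, sum_s) {
    interior <- (li - fi + 1 - k) + (lj - fj + 1 - k)
    lead <- min(fi - 1, fj - 1)
    trail <- min(la - li, lb - lj)
    sc <- sum_s + gap * (interior + lead + trail)
    if (sc > best) best <<- sc
    if (li < la && lj < lb) {
      for (p in (li + 1):la) for (q in (lj + 1):lb) {
        ext(fi, fj, p, q, k + 1, sum_s + s(p, q))
      }
    }
  }
  for (fi in seq_len(la)) for (fj in seq_len(lb)) {
    ext(fi, fj, fi, fj, 1, s(fi, fj))
  }
  best
}

# Holm stepdown from its definition: the i-th smallest adjusted p-value is
# the running maximum over j <= i of min(1, (n - j + 1) * p_(j)).
bf_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    m <- 0
    for (j in seq_len(i)) m <- max(m, min(1, (n - j + 1) * p[o[j]]))
    adj_sorted[i] <- m
  }
  out <- numeric(n)
  out[o] <- adj_sorted
  out
}

# Substitute exactly `k` positions of a sequence (deterministic given seed).
mutate_n <- function(seq, k, seed = 1) {
  set.seed(seed)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

random_seq <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Minimal hand-built reference database.
tiny_refdb <- function() {
  lin <- data.frame(
    id = c("a1", "a2", "b1"),
    kingdom = c("Animalia", "Animalia", "Animalia"),
    phylum = c("Cnidaria", "Cnidaria", "Mollusca"),
    class = c("Hydrozoa", "Hydrozoa", "Gastropoda"),
    order = c("Siphonophorae", "Siphonophorae", "Pteropoda"),
    family = c("Diphyidae", "Diphyidae", "Limacinidae"),
    genus = c("Chelophyes", "Chelophyes", "Limacina"),
    species = c("Chelophyes_appendiculata", "Chelophyes_contorta",
                "Limacina_inflata"))
  base <- random_seq(200, seed = 5)
  seqs <- c(a1 = base, a2 = mutate_n(base, 4, seed = 6),
            b1 = mutate_n(base, 80, seed = 7))
  ref_db(lin, seqs)
}

# Build an otu_table by hand from centroid sequences and a count matrix.
manual_otu_table <- function(centroids, counts) {
  ids <- sprintf("OTU_%04d", seq_along(centroids))
  names(centroids) <- ids
  rownames(counts) <- ids
  structure(list(counts = counts, centroids = centroids), class = "otu_table")
}
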