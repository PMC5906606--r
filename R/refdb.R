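#' Reference databases of marker sequences with ranked lineages
#'
#' A reference database (`ref_db`) couples one marker sequence per leaf taxon
#' with a seven-rank lineage (kingdom, phylum, class, order, family, genus,
#' species). Synthetic databases are built by evolving an ancestral sequence
#' down the lineage tree: every node mutates a fixed fraction of positions of
#' its parent's sequence, with per-rank fractions decreasing towards the tips,
#' so that pairwise identity decays with taxonomic distance. In particular,
#' within-genus identity exceeds cross-phylum identity by construction.
#'
#' @param taxa data.frame with columns `id`, the seven rank columns and
#'   optionally `is_host` (logical).
#' @param sequences named character vector of ACGT sequences, names matching
#'   `taxa$id`.
#' @return An object of class `ref_db` with elements `taxa` (data.frame,
#'   including a `sequence` column) and `sequences` (named character vector).
#' @export
ref_db <- function(taxa, sequences) {
  stopifnot(is.data.frame(taxa), all(c("id", RANKS) %in% names(taxa)))
  if (anyDuplicated(taxa$id)) stop("leaf ids must be unique")
  if (!all(taxa$id %in% names(sequences)))
    stop("every leaf needs a sequence")
  sequences <- sequences[taxa$id]
  if (any(grepl("[^ACGT]", sequences)))
    stop("sequences must use only the ACGT alphabet")
  if (!("is_host" %in% names(taxa))) taxa$is_host <- FALSE
  taxa$sequence <- unname(sequences)
  structure(list(taxa = taxa, sequences = sequences), class = "ref_db")
}

#' @export
print.ref_db <- function(x, ...) {
  cat(sprintf("ref_db: %d leaf taxa, %d phyla, sequence lengths %s nt\n",
              nrow(x$taxa), length(unique(x$taxa$phylum)),
              paste(range(nchar(x$sequences)), collapse = "-")))
  invisible(x)
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute a fraction `d` of positions (distinct, uniformly placed).
mutate_sequence <- function(seq, d) {
  L <- nchar(seq)
  k <- round(d * L)
  if (k == 0) return(seq)
  pos <- sample.int(L, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# Evolve sequences down an arbitrary lineage table: one mutation event per
# lineage node, at the divergence fraction of that node's rank.
sequences_for_lineages <- function(lineages, seq_length, divergence_per_rank) {
  stopifnot(length(divergence_per_rank) == length(RANKS))
  node_seq <- new.env(parent = emptyenv())
  root <- random_sequence(seq_length)
  get_seq <- function(path) {
    key <- paste(path, collapse = ";")
    if (!is.null(node_seq[[key]])) return(node_seq[[key]])
    parent <- if (length(path) == 1L) root
      else get_seq(path[-length(path)])
    s <- mutate_sequence(parent, divergence_per_rank[length(path)])
    node_seq[[key]] <- s
    s
  }
  out <- character(nrow(lineages))
  for (i in seq_len(nrow(lineages))) {
    out[i] <- get_seq(unlist(lineages[i, RANKS], use.names = FALSE))
  }
  names(out) <- lineages$id
  out
}

default_divergence <- function() c(
  kingdom = 0.25, phylum = 0.15, class = 0.08, order = 0.05,
  family = 0.03, genus = 0.02, species = 0.008)

#' Build a synthetic reference database on a regular taxonomy
#'
#' Generates a balanced taxonomy (`n_phyla` phyla, each with
#' `genera_per_phylum` genera of `species_per_genus` species; single
#' intermediate class/order/family nodes per phylum) and evolves one marker
#' sequence per species along the rank tree.
#'
#' @param n_phyla,genera_per_phylum,species_per_genus positive integers.
#' @param seq_length marker length in nucleotides (>= 150).
#' @param divergence_per_rank fraction of positions substituted on the edge
#'   into a node of each rank; must be non-increasing with rank depth.
#' @param seed integer seed; identical seeds give identical databases.
#' @return A [ref_db()].
#' @export
build_reference_db <- function(n_phyla = 3, genera_per_phylum = 3,
                               species_per_genus = 2, seq_length = 300,
                               divergence_per_rank = default_divergence(),
                               seed = 1) {
  if (any(c(n_phyla, genera_per_phylum, species_per_genus) < 1))
    stop("taxon counts must be positive integers")
  if (seq_length < 150) stop("seq_length must be >= 150")
  if (is.unsorted(rev(divergence_per_rank)))
    stop("divergence_per_rank must decrease with rank depth")
  rows <- list(); k <- 0
  for (p in seq_len(n_phyla)) for (g in seq_len(genera_per_phylum))
    for (s in seq_len(species_per_genus)) {
      k <- k + 1
      rows[[k]] <- data.frame(
        id = sprintf("sp%03d", k),
        kingdom = "K1",
        phylum = sprintf("P%02d", p),
        class = sprintf("C%02d", p),
        order = sprintf("O%02d", p),
        family = sprintf("F%02d.%02d", p, g),
        genus = sprintf("G%02d.%02d", p, g),
        species = sprintf("S%02d.%02d.%02d", p, g, s))
    }
  lineages <- do.call(rbind, rows)
  with_seed(seed, {
    seqs <- sequences_for_lineages(lineages, seq_length, divergence_per_rank)
    ref_db(lineages, seqs)
  })
}

#' Lineages of the synthetic study taxonomy
#'
#' A fixed table of 33 leaf taxa mirroring the taxonomic groups reported in
#' gut and marine-snow communities of the Sargasso Sea study system:
#' Hydrozoa (three siphonophores and one trachymedusa), Anthozoa, Crustacea,
#' Actinopterygii (the host *Anguilla anguilla* plus three non-anguillid
#' mesopelagic fishes), fungi, radiolarians, seagrasses, chaetognaths,
#' stramenopiles, dinoflagellates, molluscs, ciliates, tunicates and an
#' entoproct. Crustacea and Tunicata are carried at the phylum slot, as the
#' compositional figures of such studies conventionally group them.
#'
#' @return data.frame with columns `id`, the seven ranks, and `is_host`.
#' @export
study_lineages <- function() {
  lin <- function(id, k, p, c_, o, f, g, s, host = FALSE)
    data.frame(id = id, kingdom = k, phylum = p, class = c_, order = o,
               family = f, genus = g, species = s, is_host = host)
  out <- rbind(
    lin("hyd1", "Animalia", "Cnidaria", "Hydrozoa", "Siphonophorae", "Diphyidae", "Chelophyes", "Chelophyes_appendiculata"),
    lin("hyd2", "Animalia", "Cnidaria", "Hydrozoa", "Siphonophorae", "Diphyidae", "Eudoxoides", "Eudoxoides_mitra"),
    lin("hyd3", "Animalia", "Cnidaria", "Hydrozoa", "Siphonophorae", "Abylidae", "Abylopsis", "Abylopsis_tetragona"),
    lin("hyd4", "Animalia", "Cnidaria", "Hydrozoa", "Trachymedusae", "Rhopalonematidae", "Aglaura", "Aglaura_hemistoma"),
    lin("ant1", "Animalia", "Cnidaria", "Anthozoa", "Actiniaria", "Actiniidae", "Anemonia", "Anemonia_sargassensis"),
    lin("ant2", "Animalia", "Cnidaria", "Anthozoa", "Scleractinia", "Poritidae", "Porites", "Porites_porites"),
    lin("cru1", "Animalia", "Crustacea", "Copepoda", "Calanoida", "Clausocalanidae", "Clausocalanus", "Clausocalanus_furcatus"),
    lin("cru2", "Animalia", "Crustacea", "Copepoda", "Cyclopoida", "Oithonidae", "Oithona", "Oithona_similis"),
    lin("cru3", "Animalia", "Crustacea", "Copepoda", "Harpacticoida", "Ectinosomatidae", "Microsetella", "Microsetella_norvegica"),
    lin("cru4", "Animalia", "Crustacea", "Malacostraca", "Euphausiacea", "Euphausiidae", "Thysanopoda", "Thysanopoda_aequalis"),
    lin("fis0", "Animalia", "Chordata", "Actinopterygii", "Anguilliformes", "Anguillidae", "Anguilla", "Anguilla_anguilla", host = TRUE),
    lin("fis1", "Animalia", "Chordata", "Actinopterygii", "Anguilliformes", "Congridae", "Ariosoma", "Ariosoma_balearicum"),
    lin("fis2", "Animalia", "Chordata", "Actinopterygii", "Myctophiformes", "Myctophidae", "Ceratoscopelus", "Ceratoscopelus_maderensis"),
    lin("fis3", "Animalia", "Chordata", "Actinopterygii", "Stomiiformes", "Gonostomatidae", "Cyclothone", "Cyclothone_braueri"),
    lin("fun1", "Fungi", "Ascomycota", "Saccharomycetes", "Saccharomycetales", "Saccharomycetaceae", "Candida", "Candida_oceani"),
    lin("fun2", "Fungi", "Ascomycota", "Eurotiomycetes", "Eurotiales", "Aspergillaceae", "Aspergillus", "Aspergillus_maritimus"),
    lin("rad1", "Chromista", "Radiolaria", "Polycystina", "Spumellaria", "Spongosphaeridae", "Spongosphaera", "Spongosphaera_streptacantha"),
    lin("rad2", "Chromista", "Radiolaria", "Acantharea", "Chaunacanthida", "Stauracanthidae", "Stauracon", "Stauracon_pallidus"),
    lin("mag1", "Plantae", "Magnoliophyta", "Liliopsida", "Alismatales", "Zosteraceae", "Zostera", "Zostera_marina"),
    lin("mag2", "Plantae", "Magnoliophyta", "Liliopsida", "Alismatales", "Hydrocharitaceae", "Thalassia", "Thalassia_testudinum"),
    lin("cha1", "Animalia", "Chaetognatha", "Sagittoidea", "Aphragmophora", "Sagittidae", "Flaccisagitta", "Flaccisagitta_enflata"),
    lin("cha2", "Animalia", "Chaetognatha", "Sagittoidea", "Aphragmophora", "Krohnittidae", "Krohnitta", "Krohnitta_pacifica"),
    lin("str1", "Chromista", "Ochrophyta", "Phaeophyceae", "Fucales", "Sargassaceae", "Sargassum", "Sargassum_natans"),
    lin("str2", "Chromista", "Ochrophyta", "Bacillariophyceae", "Thalassiosirales", "Thalassiosiraceae", "Thalassiosira", "Thalassiosira_oceanica"),
    lin("din1", "Chromista", "Dinoflagellata", "Dinophyceae", "Gonyaulacales", "Ceratiaceae", "Tripos", "Tripos_furca"),
    lin("din2", "Chromista", "Dinoflagellata", "Dinophyceae", "Prorocentrales", "Prorocentraceae", "Prorocentrum", "Prorocentrum_micans"),
    lin("mol1", "Animalia", "Mollusca", "Gastropoda", "Pteropoda", "Limacinidae", "Limacina", "Limacina_inflata"),
    lin("mol2", "Animalia", "Mollusca", "Gastropoda", "Pteropoda", "Cavoliniidae", "Cavolinia", "Cavolinia_inflexa"),
    lin("cil1", "Chromista", "Ciliophora", "Spirotrichea", "Tintinnida", "Codonellidae", "Tintinnopsis", "Tintinnopsis_beroidea"),
    lin("cil2", "Chromista", "Ciliophora", "Spirotrichea", "Choreotrichida", "Strombidiidae", "Strombidium", "Strombidium_conicum"),
    lin("tha1", "Animalia", "Tunicata", "Thaliacea", "Salpida", "Salpidae", "Salpa", "Salpa_fusiformis"),
    lin("app1", "Animalia", "Tunicata", "Appendicularia", "Copelata", "Oikopleuridae", "Oikopleura", "Oikopleura_dioica"),
    lin("ent1", "Animalia", "Entoprocta", "Entoprocta_incertae", "Coloniales", "Pedicellinidae", "Pedicellina", "Pedicellina_cernua"))
  rownames(out) <- NULL
  out
}

#' Synthetic reference database for the study taxonomy
#'
#' Evolves marker sequences for the fixed lineage set of [study_lineages()].
#' The host (*Anguilla anguilla*) leaf is flagged `is_host` and is excluded
#' from prey-community sampling but used for host-read contamination and the
#' host-similarity OTU filter.
#'
#' @inheritParams build_reference_db
#' @return A [ref_db()].
#' @export
study_reference_db <- function(seq_length = 300,
                               divergence_per_rank = default_divergence(),
                               seed = 1) {
  lineages <- study_lineages()
  with_seed(seed, {
    seqs <- sequences_for_lineages(lineages, seq_length, divergence_per_rank)
    ref_db(lineages, seqs)
  })
}

#' Read and write FASTA, lineage tables and count matrices
#'
#' FASTA I/O is delegated to Biostrings and wrapped at 80 characters per
#' line. Lineage tables are TSV with columns `leaf_id` and a single
#' semicolon-delimited `lineage` of the seven ranks. Count matrices are TSV
#' with sample-id rows and OTU/taxon columns.
#'
#' @param x named character vector of sequences (or for counts, a matrix with
#'   features in rows and samples in columns).
#' @param path file path.
#' @name leptodiet-io
NULL

#' @rdname leptodiet-io
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' @rdname leptodiet-io
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' @rdname leptodiet-io
#' @export
write_lineage_tsv <- function(refdb, path) {
  lin <- apply(refdb$taxa[, RANKS], 1, paste, collapse = ";")
  write.table(data.frame(leaf_id = refdb$taxa$id, lineage = lin),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname leptodiet-io
#' @export
read_lineage_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  parts <- strsplit(tab$lineage, ";", fixed = TRUE)
  if (any(lengths(parts) != length(RANKS)))
    stop("lineages must have exactly 7 ranks")
  lin <- as.data.frame(do.call(rbind, parts))
  names(lin) <- RANKS
  cbind(data.frame(id = tab$leaf_id), lin)
}

#' @rdname leptodiet-io
#' @export
write_counts_tsv <- function(x, path) {
  out <- as.data.frame(t(x))
  out <- cbind(sample_id = rownames(out), out)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname leptodiet-io
#' @export
read_counts_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$sample_id
  storage.mode(m) <- "integer"
  t(m)
}
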