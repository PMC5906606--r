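#' Default end-to-end pipeline configuration
#'
#' All tunable parameters of the simulate-cluster-assign-test-budget
#' pipeline, grouped by stage. The defaults reproduce the study design:
#' 75 gut and 31 snow samples of 10,000 reads, 99% de novo clustering,
#' the <9-reads / host / host-similar-fish OTU filters, 1,000-read sample
#' minimum and 10,000-read cap, the best-hit/LCA assignment criteria, 13
#' plankton stations, and the default foraging scenario.
#'
#' @param seed master seed; stage seeds are derived from it
#'   deterministically.
#' @return list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    refdb = list(seq_length = 300, divergence = default_divergence()),
    community = list(n_gut = 75, n_snow = 31, reads_per_sample = 10000,
                     gut_overdispersion = 1.4, snow_overdispersion = 1.5),
    reads = list(error_rate = 0.005, indel_rate = 0, host_fraction = 0.5,
                 blocking_efficiency = 0.9),
    processing = list(cluster_threshold = 0.99, min_total_reads = 9,
                      host_dissimilarity = 0.02, min_sample_reads = 1000,
                      sample_cap = 10000),
    assignment = list(min_coverage = 0.98, min_identity = 0.95,
                      min_perfect_run = 100, fallback_identity = 0.80),
    stats = list(n_perm = 999),
    larvae = list(n = 75, mean_mm = 15.2, sd_mm = 2.6, min_mm = 9.2,
                  max_mm = 24.7),
    hydrozoa = list(n_stations = 13, mean_integrated_mgC_m2 = 16, cv = 0.6,
                    larval_mean_abundance = 30, larval_cv = 44 / 30),
    regression = list(a = 0.8, b = 3),
    scenario = foraging_scenario(),
    outdir = NULL), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Checks every parameter against its type's invariants and returns the
#' violations as data (an empty character vector means the configuration is
#' valid). Messages name the offending key.
#'
#' @param config a [default_config()]-shaped list.
#' @return character vector of violation messages.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1, "seed: must be a single integer")
  chk(config$refdb$seq_length >= 150, "refdb$seq_length: must be >= 150")
  chk(!is.unsorted(rev(config$refdb$divergence)),
      "refdb$divergence: must decrease with rank depth")
  chk(config$community$n_gut >= 1 && config$community$n_snow >= 1,
      "community$n_gut/n_snow: must be >= 1")
  chk(config$community$reads_per_sample >= 1,
      "community$reads_per_sample: must be >= 1")
  chk(config$community$gut_overdispersion > 0,
      "community$gut_overdispersion: must be > 0")
  chk(config$community$snow_overdispersion > 0,
      "community$snow_overdispersion: must be > 0")
  for (k in c("error_rate", "indel_rate", "host_fraction",
              "blocking_efficiency"))
    chk(config$reads[[k]] >= 0 && config$reads[[k]] <= 1,
        sprintf("reads$%s: must lie in [0, 1]", k))
  chk(config$processing$cluster_threshold > 0 &&
        config$processing$cluster_threshold <= 1,
      "processing$cluster_threshold: must lie in (0, 1]")
  chk(config$processing$min_total_reads >= 1,
      "processing$min_total_reads: must be >= 1")
  chk(config$processing$host_dissimilarity >= 0 &&
        config$processing$host_dissimilarity <= 1,
      "processing$host_dissimilarity: must lie in [0, 1]")
  chk(config$processing$min_sample_reads <= config$processing$sample_cap,
      "processing$min_sample_reads: must not exceed sample_cap")
  chk(config$assignment$min_coverage >= 0 && config$assignment$min_coverage <= 1,
      "assignment$min_coverage: must lie in [0, 1]")
  chk(config$assignment$min_identity >= 0 && config$assignment$min_identity <= 1,
      "assignment$min_identity: must lie in [0, 1]")
  chk(config$assignment$min_perfect_run >= 1,
      "assignment$min_perfect_run: must be >= 1")
  chk(config$stats$n_perm >= 99, "stats$n_perm: must be >= 99")
  chk(config$larvae$n >= 1, "larvae$n: must be >= 1")
  chk(config$larvae$min_mm < config$larvae$max_mm,
      "larvae$min_mm: must be smaller than larvae$max_mm")
  chk(config$larvae$sd_mm >= 0, "larvae$sd_mm: must be >= 0")
  chk(config$hydrozoa$n_stations >= 1, "hydrozoa$n_stations: must be >= 1")
  chk(config$hydrozoa$mean_integrated_mgC_m2 >= 0,
      "hydrozoa$mean_integrated_mgC_m2: must be >= 0")
  chk(config$hydrozoa$cv >= 0, "hydrozoa$cv: must be >= 0")
  chk(config$regression$a > 0 && config$regression$b > 0,
      "regression$a/b: must be positive")
  sc <- config$scenario
  chk(inherits(sc, "foraging_scenario"), "scenario: must be a foraging_scenario")
  if (inherits(sc, "foraging_scenario")) {
    chk(sc$carbon_fraction_dw > 0 && sc$carbon_fraction_dw <= 1,
        "scenario$carbon_fraction_dw: must lie in (0, 1]")
    chk(diff(sc$energy_density_kj_g) >= 0,
        "scenario$energy_density_kj_g: must be ordered")
  }
  v
}

stage_seeds <- function(master, n = 10) {
  with_seed(master, sample.int(.Machine$integer.max, n))
}

log_stage <- function(verbose, stage, ...) {
  if (verbose) {
    kv <- c(...)
    msg <- if (length(kv))
      paste(names(kv), unname(kv), sep = "=", collapse = " ") else ""
    message(sprintf("[%s] %s", stage, msg))
  }
}

#' Run the full pipeline
#'
#' Executes, in order: reference-database simulation, gut and snow community
#' sampling, read emission with host contamination, de novo clustering,
#' sample-depth enforcement, OTU filtering, taxonomy assignment, rank
#' aggregation, the multivariate NB permutation test and PCA, the larval
#' cohort and Hydrozoa-field simulations with biomass integration and the
#' occurrence regression, and the energy budget. Identical configurations
#' (and seeds) give identical results; when `config$outdir` is set, all
#' tabular artifacts and FASTA files are written there.
#'
#' @param config a [default_config()]; invalid configurations abort with the
#'   collected violations.
#' @param verbose emit one structured log line per stage.
#' @return list of class `run_report`; see its `print()` method for the
#'   summary layout.
#' @export
run_pipeline <- function(config = default_config(), verbose = FALSE) {
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "))
  seeds <- stage_seeds(config$seed, 10)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }

  refdb <- study_reference_db(config$refdb$seq_length,
                              config$refdb$divergence, seeds[1])
  host_seq <- refdb$sequences[refdb$taxa$is_host][1]
  log_stage(verbose, "refdb", taxa = nrow(refdb$taxa))
  tick("refdb")

  gut <- sample_counts(gut_profile(config$community$gut_overdispersion),
                       refdb, config$community$n_gut,
                       config$community$reads_per_sample, seeds[2])
  snow <- sample_counts(snow_profile(config$community$snow_overdispersion),
                        refdb, config$community$n_snow,
                        config$community$reads_per_sample, seeds[3])
  meta <- rbind(gut$samples, snow$samples)
  log_stage(verbose, "communities", gut = ncol(gut$counts),
            snow = ncol(snow$counts))
  tick("communities")

  gut_reads <- emit_reads(gut, refdb, config$reads$error_rate,
                          config$reads$indel_rate, config$reads$host_fraction,
                          config$reads$blocking_efficiency, seeds[4])
  snow_reads <- emit_reads(snow, refdb, config$reads$error_rate,
                           config$reads$indel_rate, 0, 1, seeds[5])
  reads <- c(gut_reads, snow_reads)
  n_host <- sum(vapply(reads, function(r) attr(r, "n_host"), integer(1)))
  n_reads <- sum(lengths(reads))
  log_stage(verbose, "reads", total = n_reads, host = n_host)
  tick("reads")

  method <- if (config$reads$indel_rate > 0) "align" else "auto"
  otus <- greedy_cluster(reads, config$processing$cluster_threshold,
                         method = method)
  log_stage(verbose, "cluster", otus = nrow(otus$counts))
  tick("cluster")

  otus <- enforce_sample_depth(otus, config$processing$min_sample_reads,
                               config$processing$sample_cap, seeds[6])
  dropped_samples <- attr(otus, "dropped_samples")
  otus_formed <- nrow(otus$counts)
  kept <- filter_otus(otus, config$processing$min_total_reads, host_seq,
                      config$processing$host_dissimilarity, refdb)
  removed <- attr(kept, "removed")
  log_stage(verbose, "filter", kept = nrow(kept$counts),
            removed = otus_formed - nrow(kept$counts))
  tick("filter")

  crit <- hit_criteria(config$assignment$min_coverage,
                       config$assignment$min_identity,
                       config$assignment$min_perfect_run)
  assignments <- assign_all(kept, refdb, crit,
                            config$assignment$fallback_identity)
  comp_phylum <- aggregate_by_rank(kept, assignments, "phylum")
  counts_phylum <- aggregate_by_rank(kept, assignments, "phylum", as = "count")
  comp_class <- aggregate_by_rank(kept, assignments, "class")
  counts_class <- aggregate_by_rank(kept, assignments, "class", as = "count")
  tick("assign")

  meta <- meta[meta$sample_id %in% colnames(kept$counts), , drop = FALSE]
  grp <- meta$habitat[match(colnames(kept$counts), meta$sample_id)]
  sf <- size_factors(kept, "poscounts")
  test <- mv_nb_test(kept, grp, config$stats$n_perm, seeds[7], sf = sf)
  ord <- count_pca(kept, sf)
  log_stage(verbose, "stats", p_global = test$p_global)
  tick("stats")

  larvae <- draw_larvae(config$larvae$n, config$larvae$mean_mm,
                        config$larvae$sd_mm, config$larvae$min_mm,
                        config$larvae$max_mm,
                        n_stations = config$hydrozoa$n_stations,
                        seed = seeds[8])
  reg <- carbon_regression(config$regression$a, config$regression$b)
  field <- draw_hydrozoa_field(config$hydrozoa$n_stations,
                               mean_integrated_mgC_m2 =
                                 config$hydrozoa$mean_integrated_mgC_m2,
                               cv = config$hydrozoa$cv, regression = reg,
                               seed = seeds[9])
  biomass <- integrate_station(field, reg)
  larval_abund <- with_seed(seeds[10], {
    cv <- config$hydrozoa$larval_cv
    if (cv == 0) rep(config$hydrozoa$larval_mean_abundance,
                     config$hydrozoa$n_stations)
    else rgamma(config$hydrozoa$n_stations, shape = 1 / cv^2,
                scale = config$hydrozoa$larval_mean_abundance * cv^2)
  })
  occ <- occurrence_regression(biomass$biomass_mgC_m2, larval_abund)
  tick("biomass")

  budget <- run_budget(config$scenario)
  tick("energy")

  report <- structure(list(
    config = config,
    refdb = refdb,
    counts = list(gut = gut, snow = snow),
    read_accounting = list(total_reads = n_reads, host_reads = n_host,
                           prey_reads = n_reads - n_host,
                           dropped_samples = dropped_samples),
    otu_accounting = list(formed = otus_formed, kept = nrow(kept$counts),
                          removed = removed),
    otu_table = kept,
    assignments = assignments,
    composition = list(phylum = comp_phylum, phylum_counts = counts_phylum,
                       class = comp_class, class_counts = counts_class),
    sample_meta = meta,
    size_factors = sf,
    test = test,
    ordination = ord,
    larvae = larvae,
    hydrozoa = list(field = field, biomass = biomass,
                    larval_abundance = larval_abund,
                    occurrence = occ),
    budget = budget,
    timings = timings), class = "run_report")
  if (!is.null(config$outdir)) write_artifacts(report, config$outdir)
  report
}

write_artifacts <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(report$refdb$sequences, file.path(outdir, "reference.fasta"))
  write_lineage_tsv(report$refdb, file.path(outdir, "reference_lineages.tsv"))
  write_fasta(report$otu_table$centroids, file.path(outdir, "otu_centroids.fasta"))
  write_counts_tsv(report$otu_table$counts, file.path(outdir, "otu_table.tsv"))
  write.table(report$assignments, file.path(outdir, "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$test$table, file.path(outdir, "test_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(report$size_factors),
                         size_factor = unname(report$size_factors)),
              file.path(outdir, "size_factors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  scores <- data.frame(sample_id = rownames(report$ordination$scores),
                       report$ordination$scores[, 1:min(5,
                         ncol(report$ordination$scores)), drop = FALSE])
  write.table(scores, file.path(outdir, "pca_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$hydrozoa$biomass, file.path(outdir, "station_biomass.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Pooled fraction of a taxonomic group in a habitat
#'
#' Total reads of `group` over total reads, across the samples of one
#' habitat, computed from a count aggregation (so equal-depth samples weigh
#' equally).
#'
#' @param report a `run_report`.
#' @param group group label at the chosen rank.
#' @param habitat "gut" or "snow".
#' @param rank "phylum" or "class".
#' @return fraction in [0, 1].
#' @export
pooled_group_fraction <- function(report, group, habitat = "gut",
                                  rank = "phylum") {
  counts <- report$composition[[paste0(rank, "_counts")]]
  keep <- report$sample_meta$sample_id[report$sample_meta$habitat == habitat]
  counts <- counts[rownames(counts) %in% keep, , drop = FALSE]
  if (!group %in% colnames(counts)) return(0)
  sum(counts[, group]) / sum(counts)
}

#' @export
print.run_report <- function(x, ...) {
  cat("leptodiet pipeline report\n")
  cat(sprintf("  reads: %d total (%d host) across %d samples\n",
              x$read_accounting$total_reads, x$read_accounting$host_reads,
              nrow(x$sample_meta)))
  cat(sprintf("  OTUs: %d formed, %d kept after filters\n",
              x$otu_accounting$formed, x$otu_accounting$kept))
  cat(sprintf("  gut Cnidaria: %.1f%% of reads; snow Crustacea: %.1f%%\n",
              100 * pooled_group_fraction(x, "Cnidaria", "gut"),
              100 * pooled_group_fraction(x, "Crustacea", "snow")))
  cat(sprintf("  gut vs snow NB test: LR = %.1f, p = %.4g\n",
              x$test$global_stat, x$test$p_global))
  cat(sprintf("  Hydrozoa biomass: mean %.1f mg C m-2 over %d stations\n",
              mean(x$hydrozoa$biomass$biomass_mgC_m2),
              nrow(x$hydrozoa$biomass)))
  cat(sprintf("  occurrence regression: R2 = %.2f, p = %.2f, n = %d\n",
              x$hydrozoa$occurrence$r_squared, x$hydrozoa$occurrence$p_value,
              x$hydrozoa$occurrence$n))
  cat(sprintf("  energy budget: %d encounters day-1, demand %.1f J day-1\n",
              as.integer(attr(x$budget$encounters_per_day, "report")),
              x$budget$metabolic_demand_j_day))
  invisible(x)
}
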