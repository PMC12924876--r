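.default_config <- function() {
  list(
    input = list(ped = NULL, map = NULL, genes = NULL, genes_zero_based = FALSE),
    sim = NULL,
    qc = list(maf_min = 0.01, snp_call_rate_min = 0.95,
              ind_call_rate_min = 0.90, autosomes_only = TRUE),
    ld_prune = list(window_kb = 50, step_variants = 10, r2_max = 0.5),
    roh = list(window_snps = 50, max_opposite_in_window = 0,
               max_missing_in_window = 0, prop_threshold = 0.05,
               min_snps = 50, min_length_bp = 1e6, max_gap_bp = 1e6,
               min_density_snp_per_bp = 1e-5),
    hrr = list(window_snps = 15, max_opposite_in_window = 0,
               max_missing_in_window = 0, prop_threshold = 0.05,
               min_snps = 15, min_length_bp = 1e5, max_gap_bp = 1e6,
               min_density_snp_per_bp = 1e-5),
    islands = list(top_fraction = 0.001, min_freq_roh = 0.20,
                   min_freq_hrr = 0.30, min_island_snps = 2),
    genome_length_bp = NULL,
    mds_dimensions = 2,
    output_dir = "runscan-output",
    seed = 1)
}

.merge_config <- function(defaults, raw, path = "") {
  for (key in names(raw)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      .stopf("unknown configuration key '%s'", here)
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]]) &&
        !is.null(raw[[key]])) {
      if (!is.list(raw[[key]]))
        .stopf("configuration key '%s' must be a mapping", here)
      defaults[[key]] <- .merge_config(defaults[[key]], raw[[key]], here)
    } else {
      defaults[[key]] <- raw[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Accepts a nested list or the path of a YAML file, fills every missing
#' field with the package defaults (QC 0.01 / 0.95 / 0.90; ROH
#' 50-SNP window, 0 opposite, 0 missing, 1 Mb gap, 1 Mb minimum length,
#' one SNP per 100 kb, 0.05 proportion threshold; HRR 15-SNP window and
#' 100 kb minimum; islands top 0.1\% with 20\% / 30\% frequency floors),
#' rejects unknown keys, checks ranges, and enforces that exactly one of
#' `input` (PED/MAP paths) or `sim` (a [sim_config()] specification) is
#' present.
#'
#' @param raw nested list, or path to a YAML file.
#' @return validated configuration list of class `pipeline_config`.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1L) {
    if (!file.exists(raw)) .stopf("configuration file not found: %s", raw)
    raw <- yaml::read_yaml(raw)
  }
  if (inherits(raw, "pipeline_config")) return(raw)
  if (!is.list(raw)) .stopf("configuration must be a list or a YAML path")
  defaults <- .default_config()
  ## sim has no defaults to merge field-wise against; take as given
  sim <- raw$sim
  raw$sim <- NULL
  cfg <- .merge_config(defaults, raw)
  cfg$sim <- sim

  has_input <- !is.null(cfg$input$ped) || !is.null(cfg$input$map)
  has_sim <- !is.null(cfg$sim)
  if (has_input && has_sim)
    .stopf("configuration error at 'input'/'sim': supply PED/MAP paths or a simulation, not both")
  if (!has_input && !has_sim)
    .stopf("configuration error: one of 'input' (ped + map) or 'sim' is required")
  if (has_input && (is.null(cfg$input$ped) || is.null(cfg$input$map)))
    .stopf("configuration error at 'input': both 'ped' and 'map' are required")
  if (has_sim && !inherits(cfg$sim, "sim_config")) {
    cfg$sim <- do.call(sim_config, cfg$sim)
  }

  for (fld in c("maf_min", "snp_call_rate_min", "ind_call_rate_min"))
    .assert_fraction(cfg$qc[[fld]], paste0("qc.", fld))
  for (mode in c("roh", "hrr")) {
    pt <- cfg[[mode]]$prop_threshold
    if (!is.numeric(pt) || pt < 0 || pt > 1)
      .stopf("configuration error at '%s.prop_threshold': value %s out of [0, 1]",
             mode, format(pt))
  }
  .assert_fraction(cfg$islands$top_fraction, "islands.top_fraction")
  .assert_fraction(cfg$islands$min_freq_roh, "islands.min_freq_roh")
  .assert_fraction(cfg$islands$min_freq_hrr, "islands.min_freq_hrr")
  if (!is.null(cfg$genome_length_bp) && cfg$genome_length_bp <= 0)
    .stopf("configuration error at 'genome_length_bp': must be > 0")
  structure(cfg, class = c("pipeline_config", "list"))
}

.stage_msg <- function(log, stage, text) {
  line <- sprintf("[%s] %s", stage, text)
  message(line)
  c(log, line)
}

#' Run the full genomic-characterization pipeline
#'
#' Executes, in order: ingest (or simulate), quality control, diversity
#' indices, LD pruning, IBS distances and MDS, ROH detection, HRR
#' detection, per-individual and per-breed summaries, length-class tables,
#' ROH/HRR island calling per breed, cross-breed shared regions, and (when
#' a gene table is supplied) island gene annotation. Every table is written
#' under `cfg$output_dir` together with a machine-readable run manifest;
#' re-running with the same configuration and seed reproduces identical
#' files.
#'
#' @param cfg a [validate_config()] result (or anything it accepts).
#' @return invisibly, a named list of artifact paths (class
#'   `pipeline_artifacts`).
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  log <- character(0)

  ## --- ingest -----------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$sim)) {
    sim <- simulate_dataset(cfg$sim)
    ds <- sim$dataset
    truth <- sim$truth
    art$truth <- file.path(out, "sim_truth.tsv")
    write.table(truth, art$truth, sep = "\t", quote = FALSE, row.names = FALSE)
    log <- .stage_msg(log, "ingest", sprintf(
      "simulated %d samples x %d SNPs (seed %d)", n_samples(ds), n_snps(ds),
      cfg$sim$seed))
  } else {
    if (!file.exists(cfg$input$ped))
      .stopf("ingest stage: PED file not found: %s", cfg$input$ped)
    if (!file.exists(cfg$input$map))
      .stopf("ingest stage: MAP file not found: %s", cfg$input$map)
    ds <- read_plink_text(cfg$input$ped, cfg$input$map)
    log <- .stage_msg(log, "ingest", sprintf("read %d samples x %d SNPs",
                                             n_samples(ds), n_snps(ds)))
  }

  ## --- qc ---------------------------------------------------------------
  qp <- qc_params(cfg$qc$maf_min, cfg$qc$snp_call_rate_min,
                  cfg$qc$ind_call_rate_min, cfg$qc$autosomes_only)
  qc <- apply_qc(ds, qp)
  ds <- qc$dataset
  if (n_snps(ds) == 0L) .stopf("qc stage: empty dataset after quality control")
  art$qc_report <- file.path(out, "qc_report.json")
  qc_json <- unclass(qc$report)
  qc_json$params <- unclass(qc_json$params)
  jsonlite::write_json(qc_json, art$qc_report, auto_unbox = TRUE)
  log <- .stage_msg(log, "qc", sprintf("SNPs %d -> %d, samples %d -> %d",
                                       qc$report$n_snps_in, qc$report$n_snps_out,
                                       qc$report$n_samples_in,
                                       qc$report$n_samples_out))

  ## --- diversity --------------------------------------------------------
  div <- diversity_summary(ds)
  art$diversity <- file.path(out, "diversity.tsv")
  write.table(div, art$diversity, sep = "\t", quote = FALSE, row.names = FALSE)
  log <- .stage_msg(log, "diversity", sprintf("%d breeds", nrow(div)))

  ## --- structure (LD prune -> IBS -> MDS) -------------------------------
  pp <- ld_prune_params(cfg$ld_prune$window_kb, cfg$ld_prune$step_variants,
                        cfg$ld_prune$r2_max)
  kept <- ld_prune(ds, pp)
  art$pruned_snps <- file.path(out, "pruned_snps.txt")
  writeLines(kept, art$pruned_snps)
  ds_pruned <- .subset_dataset(ds, snp_keep = match(kept, ds$snps$snp_id))
  log <- .stage_msg(log, "ld_prune", sprintf("retained %d / %d SNPs",
                                             length(kept), n_snps(ds)))
  D <- ibs_matrix(ds_pruned)
  art$ibs_distance <- file.path(out, "ibs_distance.tsv")
  write_distance_matrix(D, art$ibs_distance)
  k <- min(cfg$mds_dimensions, n_samples(ds) - 1L)
  mds <- classical_mds(D, k)
  mds_df <- data.frame(sample_id = ds$samples$sample_id,
                       breed = ds$samples$breed, mds$points,
                       stringsAsFactors = FALSE)
  art$mds <- file.path(out, "mds.tsv")
  write.table(mds_df, art$mds, sep = "\t", quote = FALSE, row.names = FALSE)
  log <- .stage_msg(log, "mds", sprintf("%d dimensions", k))

  ## --- runs -------------------------------------------------------------
  glen <- cfg$genome_length_bp %||% genome_length_from_snps(ds)
  genes <- NULL
  if (!is.null(cfg$input$genes))
    genes <- read_gene_intervals(cfg$input$genes,
                                 zero_based = isTRUE(cfg$input$genes_zero_based))
  for (mode in c("roh", "hrr")) {
    mp <- cfg[[mode]]
    p <- run_params(if (mode == "roh") "HOM" else "HET",
                    window_snps = mp$window_snps,
                    max_opposite_in_window = mp$max_opposite_in_window,
                    max_missing_in_window = mp$max_missing_in_window,
                    prop_threshold = mp$prop_threshold,
                    min_snps = mp$min_snps, min_length_bp = mp$min_length_bp,
                    max_gap_bp = mp$max_gap_bp,
                    min_density_snp_per_bp = mp$min_density_snp_per_bp)
    rs <- detect_runs(ds, p)
    art[[paste0("runs_", mode)]] <- file.path(out, sprintf("runs_%s.tsv", mode))
    write_runs(rs, art[[paste0("runs_", mode)]])
    ind <- summarize_individuals(rs, glen)
    art[[paste0("individual_", mode)]] <-
      file.path(out, sprintf("individual_summary_%s.tsv", mode))
    write.table(ind, art[[paste0("individual_", mode)]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    brd <- breed_summary(ind)
    art[[paste0("breed_", mode)]] <-
      file.path(out, sprintf("breed_summary_%s.tsv", mode))
    write.table(brd, art[[paste0("breed_", mode)]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    lc <- length_class_histogram(rs)
    art[[paste0("length_classes_", mode)]] <-
      file.path(out, sprintf("length_classes_%s.tsv", mode))
    write.table(lc, art[[paste0("length_classes_", mode)]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    log <- .stage_msg(log, mode, sprintf("%d runs", nrow(rs$runs)))

    ## islands per breed
    min_freq <- if (mode == "roh") cfg$islands$min_freq_roh else
      cfg$islands$min_freq_hrr
    isl <- list()
    for (b in unique(ds$samples$breed)) {
      track <- snp_occurrence(rs, ds, b)
      thr <- occurrence_threshold(track, cfg$islands$top_fraction)
      isl[[b]] <- call_islands(track, thr, min_freq,
                               cfg$islands$min_island_snps)
    }
    islands <- do.call(rbind, isl)
    rownames(islands) <- NULL
    if (!is.null(genes) && nrow(islands)) {
      islands <- annotate_islands(islands, genes)$islands
    }
    art[[paste0("islands_", mode)]] <-
      file.path(out, sprintf("islands_%s.tsv", mode))
    write.table(islands, art[[paste0("islands_", mode)]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    shared <- shared_islands(islands)
    art[[paste0("shared_islands_", mode)]] <-
      file.path(out, sprintf("shared_islands_%s.tsv", mode))
    write.table(shared, art[[paste0("shared_islands_", mode)]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    log <- .stage_msg(log, paste0(mode, "_islands"),
                      sprintf("%d islands, %d shared regions", nrow(islands),
                              nrow(shared)))
    if (!is.null(truth) && nrow(truth)) {
      ## QC legitimately alters the dataset between simulation and
      ## detection, so the strict fingerprint tie does not apply here
      truth_qc <- truth
      attr(truth_qc, "fingerprint") <- NULL
      rec <- evaluate_recovery(truth_qc, rs, islands)
      if (nrow(rec)) {
        art[[paste0("recovery_", mode)]] <-
          file.path(out, sprintf("recovery_%s.tsv", mode))
        write.table(rec, art[[paste0("recovery_", mode)]], sep = "\t",
                    quote = FALSE, row.names = FALSE)
      }
    }
  }

  ## --- manifest ---------------------------------------------------------
  art$log <- file.path(out, "pipeline.log")
  writeLines(log, art$log)
  art$manifest <- file.path(out, "manifest.json")
  manifest <- list(
    config = .config_for_manifest(cfg),
    fingerprint = dataset_fingerprint(ds),
    tool = list(package = "runscan",
                version = as.character(utils::packageVersion("runscan"))))
  jsonlite::write_json(manifest, art$manifest, auto_unbox = TRUE, digits = NA)
  structure(art, class = c("pipeline_artifacts", "list"))
}

.config_for_manifest <- function(cfg) {
  cfg <- unclass(cfg)
  if (!is.null(cfg$sim)) cfg$sim <- unclass(cfg$sim)
  cfg
}
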