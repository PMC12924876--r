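#' Simulation configuration
#'
#' Describes a synthetic SNP-array dataset: breed groups of individuals,
#' chromosomes of SNPs at a given mean spacing, Hardy-Weinberg background
#' genotypes with per-SNP allele frequencies drawn uniformly from a range,
#' optional missingness, and planted homozygous (`"HOM"`) or heterozygous
#' (`"HET"`) tracts carried by a stated fraction of a breed's individuals.
#' The defaults emulate a high-density array design: ~4 kb mean marker
#' spacing and allele frequencies away from fixation.
#'
#' @param seed integer RNG seed; the whole dataset is reproducible from it.
#' @param n_breeds number of breed groups (labelled "B1", "B2", ...).
#' @param n_individuals individuals per breed (scalar or one per breed).
#' @param n_chromosomes number of chromosomes (labelled "1", "2", ...).
#' @param snps_per_chromosome SNPs per chromosome (scalar or one per
#'   chromosome).
#' @param mean_spacing_bp mean inter-SNP spacing in bp (default 4000);
#'   spacings are exponential, rounded to integers >= 1.
#' @param allele_freq_range range allele-1 frequencies are drawn from
#'   (default `c(0.05, 0.95)`).
#' @param missing_rate Bernoulli missingness applied outside planted tracts
#'   (default 0).
#' @param tracts list of tract requests, each a list with elements `breed`,
#'   `chrom`, `start_snp`, `end_snp` (1-based SNP indices within the
#'   chromosome), `carrier_fraction`, `mode` (`"HOM"` or `"HET"`).
#' @param missing_in_tracts also apply missingness inside planted tracts
#'   (default FALSE, so zero-missing window rules cannot fragment planted
#'   runs).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_breeds = 1L, n_individuals = 50L,
                       n_chromosomes = 1L, snps_per_chromosome = 3000L,
                       mean_spacing_bp = 4000, allele_freq_range = c(0.05, 0.95),
                       missing_rate = 0, tracts = list(),
                       missing_in_tracts = FALSE) {
  if (length(n_individuals) == 1L)
    n_individuals <- rep(as.integer(n_individuals), n_breeds)
  if (length(snps_per_chromosome) == 1L)
    snps_per_chromosome <- rep(as.integer(snps_per_chromosome), n_chromosomes)
  stopifnot(length(n_individuals) == n_breeds,
            length(snps_per_chromosome) == n_chromosomes,
            mean_spacing_bp > 0,
            length(allele_freq_range) == 2L,
            allele_freq_range[1L] > 0, allele_freq_range[2L] < 1,
            allele_freq_range[1L] <= allele_freq_range[2L])
  .assert_fraction(missing_rate, "missing_rate")
  for (tr in tracts) {
    need <- c("breed", "chrom", "start_snp", "end_snp", "carrier_fraction",
              "mode")
    if (!all(need %in% names(tr)))
      .stopf("tract request needs fields: %s", paste(need, collapse = ", "))
    .assert_fraction(tr$carrier_fraction, "carrier_fraction")
    ci <- match(as.character(tr$chrom), as.character(seq_len(n_chromosomes)))
    if (is.na(ci)) .stopf("tract chromosome '%s' not in 1..%d", tr$chrom,
                          n_chromosomes)
    if (tr$start_snp < 1L || tr$end_snp > snps_per_chromosome[ci] ||
        tr$start_snp >= tr$end_snp)
      .stopf("tract SNP range [%d, %d] invalid for chromosome %s",
             tr$start_snp, tr$end_snp, tr$chrom)
    if (!tr$mode %in% c("HOM", "HET")) .stopf("tract mode must be HOM or HET")
  }
  structure(list(seed = as.integer(seed), n_breeds = as.integer(n_breeds),
                 n_individuals = n_individuals,
                 n_chromosomes = as.integer(n_chromosomes),
                 snps_per_chromosome = snps_per_chromosome,
                 mean_spacing_bp = mean_spacing_bp,
                 allele_freq_range = allele_freq_range,
                 missing_rate = missing_rate, tracts = tracts,
                 missing_in_tracts = isTRUE(missing_in_tracts)),
            class = "sim_config")
}

#' Simulate a genotype dataset with planted tracts
#'
#' SNP positions are cumulative sums of exponential spacings (rounded to
#' integers, minimum 1 bp). Background genotypes are drawn from
#' Hardy-Weinberg proportions at each SNP's allele frequency, independently
#' across SNPs (no background linkage disequilibrium). For a HOM tract each
#' carrier receives, at every tract SNP, a single allele drawn at the SNP's
#' frequency and doubled (a random homozygote); for a HET tract carriers
#' are set heterozygous. Carriers are drawn without replacement so that the
#' carrier count is `round(carrier_fraction * n_breed)`. Missingness is
#' Bernoulli outside tracts (everywhere when `missing_in_tracts`). Two
#' tracts that overlap in the same individual raise an error.
#'
#' @param cfg a [sim_config()].
#' @return list with `dataset` (a [genotype_dataset()]) and `truth`
#'   (data.frame of planted tracts: `tract_id`, `breed`, `chrom`,
#'   `start_bp`, `end_bp`, `mode`, `carriers` comma-joined, plus SNP index
#'   bounds), carrying the dataset fingerprint as attribute `fingerprint`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  breeds <- paste0("B", seq_len(cfg$n_breeds))
  samples <- data.frame(
    sample_id = unlist(lapply(seq_len(cfg$n_breeds), function(b) {
      sprintf("%s_i%03d", breeds[b], seq_len(cfg$n_individuals[b]))
    })),
    breed = rep(breeds, cfg$n_individuals), stringsAsFactors = FALSE)
  n <- nrow(samples)

  snp_list <- lapply(seq_len(cfg$n_chromosomes), function(ch) {
    m <- cfg$snps_per_chromosome[ch]
    gaps <- pmax(1, round(rexp(m, rate = 1 / cfg$mean_spacing_bp)))
    data.frame(chrom = as.character(ch),
               snp_id = sprintf("c%d_s%05d", ch, seq_len(m)),
               bp = cumsum(gaps), stringsAsFactors = FALSE)
  })
  snps <- do.call(rbind, snp_list)
  m_tot <- nrow(snps)
  p <- runif(m_tot, cfg$allele_freq_range[1L], cfg$allele_freq_range[2L])

  ## HWE background: two allele draws per call; code counts allele-2 copies
  calls <- matrix(
    (runif(n * m_tot) > rep(p, each = n)) + (runif(n * m_tot) > rep(p, each = n)),
    nrow = n, ncol = m_tot)
  storage.mode(calls) <- "integer"

  chrom_offset <- c(0L, cumsum(cfg$snps_per_chromosome))
  tract_cells <- matrix(FALSE, n, m_tot)
  truth <- list()
  for (t in seq_along(cfg$tracts)) {
    tr <- cfg$tracts[[t]]
    ci <- as.integer(tr$chrom)
    cols <- chrom_offset[ci] + tr$start_snp:tr$end_snp
    members <- which(samples$breed == tr$breed)
    if (!length(members)) .stopf("tract breed '%s' has no individuals", tr$breed)
    k <- round(tr$carrier_fraction * length(members))
    carriers <- sort(sample(members, k))
    if (any(tract_cells[carriers, cols]))
      .stopf("planted tracts overlap within one individual")
    for (i in carriers) {
      if (tr$mode == "HOM") {
        a2 <- runif(length(cols)) > p[cols]   # one allele draw, doubled
        calls[i, cols] <- 2L * a2
      } else {
        calls[i, cols] <- 1L
      }
    }
    tract_cells[carriers, cols] <- TRUE
    truth[[t]] <- data.frame(
      tract_id = sprintf("tract%02d", t), breed = tr$breed,
      chrom = as.character(ci), start_bp = snps$bp[cols[1L]],
      end_bp = snps$bp[cols[length(cols)]], mode = tr$mode,
      start_snp = tr$start_snp, end_snp = tr$end_snp,
      carriers = paste(samples$sample_id[carriers], collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(n * m_tot) < cfg$missing_rate, n, m_tot)
    if (!cfg$missing_in_tracts) miss[tract_cells] <- FALSE
    calls[miss] <- NA_integer_
  }

  ds <- genotype_dataset(samples, snps, calls)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(tract_id = character(0), breed = character(0),
               chrom = character(0), start_bp = numeric(0),
               end_bp = numeric(0), mode = character(0),
               start_snp = integer(0), end_snp = integer(0),
               carriers = character(0), stringsAsFactors = FALSE)
  attr(truth, "fingerprint") <- dataset_fingerprint(ds)
  list(dataset = ds, truth = truth)
}

## bp overlap between one interval and a set of runs (union-aware: runs from
## one run_set never overlap within a sample/chromosome)
.runs_overlap_bp <- function(runs, start, end) {
  if (!nrow(runs)) return(0)
  sum(.overlap_bp(runs$start_bp, runs$end_bp, start, end))
}

#' Recovery metrics for planted tracts
#'
#' For each planted tract (of the run set's mode), computes per-carrier
#' Jaccard overlap between the planted interval and the carrier's detected
#' runs on the tract chromosome (in bp, closed intervals), aggregate bp
#' precision (overlap with the tract over all detected bp on that
#' chromosome across the breed's individuals) and recall (overlap over
#' planted bp across carriers), and whether any called island of the
#' tract's breed overlaps the tract.
#'
#' @param truth truth data.frame from [simulate_dataset()] (carries the
#'   dataset fingerprint).
#' @param rs a `run_set` detected on the same dataset.
#' @param islands optional island data.frame from [call_islands()] for the
#'   matching mode.
#' @return data.frame, one row per evaluated tract: `tract_id`, `breed`,
#'   `mode`, `jaccard_mean`, `precision`, `recall`, `island_called`.
#' @export
evaluate_recovery <- function(truth, rs, islands = NULL) {
  stopifnot(inherits(rs, "run_set"))
  fp <- attr(truth, "fingerprint")
  if (!is.null(fp) && !identical(fp, rs$fingerprint))
    .stopf("dataset fingerprint mismatch between truth and run set")
  tt <- truth[truth$mode == rs$params$mode, , drop = FALSE]
  rows <- lapply(seq_len(nrow(tt)), function(t) {
    tr <- tt[t, ]
    carriers <- strsplit(tr$carriers, ",", fixed = TRUE)[[1L]]
    planted_len <- tr$end_bp - tr$start_bp + 1
    members <- rs$samples$sample_id[rs$samples$breed == tr$breed]
    jac <- vapply(carriers, function(id) {
      rr <- rs$runs[rs$runs$sample_id == id & rs$runs$chrom == tr$chrom, ,
                    drop = FALSE]
      det_len <- sum(rr$end_bp - rr$start_bp + 1)
      ov <- .runs_overlap_bp(rr, tr$start_bp, tr$end_bp)
      if (det_len + planted_len - ov == 0) return(0)
      ov / (det_len + planted_len - ov)
    }, numeric(1))
    det_tot <- 0; ov_tot <- 0; ov_carriers <- 0
    for (id in members) {
      rr <- rs$runs[rs$runs$sample_id == id & rs$runs$chrom == tr$chrom, ,
                    drop = FALSE]
      det_tot <- det_tot + sum(rr$end_bp - rr$start_bp + 1)
      ov <- .runs_overlap_bp(rr, tr$start_bp, tr$end_bp)
      ov_tot <- ov_tot + ov
      if (id %in% carriers) ov_carriers <- ov_carriers + ov
    }
    isl <- FALSE
    if (!is.null(islands) && nrow(islands)) {
      sel <- islands$breed == tr$breed & islands$chrom == tr$chrom &
        islands$start_bp <= tr$end_bp & islands$end_bp >= tr$start_bp
      isl <- any(sel)
    }
    data.frame(tract_id = tr$tract_id, breed = tr$breed, mode = tr$mode,
               jaccard_mean = if (length(jac)) mean(jac) else NA_real_,
               precision = if (det_tot > 0) ov_tot / det_tot else NA_real_,
               recall = ov_carriers / (planted_len * max(1, length(carriers))),
               island_called = isl, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tract_id = character(0), breed = character(0),
               mode = character(0), jaccard_mean = numeric(0),
               precision = numeric(0), recall = numeric(0),
               island_called = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to disk
#'
#' Emits PED/MAP via [write_plink_text()], the planted-tract truth table as
#' TSV, and a sidecar JSON recording the seed and dataset fingerprint.
#'
#' @param sim result of [simulate_dataset()].
#' @param cfg the [sim_config()] used.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulated_dataset <- function(sim, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- file.path(dir, "sim.ped"); map <- file.path(dir, "sim.map")
  write_plink_text(sim$dataset, ped, map)
  truth_path <- file.path(dir, "sim_truth.tsv")
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  side <- file.path(dir, "sim_meta.json")
  jsonlite::write_json(list(seed = cfg$seed,
                            fingerprint = attr(sim$truth, "fingerprint")),
                       side, auto_unbox = TRUE)
  invisible(c(ped = ped, map = map, truth = truth_path, meta = side))
}
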