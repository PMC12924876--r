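## small builders shared across test files

make_dataset <- function(calls, bp = NULL, chrom = NULL, breed = NULL,
                         sample_id = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  bp <- bp %||% (seq_len(m) * 1000)
  chrom <- chrom %||% rep("1", m)
  breed <- breed %||% rep("pop", n)
  sample_id <- sample_id %||% sprintf("ind%02d", seq_len(n))
  genotype_dataset(
    samples = data.frame(sample_id = sample_id, breed = breed,
                         stringsAsFactors = FALSE),
    snps = data.frame(chrom = chrom, snp_id = sprintf("snp%04d", seq_len(m)),
                      bp = bp, stringsAsFactors = FALSE),
    calls = calls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fake_run_set <- function(runs, samples, mode = "HOM") {
  if (!"length_bp" %in% names(runs) && nrow(runs))
    runs$length_bp <- runs$end_bp - runs$start_bp
  structure(list(runs = runs, params = run_params(mode), samples = samples,
                 fingerprint = list(n_samples = nrow(samples), n_snps = 0L,
                                    hash = "test")),
            class = "run_set")
}

empty_runs_df <- function() {
  data.frame(sample_id = character(0), breed = character(0),
             chrom = character(0), start_bp = numeric(0),
             end_bp = numeric(0), n_snps = integer(0),
             length_bp = numeric(0), stringsAsFactors = FALSE)
}

make_track <- function(occurrence, bp = NULL, chrom = NULL, breed = "pop") {
  m <- length(occurrence)
  structure(list(
    breed = breed,
    snps = data.frame(chrom = chrom %||% rep("1", m),
                      snp_id = sprintf("snp%04d", seq_len(m)),
                      bp = bp %||% (seq_len(m) * 1000),
                      stringsAsFactors = FALSE),
    occurrence = occurrence), class = "occurrence_track")
}

## flip 0 <-> 2 at SNPs whose first non-missing call is 2, so that the
## first-seen-allele coding of PLINK text round-trips exactly
canonical_polarity <- function(ds) {
  for (j in seq_len(ncol(ds$calls))) {
    g <- ds$calls[, j]
    nm <- g[!is.na(g)]
    if (length(nm) && nm[1L] == 2L) ds$calls[, j] <- 2L - g
  }
  ds
}
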