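#' Quality-control parameters
#'
#' Thresholds for the standard SNP-array cleaning pass: restriction to
#' autosomes, per-SNP call rate, per-individual call rate and minor allele
#' frequency. Call-rate thresholds are exclusive (a SNP/individual is kept
#' only when its call rate is strictly greater), the MAF threshold is
#' inclusive (MAF >= `maf_min` is kept).
#'
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param snp_call_rate_min per-SNP call-rate floor, exclusive (default 0.95).
#' @param ind_call_rate_min per-individual call-rate floor, exclusive
#'   (default 0.90).
#' @param autosomes_only drop unplaced and non-autosomal SNPs first
#'   (default TRUE). Autosomes are chromosome labels that are plain positive
#'   integers.
#' @return object of class `qc_params`.
#' @export
qc_params <- function(maf_min = 0.01, snp_call_rate_min = 0.95,
                      ind_call_rate_min = 0.90, autosomes_only = TRUE) {
  .assert_fraction(maf_min, "maf_min")
  .assert_fraction(snp_call_rate_min, "snp_call_rate_min")
  .assert_fraction(ind_call_rate_min, "ind_call_rate_min")
  structure(list(maf_min = maf_min,
                 snp_call_rate_min = snp_call_rate_min,
                 ind_call_rate_min = ind_call_rate_min,
                 autosomes_only = isTRUE(autosomes_only)),
            class = "qc_params")
}

#' Apply quality control to a genotype dataset
#'
#' Filters are applied in a fixed order so reports are deterministic:
#' (1) drop non-autosomal / unplaced SNPs, (2) drop SNPs with call rate at or
#' below `snp_call_rate_min`, (3) drop individuals with call rate at or below
#' `ind_call_rate_min`, (4) drop SNPs with MAF below `maf_min`, computed on
#' the surviving individuals. Applying the same parameters twice removes
#' nothing the second time.
#'
#' @param ds a [genotype_dataset()].
#' @param p a [qc_params()] object.
#' @return list with elements `dataset` (filtered [genotype_dataset()]) and
#'   `report` (class `qc_report`: in/out counts, removed ids, per-filter
#'   tallies).
#' @export
apply_qc <- function(ds, p = qc_params()) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(p, "qc_params"))
  n_snps_in <- nrow(ds$snps)
  n_samples_in <- nrow(ds$samples)
  tally <- list()

  ## 1. autosomes
  if (p$autosomes_only) {
    keep <- .is_autosome(ds$snps$chrom)
    tally$non_autosomal <- ds$snps$snp_id[!keep]
    ds <- .subset_dataset(ds, snp_keep = which(keep))
  } else tally$non_autosomal <- character(0)

  ## 2. SNP call rate (strict >)
  if (nrow(ds$snps)) {
    cr <- colMeans(!is.na(ds$calls))
    keep <- cr > p$snp_call_rate_min
    tally$snp_call_rate <- ds$snps$snp_id[!keep]
    ds <- .subset_dataset(ds, snp_keep = which(keep))
  } else tally$snp_call_rate <- character(0)

  ## 3. individual call rate (strict >)
  if (nrow(ds$samples) && nrow(ds$snps)) {
    cr <- rowMeans(!is.na(ds$calls))
    keep <- cr > p$ind_call_rate_min
    tally$ind_call_rate <- ds$samples$sample_id[!keep]
    ds <- .subset_dataset(ds, sample_keep = which(keep))
  } else tally$ind_call_rate <- character(0)
  if (nrow(ds$samples) == 0L)
    .stopf("empty dataset: quality control removed every individual")

  ## 4. MAF on surviving individuals (inclusive >=)
  if (nrow(ds$snps)) {
    f <- colMeans(ds$calls, na.rm = TRUE) / 2
    maf <- pmin(f, 1 - f)
    maf[is.nan(maf)] <- 0          # all-missing column
    keep <- maf >= p$maf_min
    tally$maf <- ds$snps$snp_id[!keep]
    ds <- .subset_dataset(ds, snp_keep = which(keep))
  } else tally$maf <- character(0)

  removed_snps <- c(tally$non_autosomal, tally$snp_call_rate, tally$maf)
  report <- structure(list(
    n_snps_in = n_snps_in, n_snps_out = nrow(ds$snps),
    n_samples_in = n_samples_in, n_samples_out = nrow(ds$samples),
    removed_snp_ids = removed_snps,
    removed_sample_ids = tally$ind_call_rate,
    per_filter = lengths(tally),
    params = p), class = "qc_report")
  list(dataset = ds, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: SNPs %d -> %d, samples %d -> %d\n",
              x$n_snps_in, x$n_snps_out, x$n_samples_in, x$n_samples_out))
  for (nm in names(x$per_filter))
    cat(sprintf("  %-15s removed %d\n", nm, x$per_filter[[nm]]))
  invisible(x)
}

#' LD-pruning parameters
#'
#' @param window_kb window width in kilobases measured from the window's
#'   first SNP (default 50). Ignored when `window_snps` is given.
#' @param step_variants number of surviving SNPs the window start advances by
#'   (default 10).
#' @param r2_max pairwise squared-correlation threshold above which one SNP
#'   of a pair is removed (default 0.5).
#' @param window_snps optional window width as a SNP count (the
#'   PLINK-idiomatic alternative to a physical window); when set, each
#'   window holds the start SNP and the next `window_snps - 1` surviving
#'   SNPs.
#' @return object of class `ld_prune_params`.
#' @export
ld_prune_params <- function(window_kb = 50, step_variants = 10, r2_max = 0.5,
                            window_snps = NULL) {
  if (window_kb <= 0) .stopf("'window_kb' must be > 0")
  if (step_variants < 1) .stopf("'step_variants' must be >= 1")
  if (!is.null(window_snps) && window_snps < 2)
    .stopf("'window_snps' must be >= 2")
  .assert_fraction(r2_max, "r2_max")
  structure(list(window_kb = window_kb, step_variants = as.integer(step_variants),
                 r2_max = r2_max,
                 window_snps = if (is.null(window_snps)) NULL else
                   as.integer(window_snps)),
            class = "ld_prune_params")
}

#' Greedy linkage-disequilibrium pruning
#'
#' One greedy pass per chromosome. The current window holds every surviving
#' SNP within `window_kb` of the window's first SNP. For each pair in the
#' window whose squared Pearson correlation of 0/1/2 codes (over
#' pairwise-complete individuals; composite LD, no phasing) exceeds
#' `r2_max`, the member with the lower MAF is removed (on a tie, the one at
#' the larger bp position). The window start then advances by
#' `step_variants` positions among the SNPs still surviving.
#'
#' @param ds a QC'd [genotype_dataset()].
#' @param p an [ld_prune_params()] object.
#' @return character vector of retained snp_ids, in map order.
#' @export
ld_prune <- function(ds, p = ld_prune_params()) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(p, "ld_prune_params"))
  m <- nrow(ds$snps)
  if (m == 0L) return(character(0))
  f <- colMeans(ds$calls, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0
  keep_global <- logical(m)

  for (ch in unique(ds$snps$chrom)) {
    jj <- which(ds$snps$chrom == ch)      # already bp-sorted
    bp <- ds$snps$bp[jj]
    mc <- length(jj)
    alive <- rep(TRUE, mc)
    pos <- 1L                             # rank of window start among survivors
    repeat {
      al <- which(alive)
      if (pos > length(al)) break
      w0 <- al[pos]
      win <- if (is.null(p$window_snps)) {
        al[al >= w0 & bp[al] <= bp[w0] + p$window_kb * 1000]
      } else {
        after <- al[al >= w0]
        after[seq_len(min(p$window_snps, length(after)))]
      }
      if (length(win) >= 2L) {
        for (a in seq_len(length(win) - 1L)) {
          ia <- win[a]
          if (!alive[ia]) next
          for (b in seq((a + 1L), length(win))) {
            ib <- win[b]
            if (!alive[ia]) break
            if (!alive[ib]) next
            r <- suppressWarnings(
              cor(ds$calls[, jj[ia]], ds$calls[, jj[ib]],
                  use = "pairwise.complete.obs"))
            if (!is.na(r) && r * r > p$r2_max) {
              ma <- maf[jj[ia]]; mb <- maf[jj[ib]]
              loser <- if (ma < mb) ia
                       else if (mb < ma) ib
                       else if (bp[ia] > bp[ib]) ia else ib
              alive[loser] <- FALSE
            }
          }
        }
      }
      al2 <- which(alive)
      pos <- sum(al2 <= w0) + p$step_variants
      if (length(al2) == 0L) break
    }
    keep_global[jj[alive]] <- TRUE
  }
  ds$snps$snp_id[keep_global]
}
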