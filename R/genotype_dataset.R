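#' Genotype dataset container
#'
#' Bundles a samples-by-SNPs genotype call matrix with its SNP map and sample
#' (breed) annotation. Calls are coded per SNP as 0 = homozygous for allele 1
#' (the first allele observed in the source file), 1 = heterozygous, 2 =
#' homozygous for allele 2, and `NA` = missing. Downstream analyses only
#' distinguish heterozygous / homozygous / missing states, so the polarity of
#' the 0/2 coding carries no meaning.
#'
#' @param samples data.frame with columns `sample_id` (unique) and `breed`
#'   (non-empty group label), one row per individual in call-matrix row order.
#' @param snps data.frame with columns `chrom` (chromosome label), `snp_id`
#'   (unique) and `bp` (1-based position). Rows are sorted by (chrom, bp) on
#'   construction, and the call matrix columns are reordered to match.
#' @param calls integer matrix, one row per sample and one column per SNP,
#'   entries in `{0, 1, 2, NA}`.
#'
#' @return An object of class `genotype_dataset` with elements `samples`,
#'   `snps` and `calls`.
#' @export
genotype_dataset <- function(samples, snps, calls) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "breed") %in% names(samples)))
    .stopf("'samples' needs columns sample_id, breed")
  if (!all(c("chrom", "snp_id", "bp") %in% names(snps)))
    .stopf("'snps' needs columns chrom, snp_id, bp")
  samples$sample_id <- as.character(samples$sample_id)
  samples$breed <- as.character(samples$breed)
  snps$chrom <- as.character(snps$chrom)
  snps$snp_id <- as.character(snps$snp_id)
  snps$bp <- as.numeric(snps$bp)
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"

  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(snps))
    .stopf("call matrix is %d x %d but %d samples and %d SNPs were given",
           nrow(calls), ncol(calls), nrow(samples), nrow(snps))
  if (anyDuplicated(samples$sample_id))
    .stopf("duplicate sample_id: %s",
           samples$sample_id[duplicated(samples$sample_id)][1L])
  if (anyDuplicated(snps$snp_id))
    .stopf("duplicate snp_id: %s", snps$snp_id[duplicated(snps$snp_id)][1L])
  if (any(!nzchar(samples$breed)) || anyNA(samples$breed))
    .stopf("every sample needs a non-empty breed label")
  if (any(snps$bp < 1) || anyNA(snps$bp))
    .stopf("SNP positions must be 1-based integers >= 1")
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad, na.rm = TRUE)) .stopf("genotype codes must be 0, 1, 2 or NA")

  ord <- .chrom_rank(snps$chrom)
  ord <- ord[order(match(snps$chrom[ord], .chrom_levels(snps$chrom)),
                   snps$bp[ord])]
  snps <- snps[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(snps) <- NULL
  rownames(samples) <- NULL

  by_chr <- split(snps$bp, factor(snps$chrom, levels = unique(snps$chrom)))
  for (ch in names(by_chr)) {
    if (anyDuplicated(by_chr[[ch]]))
      .stopf("duplicate bp position on chromosome %s", ch)
  }

  dimnames(calls) <- list(samples$sample_id, snps$snp_id)
  structure(list(samples = samples, snps = snps, calls = calls),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d SNPs\n",
              nrow(x$samples), nrow(x$snps)))
  cat(sprintf("  breeds: %s\n",
              paste(sprintf("%s (%d)", names(table(x$samples$breed)),
                            as.integer(table(x$samples$breed))),
                    collapse = ", ")))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$snps$chrom), collapse = ", ")))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / SNPs in a genotype dataset
#' @param ds a `genotype_dataset`.
#' @return integer count.
#' @export
n_samples <- function(ds) nrow(ds$samples)

#' @rdname n_samples
#' @export
n_snps <- function(ds) nrow(ds$snps)

#' Dataset fingerprint
#'
#' Cheap deterministic digest of a dataset (dimensions plus a checksum over
#' calls, positions and sample ids), used to tie detected runs and planted
#' ground truth back to the dataset they came from.
#'
#' @param ds a `genotype_dataset`.
#' @return list with `n_samples`, `n_snps`, `hash` (hex string).
#' @export
dataset_fingerprint <- function(ds) {
  x <- ds$calls
  x[is.na(x)] <- 3L
  v <- as.double(x)
  w <- (seq_along(v) - 1) %% 9973 + 1
  h <- sum(v * w) %% 2147483647
  h <- (h * 31 + sum(ds$snps$bp %% 999983)) %% 2147483647
  h <- (h * 31 +
          sum(utf8ToInt(paste(ds$samples$sample_id, collapse = "|")))) %%
    2147483647
  list(n_samples = nrow(ds$samples), n_snps = nrow(ds$snps),
       hash = sprintf("%x", as.integer(h)))
}

## subset helper keeping the invariants intact
.subset_dataset <- function(ds, sample_keep = NULL, snp_keep = NULL) {
  samples <- ds$samples
  snps <- ds$snps
  calls <- ds$calls
  if (!is.null(sample_keep)) {
    samples <- samples[sample_keep, , drop = FALSE]
    calls <- calls[sample_keep, , drop = FALSE]
  }
  if (!is.null(snp_keep)) {
    snps <- snps[snp_keep, , drop = FALSE]
    calls <- calls[, snp_keep, drop = FALSE]
  }
  rownames(samples) <- NULL
  rownames(snps) <- NULL
  structure(list(samples = samples, snps = snps, calls = calls),
            class = "genotype_dataset")
}
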