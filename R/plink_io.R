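#' Read PLINK text genotypes (PED + MAP)
#'
#' Parses the whitespace-separated PLINK text dialect: the MAP file has four
#' columns (chromosome, SNP id, genetic position, bp position) and each PED
#' row has six mandatory columns (family, individual, father, mother, sex,
#' phenotype) followed by two allele columns per SNP. Allele symbols may be
#' A/C/G/T/1/2; `0` denotes a missing allele and a genotype containing `0`
#' is treated as missing. The breed label is taken from the PED family-id
#' column.
#'
#' Genotypes are recoded per SNP against an allele dictionary in which
#' allele 1 is the first non-missing allele encountered reading down the
#' file; more than two distinct alleles at a SNP is an error.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return a [genotype_dataset()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(map_path)) .stopf("MAP file not found: %s", map_path)
  if (!file.exists(ped_path)) .stopf("PED file not found: %s", ped_path)
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "character"))
  if (ncol(map) != 4L) .stopf("MAP file must have 4 columns, found %d", ncol(map))
  snps <- data.frame(chrom = map[[1L]], snp_id = map[[2L]],
                     bp = as.numeric(map[[4L]]), stringsAsFactors = FALSE)
  if (anyDuplicated(snps$snp_id))
    .stopf("duplicate snp_id in MAP: %s",
           snps$snp_id[duplicated(snps$snp_id)][1L])
  m <- nrow(snps)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  want <- 6L + 2L * m
  fields <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(fields)
  if (any(len != want))
    .stopf("PED parse error: line %d has %d fields, expected %d",
           which(len != want)[1L], len[len != want][1L], want)

  fm <- matrix(unlist(fields), nrow = max(n, 0L), ncol = want, byrow = TRUE)
  samples <- data.frame(sample_id = if (n) fm[, 2L] else character(0),
                        breed = if (n) fm[, 1L] else character(0),
                        stringsAsFactors = FALSE)

  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  if (n > 0L && m > 0L) {
    ok_sym <- c("A", "C", "G", "T", "1", "2", "0")
    for (j in seq_len(m)) {
      a1 <- fm[, 5L + 2L * j]
      a2 <- fm[, 6L + 2L * j]
      bad <- !(a1 %in% ok_sym) | !(a2 %in% ok_sym)
      if (any(bad))
        .stopf("PED parse error: invalid allele symbol '%s' at SNP %s (line %d)",
               c(a1[bad], a2[bad])[1L], snps$snp_id[j], which(bad)[1L])
      miss <- a1 == "0" | a2 == "0"
      seen <- as.vector(rbind(a1, a2))        # file scan order
      alleles <- unique(seen[seen != "0"])
      if (length(alleles) > 2L)
        .stopf("SNP %s is not biallelic: alleles %s", snps$snp_id[j],
               paste(alleles, collapse = ", "))
      if (length(alleles) >= 1L) {
        ref <- alleles[1L]
        code <- (a1 != ref) + (a2 != ref)
        code[miss] <- NA_integer_
        calls[, j] <- as.integer(code)
      }
    }
  }
  genotype_dataset(samples, snps, calls)
}

#' Write PLINK text genotypes (PED + MAP)
#'
#' Inverse of [read_plink_text()]. Allele symbols `A` (allele 1) and `B`...
#' strictly, `A`/`G` are used so the files stay within the accepted symbol
#' set; genotype codes 0/1/2/NA are written as `A A`, `A G`, `G G`, `0 0`.
#' Re-reading recovers the same codes whenever the first non-missing call at
#' every SNP is 0 or 1 (which holds for any dataset produced by
#' [read_plink_text()]); at a SNP whose first non-missing call is 2 the
#' first-seen-allele rule flips the 0/2 polarity on re-read, which no
#' downstream analysis observes.
#'
#' @param ds a [genotype_dataset()].
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_plink_text <- function(ds, ped_path, map_path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  map <- paste(ds$snps$chrom, ds$snps$snp_id, 0, .fmt_bp(ds$snps$bp),
               sep = "\t")
  tryCatch({
    writeLines(map, map_path)
  }, error = function(e) .stopf("cannot write MAP file %s: %s",
                                map_path, conditionMessage(e)))
  geno_str <- c("A A", "A G", "G G")
  n <- nrow(ds$samples)
  rows <- character(n)
  for (i in seq_len(n)) {
    g <- ds$calls[i, ]
    gs <- ifelse(is.na(g), "0 0", geno_str[g + 1L])
    rows[i] <- paste(c(ds$samples$breed[i], ds$samples$sample_id[i],
                       "0", "0", "0", "-9", gs), collapse = "\t")
  }
  tryCatch({
    writeLines(rows, ped_path)
  }, error = function(e) .stopf("cannot write PED file %s: %s",
                                ped_path, conditionMessage(e)))
  invisible(c(ped = ped_path, map = map_path))
}
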