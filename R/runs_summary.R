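#' SNP-covered genome length of a dataset
#'
#' Sum over chromosomes of (last SNP bp - first SNP bp): the denominator
#' used for the genomic inbreeding coefficient F_ROH and the diversity
#' degree D_HRR. An override constant (e.g. `2.4e9` for the SNP-covered
#' sheep autosomal genome) can be passed directly to
#' [summarize_individuals()] instead.
#'
#' @param ds a [genotype_dataset()].
#' @return numeric, total covered length in bp.
#' @export
genome_length_from_snps <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  sum(vapply(split(ds$snps$bp,
                   factor(ds$snps$chrom, levels = unique(ds$snps$chrom))),
             function(x) max(x) - min(x), numeric(1)))
}

#' Per-individual run statistics
#'
#' For every genotyped individual (including those with zero runs) returns
#' the run count `N`, the mean run length `L_mean_mb` (Mb; 0 when `N` is 0),
#' the total run length `S_sum_mb` (Mb), and the genome fraction
#' `F = S / genome_length` — the genomic inbreeding coefficient F_ROH in
#' HOM mode, the diversity degree D_HRR in HET mode.
#'
#' @param rs a `run_set` from [detect_runs()].
#' @param genome_length_bp denominator for `F`; pass
#'   [genome_length_from_snps()] of the source dataset, or a constant such
#'   as `2.4e9` when mirroring a published SNP-covered genome length.
#' @return data.frame: `sample_id`, `breed`, `N`, `L_mean_mb`, `S_sum_mb`,
#'   `F`.
#' @export
summarize_individuals <- function(rs, genome_length_bp) {
  stopifnot(inherits(rs, "run_set"))
  if (!is.numeric(genome_length_bp) || genome_length_bp <= 0)
    .stopf("'genome_length_bp' must be > 0")
  ids <- rs$samples$sample_id
  agg_n <- tapply(rs$runs$length_bp, factor(rs$runs$sample_id, levels = ids),
                  length)
  agg_s <- tapply(rs$runs$length_bp, factor(rs$runs$sample_id, levels = ids),
                  sum)
  N <- as.integer(ifelse(is.na(agg_n), 0L, agg_n))
  S <- as.numeric(ifelse(is.na(agg_s), 0, agg_s))
  data.frame(sample_id = ids, breed = rs$samples$breed, N = N,
             L_mean_mb = ifelse(N > 0, S / N / 1e6, 0),
             S_sum_mb = S / 1e6,
             F = S / genome_length_bp, stringsAsFactors = FALSE)
}

#' Per-breed run statistics
#'
#' Aggregates [summarize_individuals()] output into the per-breed table:
#' number of individuals, total runs, and mean with sample standard
#' deviation (n - 1 denominator) of N, L, S and F over individuals. By
#' default individuals with zero runs contribute to every mean; set
#' `zero_runs = "exclude"` to average N/L/S/F over individuals that carry at
#' least one run (total counts are unaffected).
#'
#' @param summaries data.frame from [summarize_individuals()].
#' @param zero_runs `"include"` (default) or `"exclude"`.
#' @return data.frame, one row per breed: `breed`, `n_individuals`,
#'   `total_runs`, `N_mean`, `N_sd`, `L_mean`, `L_sd`, `S_mean`, `S_sd`,
#'   `F_mean`, `F_sd`.
#' @export
breed_summary <- function(summaries, zero_runs = c("include", "exclude")) {
  zero_runs <- match.arg(zero_runs)
  stopifnot(all(c("breed", "N", "L_mean_mb", "S_sum_mb", "F") %in%
                  names(summaries)))
  rows <- lapply(split(summaries, summaries$breed), function(d) {
    total <- sum(d$N)
    u <- if (zero_runs == "exclude") d[d$N > 0, , drop = FALSE] else d
    data.frame(breed = d$breed[1L], n_individuals = nrow(d),
               total_runs = total,
               N_mean = mean(u$N), N_sd = sd(u$N),
               L_mean = mean(u$L_mean_mb), L_sd = sd(u$L_mean_mb),
               S_mean = mean(u$S_sum_mb), S_sd = sd(u$S_sum_mb),
               F_mean = mean(u$F), F_sd = sd(u$F),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.length_class <- function(length_bp, mode) {
  if (mode == "HOM") {
    labs <- c("1-2 Mb", "2-4 Mb", "4-8 Mb", "8-16 Mb", ">16 Mb")
    cut(length_bp, breaks = c(1, 2, 4, 8, 16, Inf) * 1e6, right = FALSE,
        labels = labs)
  } else {
    labs <- c("<150 kb", "150-200 kb", "200-300 kb", "300-400 kb", ">400 kb")
    cut(length_bp, breaks = c(0, 150, 200, 300, 400, Inf) * 1e3,
        right = FALSE, labels = labs)
  }
}

#' Run counts by length class
#'
#' Places every run into one of five right-open length classes and counts
#' them per breed and chromosome. ROH classes: [1,2), [2,4), [4,8), [8,16),
#' [16,Inf) Mb. HRR classes: (0,150), [150,200), [200,300), [300,400),
#' [400,Inf) kb. A ROH shorter than 1 Mb violates the detection invariants
#' and raises an error.
#'
#' @param rs a `run_set`.
#' @return data.frame: `breed`, `chrom`, `class`, `count`, including zero
#'   counts for unobserved classes of observed breed-chromosome pairs.
#' @export
length_class_histogram <- function(rs) {
  stopifnot(inherits(rs, "run_set"))
  mode <- rs$params$mode
  r <- rs$runs
  if (mode == "HOM" && nrow(r) && any(r$length_bp < 1e6))
    .stopf("internal consistency error: ROH shorter than 1 Mb in run set")
  if (!nrow(r))
    return(data.frame(breed = character(0), chrom = character(0),
                      class = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  cls <- .length_class(r$length_bp, mode)
  tab <- as.data.frame(table(breed = r$breed, chrom = r$chrom, class = cls),
                       stringsAsFactors = FALSE)
  names(tab)[4L] <- "count"
  tab$count <- as.integer(tab$count)
  tab <- tab[order(tab$breed, match(tab$chrom, unique(rs$runs$chrom)),
                   match(tab$class, levels(cls))), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
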