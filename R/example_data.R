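#' Bundled example island tables
#'
#' ROH and HRR island tables for four Mediterranean sheep breeds
#' (Barbaresca "BAR", Noticiana "NOT", Sarda "SAR", Valle del Belice "VDB")
#' genotyped on a 600K ovine array: per island the chromosome, bp
#' coordinates, SNP count, mean fixation percentage, and annotated genes
#' (semicolon-joined; "-" marks islands without genes). Useful for
#' exercising the interval arithmetic, shared-region detection and gene
#' counting without running a full detection pass.
#'
#' @param mode `"HOM"` for the ROH island table (12 islands), `"HET"` for
#'   the HRR island table (16 islands).
#' @return data.frame: `breed`, `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `fix_pct`, `genes`.
#' @export
example_island_table <- function(mode = c("HOM", "HET")) {
  mode <- match.arg(mode)
  f <- if (mode == "HOM") "sheep_roh_islands.tsv" else "sheep_hrr_islands.tsv"
  path <- system.file("extdata", f, package = "runscan", mustWork = TRUE)
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "numeric",
                                 "numeric", "integer", "numeric",
                                 "character"))
  d$length_bp <- d$end_bp - d$start_bp
  d
}
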