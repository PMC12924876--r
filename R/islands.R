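#' Per-SNP run-occurrence track for one breed
#'
#' For every SNP of the dataset, the fraction of the breed's genotyped
#' individuals whose detected runs cover the SNP (a run covers a SNP when
#' `start_bp <= bp <= end_bp` on the same chromosome). The denominator is
#' all genotyped individuals of the breed, whether or not they carry runs.
#'
#' @param rs a `run_set` from [detect_runs()].
#' @param ds the [genotype_dataset()] the runs came from (shares the map).
#' @param breed breed label to profile.
#' @return object of class `occurrence_track`: `breed`, `snps` (map
#'   data.frame) and `occurrence` (numeric vector in `[0, 1]`, one value per
#'   SNP).
#' @export
snp_occurrence <- function(rs, ds, breed) {
  stopifnot(inherits(rs, "run_set"), inherits(ds, "genotype_dataset"))
  members <- ds$samples$sample_id[ds$samples$breed == breed]
  if (!length(members)) .stopf("unknown breed '%s'", breed)
  m <- nrow(ds$snps)
  counts <- integer(m)
  runs <- rs$runs[rs$runs$breed == breed, , drop = FALSE]
  chrom_of <- ds$snps$chrom
  bp <- ds$snps$bp
  for (id in members) {
    rr <- runs[runs$sample_id == id, , drop = FALSE]
    if (!nrow(rr)) next
    covered <- logical(m)
    for (k in seq_len(nrow(rr))) {
      sel <- chrom_of == rr$chrom[k] & bp >= rr$start_bp[k] &
        bp <= rr$end_bp[k]
      covered[sel] <- TRUE
    }
    counts <- counts + covered
  }
  structure(list(breed = breed, snps = ds$snps,
                 occurrence = counts / length(members)),
            class = "occurrence_track")
}

#' Top-fraction occurrence threshold (nearest rank)
#'
#' The island-calling threshold is the occurrence value of the k-th largest
#' SNP, with `k = ceiling(top_fraction * n_snps)` (nearest-rank upper
#' quantile). SNPs tied with the k-th value are admitted by the comparison
#' in [call_islands()], which is inclusive at the threshold.
#'
#' @param track an `occurrence_track` from [snp_occurrence()].
#' @param top_fraction fraction of SNPs to admit (default 0.001, i.e. the
#'   top 0.1\%).
#' @return the threshold occurrence fraction.
#' @export
occurrence_threshold <- function(track, top_fraction = 0.001) {
  stopifnot(inherits(track, "occurrence_track"))
  occ <- track$occurrence
  if (!length(occ)) .stopf("empty occurrence track")
  .assert_fraction(top_fraction, "top_fraction")
  k <- max(1L, as.integer(ceiling(top_fraction * length(occ))))
  sort(occ, decreasing = TRUE)[k]
}

#' Call ROH/HRR islands from an occurrence track
#'
#' Qualifying SNPs have occurrence at or above the rank threshold
#' (inclusive) and strictly above the `min_freq` floor (0.20 for ROH
#' islands, 0.30 for HRR islands). Islands are maximal stretches of
#' map-consecutive qualifying SNPs on one chromosome holding at least
#' `min_island_snps` SNPs; each reports its mean occurrence as a fixation
#' percentage and its span `end_bp - start_bp`.
#'
#' @param track an `occurrence_track` from [snp_occurrence()].
#' @param threshold rank threshold, typically [occurrence_threshold()].
#' @param min_freq strict occurrence floor (default 0.20).
#' @param min_island_snps minimum SNPs per island (default 2).
#' @return data.frame: `breed`, `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `fix_pct`, `length_bp`.
#' @export
call_islands <- function(track, threshold, min_freq = 0.20,
                         min_island_snps = 2L) {
  stopifnot(inherits(track, "occurrence_track"))
  occ <- track$occurrence
  qual <- occ >= threshold & occ > min_freq
  empty <- data.frame(breed = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), fix_pct = numeric(0),
                      length_bp = numeric(0), stringsAsFactors = FALSE)
  if (!any(qual)) return(empty)
  chrom <- track$snps$chrom
  bp <- track$snps$bp
  ## break stretches at chromosome boundaries
  grp <- cumsum(c(TRUE, chrom[-1L] != chrom[-length(chrom)]))
  r <- rle(qual & TRUE)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (s in which(r$values)) {
    a <- starts[s]; b <- ends[s]
    ## split by chromosome group
    for (g in unique(grp[a:b])) {
      ii <- (a:b)[grp[a:b] == g]
      if (length(ii) < min_island_snps) next
      out[[length(out) + 1L]] <- data.frame(
        breed = track$breed, chrom = chrom[ii[1L]],
        start_bp = bp[ii[1L]], end_bp = bp[ii[length(ii)]],
        n_snps = length(ii), fix_pct = 100 * mean(occ[ii]),
        length_bp = bp[ii[length(ii)]] - bp[ii[1L]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## union of 1-based closed intervals given as a 2-column matrix
.merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    last <- nrow(out)
    if (iv[i, 1L] <= out[last, 2L]) {
      out[last, 2L] <- max(out[last, 2L], iv[i, 2L])
    } else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out
}

## intersection of two interval unions (closed, >= 1 shared bp)
.intersect_intervals <- function(a, b) {
  res <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    s <- max(a[i, 1L], b[j, 1L]); e <- min(a[i, 2L], b[j, 2L])
    if (s <= e) res <- rbind(res, c(s, e))
  }
  .merge_intervals(res)
}

#' Cross-breed shared island regions
#'
#' Finds, on each chromosome, every maximal set of two or more breeds whose
#' islands share at least one bp, and reports the intersection interval.
#' Islands are first grouped into connected components of mutually
#' overlapping intervals; within a component, breed subsets that are
#' contained in a larger qualifying subset are not reported separately.
#'
#' @param islands data.frame of islands from [call_islands()] (rows from
#'   several breeds combined), needing columns `breed`, `chrom`,
#'   `start_bp`, `end_bp`.
#' @return data.frame: `chrom`, `start_bp`, `end_bp`, `n_breeds`, `breeds`
#'   (comma-joined, alphabetical).
#' @export
shared_islands <- function(islands) {
  stopifnot(all(c("breed", "chrom", "start_bp", "end_bp") %in%
                  names(islands)))
  empty <- data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_breeds = integer(0),
                      breeds = character(0), stringsAsFactors = FALSE)
  if (length(unique(islands$breed)) < 2L) return(empty)
  out <- list()
  for (ch in unique(islands$chrom)) {
    d <- islands[islands$chrom == ch, , drop = FALSE]
    if (nrow(d) < 2L) next
    d <- d[order(d$start_bp, d$end_bp), , drop = FALSE]
    ## connected components of overlapping intervals (sweep)
    comp <- integer(nrow(d))
    comp[1L] <- 1L
    reach <- d$end_bp[1L]
    for (i in seq_len(nrow(d))[-1L]) {
      if (d$start_bp[i] <= reach) comp[i] <- comp[i - 1L]
      else comp[i] <- comp[i - 1L] + 1L
      reach <- max(reach, d$end_bp[i])
    }
    for (cp in unique(comp)) {
      dc <- d[comp == cp, , drop = FALSE]
      breeds <- sort(unique(dc$breed))
      if (length(breeds) < 2L) next
      cover <- lapply(breeds, function(b) {
        .merge_intervals(as.matrix(dc[dc$breed == b,
                                      c("start_bp", "end_bp")]))
      })
      names(cover) <- breeds
      kept <- list()
      for (size in seq(length(breeds), 2L)) {
        subsets <- combn(breeds, size, simplify = FALSE)
        for (ss in subsets) {
          if (any(vapply(kept, function(k) all(ss %in% k), logical(1))))
            next  # subset of an already-reported larger set
          common <- cover[[ss[1L]]]
          for (b in ss[-1L]) common <- .intersect_intervals(common,
                                                            cover[[b]])
          if (nrow(common)) {
            kept[[length(kept) + 1L]] <- ss
            for (r in seq_len(nrow(common)))
              out[[length(out) + 1L]] <- data.frame(
                chrom = ch, start_bp = common[r, 1L],
                end_bp = common[r, 2L], n_breeds = length(ss),
                breeds = paste(ss, collapse = ","),
                stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, unique(islands$chrom)), res$start_bp), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a gene-interval table
#'
#' Tab-separated table with columns chrom, start, end, gene name. Declared
#' 1-based inclusive by default; set `zero_based = TRUE` for true BED input
#' (0-based half-open), which is converted by adding 1 to the start.
#'
#' @param path input TSV path.
#' @param zero_based input is 0-based half-open BED (default FALSE).
#' @param header does the file carry a header row (default TRUE).
#' @return data.frame: `chrom`, `start_bp`, `end_bp`, `gene_name`.
#' @export
read_gene_intervals <- function(path, zero_based = FALSE, header = TRUE) {
  g <- read.table(path, header = header, sep = "\t",
                  stringsAsFactors = FALSE,
                  col.names = c("chrom", "start_bp", "end_bp", "gene_name"))
  g$chrom <- as.character(g$chrom)
  if (zero_based) g$start_bp <- g$start_bp + 1
  if (any(g$end_bp < g$start_bp)) .stopf("gene interval with end < start")
  g
}

#' Annotate islands with overlapping genes
#'
#' A gene is assigned to an island when their (1-based, closed) intervals
#' share at least one bp; per-island gene lists are ordered by gene start.
#'
#' @param islands data.frame from [call_islands()].
#' @param genes data.frame from [read_gene_intervals()].
#' @return object of class `island_gene_report`: `islands` (input plus a
#'   `genes` column, semicolon-joined), `gene_lists` (list of character
#'   vectors), `total` and `unique` gene counts.
#' @export
annotate_islands <- function(islands, genes) {
  stopifnot(all(c("chrom", "start_bp", "end_bp") %in% names(islands)),
            all(c("chrom", "start_bp", "end_bp", "gene_name") %in%
                  names(genes)))
  lists <- lapply(seq_len(nrow(islands)), function(i) {
    sel <- genes$chrom == islands$chrom[i] &
      genes$start_bp <= islands$end_bp[i] &
      genes$end_bp >= islands$start_bp[i]
    g <- genes[sel, , drop = FALSE]
    g$gene_name[order(g$start_bp)]
  })
  islands$genes <- vapply(lists, paste, character(1), collapse = ";")
  structure(list(islands = islands, gene_lists = lists,
                 total = sum(lengths(lists)),
                 unique = length(unique(unlist(lists)))),
            class = "island_gene_report")
}

#' Count genes across island gene lists
#'
#' `total` is the summed length of the per-island gene lists (islands with
#' no genes contribute zero); `unique` counts distinct gene names across
#' all lists. Accepts an `island_gene_report`, a list of character vectors,
#' or a data.frame with a semicolon-joined `genes` column.
#'
#' @param report gene lists in one of the accepted forms.
#' @return list with elements `total` and `unique`.
#' @export
count_genes <- function(report) {
  lists <- if (inherits(report, "island_gene_report")) report$gene_lists
  else if (is.data.frame(report)) {
    if (!"genes" %in% names(report)) .stopf("data.frame needs a 'genes' column")
    lapply(strsplit(report$genes, ";", fixed = TRUE),
           function(x) x[nzchar(x) & x != "-"])
  } else if (is.list(report)) report
  else .stopf("unsupported input to count_genes()")
  list(total = sum(lengths(lists)),
       unique = length(unique(unlist(lists))))
}
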