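#' Sliding-window run-detection parameters
#'
#' Configuration for detecting runs of homozygosity (`mode = "HOM"`) or
#' heterozygosity-rich regions (`mode = "HET"`). The defaults are the
#' high-density-array settings used throughout the package: a 50-SNP window,
#' at least 50 SNPs and 1 Mb for a ROH (15 SNPs / 100 kb window and minima
#' for an HRR), no opposite and no missing genotypes allowed inside a
#' window, a maximum gap of 1 Mb between consecutive SNPs, a minimum density
#' of one SNP per 100 kb, and a 0.05 proportion threshold for classifying a
#' SNP as in-run. "Opposite" genotypes are heterozygotes in HOM mode and
#' homozygotes in HET mode.
#'
#' @param mode `"HOM"` (ROH) or `"HET"` (HRR).
#' @param window_snps sliding-window width in SNPs (HOM 50, HET 15).
#' @param max_opposite_in_window maximum opposite genotypes per window (0).
#' @param max_missing_in_window maximum missing genotypes per window (0).
#' @param prop_threshold a SNP is flagged in-run when the fraction of
#'   passing windows containing it strictly exceeds this value (0.05).
#' @param min_snps minimum SNPs per run (HOM 50, HET 15).
#' @param min_length_bp minimum run span, end - start (HOM 1e6, HET 1e5).
#' @param max_gap_bp maximum gap between consecutive run SNPs (1e6).
#' @param min_density_snp_per_bp minimum SNP density, count per bp of span
#'   (1 / 1e5).
#' @return object of class `run_params`.
#' @export
run_params <- function(mode = c("HOM", "HET"),
                       window_snps = NULL,
                       max_opposite_in_window = 0L,
                       max_missing_in_window = 0L,
                       prop_threshold = 0.05,
                       min_snps = NULL,
                       min_length_bp = NULL,
                       max_gap_bp = 1e6,
                       min_density_snp_per_bp = 1 / 1e5) {
  mode <- match.arg(mode)
  window_snps <- as.integer(window_snps %||% if (mode == "HOM") 50L else 15L)
  min_snps <- as.integer(min_snps %||% if (mode == "HOM") 50L else 15L)
  min_length_bp <- min_length_bp %||% if (mode == "HOM") 1e6 else 1e5
  if (window_snps < 2L) .stopf("'window_snps' must be >= 2")
  if (max_opposite_in_window < 0L || max_missing_in_window < 0L)
    .stopf("window tolerance counts must be non-negative")
  if (min_length_bp <= 0) .stopf("'min_length_bp' must be > 0")
  if (max_gap_bp <= 0) .stopf("'max_gap_bp' must be > 0")
  if (min_density_snp_per_bp < 0) .stopf("'min_density_snp_per_bp' must be >= 0")
  .assert_fraction(prop_threshold, "prop_threshold")
  structure(list(mode = mode, window_snps = window_snps,
                 max_opposite_in_window = as.integer(max_opposite_in_window),
                 max_missing_in_window = as.integer(max_missing_in_window),
                 prop_threshold = prop_threshold, min_snps = min_snps,
                 min_length_bp = min_length_bp, max_gap_bp = max_gap_bp,
                 min_density_snp_per_bp = min_density_snp_per_bp),
            class = "run_params")
}

#' @rdname run_params
#' @param ... arguments passed on to [run_params()].
#' @export
roh_params <- function(...) run_params("HOM", ...)

#' @rdname run_params
#' @export
hrr_params <- function(...) run_params("HET", ...)

.opposite <- function(calls, mode) {
  if (mode == "HOM") !is.na(calls) & calls == 1L
  else !is.na(calls) & calls != 1L
}

#' Window pass flags for one sample-chromosome call vector
#'
#' Slides a `window_snps`-wide window one SNP at a time over the call vector
#' (windows are index ranges `[i, i + w - 1]`; none if the vector is shorter
#' than the window). A window passes when its count of opposite genotypes is
#' at most `max_opposite_in_window` and its count of missing genotypes is at
#' most `max_missing_in_window`.
#'
#' @param calls integer vector of genotype codes 0/1/2/NA for one individual
#'   on one chromosome, in map order.
#' @param p a [run_params()] object.
#' @return logical vector of length `max(0, m - w + 1)`.
#' @export
window_flags <- function(calls, p) {
  stopifnot(inherits(p, "run_params"))
  m <- length(calls)
  w <- p$window_snps
  if (m < w) return(logical(0))
  opp <- .opposite(calls, p$mode)
  mis <- is.na(calls)
  co <- cumsum(opp)
  cm <- cumsum(mis)
  i <- seq_len(m - w + 1L)
  n_opp <- co[i + w - 1L] - c(0, co)[i]
  n_mis <- cm[i + w - 1L] - c(0, cm)[i]
  n_opp <= p$max_opposite_in_window & n_mis <= p$max_missing_in_window
}

#' Per-SNP proportion of passing windows
#'
#' For SNP `j` of `m`, the windows fully containing it are those starting in
#' `[max(1, j - w + 1), min(j, m - w + 1)]`; the proportion is the fraction
#' of those windows that pass. If the chromosome is shorter than the window
#' all proportions are zero.
#'
#' @param flags logical vector from [window_flags()].
#' @param m number of SNPs on the chromosome.
#' @param w window width in SNPs.
#' @return numeric vector of length `m` of per-SNP proportions in `[0, 1]`.
#' @export
snp_in_run_proportions <- function(flags, m, w) {
  if (m < w || length(flags) == 0L) return(numeric(m))
  nw <- m - w + 1L
  stopifnot(length(flags) == nw)
  cp <- c(0, cumsum(flags))
  j <- seq_len(m)
  first <- pmax(1L, j - w + 1L)
  last <- pmin(j, nw)
  n_pass <- cp[last + 1L] - cp[first]
  n_pass / (last - first + 1L)
}

#' Assemble runs from flagged SNPs
#'
#' Candidate segments are maximal stretches of consecutive flagged SNPs.
#' Each candidate is split wherever the gap between adjacent SNPs exceeds
#' `max_gap_bp`; the surviving pieces are kept when they hold at least
#' `min_snps` SNPs, span at least `min_length_bp` (span = last bp - first
#' bp) and satisfy `n_snps >= span * min_density_snp_per_bp`.
#'
#' @param flags logical per-SNP in-run indicators.
#' @param positions strictly increasing bp positions.
#' @param p a [run_params()] object.
#' @param sample_id,breed,chrom identifiers copied into the output rows.
#' @return data.frame with columns `sample_id`, `breed`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`, `length_bp` (possibly zero rows).
#' @export
assemble_runs <- function(flags, positions, p, sample_id = "ind",
                          breed = "pop", chrom = "1") {
  stopifnot(inherits(p, "run_params"), length(flags) == length(positions))
  empty <- data.frame(sample_id = character(0), breed = character(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0),
                      length_bp = numeric(0), stringsAsFactors = FALSE)
  if (!any(flags)) return(empty)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- cbind(starts[r$values], ends[r$values])
  out <- list()
  for (s in seq_len(nrow(segs))) {
    a <- segs[s, 1L]; b <- segs[s, 2L]
    idx <- a:b
    pos <- positions[idx]
    cut_after <- which(diff(pos) > p$max_gap_bp)
    piece_start <- c(1L, cut_after + 1L)
    piece_end <- c(cut_after, length(idx))
    for (q in seq_along(piece_start)) {
      ii <- idx[piece_start[q]:piece_end[q]]
      nsnp <- length(ii)
      span <- positions[ii[nsnp]] - positions[ii[1L]]
      if (nsnp >= p$min_snps && span >= p$min_length_bp &&
          nsnp >= span * p$min_density_snp_per_bp) {
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sample_id, breed = breed, chrom = chrom,
          start_bp = positions[ii[1L]], end_bp = positions[ii[nsnp]],
          n_snps = nsnp, length_bp = span, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

.sort_runs <- function(runs, chrom_levels) {
  if (!nrow(runs)) return(runs)
  runs <- runs[order(runs$breed, runs$sample_id,
                     match(runs$chrom, chrom_levels), runs$start_bp), ,
               drop = FALSE]
  rownames(runs) <- NULL
  runs
}

.new_run_set <- function(runs, params, samples, fingerprint, chrom_levels) {
  structure(list(runs = .sort_runs(runs, chrom_levels), params = params,
                 samples = samples, fingerprint = fingerprint),
            class = "run_set")
}

#' Detect runs of homozygosity or heterozygosity-rich regions
#'
#' Runs the sliding-window scan ([window_flags()] then
#' [snp_in_run_proportions()] then [assemble_runs()]) for every individual
#' on every chromosome. A SNP is classified in-run when its proportion of
#' passing windows strictly exceeds `p$prop_threshold`. The result is
#' deterministic and sorted by (breed, sample, chromosome, start).
#'
#' @param ds a QC'd [genotype_dataset()].
#' @param p a [run_params()] object; see [roh_params()] / [hrr_params()].
#' @return object of class `run_set`: `runs` data.frame (`sample_id`,
#'   `breed`, `chrom`, `start_bp`, `end_bp`, `n_snps`, `length_bp`),
#'   `params`, `samples`, and the dataset `fingerprint`.
#' @export
detect_runs <- function(ds, p) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(p, "run_params"))
  chroms <- unique(ds$snps$chrom)
  acc <- list()
  for (ch in chroms) {
    jj <- which(ds$snps$chrom == ch)
    pos <- ds$snps$bp[jj]
    m <- length(jj)
    for (i in seq_len(nrow(ds$samples))) {
      g <- ds$calls[i, jj]
      fl <- window_flags(g, p)
      prop <- snp_in_run_proportions(fl, m, p$window_snps)
      snp_flags <- prop > p$prop_threshold
      if (any(snp_flags)) {
        acc[[length(acc) + 1L]] <- assemble_runs(
          snp_flags, pos, p, sample_id = ds$samples$sample_id[i],
          breed = ds$samples$breed[i], chrom = ch)
      }
    }
  }
  runs <- if (length(acc)) do.call(rbind, acc) else
    assemble_runs(logical(0), numeric(0), p)
  .new_run_set(runs, p, ds$samples, dataset_fingerprint(ds), chroms)
}

#' Brute-force reference run detector
#'
#' Independent re-derivation of [detect_runs()] by explicit enumeration:
#' every window is inspected with a loop, every SNP's containing windows are
#' enumerated from the index arithmetic, and run assembly walks the SNPs one
#' by one. Intended for small inputs as an internal correctness oracle;
#' output is identical to [detect_runs()].
#'
#' @inheritParams detect_runs
#' @return a `run_set`, exactly as [detect_runs()] returns.
#' @export
oracle_detect_runs <- function(ds, p) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(p, "run_params"))
  w <- p$window_snps
  chroms <- unique(ds$snps$chrom)
  acc <- list()
  for (ch in chroms) {
    jj <- which(ds$snps$chrom == ch)
    pos <- ds$snps$bp[jj]
    m <- length(jj)
    for (i in seq_len(nrow(ds$samples))) {
      g <- ds$calls[i, jj]
      ## explicit window enumeration
      nw <- m - w + 1L
      pass <- logical(max(0L, nw))
      if (nw >= 1L) {
        for (s in seq_len(nw)) {
          win <- g[s:(s + w - 1L)]
          n_opp <- sum(.opposite(win, p$mode))
          n_mis <- sum(is.na(win))
          pass[s] <- n_opp <= p$max_opposite_in_window &&
            n_mis <= p$max_missing_in_window
        }
      }
      ## explicit per-SNP containing-window enumeration
      flagged <- logical(m)
      if (nw >= 1L) {
        for (j in seq_len(m)) {
          wins <- max(1L, j - w + 1L):min(j, nw)
          wins <- wins[wins >= 1L & wins <= nw]
          if (length(wins))
            flagged[j] <- mean(pass[wins]) > p$prop_threshold
        }
      }
      ## explicit segment walk
      runs <- list()
      s0 <- NA_integer_
      for (j in seq_len(m + 1L)) {
        inrun <- j <= m && flagged[j]
        gapped <- !is.na(s0) && j <= m && j > 1L &&
          (pos[j] - pos[j - 1L]) > p$max_gap_bp
        if (inrun && is.na(s0)) {
          s0 <- j
        } else if (!is.na(s0) && (!inrun || gapped)) {
          e0 <- j - 1L
          nsnp <- e0 - s0 + 1L
          span <- pos[e0] - pos[s0]
          if (nsnp >= p$min_snps && span >= p$min_length_bp &&
              nsnp >= span * p$min_density_snp_per_bp)
            runs[[length(runs) + 1L]] <- data.frame(
              sample_id = ds$samples$sample_id[i],
              breed = ds$samples$breed[i], chrom = ch,
              start_bp = pos[s0], end_bp = pos[e0], n_snps = nsnp,
              length_bp = span, stringsAsFactors = FALSE)
          s0 <- if (inrun && gapped) j else NA_integer_
        }
      }
      if (length(runs)) acc <- c(acc, runs)
    }
  }
  runs <- if (length(acc)) do.call(rbind, acc) else
    assemble_runs(logical(0), numeric(0), p)
  .new_run_set(runs, p, ds$samples, dataset_fingerprint(ds), chroms)
}

#' @export
print.run_set <- function(x, ...) {
  cat(sprintf("run_set (%s): %d runs over %d individuals\n",
              x$params$mode, nrow(x$runs), nrow(x$samples)))
  invisible(x)
}

#' Export a run set as TSV (and optionally BED)
#'
#' The TSV uses 1-based inclusive SNP-anchored intervals (columns `breed`,
#' `sample_id`, `chrom`, `start_bp`, `end_bp`, `n_snps`, `length_bp`). The
#' optional BED export converts to 0-based half-open coordinates
#' (`start - 1`, `end`).
#'
#' @param rs a `run_set` from [detect_runs()].
#' @param path output TSV path.
#' @param bed_path optional BED output path.
#' @return invisibly, `path`.
#' @export
write_runs <- function(rs, path, bed_path = NULL) {
  r <- rs$runs[, c("breed", "sample_id", "chrom", "start_bp", "end_bp",
                   "n_snps", "length_bp")]
  write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = r$chrom, start = .fmt_bp(r$start_bp - 1),
                      end = .fmt_bp(r$end_bp),
                      name = paste(r$sample_id, r$breed, sep = "|"))
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
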