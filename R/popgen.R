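#' Per-SNP allele frequencies and call statistics
#'
#' For every SNP (optionally within every breed) returns the allele-1
#' frequency `p` over non-missing calls, the minor allele frequency
#' `maf = min(p, 1 - p)`, the call rate, and the observed heterozygote
#' fraction. SNPs with zero non-missing calls in a group get `NA`
#' frequencies and are flagged (`n = 0`) so downstream means can exclude
#' them.
#'
#' @param ds a [genotype_dataset()].
#' @param by_breed compute within each breed instead of pooled (default
#'   FALSE).
#' @return data.frame with columns `breed` (only if `by_breed`), `snp_id`,
#'   `chrom`, `bp`, `n`, `p`, `maf`, `call_rate`, `het_obs`.
#' @export
snp_frequencies <- function(ds, by_breed = FALSE) {
  stopifnot(inherits(ds, "genotype_dataset"))
  one_group <- function(calls, breed = NULL) {
    n_tot <- nrow(calls)
    nn <- colSums(!is.na(calls))
    ## code counts allele-2 copies; allele-1 frequency p = 1 - mean(code)/2
    p <- 1 - colMeans(calls, na.rm = TRUE) / 2
    p[nn == 0L] <- NA_real_
    het <- colMeans(calls == 1L, na.rm = TRUE)
    het[nn == 0L] <- NA_real_
    out <- data.frame(snp_id = ds$snps$snp_id, chrom = ds$snps$chrom,
                      bp = ds$snps$bp, n = nn, p = p,
                      maf = pmin(p, 1 - p),
                      call_rate = if (n_tot) nn / n_tot else 0,
                      het_obs = het, stringsAsFactors = FALSE)
    if (!is.null(breed)) out <- cbind(breed = breed, out,
                                      stringsAsFactors = FALSE)
    out
  }
  if (!by_breed) return(one_group(ds$calls))
  res <- lapply(unique(ds$samples$breed), function(b) {
    one_group(ds$calls[ds$samples$breed == b, , drop = FALSE], breed = b)
  })
  do.call(rbind, res)
}

#' Per-breed diversity indices
#'
#' Computes, within each breed, the mean observed heterozygosity `H_O`, the
#' mean expected heterozygosity `H_E`, the inbreeding coefficient `F_IS`
#' (mean and s.d. over individuals), and the mean minor allele frequency.
#' Per SNP, expected heterozygosity uses the small-sample-corrected
#' estimator `2 p (1 - p) * 2n / (2n - 1)` with `n` the non-missing call
#' count. The per-individual inbreeding coefficient follows the
#' method-of-moments form `F = (O_hom - E_hom) / (L - E_hom)`, where `O_hom`
#' is the individual's observed homozygote count over its `L` non-missing
#' SNPs and `E_hom` sums `1 - 2p(1-p) * 2n/(2n-1)` over the same SNPs.
#'
#' @param ds a QC'd [genotype_dataset()] with at least 2 individuals per
#'   breed.
#' @param frequencies `"within"` (default) computes allele frequencies
#'   within each breed; `"pooled"` uses the whole dataset.
#' @return data.frame, one row per breed: `breed`, `n_individuals`, `H_O`,
#'   `H_E`, `F_IS_mean`, `F_IS_sd`, `MAF_mean`.
#' @export
diversity_summary <- function(ds, frequencies = c("within", "pooled")) {
  stopifnot(inherits(ds, "genotype_dataset"))
  frequencies <- match.arg(frequencies)
  breeds <- unique(ds$samples$breed)
  cnt <- table(ds$samples$breed)
  small <- names(cnt)[cnt < 2L]
  if (length(small))
    .stopf("breed '%s' has fewer than 2 individuals", small[1L])

  pooled <- NULL
  if (frequencies == "pooled") {
    nn <- colSums(!is.na(ds$calls))
    pp <- 1 - colMeans(ds$calls, na.rm = TRUE) / 2
    pooled <- list(n = nn, p = pp)
  }

  rows <- lapply(breeds, function(b) {
    idx <- which(ds$samples$breed == b)
    calls <- ds$calls[idx, , drop = FALSE]
    if (is.null(pooled)) {
      nn <- colSums(!is.na(calls))
      pp <- 1 - colMeans(calls, na.rm = TRUE) / 2
    } else {
      nn <- pooled$n; pp <- pooled$p
    }
    use <- nn > 0L
    het_obs <- colMeans(calls == 1L, na.rm = TRUE)
    he <- 2 * pp * (1 - pp) * (2 * nn) / pmax(2 * nn - 1, 1)
    exp_hom_snp <- 1 - he
    f_ind <- vapply(seq_len(nrow(calls)), function(i) {
      g <- calls[i, ]
      nm <- !is.na(g) & use
      L <- sum(nm)
      if (L == 0L) return(NA_real_)
      o_hom <- sum(g[nm] != 1L)
      e_hom <- sum(exp_hom_snp[nm])
      if (abs(L - e_hom) < .Machine$double.eps^0.5) return(NA_real_)
      (o_hom - e_hom) / (L - e_hom)
    }, numeric(1))
    obs_use <- use & !is.nan(het_obs)
    data.frame(breed = b, n_individuals = length(idx),
               H_O = mean(het_obs[obs_use]),
               H_E = mean(he[use]),
               F_IS_mean = mean(f_ind, na.rm = TRUE),
               F_IS_sd = sd(f_ind, na.rm = TRUE),
               MAF_mean = mean(pmin(pp, 1 - pp)[use]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise identity-by-state distance matrix
#'
#' For each pair of individuals, IBS is the mean over pairwise non-missing
#' SNPs of `(2 - |g_i - g_j|) / 2` on the 0/1/2 coding (2 shared alleles for
#' identical homozygotes, 1 for hom-vs-het, 0 for opposite homozygotes).
#' The stored distance is `1 - IBS`.
#'
#' @param ds a [genotype_dataset()] with at least 2 individuals, typically
#'   the LD-pruned set.
#' @return symmetric numeric matrix with zero diagonal, dimnames set to
#'   sample ids.
#' @export
ibs_matrix <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n <- nrow(ds$samples)
  if (n < 2L) .stopf("need at least 2 individuals for an IBS matrix")
  D <- matrix(0, n, n, dimnames = list(ds$samples$sample_id,
                                       ds$samples$sample_id))
  for (i in seq_len(n - 1L)) {
    gi <- ds$calls[i, ]
    for (j in seq((i + 1L), n)) {
      d <- abs(gi - ds$calls[j, ])
      ok <- !is.na(d)
      if (!any(ok))
        .stopf("samples %s and %s share no non-missing SNPs",
               ds$samples$sample_id[i], ds$samples$sample_id[j])
      dist <- 1 - mean((2 - d[ok]) / 2)
      D[i, j] <- D[j, i] <- dist
    }
  }
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and returns the top-`k`
#' eigenvector coordinates scaled by the square root of their eigenvalues.
#' Negative eigenvalues (non-Euclidean input) are truncated to zero with a
#' warning. For determinism each coordinate column's largest-magnitude entry
#' is made positive.
#'
#' @param d symmetric distance matrix (e.g. from [ibs_matrix()]).
#' @param k number of dimensions, `1 <= k < nrow(d)`.
#' @return list of class `mds_result`: `points` (n x k matrix, centered
#'   columns), `eig` (all eigenvalues, non-increasing).
#' @export
classical_mds <- function(d, k = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 1L || k >= n) .stopf("'k' must satisfy 1 <= k < %d", n)
  D2 <- d * d
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% D2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  tol <- 1e-9 * max(abs(ev), 1)
  if (any(ev < -tol))
    warning("distance matrix is not Euclidean; negative eigenvalues truncated to zero")
  ev_trunc <- ifelse(ev < tol, 0, ev)   # negatives and numerical noise
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev_trunc[seq_len(k)]), k)
  for (j in seq_len(k)) {
    i0 <- which.max(abs(pts[, j]))
    if (pts[i0, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("C", seq_len(k))
  structure(list(points = pts, eig = ev_trunc), class = "mds_result")
}

#' Write a distance matrix as a labelled square TSV
#'
#' @param d symmetric matrix with sample-id dimnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
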