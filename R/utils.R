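`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

## numeric-aware chromosome ordering: "1" < "2" < "10"; non-numeric labels last
.chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, chrom)
}

.chrom_levels <- function(chrom) unique(chrom[.chrom_rank(chrom)])

.is_autosome <- function(chrom) {
  ok <- grepl("^[0-9]+$", chrom)
  ok & suppressWarnings(as.integer(ifelse(ok, chrom, "0"))) >= 1L
}

## closed-interval overlap in bp (shared positions)
.overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

.assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    .stopf("'%s' must be a single value in [0, 1]", name)
  invisible(x)
}

.fmt_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
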