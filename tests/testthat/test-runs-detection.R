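## brute-force window/proportion helpers, independent of the package path
naive_window_pass <- function(g, p) {
  m <- length(g); w <- p$window_snps
  if (m < w) return(logical(0))
  sapply(seq_len(m - w + 1L), function(i) {
    win <- g[i:(i + w - 1L)]
    opp <- if (p$mode == "HOM") sum(win == 1L, na.rm = TRUE) else
      sum(win != 1L, na.rm = TRUE)
    opp <= p$max_opposite_in_window &&
      sum(is.na(win)) <= p$max_missing_in_window
  })
}

naive_props <- function(pass, m, w) {
  nw <- m - w + 1L
  sapply(seq_len(m), function(j) {
    wins <- intersect(seq_len(nw), (j - w + 1L):j)
    if (!length(wins)) return(0)
    mean(pass[wins])
  })
}

test_that("window flags count opposite and missing genotypes exactly", {
  p <- roh_params()
  g <- rep(c(0L, 2L), 30)                     # 60 homozygous calls
  expect_equal(window_flags(g, p), rep(TRUE, 11))
  g2 <- g; g2[30] <- 1L                       # every 50-window covers SNP 30
  expect_equal(window_flags(g2, p), rep(FALSE, 11))
  expect_length(window_flags(rep(0L, 40), p), 0)  # m < w -> no windows
  g3 <- g; g3[30] <- NA
  expect_equal(window_flags(g3, p), rep(FALSE, 11))
  expect_true(all(window_flags(g3, roh_params(max_missing_in_window = 1))))
  ## HET mode: homozygotes are the opposite genotype
  expect_true(all(window_flags(rep(1L, 30), hrr_params())))
  expect_false(any(window_flags(rep(0L, 30), hrr_params())))
})

test_that("per-SNP proportions agree with exhaustive window enumeration", {
  m <- 100L; w <- 50L
  flags <- c(rep(TRUE, 3), rep(FALSE, m - w + 1L - 3L))
  pr <- snp_in_run_proportions(flags, m, w)
  expect_equal(pr[1L], 1)                    # only window 1 contains SNP 1
  expect_equal(pr[60L], 0)                   # windows 11..51 all fail
  expect_equal(pr, naive_props(flags, m, w))

  expect_equal(snp_in_run_proportions(rep(TRUE, 51), m, w), rep(1, m))
  expect_equal(snp_in_run_proportions(rep(FALSE, 51), m, w), rep(0, m))
  expect_equal(snp_in_run_proportions(logical(0), 30, 50), rep(0, 30))

  set.seed(4)
  for (i in 1:10) {
    m <- sample(50:200, 1); w <- sample(5:49, 1)
    flags <- runif(m - w + 1) < 0.3
    expect_equal(snp_in_run_proportions(flags, m, w), naive_props(flags, m, w))
  }
})

test_that("run assembly applies gap, count, length and density filters", {
  p <- roh_params()
  pos <- 1 + 20000 * (0:59)                  # span 1,180,000 bp
  r <- assemble_runs(rep(TRUE, 60), pos, p)
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_snps, 60L)
  expect_equal(r$length_bp, 1180000)
  expect_equal(r$start_bp, pos[1]); expect_equal(r$end_bp, pos[60])

  ## 30 + 30 SNPs split by a 1.5 Mb gap: both pieces fall under min_snps
  pos2 <- c(1 + 20000 * (0:29), 1.5e6 + 1 + 20000 * (30:59))
  expect_equal(nrow(assemble_runs(rep(TRUE, 60), pos2, p)), 0L)

  ## HET thresholds: 15 SNPs spanning 112 kb make one HRR
  ph <- hrr_params()
  pos3 <- 1 + 8000 * (0:14)
  rh <- assemble_runs(rep(TRUE, 15), pos3, ph)
  expect_equal(nrow(rh), 1L)
  expect_equal(rh$length_bp, 112000)

  ## density: 60 SNPs over 12 Mb is one SNP per 200 kb -> rejected
  pos4 <- 1 + 2e5 * (0:59)
  expect_equal(nrow(assemble_runs(rep(TRUE, 60), pos4, p)), 0L)
})

test_that("detection trims run edges exactly as the window arithmetic dictates", {
  ## one individual, 400 SNPs at 8 kb spacing, heterozygous except a
  ## homozygous stretch over SNPs 100..250. Windows fully inside the
  ## stretch start at 100..201; SNP j is flagged iff more than 5% of its
  ## containing windows pass, i.e. at least 3 of 50, which holds for
  ## j = 102..248. The expected ROH is therefore SNPs 102..248.
  g <- rep(1L, 400); g[100:250] <- rep(c(0L, 2L), length.out = 151)
  bp <- 1 + 8000 * (0:399)
  ds <- make_dataset(matrix(g, nrow = 1), bp = bp)
  rs <- detect_runs(ds, roh_params())
  expect_equal(nrow(rs$runs), 1L)
  expect_equal(rs$runs$start_bp, bp[102])
  expect_equal(rs$runs$end_bp, bp[248])
  expect_equal(rs$runs$n_snps, 147L)
  ## and the brute-force oracle agrees
  expect_identical(oracle_detect_runs(ds, roh_params())$runs, rs$runs)
})

test_that("degenerate individuals yield the expected run counts", {
  ## heterozygous everywhere: no ROH
  ds_het <- make_dataset(matrix(1L, nrow = 1, ncol = 200),
                         bp = 1 + 8000 * (0:199))
  expect_equal(nrow(detect_runs(ds_het, roh_params())$runs), 0L)

  ## homozygous everywhere on a 2 Mb, 500-SNP chromosome: one ROH
  bp <- 1 + 4000 * (0:499)
  ds_hom <- make_dataset(matrix(0L, nrow = 1, ncol = 500), bp = bp)
  rs <- detect_runs(ds_hom, roh_params())
  expect_equal(nrow(rs$runs), 1L)
  expect_equal(rs$runs$start_bp, bp[1])
  expect_equal(rs$runs$end_bp, bp[500])

  ## empty dataset
  ds_empty <- make_dataset(matrix(integer(0), nrow = 0, ncol = 0),
                           bp = numeric(0), chrom = character(0))
  expect_equal(nrow(detect_runs(ds_empty, roh_params())$runs), 0L)
})

test_that("a single passing HET window is enough to flag its SNPs", {
  ## 1/15 > 0.05, so one isolated passing window flags all 15 member SNPs
  g <- rep(0L, 100); g[40:54] <- 1L
  bp <- 1 + 8000 * (0:99)
  ds <- make_dataset(matrix(g, nrow = 1), bp = bp)
  rs <- detect_runs(ds, hrr_params())
  expect_equal(nrow(rs$runs), 1L)
  expect_equal(rs$runs$start_bp, bp[40])
  expect_equal(rs$runs$end_bp, bp[54])
  expect_equal(rs$runs$n_snps, 15L)
})

test_that("planted homozygous tracts are recovered in a heterozygous-rich background", {
  cfg <- sim_config(seed = 1, n_individuals = 1, snps_per_chromosome = 1000,
                    mean_spacing_bp = 4000,
                    tracts = list(list(breed = "B1", chrom = 1,
                                       start_snp = 300, end_snp = 599,
                                       carrier_fraction = 1, mode = "HOM")))
  sim <- simulate_dataset(cfg)
  rs <- detect_runs(sim$dataset, roh_params())
  tr <- sim$truth
  inside <- rs$runs$start_bp >= tr$start_bp & rs$runs$end_bp <= tr$end_bp
  expect_equal(sum(inside), 1L)
  rec <- evaluate_recovery(sim$truth, rs)
  expect_gt(rec$jaccard_mean, 0.95)
})

test_that("runs contain only run-compatible genotypes and never overlap", {
  for (seed in c(11, 12)) {
    mode <- if (seed %% 2) "HOM" else "HET"
    cfg <- sim_config(seed = seed, n_individuals = 6,
                      snps_per_chromosome = 500, mean_spacing_bp = 3000,
                      missing_rate = 0.02,
                      tracts = list(list(breed = "B1", chrom = 1,
                                         start_snp = 100, end_snp = 220,
                                         carrier_fraction = 0.5, mode = mode)))
    sim <- simulate_dataset(cfg)
    ds <- sim$dataset
    p <- run_params(mode, window_snps = 15, min_snps = 15,
                    min_length_bp = 1e5)
    rs <- detect_runs(ds, p)
    expect_gt(nrow(rs$runs), 0L)
    for (k in seq_len(nrow(rs$runs))) {
      run <- rs$runs[k, ]
      i <- match(run$sample_id, ds$samples$sample_id)
      jj <- ds$snps$chrom == run$chrom & ds$snps$bp >= run$start_bp &
        ds$snps$bp <= run$end_bp
      g <- ds$calls[i, jj]
      expect_false(anyNA(g))
      if (mode == "HOM") expect_true(all(g != 1L)) else
        expect_true(all(g == 1L))
      ## boundaries coincide with SNP positions
      expect_true(run$start_bp %in% ds$snps$bp && run$end_bp %in% ds$snps$bp)
    }
    ## no overlap within one sample/chromosome
    by_sc <- split(rs$runs, paste(rs$runs$sample_id, rs$runs$chrom))
    for (d in by_sc) {
      if (nrow(d) < 2) next
      d <- d[order(d$start_bp), ]
      expect_true(all(d$start_bp[-1] > d$end_bp[-nrow(d)]))
    }
  }
})

test_that("tightening length or count thresholds never adds runs", {
  cfg <- sim_config(seed = 13, n_individuals = 5, snps_per_chromosome = 600,
                    mean_spacing_bp = 3000,
                    tracts = list(list(breed = "B1", chrom = 1,
                                       start_snp = 50, end_snp = 400,
                                       carrier_fraction = 1, mode = "HOM")))
  ds <- simulate_dataset(cfg)$dataset
  base <- nrow(detect_runs(ds, roh_params(window_snps = 20, min_snps = 20,
                                          min_length_bp = 2e5))$runs)
  for (len in c(4e5, 8e5, 1.6e6)) {
    n <- nrow(detect_runs(ds, roh_params(window_snps = 20, min_snps = 20,
                                         min_length_bp = len))$runs)
    expect_lte(n, base)
    base <- n
  }
  n1 <- nrow(detect_runs(ds, roh_params(window_snps = 20, min_snps = 20,
                                        min_length_bp = 2e5))$runs)
  n2 <- nrow(detect_runs(ds, roh_params(window_snps = 20, min_snps = 60,
                                        min_length_bp = 2e5))$runs)
  expect_lte(n2, n1)
})

test_that("vectorized detection matches the brute-force oracle on random data", {
  for (i in 1:6) {
    set.seed(40 + i)
    mode <- if (i %% 2) "HOM" else "HET"
    tr <- list(list(breed = "B1", chrom = 1, start_snp = sample(30:80, 1),
                    end_snp = sample(120:180, 1),
                    carrier_fraction = runif(1, 0.3, 1), mode = mode))
    cfg <- sim_config(seed = 300 + i, n_individuals = 5,
                      snps_per_chromosome = 200, mean_spacing_bp = 2000,
                      missing_rate = 0.03, tracts = tr)
    ds <- simulate_dataset(cfg)$dataset
    p <- run_params(mode, window_snps = sample(5:20, 1),
                    min_snps = sample(10:25, 1),
                    min_length_bp = sample(c(3e4, 5e4, 1e5), 1),
                    max_opposite_in_window = sample(0:1, 1),
                    max_missing_in_window = sample(0:1, 1))
    a <- detect_runs(ds, p)
    b <- oracle_detect_runs(ds, p)
    expect_identical(a$runs, b$runs)
  }
})
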