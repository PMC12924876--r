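test_that("PED/MAP parsing codes genotypes against a first-seen allele dictionary", {
  map <- tempfile(fileext = ".map"); ped <- tempfile(fileext = ".ped")
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\t200", "1\tsnp3\t0\t300"), map)
  writeLines(c(
    "FAM1\ts1\t0\t0\t1\t-9\tA A\tG G\t0 0",
    "FAM2\ts2\t0\t0\t2\t-9\tA G\tG G\tA A"), ped)
  ds <- read_plink_text(ped, map)
  expect_equal(ds$samples$sample_id, c("s1", "s2"))
  expect_equal(ds$samples$breed, c("FAM1", "FAM2"))   # family id carries breed
  ## snp1: A seen first -> allele1 = A: AA = 0, AG = 1
  expect_equal(unname(ds$calls[, "snp1"]), c(0L, 1L))
  ## snp2: only G observed -> monomorphic 0s
  expect_equal(unname(ds$calls[, "snp2"]), c(0L, 0L))
  ## snp3: "0 0" missing for s1; A first seen in s2
  expect_equal(unname(ds$calls[, "snp3"]), c(NA_integer_, 0L))
})

test_that("MAP order is normalised to (chrom, bp) with numeric chromosome order", {
  map <- tempfile(fileext = ".map"); ped <- tempfile(fileext = ".ped")
  writeLines(c("10\tsA\t0\t50", "2\tsB\t0\t900", "2\tsC\t0\t100"), map)
  writeLines("F\ti1\t0\t0\t0\t-9\tA A\tC C\tG G", ped)
  ds <- read_plink_text(ped, map)
  expect_equal(ds$snps$snp_id, c("sC", "sB", "sA"))
  expect_equal(ds$snps$chrom, c("2", "2", "10"))
  ## calls moved with their SNPs
  expect_equal(unname(ds$calls[1L, ]), c(0L, 0L, 0L))
})

test_that("malformed PED/MAP input is rejected with informative errors", {
  map <- tempfile(fileext = ".map"); ped <- tempfile(fileext = ".ped")
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\t200"), map)
  writeLines(c("F\ti1\t0\t0\t0\t-9\tA A\tG G",
               "F\ti2\t0\t0\t0\t-9\tA A"), ped)
  expect_error(read_plink_text(ped, map), "line 2")

  writeLines(c("F\ti1\t0\t0\t0\t-9\tA A\tG G",
               "F\ti2\t0\t0\t0\t-9\tA C\tG G",
               "F\ti3\t0\t0\t0\t-9\tT T\tG G"), ped)
  expect_error(read_plink_text(ped, map), "biallelic")

  writeLines(c("1\tdup\t0\t100", "1\tdup\t0\t200"), map)
  writeLines("F\ti1\t0\t0\t0\t-9\tA A\tG G", ped)
  expect_error(read_plink_text(ped, map), "duplicate snp_id")
})

test_that("genotype codes map to the documented allele symbols on write", {
  ds <- make_dataset(matrix(c(0L, 1L, 2L, NA_integer_), nrow = 1))
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  write_plink_text(ds, ped, map)
  fields <- strsplit(readLines(ped), "[ \t]+")[[1L]]
  expect_equal(fields[7:14],
               c("A", "A", "A", "G", "G", "G", "0", "0"))
  expect_equal(length(readLines(map)), 4L)
})

test_that("writing an empty dataset produces a MAP and an empty PED body", {
  ds <- make_dataset(matrix(integer(0), nrow = 0, ncol = 3))
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  write_plink_text(ds, ped, map)
  expect_equal(length(readLines(map)), 3L)
  expect_equal(length(readLines(ped)), 0L)
})

test_that("PLINK text round-trip is the identity on canonical-polarity datasets", {
  for (seed in c(2, 5)) {
    sim <- simulate_dataset(sim_config(seed = seed, n_breeds = 2,
                                       n_individuals = 4, n_chromosomes = 2,
                                       snps_per_chromosome = 30,
                                       missing_rate = 0.1))
    ds <- canonical_polarity(sim$dataset)
    ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
    write_plink_text(ds, ped, map)
    back <- read_plink_text(ped, map)
    expect_equal(back$samples, ds$samples)
    expect_equal(back$snps, ds$snps)
    expect_equal(back$calls, ds$calls)
    ## a second write/read cycle is always the identity, canonical or not
    raw <- sim$dataset
    write_plink_text(raw, ped, map)
    once <- read_plink_text(ped, map)
    write_plink_text(once, ped, map)
    twice <- read_plink_text(ped, map)
    expect_identical(once, twice)
  }
})

test_that("quality-control filters fire in the documented order with correct tallies", {
  ## 4 samples x 4 SNPs: snpX on chrom X (autosome filter), snp2 missing in
  ## 2/4 samples (call rate 0.5), snp3 monomorphic (MAF 0), snp1 clean
  calls <- rbind(c(0L, NA, 0L, 0L),
                 c(1L, NA, 0L, 1L),
                 c(2L, 1L, 0L, 0L),
                 c(1L, 2L, 0L, 2L))
  ds <- make_dataset(calls, chrom = c("1", "1", "1", "X"),
                     bp = c(100, 200, 300, 100))
  res <- apply_qc(ds, qc_params())
  expect_equal(unname(res$report$per_filter["non_autosomal"]), 1L)
  expect_equal(unname(res$report$per_filter["snp_call_rate"]), 1L)
  expect_equal(unname(res$report$per_filter["ind_call_rate"]), 0L)
  expect_equal(unname(res$report$per_filter["maf"]), 1L)
  expect_equal(res$dataset$snps$snp_id, "snp0001")
  expect_equal(res$report$n_snps_out,
               res$report$n_snps_in - length(res$report$removed_snp_ids))
})

test_that("no-op thresholds leave the dataset untouched and QC is idempotent", {
  sim <- simulate_dataset(sim_config(seed = 9, n_individuals = 12,
                                     snps_per_chromosome = 120,
                                     missing_rate = 0.05))
  ds <- sim$dataset
  res0 <- apply_qc(ds, qc_params(0, 0, 0, autosomes_only = FALSE))
  expect_equal(res0$dataset$calls, ds$calls)
  expect_equal(length(res0$report$removed_snp_ids), 0L)
  expect_equal(length(res0$report$removed_sample_ids), 0L)

  res1 <- apply_qc(ds, qc_params())
  res2 <- apply_qc(res1$dataset, qc_params())
  expect_equal(res2$dataset$calls, res1$dataset$calls)
  expect_equal(length(res2$report$removed_snp_ids), 0L)

  ## post-conditions hold on every surviving SNP
  kept <- res1$dataset
  cr <- colMeans(!is.na(kept$calls))
  f <- colMeans(kept$calls, na.rm = TRUE) / 2
  expect_true(all(cr > 0.95))
  expect_true(all(pmin(f, 1 - f) >= 0.01))
})

test_that("removing every individual is an explicit error", {
  calls <- rbind(c(0L, NA), c(NA, 2L))
  ds <- make_dataset(calls)
  expect_error(apply_qc(ds, qc_params(ind_call_rate_min = 0.9,
                                      snp_call_rate_min = 0)),
               "empty dataset")
})

test_that("LD pruning removes the lower-MAF member of a correlated pair", {
  ## r^2 = 0.758 > 0.5 by hand: x = (0,0,1,2), y = (0,0,0,2)
  x <- c(0L, 0L, 1L, 2L); y <- c(0L, 0L, 0L, 2L)
  expect_equal(cor(x, y)^2, 0.7576, tolerance = 1e-4)
  ds <- make_dataset(cbind(x, y), bp = c(1000, 11000))
  kept <- ld_prune(ds, ld_prune_params())
  expect_equal(kept, "snp0001")   # MAF 0.375 beats 0.25

  ## equal MAF (polarity flip, r^2 = 1): the later-bp SNP goes
  ds2 <- make_dataset(cbind(x, 2L - x), bp = c(1000, 11000))
  expect_equal(ld_prune(ds2, ld_prune_params()), "snp0001")

  ## same pair but 200 kb apart: outside the 50 kb window, both retained
  ds3 <- make_dataset(cbind(x, x), bp = c(1000, 201000))
  expect_equal(ld_prune(ds3, ld_prune_params()), c("snp0001", "snp0002"))

  ## r2_max = 1 never removes anything
  expect_equal(ld_prune(ds2, ld_prune_params(r2_max = 1)),
               c("snp0001", "snp0002"))

  ## SNP-count window semantics reach pairs a kb window would miss
  expect_equal(ld_prune(ds3, ld_prune_params(window_snps = 2)), "snp0001")
})

test_that("LD pruning output is an ordered subset of the input SNPs", {
  sim <- simulate_dataset(sim_config(seed = 21, n_individuals = 20,
                                     n_chromosomes = 2,
                                     snps_per_chromosome = 80,
                                     mean_spacing_bp = 2000))
  ds <- sim$dataset
  kept <- ld_prune(ds, ld_prune_params(window_kb = 20, step_variants = 3,
                                       r2_max = 0.2))
  expect_true(all(kept %in% ds$snps$snp_id))
  expect_equal(kept, ds$snps$snp_id[ds$snps$snp_id %in% kept])  # map order
})
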