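test_that("identical seed and config give byte-identical outputs", {
  cfg <- simulation_config(seed = 123, n_cultures = 5)
  a <- simulate_fluctuation_assay(cfg)
  b <- simulate_fluctuation_assay(cfg)
  expect_identical(a, b)

  ref <- synthetic_amplicon()
  p1 <- simulate_mutant_population(ref, 1e-3, 10, n_clones = 5, seed = 9)
  p2 <- simulate_mutant_population(ref, 1e-3, 10, n_clones = 5, seed = 9)
  expect_identical(p1, p2)

  r1 <- simulate_reads(p1$sequences, 50, 100, 1e-3, seed = 4)
  r2 <- simulate_reads(p2$sequences, 50, 100, 1e-3, seed = 4)
  expect_identical(r1, r2)

  expect_false(identical(simulate_reads(p1$sequences, 50, 100, 1e-3, seed = 5), r1))
  expect_error(simulation_config(seed = NULL), "seed is mandatory")
})

test_that("fluctuation simulator is calibrated to the estimator's closed form", {
  mu <- 6.2e-6
  cfg <- simulation_config(true_mu_bp = mu, R = 77, N0 = 1.5e7, N = 1e9,
                           n_cultures = 60, seed = 314)
  fl <- simulate_fluctuation_assay(cfg)
  expected_f <- mu * 77 * log(1e9 / 1.5e7)  # 2.005e-3
  expect_equal(fl$f_pooled, expected_f, tolerance = 0.02)

  # zero rate: no resistant mutants at all
  z <- simulate_fluctuation_assay(simulation_config(true_mu_bp = 0, seed = 1))
  expect_true(all(z$per_culture$f == 0))

  # unstable-regime warning when expected events per culture are negligible
  expect_warning(
    simulate_fluctuation_assay(simulation_config(true_mu_bp = 1e-15, seed = 2)),
    "unstable")
})

test_that("the estimator recovers the true rate from simulated assays", {
  mu <- 6.2e-6
  est <- vapply(1:50, function(s) {
    fl <- simulate_fluctuation_assay(simulation_config(
      true_mu_bp = mu, n_cultures = 2, seed = 1000 + s))
    estimate_mu_bp(fl$f_pooled, R = 77, N = 1e9, N0 = 1.5e7)
  }, numeric(1))
  expect_lt(abs(mean(est) / mu - 1), 0.15)
})

test_that("mutant populations follow the requested spectrum and truth table", {
  ref <- synthetic_amplicon(200)

  none <- simulate_mutant_population(ref, 0, 10, n_clones = 4, seed = 3)
  expect_true(all(none$sequences == ref))
  expect_equal(nrow(none$truth), 0)

  pop <- simulate_mutant_population(ref, 5e-3, 10, spectrum = broad_spectrum(),
                                    n_clones = 1000, seed = 77)
  expect_gt(nrow(pop$truth), 5e3)  # ~ mu * L * g * n_clones = 10^4 draws
  emp <- mutation_spectrum(pop$truth$ref, pop$truth$alt)
  expect_lte(spectrum_distance(emp, broad_spectrum()), 0.02)
  # truth table ref bases agree with the reference sequence
  ref_b <- strsplit(ref, "")[[1]]
  expect_equal(pop$truth$ref, ref_b[pop$truth$position])
})

test_that("read simulation respects error rate, coverage and exactness", {
  ref <- synthetic_amplicon(300)
  pop <- c(a = ref)

  exact <- simulate_reads(pop, 50, 20, base_error = 0, seed = 8)
  expect_true(all(vapply(seq_len(nrow(exact)), function(i)
    substr(ref, exact$offset[i] + 1, exact$offset[i] + 50) == exact$seq[i],
    logical(1))))
  expect_true(all(exact$qual == strrep("~", 50)))

  # observed mismatch rate ~ 1e-3 at ~1e6 sequenced bases (binomial 4 s.d.)
  noisy <- simulate_reads(pop, 100, 3334, base_error = 1e-3, seed = 21)
  n_bases <- sum(nchar(noisy$seq))
  mism <- sum(vapply(seq_len(nrow(noisy)), function(i) {
    src <- substr(ref, noisy$offset[i] + 1, noisy$offset[i] + 100)
    sum(strsplit(src, "")[[1]] != strsplit(noisy$seq[i], "")[[1]])
  }, numeric(1)))
  rate <- mism / n_bases
  expect_lt(abs(rate - 1e-3), 4 * sqrt(1e-3 / n_bases))
  # Phred string encodes the error probability used (Q30)
  expect_equal(unique(strsplit(noisy$qual[1], "")[[1]]), rawToChar(as.raw(30 + 33)))

  # mean per-position coverage within 5% of the requested depth
  cov_reads <- simulate_reads(pop, 50, 100, base_error = 0, seed = 10)
  cover <- integer(300)
  for (i in seq_len(nrow(cov_reads))) {
    idx <- (cov_reads$offset[i] + 1):(cov_reads$offset[i] + 50)
    cover[idx] <- cover[idx] + 1L
  }
  expect_lt(abs(mean(cover) / 100 - 1), 0.05)

  expect_error(simulate_reads(pop, 500, 10, 0, seed = 1), "exceeds")
})

test_that("simulate_dataset writes a regenerable file bundle", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 42, n_cultures = 3, depth = 50, read_len = 50,
                           generations = 5, true_mu_bp = 1e-4)
  paths <- simulate_dataset(cfg, dir = dir, n_clones = 5, n_plaques = 200)
  expect_true(all(file.exists(unlist(paths))))

  # the provenance records enough to regenerate byte-identically
  prov <- read_provenance(paths$provenance)
  expect_equal(prov$config$seed, 42)
  dir2 <- withr::local_tempdir()
  cfg2 <- simulation_config(
    true_mu_bp = prov$config$true_mu_bp, n_cultures = prov$config$n_cultures,
    depth = prov$config$depth, read_len = prov$config$read_len,
    generations = prov$config$generations, base_error = prov$config$base_error,
    seed = prov$config$seed)
  simulate_dataset(cfg2, dir = dir2, n_clones = prov$config$n_clones,
                   n_plaques = prov$config$n_plaques)
  for (f in c("fluctuation_f.tsv", "clones.fasta", "reads.fastq", "plaques.tsv")) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }

  # FASTQ + sidecar round-trip through the reader
  reads <- read_fastq(paths$fastq)
  side <- read_tsv_report(paths$offsets)
  joined <- dplyr::inner_join(reads, side, by = "read_id")
  expect_equal(nrow(joined), nrow(reads))
  expect_true(all(nchar(joined$seq) == 50))
})
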