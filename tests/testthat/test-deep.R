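test_that("quality filter masks by base and drops short reads", {
  reads <- tibble::tibble(
    read_id = c("hi", "lo"),
    seq = c("ACGTACGT", "ACGTACGT"),
    qual = c(strrep(rawToChar(as.raw(40 + 33)), 8),
             strrep(rawToChar(as.raw(20 + 33)), 8)),
    offset = 0L
  )
  out <- quality_filter(reads, q_min = 30, min_len = 4)
  expect_equal(out$read_id, "hi")            # all-Q20 read fully masked, dropped
  expect_equal(out$seq, "ACGTACGT")          # all-Q40 read fully retained
  expect_equal(out$n_masked, 0L)
  expect_equal(attr(out, "filter_stats")$n_kept, 1)

  # mixed qualities: only the sub-threshold bases are masked
  mixed <- tibble::tibble(
    read_id = "m", seq = "ACGT",
    qual = rawToChar(as.raw(c(40, 20, 40, 29) + 33)), offset = 0L)
  got <- quality_filter(mixed, q_min = 30, min_len = 1)
  expect_equal(got$seq, "ANGN")

  # read-mean mode drops whole reads instead of masking
  rm_mode <- quality_filter(reads, q_min = 30, min_len = 1, mode = "read_mean")
  expect_equal(rm_mode$read_id, "hi")

  bad <- tibble::tibble(read_id = "x", seq = "ACGT", qual = "!!!", offset = 0L)
  expect_error(quality_filter(bad), "malformed read 'x'")
})

test_that("per-position fractions count unmasked deviations", {
  ref <- "ACGTACGTAC"
  reads <- perfect_reads(ref, 100)
  tab <- per_position_fractions(reads, ref)
  expect_equal(tab$dev_frac, rep(0, 10))
  expect_equal(tab$depth, rep(100L, 10))

  # 5 of 100 reads carry G->T at position 7
  mut <- reads
  mut$seq[1:5] <- paste0(substr(ref, 1, 6), "T", substr(ref, 8, 10))
  tab2 <- per_position_fractions(mut, ref)
  expect_equal(tab2$dev_frac[7], 0.05)
  expect_equal(sum(tab2$dev_frac), 0.05)

  # masked bases are excluded: 50 reads, 10 masked at position 3, 4 deviant
  r3 <- perfect_reads(ref, 50)
  seq3 <- strsplit(r3$seq, "")
  for (i in 1:10) seq3[[i]][3] <- "N"
  for (i in 11:14) seq3[[i]][3] <- "A"  # ref at 3 is G
  r3$seq <- vapply(seq3, paste, character(1), collapse = "")
  tab3 <- per_position_fractions(r3, ref)
  expect_equal(tab3$depth[3], 40L)
  expect_equal(tab3$dev_frac[3], 4 / 40)

  # zero-depth positions are flagged, overhangs and missing offsets error
  short <- tibble::tibble(read_id = "s", seq = substr(ref, 1, 5),
                          qual = strrep("I", 5), offset = 0L)
  tab4 <- per_position_fractions(short, ref)
  expect_false(any(tab4$covered[6:10]))
  expect_true(all(is.na(tab4$dev_frac[6:10])))
  over <- tibble::tibble(read_id = "o", seq = ref, qual = strrep("I", 10), offset = 5L)
  expect_error(per_position_fractions(over, ref), "overhangs")
  expect_error(per_position_fractions(dplyr::select(short, -"offset"), ref),
               "offset")
})

test_that("paired-end duplicate coverage counts once per fragment", {
  ref <- "ACGTACGTAC"
  reads <- perfect_reads(ref, 4)
  reads$pair_id <- c("f1", "f1", "f2", "f3")  # f1's mates double-cover everything
  tab <- per_position_fractions(reads, ref)
  expect_equal(unique(tab$depth), 3L)
})

test_that("background subtraction floors at zero and is exactly null on itself", {
  ref <- "ACGTACGTAC"
  mk <- function(dev7) {
    reads <- perfect_reads(ref, 200)
    n <- round(dev7 * 200)
    if (n > 0) reads$seq[seq_len(n)] <- paste0(substr(ref, 1, 6), "T", substr(ref, 8, 10))
    per_position_fractions(reads, ref)
  }
  s <- mk(0.05); ctl <- mk(0.01)
  tab <- corrected_fraction(s, ctl)
  expect_equal(tab$corrected_frac[7], 0.04)

  low <- corrected_fraction(mk(0.005), mk(0.01))
  expect_equal(low$corrected_frac[7], 0)  # floored, not negative

  self <- corrected_fraction(s, s)
  expect_true(all(self$corrected_frac == 0))
  expect_equal(nrow(called_positions(call_mutations(self))), 0)

  expect_error(corrected_fraction(s, ctl[1:5, ]), "identical positions")
})

test_that("the call rule matches brute-force evaluation on a toy table", {
  ref <- "ACGTACGTAC"
  sample_reads <- perfect_reads(ref, 100)
  # spike position 4 (T) to 20% A in the sample only
  sample_reads$seq[1:20] <- paste0("ACG", "A", substr(ref, 5, 10))
  ctl_reads <- perfect_reads(ref, 100)
  ctl_reads$seq[1] <- paste0("ACGTACGTA", "T")  # 1% background at position 10
  tab <- call_mutations(corrected_fraction(
    per_position_fractions(sample_reads, ref),
    per_position_fractions(ctl_reads, ref)))

  # independent brute-force application of the rule over all positions
  dev_s <- tab$dev_frac_sample; dev_c <- tab$dev_frac_control
  corrected <- pmax(0, dev_s - dev_c)
  manual <- corrected > mean(corrected) & corrected > dev_c + stats::sd(dev_c)
  expect_equal(tab$called, manual)
  expect_equal(which(tab$called), 4L)
  expect_equal(tab$dominant_alt[4], "A")

  expect_error(call_mutations(tab[0, ]), "empty")
})

test_that("calls are invariant under read order and full duplication", {
  b <- simulate_caller_benchmark(n_mut = 5, depth = 300, seed = 404)
  base <- deep_call_pipeline(b$sample_reads, b$control_reads, b$ref_seq)
  shuffled <- deep_call_pipeline(b$sample_reads[rev(seq_len(nrow(b$sample_reads))), ],
                                 b$control_reads, b$ref_seq)
  doubled <- deep_call_pipeline(dplyr::bind_rows(b$sample_reads, b$sample_reads),
                                dplyr::bind_rows(b$control_reads, b$control_reads),
                                b$ref_seq)
  expect_equal(which(base$called), which(shuffled$called))
  expect_equal(which(base$called), which(doubled$called))
})

test_that("caller recovers spiked positions on the standard benchmark", {
  b <- simulate_caller_benchmark(seed = 2026)  # 10 positions at 5%, depth 1000
  tab <- deep_call_pipeline(b$sample_reads, b$control_reads, b$ref_seq)
  score <- score_calls(tab, b$truth)
  expect_gte(score$recall, 0.9)
  expect_gte(score$precision, 0.9)
})

test_that("called positions converge to truth at high depth and low error", {
  b <- simulate_caller_benchmark(depth = 5000, base_error = 1e-4, seed = 31)
  tab <- deep_call_pipeline(b$sample_reads, b$control_reads, b$ref_seq)
  expect_equal(sort(called_positions(tab)$position), sort(b$truth$position))
  # dominant alternate bases match the simulated alternates exactly
  calls <- called_positions(tab)
  expect_equal(calls$dominant_alt[order(calls$position)],
               b$truth$alt[order(b$truth$position)])
})

test_that("spectrum of called positions matches the realized truth", {
  b <- simulate_caller_benchmark(ref_seq = synthetic_amplicon(150), n_mut = 20,
                                 depth = 1000, seed = 555)
  tab <- deep_call_pipeline(b$sample_reads, b$control_reads, b$ref_seq)
  rec <- spectrum_from_calls(tab)
  truth_spec <- mutation_spectrum(b$truth$ref, b$truth$alt)
  expect_lte(spectrum_distance(rec, truth_spec), 0.15)
})
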