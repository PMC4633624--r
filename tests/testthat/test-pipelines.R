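test_that("rate report runs end-to-end from a colony-count TSV", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  counts <- tibble::tibble(
    sample_id = c("mp_on", "mp_off"),
    condition = c("induced", "uninduced"),
    colonies_selective = c(201L, 8L),
    dilution_selective = c(1e4, 1e4),
    colonies_nonselective = c(100L, 100L),
    dilution_nonselective = c(1e7, 1e7),
    N = 1e9
  )
  write_tsv_report(counts, tsv)
  out <- withr::local_tempfile(fileext = ".tsv")
  rep <- estimate_rate_report(tsv, baseline = "uninduced", out = out)
  expect_equal(rep$mu_bp,
               estimate_mu_bp(rep$f, R = 77, N = 1e9, N0 = 1.5e7))
  back <- read_tsv_report(out)
  expect_equal(back$mu_g, rep$mu_g)
  prov <- read_provenance(paste0(out, ".provenance.json"))
  expect_equal(prov$config$subcommand, "estimate-rate")

  expect_error(estimate_rate_report(counts[0, ]), "empty")
})

test_that("deep-caller pipeline runs from FASTQ + sidecar files with truth scoring", {
  dir <- withr::local_tempdir()
  b <- simulate_caller_benchmark(n_mut = 5, depth = 300, seed = 7)
  fq_s <- file.path(dir, "sample.fastq"); fq_c <- file.path(dir, "control.fastq")
  write_fastq(b$sample_reads, fq_s); write_fastq(b$control_reads, fq_c)
  off_s <- file.path(dir, "sample_off.tsv"); off_c <- file.path(dir, "control_off.tsv")
  write_tsv_report(b$sample_reads[, c("read_id", "offset")], off_s)
  write_tsv_report(b$control_reads[, c("read_id", "offset")], off_c)
  fa <- file.path(dir, "ref.fasta"); write_fasta(c(amplicon = b$ref_seq), fa)

  out <- file.path(dir, "run")
  tab <- call_mutations_report(fq_s, fq_c, fa, off_s, off_c,
                               out = out, truth = b$truth)
  expect_true(file.exists(paste0(out, "_positions.tsv")))
  expect_true(file.exists(paste0(out, "_spectrum.tsv")))
  summary <- jsonlite::read_json(paste0(out, "_summary.json"), simplifyVector = TRUE)
  expect_equal(summary$recall, score_calls(tab, b$truth)$recall)
  expect_equal(summary$n_called, sum(tab$called))

  # control-as-sample yields zero calls
  null_tab <- call_mutations_report(fq_c, fq_c, fa, off_c, off_c)
  expect_equal(sum(null_tab$called), 0)

  expect_error(call_mutations_report(fq_s, fq_c, file.path(dir, "nope.fasta"),
                                     off_s, off_c), "not found")
  expect_error(call_mutations_report(fq_s, fq_c, fa), "sidecar")
})

test_that("SAM input yields offset reads and rejects gapped alignments", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:amp\tLN:20",
    "r1\t0\tamp\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    "r2\t0\tamp\t5\t60\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII"
  ), sam)
  reads <- read_sam_alignments(sam)
  expect_equal(reads$offset, c(0L, 4L))
  expect_equal(reads$seq[1], "ACGTACGTAC")

  gapped <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:amp\tLN:20",
    "r1\t0\tamp\t1\t60\t5M1D5M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII"
  ), gapped)
  expect_error(read_sam_alignments(gapped), "substitution-only")
})

test_that("phage report infers rates and surfaces model assumptions", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_report(tibble::tibble(sample = c("mp6", "ctl"),
                                  n_blue = c(73L, 99L),
                                  n_light_blue = c(0L, 0L),
                                  n_white = c(27L, 1L)), tsv)
  rep <- phage_rate_report(tsv)
  expect_equal(rep$lacz_minus_fraction, c(0.27, 0.01))
  expect_equal(rep$mu_bp,
               rate_from_plaques(c(0.27, 0.01), inactivation_model()))
  expect_true(all(c("p_inactivating", "L_target") %in% names(rep)))
})

test_that("tidiers, glance and autoplot methods produce well-formed output", {
  s <- mutation_spectrum(all_12_pairs())
  expect_s3_class(tidy(s), "tbl_df")
  expect_equal(glance(s)$total, 12)
  expect_equal(glance(s)$ts_tv_ratio, 4 / 8)
  expect_s3_class(autoplot(s), "ggplot")
  expect_s3_class(autoplot(s, collapse = TRUE), "ggplot")

  b <- simulate_caller_benchmark(n_mut = 3, depth = 200, seed = 99)
  tab <- deep_call_pipeline(b$sample_reads, b$control_reads, b$ref_seq)
  expect_s3_class(autoplot(tab), "ggplot")
  g <- glance(tab)
  expect_equal(g$n_positions, 100)
  expect_true(is.finite(g$mean_corrected))

  pl <- summarize_plaques(73, 0, 27)
  expect_equal(sum(tidy(pl)$n), 100)
  expect_equal(glance(pl)$lacz_minus_fraction, 0.27)
  expect_s3_class(autoplot(pl), "ggplot")
})

test_that("the command-line driver exposes the pipelines", {
  cli <- system.file("cli", "mutascope.R", package = "mutascope")
  rscript <- file.path(R.home("bin"), "Rscript")

  help <- suppressWarnings(system2(rscript, c(cli, "--help"), stdout = TRUE))
  expect_equal(attr(help, "status") %||% 0, 0)
  expect_true(any(grepl("estimate-rate", help)))

  bad <- suppressWarnings(system2(rscript, c(cli, "frobnicate"),
                                  stdout = TRUE, stderr = TRUE))
  expect_gt(attr(bad, "status") %||% 0, 0)

  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "counts.tsv")
  write_tsv_report(tibble::tibble(
    sample_id = "s1", condition = "induced",
    colonies_selective = 201L, dilution_selective = 1e4,
    colonies_nonselective = 100L, dilution_nonselective = 1e7, N = 1e9), tsv)
  out <- file.path(dir, "report.tsv")
  res <- suppressWarnings(system2(
    rscript, c(cli, "estimate-rate", "--counts", tsv, "--out", out),
    stdout = TRUE, stderr = TRUE))
  expect_equal(attr(res, "status") %||% 0, 0)
  rep <- read_tsv_report(out)
  expect_equal(rep$mu_bp, estimate_mu_bp(201 * 1e4 / 1e9, 77, N = 1e9, N0 = 1.5e7))
})
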