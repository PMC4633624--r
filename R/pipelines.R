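#' Rate-estimation pipeline over a colony-count TSV
#'
#' Reads the colony-count table (columns `sample_id`, `condition`,
#' `colonies_selective`, `dilution_selective`, `colonies_nonselective`,
#' `dilution_nonselective`, optional `N`), runs the fluctuation-assay
#' estimator per sample, and optionally writes the report TSV and a
#' provenance JSON.
#'
#' @param counts Path to a TSV or a data frame.
#' @param out Optional output TSV path.
#' @inheritParams estimate_rates
#' @return The report tibble (see [estimate_rates()]).
#' @export
estimate_rate_report <- function(counts, R = assay_defaults()$R,
                                 N0 = assay_defaults()$N0,
                                 genome_len = assay_defaults()$genome_len,
                                 N = NULL, baseline = NULL, out = NULL) {
  tbl <- if (is.character(counts)) read_tsv_report(counts) else counts
  if (is.null(tbl) || nrow(tbl) == 0) {
    stop("empty colony-count table: nothing to estimate", call. = FALSE)
  }
  report <- estimate_rates(tbl, R = R, N0 = N0, genome_len = genome_len,
                           N = N, baseline = baseline)
  if (!is.null(out)) {
    write_tsv_report(report, out)
    write_provenance(list(
      subcommand = "estimate-rate",
      input = if (is.character(counts)) counts else "data.frame",
      R = R, N0 = N0, genome_len = genome_len, N = N, baseline = baseline
    ), paste0(out, ".provenance.json"))
  }
  report
}

#' Deep-sequencing mutation-calling pipeline over files
#'
#' Reads sample and control FASTQ files with their offset sidecar TSVs
#' (columns `read_id`, `offset`) or SAM files, the reference FASTA, and
#' runs [deep_call_pipeline()].
#'
#' @param sample,control FASTQ paths (with `sample_offsets` /
#'   `control_offsets` sidecars) or SAM paths.
#' @param ref Reference FASTA path (first record used) or a bare sequence.
#' @param sample_offsets,control_offsets Offset sidecar TSV paths; not
#'   needed for SAM input.
#' @param q_min,min_len Quality-filter settings.
#' @param out Optional output prefix; writes `<out>_positions.tsv`,
#'   `<out>_spectrum.tsv` and `<out>_summary.json`.
#' @param truth Optional truth tibble/TSV; when given, recall and precision
#'   are included in the JSON summary.
#' @return The called `position_call_table`.
#' @export
call_mutations_report <- function(sample, control, ref,
                                  sample_offsets = NULL, control_offsets = NULL,
                                  q_min = 30, min_len = 20,
                                  out = NULL, truth = NULL) {
  load_reads <- function(path, offsets) {
    if (is.data.frame(path)) return(path)
    if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) {
      return(read_sam_alignments(path))
    }
    reads <- read_fastq(path)
    if (is.null(offsets)) {
      stop(sprintf("FASTQ input %s needs an offset sidecar TSV", path), call. = FALSE)
    }
    side <- if (is.character(offsets)) read_tsv_report(offsets) else offsets
    dplyr::inner_join(reads, side[, c("read_id", "offset")], by = "read_id")
  }
  ref <- as.character(ref)[1]
  ref_seq <- if (grepl("^[ACGTacgt]+$", ref)) {
    ref
  } else if (file.exists(ref)) {
    as.character(read_fasta(ref)[[1]])
  } else {
    stop(sprintf("reference FASTA not found: %s", ref), call. = FALSE)
  }
  s <- load_reads(sample, sample_offsets)
  ctl <- load_reads(control, control_offsets)
  table <- deep_call_pipeline(s, ctl, ref_seq, q_min = q_min, min_len = min_len)
  if (!is.null(out)) {
    write_tsv_report(
      dplyr::select(tibble::as_tibble(table), "position", "ref",
                    depth = "depth_sample", "dev_frac_sample",
                    "dev_frac_control", "corrected_frac", "called"),
      paste0(out, "_positions.tsv"))
    write_tsv_report(tibble::as_tibble(spectrum_from_calls(table)),
                     paste0(out, "_spectrum.tsv"))
    summary <- list(
      n_positions = nrow(table),
      n_called = sum(table$called),
      mean_corrected = attr(table, "mean_corrected"),
      sd_control = attr(table, "sd_control"),
      q_min = q_min
    )
    if (!is.null(truth)) {
      tt <- if (is.character(truth)) read_tsv_report(truth) else truth
      summary <- c(summary, as.list(score_calls(table, tt)))
    }
    jsonlite::write_json(summary, paste0(out, "_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  table
}

#' Spectrum pipeline over a substitution TSV
#'
#' @param subs Path to a substitution TSV (`position`, `ref`, `alt`) or a
#'   data frame.
#' @param collapse Also write/return the 6-class collapsed spectrum.
#' @param out Optional output TSV path.
#' @return A `mutation_spectrum` (collapsed when `collapse = TRUE`).
#' @export
spectrum_report <- function(subs, collapse = FALSE, out = NULL) {
  tbl <- if (is.character(subs)) read_substitutions_tsv(subs) else subs
  spec <- mutation_spectrum(tbl)
  if (collapse) spec <- collapse_spectrum(spec)
  if (!is.null(out)) write_tsv_report(tibble::as_tibble(spec), out)
  spec
}

#' Phage-assay rate pipeline over a plaque-count TSV
#'
#' @param plaques Path to a TSV with `n_blue`, `n_light_blue`, `n_white`
#'   (one row per sample; extra identifier columns kept) or a data frame.
#' @param model An [inactivation_model()].
#' @param out Optional output TSV path.
#' @return A tibble with the plaque summaries plus `mu_bp` from
#'   [rate_from_plaques()] and the model assumptions echoed per row.
#' @export
phage_rate_report <- function(plaques, model = inactivation_model(), out = NULL) {
  tbl <- if (is.character(plaques)) read_tsv_report(plaques) else plaques
  res <- summarize_plaques(tbl)
  report <- dplyr::bind_cols(
    tbl[, setdiff(names(tbl), c("n_blue", "n_light_blue", "n_white")), drop = FALSE],
    res
  ) |>
    dplyr::mutate(
      mu_bp = rate_from_plaques(.data$lacz_minus_fraction, model),
      L_target = model$L_target,
      generations = model$generations,
      p_inactivating = model$p_inactivating
    )
  if (!is.null(out)) write_tsv_report(report, out)
  report
}

#' Generate a full synthetic dataset on disk
#'
#' Drives every generator from one [simulation_config()]: fluctuation-assay
#' frequencies, a mutant clone population (FASTA + truth TSV), amplicon
#' reads (FASTQ + offset sidecar), plaque counts, and a provenance JSON.
#'
#' @param config A [simulation_config()].
#' @param ref_seq Reference sequence for the clone population; default
#'   [synthetic_amplicon()].
#' @param dir Output directory (created if needed).
#' @param n_clones Clones in the mutant population.
#' @param n_plaques Plaques in the simulated screen.
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_dataset <- function(config, ref_seq = synthetic_amplicon(), dir,
                             n_clones = 20, n_plaques = 1000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  fl <- simulate_fluctuation_assay(config)
  paths$fluctuation <- file.path(dir, "fluctuation_f.tsv")
  write_tsv_report(fl$per_culture, paths$fluctuation)

  pop <- simulate_mutant_population(ref_seq, config$true_mu_bp,
                                    config$generations, config$spectrum,
                                    n_clones, seed = config$seed + 1L)
  paths$clones <- file.path(dir, "clones.fasta")
  write_fasta(pop$sequences, paths$clones)
  paths$clone_truth <- file.path(dir, "clones_truth.tsv")
  write_tsv_report(pop$truth, paths$clone_truth)

  reads <- simulate_reads(pop$sequences, min(config$read_len, nchar(as.character(ref_seq))),
                          config$depth, config$base_error, seed = config$seed + 2L)
  paths$fastq <- file.path(dir, "reads.fastq")
  write_fastq(reads, paths$fastq)
  paths$offsets <- file.path(dir, "reads_offsets.tsv")
  write_tsv_report(reads[, c("read_id", "source_id", "offset")], paths$offsets)

  model <- inactivation_model(config$L_target, config$generations,
                              config$p_inactivating)
  pl <- simulate_plaque_assay(config$true_mu_bp, model, n_plaques,
                              seed = config$seed + 3L)
  paths$plaques <- file.path(dir, "plaques.tsv")
  write_tsv_report(tibble::as_tibble(pl), paths$plaques)

  paths$provenance <- file.path(dir, "provenance.json")
  cfg <- config
  cfg$spectrum <- tibble::as_tibble(config$spectrum)[, c("class", "fraction")]
  write_provenance(c(unclass(cfg), list(n_clones = n_clones, n_plaques = n_plaques)),
                   paths$provenance)
  invisible(paths)
}
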