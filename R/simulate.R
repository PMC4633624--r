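#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators in one validated
#' list. Defaults mirror the study conditions of the assays the generators
#' emulate: an MP6-like true rate of 6.2e-6 substitutions/bp/generation,
#' R = 77 resistance sites, cultures grown from N0 = 1.5e7 to N = 1e9, and
#' Q30-grade reads (per-base error 1e-3). A seed is mandatory for every
#' stochastic run.
#'
#' @param true_mu_bp True substitution rate per bp per generation.
#' @param spectrum Sampling weights over the 12 strand-specific classes
#'   (a `mutation_spectrum` or any tibble with `class` and `fraction`);
#'   default [broad_spectrum()].
#' @param R,N0,N Fluctuation-assay constants (resistance sites, initial and
#'   final population sizes).
#' @param n_cultures Parallel cultures per assay.
#' @param generations Generations of mutagenesis for sequence populations.
#' @param read_len,depth Read length and mean per-position coverage.
#' @param base_error Per-base sequencing error probability.
#' @param L_target,p_inactivating Plaque-assay inactivation model fields.
#' @param seed Integer seed; required.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(true_mu_bp = 6.2e-6, spectrum = broad_spectrum(),
                              R = 77, N0 = 1.5e7, N = 1e9, n_cultures = 10,
                              generations = 10, read_len = 100, depth = 1000,
                              base_error = 1e-3, L_target = 3075,
                              p_inactivating = 0.33, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for every stochastic run", call. = FALSE)
  }
  stopifnot(true_mu_bp >= 0, R >= 1, N > N0, N0 > 0, n_cultures >= 1,
            generations >= 0, read_len >= 1, depth >= 1,
            base_error >= 0, base_error <= 1)
  structure(list(
    true_mu_bp = true_mu_bp, spectrum = spectrum, R = R, N0 = N0, N = N,
    n_cultures = n_cultures, generations = generations, read_len = read_len,
    depth = depth, base_error = base_error, L_target = L_target,
    p_inactivating = p_inactivating, seed = as.integer(seed)
  ), class = "sim_config")
}

#' A broad reference spectrum for simulations
#'
#' Transition-biased but with support on all 12 classes (each transition
#' class weighted twice each transversion class), emulating a broad-spectrum
#' mutator; used as the default sampling spectrum.
#'
#' @return A `mutation_spectrum` of sampling weights.
#' @export
broad_spectrum <- function() {
  cls <- mutation_classes()
  w <- ifelse(cls$type == "transition", 2, 1)
  spec <- dplyr::mutate(cls, count = as.integer(w), fraction = w / sum(w))
  new_mutation_spectrum(spec, total = sum(w))
}

#' Simulate a fluctuation assay
#'
#' Continuous-growth model of resistant-mutant accumulation: while a
#' culture grows deterministically from `N0` to `N`, resistance mutations
#' arise as a Poisson process with intensity `R * mu` per cell division,
#' and each mutant lineage grows exponentially alongside the population, so
#' a mutation arising at population size `n` contributes `N/n` resistant
#' cells at harvest. The pooled resistant frequency then satisfies
#' `E[f] = mu * R * ln(N/N0)`, the exact quantity the reporter estimator
#' inverts. A discrete per-generation binomial model is available with
#' `model = "discrete"` for benchmarking estimator bias.
#'
#' @param config A [simulation_config()]; its `true_mu_bp`, `R`, `N0`, `N`,
#'   `n_cultures` and `seed` fields are used.
#' @param model `"continuous"` (default) or `"discrete"`.
#' @return A list with `per_culture` (tibble: `culture`, `n_resistant`,
#'   `f`), `f_pooled`, and `truth` (the configuration echoed back).
#' @export
simulate_fluctuation_assay <- function(config, model = c("continuous", "discrete")) {
  model <- match.arg(model)
  mu <- config$true_mu_bp; R <- config$R; N0 <- config$N0; N <- config$N
  if (mu * R >= 1) stop("true_mu_bp * R must be << 1", call. = FALSE)
  expected_events <- mu * R * (N - N0)
  if (mu > 0 && expected_events < 1e-3) {
    warning("expected mutation events per culture < 1e-3; estimator unstable in this regime",
            call. = FALSE)
  }
  withr::with_seed(config$seed, {
    n_res <- vapply(seq_len(config$n_cultures), function(i) {
      if (mu == 0) return(0)
      if (model == "continuous") {
        k <- stats::rpois(1, expected_events)
        if (k == 0) return(0)
        n_at_event <- stats::runif(k, N0, N)
        sum(N / n_at_event)
      } else {
        g <- ceiling(log2(N / N0))
        mutants <- 0
        n_t <- N0
        for (gen in seq_len(g)) {
          n_next <- min(2 * n_t, N)
          divisions <- n_next - n_t
          mutants <- 2 * mutants + stats::rbinom(1, size = round(divisions), prob = mu * R)
          n_t <- n_next
        }
        mutants
      }
    }, numeric(1))
  })
  per_culture <- tibble::tibble(
    culture = seq_len(config$n_cultures),
    n_resistant = n_res,
    f = n_res / N
  )
  list(
    per_culture = per_culture,
    f_pooled = sum(n_res) / (config$n_cultures * N),
    truth = list(true_mu_bp = mu, R = R, N0 = N0, N = N, model = model,
                 seed = config$seed)
  )
}

#' Simulate a mutagenised clone population
#'
#' Each clone accumulates `Poisson(mu_bp * len * generations)` substitutions.
#' The substitution class is drawn from the spectrum's sampling weights and
#' the site uniformly among reference positions carrying that class's
#' reference base (so the realised spectrum follows the requested weights
#' regardless of reference base composition); sites within a clone are
#' distinct.
#'
#' @param ref_seq Reference sequence.
#' @param true_mu_bp Substitution rate per bp per generation.
#' @param generations Generations of mutagenesis.
#' @param spectrum Sampling weights (see [simulation_config()]).
#' @param n_clones Number of clones.
#' @param seed Integer seed.
#' @return A list with `sequences` (named character vector) and `truth`
#'   (tibble: `clone_id`, `position`, `ref`, `alt`).
#' @export
simulate_mutant_population <- function(ref_seq, true_mu_bp, generations,
                                       spectrum = broad_spectrum(),
                                       n_clones, seed) {
  ref <- toupper(as.character(ref_seq))
  L <- nchar(ref)
  ref_b <- strsplit(ref, "")[[1]]
  pos_by_base <- split(seq_len(L), ref_b)
  cls <- tibble::as_tibble(spectrum)[, c("class", "ref", "alt", "fraction")]
  if (any(is.na(cls$fraction)) || sum(cls$fraction) <= 0) {
    stop("spectrum must have positive total weight", call. = FALSE)
  }
  lambda <- true_mu_bp * L * generations
  withr::with_seed(seed, {
    res <- purrr::map(seq_len(n_clones), function(i) {
      k <- stats::rpois(1, lambda)
      if (k == 0) return(NULL)
      picks <- sample.int(nrow(cls), k, replace = TRUE, prob = cls$fraction)
      sub <- tibble::tibble(ref = cls$ref[picks], alt = cls$alt[picks])
      sub$position <- vapply(sub$ref, function(b) {
        sites <- pos_by_base[[b]]
        if (is.null(sites)) NA_integer_ else sites[sample.int(length(sites), 1)]
      }, integer(1))
      sub <- sub[!is.na(sub$position), , drop = FALSE]
      sub <- sub[!duplicated(sub$position), , drop = FALSE]
      dplyr::arrange(sub[, c("position", "ref", "alt")], .data$position)
    })
  })
  ids <- sprintf("clone_%03d", seq_len(n_clones))
  truth <- purrr::map2_dfr(res, ids, function(s, id) {
    if (is.null(s) || nrow(s) == 0) return(NULL)
    dplyr::mutate(s, clone_id = id, .before = 1)
  })
  if (nrow(truth) == 0) {
    truth <- tibble::tibble(clone_id = character(), position = integer(),
                            ref = character(), alt = character())
  }
  seqs <- vapply(seq_len(n_clones), function(i) {
    s <- res[[i]]
    if (is.null(s) || nrow(s) == 0) ref else apply_substitutions(ref, s)
  }, character(1))
  names(seqs) <- ids
  list(sequences = seqs, truth = truth)
}

#' Simulate Phred-scored amplicon reads
#'
#' Reads of fixed length are drawn from the clone population at uniform
#' starting offsets; each base is flipped to a uniformly chosen different
#' base with probability `base_error`, and the Phred string encodes the
#' error probability actually used. The total read count is chosen so the
#' mean per-position coverage equals `depth`.
#'
#' @param sequences Named character vector of source sequences (all the
#'   same length).
#' @param read_len Read length (<= sequence length).
#' @param depth Target mean per-position coverage.
#' @param base_error Per-base error probability.
#' @param seed Integer seed.
#' @return A tibble of reads: `read_id`, `source_id`, `offset` (0-based),
#'   `seq`, `qual` - the FASTQ payload plus its offset sidecar.
#' @export
simulate_reads <- function(sequences, read_len, depth, base_error, seed) {
  seqs <- as.character(sequences)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("source sequences must share one length", call. = FALSE)
  if (read_len > L) stop("read_len exceeds the sequence length", call. = FALSE)
  n_reads <- max(1L, round(depth * L / read_len))
  q_char <- rawToChar(as.raw(min(93L, max(0L, if (base_error > 0)
    error_to_phred(base_error) else 93L)) + 33L))
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    src <- sample.int(length(seqs), n_reads, replace = TRUE)
    offset <- sample.int(L - read_len + 1L, n_reads, replace = TRUE) - 1L
    seq_out <- substring(seqs[src], offset + 1L, offset + read_len)
    if (base_error > 0) {
      n_err <- stats::rbinom(n_reads, read_len, base_error)
      hit <- which(n_err > 0)
      for (i in hit) {
        b <- strsplit(seq_out[i], "")[[1]]
        at <- sample.int(read_len, n_err[i])
        b[at] <- vapply(b[at], function(x) sample(setdiff(bases, x), 1), character(1))
        seq_out[i] <- paste(b, collapse = "")
      }
    }
  })
  tibble::tibble(
    read_id = sprintf("read_%06d", seq_len(n_reads)),
    source_id = ids[src],
    offset = offset,
    seq = unname(seq_out),
    qual = strrep(q_char, read_len)
  )
}

#' Simulate a blue/white plaque assay
#'
#' Draws the lacZ-minus (white or light-blue) plaque count
#' `Binomial(n_plaques, expected_lacz_minus(mu, model))`; two thirds of the
#' inactive plaques are reported as white and the rest light-blue (display
#' split only - both phenotypes are lacZ-minus).
#'
#' @param true_mu_bp True substitution rate per bp per generation.
#' @param model An [inactivation_model()].
#' @param n_plaques Plaques screened.
#' @param seed Integer seed.
#' @return A `plaque_result` (see [summarize_plaques()]) plus a
#'   `truth` attribute carrying the generating parameters.
#' @export
simulate_plaque_assay <- function(true_mu_bp, model = inactivation_model(),
                                  n_plaques, seed) {
  stopifnot(n_plaques > 0)
  p <- expected_lacz_minus(true_mu_bp, model)
  withr::with_seed(seed, {
    n_minus <- stats::rbinom(1, n_plaques, p)
    n_white <- stats::rbinom(1, n_minus, 2 / 3)
  })
  out <- summarize_plaques(n_blue = n_plaques - n_minus,
                           n_light_blue = n_minus - n_white,
                           n_white = n_white)
  attr(out, "truth") <- list(true_mu_bp = true_mu_bp, model = model,
                             expected_fraction = p, seed = seed)
  out
}

#' Standard synthetic benchmark for the deep caller
#'
#' Builds an amplicon read set with exactly known truth: `n_mut` distinct
#' reference positions are each mutated in a fixed fraction of the clone
#' population (`clone_frequency`), alternate bases drawn from `spectrum`;
#' sample and control reads are then simulated at the same depth and
#' per-base error. The defaults - a 100-bp amplicon fully covered by
#' single-end 100-bp reads at depth 1000, 10 positions mutated at 5%,
#' Q30-grade error 1e-3 - are chosen so that a 5% variant sits far above
#' the sequencing-noise floor (see the methods vignette for the power
#' analysis).
#'
#' @param ref_seq Reference amplicon; default a fixed 100-bp synthetic
#'   sequence.
#' @param n_mut Number of truly mutated positions.
#' @param clone_frequency Fraction of clones carrying each mutation.
#' @param n_clones Clone population size.
#' @param depth,read_len,base_error Read-simulation settings.
#' @param spectrum Sampling weights for alternate bases.
#' @param seed Integer seed.
#' @return A list with `ref_seq`, `sample_reads`, `control_reads`, and
#'   `truth` (tibble `position`, `ref`, `alt`, `frequency`).
#' @export
simulate_caller_benchmark <- function(ref_seq = synthetic_amplicon(),
                                      n_mut = 10, clone_frequency = 0.05,
                                      n_clones = 20, depth = 1000,
                                      read_len = NULL, base_error = 1e-3,
                                      spectrum = broad_spectrum(), seed) {
  ref <- toupper(as.character(ref_seq))
  L <- nchar(ref)
  if (is.null(read_len)) read_len <- L
  ref_b <- strsplit(ref, "")[[1]]
  carriers_per_mut <- max(1L, round(clone_frequency * n_clones))
  cls <- tibble::as_tibble(spectrum)
  withr::with_seed(seed, {
    positions <- sort(sample.int(L, n_mut))
    alt <- vapply(positions, function(p) {
      opts <- cls[cls$ref == ref_b[p], ]
      opts$alt[sample.int(nrow(opts), 1, prob = opts$fraction)]
    }, character(1))
    assignment <- lapply(seq_len(n_mut), function(i) {
      sample.int(n_clones, carriers_per_mut)
    })
  })
  truth <- tibble::tibble(position = positions, ref = ref_b[positions], alt = alt,
                          frequency = carriers_per_mut / n_clones)
  clone_seqs <- vapply(seq_len(n_clones), function(ci) {
    mine <- which(vapply(assignment, function(a) ci %in% a, logical(1)))
    if (length(mine) == 0) ref
    else apply_substitutions(ref, truth[mine, c("position", "ref", "alt")])
  }, character(1))
  names(clone_seqs) <- sprintf("clone_%03d", seq_len(n_clones))
  sample_reads <- simulate_reads(clone_seqs, read_len, depth, base_error,
                                 seed = seed + 1L)
  control_reads <- simulate_reads(c(wt = ref), read_len, depth, base_error,
                                  seed = seed + 2L)
  list(ref_seq = ref, sample_reads = sample_reads, control_reads = control_reads,
       truth = truth)
}

#' A fixed synthetic amplicon sequence
#'
#' A deterministic 100-bp sequence with balanced base composition, used as
#' the default reference for deep-caller benchmarks. Synthetic; it is not
#' any natural gene.
#'
#' @param length Sequence length (default 100).
#' @return A single DNA string.
#' @export
synthetic_amplicon <- function(length = 100) {
  bases <- c("A", "C", "G", "T")
  withr::with_seed(20260101, paste(sample(bases, 1000, replace = TRUE), collapse = "")) |>
    substr(1, length)
}

#' Score caller output against a benchmark truth set
#'
#' @param table A called `position_call_table`.
#' @param truth Truth tibble with `position` (as from
#'   [simulate_caller_benchmark()]).
#' @return A one-row tibble with `n_true`, `n_called`, `tp`, `fp`, `fn`,
#'   `recall`, `precision`.
#' @export
score_calls <- function(table, truth) {
  called <- called_positions(table)$position
  tp <- sum(called %in% truth$position)
  fp <- length(called) - tp
  fn <- nrow(truth) - tp
  tibble::tibble(
    n_true = nrow(truth), n_called = length(called),
    tp = tp, fp = fp, fn = fn,
    recall = if (nrow(truth) > 0) tp / nrow(truth) else NA_real_,
    precision = if (length(called) > 0) tp / length(called) else NA_real_
  )
}
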