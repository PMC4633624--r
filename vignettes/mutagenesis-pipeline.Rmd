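---
title: "Quantifying in vivo mutagenesis: models, estimators and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying in vivo mutagenesis: models, estimators and synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutascope)
library(dplyr)
```

mutascope quantifies how strongly an inducible mutator (a mutagenesis
plasmid, a hypermutator strain, a chemical treatment) elevates the
substitution rate of a bacterial host or of a phage vector it propagates.
It covers four measurement channels that are usually analysed together:

1. a chromosomal reporter fluctuation assay (rifampin resistance via
   *rpoB*), converted to a per-bp rate by a closed-form estimator;
2. mutational spectra over the 12 strand-specific substitution classes,
   from single-clone (Sanger-style) reporter sequences;
3. amplicon deep sequencing of a phage-borne *lacZ* cassette, with
   background-subtracted per-position mutation calling;
4. a blue/white plaque screen, linked to a rate by a Poisson inactivation
   model.

A forward-time synthetic-data module generates every input with known
ground truth, so each estimator can be validated end to end without any
wet-lab data.

## The reporter-based rate estimator

Parallel cultures grow from a small inoculum to saturation; plating on
rifampin counts the resistant subpopulation. With

* `f` — resistant-mutant frequency relative to the non-selective control,
* `R` — number of distinct nucleotide sites that confer resistance
  (default 77, the canonical count for the two *rpoB* clusters; studies
  that observe fewer distinct sites in their own data may override it —
  it is an argument everywhere),
* `N` — final population size,
* `N0` — population size at which resistance first becomes observable
  (default `1.5e7`),

the per-bp substitution rate is

$$\mu_{bp} = \frac{f}{R \,\ln(N/N_0)}.$$

The logic: while the population grows from `N0` to `N` it passes through
`ln(N/N0)` "effective" exponential doublings in continuous time; each cell
division contributes `R * mu` new resistant lineages, and a lineage founded
at population size `n` coasts to a final share `N/n`. Integrating gives
`E[f] = mu * R * ln(N/N0)`, which the estimator inverts exactly. Per-genome
rates are `mu_bp * genome_len` (default `4.64e6` bp, E. coli MG1655), and
are displayed at 2 significant figures while full precision is kept in the
tibbles.

```{r}
mu <- estimate_mu_bp(f = 2.005e-3, R = 77, N = 1e9, N0 = 1.5e7)
c(mu_bp = mu, mu_g = genome_rate(mu))
```

The fluctuation simulator implements exactly this continuous-growth
compound-Poisson model (`simulate_fluctuation_assay()`): mutation events
per culture are `Poisson(R * mu * (N - N0))`, the population size at each
event is uniform on `(N0, N)` (one event per division), and the lineage
share is the deterministic `N/n`. This calibration makes the estimator
unbiased by construction, which is the property the recovery tests check.
A discrete per-generation binomial model (`model = "discrete"`) is kept for
benchmarking: it counts doublings in units of `log2`, so naively pairing it
with the `ln`-based estimator biases recovery by roughly `1/ln 2`, a useful
reminder that estimator and growth model must share a clock.

Jackpot cultures (mutations arising near `N0`) make single-culture `f`
heavy-tailed; the package therefore reports per-culture and pooled
frequencies, and the recovery tests average over replicate assays.
Maximum-likelihood fluctuation estimators (Ma–Sandri–Sarkar and kin) are
deliberately out of scope; only the frequency-based estimator above is
implemented.

## Substitution classes and spectra

`mutation_classes()` enumerates the 12 ordered substitutions; collapsing a
class with its reverse complement yields 6 base-pair classes labelled
purine-first (`G:C>A:T`, ...). The pyrimidine-first orderings and unicode
arrows that appear in the literature are accepted as input synonyms
(`normalize_collapsed_label()`). Ambiguity codes are rejected rather than
skipped so that every spectrum is an auditable tally of its inputs. Both
the 12-class and 6-class views are exposed (`collapse_spectrum()`); which
to report is the user's choice, since reporter datasets are conventionally
shown collapsed while deep-sequencing spectra are often strand-specific.

Spectra are compared by total-variation distance over the 12 fractions,
`0.5 * sum(|a_i - b_i|)` — symmetric, in `[0, 1]`, and zero only for equal
fractions.

## Clone sequencing

`diff_clone()` is a position-wise comparison: the assay products are
fixed-length amplicons, so equal-length comparison is the default and a
global aligner (match +1, mismatch −1, gap −2) exists only to *reject*
clones with indels (`has_indels()`); indel genotyping is out of scope.
Amino-acid changes are named by translating the *whole* mutated codon, so
two substitutions in one codon give one joint call — this is how a
genotype such as S531F is read off a clone. The *rpoB* cluster windows
(aa 451–754 and 84–401) and the residue-numbering offset are configuration
with documented defaults; the package does not ship the *rpoB* sequence.

## The deep-sequencing caller

The caller follows a corrected-fraction procedure:

1. **Quality filter.** Bases with Phred < 30 are masked and excluded from
   all counts (Q30 ⇔ ≥ 99.9 % base accuracy). Masking is per base — the
   procedure counts positions, so discarding whole reads for one bad cycle
   would waste signal; a per-read-mean mode exists for comparison since the
   original description does not say which was used.
2. **Per-position deviation fractions** for sample and control: the share
   of unmasked observations differing from the reference. Paired reads
   covering the same position of one fragment count once.
3. **Background subtraction.** `corrected = max(0, dev_sample - dev_control)`
   per position. The floor at zero is deliberate: a negative mutation
   fraction is meaningless and would drag down the treatment mean that the
   call rule depends on.
4. **Call rule.** A position is called when its corrected fraction is both
   greater than the *mean* corrected fraction of the treatment and more
   than one standard deviation above the control at that position. The
   s.d. is taken *across positions* of the control's deviation fractions —
   a single control table provides no per-position replicate dispersion,
   so across-position spread is the only estimable choice.
5. Each call carries its dominant alternate base (highest sample count
   among non-reference bases, alphabetical tie-break) for spectrum
   aggregation.

Reads are substitution-only and arrive with explicit reference offsets
(the synthetic sidecar, or a full-match-CIGAR SAM); no gapped alignment is
performed.

### Benchmark geometry and power

The standard synthetic truth set (`simulate_caller_benchmark()`) is a
100-bp amplicon fully covered by single-end 100-bp reads at depth 1000,
with 10 positions each mutated in 5 % of a 20-clone population and a
Q30-grade per-base error of `1e-3` in sample and control. The amplicon
length is a designed choice, not arbitrary: the treatment-mean threshold
of the call rule scales as (total true signal)/L, so at these settings it
sits near `10 * 0.05 / 100 ≈ 5e-3` — about five error counts above a
Poisson noise floor of ~1 count per position — and false calls are
vanishingly rare while a 5 % variant (≈ 50 deviant reads) is unmissable.
On substantially longer amplicons with the same sparse signal the
threshold drops toward the noise floor and the *relative* part of the rule
starts admitting Skellam-tail false positives; that regime is a property
of the published rule itself, worth knowing when applying it to long
references with few true mutations. Spectrum recovery is scored against
the generator's *realized* truth table rather than its sampling weights:
with ~20 calls, multinomial noise against the weights alone would exceed
any useful bound.

```{r}
b <- simulate_caller_benchmark(seed = 1)
tab <- deep_call_pipeline(b$sample_reads, b$control_reads, b$ref_seq)
score_calls(tab, b$truth)
```

## The plaque inactivation model

The blue/white screen reads out *lacZ* integrity. The package links the
white-or-light-blue (lacZ⁻) plaque fraction to a rate through a Poisson
hit model: substitutions strike the `L_target`-bp cassette over `g`
copyings, each inactivating with probability `p`, giving

$$F = 1 - e^{-\mu_{bp}\, L\, g\, p}, \qquad
  \hat\mu_{bp} = \frac{-\ln(1-F)}{L\,g\,p}.$$

Light-blue plaques count as lacZ⁻. Defaults: `L_target = 3075` bp (the
length of a standard *lacZ* ORF — a package default, not a measurement)
and `p = 0.33`, an explicit user assumption (roughly the share of random
substitutions that knock out function through nonsense and severe missense
changes); both appear in every report so the assumption is never silent.
At `F = 1` the assay saturates and the rate is unidentifiable — the
inversion raises an error rather than extrapolating. Phage population
dynamics during propagation (selection against mutants, multi-cycle
infection) are not modelled.

## Synthetic-data contract

Every generator takes an explicit seed, uses one local RNG scope
(`withr::with_seed`) so no global state leaks, and emits a machine-readable
truth table sufficient to score recall and precision exactly; identical
seed and configuration give byte-identical files. `simulate_dataset()`
writes a provenance JSON (config + seed + package version) from which any
report can be regenerated.

Two generator choices worth knowing:

* **Class-first substitution sampling.** `simulate_mutant_population()`
  draws the substitution class from the spectrum weights first and then a
  site uniformly among reference positions with that class's reference
  base. Position-first sampling would re-weight the realized spectrum by
  the reference's base composition, so a requested spectrum could never be
  recovered exactly on a skewed reference; class-first makes the realized
  spectrum converge to the requested weights for any reference.
* **What the reads do not emulate.** Uniform per-base error, no quality
  decay along the read, no PCR bias, chimeras or paired-insert geometry.
  Passing benchmarks therefore demonstrates correctness of the counting
  and calling arithmetic under the stated error model, not robustness to
  every artefact of a real sequencing run.

## Problem sizes

The shipped tests and the acceptance script run the recovery experiments
at desk scale, chosen to keep sampling error well inside the tested
tolerances: 50 replicate fluctuation assays of 2 cultures each
(single-culture CV of `f` is below 1 % at the default MP6-grade settings,
so the mean is far inside the 15 % band), caller benchmarks at depth
1000–5000 over 100–150-bp amplicons, and 100 plaque screens of 1000
plaques. Larger runs only shrink the Monte-Carlo error.

## Known limitations

* Substitutions only: indels are excluded everywhere by design.
* The caller corrects systematic per-position background but not
  treatment-specific propagation effects (e.g. selection during phage
  growth); counts across treatments are comparable only as far as those
  effects are shared.
* The inactivation model's `p_inactivating` is an assumption; inferred
  phage rates scale as `1/p` and should be read with that uncertainty.
* The fluctuation estimator is a frequency method: it is unbiased under
  the continuous-growth model but noisier than likelihood-based
  fluctuation estimators, which are intentionally not implemented.
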