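---
title: "Scoring pooled prime-editing screens from surrogate-target sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pooled prime-editing screens from surrogate-target sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pescreen)
library(dplyr)
```

## The assay and its statistical model

A pooled prime-editing (PE) screen delivers a library of pegRNAs by
lentivirus, one cassette per cell. Each cassette couples the pegRNA
(spacer, scaffold, 3' extension) to a 55-nt *surrogate target* (ST) — a
copy of the genomic site the pegRNA edits — a unique 16-nt pegRNA barcode
and a 10-nt library barcode. Sequencing the cassette therefore reports two
things at once: the *abundance* of each pegRNA in the population
(selection readout) and the *fraction of its STs carrying the intended
edit* (editing-activity readout, a proxy for editing of the endogenous
target, ET).

The analysis rests on three modelling commitments:

1. **Selection acts on edited cells only.** A pegRNA population is a
   mixture of unedited carriers (fitness 1) and edited cells whose fitness
   is $2^{s}$ per unit time, where $s$ is the variant effect in doublings.
   After selection time $T$, the relative abundance of a pegRNA with
   editing probability $e$ is proportional to
   $(1 - e) + e \, 2^{sT}$.
   This is why filtering on ST activity matters: an inactive pegRNA is an
   abundance control, not a measurement of its variant.
2. **pegRNA scores are pseudocounted log2 fold changes.** Counts are
   incremented by 1, converted to frequencies
   $f_i = (c_i + 1) / \sum_j (c_j + 1)$ over all pegRNAs surviving the
   negative-control filter, and scored as
   $\log_2(f^{\text{post}}_i / f^{\text{pre}}_i)$. The pseudocount keeps
   scores finite; frequencies are always computed on the full retained
   library and the frequency/activity filters are applied *afterwards*, so
   a filtered pegRNA never distorts another pegRNA's denominator.
3. **Neutral variants define zero and the null.** Synonymous (or, for
   non-coding screens, benign-intronic) variants anchor every
   normalisation step (median subtraction in log2 space) and provide the
   empirical normal null for significance: $p$-values are one-sided tail
   probabilities of $N(\hat\mu, \hat\sigma)$ fitted to neutral function
   scores by moments, BH-adjusted over all scored variants, with LoF
   called strictly below the q cutoff.

## From reads to counts

Read 1 (182 nt) covers spacer, scaffold and 3' extension; read 2 (118 nt)
covers ST, pegRNA barcode and library barcode, stored in the orientation of
the library table (the reader never guesses strand). Elements are sliced at
fixed offsets derived from the library design; an optional anchor search
(scaffold prefix, one tolerated substitution) recovers reads with small
upstream indels.

Each identity-bearing element — spacer, extension, the invariant ST 3' end,
and pegRNA barcode — is matched against the design candidates with a
Hamming tolerance of `floor(0.10 * length)` ("up to 10% substitutions",
read as an inclusive bound on the fraction). Only the ST 3' end is used so
that *edited* STs still match their design. Matching rules worth noting:

* the minimum-distance candidate wins; a tie at the minimal distance
  (including exact ties across candidates of different lengths, which can
  occur because 3' extensions vary in length) yields *no* match — identity
  is never guessed;
* `N` bases count as mismatches;
* a read is **assigned** when the intersection of the pegRNA sets implied
  by all confidently matched elements is a single pegRNA, **recombinant**
  when matched elements are mutually inconsistent (lentiviral template
  switching swaps the ST+barcode block between cassettes), and
  **unassigned** otherwise. Recombinants are discarded: their abundance
  would otherwise be credited to the wrong variant.

ST editing is quantified by *exact* containment of the intended edit
flanked by exactly 5 nt on each side. Sequencing errors inside this
11+ nt core therefore undercount editing slightly (about 1% at a
$10^{-3}$ per-base error rate); we accept this bias as the cost of never
counting a miscalled edit. Editing percentages are reported only for
pegRNAs with at least 10 ST reads — below that the percentage is noise —
and pegRNAs with more than 5% apparent editing in the editor-free negative
control (strictly greater; a control value of exactly 5% is retained) are
excluded as synthesis/sequencing artefacts. Reads with an ST that is
neither reference nor edited still count in the editing denominator: they
are genuine STs of that pegRNA whose outcome we could not read, and
dropping them would bias editing upwards.

## From counts to function scores

Replicate samples of the same condition and timepoint are collapsed
(counts summed, editing percentages averaged) before frequencies are
computed. Default thresholds follow the regimes they were designed for:

| parameter | default | meaning |
|---|---|---|
| `min_st_reads` | 10 | ST reads needed before an editing % is defined |
| `neg_ctrl_editing_max_pct` | 5% | control-editing exclusion (strict >) |
| `element_mismatch_frac` | 0.10 | per-element substitution tolerance |
| `freq_min` | 6e-5 | pre-selection frequency floor (1.4e-4 / 1.0e-4 for the positive-selection regimes) |
| `st_activity_min_pct` | 75% | activity floor (5% / 25% for high-editing cell lines in positive selection) |
| `q_cutoff` | 0.05 | LoF call threshold (0.01 for positive selection) |
| `min_neutral` | 5 | neutral entries required for any normalisation or null fit |

Two aggregation modes exist because the two screen designs normalise at
different levels:

* **single** (negative-selection essentiality screen): pegRNA scores are
  normalised to the neutral median, then averaged per variant;
* **multi** (positive-selection screens across several cell pools): per
  condition, retained pegRNA scores are averaged per variant; condition
  scores are normalised to that condition's neutral median; variants
  scored in at least two conditions are averaged (unweighted — a condition
  is a condition regardless of how many pegRNAs it contributed) and
  normalised once more. Cell-line-specific scores repeat the recipe
  restricted to one line's conditions.

After the final normalisation the neutral median is exactly zero by
construction, which the test suite asserts.

`threshold_sweep()` re-runs the entire aggregation at each ST-editing
threshold and reports the pLoF/pNeut AUC (rank-based, ties one half) and
the retention cost; `high_stringency_threshold()` returns the smallest
grid value at which the pLoF and pNeut score ranges are disjoint among
variants at or above that mean editing.

## Endogenous-target cross-validation

ET variant counts (produced externally, or by `simulate_et_counts()`) are
background-corrected by subtracting negative-control frequencies (clamped
at zero); variants whose control frequency exceeds 4e-4 are excluded
outright as site-specific sequencing error. A variant must additionally
gain at least 1 log2 unit of frequency across the editing window to count
as installed; the gain reference is the earliest pre-selection timepoint
when two exist, otherwise the negative control (both used in practice by
the screens this package models). Gains are computed on corrected
frequencies for consistency with the score step. No pseudocount is applied
at the ET level — a zero pre-selection frequency excludes the variant
(`zero_denominator`) rather than inventing a count. Exclusion precedence
is fixed: `not_programmed`, then `high_control_background`, then
`zero_denominator`, then `low_editing_gain`; each (variant, condition)
carries at most one reason. Scores then follow the multi-condition recipe
(log2 post/pre, neutral-normalise, average, renormalise).

## What the simulator emulates — and what it does not

`simulate_library()` + `simulate_screen()` generate screens with known
truth:

* **bimodal editing**: per-pegRNA baseline editing rates are drawn from a
  Beta mixture, `0.45 * Beta(0.3, 3) + 0.55 * Beta(5, 1.5)` — an inactive
  mode near 0 and an active mode near 1, mirroring the strongly bimodal
  sensor-editing distributions such screens show after extended culture.
  The weights and shapes are tunable and are a modelling choice, not a
  measured quantity;
* **editing accumulation**: the editing probability at timepoint $t$ is
  $\min(1, e_0 \cdot g^{t - t_{\text{pre}}})$ with growth factor
  $g = 1.4$ per timepoint unit, so the mixture describes editing at the
  pre-selection harvest;
* **selection**: post-selection abundance follows the mixture-fitness
  formula above; within a surviving pegRNA population the edited fraction
  is reweighted by the same factor, so strongly depleted pegRNAs also show
  depressed post-selection editing — selection is strongest against the
  most active pegRNAs;
* **effect spectrum**: 15% of variants are fully LoF ($s = -2$ doublings
  per unit time under negative selection), 30% are hypomorphic with
  effects uniform between 10% and 90% of the LoF effect, the rest neutral
  ($s = 0$). Saturation mutagenesis of a functional element produces a
  graded spectrum, not a binary one; an all-or-nothing truth would also
  make rank-recovery statistics degenerate through ties;
* **nuisance processes**: 2% cassette recombination (ST+barcode block
  swapped with a random other cassette; no quantitative rate is published,
  this is a free parameter), $10^{-3}$ per-base substitution error,
  lognormal library representation (log-sd 0.5), multinomial sampling at
  5e5 read pairs per sample, and a negative control whose apparent editing
  is pure background ($10^{-3}$).

Not modelled: PCR duplicates, GC bias, indel sequencing errors, positional
error hotspots, UMI structure, or cell-cycle/fitness effects independent
of the programmed edit. Passing the recovery tests therefore shows the
pipeline correctly inverts *this* generative model — multinomial counting
noise, bimodal activity, recombination and substitution error — not that
it is robust to every artefact of real screens.

Determinism: all outputs, including FASTQ bytes, are reproducible from
`sim_params(seed = ...)`; library generation, screen sampling and ET
sampling use distinct seed offsets so that changing one stage's output
does not silently reshuffle another's.

## Numerical choices and degenerate inputs

* Mismatch allowance `floor(0.1 * L)`: 1 substitution for a 16-nt barcode,
  2 for a 20-nt spacer.
* Median with an even neutral count is the mean of the central pair
  (standard `median()`); fewer than `min_neutral = 5` usable neutral
  values is a hard error rather than a silent wide null.
* A constant neutral set (zero variance) is an error: no null can be fit.
* AUC with an empty class is `NA`, as is a sweep threshold that retains no
  scorable variant.
* One-sided tests in the selection direction are the default: a depletion
  screen asks only whether a variant dropped out. `one_sided = FALSE` is
  available where a two-sided question is intended.
* BH is applied over all variants receiving a final function score in the
  screen — not per condition, and not over the unfiltered library.

## Worked example at desk scale

The suite and the acceptance script run everything below at these problem
sizes: 200 variants at 5 pegRNAs per variant and 5e5 read pairs per sample
for statistical properties (3 seeds; 20 seeds for the all-null false-call
rate), and 15-50-variant libraries for read-level checks. These sizes give
stable statistics while keeping a full run in seconds.

```{r example, eval = FALSE}
cfg <- screen_config(scoring_mode = "single")
sim <- simulate_library(sim_params(seed = 1))
samples <- sim_sample_sheet("single")
screen <- simulate_screen(sim, samples)
obs <- add_editing_pct(screen$observations, cfg)
run <- run_screen(sim$library, samples, cfg, observations = obs,
                  et = simulate_et_counts(sim, samples))
glance(run)
autoplot(run$sweep)
```

## Known limitations

* pegRNA scores are unweighted by editing strength; a variant scored by a
  75%-editing and a 95%-editing pegRNA treats both as equally informative.
* The activity filter uses pre-selection editing only; pegRNAs whose
  editing accumulates late are filtered out even if they carry signal.
* Hypomorphic variants are scored but the null/alternative framework is
  binary; no mixture model separates intermediate effects from noise.
* The exact-containment editing rule undercounts editing in proportion to
  the per-base error rate times the core length.
* ET analysis consumes variant count tables; amplicon alignment and
  variant calling are upstream of this package.
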