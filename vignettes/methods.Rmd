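---
title: "Fragment-mass prediction and QC for mass-spectrometric methylation assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-mass prediction and QC for mass-spectrometric methylation assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicleave)
```

## The measurement being modelled

Mass-based bisulfite re-sequencing quantifies DNA methylation of
100–600 bp genomic regions. Bisulfite treatment converts every
unmethylated cytosine to uracil (thymine after PCR) while
5-methyl-cytosine survives; a T7 tag on the reverse PCR primer drives
in-vitro transcription of the reverse strand; RNase A then cleaves the
transcript 3' of every uridine (the reaction incorporates deoxy-C, so C
positions resist cleavage); and the fragments are weighed by MALDI-TOF.
A fragment containing one or more CpGs — a *CpG unit* — appears at two
masses 16 Da apart per CpG, and the methylation fraction is the peak-area
ratio of the methylated states. Sites sharing a fragment cannot be
separated; the unit is the quantum of measurement.

`epicleave` simulates this chemistry exactly as the pipeline above:

```{r chem}
bisulfite_convert("GGATCATGGCTCGAGTCC", methylation = FALSE)
transcribe_reverse("GGGATGTTTTAGG")
t_cleave("CCUAAAACAUCCC")
```

Two useful consequences of the chemistry, both enforced as invariants and
exercised by the property tests:

* the two transcript bases arising from a CpG (a C from the genomic G, and
  G or A from the genomic C depending on methylation) are adjacent and
  neither is ever U, so a CpG always sits wholly inside one fragment and
  switching its methylation never moves a cleavage site;
* concatenating the fragments in order reproduces the transcript, and the
  fragment multiset matches a brute-force character-scan oracle on random
  sequences.

## The mass model

A fragment with transcript base counts $(n_A, n_C, n_G, n_U)$ and $m$
methylated CpGs weighs

$$M = \sum_b n_b \mu_b + \kappa + 16.00\, m,$$

with average in-chain residue masses $\mu_A = 329.21$, $\mu_C = 289.18$
(the deoxy form — dCTP is what the T reaction incorporates), $\mu_G =
345.21$, $\mu_U = 306.17$ Da. The methylation shift is not a free
parameter: a protected genomic C templates transcript G where a converted
C templates A, and $\mu_G - \mu_A = 16.00$; `mass_model()` refuses
configurations that break this identity by more than 0.05 Da.

The terminal-group constant $\kappa$ absorbs the 5'/3' end chemistry of
the cleavage products, which is not published. It was calibrated once
against the four reference unit masses of the leptin worked example
(per-row estimates 19.026–19.037 Da, i.e. consistent to about the
3-decimal rounding of the printed masses) and frozen at their mean,
19.031 Da. `calibrate_kappa()` re-derives it from any set of known
composition/mass pairs should a different instrument calibration be
needed. Masses are reported to 3 decimals and matched in tests with an
absolute tolerance of 0.05 Da.

Defaults that matter, all overridable in `mass_model()` or by CLI flags:

| parameter | default | meaning |
|---|---|---|
| `min_mass`, `max_mass` | 1500, 7000 Da | measurable window of the spectrometer |
| `collision_tolerance` | 1.0 Da | peaks closer than this are one peak; 1 Da separates all distinct compositions in the relevant range |
| `near_collision_threshold` | 15.9 Da | neighbours this close inflate triplicate variance and are reported with their distance |
| `adduct_shift` | 22 Da | sodium satellite offset, simulation-only |

## Assay evaluation

`amplicon_report()` enumerates the CpG units of the unmethylated
fragmentation and assigns warnings: `L_MASS`/`H_MASS` when any mass state
leaves the window; `DUP` when another unit has the identical composition;
`OVERLAP` when any state of one unit falls within the collision tolerance
of any state of another (both checked across *all* methylation states of
both units); `SILENT_OVERLAP` when a CpG-free fragment collides;
`NEAR` with the recorded distance otherwise when something sits closer
than 15.9 Da. A unit is measurable iff it carries none of `L_MASS`,
`H_MASS`, `DUP`, `OVERLAP`. `SILENT_OVERLAP` does not disqualify a unit
by itself — the analysis software can often subtract a silent
fragment's signal — but such units run a higher measurement error and, in
the worked example below, the affected unit ends up removed by the
success-rate rule rather than by warning class.

Conversion-control fragments are CpG-free fragments witnessing at least
one converted non-CpG cytosine, inside the window, whose unconverted
satellites (+16 Da per retained C) collide with nothing; residual signal
there flags incomplete bisulfite conversion.

```{r lep}
amp <- read_amplicon_text(
  system.file("extdata", "lep_amplicon.txt", package = "epicleave"),
  name = "LEP")
amplicon_report(amp)
```

The annotated-markup parser accepts the exchange format used for such
sequences: `[...]` around the target, `<X>` masking SNP/repeat positions,
and bare `>`/`<` as forward/reverse primer boundaries. Disambiguation is
positional — a `<...>` pair enclosing DNA is always a mask, a `>` with no
open mask is the forward-primer end, a trailing unclosed `<` is the
reverse-primer start — and nested markup is rejected rather than guessed
at. A CpG whose C or G is masked is flagged, never silently dropped;
exclusion is a QC-stage decision.

## The QC pipeline

Collapsing and filtering follow the standard rule set, in this order:

1. a (sample, unit) cell with fewer than 2 successful replicates is
   missing;
2. a cell whose replicate SD is ≥ 0.1 (10 percentage points of
   methylation) is missing — the SD uses the $n-1$ denominator, computed
   over the non-missing replicates (whether the reference convention drops
   failed replicates first is unstated; the published worked-example
   acceptance count is invariant to the choice);
3. surviving replicates are averaged;
4. units with a success rate below 80% over biological samples are
   removed — control wells (water, unconverted gDNA, or any configured id
   list) leave both the denominator and the output;
5. units warned `D`/`OL` are removed outright when `remove_overlaps` is
   on;
6. units containing a common SNP are removed;
7. clearly bi-/tri-modal units are flagged as likely SNP-confounded.

Every removal lands in an exclusion log (`scope`, `id`, `rule`,
`detail`), and the pipeline is idempotent: running `filter_units()` on
its own output changes nothing.

Multimodality (rule 7) fits one- and two-component Gaussian mixtures by
EM (`mclust`) and flags a unit when the two-component fit wins on BIC
*and* the component means differ by more than 0.2 *and* both weights
exceed 0.2 — the extra conditions stop BIC from calling slight skew or a
heavy tail "bimodal". Fewer than 20 values is not assessable, and a
constant vector is reported degenerate rather than fitted. The flag is
advisory by default because removal requires judgment; the pipeline's
`drop_multimodal` option automates it.

The per-well conversion score is `100 * unconverted / (converted +
unconverted)` signal at a conversion-control fragment, averaged over
control fragments, with scores ≥ 2 flagged. The reference
implementation's exact formula for this metric is unpublished; this
intensity-ratio definition is an explicit stand-in and is labelled as
such wherever it is reported.

```{r qc}
grid_lines <- c("Sample\tCpG_2\tCpG_3",
                "001_101_01\t0.71\t0.20", "002_101_02\t0.72\t0.55",
                "003_101_03\t0.70\t0.90", "004_102_01\t0.80\t0.40",
                "005_102_02\t0.81\t0.41", "006_102_03\t0.82\t0.42",
                "gDNA\tNA\tNA")
qc <- parse_export_grid(grid_lines, "demo") |>
  collapse_replicates() |>
  filter_units()
qc$exclusions
```

## The simulators, and what passing tests do and do not show

`simulate_plate()` emulates the exported grid: triplicate rows per sample
under the `WWW_SSSS_RR` naming convention, replicate values equal to
truth plus clipped Gaussian noise, independent replicate failures,
optional SNP-confounded subpopulations on designated units, and all-NA
control rows. Defaults are fixed once as the simulated study conditions:
noise SD 0.02 (the magnitude of well-behaved triplicate SDs in practice),
replicate failure probability 0.05, and — when a bimodal unit is
designated — half the samples shifted by 0.5. Clipping to [0,1] makes the
noise truncated-normal, appropriate because real SDs are small relative
to the unit interval. Multi-CpG units assume independent per-CpG
methylation when the spectrum simulator distributes peak area
binomially — the simplest generative model consistent with the per-unit
ratio readout.

`simulate_spectrum()`/`integrate_and_quantify()` close the loop at the
spectrum level: Gaussian peaks at every mass state with binomial areas,
additive baseline noise, trapezoidal integration in a ±6 Da window with a
median off-peak baseline subtraction, and the generalized area ratio
$\hat m = \sum_j j\,A_j / (n \sum_j A_j)$. Quantification is invariant to
intensity scaling, and estimates are flagged unreliable if two states of
one unit fall within one integration window.

What these simulators deliberately do **not** model: MALDI physics (laser
and matrix effects, arched baselines), unspecific cleavage, non-specific
PCR products, charge states and isotopic structure, and (by default)
sodium adducts — an option adds +22 Da satellites for robustness checks.
Recovery of truth by the pipeline on simulated plates therefore validates
the *rules and their composition*, not instrument behaviour; real data
still require the manual spectrum inspection the assay protocol calls
for.

## Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere a user sees them; CpG
  sites are numbered from the 5' end of the genomic sequence and the
  numbering is stable under masking.
* **Input is always the forward template**; reverse-strand assays are the
  caller's reverse complement, mirroring how designs are made per strand.
* **Primer tag bases** are excluded from fragmentation: the reference
  unit masses were produced without tag context.
* **Collision ties**: `DUP` implies `OVERLAP` at distance 0; `NEAR` and
  `OVERLAP` are mutually exclusive for a pair.
* **Determinism**: every stochastic function takes an explicit seed and
  restores the caller's RNG state, so plate layouts, simulated plates and
  simulated spectra are reproducible independently.
* **Degenerate inputs**: CpG-free amplicons give empty (not failing) unit
  tables; all-zero peak pairs give `NA` ratios; empty grids, duplicate
  sample rows and out-of-range values fail fast with the offending cell
  named.
* **Problem sizes** used by the shipped tests: 60-mer random amplicons
  (1,000 for the oracle-equivalence property), simulated plates of 30–50
  samples in triplicate, 100-seed Monte-Carlo for noisy quantification —
  desk-scale runs chosen to exercise every rule with comfortable margins.

## Known limitations

* $\kappa$ is an empirical constant; if an instrument reports masses under
  a different end-group chemistry it must be recalibrated
  (`calibrate_kappa()`).
* The vendor software occasionally emits warnings this model does not
  reproduce from sequence alone — in the leptin worked example it flagged
  a silent-fragment overlap (`SN`) on one unit where the tag-free
  fragmentation shows no collision; whether primer-tag-derived fragments
  cause it is unresolved, and the QC pipeline treats such grid warnings
  as annotations rather than recomputing them.
* The multimodality check is a screen, not a genotype inference; a real
  SNP call needs the genomic annotation the amplicon markup carries.
* The conversion score is qualitative; conversion-control fragments are
  inherently low-signal.
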