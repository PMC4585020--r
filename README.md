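# epicleave

Mass-spectrometry-based bisulfite sequencing measures region-specific DNA
methylation quantitatively and at scale: a bisulfite-PCR amplicon is
transcribed from its reverse strand, the transcript is cleaved 3' of every
uridine, and the resulting fragments are resolved by MALDI-TOF. A fragment
containing a CpG is a *CpG unit*; when the CpG was methylated the cytosine
survives bisulfite treatment and the fragment is 16 Da heavier, so the
methylation fraction of the unit is read off the peak-area ratio of the two
mass states. `epicleave` implements the computational side of this assay
for people designing and running such measurements:

* **in-silico assay evaluation** — predict the T-reaction fragmentation and
  fragment masses of a candidate amplicon before ordering primers, flag CpG
  units that fall outside the measurable mass window or collide in mass
  with other fragments, and find bisulfite conversion-control fragments;
* **quality control** — turn exported triplicate measurement grids into a
  clean sample × CpG-unit methylation matrix with the standard rule set
  (replicate count, replicate-SD, success rate, overlap, SNP and
  multimodality filters) and a complete exclusion log;
* **plate design** — randomized 384-well triplicate layouts with the
  `WWW_SSSS_RR` naming convention (126 samples plus water and unconverted
  gDNA controls);
* **synthetic data** — plate and toy-spectrum simulators with known ground
  truth, so the whole pipeline is testable end to end without instrument
  data.

## The model in brief

For the T reaction, a fragment with transcript base counts
$(n_A, n_C, n_G, n_U)$ and $m$ methylated CpGs has average mass

$$M = \sum_{b} n_b\,\mu_b + \kappa + 16.00\,m \quad\text{(Da)},$$

with in-chain residue masses $\mu_A = 329.21$, $\mu_C = 289.18$ (deoxy-C —
the T-reaction incorporates dCTP, which is what restricts cleavage to U),
$\mu_G = 345.21$, $\mu_U = 306.17$, and a terminal-group constant
$\kappa = 19.031$ calibrated once against published reference unit masses.
The +16 Da methylation shift is the G−A residue difference: a protected
cytosine on the forward strand templates G in the reverse-strand transcript
where a converted cytosine templates A. Masses between 1,500 and 7,000 Da
are measurable by default; peaks within 1 Da are treated as colliding and
neighbours within 15.9 Da are flagged as variance-inflating.

Replicate collapsing and unit filtering follow the standard rule set:
cells with fewer than 2 successful replicates or a replicate SD ≥ 0.1 are
set missing, cells are otherwise averaged, and units are removed when their
success rate over biological samples is < 80%, when they carry a
duplicate/overlap mass warning, or when they contain a common SNP.
Clearly bimodal per-unit distributions (unknown-SNP confounding) are
flagged by a BIC comparison of one- versus two-component Gaussian
mixtures.

## Worked example

The package ships the 290-bp leptin (*LEP*) upstream-promoter amplicon as
a worked example:

```r
library(epicleave)

amp <- read_amplicon_text(
  system.file("extdata", "lep_amplicon.txt", package = "epicleave"),
  name = "LEP")
rep <- amplicon_report(amp)
rep
#> <assay_report> LEP (290 bp, 5 CpG sites)
#>   4 of 5 CpG units measurable; 14 conversion-control fragment(s); 0 SNP-flagged unit(s)
#>        Name Base mass  Desc < 15.9 Da
#>  CpG_Unit_2  2260.431 CpG_2        NA
#>  CpG_Unit_3  2509.581 CpG_3        NA
#>  CpG_Unit_4  4524.871 CpG_4        NA
#>  CpG_Unit_5  2878.821 CpG_5        NA
```

The amplicon has five CpG sites, each in its own cleavage fragment. The
unit containing CpG 1 weighs under 1,500 Da and is flagged low-mass
(unmeasurable); the other four are measurable, none of them collides with
or sits within 15.9 Da of another fragment (the last column is all `NA`),
and fourteen CpG-free fragments qualify as bisulfite conversion controls.
The base masses agree with the vendor-software predictions for this
amplicon to within 0.01 Da.

QC of a (here simulated) exported plate:

```r
sim <- simulate_plate(sim_config(50, paste0("CpG_", 1:4),
                                 noise_sd = 0.02, seed = 1))
qc <- sim$grid |> collapse_replicates() |> filter_units()
glance(qc)
#> # A tibble: 1 × 6
#>   n_units_in n_units_out n_samples n_cells_out min_success_rate success_cutoff
#> 1          4           4        50         196            0.96             0.8
tidy(qc)      # the clean sample × unit matrix, long format
qc$exclusions # one logged row per applied removal
```

A thin command-line front-end covers the same ground
(`design-report`, `predict`, `qc`, `simulate`, `plate-design`,
`conv-check`):

```sh
Rscript inst/cli/epicleave.R design-report inst/extdata/lep_amplicon.txt --out out/
Rscript inst/cli/epicleave.R qc exported_grids/ --success-rate 0.8 --out out/
```

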