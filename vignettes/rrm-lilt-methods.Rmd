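---
title: "Methods: RRM wavelength prediction and light-exposure cytotoxicity analysis"
author: "rrmlilt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RRM wavelength prediction and light-exposure cytotoxicity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrmlilt)
```

# The model

The Resonant Recognition Model (RRM) treats a protein as a one-dimensional
numerical signal: each residue is replaced by its electron-ion interaction
potential (EIIP), a pseudopotential summarising the energy states of the
residue's valence electrons. A charge moving along the backbone of such a
"signal" can radiate or absorb at frequencies set by the periodicities of the
potential series, so proteins sharing a biological function are expected to
share a spectral component — the group's *characteristic frequency*
$f_{\mathrm{RRM}}$, expressed in cycles per residue and bounded by the
Nyquist limit 0.5.

The pipeline implements this chain:

1. **Encoding** — `encode_sequence()` maps one-letter residues through the
   shipped Veljkovic EIIP table (`eiip_table()`, values in Rydberg units on
   [0, 0.127]; Leu and Ile share the table minimum 0). Non-canonical
   residues, including the ambiguity codes B/J/X/Z, are rejected with the
   offending position: any imputation would alter the spectrum, and there is
   no principled value to impute.
2. **Amplitude spectra** — `amplitude_spectrum()` removes the signal mean
   (EIIP values are all positive; an unremoved DC term would dominate every
   product), zero-pads to the group's shared transform length, and keeps DFT
   magnitudes at bins $1..N/2$ (frequency of bin $k$ is $k/N$). The shared
   length is the smallest power of two at least as long as the longest group
   member, floored at 512 (`rrm_transform_length()`), the usual convention
   for unequal-length RRM groups.
3. **Consensus** — `cross_spectrum()` multiplies member amplitudes bin by
   bin. Components shared by every member survive; member-specific
   components are suppressed. Each bin's factors are multiplied in sorted
   order, so the result is bitwise identical under any permutation of the
   members.
4. **Peak scoring** — `find_characteristic_frequency()` takes the global
   argmax (ties resolved toward the lowest frequency, for determinism) and
   scores it as S/N = peak amplitude / mean consensus amplitude, significant
   at the customary threshold of 20 (configurable).

## Wavelength conversion

A characteristic frequency converts to a physical irradiation wavelength
through the fixed empirical ratio

$$\lambda = \frac{201}{f_{\mathrm{RRM}}}\ \mathrm{nm},$$

implemented in `frequency_to_wavelength()`. The constant is taken as given;
no attempt is made to re-derive it from charge-transfer velocity arguments.
Reported wavelengths are rounded to the nearest integer nm (the convention
of the published predictions, 6656 nm for $f = 0.0302$ and 3490 nm for
$f = 0.0576$); unrounded values are retained. The equivalent physical
frequency $c/\lambda$, with $c$ fixed at $2.998 \times 10^{17}$ nm/s for
deterministic classification, is checked against the
$10^{13}$–$10^{15}$ Hz window associated with protein-light interaction.
Note a boundary subtlety: with this $c$, $f = 0.0067$ maps to
$9.9933\times10^{12}$ Hz, i.e. ~0.07% below the window floor; the window
flag follows the formula, not a nominal $c = 3\times10^{17}$.

`select_led()` picks the catalog LED minimizing $|\lambda_{\mathrm{nominal}}
- \lambda_{\mathrm{target}}|$ (ties toward the shorter wavelength) and warns
when the mismatch exceeds a 200 nm tolerance rather than hiding the gap —
the shipped 12-LED catalog covers 3400–4300 nm in the far-IR, while the
oncogene prediction sits at 6656 nm, a 2356 nm mismatch that the report
surfaces explicitly.

# Plate assay quantification

Two assays, both read on a 96-well plate reader:

* **LDH cytotoxicity** (read at 492 or 495 nm — both reader filters are
  accepted under one alias set, and the value used is recorded):
  after subtracting the plate's background (medium-only) mean,
  $$\mathrm{cytotoxicity} = 100 \times
    \frac{x_{\mathrm{exp}} - \bar{x}_{\mathrm{low}}}
         {\bar{x}_{\mathrm{high}} - \bar{x}_{\mathrm{low}}},$$
  anchored by untreated (low, basal release) and lysed (high, maximal
  release) controls on the same plate/repeat. Viability is reported as
  $100 - \mathrm{cytotoxicity}$: the only monotone bounded mapping
  consistent with plotting "viability" from a release assay.
* **PrestoBlue viability** (read at 595 nm): per the resazurin reagent
  protocol, $100 \times x_{\mathrm{treated}} / \bar{x}_{\mathrm{untreated}}$
  after background subtraction.

Percentages outside [0, 100] are *retained and flagged*, never truncated:
truncation would bias the null (normal-cell) recovery toward 100%.
Background-corrected ODs below zero are clamped to zero with a logged
count; this analysis-side clamp is deliberately separate from the
simulator's truncation of ODs at zero (an instrument cannot emit negative
absorbance), so the two policies cannot be conflated.

Triplicate wells and the three experiment repeats are pooled (n = 9 per
condition) for point estimates — mean, sample SD, n — matching how single
summary percentages per condition are conventionally reported; repeat-level
means are attached for inspection.

## Statistics

`one_way_anova()` is the classic equal-variance F test (delegated to
`stats::oneway.test(var.equal = TRUE)`), with explicit conventions for the
degenerate corners: zero within-group variance with unequal means reports
$F = \infty$, $p = 0$; fully constant data report $F = 0$, $p = 1$. Two
views are emitted, both with raw p-values under an explicit `p_uncorrected`
header (no post-hoc multiple-comparison procedure is applied, and the
column name says so):

* per condition: treated vs untreated-control corrected ODs — groups on the
  same plate, so the test is exact under the null;
* across wavelengths within a regime, on per-well viabilities.

The across-regime comparison (`regime_comparison()`) runs on **repeat-level
mean viabilities**, not wells: regimes live on different plates, and all
wells of a plate/repeat share that repeat's control-mean noise. Treating
wells as independent across plates would inflate the between-regime variance
and make the test anti-conservative; the repeat is the independent unit.
Regime rankings (1 = most cytotoxic) flag ties when adjacent regime means
differ by less than `tie_tol` (default 0.5 pp).

# The synthetic-data generator

No sequence accessions and no raw ODs are deposited for this study, so the
generator stands in for both, and every number the pipeline reports is a
*parameter-recovery* result: the generator plants known truth, the pipeline
must recover it through the full OD → formula → aggregation chain.

**Protein groups** (`generate_protein_group()`): each member is a signal
$A\cos(2\pi f^{*} i + \varphi_j) + \varepsilon_i$, centred mid-EIIP-range,
with an independent uniform phase per sequence — a shared phase would make
consensus detection unrealistically easy — and Gaussian noise. Each point is
quantized to the residue with the nearest EIIP value (ties toward the
alphabetically first residue). Defaults: 5 sequences of 150–400 residues,
$A = 0.05$, noise SD 0.01 (component-to-noise ratio 5). Under these
defaults, the planted frequency is recovered within one grid bin in ≥95% of
seeds, and amplitude-0 (null) groups stay below the S/N threshold of 20 in
≥90% of seeds.

The default group size sits at the small end of the realistic 5–50 range
for a reason: the peak-to-mean statistic of a *multiplicative* consensus is
heavy-tailed and grows with member count, so a fixed S/N threshold of 20
loses its null calibration for large groups (measured null
non-significance: 1.00, 0.91, 0.76, 0.31 at 4, 5, 6, 10 members). Users
analysing larger groups should raise `snr_threshold` accordingly; the
pipeline exposes it everywhere.

**Plates** (`generate_plate()`): the study factorial — MCF7 (breast cancer)
and HEM (normal melanocyte) lines; LDH and PrestoBlue; three regimes
(1.5 h/0 h, 1.5 h/24 h, 3 h/24 h of exposure/incubation); 12 wavelengths;
triplicates × 3 repeats. OD construction inverts the assay formulas exactly
at zero noise (a tested identity). Scale constants — background 0.1 OD, LDH
low/high controls +0.2/+1.2 OD, PrestoBlue control +0.9 OD, well noise SD
0.03 OD — are instrument-side choices (no raw ODs exist to emulate), and the
recovered percentages are independent of them by construction. Layouts
place wells on a checkerboard so every used well is surrounded by empty
buffer wells, mirroring the study's anti-crosstalk plating.

**Calibration** (`default_calibration()`): the true-viability table the
simulator consumes, transcribed from the published summary statements:

| rows | value | basis |
|---|---|---|
| MCF7, LDH, far-IR, regimes 1/2/3 | pooled means 90/80/70% | reported regime-level viability means of roughly 90, 80 and 70% |
| MCF7, LDH far-IR per-wavelength | ±2 pp around the regime mean, 3600 nm lowest | 3600 nm reported most cytotoxic |
| MCF7, PrestoBlue, regime 1 | reductions 13–25 pp, 25 pp at 3600 nm | a reduction of at least 10 pp reported at every far-IR wavelength, above 20 pp at 3600 nm |
| MCF7, PrestoBlue, regimes 2/3 | regime 2 slightly below 1, regime 3 strongest | regime 3 reported as highest-impact; regime 2 comparable to 1 |
| HEM, all | 100% | normal-cell viability reported as unaffected, near 100% |
| MCF7, near-IR / visible | 95/93/91 and 98/97/96 by regime | qualitative ordering far-IR > near-IR > visible; **illustrative** — no numbers reported, excluded from any quantitative claim |

MCF7 far-IR rows are monotone non-increasing in regime severity, a
structural invariant `default_calibration()` enforces on load. Both
resources (EIIP table, calibration) are checksummed, and reports echo the
checksums so every number is traceable to a resource version.

# Numerical and design choices

* Transform length: power of two ≥ longest member, floor 512. At 512
  points, the bin nearest 0.0576 is 29/512 ≈ 0.0566, i.e. grid quantization
  alone moves the implied wavelength by ~60 nm at these frequencies; longer
  sequences (finer grids) shrink this.
* Peak ties → lowest frequency; LED-selection ties → shorter wavelength;
  both deterministic.
* Degenerate inputs: constant signals yield an all-zero spectrum returned
  with a `degenerate` flag; an all-zero consensus is rejected rather than
  scored.
* Per-plate-repeat controls: every formula is anchored to its own
  plate/repeat's controls, so background noise cancels within the LDH
  ratio.
* Seeding: all generators draw from a private seeded stream and restore the
  global RNG state, so library calls never perturb user code;
  identical specs produce byte-identical FASTA/CSV outputs.

# Problem sizes

The shipped analyses and tests run at the study's own scale: plates of 6–12
wavelengths × 3 triplicates × 3 repeats, protein groups of 5–10 members of
150–900 residues (transform lengths 512–1024), 100-seed recovery suites,
and a 200-plate null suite for the ANOVA false-positive rate (1200
uncorrected tests; the 95% binomial acceptance band around α = 0.05 is
itself expected to fail for ~5% of seeds — a rerun with another seed
distinguishes chance from miscalibration).

# What passing tests do and do not show

The generator emulates the study's *design* (factorial structure, replicate
counts, effect sizes transcribed from printed summaries) under idealised
noise: Gaussian wells, no edge effects, no drift, no pipetting error, no
plate-position artifacts, and protein groups whose shared component is a
single planted cosine rather than an evolutionarily conserved motif.
Passing recovery tests therefore demonstrates that the *pipeline* is
correct and well calibrated — formulas invert, estimators are unbiased at
the stated n, the ANOVA holds its level — not that the biological effect
sizes themselves are reproducible; those remain claims of the underlying
experiment. The near-IR and visible calibration rows are illustrative
placeholders and carry no quantitative weight anywhere in the test suite.
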