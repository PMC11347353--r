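---
title: "Methods: source-sink 13C allocation, assay calibration, and trait screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-sink 13C allocation, assay calibration, and trait screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsechase)
```

## The experimental design this package analyses

A branch of a fruiting tree is bagged and fed ¹³CO₂ for a short pulse; the
leaves fix the label, and over a 72-hour chase the labeled photosynthate is
exported to the sink organs — branches, fruit peels, and seed kernels. By
sampling each organ at 0, 6, 24, 48 and 72 h after labeling, in each of four
monthly developmental stages, the experiment maps how the carbon sink
hierarchy shifts as the fruit matures: early in the season the leaves retain
most of the label, while during the oil-conversion stage the seed kernels
become the dominant sink. A second tier of measurements — colorimetric and
HPLC sugar assays, enzyme activity panels, and RNA-seq expression tables —
links the allocation shift to sugar metabolism.

`pulsechase` implements every computational stage of that analysis, plus a
synthetic-data generator that emulates the experiment with known ground
truth, so the whole chain is testable without instrument data.

## Isotope mass balance

All allocation quantities derive from five conversions, applied per organ
$i$ and month:

* $\delta^{13}C = (R_s - R_c)/R_c \times 1000$ (per mil), with
  $R_c = 0.0112372$ the VPDB standard ¹³C/¹²C ratio;
* $\mathrm{Atom\%} = \dfrac{(\delta + 1000)\,R_c}{(\delta + 1000)\,R_c + 1000}
  \times 100$;
* $C_i = C\% \times W_i$ (g carbon) from dry biomass $W_i$ and carbon
  fraction $C\%$;
* $^{13}C_i = C_i \,(\mathrm{Atom\%} - F_n)/100 \times 1000$ (mg), the
  excess-¹³C mass above the unlabeled background $F_n$;
* $P_i = {}^{13}C_i \,/\, \sum_j {}^{13}C_j \times 100$ and
  $V_i = ({}^{13}C_i \times 1000 / W_i)/H$ (µg g⁻¹ h⁻¹) at $H$ hours of chase.

Three unit and convention choices were genuinely open and are fixed as
follows:

* **Units of $^{13}C_i$.** $C_i$ is carried in grams so that the
  $\times 1000$ factor yields milligrams; with labeled-branch biomasses of a
  few to tens of grams this puts monthly totals in the observed
  0.2–6 mg range.
* **Transport-rate denominator.** $V_i$ is reported per gram of organ dry
  biomass (dividing by $W_i$ before dividing by $H$), because its unit is
  µg g⁻¹ h⁻¹; a whole-organ rate would be µg h⁻¹.
* **Atom-percent grouping.** The conversion is evaluated as
  $((\delta + 1000) R_c)/(((\delta + 1000) R_c) + 1000)$ — the standard
  VPDB form, which is the only dimensionally consistent grouping.

Negative excess masses (organ atom percent below background, which happens
late in the season) are preserved and flagged, never clamped: clamping
would silently fabricate mass conservation. Monthly allocation percentages
are only computed when the monthly total is positive; otherwise the table
keeps the signed masses and reports `NA` shares with a warning.

When a reading carries both a raw ratio and a δ value, δ takes precedence
(and the validator flags the row). Replicate readings are averaged on the
atom-percent scale — the scale on which the mass balance is linear — before
the excess mass is formed.

## Assay calibration

Two fixed kit calibrations convert 620 nm absorbances to contents
(mg g⁻¹ fresh weight): soluble sugars $2.34 (A + 0.07)/W$ and starch
$0.578 (A + 0.0295)/W$. The constants already absorb the kit's dilution
scheme, so no additional dilution factor is applied. HPLC quantification
fits an unweighted ordinary-least-squares line to the six-point standard
gradient (0.625–20 mg ml⁻¹) and inverts it, then applies the extraction
bookkeeping (default 10 ml extract per 1 g tissue). Negative computed
contents are reported with a QC flag rather than truncated, to keep the
audit trail. The soluble-to-NSC majority flag uses a strict inequality at
50%.

A limitation worth knowing: with multiplicative (constant-CV) detector
noise, unweighted OLS over the 32-fold calibration range transfers most of
its prediction error to the low end of the range. Sample concentrations
near the 0.625 mg ml⁻¹ floor are therefore recovered with relative errors
bounded by calibration prediction error (a few percent at 1% detector CV),
not by the sample noise alone. Weighted calibration is available as a
configuration choice but is off by default, matching the protocol.

## Correlation screens, DEG filtering, and letters

Pearson correlations use the $t$ transform with $n-2$ degrees of freedom;
cells with fewer than three complete pairs or zero variance are reported
missing with a reason. Stars follow the table convention: `**` for
$p < 0.01$, `*` for $0.01 \le p < 0.05$. Enzyme columns with no
measurements in an organ (neutral invertase is not detected in peels) are
dropped from that organ's matrix, mirroring blank table columns.

Pairing is replicate-level by default (stages × replicates), with a
stage-means option. The choice matters for significance: with only four
stage means, even $r = 0.96$ does not reach $p < 0.01$, whereas
replicate-level pairing at $n = 12$ does — consistent with the starred
field tables this layout reproduces. No multiple-testing correction is
applied across cells by default, matching standard practice for these
descriptive matrices; a Benjamini–Hochberg option exists on the
correlation p values if wanted.

The DEG filter keeps records with FDR ≤ 0.05 **and** |log₂FC| ≥ 1, both
boundaries inclusive as printed conventions state; relaxing either
threshold can only grow the kept set (tested as a monotonicity property).
Overlap counts enumerate every Venn region for up to three comparisons.

Group comparisons use one-way ANOVA followed by Fisher's LSD — unadjusted
pairwise $t$ tests on the pooled error mean square — encoded as a compact
letter display by insert-and-absorb: start from one all-inclusive letter
column, split every column that still contains a significantly different
pair, then absorb columns that became subsets. The construction guarantees
that two groups share a letter *iff* the LSD test does not separate them,
which is verified in the tests against an exhaustive pairwise oracle.
Letters are assigned in descending order of group means (`a` to the highest
mean); upper-case letters are available for within-row table conventions.
A Shapiro–Wilk pre-check warns about non-normal groups but never blocks
the ANOVA, since the downstream tables always report ANOVA results. With
zero pooled variance, groups with unequal means are all declared distinct.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults live in `inst/extdata/default_sim.yaml`.

**Tracer dynamics.** No mechanistic model accompanies the field protocol,
so the generator posits the simplest defensible one: a linear first-order
compartment model. The leaf pool holds the whole pulse at the end of
labeling (treating the 2 h feeding as instantaneous relative to the 72 h
chase) and drains to each sink at a constant transfer rate and to an
explicit respired pool at the leaf respiration rate (default 0.002 h⁻¹);
sinks may respire at their own rates, though the default fixture sets sink
respiration to zero, treating sinks as net importers over the chase.
Integration is forward Euler at `dt = 0.01` h with an explicit stability
guard (`rate × dt > 0.1` errors out); Euler with conservation accounting
was chosen over the closed form so the respired pool is an explicit,
testable state — the closed form instead serves as the independent oracle
in the tests. Mass conservation (organs + respired = pulse) holds to
1e−9 relative at every step.

**Calibration, not hand-tuned rates.** Rather than storing magic rate
constants, the fixture stores the target 72 h allocation vector for each
month and inverts the model's closed form at run time
(`calibrate_transfer_rates()`), so the noiseless simulation reproduces the
field allocation table by construction and the noisy pipeline must recover
it. The pulse enriches the leaf pool by 0.2 atom% over a −27‰ background,
which places the 0 h leaf reading near +155‰ and monthly totals near
6 mg — the observed magnitudes. Measurement noise is additive Gaussian in
δ-space (1‰ sd), the scale on which isotope-ratio instruments are
specified.

**Assay and expression layers.** Assay simulation inverts the calibration
formulas exactly, so zero-noise round trips are exact to floating point;
noise is multiplicative (3% CV for kit replicates, 1% for the HPLC
detector). Expression tables plant `n_planted = 10` sucrose-correlated
genes among 1000 independent background genes: a latent Gaussian mixes the
standardized replicate-level sucrose trajectory with independent noise,
then maps to FPKM via `exp(mu + sigma * z)`. Because the exponential
transform attenuates correlation by $\sigma/\sqrt{e^{\sigma^2}-1}$, the
latent mixing weight is inflated by the inverse factor so the *population*
correlation of FPKM with sucrose equals the 0.9 target.

**What passing tests do and do not show.** The generator emulates the
structure of the experiment, not its biology: organs do not grow between
months, transfer rates are constant within a chase, photosynthesis and
refixation are absent, and assay noise is homoscedastic on the CV scale.
Recovery under these conditions demonstrates that the computational chain
is correct and numerically stable, not that the field estimates themselves
carry these error bars. One statistical marginality is worth stating
plainly: with 12 observations, the sample correlation of a gene planted at
$\rho = 0.9$ has a standard deviation of roughly 0.06, while the maximum
null correlation among 1000 background genes is typically around 0.8; the
"all ten planted genes rank in the top ten" event therefore has only
roughly a 60% per-seed probability. It holds at the committed fixture
seed, but a screen design with more observations (or fewer background
genes) would be needed for it to be a robust property.

## Problem sizes and determinism

The committed configuration simulates 4 organs × 4 months × 5 timepoints
× 3 replicates of isotope readings (240 rows), 96 colorimetric readings,
144 HPLC sample areas, 180 enzyme measurements, 1000 genes × 12
observations, and 2000 × 3 DE records — sizes chosen so every analysis
stage, including the 200-draw letter-display cross-validation, completes
in seconds while keeping Monte-Carlo assertions well-powered. All
randomness flows from the single config seed; stage-local seeds are
derived from it by fixed offsets, so identical configs give byte-identical
outputs (asserted in the tests by checksum).

## Known limitations

* The compartment model is linear and memoryless; saturating transport or
  diurnal fixation would need a different generator.
* Unweighted HPLC calibration concentrates error at the bottom of the
  standard range (see above).
* The LSD letter display inherits LSD's unadjusted pairwise error rate;
  it reproduces the field convention rather than controlling family-wise
  error.
* `venn_overlap()` enumerates regions for at most three sets, the layout
  used here; larger designs need a different summary.
* Whether monthly totals refer to the labeled branch or the whole plant is
  left as a scale choice in the organ table (biomasses are per labeled
  branch by default); allocation percentages are invariant to that scale.
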