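# pulsechase

Source–sink carbon allocation from ¹³C pulse-chase labeling, sugar assay
calibration, and trait–expression correlation screens — the analysis chain
for experiments that bag a fruiting branch, feed it ¹³CO₂, and track where
the labeled photosynthate goes as the fruit develops.

The package is for plant physiologists and analysts working with
stable-isotope tracer data plus the usual companion assays (anthrone
colorimetry, HPLC sugar panels, enzyme activity kits, RNA-seq expression
tables). It implements:

* **Isotope mass balance.** δ¹³C = (R_s − R_c)/R_c × 1000 with
  R_c = 0.0112372 (VPDB); Atom% = ((δ+1000)·R_c)/(((δ+1000)·R_c)+1000) × 100;
  organ carbon C_i = C% × W_i; excess tracer mass
  ¹³C_i = C_i (Atom% − F_n)/100 × 1000 (mg) above the unlabeled background
  F_n; allocation share P_i = ¹³C_i / Σ¹³C_j × 100; transport rate
  V_i = (¹³C_i × 1000 / W_i)/H in µg·g⁻¹·h⁻¹.
* **Assay calibration.** Kit formulas 2.34(A+0.07)/W (soluble sugars) and
  0.578(A+0.0295)/W (starch); OLS standard curves over the 0.625–20 mg·ml⁻¹
  HPLC gradient; extraction bookkeeping; NSC summaries with QC flags.
* **Screens.** Pearson r with t-transform p values and `*`/`**` stars
  (p < 0.05 / p < 0.01); sugar × enzyme matrices per organ; gene-vs-sucrose
  ranking; DEG filtering at FDR ≤ 0.05 and |log₂FC| ≥ 1 with Venn region
  counts; one-way ANOVA + Fisher's LSD compact letter displays.
* **A seeded synthetic-data generator** — a first-order source–sink
  compartment model with an explicit respired pool, plus assay, enzyme,
  expression and DE layers — so the full pipeline runs and is testable
  without instrument data.

## Worked example

The numbered scripts under `analysis/` run the whole chain on the packaged
fixture (`inst/extdata/default_sim.yaml`):

```sh
Rscript analysis/01_simulate.R    # generate all inputs under results/sim/
Rscript analysis/02_allocation.R  # isotope mass balance
Rscript analysis/03_sugars.R      # calibration + sugar profiles
Rscript analysis/04_screens.R     # correlations, gene screen, DEGs, letters
```

Stage 2 prints the allocation estimates next to the simulator truth; with
1‰ reading noise the August chase recovers the field allocation vector to
a fraction of a percentage point:

```
  Aug (total 5.66 mg):
    branches         7.86 %  (truth   7.70, err +0.16)
    leaves          54.37 %  (truth  54.55, err -0.18)
    peels           16.78 %  (truth  16.54, err +0.24)
    seed_kernels    20.99 %  (truth  21.21, err -0.22)
```

The shares always sum to 100 — they are normalised tracer masses — so the
errors reflect measurement noise propagated through the δ → atom% → mass
chain. Stage 3 fits the standard curves (r² > 0.9999 at 1% detector noise)
and finds the seed-kernel sucrose peak in September at 25.85 mg·g⁻¹ FW
against a planted truth of 25.93. Stage 4 prints the starred correlation
matrices, e.g. for seed kernels

```
Seed sucrose vs SuSy-II: r = 0.995** (n = 12)
```

ranks all 10 planted sucrose-correlated genes in the top 10 of the
1000-gene screen, and assigns LSD letters such as

```
   Sep seed_kernels 44.46      a
   Sep        peels 39.63      b
   Sep       leaves 29.95      c
```

meaning the three organs' soluble-sugar contents in September are all
pairwise separable. `run_all()` performs the same chain in one call and
writes a manifest (checksums, row counts, seeds) plus a plain-text report.

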