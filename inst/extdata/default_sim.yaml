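# Default simulation fixture: a 13C pulse-chase labeling season on one
# labeled branch (leaf source, three sinks), with assay and expression
# layers. All pipeline inputs are generated from this file; the seed makes
# every output reproducible.
seed: 20210801
rc: 0.0112372
source_organ: leaves

# Isotope layer. The pulse enriches the leaf pool by 0.2 atom percent above
# a natural-abundance background of -27 per mil, which puts the 0 h leaf
# reading near +155 per mil; measurement noise is 1 per mil (1 sd).
background_delta13c: -27.0
pulse_excess_atom_percent: 0.2
timepoints_h: [0, 6, 24, 48, 72]
dt_h: 0.01
noise_sd_delta: 1.0
n_replicates: 3
chase_month: Aug

# Labeled-branch organ pools (dry mass of the bagged branch section).
organs:
  - {organ: branches,     biomass_g: 10.0, carbon_fraction: 0.47, respiration_rate_per_h: 0.0}
  - {organ: leaves,       biomass_g: 7.0,  carbon_fraction: 0.45, respiration_rate_per_h: 0.002}
  - {organ: peels,        biomass_g: 8.0,  carbon_fraction: 0.44, respiration_rate_per_h: 0.0}
  - {organ: seed_kernels, biomass_g: 3.0,  carbon_fraction: 0.46, respiration_rate_per_h: 0.0}

months: [Jul, Aug, Sep, Oct]

# Noiseless 72 h allocation shares each month's transfer rates are
# calibrated to (percent of organ-held excess 13C).
month_allocation_targets:
  Jul: {branches: 7.77, leaves: 69.84, peels: 15.94, seed_kernels: 6.45}
  Aug: {branches: 7.70, leaves: 54.55, peels: 16.54, seed_kernels: 21.21}
  Sep: {branches: 13.17, leaves: 21.48, peels: 42.55, seed_kernels: 22.81}
  Oct: {branches: 4.90, leaves: 3.78, peels: 26.86, seed_kernels: 64.47}

# Assay layer. Colorimetric readings use 0.1 g fresh tissue; kit replicate
# CV 3%. HPLC standards span the six-point calibration gradient with a 1%
# detector CV; extraction dilutes 1 g to 10 ml.
assay_replicates: 4
assay_noise_cv: 0.03
fresh_weight_g: 0.1
hplc:
  gradient_mg_ml: [0.625, 1.25, 2.5, 5, 10, 20]
  slope_true: {sucrose: 1850.0, glucose: 2100.0, fructose: 2050.0}
  intercept_true: {sucrose: 40.0, glucose: 55.0, fructose: 35.0}
  noise_cv: 0.01
  extract_volume_ml: 10
  sample_mass_g: 1

# True sugar contents (mg per g fresh weight). Fructose dominates early in
# all organs; seed sucrose peaks in September; soluble sugars exceed starch
# everywhere.
sugar_truth:
  seed_kernels:
    Jul: {sucrose: 5.2,  glucose: 9.8,  fructose: 13.5, starch: 7.5}
    Aug: {sucrose: 10.1, glucose: 11.2, fructose: 15.8, starch: 9.0}
    Sep: {sucrose: 25.93, glucose: 8.4, fructose: 9.6,  starch: 12.0}
    Oct: {sucrose: 19.4, glucose: 6.1,  fructose: 7.2,  starch: 13.5}
  leaves:
    Jul: {sucrose: 6.8, glucose: 10.5, fructose: 14.2, starch: 8.2}
    Aug: {sucrose: 7.4, glucose: 11.8, fructose: 16.1, starch: 9.4}
    Sep: {sucrose: 8.9, glucose: 9.2,  fructose: 12.3, starch: 7.8}
    Oct: {sucrose: 7.1, glucose: 8.8,  fructose: 10.4, starch: 6.9}
  peels:
    Jul: {sucrose: 4.1, glucose: 12.4, fructose: 16.8, starch: 7.1}
    Aug: {sucrose: 4.8, glucose: 14.2, fructose: 18.9, starch: 8.6}
    Sep: {sucrose: 6.2, glucose: 15.6, fructose: 17.4, starch: 9.2}
    Oct: {sucrose: 5.4, glucose: 16.9, fructose: 15.2, starch: 8.8}

# True enzyme activity profiles (U per g). Sucrose synthase (synthesis
# direction) peaks in September in every organ; neutral invertase is not
# detected in peels (null entries).
enzyme_truth:
  seed_kernels:
    SuSy_II: {Jul: 700.0,  Aug: 1100.0, Sep: 2071.62, Oct: 1600.0}
    SPS:     {Jul: 400.0,  Aug: 600.0,  Sep: 1000.0,  Oct: 850.0}
    S_AI:    {Jul: 300.0,  Aug: 500.0,  Sep: 650.0,   Oct: 420.0}
    B_AI:    {Jul: 200.0,  Aug: 400.0,  Sep: 250.0,   Oct: 380.0}
    NI:      {Jul: 600.0,  Aug: 650.0,  Sep: 700.0,   Oct: 900.0}
  leaves:
    SuSy_II: {Jul: 900.0,  Aug: 1300.0, Sep: 1677.62, Oct: 1000.0}
    SPS:     {Jul: 500.0,  Aug: 620.0,  Sep: 700.0,   Oct: 560.0}
    S_AI:    {Jul: 80.0,   Aug: 90.0,   Sep: 85.0,    Oct: 75.0}
    B_AI:    {Jul: 150.0,  Aug: 160.0,  Sep: 140.0,   Oct: 155.0}
    NI:      {Jul: 800.0,  Aug: 850.0,  Sep: 820.0,   Oct: 790.0}
  peels:
    SuSy_II: {Jul: 1000.0, Aug: 1500.0, Sep: 2535.58, Oct: 1800.0}
    SPS:     {Jul: 800.0,  Aug: 700.0,  Sep: 650.0,   Oct: 600.0}
    S_AI:    {Jul: 900.0,  Aug: 800.0,  Sep: 700.0,   Oct: 600.0}
    B_AI:    {Jul: 300.0,  Aug: 350.0,  Sep: 320.0,   Oct: 400.0}
    NI:      {Jul: ~,      Aug: ~,      Sep: ~,       Oct: ~}

# Expression screen: planted sucrose-correlated genes among independent
# background genes, observed at replicate level (4 stages x 3 replicates).
expression:
  n_genes: 1000
  n_planted: 10
  target_r: 0.9
  sucrose_cv: 0.03
  log_mu_fpkm: 3.9
  log_sigma_fpkm: 0.25

# Differential-expression layer consumed by the DEG filter and overlap demo.
deg:
  n_genes: 2000
  comparisons: [Jul_vs_Aug, Jul_vs_Sep, Jul_vs_Oct]
  prop_de: 0.25
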