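sim_cfg <- function(...) {
  base <- list(
    seed = 7L, rc = 0.0112372, source_organ = "leaves",
    background_delta13c = -27, pulse_excess_atom_percent = 0.2,
    timepoints_h = c(0, 6, 24, 48, 72), dt_h = 0.01,
    noise_sd_delta = 0, assay_noise_cv = 0.03, n_replicates = 1,
    organs = list(
      list(organ = "branches", biomass_g = 10, carbon_fraction = 0.47,
           respiration_rate_per_h = 0),
      list(organ = "leaves", biomass_g = 7, carbon_fraction = 0.45,
           respiration_rate_per_h = 0.002),
      list(organ = "peels", biomass_g = 8, carbon_fraction = 0.44,
           respiration_rate_per_h = 0),
      list(organ = "seed_kernels", biomass_g = 3, carbon_fraction = 0.46,
           respiration_rate_per_h = 0)),
    months = "Aug",
    transfer_rates_per_h = list(branches = 0.0013, peels = 0.0029,
                                seed_kernels = 0.0037))
  mod <- list(...)
  base[names(mod)] <- mod
  base
}

test_that("transfer-rate calibration inverts the closed-form shares", {
  tgt <- c(branches = 7.70, leaves = 54.55, peels = 16.54, seed_kernels = 21.21)
  cal <- calibrate_transfer_rates(tgt)
  oc <- oracle_compartments(1, cal$transfer_rates_per_h, cal$leaf_respiration, 72)
  shares <- c(oc$sinks["branches"], leaves = oc$leaf, oc$sinks["peels"],
              oc$sinks["seed_kernels"])
  shares <- shares / sum(shares) * 100
  expect_equal(unname(shares), unname(tgt), tolerance = 1e-8)
  expect_error(calibrate_transfer_rates(c(branches = 50, peels = 50)),
               "source organ")
})

test_that("the simulator conserves pulse mass at every timestep", {
  sim <- simulate_pulse_chase(sim_cfg())
  tot <- tapply(sim$truth$excess$excess_mg,
                list(sim$truth$excess$month, sim$truth$excess$time_h), sum)
  resp <- sim$truth$respired
  for (i in seq_len(nrow(resp))) {
    organs_plus_respired <- tot[resp$month[i], as.character(resp$time_h[i])] +
      resp$respired_mg[i]
    expect_equal(organs_plus_respired, resp$pulse_mg[i], tolerance = 1e-9)
  }
})

test_that("with all rates zero the label never leaves the leaf", {
  cfg <- sim_cfg(transfer_rates_per_h = list(branches = 0, peels = 0,
                                             seed_kernels = 0),
                 organs = list(
                   list(organ = "branches", biomass_g = 10, carbon_fraction = 0.47,
                        respiration_rate_per_h = 0),
                   list(organ = "leaves", biomass_g = 7, carbon_fraction = 0.45,
                        respiration_rate_per_h = 0),
                   list(organ = "peels", biomass_g = 8, carbon_fraction = 0.44,
                        respiration_rate_per_h = 0),
                   list(organ = "seed_kernels", biomass_g = 3, carbon_fraction = 0.46,
                        respiration_rate_per_h = 0)))
  sim <- simulate_pulse_chase(cfg)
  ex <- sim$truth$excess
  leaf <- ex[ex$organ == "leaves", ]
  expect_equal(leaf$excess_mg, rep(sim$truth$pulse_mg, nrow(leaf)),
               tolerance = 1e-12)
  expect_equal(ex$excess_mg[ex$organ != "leaves"],
               rep(0, sum(ex$organ != "leaves")))
  # sinks read at background: noiseless deltas equal the configured background
  rd <- sim$readings
  expect_equal(rd$delta13c[rd$organ == "peels"],
               rep(-27, sum(rd$organ == "peels")), tolerance = 1e-9)
})

test_that("symmetric sinks approach equal thirds without respiration", {
  cfg <- sim_cfg(
    timepoints_h = c(0, 3000), dt_h = 0.05,
    transfer_rates_per_h = list(branches = 0.002, peels = 0.002,
                                seed_kernels = 0.002),
    organs = list(
      list(organ = "branches", biomass_g = 10, carbon_fraction = 0.47,
           respiration_rate_per_h = 0),
      list(organ = "leaves", biomass_g = 7, carbon_fraction = 0.45,
           respiration_rate_per_h = 0),
      list(organ = "peels", biomass_g = 8, carbon_fraction = 0.44,
           respiration_rate_per_h = 0),
      list(organ = "seed_kernels", biomass_g = 3, carbon_fraction = 0.46,
           respiration_rate_per_h = 0)))
  sim <- simulate_pulse_chase(cfg)
  ex <- sim$truth$excess
  late <- ex[ex$time_h == 3000 & ex$organ != "leaves", ]
  expect_equal(late$allocation_percent, rep(100 / 3, 3), tolerance = 0.05)
})

test_that("the Euler integrator matches the closed form and guards stability", {
  cfg <- sim_cfg(dt_h = 0.005)
  sim <- simulate_pulse_chase(cfg)
  k <- unlist(cfg$transfer_rates_per_h)
  oc <- oracle_compartments(sim$truth$pulse_mg, k, 0.002, 72)
  ex72 <- sim$truth$excess[sim$truth$excess$time_h == 72, ]
  expect_equal(ex72$excess_mg[ex72$organ == "leaves"], oc$leaf,
               tolerance = 1e-3)
  for (s in names(k))
    expect_equal(ex72$excess_mg[ex72$organ == s], unname(oc$sinks[s]),
                 tolerance = 1e-3)
  expect_error(simulate_pulse_chase(sim_cfg(dt_h = 60)), "stability")
})

test_that("the simulator is deterministic for a fixed config", {
  cfg <- sim_cfg(noise_sd_delta = 1, n_replicates = 3)
  a <- simulate_pulse_chase(cfg)
  b <- simulate_pulse_chase(cfg)
  expect_identical(a$readings, b$readings)
  expect_identical(a$truth, b$truth)
})

test_that("assay simulation round-trips through the quantification path", {
  cfg <- default_sim_config()
  cfg$assay_noise_cv <- 0
  cfg$hplc$noise_cv <- 0
  sugars <- sugar_truth_table(cfg)
  assays <- simulate_assays(sugars, cfg)
  curves <- lapply(split(assays$standards, assays$standards$analyte), function(d)
    fit_standard_curve(d$concentration_mg_ml, d$peak_area, d$analyte[1]))
  prof <- sugar_profiles(assays$colorimetric, assays$hplc_samples, curves)
  # zero-noise recovery is exact, including the September seed sucrose peak
  sep_seed <- prof[prof$organ == "seed_kernels" & prof$month == "Sep", ]
  expect_equal(sep_seed$sucrose[1], 25.93, tolerance = 1e-9)
  truth_wide <- sugars[sugars$analyte == "starch", ]
  m <- match(paste(prof$organ, prof$month),
             paste(truth_wide$organ, truth_wide$month))
  expect_equal(prof$starch, truth_wide$content[m], tolerance = 1e-9)
  # zero content, zero noise hits the calibration zero point exactly
  zero <- simulate_assays(data.frame(organ = "x", month = "Jul",
                                     analyte = "soluble_sugar", content = 0),
                          cfg)
  expect_equal(zero$colorimetric$absorbance_620, rep(-0.07, 4))
})

test_that("noisy HPLC areas recover in-range concentrations within 3x the noise", {
  cfg <- default_sim_config()    # 1 % detector noise
  grad <- unlist(cfg$hplc$gradient_mg_ml)
  set.seed(81)
  slope <- cfg$hplc$slope_true$sucrose
  icpt <- cfg$hplc$intercept_true$sucrose
  curve <- fit_standard_curve(grad, slope * grad + icpt)
  for (trial in 1:5) {
    # planted concentrations spanning the calibrated range; injected noise
    # on the sample areas (calibration noise is bounded separately by the
    # slope-recovery check)
    conc <- stats::runif(12, min(grad), max(grad))
    smp_area <- (slope * conc + icpt) * (1 + cfg$hplc$noise_cv * stats::rnorm(12))
    est <- quantify_sugar(smp_area, curve, 10, 1) / 10   # back to mg/ml
    expect_lt(max(abs(est - conc) / conc), 3 * cfg$hplc$noise_cv)
  }
})

test_that("planted genes carry the target correlation and clean backgrounds", {
  suc <- c(Jul = 5.2, Aug = 10.1, Sep = 25.93, Oct = 19.4)
  sim <- simulate_expression(suc, n_genes = 300, n_planted = 10,
                             target_r = 0.9, n_replicates = 3, seed = 71)
  expect_equal(length(unique(sim$expr$gene_id)), 300)
  expect_true(all(sim$expr$fpkm >= 0))
  by_gene <- split(sim$expr, sim$expr$gene_id)
  r <- vapply(by_gene, function(d) {
    m <- merge(d, sim$sucrose, by = c("stage", "replicate"))
    stats::cor(m$fpkm, m$sucrose)
  }, numeric(1))
  expect_lt(abs(mean(r[sim$planted_genes]) - 0.9), 0.1)
  # background |r| tails consistent with the null t distribution at n = 12
  bg <- r[setdiff(names(r), sim$planted_genes)]
  t95 <- stats::qt(0.975, 10)
  r95_null <- t95 / sqrt(t95^2 + 10)
  expect_lt(abs(stats::quantile(abs(bg), 0.95) - r95_null), 0.12)
  expect_error(simulate_expression(suc, n_genes = 5, n_planted = 10), "exceed")
  expect_error(simulate_expression(suc, target_r = 1.2), "target_r")
})

test_that("target_r in the exact-relation limit gives sample r of 1", {
  suc <- c(Jul = 5.2, Aug = 10.1, Sep = 25.93, Oct = 19.4)
  sim <- simulate_expression(suc, n_genes = 20, n_planted = 5,
                             target_r = 0.9999, n_replicates = 3, seed = 72,
                             log_sigma = 0.01)
  sc <- gene_sucrose_screen(sim$expr, sim$sucrose, top_k = 5)
  expect_true(all(sc$ranking$gene_id %in% sim$planted_genes))
  expect_equal(sc$ranking$r, rep(1, 5), tolerance = 1e-3)
})

test_that("enzyme panels reproduce profiles exactly at zero CV", {
  prof <- data.frame(organ = "seed_kernels", month = c("Jul", "Aug", "Sep", "Oct"),
                     enzyme = "SuSy_II", activity = c(700, 1100, 2071.62, 1600))
  pan <- simulate_enzyme_panels(prof, cv = 0, n_replicates = 3, seed = 1)
  expect_equal(nrow(pan), 12)
  expect_equal(pan$activity, rep(prof$activity, each = 3))
  # monotone profile in, monotone stage means out at cv = 0
  mono <- data.frame(organ = "x", month = c("Jul", "Aug", "Sep"),
                     enzyme = "SPS", activity = c(1, 2, 3))
  mp <- simulate_enzyme_panels(mono, cv = 0, n_replicates = 2, seed = 1)
  mm <- tapply(mp$activity, mp$month, mean)[c("Jul", "Aug", "Sep")]
  expect_true(all(diff(mm) > 0))
  # missing assays propagate as NA replicates
  na_prof <- data.frame(organ = "peels", month = "Jul", enzyme = "NI",
                        activity = NA_real_)
  expect_true(all(is.na(simulate_enzyme_panels(na_prof, seed = 1)$activity)))
})

test_that("the packaged fixture survives the letters and correlation stages", {
  cfg <- default_sim_config()
  pan <- simulate_enzyme_panels(enzyme_truth_table(cfg), cv = cfg$assay_noise_cv,
                                n_replicates = 3, seed = cfg$seed)
  seed_susy <- pan[pan$organ == "seed_kernels" & pan$enzyme == "SuSy_II", ]
  lt <- anova_lsd_letters(seed_susy$activity, seed_susy$month)
  expect_equal(names(lt$letters)[1], "Sep")   # the September activity peak
  sugars <- data.frame(expand.grid(month = cfg$months, replicate = 1:3,
                                   stringsAsFactors = FALSE),
                       organ = "seed_kernels")
  sucrose_true <- vapply(sugars$month, function(m)
    cfg$sugar_truth$seed_kernels[[m]]$sucrose, numeric(1))
  set.seed(cfg$seed)
  sugars$sucrose <- sucrose_true * (1 + 0.03 * stats::rnorm(nrow(sugars)))
  mat <- enzyme_sugar_matrix(pan, sugars, sugar_components = "sucrose")
  cell <- mat[mat$enzyme == "SuSy_II" & mat$organ == "seed_kernels", ]
  expect_gt(cell$r, 0.8)
  expect_equal(cell$star, "**")
})
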