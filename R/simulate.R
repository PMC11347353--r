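#' Calibrate leaf-to-sink transfer rates to a target allocation
#'
#' For the linear source-sink compartment model with a single labeled leaf
#' pool draining to sinks at rates `k_s` and respiring at `r`, the organ-level
#' allocation shares at chase time `T` have a closed form; this inverts it so
#' the noiseless simulation reproduces a prescribed allocation vector. Sink
#' respiration is assumed zero during the chase (sinks act as net importers).
#'
#' @param target_shares Named percentages per organ (must include
#'   `source_organ`); normalised internally to sum to 100.
#' @param hours Chase duration at which the target applies (default 72).
#' @param leaf_respiration Source respiration rate, h^-1 (default 0.002).
#' @param source_organ Name of the labeled source pool (default "leaves").
#' @return List with `transfer_rates_per_h` (named, sinks only) and
#'   `leaf_respiration`.
#' @export
#' @examples
#' calibrate_transfer_rates(c(branches = 7.70, leaves = 54.55,
#'                            peels = 16.54, seed_kernels = 21.21))
calibrate_transfer_rates <- function(target_shares, hours = 72,
                                     leaf_respiration = 0.002,
                                     source_organ = "leaves") {
  if (!source_organ %in% names(target_shares))
    stop("`target_shares` must include the source organ `", source_organ, "`",
         call. = FALSE)
  p <- target_shares / sum(target_shares)
  pL <- p[[source_organ]]
  if (pL <= 0 || pL >= 1)
    stop("source share must lie strictly between 0 and 100%", call. = FALSE)
  sinks <- setdiff(names(p), source_organ)
  w <- p[sinks] / sum(p[sinks])
  r <- leaf_respiration
  f <- function(Ks) {
    Kt <- Ks + r
    x <- exp(-hours * Kt)
    q <- Ks / Kt
    x / (x + q * (1 - x)) - pL
  }
  Ks <- stats::uniroot(f, c(1e-10, 10), tol = 1e-14)$root
  list(transfer_rates_per_h = stats::setNames(as.numeric(Ks * w), sinks),
       leaf_respiration = r)
}

#' Read a simulation configuration
#'
#' Parses a YAML simulation config into a validated `sim_config` list. See
#' the packaged default (`system.file("extdata", "default_sim.yaml",
#' package = "pulsechase")`) for the schema: scalar settings (seed, noise
#' levels, timepoints), the organ table, per-month target allocations, true
#' HPLC detector response, true sugar contents and enzyme activity profiles,
#' and expression-screen settings.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` list.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_sim_config(cfg)
}

#' Default simulation configuration
#'
#' The committed fixture configuration emulating the labeling study: a ~99
#' atom percent pulse to the leaves of a labeled branch, natural-abundance
#' backgrounds near -27 per mil, chase sampling at 0/6/24/48/72 h, four
#' monthly stages with allocation targets matching the field measurements,
#' six-point HPLC calibration over 0.625-20 mg ml^-1, and a planted-gene
#' expression screen.
#'
#' @param seed Optional override of the config seed.
#' @return A `sim_config` list.
#' @export
default_sim_config <- function(seed = NULL) {
  path <- system.file("extdata", "default_sim.yaml", package = "pulsechase")
  cfg <- read_sim_config(path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

validate_sim_config <- function(cfg) {
  need <- c("seed", "background_delta13c", "pulse_excess_atom_percent",
            "timepoints_h", "dt_h", "noise_sd_delta", "assay_noise_cv",
            "n_replicates", "organs", "months")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0)
    stop("config missing fields: ", paste(miss, collapse = ", "), call. = FALSE)
  cfg$organs <- as.data.frame(do.call(rbind, lapply(cfg$organs, function(o)
    data.frame(organ = o$organ, biomass_g = o$biomass_g,
               carbon_fraction = o$carbon_fraction,
               respiration_rate_per_h = o$respiration_rate_per_h %||% 0,
               stringsAsFactors = FALSE))))
  if (any(cfg$organs$biomass_g < 0) || any(cfg$organs$carbon_fraction < 0) ||
      any(cfg$organs$carbon_fraction > 1) ||
      any(cfg$organs$respiration_rate_per_h < 0))
    stop("invalid organ table (biomass >= 0, carbon fraction in [0,1], rates >= 0)",
         call. = FALSE)
  tp <- cfg$timepoints_h
  if (any(diff(tp) <= 0) || any(tp < 0))
    stop("`timepoints_h` must be non-negative and strictly increasing",
         call. = FALSE)
  if (cfg$pulse_excess_atom_percent <= 0 || cfg$pulse_excess_atom_percent >= 100)
    stop("`pulse_excess_atom_percent` must be in (0, 100)", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a 13C pulse-chase labeling experiment
#'
#' Forward-Euler integration of a linear source-sink compartment model: at
#' the end of labeling the leaf carbon pool holds the whole excess-13C pulse;
#' it drains to each sink organ at a first-order transfer rate and to a
#' respired pool at the leaf respiration rate; sinks may respire at their own
#' rates. Excess mass is converted to atom percent through each organ's
#' carbon pool, then to delta-13C, and Gaussian measurement noise is added in
#' per-mil space. Transfer rates are taken from
#' `config$month_allocation_targets` (calibrated per month via
#' [calibrate_transfer_rates()]) or, if absent, from
#' `config$transfer_rates_per_h`.
#'
#' @param config A `sim_config` list (see [default_sim_config()]).
#' @return List with `readings` (organ, month, time_h, replicate, delta13c),
#'   `pools` (input schema of [allocation_table()]), and `truth`: noiseless
#'   per organ x month x time excess mass and allocation shares, the respired
#'   pool, the pulse mass, and the rates used.
#' @export
simulate_pulse_chase <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else validate_sim_config(config)
  organs <- cfg$organs
  source_organ <- cfg$source_organ %||% "leaves"
  if (!source_organ %in% organs$organ)
    stop("source organ `", source_organ, "` missing from organ table", call. = FALSE)
  dt <- cfg$dt_h
  tp <- cfg$timepoints_h
  Rc <- iso_constants(cfg$rc %||% 0.0112372)
  Fn <- atom_percent(cfg$background_delta13c, Rc)
  Ci <- stats::setNames(total_carbon(organs$biomass_g, organs$carbon_fraction),
                        organs$organ)
  pulse_mg <- Ci[[source_organ]] * cfg$pulse_excess_atom_percent / 100 * 1000

  set.seed(cfg$seed + 101L)
  readings <- list(); truth_rows <- list(); resp_rows <- list(); rates_used <- list()
  for (month in cfg$months) {
    if (!is.null(cfg$month_allocation_targets[[month]])) {
      tgt <- unlist(cfg$month_allocation_targets[[month]])
      cal <- calibrate_transfer_rates(
        tgt, hours = max(tp),
        leaf_respiration = organs$respiration_rate_per_h[organs$organ == source_organ],
        source_organ = source_organ)
      k <- cal$transfer_rates_per_h
    } else if (!is.null(cfg$transfer_rates_per_h)) {
      k <- unlist(cfg$transfer_rates_per_h)
    } else stop("config provides neither month_allocation_targets nor ",
                "transfer_rates_per_h", call. = FALSE)
    sinks <- names(k)
    if (!all(sinks %in% organs$organ))
      stop("transfer rates name unknown organs: ",
           paste(setdiff(sinks, organs$organ), collapse = ", "), call. = FALSE)
    resp <- stats::setNames(organs$respiration_rate_per_h, organs$organ)
    out_rate <- resp
    out_rate[source_organ] <- out_rate[source_organ] + sum(k)
    if (max(out_rate) * dt > 0.1)
      stop("dt too large for stability: rate * dt = ",
           signif(max(out_rate) * dt, 3), " > 0.1", call. = FALSE)
    rates_used[[month]] <- k

    state <- stats::setNames(rep(0, nrow(organs)), organs$organ)
    state[source_organ] <- pulse_mg
    respired <- 0
    n_steps <- round(max(tp) / dt)
    grid <- c(0, seq_len(n_steps) * dt)
    rec_idx <- vapply(tp, function(t) which.min(abs(grid - t)), integer(1))
    snap <- matrix(NA_real_, nrow = length(tp), ncol = length(state),
                   dimnames = list(NULL, names(state)))
    snap_resp <- numeric(length(tp))
    ri <- match(1L, rec_idx, nomatch = 0L)
    if (1L %in% rec_idx) { w <- which(rec_idx == 1L); snap[w, ] <- rep(state, each = length(w)); snap_resp[w] <- respired }
    for (s in seq_len(n_steps)) {
      outflow <- sum(k) * state[source_organ]
      leaf_resp <- resp[source_organ] * state[source_organ]
      sink_resp <- resp[sinks] * state[sinks]
      d <- stats::setNames(rep(0, length(state)), names(state))
      d[source_organ] <- -(outflow + leaf_resp)
      d[sinks] <- k * state[source_organ] - sink_resp
      state <- state + d * dt
      respired <- respired + (leaf_resp + sum(sink_resp)) * dt
      w <- which(rec_idx == s + 1L)
      if (length(w) > 0) { snap[w, ] <- rep(state, each = length(w)); snap_resp[w] <- respired }
    }

    for (ti in seq_along(tp)) {
      ex <- snap[ti, ]
      tot <- sum(ex)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        month = month, time_h = tp[ti], organ = names(ex),
        excess_mg = as.numeric(ex),
        allocation_percent = if (tot > 0) as.numeric(ex) / tot * 100 else NA_real_,
        stringsAsFactors = FALSE)
      resp_rows[[length(resp_rows) + 1L]] <- data.frame(
        month = month, time_h = tp[ti], respired_mg = snap_resp[ti],
        pulse_mg = pulse_mg, stringsAsFactors = FALSE)
      ap <- Fn + ex / 1000 / Ci[names(ex)] * 100
      dl <- delta_from_atom_percent(ap, Rc)
      for (rep_i in seq_len(cfg$n_replicates)) {
        readings[[length(readings) + 1L]] <- data.frame(
          organ = names(ex), month = month, time_h = tp[ti], replicate = rep_i,
          delta13c = as.numeric(dl) + stats::rnorm(length(dl), 0, cfg$noise_sd_delta),
          stringsAsFactors = FALSE)
      }
    }
  }

  pools <- do.call(rbind, lapply(cfg$months, function(m)
    data.frame(organ = organs$organ, month = m, biomass_g = organs$biomass_g,
               carbon_fraction = organs$carbon_fraction,
               fn_atom_percent = Fn, stringsAsFactors = FALSE)))
  list(readings = do.call(rbind, readings),
       pools = pools,
       truth = list(excess = do.call(rbind, truth_rows),
                    respired = do.call(rbind, resp_rows),
                    pulse_mg = pulse_mg, Fn_atom_percent = Fn,
                    rates_used = rates_used))
}

#' Simulate colorimetric and HPLC assay outputs from true sugar contents
#'
#' Inverts the assay calibration formulas: soluble-sugar and starch contents
#' become 620 nm absorbances (A = content * W / 2.34 - 0.07 and the starch
#' analogue), and sucrose/glucose/fructose contents become HPLC peak areas
#' through a true linear detector response. Noise is multiplicative
#' (coefficient of variation) on contents for the colorimetric channel and on
#' areas for the HPLC channel; the standard series itself is generated at the
#' six-point calibration gradient.
#'
#' @param sugar_truth Long data frame: `organ`, `month`, `analyte` (one of
#'   sucrose, glucose, fructose, soluble_sugar, starch), `content` (mg g^-1
#'   FW).
#' @param config A `sim_config`; uses `assay_noise_cv`, `assay_replicates`,
#'   `hplc` (gradient, true slopes/intercepts, noise_cv, extraction
#'   bookkeeping), `fresh_weight_g` and `seed`.
#' @return List with `colorimetric`, `standards`, `hplc_samples` data frames
#'   in the input schemas of [sugar_profiles()].
#' @export
simulate_assays <- function(sugar_truth, config) {
  cfg <- config
  set.seed(cfg$seed + 202L)
  sugar_truth <- as.data.frame(sugar_truth)
  stopifnot(all(c("organ", "month", "analyte", "content") %in% names(sugar_truth)))
  if (any(sugar_truth$content < 0))
    stop("true contents must be >= 0", call. = FALSE)
  W <- cfg$fresh_weight_g %||% 0.1
  n_rep <- cfg$assay_replicates %||% 4L
  cv <- cfg$assay_noise_cv

  colord <- sugar_truth[sugar_truth$analyte %in% c("soluble_sugar", "starch"), ]
  colorimetric <- do.call(rbind, lapply(seq_len(nrow(colord)), function(i) {
    row <- colord[i, ]
    content <- row$content * (1 + cv * stats::rnorm(n_rep))
    content <- pmax(content, 0)
    A <- if (row$analyte == "soluble_sugar") content * W / 2.34 - 0.07
         else content * W / 0.578 - 0.0295
    data.frame(sample_id = paste(row$organ, row$month, seq_len(n_rep), sep = "_"),
               organ = row$organ, month = row$month, replicate = seq_len(n_rep),
               assay = row$analyte, absorbance_620 = A, fresh_weight_g = W,
               stringsAsFactors = FALSE)
  }))

  hp <- cfg$hplc
  gradient <- unlist(hp$gradient_mg_ml)
  analytes <- names(hp$slope_true)
  standards <- do.call(rbind, lapply(analytes, function(an) {
    area <- hp$slope_true[[an]] * gradient + hp$intercept_true[[an]]
    area <- area * (1 + (hp$noise_cv %||% 0) * stats::rnorm(length(area)))
    data.frame(analyte = an, concentration_mg_ml = gradient, peak_area = area,
               stringsAsFactors = FALSE)
  }))

  hsug <- sugar_truth[sugar_truth$analyte %in% analytes, ]
  vol <- hp$extract_volume_ml %||% 10
  mass <- hp$sample_mass_g %||% 1
  hplc_samples <- do.call(rbind, lapply(seq_len(nrow(hsug)), function(i) {
    row <- hsug[i, ]
    conc <- row$content * mass / vol
    area <- hp$slope_true[[row$analyte]] * conc + hp$intercept_true[[row$analyte]]
    area <- area * (1 + (hp$noise_cv %||% 0) * stats::rnorm(n_rep))
    data.frame(sample_id = paste(row$organ, row$month, seq_len(n_rep), sep = "_"),
               organ = row$organ, month = row$month, replicate = seq_len(n_rep),
               analyte = row$analyte, peak_area = area,
               extract_volume_ml = vol, sample_mass_g = mass,
               stringsAsFactors = FALSE)
  }))
  list(colorimetric = colorimetric, standards = standards,
       hplc_samples = hplc_samples)
}

#' Simulate an expression table with sucrose-correlated planted genes
#'
#' Planted genes are built on the latent scale as rho * s + sqrt(1 - rho^2)
#' * e, where `s` is the standardized replicate-level sucrose trajectory and
#' `e` independent Gaussian noise; latent values are mapped to non-negative
#' FPKM by exp(mu + sigma * z). Because the exponential transform attenuates
#' correlation by the factor sigma / sqrt(exp(sigma^2) - 1), the latent
#' mixing weight is set to rho = target_r * sqrt(exp(sigma^2) - 1) / sigma
#' so that the population correlation of the FPKM values with sucrose equals
#' `target_r`. Background genes are independent noise through the same
#' transform.
#'
#' @param sucrose_series Named per-stage sucrose contents (mg g^-1 FW).
#' @param n_genes Total number of genes.
#' @param n_planted Number of sucrose-correlated genes (must be <= n_genes).
#' @param target_r Population correlation of planted genes, in (0, 1).
#' @param n_replicates Replicates per stage.
#' @param seed RNG seed.
#' @param sucrose_cv Replicate-level CV of the sucrose measurements.
#' @param log_mu,log_sigma Location/scale of the log-FPKM transform.
#' @return List with `expr` (gene_id, stage, replicate, fpkm), `sucrose`
#'   (stage, replicate, sucrose), and `planted_genes`.
#' @export
simulate_expression <- function(sucrose_series, n_genes = 1000, n_planted = 10,
                                target_r = 0.9, n_replicates = 3, seed = 1,
                                sucrose_cv = 0.03, log_mu = log(50),
                                log_sigma = 0.25) {
  if (n_planted > n_genes)
    stop("`n_planted` cannot exceed `n_genes`", call. = FALSE)
  if (target_r <= 0 || target_r >= 1)
    stop("`target_r` must lie in (0, 1)", call. = FALSE)
  # undo the lognormal attenuation so corr(FPKM, sucrose) targets target_r
  rho <- target_r * sqrt(exp(log_sigma^2) - 1) / log_sigma
  if (rho >= 1)
    stop("`target_r` unreachable after the exponential transform at this ",
         "`log_sigma`", call. = FALSE)
  set.seed(seed)
  stages <- names(sucrose_series)
  n_obs <- length(stages) * n_replicates
  suc <- data.frame(stage = rep(stages, each = n_replicates),
                    replicate = rep(seq_len(n_replicates), length(stages)),
                    sucrose = rep(unname(sucrose_series), each = n_replicates) *
                      (1 + sucrose_cv * stats::rnorm(n_obs)),
                    stringsAsFactors = FALSE)
  s_std <- as.numeric(scale(suc$sucrose))
  gene_ids <- sprintf("c%06d.graph_c0", seq_len(n_genes) + 100000L)
  planted <- sort(sample(gene_ids, n_planted))
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    id <- gene_ids[g]
    z <- if (id %in% planted)
      rho * s_std + sqrt(1 - rho^2) * stats::rnorm(n_obs)
    else stats::rnorm(n_obs)
    rows[[g]] <- data.frame(gene_id = id, stage = suc$stage,
                            replicate = suc$replicate,
                            fpkm = exp(log_mu + log_sigma * z),
                            stringsAsFactors = FALSE)
  }
  list(expr = do.call(rbind, rows), sucrose = suc, planted_genes = planted)
}

#' Simulate enzyme activity panels from stage profiles
#'
#' Replicate activities are profile mean * (1 + cv * z), truncated at zero;
#' missing profile entries (assays not detected in an organ) propagate as
#' `NA` replicates.
#'
#' @param stage_profiles Long data frame: `organ`, `month`, `enzyme`,
#'   `activity` (true mean, U g^-1, `NA` for absent assays).
#' @param cv Coefficient of variation of replicate noise.
#' @param n_replicates Replicates per organ x month x enzyme.
#' @param seed RNG seed.
#' @return Long panel data frame: `organ`, `month`, `replicate`, `enzyme`,
#'   `activity`.
#' @export
simulate_enzyme_panels <- function(stage_profiles, cv = 0.05, n_replicates = 3,
                                   seed = 1) {
  set.seed(seed)
  sp <- as.data.frame(stage_profiles)
  stopifnot(all(c("organ", "month", "enzyme", "activity") %in% names(sp)))
  out <- do.call(rbind, lapply(seq_len(nrow(sp)), function(i) {
    row <- sp[i, ]
    act <- if (is.na(row$activity)) rep(NA_real_, n_replicates)
           else pmax(row$activity * (1 + cv * stats::rnorm(n_replicates)), 0)
    data.frame(organ = row$organ, month = row$month,
               replicate = seq_len(n_replicates), enzyme = row$enzyme,
               activity = act, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a differential-expression table
#'
#' Emulates the structure of upstream DE output (gene, comparison, log2 fold
#' change, FDR) for exercising [deg_filter()] and [venn_overlap()]: a fraction
#' of genes is differentially expressed in each comparison (shifted log2FC,
#' small FDR), the rest are null.
#'
#' @param n_genes Number of genes.
#' @param comparisons Character vector of comparison labels.
#' @param prop_de Proportion of DE genes per comparison.
#' @param seed RNG seed.
#' @return Data frame `gene_id`, `comparison`, `log2fc`, `fdr`.
#' @export
simulate_deg_table <- function(n_genes = 2000,
                               comparisons = c("Jul_vs_Aug", "Jul_vs_Sep", "Jul_vs_Oct"),
                               prop_de = 0.25, seed = 1) {
  set.seed(seed)
  gene_ids <- sprintf("c%06d.graph_c0", seq_len(n_genes) + 200000L)
  do.call(rbind, lapply(comparisons, function(cmp) {
    de <- stats::runif(n_genes) < prop_de
    lfc <- ifelse(de, sample(c(-1, 1), n_genes, replace = TRUE) *
                    (1 + stats::rexp(n_genes, 1)),
                  stats::rnorm(n_genes, 0, 0.4))
    fdr <- ifelse(de, stats::runif(n_genes, 0, 0.05), stats::runif(n_genes, 0, 1))
    data.frame(gene_id = gene_ids, comparison = cmp, log2fc = lfc,
               fdr = pmin(fdr, 1), stringsAsFactors = FALSE)
  }))
}

#' Extract the long sugar-truth table from a config
#'
#' Flattens `config$sugar_truth` (organ -> month -> analyte map) into the
#' long table consumed by [simulate_assays()], adding the derived
#' soluble-sugar total (sucrose + glucose + fructose).
#'
#' @param config A `sim_config`.
#' @return Long data frame `organ`, `month`, `analyte`, `content`.
#' @export
sugar_truth_table <- function(config) {
  st <- config$sugar_truth
  if (is.null(st)) stop("config has no `sugar_truth` block", call. = FALSE)
  rows <- list()
  for (org in names(st)) for (m in names(st[[org]])) {
    v <- st[[org]][[m]]
    v$soluble_sugar <- v$sucrose + v$glucose + v$fructose
    for (an in names(v))
      rows[[length(rows) + 1L]] <- data.frame(
        organ = org, month = m, analyte = an, content = v[[an]],
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Extract the enzyme stage-profile table from a config
#'
#' @param config A `sim_config` with an `enzyme_truth` block
#'   (organ -> enzyme -> month map; `~`/NULL marks an absent assay).
#' @return Long data frame `organ`, `month`, `enzyme`, `activity`.
#' @export
enzyme_truth_table <- function(config) {
  et <- config$enzyme_truth
  if (is.null(et)) stop("config has no `enzyme_truth` block", call. = FALSE)
  rows <- list()
  for (org in names(et)) for (enz in names(et[[org]])) {
    months <- et[[org]][[enz]]
    for (m in names(months))
      rows[[length(rows) + 1L]] <- data.frame(
        organ = org, month = m, enzyme = enz,
        activity = if (is.null(months[[m]])) NA_real_ else months[[m]],
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
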