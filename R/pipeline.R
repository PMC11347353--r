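#' Run the full pulse-chase analysis pipeline
#'
#' One-command reproduction over a simulation config: generates every input
#' (isotope readings, organ pools, assay readings, HPLC standards and
#' samples, enzyme panels, expression and DE tables), then runs allocation
#' mass balance, sugar quantification, the correlation screens, DEG
#' filtering with overlap counts, and ANOVA/LSD letter assignment, writing
#' all tables, a run manifest, and a plain-text report to `outdir`.
#'
#' @param config A `sim_config`, or a path to a YAML config; defaults to the
#'   packaged fixture.
#' @param outdir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return Invisibly, a list with the output paths and the in-memory result
#'   tables.
#' @export
run_all <- function(config = default_sim_config(), outdir, seed = NULL) {
  cfg <- if (is.character(config)) read_sim_config(config) else config
  if (!inherits(cfg, "sim_config")) cfg <- validate_sim_config(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  inputs_dir <- file.path(outdir, "inputs")
  dir.create(inputs_dir, showWarnings = FALSE)
  wcsv <- function(df, path) { utils::write.csv(df, path, row.names = FALSE); path }

  # --- simulate every input ------------------------------------------------
  sim <- simulate_pulse_chase(cfg)
  sugars_true <- sugar_truth_table(cfg)
  assays <- simulate_assays(sugars_true, cfg)
  panels <- simulate_enzyme_panels(enzyme_truth_table(cfg),
                                   cv = cfg$assay_noise_cv,
                                   n_replicates = cfg$n_replicates,
                                   seed = cfg$seed + 404L)
  suc_stage <- vapply(cfg$months, function(m)
    cfg$sugar_truth$seed_kernels[[m]]$sucrose, numeric(1))
  names(suc_stage) <- cfg$months
  ex <- cfg$expression
  expr_sim <- simulate_expression(
    suc_stage, n_genes = ex$n_genes, n_planted = ex$n_planted,
    target_r = ex$target_r, n_replicates = cfg$n_replicates,
    seed = cfg$seed + 303L, sucrose_cv = ex$sucrose_cv %||% 0.03,
    log_mu = ex$log_mu_fpkm %||% log(50),
    log_sigma = ex$log_sigma_fpkm %||% 0.25)
  deg <- simulate_deg_table(n_genes = cfg$deg$n_genes,
                            comparisons = unlist(cfg$deg$comparisons),
                            prop_de = cfg$deg$prop_de,
                            seed = cfg$seed + 505L)

  input_paths <- c(
    isotope_readings = wcsv(sim$readings, file.path(inputs_dir, "isotope_readings.csv")),
    organ_pools = wcsv(sim$pools, file.path(inputs_dir, "organ_pools.csv")),
    colorimetric = wcsv(assays$colorimetric, file.path(inputs_dir, "colorimetric.csv")),
    hplc_standards = wcsv(assays$standards, file.path(inputs_dir, "hplc_standards.csv")),
    hplc_samples = wcsv(assays$hplc_samples, file.path(inputs_dir, "hplc_samples.csv")),
    enzyme_panels = wcsv(panels, file.path(inputs_dir, "enzyme_panels.csv")),
    expression_fpkm = wcsv(expr_sim$expr, file.path(inputs_dir, "expression_fpkm.csv")),
    deg_table = wcsv(deg, file.path(inputs_dir, "deg_table.csv")))

  # --- isotope mass balance ------------------------------------------------
  constants <- iso_constants(cfg$rc %||% 0.0112372)
  alloc <- allocation_table(sim$readings, sim$pools, constants)

  # --- assay quantification ------------------------------------------------
  curves <- lapply(split(assays$standards, assays$standards$analyte), function(d)
    fit_standard_curve(d$concentration_mg_ml, d$peak_area, analyte = d$analyte[1L]))
  profiles <- sugar_profiles(assays$colorimetric, assays$hplc_samples, curves)

  # --- correlation screens -------------------------------------------------
  profiles$month <- as.character(profiles$month)
  corr <- enzyme_sugar_matrix(panels, profiles)
  screen <- gene_sucrose_screen(expr_sim$expr, expr_sim$sucrose,
                                top_k = ex$n_planted)

  # --- DEG filtering and overlaps ------------------------------------------
  deg_by_cmp <- split(deg, deg$comparison)
  deg_sum <- do.call(rbind, lapply(names(deg_by_cmp), function(cmp) {
    f <- deg_filter(deg_by_cmp[[cmp]])
    data.frame(comparison = cmp, n_input = nrow(deg_by_cmp[[cmp]]),
               n_kept = nrow(f$kept), n_up = f$n_up, n_down = f$n_down,
               stringsAsFactors = FALSE)
  }))
  deg_sets <- lapply(deg_by_cmp, function(d) deg_filter(d)$kept$gene_id)
  overlap <- venn_overlap(deg_sets)

  # --- significance letters (sugar content across organs, per month) -------
  col_contents <- assays$colorimetric
  col_contents$content <- NA_real_
  sol <- col_contents$assay == "soluble_sugar"
  col_contents$content[sol] <- soluble_sugar_content(
    col_contents$absorbance_620[sol], col_contents$fresh_weight_g[sol])
  col_contents$content[!sol] <- starch_content(
    col_contents$absorbance_620[!sol], col_contents$fresh_weight_g[!sol])
  letters_tab <- do.call(rbind, lapply(split(col_contents[sol, ],
                                             col_contents$month[sol]), function(d) {
    lt <- suppressWarnings(anova_lsd_letters(d$content, d$organ))
    data.frame(month = d$month[1L], organ = names(lt$letters),
               mean_soluble_sugar = as.numeric(lt$means),
               letter = unname(lt$letters), anova_p = lt$anova_p,
               stringsAsFactors = FALSE)
  }))
  rownames(letters_tab) <- NULL

  # --- outputs -------------------------------------------------------------
  out_paths <- c(
    allocation = wcsv(alloc, file.path(outdir, "allocation.csv")),
    sugar_profiles = wcsv(profiles, file.path(outdir, "sugar_profiles.csv")),
    gene_screen = wcsv(screen$ranking, file.path(outdir, "gene_screen.csv")),
    deg_summary = wcsv(deg_sum, file.path(outdir, "deg_summary.csv")),
    letters = wcsv(letters_tab, file.path(outdir, "letters.csv")))
  for (org in unique(corr$organ)) {
    p <- wcsv(corr[corr$organ == org, ],
              file.path(outdir, paste0("correlations_", org, ".csv")))
    out_paths[paste0("correlations_", org)] <- p
  }

  manifest <- run_manifest(cfg, input_paths, out_paths,
                           qc_flags = sum(profiles$qc_negative, na.rm = TRUE) +
                             sum(alloc$flag_negative_excess))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  report_path <- file.path(outdir, "report.txt")
  writeLines(render_report(alloc, corr, screen, deg_sum, overlap, letters_tab),
             report_path)

  invisible(list(paths = c(input_paths, out_paths,
                           manifest = manifest_path, report = report_path),
                 allocation = alloc, sugar_profiles = profiles,
                 correlations = corr, gene_screen = screen,
                 deg_summary = deg_sum, overlap = overlap,
                 letters = letters_tab, truth = sim$truth,
                 planted_genes = expr_sim$planted_genes, config = cfg))
}

run_manifest <- function(cfg, input_paths, out_paths, qc_flags) {
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  yaml::write_yaml(unclass(cfg), cfg_file)
  counts <- vapply(c(input_paths, out_paths), function(p)
    length(utils::count.fields(p, sep = ",", quote = "\"")) - 1L, integer(1))
  list(pipeline = "pulsechase",
       version = as.character(utils::packageVersion("pulsechase")),
       seed = cfg$seed,
       config_md5 = unname(tools::md5sum(cfg_file)),
       input_md5 = as.list(stats::setNames(unname(tools::md5sum(input_paths)),
                                           basename(input_paths))),
       output_md5 = as.list(stats::setNames(unname(tools::md5sum(out_paths)),
                                            basename(out_paths))),
       row_counts = as.list(stats::setNames(unname(counts),
                                            basename(names(counts)))),
       qc_flag_count = qc_flags)
}

render_report <- function(alloc, corr, screen, deg_sum, overlap, letters_tab) {
  out <- c("pulse-chase pipeline report", strrep("=", 60), "",
           "Allocation of excess 13C (percent of organ-held label):", "")
  for (m in unique(alloc$month)) {
    d <- alloc[alloc$month == m, ]
    out <- c(out, sprintf("  %s (total %.3f mg):", m, d$total13c_mg[1L]),
             sprintf("    %-14s %8.2f %%", d$organ, d$allocation_percent))
  }
  out <- c(out, "", "Sugar x enzyme correlations (r, starred):", "")
  for (org in unique(corr$organ)) {
    m <- format_correlation_matrix(corr[corr$organ == org, ])
    out <- c(out, paste0("  ", org, ":"),
             paste0("    ", utils::capture.output(print(m, quote = FALSE))))
  }
  out <- c(out, "", "Top genes by correlation with seed sucrose:",
           sprintf("    %-20s r = %.3f", screen$ranking$gene_id, screen$ranking$r),
           "", "DEG filter summary:",
           sprintf("    %-12s kept %5d (up %5d / down %5d)",
                   deg_sum$comparison, deg_sum$n_kept, deg_sum$n_up, deg_sum$n_down),
           sprintf("    common to all comparisons: %d", overlap$common),
           "", "Soluble sugar letters (within month, across organs):",
           sprintf("    %-4s %-14s %8.2f  %s", letters_tab$month,
                   letters_tab$organ, letters_tab$mean_soluble_sugar,
                   letters_tab$letter))
  out
}

#' Validate pipeline input files
#'
#' Schema and row-level validation of input CSVs without mutating them.
#' Checks required columns per input kind, numeric-range invariants
#' (non-negative biomass and activities, carbon fractions in [0, 1], FDR in
#' [0, 1], fresh weight positive), and the isotope-reading rule that each row
#' needs `rs` or `delta13c` (rows with both get a warning-level message;
#' `delta13c` takes precedence downstream).
#'
#' @param paths Named character vector or list; names identify the input
#'   kind (`isotope_readings`, `organ_pools`, `colorimetric`,
#'   `hplc_standards`, `hplc_samples`, `enzyme_panels`, `expression_fpkm`,
#'   `deg_table`).
#' @return Data frame: `kind`, `file`, `n_rows`, `status` ("pass", "warn",
#'   "fail"), `messages`.
#' @export
validate_inputs <- function(paths) {
  schemas <- list(
    isotope_readings = c("organ", "month", "time_h"),
    organ_pools = c("organ", "month", "biomass_g", "carbon_fraction",
                    "fn_atom_percent"),
    colorimetric = c("sample_id", "assay", "absorbance_620", "fresh_weight_g"),
    hplc_standards = c("analyte", "concentration_mg_ml", "peak_area"),
    hplc_samples = c("sample_id", "analyte", "peak_area"),
    enzyme_panels = c("organ", "month", "replicate", "enzyme", "activity"),
    expression_fpkm = c("gene_id", "stage", "replicate", "fpkm"),
    deg_table = c("gene_id", "comparison", "log2fc", "fdr"))
  rows <- lapply(names(paths), function(kind) {
    path <- paths[[kind]]
    res <- data.frame(kind = kind, file = path, n_rows = NA_integer_,
                      status = "fail", messages = "", stringsAsFactors = FALSE)
    if (!file.exists(path)) {
      res$messages <- "file not found"
      return(res)
    }
    if (is.null(schemas[[kind]])) {
      res$messages <- "unknown input kind"
      return(res)
    }
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) NULL)
    if (is.null(df)) { res$messages <- "unreadable CSV"; return(res) }
    res$n_rows <- nrow(df)
    missing <- setdiff(schemas[[kind]], names(df))
    msgs <- character()
    if (kind == "isotope_readings") {
      if (!any(c("rs", "delta13c") %in% names(df)))
        missing <- c(missing, "rs|delta13c")
    }
    if (length(missing) > 0) {
      res$messages <- paste("missing columns:", paste(missing, collapse = ", "))
      return(res)
    }
    bad_rows <- function(cond, what) {
      idx <- which(cond)
      if (length(idx) > 0)
        msgs <<- c(msgs, paste0(what, " at row(s) ",
                                paste(utils::head(idx, 5L), collapse = ", ")))
    }
    warn_rows <- character()
    switch(kind,
      isotope_readings = {
        rs <- if ("rs" %in% names(df)) df$rs else NA
        dl <- if ("delta13c" %in% names(df)) df$delta13c else NA
        bad_rows(is.na(rs) & is.na(dl), "neither rs nor delta13c")
        bad_rows(!is.na(rs) & rs < 0, "negative rs")
        bad_rows(!is.na(dl) & dl <= -1000, "delta13c <= -1000")
        bad_rows(df$time_h < 0, "negative time_h")
        both <- which(!is.na(rs) & !is.na(dl))
        if (length(both) > 0)
          warn_rows <- paste0("both rs and delta13c filled at row(s) ",
                              paste(utils::head(both, 5L), collapse = ", "),
                              "; delta13c takes precedence")
      },
      organ_pools = {
        bad_rows(df$biomass_g < 0, "negative biomass_g")
        bad_rows(df$carbon_fraction < 0 | df$carbon_fraction > 1,
                 "carbon_fraction outside [0,1]")
        bad_rows(df$fn_atom_percent < 0 | df$fn_atom_percent >= 100,
                 "fn_atom_percent outside [0,100)")
      },
      colorimetric = {
        bad_rows(df$fresh_weight_g <= 0, "non-positive fresh_weight_g")
        bad_rows(!df$assay %in% c("soluble_sugar", "starch"), "unknown assay")
      },
      hplc_standards = bad_rows(df$concentration_mg_ml <= 0,
                                "non-positive standard concentration"),
      enzyme_panels = bad_rows(!is.na(df$activity) & df$activity < 0,
                               "negative activity"),
      expression_fpkm = bad_rows(df$fpkm < 0, "negative fpkm"),
      deg_table = bad_rows(df$fdr < 0 | df$fdr > 1, "fdr outside [0,1]"))
    if (length(msgs) > 0) {
      res$messages <- paste(msgs, collapse = "; ")
      res$status <- "fail"
    } else if (length(warn_rows) > 0) {
      res$messages <- paste(warn_rows, collapse = "; ")
      res$status <- "warn"
    } else res$status <- "pass"
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
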