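#' Soluble sugar content from an anthrone microplate reading
#'
#' content (mg g^-1 FW) = 2.34 * (A + 0.07) / W, where `A` is absorbance at
#' 620 nm and `W` the fresh weight (g). The kit constants already incorporate
#' the fixed 10 ml dilution of the extraction protocol, so no extra dilution
#' factor is applied.
#'
#' @param absorbance Absorbance at 620 nm (AU).
#' @param fresh_weight_g Sample fresh weight in g, > 0.
#' @return Content in mg per g fresh weight; vectorised. Negative results are
#'   returned as-is (flag them downstream), never clamped.
#' @export
soluble_sugar_content <- function(absorbance, fresh_weight_g) {
  check_fresh_weight(fresh_weight_g)
  2.34 * (absorbance + 0.07) / fresh_weight_g
}

#' Starch content from an anthrone microplate reading
#'
#' content (mg g^-1 FW) = 0.578 * (A + 0.0295) / W.
#'
#' @inheritParams soluble_sugar_content
#' @return Content in mg per g fresh weight; vectorised.
#' @export
starch_content <- function(absorbance, fresh_weight_g) {
  check_fresh_weight(fresh_weight_g)
  0.578 * (absorbance + 0.0295) / fresh_weight_g
}

check_fresh_weight <- function(w) {
  if (!is.numeric(w) || any(!is.finite(w)) || any(w <= 0))
    stop("`fresh_weight_g` must be finite and > 0", call. = FALSE)
  invisible(w)
}

#' Fit an HPLC standard curve
#'
#' Unweighted ordinary least squares of detector peak area on standard
#' concentration: area = slope * conc + intercept.
#'
#' @param concentrations Standard concentrations (mg ml^-1); at least 3
#'   strictly positive, non-constant values.
#' @param peak_areas Detector peak areas, same length.
#' @param analyte Optional analyte label carried through to the result.
#' @return An object of class `standard_curve`: list with `analyte`, `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
#' @examples
#' fit_standard_curve(c(0.625, 1.25, 2.5, 5, 10, 20),
#'                    1000 * c(0.625, 1.25, 2.5, 5, 10, 20))
fit_standard_curve <- function(concentrations, peak_areas, analyte = NA_character_) {
  if (length(concentrations) != length(peak_areas))
    stop("`concentrations` and `peak_areas` must have equal length", call. = FALSE)
  if (length(concentrations) < 3L)
    stop("a standard curve needs at least 3 points", call. = FALSE)
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stop("standard concentrations must be finite and > 0", call. = FALSE)
  if (stats::var(concentrations) == 0)
    stop("standard concentrations are constant; cannot fit a curve", call. = FALSE)
  fit <- stats::lm(peak_areas ~ concentrations)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0)
    stop("fitted slope is not positive; curve unusable", call. = FALSE)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((peak_areas - mean(peak_areas))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(analyte = analyte, slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = min(max(r2, 0), 1), n = length(peak_areas)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("HPLC standard curve%s: area = %.6g * conc + %.6g (r2 = %.6f, n = %d)\n",
              if (is.na(x$analyte)) "" else paste0(" [", x$analyte, "]"),
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Quantify a sugar from its peak area
#'
#' Inverts a fitted [fit_standard_curve()] and applies extraction bookkeeping:
#' conc (mg ml^-1) = (area - intercept) / slope;
#' content (mg g^-1 FW) = conc * extract_volume_ml / sample_mass_g.
#' Defaults follow the protocol of 0.1-1 g tissue diluted to 10 ml.
#'
#' @param area Detector peak area(s).
#' @param curve A `standard_curve` object.
#' @param extract_volume_ml Extract volume in ml (default 10).
#' @param sample_mass_g Fresh sample mass in g (default 1), > 0.
#' @return Content in mg per g fresh weight; negative when the area falls
#'   below the curve intercept (flag, do not clamp).
#' @export
quantify_sugar <- function(area, curve, extract_volume_ml = 10, sample_mass_g = 1) {
  if (!inherits(curve, "standard_curve"))
    stop("`curve` must come from fit_standard_curve()", call. = FALSE)
  if (curve$slope <= 0) stop("curve slope must be > 0", call. = FALSE)
  if (any(sample_mass_g <= 0)) stop("`sample_mass_g` must be > 0", call. = FALSE)
  conc <- (area - curve$intercept) / curve$slope
  conc * extract_volume_ml / sample_mass_g
}

#' Non-structural carbohydrate summary
#'
#' NSC total is soluble sugar plus starch; the soluble:starch ratio is Inf
#' (flagged) when starch is zero, and the `soluble_majority` flag is TRUE when
#' soluble sugars strictly exceed half of the NSC total.
#'
#' @param soluble Soluble sugar content, mg g^-1 FW, >= 0.
#' @param starch Starch content, mg g^-1 FW, >= 0.
#' @return Data frame with `nsc_total`, `soluble_to_starch_ratio`,
#'   `soluble_majority`, and `qc_flag` ("ok", "zero_starch", "zero_nsc").
#' @export
nsc_summary <- function(soluble, starch) {
  if (any(soluble < 0) || any(starch < 0))
    stop("`soluble` and `starch` must be >= 0", call. = FALSE)
  total <- soluble + starch
  ratio <- ifelse(starch > 0, soluble / starch,
                  ifelse(soluble > 0, Inf, NA_real_))
  flag <- ifelse(total == 0, "zero_nsc", ifelse(starch == 0, "zero_starch", "ok"))
  data.frame(nsc_total = total,
             soluble_to_starch_ratio = ratio,
             soluble_majority = total > 0 & soluble / ifelse(total > 0, total, 1) > 0.5,
             qc_flag = flag,
             stringsAsFactors = FALSE)
}

#' Build per-sample sugar profiles from raw assay tables
#'
#' Applies the colorimetric formulas to soluble-sugar and starch readings,
#' quantifies sucrose/glucose/fructose from HPLC areas against per-analyte
#' standard curves, and assembles one profile row per sample with NSC
#' summaries and QC flags.
#'
#' @param colorimetric Data frame: `sample_id`, `organ`, `month`, `replicate`
#'   (optional), `assay` ("soluble_sugar" or "starch"), `absorbance_620`,
#'   `fresh_weight_g`.
#' @param hplc_samples Data frame: `sample_id`, `analyte`, `peak_area`,
#'   `extract_volume_ml`, `sample_mass_g`.
#' @param curves Named list of `standard_curve` objects keyed by analyte.
#' @return Data frame with one row per sample: sucrose, glucose, fructose,
#'   soluble_sugar, starch, nsc_total, soluble_to_starch_ratio,
#'   soluble_majority and `qc_negative` flag.
#' @export
sugar_profiles <- function(colorimetric, hplc_samples, curves) {
  colorimetric <- as.data.frame(colorimetric)
  hplc_samples <- as.data.frame(hplc_samples)
  stopifnot(all(c("sample_id", "assay", "absorbance_620", "fresh_weight_g") %in%
                  names(colorimetric)))
  stopifnot(all(c("sample_id", "analyte", "peak_area") %in% names(hplc_samples)))

  colorimetric$content <- NA_real_
  is_sol <- colorimetric$assay == "soluble_sugar"
  is_sta <- colorimetric$assay == "starch"
  if (any(!(is_sol | is_sta)))
    stop("unknown assay label(s): ",
         paste(unique(colorimetric$assay[!(is_sol | is_sta)]), collapse = ", "),
         call. = FALSE)
  colorimetric$content[is_sol] <- soluble_sugar_content(
    colorimetric$absorbance_620[is_sol], colorimetric$fresh_weight_g[is_sol])
  colorimetric$content[is_sta] <- starch_content(
    colorimetric$absorbance_620[is_sta], colorimetric$fresh_weight_g[is_sta])

  vol <- if ("extract_volume_ml" %in% names(hplc_samples))
    hplc_samples$extract_volume_ml else 10
  mas <- if ("sample_mass_g" %in% names(hplc_samples))
    hplc_samples$sample_mass_g else 1
  hplc_samples$content <- NA_real_
  for (an in unique(hplc_samples$analyte)) {
    if (is.null(curves[[an]]))
      stop("no standard curve supplied for analyte `", an, "`", call. = FALSE)
    i <- hplc_samples$analyte == an
    hplc_samples$content[i] <- quantify_sugar(
      hplc_samples$peak_area[i], curves[[an]],
      extract_volume_ml = if (length(vol) > 1) vol[i] else vol,
      sample_mass_g = if (length(mas) > 1) mas[i] else mas)
  }

  ids <- unique(colorimetric$sample_id)
  meta_cols <- intersect(c("organ", "month", "replicate"), names(colorimetric))
  rows <- lapply(ids, function(id) {
    cc <- colorimetric[colorimetric$sample_id == id, , drop = FALSE]
    hh <- hplc_samples[hplc_samples$sample_id == id, , drop = FALSE]
    pick <- function(df, sel, what) {
      v <- df$content[sel]
      if (length(v) == 0) NA_real_ else mean(v)
    }
    sol <- pick(cc, cc$assay == "soluble_sugar")
    sta <- pick(cc, cc$assay == "starch")
    out <- data.frame(sample_id = id, stringsAsFactors = FALSE)
    for (mc in meta_cols) out[[mc]] <- cc[[mc]][1L]
    out$sucrose <- pick(hh, hh$analyte == "sucrose")
    out$glucose <- pick(hh, hh$analyte == "glucose")
    out$fructose <- pick(hh, hh$analyte == "fructose")
    out$soluble_sugar <- sol
    out$starch <- sta
    vals <- c(out$sucrose, out$glucose, out$fructose, sol, sta)
    out$qc_negative <- any(vals < 0, na.rm = TRUE)
    if (!is.na(sol) && !is.na(sta) && sol >= 0 && sta >= 0) {
      ns <- nsc_summary(sol, sta)
      out$nsc_total <- ns$nsc_total
      out$soluble_to_starch_ratio <- ns$soluble_to_starch_ratio
      out$soluble_majority <- ns$soluble_majority
    } else {
      out$nsc_total <- NA_real_
      out$soluble_to_starch_ratio <- NA_real_
      out$soluble_majority <- NA
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
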