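#' Isotope constants
#'
#' Bundle of constants used by the delta-13C conversions. The only member is
#' the international standard 13C/12C ratio (VPDB), `Rc = 0.0112372`.
#'
#' @param Rc Standard 13C/12C ratio. Must be a single positive number.
#' @return A list of class `iso_constants`.
#' @export
#' @examples
#' iso_constants()
iso_constants <- function(Rc = 0.0112372) {
  if (!is.numeric(Rc) || length(Rc) != 1L || !is.finite(Rc) || Rc <= 0)
    stop("`Rc` must be a single positive number", call. = FALSE)
  structure(list(Rc = Rc), class = "iso_constants")
}

#' Convert a 13C/12C ratio to delta-13C
#'
#' delta13C (per mil) = (Rs - Rc) / Rc * 1000, where `Rs` is the sample
#' 13C/12C ratio and `Rc` the VPDB standard ratio.
#'
#' @param Rs Sample 13C/12C ratio(s), dimensionless, >= 0.
#' @param constants An [iso_constants()] object.
#' @return delta-13C in per mil; vectorised over `Rs`.
#' @export
#' @examples
#' delta_from_ratio(0.0112372)  # 0 per mil at the standard
delta_from_ratio <- function(Rs, constants = iso_constants()) {
  stopifnot(inherits(constants, "iso_constants"))
  if (!is.numeric(Rs) || any(!is.finite(Rs)) || any(Rs < 0))
    stop("`Rs` must be finite and >= 0", call. = FALSE)
  (Rs - constants$Rc) / constants$Rc * 1000
}

#' Convert delta-13C to a 13C/12C ratio
#'
#' Inverse of [delta_from_ratio()]: Rs = Rc * (1 + delta/1000).
#'
#' @param delta13c delta-13C in per mil, > -1000.
#' @inheritParams delta_from_ratio
#' @return Sample 13C/12C ratio(s).
#' @export
ratio_from_delta <- function(delta13c, constants = iso_constants()) {
  stopifnot(inherits(constants, "iso_constants"))
  if (!is.numeric(delta13c) || any(!is.finite(delta13c)) || any(delta13c <= -1000))
    stop("`delta13c` must be finite and > -1000 per mil", call. = FALSE)
  constants$Rc * (1 + delta13c / 1000)
}

#' 13C atom percent from delta-13C
#'
#' Atom%13C = ((delta + 1000) * Rc) / (((delta + 1000) * Rc) + 1000) * 100.
#' Strictly increasing in delta and bounded in (0, 100).
#'
#' @inheritParams ratio_from_delta
#' @return Atom percent 13C; vectorised.
#' @export
#' @examples
#' atom_percent(0)  # natural standard, about 1.1112 %
atom_percent <- function(delta13c, constants = iso_constants()) {
  stopifnot(inherits(constants, "iso_constants"))
  if (!is.numeric(delta13c) || any(!is.finite(delta13c)) || any(delta13c <= -1000))
    stop("`delta13c` must be finite and > -1000 per mil", call. = FALSE)
  x <- (delta13c + 1000) * constants$Rc
  x / (x + 1000) * 100
}

#' delta-13C from atom percent
#'
#' Inverse of [atom_percent()]; used when converting simulated pool
#' enrichments back into instrument-scale readings.
#'
#' @param atom_pct Atom percent 13C, in (0, 100).
#' @inheritParams delta_from_ratio
#' @return delta-13C in per mil.
#' @export
delta_from_atom_percent <- function(atom_pct, constants = iso_constants()) {
  stopifnot(inherits(constants, "iso_constants"))
  if (!is.numeric(atom_pct) || any(!is.finite(atom_pct)) ||
      any(atom_pct <= 0) || any(atom_pct >= 100))
    stop("`atom_pct` must lie strictly between 0 and 100", call. = FALSE)
  f <- atom_pct / 100
  1000 * f / ((1 - f) * constants$Rc) - 1000
}

#' Total organ carbon pool
#'
#' Ci (g) = carbon_fraction * biomass_g: the carbon mass of an organ given its
#' dry biomass and carbon fraction.
#'
#' @param biomass_g Organ dry biomass in g, >= 0.
#' @param carbon_fraction Proportion of the dry mass that is carbon, in 0..1.
#' @return Carbon mass in g; vectorised.
#' @export
total_carbon <- function(biomass_g, carbon_fraction) {
  if (!is.numeric(biomass_g) || any(!is.finite(biomass_g)) || any(biomass_g < 0))
    stop("`biomass_g` must be finite and >= 0", call. = FALSE)
  if (!is.numeric(carbon_fraction) || any(!is.finite(carbon_fraction)) ||
      any(carbon_fraction < 0) || any(carbon_fraction > 1))
    stop("`carbon_fraction` must lie in [0, 1]", call. = FALSE)
  carbon_fraction * biomass_g
}

#' Excess 13C mass of an organ
#'
#' 13Ci (mg) = Ci_g * (atom% - Fn) / 100 * 1000: the tracer mass above the
#' unlabeled background `Fn`. Negative values (atom percent below background,
#' as happens late in the season) are preserved, not clamped; downstream code
#' flags them.
#'
#' @param Ci_g Organ carbon pool in g, >= 0.
#' @param atom_pct Measured atom percent 13C.
#' @param Fn Background atom percent from unlabeled controls.
#' @return Excess 13C in mg; vectorised.
#' @export
excess_13c_mass <- function(Ci_g, atom_pct, Fn) {
  if (!is.numeric(Ci_g) || any(!is.finite(Ci_g)) || any(Ci_g < 0))
    stop("`Ci_g` must be finite and >= 0", call. = FALSE)
  Ci_g * (atom_pct - Fn) / 100 * 1000
}

#' Allocation percentages across organs
#'
#' Pi = 13Ci / sum(13Ci) * 100 over the organs of one month. Scale-invariant;
#' output sums to 100 exactly up to floating point.
#'
#' @param excess_mg Named numeric vector of per-organ excess 13C masses (mg).
#' @return Named vector of percentages summing to 100.
#' @export
#' @examples
#' allocation_ratios(c(branches = 1, leaves = 1, peels = 1, seed_kernels = 1))
allocation_ratios <- function(excess_mg) {
  if (!is.numeric(excess_mg) || length(excess_mg) < 1L || any(!is.finite(excess_mg)))
    stop("`excess_mg` must be a non-empty finite numeric vector", call. = FALSE)
  total <- sum(excess_mg)
  if (total <= 0)
    stop("no net labeled carbon in month (total excess 13C <= 0)", call. = FALSE)
  excess_mg / total * 100
}

#' Complete a partially known allocation row
#'
#' Given all but one organ's allocation percentage, the remaining organ's
#' share follows from the closure constraint sum(Pi) = 100.
#'
#' @param known_pct Numeric vector of the known percentages.
#' @return The remaining percentage, `100 - sum(known_pct)`.
#' @export
complete_allocation <- function(known_pct) {
  if (!is.numeric(known_pct) || any(!is.finite(known_pct)))
    stop("`known_pct` must be finite numeric", call. = FALSE)
  100 - sum(known_pct)
}

#' Transport rate of labeled photosynthate into an organ
#'
#' Vi (ug g^-1 h^-1) = (13Ci * 1000 / W) / H: excess 13C per gram of organ dry
#' biomass delivered per hour of chase, where `H` is the time since the end of
#' labeling.
#'
#' @param excess13c_mg Excess 13C in mg.
#' @param biomass_g Organ dry biomass in g, > 0.
#' @param hours Hours since the end of labeling, > 0.
#' @return Transport rate in ug g^-1 h^-1; vectorised.
#' @export
transport_rate <- function(excess13c_mg, biomass_g, hours) {
  if (!is.numeric(hours) || any(!is.finite(hours)) || any(hours <= 0))
    stop("`hours` must be finite and > 0", call. = FALSE)
  if (!is.numeric(biomass_g) || any(!is.finite(biomass_g)) || any(biomass_g <= 0))
    stop("`biomass_g` must be finite and > 0", call. = FALSE)
  (excess13c_mg * 1000 / biomass_g) / hours
}

#' Full allocation table from readings and organ pools
#'
#' Composes the conversion chain delta-13C -> atom percent -> excess 13C mass
#' -> allocation percentage and transport rate, one output row per organ x
#' month. Readings may carry either a raw 13C/12C ratio (`rs`) or `delta13c`;
#' when both are present `delta13c` takes precedence (with a warning).
#' Replicate readings at the same organ x month x time are averaged on the
#' atom-percent scale before mass balance.
#'
#' @param readings Data frame with columns `organ`, `month`, `time_h` and at
#'   least one of `rs`, `delta13c`.
#' @param pools Data frame with columns `organ`, `month`, `biomass_g`,
#'   `carbon_fraction`, `fn_atom_percent`.
#' @param constants An [iso_constants()] object.
#' @param at_time Chase time (h) at which to evaluate allocation; defaults to
#'   the latest time present within each month.
#' @return Data frame with one row per organ x month: `delta13c`,
#'   `atom_percent`, `Ci_g`, `excess13c_mg`, `allocation_percent`,
#'   `transport_rate`, `total13c_mg`, and `flag_negative_excess`. Months whose
#'   total excess is not positive get `NA` allocation percentages with a
#'   warning rather than an error, so that late-season sign reversals remain
#'   visible in the output.
#' @export
allocation_table <- function(readings, pools, constants = iso_constants(),
                             at_time = NULL) {
  readings <- as.data.frame(readings)
  pools <- as.data.frame(pools)
  need_r <- c("organ", "month", "time_h")
  if (!all(need_r %in% names(readings)))
    stop("`readings` must have columns: ", paste(need_r, collapse = ", "),
         call. = FALSE)
  if (!any(c("rs", "delta13c") %in% names(readings)))
    stop("`readings` must have an `rs` or `delta13c` column", call. = FALSE)
  need_p <- c("organ", "month", "biomass_g", "carbon_fraction", "fn_atom_percent")
  if (!all(need_p %in% names(pools)))
    stop("`pools` must have columns: ", paste(need_p, collapse = ", "),
         call. = FALSE)

  rs <- if ("rs" %in% names(readings)) readings$rs else rep(NA_real_, nrow(readings))
  dl <- if ("delta13c" %in% names(readings)) readings$delta13c else rep(NA_real_, nrow(readings))
  both <- !is.na(rs) & !is.na(dl)
  if (any(both))
    warning(sum(both), " reading(s) carry both `rs` and `delta13c`; ",
            "`delta13c` takes precedence", call. = FALSE)
  use_rs <- is.na(dl) & !is.na(rs)
  dl[use_rs] <- delta_from_ratio(rs[use_rs], constants)
  if (any(is.na(dl)))
    stop("reading(s) without `rs` or `delta13c` at row(s): ",
         paste(utils::head(which(is.na(dl)), 5L), collapse = ", "), call. = FALSE)
  readings$delta13c <- dl

  # restrict to the evaluation time per month
  pick <- unlist(lapply(split(seq_len(nrow(readings)), readings$month), function(idx) {
    tt <- readings$time_h[idx]
    target <- if (is.null(at_time)) max(tt) else at_time
    sel <- idx[abs(tt - target) < 1e-9]
    if (length(sel) == 0L)
      stop("no readings at time ", target, " h for month ",
           readings$month[idx[1L]], call. = FALSE)
    sel
  }), use.names = FALSE)
  rd <- readings[pick, , drop = FALSE]

  key <- interaction(rd$organ, rd$month, drop = TRUE)
  agg <- do.call(rbind, lapply(split(rd, key), function(d) {
    data.frame(organ = d$organ[1L], month = d$month[1L], time_h = d$time_h[1L],
               atom_percent = mean(atom_percent(d$delta13c, constants)),
               n_readings = nrow(d), stringsAsFactors = FALSE)
  }))
  agg$delta13c <- delta_from_atom_percent(agg$atom_percent, constants)

  m <- match(paste(agg$organ, agg$month), paste(pools$organ, pools$month))
  if (anyNA(m)) {
    miss <- agg[is.na(m), c("organ", "month")]
    stop("no organ pool for: ",
         paste(paste(miss$organ, miss$month, sep = "/"), collapse = ", "),
         call. = FALSE)
  }
  pk <- pools[m, , drop = FALSE]
  agg$Ci_g <- total_carbon(pk$biomass_g, pk$carbon_fraction)
  agg$excess13c_mg <- excess_13c_mass(agg$Ci_g, agg$atom_percent, pk$fn_atom_percent)
  agg$flag_negative_excess <- agg$excess13c_mg < 0
  agg$transport_rate <- ifelse(agg$time_h > 0 & pk$biomass_g > 0,
                               (agg$excess13c_mg * 1000 / pk$biomass_g) / agg$time_h,
                               NA_real_)

  out <- do.call(rbind, lapply(split(agg, agg$month, drop = TRUE), function(d) {
    tot <- sum(d$excess13c_mg)
    d$total13c_mg <- tot
    if (tot > 0) {
      d$allocation_percent <- d$excess13c_mg / tot * 100
    } else {
      warning("no net labeled carbon in month ", d$month[1L],
              "; allocation percentages set to NA", call. = FALSE)
      d$allocation_percent <- NA_real_
    }
    d
  }))
  rownames(out) <- NULL
  out[, c("organ", "month", "time_h", "n_readings", "delta13c", "atom_percent",
          "Ci_g", "excess13c_mg", "allocation_percent", "transport_rate",
          "total13c_mg", "flag_negative_excess")]
}
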