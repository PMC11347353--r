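# Independent one-line transcriptions of the mass-balance formulas, kept
# deliberately separate from the package implementation so the two can be
# cross-checked.
oracle_delta <- function(Rs, Rc = 0.0112372) (Rs - Rc) / Rc * 1000
oracle_atom_pct <- function(d, Rc = 0.0112372) {
  ((d + 1000) * Rc) / (((d + 1000) * Rc) + 1000) * 100
}
oracle_Ci <- function(cf, W) cf * W
oracle_excess_mg <- function(Ci, ap, Fn) Ci * (ap - Fn) / 100 * 1000
oracle_Pi <- function(ex) ex / sum(ex) * 100
oracle_Vi <- function(ex_mg, W, H) ex_mg * 1000 / W / H

# Closed-form solution of the source-sink compartment model with leaf
# respiration r, sink respiration 0: independent of the Euler integrator.
oracle_compartments <- function(pulse, k, r, t) {
  Kt <- sum(k) + r
  leaf <- pulse * exp(-Kt * t)
  sinks <- pulse * k / Kt * (1 - exp(-Kt * t))
  respired <- pulse * r / Kt * (1 - exp(-Kt * t))
  list(leaf = leaf, sinks = sinks, respired = respired)
}

# Exhaustive pairwise-LSD oracle: for every pair, the unadjusted t test on
# the pooled ANOVA error mean square. Returns a logical matrix of
# significant differences.
oracle_lsd_pairs <- function(values, groups, alpha = 0.05) {
  f <- factor(groups)
  fit <- stats::aov(values ~ f)
  an <- stats::anova(fit)
  mse <- an[["Mean Sq"]][2]
  dfe <- an[["Df"]][2]
  means <- tapply(values, f, mean)
  ns <- tapply(values, f, length)
  lv <- levels(f)
  sig <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
  for (a in lv) for (b in lv) {
    if (a == b) next
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    p <- if (se == 0) ifelse(means[[a]] == means[[b]], 1, 0)
    else 2 * stats::pt(-abs(means[[a]] - means[[b]]) / se, dfe)
    sig[a, b] <- p < alpha
  }
  sig
}

# Letter display agreement with the pairwise oracle: groups share a letter
# iff the oracle calls them not significantly different.
letters_match_oracle <- function(letters, sig) {
  lv <- names(letters)
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i >= j) next
    share <- length(intersect(strsplit(letters[[i]], "")[[1]],
                              strsplit(letters[[j]], "")[[1]])) > 0
    if (share == sig[lv[i], lv[j]]) return(FALSE)
  }
  TRUE
}

# Tiny isotope fixture: four organs, one month, delta readings chosen so
# every organ carries positive excess label.
toy_isotope <- function() {
  pools <- data.frame(
    organ = c("branches", "leaves", "peels", "seed_kernels"),
    month = "Aug", biomass_g = c(10, 7, 8, 3),
    carbon_fraction = c(0.47, 0.45, 0.44, 0.46),
    fn_atom_percent = 1.0815, stringsAsFactors = FALSE)
  readings <- data.frame(
    organ = pools$organ, month = "Aug", time_h = 72,
    delta13c = c(-15, 60, -10, 5), stringsAsFactors = FALSE)
  list(readings = readings, pools = pools)
}
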