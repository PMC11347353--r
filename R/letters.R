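#' One-way ANOVA with LSD compact-letter display
#'
#' Fits a one-way ANOVA, performs all pairwise comparisons with Fisher's
#' least significant difference (unadjusted t tests on the pooled error mean
#' square), and encodes the outcome as a compact letter display: two groups
#' share a letter if and only if they are not significantly different at
#' `alpha`. Letters are assigned in descending order of group means, so the
#' highest-mean group carries "a".
#'
#' A Shapiro-Wilk normality pre-check is run per group (when 3 <= n <= 5000)
#' and emits a warning for non-normal groups; it never blocks the ANOVA.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length; >= 2 groups with >= 2 replicates
#'   each.
#' @param alpha Significance level for the pairwise LSD tests (default 0.05).
#' @param letters_case `"lower"` (a, b, c, ...) or `"upper"` (A, B, C, ...),
#'   matching the within-column vs within-row conventions of field tables.
#' @param check_normality Run the Shapiro-Wilk gate (default TRUE).
#' @return List with `letters` (named character vector, one string per group,
#'   ordered by descending mean), `means`, `n`, `anova_p`, `mse`, `df_error`,
#'   and `pairwise` (data frame of all pairwise t statistics and p values).
#' @export
#' @examples
#' set.seed(1)
#' anova_lsd_letters(c(rnorm(4, 0), rnorm(4, 0.1, 0.05), rnorm(4, 10, 0.05)),
#'                   rep(c("x", "y", "z"), each = 4))$letters
anova_lsd_letters <- function(values, groups, alpha = 0.05,
                              letters_case = c("lower", "upper"),
                              check_normality = TRUE) {
  letters_case <- match.arg(letters_case)
  if (length(values) != length(groups))
    stop("`values` and `groups` must have equal length", call. = FALSE)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups[ok])
  tab <- table(groups)
  if (length(tab) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2L))
    stop("every group needs at least 2 replicates; offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)

  if (check_normality) {
    for (g in names(tab)) {
      v <- values[groups == g]
      if (length(v) >= 3L && length(v) <= 5000L && stats::var(v) > 0) {
        sw <- stats::shapiro.test(v)
        if (sw$p.value < alpha)
          warning("group `", g, "` fails the Shapiro-Wilk normality check (p = ",
                  signif(sw$p.value, 3), "); ANOVA proceeds", call. = FALSE)
      }
    }
  }

  f <- factor(groups)
  fit <- stats::aov(values ~ f)
  an <- stats::anova(fit)
  mse <- an[["Mean Sq"]][2L]
  df_err <- an[["Df"]][2L]
  anova_p <- an[["Pr(>F)"]][1L]

  means <- tapply(values, f, mean)
  ns <- tapply(values, f, length)
  ord <- order(-means)
  lv <- names(means)[ord]
  k <- length(lv)

  # pairwise LSD: t = |mi - mj| / sqrt(MSE (1/ni + 1/nj)), df = df_err
  pair <- list()
  sig <- matrix(FALSE, k, k, dimnames = list(lv, lv))
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    a <- lv[i]; b <- lv[j]
    d <- abs(means[[a]] - means[[b]])
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    if (se == 0) {                       # zero pooled variance
      tstat <- if (d == 0) 0 else Inf
      p <- if (d == 0) 1 else 0
    } else {
      tstat <- d / se
      p <- 2 * stats::pt(-tstat, df_err)
    }
    sig[a, b] <- sig[b, a] <- p < alpha
    pair[[length(pair) + 1L]] <- data.frame(
      group1 = a, group2 = b, diff = means[[a]] - means[[b]],
      t = tstat, p = p, significant = p < alpha, stringsAsFactors = FALSE)
  }
  pairwise <- do.call(rbind, pair)

  letters <- cld_insert_absorb(lv, sig, case = letters_case)
  list(letters = letters, means = means[ord], n = ns[ord],
       anova_p = anova_p, mse = mse, df_error = df_err, pairwise = pairwise)
}

#' Compact letter display by insert-and-absorb
#'
#' Given group labels (ordered by descending mean) and a logical matrix of
#' significant pairwise differences, builds letter columns so that two groups
#' share a letter iff their difference is not significant. Columns start as
#' one all-inclusive letter; each significant pair splits every column that
#' still contains both members; columns that become subsets of others are
#' absorbed.
#'
#' @param labels Group labels in display (descending-mean) order.
#' @param sig Symmetric logical matrix, `TRUE` where the pair differs
#'   significantly; dimnames must cover `labels`.
#' @param case `"lower"` or `"upper"` letters.
#' @return Named character vector of letter strings in `labels` order.
#' @export
cld_insert_absorb <- function(labels, sig, case = c("lower", "upper")) {
  case <- match.arg(case)
  k <- length(labels)
  cols <- list(stats::setNames(rep(TRUE, k), labels))
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    if (!sig[labels[i], labels[j]]) next
    nxt <- list()
    for (col in cols) {
      if (col[[labels[i]]] && col[[labels[j]]]) {
        c1 <- col; c1[[labels[i]]] <- FALSE
        c2 <- col; c2[[labels[j]]] <- FALSE
        nxt <- c(nxt, list(c1, c2))
      } else nxt <- c(nxt, list(col))
    }
    # absorb: drop any column whose membership is a subset of another's
    drop <- rep(FALSE, length(nxt))
    for (a in seq_along(nxt)) for (b in seq_along(nxt)) {
      if (a == b || drop[a] || drop[b]) next
      if (all(nxt[[b]][nxt[[a]]])) {     # a subset of b
        if (all(nxt[[a]][nxt[[b]]]) && a > b) next  # identical: keep first
        drop[a] <- TRUE
      }
    }
    cols <- nxt[!drop]
  }
  # order columns by their top-ranked member so "a" goes to the highest mean
  first_member <- vapply(cols, function(col) min(which(col)), integer(1))
  cols <- cols[order(first_member)]
  alphabet <- if (case == "lower") letters else LETTERS
  if (length(cols) > length(alphabet))
    stop("more letter columns than letters available", call. = FALSE)
  out <- stats::setNames(character(k), labels)
  for (ci in seq_along(cols))
    out[cols[[ci]]] <- paste0(out[cols[[ci]]], alphabet[ci])
  out
}
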