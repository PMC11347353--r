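#' Significance stars for a p value
#'
#' Journal-table convention: `**` for p < 0.01, `*` for 0.01 <= p < 0.05,
#' empty string otherwise.
#'
#' @param p Numeric p value(s).
#' @return Character vector of star annotations.
#' @export
star_label <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pearson correlation with a two-sided p value
#'
#' Sample Pearson r with the usual t transform, t = r * sqrt(n - 2) /
#' sqrt(1 - r^2) on n - 2 degrees of freedom, after pairwise-complete
#' deletion. Degenerate inputs (fewer than 3 complete pairs, or zero variance
#' in either series) yield `NA` with a reason rather than an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p`, `star`, `n`, and `reason` (`NA` when defined).
#' @export
#' @examples
#' pearson_with_p(1:4, c(1.1, 1.9, 3.2, 3.8))
pearson_with_p <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    return(list(r = NA_real_, p = NA_real_, star = NA_character_, n = n,
                reason = "fewer than 3 complete pairs"))
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(r = NA_real_, p = NA_real_, star = NA_character_, n = n,
                reason = "zero variance"))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  list(r = r, p = ct$p.value, star = star_label(ct$p.value), n = n,
       reason = NA_character_)
}

#' Sugar x enzyme correlation matrices per organ
#'
#' For each organ, correlates each sugar component (soluble sugars, fructose,
#' glucose, sucrose) with each enzyme activity across developmental stages.
#' Pairing is replicate-level by default (stage x replicate records matched by
#' organ, month, replicate); with `stage_means = TRUE` both sides are averaged
#' per stage first. Enzymes with no measurements in an organ (e.g. neutral
#' invertase in peels) are dropped from that organ's matrix, mirroring blank
#' table columns.
#'
#' @param panels Long data frame of enzyme activities: `organ`, `month`,
#'   `replicate`, `enzyme`, `activity` (U g^-1; `NA` allowed).
#' @param sugars Data frame of sugar contents with `organ`, `month`,
#'   `replicate`, and one column per sugar component.
#' @param sugar_components Character vector of sugar column names to screen.
#' @param stage_means Correlate per-stage means instead of replicate pairs.
#' @return Long data frame: `organ`, `sugar`, `enzyme`, `r`, `p`, `star`,
#'   `n_used`, `reason`. Cells with fewer than 3 matched points carry `NA`
#'   with the reason.
#' @export
enzyme_sugar_matrix <- function(panels, sugars,
                                sugar_components = c("soluble_sugar", "fructose",
                                                     "glucose", "sucrose"),
                                stage_means = FALSE) {
  panels <- as.data.frame(panels)
  sugars <- as.data.frame(sugars)
  stopifnot(all(c("organ", "month", "replicate", "enzyme", "activity") %in% names(panels)))
  stopifnot(all(c("organ", "month", "replicate") %in% names(sugars)))
  sugar_components <- intersect(sugar_components, names(sugars))
  if (length(sugar_components) == 0L)
    stop("none of the requested sugar components are columns of `sugars`",
         call. = FALSE)

  out <- list()
  for (org in unique(panels$organ)) {
    po <- panels[panels$organ == org, , drop = FALSE]
    so <- sugars[sugars$organ == org, , drop = FALSE]
    for (enz in unique(po$enzyme)) {
      pe <- po[po$enzyme == enz, , drop = FALSE]
      if (all(is.na(pe$activity))) next  # absent assay: drop the column
      for (sg in sugar_components) {
        if (stage_means) {
          months <- sort(unique(intersect(pe$month, so$month)))
          xa <- vapply(months, function(m)
            mean(pe$activity[pe$month == m], na.rm = TRUE), numeric(1))
          ya <- vapply(months, function(m)
            mean(so[[sg]][so$month == m], na.rm = TRUE), numeric(1))
          cw <- pearson_with_p(xa, ya)
        } else {
          m <- merge(pe[, c("month", "replicate", "activity")],
                     so[, c("month", "replicate", sg)],
                     by = c("month", "replicate"))
          cw <- pearson_with_p(m$activity, m[[sg]])
        }
        out[[length(out) + 1L]] <- data.frame(
          organ = org, sugar = sg, enzyme = enz,
          r = cw$r, p = cw$p, star = cw$star, n_used = cw$n,
          reason = cw$reason, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Format a correlation screen as a starred wide table
#'
#' @param mat Long output of [enzyme_sugar_matrix()], one organ.
#' @param digits Decimal places for r.
#' @return Character matrix, rows = sugars, cols = enzymes, cells "r star".
#' @export
format_correlation_matrix <- function(mat, digits = 3) {
  sugars <- unique(mat$sugar)
  enzymes <- unique(mat$enzyme)
  m <- matrix("", nrow = length(sugars), ncol = length(enzymes),
              dimnames = list(sugars, enzymes))
  for (i in seq_len(nrow(mat))) {
    val <- if (is.na(mat$r[i])) "" else
      paste0(formatC(mat$r[i], digits = digits, format = "f"), mat$star[i])
    m[mat$sugar[i], mat$enzyme[i]] <- val
  }
  m
}

#' Rank genes by correlation of expression with a sucrose trajectory
#'
#' Pearson r of each gene's FPKM series against the sucrose series, paired at
#' replicate level by default (each stage x replicate observation) or on
#' stage means. Genes are sorted by descending r, ties broken by gene id;
#' zero-variance genes are excluded and reported.
#'
#' @param expr Long expression table: `gene_id`, `stage`, `replicate`, `fpkm`.
#' @param sucrose Data frame `stage`, `replicate`, `sucrose` (replicate-level)
#'   or a named per-stage numeric vector.
#' @param top_k Number of top genes to return; `Inf` returns the full ranking.
#' @param stage_means Correlate per-stage means instead of replicate pairs.
#' @return List with `ranking` (data frame `gene_id`, `r`, `p`, `n`) truncated
#'   to `top_k`, and `excluded` (zero-variance gene ids).
#' @export
gene_sucrose_screen <- function(expr, sucrose, top_k = 10, stage_means = FALSE) {
  expr <- as.data.frame(expr)
  stopifnot(all(c("gene_id", "stage", "replicate", "fpkm") %in% names(expr)))
  if (is.numeric(sucrose) && !is.null(names(sucrose)))
    sucrose <- data.frame(stage = names(sucrose), replicate = 1L,
                          sucrose = unname(sucrose), stringsAsFactors = FALSE)
  sucrose <- as.data.frame(sucrose)
  stopifnot(all(c("stage", "sucrose") %in% names(sucrose)))
  if (!"replicate" %in% names(sucrose)) sucrose$replicate <- 1L

  if (stage_means || length(unique(sucrose$replicate)) == 1L) {
    suc_by_stage <- tapply(sucrose$sucrose, sucrose$stage, mean)
    key <- expr$stage
    expr_split <- split(expr, expr$gene_id)
    score <- lapply(expr_split, function(d) {
      xa <- tapply(d$fpkm, d$stage, mean)
      stages <- intersect(names(suc_by_stage), names(xa))
      pearson_with_p(unname(xa[stages]), unname(suc_by_stage[stages]))
    })
  } else {
    m <- merge(expr, sucrose, by = c("stage", "replicate"))
    score <- lapply(split(m, m$gene_id), function(d)
      pearson_with_p(d$fpkm, d$sucrose))
  }
  ids <- names(score)
  r <- vapply(score, `[[`, numeric(1), "r")
  p <- vapply(score, `[[`, numeric(1), "p")
  n <- vapply(score, function(s) as.numeric(s$n), numeric(1))
  excluded <- ids[is.na(r)]
  keep <- !is.na(r)
  rk <- data.frame(gene_id = ids[keep], r = r[keep], p = p[keep], n = n[keep],
                   stringsAsFactors = FALSE)
  rk <- rk[order(-rk$r, rk$gene_id), , drop = FALSE]
  rownames(rk) <- NULL
  list(ranking = utils::head(rk, n = top_k), excluded = excluded,
       n_genes = sum(keep))
}

#' Filter a differential-expression table
#'
#' Keeps records with FDR <= `fdr_max` and |log2 fold change| >=
#' `abs_log2fc_min` (both boundaries inclusive); direction follows the sign
#' of log2FC.
#'
#' @param records Data frame with `gene_id`, `log2fc`, `fdr` (and optionally
#'   `comparison`).
#' @param fdr_max FDR ceiling (default 0.05).
#' @param abs_log2fc_min Minimum absolute log2 fold change (default 1).
#' @return List with `kept` (filtered data frame plus a `direction` column),
#'   `n_up`, `n_down`.
#' @export
#' @examples
#' toy <- data.frame(gene_id = letters[1:5],
#'                   log2fc = c(1.5, 0.5, -2, 3, -1),
#'                   fdr = c(.01, .01, .04, .2, .05))
#' deg_filter(toy)  # 3 kept: 1 up, 2 down
deg_filter <- function(records, fdr_max = 0.05, abs_log2fc_min = 1) {
  records <- as.data.frame(records)
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(records)))
  if (any(records$fdr < 0 | records$fdr > 1, na.rm = TRUE))
    stop("`fdr` must lie in [0, 1]", call. = FALSE)
  keep <- !is.na(records$fdr) & records$fdr <= fdr_max &
    abs(records$log2fc) >= abs_log2fc_min
  kept <- records[keep, , drop = FALSE]
  kept$direction <- ifelse(kept$log2fc > 0, "up", "down")
  rownames(kept) <- NULL
  list(kept = kept, n_up = sum(kept$direction == "up"),
       n_down = sum(kept$direction == "down"))
}

#' Region counts for overlapping gene sets
#'
#' Exclusive region counts for every combination of 2 or 3 sets (Venn-diagram
#' regions), plus the size of the common intersection of all sets.
#'
#' @param sets Named list of >= 2 character vectors (gene ids).
#' @return List with `regions` (named integer vector; names like `"A"`,
#'   `"A&B"` denote genes in exactly those sets), `common` (genes present in
#'   every set), and `set_sizes`.
#' @export
#' @examples
#' venn_overlap(list(A = c("1", "2", "3"), B = c("2", "3", "4"),
#'                   C = c("3", "4", "5")))$common  # 1
venn_overlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("`sets` must be a named list of at least 2 sets", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all sets must be named", call. = FALSE)
  if (length(sets) > 3L)
    stop("region enumeration supports up to 3 sets", call. = FALSE)
  sets <- lapply(sets, unique)
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL, names(sets)))
  lab <- apply(member, 1L, function(row) paste(names(sets)[row], collapse = "&"))
  regions <- table(lab)
  # make every region explicit, including empty ones
  combos <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(combos)), combos)
  counts[names(regions)] <- as.integer(regions)
  common_ids <- all_ids[rowSums(member) == length(sets)]
  list(regions = counts, common = length(common_ids), common_ids = common_ids,
       set_sizes = vapply(sets, length, integer(1)))
}
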