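test_that("pearson_with_p matches a brute-force covariance oracle", {
  x <- c(1, 2, 3, 4); y <- c(1.1, 1.9, 3.2, 3.8)
  got <- pearson_with_p(x, y)
  # independent transcription: r = cov / (sd sd), p from the t transform
  r_bf <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_bf <- r_bf * sqrt(2) / sqrt(1 - r_bf^2)
  p_bf <- 2 * stats::pt(-abs(t_bf), 2)
  expect_equal(got$r, r_bf, tolerance = 1e-12)
  expect_equal(got$p, p_bf, tolerance = 1e-12)
  expect_equal(got$n, 4)

  set.seed(31)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    got <- pearson_with_p(x, y)
    r_bf <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(got$r, r_bf, tolerance = 1e-12)
  }
})

test_that("pearson_with_p handles perfect and degenerate relationships", {
  lin <- pearson_with_p(1:10, 2 * (1:10) + 1)
  expect_equal(lin$r, 1)
  expect_lt(lin$p, 1e-10)
  expect_equal(lin$star, "**")
  expect_equal(pearson_with_p(1:10, -(1:10))$r, -1)

  const <- pearson_with_p(rep(2, 5), stats::rnorm(5))
  expect_true(is.na(const$r))
  expect_equal(const$reason, "zero variance")
  short <- pearson_with_p(c(1, 2), c(3, 4))
  expect_true(is.na(short$r))
  expect_match(short$reason, "fewer than 3")
  # pairwise-complete deletion drops NA pairs
  expect_equal(pearson_with_p(c(1, 2, 3, NA, 5), c(2, 4, 6, 1, 10))$n, 4)
})

test_that("star annotations follow the table footnote rule exactly", {
  expect_equal(star_label(c(0.0099, 0.01, 0.049, 0.05, 0.5)),
               c("**", "*", "*", "", ""))
  set.seed(32)
  p <- c(stats::runif(200, 0.005, 0.015), stats::runif(200, 0.045, 0.055))
  s <- star_label(p)
  expect_true(all(s[p < 0.01] == "**"))
  expect_true(all(s[p >= 0.01 & p < 0.05] == "*"))
  expect_true(all(s[p >= 0.05] == ""))
})

test_that("enzyme-sugar matrix recovers a planted correlation and drops absent assays", {
  set.seed(33)
  months <- c("Jul", "Aug", "Sep", "Oct"); reps <- 1:3
  grid <- expand.grid(month = months, replicate = reps,
                      stringsAsFactors = FALSE)
  act <- rep(c(700, 1100, 2071, 1600), times = 3)
  r_target <- 0.95
  noise_sd <- sqrt(1 / r_target^2 - 1) * stats::sd(act)
  sucrose <- 5 + 0.01 * (act + stats::rnorm(nrow(grid), 0, noise_sd))
  panels <- rbind(
    data.frame(grid, organ = "seed_kernels", enzyme = "SuSy_II", activity = act),
    data.frame(grid, organ = "seed_kernels", enzyme = "NI", activity = NA_real_))
  sugars <- data.frame(grid, organ = "seed_kernels", sucrose = sucrose,
                       soluble_sugar = 30)
  mat <- enzyme_sugar_matrix(panels, sugars,
                             sugar_components = c("soluble_sugar", "sucrose"))
  # all-missing enzyme column is absent, like a blank table column
  expect_false("NI" %in% mat$enzyme)
  cell <- mat[mat$sugar == "sucrose" & mat$enzyme == "SuSy_II", ]
  expect_equal(cell$n_used, 12)
  expect_lt(abs(cell$r - r_target), 0.05)
  # constant sugar series yields a missing cell, not a crash
  flat <- mat[mat$sugar == "soluble_sugar", ]
  expect_true(is.na(flat$r))
  expect_equal(flat$reason, "zero variance")
})

test_that("stage-mean pairing is available as a fallback", {
  months <- c("Jul", "Aug", "Sep", "Oct")
  grid <- expand.grid(month = months, replicate = 1:3, stringsAsFactors = FALSE)
  panels <- data.frame(grid, organ = "leaves", enzyme = "SPS",
                       activity = rep(c(1, 2, 3, 4), 3))
  sugars <- data.frame(grid, organ = "leaves",
                       sucrose = rep(c(2, 4, 6, 8), 3))
  mat <- enzyme_sugar_matrix(panels, sugars, sugar_components = "sucrose",
                             stage_means = TRUE)
  expect_equal(mat$n_used, 4)
  expect_equal(mat$r, 1, tolerance = 1e-12)
})

test_that("gene screen ranks an exact affine gene first and respects top_k", {
  months <- c("Jul", "Aug", "Sep", "Oct")
  suc <- c(Jul = 5, Aug = 10, Sep = 26, Oct = 19)
  expr <- expand.grid(stage = months, replicate = 1:3, stringsAsFactors = FALSE)
  genes <- rbind(
    data.frame(expr, gene_id = "gAffine", fpkm = 3 * suc[expr$stage] + 2),
    data.frame(expr, gene_id = "gFlat", fpkm = 7),
    data.frame(expr, gene_id = "gAnti", fpkm = 100 - suc[expr$stage]))
  res <- gene_sucrose_screen(genes, suc, top_k = 10)
  expect_equal(res$ranking$gene_id[1], "gAffine")
  expect_equal(res$ranking$r[1], 1, tolerance = 1e-12)
  expect_equal(res$excluded, "gFlat")
  expect_equal(nrow(res$ranking), 2)   # top_k beyond gene count: full ranking
  expect_equal(res$ranking$r[2], -1, tolerance = 1e-12)
})

test_that("gene screen is invariant to gene-wise affine rescaling of FPKM", {
  set.seed(34)
  months <- c("Jul", "Aug", "Sep", "Oct")
  suc <- c(Jul = 5, Aug = 10, Sep = 26, Oct = 19)
  base <- expand.grid(stage = months, replicate = 1:3, stringsAsFactors = FALSE)
  expr <- do.call(rbind, lapply(1:20, function(g)
    data.frame(base, gene_id = sprintf("g%02d", g),
               fpkm = stats::rexp(nrow(base), 1 / 50))))
  r1 <- gene_sucrose_screen(expr, suc, top_k = Inf)$ranking
  expr2 <- expr
  for (g in unique(expr2$gene_id)) {
    i <- expr2$gene_id == g
    expr2$fpkm[i] <- expr2$fpkm[i] * stats::runif(1, 0.1, 10) + stats::runif(1, 0, 5)
  }
  r2 <- gene_sucrose_screen(expr2, suc, top_k = Inf)$ranking
  expect_equal(r1$gene_id, r2$gene_id)
  expect_equal(r1$r, r2$r, tolerance = 1e-9)
})

test_that("deg_filter applies both inclusive thresholds and counts directions", {
  toy <- data.frame(gene_id = paste0("g", 1:5),
                    log2fc = c(1.5, 0.5, -2, 3, -1),
                    fdr = c(0.01, 0.01, 0.04, 0.2, 0.05),
                    stringsAsFactors = FALSE)
  res <- deg_filter(toy)
  expect_equal(nrow(res$kept), 3)
  expect_equal(res$n_up, 1)
  expect_equal(res$n_down, 2)
  # boundary records |log2fc| = 1 and fdr = 0.05 are retained
  expect_true("g5" %in% res$kept$gene_id)

  empty <- deg_filter(toy[0, ])
  expect_equal(nrow(empty$kept), 0)
  strict <- deg_filter(transform(toy, fdr = c(0, 0.2, 0.3, 0.4, 0.5)),
                       fdr_max = 0)
  expect_equal(strict$kept$gene_id, "g1")
  expect_error(deg_filter(transform(toy, fdr = c(2, 0, 0, 0, 0))), "fdr")
})

test_that("deg_filter is monotone in both thresholds", {
  set.seed(35)
  tab <- data.frame(gene_id = sprintf("g%03d", 1:300),
                    log2fc = stats::rnorm(300, 0, 2),
                    fdr = stats::runif(300), stringsAsFactors = FALSE)
  for (i in 1:10) {
    f1 <- sort(stats::runif(2, 0, 0.2)); l1 <- sort(stats::runif(2, 0.5, 2))
    strict <- deg_filter(tab, fdr_max = f1[1], abs_log2fc_min = l1[2])$kept$gene_id
    loose <- deg_filter(tab, fdr_max = f1[2], abs_log2fc_min = l1[1])$kept$gene_id
    expect_true(all(strict %in% loose))
  }
})

test_that("venn regions enumerate intersections of up to three sets", {
  v <- venn_overlap(list(A = c("1", "2", "3"), B = c("2", "3", "4"),
                         C = c("3", "4", "5")))
  expect_equal(v$common, 1)
  expect_equal(v$common_ids, "3")
  expect_equal(unname(v$regions[c("A", "A&B", "B&C", "A&B&C")]),
               c(1L, 1L, 1L, 1L))

  same <- venn_overlap(list(A = letters[1:4], B = letters[1:4]))
  expect_equal(same$common, 4)
  expect_equal(unname(same$regions["A"]), 0L)
  expect_equal(unname(same$regions["A&B"]), 4L)

  disj <- venn_overlap(list(A = "x", B = "y", C = "z"))
  expect_equal(disj$common, 0)
  expect_error(venn_overlap(list(A = "x")), "at least 2")
})
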