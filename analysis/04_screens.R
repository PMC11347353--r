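#!/usr/bin/env Rscript
# Stage 4: statistical screens. Sugar x enzyme correlation matrices per
# organ with significance stars, the gene-vs-sucrose ranking, DEG filtering
# with overlap counts, and ANOVA + LSD compact letters.

suppressPackageStartupMessages(library(pulsechase))

panels <- read.csv("results/sim/inputs/enzyme_panels.csv")
profiles <- read.csv("results/sugar_profiles.csv")
expr <- read.csv("results/sim/inputs/expression_fpkm.csv")
sucrose <- read.csv("results/sim/inputs/sucrose_series.csv")
deg <- read.csv("results/sim/inputs/deg_table.csv")
planted <- readLines("results/sim/planted_genes.txt")

## sugar x enzyme matrices
corr <- enzyme_sugar_matrix(panels, profiles)
for (org in unique(corr$organ)) {
  write.csv(corr[corr$organ == org, ],
            sprintf("results/correlations_%s.csv", org), row.names = FALSE)
  cat("\n", org, ":\n", sep = "")
  print(format_correlation_matrix(corr[corr$organ == org, ]), quote = FALSE)
}
susy <- corr[corr$organ == "seed_kernels" & corr$enzyme == "SuSy_II" &
               corr$sugar == "sucrose", ]
cat(sprintf("\nSeed sucrose vs SuSy-II: r = %.3f%s (n = %d)\n",
            susy$r, susy$star, susy$n_used))

## gene screen
screen <- gene_sucrose_screen(expr, sucrose, top_k = 10)
write.csv(screen$ranking, "results/gene_screen.csv", row.names = FALSE)
hits <- sum(screen$ranking$gene_id %in% planted)
cat(sprintf("\nTop 10 genes by correlation with seed sucrose: %d/10 planted\n",
            hits))
print(screen$ranking, row.names = FALSE, digits = 3)

## DEG filter and overlaps
by_cmp <- split(deg, deg$comparison)
deg_sum <- do.call(rbind, lapply(names(by_cmp), function(cmp) {
  f <- deg_filter(by_cmp[[cmp]])
  data.frame(comparison = cmp, n_kept = nrow(f$kept), n_up = f$n_up,
             n_down = f$n_down)
}))
write.csv(deg_sum, "results/deg_summary.csv", row.names = FALSE)
ov <- venn_overlap(lapply(by_cmp, function(d) deg_filter(d)$kept$gene_id))
cat("\nDEG filter (FDR <= 0.05, |log2FC| >= 1):\n")
print(deg_sum, row.names = FALSE)
cat(sprintf("Common to all comparisons: %d genes\n", ov$common))

## compact letters: soluble sugar across organs, per month
col <- read.csv("results/sim/inputs/colorimetric.csv")
col <- col[col$assay == "soluble_sugar", ]
col$content <- soluble_sugar_content(col$absorbance_620, col$fresh_weight_g)
letters_tab <- do.call(rbind, lapply(split(col, col$month), function(d) {
  lt <- suppressWarnings(anova_lsd_letters(d$content, d$organ))
  data.frame(month = d$month[1], organ = names(lt$letters),
             mean = as.numeric(lt$means), letter = unname(lt$letters))
}))
write.csv(letters_tab, "results/letters.csv", row.names = FALSE)
cat("\nSoluble sugar letters (within month, across organs):\n")
print(letters_tab, row.names = FALSE, digits = 4)
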