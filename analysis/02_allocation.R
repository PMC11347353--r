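#!/usr/bin/env Rscript
# Stage 2: isotope mass balance. Converts the simulated delta-13C readings
# into atom percent, excess-13C mass, per-organ allocation percentages and
# transport rates, and checks the estimates against the noiseless truth
# and the closure constraint (monthly shares sum to 100).

suppressPackageStartupMessages(library(pulsechase))

readings <- read.csv("results/sim/inputs/isotope_readings.csv")
pools <- read.csv("results/sim/inputs/organ_pools.csv")
truth <- read.csv("results/sim/truth_excess.csv")

alloc <- allocation_table(readings, pools)
dir.create("results", showWarnings = FALSE)
write.csv(alloc, "results/allocation.csv", row.names = FALSE)

cat("Allocation of the excess-13C pulse at 72 h (estimate vs truth):\n")
for (m in unique(alloc$month)) {
  est <- alloc[alloc$month == m, ]
  tru <- truth[truth$month == m & truth$time_h == 72, ]
  idx <- match(est$organ, tru$organ)
  cat(sprintf("  %s (total %.2f mg):\n", m, est$total13c_mg[1]))
  for (i in seq_len(nrow(est)))
    cat(sprintf("    %-14s %6.2f %%  (truth %6.2f, err %+5.2f)\n",
                est$organ[i], est$allocation_percent[i],
                tru$allocation_percent[idx[i]],
                est$allocation_percent[i] - tru$allocation_percent[idx[i]]))
  stopifnot(abs(sum(est$allocation_percent) - 100) < 1e-9)
  stopifnot(all(abs(est$allocation_percent - tru$allocation_percent[idx]) < 2))
}

# transport slows over the chase: rate at 6 h exceeds rate at 72 h for the
# leaf source in the chase month
aug6 <- allocation_table(readings, pools, at_time = 6)
aug6 <- aug6[aug6$month == "Aug" & aug6$organ == "leaves", ]
aug72 <- alloc[alloc$month == "Aug" & alloc$organ == "leaves", ]
cat(sprintf("\nLeaf transport rate, August: %.1f ug/g/h at 6 h vs %.1f at 72 h\n",
            aug6$transport_rate, aug72$transport_rate))

cat("\nAllocation shares recovered within 2 points in every month.\n")
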