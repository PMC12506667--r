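#!/usr/bin/env Rscript
# Detect inversion-like regions from long-range linkage disequilibrium in
# the invasive population: for each fully genotyped segregating SNP, one
# random partner at 100-500 kb (+/- 5%), pairs with r^2 > 0.75 flag their
# 100-kb windows, and runs of >= 10 flagged windows are called as
# candidate inversion regions.  The native population is scanned as a
# negative control.

source("analysis/00_common.R")

co <- load_qc_cohort()
seed <- 3031

fl <- long_range_ld_scan(co, "pop2", seed = derive_seed(seed, "inv"))
regions <- call_inversion_regions(fl, min_run = 10)
cat("Invasive population: called", nrow(regions), "region(s)\n")
print(as.data.frame(regions))

truth <- read_bed("results/fixture/truth_inversions.bed")
ov <- interval_overlap_bp(truth, regions)
cat(sprintf("Overlap with injected truth: %.0f%% of %d bp\n",
            100 * ov / sum(truth$end - truth$start),
            sum(truth$end - truth$start)))

fl_native <- long_range_ld_scan(co, "pop1",
                                seed = derive_seed(seed, "native"))
native <- call_inversion_regions(fl_native, min_run = 10)
cat("Native population (negative control):", nrow(native), "region(s)\n")

write_bed(regions, "results/inversion_regions.bed")
write.table(do.call(rbind, fl$windows), "results/ld_window_flags.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# LD matrix sample for a heatmap-style view of the inversion chromosome
m <- sample_ld_matrix(co, "chr2", "pop2", n_snps = 500,
                      seed = derive_seed(seed, "ldmat"))
long <- data.frame(i = rep(seq_along(m$positions), times = length(m$positions)),
                   j = rep(seq_along(m$positions), each = length(m$positions)),
                   pos_i = rep(m$positions, times = length(m$positions)),
                   pos_j = rep(m$positions, each = length(m$positions)),
                   r2 = as.vector(m$r2))
long <- long[long$i < long$j, ]
write.table(long, "results/ld_matrix_chr2.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("LD matrix (500 SNPs, chr2) written to results/ld_matrix_chr2.tsv\n")
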