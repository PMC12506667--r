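#!/usr/bin/env Rscript
# Haplotype-based selection scan on the invasive population: iHS from
# phased haplotypes (polarized by the native major allele, standardized
# in derived-frequency bins), the among-population allele-frequency
# dispersion score with its pseudo-observed-data significance threshold,
# per-SNP FST, and the 1-kb/500-bp top-1% three-track window
# intersection.

source("analysis/00_common.R")

co <- load_qc_cohort()
seed <- 6061

aa <- co$sites$aa
aa[co$sites$aa_tie] <- NA
pan2 <- qc_panel(co, "pop2")
track <- ihs_scan(pan2, aa, min_maf = 0.05, cutoff = 0.05)
track <- standardize_ihs(track, bin_width = 0.05, min_bin = 10)
cat("iHS scored at", sum(!is.na(track$ihs_abs)), "of", nrow(track),
    "SNPs\n")
sw <- read.delim("results/fixture/truth_sweeps.tsv")
at <- which(track$chrom == sw$chrom & track$pos == sw$core_pos)
thr99 <- quantile(track$ihs_abs, 0.99, na.rm = TRUE)
cat(sprintf("Sweep core |iHS|: %.2f (genome-wide top-1%% threshold %.2f)\n",
            track$ihs_abs[at], thr99))
write.table(as.data.frame(track), "results/ihs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

pac <- invadepop:::population_allele_counts(co)
keep <- colSums(pac$copies >= 1) == nrow(pac$alt)
xtx <- differentiation_score(pac$alt[, keep], pac$copies[, keep],
                             chrom = pac$chrom[keep], pos = pac$pos[keep])
pod <- pod_threshold(pac$alt[, keep], pac$copies[, keep],
                     n_simulated = 10000, quantile_level = 0.999,
                     seed = derive_seed(seed, "pod"))
n_out <- sum(xtx$score > pod$threshold, na.rm = TRUE)
cat(sprintf("Dispersion score: %d SNPs above the 99.9%% POD threshold %.1f\n",
            n_out, pod$threshold))
write.table(as.data.frame(xtx), "results/differentiation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

fst <- wc_fst(co, co$samples$population, min_mac = 4)

inter <- outlier_window_intersection(
  list(fst = data.frame(chrom = fst$per_snp$chrom, pos = fst$per_snp$pos,
                        score = fst$per_snp$fst),
       xtx = data.frame(chrom = xtx$chrom, pos = xtx$pos,
                        score = xtx$score),
       ihs = data.frame(chrom = track$chrom, pos = track$pos,
                        score = track$ihs_abs)),
  co$chrom_lengths, window = 1000, step = 500, top_fraction = 0.01)
cat("Three-track intersection:", nrow(inter$intersection),
    "merged region(s)\n")
print(as.data.frame(inter$intersection))
hit <- any(inter$intersection$chrom == sw$chrom &
             inter$intersection$start >= sw$span_start - 1e4 &
             inter$intersection$end <= sw$span_end + 1e4)
cat("Intersection inside the injected sweep span:", hit, "\n")
write_bed(inter$intersection, "results/intersection.bed")

# EHH decay at the sweep core for both alleles
cv_d <- ehh(pan2, sw$chrom, sw$core_pos, 1L)
cv_a <- tryCatch(ehh(pan2, sw$chrom, sw$core_pos, 0L),
                 error = function(e) NULL)
span_d <- diff(range(cv_d$positions[cv_d$ehh >= 0.5]))
cat(sprintf("EHH >= 0.5 span around the core: derived %.0f kb%s\n",
            span_d / 1000,
            if (!is.null(cv_a)) {
              sprintf(", ancestral %.0f kb",
                      diff(range(cv_a$positions[cv_a$ehh >= 0.5])) / 1000)
            } else ""))
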