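#!/usr/bin/env Rscript
# Population structure with inversion regions masked: KING-robust kinship
# and relatedness degrees (recovering the planted family), inbreeding
# coefficients, LD-pruned PCA, Weir-Cockerham FST between native and
# invasive sets, and the FST-versus-elapsed-time regression across
# synthetic seasonal collections.

source("analysis/00_common.R")

co <- load_qc_cohort()
seed <- 4041

inv <- read_bed("results/inversion_regions.bed")
co_m <- mask_regions(co, inv)
cat("Masked", ncol(co$geno) - ncol(co_m$geno), "SNPs inside",
    nrow(inv), "called inversion region(s)\n")

kin <- king_kinship(co_m)
rel <- kin[kin$degree != "unrelated" & !is.na(kin$degree), ]
cat("Related pairs detected (phi > 0.0442):", nrow(rel), "\n")
print(rel[order(-rel$phi), c("id1", "id2", "phi", "ibs0", "degree")],
      row.names = FALSE)
write.table(as.data.frame(kin), "results/kinship.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

fco <- inbreeding_coefficient(co_m)
cat(sprintf("Inbreeding coefficient: mean %.4f (range %.3f to %.3f)\n",
            mean(fco$f, na.rm = TRUE), min(fco$f, na.rm = TRUE),
            max(fco$f, na.rm = TRUE)))
write.table(fco, "results/inbreeding.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

set.seed(derive_seed(seed, "prune"))
pruned <- ld_prune(co_m, r2_threshold = 0.2, min_mac = 3)
auto <- pruned[co_m$sites$chrom[pruned] != co_m$x_chrom]
pca <- pca_cohort(co_m, auto, n_components = 4)
sep <- tapply(pca$coords[, 1], co_m$samples$population, mean)
cat(sprintf("PCA on %d pruned autosomal SNPs; PC1 population means: %s\n",
            length(auto), paste(sprintf("%s=%.2f", names(sep), sep),
                                collapse = ", ")))
write.table(data.frame(id = rownames(pca$coords), pca$coords),
            "results/pca_coords.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

fst <- wc_fst(co_m, co_m$samples$population, min_mac = 4)
cat(sprintf("Multi-SNP Weir-Cockerham FST (native vs invasive): %.4f over %d SNPs\n",
            fst$fst, fst$n_snps))
write.table(fst$per_snp, "results/fst_per_snp.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# temporal differentiation: pairwise FST between synthetic seasonal
# collections of the invasive population against days between sampling
set.seed(derive_seed(seed, "fsttime"))
inv_ids <- co_m$samples$id[co_m$samples$population == "pop2"]
n_coll <- 7
coll <- setNames(rep(paste0("c", 1:n_coll), length.out = length(inv_ids)),
                 inv_ids)
dates <- setNames(as.character(as.Date("2019-07-01") +
                                 round(seq(0, 120, length.out = n_coll))),
                  paste0("c", 1:n_coll))
pairs <- t(combn(paste0("c", 1:n_coll), 2))
pf <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
  lab <- rep(NA_character_, nrow(co_m$geno))
  lab[match(names(coll)[coll == pairs[k, 1]], co_m$samples$id)] <- "a"
  lab[match(names(coll)[coll == pairs[k, 2]], co_m$samples$id)] <- "b"
  f <- tryCatch(wc_fst(co_m, lab, min_mac = 2)$fst, error = function(e) NA)
  data.frame(collection_i = pairs[k, 1], collection_j = pairs[k, 2], fst = f)
}))
pf <- pf[!is.na(pf$fst), ]
reg <- fst_vs_time_regression(pf, dates)
cat(sprintf("FST ~ days regression: slope %.2e, R^2 %.3f, p %.3f, df %d\n",
            reg$slope, reg$r_squared, reg$p_value, reg$df))
write.table(pf, "results/fst_time_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
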