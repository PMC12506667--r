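# Fixture builders and independent (brute-force / closed-form) oracles.
# Oracles deliberately avoid the package's code paths.

# small structured cohort with phased panel retained
make_sim <- function(seed = 1, n_pop = 2, n_per = c(10, 10),
                     chrom_lengths = c(chr1 = 5e5, chrX = 2e5),
                     divergence = 0.05, depth = 16, extra_missing = 0) {
  cfg <- sim_config(n_populations = n_pop, samples_per_population = n_per,
                    chrom_lengths = chrom_lengths, divergence = divergence,
                    seed = seed)
  sim <- simulate_structured_panel(cfg)
  set.seed(seed + 1000)
  cohort <- attach_read_depth(sim$panel, mean_depth = depth,
                              extra_missing_rate = extra_missing)
  list(panel = sim$panel, truth = sim$truth, cohort = cohort, config = cfg)
}

# hand-built cohort from an explicit genotype matrix (individuals x sites)
toy_cohort <- function(geno, pos = seq_len(ncol(geno)), chrom = "chr1",
                       chrom_len = max(pos) + 10, pops = NULL, dp = NULL,
                       sex = NULL, x_chrom = "chrX") {
  n <- nrow(geno)
  pops <- pops %||% rep("popA", n)
  sex <- sex %||% rep("F", n)
  samples <- data.frame(id = sprintf("s%02d", seq_len(n)),
                        population = pops, location = pops,
                        date = "2019-07-01", reported_sex = sex,
                        assigned_sex = NA_character_,
                        mean_coverage = if (is.null(dp)) NA else rowMeans(dp),
                        missingness = rowMeans(is.na(geno)),
                        stringsAsFactors = FALSE)
  sites <- data.frame(chrom = rep(chrom, length.out = ncol(geno)), pos = pos,
                      ref = "A", alt = "T", aa = NA_character_,
                      stringsAsFactors = FALSE)
  lens <- tapply(sites$pos, sites$chrom, function(p) max(p) + 10)
  lens[] <- pmax(lens, chrom_len)
  invadepop:::new_cohort(geno, dp, sites, samples,
                         setNames(as.numeric(lens), names(lens)), x_chrom)
}

# oracle: Pearson r^2 from the closed-form definition
oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  num <- sum(a * b) - sum(a) * sum(b) / n
  den <- sqrt((sum(a^2) - sum(a)^2 / n) * (sum(b^2) - sum(b)^2 / n))
  (num / den)^2
}

# oracle: EHH by direct enumeration of haplotype-pair identity
oracle_ehh <- function(hap, core, allele, x) {
  car <- which(hap[, core] == allele)
  span <- if (x >= core) core:x else x:core
  n_match <- 0
  for (i in seq_along(car)) {
    for (j in seq_len(i - 1)) {
      if (all(hap[car[i], span] == hap[car[j], span])) {
        n_match <- n_match + 1
      }
    }
  }
  n_match / choose(length(car), 2)
}

# oracle: Tajima's D from explicit pairwise haplotype differences
oracle_tajimas_d <- function(hap_alleles) {
  # hap_alleles: chromosomes x sites 0/1 matrix, complete
  n <- nrow(hap_alleles)
  freqs <- colMeans(hap_alleles)
  seg <- freqs > 0 & freqs < 1
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  # theta_pi: mean pairwise difference count over all C(n,2) pairs
  dtot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      dtot <- dtot + sum(hap_alleles[i, ] != hap_alleles[j, ])
    }
  }
  theta_pi <- dtot / choose(n, 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (theta_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# oracle: Weir-Cockerham variance components for one biallelic SNP,
# transliterated scalar-by-scalar from the 1984 definitions
oracle_wc_components <- function(geno_by_group) {
  # geno_by_group: list of dosage vectors (complete), one per group
  r <- length(geno_by_group)
  n_i <- vapply(geno_by_group, length, 0)
  p_i <- vapply(geno_by_group, function(g) mean(g) / 2, 0)
  h_i <- vapply(geno_by_group, function(g) mean(g == 1), 0)
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# oracle: pi for one window by explicit pair enumeration over allele copies
oracle_window_pi <- function(allele_counts_k, allele_counts_alt, n_callable,
                             k_full) {
  # variant sites: mismatching pairs / total pairs, plus invariant sites
  num <- sum(allele_counts_alt * (allele_counts_k - allele_counts_alt))
  den <- sum(choose(allele_counts_k, 2)) + n_callable * choose(k_full, 2)
  num / den
}

# oracle: sliding-window intersection by direct triple loop
oracle_intersection <- function(tracks, chrom_len, chrom = "chr1",
                                window = 1000, step = 500,
                                top_fraction = 0.01) {
  marked <- lapply(tracks, function(tr) {
    thr <- quantile(tr$score, 1 - top_fraction, na.rm = TRUE)
    tr$pos[!is.na(tr$score) & tr$score >= thr]
  })
  starts <- seq(1, chrom_len, by = step)
  hit <- logical(length(starts))
  for (w in seq_along(starts)) {
    lo <- starts[w]; hi <- min(starts[w] + window - 1, chrom_len)
    ok <- TRUE
    for (t in seq_along(tracks)) {
      if (!any(marked[[t]] >= lo & marked[[t]] <= hi)) { ok <- FALSE; break }
    }
    hit[w] <- ok
  }
  data.frame(start = starts[hit], end = pmin(starts[hit] + window - 1,
                                             chrom_len))
}

# minimal haplotype panel from an explicit matrix
make_panel <- function(hap, pos, chrom = "chr1", chrom_len = max(pos) + 10) {
  n <- nrow(hap) / 2
  structure(list(
    hap = hap,
    sites = data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                       aa = NA_character_, stringsAsFactors = FALSE),
    samples = data.frame(id = sprintf("s%02d", seq_len(n)),
                         population = "popA", sex = "F",
                         stringsAsFactors = FALSE),
    hap_sample = rep(seq_len(n), each = 2), hap_index = rep(1:2, n),
    chrom_lengths = setNames(chrom_len, chrom), x_chrom = "chrX"),
    class = "haplotype_panel")
}

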