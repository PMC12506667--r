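test_that("EHH: worked 4-carrier example, decay to zero, monotonicity", {
  # 4 carriers of allele 1 at the core; next site splits them (0,0,1,1)
  hap <- rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0), c(1, 1, 1),
               c(0, 0, 0), c(0, 1, 1))
  pan <- make_panel(hap, pos = c(100, 200, 300))
  cv <- ehh(pan, "chr1", 100, 1)
  expect_equal(cv$ehh[cv$positions == 100], 1)
  expect_equal(cv$ehh[cv$positions == 200], 1 / 3)   # C(2,2)+C(2,2) over C(4,2)
  expect_equal(cv$ehh[cv$positions == 300], 0)       # all four distinct
  expect_equal(cv$carriers, 4)
  # every curve from a random panel is non-increasing outward
  sim <- make_sim(seed = 101, n_pop = 1, n_per = 15,
                  chrom_lengths = c(chr1 = 1e5, chrX = 2e4))
  on1 <- sim$panel$sites$chrom == "chr1"
  freq <- colMeans(sim$panel$hap[, on1])
  core_pos <- sim$panel$sites$pos[on1][which(freq > 0.3 & freq < 0.7)[1:5]]
  for (cp in core_pos) {
    cv2 <- ehh(sim$panel, "chr1", cp, 1L)
    at <- which(cv2$positions == cp)
    expect_true(all(diff(cv2$ehh[at:length(cv2$ehh)]) <= 1e-12))
    expect_true(all(diff(rev(cv2$ehh[1:at])) <= 1e-12))
    # oracle: direct pair enumeration at three offsets
    ch <- invadepop:::chrom_hap(sim$panel, "chr1")
    core_i <- match(cp, ch$pos)
    for (off in c(1, 3, 5)) {
      x <- core_i + off
      if (x > ncol(ch$hap)) next
      at_x <- which(cv2$positions == ch$pos[x])
      if (!length(at_x)) next   # curve truncated at zero before x
      expect_equal(cv2$ehh[at_x], oracle_ehh(ch$hap, core_i, 1L, x))
    }
  }
  expect_error(ehh(pan, "chr1", 999, 1), "not a SNP")
})

test_that("iHH: rectangle area, full truncation, distance linearity", {
  # two carriers share alleles from 5000 to 15000 around the core at
  # 10000 and split completely at 4000 and 16000: EHH is 1 on the shared
  # stretch and 0 at the splits, so iHH is a 5000-bp rectangle per flank
  hap2 <- cbind(c(0, 1), matrix(1, 2, 5), c(1, 0))
  pos <- c(4000, 5000, 8000, 10000, 12000, 15000, 16000)
  pan <- make_panel(rbind(hap2, matrix(0, 2, 7)), pos = pos)
  cv <- ehh(pan, "chr1", 10000, 1)
  expect_equal(ihh(cv, cutoff = 0.05), 10000)
  # cutoff 1.0 truncates a decaying curve immediately
  hap3 <- rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0), c(1, 1, 1))
  cv3 <- ehh(make_panel(hap3, pos = c(100, 200, 300)), "chr1", 100, 1)
  expect_equal(ihh(cv3, cutoff = 1.0), 0)
  # halving all distances halves the integral
  pan2 <- make_panel(rbind(hap2, matrix(0, 2, 7)), pos = pos / 2)
  cv2 <- ehh(pan2, "chr1", 5000, 1)
  expect_equal(ihh(cv2, 0.05), 5000)
})

test_that("iHS scan: label-swap antisymmetry and sweep sign", {
  sim <- make_sim(seed = 103, n_pop = 1, n_per = 20,
                  chrom_lengths = c(chr1 = 1e6, chrX = 5e4))
  pan <- sim$panel
  aa <- rep("ref", nrow(pan$sites))
  tr <- ihs_scan(pan, aa, min_maf = 0.1)
  aa_flip <- rep("alt", nrow(pan$sites))
  tr_flip <- ihs_scan(pan, aa_flip, min_maf = 0.1)
  ok <- !is.na(tr$ihs_raw) & !is.na(tr_flip$ihs_raw)
  expect_gt(sum(ok), 10)
  expect_equal(tr$ihs_raw[ok], -tr_flip$ihs_raw[ok])
  expect_equal(tr$freq_derived[ok], 1 - tr_flip$freq_derived[ok])
  # sweep fixture: derived core iHS strongly negative
  on1 <- which(sim$panel$sites$chrom == "chr1")
  core_pos <- sim$panel$sites$pos[on1][500]
  set.seed(104)
  out <- inject_sweep(sim$panel, sim$truth, "chr1", core_pos, freq = 0.6,
                      carrier_span = 4e5, residual_mutation_rate = 0.002,
                      target_pops = "pop1")
  tr2 <- ihs_scan(out$panel, aa, min_maf = 0.05)
  at <- which(tr2$chrom == "chr1" & tr2$pos == core_pos)
  expect_lt(tr2$ihs_raw[at], -1)
  expect_error(ihs_scan(pan, rep(NA_character_, nrow(pan$sites))),
               "not polarized")
})

test_that("iHS standardization: exact bin moments and merge rule", {
  set.seed(105)
  n <- 400
  tr <- data.frame(chrom = "chr1", pos = seq_len(n) * 100,
                   freq_derived = runif(n, 0.05, 0.95),
                   ihs_raw = rnorm(n))
  tr$ihs_raw[sample(n, 20)] <- NA
  std <- standardize_ihs(tr, bin_width = 0.05, min_bin = 10)
  for (b in unique(na.omit(std$bin))) {
    at <- which(std$bin == b)
    expect_equal(mean(std$ihs_std[at]), 0, tolerance = 1e-10)
    expect_equal(sd(std$ihs_std[at]), 1, tolerance = 1e-10)
    expect_gte(length(at), 10)
  }
  # a 3-SNP bin is merged into its neighbour
  tr2 <- data.frame(chrom = "chr1", pos = 1:43 * 100,
                    freq_derived = c(runif(40, 0.1, 0.15),
                                     runif(3, 0.46, 0.50)),
                    ihs_raw = rnorm(43))
  std2 <- standardize_ihs(tr2, bin_width = 0.05, min_bin = 10)
  expect_true(all(table(std2$bin) >= 10))
  # degenerate: single zero-variance bin errors
  tr3 <- data.frame(chrom = "chr1", pos = 1:12 * 100,
                    freq_derived = rep(0.3, 12), ihs_raw = rep(0.5, 12))
  expect_error(standardize_ihs(tr3), "variance")
})

test_that("differentiation score: zero, maximal, monotone in |p1 - p2|", {
  cp <- matrix(20, 2, 11)
  same <- matrix(10, 2, 11)
  expect_equal(differentiation_score(same, cp)$score, rep(0, 11))
  p1 <- seq(0, 1, 0.1)
  alt <- rbind(p1 * 20, rep(10, 11))
  sc <- differentiation_score(alt, cp)$score
  # symmetric in distance from p2 = 0.5; non-decreasing in |p1 - 0.5|
  expect_true(all(diff(sc[6:11]) > -1e-9))
  expect_true(all(diff(sc[1:6]) < 1e-9))
  opp <- differentiation_score(rbind(c(0, 10), c(20, 10)),
                               matrix(20, 2, 2))$score
  expect_gt(opp[1], opp[2])
  expect_error(differentiation_score(rbind(c(0, 0)), matrix(20, 1, 2)),
               "2 populations")
  # monomorphic across all populations is missing, not zero
  expect_true(is.na(differentiation_score(matrix(0, 2, 1),
                                          matrix(20, 2, 1))$score))
})

test_that("POD threshold: quantile definition and determinism", {
  sim <- make_sim(seed = 107, n_per = c(20, 20),
                  chrom_lengths = c(chr1 = 1e6, chrX = 1e5),
                  divergence = 0.05, depth = 50)
  pac <- invadepop:::population_allele_counts(sim$cohort)
  keep <- colSums(pac$copies >= 2) == 2
  alt <- pac$alt[, keep]; cp <- pac$copies[, keep]
  p1 <- pod_threshold(alt, cp, n_simulated = 2000, quantile_level = 0.5,
                      seed = 9)
  expect_equal(p1$threshold, median(p1$simulated_scores))
  p2 <- pod_threshold(alt, cp, n_simulated = 2000, quantile_level = 0.5,
                      seed = 9)
  expect_identical(p1$threshold, p2$threshold)
  expect_error(pod_threshold(alt, cp, quantile_level = 1.2), "quantile")
  expect_gt(p1$f_hat, 0.01)
  expect_lt(p1$f_hat, 0.15)
})

test_that("outlier-window intersection equals brute force on a 200-SNP toy", {
  set.seed(108)
  n <- 200
  pos <- sort(sample.int(2e4, n))
  tracks <- list(
    fst = data.frame(chrom = "chr1", pos = pos, score = rnorm(n)),
    xtx = data.frame(chrom = "chr1", pos = pos, score = rnorm(n)),
    ihs = data.frame(chrom = "chr1", pos = pos, score = rnorm(n)))
  # plant a common outlier region
  at <- pos > 9000 & pos < 9500
  for (t in seq_along(tracks)) tracks[[t]]$score[at] <- 10 + rnorm(sum(at))
  res <- outlier_window_intersection(tracks, c(chr1 = 2e4),
                                     window = 1000, step = 500,
                                     top_fraction = 0.05)
  ora <- oracle_intersection(tracks, 2e4, window = 1000, step = 500,
                             top_fraction = 0.05)
  got <- res$window_flags[rowSums(as.matrix(
    res$window_flags[, 4:6])) == 3, ]
  expect_equal(got$start, ora$start)
  # a track with no marked SNPs in a region blocks intersection there
  tracks$ihs$score[tracks$ihs$pos < 1e4] <- NA
  tracks$ihs$score[tracks$ihs$pos >= 1e4] <-
    10 * as.numeric(tracks$ihs$pos[tracks$ihs$pos >= 1e4] > 1.5e4)
  res2 <- outlier_window_intersection(tracks, c(chr1 = 2e4),
                                      window = 1000, step = 500,
                                      top_fraction = 0.05)
  expect_false(any(res2$intersection$start < 9000 - 1000))
})

test_that("male X contributes exactly one haplotype to X panels", {
  sim <- make_sim(seed = 109, n_per = c(10, 10),
                  chrom_lengths = c(chr1 = 2e5, chrX = 2e5))
  ch <- invadepop:::chrom_hap(sim$panel, "chrX")
  n_f <- sum(sim$panel$samples$sex == "F")
  n_m <- sum(sim$panel$samples$sex == "M")
  expect_equal(nrow(ch$hap), 2 * n_f + n_m)
  ch1 <- invadepop:::chrom_hap(sim$panel, "chr1")
  expect_equal(nrow(ch1$hap), 2 * (n_f + n_m))
})
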