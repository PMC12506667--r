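test_that("KING kinship: self-pair 0.5, symmetry, allele-flip invariance", {
  sim <- make_sim(seed = 81, n_pop = 1, n_per = 8,
                  chrom_lengths = c(chr1 = 3e5, chrX = 1e5),
                  depth = 50, extra_missing = 0.02)
  co <- sim$cohort
  # duplicate an individual: its pair has phi = 0.5 exactly
  co2 <- co
  co2$geno <- rbind(co$geno, co$geno[1, , drop = FALSE])
  co2$dp <- rbind(co$dp, co$dp[1, , drop = FALSE])
  dup <- co$samples[1, ]; dup$id <- "dup"
  co2$samples <- rbind(co$samples, dup)
  kin <- king_kinship(co2)
  self <- kin[kin$id1 == co$samples$id[1] & kin$id2 == "dup", ]
  expect_equal(self$phi, 0.5)
  expect_equal(self$ibs0, 0)
  # allele-label flip leaves phi unchanged
  co_f <- co; co_f$geno <- 2L - co$geno
  expect_equal(king_kinship(co)$phi, king_kinship(co_f)$phi)
})

test_that("relatedness bins partition (0.0442, Inf) per the KING scheme", {
  expect_equal(classify_relatedness(0.30), "1st")
  expect_equal(classify_relatedness(0.05), "3rd")
  expect_equal(classify_relatedness(0.02), "unrelated")
  expect_equal(classify_relatedness(0.40), "duplicate")
  # boundaries: each value belongs to exactly one bin, no gaps
  eps <- 1e-12
  th <- 2^-c(1.5, 2.5, 3.5, 4.5)
  for (t in th) {
    expect_false(classify_relatedness(t) ==
                   classify_relatedness(t + eps))
  }
  phis <- seq(0.001, 0.6, by = 0.001)
  labs <- classify_relatedness(phis)
  expect_false(any(is.na(labs)))
})

test_that("parent-offspring pairs: IBS0 zero, first degree", {
  sim <- make_sim(seed = 83, n_pop = 1, n_per = 10,
                  chrom_lengths = c(chr1 = 1e6, chr2 = 1e6, chrX = 2e5))
  m <- data.frame(mother = "pop1_i01", father = "pop1_i02",
                  child = "kid", child_sex = "F")
  set.seed(84)
  out <- generate_pedigree_samples(sim$panel, sim$truth, m)
  co <- attach_read_depth(out$panel, 100, extra_missing_rate = 0)
  kin <- king_kinship(co)
  po <- kin[kin$id1 == "pop1_i01" & kin$id2 == "kid", ]
  expect_equal(po$ibs0, 0)
  expect_equal(po$degree, "1st")
})

test_that("inbreeding coefficient: closed form, extremes, HW mean near 0", {
  # 3-site toy, checked against the direct formula
  g <- rbind(c(0L, 1L, 2L),
             c(1L, 1L, 1L),
             c(2L, 0L, 0L),
             c(0L, 2L, 1L))
  co <- toy_cohort(g)
  f <- inbreeding_coefficient(co)
  ncop <- rep(8, 3); alt <- colSums(g)
  p <- alt / ncop
  e_site <- 1 - 2 * p * (1 - p) * ncop / (ncop - 1)
  for (i in 1:4) {
    o <- sum(g[i, ] != 1)
    expect_equal(f$f[i], (o - sum(e_site)) / (3 - sum(e_site)))
  }
  # fully homozygous individual at every site -> F = 1
  g2 <- rbind(c(0L, 2L, 0L, 2L), c(1L, 1L, 1L, 1L), c(2L, 0L, 1L, 1L),
              c(1L, 1L, 0L, 2L), c(0L, 1L, 1L, 0L))
  f2 <- inbreeding_coefficient(toy_cohort(g2))
  expect_equal(f2$f[1], 1)
  # Hardy-Weinberg draws: mean F within 0.02 of 0 over 10^4 SNPs
  set.seed(85)
  p <- runif(1e4, 0.1, 0.9)
  ghw <- sapply(p, function(pp) rbinom(30, 2, pp))
  fhw <- inbreeding_coefficient(toy_cohort(ghw))
  expect_lt(abs(mean(fhw$f)), 0.02)
})

test_that("LD pruning: MAC floor and no retained high-LD pair", {
  set.seed(86)
  base <- rbinom(30, 2, 0.5)
  g <- cbind(base, base, rbinom(30, 2, 0.4),
             c(1L, rep(0L, 29)),               # MAC 1: dropped
             rbinom(30, 2, 0.5))
  colnames(g) <- NULL
  co <- toy_cohort(g)
  kept <- ld_prune(co, r2_threshold = 0.2, min_mac = 3)
  expect_false(4 %in% kept)                    # MAC floor
  expect_equal(sum(kept %in% 1:2), 1)          # one of the identical pair
  # post-hoc exhaustive check on a simulated cohort
  sim <- make_sim(seed = 87, chrom_lengths = c(chr1 = 2e5, chrX = 5e4),
                  depth = 50)
  kept2 <- ld_prune(sim$cohort, r2_threshold = 0.2, window_snps = 50)
  g2 <- sim$cohort$geno[, kept2]
  ch <- sim$cohort$sites$chrom[kept2]
  for (cn in unique(ch)) {
    idx <- which(ch == cn)
    for (i in idx) {
      win <- idx[idx > i & idx <= i + 50]
      if (!length(win)) next
      r2 <- suppressWarnings(
        cor(g2[, i], g2[, win, drop = FALSE],
            use = "pairwise.complete.obs"))^2
      expect_false(any(r2 > 0.2, na.rm = TRUE))
    }
  }
})

test_that("PCA: duplicates coincide, trace identity, separation at FST 0.1", {
  sim <- make_sim(seed = 88, n_per = c(15, 15),
                  chrom_lengths = c(chr1 = 5e5, chrX = 1e5),
                  divergence = 0.1, depth = 50)
  co <- sim$cohort
  auto <- which(co$sites$chrom != "chrX")
  pc <- pca_cohort(co, auto, n_components = 2)
  expect_true(all(diff(pc$eigenvalues) < 1e-8))
  # eigenvalue sum equals the trace of the covariance (total variance)
  g <- co$geno[, pc$snp_subset]
  p <- colMeans(g, na.rm = TRUE) / 2
  X <- sweep(g, 2, 2 * p); X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  X[is.na(X)] <- 0
  expect_equal(sum(pc$eigenvalues), sum(diag(tcrossprod(X) / ncol(X))),
               tolerance = 1e-8)
  # PC1 separates the two populations
  lab <- co$samples$population
  expect_true(abs(mean(pc$coords[lab == "pop1", 1]) -
                    mean(pc$coords[lab == "pop2", 1])) >
                2 * mean(tapply(pc$coords[, 1], lab, sd)))
  # duplicated individual lands on identical coordinates
  co2 <- co
  co2$geno <- rbind(co$geno, co$geno[3, , drop = FALSE])
  co2$dp <- rbind(co$dp, co$dp[3, , drop = FALSE])
  dup <- co$samples[3, ]; dup$id <- "dup"
  co2$samples <- rbind(co$samples, dup)
  pc2 <- pca_cohort(co2, auto, 2)
  expect_equal(unname(pc2$coords[3, ]), unname(pc2$coords[31, ]),
               tolerance = 1e-6)
})

test_that("Weir-Cockerham FST: fixed difference, permutation, oracle", {
  # fixed difference at every SNP -> multi-SNP FST = 1
  g <- rbind(matrix(0L, 4, 3), matrix(2L, 4, 3))
  co <- toy_cohort(g, pops = rep(c("A", "B"), each = 4))
  f <- wc_fst(co, co$samples$population, min_mac = 1)
  expect_equal(f$fst, 1)
  # label permutation of one population: FST near 0
  sim <- make_sim(seed = 91, n_pop = 1, n_per = 60,
                  chrom_lengths = c(chr1 = 2e6, chrX = 1e5),
                  divergence = 0, depth = 50)
  co2 <- sim$cohort
  fake <- rep(c("g1", "g2"), 30)
  f2 <- wc_fst(co2, fake, min_mac = 4)
  expect_lt(abs(f2$fst), 0.02)
  # 3-SNP 2x4-diploid toy equals the independently coded components
  g3 <- rbind(c(0L, 1L, 2L), c(1L, 1L, 0L), c(2L, 0L, 1L), c(1L, 2L, 1L),
              c(0L, 0L, 2L), c(0L, 1L, 2L), c(1L, 0L, 2L), c(0L, 0L, 1L))
  co3 <- toy_cohort(g3, pops = rep(c("A", "B"), each = 4))
  f3 <- wc_fst(co3, co3$samples$population, min_mac = 1)
  for (s in 1:3) {
    ora <- oracle_wc_components(list(g3[1:4, s], g3[5:8, s]))
    expect_equal(f3$per_snp$a[s], unname(ora["a"]))
    expect_equal(f3$per_snp$b[s], unname(ora["b"]))
    expect_equal(f3$per_snp$c[s], unname(ora["c"]))
  }
})

test_that("FST recovers the simulated drift parameter", {
  recover <- function(target, reps = 6) {
    vapply(seq_len(reps), function(r) {
      cfg <- sim_config(n_populations = 2, samples_per_population = 25,
                        chrom_lengths = c(chr1 = 2e6, chrX = 1e5),
                        divergence = target, n_founders = 200,
                        seed = 900 + 37 * r + round(1000 * target))
      sim <- simulate_structured_panel(cfg)
      set.seed(950 + r)
      co <- attach_read_depth(sim$panel, 50)
      wc_fst(co, co$samples$population, min_mac = 4)$fst
    }, 0)
  }
  for (target in c(0.05, 0.1, 0.2)) {
    est <- recover(target)
    expect_lt(abs(mean(est) - target), 3 * sd(est) + 0.005)
  }
})

test_that("FST-time regression: perfect line, pair counting, permutation", {
  dates <- setNames(as.character(as.Date("2019-01-01") + c(0, 10, 30, 60,
                                                           100, 150, 210)),
                    paste0("c", 1:7))
  pairs <- t(combn(names(dates), 2))
  dt <- abs(as.numeric(as.Date(dates[pairs[, 1]]) -
                         as.Date(dates[pairs[, 2]])))
  pf <- data.frame(collection_i = pairs[, 1], collection_j = pairs[, 2],
                   fst = 0.001 + 2e-5 * dt)
  r <- suppressWarnings(fst_vs_time_regression(pf, dates))
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2e-5)
  expect_equal(r$n_pairs, 21)                   # C(7,2)
  expect_equal(r$df, 19)
  # permuted FST: slope centred on zero
  set.seed(92)
  slopes <- replicate(100, {
    pf2 <- pf; pf2$fst <- sample(pf$fst)
    fst_vs_time_regression(pf2, dates)$slope
  })
  expect_lt(abs(mean(slopes)), 2 * sd(slopes) / sqrt(100) * 3 + 1e-6)
  expect_error(fst_vs_time_regression(pf[1:2, ], dates), "fewer than 3")
})
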