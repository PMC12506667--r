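test_that("identical config and seed give bit-identical panels", {
  s1 <- simulate_structured_panel(sim_config(seed = 5))
  s2 <- simulate_structured_panel(sim_config(seed = 5))
  expect_identical(s1$panel$hap, s2$panel$hap)
  expect_identical(s1$panel$sites, s2$panel$sites)
  s3 <- simulate_structured_panel(sim_config(seed = 6))
  expect_false(identical(s1$panel$hap, s3$panel$hap))
})

test_that("panel geometry: sorted positions, haploid male X, sexes", {
  sim <- make_sim(seed = 2)
  p <- sim$panel
  for (cn in unique(p$sites$chrom)) {
    expect_false(is.unsorted(p$sites$pos[p$sites$chrom == cn],
                             strictly = TRUE))
  }
  on_x <- p$sites$chrom == "chrX"
  male2 <- p$samples$sex[p$hap_sample] == "M" & p$hap_index == 2
  expect_true(all(is.na(p$hap[male2, on_x])))
  expect_true(all(!is.na(p$hap[!male2, ])))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(divergence = 1.2), "divergence")
  expect_error(sim_config(chrom_lengths = c(a = 1e5, b = 1e5),
                          x_chrom = "chrX"), "exactly one")
  expect_error(sim_config(samples_per_population = 0), ">= 1")
})

test_that("realized frequencies track intended population frequencies", {
  # regression of realized on intended frequency over 10^4 SNPs: slope ~ 1
  cfg <- sim_config(n_populations = 1, samples_per_population = 40,
                    chrom_lengths = c(chr1 = 1e7, chrX = 1e5),
                    divergence = 0, founder_theta = 0.8, seed = 33)
  set.seed(33)
  n_snp <- round(1e7 * cfg$snp_density)
  sim <- simulate_structured_panel(cfg)
  on1 <- sim$panel$sites$chrom == "chr1"
  realized <- colMeans(sim$panel$hap[, on1])
  # recover intended frequencies by replaying the generator's RNG stream
  set.seed(cfg$seed)
  pos <- sort(sample.int(1e7, n_snp))
  p0 <- rbeta(n_snp, 0.8, 0.8)
  p0 <- pmin(pmax(p0, 1e-4), 1 - 1e-4)
  fit <- lm(realized ~ p0)
  expect_gt(coef(fit)[2], 0.95)
  expect_lt(coef(fit)[2], 1.05)
})

test_that("inversion injection: no-op at freq 0, genotypes binomial", {
  sim <- make_sim(seed = 7, chrom_lengths = c(chr1 = 2e6, chrX = 1e5))
  set.seed(1)
  out0 <- inject_inversion(sim$panel, sim$truth, "chr1", 5e5, 1.5e6,
                           freq = 0)
  expect_identical(out0$panel$hap, sim$panel$hap)
  # heterokaryotype counts over 50 diploids at freq 0.3: central 99% of
  # the arrangement-allele count Binomial(100, 0.3) is [13, 29] carriers
  # per the exact binomial; check the arrangement allele count instead
  big <- make_sim(seed = 8, n_pop = 1, n_per = 50,
                  chrom_lengths = c(chr1 = 2e6, chrX = 1e5))
  counts <- vapply(1:20, function(r) {
    set.seed(100 + r)
    out <- inject_inversion(big$panel, big$truth, "chr1", 5e5, 1.5e6,
                            freq = 0.3, target_pops = "pop1")
    sum(out$truth$inversions[[1]]$arrangement_genotype == 1)
  }, 0)
  # heterokaryotypes ~ Binomial(50, 2*0.3*0.7) -> central mass
  expect_true(mean(counts >= 13 & counts <= 29) >= 0.8)
  # overlapping injection is rejected
  set.seed(2)
  out1 <- inject_inversion(sim$panel, sim$truth, "chr1", 5e5, 1.5e6,
                           freq = 0.3)
  expect_error(inject_inversion(out1$panel, out1$truth, "chr1", 1e6, 1.8e6,
                                freq = 0.2), "overlaps")
})

test_that("sweep injection: fixed core, carrier identity, native untouched", {
  sim <- make_sim(seed = 11, chrom_lengths = c(chr1 = 2e6, chrX = 1e5))
  on1 <- which(sim$panel$sites$chrom == "chr1")
  core_pos <- sim$panel$sites$pos[on1][length(on1) %/% 2]
  set.seed(3)
  out <- inject_sweep(sim$panel, sim$truth, "chr1", core_pos, freq = 1,
                      carrier_span = 4e5, residual_mutation_rate = 0,
                      target_pops = "pop2")
  core <- which(out$panel$sites$chrom == "chr1" &
                  out$panel$sites$pos == core_pos)
  pop2_rows <- which(out$panel$samples$population[out$panel$hap_sample] ==
                       "pop2")
  expect_true(all(out$panel$hap[pop2_rows, core] == 1))
  pop1_rows <- which(out$panel$samples$population[out$panel$hap_sample] ==
                       "pop1")
  expect_true(all(out$panel$hap[pop1_rows, core] == 0))
  # zero residual mutation: carriers identical over the span
  span <- which(out$panel$sites$chrom == "chr1" &
                  abs(out$panel$sites$pos - core_pos) <= 2e5)
  carriers <- out$truth$sweeps[[1]]$carrier_rows
  h <- out$panel$hap[carriers, span]
  expect_true(all(apply(h, 2, function(x) length(unique(x)) == 1)))
  # with residual mutations, pairwise identity stays near 1 - 2*rate
  set.seed(4)
  out2 <- inject_sweep(sim$panel, sim$truth, "chr1", core_pos, freq = 0.6,
                       carrier_span = 4e5, residual_mutation_rate = 0.01,
                       target_pops = "pop2")
  carr <- out2$truth$sweeps[[1]]$carrier_rows
  h2 <- out2$panel$hap[carr, span]
  id12 <- mean(h2[1, ] == h2[2, ])
  expect_gt(id12, 1 - 4 * 0.01)
})

test_that("pedigree offspring are Mendelian-consistent at every site", {
  sim <- make_sim(seed = 21, n_pop = 1, n_per = 6,
                  chrom_lengths = c(chr1 = 5e5, chrX = 2e5))
  m <- data.frame(mother = "pop1_i01", father = "pop1_i02",
                  child = "kid", child_sex = "F")
  set.seed(5)
  out <- generate_pedigree_samples(sim$panel, sim$truth, m)
  co <- attach_read_depth(out$panel, mean_depth = 1e3,
                          extra_missing_rate = 0)
  g <- co$geno
  mo <- g["pop1_i01", ]; fa <- g["pop1_i02", ]; kid <- g["kid", ]
  # no opposite homozygotes between parent and child (autosomes)
  auto <- co$sites$chrom != "chrX"
  expect_equal(sum((mo == 0 & kid == 2) | (mo == 2 & kid == 0), na.rm = TRUE),
               0)
  opp_fa <- (fa[auto] == 0 & kid[auto] == 2) | (fa[auto] == 2 & kid[auto] == 0)
  expect_equal(sum(opp_fa, na.rm = TRUE), 0)
  expect_error(generate_pedigree_samples(
    out$panel, out$truth,
    data.frame(mother = "kid", father = "kid", child = "x",
               child_sex = "F")), "self-mating")
})

test_that("read depth: Poisson mean, halved male X, DP-0 missingness", {
  sim <- make_sim(seed = 31, n_per = c(12, 12),
                  chrom_lengths = c(chr1 = 1e6, chrX = 2.5e5), depth = 20)
  co <- sim$cohort
  expect_equal(mean(co$dp), 20 * weighted.mean(
    c(1, 0.75), c(sum(co$sites$chrom != "chrX"),
                  sum(co$sites$chrom == "chrX"))), tolerance = 0.05)
  on_x <- co$sites$chrom == "chrX"
  ratio <- rowMeans(co$dp[, on_x]) / rowMeans(co$dp[, !on_x])
  f <- co$samples$reported_sex == "F"
  expect_true(all(abs(ratio[f] - 1) < 0.1))
  expect_true(all(abs(ratio[!f] - 0.5) < 0.1))
  expect_true(all(is.na(co$geno[co$dp == 0])))
  expect_error(attach_read_depth(sim$panel, mean_depth = 0), "positive")
})

test_that("fixture write/read round trip preserves matrices and truth", {
  sim <- make_sim(seed = 41, n_per = c(6, 6),
                  chrom_lengths = c(chr1 = 2e5, chrX = 1e5),
                  depth = 40, extra_missing = 0)
  set.seed(6)
  out <- inject_inversion(sim$panel, sim$truth, "chr1", 5e4, 1.5e5,
                          freq = 0.5)
  co <- attach_read_depth(out$panel, 40, extra_missing_rate = 0)
  d <- tempfile()
  paths <- write_fixture(co, out$truth, d)
  co2 <- read_vcf(paths[["vcf"]], paths[["samples"]])
  expect_identical(unname(co$geno), unname(co2$geno))
  expect_true(all(co$dp == co2$dp))
  # male X records carry a single allele
  lines <- readLines(paths[["vcf"]])
  male_col <- 9 + which(co$samples$reported_sex == "M")[1]
  x_line <- strsplit(grep("^chrX", lines, value = TRUE)[1], "\t")[[1]]
  expect_true(grepl("^[.01](:|$)", x_line[male_col]))
  # truth BED equals the injected region (0-based half-open)
  bed <- read_bed(paths[["inversions"]])
  expect_equal(bed$start, 5e4 - 1)
  expect_equal(bed$end, 1.5e5)
})
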