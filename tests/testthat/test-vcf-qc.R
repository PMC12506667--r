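test_that("read_vcf drops multiallelic and non-SNP records and logs them", {
  d <- tempfile(); dir.create(d)
  vcf <- file.path(d, "t.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "a", "b"), collapse = "\t"),
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/0",
    "chr1\t20\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/1\t0/2",
    "chr1\t30\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t40\t.\tC\tG\t.\tPASS\t.\tGT\t./.\t1/1"), vcf)
  sheet <- file.path(d, "s.tsv")
  writeLines(c("id\tpopulation\treported_sex", "a\tp1\tF", "b\tp1\tM"), sheet)
  co <- read_vcf(vcf, sheet, x_chrom = "chrX")
  expect_equal(ncol(co$geno), 2)        # multiallelic + indel dropped
  expect_equal(co$log$read$records_dropped_non_biallelic_snp, 2)
  # "0/1" and "1/0" give the same dosage
  expect_equal(unname(co$geno[, 1]), c(1L, 1L))
  expect_equal(unname(co$geno[, 2]), c(NA_integer_, 2L))
  # sheet mismatch errors
  writeLines(c("id\tpopulation\treported_sex", "a\tp1\tF", "zz\tp1\tM"),
             sheet)
  expect_error(read_vcf(vcf, sheet), "mismatch")
})

test_that("genotype depth filter boundaries: DP 6/7 and 100/101", {
  g <- matrix(1L, 1, 4)
  dp <- matrix(c(6L, 7L, 100L, 101L), 1, 4)
  co <- toy_cohort(g, dp = dp)
  f <- filter_genotypes_by_depth(co)
  expect_equal(unname(f$geno[1, ]), c(NA_integer_, 1L, 1L, NA_integer_))
  expect_error(filter_genotypes_by_depth(toy_cohort(g)), "DP")
})

test_that("site filters: mean depth bounds, indel margin, repeat mask", {
  # 6 sites x 2 individuals; per-site mean depths 9.5, 10, 30, 50, 50.5, 30
  g <- matrix(1L, 2, 6)
  dp <- rbind(c(9L, 10L, 30L, 50L, 50L, 30L),
              c(10L, 10L, 30L, 50L, 51L, 30L))
  co <- toy_cohort(g, pos = c(100, 200, 300, 400, 500, 620), dp = dp)
  f <- filter_sites(co)
  expect_equal(f$sites$pos, c(200, 300, 400, 620))
  expect_equal(f$log$site_filter$removed_mean_depth, 2)
  # SNP exactly 20 bp from an indel is removed (inclusive margin)
  indel <- interval_set("chr1", 299, 300)   # indel base at position 300
  f2 <- filter_sites(co, indel_positions = indel, indel_margin = 20)
  # removes 300 itself and 280..320: here only site 300
  expect_false(300 %in% f2$sites$pos)
  co3 <- toy_cohort(g, pos = c(279, 280, 320, 321, 400, 500),
                    dp = matrix(30L, 2, 6))
  f3 <- filter_sites(co3, indel_positions = indel, indel_margin = 20)
  expect_equal(f3$sites$pos, c(279, 321, 400, 500))
  # repeat-masked site removed
  f4 <- filter_sites(co, repeat_mask = interval_set("chr1", 580, 640))
  expect_false(620 %in% f4$sites$pos)
})

test_that("individual filter: coverage < 7 and missingness > 10%", {
  g <- matrix(1L, 3, 20)
  g[2, 1:3] <- NA_integer_                      # 15% missing
  g[3, 1:2] <- NA_integer_                      # 10% missing, retained
  dp <- matrix(10L, 3, 20); dp[1, ] <- 6L       # coverage 6 < 7
  co <- toy_cohort(g, dp = dp)
  f <- filter_individuals(co)
  expect_equal(f$samples$id, "s03")
  rep <- f$log$individual_filter$removed
  expect_setequal(rep$reason, c("low_coverage", "high_missingness"))
  expect_error(filter_individuals(toy_cohort(
    matrix(NA_integer_, 2, 4), dp = matrix(1L, 2, 4))), "all individuals")
})

test_that("filters are idempotent and report staged counts", {
  sim <- make_sim(seed = 51, depth = 12, extra_missing = 0.01)
  co <- filter_genotypes_by_depth(sim$cohort)
  co2 <- filter_genotypes_by_depth(co)
  expect_identical(co$geno, co2$geno)
  cs <- filter_sites(co)
  cs2 <- filter_sites(cs)
  expect_identical(cs$sites, cs2$sites)
  ci <- filter_individuals(cs)
  ci2 <- filter_individuals(ci)
  expect_identical(ci$samples$id, ci2$samples$id)
  expect_true(all(c("genotype_depth", "site_filter", "individual_filter")
                  %in% names(ci$log)))
})

test_that("sex assignment by X:autosome depth ratio with 0.8 boundary", {
  g <- matrix(1L, 3, 4)
  dp <- rbind(c(20L, 20L, 20L, 21L),   # X ratio ~1 -> F
              c(20L, 20L, 10L, 10L),   # 0.5 -> M
              c(20L, 20L, 16L, 16L))   # exactly 0.8 -> M + warning
  co <- toy_cohort(g, chrom = c("chr1", "chr1", "chrX", "chrX"),
                   pos = c(1, 2, 1, 2), dp = dp,
                   sex = c("F", "F", "F"))
  expect_warning(co2 <- assign_sex(co), "threshold")
  expect_equal(co2$samples$assigned_sex, c("F", "M", "M"))
  expect_equal(co2$samples$sex_discordant, c(FALSE, TRUE, TRUE))
  co_noauto <- toy_cohort(g[, 3:4, drop = FALSE],
                          chrom = c("chrX", "chrX"), pos = c(1, 2),
                          dp = dp[, 3:4])
  expect_error(assign_sex(co_noauto), "autosomal")
})

test_that("polarization by reference major allele, ties, involution", {
  # popA is the reference; alt freq 0.7 at site 1, 0.3 at site 2, 0.5 tie
  g <- rbind(c(2L, 1L, 1L),
             c(2L, 0L, 1L),
             c(1L, 1L, 1L),
             c(2L, 0L, 0L),
             c(0L, 1L, 2L))
  co <- toy_cohort(g, pops = c(rep("popA", 5)))
  co <- polarize_by_reference_population(co, "popA")
  expect_equal(co$sites$aa, c("alt", "ref", "ref"))
  expect_equal(co$sites$aa_tie, c(FALSE, FALSE, TRUE))
  # flipping every reference genotype flips every non-tie flag
  co_f <- co; co_f$geno <- 2L - co$geno
  co_f <- polarize_by_reference_population(co_f, "popA")
  nt <- !co$sites$aa_tie
  expect_true(all(co$sites$aa[nt] != co_f$sites$aa[nt]))
  expect_error(polarize_by_reference_population(co, "nope"), "unknown")
})

test_that("mask_regions removes inside sites, keeps half-open boundary", {
  g <- matrix(1L, 2, 3)
  co <- toy_cohort(g, pos = c(100, 150, 200))
  # mask [99, 199): covers 1-based 100..199; site at 200 retained
  m <- mask_regions(co, interval_set("chr1", 99, 199))
  expect_equal(m$sites$pos, 200)
  expect_equal(mask_regions(co, interval_set())$sites$pos, co$sites$pos)
  all_mask <- interval_set("chr1", 0, 10000)
  expect_equal(ncol(mask_regions(co, all_mask)$geno), 0)
})

test_that("attrition bookkeeping sums sequenced minus retained", {
  tab <- data.frame(n_sequenced = c(10, 20), n_after_filtering = c(9, 17))
  s <- qc_attrition_summary(tab)
  expect_equal(s$removed, 4)
})
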