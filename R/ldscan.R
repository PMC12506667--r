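#' Squared genotype correlation between two dosage vectors
#'
#' Composite LD as the squared Pearson correlation of genotype dosages over
#' pairwise-complete individuals.  Returns `NA` (not 0) when fewer than two
#' shared non-missing individuals remain or either vector is monomorphic
#' among them.
#'
#' @param a,b equal-length dosage vectors.
#' @return r-squared in [0, 1], or `NA`.
#' @export
genotype_r2 <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

# eligible SNP indices: allelically segregating in the population, no
# missing genotypes (on the X, a site fixed for one allele still varies in
# dosage between sexes, so segregation is judged on allele counts)
eligible_snps <- function(cohort, population) {
  rows <- cohort$samples$population == population
  if (!any(rows)) stop("unknown population: ", population, call. = FALSE)
  g <- cohort$geno[rows, , drop = FALSE]
  complete <- colSums(is.na(g)) == 0
  ac <- allele_counts(cohort, rows)
  seg <- ac$alt > 0 & ac$alt < ac$copies
  which(complete & seg)
}

#' Sample an LD matrix for one chromosome and population
#'
#' Draws up to `n_snps` SNPs (uniformly, without replacement) from those
#' segregating in the population with no missing genotypes, and computes
#' the full pairwise r-squared matrix, position-sorted.
#'
#' @param cohort a `cohort`.
#' @param chromosome chromosome id.
#' @param population population label.
#' @param n_snps number of SNPs to sample.
#' @param seed RNG seed for the SNP sample.
#' @return A list of class `ld_matrix` with `r2`, `positions`, `snp_idx`,
#'   `population` and `shortfall` (TRUE when fewer than `n_snps` were
#'   available).
#' @export
sample_ld_matrix <- function(cohort, chromosome, population,
                             n_snps = 4000, seed = 1L) {
  set.seed(seed)
  elig <- eligible_snps(cohort, population)
  elig <- elig[cohort$sites$chrom[elig] == chromosome]
  if (length(elig) < 2) stop("fewer than 2 eligible SNPs", call. = FALSE)
  take <- if (length(elig) > n_snps) sort(sample(elig, n_snps)) else elig
  rows <- cohort$samples$population == population
  g <- cohort$geno[rows, take, drop = FALSE]
  r2 <- cor(g)^2
  structure(list(r2 = r2, positions = cohort$sites$pos[take],
                 snp_idx = take, population = population,
                 chromosome = chromosome,
                 shortfall = length(elig) < n_snps, seed = seed),
            class = "ld_matrix")
}

#' Long-range LD scan for inversion-like regions
#'
#' For each SNP segregating with complete genotypes in the population, one
#' partner SNP is sampled uniformly at each target distance (within
#' `distance_tolerance` of the distance, in either direction) and
#' r-squared is computed for the pair.  The genome is tiled with
#' non-overlapping windows; a window is flagged when at least one SNP
#' located in it (focal or partner) participates in a pair with
#' r-squared above the threshold.
#'
#' @param cohort a `cohort`.
#' @param population population label.
#' @param distances_kb target pair distances in kb.
#' @param distance_tolerance relative tolerance on each distance.
#' @param r2_threshold r-squared above which a pair counts as high LD.
#' @param window_size window size in bp.
#' @param seed RNG seed for partner sampling.
#' @return A list of class `window_flags`: per-chromosome data.frames with
#'   window start (0-based), flag, and eligible-SNP count.
#' @export
long_range_ld_scan <- function(cohort, population,
                               distances_kb = c(100, 200, 300, 400, 500),
                               distance_tolerance = 0.05,
                               r2_threshold = 0.75,
                               window_size = 1e5, seed = 1L) {
  if (window_size <= 0) stop("window size must be positive", call. = FALSE)
  set.seed(seed)
  elig <- eligible_snps(cohort, population)
  rows <- which(cohort$samples$population == population)
  out <- list()
  for (cn in names(cohort$chrom_lengths)) {
    e <- elig[cohort$sites$chrom[elig] == cn]
    len <- cohort$chrom_lengths[[cn]]
    starts <- seq(0, max(len - 1, 0), by = window_size)
    n_elig <- tabulate(findInterval(cohort$sites$pos[e] - 1, starts),
                       nbins = length(starts))
    flag <- rep(FALSE, length(starts))
    if (length(e) >= 2) {
      pos <- cohort$sites$pos[e]
      # standardized dosages: no missing among eligible SNPs by construction
      g <- cohort$geno[rows, e, drop = FALSE]
      gs <- scale(g)
      n <- nrow(g)
      ii <- integer(0); jj <- integer(0)
      for (d in distances_kb * 1000) {
        lo <- d * (1 - distance_tolerance); hi <- d * (1 + distance_tolerance)
        # index bands of candidate partners on each side (pos is sorted)
        rlo <- findInterval(pos + lo - 0.5, pos) + 1L
        rhi <- findInterval(pos + hi, pos)
        llo <- findInterval(pos - hi - 0.5, pos) + 1L
        lhi <- findInterval(pos - lo, pos)
        nr <- pmax(rhi - rlo + 1L, 0L)
        nl <- pmax(lhi - llo + 1L, 0L)
        m <- nr + nl
        has <- which(m > 0L)
        if (!length(has)) next
        u <- floor(runif(length(has)) * m[has]) + 1L
        j <- ifelse(u <= nr[has], rlo[has] + u - 1L,
                    llo[has] + (u - nr[has]) - 1L)
        ii <- c(ii, has); jj <- c(jj, as.integer(j))
      }
      if (length(ii)) {
        r <- colSums(gs[, ii, drop = FALSE] * gs[, jj, drop = FALSE]) / (n - 1)
        hit <- which(r^2 > r2_threshold)
        hit_snps <- unique(c(ii[hit], jj[hit]))
        w <- findInterval(pos[hit_snps] - 1, starts)
        flag[unique(w)] <- TRUE
      }
    }
    out[[cn]] <- data.frame(chrom = cn, start = as.integer(starts),
                            flagged = flag, n_eligible = n_elig,
                            stringsAsFactors = FALSE)
  }
  structure(list(windows = out, window_size = window_size,
                 population = population, r2_threshold = r2_threshold,
                 seed = seed),
            class = "window_flags")
}

#' Call inversion regions from flagged windows
#'
#' Maximal runs of at least `min_run` consecutive flagged windows are
#' merged into intervals.  Windows with zero eligible SNPs break runs
#' (they cannot carry evidence either way, and bridging across SNP
#' deserts would inflate calls).
#'
#' @param flags a `window_flags` object.
#' @param min_run minimum run length in windows.
#' @return An [interval_set()] of called regions.
#' @export
call_inversion_regions <- function(flags, min_run = 10) {
  chrom <- character(); s <- integer(); e <- integer()
  for (cn in names(flags$windows)) {
    w <- flags$windows[[cn]]
    eff <- w$flagged & w$n_eligible > 0
    r <- rle(eff)
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_run)) {
      chrom <- c(chrom, cn)
      s <- c(s, w$start[begins[k]])
      e <- c(e, w$start[ends[k]] + flags$window_size)
    }
  }
  interval_set(chrom, s, e)
}
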