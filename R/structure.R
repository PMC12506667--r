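#' KING-robust pairwise kinship
#'
#' For each pair, over pairwise-complete autosomal genotypes:
#' phi = (N_AaAa - 2 N_opp) / (N_het_i + N_het_j), where N_AaAa counts
#' sites at which both are heterozygous, N_opp sites with opposite
#' homozygotes, and N_het_i/N_het_j heterozygous sites of each member
#' restricted to the shared non-missing set.  The estimator is robust to
#' population structure; a sample against itself gives exactly 0.5.
#'
#' @param cohort a `cohort`.
#' @param snp_subset optional site indices (defaults to all autosomal
#'   sites).
#' @return A data.frame of class `kinship_table`: id1, id2, phi, ibs0,
#'   n_shared, degree.
#' @export
king_kinship <- function(cohort, snp_subset = NULL) {
  auto <- which(cohort$sites$chrom != cohort$x_chrom)
  use <- if (is.null(snp_subset)) auto else intersect(snp_subset, auto)
  g <- cohort$geno[, use, drop = FALSE]
  H <- (!is.na(g)) & g == 1L; H[is.na(g)] <- FALSE
  A0 <- (!is.na(g)) & g == 0L; A0[is.na(g)] <- FALSE
  A2 <- (!is.na(g)) & g == 2L; A2[is.na(g)] <- FALSE
  M <- !is.na(g)
  storage.mode(H) <- "numeric"; storage.mode(A0) <- "numeric"
  storage.mode(A2) <- "numeric"; storage.mode(M) <- "numeric"
  hethet <- tcrossprod(H)
  opp <- tcrossprod(A0, A2); opp <- opp + t(opp)
  het_in_shared <- tcrossprod(H, M)   # [i, j] = het sites of i shared with j
  shared <- tcrossprod(M)
  denom <- het_in_shared + t(het_in_shared)
  phi <- (hethet - 2 * opp) / denom
  phi[denom == 0] <- NA_real_
  n <- nrow(g)
  pr <- which(upper.tri(phi), arr.ind = TRUE)
  tab <- data.frame(id1 = cohort$samples$id[pr[, 1]],
                    id2 = cohort$samples$id[pr[, 2]],
                    phi = phi[pr],
                    ibs0 = opp[pr] / shared[pr],
                    n_shared = shared[pr],
                    stringsAsFactors = FALSE)
  tab$degree <- classify_relatedness(tab$phi)
  class(tab) <- c("kinship_table", "data.frame")
  tab
}

#' Classify kinship coefficients into relatedness degrees
#'
#' Standard powers-of-two bins: duplicate/self above 2^(-3/2) (~0.354),
#' 1st degree (0.177, 0.354], 2nd (0.0884, 0.177], 3rd (0.0442, 0.0884],
#' otherwise unrelated.
#'
#' @param phi numeric vector of kinship coefficients.
#' @param thresholds decreasing vector of the four bin boundaries.
#' @return Character vector of degree labels.
#' @export
classify_relatedness <- function(phi,
                                 thresholds = 2^-c(1.5, 2.5, 3.5, 4.5)) {
  stopifnot(length(thresholds) == 4, !is.unsorted(rev(thresholds)))
  out <- rep(NA_character_, length(phi))
  ok <- !is.na(phi)
  out[ok] <- "unrelated"
  out[ok & phi > thresholds[4]] <- "3rd"
  out[ok & phi > thresholds[3]] <- "2nd"
  out[ok & phi > thresholds[2]] <- "1st"
  out[ok & phi > thresholds[1]] <- "duplicate"
  out
}

#' Method-of-moments inbreeding coefficient per individual
#'
#' F = (O_hom - E_hom) / (L - E_hom) over the individual's non-missing
#' sites, with the per-site expected homozygosity under Hardy-Weinberg
#' 1 - 2 p (1 - p) n/(n - 1) computed from sample allele counts (the
#' vcftools --het convention).
#'
#' @param cohort a `cohort`.
#' @param snp_subset optional site indices (defaults to all autosomal
#'   sites).
#' @return A data.frame with id, o_hom, e_hom, n_sites, f.
#' @export
inbreeding_coefficient <- function(cohort, snp_subset = NULL) {
  auto <- which(cohort$sites$chrom != cohort$x_chrom)
  use <- if (is.null(snp_subset)) auto else intersect(snp_subset, auto)
  g <- cohort$geno[, use, drop = FALSE]
  ac <- allele_counts(cohort)
  ncop <- ac$copies[use]; alt <- ac$alt[use]
  p <- ifelse(ncop > 0, alt / ncop, NA_real_)
  e_site <- 1 - 2 * p * (1 - p) * ncop / pmax(ncop - 1, 1)
  usable <- ncop > 1 & !is.na(p)
  M <- !is.na(g[, usable, drop = FALSE])
  gh <- g[, usable, drop = FALSE]
  o_hom <- rowSums(gh != 1L, na.rm = TRUE)
  e_hom <- as.vector(M %*% e_site[usable])
  L <- rowSums(M)
  f <- ifelse(abs(L - e_hom) < 1e-12, NA_real_,
              (o_hom - e_hom) / (L - e_hom))
  data.frame(id = cohort$samples$id, o_hom = o_hom, e_hom = e_hom,
             n_sites = L, f = f, stringsAsFactors = FALSE)
}

#' Greedy LD pruning with a minor-allele-count floor
#'
#' SNPs with MAC below `min_mac` are removed first; then a deterministic
#' left-to-right scan drops the later SNP of any pair within the last
#' `window_snps` retained SNPs (same chromosome) whose r-squared exceeds
#' the threshold.
#'
#' @param cohort a `cohort`.
#' @param r2_threshold LD threshold.
#' @param window_snps comparison window, in retained SNPs.
#' @param min_mac minimum minor allele count.
#' @return Integer vector of retained site indices.
#' @export
ld_prune <- function(cohort, r2_threshold = 0.2, window_snps = 100,
                     min_mac = 3) {
  ac <- allele_counts(cohort)
  mac <- pmin(ac$alt, ac$copies - ac$alt)
  cand <- which(mac >= min_mac)
  kept <- integer(0)
  for (cn in unique(cohort$sites$chrom)) {
    cc <- cand[cohort$sites$chrom[cand] == cn]
    kc <- integer(0)
    for (j in cc) {
      wstart <- max(1, length(kc) - window_snps + 1)
      win <- kc[wstart:length(kc)]
      drop <- FALSE
      if (length(kc)) {
        r2 <- suppressWarnings(
          cor(cohort$geno[, j], cohort$geno[, win, drop = FALSE],
              use = "pairwise.complete.obs"))^2
        drop <- any(r2 > r2_threshold, na.rm = TRUE)
      }
      if (!drop) kc <- c(kc, j)
    }
    kept <- c(kept, kc)
  }
  sort(kept)
}

#' PCA of frequency-standardized genotypes
#'
#' Dosages are centred at 2p and scaled by sqrt(2 p (1 - p)); missing
#' genotypes are mean-imputed per SNP after standardization (i.e. set to
#' zero).  Eigendecomposition of the individual covariance matrix gives
#' coordinates ordered by eigenvalue.
#'
#' @param cohort a `cohort`.
#' @param snp_subset site indices (typically from [ld_prune()]).
#' @param n_components number of components to return.
#' @return A list of class `pca_result`: `coords` (individuals x
#'   components), `eigenvalues` (all, non-increasing), `snp_subset`.
#' @export
pca_cohort <- function(cohort, snp_subset = NULL, n_components = 4) {
  use <- snp_subset %||% seq_len(ncol(cohort$geno))
  g <- cohort$geno[, use, drop = FALSE]
  if (n_components > nrow(g)) {
    stop("fewer individuals than requested components", call. = FALSE)
  }
  p <- colMeans(g, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  g <- g[, keep, drop = FALSE]; p <- p[keep]
  X <- sweep(g, 2, 2 * p)
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  X[is.na(X)] <- 0
  K <- tcrossprod(X) / ncol(X)
  eig <- eigen(K, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  coords <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_components)]), n_components)
  rownames(coords) <- cohort$samples$id
  colnames(coords) <- paste0("PC", seq_len(n_components))
  structure(list(coords = coords, eigenvalues = ev,
                 snp_subset = use[keep]),
            class = "pca_result")
}

#' Weir-Cockerham FST variance components
#'
#' Per-SNP components a (among populations), b (among individuals within
#' populations) and c (within individuals) from Weir & Cockerham (1984),
#' computed from genotyped diploids per group; per-SNP FST = a/(a+b+c) and
#' the multi-SNP estimate is the ratio of summed components.  Sites with
#' minor allele count below `min_mac` (across the used samples) are
#' excluded.
#'
#' @param cohort a `cohort`.
#' @param group_labels character vector over individuals (NA = excluded).
#' @param snp_subset optional site indices.
#' @param min_mac minimum minor allele count (default 4, i.e. MAC > 3).
#' @return A list of class `fst_result`: `per_snp` (data.frame with a, b,
#'   c, fst), `fst` (multi-SNP), `n_snps`.
#' @export
wc_fst <- function(cohort, group_labels, snp_subset = NULL, min_mac = 4) {
  stopifnot(length(group_labels) == nrow(cohort$geno))
  use <- snp_subset %||% seq_len(ncol(cohort$geno))
  rows <- which(!is.na(group_labels))
  grp <- factor(group_labels[rows])
  if (nlevels(grp) < 2) stop("need at least 2 groups", call. = FALSE)
  g <- cohort$geno[rows, use, drop = FALSE]
  r <- nlevels(grp)
  # per-group per-site sample sizes (genotyped diploids), freqs, het freqs
  n_i <- rowsum((!is.na(g)) + 0, grp)            # r x S
  p_i <- rowsum(ifelse(is.na(g), 0, g), grp) / (2 * n_i)
  h_i <- rowsum(ifelse(is.na(g), 0, (g == 1L) + 0), grp) / n_i
  alt <- colSums(2 * n_i * p_i)
  tot <- colSums(2 * n_i)
  mac <- pmin(alt, tot - alt)
  ok <- mac >= min_mac & colSums(n_i > 0) == r
  if (!any(ok)) stop("all SNPs filtered out", call. = FALSE)
  n_i <- n_i[, ok, drop = FALSE]; p_i <- p_i[, ok, drop = FALSE]
  h_i <- h_i[, ok, drop = FALSE]
  nbar <- colMeans(n_i)
  nsum <- colSums(n_i)
  nc <- (nsum - colSums(n_i^2) / nsum) / (r - 1)
  pbar <- colSums(n_i * p_i) / nsum
  s2 <- colSums(n_i * sweep(p_i, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / nsum
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
                                (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  per <- data.frame(site = use[ok],
                    chrom = cohort$sites$chrom[use][ok],
                    pos = cohort$sites$pos[use][ok],
                    a = a, b = b, c = cc,
                    fst = a / (a + b + cc), stringsAsFactors = FALSE)
  structure(list(per_snp = per,
                 fst = sum(a) / sum(a + b + cc),
                 n_snps = sum(ok), groups = levels(grp)),
            class = "fst_result")
}

#' Regression of pairwise FST on elapsed time between collections
#'
#' Ordinary least squares of pairwise FST on the absolute number of days
#' between the two collection dates, after removing any pair involving an
#' excluded collection.  df = number of pairs - 2.
#'
#' @param pairwise_fst data.frame with columns `collection_i`,
#'   `collection_j`, `fst`.
#' @param dates named vector (collection -> date, `Date` or ISO-8601
#'   string).
#' @param exclusions collections to drop from all pairs.
#' @return A list: slope, intercept, r_squared, p_value, df, n_pairs.
#' @export
fst_vs_time_regression <- function(pairwise_fst, dates,
                                   exclusions = character()) {
  keep <- !(pairwise_fst$collection_i %in% exclusions |
              pairwise_fst$collection_j %in% exclusions)
  d <- pairwise_fst[keep, , drop = FALSE]
  if (nrow(d) < 3) stop("fewer than 3 pairs after exclusions", call. = FALSE)
  dt <- abs(as.numeric(as.Date(dates[d$collection_i]) -
                         as.Date(dates[d$collection_j])))
  fit <- lm(d$fst ~ dt)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = unname(pf(s$fstatistic[1], s$fstatistic[2],
                           s$fstatistic[3], lower.tail = FALSE)),
       df = nrow(d) - 2, n_pairs = nrow(d))
}
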