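# haplotype matrix for one chromosome: valid rows only, sites of that
# chromosome.  Missing alleles are tolerated; EHH drops a haplotype once
# it hits one (male second X haplotypes are excluded up front).
chrom_hap <- function(panel, chrom, aa = NULL) {
  on <- which(panel$sites$chrom == chrom)
  on_x <- chrom == panel$x_chrom
  rows <- valid_hap_rows(panel, on_x)
  hap <- panel$hap[rows, on, drop = FALSE]
  list(hap = hap, sites = on, pos = panel$sites$pos[on], rows = rows)
}

#' Extended haplotype homozygosity around a core SNP
#'
#' EHH at a site x is the probability that two randomly chosen carrier
#' haplotypes of the core allele are identical over the interval from the
#' core to x: sum over distinct extended haplotypes h of C(n_h, 2) /
#' C(n_c, 2).  Computed independently per flank; EHH at the core is 1 and
#' each flank is non-increasing outward.
#'
#' @param panel a `haplotype_panel` (complete phased haplotypes; each male
#'   contributes a single X haplotype).
#' @param chrom chromosome id.
#' @param core_pos position of the core SNP.
#' @param core_allele 0 or 1.
#' @return A list of class `ehh_curve`: `positions`, `ehh` (aligned,
#'   including the core with EHH 1), `core_pos`, `carriers`.
#' @export
ehh <- function(panel, chrom, core_pos, core_allele) {
  ch <- chrom_hap(panel, chrom)
  core <- match(core_pos, ch$pos)
  if (is.na(core)) stop("core position is not a SNP", call. = FALSE)
  nc <- carrier_count_cpp(ch$hap, core, core_allele)
  if (nc < 2) stop("fewer than 2 carriers of the core allele", call. = FALSE)
  left <- ehh_flank_cpp(ch$hap, core, core_allele, -1L, 0)
  right <- ehh_flank_cpp(ch$hap, core, core_allele, 1L, 0)
  pos <- c(rev(ch$pos[core - seq_along(left)]), ch$pos[core],
           ch$pos[core + seq_along(right)])
  vals <- c(rev(left), 1, right)
  structure(list(positions = pos, ehh = vals, core_pos = core_pos,
                 core_allele = core_allele, carriers = nc),
            class = "ehh_curve")
}

#' Integrated EHH (iHH) of a curve
#'
#' Trapezoidal integral of EHH against physical position on each flank,
#' truncated before the first SNP at which EHH falls below `cutoff`; the
#' two flank integrals are summed.
#'
#' @param curve an `ehh_curve`.
#' @param cutoff EHH truncation threshold.
#' @return iHH in bp.
#' @export
ihh <- function(curve, cutoff = 0.05) {
  integrate_flank <- function(pos, e) {
    keep <- which(e < cutoff)[1]
    if (!is.na(keep)) { pos <- pos[seq_len(keep - 1)]; e <- e[seq_len(keep - 1)] }
    if (length(pos) < 2) return(0)
    sum((e[-1] + e[-length(e)]) / 2 * abs(diff(pos)))
  }
  at_core <- which(curve$positions == curve$core_pos)
  lp <- rev(curve$positions[seq_len(at_core)])
  le <- rev(curve$ehh[seq_len(at_core)])
  rp <- curve$positions[at_core:length(curve$positions)]
  re <- curve$ehh[at_core:length(curve$ehh)]
  integrate_flank(lp, le) + integrate_flank(rp, re)
}

# iHH for one allele directly from the chromosome haplotype matrix
ihh_at <- function(ch, core, allele, cutoff) {
  nc <- carrier_count_cpp(ch$hap, core, allele)
  if (nc < 2) return(NA_real_)
  area <- 0
  for (dir in c(-1L, 1L)) {
    e <- ehh_flank_cpp(ch$hap, core, allele, dir, cutoff)
    keep <- which(e < cutoff)[1]
    if (!is.na(keep)) e <- e[seq_len(keep - 1)]
    if (!length(e)) next
    idx <- core + dir * seq_len(length(e))
    pos <- c(ch$pos[core], ch$pos[idx])
    ee <- c(1, e)
    area <- area + sum((ee[-1] + ee[-length(ee)]) / 2 * abs(diff(pos)))
  }
  area
}

#' Unstandardized iHS scan
#'
#' For each polarized SNP with minor derived-allele frequency at least
#' `min_maf`, iHS_raw = ln(iHH_ancestral / iHH_derived).  SNPs with an
#' unset or tied ancestral flag, with fewer than 2 carriers of either
#' allele, or with zero iHH on either side are reported missing.
#'
#' @param panel a `haplotype_panel`.
#' @param aa per-site ancestral flags ("ref"/"alt"/NA) aligned with
#'   `panel$sites`; "ref" means allele 0 is ancestral.
#' @param min_maf minimum minor allele frequency.
#' @param cutoff EHH truncation threshold for iHH.
#' @return data.frame of class `score_track`: chrom, pos, freq_derived,
#'   ihs_raw.
#' @export
ihs_scan <- function(panel, aa, min_maf = 0.05, cutoff = 0.05) {
  stopifnot(length(aa) == nrow(panel$sites))
  if (all(is.na(aa))) stop("panel is not polarized", call. = FALSE)
  out <- list()
  for (cn in unique(panel$sites$chrom)) {
    ch <- chrom_hap(panel, cn)
    n_hap <- nrow(ch$hap)
    freq1 <- colMeans(ch$hap, na.rm = TRUE)
    anc_is_ref <- aa[ch$sites]
    res <- data.frame(chrom = cn, pos = ch$pos,
                      freq_derived = NA_real_, ihs_raw = NA_real_,
                      stringsAsFactors = FALSE)
    for (i in seq_along(ch$pos)) {
      fl <- anc_is_ref[i]
      if (is.na(fl)) next
      derived_allele <- if (fl == "ref") 1L else 0L
      p_d <- if (derived_allele == 1L) freq1[i] else 1 - freq1[i]
      res$freq_derived[i] <- p_d
      if (min(p_d, 1 - p_d) < min_maf) next
      ihh_d <- ihh_at(ch, i, derived_allele, cutoff)
      ihh_a <- ihh_at(ch, i, 1L - derived_allele, cutoff)
      if (is.na(ihh_d) || is.na(ihh_a) || ihh_d == 0 || ihh_a == 0) next
      res$ihs_raw[i] <- log(ihh_a / ihh_d)
    }
    out[[cn]] <- res
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  class(res) <- c("score_track", "data.frame")
  res
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Raw scores are binned by derived frequency (bins of `bin_width`); bins
#' with fewer than `min_bin` scored SNPs are merged with their nearest
#' non-empty neighbour.  Within each final bin the mean is subtracted and
#' the SD divided out, so standardized scores have mean 0 and SD 1 per
#' bin by construction.
#'
#' @param track output of [ihs_scan()].
#' @param bin_width frequency bin width.
#' @param min_bin minimum scored SNPs per bin.
#' @return The track with columns `bin`, `ihs_std` (signed) and
#'   `ihs_abs` added.
#' @export
standardize_ihs <- function(track, bin_width = 0.05, min_bin = 10) {
  scored <- which(!is.na(track$ihs_raw))
  if (!length(scored)) stop("no scored SNPs", call. = FALSE)
  edges <- seq(0, 1, by = bin_width)
  bin <- cut(track$freq_derived[scored], edges, include.lowest = TRUE,
             labels = FALSE)
  # merge undersized bins into their nearest occupied neighbour
  repeat {
    tabb <- table(bin)
    sizes <- as.integer(tabb); ids <- as.integer(names(tabb))
    if (length(ids) <= 1 || all(sizes >= min_bin)) break
    small <- ids[which.min(sizes)]
    others <- setdiff(ids, small)
    target <- others[which.min(abs(others - small))]
    bin[bin == small] <- target
  }
  if (length(unique(bin)) == 1 && sd(track$ihs_raw[scored]) == 0) {
    stop("degenerate input: a single bin with zero variance", call. = FALSE)
  }
  z <- rep(NA_real_, length(scored))
  for (b in unique(bin)) {
    at <- bin == b
    mu <- mean(track$ihs_raw[scored][at])
    sdev <- sd(track$ihs_raw[scored][at])
    if (is.na(sdev) || sdev == 0) stop("zero-variance bin", call. = FALSE)
    z[at] <- (track$ihs_raw[scored][at] - mu) / sdev
  }
  track$bin <- NA_integer_; track$bin[scored] <- bin
  track$ihs_std <- NA_real_; track$ihs_std[scored] <- z
  track$ihs_abs <- abs(track$ihs_std)
  track
}

#' Among-population allele-frequency dispersion score (XtX analog)
#'
#' Per SNP: sum over populations of (p_k - pbar)^2 / (pbar (1 - pbar) /
#' n_eff + eps), with the unweighted mean frequency pbar and the harmonic
#' mean n_eff of per-population allele-copy counts.  The score is
#' monotone in among-population dispersion and plays the role a
#' structure-aware differentiation statistic (such as BayPass XtX) plays
#' in outlier scans; it is not a posterior quantity.
#'
#' @param alt populations x SNPs matrix of alternate-allele copy counts.
#' @param copies populations x SNPs matrix of sampled allele copies.
#' @param chrom,pos optional per-SNP coordinates for the returned track.
#' @param eps variance floor.
#' @return data.frame of class `score_track`: chrom, pos, score.
#' @export
differentiation_score <- function(alt, copies, chrom = NULL, pos = NULL,
                                  eps = 1e-6) {
  stopifnot(all(dim(alt) == dim(copies)))
  K <- nrow(alt)
  if (K < 2) stop("need at least 2 populations", call. = FALSE)
  if (any(copies < 1)) stop("each population needs >= 1 genotyped copy",
                            call. = FALSE)
  p <- alt / copies
  pbar <- colMeans(p)
  neff <- K / colSums(1 / copies)
  score <- colSums(sweep(p, 2, pbar)^2) / (pbar * (1 - pbar) / neff + eps)
  score[pbar <= 0 | pbar >= 1] <- NA_real_
  res <- data.frame(chrom = chrom %||% rep("chr?", ncol(alt)),
                    pos = pos %||% seq_len(ncol(alt)),
                    score = score, stringsAsFactors = FALSE)
  class(res) <- c("score_track", "data.frame")
  res
}

# per-population alternate/copies count matrices for a cohort
population_allele_counts <- function(cohort, populations = NULL,
                                     snp_subset = NULL,
                                     females_only = FALSE) {
  pops <- populations %||% unique(cohort$samples$population)
  use <- snp_subset %||% seq_len(ncol(cohort$geno))
  sex <- effective_sex(cohort$samples)
  alt <- copies <- matrix(0, length(pops), length(use),
                          dimnames = list(pops, NULL))
  for (k in seq_along(pops)) {
    rows <- which(cohort$samples$population == pops[k])
    if (females_only) rows <- rows[sex[rows] == "F"]
    ac <- allele_counts(cohort, rows)
    alt[k, ] <- ac$alt[use]; copies[k, ] <- ac$copies[use]
  }
  list(alt = alt, copies = copies,
       chrom = cohort$sites$chrom[use], pos = cohort$sites$pos[use])
}

#' Pseudo-observed-data threshold for the differentiation score
#'
#' Fits a neutral null to the observed counts -- a Beta distribution of
#' ancestral frequencies by moment matching (with the drift and binomial
#' sampling components of the observed frequency variance removed) and a
#' Balding-Nichols drift parameter estimated by a multi-locus
#' variance-components FST on the counts -- then simulates `n_simulated`
#' SNPs under that null with the observed sample sizes and returns the
#' requested quantile of their scores.
#'
#' @param alt,copies observed count matrices (populations x SNPs).
#' @param n_simulated number of pseudo-observed SNPs.
#' @param quantile_level quantile of the simulated score distribution.
#' @param seed RNG seed.
#' @param eps passed to [differentiation_score()].
#' @return A list: `threshold`, `f_hat`, `alpha`, `beta`,
#'   `simulated_scores`.
#' @export
pod_threshold <- function(alt, copies, n_simulated = 10000,
                          quantile_level = 0.999, seed = 1L, eps = 1e-6) {
  if (quantile_level <= 0 || quantile_level >= 1) {
    stop("quantile must be in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  K <- nrow(alt); S <- ncol(alt)
  p <- alt / copies
  pbar <- colMeans(p)
  poly <- pbar > 0 & pbar < 1
  # drift parameter: multi-locus allele-count FST (haploid Weir-Cockerham)
  f_hat <- haploid_fst(alt[, poly, drop = FALSE],
                       copies[, poly, drop = FALSE])
  f_hat <- min(max(f_hat, 0), 0.99)
  # ancestral Beta by moments, removing drift + sampling variance
  m <- mean(pbar[poly])
  v_obs <- var(pbar[poly])
  q <- m * (1 - m)
  sampling <- mean(colSums((p * (1 - p) / pmax(copies - 1, 1))[, poly,
                                                               drop = FALSE]) / K^2)
  v0 <- (v_obs - (f_hat / K) * q - sampling) / max(1 - f_hat / K, 1e-6)
  v0 <- min(max(v0, 1e-6), q * 0.99)
  ab <- q / v0 - 1
  alpha <- m * ab; beta <- (1 - m) * ab
  # simulate with observed per-population sample sizes (columns resampled)
  cols <- sample.int(S, n_simulated, replace = TRUE)
  n_sim <- copies[, cols, drop = FALSE]
  p0 <- rbeta(n_simulated, alpha, beta)
  sim_alt <- matrix(0, K, n_simulated)
  for (k in seq_len(K)) {
    pk <- if (f_hat > 0) {
      rbeta(n_simulated, p0 * (1 - f_hat) / f_hat,
            (1 - p0) * (1 - f_hat) / f_hat)
    } else p0
    sim_alt[k, ] <- rbinom(n_simulated, n_sim[k, ], pk)
  }
  sc <- differentiation_score(sim_alt, n_sim, eps = eps)$score
  sc <- sc[!is.na(sc)]
  list(threshold = unname(quantile(sc, quantile_level)),
       f_hat = f_hat, alpha = alpha, beta = beta,
       simulated_scores = sc)
}

#' Simulate Balding-Nichols allele-count matrices
#'
#' Draws ancestral frequencies from Beta(theta, theta), per-population
#' frequencies from the Balding-Nichols distribution with drift `f`, and
#' binomial allele counts with the given copy numbers.  Used as the null
#' model for POD calibration checks.
#'
#' @param n_pops number of populations.
#' @param n_snps number of SNPs.
#' @param f drift parameter in [0, 1).
#' @param theta ancestral Beta shape.
#' @param copies allele copies sampled per population (scalar or vector).
#' @param seed RNG seed.
#' @return A list with matrices `alt` and `copies` (polymorphic SNPs
#'   only).
#' @export
simulate_bn_counts <- function(n_pops = 3, n_snps = 10000, f = 0.05,
                               theta = 0.8, copies = 100, seed = 1L) {
  set.seed(seed)
  copies <- rep_len(copies, n_pops)
  p0 <- rbeta(n_snps, theta, theta)
  p0 <- pmin(pmax(p0, 1e-4), 1 - 1e-4)
  alt <- matrix(0L, n_pops, n_snps)
  for (k in seq_len(n_pops)) {
    pk <- if (f > 0) {
      rbeta(n_snps, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    } else p0
    alt[k, ] <- rbinom(n_snps, copies[k], pk)
  }
  cp <- matrix(copies, n_pops, n_snps)
  poly <- colSums(alt) > 0 & colSums(alt) < colSums(cp)
  list(alt = alt[, poly, drop = FALSE], copies = cp[, poly, drop = FALSE])
}

# multi-locus FST from allele-copy counts (haploid variance components)
haploid_fst <- function(alt, copies) {
  r <- nrow(alt)
  p <- alt / copies
  nsum <- colSums(copies)
  nbar <- nsum / r
  nc <- (nsum - colSums(copies^2) / nsum) / (r - 1)
  pbar <- colSums(copies * p) / nsum
  s2 <- colSums(copies * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
  ok <- is.finite(a) & is.finite(b)
  sum(a[ok]) / sum((a + b)[ok])
}

#' Intersect top-scoring windows across score tracks
#'
#' Per track, the genome-wide top `top_fraction` of non-missing SNPs are
#' marked (ties at the quantile boundary included).  Sliding windows of
#' `window` bp at `step` bp are flagged for a track when they contain at
#' least one marked SNP; windows flagged in every track form the
#' intersection.
#'
#' @param tracks named list of `score_track` data.frames, each with a
#'   numeric score column (the last column, or a column named `score`).
#' @param chrom_lengths named chromosome lengths.
#' @param window,step window size and step in bp.
#' @param top_fraction fraction of SNPs marked per track.
#' @return A list: `intersection` ([interval_set()], merged),
#'   `window_flags` (data.frame of per-track flags per window).
#' @export
outlier_window_intersection <- function(tracks, chrom_lengths,
                                        window = 1000, step = 500,
                                        top_fraction = 0.01) {
  stopifnot(length(tracks) >= 2)
  marked <- lapply(tracks, function(tr) {
    sc <- if ("score" %in% names(tr)) tr$score else tr[[ncol(tr)]]
    if (all(is.na(sc))) stop("empty track", call. = FALSE)
    thr <- quantile(sc, 1 - top_fraction, na.rm = TRUE)
    tr[!is.na(sc) & sc >= thr, c("chrom", "pos")]
  })
  flags_all <- list()
  for (cn in names(chrom_lengths)) {
    starts <- seq(1, chrom_lengths[[cn]], by = step)
    fl <- matrix(FALSE, length(starts), length(tracks))
    colnames(fl) <- names(tracks) %||% paste0("track", seq_along(tracks))
    for (t in seq_along(tracks)) {
      pos <- marked[[t]]$pos[marked[[t]]$chrom == cn]
      for (p in pos) {
        w1 <- ceiling((p - window) / step) + 1L   # first window covering p
        w2 <- floor((p - 1) / step) + 1L
        w1 <- max(w1, 1L); w2 <- min(w2, length(starts))
        if (w1 <= w2) fl[w1:w2, t] <- TRUE
      }
    }
    flags_all[[cn]] <- data.frame(chrom = cn, start = starts,
                                  end = pmin(starts + window - 1,
                                             chrom_lengths[[cn]]),
                                  fl, stringsAsFactors = FALSE)
  }
  wf <- do.call(rbind, flags_all); rownames(wf) <- NULL
  hit <- rowSums(as.matrix(wf[, -(1:3), drop = FALSE])) == length(tracks)
  iv <- if (any(hit)) {
    merge_intervals(interval_set(wf$chrom[hit], wf$start[hit] - 1L,
                                 wf$end[hit]))
  } else interval_set()
  list(intersection = iv, window_flags = wf)
}
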