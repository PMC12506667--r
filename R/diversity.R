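# shared helpers ------------------------------------------------------------

# tile one chromosome with non-overlapping windows; starts are 0-based
window_grid <- function(len, window) {
  starts <- seq(0, max(len - 1, 0), by = window)
  data.frame(start = as.integer(starts),
             end = as.integer(pmin(starts + window, len)))
}

pop_rows <- function(cohort, population, females_only_on_x = FALSE) {
  rows <- which(cohort$samples$population == population)
  if (!length(rows)) stop("unknown population: ", population, call. = FALSE)
  rows
}

# restrict to assigned females when analysing the X chromosome
restrict_x_rows <- function(cohort, rows, chrom) {
  if (chrom != cohort$x_chrom) return(rows)
  sex <- effective_sex(cohort$samples)
  rows[sex[rows] == "F"]
}

site_counts <- function(cohort, rows, idx) {
  g <- cohort$geno[rows, idx, drop = FALSE]
  pl <- ploidy_matrix(cohort)[rows, idx, drop = FALSE]
  obs <- !is.na(g)
  list(k = colSums(pl * obs), alt = colSums(g, na.rm = TRUE))
}

#' Windowed nucleotide diversity (pi) with invariant-site denominator
#'
#' pi per window is the ratio of summed per-site mismatch pair counts,
#' n_alt * n_ref, to summed per-site pair counts C(k, 2), accumulated over
#' variant sites and callable invariant positions (default: every
#' non-variant position in the window is callable with all sampled copies
#' present, appropriate for synthetic cohorts; real data needs an
#' all-sites VCF or callability mask).  Windows with zero comparisons are
#' reported missing.
#'
#' @param cohort a `cohort`.
#' @param population population label; on the X only assigned females are
#'   used.
#' @param window window size in bp.
#' @param callable_sites optional function(chrom, start, end) returning
#'   the number of callable invariant positions in a window; defaults to
#'   window length minus the number of variant sites.
#' @return data.frame: chrom, start, end, pop, pi, n_comparisons.
#' @export
windowed_pi <- function(cohort, population, window = 5000,
                        callable_sites = NULL) {
  out <- list()
  for (cn in names(cohort$chrom_lengths)) {
    rows <- restrict_x_rows(cohort, pop_rows(cohort, population), cn)
    k_full <- 2L * length(rows)
    wg <- window_grid(cohort$chrom_lengths[[cn]], window)
    on <- which(cohort$sites$chrom == cn)
    wof <- findInterval(cohort$sites$pos[on] - 1, wg$start)
    cnt <- site_counts(cohort, rows, on)
    num_site <- cnt$alt * (cnt$k - cnt$alt)
    den_site <- choose(cnt$k, 2)
    num <- rowsum(num_site, wof, reorder = FALSE)
    den <- rowsum(den_site, wof, reorder = FALSE)
    nvar <- tabulate(wof, nbins = nrow(wg))
    numw <- denw <- numeric(nrow(wg))
    numw[as.integer(rownames(num))] <- num
    denw[as.integer(rownames(den))] <- den
    n_invariant <- if (is.null(callable_sites)) {
      (wg$end - wg$start) - nvar
    } else {
      vapply(seq_len(nrow(wg)), function(i) {
        callable_sites(cn, wg$start[i], wg$end[i])
      }, 0) - 0
    }
    denw <- denw + pmax(n_invariant, 0) * choose(k_full, 2)
    out[[cn]] <- data.frame(chrom = cn, start = wg$start, end = wg$end,
                            pop = population,
                            pi = ifelse(denw > 0, numw / denw, NA_real_),
                            n_comparisons = denw, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out); rownames(res) <- NULL; res
}

#' Windowed absolute divergence (Dxy) between two populations
#'
#' Dxy per window is the summed cross-population mismatch count
#' n_altA * n_refB + n_refA * n_altB over the summed cross-pair count
#' k_A * k_B, over variant and callable invariant sites.
#'
#' @param cohort a `cohort`.
#' @param pop_a,pop_b population labels.
#' @param window window size in bp.
#' @param callable_sites as in [windowed_pi()].
#' @return data.frame: chrom, start, end, pop_a, pop_b, dxy,
#'   n_comparisons.
#' @export
windowed_dxy <- function(cohort, pop_a, pop_b, window = 5000,
                         callable_sites = NULL) {
  out <- list()
  for (cn in names(cohort$chrom_lengths)) {
    ra <- restrict_x_rows(cohort, pop_rows(cohort, pop_a), cn)
    rb <- restrict_x_rows(cohort, pop_rows(cohort, pop_b), cn)
    wg <- window_grid(cohort$chrom_lengths[[cn]], window)
    on <- which(cohort$sites$chrom == cn)
    wof <- findInterval(cohort$sites$pos[on] - 1, wg$start)
    ca <- site_counts(cohort, ra, on); cb <- site_counts(cohort, rb, on)
    num_site <- ca$alt * (cb$k - cb$alt) + (ca$k - ca$alt) * cb$alt
    den_site <- ca$k * cb$k
    num <- rowsum(num_site, wof, reorder = FALSE)
    den <- rowsum(den_site, wof, reorder = FALSE)
    nvar <- tabulate(wof, nbins = nrow(wg))
    numw <- denw <- numeric(nrow(wg))
    numw[as.integer(rownames(num))] <- num
    denw[as.integer(rownames(den))] <- den
    n_invariant <- if (is.null(callable_sites)) {
      (wg$end - wg$start) - nvar
    } else {
      vapply(seq_len(nrow(wg)), function(i) {
        callable_sites(cn, wg$start[i], wg$end[i])
      }, 0)
    }
    denw <- denw + pmax(n_invariant, 0) *
      (2 * length(ra)) * (2 * length(rb))
    out[[cn]] <- data.frame(chrom = cn, start = wg$start, end = wg$end,
                            pop_a = pop_a, pop_b = pop_b,
                            dxy = ifelse(denw > 0, numw / denw, NA_real_),
                            n_comparisons = denw, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out); rownames(res) <- NULL; res
}

#' Tajima's D constants for sample size n (chromosome copies)
#' @param n number of sampled chromosomes (>= 4 recommended).
#' @return Named list a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Windowed Tajima's D from hard genotypes
#'
#' Per window: S = segregating sites, theta_W = S/a1, theta_pi = summed
#' per-site heterozygosity n_alt (k - n_alt) / C(k, 2), and
#' D = (theta_pi - theta_W) / sqrt(e1 S + e2 S (S - 1)), with the
#' constants computed from the window-median non-missing chromosome
#' count.  Windows with S = 0 are reported missing.
#'
#' @param cohort a `cohort`.
#' @param population population label; only females on the X.
#' @param window window size in bp.
#' @return data.frame: chrom, start, end, pop, S, theta_w, theta_pi, D, n.
#' @export
windowed_tajimas_d <- function(cohort, population, window = 5000) {
  out <- list()
  for (cn in names(cohort$chrom_lengths)) {
    rows <- restrict_x_rows(cohort, pop_rows(cohort, population), cn)
    wg <- window_grid(cohort$chrom_lengths[[cn]], window)
    on <- which(cohort$sites$chrom == cn)
    wof <- findInterval(cohort$sites$pos[on] - 1, wg$start)
    cnt <- site_counts(cohort, rows, on)
    seg <- cnt$alt > 0 & cnt$alt < cnt$k & cnt$k >= 2
    pi_site <- ifelse(cnt$k >= 2,
                      cnt$alt * (cnt$k - cnt$alt) / choose(cnt$k, 2), 0)
    res <- data.frame(chrom = cn, start = wg$start, end = wg$end,
                      pop = population, S = 0L, theta_w = NA_real_,
                      theta_pi = NA_real_, D = NA_real_, n = NA_real_,
                      stringsAsFactors = FALSE)
    for (w in unique(wof)) {
      at <- which(wof == w)
      S <- sum(seg[at])
      n_med <- stats::median(cnt$k[at][seg[at]])
      res$S[w] <- S
      res$theta_pi[w] <- sum(pi_site[at][seg[at]])
      if (S > 0 && !is.na(n_med) && n_med >= 4) {
        cst <- tajima_constants(n_med)
        res$theta_w[w] <- S / cst$a1
        res$n[w] <- n_med
        res$D[w] <- (res$theta_pi[w] - res$theta_w[w]) /
          sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
      }
    }
    out[[cn]] <- res
  }
  res <- do.call(rbind, out); rownames(res) <- NULL; res
}

#' Windowed sequencing depth relative to the chromosome mean
#'
#' Per individual, the window mean DP divided by that individual's
#' chromosome mean DP, then averaged over the population's individuals.
#'
#' @param cohort a `cohort` with DP.
#' @param population population label.
#' @param window window size in bp.
#' @return data.frame: chrom, start, end, pop, rel_depth, n_sites.
#' @export
windowed_relative_depth <- function(cohort, population, window = 5000) {
  if (is.null(cohort$dp)) stop("DP required", call. = FALSE)
  out <- list()
  for (cn in names(cohort$chrom_lengths)) {
    rows <- pop_rows(cohort, population)
    wg <- window_grid(cohort$chrom_lengths[[cn]], window)
    on <- which(cohort$sites$chrom == cn)
    wof <- findInterval(cohort$sites$pos[on] - 1, wg$start)
    dp <- cohort$dp[rows, on, drop = FALSE]
    chrom_mean <- rowMeans(dp)
    if (any(chrom_mean == 0)) stop("zero chromosome mean depth",
                                   call. = FALSE)
    ratio <- rep(NA_real_, nrow(wg)); nsite <- tabulate(wof, nrow(wg))
    for (w in unique(wof)) {
      at <- which(wof == w)
      ratio[w] <- mean(rowMeans(dp[, at, drop = FALSE]) / chrom_mean)
    }
    out[[cn]] <- data.frame(chrom = cn, start = wg$start, end = wg$end,
                            pop = population, rel_depth = ratio,
                            n_sites = nsite, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out); rownames(res) <- NULL; res
}
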