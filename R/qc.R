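#' Genotype-level depth filter
#'
#' Individual genotype calls supported by `min_reads - 1` or fewer reads,
#' or by more than `max_reads` reads, are set missing (the defaults keep
#' DP in [7, 100]).  Per-sample missingness is recomputed.
#'
#' @param cohort a `cohort` with a DP matrix.
#' @param min_reads minimum reads for a genotype to be retained.
#' @param max_reads maximum reads for a genotype to be retained.
#' @return The filtered `cohort`.
#' @export
filter_genotypes_by_depth <- function(cohort, min_reads = 7, max_reads = 100) {
  if (is.null(cohort$dp)) stop("cohort has no DP matrix", call. = FALSE)
  bad <- cohort$dp < min_reads | cohort$dp > max_reads
  n_set <- sum(bad & !is.na(cohort$geno))
  cohort$geno[bad] <- NA_integer_
  cohort$samples$missingness <- rowMeans(is.na(cohort$geno))
  cohort$log$genotype_depth <- list(genotypes_set_missing = n_set,
                                    min_reads = min_reads,
                                    max_reads = max_reads)
  cohort
}

drop_sites <- function(cohort, keep) {
  cohort$geno <- cohort$geno[, keep, drop = FALSE]
  if (!is.null(cohort$dp)) cohort$dp <- cohort$dp[, keep, drop = FALSE]
  cohort$sites <- cohort$sites[keep, , drop = FALSE]
  rownames(cohort$sites) <- NULL
  cohort$samples$missingness <- rowMeans(is.na(cohort$geno))
  cohort
}

#' Site-level filters: mean depth, indel proximity, repeat masking
#'
#' Sites are removed when their mean depth across samples is below
#' `min_mean_depth` or above `max_mean_depth` (exact boundary values are
#' retained), when they lie within `indel_margin` bp of an indel-affected
#' position (inclusive of the margin), or when they fall inside the repeat
#' mask.  Mean depth is computed from the DP matrix after any genotype
#' filtering.
#'
#' @param cohort a `cohort`.
#' @param min_mean_depth,max_mean_depth mean-depth bounds.
#' @param indel_positions [interval_set()] of indel-affected positions
#'   (0-based half-open), or `NULL`.
#' @param indel_margin bp margin around indels, inclusive.
#' @param repeat_mask [interval_set()] of repeat regions, or `NULL`.
#' @return The filtered `cohort`; per-rule removal counts in the log.
#' @export
filter_sites <- function(cohort, min_mean_depth = 10, max_mean_depth = 50,
                         indel_positions = NULL, indel_margin = 20,
                         repeat_mask = NULL) {
  if (!is.null(cohort$dp)) {
    md <- colMeans(cohort$dp, na.rm = TRUE)
  } else if (!is.null(cohort$sites$mean_depth)) {
    md <- cohort$sites$mean_depth
  } else {
    stop("no DP to compute site mean depth", call. = FALSE)
  }
  cohort$sites$mean_depth <- md
  bad_depth <- md < min_mean_depth | md > max_mean_depth
  bad_indel <- rep(FALSE, ncol(cohort$geno))
  if (!is.null(indel_positions) && nrow(indel_positions)) {
    grown <- interval_set(indel_positions$chrom,
                          pmax(indel_positions$start - indel_margin, 0),
                          indel_positions$end + indel_margin)
    bad_indel <- positions_in_intervals(cohort$sites$chrom,
                                        cohort$sites$pos,
                                        merge_intervals(grown))
  }
  bad_repeat <- rep(FALSE, ncol(cohort$geno))
  if (!is.null(repeat_mask) && nrow(repeat_mask)) {
    bad_repeat <- positions_in_intervals(cohort$sites$chrom,
                                         cohort$sites$pos, repeat_mask)
    cohort$sites$repeat_masked <- bad_repeat
  }
  keep <- !(bad_depth | bad_indel | bad_repeat)
  cohort <- drop_sites(cohort, keep)
  cohort$log$site_filter <- list(removed_mean_depth = sum(bad_depth),
                                 removed_indel_proximity = sum(bad_indel),
                                 removed_repeat = sum(bad_repeat),
                                 removed_total = sum(!keep))
  cohort
}

#' Individual-level filter on coverage and missingness
#'
#' Removes individuals with mean coverage below `min_mean_coverage` or
#' missingness strictly above `max_missing` (an individual at exactly the
#' maximum is retained).
#'
#' @param cohort a `cohort`.
#' @param min_mean_coverage minimum mean coverage.
#' @param max_missing maximum tolerated missing-genotype fraction.
#' @return The filtered `cohort`; removed individuals and reasons in the
#'   log.
#' @export
filter_individuals <- function(cohort, min_mean_coverage = 7,
                               max_missing = 0.10) {
  cov <- cohort$samples$mean_coverage
  if (is.null(cov)) cov <- rowMeans(cohort$dp, na.rm = TRUE)
  miss <- rowMeans(is.na(cohort$geno))
  low_cov <- cov < min_mean_coverage
  high_miss <- miss > max_missing
  drop <- low_cov | high_miss
  if (all(drop)) stop("all individuals removed", call. = FALSE)
  report <- data.frame(id = cohort$samples$id[drop],
                       reason = ifelse(low_cov[drop], "low_coverage",
                                       "high_missingness"),
                       mean_coverage = cov[drop], missingness = miss[drop],
                       stringsAsFactors = FALSE)
  cohort$geno <- cohort$geno[!drop, , drop = FALSE]
  if (!is.null(cohort$dp)) cohort$dp <- cohort$dp[!drop, , drop = FALSE]
  cohort$samples <- cohort$samples[!drop, , drop = FALSE]
  rownames(cohort$samples) <- NULL
  cohort$samples$missingness <- rowMeans(is.na(cohort$geno))
  cohort$log$individual_filter <- list(removed = report,
                                       n_removed = sum(drop))
  cohort
}

#' Assign genetic sex from the X:autosome depth ratio
#'
#' The per-individual ratio of mean X-chromosome depth to mean autosomal
#' depth is compared to a threshold: ratios above it are female, below it
#' male.  A ratio exactly at the threshold is assigned male with a warning
#' (conservative for X analyses restricted to females).  Discordance with
#' the reported sex is flagged and the coverage-based call is used.
#'
#' @param cohort a `cohort` with DP and a flagged X chromosome.
#' @param ratio_threshold boundary between male and female ratios.
#' @return The `cohort` with `assigned_sex`, `depth_ratio` and
#'   `sex_discordant` columns filled in the sample sheet.
#' @export
assign_sex <- function(cohort, ratio_threshold = 0.8) {
  on_x <- cohort$sites$chrom == cohort$x_chrom
  if (!any(!on_x)) stop("no autosomal sites", call. = FALSE)
  if (!any(on_x)) stop("no X sites", call. = FALSE)
  if (is.null(cohort$dp)) stop("DP required for sex assignment", call. = FALSE)
  rx <- rowMeans(cohort$dp[, on_x, drop = FALSE], na.rm = TRUE)
  ra <- rowMeans(cohort$dp[, !on_x, drop = FALSE], na.rm = TRUE)
  ratio <- rx / ra
  assigned <- ifelse(ratio > ratio_threshold, "F", "M")
  if (any(ratio == ratio_threshold)) {
    warning("X:autosome ratio exactly at threshold; assigned male")
  }
  cohort$samples$assigned_sex <- assigned
  cohort$samples$depth_ratio <- ratio
  cohort$samples$sex_discordant <-
    !is.na(cohort$samples$reported_sex) &
    cohort$samples$reported_sex != assigned
  cohort$log$sex_assignment <- list(
    n_discordant = sum(cohort$samples$sex_discordant))
  cohort
}

#' Polarize sites by a reference population's major allele
#'
#' For each site the ancestral allele is the one with the higher frequency
#' among non-missing allele copies of the reference population.  An exact
#' 50/50 tie keeps the reference allele as ancestral and flags the site;
#' flagged and unset sites are excluded from iHS downstream.
#'
#' @param cohort a `cohort`.
#' @param reference_pop_label population label used as the ancestral proxy.
#' @return The `cohort` with `aa` ("ref"/"alt") and `aa_tie` columns set
#'   in the site table; sites with no reference data keep `aa = NA`.
#' @export
polarize_by_reference_population <- function(cohort,
                                             reference_pop_label = "Africa") {
  rows <- cohort$samples$population == reference_pop_label
  if (!any(rows)) stop("unknown population label: ", reference_pop_label,
                       call. = FALSE)
  ac <- allele_counts(cohort, rows)
  freq_alt <- ifelse(ac$copies > 0, ac$alt / ac$copies, NA_real_)
  aa <- ifelse(is.na(freq_alt), NA_character_,
               ifelse(freq_alt > 0.5, "alt", "ref"))
  cohort$sites$aa <- aa
  cohort$sites$aa_tie <- !is.na(freq_alt) & freq_alt == 0.5
  cohort$log$polarization <- list(reference = reference_pop_label,
                                  n_unset = sum(is.na(aa)),
                                  n_tie = sum(cohort$sites$aa_tie))
  cohort
}

#' Remove sites inside masked regions
#'
#' @param cohort a `cohort`.
#' @param mask an [interval_set()] (0-based half-open).
#' @return The `cohort` without sites inside the mask.
#' @export
mask_regions <- function(cohort, mask) {
  if (is.null(mask) || !nrow(mask)) return(cohort)
  inside <- positions_in_intervals(cohort$sites$chrom, cohort$sites$pos, mask)
  cohort <- drop_sites(cohort, !inside)
  cohort$log$mask <- list(removed = sum(inside))
  cohort
}

#' Per-collection QC attrition summary
#'
#' Sums sequenced and retained individual counts over a collection table
#' and reports the number removed by the coverage/missingness filter.
#'
#' @param collections data.frame with columns `n_sequenced` and
#'   `n_after_filtering` (one row per collection).
#' @return A list with totals `sequenced`, `retained` and `removed`.
#' @export
qc_attrition_summary <- function(collections) {
  stopifnot(all(c("n_sequenced", "n_after_filtering") %in%
                  names(collections)))
  s <- sum(collections$n_sequenced)
  r <- sum(collections$n_after_filtering)
  list(sequenced = s, retained = r, removed = s - r)
}
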