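#' Write a cohort as VCFv4.2 with GT:DP
#'
#' Coordinates are 1-based (VCF convention).  Male X genotypes are written
#' as a single allele.  When `phased_panel` is supplied, genotypes are
#' written phased from the haplotype matrix.
#'
#' @param cohort a `cohort`.
#' @param path output path.
#' @param phased_panel optional `haplotype_panel` aligned to the cohort.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(cohort, path, phased_panel = NULL) {
  n <- nrow(cohort$geno); S <- ncol(cohort$geno)
  sex <- effective_sex(cohort$samples)
  on_x <- cohort$sites$chrom == cohort$x_chrom
  gt <- matrix("", n, S)
  if (is.null(phased_panel)) {
    gt[cohort$geno == 0L] <- "0/0"
    gt[cohort$geno == 1L] <- "0/1"
    gt[cohort$geno == 2L] <- "1/1"
    gt[is.na(cohort$geno)] <- "./."
    if (any(on_x)) {
      mx <- which(sex == "M")
      hap <- cohort$geno[mx, on_x, drop = FALSE]
      sub <- matrix(as.character(hap), length(mx))
      sub[is.na(hap)] <- "."
      gt[mx, on_x] <- sub
    }
  } else {
    h1 <- phased_panel$hap[phased_panel$hap_index == 1L, , drop = FALSE]
    h2 <- phased_panel$hap[phased_panel$hap_index == 2L, , drop = FALSE]
    gt <- matrix(paste0(h1, "|", h2), n, S)
    gt[is.na(h1)] <- ".|."
    single <- !is.na(h1) & is.na(h2)
    gt[single] <- as.character(h1[single])
    gt[is.na(cohort$geno)] <- ifelse(single[is.na(cohort$geno)], ".", ".|.")
  }
  dp <- cohort$dp
  field <- if (is.null(dp)) gt else matrix(paste0(gt, ":", dp), n, S)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>",
                       names(cohort$chrom_lengths),
                       as.integer(cohort$chrom_lengths)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", cohort$samples$id), collapse = "\t"),
             con)
  fmt <- if (is.null(dp)) "GT" else "GT:DP"
  body <- cbind(cohort$sites$chrom, cohort$sites$pos, ".",
                cohort$sites$ref, cohort$sites$alt, ".", "PASS", ".",
                fmt, t(field))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a multi-sample VCF and sample sheet into a cohort
#'
#' Only biallelic SNP records are kept; the number of records dropped for
#' being multiallelic or non-SNP is recorded in the cohort log.  Missing
#' genotypes (`./.` or `.`) become the missing code; haploid genotypes
#' (single allele, as on the male X) are accepted and stored as dosage
#' 0/1.  Parsing is delegated to the vcfR package.
#'
#' @param path VCF path.
#' @param sample_sheet_path TSV with columns id, population, location,
#'   date, reported_sex (additional columns are preserved).
#' @param x_chrom id of the X chromosome; defaults to a contig named
#'   "chrX" if present, else the sheet must be interpretable without one.
#' @return A `cohort`.
#' @export
read_vcf <- function(path, sample_sheet_path, x_chrom = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  sheet <- read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  need <- c("id", "population", "reported_sex")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sheet$id)) stop("duplicate sample ids", call. = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  if (!setequal(vcf_samples, sheet$id)) {
    stop("sample sheet / VCF sample mismatch", call. = FALSE)
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  is_snp <- !is.na(fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_dropped <- sum(!is_snp)
  gt_raw <- vcfR::extract.gt(v, element = "GT")[is_snp, , drop = FALSE]
  has_dp <- any(grepl("DP", v@gt[, "FORMAT"]))
  dp <- NULL
  if (has_dp) {
    dp <- t(vcfR::extract.gt(v, element = "DP",
                             as.numeric = TRUE)[is_snp, , drop = FALSE])
  }
  # dosage: count "1" alleles over "/", "|" or haploid calls
  clean <- gsub("\\|", "/", gt_raw)
  dos <- matrix(NA_integer_, nrow(clean), ncol(clean))
  dos[clean %in% c("0/0", "0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L
  dos[clean %in% c("1")] <- 1L
  geno <- t(dos)
  fix <- fix[is_snp, , drop = FALSE]
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, aa = NA_character_,
                      stringsAsFactors = FALSE)
  # order samples as in the sheet
  ordm <- match(sheet$id, vcf_samples)
  geno <- geno[ordm, , drop = FALSE]
  if (!is.null(dp)) dp <- dp[ordm, , drop = FALSE]
  meta <- v@meta
  contig <- regmatches(meta, regexec(
    "##contig=<ID=([^,>]+),length=([0-9]+)", meta))
  contig <- contig[lengths(contig) == 3]
  chrom_lengths <- if (length(contig)) {
    setNames(as.numeric(vapply(contig, `[`, "", 3)),
             vapply(contig, `[`, "", 2))
  } else {
    tapply(sites$pos, sites$chrom, max)
  }
  if (is.null(x_chrom)) {
    x_chrom <- if ("chrX" %in% names(chrom_lengths)) "chrX" else NA_character_
  }
  if (!"assigned_sex" %in% names(sheet)) sheet$assigned_sex <- NA_character_
  if (!"location" %in% names(sheet)) sheet$location <- sheet$population
  if (!"date" %in% names(sheet)) sheet$date <- NA_character_
  if (!is.null(dp)) {
    sheet$mean_coverage <- rowMeans(dp, na.rm = TRUE)
    sites$mean_depth <- colMeans(dp, na.rm = TRUE)
  }
  sheet$missingness <- rowMeans(is.na(geno))
  co <- new_cohort(geno, dp, sites, sheet, chrom_lengths, x_chrom,
                   log = list(read = list(records_dropped_non_biallelic_snp =
                                            n_dropped)))
  # phased haplotypes, if every genotype call is phased or haploid
  raw <- gt_raw
  if (all(grepl("\\||^[.01]$", raw[!is.na(raw)])) && any(grepl("\\|", raw))) {
    co$panel <- haplotypes_from_phased_gt(raw, co)
  }
  co
}

# build a haplotype_panel from a phased GT character matrix (sites x samples)
haplotypes_from_phased_gt <- function(gt_raw, cohort) {
  gt_raw <- gt_raw[, cohort$samples$id, drop = FALSE]
  n <- ncol(gt_raw); S <- nrow(gt_raw)
  a1 <- substr(gt_raw, 1, 1); a2 <- rep(NA_character_, length(gt_raw))
  dip <- grepl("\\|", gt_raw)
  a2[dip] <- substr(gt_raw[dip], 3, 3)
  to_int <- function(x) { y <- suppressWarnings(as.integer(x)); y }
  h1 <- matrix(to_int(a1), S, n); h2 <- matrix(to_int(a2), S, n)
  hap <- matrix(NA_integer_, 2L * n, S)
  hap[seq(1, 2 * n, 2), ] <- t(h1)
  hap[seq(2, 2 * n, 2), ] <- t(h2)
  structure(list(
    hap = hap, sites = cohort$sites,
    samples = data.frame(id = cohort$samples$id,
                         population = cohort$samples$population,
                         sex = effective_sex(cohort$samples),
                         stringsAsFactors = FALSE),
    hap_sample = rep(seq_len(n), each = 2L), hap_index = rep(1:2, n),
    chrom_lengths = cohort$chrom_lengths, x_chrom = cohort$x_chrom),
    class = "haplotype_panel")
}
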