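# Shared prep for the analysis scripts: read the simulated fixture and
# re-apply the QC / sex-assignment / polarization stages.  Scripts source
# this file; the QC'd cohort (with attached phased panel) is `cohort`.

suppressPackageStartupMessages(library(invadepop))

load_qc_cohort <- function(dir = "results/fixture") {
  co <- read_vcf(file.path(dir, "cohort.vcf"), file.path(dir, "samples.tsv"))
  co <- filter_genotypes_by_depth(co, 7, 100)
  co <- filter_sites(co, 10, 50)
  co <- filter_individuals(co, 7, 0.10)
  co <- assign_sex(co, 0.8)
  polarize_by_reference_population(co, "pop1")
}

qc_panel <- function(co, populations = NULL) {
  # phased haplotypes restricted to QC-surviving sites and individuals
  stopifnot(!is.null(co$panel))
  keep_sites <- paste(co$panel$sites$chrom, co$panel$sites$pos) %in%
    paste(co$sites$chrom, co$sites$pos)
  ids <- co$samples$id
  if (!is.null(populations)) {
    ids <- ids[co$samples$population %in% populations]
  }
  subset_panel(co$panel, keep_sites, ids)
}
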