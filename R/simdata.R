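#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: several populations drifted apart from a shared ancestral
#' allele-frequency distribution (Balding-Nichols model), haplotypes
#' assembled by block-wise copying from a small founder pool so that local
#' linkage disequilibrium exists, one chromosome flagged as the X (haploid
#' in males), Poisson read depth with halved male X coverage, and
#' depth-dependent missingness.
#'
#' @param n_populations number of populations (>= 1).
#' @param samples_per_population diploid individuals per population; scalar
#'   or vector of length `n_populations`.
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param x_chrom name of the chromosome treated as the X.
#' @param snp_density expected SNPs per bp.
#' @param divergence per-population drift parameter F in (0, 1); the
#'   expected multi-locus FST between populations is close to F.  Use 0 for
#'   a panmictic panel.
#' @param founder_theta shape of the symmetric Beta distribution of
#'   ancestral allele frequencies.
#' @param n_founders founder haplotypes per population used by the copying
#'   process.
#' @param block_snps mean copying-block length in SNPs; larger values give
#'   longer-range background LD.
#' @param mean_depth mean sequencing depth per genotype (autosomes,
#'   females); the male X mean is halved.
#' @param extra_missing_rate Bernoulli genotype missingness applied on top
#'   of depth-zero missingness.
#' @param seed integer seed; identical configurations and seeds give
#'   bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 2,
                       samples_per_population = 25,
                       chrom_lengths = c(chr2 = 4e6, chrX = 1e6),
                       x_chrom = "chrX",
                       snp_density = 1e-3,
                       divergence = 0.1,
                       founder_theta = 0.8,
                       n_founders = 30,
                       block_snps = 20,
                       mean_depth = 16,
                       extra_missing_rate = 0.002,
                       seed = 1L) {
  stopifnot_scalar(n_populations, "n_populations", 1)
  if (any(samples_per_population < 1)) stop("samples_per_population >= 1")
  if (divergence < 0 || divergence >= 1) {
    stop("divergence must be in [0, 1)", call. = FALSE)
  }
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be named", call. = FALSE)
  }
  if (sum(names(chrom_lengths) == x_chrom) != 1) {
    stop("exactly one chromosome must be flagged as the X", call. = FALSE)
  }
  cfg <- list(n_populations = as.integer(n_populations),
              samples_per_population =
                rep_len(as.integer(samples_per_population), n_populations),
              chrom_lengths = chrom_lengths, x_chrom = x_chrom,
              snp_density = snp_density, divergence = divergence,
              founder_theta = founder_theta, n_founders = as.integer(n_founders),
              block_snps = block_snps, mean_depth = mean_depth,
              extra_missing_rate = extra_missing_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

new_sim_truth <- function() {
  structure(list(inversions = list(), sweeps = list(),
                 pedigree = data.frame(mother = character(),
                                       father = character(),
                                       child = character(),
                                       stringsAsFactors = FALSE),
                 true_sex = NULL),
            class = "sim_truth")
}

#' Simulate a structured, phased haplotype panel
#'
#' Ancestral allele frequencies are drawn per site from
#' Beta(theta, theta); population frequencies from the Balding-Nichols
#' distribution Beta(p(1-F)/F, (1-p)(1-F)/F).  Within each population a
#' founder pool of haplotypes is drawn site-wise, and sampled haplotypes
#' copy founders in blocks of geometric length, which creates local LD
#' while keeping realized frequencies unbiased.  Males carry a single X
#' haplotype.
#'
#' @param config a [sim_config()].
#' @return A list with elements `panel` (class `haplotype_panel`) and
#'   `truth` (class `sim_truth`).
#' @export
simulate_structured_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pop <- config$n_populations
  n_ind <- sum(config$samples_per_population)
  pops <- paste0("pop", seq_len(n_pop))
  pop_of <- rep(pops, config$samples_per_population)
  ids <- sprintf("%s_i%02d", pop_of, unlist(lapply(
    config$samples_per_population, seq_len)))
  # balanced sexes within each population, deterministic given the seed
  sex <- unlist(lapply(config$samples_per_population, function(n) {
    rep_len(c("F", "M"), n)
  }))
  samples <- data.frame(id = ids, population = pop_of, sex = sex,
                        stringsAsFactors = FALSE)

  site_list <- list(); hap_list <- list()
  for (cn in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[cn]]
    n_snp <- max(1L, round(len * config$snp_density))
    if (n_snp > len) stop("snp_density too high for chromosome ", cn)
    pos <- sort(sample.int(len, n_snp))
    p0 <- rbeta(n_snp, config$founder_theta, config$founder_theta)
    p0 <- pmin(pmax(p0, 1e-4), 1 - 1e-4)
    H <- matrix(NA_integer_, nrow = 2L * n_ind, ncol = n_snp)
    for (k in seq_len(n_pop)) {
      F <- config$divergence
      pk <- if (F > 0) {
        rbeta(n_snp, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
      } else p0
      founders <- matrix(rbinom(config$n_founders * n_snp, 1L,
                                rep(pk, each = config$n_founders)),
                         nrow = config$n_founders)
      in_pop <- which(pop_of == pops[k])
      for (i in in_pop) {
        for (h in 1:2) {
          src <- copy_path(n_snp, config$n_founders, config$block_snps)
          H[2L * (i - 1L) + h, ] <- founders[cbind(src, seq_len(n_snp))]
        }
      }
    }
    if (cn == config$x_chrom) {
      H[2L * which(sex == "M"), ] <- NA_integer_
    }
    ra <- matrix(c("A", "C", "G", "T")[sample.int(4L, 2L * n_snp,
                                                  replace = TRUE)], ncol = 2)
    same <- ra[, 1] == ra[, 2]
    ra[same, 2] <- c("C", "A", "T", "G")[match(ra[same, 1],
                                               c("A", "C", "G", "T"))]
    site_list[[cn]] <- data.frame(chrom = cn, pos = pos,
                                  ref = ra[, 1], alt = ra[, 2],
                                  aa = NA_character_,
                                  stringsAsFactors = FALSE)
    hap_list[[cn]] <- H
  }
  sites <- do.call(rbind, site_list)
  rownames(sites) <- NULL
  hap <- do.call(cbind, hap_list)
  panel <- structure(list(
    hap = hap, sites = sites, samples = samples,
    hap_sample = rep(seq_len(n_ind), each = 2L),
    hap_index = rep(1:2, n_ind),
    chrom_lengths = config$chrom_lengths, x_chrom = config$x_chrom,
    config = config), class = "haplotype_panel")
  truth <- new_sim_truth()
  truth$true_sex <- samples[, c("id", "sex")]
  list(panel = panel, truth = truth)
}

# founder index per site for one copied haplotype: geometric block lengths
copy_path <- function(n_snp, n_founders, block_snps) {
  switches <- runif(n_snp) < 1 / block_snps
  switches[1] <- TRUE
  seg <- cumsum(switches)
  sample.int(n_founders, max(seg), replace = TRUE)[seg]
}

# haplotype rows that are real chromosomes at the given sites (drops the
# absent second male X haplotype)
valid_hap_rows <- function(panel, on_x) {
  if (!on_x) return(seq_len(nrow(panel$hap)))
  male <- panel$samples$sex[panel$hap_sample] == "M"
  which(!(male & panel$hap_index == 2L))
}

#' Inject a polymorphic inversion into a panel
#'
#' Carrier haplotypes inside the region are replaced by draws from a
#' second, internally recombination-free arrangement pool that differs
#' from the standard arrangement at a configurable fraction of region
#' SNPs.  Heterokaryotypes therefore show suppressed recombination and the
#' region acquires block-wise long-range LD in the target populations.
#'
#' @param panel a `haplotype_panel`.
#' @param truth a `sim_truth` to extend.
#' @param chrom,start,end region (1-based inclusive positions bounding the
#'   inverted segment).
#' @param freq arrangement frequency in the target populations.
#' @param arrangement_divergence fraction of region SNPs at which the
#'   inverted arrangement differs from its source haplotype.
#' @param target_pops character vector of population labels to modify.
#' @param pool_size number of distinct haplotypes in the inverted pool.
#' @param pool_mutation per-site mutation rate applied to pool copies
#'   (within-arrangement diversity).
#' @return A list with updated `panel` and `truth`.
#' @export
inject_inversion <- function(panel, truth, chrom, start, end, freq,
                             arrangement_divergence = 0.15,
                             target_pops = unique(panel$samples$population),
                             pool_size = 4, pool_mutation = 0.01) {
  stopifnot(inherits(panel, "haplotype_panel"), freq >= 0, freq <= 1)
  for (iv in truth$inversions) {
    if (iv$chrom == chrom && start <= iv$end && end >= iv$start) {
      stop("region overlaps a previously injected inversion", call. = FALSE)
    }
  }
  idx <- which(panel$sites$chrom == chrom & panel$sites$pos >= start &
                 panel$sites$pos <= end)
  if (!length(idx)) stop("no SNPs in inversion region", call. = FALSE)
  on_x <- chrom == panel$x_chrom
  n_ind <- nrow(panel$samples)
  arr_geno <- rep(0L, n_ind)
  if (freq > 0) {
    in_target <- panel$samples$population %in% target_pops
    # arrangement source: one random target haplotype's current alleles
    cand <- intersect(which(panel$hap_sample %in% which(in_target)),
                      valid_hap_rows(panel, on_x))
    src <- panel$hap[cand[sample.int(length(cand), 1)], idx]
    # arrangement-private alleles: divergent sites are drawn where the
    # standard arrangement is (near-)fixed, so the inverted arrangement
    # carries an allele rare or absent outside it (as new mutations on a
    # non-recombining background would be)
    f1 <- colMeans(panel$hap[cand, idx, drop = FALSE])
    extremeness <- pmax(f1, 1 - f1)
    n_div <- min(max(1L, round(arrangement_divergence * length(idx))),
                 length(idx))
    cut <- sort(extremeness, decreasing = TRUE)[n_div]
    cand_sites <- which(extremeness >= min(cut, 0.95))
    div_at <- if (length(cand_sites) > n_div) {
      sample(cand_sites, n_div)
    } else cand_sites
    template <- src
    template[div_at] <- ifelse(f1[div_at] >= 0.5, 0L, 1L)
    pool <- matrix(rep(template, pool_size), nrow = pool_size, byrow = TRUE)
    mut <- matrix(runif(length(pool)) < pool_mutation, nrow = pool_size)
    pool[mut] <- 1L - pool[mut]
    for (i in which(in_target)) {
      pl <- if (on_x && panel$samples$sex[i] == "M") 1L else 2L
      g <- rbinom(1L, pl, freq)
      arr_geno[i] <- g
      if (g > 0) {
        rows <- 2L * (i - 1L) + seq_len(g)
        for (r in rows) {
          panel$hap[r, idx] <- pool[sample.int(pool_size, 1), ]
        }
      }
    }
  }
  truth$inversions[[length(truth$inversions) + 1]] <-
    list(chrom = chrom, start = start, end = end, freq = freq,
         target_pops = target_pops, arrangement_genotype = arr_geno)
  list(panel = panel, truth = truth)
}

#' Inject a hard selective sweep
#'
#' A derived allele is placed at the core site at the requested frequency
#' in the target populations; every carrier haplotype copies a single
#' template over `core +/- carrier_span/2` and then receives independent
#' residual mutations, producing the long shared haplotype that EHH-based
#' scans detect.  Populations outside `target_pops` carry only the
#' ancestral allele at the core.
#'
#' @param panel,truth as in [inject_inversion()].
#' @param chrom chromosome of the core SNP.
#' @param core_pos position of an existing SNP to use as the sweep core.
#' @param freq derived-allele frequency among target-population haplotypes.
#' @param carrier_span bp width of the shared haplotype.
#' @param residual_mutation_rate per-site probability that a span site of a
#'   carrier haplotype is flipped after copying.
#' @param target_pops population labels receiving the sweep.
#' @return A list with updated `panel` and `truth`.
#' @export
inject_sweep <- function(panel, truth, chrom, core_pos, freq,
                         carrier_span = 5e5, residual_mutation_rate = 0.01,
                         target_pops = unique(panel$samples$population)) {
  stopifnot(freq > 0, freq <= 1)
  core <- which(panel$sites$chrom == chrom & panel$sites$pos == core_pos)
  if (length(core) != 1) stop("core position is not a panel SNP", call. = FALSE)
  if (carrier_span > panel$chrom_lengths[[chrom]]) {
    stop("carrier_span exceeds chromosome length", call. = FALSE)
  }
  span <- which(panel$sites$chrom == chrom &
                  abs(panel$sites$pos - core_pos) <= carrier_span / 2)
  on_x <- chrom == panel$x_chrom
  rows <- valid_hap_rows(panel, on_x)
  in_target <- rows[panel$samples$population[panel$hap_sample[rows]] %in%
                      target_pops]
  # exact carrier count: the derived allele is placed at the given
  # frequency, not at a Bernoulli draw around it
  n_car <- max(1L, round(freq * length(in_target)))
  carriers <- if (n_car >= length(in_target)) in_target else
    in_target[sample.int(length(in_target), n_car)]
  template <- panel$hap[carriers[sample.int(length(carriers), 1)], span]
  template[span == core] <- 1L
  for (r in carriers) {
    h <- template
    mut <- runif(length(span)) < residual_mutation_rate
    mut[span == core] <- FALSE
    h[mut] <- 1L - h[mut]
    panel$hap[r, span] <- h
  }
  non_carrier <- setdiff(rows, carriers)
  panel$hap[non_carrier, core] <- 0L
  truth$sweeps[[length(truth$sweeps) + 1]] <-
    list(chrom = chrom, core_pos = core_pos, freq = freq,
         span_start = core_pos - carrier_span / 2,
         span_end = core_pos + carrier_span / 2,
         carrier_rows = carriers, target_pops = target_pops)
  list(panel = panel, truth = truth)
}

#' Add pedigree offspring to a panel
#'
#' Each offspring receives one recombinant haplotype per parent (Poisson
#' crossovers at `xover_rate` per bp per meiosis).  On the X a son inherits
#' a single maternal recombinant and a daughter inherits a maternal
#' recombinant plus the father's X.  Matings can be chained (children may
#' appear as parents of later rows) to build 2nd- and 3rd-degree pairs.
#'
#' @param panel,truth as in [inject_inversion()].
#' @param matings data.frame with columns mother, father, child, child_sex.
#' @param xover_rate crossovers per bp per meiosis.  The default map is
#'   denser than a physical-scale drosophilid map so that realized
#'   relatedness on the scaled-down fixture genome has roughly the
#'   dispersion of a full-size genome; see the methods vignette.
#' @return A list with updated `panel` and `truth`.
#' @export
generate_pedigree_samples <- function(panel, truth, matings,
                                      xover_rate = 1e-5) {
  for (j in seq_len(nrow(matings))) {
    mo <- matings$mother[j]; fa <- matings$father[j]
    if (mo == fa) stop("self-mating disallowed", call. = FALSE)
    mi <- match(mo, panel$samples$id); fi <- match(fa, panel$samples$id)
    if (is.na(mi) || is.na(fi)) stop("unknown parent id", call. = FALSE)
    if (panel$samples$sex[mi] != "F" || panel$samples$sex[fi] != "M") {
      stop("mother must be F and father M", call. = FALSE)
    }
    child_sex <- matings$child_sex[j]
    h_m <- meiosis(panel, mi, xover_rate)        # maternal gamete, all chroms
    h_f <- meiosis(panel, fi, xover_rate)        # paternal gamete
    on_x <- panel$sites$chrom == panel$x_chrom
    h_f[on_x] <- panel$hap[2L * (fi - 1L) + 1L, on_x]  # father's single X
    if (child_sex == "M") h_f[on_x] <- NA_integer_
    panel$hap <- rbind(panel$hap, h_m, h_f)
    ci <- nrow(panel$samples) + 1L
    panel$samples <- rbind(panel$samples, data.frame(
      id = matings$child[j], population = panel$samples$population[mi],
      sex = child_sex, stringsAsFactors = FALSE))
    panel$hap_sample <- c(panel$hap_sample, ci, ci)
    panel$hap_index <- c(panel$hap_index, 1L, 2L)
    truth$pedigree <- rbind(truth$pedigree, data.frame(
      mother = mo, father = fa, child = matings$child[j],
      stringsAsFactors = FALSE))
    truth$true_sex <- rbind(truth$true_sex, data.frame(
      id = matings$child[j], sex = child_sex, stringsAsFactors = FALSE))
  }
  list(panel = panel, truth = truth)
}

# one gamete: per chromosome, recombine the parent's two haplotypes
meiosis <- function(panel, ind, xover_rate) {
  g <- rep(NA_integer_, ncol(panel$hap))
  for (cn in names(panel$chrom_lengths)) {
    on <- which(panel$sites$chrom == cn)
    if (!length(on)) next
    if (cn == panel$x_chrom && panel$samples$sex[ind] == "M") next
    len <- panel$chrom_lengths[[cn]]
    n_x <- rpois(1, len * xover_rate)
    brk <- sort(runif(n_x, 0, len))
    src <- (findInterval(panel$sites$pos[on], brk) +
              sample.int(2L, 1)) %% 2L + 1L
    g[on] <- panel$hap[cbind(2L * (ind - 1L) + src, on)]
  }
  g
}

#' Attach read depth and produce an unphased cohort
#'
#' Per-genotype depth is Poisson with the configured mean; the male X mean
#' is halved.  Genotypes with DP = 0 are missing, and additional Bernoulli
#' missingness can be layered on.  The phased panel is retained alongside
#' the returned cohort by the caller; the cohort stores unphased dosages.
#'
#' @param panel a `haplotype_panel`.
#' @param mean_depth mean autosomal depth.
#' @param extra_missing_rate extra genotype missingness.
#' @param dates optional named vector of collection dates per population.
#' @return A `cohort` object (genotype dosages, DP, site table, sample
#'   sheet).
#' @export
attach_read_depth <- function(panel, mean_depth = 16,
                              extra_missing_rate = 0.002, dates = NULL) {
  if (mean_depth <= 0) stop("mean_depth must be positive", call. = FALSE)
  n <- nrow(panel$samples); S <- nrow(panel$sites)
  h1 <- panel$hap[panel$hap_index == 1L, , drop = FALSE]
  h2 <- panel$hap[panel$hap_index == 2L, , drop = FALSE]
  geno <- h1 + ifelse(is.na(h2), 0L, h2)   # male X: single copy, dosage 0/1
  mu <- matrix(mean_depth, n, S)
  on_x <- panel$sites$chrom == panel$x_chrom
  male <- panel$samples$sex == "M"
  mu[male, on_x] <- mean_depth / 2
  dp <- matrix(rpois(n * S, as.vector(mu)), n, S)
  geno[dp == 0L] <- NA_integer_
  if (extra_missing_rate > 0) {
    geno[matrix(runif(n * S) < extra_missing_rate, n, S)] <- NA_integer_
  }
  pops <- unique(panel$samples$population)
  if (is.null(dates)) {
    dates <- setNames(as.character(as.Date("2019-07-01") +
                                     30 * (seq_along(pops) - 1)), pops)
  }
  samples <- data.frame(
    id = panel$samples$id, population = panel$samples$population,
    location = panel$samples$population,
    date = unname(dates[panel$samples$population]),
    reported_sex = panel$samples$sex, assigned_sex = NA_character_,
    mean_coverage = rowMeans(dp), missingness = rowMeans(is.na(geno)),
    stringsAsFactors = FALSE)
  sites <- panel$sites
  sites$mean_depth <- colMeans(dp)
  new_cohort(geno, dp, sites, samples, panel$chrom_lengths, panel$x_chrom)
}

new_cohort <- function(geno, dp, sites, samples, chrom_lengths, x_chrom,
                       log = list()) {
  rownames(geno) <- samples$id
  if (!is.null(dp)) rownames(dp) <- samples$id
  structure(list(geno = geno, dp = dp, sites = sites, samples = samples,
                 chrom_lengths = chrom_lengths, x_chrom = x_chrom,
                 log = log), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d individuals x %d sites on %d chromosome(s); X = %s\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$sites$chrom)),
              x$x_chrom))
  invisible(x)
}

#' Write a synthetic cohort and its ground truth to disk
#'
#' Emits a VCFv4.2 file with GT:DP (haploid male X records carry a single
#' allele), a sample sheet TSV, truth BED/TSV files for injected
#' inversions, sweeps and pedigree, and a config echo in YAML.
#'
#' @param cohort a `cohort`.
#' @param truth a `sim_truth` (may be `NULL`).
#' @param out_dir output directory, created if needed.
#' @param phased_panel optional `haplotype_panel`; when given, genotypes
#'   are written phased (`|`) from the panel instead of unphased dosages.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(cohort, truth, out_dir, phased_panel = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "cohort.vcf"),
             samples = file.path(out_dir, "samples.tsv"))
  write_vcf(cohort, paths[["vcf"]], phased_panel = phased_panel)
  write.table(cohort$samples, paths[["samples"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    if (length(truth$inversions)) {
      iv <- do.call(rbind, lapply(truth$inversions, function(v) {
        data.frame(chrom = v$chrom, start = v$start - 1L, end = v$end,
                   stringsAsFactors = FALSE)
      }))
      paths[["inversions"]] <- file.path(out_dir, "truth_inversions.bed")
      write.table(iv, paths[["inversions"]], sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
    if (length(truth$sweeps)) {
      sw <- do.call(rbind, lapply(truth$sweeps, function(v) {
        data.frame(chrom = v$chrom, core_pos = v$core_pos, freq = v$freq,
                   span_start = v$span_start, span_end = v$span_end,
                   stringsAsFactors = FALSE)
      }))
      paths[["sweeps"]] <- file.path(out_dir, "truth_sweeps.tsv")
      write.table(sw, paths[["sweeps"]], sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    if (nrow(truth$pedigree)) {
      paths[["pedigree"]] <- file.path(out_dir, "truth_pedigree.tsv")
      write.table(truth$pedigree, paths[["pedigree"]], sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  invisible(paths)
}
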