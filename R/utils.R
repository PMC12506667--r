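#' @useDynLib invadepop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor lm pf quantile rbeta rbinom rpois runif sd var
#'   median complete.cases coef rnorm setNames
#' @importFrom utils read.delim write.table head tail
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a global seed
#'
#' Stages of the pipeline each consume their own RNG stream so that a rerun
#' of one stage reproduces its output regardless of what ran before.  The
#' stage seed is a stable 31-bit hash of the global seed and the stage name.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed in [0, 2^31).
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(paste0(stage, ":", as.integer(seed)))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Per-genotype ploidy of a cohort
#'
#' Males carry a single allele copy on the X chromosome; all other entries
#' are diploid.  Sex is taken from `assigned_sex` when set, otherwise from
#' `reported_sex`.
#'
#' @param cohort a [cohort] object.
#' @return Integer matrix (individuals x sites) of 1s and 2s.
#' @export
ploidy_matrix <- function(cohort) {
  sex <- effective_sex(cohort$samples)
  on_x <- cohort$sites$chrom == cohort$x_chrom
  pl <- matrix(2L, nrow(cohort$geno), ncol(cohort$geno))
  if (any(on_x) && any(sex == "M")) {
    pl[sex == "M", on_x] <- 1L
  }
  pl
}

effective_sex <- function(samples) {
  sex <- samples$assigned_sex
  if (is.null(sex)) sex <- rep(NA_character_, nrow(samples))
  ifelse(is.na(sex), samples$reported_sex, sex)
}

#' Allele copy counts and alternate-allele counts per site
#'
#' @param cohort a [cohort] object.
#' @param rows optional integer/logical row subset (individuals).
#' @return A list with vectors `copies` (non-missing allele copies) and
#'   `alt` (alternate-allele copies) per site.
#' @export
allele_counts <- function(cohort, rows = NULL) {
  g <- cohort$geno
  pl <- ploidy_matrix(cohort)
  if (!is.null(rows)) {
    g <- g[rows, , drop = FALSE]
    pl <- pl[rows, , drop = FALSE]
  }
  obs <- !is.na(g)
  list(
    copies = colSums(pl * obs),
    alt = colSums(g, na.rm = TRUE)
  )
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a scalar in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
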