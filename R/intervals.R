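#' Genomic interval sets (BED semantics)
#'
#' Intervals are stored 0-based half-open, mirroring BED.  All pipeline
#' masks (repeats, indel neighbourhoods, called inversion regions) use this
#' representation; VCF positions are 1-based and converted at the boundary.
#'
#' @param chrom character vector of chromosome ids.
#' @param start,end integer vectors, 0-based half-open.
#' @return A data.frame of class `interval_set`, sorted by chrom and start.
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer()) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(start) && (any(start < 0) || any(end < start))) {
    stop("intervals must satisfy 0 <= start <= end", call. = FALSE)
  }
  iv <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
  rownames(iv) <- NULL
  class(iv) <- c("interval_set", "data.frame")
  iv
}

#' Test 1-based positions for membership in an interval set
#'
#' A position p (1-based, VCF convention) lies in interval [start, end)
#' iff start <= p - 1 < end.
#'
#' @param chrom,pos equal-length vectors of chromosome and 1-based position.
#' @param intervals an [interval_set()].
#' @return Logical vector.
#' @export
positions_in_intervals <- function(chrom, pos, intervals) {
  hit <- logical(length(pos))
  if (!nrow(intervals)) return(hit)
  p0 <- pos - 1L
  for (cn in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == cn, , drop = FALSE]
    on <- which(chrom == cn)
    if (!length(on)) next
    # findInterval over interleaved breakpoints: odd slot => inside
    brk <- as.vector(rbind(iv$start, iv$end))
    slot <- findInterval(p0[on], brk)
    hit[on] <- slot %% 2L == 1L
  }
  hit
}

#' Merge overlapping or bookended intervals
#' @param intervals an [interval_set()].
#' @return A merged [interval_set()].
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) < 2) return(intervals)
  out <- list()
  for (cn in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == cn, , drop = FALSE]
    s <- iv$start[1]; e <- iv$end[1]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start[i] <= e) e <- max(e, iv$end[i])
      else { out[[length(out) + 1]] <- c(cn, s, e); s <- iv$start[i]; e <- iv$end[i] }
    }
    out[[length(out) + 1]] <- c(cn, s, e)
  }
  m <- do.call(rbind, out)
  interval_set(m[, 1], as.integer(m[, 2]), as.integer(m[, 3]))
}

#' Read / write BED files
#' @param path file path.
#' @return `read_bed` returns an [interval_set()].
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) return(interval_set())
  b <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  interval_set(b[[1]], b[[2]], b[[3]])
}

#' @rdname read_bed
#' @param intervals an [interval_set()].
#' @export
write_bed <- function(intervals, path) {
  df <- as.data.frame(intervals)[, c("chrom", "start", "end")]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Total overlap (bp) between two interval sets
#' @param a,b [interval_set()] objects.
#' @return Numeric, total overlapping base pairs.
#' @export
interval_overlap_bp <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a))) {
    bb <- b[b$chrom == a$chrom[i], , drop = FALSE]
    if (!nrow(bb)) next
    ov <- pmin(bb$end, a$end[i]) - pmax(bb$start, a$start[i])
    tot <- tot + sum(pmax(ov, 0))
  }
  tot
}
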