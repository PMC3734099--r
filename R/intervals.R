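# Shared interval helpers. Internal convention everywhere: 1-based, fully
# closed intervals; a single interval must satisfy start < end (size > 0),
# and overlap arithmetic uses closed lengths (end - start + 1).

# strip a leading "chr" so "chr2" and "2" compare equal
norm_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  sub("^chr", "", chrom, ignore.case = TRUE)
}

warn_sex_chroms <- function(chrom) {
  sex <- unique(chrom[chrom %in% c("X", "Y", "x", "y")])
  if (length(sex) > 0) {
    warning("sex chromosome(s) ", paste(sex, collapse = ", "),
            " present: carrier-frequency handling does not model ",
            "hemizygosity", call. = FALSE)
  }
  invisible(chrom)
}

# IRanges view of a (start, end) closed-interval data frame
as_iranges <- function(df) {
  IRanges::IRanges(start = df$start, end = df$end)
}

#' Reciprocal overlap of two closed genomic intervals
#'
#' The standard CNV-equivalence measure: the length of the intersection
#' divided by the length of each interval, taking the minimum of the two
#' fractions. Lengths are closed-interval lengths (`end - start + 1`).
#' Intervals on different chromosomes (when chromosomes are supplied) and
#' disjoint intervals score 0.
#'
#' @param start1,end1,start2,end2 Numeric vectors of interval bounds
#'   (1-based, closed); recycled to a common length.
#' @param chrom1,chrom2 Optional chromosome names; when both are given,
#'   pairs on different chromosomes return 0.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' reciprocal_overlap(100, 199, 100, 199)  # identical -> 1
#' reciprocal_overlap(1, 100, 51, 200)     # min(50/100, 50/150) on closed lengths
#' @export
reciprocal_overlap <- function(start1, end1, start2, end2,
                               chrom1 = NULL, chrom2 = NULL) {
  n <- max(length(start1), length(start2))
  start1 <- rep_len(as.numeric(start1), n); end1 <- rep_len(as.numeric(end1), n)
  start2 <- rep_len(as.numeric(start2), n); end2 <- rep_len(as.numeric(end2), n)
  ov <- pmin(end1, end2) - pmax(start1, start2) + 1
  ov <- pmax(ov, 0)
  ro <- pmin(ov / (end1 - start1 + 1), ov / (end2 - start2 + 1))
  if (!is.null(chrom1) && !is.null(chrom2)) {
    same <- rep_len(norm_chrom(chrom1), n) == rep_len(norm_chrom(chrom2), n)
    ro[!same] <- 0
  }
  ro
}

# closed-interval gap between two intervals on one chromosome:
# 0 if they share >= 1 bp, else number of bases strictly between them
interval_gap <- function(start1, end1, start2, end2) {
  gap <- pmax(pmax(start1, start2) - pmin(end1, end2) - 1, 0)
  ov <- pmin(end1, end2) - pmax(start1, start2) + 1
  gap[ov > 0] <- 0
  gap
}

# fraction of [start, end] covered by the union of track intervals on the
# same chromosome (union sweep via IRanges::reduce, no double counting)
coverage_fraction <- function(chrom, start, end, track) {
  ti <- track_intervals(track)
  ti <- ti[norm_chrom(ti$chrom) == norm_chrom(chrom), , drop = FALSE]
  if (nrow(ti) == 0) return(0)
  red <- IRanges::reduce(as_iranges(ti))
  span <- IRanges::IRanges(start = start, end = end)
  hit <- IRanges::intersect(red, span)
  sum(IRanges::width(hit)) / IRanges::width(span)
}
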