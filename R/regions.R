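# Candidate-region discovery: single-linkage overlap clustering of case
# calls, merging of nearby clusters into loci, and the region-level
# screen filters (recurrence, control absence, common-variant overlap,
# repeat fraction). Regions travel as a `region_set`: the per-region
# summary table, the member calls (with their overlap-cluster id), and an
# audit trail recording every filter decision.

# deterministic chromosome ordering: numeric chromosomes first in numeric
# order, then others lexicographically
chrom_sort_key <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  key <- ifelse(is.na(num), Inf, num)
  list(key, as.character(chrom))
}

order_by_chrom <- function(chrom, ...) {
  k <- chrom_sort_key(chrom)
  order(k[[1]], k[[2]], ...)
}

#' Cluster case CNV calls by single-linkage interval overlap
#'
#' Per chromosome, calls sharing at least 1 bp are linked and the
#' connected components form clusters (so a chain a-b, b-c places a and c
#' in one cluster even if they do not touch). Copy-number type is ignored
#' at this stage: losses and gains at one position belong to one cluster.
#' Cluster identifiers are assigned in (chromosome, leftmost start)
#' order.
#'
#' @param calls Call-set data frame.
#' @return `calls` with a `cluster_id` column appended, ordered by
#'   (chromosome, start, end, sample).
#' @export
overlap_clusters <- function(calls) {
  if (nrow(calls) == 0) {
    out <- calls
    out$cluster_id <- character()
    return(out)
  }
  chrom <- norm_chrom(calls$chrom)
  ord <- order_by_chrom(chrom, calls$start, calls$end, calls$sample_id)
  calls <- calls[ord, , drop = FALSE]
  chrom <- chrom[ord]
  cluster <- integer(nrow(calls))
  next_id <- 0L
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    # sorted by start: a new component starts when the next interval
    # begins beyond the running maximum end (closed intervals: > max_end)
    max_end <- -Inf
    for (i in idx) {
      if (calls$start[i] > max_end) next_id <- next_id + 1L
      cluster[i] <- next_id
      max_end <- max(max_end, calls$end[i])
    }
  }
  calls$cluster_id <- sprintf("c%04d", cluster)
  rownames(calls) <- NULL
  calls
}

# assemble the per-region summary table from member calls carrying a
# region_id (and cluster_id) column
build_region_table <- function(members) {
  if (nrow(members) == 0) {
    return(data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_members = integer(), n_distinct_cases = integer(),
                      n_clusters = integer(),
                      n_recurrent_clusters = integer()))
  }
  sp <- split(members, members$region_id)
  rows <- lapply(sp, function(m) {
    cl <- split(m$sample_id, m$cluster_id)
    data.frame(region_id = m$region_id[1], chrom = m$chrom[1],
               start = min(m$start), end = max(m$end),
               n_members = nrow(m),
               n_distinct_cases = length(unique(m$sample_id)),
               n_clusters = length(cl),
               n_recurrent_clusters = sum(vapply(cl, function(s)
                 length(unique(s)) >= 2, logical(1))))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order_by_chrom(tab$chrom, tab$start, tab$end), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

new_region_set <- function(members, trail = empty_trail()) {
  structure(list(regions = build_region_table(members),
                 members = members, trail = trail),
            class = "region_set")
}

empty_trail <- function() {
  data.frame(filter = character(), region_id = character(),
             statistic = character(), value = numeric(),
             threshold = numeric(), pass = logical())
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set>", nrow(x$regions), "region(s),",
      nrow(x$members), "member call(s)\n")
  if (nrow(x$regions) > 0) print(head(x$regions, 10))
  invisible(x)
}

#' Promote overlap clusters to candidate regions
#'
#' Wraps each overlap cluster from [overlap_clusters()] as a candidate
#' region (one region per cluster) so the region-level filters can run
#' before clusters are merged into loci.
#'
#' @param clustered Output of [overlap_clusters()].
#' @return A `region_set`.
#' @export
cluster_regions <- function(clustered) {
  if (!"cluster_id" %in% names(clustered)) clustered <- overlap_clusters(clustered)
  members <- clustered
  # region ids in (chrom, start) order of the cluster spans
  if (nrow(members) > 0) {
    spans <- do.call(rbind, lapply(split(members, members$cluster_id),
                                   function(m) data.frame(
                                     cluster_id = m$cluster_id[1],
                                     chrom = m$chrom[1], start = min(m$start),
                                     end = max(m$end))))
    spans <- spans[order_by_chrom(spans$chrom, spans$start, spans$end), ]
    spans$region_id <- sprintf("R%04d", seq_len(nrow(spans)))
    members$region_id <- spans$region_id[match(members$cluster_id,
                                               spans$cluster_id)]
  } else {
    members$region_id <- character()
  }
  new_region_set(members)
}

#' Merge nearby clusters into loci
#'
#' Single-linkage merge of candidate regions on one chromosome whose
#' spans are separated by at most `locus_merge_gap` bases (overlapping
#' spans always merge; `locus_merge_gap = 0` merges only
#' touching/overlapping spans, a no-op beyond overlap clustering). Each
#' merged locus keeps the partition of its members into the original
#' overlap clusters (`cluster_id`), and the summary table reports both
#' the number of sub-clusters and the number of *recurrent* sub-clusters
#' (those carried by two or more distinct samples).
#'
#' @param regions A `region_set` (or the output of [overlap_clusters()]).
#' @param locus_merge_gap Maximum span gap in bp, default 1e6.
#' @return A `region_set` of merged loci with identifiers `L01`, `L02`,
#'   ... in (chromosome, start) order; the filter trail is carried over.
#' @export
merge_loci <- function(regions, locus_merge_gap = 1e6) {
  stopifnot(locus_merge_gap >= 0)
  if (!inherits(regions, "region_set")) regions <- cluster_regions(regions)
  members <- regions$members
  if (nrow(members) == 0) return(new_region_set(members, regions$trail))
  spans <- regions$regions
  ord <- order_by_chrom(spans$chrom, spans$start, spans$end)
  spans <- spans[ord, , drop = FALSE]
  locus <- integer(nrow(spans))
  next_id <- 0L
  for (chr in unique(spans$chrom)) {
    idx <- which(spans$chrom == chr)
    max_end <- -Inf
    for (i in idx) {
      gap <- spans$start[i] - max_end - 1
      if (!is.finite(max_end) || gap > locus_merge_gap) next_id <- next_id + 1L
      locus[i] <- next_id
      max_end <- max(max_end, spans$end[i])
    }
  }
  n_loci <- next_id
  width <- if (n_loci >= 100) 3 else 2
  locus_id <- sprintf(paste0("L%0", width, "d"), locus)
  members$region_id <- locus_id[match(members$region_id, spans$region_id)]
  new_region_set(members, regions$trail)
}

# internal: drop regions, recording one trail row per region
apply_region_filter <- function(rs, filter, value, threshold, pass) {
  if (nrow(rs$regions) == 0) return(rs)
  trail <- rbind(rs$trail, data.frame(
    filter = filter, region_id = rs$regions$region_id,
    statistic = filter, value = value, threshold = threshold, pass = pass))
  keep_ids <- rs$regions$region_id[pass]
  members <- rs$members[rs$members$region_id %in% keep_ids, , drop = FALSE]
  rownames(members) <- NULL
  new_region_set(members, trail)
}

#' Recurrence filter: two or more unrelated cases
#'
#' Retains regions carried by at least `min_cases` distinct *unrelated*
#' case samples. Relatedness is defined by `family_id` where present
#' (calls without one count as their own family), so two affected members
#' of one family support a region only once.
#'
#' @param rs A `region_set`.
#' @param min_cases Minimum number of unrelated case carriers, default 2.
#' @param pedigree Optional pedigree (unused for relatedness, which is
#'   carried by `family_id` on the calls; accepted for interface
#'   symmetry with [determine_inheritance()]).
#' @return Filtered `region_set`.
#' @export
recurrence_filter <- function(rs, min_cases = 2, pedigree = NULL) {
  stopifnot(min_cases >= 1)
  fam <- function(m) {
    f <- m$family_id
    ifelse(is.na(f) | !nzchar(f), m$sample_id, f)
  }
  value <- vapply(rs$regions$region_id, function(id) {
    m <- rs$members[rs$members$region_id == id, , drop = FALSE]
    length(unique(fam(m)))
  }, numeric(1))
  apply_region_filter(rs, "recurrence", value, min_cases,
                      value >= min_cases)
}

#' Control-absence filter
#'
#' Removes regions in which more than `max_control_carriers` distinct
#' control samples carry a CNV matching any member call. The default
#' (`max_control_carriers = 0`) implements strict absence from controls.
#' Matching is any-overlap (at least 1 bp) with the same copy-number type
#' by default; set `match = "ro"` for reciprocal-overlap matching.
#'
#' @param rs A `region_set`.
#' @param control_calls Control call-set data frame.
#' @param max_control_carriers Maximum tolerated control carriers,
#'   default 0.
#' @param same_type Require the control call to match the member call's
#'   type? Default `TRUE`.
#' @param match `"any"` (1 bp overlap) or `"ro"` (reciprocal overlap at
#'   `ro_threshold`).
#' @param ro_threshold Reciprocal-overlap threshold used when
#'   `match = "ro"`.
#' @return Filtered `region_set`.
#' @export
control_absence_filter <- function(rs, control_calls,
                                   max_control_carriers = 0,
                                   same_type = TRUE,
                                   match = c("any", "ro"),
                                   ro_threshold = 0.5) {
  match <- match.arg(match)
  value <- vapply(rs$regions$region_id, function(id) {
    m <- rs$members[rs$members$region_id == id, , drop = FALSE]
    carriers <- character()
    cc <- control_calls[norm_chrom(control_calls$chrom) ==
                          norm_chrom(m$chrom[1]), , drop = FALSE]
    if (nrow(cc) == 0) return(0)
    for (i in seq_len(nrow(m))) {
      cand <- cc
      if (same_type) cand <- cand[cand$cnv_type == m$cnv_type[i], ,
                                  drop = FALSE]
      if (nrow(cand) == 0) next
      if (match == "any") {
        hit <- cand$start <= m$end[i] & cand$end >= m$start[i]
      } else {
        hit <- reciprocal_overlap(m$start[i], m$end[i], cand$start,
                                  cand$end) >= ro_threshold
      }
      carriers <- c(carriers, cand$sample_id[hit])
    }
    length(unique(carriers))
  }, numeric(1))
  apply_region_filter(rs, "control_absence", value, max_control_carriers,
                      value <= max_control_carriers)
}

#' Common-variant (DGV-style) overlap filter
#'
#' Removes regions whose merged span is covered by intervals of the
#' common-variant track over a fraction at or above `dgv_max_overlap`
#' (coverage is computed on the union of track intervals, with no double
#' counting). A region lying entirely inside a catalogued common variant
#' is eliminated as non-disease-specific.
#'
#' @param rs A `region_set`.
#' @param common_variant_track An `evidence_track` (or interval data
#'   frame) of catalogued common variants.
#' @param dgv_max_overlap Coverage fraction at or above which a region is
#'   removed, default 0.5.
#' @return Filtered `region_set`.
#' @export
dgv_filter <- function(rs, common_variant_track, dgv_max_overlap = 0.5) {
  stopifnot(dgv_max_overlap >= 0, dgv_max_overlap <= 1)
  value <- vapply(seq_len(nrow(rs$regions)), function(i) {
    coverage_fraction(rs$regions$chrom[i], rs$regions$start[i],
                      rs$regions$end[i], common_variant_track)
  }, numeric(1))
  apply_region_filter(rs, "common_variant", value, dgv_max_overlap,
                      value < dgv_max_overlap)
}

#' Repeat-fraction filter
#'
#' Removes regions whose merged span is masked as repetitive over a
#' fraction strictly greater than `repeat_max_fraction` (default 0.8, so
#' a region exactly 80% masked is retained). The measured masked
#' fraction is recorded in the filter trail.
#'
#' @param rs A `region_set`.
#' @param repeat_track An `evidence_track` (or interval data frame) of
#'   repeat-masked intervals.
#' @param repeat_max_fraction Masked fraction above which a region is
#'   removed (strict inequality), default 0.8.
#' @return Filtered `region_set`.
#' @export
repeat_filter <- function(rs, repeat_track, repeat_max_fraction = 0.8) {
  stopifnot(repeat_max_fraction >= 0, repeat_max_fraction <= 1)
  value <- vapply(seq_len(nrow(rs$regions)), function(i) {
    coverage_fraction(rs$regions$chrom[i], rs$regions$start[i],
                      rs$regions$end[i], repeat_track)
  }, numeric(1))
  apply_region_filter(rs, "repeat_fraction", value, repeat_max_fraction,
                      value <= repeat_max_fraction)
}
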