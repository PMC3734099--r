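# Locus annotation: nearest gene and distance, candidate-gene status,
# evidence-track overlap, mechanism bin, and trio-based inheritance.

# closed-interval gap from one interval to each gene on its chromosome
gene_gaps <- function(chrom, start, end, genes) {
  g <- genes[norm_chrom(genes$chrom) == norm_chrom(chrom), , drop = FALSE]
  if (nrow(g) == 0) return(NULL)
  g$gap <- interval_gap(start, end, g$start, g$end)
  g
}

#' Nearest gene and distance for a candidate region
#'
#' The nearest gene minimizes the gap between its transcript span and the
#' region's merged span (gap 0 when abutting; intergenic regions cannot
#' overlap a gene). Ties are broken toward the gene with the smaller
#' start coordinate. Two distances are reported: `nearest_distance_bp`,
#' the minimal gap from the merged span, and `furthest_distance_bp`, the
#' largest gap from any individual member CNV to that same gene (for a
#' single-member region the two coincide).
#'
#' @param region One row of a `region_set` summary table (list or
#'   single-row data frame with `chrom`, `start`, `end`).
#' @param genes Gene-model data frame.
#' @param members Optional member calls of the region (for the furthest
#'   distance); when omitted, the merged span is used for both.
#' @return A list with `gene_id`, `nearest_distance_bp`,
#'   `furthest_distance_bp`, `direction` (`"upstream"`, `"downstream"`,
#'   `"flanking_both"` relative to the gene's strand) and `status`
#'   (`"ok"` or `"none"` when the chromosome has no gene).
#' @export
nearest_gene_distance <- function(region, genes, members = NULL) {
  g <- gene_gaps(region$chrom, region$start, region$end, genes)
  if (is.null(g)) {
    return(list(gene_id = NA_character_, nearest_distance_bp = NA_real_,
                furthest_distance_bp = NA_real_, direction = NA_character_,
                status = "none"))
  }
  g <- g[order(g$gap, g$start), , drop = FALSE]
  best <- g[1, ]
  if (is.null(members) || nrow(members) == 0) {
    members <- data.frame(start = region$start, end = region$end)
  }
  per_member <- interval_gap(members$start, members$end, best$start, best$end)
  # side of each member relative to the gene, oriented by strand
  left <- members$end < best$start
  right <- members$start > best$end
  side <- if (any(left) && any(right)) "both" else if (any(right))
    "after" else "before"
  strand <- if (!is.null(best$strand)) best$strand else "+"
  direction <- switch(side,
    both = "flanking_both",
    # members before the gene start are upstream of a + gene
    before = if (strand == "-") "downstream" else "upstream",
    after = if (strand == "-") "upstream" else "downstream")
  list(gene_id = best$gene_id,
       nearest_distance_bp = best$gap,
       furthest_distance_bp = max(per_member),
       direction = direction, status = "ok")
}

#' Flag loci near known or candidate risk genes
#'
#' A locus is flagged when its nearest gene, or any gene within `window`
#' bases of the merged span, is on the candidate-gene list.
#'
#' @param annotation Locus-annotation data frame (from
#'   [annotate_regions()]), with columns `region_id`, `chrom`, `start`,
#'   `end`, `nearest_gene`.
#' @param genes Gene-model data frame.
#' @param candidate_list Character vector of candidate gene identifiers
#'   (default: the packaged list, [read_candidate_genes()]).
#' @param window Search window in bp around the merged span, default 1e6.
#' @return `annotation` with a logical `is_candidate_gene` column set.
#' @export
flag_candidate_genes <- function(annotation, genes,
                                 candidate_list = read_candidate_genes(),
                                 window = 1e6) {
  flag <- vapply(seq_len(nrow(annotation)), function(i) {
    if (annotation$nearest_gene[i] %in% candidate_list) return(TRUE)
    g <- gene_gaps(annotation$chrom[i], annotation$start[i],
                   annotation$end[i], genes)
    if (is.null(g)) return(FALSE)
    any(g$gene_id[g$gap <= window] %in% candidate_list)
  }, logical(1))
  annotation$is_candidate_gene <- flag
  annotation
}

#' Evidence-track overlap labels for a region
#'
#' @param region List or single-row data frame with `chrom`, `start`,
#'   `end`.
#' @param tracks List of `evidence_track` objects (may be empty).
#' @return Character vector of the names of every track with at least
#'   1 bp of overlap with the region span.
#' @export
evidence_overlap <- function(region, tracks) {
  labs <- character()
  for (tr in tracks) {
    ti <- track_intervals(tr)
    ti <- ti[norm_chrom(ti$chrom) == norm_chrom(region$chrom), ,
             drop = FALSE]
    if (nrow(ti) == 0) next
    if (any(ti$start <= region$end & ti$end >= region$start)) {
      labs <- c(labs, tr$name)
    }
  }
  unique(labs)
}

#' Assign mechanism bins to a region
#'
#' A transparent rule set for the three hypothesized modes of action of
#' an intergenic CNV, applied to the region's evidence overlaps and
#' nearest-gene geometry (ambiguity yields compound bins such as
#' `"i or ii"` rather than a forced choice):
#'
#' * `iii` - an expressed-sequence interval overlaps the region *and*
#'   reaches to within `gene_link_gap` of the nearest gene's span: the
#'   signature of an uncharacterized extended isoform of that gene being
#'   disrupted;
#' * `ii` - expressed-sequence or conserved-element evidence overlaps the
#'   region without being linked to the nearest gene: a possible
#'   undiscovered gene or non-coding RNA inside the region;
#' * `i` - whenever a nearest gene exists: perturbation of regulatory
#'   elements of a nearby gene can never be excluded for an intergenic
#'   CNV.
#'
#' @param region List or single-row data frame with `chrom`, `start`,
#'   `end`.
#' @param nearest List from [nearest_gene_distance()] for this region.
#' @param genes Gene-model data frame (to locate the nearest gene span).
#' @param tracks List of `evidence_track` objects.
#' @param gene_link_gap Maximum gap (bp) between an expressed-sequence
#'   interval and the nearest gene's span for the interval to count as
#'   gene-linked, default 1e6.
#' @return Character vector of bins, a non-empty subset of
#'   `c("i", "ii", "iii")` whenever a nearest gene exists.
#' @export
assign_bin <- function(region, nearest, genes, tracks,
                       gene_link_gap = 1e6) {
  bins <- character()
  if (!is.null(nearest$status) && nearest$status == "ok") bins <- "i"
  gene <- genes[genes$gene_id %in% nearest$gene_id &
                  norm_chrom(genes$chrom) == norm_chrom(region$chrom), ,
                drop = FALSE]
  for (tr in tracks) {
    if (!tr$name %in% c("expressed_sequence", "conserved_element")) next
    ti <- track_intervals(tr)
    ti <- ti[norm_chrom(ti$chrom) == norm_chrom(region$chrom), ,
             drop = FALSE]
    if (nrow(ti) == 0) next
    ov <- ti[ti$start <= region$end & ti$end >= region$start, ,
             drop = FALSE]
    if (nrow(ov) == 0) next
    linked <- rep(FALSE, nrow(ov))
    if (tr$name == "expressed_sequence" && nrow(gene) == 1) {
      linked <- interval_gap(ov$start, ov$end, gene$start, gene$end) <=
        gene_link_gap
    }
    if (tr$name == "expressed_sequence" && any(linked)) bins <- c(bins, "iii")
    if (any(!linked)) bins <- c(bins, "ii")
  }
  sort(unique(bins))
}

format_bins <- function(bins) paste(bins, collapse = " or ")

#' Determine mode of inheritance of proband CNVs
#'
#' For each proband call, looks for a parental call of the same
#' copy-number type with reciprocal overlap at or above `ro_threshold`.
#' The mother is checked first, then the father; a match in both parents
#' is reported as maternal with `both_parents = TRUE`. A call matching
#' neither parent is `de_novo` only when both parents have call data;
#' with any parent missing from the pedigree the status is `unknown`.
#'
#' @param proband_calls Call-set data frame of proband (case) calls.
#' @param parent_calls Call-set data frame of parental calls.
#' @param pedigree Pedigree data frame from [read_pedigree()].
#' @param ro_threshold Reciprocal-overlap threshold for parent-child call
#'   matching, default 0.5 (the same criterion used for cohort
#'   frequency).
#' @return `proband_calls` with columns `inheritance` (one of
#'   `inherited_maternal`, `inherited_paternal`, `de_novo`, `unknown`)
#'   and `both_parents` appended.
#' @export
determine_inheritance <- function(proband_calls, parent_calls, pedigree,
                                  ro_threshold = 0.5) {
  match_in <- function(call, parent_id) {
    if (is.na(parent_id)) return(NA)
    pc <- parent_calls[parent_calls$sample_id == parent_id &
                         norm_chrom(parent_calls$chrom) ==
                           norm_chrom(call$chrom) &
                         parent_calls$cnv_type == call$cnv_type, ,
                       drop = FALSE]
    if (nrow(pc) == 0) return(FALSE)
    any(reciprocal_overlap(call$start, call$end, pc$start, pc$end) >=
          ro_threshold)
  }
  status <- character(nrow(proband_calls))
  both <- logical(nrow(proband_calls))
  for (i in seq_len(nrow(proband_calls))) {
    call <- proband_calls[i, ]
    ped <- pedigree[pedigree$proband == call$sample_id, , drop = FALSE]
    father <- if (nrow(ped) == 1) ped$father else NA_character_
    mother <- if (nrow(ped) == 1) ped$mother else NA_character_
    in_mother <- match_in(call, mother)
    in_father <- match_in(call, father)
    status[i] <- if (isTRUE(in_mother)) {
      both[i] <- isTRUE(in_father)
      "inherited_maternal"
    } else if (isTRUE(in_father)) {
      "inherited_paternal"
    } else if (identical(in_mother, FALSE) && identical(in_father, FALSE)) {
      "de_novo"
    } else {
      "unknown"
    }
  }
  proband_calls$inheritance <- status
  proband_calls$both_parents <- both
  proband_calls
}

#' Annotate candidate loci
#'
#' Runs the full annotation layer over a `region_set`: nearest gene and
#' distances ([nearest_gene_distance()]), candidate-gene status
#' ([flag_candidate_genes()]), evidence overlap ([evidence_overlap()]),
#' mechanism bin ([assign_bin()]) and, when trio data are supplied,
#' per-member inheritance ([determine_inheritance()]).
#'
#' @param rs A `region_set`.
#' @param genes Gene-model data frame.
#' @param tracks Named list of `evidence_track` objects (any subset of
#'   the four track types; may be empty).
#' @param candidate_list Candidate-gene identifiers, default the packaged
#'   list.
#' @param pedigree,parent_calls Optional trio data; when both are given,
#'   member calls gain an `inheritance` column.
#' @param ro_threshold Reciprocal-overlap threshold for inheritance
#'   matching.
#' @param gene_link_gap Gene-linkage gap for bin `iii` and the
#'   candidate-gene window, default 1e6.
#' @return The `region_set` with an `annotations` data frame (one row per
#'   region) attached, and `inheritance` on the member calls when trio
#'   data were supplied.
#' @export
annotate_regions <- function(rs, genes, tracks = list(),
                             candidate_list = read_candidate_genes(),
                             pedigree = NULL, parent_calls = NULL,
                             ro_threshold = 0.5, gene_link_gap = 1e6) {
  reg <- rs$regions
  ann_rows <- lapply(seq_len(nrow(reg)), function(i) {
    region <- reg[i, ]
    members <- rs$members[rs$members$region_id == region$region_id, ,
                          drop = FALSE]
    near <- nearest_gene_distance(region, genes, members)
    ev <- evidence_overlap(region, tracks)
    bins <- assign_bin(region, near, genes, tracks,
                       gene_link_gap = gene_link_gap)
    data.frame(region_id = region$region_id, chrom = region$chrom,
               start = region$start, end = region$end,
               nearest_gene = near$gene_id,
               nearest_distance_bp = near$nearest_distance_bp,
               furthest_distance_bp = near$furthest_distance_bp,
               direction = if (is.null(near$direction)) NA_character_ else
                 near$direction,
               evidence = paste(ev, collapse = ","),
               bin = format_bins(bins), stringsAsFactors = FALSE)
  })
  ann <- if (length(ann_rows)) do.call(rbind, ann_rows) else
    data.frame(region_id = character(), chrom = character(),
               start = numeric(), end = numeric(),
               nearest_gene = character(), nearest_distance_bp = numeric(),
               furthest_distance_bp = numeric(), direction = character(),
               evidence = character(), bin = character())
  ann <- flag_candidate_genes(ann, genes, candidate_list,
                              window = gene_link_gap)
  if (!is.null(pedigree) && !is.null(parent_calls)) {
    rs$members <- determine_inheritance(rs$members, parent_calls, pedigree,
                                        ro_threshold = ro_threshold)
  } else if (nrow(rs$members) > 0) {
    rs$members$inheritance <- "unknown"
  } else {
    rs$members$inheritance <- character()
  }
  rs$annotations <- ann
  rs
}
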