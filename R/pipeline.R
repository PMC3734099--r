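# End-to-end screen: load -> rarity -> intergenic -> overlap clustering
# -> recurrence -> control absence -> common-variant -> repeat -> locus
# merge -> annotate -> report.

#' Default screen configuration
#'
#' All thresholds of the screen with their defaults: rarity below 1%
#' cohort frequency at 50% reciprocal overlap with type matching;
#' span-level genic masking; at least 2 unrelated case carriers; strict
#' control absence; removal at 50% common-variant coverage or above 80%
#' repeat-masked fraction; 1 Mb locus merging.
#'
#' @param ... Named overrides, merged recursively into the defaults
#'   (e.g. `filters = list(min_cases = 3)`).
#' @return Nested configuration list.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    genome_build = "unspecified",
    dataset_size = NULL,
    inputs = list(cases = NULL, controls = NULL, genes = NULL,
                  genes_format = "gff3", tracks = list(), pedigree = NULL,
                  parents = NULL, candidate_genes = NULL),
    rarity = list(max_freq = 0.01, ro_threshold = 0.5, same_type = TRUE,
                  stratify_by_platform = FALSE),
    genic = list(mode = "span"),
    filters = list(min_cases = 2, max_control_carriers = 0,
                   dgv_max_overlap = 0.5, repeat_max_fraction = 0.8,
                   locus_merge_gap = 1e6),
    annotate = list(ro_threshold = 0.5, gene_link_gap = 1e6))
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  utils::modifyList(cfg, overrides)
}

#' Read a screen configuration from YAML
#'
#' Values found in the file override the [cohort_config()] defaults;
#' anything not mentioned keeps its default.
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cohort_config(yaml::read_yaml(path))
}

#' Run the screen on in-memory inputs
#'
#' Executes the stages in fixed order: rarity filter, intergenic filter,
#' overlap clustering, recurrence, control absence, common-variant
#' overlap, repeat fraction, locus merging, annotation. Every stage only
#' removes calls or regions; the per-region filter decisions accumulate
#' in the region set's trail.
#'
#' @param case_calls Case call-set data frame.
#' @param control_calls Control call-set data frame (may be empty).
#' @param genes Gene-model data frame (may be `NULL` for no genic
#'   masking).
#' @param tracks Named list of `evidence_track`s; the
#'   `common_variant` and `repeat` entries drive their filters (a
#'   missing track skips that filter), all tracks feed annotation.
#' @param pedigree,parent_calls Optional trio data for inheritance.
#' @param config Configuration list from [cohort_config()].
#' @param skip Character vector of filters to skip (any of `"rarity"`,
#'   `"intergenic"`, `"recurrence"`, `"control_absence"`,
#'   `"common_variant"`, `"repeat"`), for ablation runs.
#' @return A list of class `cnv_screen` with elements `regions` (the
#'   annotated final `region_set`), `summary` (stage-by-stage counts)
#'   and `config`.
#' @export
screen_cnvs <- function(case_calls, control_calls = empty_calls(),
                        genes = NULL, tracks = list(), pedigree = NULL,
                        parent_calls = NULL, config = cohort_config(),
                        skip = character()) {
  summary <- list()
  note <- function(stage, n) summary[[length(summary) + 1]] <<-
    data.frame(stage = stage, count = n)
  note("input_case_calls", nrow(case_calls))

  all_calls <- rbind(case_calls[, CALL_COLUMNS], control_calls[, CALL_COLUMNS])
  dataset_size <- config$dataset_size
  calls <- case_calls
  if (!"rarity" %in% skip && nrow(calls) > 0) {
    r <- config$rarity
    if (isTRUE(r$stratify_by_platform)) {
      grp <- ifelse(is.na(calls$platform), "", calls$platform)
      agrp <- ifelse(is.na(all_calls$platform), "", all_calls$platform)
      parts <- lapply(unique(grp), function(p) {
        filter_rare(calls[grp == p, , drop = FALSE],
                    all_calls[agrp == p, , drop = FALSE],
                    max_freq = r$max_freq, ro_threshold = r$ro_threshold,
                    same_type = r$same_type,
                    dataset_size = if (is.null(dataset_size)) NULL else
                      dataset_size[[p]])
      })
      calls <- do.call(rbind, parts)
    } else {
      calls <- filter_rare(calls, all_calls, max_freq = r$max_freq,
                           ro_threshold = r$ro_threshold,
                           same_type = r$same_type,
                           dataset_size = dataset_size)
    }
  }
  note("rare_calls", nrow(calls))

  if (!"intergenic" %in% skip && !is.null(genes)) {
    calls <- filter_intergenic(calls, genes)
  }
  note("intergenic_calls", nrow(calls))

  rs <- cluster_regions(overlap_clusters(calls))
  note("overlap_clusters", nrow(rs$regions))

  if (!"recurrence" %in% skip) {
    rs <- recurrence_filter(rs, min_cases = config$filters$min_cases,
                            pedigree = pedigree)
  }
  note("after_recurrence", nrow(rs$regions))

  if (!"control_absence" %in% skip && nrow(control_calls) > 0) {
    rs <- control_absence_filter(
      rs, control_calls,
      max_control_carriers = config$filters$max_control_carriers,
      same_type = config$rarity$same_type)
  }
  note("after_control_absence", nrow(rs$regions))

  if (!"common_variant" %in% skip && !is.null(tracks$common_variant)) {
    rs <- dgv_filter(rs, tracks$common_variant,
                     dgv_max_overlap = config$filters$dgv_max_overlap)
  }
  note("after_common_variant", nrow(rs$regions))

  if (!"repeat" %in% skip && !is.null(tracks$`repeat`)) {
    rs <- repeat_filter(
      rs, tracks$`repeat`,
      repeat_max_fraction = config$filters$repeat_max_fraction)
  }
  note("after_repeat", nrow(rs$regions))

  rs <- merge_loci(rs, locus_merge_gap = config$filters$locus_merge_gap)
  note("loci", nrow(rs$regions))

  candidate_list <- if (is.null(config$inputs$candidate_genes))
    read_candidate_genes() else
      read_candidate_genes(config$inputs$candidate_genes)
  rs <- annotate_regions(rs, genes = if (is.null(genes)) empty_genes()
                         else genes,
                         tracks = tracks, candidate_list = candidate_list,
                         pedigree = pedigree, parent_calls = parent_calls,
                         ro_threshold = config$annotate$ro_threshold,
                         gene_link_gap = config$annotate$gene_link_gap)
  structure(list(regions = rs,
                 summary = do.call(rbind, summary),
                 config = config),
            class = "cnv_screen")
}

empty_genes <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             gene_id = character(), strand = character())
}

#' @export
print.cnv_screen <- function(x, ...) {
  cat("<cnv_screen>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run the full screen from a configuration file
#'
#' Loads every input named in the configuration (all paths are checked
#' before any stage runs), executes [screen_cnvs()], and, when `out_dir`
#' is given, writes the region report (`regions.tsv`,
#' [write_region_report()]), the filter trail as JSON lines
#' (`filter_trail.jsonl`) and the stage summary (`summary.tsv`). Output
#' is deterministic for fixed inputs.
#'
#' @param config Configuration list ([cohort_config()]) or path to a
#'   YAML file ([read_config_yaml()]).
#' @param out_dir Optional output directory.
#' @param skip Filters to skip, see [screen_cnvs()].
#' @return The `cnv_screen` result, invisibly when `out_dir` is given.
#' @export
run_screen <- function(config, out_dir = NULL, skip = character()) {
  if (is.character(config)) config <- read_config_yaml(config)
  inp <- config$inputs
  if (is.null(inp$cases)) stop("config names no case call file (inputs.cases)")
  paths <- c(inp$cases, inp$controls, inp$genes, inp$pedigree, inp$parents,
             inp$candidate_genes, unlist(inp$tracks))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  case_calls <- read_cnv_bed(inp$cases, cohort = "case")
  control_calls <- if (is.null(inp$controls)) empty_calls() else
    read_cnv_bed(inp$controls, cohort = "control")
  genes <- if (is.null(inp$genes)) NULL else
    read_gene_annotation(inp$genes, fmt = inp$genes_format)
  tracks <- list()
  for (nm in names(inp$tracks)) {
    tracks[[nm]] <- read_track_bed(inp$tracks[[nm]], name = nm)
  }
  pedigree <- if (is.null(inp$pedigree)) NULL else read_pedigree(inp$pedigree)
  parent_calls <- if (is.null(inp$parents)) NULL else
    read_cnv_bed(inp$parents, cohort = "parent")
  res <- screen_cnvs(case_calls, control_calls, genes = genes,
                     tracks = tracks, pedigree = pedigree,
                     parent_calls = parent_calls, config = config,
                     skip = skip)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_region_report(res$regions, file.path(out_dir, "regions.tsv"))
    write_filter_trail(res$regions, file.path(out_dir, "filter_trail.jsonl"))
    write.table(res$summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(res))
  }
  res
}

#' Write the per-CNV region report
#'
#' One line per member CNV, grouped by locus, ordered by (chromosome,
#' region start, sample). Columns: `locus_id`, `chrom`, `region_start`,
#' `region_end`, `gene`, `distance_bp`, `sample`, `cnv_type`, `start`,
#' `end`, `size`, `inheritance`, `bin`.
#'
#' @param rs An annotated `region_set` (see [annotate_regions()]); an
#'   unannotated set is reported with empty annotation columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_report <- function(rs, path) {
  cols <- c("locus_id", "chrom", "region_start", "region_end", "gene",
            "distance_bp", "sample", "cnv_type", "start", "end", "size",
            "inheritance", "bin")
  m <- rs$members
  if (nrow(m) == 0) {
    out <- setNames(data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
  } else {
    reg <- rs$regions
    ann <- rs$annotations
    i <- match(m$region_id, reg$region_id)
    out <- data.frame(
      locus_id = m$region_id, chrom = m$chrom,
      region_start = reg$start[i], region_end = reg$end[i],
      gene = NA_character_, distance_bp = NA_real_,
      sample = m$sample_id, cnv_type = m$cnv_type,
      start = m$start, end = m$end, size = m$end - m$start,
      inheritance = if (is.null(m$inheritance)) "unknown" else m$inheritance,
      bin = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(ann) && nrow(ann) > 0) {
      j <- match(m$region_id, ann$region_id)
      out$gene <- ann$nearest_gene[j]
      out$distance_bp <- ann$furthest_distance_bp[j]
      out$bin <- ann$bin[j]
    }
    out <- out[order_by_chrom(out$chrom, out$region_start, out$sample,
                              out$start), , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out) > 0) {
    write.table(format(out, scientific = FALSE, trim = TRUE), con,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Write the filter trail as JSON lines
#'
#' One JSON object per filter decision (filter name, region, measured
#' statistic, threshold, pass/fail), doubling as provenance for every
#' removal.
#'
#' @param rs A `region_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_trail <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tr <- rs$trail
  for (i in seq_len(nrow(tr))) {
    writeLines(jsonlite::toJSON(as.list(tr[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}

#' Regression check against the packaged 15-locus reference table
#'
#' Re-runs overlap clustering and 1 Mb locus merging on the packaged
#' reference CNVs and compares the outcome with the transcription
#' itself: the locus count, each locus's member calls, the number of
#' distinct cohort samples (the literature-derived carrier SK0167-003 is
#' excluded from that count), the samples hitting several loci, and the
#' size identity `end - start == size` of every row.
#'
#' @param calls Call set to check; defaults to the packaged reference
#'   table, so a clean run reports zero mismatches.
#' @param locus_merge_gap Merge gap in bp, default 1e6.
#' @return An object of class `table1_regression`: the computed
#'   `region_set`, a `checks` data frame (one row per comparison) and
#'   `n_mismatch`.
#' @export
regression_table1 <- function(calls = load_table1_fixture(),
                              locus_merge_gap = 1e6) {
  ref <- load_table1_fixture()
  rs <- merge_loci(cluster_regions(overlap_clusters(calls)),
                   locus_merge_gap = locus_merge_gap)
  checks <- list()
  add <- function(check, expected, observed) {
    checks[[length(checks) + 1]] <<- data.frame(
      check = check, expected = as.character(expected),
      observed = as.character(observed),
      match = identical(as.character(expected), as.character(observed)))
  }
  # locus count
  add("locus_count", length(unique(ref$locus_entry)), nrow(rs$regions))
  # per-locus membership: every reference table entry must appear as one
  # computed locus with exactly the same member calls
  key <- function(df) sort(paste(df$sample_id, df$start, df$end, sep = "|"))
  ref_sets <- lapply(split(ref, ref$locus_entry), key)
  got_sets <- if (nrow(rs$members) > 0)
    lapply(split(rs$members, rs$members$region_id), key) else list()
  unmatched <- sum(!vapply(ref_sets, function(k)
    any(vapply(got_sets, identical, logical(1), y = k)), logical(1)))
  add("table_entries_without_matching_locus", 0, unmatched)
  # distinct cohort samples (excluding the literature case)
  lit <- "SK0167-003"
  add("distinct_cohort_samples",
      length(unique(ref$sample_id[ref$sample_id != lit])),
      length(unique(rs$members$sample_id[rs$members$sample_id != lit])))
  # samples hitting more than one locus
  hits <- function(members) {
    t <- table(unique(members[, c("sample_id", "region_id")])$sample_id)
    sort(names(t)[t >= 2])
  }
  ref2 <- ref
  ref2$region_id <- ref2$locus_entry
  add("multi_locus_samples", paste(hits(ref2), collapse = ","),
      paste(hits(rs$members), collapse = ","))
  # printed size identity
  if ("size" %in% names(calls)) {
    add("rows_with_size_identity", nrow(ref),
        sum(calls$end - calls$start == calls$size))
  }
  # loci harbouring two or more recurrent clusters (distinct clusters of
  # CNVs from >= 2 samples at one locus); expected side re-derived by
  # clustering each reference table entry on its own
  expected_multi <- sum(vapply(split(ref, ref$locus_entry), function(m) {
    cl <- overlap_clusters(m)
    rec <- vapply(split(cl$sample_id, cl$cluster_id),
                  function(s) length(unique(s)) >= 2, logical(1))
    sum(rec) >= 2
  }, logical(1)))
  add("multi_recurrent_cluster_loci", expected_multi,
      sum(rs$regions$n_recurrent_clusters >= 2))
  checks <- do.call(rbind, checks)
  structure(list(regions = rs, checks = checks,
                 n_mismatch = sum(!checks$match)),
            class = "table1_regression")
}

#' @export
print.table1_regression <- function(x, ...) {
  cat("<table1_regression>", if (x$n_mismatch == 0) "PASS" else
    paste0("FAIL (", x$n_mismatch, " mismatch(es))"), "\n")
  print(x$checks, row.names = FALSE)
  invisible(x)
}
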