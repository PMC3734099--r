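# Readers and writers for the screen's file formats. CNV call sets travel
# as plain data frames with the columns below; evidence tracks are a light
# S3 wrapper around an interval data frame.

CALL_COLUMNS <- c("chrom", "start", "end", "cnv_type", "sample_id",
                  "cohort", "platform", "family_id")

LOSS_TOKENS <- c("loss", "del", "deletion")
GAIN_TOKENS <- c("gain", "dup", "duplication")

normalize_cnv_type <- function(x) {
  x <- tolower(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% LOSS_TOKENS] <- "loss"
  out[x %in% GAIN_TOKENS] <- "gain"
  out
}

# canonical empty call set
empty_calls <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             cnv_type = character(), sample_id = character(),
             cohort = character(), platform = character(),
             family_id = character(), stringsAsFactors = FALSE)
}

# coerce a data frame to the canonical call-set layout, checking invariants
as_cnv_calls <- function(df, cohort = NULL) {
  stopifnot(all(c("chrom", "start", "end", "cnv_type", "sample_id") %in%
                  names(df)))
  df$chrom <- norm_chrom(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$cnv_type <- as.character(df$cnv_type)
  df$sample_id <- as.character(df$sample_id)
  if (!is.null(cohort)) df$cohort <- cohort
  if (is.null(df$cohort)) df$cohort <- NA_character_
  if (is.null(df$platform)) df$platform <- NA_character_
  if (is.null(df$family_id)) df$family_id <- NA_character_
  bad_type <- !df$cnv_type %in% c("loss", "gain")
  bad_coord <- !is.finite(df$start) | !is.finite(df$end) | df$start >= df$end |
    df$start < 0
  if (any(bad_type | bad_coord)) {
    stop("invalid CNV call record(s) at row(s) ",
         paste(which(bad_type | bad_coord), collapse = ", "))
  }
  warn_sex_chroms(df$chrom)
  df <- df[, CALL_COLUMNS, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read per-sample CNV calls from a BED-like tab-separated file
#'
#' Expects at least five columns: chromosome, start, end, copy-number type
#' and sample identifier, with optional platform and family columns.
#' Comment lines (`#`) and a leading header line are skipped. Type tokens
#' are normalized case-insensitively (`DEL`/`deletion` to `loss`,
#' `DUP`/`duplication` to `gain`). With `coords = "bed"` (the default)
#' starts are 0-based half-open on disk and shifted to the internal
#' 1-based closed convention on read; `coords = "onebased"` reads
#' coordinates as printed.
#'
#' Records with a malformed coordinate, an unknown type token, or
#' `start >= end` (after conversion) are rejected rather than fatal: they
#' are reported via a warning with their line numbers and returned in the
#' `"rejected"` attribute of the result.
#'
#' @param path Path to the tab-separated file.
#' @param cohort Cohort label stored on every call: `"case"`, `"control"`
#'   or `"parent"`.
#' @param coords Coordinate convention of the file, `"bed"` or
#'   `"onebased"`.
#' @return A call-set data frame (columns `chrom`, `start`, `end`,
#'   `cnv_type`, `sample_id`, `cohort`, `platform`, `family_id`), with a
#'   `"rejected"` attribute describing any skipped records.
#' @seealso [write_cnv_bed()] for the inverse operation.
#' @export
read_cnv_bed <- function(path, cohort = c("case", "control", "parent"),
                         coords = c("bed", "onebased")) {
  cohort <- match.arg(cohort)
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("CNV file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  rejected <- data.frame(line = integer(), reason = character())
  if (length(lines) == 0) {
    out <- empty_calls()
    attr(out, "rejected") <- rejected
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # header: first retained line whose coordinate columns do not parse
  is_header <- function(f) {
    length(f) >= 3 && (is.na(suppressWarnings(as.numeric(f[2]))) ||
                         is.na(suppressWarnings(as.numeric(f[3]))))
  }
  if (is_header(fields[[1]])) {
    fields <- fields[-1]
    line_no <- line_no[-1]
  }
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 5) {
      rejected <- rbind(rejected, data.frame(line = line_no[i],
                                             reason = "fewer than 5 columns"))
      next
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    type <- normalize_cnv_type(f[4])
    if (is.na(start) || is.na(end) || start < 0) {
      rejected <- rbind(rejected, data.frame(line = line_no[i],
                                             reason = "malformed coordinate"))
      next
    }
    if (is.na(type)) {
      rejected <- rbind(rejected, data.frame(
        line = line_no[i], reason = paste0("unknown type token '", f[4], "'")))
      next
    }
    if (coords == "bed") start <- start + 1
    if (start >= end) {
      rejected <- rbind(rejected, data.frame(line = line_no[i],
                                             reason = "start >= end"))
      next
    }
    rows[[i]] <- data.frame(
      chrom = f[1], start = start, end = end, cnv_type = type,
      sample_id = f[5],
      platform = if (length(f) >= 6 && nzchar(f[6])) f[6] else NA_character_,
      family_id = if (length(f) >= 7 && nzchar(f[7])) f[7] else NA_character_,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0) empty_calls() else
    as_cnv_calls(do.call(rbind, rows), cohort = cohort)
  if (nrow(rejected) > 0) {
    warning(nrow(rejected), " record(s) rejected in ", path, " (line ",
            paste(rejected$line, collapse = ", "), ")", call. = FALSE)
  }
  attr(out, "rejected") <- rejected
  out
}

#' Write CNV calls to a BED-like tab-separated file
#'
#' Inverse of [read_cnv_bed()]: columns chrom, start, end, cnv_type,
#' sample_id, platform, family_id. With `coords = "bed"` the internal
#' 1-based closed start is shifted back to 0-based half-open on disk.
#'
#' @param calls Call-set data frame.
#' @param path Output path.
#' @param coords `"bed"` or `"onebased"`.
#' @return `path`, invisibly.
#' @export
write_cnv_bed <- function(calls, path, coords = c("bed", "onebased")) {
  coords <- match.arg(coords)
  out <- calls[, c("chrom", "start", "end", "cnv_type", "sample_id",
                   "platform", "family_id"), drop = FALSE]
  if (coords == "bed") out$start <- out$start - 1
  out$platform[is.na(out$platform)] <- ""
  out$family_id[is.na(out$family_id)] <- ""
  write.table(format(out, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3 or BED annotation
#'
#' GFF3 input keeps only features of type `gene` (other feature types such
#' as exons are ignored); BED input takes every interval as a gene. BED's
#' 0-based half-open starts are converted to the internal 1-based closed
#' convention (handled by `rtracklayer`). Gene identifiers come from the
#' `Name`, `gene_id` or `ID` attribute (GFF3) or the name column (BED).
#'
#' @param path Annotation file path.
#' @param fmt `"gff3"` or `"bed"`.
#' @return Data frame with columns `chrom`, `start`, `end`, `gene_id`,
#'   `strand`.
#' @export
read_gene_annotation <- function(path, fmt = c("gff3", "bed")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (fmt == "gff3") "gff3" else "bed"),
    error = function(e) stop("failed to parse ", fmt, " annotation ", path,
                             ": ", conditionMessage(e), call. = FALSE))
  if (fmt == "gff3") {
    type <- as.character(gr$type)
    gr <- gr[type == "gene"]
    meta <- S4Vectors::mcols(gr)
    id <- NULL
    for (col in c("Name", "gene_id", "ID")) {
      if (col %in% names(meta)) {
        cand <- as.character(meta[[col]])
        id <- if (is.null(id)) cand else ifelse(is.na(id), cand, id)
      }
    }
    if (is.null(id)) id <- paste0("gene", seq_along(gr))
  } else {
    id <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene", seq_along(gr))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[!strand %in% c("+", "-")] <- "unknown"
  df <- data.frame(
    chrom = norm_chrom(as.character(GenomicRanges::seqnames(gr))),
    start = as.numeric(GenomicRanges::start(gr)),
    end = as.numeric(GenomicRanges::end(gr)),
    gene_id = id, strand = strand, stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) {
    stop("gene annotation ", path, " contains records with start >= end")
  }
  rownames(df) <- NULL
  df
}

#' Construct an evidence track
#'
#' An evidence track is a named set of genomic intervals used by the
#' overlap filters and annotation: the common-variant (DGV-style)
#' catalogue, the repeat mask, expressed-sequence (mRNA/EST) evidence, or
#' conserved/enhancer elements.
#'
#' @param name One of `"common_variant"`, `"repeat"`,
#'   `"expressed_sequence"`, `"conserved_element"`.
#' @param intervals Data frame with columns `chrom`, `start`, `end` and
#'   optionally `label`.
#' @return An object of class `evidence_track`.
#' @export
evidence_track <- function(name = c("common_variant", "repeat",
                                    "expressed_sequence",
                                    "conserved_element"),
                           intervals) {
  name <- match.arg(name)
  intervals <- as.data.frame(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  intervals$chrom <- norm_chrom(intervals$chrom)
  intervals$start <- as.numeric(intervals$start)
  intervals$end <- as.numeric(intervals$end)
  if (is.null(intervals$label)) {
    intervals$label <- if (nrow(intervals)) paste0(name, seq_len(nrow(intervals)))
    else character()
  }
  if (any(intervals$start >= intervals$end)) {
    stop("evidence track '", name, "' has interval(s) with start >= end")
  }
  structure(list(name = name,
                 intervals = intervals[, c("chrom", "start", "end", "label")]),
            class = "evidence_track")
}

track_intervals <- function(track) {
  if (inherits(track, "evidence_track")) track$intervals else
    as.data.frame(track)
}

#' @export
print.evidence_track <- function(x, ...) {
  cat("<evidence_track>", x$name, ":", nrow(x$intervals), "interval(s)\n")
  invisible(x)
}

#' Read an evidence track from a BED file
#'
#' @param path BED file (0-based half-open on disk; converted on read).
#' @param name Track label, see [evidence_track()].
#' @return An `evidence_track`.
#' @export
read_track_bed <- function(path, name) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("failed to parse BED track ", path,
                                          ": ", conditionMessage(e),
                                          call. = FALSE))
  df <- data.frame(
    chrom = norm_chrom(as.character(GenomicRanges::seqnames(gr))),
    start = as.numeric(GenomicRanges::start(gr)),
    end = as.numeric(GenomicRanges::end(gr)),
    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) df$label <- as.character(gr$name)
  evidence_track(name, df)
}

#' Write an evidence track to BED
#' @param track An `evidence_track` or interval data frame.
#' @param path Output path (0-based half-open starts on disk).
#' @return `path`, invisibly.
#' @export
write_track_bed <- function(track, path) {
  ti <- track_intervals(track)
  out <- data.frame(chrom = ti$chrom, start = ti$start - 1, end = ti$end,
                    name = ti$label)
  write.table(format(out, scientific = FALSE, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a trio pedigree
#'
#' Three tab-separated columns: proband, father, mother, with `NA` (or
#' empty) marking a missing parent. A header line is detected and skipped.
#'
#' @param path Pedigree file path.
#' @return Data frame with columns `proband`, `father`, `mother`.
#' @export
read_pedigree <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("proband", "father", "mother"))
  if (nrow(df) > 0 && tolower(df$proband[1]) %in% c("proband", "sample",
                                                    "sample_id")) {
    df <- df[-1, , drop = FALSE]
  }
  for (col in names(df)) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][df[[col]] %in% c("NA", "", ".")] <- NA_character_
  }
  if (any(!is.na(df$father) & df$father == df$proband) ||
      any(!is.na(df$mother) & df$mother == df$proband)) {
    stop("pedigree ", path, ": a proband is listed as its own parent")
  }
  rownames(df) <- NULL
  df
}

#' Write a trio pedigree
#' @param pedigree Data frame with columns `proband`, `father`, `mother`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- pedigree[, c("proband", "father", "mother")]
  out[is.na(out)] <- "NA"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Load the packaged 15-locus reference CNV table
#'
#' Returns the packaged transcription of the published reference set of
#' rare intergenic CNVs: 45 calls across 15 loci, with cytoband locus
#' labels, flanking gene(s), the published furthest-distance values and
#' mechanism bins. Coordinates are 1-based closed as printed; every row
#' satisfies `size == end - start`, which is checked on load.
#'
#' @return A call-set data frame (cohort `"case"`) with extra columns
#'   `locus_entry`, `locus`, `genes`, `furthest_distance`, `bin`, `size`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_cnvs.tsv", package = "cnvscan")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged reference CNV table is missing")
  }
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character"))
  if (nrow(df) != 45) {
    stop("packaged reference CNV table is corrupt: expected 45 rows, found ",
         nrow(df))
  }
  if (!all(df$end - df$start == df$size)) {
    stop("packaged reference CNV table is corrupt: size != end - start")
  }
  calls <- as_cnv_calls(df, cohort = "case")
  cbind(calls, df[, c("locus_entry", "locus", "genes", "furthest_distance",
                      "bin", "size")])
}

#' Default candidate-gene list
#'
#' The packaged default list of known or candidate risk genes flanking the
#' reference loci, one gene symbol per line.
#'
#' @param path Optional path to a plain-text list (one gene per line);
#'   defaults to the packaged list.
#' @return Character vector of gene identifiers.
#' @export
read_candidate_genes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "candidate_genes.txt", package = "cnvscan")
  }
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !grepl("^#", x)]
}
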