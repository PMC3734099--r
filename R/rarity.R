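# Cohort-frequency filtering. Two calls are "the same" CNV when they lie
# on one chromosome, reciprocally overlap by at least `ro_threshold`, and
# (by default) share copy-number type. A call's frequency is the number
# of distinct samples in the pooled case+control dataset carrying an
# equivalent call, divided by the number of genotyped samples.

# per-call carrier statistics; the workhorse behind carrier_count() and
# filter_rare(). Matching is done per (chromosome [, type]) block with
# IRanges::findOverlaps, then thinned by reciprocal overlap.
carrier_table <- function(calls, all_calls, ro_threshold = 0.5,
                          same_type = TRUE, dataset_size = NULL) {
  if (nrow(all_calls) == 0) stop("'all_calls' is empty: the overall dataset must contain at least one call")
  stopifnot(ro_threshold > 0, ro_threshold <= 1)
  if (is.null(dataset_size)) {
    dataset_size <- length(unique(all_calls$sample_id))
  }
  if (nrow(calls) == 0) {
    return(data.frame(carrier_count = integer(), dataset_size = integer(),
                      frequency = numeric()))
  }
  carriers <- lapply(seq_len(nrow(calls)), function(i) calls$sample_id[i])
  qkey <- paste(norm_chrom(calls$chrom),
                if (same_type) calls$cnv_type else "", sep = "|")
  skey <- paste(norm_chrom(all_calls$chrom),
                if (same_type) all_calls$cnv_type else "", sep = "|")
  for (key in unique(qkey)) {
    qi <- which(qkey == key)
    si <- which(skey == key)
    if (length(si) == 0) next
    hits <- IRanges::findOverlaps(as_iranges(calls[qi, ]),
                                  as_iranges(all_calls[si, ]))
    if (length(hits) == 0) next
    q <- qi[S4Vectors::queryHits(hits)]
    s <- si[S4Vectors::subjectHits(hits)]
    ro <- reciprocal_overlap(calls$start[q], calls$end[q],
                             all_calls$start[s], all_calls$end[s])
    keep <- ro >= ro_threshold
    q <- q[keep]; s <- s[keep]
    if (length(q)) {
      sm <- split(all_calls$sample_id[s], q)
      for (nm in names(sm)) {
        i <- as.integer(nm)
        carriers[[i]] <- c(carriers[[i]], sm[[nm]])
      }
    }
  }
  n <- vapply(carriers, function(x) length(unique(x)), integer(1))
  data.frame(carrier_count = n, dataset_size = dataset_size,
             frequency = n / dataset_size)
}

#' Count carriers of a CNV in the overall dataset
#'
#' Counts the distinct samples in `all_calls` (the pooled case+control
#' dataset) that own at least one call equivalent to `call`, i.e. on the
#' same chromosome with reciprocal overlap at or above `ro_threshold`
#' and, when `same_type` is set, the same copy-number type. The query
#' call's own sample always counts, so the count is at least 1.
#'
#' @param call A single-row call-set data frame (or list with fields
#'   `chrom`, `start`, `end`, `cnv_type`, `sample_id`).
#' @param all_calls Call-set data frame for the overall dataset.
#' @param ro_threshold Reciprocal-overlap threshold in `(0, 1]`.
#' @param same_type Require matching copy-number type?
#' @param dataset_size Number of genotyped samples in the overall dataset
#'   (the frequency denominator). Defaults to the number of distinct
#'   sample identifiers in `all_calls`, which undercounts samples with no
#'   calls; pipelines should pass the true cohort size.
#' @return A one-row data frame with `carrier_count`, `dataset_size` and
#'   `frequency`.
#' @export
carrier_count <- function(call, all_calls, ro_threshold = 0.5,
                          same_type = TRUE, dataset_size = NULL) {
  call <- as.data.frame(call, stringsAsFactors = FALSE)
  stopifnot(nrow(call) == 1)
  carrier_table(call, all_calls, ro_threshold = ro_threshold,
                same_type = same_type, dataset_size = dataset_size)
}

#' Retain rare CNV calls
#'
#' Keeps exactly the calls whose carrier frequency in the overall dataset
#' is strictly below `max_freq` (a call carried by exactly 1% of samples
#' is removed). Input order is preserved.
#'
#' @inheritParams carrier_count
#' @param calls Calls to filter (typically the case calls).
#' @param max_freq Maximum allowed frequency, default 0.01.
#' @return The retained subset of `calls`, with `carrier_count` and
#'   `frequency` columns appended.
#' @export
filter_rare <- function(calls, all_calls, max_freq = 0.01,
                        ro_threshold = 0.5, same_type = TRUE,
                        dataset_size = NULL) {
  stopifnot(max_freq > 0, max_freq <= 1)
  ct <- carrier_table(calls, all_calls, ro_threshold = ro_threshold,
                      same_type = same_type, dataset_size = dataset_size)
  out <- cbind(calls, ct[, c("carrier_count", "frequency")])
  out <- out[ct$frequency < max_freq, , drop = FALSE]
  rownames(out) <- NULL
  out
}
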