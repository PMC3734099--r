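# Brute-force oracles and small builders shared across tests. The
# oracles deliberately avoid the package's interval-tree code paths:
# they enumerate bases or loop over all pairs.

mk_calls <- function(chrom, start, end, type = "loss", sample = "s1",
                     cohort = "case", family = NA_character_) {
  n <- max(length(chrom), length(start), length(end), length(type),
           length(sample))
  if (length(chrom) == 0 && length(start) == 0) n <- 0
  data.frame(chrom = as.character(rep_len(chrom, n)),
             start = rep_len(start, n), end = rep_len(end, n),
             cnv_type = rep_len(type, n),
             sample_id = rep_len(sample, n),
             cohort = rep_len(cohort, n),
             platform = rep_len(NA_character_, n),
             family_id = rep_len(family, n), stringsAsFactors = FALSE)
}

mk_genes <- function(chrom, start, end, id = NULL, strand = "+") {
  n <- max(length(chrom), length(start), length(end))
  data.frame(chrom = as.character(rep_len(chrom, n)),
             start = rep_len(start, n), end = rep_len(end, n),
             gene_id = if (is.null(id)) sprintf("G%02d", seq_len(n)) else
               rep_len(id, n),
             strand = rep_len(strand, n), stringsAsFactors = FALSE)
}

# reciprocal overlap by base enumeration (closed intervals); only for
# small coordinates
enum_ro <- function(s1, e1, s2, e2) {
  a <- seq(s1, e1)
  b <- seq(s2, e2)
  ov <- length(intersect(a, b))
  min(ov / length(a), ov / length(b))
}

# all-pairs carrier count: distinct samples owning a call on the same
# chromosome (and type, optionally) with reciprocal overlap >= thr;
# every pair is examined, no interval index
bf_carrier_count <- function(i, calls, thr = 0.5, same_type = TRUE) {
  chrom <- calls$chrom; s <- calls$start; e <- calls$end
  type <- calls$cnv_type; sid <- calls$sample_id
  ok <- chrom == chrom[i]
  if (same_type) ok <- ok & type == type[i]
  ov <- pmin(e, e[i]) - pmax(s, s[i]) + 1
  ro <- pmin(ov / (e - s + 1), ov / (e[i] - s[i] + 1))
  ok <- ok & ov > 0 & ro >= thr
  length(unique(c(sid[i], sid[ok])))
}

# single-linkage components over all O(n^2) pairs via union-find,
# returned as a canonical partition (list of sorted index vectors,
# ordered by smallest member)
bf_clusters <- function(calls) {
  n <- nrow(calls)
  chrom <- calls$chrom; s <- calls$start; e <- calls$end
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    js <- which(chrom == chrom[i] & s <= e[i] & e >= s[i])
    for (j in js[js > i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  parts <- split(seq_len(n), roots)
  parts <- lapply(parts, sort)
  names(parts) <- NULL
  parts[order(vapply(parts, min, integer(1)))]
}

# canonical partition from an overlap_clusters() result, mapped back to
# the original row order of `calls`
clusters_as_partition <- function(clustered, calls) {
  key <- paste(calls$chrom, calls$start, calls$end, calls$sample_id,
               calls$cnv_type)
  ckey <- paste(clustered$chrom, clustered$start, clustered$end,
                clustered$sample_id, clustered$cnv_type)
  idx <- match(ckey, key)
  parts <- split(idx, clustered$cluster_id)
  parts <- lapply(parts, sort)
  names(parts) <- NULL
  parts[order(vapply(parts, min, integer(1)))]
}

# per-base genic membership oracle (small instances only)
bf_genic <- function(call, genes) {
  g <- genes[genes$chrom == call$chrom, , drop = FALSE]
  if (nrow(g) == 0) return("intergenic")
  gene_bases <- unlist(lapply(seq_len(nrow(g)),
                              function(i) seq(g$start[i], g$end[i])))
  if (any(seq(call$start, call$end) %in% gene_bases)) "genic" else
    "intergenic"
}

# union length of track coverage inside [start, end] by manual sweep
bf_coverage <- function(chrom, start, end, intervals) {
  iv <- intervals[intervals$chrom == chrom, , drop = FALSE]
  iv$start <- pmax(iv$start, start)
  iv$end <- pmin(iv$end, end)
  iv <- iv[iv$start <= iv$end, , drop = FALSE]
  if (nrow(iv) == 0) return(0)
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  covered <- 0
  cur_s <- iv$start[1]; cur_e <- iv$end[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= cur_e + 1) {
      cur_e <- max(cur_e, iv$end[i])
    } else {
      covered <- covered + (cur_e - cur_s + 1)
      cur_s <- iv$start[i]; cur_e <- iv$end[i]
    }
  }
  covered <- covered + (cur_e - cur_s + 1)
  covered / (end - start + 1)
}

# random call set on a sparse genome (used by the oracle-equivalence
# properties)
random_calls <- function(n, n_samples = max(2, n %/% 4), seed = 1,
                         chroms = c("1", "2", "3"), chrom_len = 2e8,
                         min_len = 1e4, max_len = 1e5) {
  set.seed(seed)
  len <- round(runif(n, min_len, max_len))
  start <- round(runif(n, 1, chrom_len - max_len))
  mk_calls(chrom = sample(chroms, n, replace = TRUE),
           start = start, end = start + len,
           type = sample(c("loss", "gain"), n, replace = TRUE),
           sample = sprintf("s%03d", sample(n_samples, n, replace = TRUE)))
}
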