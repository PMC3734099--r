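# Seeded synthetic cohort with exact ground truth. The generator plants
# rare intergenic recurrent CNV clusters, common copy-number
# polymorphisms, genic decoys and one repeat-masked decoy into a small
# genome, adds per-sample singleton background calls, and builds trios
# whose inherited calls are copied (with bounded boundary jitter) into a
# parent. Placement is by rejection sampling against kind-aware
# separation rules, so the expected output of the screen on a simulated
# cohort is exactly the planted regions.

#' Simulation configuration
#'
#' Parameters of the synthetic case/control/trio cohort. Defaults are a
#' desk-scale cohort: two 50-Mb chromosomes, 150 cases, 150 controls,
#' 40 genes and 5 planted rare intergenic regions with 2 case carriers
#' each (2/300 carriers keeps a planted call strictly below the 1%
#' rarity bound). The `"paper_scale"` preset swaps in the full published
#' cohort sizes (1491 cases genotyped on two platforms; 1287 + 1234 +
#' 1123 = 3644 controls) for runtime benchmarking.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param genome Named numeric vector of chromosome lengths in bp.
#' @param n_genes Number of non-overlapping gene spans to place.
#' @param n_planted_regions Number of planted rare intergenic recurrent
#'   regions.
#' @param planted_cases_per_region Distinct case carriers per planted
#'   region (at least 2).
#' @param n_common_cnp Number of common copy-number-polymorphism loci.
#' @param common_cnp_freq Carrier frequency of each polymorphism in each
#'   cohort, in (0.01, 0.5].
#' @param background_rate Expected number of rare singleton background
#'   CNVs per sample (Poisson).
#' @param repeat_fraction_target Fraction of the genome covered by the
#'   random part of the repeat-mask track.
#' @param trio_fraction Fraction of cases with both parents available.
#' @param inherited_fraction Probability that a trio proband's CNV is
#'   present in one parent (the rest are de novo).
#' @param seed Integer seed; every placement and draw uses one global
#'   stream seeded from it.
#' @param preset `"desk"` (default) or `"paper_scale"`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 150, n_controls = 150,
                       genome = c(`1` = 5e7, `2` = 5e7),
                       n_genes = 40, n_planted_regions = 5,
                       planted_cases_per_region = 2,
                       n_common_cnp = 5, common_cnp_freq = 0.05,
                       background_rate = 1,
                       repeat_fraction_target = 0.1,
                       trio_fraction = 0.5, inherited_fraction = 0.9,
                       seed = 1, preset = c("desk", "paper_scale")) {
  preset <- match.arg(preset)
  if (preset == "paper_scale") {
    n_cases <- 1491
    n_controls <- 3644
  }
  cfg <- list(n_cases = n_cases, n_controls = n_controls, genome = genome,
              n_genes = n_genes, n_planted_regions = n_planted_regions,
              planted_cases_per_region = planted_cases_per_region,
              n_common_cnp = n_common_cnp,
              common_cnp_freq = common_cnp_freq,
              background_rate = background_rate,
              repeat_fraction_target = repeat_fraction_target,
              trio_fraction = trio_fraction,
              inherited_fraction = inherited_fraction, seed = seed)
  stopifnot(n_cases >= 0, n_controls >= 0, n_genes >= 0,
            n_planted_regions >= 0,
            planted_cases_per_region >= 2,
            n_common_cnp >= 0,
            common_cnp_freq > 0, common_cnp_freq <= 0.5,
            background_rate >= 0,
            repeat_fraction_target >= 0, repeat_fraction_target <= 1,
            trio_fraction >= 0, trio_fraction <= 1,
            inherited_fraction >= 0, inherited_fraction <= 1,
            length(genome) >= 1, all(genome > 0),
            !is.null(names(genome)))
  class(cfg) <- "sim_config"
  cfg
}

# minimum separation (bp) required between a candidate interval of kind
# `kind_new` / length `len` and an existing zone of kind `kind_old`.
# Planted regions (and the repeat decoy) keep >1 Mb clear of each other
# so surviving loci never merge; jitter headroom keeps planted carriers
# intergenic and clear of other carrier groups.
zone_separation <- function(kind_new, kind_old, len) {
  big <- c("planted", "decoy")
  if (kind_new %in% big && kind_old %in% big) return(1.5e6)
  if (kind_new %in% big || kind_old %in% big) {
    if (kind_old == "gene" || kind_new == "gene") return(0.2 * len + 1e4)
    return(2e5)
  }
  if (kind_new == "cnp" || kind_old == "cnp") return(0.15 * len + 1e4)
  1e4  # gene-gene and everything else
}

# rejection-sample one interval of length `len` against the zone table
place_interval <- function(len, genome, zones, kind, max_tries = 4000) {
  chroms <- names(genome)
  for (try in seq_len(max_tries)) {
    chr <- sample(chroms, 1, prob = as.numeric(genome))
    if (genome[[chr]] <= len + 2) next
    start <- floor(runif(1, 1, genome[[chr]] - len))
    end <- start + len
    zc <- zones[zones$chrom == chr, , drop = FALSE]
    ok <- TRUE
    if (nrow(zc) > 0) {
      gaps <- interval_gap(start, end, zc$start, zc$end)
      req <- vapply(zc$kind, zone_separation, numeric(1),
                    kind_new = kind, len = len)
      ok <- all(gaps >= req)
    }
    if (ok) return(data.frame(chrom = chr, start = start, end = end,
                              kind = kind, stringsAsFactors = FALSE))
  }
  stop("genome too small to place a ", kind, " interval of ", len,
       " bp without violating separation rules after ", max_tries,
       " tries; enlarge the genome or reduce the number of placed features")
}

# jitter both boundaries by up to `frac` of the length; all copies of one
# template keep the central (1 - 2*frac) core, so pairwise reciprocal
# overlap stays >= (1 - 2*frac) / (1 + 2*frac)
jitter_interval <- function(start, end, frac = 0.1) {
  len <- end - start
  s <- round(start + runif(1, -frac, frac) * len)
  e <- round(end + runif(1, -frac, frac) * len)
  c(start = s, end = e)
}

# layout shared by simulate_cohort() and make_repeat_track(): gene spans,
# planted-region templates, the repeat decoy and CNP loci. Caller must
# have seeded the RNG.
sim_layout <- function(config) {
  genome <- config$genome
  zones <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), kind = character())
  add <- function(zones, row) rbind(zones, row)
  genes <- NULL
  for (i in seq_len(config$n_genes)) {
    len <- round(runif(1, 2e4, 2e5))
    z <- place_interval(len, genome, zones, "gene")
    zones <- add(zones, z)
    genes <- rbind(genes, data.frame(
      chrom = z$chrom, start = z$start, end = z$end,
      gene_id = sprintf("GENE%03d", i),
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE))
  }
  planted <- NULL
  for (i in seq_len(config$n_planted_regions)) {
    len <- round(runif(1, 5e4, 1.5e5))
    z <- place_interval(len, genome, zones, "planted")
    zones <- add(zones, z)
    planted <- rbind(planted, data.frame(
      region = i, chrom = z$chrom, start = z$start, end = z$end,
      stringsAsFactors = FALSE))
  }
  decoy <- place_interval(8e4, genome, zones, "decoy")
  zones <- add(zones, decoy)
  cnp <- NULL
  for (i in seq_len(config$n_common_cnp)) {
    len <- round(runif(1, 2e4, 8e4))
    z <- place_interval(len, genome, zones, "cnp")
    zones <- add(zones, z)
    cnp <- rbind(cnp, data.frame(locus = i, chrom = z$chrom,
                                 start = z$start, end = z$end,
                                 stringsAsFactors = FALSE))
  }
  list(genes = genes, planted = planted, decoy = decoy, cnp = cnp,
       zones = zones)
}

# repeat-track generation from a layout (RNG position matters: called
# directly after sim_layout in both entry points)
build_repeat_track <- function(config, layout) {
  genome <- config$genome
  decoy <- layout$decoy
  # decoy intervals: two blocks covering ~95% of the decoy region, so its
  # masked fraction is decisively above the 0.8 removal bound
  len <- decoy$end - decoy$start
  decoy_iv <- data.frame(
    chrom = decoy$chrom,
    start = c(decoy$start, decoy$start + round(0.50 * len)),
    end = c(decoy$start + round(0.45 * len), decoy$end),
    label = c("decoy_repeat_1", "decoy_repeat_2"))
  total_target <- config$repeat_fraction_target * sum(genome)
  placed <- 0
  rnd <- NULL
  zones <- layout$zones
  zones <- zones[zones$kind %in% c("planted", "decoy"), , drop = FALSE]
  i <- 0
  while (placed < total_target) {
    i <- i + 1
    rlen <- round(runif(1, 1e4, 1e5))
    z <- place_interval(rlen, genome, zones, "repeat_block")
    rnd <- rbind(rnd, data.frame(chrom = z$chrom, start = z$start,
                                 end = z$end,
                                 label = sprintf("rep%04d", i)))
    placed <- placed + rlen
  }
  evidence_track("repeat", rbind(decoy_iv, rnd))
}

#' Build the simulated repeat-mask track
#'
#' Deterministic given `config$seed`: the same track `simulate_cohort()`
#' emits. It always contains decoy intervals masking more than 80% of a
#' region that also carries a planted-style recurrent case cluster, so
#' the repeat filter has a true positive to remove; random repeat blocks
#' are added (outside planted zones) until `repeat_fraction_target` of
#' the genome is covered.
#'
#' @param config A [sim_config()].
#' @return An `evidence_track` of name `"repeat"`.
#' @export
make_repeat_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- sim_layout(config)
  build_repeat_track(config, layout)
}

# "repeat_block" reuses the background separation rules
# (zone_separation treats unknown kinds as small features)

one_call <- function(chrom, start, end, type, sample_id, cohort,
                     family_id = NA_character_) {
  data.frame(chrom = chrom, start = start, end = end, cnv_type = type,
             sample_id = sample_id, cohort = cohort,
             platform = "sim", family_id = family_id,
             stringsAsFactors = FALSE)
}

#' Simulate a case/control/trio CNV cohort with known ground truth
#'
#' Generates, deterministically for a given seed, the full input set of
#' the screen: case and control call sets, parental call sets, gene
#' models, the four evidence tracks, a pedigree and a ground-truth
#' record. Structure:
#'
#' * planted rare intergenic regions: `planted_cases_per_region` distinct
#'   case samples each carry a boundary-jittered copy of the region
#'   template (jitter at most 10% of length per boundary, so all copies
#'   mutually overlap and reciprocally overlap above 0.5); the regions
#'   lie outside every gene, common-polymorphism locus and repeat block,
#'   and more than 1 Mb from each other;
#' * common copy-number polymorphisms carried by at least
#'   `common_cnp_freq` of cases *and* of controls (removed by the rarity
#'   filter; also catalogued in the common-variant track);
#' * genic decoys: recurrent case clusters overlapping gene spans
#'   (removed by the intergenic filter);
#' * one repeat decoy: a recurrent intergenic case cluster in a region
#'   masked over 80% (removed only by the repeat filter);
#' * singleton background calls per sample (Poisson,
#'   `background_rate`): case background calls are placed so that no two
#'   from different samples overlap, keeping the planted regions the
#'   only true recurrent intergenic signal;
#' * trios for `trio_fraction` of cases: each proband call is labelled
#'   inherited with probability `inherited_fraction` and copied (with
#'   jitter) into one parent's call set; de-novo calls appear in neither
#'   parent.
#'
#' @param config A [sim_config()].
#' @return A list of class `cnv_simulation` with elements `config`,
#'   `case_calls`, `control_calls`, `parent_calls`, `genes`, `tracks`
#'   (named list of four `evidence_track`s), `pedigree` and
#'   `ground_truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- sim_layout(config)
  repeat_track <- build_repeat_track(config, layout)

  case_ids <- sprintf("case_%04d", seq_len(config$n_cases))
  case_fams <- sprintf("F%04d", seq_len(config$n_cases))
  ctrl_ids <- sprintf("ctrl_%04d", seq_len(config$n_controls))

  calls <- list()
  push <- function(x) calls[[length(calls) + 1]] <<- x

  # planted rare intergenic recurrent regions
  planted_members <- NULL
  if (!is.null(layout$planted)) {
    for (i in seq_len(nrow(layout$planted))) {
      p <- layout$planted[i, ]
      type <- sample(c("loss", "gain"), 1, prob = c(0.8, 0.2))
      members <- sample(case_ids, config$planted_cases_per_region)
      for (sid in members) {
        iv <- jitter_interval(p$start, p$end)
        push(one_call(p$chrom, iv["start"], iv["end"], type, sid, "case",
                      case_fams[match(sid, case_ids)]))
        planted_members <- rbind(planted_members, data.frame(
          region = p$region, chrom = p$chrom, start = iv["start"],
          end = iv["end"], sample_id = sid, stringsAsFactors = FALSE))
      }
    }
  }

  # common copy-number polymorphisms (cases and controls)
  ctrl_calls <- list()
  cpush <- function(x) ctrl_calls[[length(ctrl_calls) + 1]] <<- x
  if (!is.null(layout$cnp)) {
    for (i in seq_len(nrow(layout$cnp))) {
      cn <- layout$cnp[i, ]
      type <- sample(c("loss", "gain"), 1)
      n_case_car <- min(config$n_cases,
                        ceiling(config$common_cnp_freq * config$n_cases))
      n_ctrl_car <- min(config$n_controls,
                        ceiling(config$common_cnp_freq * config$n_controls))
      for (sid in sample(case_ids, n_case_car)) {
        iv <- jitter_interval(cn$start, cn$end, frac = 0.05)
        push(one_call(cn$chrom, iv["start"], iv["end"], type, sid, "case",
                      case_fams[match(sid, case_ids)]))
      }
      for (sid in sample(ctrl_ids, n_ctrl_car)) {
        iv <- jitter_interval(cn$start, cn$end, frac = 0.05)
        cpush(one_call(cn$chrom, iv["start"], iv["end"], type, sid,
                       "control"))
      }
    }
  }

  # genic decoys: recurrent case clusters overlapping gene spans
  genic_decoys <- NULL
  if (!is.null(layout$genes) && nrow(layout$genes) > 0 &&
      config$n_planted_regions > 0) {
    for (i in seq_len(config$n_planted_regions)) {
      g <- layout$genes[sample(nrow(layout$genes), 1), ]
      glen <- g$end - g$start
      # keep the decoy (and its jitter) strictly inside the gene span so
      # it stays genic and cannot drift toward a planted zone
      start <- g$start + round(0.2 * glen)
      dlen <- min(round(runif(1, 2e4, 6e4)), round(0.5 * glen))
      end <- start + dlen
      type <- sample(c("loss", "gain"), 1)
      for (sid in sample(case_ids, 2)) {
        iv <- jitter_interval(start, end, frac = 0.05)
        push(one_call(g$chrom, iv["start"], iv["end"], type, sid, "case",
                      case_fams[match(sid, case_ids)]))
      }
      genic_decoys <- rbind(genic_decoys, data.frame(
        chrom = g$chrom, start = start, end = end, gene_id = g$gene_id,
        stringsAsFactors = FALSE))
    }
  }

  # repeat decoy: recurrent intergenic cluster inside the masked region
  # (only when planted-style clusters are being generated at all)
  decoy <- layout$decoy
  decoy_carriers <- if (config$n_planted_regions > 0 &&
                          config$n_cases >= 2) sample(case_ids, 2) else
                            character()
  for (sid in decoy_carriers) {
    iv <- jitter_interval(decoy$start + 5e3, decoy$end - 5e3, frac = 0.05)
    push(one_call(decoy$chrom, iv["start"], iv["end"], "loss", sid, "case",
                  case_fams[match(sid, case_ids)]))
  }

  # singleton background calls; case backgrounds never overlap each other
  bg_zones <- layout$zones[layout$zones$kind %in%
                             c("planted", "decoy", "cnp"), , drop = FALSE]
  case_bg_zones <- bg_zones
  for (sid in case_ids) {
    for (k in seq_len(rpois(1, config$background_rate))) {
      len <- round(runif(1, 5e3, 4e4))
      z <- place_interval(len, config$genome, case_bg_zones, "background")
      case_bg_zones <- rbind(case_bg_zones, z)
      push(one_call(z$chrom, z$start, z$end,
                    sample(c("loss", "gain"), 1), sid, "case",
                    case_fams[match(sid, case_ids)]))
    }
  }
  for (sid in ctrl_ids) {
    for (k in seq_len(rpois(1, config$background_rate))) {
      len <- round(runif(1, 5e3, 4e4))
      z <- place_interval(len, config$genome, bg_zones, "background")
      cpush(one_call(z$chrom, z$start, z$end,
                     sample(c("loss", "gain"), 1), sid, "control"))
    }
  }

  case_calls <- if (length(calls)) as_cnv_calls(do.call(rbind, calls)) else
    empty_calls()
  control_calls <- if (length(ctrl_calls))
    as_cnv_calls(do.call(rbind, ctrl_calls)) else empty_calls()

  # trios: inherited proband calls are copied into one parent
  n_trio <- round(config$trio_fraction * config$n_cases)
  trio_ids <- if (n_trio > 0) sample(case_ids, n_trio) else character()
  suffix <- function(x, s) if (length(x)) paste0(x, s) else character()
  pedigree <- data.frame(proband = trio_ids,
                         father = suffix(trio_ids, "_f"),
                         mother = suffix(trio_ids, "_m"),
                         stringsAsFactors = FALSE)
  parent_calls <- list()
  labels <- NULL
  if (nrow(case_calls) > 0) {
    for (i in seq_len(nrow(case_calls))) {
      sid <- case_calls$sample_id[i]
      if (!sid %in% trio_ids) next
      inherited <- runif(1) < config$inherited_fraction
      if (inherited) {
        parent <- paste0(sid, if (runif(1) < 0.5) "_m" else "_f")
        iv <- jitter_interval(case_calls$start[i], case_calls$end[i])
        parent_calls[[length(parent_calls) + 1]] <-
          one_call(case_calls$chrom[i], iv["start"], iv["end"],
                   case_calls$cnv_type[i], parent, "parent")
      }
      labels <- rbind(labels, data.frame(
        sample_id = sid, chrom = case_calls$chrom[i],
        start = case_calls$start[i], end = case_calls$end[i],
        status = if (inherited) "inherited" else "de_novo",
        stringsAsFactors = FALSE))
    }
  }
  parent_calls <- if (length(parent_calls))
    as_cnv_calls(do.call(rbind, parent_calls)) else empty_calls()

  tracks <- list(
    common_variant = evidence_track("common_variant", if (is.null(layout$cnp))
      data.frame(chrom = character(), start = numeric(), end = numeric())
      else data.frame(chrom = layout$cnp$chrom,
                      start = pmax(1, layout$cnp$start - 5e3),
                      end = layout$cnp$end + 5e3,
                      label = sprintf("cnp%02d", layout$cnp$locus))),
    `repeat` = repeat_track,
    expressed_sequence = evidence_track("expressed_sequence",
      if (is.null(layout$planted) || nrow(layout$planted) == 0)
        data.frame(chrom = character(), start = numeric(), end = numeric())
      else {
        es <- layout$planted[seq(1, nrow(layout$planted), by = 2), ,
                             drop = FALSE]
        data.frame(chrom = es$chrom,
                   start = round((es$start + es$end) / 2) - 5e3,
                   end = round((es$start + es$end) / 2) + 5e3,
                   label = sprintf("EST%02d", es$region))
      }),
    conserved_element = evidence_track("conserved_element",
      if (is.null(layout$planted) || nrow(layout$planted) < 2)
        data.frame(chrom = character(), start = numeric(), end = numeric())
      else {
        ce <- layout$planted[2, , drop = FALSE]
        data.frame(chrom = ce$chrom,
                   start = round((ce$start + ce$end) / 2) - 2e3,
                   end = round((ce$start + ce$end) / 2) + 2e3,
                   label = "cons01")
      }))

  ground_truth <- list(
    planted_regions = layout$planted,
    planted_members = planted_members,
    common_cnp_loci = layout$cnp,
    genic_decoys = genic_decoys,
    repeat_decoys = data.frame(chrom = decoy$chrom, start = decoy$start,
                               end = decoy$end, stringsAsFactors = FALSE),
    inheritance_labels = labels)

  structure(list(config = config, case_calls = case_calls,
                 control_calls = control_calls,
                 parent_calls = parent_calls, genes = layout$genes,
                 tracks = tracks, pedigree = pedigree,
                 ground_truth = ground_truth),
            class = "cnv_simulation")
}

#' @export
print.cnv_simulation <- function(x, ...) {
  cat("<cnv_simulation>", x$config$n_cases, "cases /",
      x$config$n_controls, "controls;",
      nrow(x$case_calls), "case calls,", nrow(x$control_calls),
      "control calls,", nrow(x$parent_calls), "parent calls;",
      if (is.null(x$ground_truth$planted_regions)) 0 else
        nrow(x$ground_truth$planted_regions), "planted region(s)\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the formats the readers consume: BED-like TSV call sets
#' (`cases.tsv`, `controls.tsv`, `parents.tsv`), `genes.gff3`, one BED
#' per evidence track, `pedigree.tsv`, plus `ground_truth.json` and
#' `config.yaml`.
#'
#' @param sim A `cnv_simulation`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cnv_bed(sim$case_calls, file.path(dir, "cases.tsv"))
  write_cnv_bed(sim$control_calls, file.path(dir, "controls.tsv"))
  write_cnv_bed(sim$parent_calls, file.path(dir, "parents.tsv"))
  gr <- GenomicRanges::GRanges(
    seqnames = sim$genes$chrom,
    ranges = IRanges::IRanges(sim$genes$start, sim$genes$end),
    strand = ifelse(sim$genes$strand %in% c("+", "-"), sim$genes$strand,
                    "*"),
    type = "gene", ID = sim$genes$gene_id, Name = sim$genes$gene_id)
  rtracklayer::export(gr, file.path(dir, "genes.gff3"), format = "gff3")
  for (nm in names(sim$tracks)) {
    write_track_bed(sim$tracks[[nm]],
                    file.path(dir, paste0(nm, ".bed")))
  }
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.tsv"))
  jsonlite::write_json(sim$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- sim$config
  class(cfg) <- NULL
  cfg$genome <- as.list(cfg$genome)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
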