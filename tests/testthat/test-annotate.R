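# Nearest-gene geometry, candidate flags, evidence, bins, inheritance.

region1 <- function(chrom = "1", start = 10000, end = 20000) {
  list(chrom = chrom, start = start, end = end)
}

test_that("nearest gene minimizes the gap, with deterministic ties", {
  genes <- mk_genes("1", c(25001, 40000), c(30000, 45000),
                    id = c("NEAR", "FAR"))
  near <- nearest_gene_distance(region1(), genes)
  expect_equal(near$gene_id, "NEAR")
  expect_equal(near$nearest_distance_bp, 5000)
  expect_equal(near$status, "ok")
  # abutting gene -> distance 0
  ab <- nearest_gene_distance(region1(), mk_genes("1", 20001, 30000))
  expect_equal(ab$nearest_distance_bp, 0)
  # tie broken toward the smaller gene start
  tie <- mk_genes("1", c(25001, 1, 25001), c(30000, 4999, 26000),
                  id = c("B", "LEFT", "A"))
  # LEFT gap: 10000 - 4999 - 1 = 5000, equal to both right genes
  got <- nearest_gene_distance(region1(), tie)
  expect_equal(got$gene_id, "LEFT")
  # no gene on the chromosome
  none <- nearest_gene_distance(region1("9"), genes)
  expect_equal(none$status, "none")
  expect_true(is.na(none$gene_id))
})

test_that("furthest distance is the largest member gap to the named gene", {
  genes <- mk_genes("1", 25001, 30000, id = "G")
  members <- mk_calls("1", c(10000, 14000), c(20000, 16000),
                      sample = c("a", "b"))
  got <- nearest_gene_distance(region1(), genes, members)
  expect_equal(got$nearest_distance_bp, 5000)
  expect_equal(got$furthest_distance_bp, 25001 - 16000 - 1)
  # single member: nearest == furthest
  one <- nearest_gene_distance(region1(), genes,
                               mk_calls("1", 10000, 20000))
  expect_equal(one$nearest_distance_bp, one$furthest_distance_bp)
})

test_that("direction is strand-aware", {
  plus <- mk_genes("1", 25001, 30000, strand = "+")
  minus <- mk_genes("1", 25001, 30000, strand = "-")
  expect_equal(nearest_gene_distance(region1(), plus)$direction, "upstream")
  expect_equal(nearest_gene_distance(region1(), minus)$direction,
               "downstream")
  after <- region1(start = 40000, end = 50000)
  expect_equal(nearest_gene_distance(after, plus)$direction, "downstream")
  both <- nearest_gene_distance(
    region1(start = 20000, end = 42000),
    plus, members = mk_calls("1", c(20000, 32000), c(24000, 42000),
                             sample = c("a", "b")))
  expect_equal(both$direction, "flanking_both")
})

test_that("candidate-gene flag covers nearest and in-window genes", {
  genes <- mk_genes("1", c(25001, 500000), c(30000, 600000),
                    id = c("PLAIN", "RISK"))
  ann <- data.frame(region_id = "L01", chrom = "1", start = 10000,
                    end = 20000, nearest_gene = "PLAIN")
  expect_true(flag_candidate_genes(ann, genes, "RISK")$is_candidate_gene)
  expect_false(flag_candidate_genes(ann, genes,
                                    character(0))$is_candidate_gene)
  expect_true(flag_candidate_genes(ann, genes, "PLAIN")$is_candidate_gene)
  # outside the window the non-nearest gene stops counting
  expect_false(flag_candidate_genes(ann, genes, "RISK",
                                    window = 1e5)$is_candidate_gene)
})

test_that("evidence labels collect every overlapping track", {
  es <- evidence_track("expressed_sequence",
                       data.frame(chrom = "1", start = 15000, end = 16000))
  ce <- evidence_track("conserved_element",
                       data.frame(chrom = "1", start = 19000, end = 25000))
  far <- evidence_track("repeat",
                        data.frame(chrom = "1", start = 9e5, end = 1e6))
  expect_setequal(evidence_overlap(region1(), list(es, ce, far)),
                  c("expressed_sequence", "conserved_element"))
  expect_equal(evidence_overlap(region1(), list()), character(0))
})

test_that("mechanism bins follow the evidence rules", {
  genes <- mk_genes("1", 25001, 30000, id = "G")
  near <- nearest_gene_distance(region1(), genes)
  # no evidence, gene nearby -> {i}
  expect_equal(assign_bin(region1(), near, genes, list()), "i")
  # expressed sequence overlapping the region but far from the gene
  es_far <- evidence_track("expressed_sequence",
                           data.frame(chrom = "1", start = 15000,
                                      end = 16000))
  expect_equal(assign_bin(region1(), near, genes, list(es_far),
                          gene_link_gap = 1000), c("i", "ii"))
  # expressed sequence reaching to within the link gap of the gene span
  es_linked <- evidence_track("expressed_sequence",
                              data.frame(chrom = "1", start = 15000,
                                         end = 24800))
  expect_equal(assign_bin(region1(), near, genes, list(es_linked),
                          gene_link_gap = 1000), c("i", "iii"))
  # conserved element is never gene-linked -> ii
  ce <- evidence_track("conserved_element",
                       data.frame(chrom = "1", start = 15000, end = 16000))
  expect_equal(assign_bin(region1(), near, genes, list(ce)), c("i", "ii"))
  # purity: identical inputs, identical bins
  expect_identical(assign_bin(region1(), near, genes, list(es_far)),
                   assign_bin(region1(), near, genes, list(es_far)))
})

test_that("inheritance follows parent matching with maternal priority", {
  ped <- data.frame(proband = c("kid1", "kid2", "kid3"),
                    father = c("dad1", NA, "dad3"),
                    mother = c("mom1", "mom2", "mom3"),
                    stringsAsFactors = FALSE)
  kid_calls <- mk_calls("1", c(1000, 1000, 1000, 1000),
                        c(2000, 2000, 2000, 2000),
                        sample = c("kid1", "kid2", "kid3", "kid4"))
  parent_calls <- rbind(
    mk_calls("1", 1050, 2020, sample = "mom1", cohort = "parent"),
    mk_calls("1", 1050, 2020, sample = "dad1", cohort = "parent"),
    mk_calls("1", 950, 1980, sample = "dad3", cohort = "parent"))
  got <- determine_inheritance(kid_calls, parent_calls, ped)
  expect_equal(got$inheritance,
               c("inherited_maternal",  # both parents carry it -> maternal
                 "unknown",             # father missing, mother no match
                 "inherited_paternal",
                 "unknown"))            # kid4 not in the pedigree
  expect_true(got$both_parents[1])
  expect_false(got$both_parents[3])
  # both parents present, neither matches -> de novo
  dn <- determine_inheritance(
    mk_calls("1", 5e5, 6e5, sample = "kid1"), parent_calls, ped)
  expect_equal(dn$inheritance, "de_novo")
  # same-type requirement: an overlapping parental gain does not explain
  # a proband loss
  wrongtype <- determine_inheritance(
    mk_calls("1", 1000, 2000, type = "gain", sample = "kid3"),
    parent_calls, ped)
  expect_equal(wrongtype$inheritance, "de_novo")
})

test_that("annotate_regions assembles one annotation row per locus", {
  fx <- load_table1_fixture()
  rs <- merge_loci(cluster_regions(overlap_clusters(fx)))
  genes <- mk_genes(c("2", "16"), c(50000000, 61840001),
                    c(51157000, 62000000), id = c("NRXN1", "CDH8"),
                    strand = c("-", "+"))
  ann <- annotate_regions(rs, genes)
  expect_equal(nrow(ann$annotations), 15)
  a2p <- ann$annotations[ann$annotations$chrom == "2", ]
  expect_equal(a2p$nearest_gene, "NRXN1")
  expect_true(a2p$is_candidate_gene)
  expect_true(all(ann$members$inheritance == "unknown"))
  # loci on chromosomes without genes are annotated as having none
  a11 <- ann$annotations[ann$annotations$chrom == "11", ]
  expect_true(all(is.na(a11$nearest_gene)))
})
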