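# Overlap clustering, locus merging and the region-level filters.

test_that("overlap clustering is single-linkage per chromosome", {
  # two disjoint calls -> two singleton clusters
  cl <- overlap_clusters(mk_calls("1", c(100, 5000), c(200, 6000),
                                  sample = c("a", "b")))
  expect_equal(length(unique(cl$cluster_id)), 2)
  # chain: a-b overlap, b-c overlap, a-c disjoint -> one cluster
  cl2 <- overlap_clusters(mk_calls("1", c(100, 150, 260), c(170, 300, 400),
                                   sample = c("a", "b", "c")))
  expect_equal(length(unique(cl2$cluster_id)), 1)
  # type is ignored: a loss and a gain at one position cluster together
  cl3 <- overlap_clusters(mk_calls("1", c(100, 150), c(200, 250),
                                   type = c("loss", "gain"),
                                   sample = c("a", "b")))
  expect_equal(length(unique(cl3$cluster_id)), 1)
  # same coordinates on different chromosomes never cluster
  cl4 <- overlap_clusters(mk_calls(c("1", "2"), 100, 200,
                                   sample = c("a", "b")))
  expect_equal(length(unique(cl4$cluster_id)), 2)
})

test_that("the 2p16.3 reference rows form three overlap clusters", {
  fx <- load_table1_fixture()
  p <- fx[fx$locus == "2p16.3", ]
  cl <- overlap_clusters(p)
  spans <- sapply(split(cl, cl$cluster_id),
                  function(m) paste(min(m$start), max(m$end)))
  expect_equal(length(spans), 3)
  expect_setequal(unname(spans),
                  c("51157414 51225851", "51405882 51524684",
                    "52220120 52253660"))
})

test_that("cluster partitions equal the all-pairs union-find oracle", {
  calls <- random_calls(400, seed = 3, chroms = c("1", "2", "3"),
                        chrom_len = 5e7)
  got <- clusters_as_partition(overlap_clusters(calls), calls)
  expect_equal(got, bf_clusters(calls))
})

test_that("locus merging joins clusters within the gap and not beyond", {
  fx <- load_table1_fixture()
  # the two 4q13.1 clusters (gap ~412 kb) merge under 1 Mb
  q4 <- fx[fx$locus == "4q13.1", ]
  rs <- merge_loci(cluster_regions(overlap_clusters(q4)), 1e6)
  expect_equal(nrow(rs$regions), 1)
  expect_equal(rs$regions$n_clusters, 2)
  # the two 11p12 table entries (gap ~1.29 Mb) stay separate
  p11 <- fx[fx$locus == "11p12", ]
  rs2 <- merge_loci(cluster_regions(overlap_clusters(p11)), 1e6)
  expect_equal(nrow(rs2$regions), 2)
  # boundary: span gap exactly equal to the threshold merges
  two <- mk_calls("1", c(1000, 2000 + 1e6 + 1), c(2000, 3000 + 1e6),
                  sample = c("a", "b"))
  expect_equal(nrow(merge_loci(cluster_regions(overlap_clusters(two)),
                               1e6)$regions), 1)
  three <- mk_calls("1", c(1000, 2000 + 1e6 + 2), c(2000, 3000 + 1e6),
                    sample = c("a", "b"))
  expect_equal(nrow(merge_loci(cluster_regions(overlap_clusters(three)),
                               1e6)$regions), 2)
  # gap 0 is a no-op beyond overlap clustering
  cl <- cluster_regions(overlap_clusters(fx))
  expect_equal(nrow(merge_loci(cl, 0)$regions), nrow(cl$regions))
})

test_that("recurrence requires unrelated case carriers", {
  related <- mk_calls("1", c(100, 150), c(300, 350),
                      sample = c("sib1", "sib2"), family = "FAM1")
  rs <- cluster_regions(overlap_clusters(related))
  expect_equal(nrow(recurrence_filter(rs, min_cases = 2)$regions), 0)
  unrelated <- mk_calls("1", c(100, 150), c(300, 350),
                        sample = c("p1", "p2"),
                        family = c("FAM1", "FAM2"))
  rs2 <- cluster_regions(overlap_clusters(unrelated))
  expect_equal(nrow(recurrence_filter(rs2, min_cases = 2)$regions), 1)
  # missing family ids fall back to sample ids
  nofam <- mk_calls("1", c(100, 150), c(300, 350), sample = c("p1", "p2"))
  rs3 <- cluster_regions(overlap_clusters(nofam))
  expect_equal(nrow(recurrence_filter(rs3, min_cases = 2)$regions), 1)
  # the reference 7q21.11 pair is retained
  fx <- load_table1_fixture()
  rs4 <- recurrence_filter(
    cluster_regions(overlap_clusters(fx[fx$locus == "7q21.11", ])))
  expect_equal(sort(unique(rs4$members$sample_id)),
               c("1-0345-005", "8-6258-03"))
})

test_that("control absence is strict by default and type-aware", {
  region <- cluster_regions(overlap_clusters(
    mk_calls("1", c(1000, 1200), c(2000, 2100), sample = c("a", "b"))))
  hit <- mk_calls("1", 1500, 1600, type = "loss", sample = "ctrl1",
                  cohort = "control")
  expect_equal(nrow(control_absence_filter(region, hit)$regions), 0)
  # a control CNV of the opposite type does not remove the region
  opp <- mk_calls("1", 1500, 1600, type = "gain", sample = "ctrl1",
                  cohort = "control")
  expect_equal(nrow(control_absence_filter(region, opp)$regions), 1)
  expect_equal(nrow(control_absence_filter(region, opp,
                                           same_type = FALSE)$regions), 0)
  # tolerance knob
  expect_equal(nrow(control_absence_filter(region, hit,
                                           max_control_carriers = 1)$regions),
               1)
  # no controls at all
  expect_equal(nrow(control_absence_filter(
    region, mk_calls(character(0), numeric(0), numeric(0)))$regions), 1)
})

test_that("common-variant coverage removes regions at or above the bound", {
  region <- cluster_regions(overlap_clusters(
    mk_calls("1", c(1, 101), c(1000, 900), sample = c("a", "b"))))
  inside <- evidence_track("common_variant",
                           data.frame(chrom = "1", start = 1, end = 5000))
  expect_equal(nrow(dgv_filter(region, inside)$regions), 0)
  none <- evidence_track("common_variant",
                         data.frame(chrom = "1", start = 4000, end = 5000))
  expect_equal(nrow(dgv_filter(region, none)$regions), 1)
  # exactly half the 1000-bp span covered -> removed (>= boundary)
  half <- evidence_track("common_variant",
                         data.frame(chrom = "1", start = 1, end = 500))
  expect_equal(nrow(dgv_filter(region, half, dgv_max_overlap = 0.5)$regions),
               0)
  # split intervals must not double-count overlap
  split_cov <- evidence_track("common_variant",
                              data.frame(chrom = "1", start = c(1, 200),
                                         end = c(400, 450)))
  expect_equal(nrow(dgv_filter(region, split_cov,
                               dgv_max_overlap = 0.5)$regions), 1)
})

test_that("repeat filter removes strictly above the masked fraction", {
  region <- cluster_regions(overlap_clusters(
    mk_calls("1", c(1, 101), c(1000, 900), sample = c("a", "b"))))
  at80 <- evidence_track("repeat",
                         data.frame(chrom = "1", start = 1, end = 800))
  expect_equal(nrow(repeat_filter(region, at80)$regions), 1)
  at81 <- evidence_track("repeat",
                         data.frame(chrom = "1", start = 1, end = 810))
  expect_equal(nrow(repeat_filter(region, at81)$regions), 0)
  # measured fraction lands in the trail
  tr <- repeat_filter(region, at81)$trail
  expect_equal(tr$value, 0.81)
  expect_false(tr$pass)
})

test_that("region filters only remove and keep a full audit trail", {
  calls <- random_calls(200, n_samples = 80, seed = 21, chroms = "1",
                        chrom_len = 2e7)
  rs <- cluster_regions(overlap_clusters(calls))
  track <- evidence_track("repeat",
                          data.frame(chrom = "1",
                                     start = seq(1, 2e7, by = 1e6),
                                     end = seq(1, 2e7, by = 1e6) + 4e5))
  controls <- random_calls(100, n_samples = 40, seed = 22, chroms = "1",
                           chrom_len = 2e7)
  controls$cohort <- "control"
  steps <- list(
    function(x) recurrence_filter(x),
    function(x) control_absence_filter(x, controls),
    function(x) dgv_filter(x, track),
    function(x) repeat_filter(x, track))
  cur <- rs
  for (step in steps) {
    nxt <- step(cur)
    expect_true(all(nxt$regions$region_id %in% cur$regions$region_id))
    # one trail row per region examined at this step
    expect_equal(nrow(nxt$trail) - nrow(cur$trail), nrow(cur$regions))
    cur <- nxt
  }
  # coverage-based filters commute
  ab <- repeat_filter(dgv_filter(rs, track), track)
  ba <- dgv_filter(repeat_filter(rs, track), track)
  expect_equal(ab$regions, ba$regions)
})
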