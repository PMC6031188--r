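## small fixed site table used throughout (two overlapping, one distant)
mk_sites <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000L, 1010L, 5000L, 700L),
    end = c(1023L, 1033L, 5023L, 723L),
    strand = "+", guide_id = "g1",
    n_mismatch = c(1L, 3L, 0L, 2L), seed_mismatch = c(1L, 2L, 0L, 1L),
    pam_observed = "TGG", pam_canonical = TRUE,
    protospacer_observed = "X", stringsAsFactors = FALSE)
}

test_that("variants map to overlapping sites with mismatch tie-breaking", {
  sites <- mk_sites()
  v <- rbind(
    vrow("chr1", 1015, "ATGC", "A"),   # overlaps sites 1 and 2
    vrow("chr1", 1100, "C", "T"),      # 100 bp away: none
    vrow("chr2", 698, "G", "GTT"),     # within 5-bp window of site 4
    vrow("chr2", 600, "G", "A"))       # none
  a <- assign_to_sites(v, sites, window = 5)
  expect_equal(a$site_idx, c(1L, NA, 4L, NA))  # lowest n_mismatch wins
  expect_equal(a$site_n_mismatch[1], 1L)
  ## window boundary: interval [start+1-w, end+w]
  edge <- assign_to_sites(vrow("chr1", 5028, "A", "T"), sites, window = 5)
  expect_equal(edge$site_idx, 3L)
  out <- assign_to_sites(vrow("chr1", 5029, "A", "T"), sites, window = 5)
  expect_true(is.na(out$site_idx))
})

test_that("replicate overlap partitions by exact key and reports shared loci", {
  ## disjoint sets
  a <- rbind(vrow("chr1", 10, "A", "T"), vrow("chr1", 500, "C", "G"))
  b <- vrow("chr1", 900, "G", "A", sample_id = "s2")
  ro <- replicate_overlap(a, b)
  expect_equal(nrow(ro$shared), 0)
  expect_equal(nrow(ro$unique_a), 2)
  expect_equal(nrow(ro$unique_b), 1)
  ## identical-allele sharing: 7 SNVs + 3 indels shared exactly
  shared <- rbind(
    do.call(rbind, lapply(1:7, function(i)
      vrow("chr1", i * 100, "A", "T"))),
    vrow("chr2", 100, "CA", "C"), vrow("chr2", 300, "G", "GAT"),
    vrow("chr2", 500, "TGG", "T"))
  a2 <- rbind(shared, vrow("chr3", 50, "A", "C"))
  b2 <- shared; b2$sample_id <- "s2"
  ro2 <- replicate_overlap(a2, b2)
  expect_equal(nrow(ro2$shared), 10)
  expect_equal(nrow(ro2$unique_a), 1)
  ## same locus, distinct alleles: 0 shared keys, 1 shared locus
  a3 <- vrow("chr1", 1017, "ATG", "A")
  b3 <- vrow("chr1", 1017, "ATGCC", "A", sample_id = "s2")
  ro3 <- replicate_overlap(a3, b3)
  expect_equal(nrow(ro3$shared), 0)
  expect_equal(nrow(ro3$shared_loci), 1)
})

test_that("classification follows the decision order with evidence", {
  sites <- mk_sites()
  ledger <- vrow("chr1", 9000, "T", "C")
  ledger$absorbed_by_group <- "TC_only"
  ledger_wt <- vrow("chr1", 9500, "G", "A")
  ledger_wt$absorbed_by_group <- "WT_G1"
  v <- rbind(
    vrow("chr1", 9000, "T", "C"),      # in TC control -> background
    vrow("chr1", 9500, "G", "A"),      # in WT control -> pre_existing
    vrow("chr1", 5010, "GAT", "G"),    # at declared target -> on_target
    vrow("chr1", 1015, "ATGC", "A"),   # indel at 1-mm site
    vrow("chr2", 710, "C", "A"),       # SNV at a site: candidate only
    vrow("chr1", 40000, "A", "T"))     # nothing -> spontaneous
  rep_v <- rbind(
    vrow("chr1", 1016, "TG", "T", sample_id = "s2"),  # distinct allele, same site
    vrow("chr1", 40000, "A", "T", sample_id = "s2"))
  cls <- classify_variants(v, sites, target_site_idx = 3L,
                           replicate_variants = rep_v,
                           controls_ledger = rbind(ledger, ledger_wt))
  expect_equal(cls$class,
               c("background", "pre_existing", "on_target",
                 "off_target_validated", "off_target_candidate",
                 "pre_existing"))
  expect_match(cls$evidence[1], "in_control:TC_only")
  expect_match(cls$evidence[4], "replicate_distinct_allele")
  expect_match(cls$evidence[5], "snv_at_site_not_validated")
  ## every variant gets exactly one class; counts conserve input size
  expect_equal(sum(table(cls$class)), nrow(v))
})

test_that("shared identical alleles with poor homology are pre-existing; last row is spontaneous without a replicate", {
  sites <- mk_sites()
  v <- vrow("chr1", 40000, "A", "T")
  ## no replicate: residue class
  solo <- classify_variants(v, sites, controls_ledger = v[0, ])
  expect_equal(solo$class, "spontaneous")
  ## identical allele in the replicate, no site homology -> pre-existing
  rep_v <- vrow("chr1", 40000, "A", "T", sample_id = "s2")
  dup <- classify_variants(v, sites, replicate_variants = rep_v)
  expect_equal(dup$class, "pre_existing")
  expect_match(dup$evidence, "shared_identical_allele")
})

test_that("removing the replicate demotes replicate-promoted calls", {
  sites <- mk_sites()
  v <- vrow("chr1", 1015, "ATGC", "A")
  rep_v <- vrow("chr1", 1016, "TG", "T", sample_id = "s2")
  with_rep <- classify_variants(v, sites, replicate_variants = rep_v)
  expect_equal(with_rep$class, "off_target_validated")
  ## no replicate and no control certification: candidate only
  without <- classify_variants(v, sites)
  expect_equal(without$class, "off_target_candidate")
  ## controls certify absence: single-line promotion applies at
  ## prediction-grade homology
  with_controls <- classify_variants(v, sites,
                                     controls_ledger = v[0, ])
  expect_equal(with_controls$class, "off_target_validated")
  expect_match(with_controls$evidence, "absent_from_controls")
})

test_that("classification is invariant to input row order", {
  sites <- mk_sites()
  v <- rbind(vrow("chr1", 1015, "ATGC", "A"),
             vrow("chr1", 40000, "A", "T"),
             vrow("chr2", 710, "C", "A"))
  rep_v <- vrow("chr1", 1016, "TG", "T", sample_id = "s2")
  c1 <- classify_variants(v, sites, replicate_variants = rep_v)
  c2 <- classify_variants(v[c(3, 1, 2), ], sites,
                          replicate_variants = rep_v)
  m <- match(variant_key(c1), variant_key(c2))
  expect_equal(c1$class, c2$class[m])
})

test_that("conflicting control attribution raises a classification error", {
  sites <- mk_sites()
  led <- rbind(vrow("chr1", 9000, "T", "C"), vrow("chr1", 9000, "T", "C"))
  led$absorbed_by_group <- c("TC_only", "WT_G1")
  expect_error(
    classify_variants(vrow("chr1", 9000, "T", "C"), sites,
                      controls_ledger = led),
    "conflicting")
})

test_that("per-guide summaries count validated loci and flag unsafe guides", {
  sites <- mk_sites()
  v1 <- classify_variants(vrow("chr1", 1015, "ATGC", "A"), sites,
                          replicate_variants =
                            vrow("chr1", 1016, "TG", "T",
                                 sample_id = "s2"))
  v1$guide_id <- "g1"
  v2 <- classify_variants(vrow("chr2", 600, "G", "A"), sites,
                          controls_ledger = v1[0, seq_len(8)])
  v2$guide_id <- "g2"
  summ <- summarize_guides(rbind(v1, v2))
  expect_equal(summ$n_validated_loci[summ$guide_id == "g1"], 1)
  expect_false(summ$safe[summ$guide_id == "g1"])
  expect_true(summ$safe[summ$guide_id == "g2"])
  ## no site-assigned variants anywhere: all guides report zero
  none <- classify_variants(vrow("chr1", 40000, "A", "T"), sites)
  none$guide_id <- "g1"
  s2 <- summarize_guides(none)
  expect_equal(s2$n_validated_loci, 0)
  expect_true(s2$safe)
})
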