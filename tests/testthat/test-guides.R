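proto <- "GATTACAGATTACAGGTTAC"

test_that("an exact protospacer+AGG site is found once with zero mismatches", {
  g <- simulate_reference(1, 10000, 0.5, seed = 3)
  g <- plant_seq(g, "chr1", 5000, paste0(proto, "AGG"))
  hits <- find_sites(g, guide_spec("g1", proto), 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 4999)           # 0-based
  expect_equal(hits$end - hits$start, 23)  # protospacer + PAM
  expect_equal(hits$n_mismatch, 0)
  expect_equal(hits$strand, "+")
})

test_that("a silent PAM variant (TGG vs CGG) is a 0-mismatch canonical match", {
  g <- simulate_reference(1, 20000, 0.5, seed = 4)
  g <- plant_seq(g, "chr1", 2000, paste0(proto, "TGG"))
  g <- plant_seq(g, "chr1", 9000, paste0(proto, "CGG"))
  hits <- find_sites(g, guide_spec("g1", proto), 0)
  expect_equal(nrow(hits), 2)
  expect_true(all(hits$n_mismatch == 0))
  expect_true(all(hits$pam_canonical))     # both satisfy NGG
})

test_that("the alternative NAG PAM is matched only when enabled", {
  g <- simulate_reference(1, 10000, 0.5, seed = 5)
  g <- plant_seq(g, "chr1", 3000, paste0(proto, "CAG"))
  gd <- guide_spec("g1", proto)
  expect_equal(nrow(find_sites(g, gd, 0)), 0)
  hits <- find_sites(g, gd, 0, pam_patterns = c("NGG", "NAG"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$pam_observed, "CAG")
  expect_false(hits$pam_canonical)         # CAG does not satisfy NGG
})

test_that("reference N never matches a PAM or protospacer position", {
  g <- reference_genome(c(chr1 = paste0(strrep("ACGT", 10), proto, "NGG",
                                        strrep("ACGT", 10))))
  expect_equal(nrow(find_sites(g, guide_spec("g1", proto), 0)), 0)
  g2 <- reference_genome(c(chr1 = paste0(
    strrep("ACGT", 10), sub("^G", "N", proto), "AGG", strrep("ACGT", 10))))
  hits <- find_sites(g2, guide_spec("g1", proto), 1)
  expect_equal(hits$n_mismatch, 1)         # N counts as a mismatch
})

test_that("site lists are monotone in the mismatch budget", {
  g <- simulate_reference(1, 30000, 0.5, seed = 6)
  gd <- guide_spec("g1", proto)
  prev <- character(0)
  for (k in 0:6) {
    keys <- with(find_sites(g, gd, k, pam_patterns = c("NGG", "NAG")),
                 paste(chrom, start, strand))
    expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("scanning matches the exhaustive window oracle on random genomes", {
  withr::with_seed(707, {
    for (case in 1:5) {
      g <- reference_genome(c(
        c1 = random_protospacer(20000), c2 = random_protospacer(10000)))
      gd <- guide_spec("g1", random_protospacer(20))
      mm <- sample(0:3, 1)
      pams <- list("NGG", c("NGG", "NAG"))[[sample(2, 1)]]
      got <- find_sites(g, gd, mm, pam_patterns = pams)
      want <- oracle_find_sites(g, gd, mm, pam_patterns = pams)
      expect_identical(site_view(got), site_view(want),
                       info = paste("case", case))
    }
  })
})

test_that("strand symmetry: scanning the reverse-complemented genome mirrors sites", {
  g <- simulate_reference(1, 20000, 0.5, seed = 8)
  g <- plant_seq(g, "chr1", 4000, paste0(proto, "TGG"))
  g <- plant_seq(g, "chr1", 12000, revcomp(paste0(proto, "AGG")))
  gd <- guide_spec("g1", proto)
  fwd <- find_sites(g, gd, 2)
  grc <- reference_genome(c(chr1 = revcomp(g$seq[["chr1"]])))
  rev <- find_sites(grc, gd, 2)
  L <- g$lengths[["chr1"]]
  mirrored <- data.frame(start = L - rev$end,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         n_mismatch = rev$n_mismatch)
  mirrored <- mirrored[order(mirrored$start), ]
  fwd2 <- fwd[order(fwd$start), c("start", "strand", "n_mismatch")]
  rownames(mirrored) <- rownames(fwd2) <- NULL
  expect_equal(fwd2, mirrored)
})

test_that("seed mismatches are counted PAM-proximally", {
  g <- simulate_reference(1, 10000, 0.5, seed = 9)
  ## mismatch at PAM-distal position 20 (= protospacer position 1 as
  ## written for Cas9): outside an 18-nt seed
  distal <- paste0(sub("^G", "C", proto), "TGG")
  g1 <- plant_seq(g, "chr1", 2000, distal)
  hit <- find_sites(g1, guide_spec("g1", proto), 1)
  expect_equal(hit$n_mismatch, 1)
  expect_equal(hit$seed_mismatch, 0)
  expect_equal(count_seed_mismatches(hit, guide_spec("g1", proto), 18), 0)
  expect_equal(count_seed_mismatches(hit, guide_spec("g1", proto), 20), 1)
  ## 3 mismatches with exactly one in the 1-18 window from the PAM
  ch <- strsplit(proto, "")[[1]]
  for (p in c(1, 2, 10)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  g2 <- plant_seq(g, "chr1", 6000, paste0(paste(ch, collapse = ""), "AGG"))
  hit2 <- find_sites(g2, guide_spec("g1", proto), 3)
  expect_equal(hit2$n_mismatch, 3)
  expect_equal(hit2$seed_mismatch, 1)
})

test_that("flank alignment finds exact, bulged and no-homology cases", {
  gd <- guide_spec("g1", proto)
  flank <- paste0(random_protospacer(15), proto, random_protospacer(16))
  hits <- flank_align(flank, gd, min_match = 15)
  expect_gte(nrow(hits), 1)
  expect_equal(hits$matches[1], 20)        # full-length
  expect_equal(hits$bulges[1], 0)
  expect_equal(hits$start[1], 16)
  ## protospacer with one base deleted: best hit carries exactly one gap
  del <- paste0(substr(proto, 1, 9), substr(proto, 11, 20))
  flank2 <- paste0(random_protospacer(16), del, random_protospacer(16))
  hits2 <- flank_align(flank2, gd, min_match = 15)
  expect_equal(hits2$bulges[1], 1)
  expect_equal(hits2$matches[1], 19)
  expect_equal(hits2$span[1], 19)
  ## extra base inserted into the protospacer: one gap on the other side
  ins <- paste0(substr(proto, 1, 10), "A", substr(proto, 11, 20))
  hits3 <- flank_align(paste0(random_protospacer(15), ins,
                              random_protospacer(15)), gd, min_match = 15)
  expect_equal(hits3$bulges[1], 1)
  expect_equal(hits3$span[1], 21)
})

test_that("random flanks yield hits no more often than the alignment null predicts", {
  ## with min_match = 16, P(Bin(20, 1/4) >= 16) ~ 3.9e-7; over the ~2400
  ## enumerated alignments per flank the expected number of hit-carrying
  ## flanks in 400 draws is < 0.4 (gapped alignments are even less likely
  ## to reach 16 matches); allow a generous margin above that
  gd <- guide_spec("g1", proto)
  withr::with_seed(4242, {
    n_hit <- sum(vapply(1:400, function(i) {
      nrow(flank_align(random_protospacer(51), gd, min_match = 16)) > 0
    }, logical(1)))
  })
  expect_lte(n_hit, 3)
})

test_that("guide safety applies the 2-mismatch seed rule", {
  g <- simulate_reference(1, 50000, 0.5, seed = 10)
  g <- plant_seq(g, "chr1", 1000, paste0(proto, "TGG"))  # on-target
  gd <- guide_spec("g1", proto,
                   target = list(chrom = "chr1", start = 999L,
                                 strand = "+"))
  expect_true(guide_specificity(g, gd)$safe)
  ## a second perfect protospacer under NGG makes the guide unsafe
  g2 <- plant_seq(g, "chr1", 30000, paste0(proto, "GGG"))
  spec2 <- guide_specificity(g2, gd)
  expect_false(spec2$safe)
  expect_equal(spec2$best_offtarget$start, 29999)
  ## a 3-mismatch site with all mismatches in the seed stays safe
  ch <- strsplit(proto, "")[[1]]
  for (p in c(10, 14, 18)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  g3 <- plant_seq(g, "chr1", 30000, paste0(paste(ch, collapse = ""), "AGG"))
  spec3 <- guide_specificity(g3, gd)
  expect_true(spec3$safe)
  expect_equal(spec3$best_offtarget$seed_mismatch, 3)
})

test_that("guide construction validates inputs", {
  expect_error(guide_spec("g", "ACGTN"), "A/C/G/T")
  expect_error(guide_spec("g", "ACGT", pam_patterns = "XGG"), "IUPAC")
  expect_error(find_sites(simulate_reference(1, 1000, 0.5, seed = 1),
                          guide_spec("g", "ACGTACGT"), 9),
               "max_mismatch")
})
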