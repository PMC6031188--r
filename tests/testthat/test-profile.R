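test_that("mutation rate arithmetic and errors", {
  r <- mutation_rate(41, 3.74e8)
  expect_equal(r$rate, 41 / (2 * 3.74e8))
  expect_equal(mutation_rate(0, 1e6)$rate, 0)
  expect_equal(mutation_rate(150, 3.74e8)$rate, 2.005e-7, tolerance = 1e-3)
  ## haploid mode and generations
  expect_equal(mutation_rate(10, 1e6, n_generations = 2, ploidy = 1)$rate,
               10 / (1e6 * 2))
  expect_error(mutation_rate(10, 0), "genome length")
  expect_error(mutation_rate(10, 1e6, n_generations = 0), "n_generations")
  expect_error(mutation_rate(-1, 1e6), "n_mutations")
})

test_that("SNV spectrum folds purine changes onto the pyrimidine strand", {
  v <- vrow("chr1", 1, "G", "A")
  sp <- snv_spectrum(v)
  expect_equal(unname(sp$counts[["C>T"]]), 1)
  expect_equal(sum(sp$counts), 1)
  expect_equal(sp$gc_to_at_fraction, 1)
  ## all 12 raw changes once: counts fold 2:1, Ts/Tv = 4/8 = 0.5
  bases <- c("A", "C", "G", "T")
  all12 <- do.call(rbind, lapply(bases, function(r)
    do.call(rbind, lapply(setdiff(bases, r), function(a)
      vrow("chr1", 1, r, a)))))
  sp12 <- snv_spectrum(all12)
  expect_true(all(sp12$counts == 2))
  expect_equal(sum(sp12$counts), 12)
  expect_equal(sp12$ts_tv, 0.5)
  ## empty input: zero spectrum, undefined ratio
  sp0 <- snv_spectrum(all12[0, ])
  expect_true(all(sp0$counts == 0))
  expect_true(is.na(sp0$ts_tv))
  expect_error(snv_spectrum(vrow("chr1", 1, "GA", "G")), "SNVs only")
})

test_that("AF bins use the documented boundaries and conserve counts", {
  v <- rbind(vrow("chr1", 1, "A", "T", af = 0.0),
             vrow("chr1", 2, "A", "T", af = 0.25),   # downward
             vrow("chr1", 3, "A", "T", af = 0.26),
             vrow("chr1", 4, "A", "T", af = 0.5),
             vrow("chr1", 5, "A", "T", af = 0.7499),
             vrow("chr1", 6, "A", "T", af = 0.75),   # upward
             vrow("chr1", 7, "A", "T", af = 1.0))
  b <- af_bins(v)
  expect_equal(unname(b), c(2, 3, 2))
  expect_equal(sum(b), nrow(v))
  expect_error(af_bins(vrow("chr1", 1, "A", "T", af = 1.2)), "af")
  ## heterozygous calls with realistic AF noise stay heterozygous-like
  withr::with_seed(55, {
    noisy <- vrow("chr1", seq_len(1000), "A", "T",
                  af = pmin(1, pmax(0, 0.5 + rnorm(1000, sd = 0.05))))
  })
  bn <- af_bins(noisy)
  expect_gte(bn[["heterozygous_like"]] / 1000, 0.99)
})

test_that("feature tracks resolve category precedence and cover the genome", {
  g <- simulate_reference(1, 10000, 0.5, seed = 20)
  iv <- data.frame(
    chrom = "chr1",
    start = c(1, 1, 3001), end = c(2000, 1000, 5000),
    category = c("TE", "CDS", "repeat"), stringsAsFactors = FALSE)
  tr <- feature_track(iv, g)
  ## CDS outranks TE on the first kb
  expect_equal(unname(tr$fractions[["CDS"]]), 0.1)
  expect_equal(unname(tr$fractions[["TE"]]), 0.1)
  expect_equal(unname(tr$fractions[["repeat"]]), 0.2)
  expect_equal(sum(tr$fractions), 1)
  expect_equal(variant_categories(vrow("chr1", 500, "A", "T")[, ], tr),
               "CDS")
  expect_equal(variant_categories(vrow("chr1", 9000, "A", "T"), tr),
               "intergenic")
  expect_error(feature_track(data.frame(chrom = "chr1", start = 1,
                                        end = 10, category = "exonic"), g),
               "unknown categories")
})

test_that("enrichment arithmetic: all variants in a 20% category give ratio 5", {
  g <- simulate_reference(1, 10000, 0.5, seed = 21)
  tr <- feature_track(data.frame(chrom = "chr1", start = 1, end = 2000,
                                 category = "TE"), g)
  v <- vrow("chr1", c(100, 500, 900, 1500, 1900), "A", "T")
  enr <- feature_enrichment(v, tr)
  te <- enr[enr$category == "TE", ]
  expect_equal(te$observed, 5)
  expect_equal(te$expected, 1)
  expect_equal(te$enrichment, 5)
  expect_lt(te$p_value, 0.01)
})

test_that("uniform variants show no enrichment and null p-values are super-uniform", {
  g <- simulate_reference(1, 50000, 0.5, seed = 22)
  tr <- feature_track(data.frame(chrom = "chr1", start = 1, end = 25000,
                                 category = "TE"), g)
  withr::with_seed(777, {
    ratios <- numeric(200)
    pvals <- numeric(200)
    for (i in 1:200) {
      pos <- sample.int(50000, 60)
      v <- data.frame(sample_id = "s", chrom = "chr1", pos = pos,
                      ref = "A", alt = "T", kind = "SNV", af = 0.5,
                      dp = 60, stringsAsFactors = FALSE)
      enr <- feature_enrichment(v, tr)
      ratios[i] <- enr$enrichment[enr$category == "TE"]
      pvals[i] <- enr$p_value[enr$category == "TE"]
    }
  })
  ## ratio centred on 1 within binomial error of the mean
  se <- sqrt(0.5 * 0.5 / 60) / 0.5 / sqrt(200)
  expect_lt(abs(mean(ratios) - 1), 4 * se)
  ## super-uniform: empirical exceedance below nominal plus sampling slack
  for (alpha in c(0.01, 0.05, 0.1)) {
    expect_lte(mean(pvals <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / 200))
  }
})
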