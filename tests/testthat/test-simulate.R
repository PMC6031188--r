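test_that("truth sets are deterministic, on-genome and collision-free", {
  g <- simulate_reference(2, 50000, 0.43, seed = 1)
  m <- mutation_load_model(40, 20)
  t1 <- simulate_truth_set(g, m, seed = 11, sample_id = "s1")
  t2 <- simulate_truth_set(g, m, seed = 11, sample_id = "s1")
  expect_identical(t1, t2)
  t3 <- simulate_truth_set(g, m, seed = 12, sample_id = "s1")
  expect_false(identical(t1$pos, t3$pos))
  ## ref alleles match the genome; intervals do not overlap
  expect_silent(apply_variants(g, "chr1",
                               t1[t1$chrom == "chr1", , drop = FALSE]))
  expect_silent(apply_variants(g, "chr2",
                               t1[t1$chrom == "chr2", , drop = FALSE]))
})

test_that("zero-mean models yield empty truth sets and loads are Poisson", {
  g <- simulate_reference(1, 100000, 0.43, seed = 2)
  expect_equal(nrow(simulate_truth_set(g, mutation_load_model(0, 0),
                                       seed = 1)), 0)
  ## 200 replicate draws: sample mean within 3 Poisson standard errors
  n <- vapply(1:200, function(s)
    nrow(simulate_truth_set(g, mutation_load_model(114, 0), seed = s)),
    integer(1))
  expect_lt(abs(mean(n) - 114), 3 * sqrt(114 / 200))
})

test_that("allele-frequency modes have the documented structure", {
  g <- simulate_reference(1, 100000, 0.43, seed = 3)
  het <- simulate_truth_set(g, mutation_load_model(50, 10), seed = 4)
  expect_true(all(het$true_af == 0.5))
  hom <- simulate_truth_set(g, mutation_load_model(50, 10,
                                                   af_mode = "homozygous"),
                            seed = 4)
  expect_true(all(hom$true_af == 1))
  som <- simulate_truth_set(g, mutation_load_model(50, 10,
                                                   af_mode = "somatic"),
                            seed = 4)
  expect_true(all(som$true_af > 0 & som$true_af < 0.25))
})

test_that("load models validate their parameters", {
  expect_error(mutation_load_model(-1, 0), "means")
  expect_error(mutation_load_model(10, 10, indel_size_range = c(0, 5)),
               "indel_size_range")
  g <- simulate_reference(1, 1000, 0.43, seed = 1)
  expect_error(simulate_truth_set(g, mutation_load_model(500, 0), seed = 1),
               "capacity")
})

test_that("guide edits respect efficiency and draw independent alleles", {
  g <- simulate_reference(1, 200000, 0.43, seed = 5)
  bench <- build_benchmark_guides(g, n_safe = 0, seed = 6)
  gd <- bench$guides[["guideX"]]
  sites <- bench$edit_sites[["guideX"]]
  ## efficiency 1: both replicates edited at all sites
  reps <- plant_guide_edits(bench$genome, gd, sites, efficiency = 1,
                            n_replicates = 2, seed = 7)
  expect_equal(nrow(reps[[1]]), nrow(sites))
  expect_equal(nrow(reps[[2]]), nrow(sites))
  expect_setequal(unique(reps[[1]]$class), c("on_target", "off_target"))
  ## efficiency 0: nothing
  none <- plant_guide_edits(bench$genome, gd, sites, efficiency = 0,
                            n_replicates = 2, seed = 7)
  expect_equal(nrow(none[[1]]), 0)
  expect_error(plant_guide_edits(bench$genome, gd, sites, 1.2, 1, 1),
               "efficiency")
  ## allele identity between replicates ~ 1 / catalog size (25):
  ## 25 seeds x 13 sites = 325 site-pairs, binomial 3-sigma band
  n_pairs <- 0; n_same <- 0
  for (s in 1:25) {
    r <- plant_guide_edits(bench$genome, gd, sites, 1, 2, seed = s)
    k1 <- variant_key(r[[1]]); k2 <- variant_key(r[[2]])
    n_pairs <- n_pairs + length(k1)
    n_same <- n_same + sum(k1 == k2)
  }
  p <- 1 / nrow(indel_catalog())
  expect_lt(abs(n_same - n_pairs * p), 3 * sqrt(n_pairs * p * (1 - p)) + 1)
  ## edits land inside their site interval (cut placement)
  expect_true(all(reps[[1]]$pos >= sites$start - 1 &
                    reps[[1]]$pos <= sites$end + 1))
})

test_that("caller emulation degenerates to the truth and respects rates", {
  g <- simulate_reference(1, 100000, 0.43, seed = 8)
  truth <- simulate_truth_set(g, mutation_load_model(60, 20), seed = 9,
                              sample_id = "s1")
  exact <- emulate_callers(truth, caller_emulation_model(
    fp_rate = 0, fn_rate = 0, af_noise_sd = 0), g, seed = 10)
  for (cs in exact) {
    expect_setequal(variant_key(cs), variant_key(truth))
    expect_equal(sort(cs$af), sort(truth$true_af))
  }
  ## fn_rate 1: only false positives remain
  only_fp <- emulate_callers(truth, caller_emulation_model(
    fp_rate = 1e-4, fn_rate = 1), g, seed = 10)
  for (cs in only_fp)
    expect_false(any(variant_key(cs) %in% variant_key(truth)))
  ## false positives never coincide with truth positions, and the FP count
  ## is Poisson(fp_rate * L): 30 seeds, 3-sigma band around 10
  fp_counts <- vapply(1:30, function(s) {
    cs <- emulate_callers(truth, caller_emulation_model(fp_rate = 1e-4,
                                                        fn_rate = 0),
                          g, seed = s)[[1]]
    expect_false(any(paste(cs$chrom, cs$pos) %in%
                       paste(truth$chrom, truth$pos) &
                       !variant_key(cs) %in% variant_key(truth)))
    sum(!variant_key(cs) %in% variant_key(truth))
  }, numeric(1))
  expect_lt(abs(mean(fp_counts) - 10), 3 * sqrt(10 / 30))
})

test_that("cohorts share pedigree variants with identical alleles", {
  g <- simulate_reference(2, 100000, 0.43, seed = 12)
  design <- cohort_design(data.frame(
    sample_id = c("WT1", "WT2", "WT3", "TC1"),
    group = c("WT_G1", "WT_G2", "WT_G3", "TC_only"),
    guide_id = NA, replicate_of = NA,
    parent_id = c(NA, "WT1", "WT2", NA), stringsAsFactors = FALSE))
  loads <- load_presets(founder_snv = 20, founder_indel = 5)
  loads$tissue_culture <- mutation_load_model(30, 10)
  loads$spontaneous <- mutation_load_model(8, 4)
  cohort <- simulate_cohort(g, design, guides = list(), loads = loads,
                            seed = 13)
  k <- lapply(cohort$truth, variant_key)
  ## founder pre-existing variants appear in every line
  founder_keys <- variant_key(
    cohort$truth$WT1[cohort$truth$WT1$class == "pre_existing", ])
  for (sid in names(k)) expect_true(all(founder_keys %in% k[[sid]]))
  ## children carry all parental variants (identical alleles)
  expect_true(all(k$WT1 %in% k$WT2))
  expect_true(all(k$WT2 %in% k$WT3))
  ## WT chains gain spontaneous mutations; TC gains culture background
  expect_gt(length(k$WT2), length(k$WT1))
  expect_true(any(cohort$truth$TC1$class == "background_tc"))
  ## per-sample caller sets exist and are deterministic under the seed
  cohort2 <- simulate_cohort(g, design, guides = list(), loads = loads,
                             seed = 13)
  expect_identical(cohort$truth, cohort2$truth)
  expect_identical(cohort$calls, cohort2$calls)
})

test_that("design validation catches structural errors", {
  base <- data.frame(sample_id = c("a", "b"), group = c("WT_G1", "WT_G2"),
                     guide_id = NA, replicate_of = NA,
                     parent_id = c(NA, "a"), stringsAsFactors = FALSE)
  expect_s3_class(cohort_design(base), "cohort_design")
  dup <- base; dup$sample_id <- c("a", "a")
  expect_error(cohort_design(dup), "unique")
  cyc <- base; cyc$parent_id <- c("b", "a")
  expect_error(cohort_design(cyc), "cycle")
  ed <- base; ed$group[2] <- "Edited_T0"
  expect_error(cohort_design(ed), "guide_id")
  bad <- base; bad$group[1] <- "mystery"
  expect_error(cohort_design(bad), "unknown group")
})
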