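## Planted-truth benchmark construction and recovery studies.
##
## These helpers build the simulation studies used to validate the
## pipeline: a guide set with one deliberately promiscuous guide whose
## homologous sites are planted into the reference, and driver loops that
## re-run the simulate -> consensus -> subtract -> classify chain over
## many seeds and score recovery against the generator's truth.

#' Sample a protospacer with a canonical PAM from a genome
#'
#' Picks a random plus-strand position whose downstream (Cas9) or upstream
#' (Cpf1) context carries a canonical PAM and returns the corresponding
#' guide with its declared target site.
#'
#' @param genome a `ref_genome`.
#' @param guide_id identifier for the new guide.
#' @param nuclease "Cas9" or "Cpf1".
#' @param seed integer seed.
#' @return a `guide_spec` with `target` set.
#' @export
sample_protospacer <- function(genome, guide_id, nuclease = "Cas9", seed) {
  P <- if (nuclease == "Cas9") 20L else 23L
  contigs <- names(genome$seq)
  wts <- genome$lengths / sum(genome$lengths)
  withr::with_seed(derive_seed(seed, "protospacer", guide_id), {
    for (try in 1:10000) {
      chrom <- sample(contigs, 1, prob = wts)
      L <- genome$lengths[[chrom]]
      if (nuclease == "Cas9") {
        pos <- sample.int(L - P - 3L, 1)     # proto start, 1-based
        pam <- genome_subseq(genome, chrom, pos + P, pos + P + 2L)
        if (substr(pam, 2, 3) != "GG") next
        proto <- genome_subseq(genome, chrom, pos, pos + P - 1L)
        start0 <- pos - 1L
      } else {
        pos <- sample.int(L - P - 4L, 1) + 4L
        pam <- genome_subseq(genome, chrom, pos - 4L, pos - 1L)
        if (!(substr(pam, 1, 3) == "TTT" &&
              substr(pam, 4, 4) %in% c("A", "C", "G"))) next
        proto <- genome_subseq(genome, chrom, pos, pos + P - 1L)
        start0 <- pos - 4L - 1L
      }
      if (grepl("N", proto)) next
      return(guide_spec(guide_id, proto, nuclease,
                        target = list(chrom = chrom, start = start0,
                                      strand = "+")))
    }
    stop_input("no PAM-adjacent protospacer found")
  })
}

mutate_protospacer <- function(proto, positions) {
  ch <- strsplit(proto, "")[[1]]
  for (p in positions) ch[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                               ch[p]), 1)
  paste(ch, collapse = "")
}

#' Plant homologous off-target sites for a guide
#'
#' Writes degenerate copies of the guide's protospacer (plus a PAM) into
#' the reference at random non-overlapping plus-strand loci, reproducing
#' the homology structure of a promiscuous guide: one exact protospacer
#' under a silent PAM variant, several single-mismatch sites (one under
#' the alternative NAG PAM), and a few 2-3-mismatch sites with at most one
#' mismatch inside the 18-nt seed.
#'
#' @param genome a `ref_genome` (Cas9 guides only).
#' @param guide a `guide_spec` with a declared target.
#' @param n_one number of 1-mismatch sites (default 8).
#' @param n_two,n_three number of 2-/3-mismatch sites (default 2 and 1);
#'   the exact-copy site is always planted.
#' @param seed integer seed.
#' @return list: `genome` (modified), `sites` (planted sites plus the
#'   target, in [find_sites()] layout with an `is_target` column).
#' @export
plant_homologous_sites <- function(genome, guide, n_one = 8, n_two = 2,
                                   n_three = 1, seed) {
  stopifnot(guide$nuclease == "Cas9")
  P <- nchar(guide$protospacer)
  seed_idx <- seed_positions(guide, 18)
  nonseed <- setdiff(seq_len(P), seed_idx)
  plan <- c(list(list(mm = 0L, pam = "CGG")),
            lapply(seq_len(n_one), function(i)
              list(mm = 1L, pam = if (i == 1) "CAG" else "TGG")),
            lapply(seq_len(n_two), function(i) list(mm = 2L, pam = "AGG")),
            lapply(seq_len(n_three), function(i)
              list(mm = 3L, pam = "GGG")))
  contigs <- names(genome$seq)
  wts <- genome$lengths / sum(genome$lengths)
  site_len <- P + 3L
  occupied <- data.frame(
    chrom = guide$target$chrom,
    start = guide$target$start + 1L,
    end = guide$target$start + site_len)
  rows <- list()
  withr::with_seed(derive_seed(seed, "plant", guide$guide_id), {
    for (k in seq_along(plan)) {
      pl <- plan[[k]]
      mm_pos <- if (pl$mm == 0) integer(0)
      else if (pl$mm == 1) sample(seq_len(P), 1)
      else c(sample(seed_idx, 1), sample(nonseed, pl$mm - 1L))
      proto_var <- mutate_protospacer(guide$protospacer, mm_pos)
      site_seq <- paste0(proto_var, pl$pam)
      repeat {
        chrom <- sample(contigs, 1, prob = wts)
        L <- genome$lengths[[chrom]]
        pos <- sample.int(L - site_len, 1)
        if (!overlaps_any(chrom, pos, pos + site_len - 1L, occupied)) break
      }
      occupied <- rbind(occupied, data.frame(chrom = chrom, start = pos,
                                             end = pos + site_len - 1L))
      s <- genome$seq[[chrom]]
      genome$seq[[chrom]] <- paste0(substr(s, 1, pos - 1L), site_seq,
                                    substr(s, pos + site_len, nchar(s)))
      rows[[k]] <- data.frame(
        chrom = chrom, start = pos - 1L, end = pos - 1L + site_len,
        strand = "+", guide_id = guide$guide_id,
        n_mismatch = pl$mm,
        seed_mismatch = sum(mm_pos %in% seed_idx),
        pam_observed = pl$pam, pam_canonical = pl$pam != "CAG",
        protospacer_observed = proto_var, is_target = FALSE,
        stringsAsFactors = FALSE)
    }
  })
  target_row <- data.frame(
    chrom = guide$target$chrom, start = guide$target$start,
    end = guide$target$start + site_len, strand = "+",
    guide_id = guide$guide_id, n_mismatch = 0L, seed_mismatch = 0L,
    pam_observed = genome_subseq(genome, guide$target$chrom,
                                 guide$target$start + P + 1L,
                                 guide$target$start + site_len),
    pam_canonical = TRUE, protospacer_observed = guide$protospacer,
    is_target = TRUE, stringsAsFactors = FALSE)
  sites <- rbind(target_row, do.call(rbind, rows))
  rownames(sites) <- NULL
  list(genome = reference_genome(genome$seq), sites = sites)
}

#' Build a benchmark guide panel with one promiscuous guide
#'
#' Samples `n_safe` specific Cas9 guides from the genome (each verified to
#' have no second site within 3 mismatches) plus one promiscuous guide
#' whose 12 homologous sites are planted into the reference.
#'
#' @param genome a `ref_genome`.
#' @param n_safe number of specific guides (default 14).
#' @param seed integer seed.
#' @return list: `genome` (with planted sites), `guides` (named list of
#'   `guide_spec`), `edit_sites` (named list guide_id -> editable sites;
#'   for safe guides just their target).
#' @export
build_benchmark_guides <- function(genome, n_safe = 14, seed) {
  guides <- list(); edit_sites <- list()
  k <- 0L
  for (i in seq_len(n_safe)) {
    repeat {
      k <- k + 1L
      gid <- sprintf("guide%02d", i)
      g <- sample_protospacer(genome, gid, "Cas9", derive_seed(seed, k))
      spec <- guide_specificity(genome, g, max_mismatch = 3)
      if (spec$safe) break
    }
    guides[[g$guide_id]] <- g
    t_site <- spec$on_target
    t_site$is_target <- TRUE
    edit_sites[[g$guide_id]] <- t_site
  }
  ug <- sample_protospacer(genome, "guideX", "Cas9",
                           derive_seed(seed, "unsafe"))
  planted <- plant_homologous_sites(genome, ug, seed = seed)
  guides[[ug$guide_id]] <- ug
  edit_sites[[ug$guide_id]] <- planted$sites
  list(genome = planted$genome, guides = guides, edit_sites = edit_sites)
}

#' Default benchmark cohort design
#'
#' Three wild-type generations, two tissue-culture-only controls, an
#' Agrobacterium-infected and a nuclease-backbone control, and two
#' independent T0 lines per guide.
#'
#' @param guide_ids guide identifiers.
#' @return a `cohort_design`.
#' @export
benchmark_design <- function(guide_ids) {
  ctrl <- data.frame(
    sample_id = c("WT1", "WT2", "WT3", "TC1", "TC2", "AG1", "BB1"),
    group = c("WT_G1", "WT_G2", "WT_G3", "TC_only", "TC_only", "Agro",
              "Cas9_backbone"),
    guide_id = NA_character_,
    replicate_of = NA_character_,
    parent_id = c(NA, "WT1", "WT2", NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  t0 <- do.call(rbind, lapply(guide_ids, function(g) data.frame(
    sample_id = paste0(g, "_T0", 1:2), group = "Edited_T0", guide_id = g,
    replicate_of = c(NA, paste0(g, "_T01")), parent_id = NA_character_,
    stringsAsFactors = FALSE)))
  cohort_design(rbind(ctrl, t0))
}

## consensus + subtraction + classification of one simulated cohort;
## returns per-sample classified tables and the per-sample truth keys
adjudicate_cohort <- function(cohort, sites_by_guide, min_af = 0.10,
                              window = 5, homology_budget = 6) {
  genome <- cohort$genome
  design <- cohort$design
  consensus <- lapply(design$sample_id, function(sid)
    consensus_sample(cohort$calls[[sid]], genome, min_af = min_af))
  names(consensus) <- design$sample_id
  ctrl_ids <- design$sample_id[!grepl("^Edited_", design$group)]
  controls <- consensus[ctrl_ids]
  names(controls) <- design$group[match(ctrl_ids, design$sample_id)]
  edited <- design$sample_id[design$group == "Edited_T0"]
  subs <- lapply(edited, function(sid)
    subtract_controls(consensus[[sid]], controls))
  names(subs) <- edited
  assigned <- lapply(edited, function(sid) {
    gid <- design$guide_id[design$sample_id == sid]
    assign_to_sites(subs[[sid]]$variants, sites_by_guide[[gid]],
                    window = window)
  })
  names(assigned) <- edited
  classified <- list()
  for (sid in edited) {
    gid <- design$guide_id[design$sample_id == sid]
    g <- cohort$guides[[gid]]
    sites <- sites_by_guide[[gid]]
    target_idx <- NA_integer_
    if (!is.null(g$target)) {
      m <- which(sites$chrom == g$target$chrom &
                   sites$start == g$target$start &
                   sites$strand == g$target$strand)
      if (length(m) > 0) target_idx <- m[1]
    }
    rep_id <- setdiff(edited[design$guide_id[match(edited,
                                                   design$sample_id)] == gid],
                      sid)
    cls <- classify_variants(assigned[[sid]], sites,
                             target_site_idx = target_idx,
                             replicate_variants =
                               if (length(rep_id) > 0)
                                 assigned[[rep_id[1]]] else NULL,
                             controls_ledger = subs[[sid]]$ledger,
                             window = window,
                             homology_budget = homology_budget)
    cls$guide_id <- gid
    classified[[sid]] <- cls
  }
  list(consensus = consensus, classified = classified)
}

#' Planted-truth recovery study
#'
#' Repeatedly simulates a cohort on a fixed benchmark (genome, guides,
#' planted sites), runs consensus, control subtraction and classification,
#' and scores recovery of the planted off-target edits against the
#' generator's truth.
#'
#' @param bench result of [build_benchmark_guides()].
#' @param n_seeds number of cohort replicates.
#' @param seed master seed.
#' @param loads,caller_model,efficiency generator settings (defaults:
#'   [load_presets()], [caller_emulation_model()], 1.0).
#' @param sites_by_guide precomputed [find_sites()] tables (scanned once
#'   when omitted: mismatch budget 3, NGG+NAG).
#' @return list: per-seed data.frame `per_seed` (n_offtarget_truth,
#'   n_recovered, n_background_validated, n_guides_flagged) and overall
#'   `sensitivity`, `background_validated`, `guides_flagged_mode`.
#' @export
offtarget_recovery_study <- function(bench, n_seeds = 50, seed = 1,
                                     loads = load_presets(),
                                     caller_model = caller_emulation_model(),
                                     efficiency = 1.0,
                                     sites_by_guide = NULL) {
  genome <- bench$genome
  design <- benchmark_design(names(bench$guides))
  if (is.null(sites_by_guide)) {
    sites_by_guide <- lapply(bench$guides, function(g)
      find_sites(genome, g, 3, pam_patterns = c(g$pam_patterns, "NAG")))
  }
  per_seed <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    cohort <- simulate_cohort(genome, design, bench$guides,
                              bench$edit_sites, loads = loads,
                              caller_model = caller_model,
                              efficiency = efficiency,
                              seed = derive_seed(seed, "cohort", s))
    adj <- adjudicate_cohort(cohort, sites_by_guide)
    n_truth <- 0L; n_rec <- 0L; n_bg_val <- 0L
    for (sid in names(adj$classified)) {
      truth <- normalize_variants(cohort$truth[[sid]], genome)
      tkeys_off <- variant_key(truth[truth$class == "off_target", ,
                                     drop = FALSE])
      cls <- adj$classified[[sid]]
      ckeys <- variant_key(cls)
      val <- ckeys[cls$class == "off_target_validated"]
      n_truth <- n_truth + length(tkeys_off)
      n_rec <- n_rec + sum(tkeys_off %in% val)
      n_bg_val <- n_bg_val + sum(!val %in% tkeys_off)
    }
    flagged <- sum(!summarize_guides(do.call(rbind, adj$classified))$safe)
    per_seed[[s]] <- data.frame(
      seed_index = s, n_offtarget_truth = n_truth, n_recovered = n_rec,
      n_background_validated = n_bg_val, n_guides_flagged = flagged)
  }
  per_seed <- do.call(rbind, per_seed)
  list(per_seed = per_seed,
       sensitivity = sum(per_seed$n_recovered) /
         sum(per_seed$n_offtarget_truth),
       background_validated = sum(per_seed$n_background_validated),
       guides_flagged = per_seed$n_guides_flagged)
}

#' Default full-scale benchmark
#'
#' Builds the package's reference validation setting: a 20-Mb, 10-contig
#' genome (a desk-scale stand-in for a ~374-Mb plant genome), 14 specific
#' guides plus one promiscuous guide with 12 planted homologous sites, and
#' the per-guide site tables scanned once at the prediction budget
#' (3 mismatches, NGG+NAG).
#'
#' @param seed integer seed.
#' @param n_contigs,contig_bp genome shape (default 10 x 2 Mb).
#' @param n_safe number of specific guides (default 14).
#' @return list: `bench` ([build_benchmark_guides()] result) and
#'   `sites_by_guide` (named list of site tables).
#' @export
default_benchmark <- function(seed, n_contigs = 10, contig_bp = 2e6,
                              n_safe = 14) {
  g <- simulate_reference(n_contigs, contig_bp, 0.43,
                          seed = derive_seed(seed, "bench-genome"))
  bench <- build_benchmark_guides(g, n_safe = n_safe,
                                  seed = derive_seed(seed, "bench-guides"))
  sites_by_guide <- lapply(bench$guides, function(gd)
    find_sites(bench$genome, gd, 3,
               pam_patterns = c(gd$pam_patterns, "NAG")))
  list(bench = bench, sites_by_guide = sites_by_guide)
}

#' Two-replicate adjudication worked example
#'
#' Constructs the canonical replicate-logic scenario on a small genome:
#' a guide with 12 planted homologous sites, seven of them carrying
#' distinct indel alleles in two independent T0 lines, five edited in one
#' line only, plus ten variants shared with identical alleles far from any
#' homologous site. Classification must validate exactly the 12 loci as
#' off-target and call the 10 shared variants pre-existing.
#'
#' @param seed integer seed.
#' @return list: n_validated_loci, n_pre_existing_a, n_pre_existing_b and
#'   the two classified tables.
#' @export
replicate_logic_example <- function(seed) {
  g <- simulate_reference(1, 100000, 0.5,
                          seed = derive_seed(seed, "figlogic-genome"))
  gd <- sample_protospacer(g, "guideJ", "Cas9",
                           seed = derive_seed(seed, "figlogic-guide"))
  planted <- plant_homologous_sites(g, gd,
                                    seed = derive_seed(seed, "figlogic"))
  genome <- planted$genome
  sites <- find_sites(genome, gd, 3, pam_patterns = c("NGG", "NAG"))
  target_idx <- which(sites$chrom == gd$target$chrom &
                        sites$start == gd$target$start)
  off_idx <- setdiff(seq_len(nrow(sites)), target_idx)
  P <- nchar(gd$protospacer)
  edit_at <- function(site, del_len) {
    anchor <- if (site$strand == "+") site$start + P - 3L else
      site$start + (site$end - site$start - P) + 3L
    ref <- genome_subseq(genome, site$chrom, anchor, anchor + del_len)
    data.frame(sample_id = NA_character_, chrom = site$chrom,
               pos = anchor, ref = ref, alt = substr(ref, 1, 1),
               kind = "DEL", af = 0.5, dp = 60, stringsAsFactors = FALSE)
  }
  a <- list(); b <- list()
  for (k in seq_along(off_idx)) {
    site <- sites[off_idx[k], ]
    if (k <= 7) {               # shared locus, distinct alleles
      a[[length(a) + 1]] <- edit_at(site, 3L)
      b[[length(b) + 1]] <- edit_at(site, 6L)
    } else {                    # single-line sites
      a[[length(a) + 1]] <- edit_at(site, 4L)
    }
  }
  ## ten shared variants with identical alleles, far from any site
  withr::with_seed(derive_seed(seed, "figlogic-shared"), {
    shared_pos <- sample(seq(60000, 99000), 10)
  })
  shared <- do.call(rbind, lapply(shared_pos, function(p) {
    ref <- genome_subseq(genome, sites$chrom[1], p, p)
    data.frame(sample_id = NA_character_, chrom = sites$chrom[1], pos = p,
               ref = ref, alt = c("A", "C", "G", "T")[
                 match(ref, c("C", "G", "T", "A"))],
               kind = "SNV", af = 0.5, dp = 60, stringsAsFactors = FALSE)
  }))
  set_a <- rbind(do.call(rbind, a), shared); set_a$sample_id <- "T0a"
  set_b <- rbind(do.call(rbind, b), shared); set_b$sample_id <- "T0b"
  set_a <- normalize_variants(set_a, genome)
  set_b <- normalize_variants(set_b, genome)
  empty_ledger <- set_a[0, ]
  empty_ledger$absorbed_by_group <- character(0)
  cls_a <- classify_variants(set_a, sites, target_site_idx = target_idx,
                             replicate_variants = set_b,
                             controls_ledger = empty_ledger)
  cls_b <- classify_variants(set_b, sites, target_site_idx = target_idx,
                             replicate_variants = set_a,
                             controls_ledger = empty_ledger)
  val <- rbind(cls_a[cls_a$class == "off_target_validated", ],
               cls_b[cls_b$class == "off_target_validated", ])
  list(n_validated_loci = length(unique(paste(val$site_chrom,
                                              val$site_start))),
       n_pre_existing_a = sum(cls_a$class == "pre_existing"),
       n_pre_existing_b = sum(cls_b$class == "pre_existing"),
       classified_a = cls_a, classified_b = cls_b)
}

#' Consensus robustness study
#'
#' Repeatedly draws a truth set on a fixed genome, emulates independent
#' callers, intersects them strictly, and reports consensus recall and the
#' number of surviving false-positive calls.
#'
#' @param genome a `ref_genome`.
#' @param n_seeds replicates.
#' @param seed master seed.
#' @param load_model truth load per replicate (default tissue-culture
#'   114 SNVs + 36 indels).
#' @param caller_model caller emulation settings.
#' @param min_af consensus AF floor.
#' @return data.frame with one row per seed: n_truth, n_recalled,
#'   n_false_positive.
#' @export
consensus_recovery_study <- function(genome, n_seeds = 100, seed = 1,
                                     load_model = mutation_load_model(114, 36),
                                     caller_model = caller_emulation_model(
                                       fp_rate = 1e-5, fn_rate = 0.02),
                                     min_af = 0.10) {
  out <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    truth <- simulate_truth_set(genome, load_model,
                                derive_seed(seed, "truth", s),
                                sample_id = "s1")
    calls <- emulate_callers(truth, caller_model, genome,
                             derive_seed(seed, "calls", s))
    cons <- consensus_sample(calls, genome, min_af = min_af)
    tkeys <- variant_key(normalize_variants(truth, genome))
    ckeys <- variant_key(cons)
    out[[s]] <- data.frame(seed_index = s, n_truth = length(tkeys),
                           n_recalled = sum(tkeys %in% ckeys),
                           n_false_positive = sum(!ckeys %in% tkeys))
  }
  do.call(rbind, out)
}

#' Wild-type trio rate-recovery study
#'
#' Simulates parent-to-progeny mutation accumulation at a known true rate
#' and re-estimates the per-site per-diploid-genome per-generation rate
#' from the simulated counts.
#'
#' @param genome a `ref_genome`.
#' @param true_rate per site per diploid genome per generation.
#' @param n_links parent-to-progeny links per replicate (default 8).
#' @param n_seeds replicates (default 50).
#' @param seed master seed.
#' @return numeric vector of per-replicate rate estimates.
#' @export
trio_rate_study <- function(genome, true_rate = 5.4e-8, n_links = 8,
                            n_seeds = 50, seed = 1) {
  L <- genome_length(genome)
  model <- mutation_load_model(mean_snv = true_rate * 2 * L, mean_indel = 0)
  vapply(seq_len(n_seeds), function(s) {
    n <- sum(vapply(seq_len(n_links), function(l)
      nrow(simulate_truth_set(genome, model, derive_seed(seed, s, l),
                              sample_id = paste0("link", l),
                              class = "spontaneous")), integer(1)))
    mutation_rate(n, L, n_generations = n_links)$rate
  }, numeric(1))
}
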