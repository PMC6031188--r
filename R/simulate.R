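## Synthetic cohorts.
##
## The generator emulates the statistical structure of an edited-plant WGS
## study: a founder line carrying shared pre-existing variants, wild-type
## generations accumulating spontaneous mutations, tissue-culture and
## Agrobacterium-derived background in regenerated plants, planted guide
## edits (on-target and at homologous off-target sites, with alleles drawn
## independently per replicate line), and noisy per-caller views of each
## sample's truth set. No reads are simulated; callers are emulated at the
## call level with false-negative drops, uniform false-positive calls and
## allele-frequency noise.

SAMPLE_GROUPS <- c("WT_G1", "WT_G2", "WT_G3", "TC_only", "Agro",
                   "Cas9_backbone", "Cpf1_backbone", "Edited_T0",
                   "Edited_T1")

#' Mutation load model for one sample class
#'
#' @param mean_snv,mean_indel expected SNV/indel counts per sample
#'   (Poisson means).
#' @param af_mode "heterozygous" (AF 0.5), "homozygous" (AF 1.0) or
#'   "somatic" (AF uniform in (0, 0.25)).
#' @param indel_size_range allowed indel sizes in bp, within `[1, 50]`.
#' @return an object of class `mutation_load_model`.
#' @export
mutation_load_model <- function(mean_snv, mean_indel,
                                af_mode = c("heterozygous", "somatic",
                                            "homozygous"),
                                indel_size_range = c(1, 15)) {
  af_mode <- match.arg(af_mode)
  if (mean_snv < 0 || mean_indel < 0) stop_input("means must be >= 0")
  if (indel_size_range[1] < 1 || indel_size_range[2] > 50 ||
      indel_size_range[1] > indel_size_range[2])
    stop_input("indel_size_range must lie within [1, 50]")
  structure(list(mean_snv = mean_snv, mean_indel = mean_indel,
                 af_mode = af_mode, indel_size_range = indel_size_range),
            class = "mutation_load_model")
}

#' Caller emulation model
#'
#' @param n_callers number of emulated callers (>= 2, default 3).
#' @param fp_rate false calls per bp per caller.
#' @param fn_rate probability a true variant is missed per caller.
#' @param af_noise_sd sd of additive Gaussian noise on reported AF
#'   (truncated to `[0,1]`).
#' @return an object of class `caller_emulation_model`.
#' @export
caller_emulation_model <- function(n_callers = 3, fp_rate = 1e-5,
                                   fn_rate = 0.01, af_noise_sd = 0.05) {
  if (n_callers < 2) stop_input("n_callers must be >= 2")
  if (fp_rate < 0 || fp_rate > 1 || fn_rate < 0 || fn_rate > 1)
    stop_input("rates must be in [0, 1]")
  structure(list(n_callers = n_callers, fp_rate = fp_rate,
                 fn_rate = fn_rate, af_noise_sd = af_noise_sd),
            class = "caller_emulation_model")
}

#' Default per-class mutation loads
#'
#' Means reflect the per-sample loads reported for rice regenerants:
#' tissue culture contributes on average 114 SNVs + 36 indels,
#' a parent-to-progeny generation 23 SNVs + 18 indels, and
#' Agrobacterium-related steps an additional 15-41 indels (exposed here as
#' a configurable mean, default the midpoint 28). The founder pre-existing
#' load (variants shared by the whole pedigree) is a package choice.
#' All classes are heterozygous-like, matching the allele-frequency
#' structure of culture-derived mutations.
#'
#' @param agro_extra_indels mean extra indels from Agrobacterium steps.
#' @param founder_snv,founder_indel pre-existing founder load.
#' @return named list of `mutation_load_model`s: pre_existing,
#'   tissue_culture, spontaneous, agro_extra.
#' @export
load_presets <- function(agro_extra_indels = 28, founder_snv = 50,
                         founder_indel = 20) {
  list(
    pre_existing = mutation_load_model(founder_snv, founder_indel),
    tissue_culture = mutation_load_model(114, 36),
    spontaneous = mutation_load_model(23, 18),
    agro_extra = mutation_load_model(0, agro_extra_indels))
}

#' Fixed indel allele catalog
#'
#' Deletions of 1-15 bp and insertions of 1-10 bp with a fixed inserted
#' sequence per length, so "same allele vs distinct allele" comparisons
#' between replicate lines are well defined and the allele space has a
#' known size (25 by default).
#'
#' @param del_sizes,ins_sizes integer vectors of allowed sizes.
#' @return data.frame with columns type ("DEL"/"INS"), size, ins_seq.
#' @export
indel_catalog <- function(del_sizes = 1:15, ins_sizes = 1:10) {
  motif <- strrep("ACGT", 4)
  rbind(
    data.frame(type = "DEL", size = del_sizes, ins_seq = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(type = "INS", size = ins_sizes,
               ins_seq = substring(motif, 1, ins_sizes),
               stringsAsFactors = FALSE))
}

## interval-collision test against an occupied table (1-based inclusive)
overlaps_any <- function(chrom, start, end, occ) {
  nrow(occ) > 0 && any(occ$chrom == chrom & start <= occ$end &
                         end >= occ$start)
}

draw_af <- function(n, af_mode) {
  switch(af_mode,
         heterozygous = rep(0.5, n),
         homozygous = rep(1.0, n),
         somatic = stats::runif(n, 0, 0.25))
}

#' Simulate a truth variant set
#'
#' Draws SNV and indel counts from Poisson distributions with the model
#' means, places them uniformly on the genome without interval collisions
#' (colliding draws are resampled), and assigns allele frequencies by the
#' model's AF mode. Deterministic for a fixed seed.
#'
#' @param genome a `ref_genome`.
#' @param model a `mutation_load_model`.
#' @param seed integer seed.
#' @param sample_id label recorded on each row.
#' @param class truth class label (e.g. "background_tc").
#' @param avoid data.frame(chrom, start, end) of 1-based intervals the new
#'   variants must not overlap (e.g. variants the sample already carries).
#' @return truth data.frame: sample_id, chrom, pos, ref, alt, kind, class,
#'   true_af.
#' @export
simulate_truth_set <- function(genome, model, seed, sample_id = "sample",
                               class = "background", avoid = NULL) {
  if (sum(genome$lengths) == 0) stop_input("empty genome")
  if ((model$mean_snv + model$mean_indel) * 100 > genome_length(genome))
    stop_input("mutation load exceeds genome capacity")
  cat_tab <- indel_catalog(
    del_sizes = seq(model$indel_size_range[1],
                    min(model$indel_size_range[2], 15)),
    ins_sizes = seq(model$indel_size_range[1],
                    min(model$indel_size_range[2], 10)))
  if (is.null(avoid) || nrow(avoid) == 0) {
    occ_chrom <- character(0); occ_start <- integer(0); occ_end <- integer(0)
  } else {
    occ_chrom <- avoid$chrom; occ_start <- avoid$start; occ_end <- avoid$end
  }
  contigs <- names(genome$seq)
  wts <- genome$lengths / sum(genome$lengths)
  withr::with_seed(derive_seed(seed, "truth", sample_id, class), {
    n_snv <- stats::rpois(1, model$mean_snv)
    n_indel <- stats::rpois(1, model$mean_indel)
    n <- n_snv + n_indel
    if (n == 0) {
      out <- empty_variants()
      out$class <- character(0); out$true_af <- numeric(0)
      out$dp <- NULL; out$af <- NULL
      return(out)
    }
    is_indel <- c(rep(FALSE, n_snv), rep(TRUE, n_indel))
    v_chrom <- character(n); v_pos <- integer(n)
    v_ref <- character(n); v_alt <- character(n)
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in 1:200) {
        chrom <- contigs[sample.int(length(contigs), 1, prob = wts)]
        L <- genome$lengths[[chrom]]
        if (is_indel[i]) {
          a <- cat_tab[sample.int(nrow(cat_tab), 1), ]
          span <- if (a$type == "DEL") a$size + 1L else 1L
          pos <- sample.int(L - span, 1) # keeps pos >= 1, fits contig
          ref <- substr(genome$seq[[chrom]], pos, pos + span - 1L)
          if (grepl("N", ref, fixed = TRUE)) next
          alt <- if (a$type == "DEL") substr(ref, 1, 1) else
            paste0(ref, a$ins_seq)
        } else {
          span <- 1L
          pos <- sample.int(L, 1)
          ref <- substr(genome$seq[[chrom]], pos, pos)
          if (ref == "N") next
          alt <- sample(bases[bases != ref], 1)
        }
        end <- pos + span - 1L
        if (!any(occ_chrom == chrom & pos <= occ_end & end >= occ_start)) {
          occ_chrom <- c(occ_chrom, chrom)
          occ_start <- c(occ_start, pos)
          occ_end <- c(occ_end, end)
          v_chrom[i] <- chrom; v_pos[i] <- pos
          v_ref[i] <- ref; v_alt[i] <- alt
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop_input("could not place variant without collision; ",
                   "genome too small for the requested load")
    }
    out <- data.frame(
      sample_id = sample_id, chrom = v_chrom, pos = v_pos, ref = v_ref,
      alt = v_alt, kind = variant_kind(v_ref, v_alt), class = class,
      true_af = draw_af(n, model$af_mode), stringsAsFactors = FALSE)
  })
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## 1-based anchor base immediately left of the nuclease cut
cut_anchor <- function(site, guide) {
  P <- nchar(guide$protospacer)
  Q <- (site$end - site$start) - P
  s0 <- site$start
  if (guide$pam_side == "3p") {       # Cas9: blunt cut 3 bp 5' of the PAM
    if (site$strand == "+") s0 + P - 3L else s0 + Q + 3L
  } else {                            # Cpf1: staggered cut, PAM-distal
    if (site$strand == "+") s0 + Q + 18L else s0 + P - 18L
  }
}

#' Plant guide edits into replicate lines
#'
#' Each replicate line independently receives an indel at each site with
#' probability `efficiency`; alleles are drawn independently per replicate
#' and site from the fixed indel catalog and placed at the nuclease cut
#' position (Cas9: 3 bp 5' of the PAM; Cpf1: after protospacer position 18,
#' the staggered-cut region). Replicates therefore carry distinct alleles
#' at shared sites with high probability.
#'
#' @param genome a `ref_genome`.
#' @param guide a `guide_spec`.
#' @param sites site data.frame ([find_sites()] layout); an optional
#'   logical column `is_target` marks the declared on-target site.
#' @param efficiency per-site editing probability in `[0,1]`.
#' @param n_replicates number of independent lines.
#' @param seed integer seed.
#' @return list of `n_replicates` truth data.frames (class "on_target" or
#'   "off_target").
#' @export
plant_guide_edits <- function(genome, guide, sites, efficiency,
                              n_replicates, seed) {
  if (efficiency < 0 || efficiency > 1)
    stop_input("efficiency must be in [0, 1]")
  cat_tab <- indel_catalog()
  is_target <- sites$is_target %||% rep(FALSE, nrow(sites))
  lapply(seq_len(n_replicates), function(r) {
    withr::with_seed(derive_seed(seed, "edits", guide$guide_id, r), {
      rows <- list()
      for (i in seq_len(nrow(sites))) {
        if (stats::rbinom(1, 1, efficiency) == 0) next
        site <- sites[i, ]
        anchor <- cut_anchor(site, guide)
        a <- cat_tab[sample(nrow(cat_tab), 1), ]
        L <- genome$lengths[[site$chrom]]
        if (a$type == "DEL") {
          end <- min(anchor + a$size, L)
          ref <- genome_subseq(genome, site$chrom, anchor, end)
          alt <- substr(ref, 1, 1)
        } else {
          ref <- genome_subseq(genome, site$chrom, anchor, anchor)
          alt <- paste0(ref, a$ins_seq)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = NA_character_, chrom = site$chrom, pos = anchor,
          ref = ref, alt = alt, kind = variant_kind(ref, alt),
          class = if (isTRUE(is_target[i])) "on_target" else "off_target",
          true_af = 0.5, stringsAsFactors = FALSE)
      }
      if (length(rows) == 0) {
        out <- empty_variants()
        out$class <- character(0); out$true_af <- numeric(0)
        out$af <- NULL; out$dp <- NULL
        out
      } else do.call(rbind, rows)
    })
  })
}

#' Emulate per-caller call sets from a truth set
#'
#' Each emulated caller reports the truth set minus independent
#' false-negative drops, plus independent uniformly placed false-positive
#' SNV calls at `fp_rate` per bp (never coinciding with a truth position),
#' with allele frequencies perturbed by truncated Gaussian noise.
#'
#' @param truth truth data.frame (from [simulate_truth_set()] /
#'   [plant_guide_edits()]), with `true_af`.
#' @param model a `caller_emulation_model`.
#' @param genome a `ref_genome`.
#' @param seed integer seed.
#' @param caller_ids caller names (length `model$n_callers`).
#' @return named list of per-caller variant data.frames.
#' @export
emulate_callers <- function(truth, model, genome, seed,
                            caller_ids = NULL) {
  caller_ids <- caller_ids %||% paste0("caller", seq_len(model$n_callers))
  if (length(caller_ids) != model$n_callers)
    stop_input("caller_ids length must equal n_callers")
  G <- genome_length(genome)
  contigs <- names(genome$seq)
  wts <- genome$lengths / G
  truth_pos <- paste(truth$chrom, truth$pos)
  sets <- lapply(seq_along(caller_ids), function(j) {
    withr::with_seed(derive_seed(seed, "caller", j), {
      keep <- stats::runif(nrow(truth)) >= model$fn_rate
      tp <- truth[keep, , drop = FALSE]
      af <- tp$true_af
      if (model$af_noise_sd > 0 && length(af) > 0)
        af <- pmin(1, pmax(0, af + stats::rnorm(length(af),
                                                sd = model$af_noise_sd)))
      calls <- data.frame(
        sample_id = tp$sample_id, chrom = tp$chrom, pos = tp$pos,
        ref = tp$ref, alt = tp$alt, kind = tp$kind, af = af,
        dp = if (nrow(tp)) round(stats::runif(nrow(tp), 45, 105)) else
          numeric(0),
        stringsAsFactors = FALSE)
      n_fp <- stats::rpois(1, model$fp_rate * G)
      fp_chrom <- character(0); fp_pos <- integer(0); fp_ref <- character(0)
      while (length(fp_pos) < n_fp) {
        need <- n_fp - length(fp_pos)
        ch <- contigs[sample.int(length(contigs), need, replace = TRUE,
                                 prob = wts)]
        po <- vapply(ch, function(c2)
          sample.int(genome$lengths[[c2]], 1), integer(1))
        rf <- substr(vapply(ch, function(c2) genome$seq[[c2]],
                            character(1)), po, po)
        ok <- !(paste(ch, po) %in% c(truth_pos, paste(fp_chrom, fp_pos))) &
          rf != "N" & !duplicated(paste(ch, po))
        fp_chrom <- c(fp_chrom, ch[ok])
        fp_pos <- c(fp_pos, po[ok])
        fp_ref <- c(fp_ref, rf[ok])
      }
      if (n_fp > 0) {
        bases <- c("A", "C", "G", "T")
        fp_alt <- vapply(fp_ref, function(r)
          sample(bases[bases != r], 1), character(1))
        calls <- rbind(calls, data.frame(
          sample_id = truth$sample_id[1] %||% NA_character_,
          chrom = fp_chrom, pos = fp_pos, ref = fp_ref, alt = fp_alt,
          kind = "SNV", af = stats::runif(n_fp, 0.1, 0.6),
          dp = round(stats::runif(n_fp, 45, 105)),
          stringsAsFactors = FALSE))
      }
      calls$sample_id <- truth$sample_id[1] %||% NA_character_
      calls$caller_id <- caller_ids[j]
      calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
      rownames(calls) <- NULL
      calls
    })
  })
  names(sets) <- caller_ids
  sets
}

#' Cohort design table
#'
#' @param samples data.frame with columns sample_id, group (one of
#'   WT_G1/WT_G2/WT_G3/TC_only/Agro/Cas9_backbone/Cpf1_backbone/
#'   Edited_T0/Edited_T1), guide_id (NA for unedited samples),
#'   replicate_of (NA or a sample_id), parent_id (NA or a sample_id).
#' @return validated design data.frame of class `cohort_design`.
#' @export
cohort_design <- function(samples) {
  need <- c("sample_id", "group")
  if (!all(need %in% names(samples)))
    stop_input("design needs columns: ", paste(need, collapse = ", "))
  for (col in c("guide_id", "replicate_of", "parent_id"))
    if (is.null(samples[[col]])) samples[[col]] <- NA_character_
  if (anyDuplicated(samples$sample_id))
    stop_input("sample_ids must be unique")
  bad <- !samples$group %in% SAMPLE_GROUPS
  if (any(bad))
    stop_input("unknown group(s): ", paste(unique(samples$group[bad]),
                                           collapse = ", "))
  edited <- grepl("^Edited_", samples$group)
  if (any(edited & is.na(samples$guide_id)))
    stop_input("Edited_* samples must reference a guide_id")
  ## parent links must be acyclic and resolvable
  known <- samples$sample_id
  p <- samples$parent_id
  if (any(!is.na(p) & !p %in% known))
    stop_input("parent_id references unknown sample(s)")
  resolved <- is.na(p)
  for (iter in seq_len(nrow(samples) + 1)) {
    newly <- !resolved & p %in% samples$sample_id[resolved]
    if (!any(newly)) break
    resolved <- resolved | newly
  }
  if (!all(resolved)) stop_input("parent links contain a cycle")
  class(samples) <- c("cohort_design", class(samples))
  samples
}

## samples ordered so parents precede children
topo_order <- function(design) {
  ord <- character(0)
  left <- design$sample_id
  repeat {
    ready <- left[is.na(design$parent_id[match(left, design$sample_id)]) |
                    design$parent_id[match(left, design$sample_id)] %in% ord]
    if (length(ready) == 0) break
    ord <- c(ord, ready)
    left <- setdiff(left, ready)
  }
  ord
}

#' Simulate a full cohort: truth sets and per-caller call sets
#'
#' Builds every sample's truth set from the pedigree: a founder
#' pre-existing set shared by all lines, spontaneous mutations added along
#' each parent link, tissue-culture (and Agrobacterium) background in all
#' regenerated samples, and planted guide edits in `Edited_T0` lines
#' (alleles independent across replicate lines). `Edited_T1` samples
#' inherit their parent T0 set plus one spontaneous generation. Each truth
#' set is then viewed through emulated callers. One integer seed drives a
#' derived-stream hierarchy (one stream per sample), so adding samples does
#' not perturb earlier ones.
#'
#' @param genome a `ref_genome`.
#' @param design a `cohort_design`.
#' @param guides named list of `guide_spec` (names = guide_id).
#' @param edit_sites named list: guide_id -> site data.frame where that
#'   guide's edits are planted (include the target with `is_target = TRUE`).
#' @param loads list from [load_presets()].
#' @param caller_model a `caller_emulation_model`.
#' @param efficiency per-site editing probability for T0 lines.
#' @param seed integer master seed.
#' @return list with elements genome, design, guides, edit_sites, truth
#'   (named list of truth data.frames), calls (named list: sample ->
#'   caller -> variant data.frame).
#' @export
simulate_cohort <- function(genome, design, guides, edit_sites = list(),
                            loads = load_presets(),
                            caller_model = caller_emulation_model(),
                            efficiency = 1.0, seed = 1) {
  design <- if (inherits(design, "cohort_design")) design else
    cohort_design(design)
  founder <- simulate_truth_set(genome, loads$pre_existing,
                                derive_seed(seed, "founder"),
                                sample_id = "founder",
                                class = "pre_existing")
  ## plant edits per guide, one replicate per Edited_T0 sample (in design
  ## order) so replicate lines draw independent alleles
  t0 <- design[design$group == "Edited_T0", , drop = FALSE]
  edits_by_sample <- list()
  for (gid in unique(t0$guide_id)) {
    s_ids <- t0$sample_id[t0$guide_id == gid]
    if (is.null(guides[[gid]])) stop_input("unknown guide_id: ", gid)
    sites <- edit_sites[[gid]]
    reps <- if (is.null(sites) || nrow(sites) == 0)
      replicate(length(s_ids),
                {
                  out <- empty_variants()
                  out$class <- character(0); out$true_af <- numeric(0)
                  out$af <- NULL; out$dp <- NULL
                  out
                }, simplify = FALSE)
    else plant_guide_edits(genome, guides[[gid]], sites, efficiency,
                           length(s_ids), seed)
    for (k in seq_along(s_ids)) edits_by_sample[[s_ids[k]]] <- reps[[k]]
  }
  interval_table <- function(v) {
    if (nrow(v) == 0)
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))
    data.frame(chrom = v$chrom, start = v$pos,
               end = v$pos + nchar(v$ref) - 1L)
  }
  truth <- list()
  for (sid in topo_order(design)) {
    row <- design[design$sample_id == sid, ]
    base <- if (!is.na(row$parent_id)) truth[[row$parent_id]] else founder
    acc <- base
    add <- function(model, class, acc) {
      new <- simulate_truth_set(genome, model, seed, sample_id = sid,
                                class = class,
                                avoid = interval_table(acc))
      rbind(acc, new)
    }
    grp <- row$group
    if (grp %in% c("WT_G2", "WT_G3", "Edited_T1"))
      acc <- add(loads$spontaneous, "spontaneous", acc)
    if (grp %in% c("TC_only", "Agro", "Cas9_backbone", "Cpf1_backbone",
                   "Edited_T0")) {
      if (grp == "Edited_T0" && !is.null(edits_by_sample[[sid]])) {
        ed <- edits_by_sample[[sid]]
        ed$sample_id <- sid
        acc <- rbind(acc, ed)   # edits planted first: background avoids them
      }
      acc <- add(loads$tissue_culture, "background_tc", acc)
      if (grp != "TC_only")
        acc <- add(loads$agro_extra, "background_agro", acc)
    }
    acc$sample_id <- sid
    acc <- acc[order(acc$chrom, acc$pos), , drop = FALSE]
    rownames(acc) <- NULL
    truth[[sid]] <- acc
  }
  calls <- lapply(design$sample_id, function(sid)
    emulate_callers(truth[[sid]], caller_model, genome,
                    derive_seed(seed, "sample", sid)))
  names(calls) <- design$sample_id
  list(genome = genome, design = design, guides = guides,
       edit_sites = edit_sites, truth = truth, calls = calls,
       efficiency = efficiency, seed = seed)
}

#' Write a truth table as TSV
#' @param truth named list of truth data.frames (or one data.frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  if (is.data.frame(truth)) truth <- list(truth)
  df <- do.call(rbind, truth)
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", "class", "true_af")
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' Layout: `genome.fa`, `design.tsv`, `guides.tsv`, `truth.tsv` and
#' `vcf/<sample>__<caller>.vcf` — the on-disk interface consumed by
#' [run_pipeline()].
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(cohort$genome, file.path(dir, "genome.fa"))
  utils::write.table(as.data.frame(cohort$design)[
    , c("sample_id", "group", "guide_id", "replicate_of", "parent_id")],
    file.path(dir, "design.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  g <- do.call(rbind, lapply(cohort$guides, function(gd) data.frame(
    guide_id = gd$guide_id, protospacer = gd$protospacer,
    nuclease = gd$nuclease,
    pam_patterns = paste(gd$pam_patterns, collapse = ";"),
    target_chrom = gd$target$chrom %||% NA_character_,
    target_start = gd$target$start %||% NA_integer_,
    target_strand = gd$target$strand %||% NA_character_,
    stringsAsFactors = FALSE)))
  utils::write.table(g, file.path(dir, "guides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_truth_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  for (sid in names(cohort$calls))
    for (cid in names(cohort$calls[[sid]]))
      write_vcf(cohort$calls[[sid]][[cid]],
                file.path(dir, "vcf", paste0(sid, "__", cid, ".vcf")),
                cohort$genome, sample_id = sid)
  invisible(dir)
}
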