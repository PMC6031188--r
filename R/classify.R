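## Off-target adjudication.
##
## Each post-subtraction variant of an edited sample gets exactly one
## provenance class:
##   pre_existing / background  - absorbed by a control or pedigree sample
##   on_target                  - overlaps the declared target site
##   off_target_candidate       - indel at a guide-homologous site
##   off_target_validated       - candidate confirmed by an independent
##                                replicate carrying a distinct allele at
##                                the same site, or (for prediction-grade
##                                sites) by absence from all controls
##   spontaneous                - everything else
## SNVs at homologous sites remain candidates with a warning tag and are
## never validated: nuclease repair products are indels, and SNV dominance
## at shared loci is evidence *against* nuclease origin.

#' Assign variants to guide-homologous sites
#'
#' A variant is assigned to a site iff its affected reference interval
#' intersects the site's protospacer+PAM interval expanded by `window` bp
#' on each side. Ties across overlapping sites break by lowest n_mismatch,
#' then lowest seed_mismatch, then leftmost start.
#'
#' @param variants normalized variant data.frame.
#' @param sites site data.frame from [find_sites()].
#' @param window expansion in bp (default 5, covering resection around the
#'   cut).
#' @return `variants` with columns `site_idx` (row index into `sites` or
#'   NA) plus copied site columns `site_chrom`, `site_start`,
#'   `site_strand`, `site_n_mismatch`, `site_seed_mismatch`,
#'   `site_pam_observed`.
#' @export
assign_to_sites <- function(variants, sites, window = 5) {
  n <- nrow(variants)
  variants$site_idx <- rep(NA_integer_, n)
  if (n > 0 && nrow(sites) > 0) {
    if (nrow(sites) <= 100) {
      ## small site lists (the common case): direct vectorized overlap
      v_end <- variants$pos + nchar(variants$ref) - 1L
      h_v <- integer(0); h_s <- integer(0)
      for (j in seq_len(nrow(sites))) {
        lo <- sites$start[j] + 1L - window
        hi <- sites$end[j] + window
        hit <- which(variants$chrom == sites$chrom[j] &
                       variants$pos <= hi & v_end >= lo)
        h_v <- c(h_v, hit); h_s <- c(h_s, rep(j, length(hit)))
      }
    } else {
      v_gr <- GenomicRanges::GRanges(
        variants$chrom,
        IRanges::IRanges(variants$pos,
                         variants$pos + nchar(variants$ref) - 1L))
      s_gr <- GenomicRanges::GRanges(
        sites$chrom,
        IRanges::IRanges(pmax(1L, sites$start + 1L - window),
                         sites$end + window))
      hits <- GenomicRanges::findOverlaps(v_gr, s_gr)
      h_v <- S4Vectors::queryHits(hits)
      h_s <- S4Vectors::subjectHits(hits)
    }
    if (length(h_v) > 0) {
      o <- order(h_v, sites$n_mismatch[h_s], sites$seed_mismatch[h_s],
                 sites$start[h_s])
      h_v <- h_v[o]; h_s <- h_s[o]
      first <- !duplicated(h_v)
      variants$site_idx[h_v[first]] <- h_s[first]
    }
  }
  idx <- variants$site_idx
  variants$site_chrom <- sites$chrom[idx]
  variants$site_start <- sites$start[idx]
  variants$site_strand <- sites$strand[idx]
  variants$site_n_mismatch <- sites$n_mismatch[idx]
  variants$site_seed_mismatch <- sites$seed_mismatch[idx]
  variants$site_pam_observed <- sites$pam_observed[idx]
  variants
}

#' Replicate overlap between two independently edited lines
#'
#' Partitions the two post-subtraction variant sets by exact normalized
#' key; locus-level sharing (overlapping reference intervals within
#' `locus_window` bp but different alleles) is reported separately — the
#' signature of a nuclease cutting the same site in both lines.
#'
#' @param set_a,set_b normalized variant data.frames from two replicate
#'   lines carrying the same guide.
#' @param locus_window bp tolerance for locus-level sharing (default 5).
#' @return list: `shared` (rows of `set_a` whose key is in `set_b`),
#'   `unique_a`, `unique_b`, and `shared_loci` (data.frame pairing
#'   key-distinct variants at the same locus).
#' @export
replicate_overlap <- function(set_a, set_b, locus_window = 5) {
  ka <- variant_key(set_a); kb <- variant_key(set_b)
  shared <- set_a[ka %in% kb, , drop = FALSE]
  ua <- set_a[!ka %in% kb, , drop = FALSE]
  ub <- set_b[!kb %in% ka, , drop = FALSE]
  loci <- list()
  if (nrow(ua) > 0 && nrow(ub) > 0) {
    ga <- GenomicRanges::GRanges(
      ua$chrom, IRanges::IRanges(pmax(1L, ua$pos - locus_window),
                                 ua$pos + nchar(ua$ref) - 1L + locus_window))
    gb <- GenomicRanges::GRanges(
      ub$chrom, IRanges::IRanges(ub$pos, ub$pos + nchar(ub$ref) - 1L))
    hits <- GenomicRanges::findOverlaps(ga, gb)
    if (length(hits) > 0)
      loci <- data.frame(
        chrom = ua$chrom[S4Vectors::queryHits(hits)],
        pos_a = ua$pos[S4Vectors::queryHits(hits)],
        pos_b = ub$pos[S4Vectors::subjectHits(hits)],
        key_a = variant_key(ua)[S4Vectors::queryHits(hits)],
        key_b = variant_key(ub)[S4Vectors::subjectHits(hits)],
        stringsAsFactors = FALSE)
  }
  if (length(loci) == 0)
    loci <- data.frame(chrom = character(0), pos_a = integer(0),
                       pos_b = integer(0), key_a = character(0),
                       key_b = character(0), stringsAsFactors = FALSE)
  list(shared = shared, unique_a = ua, unique_b = ub, shared_loci = loci)
}

#' Classify one edited sample's variants
#'
#' Applies the adjudication decision order: (1) variants absorbed by a
#' control or pedigree sample are pre-existing/background; (2) variants at
#' the declared target site are on-target; (3) indels at other
#' guide-homologous sites are off-target candidates, promoted to validated
#' when an independent replicate line carries a distinct allele at the same
#' site, or when controls were checked, the variant is absent from all of
#' them and the pedigree, and the site has prediction-grade homology
#' (n_mismatch <= `promotion_budget`); (4) variants shared with an
#' identical allele by the replicate but unassigned or at poor homology
#' (n_mismatch > `homology_budget`) are pre-existing; (5) everything else
#' is spontaneous.
#'
#' @param variants post-subtraction, normalized variant data.frame of one
#'   sample, already passed through [assign_to_sites()] (i.e. carrying
#'   `site_idx` etc.). If not, supply `sites` and it is done here.
#' @param sites site table used for assignment (required when promoting or
#'   when `variants` lacks site columns).
#' @param target_site_idx row index in `sites` of the declared on-target
#'   site (NA when unknown).
#' @param replicate_variants post-subtraction variant data.frame of an
#'   independent line carrying the same guide, or NULL.
#' @param controls_ledger ledger from [subtract_controls()] for this
#'   sample; its presence certifies that controls were checked.
#' @param pedigree_keys normalized keys of variants carried by declared
#'   ancestor samples (always pre-existing, outranking homology).
#' @param window assignment window (default 5 bp).
#' @param homology_budget mismatch count above which a site counts as poor
#'   homology (default 6).
#' @param promotion_budget maximum site mismatches for single-line
#'   promotion (default 3, the prediction budget).
#' @return `variants` with columns `class` and `evidence`
#'   (comma-separated stable rule tags).
#' @export
classify_variants <- function(variants, sites,
                              target_site_idx = NA_integer_,
                              replicate_variants = NULL,
                              controls_ledger = NULL,
                              pedigree_keys = character(0),
                              window = 5, homology_budget = 6,
                              promotion_budget = 3) {
  if (is.null(variants$site_idx))
    variants <- assign_to_sites(variants, sites, window = window)
  n <- nrow(variants)
  variants$class <- rep(NA_character_, n)
  variants$evidence <- rep("", n)
  if (n == 0) return(variants)
  keys <- variant_key(variants)

  ledger_keys <- character(0); ledger_groups <- character(0)
  if (!is.null(controls_ledger) && nrow(controls_ledger) > 0) {
    ledger_keys <- variant_key(controls_ledger)
    ledger_groups <- controls_ledger$absorbed_by_group
    dup <- tapply(ledger_groups, ledger_keys,
                  function(g) length(unique(g)))
    if (any(dup > 1))
      stop("conflicting control attribution for key(s): ",
           paste(names(dup)[dup > 1], collapse = ", "), call. = FALSE)
  }
  controls_checked <- !is.null(controls_ledger)

  rep_keys <- if (is.null(replicate_variants)) character(0) else
    variant_key(replicate_variants)
  rep_assigned <- NULL
  if (!is.null(replicate_variants) && nrow(replicate_variants) > 0) {
    rep_assigned <- if (!is.null(replicate_variants$site_idx))
      replicate_variants else
        assign_to_sites(replicate_variants, sites, window = window)
  }
  rep_site_idx <- if (is.null(rep_assigned)) integer(0) else
    rep_assigned$site_idx
  rep_is_indel <- if (is.null(rep_assigned)) logical(0) else
    rep_assigned$kind %in% c("INS", "DEL")
  rep_keys_a <- if (is.null(rep_assigned)) character(0) else
    variant_key(rep_assigned)

  cls <- character(n); evd <- character(n)
  v_site_idx <- variants$site_idx
  v_kind <- variants$kind
  v_mm <- variants$site_n_mismatch
  v_smm <- variants$site_seed_mismatch
  for (i in seq_len(n)) {
    key <- keys[i]
    ev <- character(0)
    ## (1) control / pedigree absorption
    if (key %in% pedigree_keys) {
      cls[i] <- "pre_existing"; evd[i] <- "in_pedigree"
      next
    }
    if (key %in% ledger_keys) {
      grp <- ledger_groups[match(key, ledger_keys)]
      cls[i] <- if (grepl("^WT", grp)) "pre_existing" else "background"
      evd[i] <- paste0("in_control:", grp)
      next
    }
    sidx <- v_site_idx[i]
    ## (2) declared target
    if (!is.na(sidx) && !is.na(target_site_idx) && sidx == target_site_idx) {
      cls[i] <- "on_target"; evd[i] <- "target_site_overlap"
      next
    }
    ## (3) indel at a homologous site
    if (!is.na(sidx)) {
      ev <- c(ev, sprintf("site_overlap:mm=%d,seed_mm=%d",
                          v_mm[i], v_smm[i]))
      if (v_kind[i] %in% c("INS", "DEL")) {
        promoted <- FALSE
        at_site <- which(!is.na(rep_site_idx) & rep_site_idx == sidx &
                           rep_is_indel)
        if (length(at_site) > 0) {
          if (any(rep_keys_a[at_site] != key)) {
            promoted <- TRUE
            ev <- c(ev, "replicate_distinct_allele")
          } else ev <- c(ev, "replicate_identical_allele")
        }
        if (!promoted && controls_checked && !key %in% ledger_keys &&
            !key %in% pedigree_keys && v_mm[i] <= promotion_budget) {
          promoted <- TRUE
          ev <- c(ev, "absent_from_controls")
        }
        cls[i] <- if (promoted) "off_target_validated" else
          "off_target_candidate"
        evd[i] <- paste(ev, collapse = ",")
        next
      } else {
        ## SNV at a site: candidate with warning, never validated
        cls[i] <- "off_target_candidate"
        evd[i] <- paste(c(ev, "snv_at_site_not_validated"), collapse = ",")
        next
      }
    }
    ## (4) shared identical allele, unassigned or poor homology
    if (key %in% rep_keys &&
        (is.na(sidx) || v_mm[i] > homology_budget)) {
      cls[i] <- "pre_existing"
      evd[i] <- paste(c(ev, "shared_identical_allele", "poor_homology"),
                      collapse = ",")
      next
    }
    ## (5) residue
    cls[i] <- "spontaneous"
    evd[i] <- paste(c(ev, "no_site_no_control"), collapse = ",")
  }
  variants$class <- cls
  variants$evidence <- evd
  variants
}

site_id <- function(x, prefix = "site") {
  paste(x$site_chrom, x$site_start, x$site_strand, sep = ":")
}

#' Per-guide off-target summary
#'
#' Aggregates classified variants across the cohort into a per-guide
#' report. Loci are counted as unique sites; a guide is flagged unsafe when
#' at least one locus carries a validated off-target mutation.
#'
#' @param classified data.frame of classified variants (rows from
#'   [classify_variants()] across samples) with a `guide_id` column.
#' @return data.frame: guide_id, n_validated_loci, n_candidate_loci,
#'   n_validated_variants, n_candidate_variants, n_on_target, safe.
#' @export
summarize_guides <- function(classified) {
  gids <- unique(classified$guide_id)
  gids <- gids[!is.na(gids)]
  out <- lapply(gids, function(g) {
    x <- classified[!is.na(classified$guide_id) &
                      classified$guide_id == g, , drop = FALSE]
    val <- x[x$class == "off_target_validated", , drop = FALSE]
    cand <- x[x$class == "off_target_candidate", , drop = FALSE]
    data.frame(
      guide_id = g,
      n_validated_loci = length(unique(site_id(val))),
      n_candidate_loci = length(unique(site_id(cand))),
      n_validated_variants = nrow(val),
      n_candidate_variants = nrow(cand),
      n_on_target = sum(x$class == "on_target"),
      safe = nrow(val) == 0,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out) %||%
    data.frame(guide_id = character(0), n_validated_loci = integer(0),
               n_candidate_loci = integer(0),
               n_validated_variants = integer(0),
               n_candidate_variants = integer(0), n_on_target = integer(0),
               safe = logical(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write a classification table as TSV
#' @param classified classified variant data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(classified, path) {
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", "kind", "class",
            "guide_id", "site_chrom", "site_start", "site_n_mismatch",
            "site_seed_mismatch", "site_pam_observed", "evidence")
  utils::write.table(
    classified[, intersect(cols, names(classified)), drop = FALSE], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
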