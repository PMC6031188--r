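## Multi-caller consensus and control subtraction.
##
## The confidence model is strict intersection: a variant is retained only
## when every caller reports the identical normalized (chrom,pos,ref,alt)
## key. Near-miss indels (same locus, different allele) never match; exact
## allele identity is what later distinguishes independently edited
## replicate lines from inherited variation.

#' Strict tri-caller (or n-caller) intersection
#'
#' Returns variants whose normalized key is present in every caller set for
#' one sample. The retained call's AF and DP are the medians across
#' callers, robust to a single outlier caller.
#'
#' @param sets list of >= 2 variant data.frames, one per caller, all for
#'   the same sample and already normalized.
#' @return a variant data.frame (caller_id dropped).
#' @export
intersect_callers <- function(sets) {
  if (length(sets) < 2) stop_input("need at least 2 caller sets")
  sids <- unique(unlist(lapply(sets, function(s)
    unique(s$sample_id[!is.na(s$sample_id)]))))
  if (length(sids) > 1)
    stop_input("mixed sample_ids in caller sets: ",
               paste(sids, collapse = ", "))
  keys <- lapply(sets, variant_key)
  shared <- Reduce(intersect, keys)
  base <- sets[[1]][match(shared, keys[[1]]), , drop = FALSE]
  if (length(shared) > 0) {
    af_mat <- vapply(seq_along(sets),
                     function(j) sets[[j]]$af[match(shared, keys[[j]])],
                     numeric(length(shared)))
    dp_mat <- vapply(seq_along(sets),
                     function(j) sets[[j]]$dp[match(shared, keys[[j]])],
                     numeric(length(shared)))
    af_mat <- matrix(af_mat, nrow = length(shared))
    dp_mat <- matrix(dp_mat, nrow = length(shared))
    base$af <- apply(af_mat, 1, stats::median, na.rm = TRUE)
    base$dp <- apply(dp_mat, 1, stats::median, na.rm = TRUE)
  }
  base$caller_id <- NULL
  rownames(base) <- NULL
  base[order(base$chrom, base$pos, base$ref, base$alt), , drop = FALSE]
}

#' Allele-frequency floor
#'
#' Drops calls whose allele frequency is below `min_af`. The boundary is
#' inclusive: af == min_af is retained, so the default 0.10 excludes
#' exactly the calls "below 10%".
#'
#' @param variants variant data.frame.
#' @param min_af minimum allele frequency in `[0,1]`; default 0.10.
#' @return filtered data.frame.
#' @export
af_filter <- function(variants, min_af = 0.10) {
  if (min_af < 0 || min_af > 1) stop_input("min_af must be in [0,1]")
  variants[is.na(variants$af) | variants$af >= min_af, , drop = FALSE]
}

#' Subtract control-derived variants
#'
#' Removes from a sample every variant whose normalized key appears in any
#' control set; removed variants are kept in a side ledger tagged with the
#' control group that absorbed them (the first matching control, in the
#' order given — put wild-type/pedigree controls first so shared inherited
#' variants are attributed to them).
#'
#' @param variants normalized variant data.frame for one sample.
#' @param controls named list of normalized variant data.frames; names are
#'   the control group labels (e.g. "WT_G1", "TC_only").
#' @return list with `variants` (retained rows) and `ledger` (removed rows
#'   plus column `absorbed_by_group`).
#' @export
subtract_controls <- function(variants, controls = list()) {
  if (length(controls) == 0) {
    ledger <- variants[0, , drop = FALSE]
    ledger$absorbed_by_group <- character(0)
    return(list(variants = variants, ledger = ledger))
  }
  if (is.null(names(controls)) || any(!nzchar(names(controls))))
    stop_input("controls must be a named list (names = control groups)")
  keys <- variant_key(variants)
  absorbed <- rep(NA_character_, length(keys))
  for (g in names(controls)) {
    ck <- variant_key(controls[[g]])
    hit <- is.na(absorbed) & keys %in% ck
    absorbed[hit] <- g
  }
  ledger <- variants[!is.na(absorbed), , drop = FALSE]
  ledger$absorbed_by_group <- absorbed[!is.na(absorbed)]
  list(variants = variants[is.na(absorbed), , drop = FALSE], ledger = ledger)
}

#' Write a subtraction ledger as TSV
#' @param ledger data.frame from [subtract_controls()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ledger_tsv <- function(ledger, path) {
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", "absorbed_by_group")
  utils::write.table(ledger[, intersect(cols, names(ledger)), drop = FALSE],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' One-sample consensus pipeline
#'
#' Convenience wrapper: normalize each caller set, intersect strictly,
#' apply the allele-frequency floor. By default the floor is applied to
#' the consensus (median) AF after intersection; set `af_per_caller` to
#' filter each caller's calls before intersecting instead.
#'
#' @param sets list of per-caller variant data.frames (raw representation).
#' @param genome a `ref_genome`.
#' @param min_af allele-frequency floor (default 0.10).
#' @param af_per_caller apply the floor per caller before intersection
#'   (default FALSE: post-intersection on consensus AF).
#' @return consensus variant data.frame.
#' @export
consensus_sample <- function(sets, genome, min_af = 0.10,
                             af_per_caller = FALSE) {
  sets <- lapply(sets, normalize_variants, genome = genome)
  if (af_per_caller)
    sets <- lapply(sets, af_filter, min_af = min_af)
  out <- intersect_callers(sets)
  if (!af_per_caller) out <- af_filter(out, min_af = min_af)
  out
}
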