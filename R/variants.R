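## Variant tables
##
## Variants travel through the package as plain data.frames with columns
##   sample_id, chrom, pos (1-based), ref, alt, kind (SNV/INS/DEL/MNV),
##   af (alt allele frequency in [0,1]), dp (read depth)
## plus caller_id where caller provenance matters. One row per
## (chrom,pos,ref,alt) key per sample; keys are compared only after
## normalization (left-aligned, minimal representation).

#' Classify a variant as SNV, insertion or deletion
#' @param ref,alt allele strings.
#' @return character vector over {"SNV","INS","DEL","MNV"}.
#' @export
variant_kind <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  out <- rep("MNV", length(ref))
  out[lr == 1 & la == 1] <- "SNV"
  out[lr < la] <- "INS"
  out[lr > la] <- "DEL"
  out
}

#' Normalized variant key
#' @param x variant data.frame.
#' @return character vector "chrom:pos:ref:alt".
#' @export
variant_key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

as_variant_table <- function(x, sample_id = NULL) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(x)))
    stop_input("variant table needs columns: ", paste(need, collapse = ", "))
  x$pos <- as.integer(x$pos)
  x$kind <- variant_kind(x$ref, x$alt)
  if (!is.null(sample_id)) x$sample_id <- sample_id
  if (is.null(x$af)) x$af <- NA_real_
  if (is.null(x$dp)) x$dp <- NA_real_
  if (any(x$ref == x$alt)) stop_input("ref == alt in variant table")
  x
}

#' Left-align and minimize variant representations
#'
#' Rewrites each variant into the canonical VCF form: shared suffix removed,
#' indels anchored on one leading reference base, and indels in repetitive
#' context shifted to their leftmost equivalent position. Idempotent. The
#' reference allele of every input row must match the genome.
#'
#' @param variants variant data.frame.
#' @param genome a `ref_genome`.
#' @return the data.frame with pos/ref/alt/kind rewritten.
#' @export
normalize_variants <- function(variants, genome) {
  if (nrow(variants) == 0) return(variants)
  if (!all(variants$chrom %in% names(genome$seq)))
    stop_input("unknown contig: ",
               setdiff(variants$chrom, names(genome$seq))[1])
  ## vectorized reference check
  contig_v <- unlist(genome$seq[variants$chrom], use.names = FALSE)
  obs <- substr(contig_v, variants$pos,
                variants$pos + nchar(variants$ref) - 1L)
  bad <- which(obs != variants$ref)
  if (length(bad) > 0)
    stop_input("reference mismatch at ", variants$chrom[bad[1]], ":",
               variants$pos[bad[1]], " (expected ", obs[bad[1]],
               ", got ", variants$ref[bad[1]], ")")
  v_pos <- variants$pos; v_ref <- variants$ref; v_alt <- variants$alt
  ## SNVs are already minimal; only indel-like rows enter the loop
  for (i in which(nchar(v_ref) != 1L | nchar(v_alt) != 1L)) {
    s <- contig_v[i]
    pos <- v_pos[i]; ref <- v_ref[i]; alt <- v_alt[i]
    repeat {
      lr <- nchar(ref); la <- nchar(alt)
      ## trim a shared last base (never reduces an SNV), extending left
      ## from the reference when an allele would empty: this is what
      ## shifts indels leftward through repeats
      if (lr > 0 && la > 0 && (lr > 1 || la > 1) &&
          substr(ref, lr, lr) == substr(alt, la, la)) {
        ref <- substr(ref, 1L, lr - 1L)
        alt <- substr(alt, 1L, la - 1L)
        if (nchar(ref) == 0 || nchar(alt) == 0) {
          if (pos == 1L) {        # cannot extend: re-anchor and stop
            b <- substr(s, pos, pos)
            ref <- paste0(b, ref); alt <- paste0(b, alt)
            break
          }
          pos <- pos - 1L
          b <- substr(s, pos, pos)
          ref <- paste0(b, ref); alt <- paste0(b, alt)
        }
        next
      }
      break
    }
    ## trim shared leading bases down to the single anchor base
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
    }
    v_pos[i] <- pos
    v_ref[i] <- ref
    v_alt[i] <- alt
  }
  variants$pos <- v_pos
  variants$ref <- v_ref
  variants$alt <- v_alt
  variants$kind <- variant_kind(v_ref, v_alt)
  variants
}

#' Read one sample/caller VCF
#'
#' Parses a VCF 4.2 file into a variant table. Multi-allelic records are
#' split into one row per alternate allele. AF and DP are taken from INFO
#' when present, falling back to the first sample's FORMAT fields; AF is
#' imputed from FORMAT/AD when neither carries it and `on_missing_af`
#' is "impute".
#'
#' @param path VCF file (plain text or gzipped).
#' @param sample_id,caller_id identifiers recorded on every row.
#' @param on_missing_af "error" (default) or "impute".
#' @return a variant data.frame.
#' @export
read_vcf <- function(path, sample_id, caller_id = NA_character_,
                     on_missing_af = c("error", "impute")) {
  on_missing_af <- match.arg(on_missing_af)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(nrow(fix)) && length(fix) > 0)   # single record: vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (is.null(nrow(fix)) || nrow(fix) == 0) {
    out <- empty_variants()
    out$caller_id <- character(0)
    return(out)
  }
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt_raw <- fix[, "ALT"]

  af_raw <- suppressWarnings(vcfR::extract.info(v, "AF"))
  dp_raw <- suppressWarnings(vcfR::extract.info(v, "DP"))
  if (all(is.na(af_raw)) && ncol(v@gt) >= 2) {
    gt_af <- suppressWarnings(vcfR::extract.gt(v, "AF"))
    if (!is.null(gt_af)) af_raw <- gt_af[, 1]
  }
  if (all(is.na(dp_raw)) && ncol(v@gt) >= 2) {
    gt_dp <- suppressWarnings(vcfR::extract.gt(v, "DP"))
    if (!is.null(gt_dp)) dp_raw <- gt_dp[, 1]
  }
  if (all(is.na(af_raw)) && ncol(v@gt) >= 2 && on_missing_af == "impute") {
    ad <- suppressWarnings(vcfR::extract.gt(v, "AD"))
    if (!is.null(ad)) {
      af_raw <- vapply(strsplit(ad[, 1], ",", fixed = TRUE), function(a) {
        a <- suppressWarnings(as.numeric(a))
        if (length(a) < 2 || sum(a) == 0) return(NA_character_)
        paste(a[-1] / sum(a), collapse = ",")
      }, character(1))
    }
  }
  if (all(is.na(af_raw)))
    stop_input("VCF has no AF in INFO or FORMAT (", path, ")")

  rows <- vector("list", length(pos))
  for (i in seq_along(pos)) {
    alts <- strsplit(alt_raw[i], ",", fixed = TRUE)[[1]]
    afs <- suppressWarnings(as.numeric(
      strsplit(as.character(af_raw[i]), ",", fixed = TRUE)[[1]]))
    if (length(afs) < length(alts)) afs <- rep(afs[1], length(alts))
    rows[[i]] <- data.frame(
      sample_id = sample_id, chrom = unname(chrom[i]), pos = unname(pos[i]),
      ref = unname(ref[i]), alt = unname(alts),
      kind = variant_kind(ref[i], alts),
      af = unname(afs[seq_along(alts)]),
      dp = suppressWarnings(as.numeric(unname(dp_raw[i]))),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  out$caller_id <- caller_id
  if (any(!is.na(out$af) & (out$af < 0 | out$af > 1)))
    stop_input("AF outside [0,1] in ", path)
  rownames(out) <- NULL
  out
}

#' Write a variant table as a single-sample VCF 4.2
#'
#' Emits DP and AF both in INFO and as FORMAT fields. Records are sorted by
#' (chrom, pos).
#'
#' @param variants variant data.frame for one sample.
#' @param path output file.
#' @param genome a `ref_genome` (used for contig header lines).
#' @param sample_id sample column name; defaults to the table's sample_id.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, genome, sample_id = NULL) {
  sample_id <- sample_id %||%
    (if (nrow(variants) > 0) variants$sample_id[1] else "SAMPLE")
  if (is.na(sample_id)) sample_id <- "SAMPLE"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=otwgs",
    paste0("##contig=<ID=", names(genome$seq), ",length=", genome$lengths, ">"),
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Alt allele frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Alt allele frequency">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t"))
  if (nrow(variants) > 0) {
    v <- variants[order(variants$chrom, variants$pos, variants$ref,
                        variants$alt), , drop = FALSE]
    dp <- ifelse(is.na(v$dp), ".", format(round(v$dp), scientific = FALSE,
                                          trim = TRUE))
    af <- ifelse(is.na(v$af), ".", formatC(v$af, digits = 6, format = "g"))
    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                  paste0("DP=", dp, ";AF=", af),
                  "GT:DP:AF",
                  paste0("0/1:", dp, ":", af), sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
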