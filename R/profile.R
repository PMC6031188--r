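## Mutation-rate, spectrum, allele-frequency and feature profiling.

#' Per-site mutation rate estimate
#'
#' rate = n_mutations / (ploidy * genome_length_bp * n_generations),
#' reported per site per diploid genome per generation by default.
#'
#' @param n_mutations mutation count (>= 0).
#' @param genome_length_bp haploid genome length in bp.
#' @param n_generations number of parent-to-progeny links (default 1).
#' @param ploidy denominator multiplier (default 2, diploid; use 1 for a
#'   per-haploid-site rate).
#' @return object of class `rate_estimate` with fields n_mutations,
#'   diploid_sites, n_generations, rate.
#' @examples
#' mutation_rate(41, 3.74e8)$rate   # ~5.5e-8
#' @export
mutation_rate <- function(n_mutations, genome_length_bp, n_generations = 1,
                          ploidy = 2) {
  if (genome_length_bp <= 0) stop_input("genome length must be > 0")
  if (n_generations <= 0) stop_input("n_generations must be > 0")
  if (n_mutations < 0) stop_input("n_mutations must be >= 0")
  sites <- ploidy * genome_length_bp
  structure(list(n_mutations = n_mutations, diploid_sites = sites,
                 n_generations = n_generations,
                 rate = n_mutations / (sites * n_generations)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> %g mutations / (%g sites x %g generations) = %.3g per site per generation\n",
    x$n_mutations, x$diploid_sites, x$n_generations, x$rate))
  invisible(x)
}

SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' SNV spectrum with pyrimidine-strand folding
#'
#' Maps each SNV to one of the six pyrimidine-context classes (changes
#' from a purine reference are complemented first, so G>A counts under
#' C>T, i.e. G:C>A:T). Also reports the transition/transversion ratio and
#' the fraction of G:C>A:T transitions.
#'
#' @param variants variant data.frame; non-SNV rows are an error.
#' @return list: `counts` (named integer vector over the 6 classes),
#'   `ts_tv` (NA when no transversions... NA when input empty),
#'   `gc_to_at_fraction`.
#' @export
snv_spectrum <- function(variants) {
  if (any(variants$kind != "SNV"))
    stop_input("snv_spectrum takes SNVs only")
  counts <- stats::setNames(integer(6), SPECTRUM_CLASSES)
  if (nrow(variants) == 0)
    return(list(counts = counts, ts_tv = NA_real_,
                gc_to_at_fraction = NA_real_))
  ref <- variants$ref; alt <- variants$alt
  purine <- ref %in% c("A", "G")
  ref[purine] <- complement_base(variants$ref[purine])
  alt[purine] <- complement_base(variants$alt[purine])
  cls <- paste0(ref, ">", alt)
  tab <- table(factor(cls, levels = SPECTRUM_CLASSES))
  counts[] <- as.integer(tab)
  ts <- counts[["C>T"]] + counts[["T>C"]]
  tv <- sum(counts) - ts
  list(counts = counts,
       ts_tv = if (tv == 0) NA_real_ else ts / tv,
       gc_to_at_fraction = counts[["C>T"]] / sum(counts))
}

#' Allele-frequency bins
#'
#' Bins calls into somatic-like (AF in `[0, 0.25]`), heterozygous-like
#' (AF in (0.25, 0.75)) and homozygous-like (AF in `[0.75, 1.0]`): the
#' boundary 0.25 is assigned downward, 0.75 upward.
#'
#' @param calls variant data.frame with an `af` column in `[0,1]`.
#' @return named integer vector: somatic_like, heterozygous_like,
#'   homozygous_like (summing to `nrow(calls)`).
#' @export
af_bins <- function(calls) {
  af <- calls$af
  if (any(is.na(af)) || any(af < 0 | af > 1))
    stop_input("af must be present and in [0, 1]")
  c(somatic_like = sum(af <= 0.25),
    heterozygous_like = sum(af > 0.25 & af < 0.75),
    homozygous_like = sum(af >= 0.75))
}

FEATURE_CATEGORIES <- c("CDS", "UTR", "intron", "TE", "repeat", "intergenic")

#' Build a feature annotation track
#'
#' @param intervals data.frame with chrom, start, end (1-based inclusive)
#'   and category (one of CDS/UTR/intron/TE/repeat/intergenic), or a
#'   GRanges with a `category` metadata column. Overlapping categories are
#'   resolved by the precedence CDS > UTR > intron > TE > repeat >
#'   intergenic; genome not covered by any interval is intergenic.
#' @param genome a `ref_genome` (defines total length and contigs).
#' @return object of class `feature_track`: list with `gr` (category-
#'   disjoint GRanges) and `fractions` (named genomic fraction per
#'   category, summing to 1).
#' @export
feature_track <- function(intervals, genome) {
  if (inherits(intervals, "GRanges")) {
    gr <- intervals
    cat_col <- S4Vectors::mcols(gr)$category
  } else {
    gr <- GenomicRanges::GRanges(
      intervals$chrom, IRanges::IRanges(intervals$start, intervals$end))
    cat_col <- intervals$category
  }
  if (is.null(cat_col)) stop_input("intervals need a category column")
  cat_col <- as.character(cat_col)
  bad <- !cat_col %in% FEATURE_CATEGORIES
  if (any(bad)) stop_input("unknown categories: ",
                           paste(unique(cat_col[bad]), collapse = ", "))
  ## precedence flattening: higher categories mask lower ones
  taken <- GenomicRanges::GRanges()
  pieces <- list()
  for (cat in setdiff(FEATURE_CATEGORIES, "intergenic")) {
    g <- GenomicRanges::reduce(gr[cat_col == cat])
    g <- GenomicRanges::setdiff(g, taken)
    if (length(g) > 0) {
      S4Vectors::mcols(g)$category <- cat
      pieces[[cat]] <- g
    }
    taken <- GenomicRanges::reduce(c(taken, g))
  }
  flat <- if (length(pieces)) do.call(c, unname(pieces)) else
    GenomicRanges::GRanges()
  total <- genome_length(genome)
  widths <- vapply(FEATURE_CATEGORIES, function(cat) {
    if (cat == "intergenic") return(NA_real_)
    if (is.null(pieces[[cat]])) 0 else
      sum(as.numeric(GenomicRanges::width(pieces[[cat]])))
  }, numeric(1))
  widths["intergenic"] <- total - sum(widths, na.rm = TRUE)
  if (widths["intergenic"] < 0)
    stop_input("annotation exceeds genome length")
  structure(list(gr = flat, fractions = widths / total), class = "feature_track")
}

#' Read a feature track from GFF3 or BED
#'
#' The category is taken from the `type` column (GFF3) or the name column
#' (BED); values are matched case-insensitively against
#' CDS/UTR/intron/TE/repeat/intergenic (unknown types are dropped with a
#' message).
#'
#' @param path GFF3/BED file.
#' @param genome a `ref_genome`.
#' @return a `feature_track`.
#' @export
read_feature_track <- function(path, genome) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_input("rtracklayer is required to import feature files")
  gr <- rtracklayer::import(path)
  m <- S4Vectors::mcols(gr)
  raw <- as.character(m$type %||% m$name)
  idx <- match(toupper(raw), toupper(FEATURE_CATEGORIES))
  if (any(is.na(idx)))
    message("dropping ", sum(is.na(idx)), " feature(s) with unknown type")
  gr <- gr[!is.na(idx)]
  S4Vectors::mcols(gr)$category <- FEATURE_CATEGORIES[idx[!is.na(idx)]]
  feature_track(gr, genome)
}

#' Feature-category assignment of variant positions
#' @param variants variant data.frame.
#' @param track a `feature_track`.
#' @return character vector of categories (uncovered -> "intergenic").
#' @export
variant_categories <- function(variants, track) {
  if (nrow(variants) == 0) return(character(0))
  v_gr <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(variants$pos, variants$pos))
  out <- rep("intergenic", nrow(variants))
  if (length(track$gr) > 0) {
    hits <- GenomicRanges::findOverlaps(v_gr, track$gr, select = "first")
    hit <- !is.na(hits)
    out[hit] <- S4Vectors::mcols(track$gr)$category[hits[hit]]
  }
  out
}

#' Feature-annotation enrichment of mutations
#'
#' For each category: observed variant count, expected count under uniform
#' placement (n * genomic fraction), enrichment ratio, and a two-sided
#' binomial test with Benjamini-Hochberg correction across categories.
#'
#' @param variants variant data.frame.
#' @param track a `feature_track`.
#' @return data.frame: category, genomic_fraction, observed, expected,
#'   enrichment, p_value, p_adj.
#' @export
feature_enrichment <- function(variants, track) {
  n <- nrow(variants)
  cats <- variant_categories(variants, track)
  out <- do.call(rbind, lapply(FEATURE_CATEGORIES, function(cat) {
    frac <- track$fractions[[cat]]
    obs <- sum(cats == cat)
    exp <- n * frac
    p <- if (n == 0 || frac <= 0 || frac >= 1) NA_real_ else
      stats::binom.test(obs, n, frac, alternative = "two.sided")$p.value
    data.frame(category = cat, genomic_fraction = frac, observed = obs,
               expected = exp,
               enrichment = if (exp > 0) obs / exp else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  }))
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
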