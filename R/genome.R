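#' Reference genome container
#'
#' A minimal in-memory reference: a named character vector of uppercase
#' contig sequences. This stands in for a real assembly at desk scale;
#' coordinates throughout the package are 1-based inclusive (VCF
#' convention) unless a function documents otherwise.
#'
#' @param sequences named character vector, one uppercase DNA string
#'   (A/C/G/T, N tolerated) per contig; names are contig names.
#' @return an object of class `ref_genome` with elements `seq` (the
#'   sequences) and `lengths` (per-contig bp).
#' @examples
#' g <- reference_genome(c(chr1 = "ACGTACGTAA"))
#' genome_length(g)
#' @export
reference_genome <- function(sequences) {
  if (length(sequences) == 0 || is.null(names(sequences)) ||
      any(!nzchar(names(sequences))))
    stop_input("sequences must be a non-empty named character vector")
  if (anyDuplicated(names(sequences)))
    stop_input("contig names must be unique")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop_input("contig(s) contain non-ACGTN characters: ",
               paste(names(sequences)[bad], collapse = ", "))
  structure(list(seq = sequences, lengths = nchar(sequences)),
            class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("<ref_genome> ", length(x$seq), " contig(s), ",
      format(sum(x$lengths), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Total genome length in bp
#' @param genome a `ref_genome`.
#' @return integer total bp.
#' @export
genome_length <- function(genome) sum(genome$lengths)

#' Extract a reference subsequence
#'
#' @param genome a `ref_genome`.
#' @param chrom contig name.
#' @param start,end 1-based inclusive coordinates.
#' @return character string.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  s <- genome$seq[[chrom]]
  if (is.null(s)) stop_input("unknown contig: ", chrom)
  if (any(start < 1) || any(end > nchar(s)))
    stop_input("coordinates outside contig ", chrom)
  substr(rep(s, length(start)), start, end)
}

#' Simulate a random reference genome
#'
#' Draws i.i.d. bases with the requested GC content. Deterministic for a
#' fixed seed.
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig in bp (>= 1000).
#' @param gc target GC fraction in (0, 1).
#' @param seed integer seed.
#' @return a `ref_genome`.
#' @examples
#' g <- simulate_reference(1, 10000, 0.43, seed = 1)
#' @export
simulate_reference <- function(n_contigs, contig_length, gc = 0.43, seed) {
  if (n_contigs < 1) stop_input("n_contigs must be >= 1")
  if (contig_length < 1000) stop_input("contig_length must be >= 1000")
  if (gc <= 0 || gc >= 1) stop_input("gc must be in (0, 1)")
  withr::with_seed(derive_seed(seed, "reference"), {
    seqs <- vapply(seq_len(n_contigs), function(i) {
      paste(sample(c("A", "C", "G", "T"), contig_length, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1))
  })
  names(seqs) <- paste0("chr", seq_len(n_contigs))
  reference_genome(seqs)
}

#' Read a reference genome from FASTA
#' @param path FASTA file.
#' @return a `ref_genome`.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  ## keep only the first word of each FASTA header
  names(seqs) <- sub("\\s.*$", "", names(ss))
  reference_genome(seqs)
}

#' Write a reference genome to FASTA (60-column wrapped)
#' @param genome a `ref_genome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Apply variants to a genome sequence
#'
#' Produces the edited sequence of one contig given non-overlapping,
#' VCF-style variants on it. Used by tests and the simulator to check that
#' variant representations are coherent with the reference.
#'
#' @param genome a `ref_genome`.
#' @param chrom contig name.
#' @param variants data.frame with pos/ref/alt on that contig.
#' @return edited sequence as a character string.
#' @export
apply_variants <- function(genome, chrom, variants) {
  s <- genome$seq[[chrom]]
  if (nrow(variants) == 0) return(s)
  v <- variants[order(variants$pos), , drop = FALSE]
  out <- character(0)
  cursor <- 1L
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]; ref <- v$ref[i]; alt <- v$alt[i]
    if (p < cursor) stop_input("overlapping variants on ", chrom)
    if (substr(s, p, p + nchar(ref) - 1L) != ref)
      stop_input("ref allele mismatch at ", chrom, ":", p)
    out <- c(out, substr(s, cursor, p - 1L), alt)
    cursor <- p + nchar(ref)
  }
  paste(c(out, substr(s, cursor, nchar(s))), collapse = "")
}
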