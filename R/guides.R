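## Protospacer + PAM genome scanning.
##
## Sites are found by anchoring on PAM-compatible positions (IUPAC
## expansion) and counting Hamming mismatches over the protospacer, on both
## strands. Coordinates are 0-based half-open internally (the `start`/`end`
## columns of a site table) and converted to 1-based only in reports, so
## they compose cleanly with VCF positions.

#' Guide specification
#'
#' @param guide_id identifier.
#' @param protospacer genomic protospacer sequence, 5'->3' on the
#'   protospacer strand (20 nt for Cas9, 23 nt for Cpf1 by convention;
#'   other lengths are accepted).
#' @param nuclease "Cas9" (3' NGG-type PAM) or "Cpf1" (5' TTTV-type PAM).
#' @param pam_patterns IUPAC PAM patterns in guide orientation; defaults to
#'   "NGG" (Cas9) or "TTTV" (Cpf1). The first pattern is the canonical one;
#'   alternatives such as "NAG" may be appended.
#' @param target optional declared on-target site: list(chrom, start,
#'   strand) with `start` the 0-based start of the protospacer+PAM
#'   interval, as reported by [find_sites()].
#' @return an object of class `guide_spec`.
#' @export
guide_spec <- function(guide_id, protospacer,
                       nuclease = c("Cas9", "Cpf1"),
                       pam_patterns = NULL, target = NULL) {
  nuclease <- match.arg(nuclease)
  protospacer <- toupper(protospacer)
  if (grepl("[^ACGT]", protospacer))
    stop_input("protospacer must contain only A/C/G/T")
  if (is.null(pam_patterns))
    pam_patterns <- if (nuclease == "Cas9") "NGG" else "TTTV"
  pam_patterns <- toupper(pam_patterns)
  for (p in pam_patterns)
    if (!all(strsplit(p, "")[[1]] %in% names(IUPAC)))
      stop_input("invalid IUPAC PAM pattern: ", p)
  structure(list(
    guide_id = guide_id, protospacer = protospacer, nuclease = nuclease,
    pam_side = if (nuclease == "Cas9") "3p" else "5p",
    pam_patterns = pam_patterns, target = target), class = "guide_spec")
}

#' @export
print.guide_spec <- function(x, ...) {
  cat("<guide_spec> ", x$guide_id, ": ", x$nuclease, " ", x$protospacer,
      " PAM(", x$pam_side, "): ", paste(x$pam_patterns, collapse = ","),
      "\n", sep = "")
  invisible(x)
}

## protospacer positions (1 = 5' end of the protospacer as written) that
## fall inside the PAM-proximal seed of length seed_len
seed_positions <- function(guide, seed_len) {
  P <- nchar(guide$protospacer)
  if (seed_len > P) stop_input("seed_len exceeds protospacer length")
  if (guide$pam_side == "3p") (P - seed_len + 1L):P else 1:seed_len
}

iupac_match <- function(s, pattern) {
  sc <- strsplit(s, "")[[1]]; pc <- strsplit(pattern, "")[[1]]
  length(sc) == length(pc) &&
    all(mapply(function(b, p) b %in% IUPAC[[p]], sc, pc))
}

empty_sites <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), guide_id = character(0),
             n_mismatch = integer(0), seed_mismatch = integer(0),
             pam_observed = character(0), pam_canonical = logical(0),
             protospacer_observed = character(0),
             stringsAsFactors = FALSE)
}

#' Scan a genome for guide-matching sites
#'
#' Finds every position, on both strands, where a PAM pattern matches
#' exactly (IUPAC expansion) and the protospacer matches within
#' `max_mismatch` Hamming mismatches. Reference N bases never match a
#' protospacer position and never satisfy a PAM position.
#'
#' @param genome a `ref_genome`.
#' @param guide a `guide_spec`.
#' @param max_mismatch maximum protospacer mismatches (<= protospacer
#'   length).
#' @param pam_patterns override of the guide's PAM patterns (e.g. add
#'   "NAG" when mapping mutations rather than designing guides).
#' @param seed_len seed length used for the reported `seed_mismatch`
#'   (PAM-proximal positions 1..seed_len; default 18).
#' @return data.frame of sites sorted by (chrom, start): `start`/`end` are
#'   the 0-based half-open protospacer+PAM interval; `pam_observed` and
#'   `protospacer_observed` read 5'->3' on the matching strand;
#'   `pam_canonical` is TRUE when the observed PAM satisfies the guide's
#'   first (canonical) pattern.
#' @export
find_sites <- function(genome, guide, max_mismatch,
                       pam_patterns = guide$pam_patterns, seed_len = 18) {
  P <- nchar(guide$protospacer)
  if (max_mismatch > P) stop_input("max_mismatch exceeds protospacer length")
  pchars <- strsplit(guide$protospacer, "")[[1]]
  seed_idx <- seed_positions(guide, min(seed_len, P))
  out <- list()
  for (chrom in names(genome$seq)) {
    contig <- genome$seq[[chrom]]
    L <- nchar(contig)
    dna <- Biostrings::DNAString(contig)
    for (pi in seq_along(pam_patterns)) {
      pat <- pam_patterns[[pi]]
      Q <- nchar(pat)
      site_len <- P + Q
      if (L < site_len) next
      pam_sets <- IUPAC[strsplit(pat, "")[[1]]]
      for (strand in c("+", "-")) {
        ## PAM anchoring at C speed; candidates are then re-verified
        ## (handles reference N pessimistically) and Hamming-scored
        pam_plus <- if (strand == "+") pat else revcomp(pat)
        hits <- Biostrings::matchPattern(
          Biostrings::DNAString(pam_plus), dna, fixed = "subject")
        pam_pos <- Biostrings::start(hits)
        if (length(pam_pos) == 0) next
        pam_left <- (guide$pam_side == "3p") != (strand == "+")
        cand <- if (pam_left) pam_pos else pam_pos - P
        cand <- cand[cand >= 1L & cand + site_len - 1L <= L]
        if (length(cand) == 0) next
        ## Hamming distance of the protospacer at each candidate (C level;
        ## reference N counts as a mismatch since matching is fixed-letter)
        proto_plus <- if (strand == "+") guide$protospacer else
          revcomp(guide$protospacer)
        proto_start <- cand + if (pam_left) Q else 0L
        mm <- Biostrings::neditStartingAt(
          Biostrings::DNAString(proto_plus), dna,
          starting.at = proto_start, with.indels = FALSE)
        keep <- mm <= max_mismatch
        cand <- cand[keep]; proto_start <- proto_start[keep]
        mm <- mm[keep]
        if (length(cand) == 0) next
        ## seed mismatches: the seed is a contiguous protospacer block
        a <- min(seed_idx); b <- max(seed_idx)
        if (strand == "+") {
          seed_pat <- substr(guide$protospacer, a, b)
          seed_start <- proto_start + a - 1L
        } else {
          seed_pat <- substr(proto_plus, P - b + 1L, P - a + 1L)
          seed_start <- proto_start + (P - b)
        }
        smm <- Biostrings::neditStartingAt(
          Biostrings::DNAString(seed_pat), dna,
          starting.at = seed_start, with.indels = FALSE)
        site_seq <- substring(contig, cand, cand + site_len - 1L)
        if (strand == "-") site_seq <- revcomp(site_seq)
        ## pessimistic N handling in the PAM: drop sites whose observed
        ## PAM contains N, whatever the anchor matcher decided
        pam_chk <- if (guide$pam_side == "3p")
          substr(site_seq, P + 1L, site_len) else substr(site_seq, 1L, Q)
        ok_n <- !grepl("N", pam_chk, fixed = TRUE)
        cand <- cand[ok_n]; mm <- mm[ok_n]; smm <- smm[ok_n]
        site_seq <- site_seq[ok_n]
        if (length(cand) == 0) next
        if (guide$pam_side == "3p") {
          proto_obs <- substr(site_seq, 1L, P)
          pam_obs <- substr(site_seq, P + 1L, site_len)
        } else {
          pam_obs <- substr(site_seq, 1L, Q)
          proto_obs <- substr(site_seq, Q + 1L, site_len)
        }
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = cand - 1L, end = cand - 1L + site_len,
          strand = strand, guide_id = guide$guide_id,
          n_mismatch = mm, seed_mismatch = smm,
          pam_observed = pam_obs,
          pam_canonical = vapply(pam_obs, iupac_match, logical(1),
                                 pattern = guide$pam_patterns[1]),
          protospacer_observed = proto_obs,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty_sites())
  res <- do.call(rbind, out)
  ## a site can satisfy several patterns; keep the first-listed pattern's row
  res <- res[!duplicated(paste(res$chrom, res$start, res$strand)), ,
             drop = FALSE]
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count seed mismatches of a site
#'
#' Recounts mismatches over the `seed_len` PAM-proximal protospacer
#' positions of one site row, for seed definitions other than the one used
#' at scan time.
#'
#' @param site one row of a [find_sites()] table.
#' @param guide the `guide_spec`.
#' @param seed_len seed length (default 18, i.e. positions 1-18 from the
#'   PAM).
#' @return integer mismatch count.
#' @export
count_seed_mismatches <- function(site, guide, seed_len = 18) {
  idx <- seed_positions(guide, seed_len)
  g <- strsplit(guide$protospacer, "")[[1]]
  o <- strsplit(site$protospacer_observed[1], "")[[1]]
  sum(g[idx] != o[idx])
}

#' Bulge-aware alignment of a guide to a mutation flank
#'
#' Enumerates local alignments of the protospacer against a short flank
#' (both strands): every ungapped offset plus every placement of a single
#' 1-nt gap. A gap on the target side (base missing from the flank,
#' unpaired guide base: "rna" bulge) or on the guide side (extra flank
#' base: "dna" bulge) is allowed. The gap penalty (1.5 matches) makes one
#' bulge outrank two mismatches. Hits with fewer than `min_match` matching
#' bases are suppressed.
#'
#' @param flank character string, typically the 25 bp up- and downstream of
#'   a mutation (51 bp; shorter at contig ends).
#' @param guide a `guide_spec`.
#' @param min_match minimum matching bases to report (default 15).
#' @return data.frame of hits sorted by decreasing score: strand, start
#'   (1-based offset in the flank), span, matches, mismatches, bulges,
#'   gap_type ("none"/"rna"/"dna"), score.
#' @export
flank_align <- function(flank, guide, min_match = 15) {
  flank <- toupper(flank)
  Fn <- nchar(flank)
  P <- nchar(guide$protospacer)
  hits <- list()
  add <- function(strand, start, span, matches, aligned, bulges, gap_type) {
    if (matches < min_match) return()
    hits[[length(hits) + 1L]] <<- data.frame(
      strand = strand, start = start, span = span, matches = matches,
      mismatches = aligned - matches, bulges = bulges, gap_type = gap_type,
      score = matches - 1.5 * bulges, stringsAsFactors = FALSE)
  }
  fch <- strsplit(flank, "")[[1]]
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") guide$protospacer else revcomp(guide$protospacer)
    gch <- strsplit(pat, "")[[1]]
    ## ungapped
    if (Fn >= P) for (o in 1:(Fn - P + 1L)) {
      m <- sum(gch == fch[o:(o + P - 1L)])
      add(strand, o, P, m, P, 0L, "none")
    }
    ## guide base unpaired: span P-1 in the flank ("rna" bulge)
    if (Fn >= P - 1L) for (o in 1:(Fn - (P - 1L) + 1L)) {
      w <- fch[o:(o + P - 2L)]
      for (k in 2:(P - 1L)) {
        m <- sum(gch[-k] == w)
        add(strand, o, P - 1L, m, P - 1L, 1L, "rna")
      }
    }
    ## extra flank base unpaired: span P+1 in the flank ("dna" bulge)
    if (Fn >= P + 1L) for (o in 1:(Fn - (P + 1L) + 1L)) {
      w <- fch[o:(o + P)]
      for (k in 2:P) {
        m <- sum(gch == w[-k])
        add(strand, o, P + 1L, m, P, 1L, "dna")
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(strand = character(0), start = integer(0),
                      span = integer(0), matches = integer(0),
                      mismatches = integer(0), bulges = integer(0),
                      gap_type = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, hits)
  res <- res[order(-res$score, res$bulges, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract the flank around a genomic position
#'
#' @param genome a `ref_genome`.
#' @param chrom contig.
#' @param pos 1-based position.
#' @param width bp on each side (default 25, for a 51-bp flank).
#' @return character string (shorter at contig ends).
#' @export
extract_flank <- function(genome, chrom, pos, width = 25) {
  L <- genome$lengths[[chrom]]
  genome_subseq(genome, chrom, max(1L, pos - width), min(L, pos + width))
}

#' Guide-safety check against the seed rule
#'
#' Scans the genome at a small mismatch budget (default 3, the usual
#' prediction budget) with the guide's canonical PAM patterns, designates
#' the on-target site (the declared target when the guide carries one,
#' otherwise the best match), and applies the seed rule: the guide is safe
#' iff every other site has at least 2 mismatches inside the
#' `seed_len` PAM-proximal positions.
#'
#' @param genome a `ref_genome`.
#' @param guide a `guide_spec`.
#' @param seed_len seed length (default 18).
#' @param max_mismatch scan budget (default 3).
#' @param pam_patterns PAM override; defaults to the guide's own patterns
#'   (alternative PAMs such as NAG are deliberately not added for design
#'   safety checks).
#' @return list: `safe` (logical), `best_offtarget` (one-row site
#'   data.frame or NULL), `on_target` (site row or NULL), `sites` (all
#'   scanned sites).
#' @export
guide_specificity <- function(genome, guide, seed_len = 18,
                              max_mismatch = 3,
                              pam_patterns = guide$pam_patterns) {
  sites <- find_sites(genome, guide, max_mismatch,
                      pam_patterns = pam_patterns, seed_len = seed_len)
  if (nrow(sites) == 0)
    return(list(safe = TRUE, best_offtarget = NULL, on_target = NULL,
                sites = sites))
  is_target <- rep(FALSE, nrow(sites))
  if (!is.null(guide$target)) {
    is_target <- sites$chrom == guide$target$chrom &
      sites$start == guide$target$start &
      sites$strand == guide$target$strand
  }
  if (!any(is_target)) {
    best <- order(sites$n_mismatch, sites$seed_mismatch, sites$chrom,
                  sites$start)[1]
    is_target[best] <- TRUE
  }
  off <- sites[!is_target, , drop = FALSE]
  safe <- nrow(off) == 0 || all(off$seed_mismatch >= 2)
  best_off <- if (nrow(off) == 0) NULL else
    off[order(off$seed_mismatch, off$n_mismatch, off$chrom, off$start)[1], ,
        drop = FALSE]
  list(safe = safe, best_offtarget = best_off,
       on_target = sites[which(is_target)[1], , drop = FALSE], sites = sites)
}

#' Write a site table as BED6+
#'
#' Columns: chrom, start, end, name (guide_id), score (n_mismatch), strand,
#' then seed_mismatch and pam_observed.
#'
#' @param sites a [find_sites()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  df <- data.frame(sites$chrom, sites$start, sites$end, sites$guide_id,
                   sites$n_mismatch, sites$strand, sites$seed_mismatch,
                   sites$pam_observed)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
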