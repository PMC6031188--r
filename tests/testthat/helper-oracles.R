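## Independent oracles and fixture builders used across the suite.

## Exhaustive both-strand window scan: enumerates every window of the
## genome (and of its reverse complement), checks the PAM by regular
## expression and counts protospacer mismatches character by character.
## Deliberately structured unlike the PAM-anchored scanner it checks.
oracle_find_sites <- function(genome, guide, max_mismatch,
                              pam_patterns = guide$pam_patterns,
                              seed_len = 18) {
  P <- nchar(guide$protospacer)
  pchars <- strsplit(guide$protospacer, "")[[1]]
  seed_idx <- if (guide$pam_side == "3p") (P - seed_len + 1):P else
    1:seed_len
  iupac_re <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
                B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
                N = "[ACGT]")
  rows <- list()
  for (chrom in names(genome$seq)) {
    s <- genome$seq[[chrom]]
    L <- nchar(s)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (pat in pam_patterns) {
      Q <- nchar(pat)
      site_len <- P + Q
      if (L < site_len) next
      pam_re <- paste0("^", paste(iupac_re[strsplit(pat, "")[[1]]],
                                  collapse = ""), "$")
      for (strand in c("+", "-")) {
        text <- if (strand == "+") s else rc
        starts <- 1:(L - site_len + 1)
        wins <- substring(text, starts, starts + site_len - 1)
        if (guide$pam_side == "3p") {
          pr <- substr(wins, 1, P); pm <- substr(wins, P + 1, site_len)
        } else {
          pm <- substr(wins, 1, Q); pr <- substr(wins, Q + 1, site_len)
        }
        for (i in which(grepl(pam_re, pm))) {
          d <- strsplit(pr[i], "")[[1]] != pchars
          if (sum(d) > max_mismatch) next
          start0 <- if (strand == "+") starts[i] - 1 else
            L - (starts[i] - 1) - site_len
          rows[[length(rows) + 1]] <- data.frame(
            chrom = chrom, start = start0, strand = strand,
            n_mismatch = sum(d), seed_mismatch = sum(d[seed_idx]),
            pam_observed = pm[i], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), n_mismatch = integer(0),
                      seed_mismatch = integer(0),
                      pam_observed = character(0)))
  res <- do.call(rbind, rows)
  res <- res[!duplicated(paste(res$chrom, res$start, res$strand)), ,
             drop = FALSE]
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

## sorted comparable view of a site table
site_view <- function(sites) {
  v <- sites[order(sites$chrom, sites$start, sites$strand),
             c("chrom", "start", "strand", "n_mismatch", "seed_mismatch"),
             drop = FALSE]
  rownames(v) <- NULL
  v
}

## overwrite genome sequence at a 1-based position
plant_seq <- function(genome, chrom, at, seq) {
  s <- genome$seq[[chrom]]
  stopifnot(at + nchar(seq) - 1 <= nchar(s))
  genome$seq[[chrom]] <- paste0(substr(s, 1, at - 1), seq,
                                substr(s, at + nchar(seq), nchar(s)))
  reference_genome(genome$seq)
}

random_protospacer <- function(n = 20) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## minimal variant row constructor for classifier/consensus tests
vrow <- function(chrom, pos, ref, alt, af = 0.5, dp = 60,
                 sample_id = "s1", caller_id = NULL) {
  out <- data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
                    ref = ref, alt = alt, kind = variant_kind(ref, alt),
                    af = af, dp = dp, stringsAsFactors = FALSE)
  if (!is.null(caller_id)) out$caller_id <- caller_id
  out
}
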