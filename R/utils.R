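#' @keywords internal
"_PACKAGE"

## IUPAC nucleotide codes expanded to the plain bases they match.
## N deliberately matches the four unambiguous bases only: an N in the
## reference can never satisfy a PAM position (pessimistic match).
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                B = "V", V = "B", D = "H", H = "D")

#' Reverse-complement DNA strings
#'
#' Vectorised over character strings; IUPAC ambiguity codes are complemented
#' to their partners and N is preserved.
#'
#' @param x character vector of DNA strings (A/C/G/T/N + IUPAC codes).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNRYSWKMBVDHacgtn", "TGCANYRSWMKVBHDtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

complement_base <- function(b) unname(COMPLEMENT[b])

#' Derive a reproducible sub-stream seed
#'
#' Folds one or more string/integer tags into a parent seed with a
#' multiplicative string hash, so each sample, stage or replicate gets its
#' own deterministic RNG stream and adding streams never perturbs existing
#' ones. Result is always a positive integer below 2^31.
#'
#' @param seed integer parent seed.
#' @param ... tags (coerced to character) identifying the sub-stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  tag <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed) %% 2147483629
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% 2147483629
  ## Lehmer scrambling rounds: tags differing in one trailing character
  ## would otherwise yield adjacent seeds, whose Mersenne-Twister streams
  ## are noticeably correlated in their first draws
  for (r in 1:3) h <- (h * 48271) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

## shared empty variant-table prototype
empty_variants <- function(sample_id = character(0)) {
  data.frame(sample_id = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             kind = character(0), af = numeric(0), dp = numeric(0),
             stringsAsFactors = FALSE)
}
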