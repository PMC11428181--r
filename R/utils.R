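#' Reverse-complement an RNA sequence
#'
#' Complements A<->U and C<->G and reverses the string. Input containing T is
#' transcribed to U first.
#'
#' @param x Character vector of RNA sequences (5'->3').
#' @return Character vector of reverse complements (5'->3').
#' @export
#' @examples
#' rna_revcomp("CACAGUG")  # "CACUGUG"
rna_revcomp <- function(x) {
  vapply(x, function(s) {
    s <- as_rna(s)
    chars <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(unname(.RNA_COMPLEMENT[chars]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")
.RNA_ALPHABET <- c("A", "C", "G", "U")

# Uppercase, transcribe T->U, validate alphabet; errors name the first offending
# position so malformed FASTA records are easy to locate.
as_rna <- function(x) {
  s <- chartr("t", "u", toupper(x))
  s <- chartr("T", "U", s)
  bad <- regexpr("[^ACGU]", s)
  if (bad > 0L) {
    stop("invalid character '", substr(s, bad, bad), "' at position ", bad,
         call. = FALSE)
  }
  s
}

# Canonical biotype vocabulary: {protein_coding, lincRNA, other_noncoding}.
# Anything unrecognized maps to other_noncoding; the mapping count is reported.
.BIOTYPES <- c("protein_coding", "lincRNA", "other_noncoding")

canonical_biotype <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "other_noncoding"
  x[x %in% c("lincRNA", "lncRNA")] <- "lincRNA"
  unknown <- !(x %in% .BIOTYPES)
  if (any(unknown)) {
    message(sum(unknown), " record(s) with unrecognized biotype mapped to other_noncoding")
    x[unknown] <- "other_noncoding"
  }
  x
}

# 0-based half-open interval overlap test (vectorized on the first interval set)
iv_overlaps <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2

# Stable integer rounding of n * fractions so the counts sum exactly to n
# (largest-remainder method; ties resolved by original order).
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}
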