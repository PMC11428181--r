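#' Construct a miRNA object
#'
#' Stores the mature sequence (5'->3', RNA alphabet; T is transcribed on read)
#' together with the two seed substrings that define canonical target sites:
#' positions 2-8 (extended seed) and 2-7 (core seed).
#'
#' @param name miRNA name.
#' @param mature Mature sequence, at least 8 nt.
#' @return Object of class \code{mirna} with fields \code{name},
#'   \code{mature}, \code{seed_2_8}, \code{seed_2_7}.
#' @export
#' @examples
#' m <- mirna("miR-128-3p", "UCACAGUGAACCGGUCUCUUU")
#' m$seed_2_8  # "CACAGUG"
mirna <- function(name, mature) {
  mature <- as_rna(mature)
  if (nchar(mature) < 8L) stop("mature sequence must be at least 8 nt")
  structure(list(name = as.character(name), mature = mature,
                 seed_2_8 = substr(mature, 2, 8),
                 seed_2_7 = substr(mature, 2, 7)),
            class = "mirna")
}

#' @export
print.mirna <- function(x, ...) {
  cat("miRNA", x$name, " mature:", x$mature, " seed(2-8):", x$seed_2_8, "\n")
  invisible(x)
}

#' Scan a transcript for strict canonical miRNA seed sites
#'
#' Finds every occurrence of the reverse complement of the seed and classifies
#' it at its t1 coordinate (the target base opposite miRNA position 1, i.e. the
#' 3'-most base of the site):
#' \itemize{
#'   \item \strong{8mer-1a}: revcomp(seed 2-8) immediately 5' of an A at t1;
#'   \item \strong{7mer-m8}: revcomp(seed 2-8) with a non-A base at t1 (keeping
#'     the classes disjoint);
#'   \item \strong{7mer-1a}: revcomp(seed 2-7) immediately 5' of an A at t1,
#'     only when the position-8 match fails.
#' }
#' Matching is strict: no G:U wobble, no supplementary 3' pairing. One site per
#' t1; a site needs its t1 base inside the sequence, so a seed match flush with
#' the 3' end is not reported.
#'
#' @param sequence Transcript sequence (RNA or DNA; T transcribed to U).
#' @param mirna A \code{\link{mirna}} object.
#' @return data.frame with columns \code{mirna}, \code{t1} (0-based),
#'   \code{site_class}, sorted by t1.
#' @export
#' @examples
#' m <- mirna("miR-128-3p", "UCACAGUGAACCGGUCUCUUU")
#' scan_sites("GGGCACUGUGAGGG", m)  # one 8mer-1a at t1 = 10
scan_sites <- function(sequence, mirna) {
  stopifnot(inherits(mirna, "mirna"))
  s <- as_rna(as.character(sequence))
  n <- nchar(s)
  empty <- data.frame(mirna = character(), t1 = integer(),
                      site_class = character(), stringsAsFactors = FALSE)
  if (n < 7L) return(empty)
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  m7 <- strsplit(rna_revcomp(mirna$seed_2_7), "", fixed = TRUE)[[1]]  # 6 nt
  m8_first <- unname(.RNA_COMPLEMENT[substr(mirna$seed_2_8, 7, 7)])   # pairs m8

  # all (overlapping) core-seed matches: start positions q, 1-based
  starts <- seq_len(n - 5L)
  ok <- rep(TRUE, length(starts))
  for (j in 1:6) ok <- ok & sv[starts + j - 1L] == m7[j]
  q <- starts[ok]
  if (length(q) == 0L) return(empty)

  t1 <- q + 6L                       # 1-based coordinate of the t1 base
  q <- q[t1 <= n]
  t1 <- t1[t1 <= n]
  if (length(t1) == 0L) return(empty)

  has_m8 <- q >= 2L & sv[pmax(q - 1L, 1L)] == m8_first
  is_a <- sv[t1] == "A"
  cls <- ifelse(has_m8, ifelse(is_a, "8mer-1a", "7mer-m8"),
                ifelse(is_a, "7mer-1a", NA_character_))
  keep <- !is.na(cls)
  data.frame(mirna = rep(mirna$name, sum(keep)), t1 = t1[keep] - 1L,
             site_class = cls[keep], stringsAsFactors = FALSE)
}

#' Count seed sites by class
#'
#' @param sites data.frame from \code{\link{scan_sites}} (one sequence/miRNA).
#' @return Named integer vector over the classes 8mer-1a, 7mer-m8, 7mer-1a;
#'   counts sum to \code{nrow(sites)}.
#' @export
count_by_class <- function(sites) {
  tab <- table(factor(sites$site_class,
                      levels = c("8mer-1a", "7mer-m8", "7mer-1a")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Background site rate per kilobase
#'
#' The mean number of strict seed sites per kb over a reference transcriptome
#' (e.g. all transcripts expressed in the focal condition); used as the Poisson
#' rate in \code{\link{poisson_enrichment}}.
#'
#' @param transcriptome Character vector (or named list) of sequences.
#' @param mirna A \code{\link{mirna}}.
#' @return Rate (sites per kb).
#' @export
background_lambda <- function(transcriptome, mirna) {
  seqs <- as.character(unlist(transcriptome, use.names = FALSE))
  if (length(seqs) == 0L) stop("empty transcriptome")
  total_len <- sum(nchar(seqs))
  if (total_len == 0) stop("zero total length")
  total_sites <- sum(vapply(seqs, function(s) nrow(scan_sites(s, mirna)),
                            numeric(1)))
  total_sites / (total_len / 1000)
}

#' Poisson enrichment of seed-site counts
#'
#' Upper-tail probability P(X >= k) for X ~ Poisson(lambda * L): how surprising
#' it is to see \code{observed_k} sites on a transcript of \code{length_kb}
#' kilobases when sites occur at the background rate. Computed via the
#' survival function (evaluated in log space internally), so extreme counts do
#' not underflow.
#'
#' @param observed_k Observed site count (nonnegative integer).
#' @param length_kb Sequence length in kb (> 0).
#' @param lambda_per_kb Background rate from \code{\link{background_lambda}}.
#' @return List of class \code{EnrichmentResult}: \code{observed_k},
#'   \code{length_kb}, \code{lambda_per_kb}, \code{p_value},
#'   \code{log10_p_value}.
#' @export
poisson_enrichment <- function(observed_k, length_kb, lambda_per_kb) {
  if (length_kb <= 0) stop("length_kb must be > 0")
  if (lambda_per_kb < 0) stop("lambda_per_kb must be >= 0")
  observed_k <- as.integer(observed_k)
  if (observed_k < 0) stop("observed_k must be >= 0")
  if (lambda_per_kb == 0 && observed_k >= 1L) stop("degenerate background")
  mu <- lambda_per_kb * length_kb
  p <- if (observed_k == 0L) 1 else stats::ppois(observed_k - 1L, mu,
                                                 lower.tail = FALSE)
  log10p <- if (observed_k == 0L) 0 else
    stats::ppois(observed_k - 1L, mu, lower.tail = FALSE, log.p = TRUE) / log(10)
  structure(list(observed_k = observed_k, length_kb = length_kb,
                 lambda_per_kb = lambda_per_kb, p_value = p,
                 log10_p_value = log10p),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("Poisson enrichment: k = %d over %.3f kb (lambda = %.4g/kb), P(X >= k) = %.4g\n",
              x$observed_k, x$length_kb, x$lambda_per_kb, x$p_value))
  invisible(x)
}

#' Spacing regularity of seed sites
#'
#' Computes successive t1 differences, takes the most frequent difference as
#' the modal spacing (ties broken toward the smallest), and counts a site as
#' regular when its gap to the previous or the next site equals the modal
#' spacing exactly.
#'
#' @param sites data.frame from \code{\link{scan_sites}}, or a numeric vector
#'   of t1 coordinates; at least 2 sites.
#' @return List with \code{modal_spacing} and \code{regular_count}.
#' @export
spacing_regularity <- function(sites) {
  t1 <- if (is.data.frame(sites)) sites$t1 else as.numeric(sites)
  if (length(t1) < 2L) stop("need at least 2 sites")
  t1 <- sort(t1)
  d <- diff(t1)
  tab <- table(d)
  modal <- min(as.numeric(names(tab)[tab == max(tab)]))
  k <- length(t1)
  left_ok <- c(FALSE, d == modal)
  right_ok <- c(d == modal, FALSE)
  list(modal_spacing = modal, regular_count = sum(left_ok | right_ok))
}
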