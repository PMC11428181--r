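#' Promoter windows of a gene class
#'
#' One stranded window per gene on the gene's transcriptional orientation:
#' oriented offsets d relative to the TSS in [-upstream, downstream), mapped
#' to the forward axis (so a minus-strand gene's window lies 3' of its
#' genomic coordinate). Defaults follow the convention of testing the 1 kb
#' upstream of the TSS of protein-coding genes.
#'
#' @param annotation An \code{\link{annotation_set}}.
#' @param upstream,downstream Window extent (bp) on the gene's orientation.
#' @param biotype Gene class to keep (\code{NULL} keeps all genes).
#' @return data.frame: \code{gene_id}, \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open, forward axis), \code{strand}.
#' @export
promoter_windows <- function(annotation, upstream = 1000, downstream = 0,
                             biotype = "protein_coding") {
  g <- annotation$genes
  if (!is.null(biotype)) g <- g[g$biotype %in% biotype, , drop = FALSE]
  pw <- promoter_window_coords(g$tss, g$strand, upstream, downstream)
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = pw$start, end = pw$end, strand = g$strand,
             stringsAsFactors = FALSE)
}

#' Random peaks: the length-preserving uniform null
#'
#' Replaces each peak with one of identical width placed uniformly at random:
#' the chromosome is chosen with probability proportional to its length
#' (among chromosomes the peak fits on) and the start uniformly among valid
#' positions. Width multiset and peak count are conserved exactly.
#'
#' @param peaks data.frame with \code{chrom}, \code{start}, \code{end}.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param seed RNG seed.
#' @return data.frame of shuffled peaks (chrom, start, end, summit).
#' @export
random_peaks <- function(peaks, chrom_sizes, seed) {
  widths <- peaks$end - peaks$start
  if (any(widths > max(chrom_sizes))) {
    stop("peak wider than every chromosome")
  }
  set.seed(seed)
  chroms <- names(chrom_sizes)
  out <- lapply(widths, function(w) {
    fit <- chrom_sizes >= w
    chr <- sample(chroms[fit], 1, prob = chrom_sizes[fit])
    start <- sample.int(chrom_sizes[[chr]] - w + 1, 1) - 1
    c(chr = chr, start = start)
  })
  start <- as.numeric(vapply(out, `[[`, character(1), "start"))
  data.frame(chrom = vapply(out, `[[`, character(1), "chr"),
             start = start, end = start + widths,
             summit = floor(start + widths / 2),
             stringsAsFactors = FALSE)
}

#' Count gene-set promoters hit by peaks
#'
#' A promoter is hit when at least one peak overlaps it by >= 1 bp (half-open
#' semantics: a peak merely touching the window end does not count); multiple
#' peaks in one promoter count once. Genes in the set without a window are
#' excluded with a warning.
#'
#' @param peaks data.frame with \code{chrom}, \code{start}, \code{end}.
#' @param windows data.frame from \code{\link{promoter_windows}}.
#' @param gene_set Character vector of gene IDs (subset of window genes).
#' @return Integer vector \code{c(a, b)}: promoters hit, promoters not hit.
#' @export
overlap_counts <- function(peaks, windows, gene_set) {
  missing <- setdiff(gene_set, windows$gene_id)
  if (length(missing) > 0L) {
    warning(length(missing), " gene(s) without a promoter window excluded")
    gene_set <- setdiff(gene_set, missing)
  }
  w <- windows[windows$gene_id %in% gene_set, , drop = FALSE]
  hit <- vapply(seq_len(nrow(w)), function(i) {
    any(peaks$chrom == w$chrom[i] &
          iv_overlaps(peaks$start, peaks$end, w$start[i], w$end[i]))
  }, logical(1))
  c(a = sum(hit), b = length(gene_set) - sum(hit))
}

#' One-sided Fisher exact test for enrichment
#'
#' Upper-tail probability P(A >= a) under the hypergeometric null with fixed
#' margins for the 2x2 table rows (real peaks: a hit, b not) and (random
#' peaks: c hit, d not); the odds ratio is the sample estimate (a d)/(b c),
#' reported as infinite when the denominator is 0.
#'
#' @param table 2x2 matrix (or length-4 vector a, b, c, d) of nonnegative
#'   integer counts.
#' @return List of class \code{FisherResult}: \code{table}, \code{odds},
#'   \code{p_one_sided}, \code{intersection_size} (= a).
#' @export
fisher_one_sided <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4L) stop("need a 2x2 table")
  if (any(x < 0)) stop("negative entry")
  if (any(x != round(x))) stop("counts must be integers")
  if (is.matrix(table)) {
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else {
    a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  }
  p <- stats::phyper(a - 1, m = a + c, n = b + d, k = a + b,
                     lower.tail = FALSE)
  odds <- if (b * c == 0) Inf else (a * d) / (b * c)
  structure(list(table = matrix(c(a, c, b, d), 2, 2), odds = odds,
                 p_one_sided = p, intersection_size = a),
            class = "FisherResult")
}

#' @export
print.FisherResult <- function(x, ...) {
  cat(sprintf("one-sided Fisher: a = %d, odds = %.3g, p = %.4g\n",
              x$intersection_size, x$odds, x$p_one_sided))
  invisible(x)
}

#' Promoter enrichment of one TF's peaks over a gene set
#'
#' Builds the 2x2 table (real vs random peaks over hit / not-hit gene-set
#' promoters) and applies \code{\link{fisher_one_sided}}. The random-peak row
#' uses the length-preserving uniform null with a fixed seed.
#'
#' @param peaks TF peak data.frame (chrom, start, end).
#' @param annotation An \code{\link{annotation_set}}.
#' @param gene_set Character vector of gene IDs.
#' @param seed Seed for \code{\link{random_peaks}}.
#' @param upstream,downstream Promoter window extent (bp).
#' @param biotype Gene class for the windows.
#' @return A \code{FisherResult}.
#' @export
tf_promoter_enrichment <- function(peaks, annotation, gene_set, seed,
                                   upstream = 1000, downstream = 0,
                                   biotype = "protein_coding") {
  windows <- promoter_windows(annotation, upstream, downstream, biotype)
  real <- overlap_counts(peaks, windows, gene_set)
  rnd <- random_peaks(peaks, annotation$chrom_sizes, seed)
  null <- overlap_counts(rnd, windows, gene_set)
  fisher_one_sided(matrix(c(real["a"], null["a"], real["b"], null["b"]), 2, 2))
}

#' Flag enriched TFs for the odds / significance scatter
#'
#' @param results Named list of \code{FisherResult} objects (one per TF).
#' @param odds_min,logp_min Enrichment thresholds: a TF is enriched when
#'   odds >= \code{odds_min} and -log10(p) >= \code{logp_min} (the top-right
#'   area of the scatter). No defaults pretend to be canonical; both are
#'   required.
#' @return data.frame: \code{tf}, \code{odds}, \code{p}, \code{neg_log10_p},
#'   \code{intersection}, \code{enriched}.
#' @export
enrichment_scatter <- function(results, odds_min, logp_min) {
  df <- do.call(rbind, lapply(names(results), function(tf) {
    r <- results[[tf]]
    data.frame(tf = tf, odds = r$odds, p = r$p_one_sided,
               neg_log10_p = -log10(r$p_one_sided),
               intersection = r$intersection_size,
               stringsAsFactors = FALSE)
  }))
  df$enriched <- df$odds >= odds_min & df$neg_log10_p >= logp_min
  df
}
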