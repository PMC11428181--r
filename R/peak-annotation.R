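# Forward-axis promoter window of a TSS under the gene's orientation:
# oriented offsets d in [-up, down) with d = pos - tss on "+" and tss - pos on
# "-". Returns 0-based half-open forward intervals.
promoter_window_coords <- function(tss, strand, up, down) {
  start <- ifelse(strand == "+", tss - up, tss - down + 1)
  end <- ifelse(strand == "+", tss + down, tss + up + 1)
  data.frame(start = start, end = end)
}

#' Categorize ChIP peaks by genomic location
#'
#' Each peak is classified by its summit position with precedence
#' promoter > exon > first intron > other intron > distal intergenic. The
#' promoter is a configurable window around the TSS on the gene's orientation
#' (default 1 kb each side); the exon category is split by host-gene biotype
#' into \code{exon_coding} / \code{exon_noncoding}; the first intron is the
#' 5'-most intron on the gene's strand.
#'
#' @param peaks data.frame with \code{chrom} and \code{summit} columns (as
#'   from \code{\link{read_peaks}}).
#' @param annotation An \code{\link{annotation_set}}.
#' @param promoter_up,promoter_down Window half-widths (bp) upstream /
#'   downstream of the TSS on the gene's orientation.
#' @return Character vector of categories, one per peak, from
#'   \{promoter, exon_coding, exon_noncoding, first_intron, other_intron,
#'   distal_intergenic\}.
#' @export
categorize_peak <- function(peaks, annotation, promoter_up = 1000,
                            promoter_down = 1000) {
  g <- annotation$genes
  unknown <- setdiff(unique(peaks$chrom), names(annotation$chrom_sizes))
  if (length(unknown) > 0L) {
    stop("unknown chromosome: ", paste(unknown, collapse = ", "))
  }
  pw <- promoter_window_coords(g$tss, g$strand, promoter_up, promoter_down)

  vapply(seq_len(nrow(peaks)), function(i) {
    pos <- peaks$summit[i]
    on_chr <- g$chrom == peaks$chrom[i]
    if (any(on_chr & pos >= pw$start & pos < pw$end)) return("promoter")

    hosts <- which(on_chr & pos >= g$start & pos < g$end)
    if (length(hosts) > 0L) {
      in_exon <- logical(0)
      intron_first <- logical(0)
      for (h in hosts) {
        ex <- annotation$exons[annotation$exons$gene_id == g$gene_id[h], ,
                               drop = FALSE]
        ex <- ex[order(ex$start), , drop = FALSE]
        if (any(pos >= ex$start & pos < ex$end)) {
          in_exon <- c(in_exon, g$biotype[h] == "protein_coding")
        } else if (nrow(ex) > 1L) {
          idx <- findInterval(pos, ex$start)  # intron after exon idx
          genomic_intron <- idx               # 1 .. nrow(ex)-1
          n_intr <- nrow(ex) - 1L
          stranded <- if (g$strand[h] == "+") genomic_intron else
            n_intr - genomic_intron + 1L
          intron_first <- c(intron_first, stranded == 1L)
        }
      }
      if (length(in_exon) > 0L) {
        return(if (any(in_exon)) "exon_coding" else "exon_noncoding")
      }
      if (length(intron_first) > 0L) {
        return(if (any(intron_first)) "first_intron" else "other_intron")
      }
    }
    "distal_intergenic"
  }, character(1))
}

#' Category composition of a peak set
#'
#' @param categories Character vector from \code{\link{categorize_peak}} (or
#'   a data.frame with a \code{category} column).
#' @return Named numeric of fractions over the six categories; sums to 1.
#' @export
peak_distribution <- function(categories) {
  if (is.data.frame(categories)) categories <- categories$category
  if (length(categories) == 0L) stop("no peaks to summarize")
  lev <- c("promoter", "exon_coding", "exon_noncoding", "first_intron",
           "other_intron", "distal_intergenic")
  tab <- table(factor(categories, levels = lev))
  stats::setNames(as.numeric(tab) / length(categories), lev)
}

#' Associate peaks with their nearest gene on each strand
#'
#' For each peak and each strand independently, the gene whose TSS is closest
#' to the peak summit is associated when the distance is within \code{window}
#' bp, giving up to two genes per peak. Distances are signed as
#' \code{summit - TSS} on the forward axis. Proximity ties are broken toward
#' the lexicographically smaller gene ID and reported via a message.
#'
#' @param peaks data.frame with \code{chrom} and \code{summit}.
#' @param annotation An \code{\link{annotation_set}}.
#' @param window Maximum |summit - TSS| distance (bp, default 5000).
#' @return data.frame with one row per (peak, associated gene):
#'   \code{peak}, \code{chrom}, \code{summit}, \code{gene_id}, \code{strand},
#'   \code{biotype}, \code{distance}.
#' @export
associate_peak <- function(peaks, annotation, window = 5000) {
  g <- annotation$genes
  rows <- list()
  n_ties <- 0L
  for (i in seq_len(nrow(peaks))) {
    pos <- peaks$summit[i]
    for (str in c("+", "-")) {
      cand <- g[g$chrom == peaks$chrom[i] & g$strand == str, , drop = FALSE]
      if (nrow(cand) == 0L) next
      d <- pos - cand$tss
      ok <- abs(d) <= window
      if (!any(ok)) next
      cand <- cand[ok, , drop = FALSE]
      d <- d[ok]
      best <- abs(d) == min(abs(d))
      if (sum(best) > 1L) n_ties <- n_ties + 1L
      pick <- which(best)[order(cand$gene_id[best])][1]
      rows[[length(rows) + 1L]] <- data.frame(
        peak = i, chrom = peaks$chrom[i], summit = pos,
        gene_id = cand$gene_id[pick], strand = str,
        biotype = cand$biotype[pick], distance = d[pick],
        stringsAsFactors = FALSE)
    }
  }
  if (n_ties > 0L) message(n_ties, " proximity tie(s) broken by gene ID")
  if (length(rows) == 0L) {
    return(data.frame(peak = integer(), chrom = character(),
                      summit = numeric(), gene_id = character(),
                      strand = character(), biotype = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Signed summit-to-TSS distances of peak associations
#'
#' @param associations Output of \code{\link{associate_peak}}.
#' @return Numeric vector, one signed distance per (peak, gene) association.
#' @export
tss_distances <- function(associations) {
  as.numeric(associations$distance)
}

#' Call TF-dependent specific lincRNAs
#'
#' The subset of the focal-specific lincRNA set having at least one peak
#' associated with it (nearest gene on its strand, summit within
#' \code{window} bp of the TSS).
#'
#' @param peaks data.frame with \code{chrom} and \code{summit}.
#' @param annotation An \code{\link{annotation_set}}.
#' @param lincES Character vector of specific lincRNA gene IDs (from
#'   \code{\link{select_lincES}}).
#' @param window Association window (bp, default 5000).
#' @return Named integer vector: called gene IDs with their peak counts.
#' @export
call_lincS <- function(peaks, annotation, lincES, window = 5000) {
  assoc <- associate_peak(peaks, annotation, window = window)
  hits <- assoc[assoc$gene_id %in% lincES, , drop = FALSE]
  if (nrow(hits) == 0L) return(stats::setNames(integer(0), character(0)))
  counts <- table(hits$gene_id)
  stats::setNames(as.integer(counts), names(counts))
}
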