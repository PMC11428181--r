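#' Simulate an expression atlas with planted condition-specific genes
#'
#' Background genes get a gene-level baseline drawn log-normal(meanlog, sdlog)
#' with multiplicative log-normal noise in every sample. Planted specific genes
#' follow an on/off model: ON in the focal sample at \code{fold} times their
#' baseline, OFF elsewhere at baseline divided by \code{fold^2}, with the same
#' noise. At \code{fold = 1} the model collapses exactly to the background, so
#' planted genes are then indistinguishable from it; at large fold the OFF
#' state drops below the usual FPKM detection threshold, emulating genes
#' expressed exclusively in the focal condition.
#'
#' @param n_genes,n_tissues Matrix dimensions (samples include the focal one).
#' @param n_specific Number of planted specific genes (<= n_genes).
#' @param fold Planted fold-change of the focal sample versus the background
#'   mean (> 0; 1 disables planting in effect).
#' @param noise_sd Log-scale noise standard deviation (>= 0).
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @param meanlog,sdlog Baseline log-normal parameters.
#' @param focal_sample Name of the focal sample column.
#' @param gene_ids Optional gene IDs (length n_genes).
#' @param specific_gene_ids Optional IDs to plant (default: sampled).
#' @return List with \code{matrix} (an \code{\link{expression_matrix}}) and
#'   \code{truth} (fields \code{specific_gene_ids}, \code{fold},
#'   \code{noise_sd}).
#' @export
make_atlas <- function(n_genes, n_tissues, n_specific, fold, noise_sd, seed,
                       meanlog = 1, sdlog = 1, focal_sample = "ESC",
                       gene_ids = NULL, specific_gene_ids = NULL) {
  if (n_specific > n_genes) stop("n_specific exceeds n_genes")
  if (n_tissues < 2L) stop("need at least 2 samples")
  if (fold <= 0) stop("fold must be > 0")
  set.seed(seed)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%05d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  samples <- c(focal_sample, sprintf("T%02d", seq_len(n_tissues - 1L)))

  baseline <- stats::rlnorm(n_genes, meanlog = meanlog, sdlog = sdlog)
  noise <- matrix(exp(stats::rnorm(n_genes * n_tissues, 0, noise_sd)),
                  n_genes, n_tissues)
  values <- baseline * noise
  dimnames(values) <- list(gene_ids, samples)

  if (is.null(specific_gene_ids)) {
    specific_gene_ids <- sort(sample(gene_ids, n_specific))
  }
  stopifnot(all(specific_gene_ids %in% gene_ids))
  sp <- rownames(values) %in% specific_gene_ids
  values[sp, 1] <- values[sp, 1] * fold
  if (ncol(values) > 1L) values[sp, -1] <- values[sp, -1] / fold^2

  list(matrix = expression_matrix(values, focal_sample),
       truth = list(specific_gene_ids = specific_gene_ids,
                    fold = fold, noise_sd = noise_sd))
}

#' Simulate a toy genome annotation
#'
#' Stranded multi-exon genes (2-6 exons) placed on one chromosome with at
#' least \code{min_gap} bp between adjacent gene bodies, so the +/-5 kb
#' peak-to-gene association rule has unambiguous truth. Biotypes are assigned
#' protein_coding/lincRNA at a configurable ratio.
#'
#' @param n_genes Number of genes.
#' @param chrom_length Chromosome length (bp).
#' @param seed RNG seed.
#' @param lincRNA_fraction Fraction of genes labelled lincRNA.
#' @param min_gap Minimum gap between gene bodies (bp).
#' @param chrom Chromosome name.
#' @return An \code{\link{annotation_set}}.
#' @export
make_genome <- function(n_genes, chrom_length, seed, lincRNA_fraction = 0.5,
                        min_gap = 12000, chrom = "chr1") {
  set.seed(seed)
  ids <- sprintf("GENE%04d", seq_len(n_genes))
  exon_counts <- sample(2:6, n_genes, replace = TRUE)
  structures <- lapply(exon_counts, function(k) {
    ex_len <- sample(150:400, k, replace = TRUE)
    in_len <- if (k > 1) sample(500:2000, k - 1, replace = TRUE) else integer(0)
    list(ex = ex_len, intr = in_len, len = sum(ex_len) + sum(in_len))
  })
  lens <- vapply(structures, `[[`, numeric(1), "len")
  needed <- sum(lens) + (n_genes + 1) * min_gap
  if (needed > chrom_length) {
    stop("insufficient space: need ", needed, " bp, have ", chrom_length)
  }
  slack <- chrom_length - needed
  extra <- as.vector(stats::rmultinom(1, size = slack,
                                      prob = rep(1, n_genes + 1)))
  gaps <- min_gap + extra

  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  biotype <- sample(c("lincRNA", "protein_coding"), n_genes, replace = TRUE,
                    prob = c(lincRNA_fraction, 1 - lincRNA_fraction))

  genes <- vector("list", n_genes)
  exons <- vector("list", n_genes)
  pos <- gaps[1]
  for (i in seq_len(n_genes)) {
    st <- structures[[i]]
    ex_start <- pos + c(0, cumsum(st$ex[-length(st$ex)] + st$intr))
    exons[[i]] <- data.frame(gene_id = ids[i], start = ex_start,
                             end = ex_start + st$ex, stringsAsFactors = FALSE)
    genes[[i]] <- data.frame(gene_id = ids[i], chrom = chrom, start = pos,
                             end = pos + st$len, strand = strand[i],
                             biotype = biotype[i], stringsAsFactors = FALSE)
    pos <- pos + st$len + gaps[i + 1]
  }
  annotation_set(do.call(rbind, genes), do.call(rbind, exons),
                 stats::setNames(chrom_length, chrom))
}

# Candidate summit regions (0-based half-open, forward axis) per truth
# category, built by exact interval arithmetic so placement never straddles a
# category boundary. Categories: promoter, exon, first_intron, other_intron,
# distal. The promoter definition must match categorize_peak's default.
.category_regions <- function(annotation, promoter_up, promoter_down) {
  g <- annotation$genes
  out <- list(promoter = NULL, exon = NULL, first_intron = NULL,
              other_intron = NULL, distal = NULL)
  to_ir <- function(s, e) IRanges::IRanges(start = s + 1, end = e)  # [s,e) -> 1-based
  from_ir <- function(ir, chrom) {
    if (length(ir) == 0L) return(NULL)
    data.frame(chrom = chrom, start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  }
  for (chr in names(annotation$chrom_sizes)) {
    gi <- g[g$chrom == chr, , drop = FALSE]
    if (nrow(gi) == 0L) next
    pw <- promoter_window_coords(gi$tss, gi$strand, promoter_up, promoter_down)
    prom <- IRanges::reduce(to_ir(pmax(pw$start, 0),
                                  pmin(pw$end, annotation$chrom_sizes[[chr]])))
    ex_all <- first_in <- other_in <- IRanges::IRanges()
    for (i in seq_len(nrow(gi))) {
      ex <- annotation$exons[annotation$exons$gene_id == gi$gene_id[i], , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      ex_all <- c(ex_all, to_ir(ex$start, ex$end))
      if (nrow(ex) > 1L) {
        intr <- data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
        first_idx <- if (gi$strand[i] == "+") 1L else nrow(intr)
        first_in <- c(first_in, to_ir(intr$start[first_idx], intr$end[first_idx]))
        if (nrow(intr) > 1L) {
          oth <- intr[-first_idx, , drop = FALSE]
          other_in <- c(other_in, to_ir(oth$start, oth$end))
        }
      }
    }
    bodies <- IRanges::reduce(c(to_ir(gi$start, gi$end), prom))
    genome_ir <- to_ir(0, annotation$chrom_sizes[[chr]])
    add <- function(slot, ir) rbind(out[[slot]], from_ir(ir, chr))
    out$promoter <- add("promoter", prom)
    out$exon <- add("exon", IRanges::setdiff(IRanges::reduce(ex_all), prom))
    out$first_intron <- add("first_intron",
                            IRanges::setdiff(IRanges::reduce(first_in), prom))
    out$other_intron <- add("other_intron",
                            IRanges::setdiff(IRanges::reduce(other_in),
                                             c(prom, first_in)))
    out$distal <- add("distal", IRanges::setdiff(genome_ir, bodies))
  }
  out
}

.sample_positions <- function(regions, count) {
  w <- regions$end - regions$start
  total <- sum(w)
  offs <- sample.int(total, count, replace = TRUE) - 1
  idx <- findInterval(offs, cumsum(c(0, w)), rightmost.closed = FALSE)
  list(chrom = regions$chrom[idx],
       pos = regions$start[idx] + (offs - cumsum(c(0, w))[idx]))
}

#' Simulate ChIP peaks with known category composition
#'
#' Summits are placed inside regions of their truth category by exact interval
#' arithmetic under the same promoter definition \code{\link{categorize_peak}}
#' uses, so the planted composition is recovered by construction. Peak widths
#' are sampled uniformly in 200-500 bp around the summit.
#'
#' @param annotation An \code{\link{annotation_set}}.
#' @param proportions Named fractions over \code{promoter}, \code{exon},
#'   \code{first_intron}, \code{other_intron}, \code{distal}; must sum to 1
#'   (tolerance 1e-9).
#' @param n_peaks Number of peaks.
#' @param seed RNG seed.
#' @param promoter_up,promoter_down Promoter window half-widths (bp) around the
#'   TSS on the gene's orientation.
#' @return List with \code{peaks} (data.frame chrom/start/end/summit) and
#'   \code{truth} (character vector of planted categories, aligned by row).
#' @export
make_peaks <- function(annotation, proportions, n_peaks, seed,
                       promoter_up = 1000, promoter_down = 1000) {
  allowed <- c("promoter", "exon", "first_intron", "other_intron", "distal")
  if (!all(names(proportions) %in% allowed)) {
    stop("unknown category: ",
         paste(setdiff(names(proportions), allowed), collapse = ", "))
  }
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  set.seed(seed)
  counts <- largest_remainder(unlist(proportions), n_peaks)
  names(counts) <- names(proportions)
  regions <- .category_regions(annotation, promoter_up, promoter_down)

  rows <- list()
  for (cat in names(counts)) {
    k <- counts[[cat]]
    if (k == 0L) next
    reg <- regions[[cat]]
    if (is.null(reg) || sum(reg$end - reg$start) == 0) {
      stop("no available region for category: ", cat)
    }
    smp <- .sample_positions(reg, k)
    width <- sample(200:500, k, replace = TRUE)
    off <- vapply(width, function(w) sample.int(w, 1L) - 1L, integer(1))
    start <- smp$pos - off
    end <- start + width
    L <- annotation$chrom_sizes[smp$chrom]
    start <- pmax(0, pmin(start, smp$pos))
    end <- pmin(L, pmax(end, smp$pos + 1))
    rows[[cat]] <- data.frame(chrom = smp$chrom, start = start, end = end,
                              summit = smp$pos, truth = cat,
                              stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  perm <- sample.int(nrow(df))
  df <- df[perm, , drop = FALSE]
  rownames(df) <- NULL
  list(peaks = df[, c("chrom", "start", "end", "summit")], truth = df$truth)
}

#' Generate a sequence with seed sites planted at controlled positions
#'
#' The background is drawn uniformly over {A,C,G,U} and then scrubbed of
#' accidental seed matches for the given miRNA(s) by resampling offending
#' windows (keeping generation linear in length), so
#' \code{\link{scan_sites}} recovers exactly the planted sites, with their
#' planted classes, and nothing else.
#'
#' @param length Sequence length (nt).
#' @param mirna A \code{\link{mirna}} or list of them (recycled over
#'   positions).
#' @param t1_positions Sorted 0-based t1 coordinates of the planted sites;
#'   each needs \code{t1 >= 7} and \code{t1 < length}, and consecutive sites
#'   must be at least 8 nt apart (non-overlapping footprints).
#' @param site_class Class per site: "8mer-1a", "7mer-m8" or "7mer-1a"
#'   (recycled).
#' @param seed RNG seed.
#' @param scrub_mirnas Optional extra \code{\link{mirna}} list whose accidental
#'   sites are also scrubbed (beyond the planted ones).
#' @return List with \code{sequence} (character) and \code{sites} (data.frame
#'   \code{t1}, \code{mirna}, \code{site_class} - the planted truth).
#' @export
make_mre_sequence <- function(length, mirna, t1_positions, site_class, seed,
                              scrub_mirnas = NULL) {
  mirnas <- if (inherits(mirna, "mirna")) list(mirna) else mirna
  stopifnot(all(vapply(mirnas, inherits, logical(1), "mirna")))
  k <- base::length(t1_positions)
  # one miRNA for all positions, or one per position
  if (k == 0L) {
    m_idx <- integer(0)
  } else if (base::length(mirnas) == 1L) {
    m_idx <- rep(1L, k)
  } else if (base::length(mirnas) == k) {
    m_idx <- seq_len(k)
  } else {
    stop("mirna must be a single miRNA or one per planted position")
  }
  cls <- rep_len(site_class, max(k, 1L))[seq_len(k)]
  if (k > 0L) {
    stopifnot(all(cls %in% c("8mer-1a", "7mer-m8", "7mer-1a")))
    if (is.unsorted(t1_positions)) stop("t1_positions must be sorted")
    if (any(t1_positions < 7 | t1_positions >= length)) {
      stop("planted site out of bounds")
    }
    if (k > 1L && any(diff(t1_positions) < 8)) stop("overlapping plants")
  }

  set.seed(seed)
  s <- sample(.RNA_ALPHABET, length, replace = TRUE)
  protected <- integer(0)
  for (i in seq_len(k)) {
    m <- mirnas[[m_idx[i]]]
    p1 <- t1_positions[i] + 1L       # 1-based t1 index
    m8 <- strsplit(rna_revcomp(m$seed_2_8), "", fixed = TRUE)[[1]]
    if (cls[i] %in% c("8mer-1a", "7mer-m8")) {
      s[(p1 - 7L):(p1 - 1L)] <- m8
      s[p1] <- if (cls[i] == "8mer-1a") "A" else sample(c("C", "G", "U"), 1L)
    } else {
      s[(p1 - 6L):(p1 - 1L)] <- m8[2:7]
      s[p1] <- "A"
      s[p1 - 7L] <- sample(setdiff(.RNA_ALPHABET, m8[1]), 1L)
    }
    protected <- c(protected, (p1 - 7L):p1)
  }

  scan_set <- c(mirnas, scrub_mirnas)
  scan_names <- vapply(scan_set, `[[`, character(1), "name")
  planted_by <- split(t1_positions, vapply(m_idx, function(j) mirnas[[j]]$name,
                                           character(1)))
  for (iter in 1:500) {
    clean <- TRUE
    for (j in seq_along(scan_set)) {
      hits <- scan_sites(paste(s, collapse = ""), scan_set[[j]])
      extras <- setdiff(hits$t1, planted_by[[scan_names[j]]])
      for (t1e in extras) {
        win <- max(1L, t1e - 5L):min(length, t1e + 1L)
        free <- setdiff(win, protected)
        if (base::length(free) == 0L) {
          stop("cannot scrub accidental site overlapping planted footprints")
        }
        s[free] <- sample(.RNA_ALPHABET, base::length(free), replace = TRUE)
        clean <- FALSE
      }
    }
    if (clean) break
    if (iter == 500L) stop("scrub did not converge")
  }

  sites <- data.frame(t1 = t1_positions,
                      mirna = if (k > 0L) scan_names[m_idx] else character(0),
                      site_class = cls, stringsAsFactors = FALSE)
  list(sequence = paste(s, collapse = ""), sites = sites)
}

# Random mature miRNA sequences whose seeds cannot be confused with each other:
# all core seeds distinct, no core seed of one inside the extended-seed
# complement region of another. Keeps multi-family planting conflict-free.
.random_mirna_set <- function(n, seed) {
  set.seed(seed)
  for (try in 1:1000) {
    mats <- replicate(n, paste(sample(.RNA_ALPHABET, 21, replace = TRUE),
                               collapse = ""))
    ms <- Map(mirna, sprintf("miR-%02d", seq_len(n)), mats)
    m7 <- vapply(ms, function(m) rna_revcomp(m$seed_2_7), character(1))
    m8 <- vapply(ms, function(m) rna_revcomp(m$seed_2_8), character(1))
    ok <- !anyDuplicated(m7)
    if (ok) {
      for (f in seq_len(n)) for (g in seq_len(n)) {
        if (f == g) next
        if (grepl(m7[g], m8[f], fixed = TRUE) ||
            substr(m7[g], 1, 5) == substr(m8[f], 3, 7)) ok <- FALSE
      }
    }
    if (ok) return(stats::setNames(ms, sprintf("miR-%02d", seq_len(n))))
  }
  stop("could not draw a conflict-free miRNA set")
}

#' Simulate a ceRNA system with known sharing structure
#'
#' Builds a lncRNA carrying one seed site for every miRNA family, mRNA 3'UTRs
#' carrying sites exactly for their assigned families, and expression values
#' for every transcript and miRNA, so the ceRNA ranking can be checked against
#' planted truth.
#'
#' @param n_mrnas,n_mirnas System size.
#' @param sharing Named list: mRNA name -> character vector of family names
#'   (subset of the generated \code{miR-01..}); mRNAs absent from the list
#'   share nothing.
#' @param seed RNG seed.
#' @param expr_ranges List of c(min, max) uniform expression ranges for
#'   \code{lnc}, \code{mrna} and \code{mirna}.
#' @param utr_length,lnc_length Sequence lengths (nt).
#' @param focal_sample Sample name of the single expression column.
#' @return List: \code{sequences} (list with \code{lnc} and named \code{mrnas}),
#'   \code{mirnas} (named \code{\link{mirna}} list), \code{expr}
#'   (\code{\link{expression_matrix}} with one column), \code{lnc_id},
#'   \code{truth} (the sharing list).
#' @export
make_cerna_system <- function(n_mrnas, n_mirnas, sharing, seed,
                              expr_ranges = list(lnc = c(20, 100),
                                                 mrna = c(5, 50),
                                                 mirna = c(5, 50)),
                              utr_length = 800, lnc_length = 2000,
                              focal_sample = "ESC") {
  mirnas <- .random_mirna_set(n_mirnas, seed)
  fam <- names(mirnas)
  bad <- setdiff(unique(unlist(sharing)), fam)
  if (length(bad) > 0L) stop("unknown family: ", paste(bad, collapse = ", "))
  mrna_ids <- if (!is.null(names(sharing)) && length(sharing) == n_mrnas) {
    names(sharing)
  } else {
    sprintf("mRNA%02d", seq_len(n_mrnas))
  }
  sharing_full <- stats::setNames(
    lapply(mrna_ids, function(id) as.character(sharing[[id]])), mrna_ids)

  lnc_pos <- 50 + 40 * (seq_len(n_mirnas) - 1)
  lnc <- make_mre_sequence(lnc_length, mirnas, lnc_pos,
                           rep("7mer-m8", n_mirnas), seed = seed + 1L)
  utrs <- character(0)
  for (i in seq_along(mrna_ids)) {
    fams <- sharing_full[[i]]
    if (length(fams) == 0L) {
      g <- make_mre_sequence(utr_length, mirnas, integer(0), character(0),
                             seed = seed + 1L + i)
    } else {
      g <- make_mre_sequence(utr_length, mirnas[fams],
                             50 + 40 * (seq_along(fams) - 1),
                             rep("7mer-m8", length(fams)), seed = seed + 1L + i,
                             scrub_mirnas = mirnas[setdiff(fam, fams)])
    }
    utrs[mrna_ids[i]] <- g$sequence
  }

  set.seed(seed + 5000L)
  runif_in <- function(r, n) stats::runif(n, r[1], r[2])
  expr <- c(LNC1 = runif_in(expr_ranges$lnc, 1),
            stats::setNames(runif_in(expr_ranges$mrna, n_mrnas), mrna_ids),
            stats::setNames(runif_in(expr_ranges$mirna, n_mirnas), fam))
  em <- expression_matrix(matrix(expr, ncol = 1,
                                 dimnames = list(names(expr), focal_sample)),
                          focal_sample)
  list(sequences = list(lnc = lnc$sequence, mrnas = utrs),
       mirnas = mirnas, expr = em, lnc_id = "LNC1", truth = sharing_full)
}
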