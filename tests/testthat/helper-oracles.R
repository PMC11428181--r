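# Independent oracles and fixture builders used across the suite.

# Brute-force seed-site scan by window enumeration: every t1 is tested by
# literal substring comparison against the revcomp seed strings. Independent
# of the vectorized scanner's mechanics.
oracle_scan <- function(seq, mir) {
  s <- chartr("T", "U", toupper(seq))
  n <- nchar(s)
  m8 <- stemlinc::rna_revcomp(mir$seed_2_8)
  m7 <- stemlinc::rna_revcomp(mir$seed_2_7)
  out <- list()
  for (t1 in 8:n) {
    w7 <- substring(s, t1 - 7, t1 - 1)
    w6 <- substring(s, t1 - 6, t1 - 1)
    base <- substring(s, t1, t1)
    cls <- if (w7 == m8) {
      if (base == "A") "8mer-1a" else "7mer-m8"
    } else if (w6 == m7 && base == "A") {
      "7mer-1a"
    } else {
      NA_character_
    }
    if (!is.na(cls)) {
      out[[length(out) + 1L]] <- data.frame(mirna = mir$name, t1 = t1 - 1L,
                                            site_class = cls,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(mirna = character(), t1 = integer(),
                      site_class = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Exhaustive 1-D 2-means: every threshold between sorted values is tried and
# the within-cluster sum of squares minimized; returns logical "high side".
oracle_kmeans2_1d <- function(x) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  best_ss <- Inf
  best_cut <- 1L
  for (cut in 1:(n - 1)) {
    lo <- xs[1:cut]
    hi <- xs[(cut + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss) {
      best_ss <- ss
      best_cut <- cut
    }
  }
  high <- logical(n)
  high[o[(best_cut + 1):n]] <- TRUE
  high
}

# One-sided Fisher p by explicit enumeration of all more-extreme tables,
# computed from binomial coefficients only.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  xs <- a:min(m, k)
  sum(choose(m, xs) * choose(n, k - xs)) / choose(m + n, k)
}

# Independent nearest-TSS-per-strand association by a plain double loop.
oracle_associate <- function(peaks, annotation, window = 5000) {
  g <- annotation$genes
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    for (str in c("+", "-")) {
      best_id <- NA_character_
      best_d <- Inf
      for (j in seq_len(nrow(g))) {
        if (g$chrom[j] != peaks$chrom[i] || g$strand[j] != str) next
        d <- peaks$summit[i] - g$tss[j]
        if (abs(d) > window) next
        if (abs(d) < abs(best_d) ||
            (abs(d) == abs(best_d) && g$gene_id[j] < best_id)) {
          best_d <- d
          best_id <- g$gene_id[j]
        }
      }
      if (!is.na(best_id)) {
        rows[[length(rows) + 1L]] <- data.frame(peak = i, gene_id = best_id,
                                                strand = str, distance = best_d,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(peak = integer(), gene_id = character(),
                      strand = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

iv_overlaps_test <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2

random_mirna <- function(seed) {
  set.seed(seed)
  mirna(paste0("rnd-", seed),
        paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE), collapse = ""))
}

random_rna <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Tiny single-exon-per-gene annotation from a compact spec data.frame.
toy_annotation <- function(genes, chrom_sizes = NULL) {
  exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                      end = genes$end, stringsAsFactors = FALSE)
  annotation_set(genes, exons, chrom_sizes)
}

write_gtf <- function(path, rows) {
  # rows: data.frame chrom, feature, start1, end1, strand, gene_id, biotype
  lines <- sprintf(
    '%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
    rows$chrom, rows$feature, rows$start1, rows$end1, rows$strand,
    rows$gene_id, rows$biotype)
  writeLines(lines, path)
  path
}
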