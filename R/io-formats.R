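#' Construct an annotation set
#'
#' The container used by all genomic operations: one record per gene plus its
#' exon structure, with every coordinate in the package-wide convention of
#' 0-based half-open intervals on the forward genomic strand. The TSS of a
#' minus-strand gene is therefore \code{end - 1}.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} ("+"/"-"), \code{biotype}.
#' @param exons data.frame with columns \code{gene_id}, \code{start}, \code{end}.
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp). If
#'   \code{NULL}, each chromosome's size is taken as the largest end coordinate
#'   observed on it.
#' @return An object of class \code{AnnotationSet}: a list with elements
#'   \code{genes} (with a derived \code{tss} column), \code{exons} and
#'   \code{chrom_sizes}.
#' @export
annotation_set <- function(genes, exons, chrom_sizes = NULL) {
  stopifnot(is.data.frame(genes), is.data.frame(exons))
  need <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  if (!all(need %in% names(genes))) {
    stop("genes must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene ID: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  genes$biotype <- canonical_biotype(genes$biotype)
  if (!all(exons$gene_id %in% genes$gene_id)) stop("exon with unknown gene_id")

  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(genes$end, genes$chrom, max)
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
  if (!all(genes$chrom %in% names(chrom_sizes))) {
    stop("gene on chromosome absent from chrom_sizes")
  }
  if (any(genes$end > chrom_sizes[genes$chrom])) {
    stop("gene coordinates exceed chromosome length")
  }

  # TSS = start of the 5'-most exon on the gene's strand
  genes$tss <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- exons[exons$gene_id == genes$gene_id[i], , drop = FALSE]
    if (nrow(ex) == 0L) {
      if (genes$strand[i] == "+") genes$start[i] else genes$end[i] - 1
    } else if (genes$strand[i] == "+") {
      min(ex$start)
    } else {
      max(ex$end) - 1
    }
  }, numeric(1))

  rownames(genes) <- NULL
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons, chrom_sizes = chrom_sizes),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet:", nrow(x$genes), "genes on",
      length(x$chrom_sizes), "chromosome(s)\n")
  print(table(x$genes$biotype))
  invisible(x)
}

#' Read a gene annotation (GTF/GFF3 or BED12)
#'
#' Parses the file with \pkg{rtracklayer} and normalizes everything to the
#' internal 0-based half-open convention (GTF/GFF input is 1-based closed and is
#' shifted on read). Records without a strand are rejected with a warning that
#' reports their count. For GTF/GFF input the biotype is taken from the
#' attribute named by \code{biotype_key}; BED12 carries no biotype, so
#' \code{biotypes} (a named vector keyed by gene ID) may be supplied, with
#' unlisted genes defaulting to \code{other_noncoding}.
#'
#' @param path Path to a .gtf/.gff/.gff3 or .bed (BED12) file.
#' @param biotype_key Attribute name holding the biotype in GTF/GFF input.
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @param biotypes Optional named character vector gene_id -> biotype (BED12).
#' @return An \code{\link{annotation_set}}.
#' @export
read_annotation <- function(path, biotype_key = "gene_biotype",
                            chrom_sizes = NULL, biotypes = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    .read_annotation_gff(path, biotype_key, chrom_sizes)
  } else if (ext == "bed") {
    .read_annotation_bed12(path, chrom_sizes, biotypes)
  } else {
    stop("unsupported annotation format: .", ext)
  }
}

.read_annotation_gff <- function(path, biotype_key, chrom_sizes) {
  lines <- readLines(path)
  body <- which(nzchar(lines) & !startsWith(lines, "#"))
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nfield < 8L)) {
    stop("parse error at line ", body[which(nfield < 8L)[1]], " of ", path)
  }
  gr <- rtracklayer::import(path)
  df <- S4Vectors::mcols(gr)
  if (!is.null(df$type)) {
    is_gene_row <- as.character(df$type) == "gene"
    if (any(is_gene_row) && anyDuplicated(df$gene_id[is_gene_row])) {
      stop("duplicate gene ID")
    }
    keep <- as.character(df$type) == "exon"
    gr <- gr[keep]
    df <- S4Vectors::mcols(gr)
  }
  if (is.null(df$gene_id)) stop("GTF/GFF records carry no gene_id attribute")
  nostrand <- as.character(GenomicRanges::strand(gr)) == "*"
  if (any(nostrand)) {
    warning(sum(nostrand), " record(s) without strand rejected")
    gr <- gr[!nostrand]
    df <- S4Vectors::mcols(gr)
  }
  bt <- if (biotype_key %in% names(df)) as.character(df[[biotype_key]]) else NA_character_

  exons <- data.frame(
    gene_id = as.character(df$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,  # 1-based closed -> 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = if (all(is.na(bt))) NA_character_ else bt,
    stringsAsFactors = FALSE
  )
  .genes_from_exons(exons, chrom_sizes)
}

.read_annotation_bed12 <- function(path, chrom_sizes, biotypes) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- as.character(gr$name)
  if (anyDuplicated(nm)) stop("duplicate gene ID")
  nostrand <- as.character(GenomicRanges::strand(gr)) == "*"
  if (any(nostrand)) {
    warning(sum(nostrand), " record(s) without strand rejected")
    gr <- gr[!nostrand]
    nm <- nm[!nostrand]
  }
  ex_list <- lapply(seq_along(gr), function(i) {
    gstart <- GenomicRanges::start(gr)[i] - 1
    blocks <- gr$blocks[[i]]
    if (is.null(blocks) || length(blocks) == 0L) {
      data.frame(start = gstart, end = as.numeric(GenomicRanges::end(gr)[i]))
    } else {
      data.frame(start = gstart + GenomicRanges::start(blocks) - 1,
                 end = gstart + as.numeric(GenomicRanges::end(blocks)))
    }
  })
  exons <- do.call(rbind, lapply(seq_along(gr), function(i) {
    cbind(gene_id = nm[i],
          chrom = as.character(GenomicRanges::seqnames(gr))[i],
          ex_list[[i]],
          strand = as.character(GenomicRanges::strand(gr))[i],
          stringsAsFactors = FALSE)
  }))
  exons$biotype <- if (is.null(biotypes)) NA_character_ else
    unname(biotypes[exons$gene_id])
  .genes_from_exons(exons, chrom_sizes)
}

.genes_from_exons <- function(exons, chrom_sizes) {
  ids <- unique(exons$gene_id)
  genes <- do.call(rbind, lapply(ids, function(id) {
    ex <- exons[exons$gene_id == id, , drop = FALSE]
    if (length(unique(ex$chrom)) > 1L || length(unique(ex$strand)) > 1L) {
      stop("duplicate gene ID: ", id, " spans multiple chromosomes or strands")
    }
    data.frame(gene_id = id, chrom = ex$chrom[1],
               start = min(ex$start), end = max(ex$end),
               strand = ex$strand[1],
               biotype = ex$biotype[1],
               stringsAsFactors = FALSE)
  }))
  annotation_set(genes,
                 exons[, c("gene_id", "start", "end")],
                 chrom_sizes)
}

#' Write an annotation set as BED12
#'
#' One record per gene with its exons as blocks; coordinates are already
#' 0-based half-open, BED's native convention, so they are written as-is.
#'
#' @param annotation An \code{\link{annotation_set}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "AnnotationSet"))
  g <- annotation$genes
  lines <- vapply(seq_len(nrow(g)), function(i) {
    ex <- annotation$exons[annotation$exons$gene_id == g$gene_id[i], , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    paste(g$chrom[i], format(g$start[i], scientific = FALSE),
          format(g$end[i], scientific = FALSE),
          g$gene_id[i], 0, g$strand[i],
          format(g$start[i], scientific = FALSE),
          format(g$end[i], scientific = FALSE), "0",
          nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(format(ex$start - g$start[i], scientific = FALSE),
                       collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read ChIP peaks (BED3/BED6/ENCODE narrowPeak)
#'
#' @param path Path to a peak file. narrowPeak is recognized by its 10 columns
#'   (or the .narrowPeak extension); column 10 >= 0 places the summit at
#'   \code{start + offset}, otherwise (and for plain BED) the summit is the
#'   interval midpoint (floor). Records with \code{start >= end} are rejected
#'   with a warning.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{summit}, \code{score} (NA when absent); 0-based half-open.
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      summit = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) {
    warning("empty peak file: ", path)
    return(empty)
  }
  tab <- utils::read.table(text = lines, sep = "", header = FALSE,
                           stringsAsFactors = FALSE)
  bad <- tab$V2 >= tab$V3
  if (any(bad)) {
    warning(sum(bad), " record(s) with start >= end rejected")
    tab <- tab[!bad, , drop = FALSE]
  }
  if (nrow(tab) == 0L) return(empty)
  offset <- if (ncol(tab) >= 10L) tab$V10 else rep(-1, nrow(tab))
  summit <- ifelse(offset >= 0, tab$V2 + offset, floor((tab$V2 + tab$V3) / 2))
  data.frame(chrom = as.character(tab$V1), start = tab$V2, end = tab$V3,
             summit = summit,
             score = if (ncol(tab) >= 5L) as.numeric(tab$V5) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Construct an expression matrix
#'
#' A plain numeric matrix (genes x samples, FPKM) carrying the focal sample —
#' the condition whose specific genes the pipeline hunts — as an attribute.
#'
#' @param values Numeric matrix with gene IDs as rownames and sample IDs as
#'   colnames; no negative entries.
#' @param focal_sample Sample ID of the focal condition; must be a column.
#' @return The matrix with attribute \code{focal_sample}.
#' @export
expression_matrix <- function(values, focal_sample) {
  values <- as.matrix(values)
  if (nrow(values) > 0 && is.null(rownames(values))) {
    stop("values must have gene IDs as rownames")
  }
  if (is.null(colnames(values))) {
    stop("values must have sample IDs as colnames")
  }
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (any(values < 0)) stop("negative expression")
  if (!(focal_sample %in% colnames(values))) {
    stop("focal sample '", focal_sample, "' not among samples")
  }
  attr(values, "focal_sample") <- focal_sample
  values
}

#' Focal sample of an expression matrix
#' @param matrix An \code{\link{expression_matrix}}.
#' @return The focal sample ID.
#' @export
focal_sample <- function(matrix) {
  fs <- attr(matrix, "focal_sample")
  if (is.null(fs)) stop("matrix carries no focal_sample attribute")
  fs
}

#' Read an FPKM expression matrix from TSV
#'
#' First column = gene IDs, header = sample IDs.
#'
#' @inheritParams expression_matrix
#' @param path Path to a tab-separated file.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression <- function(path, focal_sample) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  expression_matrix(m, focal_sample)
}

#' Write an expression matrix to TSV
#' @param matrix An \code{\link{expression_matrix}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read mature miRNA sequences
#'
#' FASTA (via \pkg{Biostrings}) or two-column TSV (name, mature sequence).
#'
#' @param path Path to a .fa/.fasta file or a TSV.
#' @return Named list of \code{\link{mirna}} objects.
#' @export
read_mirnas <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fa", "fasta")) {
    set <- Biostrings::readBStringSet(path)
    seqs <- as.character(set)
    nms <- sub("\\s.*$", "", names(set))
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    nms <- as.character(tab[[1]])
    seqs <- as.character(tab[[2]])
  }
  out <- Map(mirna, nms, seqs)
  stats::setNames(out, nms)
}
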