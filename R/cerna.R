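#' IDs expressed in the focal sample
#'
#' Candidate ceRNA partners and miRNA families are restricted to species
#' actually expressed in the focal condition.
#'
#' @param expr An \code{\link{expression_matrix}}.
#' @param min_expr Expression threshold (inclusive).
#' @return Character vector of IDs with focal expression >= \code{min_expr}.
#' @export
expressed_subset <- function(expr, min_expr) {
  fs <- focal_sample(expr)
  rownames(expr)[expr[, fs] >= min_expr]
}

#' miRNA families shared between two transcripts
#'
#' @param lnc_sites,utr_sites Site data.frames from \code{\link{scan_sites}}
#'   (rows may mix miRNAs).
#' @return Character vector: families with at least one site on each side.
#' @export
shared_families <- function(lnc_sites, utr_sites) {
  sort(intersect(unique(lnc_sites$mirna), unique(utr_sites$mirna)))
}

#' Site-count table from per-transcript scans
#'
#' @param site_lists Named list (transcript ID -> \code{\link{scan_sites}}
#'   data.frame, possibly row-bound over miRNAs).
#' @return data.frame with columns \code{transcript}, \code{mirna}, \code{n}
#'   (only nonzero counts).
#' @export
site_counts <- function(site_lists) {
  rows <- lapply(names(site_lists), function(id) {
    st <- site_lists[[id]]
    if (is.null(st) || nrow(st) == 0L) return(NULL)
    agg <- table(st$mirna)
    data.frame(transcript = id, mirna = names(agg), n = as.integer(agg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(transcript = character(), mirna = character(),
                      n = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Susceptibility score of a candidate ceRNA partner
#'
#' Expression-weighted score of how strongly fluctuations of the sponge
#' lncRNA should propagate to an mRNA through their shared miRNA families:
#' \deqn{score = \sum_{f \in shared} E(miR_f)\, n_f(mRNA)\,
#'   \frac{n_f(lnc)\, E(lnc)}{\sum_t n_f(t)\, E(t)},}
#' where the denominator runs over every expressed transcript carrying
#' family-f sites (the family's target pool). The bracketed pool share lies in
#' (0, 1] and equals 1 when the lncRNA is the family's only expressed target;
#' the score is nonnegative and increases in each factor.
#'
#' @param mrna_id,lnc_id Transcript IDs (must appear in \code{site_counts}).
#' @param site_counts data.frame from \code{\link{site_counts}}, restricted to
#'   expressed transcripts (the pool is defined over its rows).
#' @param expr Named numeric vector of expression levels covering every
#'   transcript and miRNA referenced.
#' @return List of class \code{CernaScore}: \code{mrna_id},
#'   \code{shared_families}, \code{score}.
#' @export
susceptibility_score <- function(mrna_id, lnc_id, site_counts, expr) {
  sc <- site_counts
  lnc_fams <- sc$mirna[sc$transcript == lnc_id & sc$n > 0]
  mrna_fams <- sc$mirna[sc$transcript == mrna_id & sc$n > 0]
  shared <- sort(intersect(lnc_fams, mrna_fams))
  if (length(shared) == 0L) stop("not a candidate: no shared family")
  need <- c(mrna_id, lnc_id, shared)
  missing <- setdiff(need, names(expr))
  if (length(missing) > 0L) {
    stop("no expression value for: ", paste(missing, collapse = ", "))
  }
  total <- 0
  for (f in shared) {
    rows <- sc[sc$mirna == f & sc$n > 0, , drop = FALSE]
    pool <- sum(rows$n * expr[rows$transcript])
    n_lnc <- rows$n[rows$transcript == lnc_id]
    n_mrna <- rows$n[rows$transcript == mrna_id]
    total <- total + expr[[f]] * n_mrna * (n_lnc * expr[[lnc_id]] / pool)
  }
  structure(list(mrna_id = mrna_id, shared_families = shared,
                 score = unname(total)),
            class = "CernaScore")
}

#' Rank ceRNA candidates by decreasing score
#'
#' Stable sort; score ties are broken by mRNA ID and reported via a message.
#'
#' @param scores List of \code{CernaScore} objects (from
#'   \code{\link{susceptibility_score}}) or a data.frame with \code{mrna_id}
#'   and \code{score} columns.
#' @return data.frame with \code{mrna_id}, \code{shared_families}
#'   (comma-separated), \code{score}, \code{rank} (1..n, decreasing score).
#' @export
rank_candidates <- function(scores) {
  if (is.data.frame(scores)) {
    df <- scores
    if (is.null(df$shared_families)) df$shared_families <- NA_character_
  } else {
    df <- do.call(rbind, lapply(scores, function(s) {
      data.frame(mrna_id = s$mrna_id,
                 shared_families = paste(s$shared_families, collapse = ","),
                 score = s$score, stringsAsFactors = FALSE)
    }))
  }
  if (anyDuplicated(df$score)) message("score tie(s) broken by mRNA ID")
  ord <- order(-df$score, df$mrna_id)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Rank candidate sponge partners of a lncRNA
#'
#' End-to-end ceRNA ranking: restricts transcripts and miRNAs to those
#' expressed in the focal sample, scans every kept sequence for strict seed
#' sites of every kept miRNA, keeps mRNAs sharing at least one family with
#' the lncRNA, scores them with \code{\link{susceptibility_score}} and ranks
#' by decreasing score.
#'
#' @param lnc_id lncRNA ID (must be expressed).
#' @param sequences Named character vector/list of transcript sequences,
#'   including \code{lnc_id}; the others are treated as mRNA 3'UTRs.
#' @param mirnas Named list of \code{\link{mirna}} objects.
#' @param expr An \code{\link{expression_matrix}} covering transcripts and
#'   miRNAs.
#' @param min_expr Expression threshold for inclusion (default 1).
#' @return Ranked data.frame as from \code{\link{rank_candidates}}.
#' @export
rank_cerna_partners <- function(lnc_id, sequences, mirnas, expr,
                                min_expr = 1) {
  sequences <- as.list(sequences)
  expressed <- expressed_subset(expr, min_expr)
  if (!(lnc_id %in% expressed)) stop("lncRNA not expressed")
  keep_tx <- intersect(names(sequences), expressed)
  keep_mir <- names(mirnas)[names(mirnas) %in% expressed]

  scans <- lapply(keep_tx, function(id) {
    do.call(rbind, lapply(keep_mir, function(f) {
      scan_sites(sequences[[id]], mirnas[[f]])
    }))
  })
  names(scans) <- keep_tx
  sc <- site_counts(scans)

  lnc_fams <- sc$mirna[sc$transcript == lnc_id]
  cand <- setdiff(unique(sc$transcript[sc$mirna %in% lnc_fams]), lnc_id)
  if (length(cand) == 0L) {
    return(data.frame(mrna_id = character(), shared_families = character(),
                      score = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  ev <- stats::setNames(expr[c(keep_tx, keep_mir), focal_sample(expr)],
                        c(keep_tx, keep_mir))
  scores <- lapply(cand, susceptibility_score, lnc_id = lnc_id,
                   site_counts = sc, expr = ev)
  rank_candidates(scores)
}
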