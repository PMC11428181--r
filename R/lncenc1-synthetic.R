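#' Synthetic reconstruction of a sponge transcript's MRE architecture
#'
#' Builds a 3.3 kb transcript whose strict seed-site content mirrors the
#' MRE architecture reported for the Lncenc1 sponge lncRNA in mouse ESCs:
#' 22 miR-128-3p sites of which 21 are 7mer-m8 and 20 sit at a regular 22-nt
#' spacing, plus 17 miR-138-5p sites (12 8mer-1a and 5 7mer-1a), planted on a
#' random background scrubbed of accidental matches for both miRNAs. This is
#' a \emph{synthetic} stand-in generated by \code{\link{make_mre_sequence}} -
#' not the real transcript sequence - so it exercises the scanner, the
#' enrichment statistic and the spacing analysis against a known truth with
#' the published site composition.
#'
#' The mature miR-128-3p / miR-138-5p sequences are the real ones, bundled in
#' \code{inst/extdata/mirnas_mature.fa}.
#'
#' @param seed Background RNG seed; the default fixes the reference sequence.
#' @return List: \code{sequence} (3300 nt), \code{sites} (planted truth,
#'   data.frame t1/mirna/site_class), \code{mirnas} (named
#'   \code{\link{mirna}} list for miR-128-3p and miR-138-5p).
#' @export
lncenc1_like_transcript <- function(seed = 20230831) {
  mirs <- read_mirnas(system.file("extdata", "mirnas_mature.fa",
                                  package = "stemlinc"))
  m128 <- mirs[["mmu-miR-128-3p"]]
  m138 <- mirs[["mmu-miR-138-5p"]]

  # miR-128: 20 sites at exact 22-nt spacing, then two at irregular gaps
  # (47 and 36 nt) -> 20 of 22 regular; classes 21x 7mer-m8 + 1x 8mer-1a.
  t128 <- c(100 + 22 * (0:19), 565, 601)
  cls128 <- c(rep("7mer-m8", 21), "8mer-1a")
  # miR-138: 17 sites at irregular spacing; 12x 8mer-1a + 5x 7mer-1a.
  gaps138 <- c(31, 37, 41, 43, 53, 59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103)
  t138 <- 1200 + cumsum(c(0, gaps138))
  cls138 <- c(rep("8mer-1a", 12), rep("7mer-1a", 5))

  t1 <- c(t128, t138)
  plant_mirnas <- c(rep(list(m128), length(t128)), rep(list(m138), length(t138)))
  ord <- order(t1)
  gen <- make_mre_sequence(3300, plant_mirnas[ord], t1[ord],
                           c(cls128, cls138)[ord], seed = seed)
  list(sequence = gen$sequence, sites = gen$sites,
       mirnas = list("mmu-miR-128-3p" = m128, "mmu-miR-138-5p" = m138))
}
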