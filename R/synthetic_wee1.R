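#' Synthetic WEE1-like reference and plant panel
#'
#' Deterministic, fully synthetic stand-ins for a human WEE1A-like
#' reference and four plant orthologs, built so that every functional
#' feature the analysis tests for sits at its documented human position:
#' the G-loop glutamate at 309, K328, the gatekeeper asparagine at 376, the
#' 376–379 hinge ending in C379, the catalytic segment matching
#' `IVHxDLKPxNIx` at 422–433 (catalytic aspartate at 426, K428, N431), the
#' DLG motif at 463–465, the EGD motif at 477–479, and the docking
#' arginines at 481 and 518.  These are not database sequences — filler
#' positions are drawn from a fixed internal seed — but they present the
#' same analytical surface (motif scanning, reference-anchored transfer of
#' numbering, site calling) as the real family, with the truth known by
#' construction.
#'
#' The plant stand-ins are N-terminally shortened and diverged copies
#' carrying the substitutions the plant family is known for: the G-loop
#' glutamate replaced by histidine (*A. thaliana*-like, own position 259),
#' tyrosine (*M. truncatula*-like, position 248) or asparagine
#' (*P. sativum*-like, position 256); a methionine gatekeeper; and
#' glutamate in place of the second docking arginine (R518).  The
#' `vunguiculata_chr6.1`-like paralog additionally loses both the catalytic
#' and the DFG aspartates (D426 and D463, the latter to glycine), carries
#' A477 in the EGD motif and a substituted R481 — the catalytically dead
#' configuration.
#'
#' @return `synthetic_wee1_reference()`: one [seq_record] of length 646.
#' @export
synthetic_wee1_reference <- function() {
  L <- 646L
  ch <- with_seed(20260101L, sample(AA20, L, replace = TRUE))
  put <- function(pos, s) {
    repl <- str_chars(s)
    ch[pos:(pos + length(repl) - 1L)] <<- repl
  }
  put(303L, "GSGEFGEVFK")   # glycine-rich loop context; E at 309
  put(326L, "AIKVI")        # beta-3 lysine context; K at 328
  put(374L, "EFNALC")       # hinge; gatekeeper N at 376, C at 379
  put(422L, "IVHRDLKPENIL") # catalytic segment consensus; D426, K428, N431
  put(461L, "SIDLG")        # activation-segment start; DLG at 463-465
  put(477L, "EGDYR")        # signatory EGD + docking R481
  put(516L, "GLRQP")        # second docking arginine R518
  # scrub accidental extra motif hits so consensus scans are unambiguous
  s <- paste0(ch, collapse = "")
  for (hit in scan_consensus(s, "EGD")$start) {
    if (hit != 477L) ch[hit + 1L] <- "A"
  }
  s <- paste0(ch, collapse = "")
  stopifnot(identical(scan_consensus(s, "EGD")$start, 477L),
            identical(scan_consensus(s, "IVHxDLKPxNIx")$start, 422L))
  seq_record("HsWEE1_synth", s, species = "Homo sapiens",
             accession = "synthetic",
             description = "synthetic human WEE1A-like reference (stand-in, not a database sequence)")
}

plant_variants <- list(
  athaliana = list(id = "AtWEE1_synth", species = "Arabidopsis thaliana",
                   offset = 50L, gloop = "H", seed = 20260111L),
  mtruncatula = list(id = "MtWEE1_synth", species = "Medicago truncatula",
                     offset = 61L, gloop = "Y", seed = 20260112L),
  psativum = list(id = "PsWEE1_synth", species = "Pisum sativum",
                  offset = 53L, gloop = "N", seed = 20260113L),
  vunguiculata_chr6.1 = list(id = "VuWEE1_Chr6.1_synth",
                             species = "Vigna unguiculata",
                             offset = 55L, gloop = "S", seed = 20260114L,
                             dead = TRUE))

#' @rdname synthetic_wee1_reference
#' @param variant One of `"athaliana"`, `"mtruncatula"`, `"psativum"`,
#'   `"vunguiculata_chr6.1"`.
#' @param divergence Fraction of unprotected positions substituted
#'   (default 0.6, which with the conserved functional windows yields
#'   overall identities near the 40-50% typical of plant-vs-human WEE1
#'   kinase regions).
#' @return `synthetic_plant_wee1()`: one [seq_record].
#' @export
synthetic_plant_wee1 <- function(variant = names(plant_variants),
                                 divergence = 0.6) {
  variant <- match.arg(variant)
  v <- plant_variants[[variant]]
  ref <- synthetic_wee1_reference()
  ch <- str_chars(ref$residues)
  cat <- builtin_wee1_catalog()
  protected <- unique(unlist(lapply(cat$sites$ref_pos, function(p) (p - 3L):(p + 3L))))
  protected <- union(protected, 422L:433L)
  with_seed(v$seed, {
    free <- setdiff(seq_along(ch), protected)
    free <- free[free > v$offset]
    hit <- free[stats::runif(length(free)) < divergence]
    for (p in hit) ch[p] <- sample(setdiff(AA20, ch[p]), 1L)
  })
  ch[309L] <- v$gloop
  ch[376L] <- "M"  # plant gatekeeper methionine
  ch[518L] <- "E"  # plants: second docking arginine replaced by glutamate
  if (isTRUE(v$dead)) {
    ch[426L] <- "N" # catalytic aspartate lost
    ch[463L] <- "G" # DFG aspartate -> glycine
    ch[477L] <- "A" # EGD glutamate -> alanine
    ch[481L] <- "S" # first docking arginine substituted
  }
  seq_record(v$id, paste0(ch[(v$offset + 1L):length(ch)], collapse = ""),
             species = v$species, accession = "synthetic",
             description = sprintf("synthetic %s WEE1-like ortholog (stand-in, not a database sequence)",
                                   v$species))
}

#' @rdname synthetic_wee1_reference
#' @return `synthetic_wee1_panel()`: named list of five [seq_record]s
#'   (reference first).
#' @export
synthetic_wee1_panel <- function() {
  out <- c(list(synthetic_wee1_reference()),
           lapply(names(plant_variants), synthetic_plant_wee1))
  names(out) <- c("reference", names(plant_variants))
  out
}
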