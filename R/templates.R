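# Construct templates for the three reporter screens and the gene-specific
# RNA-seq readout.
#
# Raw sequencing reads come off the instrument as reverse complements of the
# construct sense strand, so the filtering anchors are stored in raw-read
# orientation:
#   read 5' -> 3' = [dam-CDS anchor][revcomp(variable region)][upstream anchor]
# The upstream anchor carries the 4x GATC cassette (promoter screen) or the
# fixed promoter (UTR screens). Variants are reported on the sense strand.

ANCHOR_DAM_RC       <- "TGCCCACTTCAAAAAAGCGCGATTTTTCTTCAT"
ANCHOR_PROMOTER_RC  <- "GACCGGAACTTCTATGATCGAGATCGAGATCGAGATCGCGGCCGCAAC"
ANCHOR_UTR_STRONG_RC <- "AGTTTATATTATAACACTTTAACCTATGGC"
ANCHOR_UTR_WEAK_RC  <- "TGCAATTATTCTAACAAACCCCAAACTTATTTCAA"
RNA_ANCHOR          <- "ATGAAGAAAAATCG"
PRIBNOW             <- "TATAAT"

# Sense-strand dam coding prefix. The first 33 nt are the reverse complement
# of the dam anchor; the continuation is a fixed synthetic filler so that
# folding windows extending to +100 always have sequence available (the true
# downstream CDS is not part of the template definition).
DAM_CDS_CONTEXT <- paste0(
  "ATGAAGAAAAATCGCGCTTTTTTGAAGTGGGCA",
  "GATCTTGAAACCAGTTGGTAAAGAACTGGTTCAACGTTATCCAGAAGTT",
  "GATCGTTTAGTTGAAGTTTCTCCAGAAAAAGCTCAACT"
)

#' Construct template for a reporter screen
#'
#' A template describes the fixed architecture of one screen: the exact
#' anchor sequences used for read filtering (in raw-read, reverse-complement
#' orientation), the layout of the randomized region, and the screen's
#' coordinate system.
#'
#' Screens:
#' \describe{
#'   \item{promoter}{25 random nt (N25), a fixed Pribnow box \code{TATAAT},
#'     then 7 random nt (N7). Variant = N25 + N7 (32 nt). Coordinates
#'     -37..+1 with no 0: -37..-13 = N25, -12..-7 = TATAAT, -6..+1 = N7,
#'     +1 being the theoretical transcription start.}
#'   \item{utr_strong, utr_weak}{25 random nt immediately upstream of the
#'     dam start codon, behind a fixed strong or weak promoter. Variant
#'     positions -25..-1; position -26 is the fixed promoter +1 base
#'     (strong: T, weak: A); +1 = A of ATG.}
#' }
#'
#' @param screen one of `"promoter"`, `"utr_strong"`, `"utr_weak"`.
#' @return an object of class `elm_template`.
#' @export
elm_template <- function(screen = c("promoter", "utr_strong", "utr_weak")) {
  screen <- match.arg(screen)
  tpl <- switch(screen,
    promoter = list(
      screen = screen,
      anchor_dam = ANCHOR_DAM_RC,
      anchor_upstream = ANCHOR_PROMOTER_RC,
      inner = list(motif = revcomp(PRIBNOW), offset = 8L), # raw-read offset
      var_span = 38L,
      variant_len = 32L,
      positions = c(-37:-13, -6:-1, 1L),
      span_positions = c(-37:-1, 1L),
      plus1_base = NA_character_
    ),
    utr_strong = list(
      screen = screen,
      anchor_dam = ANCHOR_DAM_RC,
      anchor_upstream = ANCHOR_UTR_STRONG_RC,
      inner = NULL,
      var_span = 25L,
      variant_len = 25L,
      positions = -25:-1,
      span_positions = -25:-1,
      plus1_base = "T"
    ),
    utr_weak = list(
      screen = screen,
      anchor_dam = ANCHOR_DAM_RC,
      anchor_upstream = ANCHOR_UTR_WEAK_RC,
      inner = NULL,
      var_span = 25L,
      variant_len = 25L,
      positions = -25:-1,
      plus1_base = "A"
    )
  )
  tpl$span_positions <- tpl$span_positions %||% tpl$positions
  tpl$orientation <- "reverse"
  tpl$rna_anchor <- RNA_ANCHOR
  tpl$barcode_trim <- 6L
  tpl$cds_context <- DAM_CDS_CONTEXT
  stopifnot(nchar(tpl$anchor_dam) >= 10, nchar(tpl$anchor_upstream) >= 10)
  structure(tpl, class = "elm_template")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.elm_template <- function(x, ...) {
  cat("ELM-seq construct template:", x$screen, "\n")
  cat("  raw-read layout: [dam anchor ", nchar(x$anchor_dam), " nt][",
      x$var_span, " nt variable][upstream anchor ",
      nchar(x$anchor_upstream), " nt]\n", sep = "")
  cat("  variant length:", x$variant_len,
      "nt, sense-strand coordinates", x$positions[1], "..",
      x$positions[length(x$positions)], "(no position 0)\n")
  if (!is.na(x$plus1_base))
    cat("  fixed promoter +1 base:", x$plus1_base, "\n")
  invisible(x)
}

#' Full raw read for a variant under a template
#'
#' Assembles the error-free raw (reverse-complement orientation) read a
#' sequencer would produce for a given sense-strand variant. Used by the
#' simulator and by tests.
#'
#' @param variant sense-strand randomized bases (32 nt promoter / 25 nt UTR).
#' @param template an [elm_template()].
#' @return character vector of raw reads.
#' @export
template_read <- function(variant, template) {
  sense <- sense_span(variant, template)
  paste0(template$anchor_dam, revcomp(sense), template$anchor_upstream)
}

# Sense-strand variable span for a variant (inserts the fixed Pribnow box
# for the promoter screen).
sense_span <- function(variant, template) {
  if (any(nchar(variant) != template$variant_len))
    stop("variant length does not match template")
  if (template$screen == "promoter") {
    paste0(substr(variant, 1L, 25L), PRIBNOW, substr(variant, 26L, 32L))
  } else {
    variant
  }
}

#' mRNA context of a 5'-UTR variant
#'
#' The 26-nt UTR (fixed promoter +1 base followed by the 25 randomized
#' bases) joined to the dam coding prefix; this is the sequence folding
#' windows are cut from.
#'
#' @param variant 25-nt UTR variant(s).
#' @param template a UTR-screen [elm_template()].
#' @return character vector of mRNA context sequences.
#' @export
utr_mrna <- function(variant, template) {
  if (is.na(template$plus1_base))
    stop("utr_mrna() is defined for UTR-screen templates only")
  paste0(template$plus1_base, variant, template$cds_context)
}

# Map screen coordinates (no position 0; negative = upstream of +1) to
# 1-based indices into the mRNA context string with a `utr_len`-nt UTR.
pos_to_index <- function(pos, utr_len = 26L) {
  if (any(pos == 0L)) stop("position 0 does not exist in screen coordinates")
  ifelse(pos < 0L, utr_len + 1L + pos, utr_len + pos)
}
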