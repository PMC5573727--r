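# RNA folding energies behind a pluggable provider, sliding-window
# folding-expression correlation scans, and structure-exposure analysis.

#' Folding-energy provider
#'
#' Two backends share one contract (`sequence -> list(energy, structure)`):
#' \describe{
#'   \item{stub}{The package's deterministic reference: Nussinov-style
#'     maximum base pairing (Watson–Crick + GU wobble, minimum hairpin loop
#'     3), scored at -1.0 kcal/mol per pair, with one maximizing
#'     dot-bracket structure. Self-contained and reproducible; a structural
#'     stand-in, not a thermodynamic model.}
#'   \item{vienna}{Minimum free energy from the ViennaRNA `RNAfold` binary,
#'     when present on the PATH.}
#' }
#' DNA input is transcribed (T to U) before folding.
#'
#' @param name `"stub"` (default) or `"vienna"`.
#' @return an object of class `elm_fold_provider`.
#' @export
fold_provider <- function(name = c("stub", "vienna")) {
  name <- match.arg(name)
  fold <- switch(name,
    stub = function(seq) {
      rna <- chartr("Tt", "Uu", toupper(seq))
      res <- nussinov_cpp(rna)
      list(energy = -1.0 * res$pairs, structure = res$structure)
    },
    vienna = function(seq) {
      if (Sys.which("RNAfold") == "")
        stop("folding backend 'vienna' unavailable: RNAfold not on PATH")
      out <- system2("RNAfold", c("--noPS"), input = chartr("T", "U", seq),
                     stdout = TRUE)
      m <- regmatches(out[2], regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)",
                                      out[2]))[[1]]
      list(energy = as.numeric(m[3]), structure = m[2])
    }
  )
  structure(list(name = name, fold = fold), class = "elm_fold_provider")
}

#' Folding free energy of a sequence
#'
#' @param seqs character vector of DNA/RNA sequences.
#' @param provider a [fold_provider()].
#' @param structure also return dot-bracket structures.
#' @return numeric vector of energies (kcal/mol), or, with
#'   `structure = TRUE`, a list with `energy` and `structure`.
#' @export
fold_energy <- function(seqs, provider = fold_provider("stub"),
                        structure = FALSE) {
  stopifnot(inherits(provider, "elm_fold_provider"), all(nchar(seqs) >= 1))
  res <- lapply(seqs, provider$fold)
  e <- vapply(res, `[[`, numeric(1), "energy")
  if (!structure) return(e)
  list(energy = e, structure = vapply(res, `[[`, character(1), "structure"))
}

#' Sliding-window folding-expression correlation scan
#'
#' For every admissible (start, end) window over the mRNA (UTR + coding
#' prefix), the Pearson correlation across variants between the window's
#' folding energy and log10 DAMRatio. Coordinates: -26 is the transcript 5'
#' end of a 26-nt UTR, +1 the A of the start codon, no position 0.
#'
#' @param variants 25-nt UTR variants.
#' @param ratios log10 DAMRatios, same length (>= 3 variants).
#' @param template a UTR-screen [elm_template()].
#' @param start_range,end_range screen-coordinate ranges scanned; defaults
#'   -26..-1 and -10..100.
#' @param min_len minimum window length in nt (default 4).
#' @param provider a [fold_provider()].
#' @return an `elm_foldscan`: list with the correlation matrix `r`
#'   (starts x ends, `NA` where the window is inadmissible or runs off the
#'   sequence), `starts`, `ends`, `n_windows` (realized window count), and
#'   `argmax` (window with the largest |r|).
#' @export
window_scan <- function(variants, ratios, template,
                        start_range = c(-26L, -1L), end_range = c(-10L, 100L),
                        min_len = 4L, provider = fold_provider("stub")) {
  if (length(variants) < 3L)
    stop("window_scan needs at least 3 variants for a correlation")
  stopifnot(length(variants) == length(ratios))
  mrna <- utr_mrna(variants, template)
  avail <- min(nchar(mrna))
  starts <- setdiff(seq(start_range[1], start_range[2]), 0L)
  ends <- setdiff(seq(end_range[1], end_range[2]), 0L)
  rmat <- matrix(NA_real_, length(starts), length(ends),
                 dimnames = list(starts, ends))
  n_win <- 0L
  for (si in seq_along(starts)) {
    i1 <- pos_to_index(starts[si])
    for (ei in seq_along(ends)) {
      if (ends[ei] <= starts[si]) next
      i2 <- pos_to_index(ends[ei])
      if (i2 - i1 + 1L < min_len || i2 > avail) next
      dg <- fold_energy(substr(mrna, i1, i2), provider)
      if (sd(dg) == 0 || sd(ratios) == 0) next
      rmat[si, ei] <- cor(dg, ratios)
      n_win <- n_win + 1L
    }
  }
  best <- which(abs(rmat) == max(abs(rmat), na.rm = TRUE), arr.ind = TRUE)[1, ]
  out <- list(r = rmat, starts = starts, ends = ends, n_windows = n_win,
              argmax = list(start = starts[best[1]], end = ends[best[2]],
                            r = rmat[best[1], best[2]]))
  class(out) <- "elm_foldscan"
  out
}

#' @export
print.elm_foldscan <- function(x, ...) {
  cat("Folding-expression window scan:", x$n_windows, "windows\n")
  cat("  max |r| window: (", x$argmax$start, ",", x$argmax$end, ") r =",
      round(x$argmax$r, 4), "\n")
  invisible(x)
}

#' Per-position exposure from a dot-bracket structure
#'
#' A position is `hidden` iff it is base-paired in the structure, `exposed`
#' otherwise.
#'
#' @param seq sequence (only its length is used; kept for interface
#'   symmetry with providers returning both).
#' @param structure dot-bracket string, same length as `seq`.
#' @return character vector of `"exposed"`/`"hidden"` per position.
#' @export
exposure_profile <- function(seq, structure) {
  if (nchar(structure) != nchar(seq))
    stop("structure and sequence lengths differ")
  ch <- strsplit(structure, NULL)[[1]]
  if (!all(ch %in% c(".", "(", ")")))
    stop("structure must be dot-bracket over '.', '(', ')'")
  depth <- cumsum((ch == "(") - (ch == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0)
    stop("unbalanced dot-bracket structure")
  ifelse(ch == ".", "exposed", "hidden")
}

#' Positional exposure enrichment between classes, stratified by folding energy
#'
#' Compares, per position of the fixed folding region, the fraction of
#' exposed (unpaired) bases in high- versus low-productive sequences.
#' Folding energy itself separates the classes, so sequences are first
#' binned by their window energy (bins of `bin_width` kcal/mol) and the
#' per-bin log2 exposure odds are combined across bins weighted by bin
#' occupancy. A per-position Fisher exact test on the pooled exposed/hidden
#' counts is Bonferroni-corrected across positions.
#'
#' @param high_struct,low_struct dot-bracket structures (equal lengths).
#' @param high_dg,low_dg window folding energies (kcal/mol), same lengths
#'   as the structure vectors.
#' @param bin_width energy bin width in kcal/mol (default 1); `Inf` gives
#'   the unstratified comparison.
#' @param positions optional coordinate labels for the region.
#' @return data frame with `position`, `exposed_high`, `exposed_low`
#'   (pooled fractions), `enrichment` (bin-weighted log2 odds), `p`,
#'   `p_bonf`.
#' @export
exposure_compare <- function(high_struct, low_struct, high_dg, low_dg,
                             bin_width = 1, positions = NULL) {
  L <- unique(nchar(c(high_struct, low_struct)))
  if (length(L) != 1L) stop("structures must share one length")
  if (is.null(positions)) positions <- seq_len(L)
  expo <- function(ss) {
    t(vapply(ss, function(s) strsplit(s, NULL)[[1]] == ".", logical(L)))
  }
  eh <- expo(high_struct); el <- expo(low_struct)
  if (is.infinite(bin_width)) {
    bh <- rep(1L, length(high_dg)); bl <- rep(1L, length(low_dg))
  } else {
    bh <- floor(high_dg / bin_width); bl <- floor(low_dg / bin_width)
  }
  bins <- intersect(unique(bh), unique(bl))
  if (!length(bins)) stop("no energy bin is occupied by both classes")
  enr <- numeric(L); wsum <- 0
  for (b in bins) {
    ih <- bh == b; il <- bl == b
    nh <- sum(ih); nl <- sum(il)
    ch <- colSums(eh[ih, , drop = FALSE]); cl <- colSums(el[il, , drop = FALSE])
    w <- nh + nl
    enr <- enr + w * log2(((ch + 0.5) / (nh - ch + 0.5)) /
                          ((cl + 0.5) / (nl - cl + 0.5)))
    wsum <- wsum + w
  }
  enr <- enr / wsum
  ch <- colSums(eh); cl <- colSums(el)
  p <- vapply(seq_len(L), function(j) {
    fisher.test(matrix(c(ch[j], nrow(eh) - ch[j],
                         cl[j], nrow(el) - cl[j]), 2))$p.value
  }, numeric(1))
  data.frame(position = positions,
             exposed_high = ch / nrow(eh), exposed_low = cl / nrow(el),
             enrichment = enr, p = p, p_bonf = pmin(p * L, 1))
}
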