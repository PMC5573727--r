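# Positional and motif-level contrasts between high- and low-productive
# sequence classes.

#' Per-position, per-base log2 odds ratios between classes
#'
#' For every (position, base) cell, the log2 odds ratio of observing the
#' base at the position in the high-productive versus the low-productive
#' class, with a Haldane–Anscombe pseudocount on each cell so zero counts
#' stay defined. Comparing the two classes against each other cancels any
#' base-composition bias introduced by random library synthesis. A Fisher
#' exact test (on the raw counts) is run per cell, Bonferroni-corrected
#' over all cells.
#'
#' @param high_seqs,low_seqs character vectors of equal-length sequences.
#' @param pseudocount added to each odds cell (default 0.5).
#' @param positions optional coordinate labels, length = sequence length
#'   (e.g. `elm_template("promoter")$positions`).
#' @return data frame with `position`, `base`, `count_high`, `count_low`,
#'   `log2_odds`, `p`, `p_bonf`.
#' @export
position_base_odds <- function(high_seqs, low_seqs, pseudocount = 0.5,
                               positions = NULL) {
  if (!length(high_seqs) || !length(low_seqs))
    stop("both sequence sets must be non-empty")
  L <- unique(nchar(c(high_seqs, low_seqs)))
  if (length(L) != 1L) stop("sequence sets must have a single common length")
  if (is.null(positions)) positions <- seq_len(L)
  if (length(positions) != L) stop("positions must have length ", L)
  mh <- seq_matrix(high_seqs); ml <- seq_matrix(low_seqs)
  nh <- length(high_seqs); nl <- length(low_seqs)
  cells <- expand.grid(base = BASES, position = positions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[, c("position", "base")]
  ch <- cl <- integer(nrow(cells))
  for (j in seq_len(L)) {
    th <- tabulate(match(mh[, j], BASES), 4L)
    tl <- tabulate(match(ml[, j], BASES), 4L)
    idx <- (j - 1L) * 4L + 1:4
    ch[idx] <- th; cl[idx] <- tl
  }
  a <- pseudocount
  log2_odds <- log2(((ch + a) / (nh - ch + a)) / ((cl + a) / (nl - cl + a)))
  p <- vapply(seq_len(nrow(cells)), function(i) {
    fisher.test(matrix(c(ch[i], nh - ch[i], cl[i], nl - cl[i]), 2))$p.value
  }, numeric(1))
  data.frame(cells, count_high = ch, count_low = cl,
             log2_odds = log2_odds, p = p,
             p_bonf = pmin(p * nrow(cells), 1))
}

#' Compare log10 DAMRatios between motif-defined sequence groups
#'
#' Partitions sequences by which motif variant they carry at an anchored
#' slot (sequences matching none are excluded; a sequence matching several
#' patterns is assigned to the first match) and runs a two-tailed t-test
#' on log10 DAMRatio for every pair of groups, Bonferroni-corrected across
#' comparisons.
#'
#' @param seqs character vector of variant sequences.
#' @param ratios numeric log10 DAMRatios, same length.
#' @param motif_variants named list of patterns; each element is either a
#'   pattern string anchored at `anchor` or `list(pattern=, at=)` with its
#'   own 1-based anchor index.
#' @param anchor default 1-based anchor index into the sequences.
#' @param var_equal equal-variance t-test (default, the classical two-sample
#'   test); `FALSE` for Welch.
#' @return data frame of pairwise comparisons (`group1`, `group2`, `n1`,
#'   `n2`, `mean1`, `mean2`, `t`, `p`, `p_bonf`); per-group summaries in
#'   `attr(, "groups")`.
#' @export
motif_group_compare <- function(seqs, ratios, motif_variants, anchor = 1L,
                                var_equal = TRUE) {
  stopifnot(length(seqs) == length(ratios))
  specs <- lapply(motif_variants, function(m) {
    if (is.list(m)) list(pattern = m$pattern, at = m$at %||% anchor)
    else list(pattern = m, at = anchor)
  })
  if (is.null(names(motif_variants)))
    names(specs) <- vapply(specs, `[[`, character(1), "pattern")
  group <- rep(NA_character_, length(seqs))
  for (nm in names(specs)) {
    s <- specs[[nm]]
    if (s$at < 1L || s$at + nchar(s$pattern) - 1L > min(nchar(seqs)))
      stop("pattern '", s$pattern, "' does not fit at anchor ", s$at)
    hit <- substr(seqs, s$at, s$at + nchar(s$pattern) - 1L) == s$pattern
    group[is.na(group) & hit] <- nm
  }
  keep <- !is.na(group)
  g <- factor(group[keep], levels = names(specs))
  r <- ratios[keep]
  gs <- data.frame(group = levels(g),
                   n = as.integer(table(g)),
                   mean = as.numeric(tapply(r, g, mean)),
                   sd = as.numeric(tapply(r, g, sd)))
  pairs <- utils::combn(levels(g), 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    x <- r[g == g1]; y <- r[g == g2]
    if (length(x) < 2L || length(y) < 2L) {
      warning("group comparison ", g1, " vs ", g2,
              " skipped (fewer than 2 sequences)")
      return(NULL)
    }
    tt <- t.test(x, y, var.equal = var_equal)
    data.frame(group1 = g1, group2 = g2, n1 = length(x), n2 = length(y),
               mean1 = mean(x), mean2 = mean(y),
               t = unname(tt$statistic), p = tt$p.value)
  })
  res <- do.call(rbind, res)
  if (!is.null(res)) res$p_bonf <- pmin(res$p * nrow(res), 1)
  attr(res, "groups") <- gs
  res
}

#' Scan promoter variants for alternative Pribnow boxes
#'
#' Finds every exact occurrence (overlaps included) of any motif from the
#' set inside the full promoter span — the fixed box reinserted between N25
#' and N7 — excluding the fixed box's own slot, so hits are tandem or
#' alternative boxes contributed by the randomized bases.
#'
#' @param variants 32-nt promoter variant(s) (N25 + N7).
#' @param template the promoter [elm_template()].
#' @param motif_set motifs to scan for; default the canonical box plus the
#'   three alternatives assayed in the screen.
#' @return data frame with `seq` (index into `variants`), `motif`,
#'   `position` (screen coordinate of the match start).
#' @export
scan_alternative_pribnow <- function(variants, template = elm_template("promoter"),
                                     motif_set = c("TATAAT", "TAAAAT",
                                                   "TACAAT", "TAGAAT")) {
  spans <- sense_span(variants, template)
  L <- nchar(spans[1])
  fixed_at <- 26L  # sense-span index of the fixed box (promoter screen)
  w <- unique(nchar(motif_set))
  stopifnot(length(w) == 1L)
  out <- list()
  for (start in seq_len(L - w + 1L)) {
    if (template$screen == "promoter" && start == fixed_at) next
    sub <- substr(spans, start, start + w - 1L)
    hit <- sub %in% motif_set
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        seq = which(hit), motif = sub[hit],
        position = template$span_positions[start])
    }
  }
  if (!length(out))
    return(data.frame(seq = integer(), motif = character(),
                      position = integer()))
  res <- do.call(rbind, out)
  res[order(res$seq, res$position), , drop = FALSE]
}

#' Detect alternative start codons in a 5'-UTR
#'
#' Every occurrence of a start-codon candidate inside the UTR, with its
#' distance (nt) from the native A of ATG at +1 and whether it is in frame
#' with the native reading frame. Out-of-frame upstream codons create
#' frameshifted reading and are the translation-damping cases when close
#' to the native start.
#'
#' @param utr_seq a single UTR sequence ending at position -1 (the base
#'   immediately 5' of the native ATG); 25- or 26-nt UTRs both accepted.
#' @param codon_set codons to scan for; default `"ATG"`, extended set
#'   `c("ATG","GTG","TTG")` available.
#' @return data frame with `codon`, `position` (screen coordinate of the
#'   codon's first base), `distance` (nt from the native A), `in_frame`.
#' @export
detect_alt_start_codons <- function(utr_seq, codon_set = "ATG") {
  stopifnot(length(utr_seq) == 1L)
  L <- nchar(utr_seq)
  out <- list()
  for (i in seq_len(max(L - 2L, 0L))) {
    cod <- substr(utr_seq, i, i + 2L)
    if (cod %in% codon_set) {
      dist <- L - i + 1L                      # codon start is at -dist
      out[[length(out) + 1L]] <- data.frame(
        codon = cod, position = -dist, distance = dist,
        in_frame = dist %% 3L == 0L)
    }
  }
  if (!length(out))
    return(data.frame(codon = character(), position = integer(),
                      distance = integer(), in_frame = logical()))
  do.call(rbind, out)
}

#' Shine–Dalgarno-like sequence detection
#'
#' Longest contiguous Watson–Crick complementarity run between a window of
#' the UTR and the anti-SD sequence (the 16S rRNA 3' tail; default
#' `CCTCCT`, the reverse complement of the SD consensus `AGGAGG`, written
#' in DNA alphabet). A UTR substring pairs with the anti-SD iff it equals
#' the reverse complement of an anti-SD substring. This contiguous-run rule
#' is a declared approximation — the screen's organism has no annotated
#' anti-SD to calibrate against.
#'
#' @param utr_seq a single UTR sequence ending at position -1.
#' @param anti_sd anti-SD sequence (DNA alphabet).
#' @param region screen-coordinate window searched, default `c(-20, -1)`.
#' @param min_run minimum pairing run to call an SD-like element (default 4).
#' @return list with `has_sd`, `run` (longest pairing run, nt) and
#'   `position` (screen coordinate of the run start, or `NA`).
#' @export
sd_score <- function(utr_seq, anti_sd = "CCTCCT", region = c(-20L, -1L),
                     min_run = 4L) {
  stopifnot(length(utr_seq) == 1L)
  L <- nchar(utr_seq)
  i1 <- max(L + 1L + region[1], 1L); i2 <- L + 1L + region[2]
  win <- substr(utr_seq, i1, i2)
  target <- revcomp(anti_sd)   # what an SD-like element looks like in the UTR
  best <- 0L; best_pos <- NA_integer_
  for (len in seq(nchar(target), 1L)) {
    for (s in seq_len(nchar(target) - len + 1L)) {
      sub <- substr(target, s, s + len - 1L)
      hit <- regexpr(sub, win, fixed = TRUE)
      if (hit > 0L) { best <- len; best_pos <- region[1] + hit - 1L; break }
    }
    if (best > 0L) break
  }
  list(has_sd = best >= min_run, run = best, position = best_pos)
}
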