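# Gene-specific 5'-end RNA-seq: anchor filtering, UTR-length mapping, TPM,
# TSS calling and DNA-dosage normalization.

#' Filter RNA-seq reads by the dam-coding anchor
#'
#' Keeps reads containing the dam coding-sequence anchor exactly.
#'
#' @param reads character vector of RNA-seq reads (sense orientation).
#' @param anchor anchor sequence (default the dam CDS 5' anchor).
#' @return the kept reads; `attr(, "n_discarded")` counts the rest.
#' @export
filter_rna_reads <- function(reads, anchor = RNA_ANCHOR) {
  keep <- grepl(anchor, reads, fixed = TRUE)
  out <- reads[keep]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Map RNA-seq reads to (variant, 5'-UTR length)
#'
#' After trimming the 5' barcode, each read is `UTR portion + dam CDS`; the
#' UTR portion (the prefix before the anchor) of length l is matched
#' exactly against the 3'-most l bases of each library UTR (the fixed
#' promoter +1 base followed by the 25 randomized bases). Lengths below
#' `min_len` are discarded as unmappable; a 26-nt UTR can only match if its
#' 5' base is the correct promoter +1 base, which the full-UTR comparison
#' enforces. Reads whose UTR portion matches more than one library variant
#' are discarded as ambiguous.
#'
#' @param reads anchor-filtered reads ([filter_rna_reads()]).
#' @param library character vector of 25-nt library variants.
#' @param template a UTR-screen [elm_template()] (supplies the +1 base, the
#'   anchor and the barcode trim length).
#' @param min_len minimum mappable UTR length (default 15).
#' @return data frame of counts (`variant`, `utr_length`, `count`);
#'   `attr(, "discarded")` tallies `no_anchor`, `too_short`, `too_long`,
#'   `unmatched`, `ambiguous`.
#' @export
map_utr_lengths <- function(reads, library, template, min_len = 15L) {
  trimmed <- substr(reads, template$barcode_trim + 1L, nchar(reads))
  pos <- regexpr(template$rna_anchor, trimmed, fixed = TRUE)
  disc <- c(no_anchor = sum(pos < 0L), too_short = 0L, too_long = 0L,
            unmatched = 0L, ambiguous = 0L)
  trimmed <- trimmed[pos > 0L]
  l <- pos[pos > 0L] - 1L
  utr <- substr(trimmed, 1L, l)
  utr26 <- paste0(template$plus1_base, library)
  maxl <- nchar(utr26[1])
  disc[["too_short"]] <- sum(l < min_len)
  disc[["too_long"]] <- sum(l > maxl)
  ok <- l >= min_len & l <= maxl
  utr <- utr[ok]; l <- l[ok]
  rows <- list()
  for (len in sort(unique(l))) {
    suffix <- substr(utr26, maxl - len + 1L, maxl)
    dup <- suffix %in% suffix[duplicated(suffix)]
    sel <- l == len
    hit <- match(utr[sel], suffix)
    amb <- !is.na(hit) & dup[pmax(hit, 1L)]
    disc[["ambiguous"]] <- disc[["ambiguous"]] + sum(amb, na.rm = TRUE)
    disc[["unmatched"]] <- disc[["unmatched"]] + sum(is.na(hit))
    good <- !is.na(hit) & !amb
    if (any(good)) {
      tab <- table(hit[good])
      rows[[length(rows) + 1L]] <- data.frame(
        variant = library[as.integer(names(tab))],
        utr_length = len, count = as.integer(tab))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant = character(), utr_length = integer(),
               count = integer())
  out <- out[order(out$variant, -out$utr_length), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded") <- disc
  out
}

#' Transcripts per million
#'
#' TPM = N_il / N_tot * 1e6, where N_tot is the total number of
#' anchor-filtered reads. No pseudocount.
#'
#' @param n_il read count for a (variant, UTR length) cell.
#' @param n_tot total filtered reads (> 0).
#' @return numeric TPM value(s).
#' @export
tpm <- function(n_il, n_tot) {
  if (any(n_tot <= 0)) stop("n_tot must be positive")
  if (any(n_il < 0) || any(n_il > n_tot)) stop("need 0 <= n_il <= n_tot")
  n_il / n_tot * 1e6
}

#' Call the transcription start site per variant
#'
#' The TSS of a variant is the 5'-UTR length with the most reads; ties go
#' to the longer UTR (the more 5' start) and are flagged. Labels follow
#' the screen convention: a 26-nt UTR starts at the theoretical +1 ("N7"),
#' a 25-nt UTR one base downstream ("N8").
#'
#' @param length_counts data frame from [map_utr_lengths()].
#' @return data frame with `variant`, `tss_length`, `tss_label`, `tie`,
#'   `n_reads` (reads supporting the variant across retained lengths).
#' @export
call_tss <- function(length_counts) {
  if (!nrow(length_counts))
    return(data.frame(variant = character(), tss_length = integer(),
                      tss_label = character(), tie = logical(),
                      n_reads = integer()))
  sp <- split(length_counts, length_counts$variant)
  res <- lapply(sp, function(d) {
    best <- max(d$count)
    at <- d$utr_length[d$count == best]
    l <- max(at)  # tie -> longer UTR
    data.frame(variant = d$variant[1], tss_length = l,
               tss_label = if (l == 26L) "N7" else if (l == 25L) "N8"
                           else paste0("l", l),
               tie = length(at) > 1L, n_reads = sum(d$count))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Full RNA-seq pipeline for one screen
#'
#' Anchor filtering, UTR-length mapping, TPM, TSS calls and per-variant
#' RNA abundance (the TPM sum over all retained UTR lengths).
#'
#' @param reads raw RNA-seq reads.
#' @inheritParams map_utr_lengths
#' @return an `elm_tss` list: `lengths` (per-(variant, length) counts and
#'   TPM), `tss` (per-variant calls with `abundance`), `n_tot` (filtered
#'   reads), `discarded`.
#' @export
tss_table <- function(reads, library, template, min_len = 15L) {
  filt <- filter_rna_reads(reads, template$rna_anchor)
  n_tot <- length(filt)
  lc <- map_utr_lengths(filt, library, template, min_len)
  lc$tpm <- tpm(lc$count, n_tot)
  calls <- call_tss(lc)
  ab <- tapply(lc$tpm, lc$variant, sum)
  calls$abundance <- as.numeric(ab[calls$variant])
  structure(list(lengths = lc, tss = calls, n_tot = n_tot,
                 discarded = attr(lc, "discarded")),
            class = "elm_tss")
}

#' @export
print.elm_tss <- function(x, ...) {
  cat("Gene-specific RNA-seq:", x$n_tot, "anchor-filtered reads,",
      nrow(x$tss), "variants with a called TSS\n")
  cat("  discarded:", paste(names(x$discarded), x$discarded,
                            collapse = ", "), "\n")
  print(head(x$tss, 6))
  invisible(x)
}

#' Normalize RNA abundance by DNA dosage
#'
#' Divides the RNA abundance by the log10 of the variant's read count in
#' the undigested ("no restriction enzyme") DNA pool, the screen's proxy
#' for construct dosage. Variants with an uncut count of 1 or less cannot
#' be normalized (log10 <= 0) and are flagged.
#'
#' @param rna_abundance numeric RNA abundances (summed TPM).
#' @param uncut_counts matching uncut DNA read counts.
#' @return data frame with `abundance`, `uncut`, `normalized` (`NA` where
#'   not normalizable) and `flag_unnormalized`.
#' @export
normalize_by_dna <- function(rna_abundance, uncut_counts) {
  stopifnot(length(rna_abundance) == length(uncut_counts))
  can <- uncut_counts > 1
  out <- data.frame(abundance = rna_abundance, uncut = uncut_counts,
                    normalized = NA_real_, flag_unnormalized = !can)
  out$normalized[can] <- rna_abundance[can] / log10(uncut_counts[can])
  out
}
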