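# Raw-read processing: demultiplexing, exact anchor filtering, variant
# extraction and per-condition count tables.

#' Read sequences from FASTA/FASTQ
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; the format is taken
#' from the file extension (`.fq`/`.fastq`, optionally `.gz`, is FASTQ,
#' anything else FASTA). Quality scores are discarded — filtering is by
#' exact anchor match only.
#'
#' @param path path to a FASTA or FASTQ file (plain or gzipped).
#' @return character vector of read sequences.
#' @export
read_seq_file <- function(path) {
  fq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  x <- Biostrings::readDNAStringSet(path, format = if (fq) "fastq" else "fasta")
  as.character(x, use.names = FALSE)
}

#' Demultiplex reads by an inline condition index
#'
#' Each experimental condition (no digestion, DpnI, MboI) is labeled with a
#' distinct index sequence at the start of the read. Reads whose index is
#' not in the map are rejected with reason `"unknown_index"`; assigned reads
#' are returned with the index stripped.
#'
#' @param reads character vector of raw reads.
#' @param index_map named character vector, `index sequence -> condition
#'   label`; all indexes must be distinct and of equal length.
#' @return list with one character vector per condition label, plus
#'   `rejected` (the unassigned reads) and `n_rejected`.
#' @export
demultiplex <- function(reads, index_map) {
  idx <- names(index_map)
  if (is.null(idx) || anyDuplicated(idx))
    stop("index_map must have distinct index sequences as names")
  len <- unique(nchar(idx))
  if (length(len) != 1L) stop("all index sequences must have equal length")
  key <- substr(reads, 1L, len)
  cond <- index_map[match(key, idx)]
  out <- lapply(split(substr(reads, len + 1L, nchar(reads)),
                      factor(cond, levels = unique(unname(index_map)))),
                unname)
  out$rejected <- reads[is.na(cond)]
  out$n_rejected <- sum(is.na(cond))
  out
}

#' Extract randomized-region variants from raw reads
#'
#' Applies the screen's exact-match anchor filters and returns the
#' randomized bases on the construct sense strand. A read is accepted only
#' if every anchor matches exactly at its template position (the default),
#' or, with `floating = TRUE`, wherever the two anchors are found with the
#' correct spacing. Rejection reasons name the first failed check:
#' `too_short`, `anchor_dam`, `anchor_pribnow` (promoter screen only),
#' `anchor_upstream`, `length_mismatch` (floating mode), `ambiguous_base`
#' (N inside the variant region).
#'
#' @param reads character vector of reads.
#' @param template an [elm_template()].
#' @param orientation `"reverse"` (default: reads are reverse complements of
#'   the construct, as sequenced) or `"sense"`.
#' @param floating search for the anchors instead of requiring them at the
#'   template-fixed offsets.
#' @return list with `variant` (character, `NA` where rejected) and
#'   `reason` (character, `NA` where accepted).
#' @export
extract_variant <- function(reads, template,
                            orientation = c("reverse", "sense"),
                            floating = FALSE) {
  orientation <- match.arg(orientation)
  if (orientation == "sense") reads <- revcomp(reads)
  n5 <- nchar(template$anchor_dam)
  n3 <- nchar(template$anchor_upstream)
  span <- template$var_span
  total <- n5 + span + n3
  n <- length(reads)
  reason <- rep(NA_character_, n)
  span_raw <- rep(NA_character_, n)

  if (!floating) {
    short <- nchar(reads) < total
    reason[short] <- "too_short"
    ok <- !short
    bad5 <- ok & substr(reads, 1L, n5) != template$anchor_dam
    reason[bad5] <- "anchor_dam"
    ok <- ok & !bad5
    if (!is.null(template$inner)) {
      o <- n5 + template$inner$offset
      w <- nchar(template$inner$motif)
      badp <- ok & substr(reads, o, o + w - 1L) != template$inner$motif
      reason[badp] <- "anchor_pribnow"
      ok <- ok & !badp
    }
    bad3 <- ok & substr(reads, n5 + span + 1L, total) != template$anchor_upstream
    reason[bad3] <- "anchor_upstream"
    ok <- ok & !bad3
    span_raw[ok] <- substr(reads[ok], n5 + 1L, n5 + span)
  } else {
    p5 <- regexpr(template$anchor_dam, reads, fixed = TRUE)
    p3 <- regexpr(template$anchor_upstream, reads, fixed = TRUE)
    bad5 <- p5 < 0L
    reason[bad5] <- "anchor_dam"
    bad3 <- !bad5 & p3 < 0L
    reason[bad3] <- "anchor_upstream"
    ok <- !bad5 & !bad3
    mism <- ok & (p3 - (p5 + n5)) != span
    reason[mism] <- "length_mismatch"
    ok <- ok & !mism
    if (!is.null(template$inner)) {
      o <- p5 + n5 - 1L + template$inner$offset
      w <- nchar(template$inner$motif)
      badp <- ok & substr(reads, o, o + w - 1L) != template$inner$motif
      reason[badp] <- "anchor_pribnow"
      ok <- ok & !badp
    }
    span_raw[ok] <- substr(reads[ok], p5[ok] + n5, p5[ok] + n5 + span - 1L)
  }

  variant <- rep(NA_character_, n)
  if (any(ok)) {
    sense <- revcomp(span_raw[ok])
    if (template$screen == "promoter") {
      sense <- paste0(substr(sense, 1L, 25L), substr(sense, 32L, 38L))
    }
    hasN <- grepl("N", sense, fixed = TRUE)
    idx <- which(ok)
    reason[idx[hasN]] <- "ambiguous_base"
    variant[idx[!hasN]] <- sense[!hasN]
  }
  list(variant = variant, reason = reason)
}

#' Tabulate extracted variants into a per-condition count table
#'
#' @param uncut,dpn,mbo character vectors of accepted variants (one entry
#'   per accepted read) for the undigested, DpnI- and MboI-digested pools.
#' @param rejected optional named list of per-condition rejection-reason
#'   vectors, carried along as metadata.
#' @return an `elm_counts` data frame with columns `variant`, `uncut`,
#'   `dpn`, `mbo`; condition totals (accepted reads only) are the column
#'   sums and are also stored in `attr(, "totals")`, the rejection
#'   breakdown in `attr(, "rejected")`.
#' @export
tabulate_variants <- function(uncut = character(), dpn = character(),
                              mbo = character(), rejected = NULL) {
  lens <- nchar(c(uncut, dpn, mbo))
  if (length(lens) && length(unique(lens)) != 1L)
    stop("variants must all have the same length")
  vars <- sort(unique(c(uncut, dpn, mbo)))
  cnt <- function(v) {
    if (!length(vars)) return(integer(0))
    as.integer(table(factor(v, levels = vars)))
  }
  out <- data.frame(variant = vars, uncut = cnt(uncut), dpn = cnt(dpn),
                    mbo = cnt(mbo), stringsAsFactors = FALSE)
  attr(out, "totals") <- c(uncut = length(uncut), dpn = length(dpn),
                           mbo = length(mbo))
  attr(out, "rejected") <- lapply(rejected %||% list(),
                                  function(r) table(r[!is.na(r)]))
  class(out) <- c("elm_counts", "data.frame")
  out
}

#' Full read-to-counts pipeline for one screen
#'
#' Demultiplexed read pools in, count table out: anchor filtering, variant
#' extraction and tabulation for the three digestion conditions.
#'
#' @param template an [elm_template()].
#' @param uncut,dpn,mbo character vectors of reads, or paths to FASTA/FASTQ
#'   files.
#' @inheritParams extract_variant
#' @return an `elm_counts` table (see [tabulate_variants()]).
#' @export
count_reads <- function(template, uncut, dpn, mbo, floating = FALSE) {
  get_reads <- function(x) {
    if (length(x) == 1L && !grepl("^[ACGTN]+$", x) && file.exists(x))
      read_seq_file(x) else x
  }
  ext <- lapply(list(uncut = uncut, dpn = dpn, mbo = mbo), function(x) {
    extract_variant(get_reads(x), template, floating = floating)
  })
  tabulate_variants(
    uncut = ext$uncut$variant[!is.na(ext$uncut$variant)],
    dpn   = ext$dpn$variant[!is.na(ext$dpn$variant)],
    mbo   = ext$mbo$variant[!is.na(ext$mbo$variant)],
    rejected = lapply(ext, `[[`, "reason")
  )
}

#' Write / read a count table as TSV
#'
#' @param counts an `elm_counts` table.
#' @param path output / input TSV path.
#' @export
write_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant", "uncut", "dpn", "mbo") %in% names(df)))
  attr(df, "totals") <- c(uncut = sum(df$uncut), dpn = sum(df$dpn),
                          mbo = sum(df$mbo))
  class(df) <- c("elm_counts", "data.frame")
  df
}
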