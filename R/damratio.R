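# CPM normalization, the DAMRatio expression statistic, read-support
# filtering and replicate combination.

#' Counts per million with pseudocount
#'
#' CPM = (X + 1) / (N + 1) * 1e6. The +1 pseudocounts keep every CPM
#' strictly positive, so DAMRatios are always defined.
#'
#' @param x read count(s) for a variant in one condition.
#' @param n total accepted reads in that condition (scalar or vector).
#' @return numeric CPM value(s).
#' @export
cpm <- function(x, n) {
  if (any(x < 0) || any(x != floor(x)) || any(n != floor(n)))
    stop("counts must be non-negative integers")
  if (any(n < x)) stop("condition total must be >= each count")
  (x + 1) / (n + 1) * 1e6
}

#' DAMRatio of a variant
#'
#' Ratio of the variant's CPM in the MboI-digested pool (survivors are
#' methylated, i.e. Dam was expressed) to its CPM in the DpnI-digested pool
#' (survivors are unmethylated). Higher ratio = more methylation = more Dam.
#'
#' @param cpm_mbo,cpm_dpn CPM values from the MboI and DpnI digestions.
#' @return numeric DAMRatio value(s).
#' @export
dam_ratio <- function(cpm_mbo, cpm_dpn) {
  if (any(cpm_mbo <= 0) || any(cpm_dpn <= 0))
    stop("CPM values must be strictly positive")
  cpm_mbo / cpm_dpn
}

#' Keep variants with real read support
#'
#' Retains a variant iff it was seen more than `threshold` times in at
#' least one of the two digestion pools (strict inequality; the undigested
#' pool is not consulted — it is reserved for RNA/DNA normalization).
#'
#' @param counts an `elm_counts` table.
#' @param threshold minimum read support (exclusive); default 100.
#' @return the filtered `elm_counts` table; `attr(, "filter")` records the
#'   threshold and the retained/removed tallies.
#' @export
apply_read_filter <- function(counts, threshold = 100L) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0)
    stop("threshold must be a single non-negative number")
  keep <- counts$dpn > threshold | counts$mbo > threshold
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "totals") <- attr(counts, "totals")
  attr(out, "rejected") <- attr(counts, "rejected")
  attr(out, "filter") <- list(threshold = threshold,
                              retained = sum(keep), removed = sum(!keep))
  class(out) <- c("elm_counts", "data.frame")
  out
}

#' Per-variant DAMRatio table
#'
#' Computes CPM values for the three conditions (totals = accepted reads in
#' the full, unfiltered table), the DAMRatio and its log10, and flags
#' variants passing the read-support filter.
#'
#' @param counts an `elm_counts` table.
#' @param min_reads read-support threshold passed to [apply_read_filter()]
#'   semantics (flagging only; no rows are dropped here).
#' @return an `elm_dam` data frame with columns `variant`, `uncut`, `dpn`,
#'   `mbo`, `cpm_uncut`, `cpm_dpn`, `cpm_mbo`, `damratio`,
#'   `log10_damratio`, `pass_filter`.
#' @export
dam_table <- function(counts, min_reads = 100L) {
  tot <- attr(counts, "totals")
  if (is.null(tot))
    tot <- c(uncut = sum(counts$uncut), dpn = sum(counts$dpn),
             mbo = sum(counts$mbo))
  out <- data.frame(
    variant = counts$variant,
    uncut = counts$uncut, dpn = counts$dpn, mbo = counts$mbo,
    cpm_uncut = cpm(counts$uncut, tot[["uncut"]]),
    cpm_dpn = cpm(counts$dpn, tot[["dpn"]]),
    cpm_mbo = cpm(counts$mbo, tot[["mbo"]]),
    stringsAsFactors = FALSE
  )
  out$damratio <- dam_ratio(out$cpm_mbo, out$cpm_dpn)
  out$log10_damratio <- log10(out$damratio)
  out$pass_filter <- counts$dpn > min_reads | counts$mbo > min_reads
  attr(out, "totals") <- tot
  attr(out, "min_reads") <- min_reads
  class(out) <- c("elm_dam", "data.frame")
  out
}

#' Combine two biological replicates
#'
#' Puts replicate B on replicate A's scale with an ordinary least-squares
#' fit of B's log10 DAMRatio on A's over the shared variants, maps B's
#' values back through the fitted line, and averages the values available
#' for each variant. Variants present in one replicate only keep their
#' single (mapped) value.
#'
#' @param repA,repB `elm_dam` tables (or data frames with `variant` and
#'   `log10_damratio` columns).
#' @param min_shared minimum number of shared variants required to fit the
#'   regression (default 50).
#' @return data frame with `variant`, `log10_damratio` (combined),
#'   `n_reps`; `attr(, "fit")` holds slope, intercept and Pearson r of the
#'   B-on-A regression.
#' @export
combine_replicates <- function(repA, repB, min_shared = 50L) {
  shared <- intersect(repA$variant, repB$variant)
  if (length(shared) < min_shared)
    stop("insufficient_overlap: ", length(shared), " shared variants (need ",
         min_shared, ")")
  a <- repA$log10_damratio[match(shared, repA$variant)]
  b <- repB$log10_damratio[match(shared, repB$variant)]
  fit <- lm(b ~ a)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (abs(slope) < 1e-12) stop("degenerate replicate regression (slope ~ 0)")
  # map every repB value through the inverse of the fitted line onto A's scale
  b_all <- (repB$log10_damratio - intercept) / slope
  vars <- union(repA$variant, repB$variant)
  va <- repA$log10_damratio[match(vars, repA$variant)]
  vb <- b_all[match(vars, repB$variant)]
  comb <- rowMeans(cbind(va, vb), na.rm = TRUE)
  out <- data.frame(variant = vars, log10_damratio = comb,
                    n_reps = (!is.na(va)) + (!is.na(vb)),
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- list(slope = slope, intercept = intercept,
                           pearson_r = cor(a, b), n_shared = length(shared),
                           mapping = "OLS B-on-A inverse map, then mean")
  out
}

#' @export
print.elm_counts <- function(x, ...) {
  tot <- attr(x, "totals")
  cat("ELM-seq count table:", nrow(x), "variants\n")
  if (!is.null(tot))
    cat("  accepted reads: uncut", tot[["uncut"]], "| dpn", tot[["dpn"]],
        "| mbo", tot[["mbo"]], "\n")
  f <- attr(x, "filter")
  if (!is.null(f))
    cat("  read filter >", f$threshold, ": retained", f$retained,
        "removed", f$removed, "\n")
  print(head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more variants\n")
  invisible(x)
}

#' @export
print.elm_dam <- function(x, ...) {
  cat("ELM-seq DAMRatio table:", nrow(x), "variants;",
      sum(x$pass_filter), "pass the >", attr(x, "min_reads"),
      "read filter\n")
  print(head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more variants\n")
  invisible(x)
}
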