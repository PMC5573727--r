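# Generative model of the reporter experiment with planted ground truth:
# sequence effects -> expression -> per-site methylation (incl.
# hemimethylation) -> digestion survival -> sequencing reads, plus
# gene-specific 5'-end RNA-seq with planted TSS distributions.

#' Simulate a randomized reporter library with planted truth
#'
#' Variant sequences are uniform random (optionally composition-biased, to
#' mimic synthesis bias). True expression is log-linear in planted
#' per-(position, base) weights plus optional pairwise epistasis terms
#' (a bonus when the bases at two positions match) and Gaussian noise:
#' `E = exp(sum weights + sum epistasis + noise)`. The per-molecule,
#' per-GATC-site methylation probability follows the saturating link
#' `m = E / (E + k_half)`; the class label is high iff `E` exceeds the
#' threshold. Defaults place `k_half` and the threshold at the median of
#' `E`, so methylation probabilities straddle 0.5 and classes are balanced.
#'
#' @param n library size (distinct variants).
#' @param template an [elm_template()].
#' @param weights 4 x L matrix of ln-scale positional weights (rows
#'   A,C,G,T); default: drawn N(0, `weight_sd`), centered per position.
#' @param weight_sd sd of the default weight draw (default 0.5 ln-units).
#' @param epistasis_pairs list of `list(i =, j =, strength =)` planted
#'   couplings (ln-scale bonus when bases at i and j are equal).
#' @param noise_sd sd of the expression noise (default 0.3 ln-units).
#' @param base_probs sampling probabilities for A,C,G,T (default uniform).
#' @param k_half half-saturation constant of the methylation link;
#'   default `median(E)`.
#' @param class_threshold expression threshold for the high label;
#'   default `median(E)`.
#' @param seed RNG seed; identical seeds give bit-identical libraries.
#' @return an object of class `elm_sim` with `truth` (data frame:
#'   `variant`, `logE`, `E`, `m`, `label`, `tss_length`), the planted
#'   `weights`, `epistasis_pairs` and parameters.
#' @export
simulate_library <- function(n = 1000L, template = elm_template("promoter"),
                             weights = NULL, weight_sd = 0.5,
                             epistasis_pairs = list(), noise_sd = 0.3,
                             base_probs = c(0.25, 0.25, 0.25, 0.25),
                             k_half = NULL, class_threshold = NULL,
                             seed = 1L) {
  L <- template$variant_len
  with_seed(seed, {
    if (is.null(weights)) {
      weights <- matrix(rnorm(4L * L, 0, weight_sd), 4L, L,
                        dimnames = list(BASES, NULL))
      weights <- sweep(weights, 2L, colMeans(weights))
    }
    stopifnot(nrow(weights) == 4L, ncol(weights) == L)
    im <- matrix(sample.int(4L, n * L, replace = TRUE, prob = base_probs),
                 n, L)
    variants <- apply(im, 1, function(r) paste(BASES[r], collapse = ""))
    while (anyDuplicated(variants)) {  # keep variants distinct
      d <- which(duplicated(variants))
      im[d, ] <- sample.int(4L, length(d) * L, replace = TRUE,
                            prob = base_probs)
      variants[d] <- apply(im[d, , drop = FALSE], 1,
                           function(r) paste(BASES[r], collapse = ""))
    }
    logE <- vapply(seq_len(n), function(r) {
      sum(weights[cbind(im[r, ], seq_len(L))])
    }, numeric(1))
    for (p in epistasis_pairs) {
      logE <- logE + p$strength * (im[, p$i] == im[, p$j])
    }
    logE <- logE + rnorm(n, 0, noise_sd)
    E <- exp(logE)
    if (is.null(k_half)) k_half <- median(E)
    if (is.null(class_threshold)) class_threshold <- median(E)
    m <- E / (E + k_half)
    # planted TSS: dominant UTR length 25 (theoretical +2) for 2/3 of
    # variants, 26 (theoretical +1) for 1/3 — the screen's observed shift
    tss_length <- sample(c(25L, 26L), n, replace = TRUE, prob = c(2, 1) / 3)
    truth <- data.frame(variant = variants, logE = logE, E = E, m = m,
                        label = ifelse(E > class_threshold, "high", "low"),
                        tss_length = tss_length, stringsAsFactors = FALSE)
  })
  structure(list(truth = truth, weights = weights,
                 epistasis_pairs = epistasis_pairs, template = template,
                 noise_sd = noise_sd, k_half = k_half,
                 class_threshold = class_threshold, seed = seed),
            class = "elm_sim")
}

#' @export
print.elm_sim <- function(x, ...) {
  cat("Simulated reporter library:", nrow(x$truth), "variants (",
      x$template$screen, " screen)\n", sep = "")
  cat("  high-productive:", sum(x$truth$label == "high"),
      "| k_half:", signif(x$k_half, 4), "| seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate the three digestion pools
#'
#' Per molecule, each of the four GATC sites is independently
#' hemimethylated with probability `h` (resists both enzymes), otherwise
#' methylated with the variant's probability `m` (resists MboI, cut by
#' DpnI) or unmethylated (resists DpnI, cut by MboI). A fragment amplifies
#' only if all four sites survive, so the per-variant survival
#' probabilities are `(h + (1-h) m)^4` for MboI and `(h + (1-h)(1-m))^4`
#' for DpnI. Pool reads are drawn multinomially with probabilities
#' proportional to abundance times survival; the uncut pool samples
#' abundance directly.
#'
#' @param sim an [simulate_library()] result.
#' @param depth reads per pool (default 1e6).
#' @param h hemimethylation probability per site (default 0).
#' @param abundance per-variant library abundance (default equimolar).
#' @param seed RNG seed.
#' @param as_reads return raw reads (named list `uncut`, `dpn`, `mbo`)
#'   instead of a count table.
#' @param error_rate uniform per-base substitution rate applied to raw
#'   reads (only with `as_reads = TRUE`; default 0).
#' @return an `elm_counts` table, or read pools with `as_reads = TRUE`.
#' @export
simulate_digestion_reads <- function(sim, depth = 1e6, h = 0,
                                     abundance = NULL, seed = 1L,
                                     as_reads = FALSE, error_rate = 0) {
  stopifnot(inherits(sim, "elm_sim"), depth >= 1, h >= 0, h <= 0.5)
  tr <- sim$truth
  n <- nrow(tr)
  if (is.null(abundance)) abundance <- rep(1, n)
  p_site_mbo <- h + (1 - h) * tr$m
  p_site_dpn <- h + (1 - h) * (1 - tr$m)
  w <- list(uncut = abundance,
            dpn = abundance * p_site_dpn^4,
            mbo = abundance * p_site_mbo^4)
  counts <- with_seed(seed, lapply(w, function(wi) {
    if (sum(wi) == 0) return(integer(n))  # nothing survives this digestion
    as.integer(stats::rmultinom(1, depth, wi / sum(wi)))
  }))
  if (!as_reads) {
    out <- data.frame(variant = tr$variant, uncut = counts$uncut,
                      dpn = counts$dpn, mbo = counts$mbo,
                      stringsAsFactors = FALSE)
    o <- order(out$variant)
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "totals") <- c(uncut = sum(out$uncut), dpn = sum(out$dpn),
                             mbo = sum(out$mbo))
    attr(out, "sim") <- list(depth = depth, h = h, seed = seed)
    class(out) <- c("elm_counts", "data.frame")
    return(out)
  }
  with_seed(seed + 1L, {
    lapply(counts, function(cnt) {
      reads <- rep(template_read(tr$variant, sim$template), cnt)
      if (error_rate > 0) reads <- mutate_reads(reads, error_rate)
      sample(reads)
    })
  })
}

# Uniform substitution errors at the given per-base rate.
mutate_reads <- function(reads, rate) {
  vapply(reads, function(r) {
    ch <- strsplit(r, NULL)[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(BASES, b), 1L)
      }, character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate gene-specific 5'-end RNA-seq reads
#'
#' Reads are `barcode + UTR suffix + dam CDS prefix`: the variant is drawn
#' with probability proportional to its true expression (RNA abundance),
#' the 5'-UTR length from the variant's planted TSS distribution (the
#' planted length with probability 0.7, one and two bases shorter with 0.2
#' and 0.1).
#'
#' @param sim an [simulate_library()] result built on a UTR-screen
#'   template.
#' @param depth number of reads (default 1e5).
#' @param seed RNG seed.
#' @param barcode 5' barcode bases prepended to every read (length must
#'   equal the template's `barcode_trim`).
#' @param cds_len length of the dam CDS prefix included (default 30).
#' @return character vector of reads.
#' @export
simulate_rnaseq <- function(sim, depth = 1e5, seed = 1L, barcode = "ACGTGT",
                            cds_len = 30L) {
  stopifnot(inherits(sim, "elm_sim"))
  tpl <- sim$template
  if (is.na(tpl$plus1_base))
    stop("RNA-seq simulation needs a UTR-screen template")
  stopifnot(nchar(barcode) == tpl$barcode_trim)
  tr <- sim$truth
  utr26 <- paste0(tpl$plus1_base, tr$variant)
  cds <- substr(tpl$cds_context, 1L, cds_len)
  with_seed(seed, {
    vi <- sample.int(nrow(tr), depth, replace = TRUE, prob = tr$E)
    off <- sample(c(0L, 1L, 2L), depth, replace = TRUE,
                  prob = c(0.7, 0.2, 0.1))
    l <- tr$tss_length[vi] - off
    paste0(barcode, substr(utr26[vi], 27L - l, 26L), cds)
  })
}

#' Write reads as FASTQ
#'
#' Minimal plain-text FASTQ writer (constant quality) for simulator
#' output; pairs with [read_seq_file()].
#'
#' @param reads character vector of reads.
#' @param path output path (`.fq`/`.fastq`).
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- paste0("@sim", seq_along(reads))
  writeLines(c(rbind(ids, reads, "+", strrep("I", nchar(reads)))), con)
  invisible(path)
}
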