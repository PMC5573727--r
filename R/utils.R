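#' @useDynLib elmseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor dnorm fisher.test lm median predict rnorm
#'   runif sd t.test
#' @importFrom utils head read.delim write.table
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper used throughout the read-processing
#' code; `N` is preserved.
#'
#' @param x character vector of DNA strings (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, NULL), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Split sequences of equal length into an n x L character matrix.
seq_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must all have the same length")
  matrix(unlist(strsplit(seqs, NULL), use.names = FALSE),
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

# Integer-coded (A=1,C=2,G=3,T=4) n x L matrix.
seq_int_matrix <- function(seqs) {
  m <- seq_matrix(seqs)
  im <- match(m, BASES)
  if (anyNA(im)) stop("sequences contain non-ACGT characters")
  matrix(im, nrow = nrow(m), ncol = ncol(m))
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single non-negative integer", name))
  }
}
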