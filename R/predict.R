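# Sequence- and folding-based expression predictors: one-hot encoding,
# Bernoulli naive Bayes, epsilon-SVR, folding-feature selection, AUC.

#' One-hot encode DNA sequences
#'
#' Each base becomes an orthonormal 4-vector — A = (1,0,0,0),
#' C = (0,1,0,0), G = (0,0,1,0), T = (0,0,0,1) — and the per-position
#' vectors are concatenated.
#'
#' @param seqs character vector of equal-length ACGT sequences.
#' @return binary matrix, `length(seqs)` x `4 * L`, columns named
#'   `p<position>_<base>`.
#' @export
one_hot <- function(seqs) {
  im <- seq_int_matrix(seqs)  # errors on non-ACGT
  n <- nrow(im); L <- ncol(im)
  out <- matrix(0L, n, 4L * L,
                dimnames = list(NULL, paste0("p", rep(seq_len(L), each = 4),
                                             "_", rep(BASES, L))))
  for (j in seq_len(L)) out[cbind(seq_len(n), (j - 1L) * 4L + im[, j])] <- 1L
  out
}

#' Decode a one-hot matrix back to sequences
#'
#' @param x a matrix produced by [one_hot()] (extra appended numeric
#'   feature columns are ignored).
#' @return character vector of sequences.
#' @export
one_hot_decode <- function(x) {
  L <- attr(x, "seq_length") %||% (ncol(x) %/% 4L)
  apply(x[, seq_len(4L * L), drop = FALSE], 1, function(r) {
    paste(BASES[apply(matrix(r, nrow = 4L), 2, which.max)], collapse = "")
  })
}

#' Bernoulli naive Bayes classifier for expression class
#'
#' Assumes independent contributions of the binary features (i.e. of the
#' individual bases); per-feature Bernoulli likelihoods with Laplace
#' smoothing 1. Deterministic.
#'
#' @param x binary feature matrix ([one_hot()] output).
#' @param labels class labels: `"high"`/`"low"` (or a logical vector,
#'   `TRUE` = high). Both classes must be present.
#' @return an object of class `elm_nb`.
#' @export
train_nb <- function(x, labels) {
  y <- normalize_labels(labels)
  if (length(unique(y)) < 2L) stop("training set must contain both classes")
  n1 <- sum(y); n0 <- sum(!y)
  p1 <- (colSums(x[y, , drop = FALSE]) + 1) / (n1 + 2)
  p0 <- (colSums(x[!y, , drop = FALSE]) + 1) / (n0 + 2)
  structure(list(log_prior = log(c(low = n0, high = n1) / (n0 + n1)),
                 logp1 = log(p1), log1mp1 = log(1 - p1),
                 logp0 = log(p0), log1mp0 = log(1 - p0),
                 features = colnames(x),
                 event_model = "Bernoulli, Laplace smoothing 1"),
            class = "elm_nb")
}

#' @rdname train_nb
#' @param model a fitted `elm_nb`.
#' @return `predict_nb`: numeric vector of posterior probabilities of the
#'   high class.
#' @export
predict_nb <- function(model, x) {
  stopifnot(inherits(model, "elm_nb"), ncol(x) == length(model$logp1))
  lo_high <- model$log_prior[["high"]] +
    x %*% model$logp1 + (1 - x) %*% model$log1mp1
  lo_low <- model$log_prior[["low"]] +
    x %*% model$logp0 + (1 - x) %*% model$log1mp0
  as.numeric(1 / (1 + exp(lo_low - lo_high)))
}

#' @export
predict.elm_nb <- function(object, newdata, ...) predict_nb(object, newdata)

#' Epsilon-insensitive support vector regression of log10 DAMRatio
#'
#' Radial-basis-function SVR (libsvm via e1071) on the encoded features:
#' deviations inside the epsilon tube are unpenalized, larger ones pay
#' the slack cost C. Defaults: epsilon 0.2, C 1, gamma 1/#features.
#'
#' @param x feature matrix.
#' @param y numeric response (log10 DAMRatio), non-constant, n >= 50.
#' @param epsilon tube half-width (default 0.2).
#' @param C regularization cost (default 1).
#' @param gamma rbf kernel bandwidth (default `1/ncol(x)`).
#' @return an object of class `elm_svr`, with the training-set Pearson r
#'   in `$train_r`.
#' @export
train_svr <- function(x, y, epsilon = 0.2, C = 1.0, gamma = 1 / ncol(x)) {
  if (length(y) < 50L) stop("SVR training needs at least 50 observations")
  if (!all(is.finite(y))) stop("y must be finite")
  if (sd(y) == 0) stop("constant response: nothing to regress")
  stopifnot(epsilon > 0, C > 0)
  fit <- e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                    epsilon = epsilon, cost = C, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, epsilon = epsilon, C = C, gamma = gamma,
                 features = colnames(x),
                 train_r = cor(as.numeric(predict(fit, x)), y)),
            class = "elm_svr")
}

#' @rdname train_svr
#' @param model a fitted `elm_svr`.
#' @return `predict_svr`: numeric vector of predicted log10 DAMRatios.
#' @export
predict_svr <- function(model, x) {
  stopifnot(inherits(model, "elm_svr"))
  if (!is.null(model$features) && !is.null(colnames(x)))
    x <- x[, model$features, drop = FALSE]
  as.numeric(predict(model$fit, x))
}

#' @export
predict.elm_svr <- function(object, newdata, ...) predict_svr(object, newdata)

#' Sequence + folding feature matrix
#'
#' One-hot sequence features with appended window folding energies for
#' exactly those windows whose folding-expression correlation was positive
#' in the training scan (negative- and zero-correlation windows carry no
#' usable signal and only inflate the feature space). Compute the scan on
#' the training split only: the selected window list is frozen into the
#' matrix's metadata.
#'
#' @param variants 25-nt UTR variants.
#' @param fold_scan an [window_scan()] result computed on the training
#'   split.
#' @param template a UTR-screen [elm_template()].
#' @param provider a [fold_provider()].
#' @return feature matrix; `attr(, "windows")` is the selected window
#'   data frame, `attr(, "seq_length")` the sequence length.
#' @export
build_features <- function(variants, fold_scan, template,
                           provider = fold_provider("stub")) {
  x <- one_hot(variants)
  sel <- which(!is.na(fold_scan$r) & fold_scan$r > 0, arr.ind = TRUE)
  if (!nrow(sel)) {
    warning("no window has positive folding-expression correlation; ",
            "using sequence features only")
    attr(x, "windows") <- data.frame(start = integer(), end = integer())
    attr(x, "seq_length") <- nchar(variants[1])
    return(x)
  }
  wins <- data.frame(start = fold_scan$starts[sel[, 1]],
                     end = fold_scan$ends[sel[, 2]])
  mrna <- utr_mrna(variants, template)
  dg <- vapply(seq_len(nrow(wins)), function(k) {
    fold_energy(substr(mrna, pos_to_index(wins$start[k]),
                       pos_to_index(wins$end[k])), provider)
  }, numeric(length(variants)))
  dg <- matrix(dg, ncol = nrow(wins),
               dimnames = list(NULL, paste0("dG_", wins$start, "_", wins$end)))
  out <- cbind(x, dg)
  attr(out, "windows") <- wins
  attr(out, "seq_length") <- nchar(variants[1])
  out
}

#' Area under the ROC curve
#'
#' Rank-based (Mann–Whitney) AUC; tied scores contribute 1/2.
#'
#' @param labels class labels (`"high"`/`"low"` or logical, `TRUE` = high).
#' @param scores numeric scores, higher = more high-class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  y <- normalize_labels(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  u <- unique(labels)
  if (!all(u %in% c("high", "low")))
    stop("labels must be 'high'/'low' or logical")
  labels == "high"
}
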