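# Gaussian-mixture modelling of log10 DAMRatio distributions: fitting,
# left-most-peak standardization, and high/low-productive classification.

#' Fit a univariate Gaussian mixture to log10 DAMRatios
#'
#' EM fit with k-means++ initialization, multiple restarts (best
#' log-likelihood kept) and BIC model selection between 2 and 3 components
#' when `K = "auto"`. Components are reported sorted by mean; the left-most
#' component is the "low-productive" peak and its mean is the
#' standardization shift, the right-most is the "high-productive" peak.
#'
#' @param values numeric vector of log10 DAMRatios (>= 200 values).
#' @param K `"auto"` (BIC over 2 and 3), or 2, or 3.
#' @param seed RNG seed for the restarts (recorded in the fit).
#' @param restarts number of EM restarts per K (default 20).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter EM iteration cap (default 500).
#' @return an object of class `elm_mixture` with elements `K`, `weights`,
#'   `means`, `sds`, `shift`, `loglik`, `bic` (named vector over candidate
#'   K), `seed`, `n`.
#' @export
fit_mixture <- function(values, K = "auto", seed = 1L, restarts = 20L,
                        tol = 1e-6, max_iter = 500L) {
  if (any(!is.finite(values))) stop("values must all be finite")
  if (length(values) < 200L) stop("need at least 200 values to fit a mixture")
  if (sd(values) < 1e-8) stop("degenerate input: values have zero variance")
  Ks <- if (identical(K, "auto")) c(2L, 3L) else as.integer(K)
  if (!all(Ks %in% 2:3)) stop("K must be 'auto', 2 or 3")

  fits <- with_seed(seed, lapply(Ks, function(k) {
    best <- NULL
    for (r in seq_len(restarts)) {
      f <- tryCatch(em_gmm1d(values, k, tol, max_iter), error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$loglik > best$loglik)) best <- f
    }
    if (is.null(best)) stop("EM failed for K = ", k)
    best
  }))
  bic <- vapply(seq_along(Ks), function(i) {
    p <- 3L * length(fits[[i]]$means) - 1L
    -2 * fits[[i]]$loglik + p * log(length(values))
  }, numeric(1))
  names(bic) <- paste0("K", Ks)
  pick <- which.min(bic)
  f <- fits[[pick]]
  structure(list(K = length(f$means), weights = f$weights, means = f$means,
                 sds = f$sds, shift = f$means[1], loglik = f$loglik,
                 bic = bic, seed = seed, n = length(values)),
            class = "elm_mixture")
}

# One EM run for a K-component univariate Gaussian mixture; components are
# returned sorted by mean. Components collapsing below sd 1e-4 are pruned
# with a warning.
em_gmm1d <- function(x, k, tol, max_iter) {
  n <- length(x)
  mu <- kmeanspp_centers(x, k)
  cl <- apply(abs(outer(x, mu, "-")), 1, which.min)
  w <- tabulate(cl, k) / n
  s <- vapply(seq_len(k), function(j) {
    xi <- x[cl == j]
    max(sd(xi), sd(x) / (2 * k), 1e-3, na.rm = TRUE)
  }, numeric(1))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], s[j]),
                   numeric(n))
    rowsum_d <- rowSums(dens)
    ll <- sum(log(pmax(rowsum_d, .Machine$double.xmin)))
    resp <- dens / pmax(rowsum_d, .Machine$double.xmin)
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    s <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    if (any(!is.finite(s)) || any(s < 1e-4)) {
      keep <- is.finite(s) & s >= 1e-4
      if (sum(keep) < 2L) stop("mixture collapsed to fewer than 2 components")
      warning("pruned degenerate mixture component (sd < 1e-4)")
      return(em_gmm1d_fixed(x, mu[keep], s[keep], w[keep] / sum(w[keep]),
                            tol, max_iter))
    }
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  o <- order(mu)
  list(weights = w[o], means = mu[o], sds = s[o], loglik = ll)
}

# Continue EM from given parameters (used after pruning a component).
em_gmm1d_fixed <- function(x, mu, s, w, tol, max_iter) {
  n <- length(x); k <- length(mu); ll_old <- -Inf; ll <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], s[j]),
                   numeric(n))
    rowsum_d <- pmax(rowSums(dens), .Machine$double.xmin)
    ll <- sum(log(rowsum_d))
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    s <- pmax(sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk), 1e-4)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  o <- order(mu)
  list(weights = w[o], means = mu[o], sds = s[o], loglik = ll)
}

# k-means++ seeding in 1-D: first center uniform, later centers with
# probability proportional to squared distance from the nearest center.
kmeanspp_centers <- function(x, k) {
  centers <- x[sample.int(length(x), 1L)]
  d2 <- (x - centers)^2
  while (length(centers) < k) {
    new <- if (sum(d2) == 0) x[sample.int(length(x), 1L)] else
      x[sample.int(length(x), 1L, prob = d2)]
    centers <- c(centers, new)
    d2 <- pmin(d2, (x - new)^2)
  }
  sort(centers)
}

#' Standardize values by the left-most mixture peak
#'
#' Subtracts the fitted mean of the left-most (low-productive) component,
#' so that after standardization the low peak sits exactly at zero and
#' screens become comparable.
#'
#' @param values numeric vector.
#' @param fit an [fit_mixture()] result.
#' @return shifted values, same order.
#' @export
standardize <- function(values, fit) {
  stopifnot(inherits(fit, "elm_mixture"))
  values - fit$shift
}

#' Classify variants as high- or low-productive
#'
#' Posterior comparison between the right-most ("high") and left-most
#' ("low") mixture components: a variant is labeled high iff its posterior
#' under the high component exceeds its posterior under the low component
#' (ties go to low). With K = 3 the middle component's mass is reported but
#' never labels a variant.
#'
#' @param values numeric vector of log10 DAMRatios on the fit's scale.
#' @param fit an [fit_mixture()] result.
#' @return data frame with `value`, `posterior_low`, `posterior_high`,
#'   optionally `posterior_mid`, and `label` (`"high"`/`"low"`).
#' @export
classify <- function(values, fit) {
  stopifnot(inherits(fit, "elm_mixture"))
  k <- fit$K
  dens <- vapply(seq_len(k), function(j) {
    fit$weights[j] * dnorm(values, fit$means[j], fit$sds[j])
  }, numeric(length(values)))
  dens <- matrix(dens, ncol = k)
  resp <- dens / pmax(rowSums(dens), .Machine$double.xmin)
  out <- data.frame(value = values,
                    posterior_low = resp[, 1],
                    posterior_high = resp[, k])
  if (k == 3L) out$posterior_mid <- resp[, 2]
  out$label <- ifelse(out$posterior_high > out$posterior_low, "high", "low")
  out
}

#' @export
predict.elm_mixture <- function(object, newdata, ...) classify(newdata, object)

#' @export
print.elm_mixture <- function(x, ...) {
  cat("Gaussian mixture over log10 DAMRatio (", x$n, " values)\n", sep = "")
  cat("  K =", x$K, "| BIC:", paste(names(x$bic), round(x$bic, 1),
                                    collapse = "  "), "\n")
  comp <- data.frame(weight = round(x$weights, 4),
                     mean = round(x$means, 4), sd = round(x$sds, 4))
  rownames(comp) <- c("low", if (x$K == 3) "mid", "high")
  print(comp)
  cat("  standardization shift (left-most mean):", round(x$shift, 4), "\n")
  invisible(x)
}
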