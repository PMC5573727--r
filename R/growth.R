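# Plate-reader growth quantification: early and late slopes of the
# growth-index curve (absorbance ratio 430/560 nm).

# Pairwise slopes between points `gap` measurements apart, then the
# maximum over sliding windows of `window` consecutive slopes (step 1,
# incomplete edge windows dropped) of the window median.
max_median_slope <- function(time, value, gap, window) {
  stopifnot(length(time) == length(value))
  if (is.unsorted(time, strictly = TRUE))
    stop("time points must be strictly increasing")
  n <- length(time)
  ns <- n - gap
  if (ns < window)
    stop("too few points: need at least ", window + gap,
         " (have ", n, ")")
  i <- seq_len(ns)
  s <- (value[i] - value[i + gap]) / (time[i] - time[i + gap])
  max(vapply(seq_len(ns - window + 1L), function(w) {
    median(s[w:(w + window - 1L)])
  }, numeric(1)))
}

#' Early growth slope
#'
#' Slopes between measurements three time points apart, restricted to the
#' early-growth interval (default 10-30 h), summarized as the maximum over
#' sliding 30-slope windows of the window median. Units: growth index per
#' hour.
#'
#' @param time time points in hours, strictly increasing.
#' @param value growth-index values (dimensionless 430/560 absorbance
#'   ratio).
#' @param interval time interval (h) used for the early slope; `NULL`
#'   disables the restriction.
#' @param window window length in slopes (default 30).
#' @return numeric scalar.
#' @export
early_slope <- function(time, value, interval = c(10, 30), window = 30L) {
  if (!is.null(interval)) {
    keep <- time >= interval[1] & time <= interval[2]
    time <- time[keep]; value <- value[keep]
  }
  max_median_slope(time, value, gap = 3L, window = window)
}

#' Late growth slope
#'
#' As [early_slope()] but with a four-measurement gap over the whole
#' curve; reflects late metabolic activity rather than early growth.
#'
#' @inheritParams early_slope
#' @return numeric scalar.
#' @export
late_slope <- function(time, value, window = 30L) {
  max_median_slope(time, value, gap = 4L, window = window)
}
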