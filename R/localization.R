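## Histogram-based nuclear-localization scoring.
##
## When a tagged transcription factor moves into the nucleus its total
## cellular amount is unchanged but it becomes locally concentrated, so the
## pixel-intensity histogram of the cell grows an upper tail. The score
## quantifies that tail: pool pre-starvation pixels into a reference, record
## the q-quantile of the median-normalized reference, and report how much
## probability mass of a (median-normalized) test frame exceeds that
## threshold beyond the (1 - q) expected under the reference. Per-frame
## median normalization makes the score invariant to overall expression or
## illumination scale.

.validate_frame <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("image frame must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(frame)) || any(frame < 0))
    stop("pixel intensities must be finite and nonnegative", call. = FALSE)
  invisible(frame)
}

## Otsu two-class cutoff, keeping the brighter class. The threshold is
## computed on the intensity range of the frame itself, so it scales with
## the frame (scale equivariance -> score scale invariance).
.otsu_cutoff <- function(frame) {
  rng <- range(frame)
  if (diff(rng) == 0) return(rng[1] - 1)   # uniform frame: keep everything
  x01 <- (frame - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(x01), range = c(0, 1), levels = 256L)
  rng[1] + th * diff(rng)
}

## pixels entering the histogram: mask pixels if a mask is given, otherwise
## the brighter Otsu class (background must not dilute the tail)
.included_pixels <- function(frame, mask = NULL) {
  .validate_frame(frame)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(frame)))
      stop("mask dimensions must match the frame", call. = FALSE)
    return(frame[mask > 0])
  }
  frame[frame > .otsu_cutoff(frame)]
}

#' Build a pre-starvation reference histogram model
#'
#' Pools the included pixels of one or more pre-starvation frames (mask
#' pixels when masks are given, otherwise the brighter Otsu class of each
#' frame), normalizes them by their pooled median, and stores the
#' q-quantile of the normalized sample as the tail threshold against which
#' later frames are scored.
#'
#' @param frames A numeric matrix or list of numeric matrices
#'   (nonnegative pixel intensities).
#' @param q Tail quantile in `(0.5, 1)`; default 0.995.
#' @param masks Optional mask matrix or list of mask matrices (same shapes
#'   as `frames`; nonzero = include).
#' @param min_pixels Minimum included pixels required per frame.
#' @return An object of class `pho4_reference` with elements `sample`
#'   (sorted normalized pixels), `median`, `q` and `t_q`.
#' @export
build_reference <- function(frames, q = 0.995, masks = NULL,
                            min_pixels = 1000L) {
  if (is.matrix(frames)) frames <- list(frames)
  if (!length(frames)) stop("need at least one frame", call. = FALSE)
  if (is.matrix(masks)) masks <- list(masks)
  if (!is.null(masks) && length(masks) != length(frames))
    stop("need one mask per frame", call. = FALSE)
  if (q <= 0.5 || q >= 1)
    stop("'q' must be in (0.5, 1)", call. = FALSE)
  px <- unlist(lapply(seq_along(frames), function(i) {
    v <- .included_pixels(frames[[i]], if (is.null(masks)) NULL else masks[[i]])
    if (length(v) < min_pixels)
      stop("frame ", i, " contributes fewer than ", min_pixels,
           " included pixels", call. = FALSE)
    v
  }))
  med <- stats::median(px)
  if (med <= 0) stop("median of included pixels is zero", call. = FALSE)
  s <- sort(px / med)
  ## type-1 (inverse empirical CDF) quantile: the fraction of the pooled
  ## sample strictly above t_q is then as close as possible to 1 - q
  t_q <- unname(stats::quantile(s, q, type = 1))
  structure(list(sample = s, median = med, q = q, t_q = t_q),
            class = "pho4_reference")
}

#' @export
print.pho4_reference <- function(x, ...) {
  cat(sprintf(
    "Pre-starvation reference: %d pooled pixels, median %.4g, t_%.3f = %.4f\n",
    length(x$sample), x$median, x$q, x$t_q))
  invisible(x)
}

#' Nuclear-localization score of an image frame
#'
#' Normalizes the frame's included pixels by their own median and returns
#' the probability mass above the reference tail threshold in excess of the
#' expectation under the reference:
#' `score = P(pixel / median > t_q) - (1 - q)`.
#' Zero means the frame is indistinguishable from the pre-starvation
#' reference; positive values mean more high-intensity pixels, i.e. more
#' nuclear concentration. Small negative values can occur under sampling
#' noise. The score is invariant to multiplying the frame by any positive
#' constant.
#'
#' @param frame Numeric matrix of nonnegative pixel intensities.
#' @param ref A [build_reference()] object.
#' @param mask Optional mask (same inclusion rule as the reference).
#' @param min_pixels Minimum included pixels required.
#' @return A single numeric score in `[-(1 - q), 1]`.
#' @export
localization_score <- function(frame, ref, mask = NULL, min_pixels = 1000L) {
  stopifnot(inherits(ref, "pho4_reference"))
  v <- .included_pixels(frame, mask)
  if (length(v) < min_pixels)
    stop("fewer than ", min_pixels, " included pixels", call. = FALSE)
  med <- stats::median(v)
  if (med <= 0) stop("median of included pixels is zero", call. = FALSE)
  mean(v / med > ref$t_q) - (1 - ref$q)
}

#' Score a time series of frames
#'
#' Applies [localization_score()] to each frame of a time-lapse stack. The
#' map is purely per-frame (stateless), so frame order only affects row
#' order.
#'
#' @param frames List of numeric matrices.
#' @param times Strictly increasing numeric timestamps, one per frame.
#' @param ref A [build_reference()] object.
#' @param masks Optional list of masks, one per frame.
#' @inheritParams localization_score
#' @return A `data.frame` with columns `time`, `score`, `n_pixels`.
#' @export
score_timeseries <- function(frames, times, ref, masks = NULL,
                             min_pixels = 1000L) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(times) == length(frames))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (!is.null(masks) && length(masks) != length(frames))
    stop("need one mask per frame", call. = FALSE)
  sc <- vapply(seq_along(frames), function(i) {
    m <- if (is.null(masks)) NULL else masks[[i]]
    c(localization_score(frames[[i]], ref, m, min_pixels),
      length(.included_pixels(frames[[i]], m)))
  }, numeric(2))
  data.frame(time = times, score = sc[1, ], n_pixels = as.integer(sc[2, ]))
}

#' Steady-state localization score
#'
#' Mean and standard error of the localization scores inside a time
#' window.
#'
#' @param series A `data.frame` with columns `time` and `score`, as from
#'   [score_timeseries()].
#' @param window Numeric length-2 time range `c(from, to)` (inclusive).
#' @return A list with `mean`, `se` and `n` (frames in the window).
#' @export
steady_state_score <- function(series, window = range(series$time)) {
  stopifnot(is.data.frame(series), all(c("time", "score") %in% names(series)),
            length(window) == 2L)
  sel <- series$score[series$time >= window[1] & series$time <= window[2]]
  if (length(sel) < 3L)
    stop("need at least 3 frames in the window", call. = FALSE)
  list(mean = mean(sel), se = stats::sd(sel) / sqrt(length(sel)),
       n = length(sel))
}

#' Median intensity of activated cells
#'
#' Median of the per-cell intensities that exceed a threshold, restricting
#' the statistic to the activated subpopulation (in a bimodal population
#' the plain median sits between the modes and tracks neither). Returns
#' `NA` when no cell exceeds the threshold.
#'
#' @param values Non-empty numeric vector of per-cell intensities.
#' @param threshold Activation threshold.
#' @return The activated-subpopulation median, or `NA_real_`.
#' @examples
#' activated_median(c(1, 2, 3), 10)    # NA: nobody activated
#' activated_median(c(1, 2, 3), -Inf)  # 2: plain median
#' @export
activated_median <- function(values, threshold) {
  if (!length(values) || !is.numeric(values))
    stop("'values' must be a non-empty numeric vector", call. = FALSE)
  act <- values[values > threshold]
  if (!length(act)) return(NA_real_)
  stats::median(act)
}
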