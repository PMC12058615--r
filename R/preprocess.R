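#' Subtract the best-fit plane from a frame
#'
#' Least-squares plane over all pixels, then a median shift so the output
#' background sits at 0 nm. Removes sample tilt before particle detection.
#'
#' @param frame a [scan_frame].
#' @return A leveled [scan_frame] with identical geometry and timestamp.
#' @export
level_plane <- function(frame) {
  stopifnot(inherits(frame, "scan_frame"))
  h <- frame$heights
  nr <- nrow(h); nc <- ncol(h)
  xy <- pixel_coords(frame)
  X <- xy$x[col(h)]
  Y <- xy$y[row(h)]
  fit <- stats::lm.fit(cbind(1, as.numeric(X), as.numeric(Y)), as.numeric(h))
  res <- matrix(fit$residuals, nr, nc)
  res <- res - stats::median(res)
  out <- frame
  out$heights <- res
  out
}

#' Per-scan-line flattening
#'
#' Removes per-line offsets and (for `order >= 1`) per-line polynomial
#' background, robustly at any surface coverage. Offsets are first
#' estimated from the median of adjacent-line differences and removed
#' cumulatively: adjacent scan lines image nearly the same topography, so
#' the differential median isolates the scan-line offset even on closed
#' monolayers. Because cumulative alignment performs a random walk under
#' pixel noise, each line is then re-anchored on the weighted mean of its
#' background pixels, with smooth global weights (logistic taper around
#' the frame's median + 1 MAD): the weights select the same height class
#' on every line, which is what a line-by-line background mask fails to do
#' once most of a line is covered. Lines with essentially no background
#' keep the differential alignment only. For `order >= 1` the non-constant
#' polynomial terms are fitted per line under the same weights. The whole
#' cycle is iterated to a fixed point, making the operation idempotent to
#' well below 1e-6 nm.
#'
#' @param frame a [scan_frame].
#' @param order polynomial order per line: 0 (offsets only), 1 or 2.
#' @return A flattened [scan_frame]; geometry and timestamp unchanged.
#' @export
flatten_lines <- function(frame, order = 1L) {
  stopifnot(inherits(frame, "scan_frame"))
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  h <- frame$heights
  nr <- nrow(h); nc <- ncol(h)
  x <- seq_len(nc) / nc  # scaled abscissa, conditioning
  P <- if (order >= 1)
    stats::poly(x, degree = order, raw = FALSE)[, seq_len(order),
                                                drop = FALSE] else NULL

  bg_weights <- function(h) {
    med <- stats::median(h); madv <- stats::mad(h)
    # floor the scale so an (almost) flat frame gets uniform weights
    # instead of classifying rounding dust
    madv <- max(madv, 1e-9 * max(abs(h - med)), 1e-12)
    1 / (1 + exp(pmin(pmax((h - (med + madv)) / (0.2 * madv), -40), 40)))
  }

  off_active <- TRUE
  for (it in 1:60) {
    adj <- 0
    if (off_active) {
      # differential alignment runs once: it fixes gross offsets on lines
      # with no usable background; afterwards the background anchor owns
      # line levels (iterating both would have them fight over the anchor)
      delta <- vapply(seq_len(nr - 1), function(i)
        stats::median(h[i + 1, ] - h[i, ]), numeric(1))
      off <- c(0, cumsum(delta))
      h <- h - off
      adj <- max(abs(off - mean(off)))
      off_active <- FALSE
    }

    W <- bg_weights(h)
    wsum <- rowSums(W)
    ok <- wsum > max(order + 2, nc / 20)

    # re-anchor lines on their background level (kills alignment drift)
    m <- rowSums(W * h) / wsum
    m[!ok | !is.finite(m)] <- 0
    h <- h - m
    adj <- max(adj, max(abs(m)))

    if (order >= 1) {
      if (order == 1L) {
        # closed-form weighted fit of (intercept, slope) per row,
        # vectorized over rows; only the slope term is subtracted
        p <- P[, 1]
        Sw <- wsum
        Swp <- W %*% p
        Swpp <- W %*% p^2
        Swh <- rowSums(W * h)
        Swph <- (W * h) %*% p
        det <- Sw * Swpp - Swp^2
        b <- drop((Sw * Swph - Swp * Swh) / det)
        b[!ok | !is.finite(b)] <- 0
        h <- h - outer(b, p)
        adj <- max(adj, max(abs(b)) * max(abs(p)))
      } else {
        X <- cbind(rep(1, nc), P)
        for (i in which(ok)) {
          fit <- stats::lm.wfit(X, h[i, ], W[i, ])
          co <- fit$coefficients; co[1] <- 0
          corr <- drop(X %*% co)
          h[i, ] <- h[i, ] - corr
          adj <- max(adj, max(abs(corr)))
        }
      }
    }
    if (adj < 5e-8) break
  }
  out <- frame
  out$heights <- h
  out
}
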