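#' Zero-phase IIR filtering with steady-state initial conditions
#'
#' Applies an IIR filter forward and backward so the net phase response is
#' zero, the way biosignal pipelines align filtered streams with event
#' timestamps. The series is extended at both ends by odd reflection and each
#' pass is started from the filter's steady state for the first sample, so a
#' constant input is reproduced exactly and edge transients decay inside the
#' padding rather than inside the data.
#'
#' @param filt a filter as returned by [signal::butter()] (list with `b`, `a`).
#' @param x numeric series.
#' @param pad reflection padding length in samples; choose several filter time
#'   constants (roughly `10 * rate / fc` for a cutoff `fc`). Capped at
#'   `length(x) - 1`.
#' @return filtered series, same length as `x`.
#' @keywords internal
zero_phase_filter <- function(filt, x, pad = 0L) {
  b <- filt$b
  a <- filt$a
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  n <- length(x)
  if (n <= nfilt * 3L) {
    stop("series too short to filter (", n, " samples)")
  }
  nfact <- min(n - 1L, max(3L * (nfilt - 1L), as.integer(pad)))
  dc_gain <- sum(b) / sum(a)
  run <- function(z) {
    signal::filter(b, a, z,
      init.x = rep(z[1L], nfilt - 1L),
      init.y = rep(z[1L] * dc_gain, nfilt - 1L)
    )
  }
  xp <- c(2 * x[1L] - x[(nfact + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - nfact)])
  y <- run(xp)
  y <- rev(run(rev(y)))
  as.numeric(y[(nfact + 1L):(nfact + n)])
}

#' Centered moving average with shrinking edge windows
#'
#' O(n) cumulative-sum implementation of a centered moving mean. At the edges
#' the window shrinks to the available samples instead of padding, so constant
#' series are reproduced exactly everywhere.
#'
#' @param x numeric series.
#' @param width window width in samples; forced odd (incremented when even) so
#'   the window is symmetric around each sample.
#' @return smoothed series, same length as `x`.
#' @keywords internal
moving_mean <- function(x, width) {
  width <- as.integer(width)
  if (width < 1L) stop("window must span at least one sample")
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(x)
  half <- (width - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  idx <- seq_len(n)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
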