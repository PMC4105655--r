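# internal numerical helpers

nextPow2 <- function(n) 2^ceiling(log2(max(n, 1)))

# full linear convolution via FFT; agrees with direct convolution to
# ~1e-9 relative on short inputs (see tests)
fftConvolve <- function(a, b) {
  n <- length(a) + length(b) - 1L
  nf <- nextPow2(n)
  A <- stats::fft(c(a, rep(0, nf - length(a))))
  B <- stats::fft(c(b, rep(0, nf - length(b))))
  Re(stats::fft(A * B, inverse = TRUE))[seq_len(n)] / nf
}

# short-time RMS envelope (moving average of x^2 over `win` samples)
movingRms <- function(x, win) {
  win <- max(3L, as.integer(win))
  if (win %% 2 == 0) win <- win + 1L
  e <- stats::filter(x^2, rep(1 / win, win), sides = 2)
  e[is.na(e)] <- 0
  sqrt(pmax(as.numeric(e), 0))
}

# local maxima with prominence, on a plain numeric vector.
# Returns data.frame(index, value, prominence).  Plateaus count once
# (their first index).  Prominence of a peak is its height above the
# higher of the two deepest valleys separating it from higher terrain.
peaksWithProminence <- function(y) {
  n <- length(y)
  # collapse exact plateaus so ties register as single peaks
  idx <- integer()
  plateau <- logical()
  i <- 2L
  while (i < n) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1]) {
      j <- i
      while (j < n && y[j + 1] == y[i]) j <- j + 1L
      if (j == n || y[j + 1] < y[i]) {
        idx <- c(idx, i)
        plateau <- c(plateau, j > i)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(idx))
    return(data.frame(index = integer(), value = numeric(),
                      prominence = numeric(), plateau = logical()))
  prom <- vapply(idx, function(p) {
    h <- y[p]
    left <- y[seq_len(p)]
    hi <- which(left > h)
    lmin <- if (length(hi)) min(left[max(hi):p]) else min(left)
    right <- y[p:n]
    hi <- which(right > h)
    rmin <- if (length(hi)) min(right[1:min(hi)]) else min(right)
    h - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = idx, value = y[idx], prominence = prom,
             plateau = plateau)
}

# linear interpolation with constant extrapolation at both ends
interpHold <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

# realise a transfer function magnitude as a linear-phase FIR at rate fs
tfToFir <- function(tf, fs, n = 1024) {
  if (fs < 2 * max(tf@freq))
    stop("fs must be at least twice the highest grid frequency (",
         max(tf@freq), " Hz)")
  mag <- 10^(magnitudeDb(tf) / 20)
  fgrid <- seq(0, fs / 2, length.out = 257)
  m <- interpHold(tf@freq, mag, fgrid)
  as.numeric(signal::fir2(n, fgrid / (fs / 2), m))
}
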