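#' @include ic-model.R
NULL

#' Welch power spectral density of an IC source signal
#'
#' Averaged modified periodogram with Hann-windowed segments of one second
#' (or the full epoch, if shorter), 50\% overlap and per-segment mean
#' removal. Epoched signals are segmented within each epoch and all
#' segments pooled, so the estimate is the across-epoch average. Scaling is
#' one-sided density: the integral of the PSD over frequency approximates
#' the signal variance (Parseval).
#'
#' @param x an \linkS4class{ICComponent}, or a numeric epochs x samples
#'   matrix (then \code{fs} is required).
#' @param fs sampling rate in Hz (taken from the component if omitted).
#' @param segSeconds segment length in seconds (default 1; frequency
#'   resolution is \code{1/segSeconds} Hz).
#' @return list with \code{freq} (Hz, 0..Nyquist) and \code{psd}
#'   (density, units^2/Hz).
#' @examples
#' ic <- ICComponent("a", "s", "Cz", 1, matrix(rnorm(2500), 10, 250), 250)
#' p <- welchPSD(ic)
#' sum(p$psd) * (p$freq[2] - p$freq[1])  # ~ var(signal)
#' @export
welchPSD <- function(x, fs = NULL, segSeconds = 1) {
  if (is(x, "ICComponent")) {
    if (is.null(fs)) fs <- samplingRate(x)
    x <- epochView(x)
  }
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  stopifnot(is.numeric(fs), fs > 0, ncol(x) >= 2L)
  n <- ncol(x)
  L <- min(n, max(8L, round(fs * segSeconds)))
  step <- max(1L, floor(L / 2L))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0L, L - 1L) / (L - 1L))
  ## segment matrix: L x (nStarts * nEpochs), demeaned and windowed
  seg <- matrix(0, L, length(starts) * nrow(x))
  k <- 0L
  for (s in starts) {
    blk <- t(x[, s:(s + L - 1L), drop = FALSE])
    blk <- sweep(blk, 2L, colMeans(blk))
    seg[, k + seq_len(ncol(blk))] <- blk
    k <- k + ncol(blk)
  }
  pw <- Mod(stats::mvfft(seg * w))^2
  nF <- floor(L / 2) + 1L
  pxx <- rowMeans(pw[seq_len(nF), , drop = FALSE]) / (fs * sum(w^2))
  ## one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, nF); dbl[1L] <- 1
  if (L %% 2 == 0) dbl[nF] <- 1
  list(freq = seq(0L, nF - 1L) * fs / L, psd = pxx * dbl)
}
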