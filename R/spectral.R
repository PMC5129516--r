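## Composite Fourier spectrum of lifelines: a diagnostic evaluated
## and then set aside in favour of the time-domain regime analysis --
## broadly distributed circulation times leave no dominant frequency
## to read off.

#' Composite Fourier spectrum of a lifeline set
#'
#' Per lifeline: subtract the series mean, taper with a Blackman
#' window, take the discrete Fourier transform, and keep the
#' one-sided magnitude; the per-track magnitude spectra are then
#' summed across lifelines (unnormalized, matching the qualitative
#' use of this diagnostic). Adding a constant to any track leaves the
#' result unchanged, and the composite of a set equals the sum of the
#' composites of its parts.
#'
#' @param lifelines a \linkS4class{LifelineSet} with at least 2
#'   timepoints on a uniform grid
#' @param chunk number of lifelines transformed per block (bounds the
#'   complex workspace)
#' @return data.frame with columns \code{frequency} (Hz) and
#'   \code{magnitude} (summed |DFT|)
#' @examples
#' t <- seq(0, 30, by = 0.03)
#' ll <- LifelineSet(matrix(0.5 + 0.2 * sin(2 * pi * 0.8 * t), 1), t)
#' sp <- compositeSpectrum(ll)
#' sp$frequency[which.max(sp$magnitude)]  # ~0.8 Hz
#' @export
compositeSpectrum <- function(lifelines, chunk = 256L) {
  stopifnot(is(lifelines, "LifelineSet"))
  q <- qsFrac(lifelines)
  n <- ncol(q)
  if (n < 2L) stop("need at least 2 samples per lifeline")
  dt <- timeStep(lifelines)
  w <- signal::blackman(n)
  n_keep <- n %/% 2L + 1L
  total <- numeric(n_keep)
  for (lo in seq(1L, nrow(q), by = chunk)) {
    hi <- min(lo + chunk - 1L, nrow(q))
    block <- q[lo:hi, , drop = FALSE]
    block <- (block - rowMeans(block)) * rep(w, each = nrow(block))
    sp <- Mod(stats::mvfft(t(block)))[seq_len(n_keep), , drop = FALSE]
    total <- total + rowSums(sp)
  }
  data.frame(frequency = (seq_len(n_keep) - 1L) / (n * dt),
             magnitude = total)
}
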