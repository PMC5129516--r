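## Turbulence filtering of lifelines prior to regime analysis:
## (1) nondimensionalize with qs_max, (2) centered moving-average
## smoothing, (3) removal of rapid low-amplitude boundary crossings.
## Smoothing always precedes amplitude filtering.

#' Normalize lifelines to qs/qs_max
#'
#' Converts lifelines stored as raw uptake rates (mol_s/Cmol_x/s) or
#' substrate concentrations (mol/kg, mapped through the Monod
#' relation) to the dimensionless qs/qs_max scale used by all
#' downstream analyses. Idempotent on already-normalized input. The
#' interpretation of stored values is taken from
#' \code{metadata()$value_type} ("qs_frac", "qs" or "Cs";
#' missing means already normalized).
#'
#' @param lifelines a \linkS4class{LifelineSet}
#' @param params a \linkS4class{KineticParameters}
#' @return a normalized \linkS4class{LifelineSet}
#' @export
normalizeLifelines <- function(lifelines, params) {
  stopifnot(is(lifelines, "LifelineSet"))
  md <- metadata(lifelines)
  type <- md$value_type
  if (is.null(type)) type <- "qs_frac"
  if (type == "qs_frac") return(lifelines)
  q <- qsFrac(lifelines)
  q <- switch(type,
    qs = q / params@qs_max,
    Cs = uptakeRate(q, params) / params@qs_max,
    stop("unknown value_type: ", type))
  md$value_type <- "qs_frac"
  md$provenance <- c(md$provenance, paste0("normalize[from=", type, "]"))
  LifelineSet(q, lifelineTimes(lifelines),
              particle_id = particleIds(lifelines), metadata = md)
}

## centered moving average with shrinking windows at the edges,
## O(n) via cumulative sums; no padding values are invented
.moving_average <- function(x, half) {
  if (half == 0L) return(x)
  n <- length(x)
  cs <- cumsum(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

#' Moving-average smoothing of lifelines
#'
#' Centered moving average with the window rounded to the nearest odd
#' sample count; edge samples use symmetric shrinking windows (the
#' average runs over the available samples only). The default window
#' of 0.45 s (15 samples at the default 0.03 s sampling) is of the
#' order of the substrate consumption timescale, so metabolically
#' relevant excursions survive while turbulent jitter is averaged
#' out.
#'
#' @param lifelines a \linkS4class{LifelineSet}
#' @param window smoothing window length in seconds (>= dt)
#' @return a smoothed \linkS4class{LifelineSet}
#' @export
smoothLifelines <- function(lifelines, window = 0.45) {
  stopifnot(is(lifelines, "LifelineSet"))
  dt <- timeStep(lifelines)
  if (window < dt) stop("'window' must be at least one sampling interval")
  k <- max(1L, round(window / dt))
  if (k %% 2L == 0L) k <- k + 1L          # nearest odd sample count
  half <- (k - 1L) %/% 2L
  q <- qsFrac(lifelines)
  if (half > 0L) {
    for (i in seq_len(nrow(q))) q[i, ] <- .moving_average(q[i, ], half)
    q <- pmin(pmax(q, 0), 1)   # clamp cumsum round-off back into range
  }
  md <- metadata(lifelines)
  md$provenance <- c(md$provenance,
                     sprintf("smooth[window=%gs,samples=%d]", window, k))
  md$filter <- c(md$filter, list(smooth_window_s = window, smooth_samples = k))
  LifelineSet(q, lifelineTimes(lifelines),
              particle_id = particleIds(lifelines), metadata = md)
}

## pin sub-threshold excursions beyond `bound` back to the boundary.
## `above`: TRUE for the excess boundary (x > bound), FALSE for the
## starvation boundary (x < bound).
.pin_excursions <- function(x, bound, delta, above) {
  beyond <- if (above) x > bound else x < bound
  if (!any(beyond)) return(x)
  r <- rle(beyond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    depth <- if (above) max(x[seg]) - bound else bound - min(x[seg])
    if (depth < delta) x[seg] <- bound
  }
  x
}

#' Low-amplitude crossing filter
#'
#' Removes regime-boundary crossings whose excursion beyond the
#' crossed boundary has a peak depth smaller than \code{delta}: the
#' offending samples are pinned at the boundary value, so the
#' sub-threshold regime visit disappears while every deeper crossing
#' is left untouched. This suppresses rapid, low-amplitude
#' oscillations across the 0.05/0.95 boundaries that would otherwise
#' flood the residence-time statistics with spurious short visits.
#'
#' @param lifelines a \linkS4class{LifelineSet} (normalized, and
#'   typically smoothed first)
#' @param delta minimum excursion depth to keep, in qs/qs_max units
#'   (0 < delta < 0.5). Note the geometry of the normalized scale:
#'   the deepest possible excursion beyond either boundary is 0.05
#'   (the distance to saturation/zero), so thresholds of 0.05 or more
#'   delete essentially every excess and starvation visit. The
#'   default 0.02 sits above the residual turbulence amplitude that
#'   survives the default smoothing while leaving genuine regime
#'   visits intact.
#' @param boundaries the two regime boundaries (default 0.05 and
#'   0.95)
#' @return a filtered \linkS4class{LifelineSet}
#' @export
amplitudeFilter <- function(lifelines, delta = 0.02,
                            boundaries = c(0.05, 0.95)) {
  stopifnot(is(lifelines, "LifelineSet"))
  if (!(delta > 0 && delta < 0.5))
    stop("'delta' must lie in (0, 0.5)")
  lo <- min(boundaries)
  hi <- max(boundaries)
  q <- qsFrac(lifelines)
  for (i in seq_len(nrow(q))) {
    q[i, ] <- .pin_excursions(q[i, ], hi, delta, above = TRUE)
    q[i, ] <- .pin_excursions(q[i, ], lo, delta, above = FALSE)
  }
  md <- metadata(lifelines)
  md$provenance <- c(md$provenance, sprintf("amplitude_filter[delta=%g]", delta))
  md$filter <- c(md$filter, list(delta = delta, boundaries = c(lo, hi)))
  LifelineSet(q, lifelineTimes(lifelines),
              particle_id = particleIds(lifelines), metadata = md)
}

#' Standard turbulence-filter chain
#'
#' Convenience wrapper applying the two filtering steps in their
#' canonical order: moving-average smoothing, then the low-amplitude
#' crossing filter. Settings are recorded in the output metadata.
#'
#' @inheritParams smoothLifelines
#' @inheritParams amplitudeFilter
#' @return a filtered \linkS4class{LifelineSet}
#' @export
filterLifelines <- function(lifelines, window = 0.45, delta = 0.02,
                            boundaries = c(0.05, 0.95)) {
  amplitudeFilter(smoothLifelines(lifelines, window = window),
                  delta = delta, boundaries = boundaries)
}
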