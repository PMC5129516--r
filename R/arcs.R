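## Intra-limitation fluctuation analysis: excursions ("arcs") of the
## lifeline away from and back to the qs/qs_max = 0.5 baseline, their
## durations (tau_arc), magnitudes (M_arc), peak timing, and the
## comparison against the fastest change achievable by substrate
## consumption alone.

## strict sign of (x - baseline) with tangential touches carried over:
## a crossing requires a strict sign change between consecutive samples
.carried_sign <- function(x, baseline) {
  s <- sign(x - baseline)
  nz <- s != 0
  if (!any(nz)) return(s)
  idx <- cumsum(nz)
  first <- which(nz)[1L]
  filled <- s[nz][pmax(idx, 1L)]
  filled[seq_len(first - 1L)] <- s[nz][1L]   # leading touches take next sign
  filled
}

#' Detect arcs against a baseline
#'
#' An arc is the stretch of a lifeline between two consecutive
#' crossings of the baseline qs/qs_max = 0.5: the duration between
#' two registrations of the baseline value (\code{tau_arc}), the
#' largest deviation from the baseline over the stretch
#' (\code{M_arc}), and the timing of that extreme within the arc
#' (\code{t_max}, first extreme on ties). Crossing times are at
#' sample resolution; a tangential touch of the baseline without a
#' sign change does not terminate an arc.
#'
#' With \code{restrict_to_L} (the default, matching how these
#' statistics are used for scale-down design), arcs that touch the
#' excess or starvation regime are discarded, so only fluctuations
#' fully inside the limitation band are counted.
#'
#' @param lifelines a normalized, filtered \linkS4class{LifelineSet}
#' @param baseline the reference level (default 0.5); must lie
#'   strictly inside (0.05, 0.95) when \code{restrict_to_L}
#' @param restrict_to_L discard arcs leaving the limitation band
#' @return data.frame with columns \code{particle_id},
#'   \code{direction} ("up"/"down"), \code{t_start}, \code{tau_arc},
#'   \code{M_arc}, \code{t_max} (time of the extreme relative to arc
#'   start), \code{fully_in_L}
#' @examples
#' t <- seq(0, 60, by = 0.03)
#' ll <- LifelineSet(matrix(0.5 + 0.3 * sin(2 * pi * t / 12), 1), t)
#' head(detectArcs(ll), 3)  # tau_arc = 6, M_arc = 0.3
#' @export
detectArcs <- function(lifelines, baseline = 0.5, restrict_to_L = TRUE) {
  stopifnot(is(lifelines, "LifelineSet"))
  if (restrict_to_L && !(baseline > 0.05 && baseline < 0.95))
    stop("'baseline' must lie strictly inside (0.05, 0.95) when restricting to L")
  q <- qsFrac(lifelines)
  t <- lifelineTimes(lifelines)
  dt <- timeStep(lifelines)
  ids <- particleIds(lifelines)
  out <- list()
  for (i in seq_len(nrow(q))) {
    x <- q[i, ]
    s <- .carried_sign(x, baseline)
    if (all(s == 0)) next
    ## crossing at k: sign changes strictly between samples k-1 and k;
    ## the crossing is registered at the first sample of the new sign
    cross <- which(s[-1] * s[-length(s)] < 0) + 1L
    if (length(cross) < 2L) next
    for (a in seq_len(length(cross) - 1L)) {
      lo <- cross[a]
      hi <- cross[a + 1L] - 1L
      seg <- x[lo:hi]
      dir_up <- s[lo] > 0
      fully_L <- all(seg >= 0.05 & seg <= 0.95)
      if (restrict_to_L && !fully_L) next
      ext <- if (dir_up) which.max(seg) else which.min(seg)
      out[[length(out) + 1L]] <- data.frame(
        particle_id = ids[i],
        direction = if (dir_up) "up" else "down",
        t_start = t[lo],
        tau_arc = (hi - lo + 1L) * dt,
        M_arc = abs(seg[ext] - baseline),
        t_max = (ext - 1L) * dt,
        fully_in_L = fully_L)
    }
  }
  arcs <- do.call(rbind, out)
  if (is.null(arcs))
    arcs <- data.frame(particle_id = integer(), direction = character(),
                       t_start = numeric(), tau_arc = numeric(),
                       M_arc = numeric(), t_max = numeric(),
                       fully_in_L = logical())
  rownames(arcs) <- NULL
  attr(arcs, "baseline") <- baseline
  arcs
}

#' Summary statistics of an arc set
#'
#' Per-direction mean arc times, the fraction of upward arcs, and the
#' mean relative peak timing \code{t_max / tau_arc} per direction (a
#' value of 0.5 means temporally symmetric arcs).
#'
#' @param arcs arc table from [detectArcs()]
#' @return list with \code{n}, \code{fraction_up},
#'   \code{mean_tau_up}, \code{mean_tau_down}, \code{mean_peak_up},
#'   \code{mean_peak_down}, \code{mean_M_up}, \code{mean_M_down}
#' @export
arcStatistics <- function(arcs) {
  if (!nrow(arcs)) stop("empty arc list")
  up <- arcs$direction == "up"
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  list(
    n = nrow(arcs),
    fraction_up = mean(up),
    mean_tau_up = mean_or_na(arcs$tau_arc[up]),
    mean_tau_down = mean_or_na(arcs$tau_arc[!up]),
    mean_peak_up = mean_or_na((arcs$t_max / arcs$tau_arc)[up]),
    mean_peak_down = mean_or_na((arcs$t_max / arcs$tau_arc)[!up]),
    mean_M_up = mean_or_na(arcs$M_arc[up]),
    mean_M_down = mean_or_na(arcs$M_arc[!up]))
}

#' Conditional M_arc distribution over arc time
#'
#' Two-dimensional histogram of arc magnitude against arc duration,
#' normalized per duration bin (occupied columns sum to 1), plus the
#' mean magnitude per duration bin.
#'
#' @param arcs arc table from [detectArcs()]
#' @param tau_bins bin edges for tau_arc (s)
#' @param M_bins bin edges for M_arc
#' @param direction "up", "down" or "both"
#' @return list with \code{tau_bins}, \code{M_bins}, \code{fraction}
#'   (length(M_bins)-1 x length(tau_bins)-1 matrix), \code{mean_M}
#'   (per tau bin), \code{n} (per tau bin)
#' @export
marcTauMap <- function(arcs, tau_bins = seq(0, 30, by = 0.5),
                       M_bins = seq(0, 0.45, by = 0.025),
                       direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (is.unsorted(tau_bins, strictly = TRUE) ||
      is.unsorted(M_bins, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  a <- arcs
  if (direction != "both") a <- a[a$direction == direction, , drop = FALSE]
  ti <- cut(a$tau_arc, tau_bins, include.lowest = TRUE, labels = FALSE)
  mi <- cut(a$M_arc, M_bins, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(ti) & !is.na(mi)
  ti <- ti[keep]; mi <- mi[keep]
  nt <- length(tau_bins) - 1L
  nm <- length(M_bins) - 1L
  counts <- matrix(0, nm, nt)
  for (k in seq_along(ti)) counts[mi[k], ti[k]] <- counts[mi[k], ti[k]] + 1
  coln <- colSums(counts)
  frac <- sweep(counts, 2, pmax(coln, 1), "/")
  mean_M <- vapply(seq_len(nt), function(j)
    if (coln[j] > 0) mean(a$M_arc[keep][ti == j]) else NA_real_, numeric(1))
  list(tau_bins = tau_bins, M_bins = M_bins, fraction = frac,
       mean_M = mean_M, n = coln)
}

#' Simulation vs consumption-only transition times
#'
#' For a grid of arc magnitudes M, compares the time the average arc
#' takes to return from its extreme to the baseline against the time
#' substrate consumption alone would need for the same change in
#' qs/qs_max. The return leg of an average arc occupies a fixed
#' fraction of the arc time (0.6 for upward, 0.5 for downward arcs by
#' default, reflecting the average arc shape; recomputable from the
#' measured peak timings via \code{shape_from_arcs}). Where the
#' simulation-side time falls below the consumption-only time,
#' mixing/dilution locally outpaces consumption -- the regime an
#' ideally mixed scale-down simulator cannot reach at the same
#' biomass concentration.
#'
#' @param arcs arc table from [detectArcs()]
#' @param params a \linkS4class{KineticParameters}
#' @param M_grid magnitudes at which to evaluate (default: centers of
#'   0.025-wide bins up to 0.45)
#' @param shape_up,shape_down fraction of the arc time spent on the
#'   return leg
#' @param shape_from_arcs recompute the shape factors from the
#'   measured mean \code{t_max/tau_arc}
#' @param baseline arc baseline (default 0.5)
#' @return data.frame with columns \code{M}, \code{direction},
#'   \code{t_sim} (s; NA for unoccupied magnitude bins),
#'   \code{t_consumption} (s)
#' @export
consumptionComparison <- function(arcs, params,
                                  M_grid = seq(0.0125, 0.4375, by = 0.025),
                                  shape_up = 0.6, shape_down = 0.5,
                                  shape_from_arcs = FALSE,
                                  baseline = 0.5) {
  if (shape_from_arcs) {
    st <- arcStatistics(arcs)
    if (is.finite(st$mean_peak_up)) shape_up <- 1 - st$mean_peak_up
    if (is.finite(st$mean_peak_down)) shape_down <- st$mean_peak_down
  }
  half <- if (length(M_grid) >= 2L) diff(M_grid[1:2]) / 2 else 0.0125
  rows <- list()
  for (dir in c("up", "down")) {
    sel <- arcs[arcs$direction == dir, , drop = FALSE]
    shape <- if (dir == "up") shape_up else shape_down
    for (M in M_grid) {
      in_bin <- abs(sel$M_arc - M) <= half
      t_sim <- if (any(in_bin)) shape * mean(sel$tau_arc[in_bin]) else NA_real_
      t_cons <- if (dir == "up")
        consumptionTransitionTime(baseline + M, baseline, params)
      else
        consumptionTransitionTime(baseline, baseline - M, params)
      rows[[length(rows) + 1L]] <- data.frame(
        M = M, direction = dir, t_sim = t_sim, t_consumption = t_cons)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
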