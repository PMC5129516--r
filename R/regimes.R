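## Metabolic regime analysis: classification of qs/qs_max into
## excess (E), limitation (L) and starvation (S); run-length
## segmentation; transition patterns and residence-time statistics;
## Eulerian vs Lagrangian regime fractions.

.PATTERNS <- c("LEL", "ELE", "ELS", "SLE", "SLS", "LSL")

#' Classify normalized uptake into metabolic regimes
#'
#' E (excess): qs/qs_max > 0.95, uptake insensitive to substrate
#' variations. S (starvation): qs/qs_max < 0.05, uptake linear in
#' substrate but negligibly small. L (limitation): the band in
#' between, where fluctuations matter. The inequalities are strict;
#' samples exactly on a boundary are assigned to L (the complement),
#' a measure-zero convention fixed for determinism.
#'
#' @param qs_frac numeric vector/matrix of qs/qs_max in [0, 1]
#' @return character vector/matrix of "E", "L", "S"
#' @examples
#' classifyRegime(c(0.96, 0.5, 0.01, 0.95, 0.05))
#' @export
classifyRegime <- function(qs_frac) {
  if (any(qs_frac < 0 | qs_frac > 1))
    stop("'qs_frac' must lie in [0, 1]")
  out <- ifelse(qs_frac > 0.95, "E", ifelse(qs_frac < 0.05, "S", "L"))
  if (is.matrix(qs_frac)) dim(out) <- dim(qs_frac)
  out
}

#' Convert lifelines to regime series
#'
#' Run-length encodes the per-sample regime classification of each
#' lifeline into contiguous regime visits. Crossing times are at
#' sample resolution (each sample contributes one sampling interval
#' \code{dt}, so segment durations sum exactly to the lifeline span);
#' the first and last segment of every lifeline are flagged
#' truncated, since their true start/end lies outside the recording.
#'
#' @param lifelines a normalized (and typically filtered)
#'   \linkS4class{LifelineSet}
#' @return a \linkS4class{RegimeSeries}
#' @seealso [extractTransitions()]
#' @export
toRegimeSeries <- function(lifelines) {
  stopifnot(is(lifelines, "LifelineSet"))
  q <- qsFrac(lifelines)
  dt <- timeStep(lifelines)
  t0 <- lifelineTimes(lifelines)[1L]
  ids <- particleIds(lifelines)
  pieces <- vector("list", nrow(q))
  for (i in seq_len(nrow(q))) {
    r <- rle(classifyRegime(q[i, ]))
    k <- length(r$lengths)
    ends_idx <- cumsum(r$lengths)
    dur <- r$lengths * dt
    start <- t0 + c(0, ends_idx[-k]) * dt
    pieces[[i]] <- data.frame(
      particle_id = rep(ids[i], k), regime = r$values,
      start = start, end = start + dur, duration = dur,
      truncated_head = seq_len(k) == 1L,
      truncated_tail = seq_len(k) == k)
  }
  seg <- do.call(rbind, pieces)
  rownames(seg) <- NULL
  new("RegimeSeries", segments = seg, dt = dt,
      span = ncol(q) * dt, n_particles = nrow(q))
}

#' Extract transition events from a regime series
#'
#' Every non-truncated regime visit yields one transition event,
#' labelled origin-regime + visited-regime + destination-regime (the
#' six patterns LEL, ELE, ELS, SLE, SLS, LSL) with its residence
#' time. Truncated head/tail visits are excluded (their origin or
#' fate is unknown) and counted in the \code{truncated} attribute.
#'
#' Direct E-S adjacency can only arise when the lifeline jumps across
#' the whole limitation band between two samples; such crossings are
#' repaired by inserting a zero-duration L visit, counted in the
#' \code{direct_crossings} attribute, and flagged with a warning.
#'
#' @param series a \linkS4class{RegimeSeries}
#' @return data.frame with columns \code{particle_id},
#'   \code{pattern}, \code{regime} (the visited, middle regime),
#'   \code{origin}, \code{destination}, \code{residence} (s),
#'   \code{start} (s); attributes \code{truncated} (count) and
#'   \code{direct_crossings} (count)
#' @examples
#' ll <- LifelineSet(matrix(rep(c(0.99, 0.5, 0.01, 0.5, 0.99),
#'                              c(5, 2, 7, 3, 4)), 1), t = 0:20)
#' extractTransitions(toRegimeSeries(ll))
#' @export
extractTransitions <- function(series) {
  stopifnot(is(series, "RegimeSeries"))
  seg <- series@segments
  out <- list()
  n_trunc <- 0L
  n_direct <- 0L
  for (chunk in split(seg, factor(seg$particle_id,
                                  levels = unique(seg$particle_id)))) {
    k <- nrow(chunk)
    reg <- chunk$regime
    start <- chunk$start
    dur <- chunk$duration
    ## repair direct E<->S adjacencies with a zero-duration L visit
    jump <- which(abs(match(reg[-1], c("S", "L", "E")) -
                      match(reg[-k], c("S", "L", "E"))) == 2L)
    if (length(jump)) {
      n_direct <- n_direct + length(jump)
      for (j in rev(jump)) {
        reg <- append(reg, "L", after = j)
        start <- append(start, start[j + 1L], after = j)
        dur <- append(dur, 0, after = j)
      }
      k <- length(reg)
    }
    n_trunc <- n_trunc + min(k, 2L)
    if (k < 3L) next
    mid <- 2:(k - 1L)
    out[[length(out) + 1L]] <- data.frame(
      particle_id = rep(chunk$particle_id[1L], length(mid)),
      pattern = paste0(reg[mid - 1L], reg[mid], reg[mid + 1L]),
      regime = reg[mid], origin = reg[mid - 1L],
      destination = reg[mid + 1L],
      residence = dur[mid], start = start[mid])
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(particle_id = integer(), pattern = character(),
                     regime = character(), origin = character(),
                     destination = character(), residence = numeric(),
                     start = numeric())
  rownames(ev) <- NULL
  if (n_direct > 0L)
    warning(n_direct, " direct E<->S crossing(s) repaired with ",
            "zero-duration L visits; consider a finer sampling interval")
  attr(ev, "truncated") <- n_trunc
  attr(ev, "direct_crossings") <- n_direct
  ev
}

#' Default residence-time histogram bins
#'
#' Log-spaced bin edges from 0.03 s (the sampling interval) to 300 s.
#'
#' @param n number of bins
#' @return numeric vector of n + 1 edges (s)
#' @export
defaultResidenceBins <- function(n = 50) {
  exp(seq(log(0.03), log(300), length.out = n + 1))
}

#' Residence-time distribution for one transition pattern
#'
#' Non-normalized histogram of residence times (counts per bin,
#' matching the field's presentation of these distributions) plus the
#' mean residence time.
#'
#' @param events transition events from [extractTransitions()]
#' @param pattern one of "LEL", "ELE", "ELS", "SLE", "SLS", "LSL"
#' @param bin_edges histogram bin edges in seconds (default
#'   log-spaced 0.03-300 s)
#' @return list with \code{pattern}, \code{bin_edges}, \code{counts},
#'   \code{n} (number of events), and \code{mean} (s; \code{NA} when
#'   no event matches)
#' @export
residenceDistribution <- function(events, pattern,
                                  bin_edges = defaultResidenceBins()) {
  if (!pattern %in% .PATTERNS)
    stop("'pattern' must be one of: ", paste(.PATTERNS, collapse = ", "))
  res <- events$residence[events$pattern == pattern]
  counts <- if (length(res))
    graphics::hist(pmin(pmax(res, min(bin_edges)), max(bin_edges)),
                   breaks = bin_edges, plot = FALSE)$counts
  else rep(0L, length(bin_edges) - 1L)
  list(pattern = pattern, bin_edges = bin_edges, counts = counts,
       n = length(res),
       mean = if (length(res)) mean(res) else NA_real_)
}

#' Transition fate fractions
#'
#' For all visits to one regime, the fraction of each
#' origin-destination pattern, normalized per origin: e.g. among L
#' visits entered from excess, which fraction returns to excess (ELE)
#' versus continues to starvation (ELS).
#'
#' @param events transition events from [extractTransitions()]
#' @param visited_regime the middle regime ("E", "L" or "S")
#' @return data.frame with columns \code{origin}, \code{pattern},
#'   \code{count}, \code{fraction}; fractions sum to 1 within each
#'   origin
#' @export
transitionFateFractions <- function(events, visited_regime = "L") {
  ev <- events[events$regime == visited_regime, , drop = FALSE]
  if (!nrow(ev)) stop("no events visit regime ", visited_regime)
  tab <- as.data.frame(table(origin = ev$origin, pattern = ev$pattern),
                       responseName = "count", stringsAsFactors = FALSE)
  tab <- tab[substr(tab$pattern, 1, 1) == tab$origin &
             substr(tab$pattern, 2, 2) == visited_regime, ]
  totals <- tapply(tab$count, tab$origin, sum)
  tab$fraction <- tab$count / as.vector(totals[tab$origin])
  rownames(tab) <- NULL
  tab[order(tab$origin, tab$pattern), ]
}

#' Volumetric regime fractions
#'
#' Eulerian form: volume-weighted regime percentages of a steady
#' compartment field. Lagrangian form: particle-sample percentages
#' over a lifeline set. Both sum to 100; at stationarity the particle
#' jump process distributes mass-proportionally, so the two agree up
#' to sampling error -- the standard consistency check between field
#' and particle views.
#'
#' @param x a \linkS4class{CompartmentNetwork} (Eulerian; supply
#'   \code{Cs}) or a \linkS4class{LifelineSet} (Lagrangian)
#' @param params a \linkS4class{KineticParameters} (Eulerian form)
#' @param Cs compartment concentrations, e.g. from
#'   [steadySubstrateField()] (Eulerian form; computed if missing)
#' @return named numeric vector \code{c(E=, L=, S=)} in percent
#' @export
regimeFractions <- function(x, params = NULL, Cs = NULL) {
  if (is(x, "CompartmentNetwork")) {
    if (is.null(params)) stop("Eulerian fractions need 'params'")
    if (is.null(Cs)) Cs <- steadySubstrateField(x, params)
    reg <- classifyRegime(uptakeRate(Cs, params) / params@qs_max)
    w <- x@volume / sum(x@volume)
    out <- vapply(c("E", "L", "S"),
                  function(r) 100 * sum(w[reg == r]), numeric(1))
  } else if (is(x, "LifelineSet")) {
    reg <- classifyRegime(qsFrac(x))
    out <- vapply(c("E", "L", "S"),
                  function(r) 100 * mean(reg == r), numeric(1))
  } else stop("'x' must be a CompartmentNetwork or a LifelineSet")
  out
}
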