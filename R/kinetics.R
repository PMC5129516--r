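## Biomass-specific kinetics: Monod uptake, Herbert-Pirt growth,
## dynamic penicillin production. Internal time unit is seconds;
## mu, beta, KdE, ms are carried in per-hour units as is conventional
## for these constants, with conversions at operation boundaries.

#' Unit conversion helpers
#'
#' \code{perHour} converts a per-second specific rate to per-hour;
#' \code{perSecond} the reverse.
#'
#' @param x numeric rate(s)
#' @return converted rate(s)
#' @export
perHour <- function(x) x * 3600

#' @rdname perHour
#' @export
perSecond <- function(x) x / 3600

#' Monod substrate uptake rate
#'
#' Biomass-specific glucose uptake,
#' \code{qs = qs_max * Cs / (Ks + Cs)}.
#'
#' @param Cs substrate concentration(s), mol/kg, must be >= 0
#' @param params a \linkS4class{KineticParameters}
#' @return qs in mol_s/Cmol_x/s, same length as \code{Cs}
#' @examples
#' p <- kineticParameters()
#' uptakeRate(c(0, 7.8e-6), p)  # 0 and qs_max/2
#' @export
uptakeRate <- function(Cs, params) {
  stopifnot(is(params, "KineticParameters"))
  if (any(Cs < 0)) stop("'Cs' must be >= 0")
  params@qs_max * Cs / (params@Ks + Cs)
}

## derivative dqs/dCs, used by the compartment-field Newton solve
uptakeRateDeriv <- function(Cs, params) {
  params@qs_max * params@Ks / (params@Ks + Cs)^2
}

#' Invert the Monod relation
#'
#' Substrate concentration at which the uptake rate equals a given
#' fraction \code{f} of \code{qs_max}: \code{Cs = Ks * f / (1 - f)}.
#'
#' @param f fraction(s) of qs_max in [0, 1); values above \code{cap}
#'   are capped to avoid the saturation singularity
#' @param params a \linkS4class{KineticParameters}
#' @param cap largest admissible fraction (default 0.999)
#' @return Cs in mol/kg
#' @export
invertUptake <- function(f, params, cap = 0.999) {
  stopifnot(is(params, "KineticParameters"))
  if (any(f < 0)) stop("'f' must be >= 0")
  f <- pmin(f, cap)
  params@Ks * f / (1 - f)
}

#' Specific growth rate (Herbert-Pirt)
#'
#' Partitions uptake into growth, production and maintenance:
#' \code{mu = Ysx * (qs*3600 - ms - qp/Ysp)}. The production term is
#' small and neglected by default, making mu a function of uptake
#' alone. The result is clipped from below at \code{mu_floor}
#' (default 0), a regularization preventing nonphysical negative
#' growth at very low uptake.
#'
#' @param qs specific uptake rate(s) in mol_s/Cmol_x/s, >= 0
#' @param params a \linkS4class{KineticParameters}
#' @param qp specific production rate (mol_p/Cmol_x/h), only used
#'   when \code{include_qp_term}
#' @param include_qp_term include the \code{qp/Ysp} drain (default
#'   FALSE)
#' @return mu in 1/h
#' @examples
#' p <- kineticParameters()
#' growthRate(uptakeRate(3.06e-6, p), p)  # ~0.045 1/h
#' @export
growthRate <- function(qs, params, qp = 0, include_qp_term = FALSE) {
  stopifnot(is(params, "KineticParameters"))
  if (any(qs < 0)) stop("'qs' must be >= 0")
  drain <- if (include_qp_term) qp / params@Ysp else 0
  mu <- params@Ysx * (perHour(qs) - params@ms - drain)
  pmax(mu, params@mu_floor)
}

## mu as a function of Cs (composition used by the qp dynamics)
growthRateFromCs <- function(Cs, params, ...) {
  growthRate(uptakeRate(Cs, params), params, ...)
}

#' Rate of change of the specific production rate
#'
#' Dynamic gene-regulation model of penicillin production:
#' \deqn{dq_p/dt = \beta \max(0, \mu) / (1 + (C_s/K_p)^2)
#'       - (K_{dE} + \mu) q_p}
#' with mu evaluated from \code{Cs} through the Monod uptake and
#' Herbert-Pirt relations. Production is induced by growth, repressed
#' by high substrate, and washed out by enzyme decay plus dilution by
#' growth.
#'
#' @param qp current specific production rate(s), mol_p/Cmol_x/h,
#'   must be >= 0
#' @param Cs substrate concentration(s), mol/kg
#' @param params a \linkS4class{KineticParameters}
#' @return dqp/dt in mol_p/Cmol_x/h per hour
#' @export
qpRate <- function(qp, Cs, params) {
  if (any(qp < 0)) stop("'qp' must be >= 0")
  mu <- growthRateFromCs(Cs, params)
  prod <- params@beta * pmax(0, mu) / (1 + (Cs / params@Kp)^2)
  prod - (params@KdE + mu) * qp
}

#' Steady-state specific production rate
#'
#' Fixed point of the production dynamics at constant substrate:
#' \code{qp_ss = beta * max(0, mu) / ((1 + (Cs/Kp)^2) * (KdE + mu))}.
#'
#' @param Cs substrate concentration(s), mol/kg
#' @param params a \linkS4class{KineticParameters}
#' @return qp_ss in mol_p/Cmol_x/h
#' @examples
#' p <- kineticParameters()
#' qpSteadyState(3.06e-6, p)   # ~5.2e-4 (ideal mixing)
#' qpSteadyState(34.4e-6, p)   # ~0.29e-4 (at the Eulerian mean)
#' @export
qpSteadyState <- function(Cs, params) {
  mu <- growthRateFromCs(Cs, params)
  denom <- params@KdE + mu
  if (any(denom <= 0))
    stop("degenerate parameters: KdE + mu <= 0, no stable steady state")
  params@beta * pmax(0, mu) / ((1 + (Cs / params@Kp)^2) * denom)
}

#' Adaptation time of the production rate
#'
#' Relaxation timescale of the production dynamics,
#' \code{tau_qp = 1 / (KdE + |mu|)}. At the ideal-mixing operating
#' point this is about 20 h, orders of magnitude above the
#' seconds-scale substrate fluctuations.
#'
#' @param Cs substrate concentration(s), mol/kg
#' @param params a \linkS4class{KineticParameters}
#' @return tau_qp in hours
#' @export
qpAdaptationTime <- function(Cs, params) {
  mu <- growthRateFromCs(Cs, params)
  1 / (params@KdE + abs(mu))
}

#' Integrate the production dynamics along a lifeline
#'
#' Propagates qp along a uniformly sampled qs/qs_max series using an
#' exact exponential update per sample: within each sampling interval
#' the forcing is frozen, for which \code{dqp/dt = a - b qp} has the
#' closed-form step \code{qp <- a/b + (qp - a/b) exp(-b dt)}. This is
#' unconditionally stable and, since the qp timescale (~20 h) vastly
#' exceeds the sampling interval (0.03 s), accurate to the
#' piecewise-constant representation of the input.
#'
#' Substrate concentration is recovered from the normalized uptake by
#' Monod inversion (capped at qs/qs_max = 0.999, see
#' [invertUptake()]).
#'
#' @param qs_frac numeric vector of qs/qs_max samples, or a
#'   \linkS4class{LifelineSet} (each row integrated independently)
#' @param t time grid in seconds (ignored for a LifelineSet); must be
#'   uniform
#' @param params a \linkS4class{KineticParameters}
#' @param qp0 initial qp (mol_p/Cmol_x/h), >= 0
#' @return numeric vector (or matrix for a LifelineSet) of qp at the
#'   input timepoints, in mol_p/Cmol_x/h
#' @examples
#' p <- kineticParameters()
#' t <- seq(0, 200 * 3600, by = 3600)  # 200 h, 1 h sampling
#' f <- rep(uptakeRate(3.06e-6, p) / 12.47e-6, length(t))
#' tail(integrateQp(f, t, p, qp0 = 0), 1)  # -> qpSteadyState(3.06e-6, p)
#' @export
integrateQp <- function(qs_frac, t = NULL, params, qp0 = 0) {
  if (is(qs_frac, "LifelineSet")) {
    t <- lifelineTimes(qs_frac)
    m <- qsFrac(qs_frac)
    out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
    for (i in seq_len(nrow(m)))
      out[i, ] <- integrateQp(m[i, ], t, params, qp0 = qp0)
    return(out)
  }
  if (qp0 < 0) stop("'qp0' must be >= 0")
  n <- length(qs_frac)
  stopifnot(length(t) == n)
  if (n >= 3L) {
    dts <- diff(t)
    if (max(abs(dts - dts[1])) > 1e-6 * dts[1])
      stop("time grid must be uniform")
  }
  if (n == 1L) return(qp0)
  dt_h <- (t[2] - t[1]) / 3600
  Cs <- invertUptake(qs_frac, params)
  mu <- growthRateFromCs(Cs, params)
  a <- params@beta * pmax(0, mu) / (1 + (Cs / params@Kp)^2)
  b <- params@KdE + mu
  qp <- numeric(n)
  qp[1] <- qp0
  ## vectorized scan of the linear recursion, chunked so the running
  ## exponent exp(cumsum(b dt)) stays within double range
  idx <- 2L
  chunk <- max(1L, min(262144L, floor(30 / (max(b) * dt_h))))
  while (idx <= n) {
    j <- idx:min(idx + chunk - 1L, n)
    bj <- b[j - 1L]          # forcing frozen over [t_{k-1}, t_k)
    aj <- a[j - 1L]
    L <- cumsum(bj * dt_h)   # bounded: chunk * b * dt << 700
    f <- exp(-bj * dt_h)
    term <- (aj / bj) * (1 - f) * exp(L)
    qp[j] <- exp(-L) * (qp[idx - 1L] + cumsum(term))
    idx <- j[length(j)] + 1L
  }
  pmax(qp, 0)
}
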