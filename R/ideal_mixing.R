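## Ideal-mixing reference state and consumption-only timescales.
## These are the benchmarks against which gradient effects are
## measured, and the quantities that anchor scale-down design
## arguments.

#' Ideal-mixing specific uptake rate
#'
#' At steady state with spatially uniform broth, the fed substrate is
#' consumed uniformly: \code{qs = F / (broth_mass * Cx)}. For the
#' default 54 m3 vessel this gives ~3.5e-6 mol_s/Cmol_x/s.
#'
#' @param globals a \linkS4class{ReactorGlobals}
#' @param params a \linkS4class{KineticParameters}
#' @return qs in mol_s/Cmol_x/s
#' @examples
#' idealUptake(reactorGlobals(), kineticParameters())
#' @export
idealUptake <- function(globals, params) {
  stopifnot(is(globals, "ReactorGlobals"), is(params, "KineticParameters"))
  cap <- globals@broth_mass * params@Cx * params@qs_max
  if (globals@F >= cap)
    stop(sprintf(
      "infeasible steady state: feed %.3g mol/s >= maximum uptake capacity %.3g mol/s",
      globals@F, cap))
  globals@F / (globals@broth_mass * params@Cx)
}

#' Residual substrate concentration under ideal mixing
#'
#' Monod inversion of the ideal-mixing uptake rate:
#' \code{Cs_res = Ks * qs / (qs_max - qs)}; ~3.0e-6 mol/kg for the
#' default vessel. Satisfies
#' \code{uptakeRate(Cs_res) == idealUptake()} exactly.
#'
#' @inheritParams idealUptake
#' @return Cs_res in mol/kg
#' @export
residualConcentration <- function(globals, params) {
  qs <- idealUptake(globals, params)
  params@Ks * qs / (params@qs_max - qs)
}

#' Substrate consumption timescale
#'
#' Representative time to consume the local substrate pool,
#' \code{tau_rs = Cs / (Cx * qs(Cs))}. At the ideal-mixing residual
#' concentration this is ~0.44 s, far below the ~19 s circulation
#' time: the origin of the steep axial gradient.
#'
#' @param Cs substrate concentration(s), mol/kg, > 0
#' @param params a \linkS4class{KineticParameters}
#' @return tau_rs in seconds
#' @export
substrateTimescale <- function(Cs, params) {
  if (any(Cs <= 0)) stop("'Cs' must be > 0")
  Cs / (params@Cx * uptakeRate(Cs, params))
}

#' Time to cross the limitation regime by consumption alone
#'
#' Elapsed time of the batch balance \code{dCs/dt = -Cx * qs(Cs)}
#' between the concentrations where qs/qs_max equals
#' \code{frac_from} and \code{frac_to}. This is the fastest possible
#' downward transition in an ideally mixed (or plug-flow) scale-down
#' simulator, where dilution cannot assist consumption.
#'
#' For pure Monod kinetics the integral has the closed form
#' \deqn{t = [\Delta C_s + K_s \ln(C_{s,0}/C_{s,1})] / (C_x q_{s,max})}
#' which \code{method = "closed_form"} evaluates; \code{"numeric"}
#' performs adaptive quadrature of \code{dt = dCs / (Cx qs(Cs))} and
#' is the route to use with modified uptake kinetics.
#'
#' @param frac_from,frac_to start/end values of qs/qs_max, with
#'   \code{0 < frac_to <= frac_from < 1}
#' @param params a \linkS4class{KineticParameters}
#' @param method "closed_form" (default) or "numeric"
#' @return elapsed time in seconds
#' @examples
#' p <- kineticParameters()
#' consumptionTransitionTime(0.95, 0.05, p)  # excess -> starvation boundary
#' @export
consumptionTransitionTime <- function(frac_from, frac_to, params,
                                      method = c("closed_form", "numeric")) {
  method <- match.arg(method)
  if (!(frac_from > 0 && frac_from < 1 && frac_to > 0 && frac_to < 1))
    stop("fractions must lie strictly inside (0, 1)")
  if (frac_to > frac_from)
    stop("'frac_to' must not exceed 'frac_from' (consumption only decreases qs)")
  if (frac_to == frac_from) return(0)
  Cs0 <- params@Ks * frac_from / (1 - frac_from)
  Cs1 <- params@Ks * frac_to / (1 - frac_to)
  if (method == "closed_form") {
    ((Cs0 - Cs1) + params@Ks * log(Cs0 / Cs1)) / (params@Cx * params@qs_max)
  } else {
    stats::integrate(function(C) 1 / (params@Cx * uptakeRate(C, params)),
                     lower = Cs1, upper = Cs0,
                     rel.tol = 1e-10)$value
  }
}

#' Ideal-mixing reference table
#'
#' Computes the full reference block in one call: the steady uptake
#' rate, residual concentration, growth rate, steady production rate,
#' substrate timescale, production adaptation time, and the
#' consumption-only excess-to-starvation transition time.
#'
#' @inheritParams idealUptake
#' @return named list with elements \code{qs} (mol_s/Cmol_x/s),
#'   \code{Cs_res} (mol/kg), \code{mu} (1/h), \code{qp_ss}
#'   (mol_p/Cmol_x/h), \code{tau_rs} (s), \code{tau_qp} (h),
#'   \code{t_ELS_consumption} (s)
#' @examples
#' idealReference(reactorGlobals(), kineticParameters())
#' @export
idealReference <- function(globals = reactorGlobals(),
                           params = kineticParameters()) {
  qs <- idealUptake(globals, params)
  Cs_res <- residualConcentration(globals, params)
  list(
    qs = qs,
    Cs_res = Cs_res,
    mu = growthRate(qs, params),
    qp_ss = qpSteadyState(Cs_res, params),
    tau_rs = substrateTimescale(Cs_res, params),
    tau_qp = qpAdaptationTime(Cs_res, params),
    t_ELS_consumption = consumptionTransitionTime(0.95, 0.05, params,
                                                  method = "numeric")
  )
}
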