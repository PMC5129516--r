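#' Create kinetic parameters
#'
#' Constructor for \linkS4class{KineticParameters}. Defaults
#' reproduce the DS12975 strain parameterization used throughout the
#' package: \code{qs_max = 12.47e-6} mol_s/Cmol_x/s and
#' \code{Ks = 7.8e-6} mol_s/kg, with the production-dynamics and
#' Herbert-Pirt constants calibrated so that the ideal-mixing
#' reference sits at mu = 0.045 1/h, qp = 5.2e-4 mol_p/Cmol_x/h and a
#' production adaptation time of 20 h (see the package vignette).
#'
#' @param qs_max maximum specific uptake rate (mol_s/Cmol_x/s)
#' @param Ks substrate affinity constant (mol_s/kg)
#' @param beta production rate constant (mol_p/Cmol_x/h)
#' @param Kp substrate repression constant (mol_s/kg)
#' @param KdE production-enzyme decay rate (1/h)
#' @param Ysx maximum biomass yield (Cmol_x/mol_s)
#' @param Ysp maximum product yield (mol_p/mol_s)
#' @param ms maintenance coefficient (mol_s/Cmol_x/h)
#' @param Cx biomass concentration (Cmol_x/kg)
#' @param mu_floor lower clip on the growth rate (1/h)
#' @return a \linkS4class{KineticParameters} object
#' @examples
#' p <- kineticParameters()
#' uptakeRate(7.8e-6, p)  # half saturation: qs_max / 2
#' @export
kineticParameters <- function(qs_max = 12.47e-6, Ks = 7.8e-6,
                              beta = 6.77e-4, Kp = 7.4e-6,
                              KdE = 5e-3, Ysx = 4.5, Ysp = 0.9,
                              ms = 2.65e-3, Cx = 1.96, mu_floor = 0) {
  new("KineticParameters", qs_max = qs_max, Ks = Ks, beta = beta,
      Kp = Kp, KdE = KdE, Ysx = Ysx, Ysp = Ysp, ms = ms, Cx = Cx,
      mu_floor = mu_floor)
}

#' Read kinetic parameters from a YAML file
#'
#' Flat key-value YAML with keys named exactly as the
#' \linkS4class{KineticParameters} slots. Missing keys fall back to
#' the DS12975 defaults. A bundled default file is available via
#' \code{system.file("extdata", "ds12975.yaml", package =
#' "ReactorLifelines")}.
#'
#' @param path YAML file path
#' @return a \linkS4class{KineticParameters} object
#' @export
readKineticParameters <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(kineticParameters))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown kinetic parameter keys: ", paste(bad, collapse = ", "))
  do.call(kineticParameters, lapply(vals, as.numeric))
}

#' Create reactor-scale globals
#'
#' Defaults describe the 54 m3 production fermentor: feed
#' 0.37 mol_s/s, density 1000 kg/m3, height 7.7 m, diameter 3.0 m.
#'
#' @param F substrate feed rate (mol_s/s)
#' @param V broth volume (m3)
#' @param rho broth density (kg/m3)
#' @param H broth height (m)
#' @param T tank diameter (m)
#' @return a \linkS4class{ReactorGlobals} object
#' @export
reactorGlobals <- function(F = 0.37, V = 54, rho = 1000, H = 7.7, T = 3.0) {
  new("ReactorGlobals", F = F, V = V, rho = rho, broth_mass = V * rho,
      H = H, T = T)
}

#' Create a compartment network
#'
#' @param volume compartment volumes (m3)
#' @param flow n x n exchange matrix (kg/s), diagonal zero
#' @param feed per-compartment substrate feed (mol_s/s)
#' @param Cx per-compartment biomass concentration (Cmol_x/kg);
#'   a scalar is recycled
#' @param rho broth density (kg/m3)
#' @param labels compartment labels
#' @return a \linkS4class{CompartmentNetwork}
#' @seealso [buildDefaultFermentor()]
#' @export
compartmentNetwork <- function(volume, flow, feed, Cx = 1.96,
                               rho = 1000,
                               labels = paste0("compartment-", seq_along(volume))) {
  n <- length(volume)
  if (length(Cx) == 1L) Cx <- rep(Cx, n)
  new("CompartmentNetwork", n = as.integer(n), volume = as.numeric(volume),
      flow = flow, feed = as.numeric(feed), Cx = as.numeric(Cx),
      rho = rho, labels = labels)
}

#' Create a simulation configuration
#'
#' Desk-scale defaults: 2000 particles tracked for 600 s, sampled
#' every 0.03 s, with mean-zero exponentially correlated turbulence
#' noise of standard deviation 0.05 and correlation time 0.3 s.
#'
#' @param n_particles number of particles
#' @param duration flow time to simulate (s)
#' @param dt output sampling interval (s)
#' @param seed integer seed
#' @param noise_sigma turbulence noise standard deviation
#'   (qs/qs_max units); 0 disables noise
#' @param noise_tau turbulence noise correlation time (s)
#' @return a \linkS4class{SimulationConfig}
#' @export
simulationConfig <- function(n_particles = 2000, duration = 600,
                             dt = 0.03, seed = 1L,
                             noise_sigma = 0.05, noise_tau = 0.3) {
  new("SimulationConfig", n_particles = as.integer(n_particles),
      duration = duration, dt = dt, seed = as.integer(seed),
      noise_sigma = noise_sigma, noise_tau = noise_tau)
}

#' Construct a LifelineSet
#'
#' @param qs_frac particles x timepoints matrix of qs/qs_max
#' @param t shared uniform time grid (s)
#' @param Cs optional matrix of substrate concentrations (mol/kg)
#' @param particle_id particle identifiers (default 1..n)
#' @param metadata list of provenance/config/parameter records
#' @return a \linkS4class{LifelineSet}
#' @examples
#' ll <- LifelineSet(matrix(0.5, 2, 10), t = seq(0, 0.27, by = 0.03))
#' qsFrac(ll)[1, 1:3]
#' @export
LifelineSet <- function(qs_frac, t, Cs = NULL,
                        particle_id = seq_len(nrow(qs_frac)),
                        metadata = list()) {
  qs_frac <- as.matrix(qs_frac)
  assays <- list(qs_frac = qs_frac)
  if (!is.null(Cs)) assays$Cs <- as.matrix(Cs)
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(particle_id = particle_id),
    colData = DataFrame(t = as.numeric(t))
  )
  out <- new("LifelineSet", se)
  metadata(out) <- metadata
  out
}

## ---- accessors -------------------------------------------------------------

#' Lifeline accessors
#'
#' \code{qsFrac} returns the particles x timepoints matrix of
#' normalized uptake; \code{lifelineTimes} the shared time grid (s);
#' \code{timeStep} the sampling interval (s); \code{nParticles} the
#' number of lifelines; \code{particleIds} their identifiers.
#'
#' @param x a \linkS4class{LifelineSet}
#' @return see Description
#' @name lifeline-accessors
NULL

#' @rdname lifeline-accessors
#' @export
qsFrac <- function(x) assay(x, "qs_frac")

#' @rdname lifeline-accessors
#' @export
lifelineTimes <- function(x) colData(x)$t

#' @rdname lifeline-accessors
#' @export
timeStep <- function(x) {
  t <- lifelineTimes(x)
  if (length(t) < 2L) stop("need at least two timepoints")
  t[2L] - t[1L]
}

#' @rdname lifeline-accessors
#' @export
nParticles <- function(x) nrow(x)

#' @rdname lifeline-accessors
#' @export
particleIds <- function(x) rowData(x)$particle_id

## ---- show methods ----------------------------------------------------------

setMethod("show", "KineticParameters", function(object) {
  cat("KineticParameters (strain defaults: P. chrysogenum DS12975)\n")
  cat(sprintf("  qs_max: %.4g mol_s/Cmol_x/s   Ks: %.4g mol_s/kg\n",
              object@qs_max, object@Ks))
  cat(sprintf("  beta:   %.4g mol_p/Cmol_x/h   Kp: %.4g mol_s/kg   KdE: %.4g 1/h\n",
              object@beta, object@Kp, object@KdE))
  cat(sprintf("  Ysx: %.4g Cmol_x/mol_s   Ysp: %.4g mol_p/mol_s   ms: %.4g mol_s/Cmol_x/h\n",
              object@Ysx, object@Ysp, object@ms))
  cat(sprintf("  Cx: %.4g Cmol_x/kg   mu_floor: %.4g 1/h\n",
              object@Cx, object@mu_floor))
})

setMethod("show", "ReactorGlobals", function(object) {
  cat(sprintf("ReactorGlobals: V = %g m3 (H = %g m, T = %g m), rho = %g kg/m3\n",
              object@V, object@H, object@T, object@rho))
  cat(sprintf("  feed F = %g mol_s/s, broth mass = %g kg\n",
              object@F, object@broth_mass))
})

setMethod("show", "CompartmentNetwork", function(object) {
  cat(sprintf("CompartmentNetwork with %d compartments, total volume %g m3\n",
              object@n, sum(object@volume)))
  cat(sprintf("  total feed %g mol_s/s; largest flow %g kg/s, smallest nonzero flow %g kg/s\n",
              sum(object@feed), max(object@flow),
              min(object@flow[object@flow > 0])))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d particles x %g s at dt = %g s (seed %d)\n",
              object@n_particles, object@duration, object@dt, object@seed))
  cat(sprintf("  turbulence noise: sigma = %g, tau_corr = %g s\n",
              object@noise_sigma, object@noise_tau))
})

setMethod("show", "LifelineSet", function(object) {
  t <- colData(object)$t
  cat(sprintf("LifelineSet: %d lifelines x %d timepoints (dt = %g s, span = %g s)\n",
              nrow(object), ncol(object),
              if (length(t) > 1) t[2] - t[1] else NA_real_,
              if (length(t) > 1) t[length(t)] - t[1] + (t[2] - t[1]) else NA_real_))
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  prov <- metadata(object)$provenance
  if (!is.null(prov)) cat("  provenance:", paste(prov, collapse = " -> "), "\n")
})

setMethod("show", "RegimeSeries", function(object) {
  cat(sprintf("RegimeSeries: %d segments over %d lifelines (span %g s, dt %g s)\n",
              nrow(object@segments), object@n_particles, object@span, object@dt))
  if (nrow(object@segments))
    print(table(object@segments$regime))
})

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport\n")
  cat("  stages:",
      paste(names(which(vapply(
        list(ideal = object@ideal, regimes = object@regime_fractions,
             residence = object@residence, fates = object@fates,
             arcs = object@arcs, spectrum = object@spectrum, qp = object@qp),
        function(x) length(x) > 0, logical(1)))), collapse = ", "), "\n")
})

#' Segment table of a RegimeSeries
#' @param x a \linkS4class{RegimeSeries}
#' @return data.frame of segments
#' @export
regimeSegments <- function(x) x@segments
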