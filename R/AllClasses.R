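#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

#' Kinetic parameters of the biomass-specific black-box model
#'
#' Container for all constants of the kinetic model of
#' \emph{Penicillium chrysogenum} DS12975: Monod substrate uptake,
#' dynamic (gene-regulation) penicillin production, and the
#' Herbert-Pirt partition of uptake into growth, production and
#' maintenance.
#'
#' Units follow bioprocess convention: \code{qs_max} is in
#' mol_s/Cmol_x/s while \code{beta}, \code{KdE}, \code{ms} (and the
#' growth rate mu derived from them) are in per-hour units.
#' Conversions happen at operation boundaries (see
#' \code{\link{perHour}} / \code{\link{perSecond}}).
#'
#' @slot qs_max maximum biomass-specific substrate uptake rate
#'   (mol_s/Cmol_x/s)
#' @slot Ks substrate affinity constant (mol_s/kg)
#' @slot beta production rate constant (mol_p/Cmol_x/h)
#' @slot Kp substrate repression constant (mol_s/kg)
#' @slot KdE first-order decay rate of the production enzyme (1/h)
#' @slot Ysx maximum biomass yield on substrate (Cmol_x/mol_s)
#' @slot Ysp maximum product yield on substrate (mol_p/mol_s)
#' @slot ms maintenance coefficient (mol_s/Cmol_x/h)
#' @slot Cx biomass concentration (Cmol_x/kg broth)
#' @slot mu_floor lower clip applied to the growth rate at very low
#'   uptake (1/h); the default 0 keeps mu nonnegative
#'
#' @seealso [kineticParameters()], [uptakeRate()], [growthRate()]
#' @exportClass KineticParameters
setClass("KineticParameters",
  representation(
    qs_max = "numeric", Ks = "numeric", beta = "numeric", Kp = "numeric",
    KdE = "numeric", Ysx = "numeric", Ysp = "numeric", ms = "numeric",
    Cx = "numeric", mu_floor = "numeric"
  )
)

setValidity("KineticParameters", function(object) {
  msgs <- character()
  for (s in c("qs_max", "Ks", "beta", "Kp", "KdE", "Ysx", "Ysp", "ms", "Cx")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msgs <- c(msgs, sprintf("'%s' must be a single strictly positive number", s))
  }
  mf <- object@mu_floor
  if (length(mf) != 1L || !is.finite(mf) || mf < 0)
    msgs <- c(msgs, "'mu_floor' must be a single number >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Reactor-scale operating quantities
#'
#' Global (well-mixed) description of the production fermentor:
#' substrate feed rate, broth volume, density and vessel geometry.
#' Defaults describe a 54 m3 vessel (height 7.7 m, diameter 3.0 m)
#' fed at 0.37 mol_s/s with broth density 1000 kg/m3.
#'
#' @slot F substrate feed rate (mol_s/s)
#' @slot V broth volume (m3)
#' @slot rho broth density (kg/m3)
#' @slot broth_mass broth mass (kg), equal to \code{V * rho}
#' @slot H broth height (m)
#' @slot T tank diameter (m)
#'
#' @seealso [reactorGlobals()], [idealUptake()]
#' @exportClass ReactorGlobals
setClass("ReactorGlobals",
  representation(F = "numeric", V = "numeric", rho = "numeric",
                 broth_mass = "numeric", H = "numeric", T = "numeric")
)

setValidity("ReactorGlobals", function(object) {
  msgs <- character()
  for (s in c("F", "V", "rho", "broth_mass", "H", "T")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msgs <- c(msgs, sprintf("'%s' must be a single strictly positive number", s))
  }
  if (!length(msgs) &&
      abs(object@broth_mass - object@V * object@rho) >
        1e-9 * object@broth_mass)
    msgs <- c(msgs, "'broth_mass' must equal V * rho (1e-9 relative)")
  if (length(msgs)) msgs else TRUE
})

#' Compartment-network surrogate of the stirred fermentor
#'
#' A coarse network of ideally mixed compartments exchanging broth,
#' used as a desk-scale surrogate for the full hydrodynamic
#' simulation. Particle motion on the network is a continuous-time
#' Markov jump process whose residence and circulation statistics
#' emulate those of the vessel.
#'
#' @slot n number of compartments
#' @slot volume compartment volumes (m3)
#' @slot flow n x n broth exchange matrix (kg/s); \code{flow[i, j]} is
#'   the convective flow from compartment i to j, diagonal zero
#' @slot feed substrate feed into each compartment (mol_s/s)
#' @slot Cx biomass concentration per compartment (Cmol_x/kg)
#' @slot rho broth density (kg/m3)
#' @slot labels free-text compartment labels
#'
#' @details Validity enforces the incompressible constant-holdup
#' balance: total flow out of every compartment equals total flow in.
#'
#' @seealso [compartmentNetwork()], [buildDefaultFermentor()],
#'   [steadySubstrateField()], [simulateLifelines()]
#' @exportClass CompartmentNetwork
setClass("CompartmentNetwork",
  representation(n = "integer", volume = "numeric", flow = "matrix",
                 feed = "numeric", Cx = "numeric", rho = "numeric",
                 labels = "character")
)

setValidity("CompartmentNetwork", function(object) {
  n <- object@n
  msgs <- character()
  if (length(object@volume) != n || any(object@volume <= 0))
    msgs <- c(msgs, "'volume' must be n positive values")
  if (!is.numeric(object@flow) || !all(dim(object@flow) == c(n, n)))
    msgs <- c(msgs, "'flow' must be an n x n numeric matrix")
  else {
    if (any(diag(object@flow) != 0))
      msgs <- c(msgs, "diagonal of 'flow' must be zero")
    if (any(object@flow < 0))
      msgs <- c(msgs, "off-diagonal flows must be >= 0")
    imb <- rowSums(object@flow) - colSums(object@flow)
    scale <- max(rowSums(object@flow), 1e-300)
    if (max(abs(imb)) > 1e-8 * scale)
      msgs <- c(msgs, "mass balance violated: flow out != flow in for some compartment")
  }
  if (length(object@feed) != n || any(object@feed < 0))
    msgs <- c(msgs, "'feed' must be n values >= 0")
  if (length(object@Cx) != n || any(object@Cx < 0))
    msgs <- c(msgs, "'Cx' must be n values >= 0")
  if (length(object@rho) != 1L || object@rho <= 0)
    msgs <- c(msgs, "'rho' must be a single positive number")
  if (length(object@labels) != n)
    msgs <- c(msgs, "'labels' must have length n")
  if (length(msgs)) msgs else TRUE
})

#' Configuration of a lifeline simulation run
#'
#' @slot n_particles number of tracked particles
#' @slot duration simulated flow time (s)
#' @slot dt output sampling interval (s); default 0.03
#' @slot seed integer seed making the run bit-reproducible
#' @slot noise_sigma stationary standard deviation of the
#'   superimposed turbulence noise (dimensionless, in qs/qs_max space)
#' @slot noise_tau correlation time of the turbulence noise (s)
#'
#' @seealso [simulationConfig()], [simulateLifelines()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(n_particles = "integer", duration = "numeric",
                 dt = "numeric", seed = "integer",
                 noise_sigma = "numeric", noise_tau = "numeric")
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@n_particles < 1L) msgs <- c(msgs, "'n_particles' must be >= 1")
  if (object@dt <= 0) msgs <- c(msgs, "'dt' must be > 0")
  if (object@duration < object@dt) msgs <- c(msgs, "'duration' must be >= dt")
  if (object@noise_sigma < 0) msgs <- c(msgs, "'noise_sigma' must be >= 0")
  if (object@noise_tau <= 0) msgs <- c(msgs, "'noise_tau' must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Set of organism lifelines
#'
#' A \linkS4class{SummarizedExperiment} holding per-particle,
#' uniformly sampled lifelines: rows are particles, columns are
#' timepoints. The canonical assay \code{"qs_frac"} stores the
#' normalized uptake rate qs/qs_max in [0, 1]; an optional assay
#' \code{"Cs"} holds the substrate concentration (mol/kg). The shared
#' time grid lives in \code{colData()$t} (seconds);
#' \code{metadata()} records kinetic parameters, simulation
#' configuration and processing provenance.
#'
#' @seealso [LifelineSet()], [qsFrac()], [lifelineTimes()]
#' @exportClass LifelineSet
setClass("LifelineSet", contains = "SummarizedExperiment")

setValidity("LifelineSet", function(object) {
  msgs <- character()
  if (!"t" %in% colnames(colData(object)))
    return("colData must contain a time column 't'")
  t <- colData(object)$t
  if (ncol(object) >= 2L) {
    dt <- diff(t)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1])
      msgs <- c(msgs, "time grid must be uniform and increasing")
  }
  if ("qs_frac" %in% assayNames(object)) {
    q <- assay(object, "qs_frac")
    if (anyNA(q) || min(q) < -1e-12 || max(q) > 1 + 1e-12)
      msgs <- c(msgs, "'qs_frac' values must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Run-length regime encoding of a lifeline set
#'
#' Per-particle segmentation of lifelines into contiguous visits to
#' the metabolic regimes E (excess), L (limitation) and S
#' (starvation). Segments are stored long-format in a data.frame with
#' columns \code{particle_id}, \code{regime}, \code{start},
#' \code{end}, \code{duration} (all times in seconds) and
#' \code{truncated_head}/\code{truncated_tail} flags marking the
#' first/last visit of each lifeline, whose true extent is unknown.
#'
#' @slot segments the segment table (see Description)
#' @slot dt sampling interval of the underlying lifelines (s)
#' @slot span duration covered by each lifeline (s)
#' @slot n_particles number of lifelines encoded
#'
#' @seealso [toRegimeSeries()], [extractTransitions()]
#' @exportClass RegimeSeries
setClass("RegimeSeries",
  representation(segments = "data.frame", dt = "numeric",
                 span = "numeric", n_particles = "integer")
)

setValidity("RegimeSeries", function(object) {
  seg <- object@segments
  need <- c("particle_id", "regime", "start", "end", "duration",
            "truncated_head", "truncated_tail")
  if (!all(need %in% colnames(seg)))
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  if (nrow(seg) && !all(seg$regime %in% c("E", "L", "S")))
    return("regime labels must be E, L or S")
  if (nrow(seg) && any(seg$duration < 0))
    return("segment durations must be >= 0")
  TRUE
})

#' Full pipeline analysis report
#'
#' Machine-readable result of [runPipeline()]: every statistic is
#' stored next to the settings that produced it, so each number is
#' traceable to a stage plus configuration.
#'
#' @slot provenance list: seed, configuration, filter settings
#' @slot ideal ideal-mixing reference block
#' @slot regime_fractions Eulerian/Lagrangian regime percentages
#' @slot residence per-pattern residence statistics
#' @slot fates transition fate fractions
#' @slot arcs arc statistics
#' @slot spectrum spectrum summary
#' @slot qp population product-rate block
#'
#' @seealso [runPipeline()], [writeReport()]
#' @exportClass AnalysisReport
setClass("AnalysisReport",
  representation(provenance = "list", ideal = "list",
                 regime_fractions = "list", residence = "list",
                 fates = "list", arcs = "list", spectrum = "list",
                 qp = "list")
)
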