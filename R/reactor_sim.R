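## Compartment-network surrogate of the stirred fermentor. Substrate
## is balanced over a small network of well-mixed zones; particles
## perform a continuous-time Markov jump process over the zones. The
## network is calibrated to the vessel's circulation statistics (mean
## loop time ~19 s, weak exchange across the mid-height impeller
## barrier), which are exactly the statistics the lifeline analysis
## consumes.

#' Build the default two-loop fermentor network
#'
#' Constructs a stacked-loop compartment network emulating the 54 m3
#' two-Rushton vessel: a top circulation loop containing the feed
#' zone and a bottom loop, joined by a single weak exchange
#' connection representing the axial-mixing barrier formed by the
#' diverging impeller jets. Each loop is a directed ring of equal
#' compartments whose circulation flow is set so one loop traversal
#' takes \code{tau_circ} on average; the barrier exchange is the
#' smallest flow in the network.
#'
#' @param globals a \linkS4class{ReactorGlobals}
#' @param params a \linkS4class{KineticParameters} (supplies the
#'   biomass concentration)
#' @param n number of compartments; 1 gives a single ideally mixed
#'   compartment, otherwise an even number >= 4
#' @param tau_circ target mean circulation (loop traversal) time, s
#' @param exchange_frac barrier exchange flow as a fraction of the
#'   loop circulation flow (default 0.25)
#' @return a \linkS4class{CompartmentNetwork}
#' @examples
#' net <- buildDefaultFermentor()
#' net
#' @export
buildDefaultFermentor <- function(globals = reactorGlobals(),
                                  params = kineticParameters(),
                                  n = 12, tau_circ = 19,
                                  exchange_frac = 0.25) {
  rho <- globals@rho
  if (n == 1) {
    return(compartmentNetwork(
      volume = globals@V, flow = matrix(0, 1, 1), feed = globals@F,
      Cx = params@Cx, rho = rho, labels = "ideally-mixed"))
  }
  if (n %% 2 != 0 || n < 4)
    stop("'n' must be 1 or an even number >= 4")
  m <- n %/% 2
  vol <- rep(globals@V / n, n)
  loop_mass <- rho * globals@V / 2
  Q <- loop_mass / tau_circ           # ring circulation flow, kg/s
  x <- exchange_frac * Q              # barrier exchange, kg/s
  flow <- matrix(0, n, n)
  ring <- function(idx) for (k in seq_along(idx))
    flow[idx[k], idx[k %% length(idx) + 1L]] <<- Q
  ring(1:m)
  ring((m + 1L):n)
  barrier_top <- m %/% 2 + 1L         # mid-ring node, at the impeller plane
  barrier_bot <- m + 1L
  flow[barrier_top, barrier_bot] <- flow[barrier_top, barrier_bot] + x
  flow[barrier_bot, barrier_top] <- flow[barrier_bot, barrier_top] + x
  feed <- numeric(n)
  feed[1L] <- globals@F               # feed enters at the top surface
  labels <- c("feed-zone", paste0("top-loop-", 2:m),
              paste0("bottom-loop-", 1:m))
  labels[barrier_top] <- "top-barrier"
  labels[barrier_bot] <- "bottom-barrier"
  compartmentNetwork(volume = vol, flow = flow, feed = feed,
                     Cx = params@Cx, rho = rho, labels = labels)
}

#' Steady substrate field over a compartment network
#'
#' Solves the coupled steady-state substrate balances
#' \deqn{\sum_j (Q_{ji} C_{s,j} - Q_{ij} C_{s,i}) + feed_i
#'       - m_i C_{x,i} q_s(C_{s,i}) = 0}
#' (with \code{m_i = rho * V_i} the compartment broth mass) by a
#' damped Newton iteration with the analytic Monod Jacobian.
#'
#' @param net a \linkS4class{CompartmentNetwork}
#' @param params a \linkS4class{KineticParameters}
#' @param tol absolute residual tolerance, as a fraction of the total
#'   feed (or total uptake capacity when feed is zero)
#' @param max_iter maximum Newton iterations
#' @return named numeric vector of compartment concentrations
#'   (mol/kg)
#' @examples
#' Cs <- steadySubstrateField(buildDefaultFermentor(), kineticParameters())
#' round(Cs / 7.8e-6, 3)  # in units of Ks: excess at feed, ~0 below barrier
#' @export
steadySubstrateField <- function(net, params, tol = 1e-12,
                                 max_iter = 200L) {
  stopifnot(is(net, "CompartmentNetwork"))
  mass <- net@rho * net@volume
  cap <- mass * net@Cx * params@qs_max
  scale <- max(sum(net@feed), sum(cap) * 1e-3)
  if (sum(net@feed) >= sum(cap))
    stop("infeasible: total feed exceeds total uptake capacity")
  resid <- function(Cs) {
    transport <- as.vector(crossprod(net@flow, Cs)) - rowSums(net@flow) * Cs
    transport + net@feed - mass * net@Cx * uptakeRate(Cs, params)
  }
  Cs <- rep(params@Ks, net@n)
  r <- resid(Cs)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) <= tol * scale) break
    J <- t(net@flow) - diag(rowSums(net@flow), net@n) -
      diag(mass * net@Cx * uptakeRateDeriv(Cs, params), net@n)
    step <- tryCatch(solve(J, -r), error = function(e)
      stop("steady-state solve failed: singular Jacobian (residual norm ",
           format(max(abs(r))), ")"))
    lambda <- 1
    repeat {
      Cs_new <- pmax(Cs + lambda * step, 0)
      r_new <- resid(Cs_new)
      if (max(abs(r_new)) < max(abs(r)) || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    Cs <- Cs_new
    r <- r_new
  }
  if (max(abs(r)) > tol * scale * 100)
    stop("steady-state solve did not converge: residual norm ",
         format(max(abs(r))), " mol/s")
  names(Cs) <- net@labels
  Cs
}

#' Stationary compartment occupancy of the particle jump process
#'
#' For the continuous-time jump process with exit rate
#' \code{sum_j Q_ij / (rho V_i)} and destination probabilities
#' proportional to the flows, the stationary law solves
#' \code{pi Q = 0}. For any mass-balanced network this is
#' proportional to compartment broth mass, i.e. particles distribute
#' homogeneously over the broth.
#'
#' @param net a \linkS4class{CompartmentNetwork}
#' @return named probability vector over compartments
#' @export
stationaryDistribution <- function(net) {
  if (net@n == 1L) return(stats::setNames(1, net@labels))
  mass <- net@rho * net@volume
  rates <- net@flow / mass            # generator off-diagonals
  Q <- rates
  diag(Q) <- -rowSums(rates)
  A <- rbind(t(Q), rep(1, net@n))     # pi Q = 0, sum(pi) = 1
  pi_hat <- qr.solve(A, c(rep(0, net@n), 1))
  stats::setNames(pmax(pi_hat, 0) / sum(pmax(pi_hat, 0)), net@labels)
}

## one particle's compartment index on the output grid
.simulate_path <- function(start, rate, cum_p, dest_idx, n_grid, dt) {
  horizon <- n_grid * dt
  times <- numeric(64)
  states <- integer(64)
  k <- 0L
  t_now <- 0
  s <- start
  while (t_now <= horizon) {
    k <- k + 1L
    if (k > length(times)) {
      length(times) <- 2L * length(times)
      length(states) <- 2L * length(states)
    }
    times[k] <- t_now
    states[k] <- s
    if (rate[s] <= 0) break                      # absorbing (single compartment)
    t_now <- t_now + stats::rexp(1L, rate[s])
    row <- cum_p[s, ]
    s <- dest_idx[s, findInterval(stats::runif(1L), row) + 1L]
  }
  states[findInterval((seq_len(n_grid) - 1L) * dt, times[seq_len(k)])]
}

#' Simulate organism lifelines on a compartment network
#'
#' Each particle performs a continuous-time Markov jump process over
#' the compartments: the rate of leaving compartment i is the total
#' outflow divided by the compartment broth mass, and the destination
#' is drawn proportionally to the individual flows. The lifeline
#' records the normalized uptake qs/qs_max of the occupied
#' compartment on a uniform output grid.
#'
#' In \code{"frozen_field"} mode (the default, appropriate for the
#' statistically steady gradient) compartment concentrations are the
#' steady field; in \code{"dynamic"} mode they evolve concurrently
#' with feeding and consumption from \code{Cs0}, integrated with
#' \code{deSolve} together with a cumulative-consumption state so
#' substrate conservation can be audited exactly
#' (\code{metadata()$mass_balance}).
#'
#' Runs are bit-reproducible for a given \code{config@seed}.
#'
#' @param net a \linkS4class{CompartmentNetwork}
#' @param config a \linkS4class{SimulationConfig}
#' @param params a \linkS4class{KineticParameters}
#' @param mode "frozen_field" or "dynamic"
#' @param Cs0 initial concentrations for dynamic mode (default: the
#'   steady field)
#' @param store_Cs also store the Cs lifelines as an assay
#' @param noise apply the configured turbulence noise (default TRUE;
#'   a zero \code{noise_sigma} disables it regardless)
#' @return a \linkS4class{LifelineSet}
#' @examples
#' net <- buildDefaultFermentor()
#' cfg <- simulationConfig(n_particles = 5, duration = 60, seed = 7)
#' simulateLifelines(net, cfg, kineticParameters())
#' @export
simulateLifelines <- function(net, config, params,
                              mode = c("frozen_field", "dynamic"),
                              Cs0 = NULL, store_Cs = FALSE,
                              noise = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is(net, "CompartmentNetwork"), is(config, "SimulationConfig"))
  dt <- config@dt
  n_grid <- as.integer(floor(config@duration / dt)) + 1L
  t_grid <- (seq_len(n_grid) - 1L) * dt
  mass <- net@rho * net@volume
  out_flow <- rowSums(net@flow)
  rate <- out_flow / mass
  if (any(rate > 0) && dt > min(1 / rate[rate > 0]))
    warning("output dt exceeds the shortest mean compartment residence time; ",
            "fast visits will be aliased")
  ## destination tables (cumulative probabilities over positive flows)
  cum_p <- matrix(1, net@n, net@n)
  dest_idx <- matrix(1L, net@n, net@n)
  for (i in seq_len(net@n)) {
    j <- which(net@flow[i, ] > 0)
    if (length(j)) {
      p <- net@flow[i, j] / out_flow[i]
      cum_p[i, seq_along(j)] <- cumsum(p)
      cum_p[i, ] <- pmin(cum_p[i, ], 1)
      dest_idx[i, seq_along(j)] <- j
    }
  }
  Cs_steady <- steadySubstrateField(net, params)
  withr::local_seed(deriveSeed(config@seed, "simulate"))
  pi0 <- stationaryDistribution(net)
  starts <- sample.int(net@n, config@n_particles, replace = TRUE, prob = pi0)
  comp <- matrix(0L, config@n_particles, n_grid)
  for (p in seq_len(config@n_particles))
    comp[p, ] <- .simulate_path(starts[p], rate, cum_p, dest_idx, n_grid, dt)

  if (mode == "frozen_field") {
    Cs_field <- NULL
    mass_balance <- NULL
  } else {
    if (is.null(Cs0)) Cs0 <- Cs_steady
    derivs <- function(t, y, parms) {
      Cs <- pmax(y[seq_len(net@n)], 0)
      uptake <- mass * net@Cx * uptakeRate(Cs, params)
      transport <- as.vector(crossprod(net@flow, Cs)) - out_flow * Cs
      list(c((transport + net@feed - uptake) / mass, sum(uptake)))
    }
    sol <- deSolve::ode(y = c(Cs0, consumed = 0), times = t_grid,
                        func = derivs, parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-16)
    Cs_field <- sol[, 1L + seq_len(net@n), drop = FALSE]
    fed <- sum(net@feed) * (t_grid[n_grid] - t_grid[1L])
    consumed <- sol[n_grid, "consumed"]
    accumulated <- sum(mass * (Cs_field[n_grid, ] - Cs_field[1L, ]))
    mass_balance <- list(
      fed = fed, consumed = consumed, accumulated = accumulated,
      residual_rel = (fed - consumed - accumulated) /
        max(fed, consumed, abs(accumulated)))
  }
  if (mode == "frozen_field") {
    qfrac_comp <- uptakeRate(Cs_steady, params) / params@qs_max
    qmat <- matrix(qfrac_comp[comp], config@n_particles, n_grid)
    Cs_mat <- if (store_Cs) matrix(Cs_steady[comp], config@n_particles, n_grid)
  } else {
    ## Cs_field is n_grid x n (time-varying); index by (time, compartment)
    idx <- cbind(rep(seq_len(n_grid), each = config@n_particles),
                 as.vector(comp))
    qfrac_field <- uptakeRate(Cs_field, params) / params@qs_max
    qmat <- matrix(qfrac_field[idx], config@n_particles, n_grid)
    Cs_mat <- if (store_Cs) matrix(Cs_field[idx], config@n_particles, n_grid)
  }

  ll <- LifelineSet(
    qs_frac = qmat, t = t_grid, Cs = Cs_mat,
    metadata = list(
      provenance = paste0("simulate[", mode, "]"),
      value_type = "qs_frac",
      params = paramsAsList(params),
      config = list(n_particles = config@n_particles,
                    duration = config@duration, dt = dt,
                    seed = config@seed,
                    noise = list(sigma = config@noise_sigma,
                                 tau_corr = config@noise_tau)),
      network = list(n = net@n, labels = net@labels,
                     volume = net@volume, Cs_steady = Cs_steady),
      mass_balance = mass_balance))
  if (noise && config@noise_sigma > 0)
    ll <- addTurbulenceNoise(ll, config@noise_sigma, config@noise_tau,
                             seed = deriveSeed(config@seed, "noise"))
  ll
}

#' Superimpose turbulence noise on lifelines
#'
#' Adds mean-zero, exponentially correlated (Ornstein-Uhlenbeck)
#' noise in qs/qs_max space, emulating the rapid low-amplitude
#' oscillations that turbulent dispersion superimposes on the
#' convective lifeline signal. The exact OU discretization is used,
#' so the sample standard deviation matches \code{sigma} and the
#' autocorrelation time matches \code{tau_corr}; results are clipped
#' to [0, 1].
#'
#' @param lifelines a \linkS4class{LifelineSet}
#' @param sigma stationary standard deviation (>= 0; 0 is identity)
#' @param tau_corr correlation time, s (> 0)
#' @param seed integer seed
#' @return a \linkS4class{LifelineSet}
#' @export
addTurbulenceNoise <- function(lifelines, sigma, tau_corr, seed = 1L) {
  stopifnot(is(lifelines, "LifelineSet"))
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (tau_corr <= 0) stop("'tau_corr' must be > 0")
  if (sigma == 0) return(lifelines)
  q <- qsFrac(lifelines)
  n <- nrow(q)
  K <- ncol(q)
  phi <- exp(-timeStep(lifelines) / tau_corr)
  innov_sd <- sigma * sqrt(1 - phi^2)
  withr::local_seed(as.integer(seed))
  z <- sigma * stats::rnorm(n)
  q[, 1L] <- q[, 1L] + z
  for (k in 2:K) {
    z <- phi * z + innov_sd * stats::rnorm(n)
    q[, k] <- q[, k] + z
  }
  q <- pmin(pmax(q, 0), 1)
  md <- metadata(lifelines)
  md$provenance <- c(md$provenance,
                     sprintf("noise[sigma=%g,tau=%g]", sigma, tau_corr))
  out <- LifelineSet(q, lifelineTimes(lifelines),
                     particle_id = particleIds(lifelines), metadata = md)
  out
}
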