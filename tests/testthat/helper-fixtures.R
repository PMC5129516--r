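# Shared fixtures: all inputs are built in code at test time.

ds_params <- kineticParameters()
ds_globals <- reactorGlobals()

# lifeline set from a vector (one track) or matrix of qs_frac values
make_ll <- function(x, dt = 0.03) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  LifelineSet(x, t = (seq_len(ncol(x)) - 1) * dt)
}

# lifeline built from regime-level durations (seconds):
# levels is a vector of qs_frac values, durations their lengths
make_step_ll <- function(levels, durations, dt = 1) {
  make_ll(rep(levels, times = round(durations / dt)), dt = dt)
}

# symmetric two-compartment network: equal volumes V (m3), exchange Q (kg/s)
two_compartment_net <- function(V = 27, Q = 1000, feed = c(0.37, 0),
                                rho = 1000, Cx = 1.96) {
  compartmentNetwork(volume = c(V, V),
                     flow = matrix(c(0, Q, Q, 0), 2, 2),
                     feed = feed, Cx = Cx, rho = rho)
}

# independent reference integrator for the qp dynamics: classical RK4
# on dqp/dt = a(Cs) - b(Cs) qp with piecewise-constant forcing,
# refined substeps per sample
ref_integrate_qp <- function(qs_frac, t, params, qp0 = 0, refine = 10) {
  n <- length(qs_frac)
  dt_h <- (t[2] - t[1]) / 3600
  Cs <- invertUptake(qs_frac, params)
  mu <- growthRate(uptakeRate(Cs, params), params)
  a <- params@beta * pmax(0, mu) / (1 + (Cs / params@Kp)^2)
  b <- params@KdE + mu
  qp <- numeric(n)
  qp[1] <- qp0
  h <- dt_h / refine
  for (k in 2:n) {
    y <- qp[k - 1]
    f <- function(y) a[k - 1] - b[k - 1] * y
    for (s in seq_len(refine)) {
      k1 <- f(y); k2 <- f(y + h * k1 / 2)
      k3 <- f(y + h * k2 / 2); k4 <- f(y + h * k3)
      y <- y + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    }
    qp[k] <- y
  }
  qp
}

# brute-force excursion scanner: all maximal runs beyond a boundary
# with their peak depths (oracle for the amplitude filter)
brute_force_excursions <- function(x, bound, above) {
  beyond <- if (above) x > bound else x < bound
  out <- list()
  k <- 1
  while (k <= length(x)) {
    if (beyond[k]) {
      j <- k
      while (j < length(x) && beyond[j + 1]) j <- j + 1
      depth <- if (above) max(x[k:j]) - bound else bound - min(x[k:j])
      out[[length(out) + 1]] <- list(start = k, end = j, depth = depth)
      k <- j + 1
    } else k <- k + 1
  }
  out
}

# expected hitting time of `target` for the compartment jump process,
# by linear solve on the generator (independent CTMC oracle)
ctmc_hitting_times <- function(net, target) {
  mass <- net@rho * net@volume
  R <- net@flow / mass                  # off-diagonal rates
  n <- net@n
  idx <- setdiff(seq_len(n), target)
  A <- matrix(0, length(idx), length(idx))
  rhs <- rep(-1, length(idx))
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    A[ii, ii] <- -sum(R[i, ])
    for (jj in seq_along(idx)) {
      j <- idx[jj]
      if (i != j) A[ii, jj] <- A[ii, jj] + R[i, j]
    }
  }
  h <- solve(A, rhs)
  full <- numeric(n)
  full[idx] <- h
  full
}
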