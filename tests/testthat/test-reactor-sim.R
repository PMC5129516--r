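test_that("default fermentor network is balanced, zoned, and calibrated", {
  net <- buildDefaultFermentor(ds_globals, ds_params)
  expect_s4_class(net, "CompartmentNetwork")
  expect_identical(net@n, 12L)
  # constructor invariant: row mass balance exact
  expect_equal(rowSums(net@flow), colSums(net@flow))
  expect_equal(sum(net@feed), ds_globals@F)
  expect_equal(sum(net@volume), ds_globals@V)
  # barrier exchange is the smallest flow in the network
  pos <- net@flow[net@flow > 0]
  expect_lt(min(pos), max(pos) / 2)
  bt <- which(net@labels == "top-barrier")
  bb <- which(net@labels == "bottom-barrier")
  expect_equal(net@flow[bt, bb], min(pos))
  # ring circulation flow gives the configured loop traversal time:
  # mean first-return to the feed zone around the isolated top ring,
  # by linear solve on the jump-process generator
  net0 <- buildDefaultFermentor(ds_globals, ds_params, exchange_frac = 0)
  m <- net0@n %/% 2
  top <- compartmentNetwork(volume = net0@volume[1:m],
                            flow = net0@flow[1:m, 1:m],
                            feed = rep(0, m), Cx = ds_params@Cx)
  h <- ctmc_hitting_times(top, target = 1)
  loop_time <- (top@rho * top@volume[1] / sum(top@flow[1, ])) + h[2]
  expect_equal(loop_time, 19, tolerance = 1e-10)
})

test_that("single-compartment request gives an ideally mixed reactor", {
  net <- buildDefaultFermentor(ds_globals, ds_params, n = 1)
  expect_identical(net@n, 1L)
  Cs <- steadySubstrateField(net, ds_params)
  expect_equal(unname(Cs), residualConcentration(ds_globals, ds_params),
               tolerance = 1e-10)
  expect_error(buildDefaultFermentor(n = 5), "even")
})

test_that("steady field balances feed against consumption and mirrors zoning", {
  p <- ds_params
  net <- buildDefaultFermentor(ds_globals, p)
  Cs <- steadySubstrateField(net, p)
  expect_true(all(Cs >= 0))
  mass <- net@rho * net@volume
  consumed <- sum(mass * net@Cx * uptakeRate(Cs, p))
  expect_equal(consumed, sum(net@feed), tolerance = 1e-8)
  # monotone decrease from the feed zone down the top loop
  m <- net@n %/% 2
  expect_true(all(diff(Cs[1:m]) < 0))
  # excess at the feed, starvation below the barrier
  f <- uptakeRate(Cs, p) / p@qs_max
  expect_gt(f[1], 0.95)
  expect_true(all(f[(m + 1):net@n] < 0.05))
  # zero feed -> identically zero field
  net0 <- compartmentNetwork(volume = net@volume, flow = net@flow,
                             feed = rep(0, net@n), Cx = p@Cx)
  expect_equal(max(abs(steadySubstrateField(net0, p))), 0)
})

test_that("network validity catches unbalanced flows", {
  flow <- matrix(c(0, 5, 0, 0), 2, 2)   # 1 -> 2 only: holdup not constant
  expect_error(compartmentNetwork(volume = c(1, 1), flow = flow,
                                  feed = c(0, 0)),
               "mass balance")
})

test_that("jump process matches its analytic laws on two compartments", {
  net <- two_compartment_net(V = 1, Q = 500,   # mean residence 2 s each
                             feed = c(0.01, 0))
  cfg <- simulationConfig(n_particles = 400, duration = 120, dt = 0.03,
                          seed = 42, noise_sigma = 0)
  ll <- simulateLifelines(net, cfg, ds_params)
  q <- qsFrac(ll)
  # long-run occupancy 0.5/0.5 within 3 standard errors
  lvl <- sort(unique(as.vector(q)))
  expect_length(lvl, 2)
  occ <- mean(q == lvl[1])
  se <- sqrt(0.25 / (400 * 120 / (2 * 2)))  # ~independent visits
  expect_lt(abs(occ - 0.5), 3 * se)
  # per-visit residence times exponential with mean rho V / Q = 2 s
  res <- unlist(lapply(seq_len(nrow(q)), function(i) {
    r <- rle(q[i, ])
    r$lengths[-c(1, length(r$lengths))] * 0.03
  }))
  expect_equal(mean(res), 2, tolerance = 0.1)
  # de-discretize the grid-quantized durations with uniform jitter and
  # test a moderate subsample so KS probes the law, not the 0.03 s grid
  set.seed(1)
  res_ks <- res[seq_len(3000)] + stats::runif(3000, -0.015, 0.015)
  ks <- suppressWarnings(stats::ks.test(res_ks, "pexp", rate = 1 / 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("stationary law is volume-proportional and chi-square consistent", {
  net <- buildDefaultFermentor(ds_globals, ds_params)
  pi0 <- stationaryDistribution(net)
  expect_equal(unname(pi0), net@volume / sum(net@volume), tolerance = 1e-10)
  # empirical end-state occupancy over many particles
  cfg <- simulationConfig(n_particles = 10000, duration = 40, dt = 20,
                          seed = 11, noise_sigma = 0)
  ll <- suppressWarnings(simulateLifelines(net, cfg, ds_params,
                                           store_Cs = TRUE))
  Cs_end <- assay(ll, "Cs")[, ncol(ll)]
  lvl <- steadySubstrateField(net, ds_params)
  counts <- table(factor(match(round(Cs_end, 12), round(lvl, 12)),
                         levels = seq_len(net@n)))
  chi <- stats::chisq.test(as.vector(counts), p = unname(pi0))
  expect_gt(chi$p.value, 0.01)
})

test_that("identical seeds give identical lifelines, different seeds differ", {
  net <- buildDefaultFermentor(ds_globals, ds_params)
  cfg <- simulationConfig(n_particles = 20, duration = 30, seed = 9)
  a <- simulateLifelines(net, cfg, ds_params)
  b <- simulateLifelines(net, cfg, ds_params)
  expect_identical(qsFrac(a), qsFrac(b))
  cfg2 <- simulationConfig(n_particles = 20, duration = 30, seed = 10)
  expect_false(identical(qsFrac(a),
                         qsFrac(simulateLifelines(net, cfg2, ds_params))))
})

test_that("coarse output sampling triggers the aliasing warning", {
  net <- two_compartment_net(V = 1, Q = 500, feed = c(0.01, 0))  # residence 2 s
  cfg <- simulationConfig(n_particles = 2, duration = 40, dt = 10, seed = 1,
                          noise_sigma = 0)
  expect_warning(simulateLifelines(net, cfg, ds_params), "aliased")
})

test_that("dynamic mode conserves substrate to 1e-6 relative", {
  p <- ds_params
  net <- buildDefaultFermentor(ds_globals, p)
  cfg <- simulationConfig(n_particles = 2, duration = 60, dt = 0.1,
                          seed = 3, noise_sigma = 0)
  # start away from steady state so accumulation is nonzero
  ll <- simulateLifelines(net, cfg, p, mode = "dynamic",
                          Cs0 = rep(2e-5, net@n))
  mb <- metadata(ll)$mass_balance
  expect_false(is.null(mb))
  expect_gt(abs(mb$accumulated), 0)
  expect_lt(abs(mb$residual_rel), 1e-6)
})

test_that("turbulence noise has the configured variance and correlation", {
  t <- seq(0, 600, by = 0.03)
  base <- make_ll(matrix(0.5, 4, length(t)))
  noisy <- addTurbulenceNoise(base, sigma = 0.05, tau_corr = 0.3, seed = 5)
  z <- qsFrac(noisy) - 0.5
  expect_equal(sd(as.vector(z)), 0.05, tolerance = 0.05)
  # autocorrelation time: first crossing of 1/e
  ac <- stats::acf(z[1, ], lag.max = 60, plot = FALSE)$acf
  tau_est <- (which(ac < exp(-1))[1] - 1) * 0.03
  expect_equal(tau_est, 0.3, tolerance = 0.25)
  # sigma = 0 is the identity
  expect_identical(qsFrac(addTurbulenceNoise(base, 0, 0.3)), qsFrac(base))
  # clipping keeps values inside [0, 1]
  hi <- make_ll(matrix(0.99, 2, length(t)))
  qn <- qsFrac(addTurbulenceNoise(hi, sigma = 0.2, tau_corr = 0.3, seed = 1))
  expect_true(all(qn >= 0 & qn <= 1))
  expect_gt(mean(qn == 1), 0)   # clipping actually engaged
})
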