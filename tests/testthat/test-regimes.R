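test_that("regime classification follows the strict 0.05/0.95 boundaries", {
  expect_identical(classifyRegime(c(0.96, 0.5, 0.01)), c("E", "L", "S"))
  # boundary samples belong to L (strict inequalities for E and S)
  expect_identical(classifyRegime(c(0.95, 0.05)), c("L", "L"))
  # Monod arithmetic: Cs = 19 Ks maps onto the E/L boundary -> L
  f <- uptakeRate(19 * ds_params@Ks, ds_params) / ds_params@qs_max
  expect_identical(classifyRegime(f), "L")
  expect_error(classifyRegime(1.2), "0, 1")
  # regime changes happen exactly at the 19 Ks and Ks/19 crossings
  Cs <- c(18.9, 19.1, 1 / 19.1, 1 / 18.9) * ds_params@Ks
  f <- uptakeRate(Cs, ds_params) / ds_params@qs_max
  expect_identical(classifyRegime(f), c("L", "E", "S", "L"))
})

test_that("run-length segmentation reproduces hand-built visit durations", {
  # E(5 s) L(2 s) S(7 s) L(3 s) E(4 s) at 1 s sampling
  ll <- make_step_ll(c(0.99, 0.5, 0.01, 0.5, 0.99), c(5, 2, 7, 3, 4))
  rs <- toRegimeSeries(ll)
  seg <- regimeSegments(rs)
  expect_equal(seg$regime, c("E", "L", "S", "L", "E"))
  expect_equal(seg$duration, c(5, 2, 7, 3, 4))
  expect_equal(seg$truncated_head, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(seg$truncated_tail, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # durations always sum to the lifeline span
  expect_equal(sum(seg$duration), rs@span)
  # constant series: one segment, both truncation flags set
  rs1 <- toRegimeSeries(make_ll(rep(0.5, 40)))
  seg1 <- regimeSegments(rs1)
  expect_equal(nrow(seg1), 1L)
  expect_true(seg1$truncated_head && seg1$truncated_tail)
})

test_that("segment durations sum to span on arbitrary random lifelines", {
  set.seed(5)
  q <- matrix(runif(6 * 300), 6)
  rs <- toRegimeSeries(make_ll(q, dt = 0.03))
  seg <- regimeSegments(rs)
  sums <- tapply(seg$duration, seg$particle_id, sum)
  expect_equal(unname(as.vector(sums)), rep(rs@span, 6))
  # segments are contiguous and alternate regimes within each particle
  for (chunk in split(seg, seg$particle_id)) {
    expect_equal(chunk$start[-1], chunk$end[-nrow(chunk)])
    expect_true(all(chunk$regime[-1] != chunk$regime[-nrow(chunk)]))
  }
})

test_that("transition extraction labels the hand series correctly", {
  ll <- make_step_ll(c(0.99, 0.5, 0.01, 0.5, 0.99), c(5, 2, 7, 3, 4))
  ev <- extractTransitions(toRegimeSeries(ll))
  expect_equal(ev$pattern, c("ELS", "LSL", "SLE"))
  expect_equal(ev$residence, c(2, 7, 3))
  expect_equal(attr(ev, "truncated"), 2L)
  expect_equal(attr(ev, "direct_crossings"), 0L)
  # single-segment series: no events
  ev0 <- extractTransitions(toRegimeSeries(make_ll(rep(0.5, 10))))
  expect_equal(nrow(ev0), 0L)
})

test_that("alternating E/L square wave yields only LEL and ELE events", {
  n_cycles <- 6
  ll <- make_step_ll(rep(c(0.99, 0.5), n_cycles),
                     rep(c(3, 4), n_cycles))
  ev <- extractTransitions(toRegimeSeries(ll))
  # 2*n_cycles segments, minus two truncated
  expect_equal(nrow(ev), 2L * n_cycles - 2L)
  expect_true(all(ev$pattern %in% c("LEL", "ELE")))
  expect_equal(sum(ev$pattern == "LEL"), n_cycles - 1L)
})

test_that("direct E-S jumps are repaired with zero-duration L visits", {
  ll <- make_step_ll(c(0.5, 0.99, 0.01, 0.5), c(3, 4, 5, 3))
  expect_warning(ev <- extractTransitions(toRegimeSeries(ll)),
                 "direct E<->S")
  expect_equal(attr(ev, "direct_crossings"), 1L)
  i <- which(ev$residence == 0)
  expect_equal(ev$pattern[i], "ELS")
  # bookkeeping still exact: the E visit's destination is now L
  expect_equal(ev$pattern[ev$regime == "E"], "LEL")
})

test_that("transition bookkeeping identities hold exactly", {
  set.seed(13)
  q <- matrix(pmin(pmax(0.5 + apply(matrix(rnorm(4 * 500, 0, 0.12), 4), 1,
                                    cumsum), 0), 1), nrow = 4, byrow = TRUE)
  rs <- toRegimeSeries(make_ll(q, dt = 0.03))
  seg <- regimeSegments(rs)
  ev <- suppressWarnings(extractTransitions(rs))
  for (r in c("E", "L", "S")) {
    # sum of event residences = total non-truncated time in the regime
    interior <- seg$regime == r & !seg$truncated_head & !seg$truncated_tail
    expect_equal(sum(ev$residence[ev$regime == r]),
                 sum(seg$duration[interior]))
  }
  # count identity: L visits entered from E split into ELE + ELS
  expect_equal(sum(ev$pattern %in% c("ELE", "ELS")),
               sum(ev$regime == "L" & ev$origin == "E"))
  expect_equal(sum(ev$pattern %in% c("SLE", "SLS")),
               sum(ev$regime == "L" & ev$origin == "S"))
})

test_that("residence distributions count, bin and average correctly", {
  ev <- data.frame(particle_id = 1, pattern = rep(c("ELE", "LSL"), c(5, 3)),
                   regime = rep(c("L", "S"), c(5, 3)),
                   origin = rep(c("E", "L"), c(5, 3)),
                   destination = rep(c("E", "L"), c(5, 3)),
                   residence = c(1, 2, 3, 4, 5, 8, 9, 10), start = 0)
  rd <- residenceDistribution(ev, "ELE")
  expect_equal(sum(rd$counts), 5)
  expect_equal(rd$mean, 3)
  expect_equal(rd$n, 5)
  # empty pattern: zero histogram, absent mean
  rd0 <- residenceDistribution(ev, "SLE")
  expect_equal(sum(rd0$counts), 0)
  expect_true(is.na(rd0$mean))
  expect_error(residenceDistribution(ev, "XYZ"), "must be one of")
})

test_that("synthetic exponential residences recover the decay rate", {
  set.seed(99)
  res <- rexp(4000, rate = 1 / 3)
  ev <- data.frame(particle_id = 1, pattern = "LEL", regime = "E",
                   origin = "L", destination = "L",
                   residence = res, start = 0)
  rd <- residenceDistribution(ev, "LEL")
  # exponential MLE of the rate is 1/mean
  expect_equal(1 / rd$mean, 1 / 3, tolerance = 0.05)
  expect_equal(sum(rd$counts), 4000)
})

test_that("fate fractions normalize per origin", {
  ev <- data.frame(particle_id = 1,
                   pattern = rep(c("ELE", "ELS", "SLS", "SLE"),
                                 c(39, 61, 80, 20)),
                   regime = "L",
                   origin = rep(c("E", "E", "S", "S"), c(39, 61, 80, 20)),
                   destination = rep(c("E", "S", "S", "E"),
                                     c(39, 61, 80, 20)),
                   residence = 1, start = 0)
  ff <- transitionFateFractions(ev, "L")
  expect_equal(ff$fraction[ff$pattern == "ELE"], 0.39)
  expect_equal(ff$fraction[ff$pattern == "SLS"], 0.80)
  for (o in unique(ff$origin))
    expect_equal(sum(ff$fraction[ff$origin == o]), 1)
  # degenerate all-one-pattern input
  ev2 <- ev[ev$pattern == "ELE", ]
  ff2 <- transitionFateFractions(ev2, "L")
  expect_equal(ff2$fraction, 1)
})

test_that("regime fractions: Eulerian weighting and degenerate fields", {
  p <- ds_params
  # uniform excess field
  net <- two_compartment_net(V = 27, Q = 1000)
  fr <- regimeFractions(net, p, Cs = c(1e-3, 1e-3))
  expect_equal(unname(fr), c(100, 0, 0))
  # one excess + one starvation compartment, equal volumes
  fr2 <- regimeFractions(net, p, Cs = c(1e-3, 1e-9))
  expect_equal(unname(fr2), c(50, 0, 50))
  # Lagrangian: fractions over all particle-samples
  ll <- make_ll(matrix(c(0.99, 0.5, 0.01, 0.5), 2, 2))
  expect_equal(sum(regimeFractions(ll)), 100)
})

test_that("Eulerian and Lagrangian fractions agree on the default fermentor", {
  p <- ds_params
  net <- buildDefaultFermentor(ds_globals, p)
  eul <- regimeFractions(net, p)
  cfg <- simulationConfig(n_particles = 3000, duration = 300, dt = 1,
                          seed = 17, noise_sigma = 0)
  lag <- regimeFractions(suppressWarnings(
    simulateLifelines(net, cfg, p)))
  expect_lt(max(abs(eul - lag)), 2)
})
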