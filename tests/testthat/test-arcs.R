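test_that("sine lifeline produces alternating analytic arcs", {
  T_p <- 12                       # period, multiple of 4 dt
  dt <- 0.03
  t <- seq(0, 20 * T_p, by = dt)
  ll <- make_ll(0.5 + 0.3 * sin(2 * pi * t / T_p), dt = dt)
  arcs <- detectArcs(ll)
  expect_gt(nrow(arcs), 30)
  # alternating directions, half-period durations, amplitude magnitude
  expect_true(all(abs(arcs$tau_arc - T_p / 2) <= dt + 1e-9))
  expect_equal(mean(arcs$M_arc), 0.3, tolerance = 1e-3)
  expect_true(all(arcs$direction[c(TRUE, FALSE)] ==
                  arcs$direction[1]))
  st <- arcStatistics(arcs)
  expect_equal(st$fraction_up, 0.5, tolerance = 0.03)
  # symmetric waveform: extreme at mid-arc in both directions
  expect_equal(st$mean_peak_up, 0.5, tolerance = 0.01)
  expect_equal(st$mean_peak_down, 0.5, tolerance = 0.01)
})

test_that("monotone series and tangential touches give no arcs", {
  ll <- make_ll(seq(0.1, 0.9, length.out = 50))
  expect_equal(nrow(detectArcs(ll)), 0L)
  # a touch of the baseline without sign change does not split an arc:
  # the up stretch containing the 0.5 touch stays one arc of 3 samples
  x <- c(0.4, 0.6, 0.5, 0.6, 0.4, 0.6)
  arcs <- detectArcs(make_ll(x, dt = 1), restrict_to_L = FALSE)
  expect_equal(arcs$direction, c("up", "down"))
  expect_equal(arcs$tau_arc, c(3, 1))
  expect_equal(arcs$M_arc, c(0.1, 0.1))
})

test_that("sawtooth peak timing follows the waveform slope ratio", {
  # up-arc rising fast (1 s) and falling slow (3 s): t_max / tau = 0.25
  dt <- 0.01
  period <- 8
  nodes_t <- c(0, 1, 4, 6, 8)
  nodes_x <- c(0.5, 0.8, 0.5, 0.2, 0.5)
  t <- seq(0, 12 * period, by = dt)
  x <- stats::approx(nodes_t, nodes_x, xout = t %% period)$y
  arcs <- detectArcs(make_ll(x, dt = dt))
  up <- arcs[arcs$direction == "up", ]
  expect_gt(nrow(up), 5)
  expect_equal(mean(up$t_max / up$tau_arc), 0.25, tolerance = 0.02)
  expect_equal(mean(up$M_arc), 0.3, tolerance = 0.01)
  dn <- arcs[arcs$direction == "down", ]
  expect_equal(mean(dn$t_max / dn$tau_arc), 0.5, tolerance = 0.02)
})

test_that("arcs restricted to L discard excursions touching E or S", {
  # three complete arcs: up into excess (discarded under restriction),
  # down inside L, up inside L
  x <- c(0.4, rep(0.97, 3), rep(0.3, 3), rep(0.7, 2), 0.3)
  ll <- make_ll(x)
  a_all <- detectArcs(ll, restrict_to_L = FALSE)
  a_L <- detectArcs(ll, restrict_to_L = TRUE)
  expect_equal(nrow(a_all), 3L)
  expect_equal(nrow(a_L), 2L)
  expect_equal(a_L$direction, c("down", "up"))
  expect_true(all(a_L$M_arc <= 0.45))
  expect_error(detectArcs(ll, baseline = 0.97), "strictly inside")
})

test_that("arc partition tiles the span between first and last crossing", {
  set.seed(31)
  x <- pmin(pmax(0.5 + cumsum(rnorm(2000, 0, 0.05)), 0), 1)
  ll <- make_ll(x, dt = 0.03)
  arcs <- detectArcs(ll, restrict_to_L = FALSE)
  if (nrow(arcs) > 1) {
    starts <- arcs$t_start
    ends <- arcs$t_start + arcs$tau_arc
    expect_equal(starts[-1], ends[-nrow(arcs)])
  }
})

test_that("time reversal preserves tau, M and excursion side", {
  # an excursion above the baseline is still above it when the
  # lifeline is played backwards: durations, magnitudes and direction
  # labels are all invariant, only the arc order and peak timing flip
  set.seed(8)
  x <- pmin(pmax(0.5 + cumsum(rnorm(1500, 0, 0.04)), 0.06), 0.94)
  fwd <- detectArcs(make_ll(x, dt = 0.03))
  rev_ <- detectArcs(make_ll(rev(x), dt = 0.03))
  expect_equal(nrow(fwd), nrow(rev_))
  expect_equal(sort(fwd$tau_arc), sort(rev_$tau_arc))
  expect_equal(sort(fwd$M_arc), sort(rev_$M_arc), tolerance = 1e-12)
  expect_equal(table(fwd$direction), table(rev_$direction))
  # arc-by-arc: the reversed list is the forward list read backwards
  expect_equal(rev_$tau_arc, rev(fwd$tau_arc))
  expect_equal(rev_$M_arc, rev(fwd$M_arc))
})

test_that("arc statistics equal brute-force averages over the table", {
  set.seed(12)
  x <- pmin(pmax(0.5 + cumsum(rnorm(3000, 0, 0.05)), 0), 1)
  arcs <- detectArcs(make_ll(x, dt = 0.03))
  st <- arcStatistics(arcs)
  up <- arcs$direction == "up"
  expect_equal(st$fraction_up, mean(up))
  expect_equal(st$mean_tau_up, mean(arcs$tau_arc[up]))
  expect_equal(st$mean_tau_down, mean(arcs$tau_arc[!up]))
  expect_equal(st$mean_M_down, mean(arcs$M_arc[!up]))
  expect_error(arcStatistics(arcs[0, ]), "empty")
})

test_that("M_arc-tau map normalizes per occupied duration bin", {
  arcs <- data.frame(particle_id = 1,
                     direction = rep(c("up", "down"), c(6, 2)),
                     t_start = 0,
                     tau_arc = c(1.2, 1.3, 1.1, 4.5, 4.6, 4.4, 1.2, 4.5),
                     M_arc = c(0.1, 0.12, 0.3, 0.3, 0.32, 0.1, 0.2, 0.2),
                     t_max = 0.5, fully_in_L = TRUE)
  mp <- marcTauMap(arcs, tau_bins = c(0, 2, 4, 6),
                   M_bins = seq(0, 0.45, by = 0.05))
  cs <- colSums(mp$fraction)
  expect_true(all(abs(cs[mp$n > 0] - 1) < 1e-12))
  expect_true(all(cs[mp$n == 0] == 0))
  # mean curve equals per-bin arithmetic means
  expect_equal(mp$mean_M[1], mean(c(0.1, 0.12, 0.3, 0.2)))
  expect_equal(mp$mean_M[3], mean(c(0.3, 0.32, 0.1, 0.2)))
  expect_true(is.na(mp$mean_M[2]))
  # single arc: one occupied cell with fraction 1
  mp1 <- marcTauMap(arcs[1, ], tau_bins = c(0, 2), M_bins = c(0, 0.45))
  expect_equal(as.vector(mp1$fraction), 1)
  expect_error(marcTauMap(arcs, tau_bins = c(1, 1)), "strictly increasing")
})

test_that("consumption comparison is continuous, monotone, closed-form exact", {
  p <- ds_params
  arcs <- data.frame(particle_id = 1, direction = "up", t_start = 0,
                     tau_arc = 3, M_arc = 0.2, t_max = 1.2,
                     fully_in_L = TRUE)
  cc <- consumptionComparison(arcs, p, M_grid = c(0.01, 0.1, 0.2, 0.4))
  up <- cc[cc$direction == "up", ]
  dn <- cc[cc$direction == "down", ]
  # M -> 0: consumption time -> 0
  expect_lt(up$t_consumption[1], 0.1)
  # monotone increasing in M for both directions
  expect_true(all(diff(up$t_consumption) > 0))
  expect_true(all(diff(dn$t_consumption) > 0))
  # within-L endpoint matches the closed form directly
  expect_equal(up$t_consumption[up$M == 0.2],
               consumptionTransitionTime(0.7, 0.5, p))
  expect_equal(dn$t_consumption[dn$M == 0.2],
               consumptionTransitionTime(0.5, 0.3, p))
  # simulation-side time uses the arc-shape factor
  expect_equal(up$t_sim[up$M == 0.2], 0.6 * 3)
  expect_true(is.na(up$t_sim[up$M == 0.4]))
  # shape factors recomputable from measured peak timing
  cc2 <- consumptionComparison(arcs, p, M_grid = 0.2,
                               shape_from_arcs = TRUE)
  expect_equal(cc2$t_sim[cc2$direction == "up"], (1 - 1.2 / 3) * 3)
})
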