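make_events <- function(t_exit_ns, direction = "outward", run = NULL,
                        species = "K") {
  n <- length(t_exit_ns)
  ev <- data.frame(ion_id = seq_len(n), species = rep(species, n),
                   direction = rep(direction, length.out = n),
                   t_enter_ps = t_exit_ns * 1000 - 100,
                   t_exit_ps = t_exit_ns * 1000,
                   dwell_ps = rep(100, n), entry_pathway = rep(NA, n))
  if (!is.null(run)) ev$run <- run
  ev
}

test_that("applied-field voltage is E times Lz", {
  expect_equal(field_voltage(0.01, 10), 100)
  expect_equal(field_voltage(0, 10), 0)
  expect_equal(field_voltage(-0.02, 12.5), -250)
})

test_that("Poisson double integration reproduces the parallel-plate capacitor", {
  z <- seq(0.005, 11.995, by = 0.01)     # 0.01 nm bins over a 12 nm box
  dz <- 0.01
  sigma <- 0.01                          # e/nm^2 per sheet
  rho <- numeric(length(z))
  rho[which.min(abs(z - 3.5))] <- sigma / dz
  rho[which.min(abs(z - 8.5))] <- -sigma / dz
  out <- charge_density_voltage(z, rho, plateau_lower = c(0, 2),
                                plateau_upper = c(10, 12))
  closed <- -sigma * 1.602176634e-19 * 1e18 * 5e-9 / 8.8541878128e-12 * 1000
  expect_equal(out$delta_mV, closed, tolerance = 0.01)
  # zero density, zero voltage
  expect_equal(charge_density_voltage(z, rho * 0, c(0, 2), c(10, 12))$delta_mV, 0)
  # linearity: doubled sheet charge doubles the voltage
  out2 <- charge_density_voltage(z, 2 * rho, c(0, 2), c(10, 12))
  expect_equal(out2$delta_mV, 2 * out$delta_mV, tolerance = 1e-10)
})

test_that("segment conductance evaluates the defining formula exactly", {
  # 160 net events completing inside segment 2 of a 1000 ns run at 100 mV
  ev <- make_events(seq(100.1, 199.9, length.out = 160))
  est <- segment_conductance(ev, voltage_mV = 100, segment_ns = 100,
                             n_discard = 1, run_length_ns = 1000)
  seg2 <- est$per_segment[est$per_segment$segment == 2, ]
  expect_identical(seg2$n_net, 160L)
  g_expected <- 160 * 1.602176634e-19 / (1e-7 * 0.1) * 1e12
  expect_equal(seg2$g_pS, g_expected, tolerance = 1e-13)
  expect_equal(round(g_expected, 1), 2563.5)
  expect_error(segment_conductance(ev, voltage_mV = 0, run_length_ns = 1000),
               "undefined-conductance")
})

test_that("the 5-run one-microsecond scheme retains 45 segments", {
  ev <- make_events(rep(500, 5), run = 1:5)
  est <- segment_conductance(ev, voltage_mV = 100, segment_ns = 100,
                             n_discard = 1, run_length_ns = 1000)
  expect_identical(est$n_segments, 45L)
  # single run before discard: 10 segments
  est1 <- segment_conductance(make_events(500), voltage_mV = 100,
                              segment_ns = 100, n_discard = 0,
                              run_length_ns = 1000)
  expect_identical(est1$n_segments, 10L)
})

test_that("opposed crossings subtract in net counts but add in gross counts", {
  ev <- make_events(c(150, 151, 152, 153), direction = c("outward", "outward",
                                                         "outward", "inward"))
  net <- segment_conductance(ev, voltage_mV = 100, segment_ns = 100,
                             n_discard = 1, run_length_ns = 200)
  gross <- segment_conductance(ev, voltage_mV = 100, segment_ns = 100,
                               n_discard = 1, run_length_ns = 200,
                               count = "gross")
  expect_identical(net$per_segment$n_net, 2L)
  expect_identical(gross$per_segment$n_gross, 4L)
  # negative voltage favors inward traversals
  neg <- segment_conductance(ev, voltage_mV = -100, segment_ns = 100,
                             n_discard = 1, run_length_ns = 200)
  expect_identical(neg$per_segment$n_net, -2L)
})

test_that("conductance is invariant to run relabeling and event order", {
  set.seed(6)
  ev <- make_events(runif(60, 0, 500), run = sample(1:5, 60, TRUE))
  a <- segment_conductance(ev, 100, segment_ns = 100, n_discard = 1,
                           run_length_ns = 500)
  ev2 <- ev[sample(nrow(ev)), ]
  ev2$run <- 6 - ev2$run
  b <- segment_conductance(ev2, 100, segment_ns = 100, n_discard = 1,
                           run_length_ns = 500)
  expect_equal(a$mean_pS, b$mean_pS)
  expect_equal(a$sd_pS, b$sd_pS)
})

test_that("instantaneous conductance counts windows conservatively", {
  expect_equal(instantaneous_conductance(make_events(numeric(0)), 100,
                                         window_ns = 20, total_ns = 100)$n_net,
               rep(0L, 5))
  # uniform 1 event/ns: every 20 ns window holds 20 events -> 160.2 pS
  ev <- make_events(seq(0.5, 99.5, by = 1))
  ic <- instantaneous_conductance(ev, 100, window_ns = 20, total_ns = 100)
  expect_equal(ic$n_net, rep(20L, 5))
  expect_equal(ic$g_pS, rep(20 * 1.602176634e-19 / (2e-8 * 0.1) * 1e12, 5),
               tolerance = 1e-13)
  # bookkeeping: window counts sum to the total net count
  set.seed(3)
  ev2 <- make_events(runif(200, 0, 100),
                     direction = sample(c("outward", "inward"), 200, TRUE,
                                        prob = c(0.8, 0.2)))
  ic2 <- instantaneous_conductance(ev2, 100, window_ns = 20, total_ns = 100)
  expect_equal(sum(ic2$n_net),
               sum(ev2$direction == "outward") - sum(ev2$direction == "inward"))
})

test_that("the current-voltage table applies Ohm's law with propagated error", {
  ev <- make_events(seq(110, 990, by = 5))
  gp <- segment_conductance(ev, 100, 100, 1, 1000)
  gm <- segment_conductance(make_events(seq(110, 990, by = 5),
                                        direction = "inward"), -100, 100, 1, 1000)
  iv <- iv_curve(list(gp, gm))
  expect_equal(iv$I_pA, iv$g_pS * iv$V_mV / 1000)
  expect_equal(iv$V_mV, c(-100, 100))
  expect_error(iv_curve(list(gp)), "usage error")
  expect_error(iv_curve(list(gp, gp)), "duplicate")
})

test_that("a uniform field represented as sheet charges matches E times distance", {
  # sheets sized so the interior field is 0.005 V/nm; the plateau-to-plateau
  # voltage then equals the field times the sheet separation
  z <- seq(0.005, 9.995, by = 0.01)
  E <- 0.005
  sigma_C_m2 <- E / 1e-9 * 8.8541878128e-12       # E = sigma/eps0
  sigma <- sigma_C_m2 / (1.602176634e-19 * 1e18)  # back to e/nm^2
  rho <- numeric(length(z))
  i1 <- which.min(abs(z - 0.505)); i2 <- which.min(abs(z - 9.495))
  rho[i1] <- sigma / 0.01
  rho[i2] <- -sigma / 0.01
  d <- z[i2] - z[i1]
  out <- charge_density_voltage(z, rho, c(0, 0.4), c(9.6, 10))
  expect_equal(abs(out$delta_mV), abs(field_voltage(E, d)), tolerance = 0.01)
})
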