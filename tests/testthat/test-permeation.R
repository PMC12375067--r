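test_that("single-ion crossing sequences are classified correctly", {
  b <- simple_bounds()
  # monotone inward crossing
  fr <- make_ion_frames(c(3.0, 0.5, -3.0))
  ev <- detect_events(fr, b, "K")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "inward")
  # dip below the upper boundary and return: cancelled entry
  fr2 <- make_ion_frames(c(3.0, 1.5, 3.0))
  expect_equal(nrow(detect_events(fr2, b, "K")), 0)
  # repeated excursions inside that never reach the far boundary
  fr3 <- make_ion_frames(c(3.0, 1.0, 2.5, 0.5, 3.0))
  expect_equal(nrow(detect_events(fr3, b, "K")), 0)
  # outward traversal
  fr4 <- make_ion_frames(c(-3.0, 0.0, 3.0))
  ev4 <- detect_events(fr4, b, "K")
  expect_equal(ev4$direction, "outward")
  # traversal, then return through the pore: one event each way
  fr5 <- make_ion_frames(c(3, 0, -3, 0, 3))
  ev5 <- detect_events(fr5, b, "K")
  expect_equal(ev5$direction, c("inward", "outward"))
})

test_that("repeat traversals through periodic images are each counted", {
  # ion drifting steadily downward across three box heights (unwrapped)
  b <- simple_bounds()
  z <- seq(3, 3 - 3 * 10, by = -0.5)
  fr <- make_ion_frames(z, box = c(4, 4, 10))
  ev <- detect_events(fr, b, "K")
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$direction == "inward"))
  # net (inward - outward) equals the net number of box-spanning displacements
  net <- sum(ev$direction == "inward") - sum(ev$direction == "outward")
  expect_equal(net, floor((z[1] - z[length(z)]) / 10))
})

test_that("time reversal swaps event directions and preserves dwell times", {
  set.seed(11)
  for (rep in 1:5) {
    z <- cumsum(c(3.5, rnorm(600, mean = -0.05, sd = 0.25)))
    fr <- make_ion_frames(z)
    frr <- make_ion_frames(rev(z))
    b <- simple_bounds()
    ev <- detect_events(fr, b, "K")
    evr <- detect_events(frr, b, "K")
    expect_equal(nrow(ev), nrow(evr))
    if (nrow(ev)) {
      swap <- c(inward = "outward", outward = "inward")
      expect_equal(sort(unname(swap[ev$direction])), sort(evr$direction))
      expect_equal(sort(ev$dwell_ps), sort(evr$dwell_ps))
    }
  }
})

test_that("detection matches the brute-force per-frame oracle on synthetic runs", {
  for (seed in c(3, 17, 91)) {
    spec <- channel_spec(n_ions_per_species = 20, n_waters = 0,
                         n_steps = 20000, save_stride = 2, seed = seed,
                         repulsion = list(amplitude_kT_nm = 0, screening_nm = 0.8))
    sim <- simulate_channel(spec)
    b <- boundaries_from_spec(spec)
    ev <- detect_events(sim$frames, b, "K")
    orc <- oracle_detect_events(t(sim$truth$unwrapped_z), sim$truth$times,
                                sim$frames$atoms$atom_id[1:20],
                                spec$z_upper, spec$z_lower, spec$box[3])
    expect_equal(nrow(ev), nrow(orc))
    expect_equal(ev$ion_id, orc$ion_id)
    expect_equal(ev$direction, orc$direction)
    expect_equal(ev$t_enter_ps, orc$t_enter_ps)
    expect_equal(ev$t_exit_ps, orc$t_exit_ps)
  }
})

test_that("event counts are stable under subsampling up to the passage time", {
  spec <- channel_spec(n_ions_per_species = 10, n_waters = 0, n_steps = 40000,
                       save_stride = 1, seed = 5,
                       repulsion = list(amplitude_kT_nm = 0, screening_nm = 0.8))
  sim <- simulate_channel(spec)
  b <- boundaries_from_spec(spec)
  n_full <- nrow(detect_events(sim$frames, b, "K"))
  # mild subsampling (well below the boundary-to-boundary passage time)
  sub <- sim$frames
  keep <- seq(1, length(sub$times), by = 4)
  sub$times <- sub$times[keep]
  sub$box <- sub$box[keep, , drop = FALSE]
  sub$xyz <- sub$xyz[, , keep, drop = FALSE]
  n_sub <- nrow(detect_events(sub, b, "K"))
  expect_equal(n_sub, n_full)
})

test_that("dwell-time summaries follow from the event stream", {
  # deterministic drift: v = 1 nm/ns across a 4 nm span, frames every 0.1 ns
  b <- simple_bounds()
  z <- seq(3.05, -3.05, by = -0.1)
  fr <- make_ion_frames(z, dt = 100)   # 0.1 nm per 100 ps = 1 nm/ns
  ev <- detect_events(fr, b, "K")
  dw <- dwell_times(ev)
  expect_equal(dw$dwell_ns, 4)
  # arithmetic on a fabricated pair of events
  ev2 <- data.frame(ion_id = 1:2, species = "K", direction = "inward",
                    t_enter_ps = c(0, 0), t_exit_ps = c(2000, 4000),
                    dwell_ps = c(2000, 4000), entry_pathway = NA)
  expect_equal(dwell_times(ev2)$mean_ns, 3)
  expect_warning(d0 <- dwell_times(ev2[0, ]), "no events")
  expect_equal(d0$n, 0L)
})

test_that("entry pathways honor the pocket sphere and the memory window", {
  # path: through the pocket at t = 450 ps, filter entry at t = 500 ps
  nf <- 11
  z <- c(3, 2.8, 2.6, 2.4, 2.2, 1.55, 0.5, -0.5, -1.5, -2.5, -3)
  xy <- cbind(c(0, 0, 0, 0, 0.45, 0, 0, 0, 0, 0, 0), rep(0, nf))
  fr <- make_ion_frames(z, dt = 100, xy = xy)
  pocket <- list(list(center = c(0.45, 0, 2.2), radius = 0.25))
  b100 <- simple_bounds(side_pocket_regions = pocket, pathway_memory = 150)
  ev <- detect_events(fr, b100, "K")
  cl <- classify_entry_pathway(fr, ev, b100)
  expect_equal(cl$events$entry_pathway, "side_pocket")
  expect_equal(cl$fractions$fraction, 1)
  b10 <- simple_bounds(side_pocket_regions = pocket, pathway_memory = 50)
  cl2 <- classify_entry_pathway(fr, detect_events(fr, b10, "K"), b10)
  expect_equal(cl2$events$entry_pathway, "on_axis")
  expect_error(simple_bounds(side_pocket_regions = pocket, pathway_memory = 0),
               "pathway_memory")
})

test_that("pathway fractions match generator truth on a stride-1 run", {
  spec <- channel_spec(n_ions_per_species = 30, n_waters = 0, n_steps = 30000,
                       save_stride = 1, seed = 23,
                       repulsion = list(amplitude_kT_nm = 0, screening_nm = 0.8))
  sim <- simulate_channel(spec)
  b <- boundaries_from_spec(spec)
  ev <- detect_events(sim$frames, b, "K")
  expect_gt(nrow(ev), 0)
  cl <- classify_entry_pathway(sim$frames, ev, b)
  truth <- sim$truth$events
  key <- function(d) paste(d$ion_id, round(d$t_exit_ps, 3))
  m <- match(key(cl$events), key(truth))
  expect_false(anyNA(m))
  expect_equal(cl$events$entry_pathway == "side_pocket",
               truth$via_side_pocket[m])
})
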