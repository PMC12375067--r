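write_toy_gro <- function(path) {
  lines <- c(
    "toy channel box", " 3",
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "POT", "K", 1L, 1.0, 1.0, 2.0),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 2L, "SOL", "OW", 2L, 2.0, 2.0, 2.0),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 3L, "GLY", "CA", 3L, 3.0, 3.0, 3.0),
    "   6.00000   6.00000   6.00000")
  writeLines(lines, path)
  path
}

test_that("GRO topologies load with roles assigned by the selection rules", {
  gro <- write_toy_gro(tempfile(fileext = ".gro"))
  fr <- load_trajectory(gro)
  expect_s3_class(fr, "pore_frames")
  expect_equal(dim(fr$xyz), c(3, 3, 1))
  expect_equal(fr$atoms$role, c("ion_K", "water_O", "protein"))
  expect_equal(fr$box[1, ], c(6, 6, 6))
  # rule lookup: POT -> ion_K comes from the residue map, not the element
  expect_equal(assign_roles(fr$atoms)$role[1], "ion_K")
})

test_that("topology/trajectory atom-count mismatch is a format error", {
  gro <- write_toy_gro(tempfile(fileext = ".gro"))
  four <- make_static_frames(matrix(runif(12), 4, 3),
                             roles = rep("water_O", 4))
  tf <- tempfile(fileext = ".json")
  write_frames(four, tf)
  expect_error(load_trajectory(gro, tf), "format error")
})

test_that("the JSON trajectory dialect round-trips bit-exactly", {
  set.seed(4)
  spec <- channel_spec(n_ions_per_species = 3, n_waters = 5, n_steps = 200,
                       save_stride = 20, seed = 4)
  fr <- simulate_channel(spec)$frames
  tf <- tempfile(fileext = ".json")
  write_frames(fr, tf)
  back <- read_frames(tf)
  expect_identical(back$times, fr$times)
  expect_identical(back$box, fr$box)
  expect_identical(as.numeric(back$xyz), as.numeric(fr$xyz))
  expect_equal(back$atoms, fr$atoms)
})

test_that("pore-axis definition reports coordinates relative to the centroid", {
  coords <- rbind(c(2, 2, 5), c(2, 2, 7))     # reference atom + ion
  fr <- make_static_frames(coords, roles = c("protein", "ion_K"))
  fr <- define_pore_axis(fr, reference_selection = 1)
  expect_equal(fr$axis_origin, c(2, 2, 5))
  z <- poreflux:::.z_rel(fr, 2)
  expect_equal(as.numeric(z), 2)
  # symmetric tetramer: axis through the 4-fold symmetry point
  tet <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  ft <- make_static_frames(tet + 3, roles = rep("protein", 4))
  ft <- define_pore_axis(ft, 1:4)
  expect_equal(ft$axis_origin[1:2], c(3, 3))
})

test_that("rigid translation leaves all relative coordinates unchanged", {
  set.seed(9)
  coords <- matrix(runif(30, -2, 2), 10, 3)
  fr <- make_static_frames(coords, roles = c(rep("protein", 6), rep("ion_K", 4)))
  fr2 <- make_static_frames(sweep(coords, 2, c(0.7, -0.3, 1.1), "+"),
                            roles = c(rep("protein", 6), rep("ion_K", 4)))
  a1 <- define_pore_axis(fr, 1:6)
  a2 <- define_pore_axis(fr2, 1:6)
  expect_equal(poreflux:::.z_rel(a1, 7:10), poreflux:::.z_rel(a2, 7:10))
  expect_equal(poreflux:::.r_rel(a1, 7:10), poreflux:::.r_rel(a2, 7:10))
})

test_that("axial unwrapping removes periodic jumps and is idempotent", {
  fr <- make_ion_frames(c(4.9, -4.9), box = c(4, 4, 10))
  u <- unwrap_axial(fr)
  expect_equal(as.numeric(u$xyz[1, 3, ]), c(4.9, 5.1))
  # already-continuous series unchanged
  fr2 <- make_ion_frames(seq(-3, 3, by = 0.5), box = c(4, 4, 10))
  expect_equal(unwrap_axial(fr2)$xyz, fr2$xyz)
  # idempotence
  expect_equal(unwrap_axial(u)$xyz, u$xyz)
})

test_that("unwrapping a long wrapped walk recovers the integrated displacements", {
  set.seed(21)
  steps <- rnorm(1000, mean = 0.02, sd = 0.3)
  true_z <- cumsum(c(0.5, steps))
  Lz <- 10
  wrapped <- true_z - Lz * round(true_z / Lz)
  fr <- make_ion_frames(wrapped, box = c(4, 4, Lz))
  u <- unwrap_axial(fr)
  expect_equal(as.numeric(u$xyz[1, 3, ]), true_z)
})

test_that("Kabsch superposition recovers rigid motions and residual RMSD", {
  set.seed(2)
  ref <- matrix(rnorm(15), 5, 3)
  fit0 <- kabsch_superpose(ref, ref)
  expect_equal(fit0$rmsd_after_fit, 0, tolerance = 1e-12)
  # planted rigid motion
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mob <- ref %*% t(R) + matrix(c(1, 2, 3), 5, 3, byrow = TRUE)
  fit <- kabsch_superpose(mob, ref)
  expect_lt(fit$rmsd_after_fit, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # rmsd is symmetric under exchanging mobile and reference
  noisy <- ref + matrix(rnorm(15, sd = 0.1), 5, 3)
  expect_equal(kabsch_superpose(noisy, ref)$rmsd_after_fit,
               kabsch_superpose(ref, noisy)$rmsd_after_fit, tolerance = 1e-12)
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "geometry error")
})

test_that("the fitted RMSD equals an independent rigid-fit optimizer's minimum", {
  # brute-force oracle: minimize RMSD over Euler angles + translation with
  # a general-purpose optimizer, independent of the SVD solution
  oracle_min_rmsd <- function(mobile, reference) {
    rot <- function(a) {
      Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
      Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
      Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
      Rz %*% Ry %*% Rx
    }
    f <- function(p) {
      moved <- mobile %*% t(rot(p[1:3]))
      moved <- sweep(moved, 2, -p[4:6])
      sqrt(mean(rowSums((moved - reference)^2)))
    }
    best <- Inf
    for (s in 1:6) {
      o <- optim(runif(6, -0.5, 0.5), f, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
      best <- min(best, o$value)
    }
    best
  }
  set.seed(13)
  for (case in 1:3) {
    ref <- matrix(rnorm(18), 6, 3)
    mob <- ref + matrix(rnorm(18, sd = 0.05), 6, 3)
    fit <- kabsch_superpose(mob, ref)
    expect_equal(fit$rmsd_after_fit, oracle_min_rmsd(mob, ref),
                 tolerance = 1e-5)
  }
})

test_that("RMSF reproduces closed forms for planted motions", {
  # static structure: zero fluctuation
  coords <- matrix(runif(12), 4, 3)
  fr <- make_static_frames(coords, roles = rep("protein", 4), n_frames = 10)
  r <- rmsf_per_atom(fr, fit_selection = 1:4, measure_selection = 1:4)
  expect_equal(r$rmsf_nm, rep(0, 4), tolerance = 1e-12)
  # one atom oscillating +/- d along x about its mean: rmsf = d
  d <- 0.25
  fr2 <- fr
  fr2$xyz[4, 1, ] <- coords[4, 1] + d * rep(c(1, -1), 5)
  r2 <- rmsf_per_atom(fr2, fit_selection = 1:3, measure_selection = 4)
  expect_equal(r2$rmsf_nm, d, tolerance = 1e-10)
  expect_error(rmsf_per_atom(fr, integer(0), 1:4), "selection error")
})

test_that("isotropic Gaussian jitter gives rmsf near sigma*sqrt(3)", {
  set.seed(31)
  nf <- 10000
  sigma <- 0.08
  anchors <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  n <- nrow(anchors) + 1
  xyz <- array(0, dim = c(n, 3, nf))
  for (t in seq_len(nf)) {
    xyz[1:4, , t] <- anchors
    xyz[5, , t] <- rnorm(3, sd = sigma)
  }
  atoms <- data.frame(atom_id = 1:n, element = "C", residue_name = "GLY",
                      residue_seq = 1:n, chain_id = "X", role = "protein")
  fr <- pore_frames(times = seq_len(nf), box = matrix(6, nf, 3),
                    xyz = xyz, atoms = atoms)
  r <- rmsf_per_atom(fr, fit_selection = 1:4, measure_selection = 5)
  expect_equal(r$rmsf_nm, sigma * sqrt(3), tolerance = 0.05)
})
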