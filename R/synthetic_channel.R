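# Synthetic ion-trajectory generator: overdamped Langevin dynamics of ions in
# a three-well axial landscape (the S_intra / S_central / S_extra binding
# regions) with a uniform applied field, an off-axis side-pocket well,
# screened-Coulomb ion-ion repulsion, a radial confining wall standing in for
# the pore, and freely diffusing idealized waters.  Every run carries a
# ground-truth traversal log recorded at integration-step resolution, so the
# frame-resolution analysis stages can be validated against known truth.

# evaluate a block of code under a fixed RNG seed without disturbing the
# caller's RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default pore-radius wall function
#'
#' A smooth accessible-radius profile: narrow (`r_pore`) across the pore
#' window, opening to `r_bulk` outside it over `taper` nm.
#'
#' @param r_pore,r_bulk radii in nm.
#' @param pore_window z-window (nm) of the narrow section.
#' @param taper softness of the opening (nm).
#' @return a function of z (nm) returning the wall radius (nm).
#' @export
default_wall <- function(r_pore = 0.35, r_bulk = 2.5,
                         pore_window = c(-1.6, 1.9), taper = 0.15) {
  function(z) {
    # ~1 inside the window, ~0 outside, smooth over the taper length
    inside <- 0.5 * (tanh((pore_window[2] - z) / taper) +
                     tanh((z - pore_window[1]) / taper))
    r_bulk + (r_pore - r_bulk) * pmax(pmin(inside, 1), 0)
  }
}

#' Specification of a synthetic channel run
#'
#' Defaults emulate the study system at desk scale: a tetrameric pore along
#' z with three cation-binding wells in the filter region (S_intra,
#' S_central, S_extra), an off-axis side pocket behind the filter, a uniform
#' field giving about +100 mV across the box, 150 mM-scale ion numbers, and
#' Na wells deeper than K wells (Na shows the higher filter occupancy).
#' Energies are in kT at 300 K, lengths nm, times ps.
#'
#' @param species character subset of `c("K", "Na")`.
#' @param n_ions_per_species ions per species.
#' @param box box lengths (nm).
#' @param well_centers,well_widths z-positions and Gaussian widths (nm) of
#'   the S_intra/S_central/S_extra wells.
#' @param well_depths named list of per-species well depths (kT), one value
#'   per well.
#' @param side_pocket list(center, width, radius, depth) for the off-axis
#'   pocket: 3D Gaussian well of the given width/depth (kT), with `radius`
#'   the sphere used to log pocket visits; `NULL` disables it.
#' @param voltage_mV transmembrane voltage; the uniform field is
#'   `E = V / Lz`.  Overridden by `field_V_per_nm` if given.
#' @param field_V_per_nm applied field along z (V/nm), or `NULL`.
#' @param diffusion named per-species diffusion coefficients (nm^2/ps).
#' @param repulsion list(amplitude_kT_nm, screening_nm) of the screened
#'   Coulomb pair term `U/kT = A exp(-d/lambda) / d`; amplitude 0 disables.
#' @param radial_wall function z -> wall radius (nm); default [default_wall()].
#' @param wall_k harmonic wall stiffness (kT/nm^2).
#' @param n_waters,water_D idealized water count and diffusion coefficient.
#' @param timestep_ps,n_steps,save_stride integration step, step count, and
#'   frame-saving stride.
#' @param z_upper,z_lower traversal boundaries (nm) used for the ground-truth
#'   event log (and as analysis defaults).
#' @param sf_window z-window (nm) of the selectivity filter.
#' @param pathway_memory ps; a traversal is flagged `via_side_pocket` when
#'   the ion visited the pocket sphere within this time before first filter
#'   entry.
#' @param deterministic drop the noise term (pure drift; for closed-form
#'   checks).
#' @param seed integer; fixes the full output bit-exactly.
#' @return a `channel_spec` list.
#' @export
channel_spec <- function(species = "K", n_ions_per_species = 40,
                         box = c(6, 6, 12),
                         well_centers = c(1.05, 1.40, 1.75),
                         well_widths = c(0.12, 0.12, 0.12),
                         well_depths = list(K = c(2.5, 2.5, 2.5),
                                            Na = c(3.5, 3.5, 3.5)),
                         side_pocket = list(center = c(0.45, 0, 2.0),
                                            width = 0.15, radius = 0.25,
                                            depth = c(K = 3, Na = 3)),
                         voltage_mV = 100, field_V_per_nm = NULL,
                         diffusion = c(K = 1.96e-3, Na = 1.33e-3),
                         repulsion = list(amplitude_kT_nm = 0.7,
                                          screening_nm = 0.8),
                         radial_wall = NULL, wall_k = 200,
                         n_waters = 200, water_D = 4.3e-3,
                         timestep_ps = 0.5, n_steps = 200000,
                         save_stride = 10,
                         z_upper = 2.1, z_lower = -1.8,
                         sf_window = c(0.9, 1.9),
                         pathway_memory = 200,
                         deterministic = FALSE, seed = 1) {
  stopifnot(all(species %in% c("K", "Na")), n_ions_per_species >= 0,
            all(box > 0), length(well_centers) == length(well_widths),
            timestep_ps > 0, n_steps >= 1, save_stride >= 1,
            z_lower < z_upper)
  if (length(well_centers) &&
      (any(well_centers <= -box[3] / 2) || any(well_centers >= box[3] / 2)))
    stop("well centers must lie inside (-Lz/2, Lz/2)")
  if (is.null(field_V_per_nm)) field_V_per_nm <- voltage_mV / 1000 / box[3]
  if (is.null(radial_wall)) radial_wall <- default_wall()
  spec <- list(species = species, n_ions_per_species = n_ions_per_species,
               box = box, well_centers = well_centers,
               well_widths = well_widths, well_depths = well_depths,
               side_pocket = side_pocket,
               field_V_per_nm = field_V_per_nm,
               diffusion = diffusion, repulsion = repulsion,
               radial_wall = radial_wall, wall_k = wall_k,
               n_waters = n_waters, water_D = water_D,
               timestep_ps = timestep_ps, n_steps = as.integer(n_steps),
               save_stride = as.integer(save_stride),
               z_upper = z_upper, z_lower = z_lower, sf_window = sf_window,
               pathway_memory = pathway_memory,
               deterministic = isTRUE(deterministic), seed = as.integer(seed))
  class(spec) <- "channel_spec"
  spec
}

# largest drift displacement in one step; used for the stability check
.max_drift_step <- function(spec) {
  fmax <- abs(spec$field_V_per_nm) / .kT_volts
  for (s in spec$species) {
    dep <- spec$well_depths[[s]]
    if (length(dep))
      fmax <- max(fmax, abs(spec$field_V_per_nm) / .kT_volts +
                    sum(abs(dep) * exp(-0.5) / spec$well_widths))
  }
  max(unlist(spec$diffusion[spec$species])) * fmax * spec$timestep_ps
}

#' Run the synthetic channel generator
#'
#' Propagates ions and waters with the overdamped Langevin update
#' `x <- x + D f dt + sqrt(2 D dt) eta` (forces per kT), wraps coordinates
#' into the periodic box for the emitted frames, and records the true
#' (unwrapped) axial paths plus a ground-truth log of completed traversals at
#' integration-step resolution.
#'
#' @param spec a [channel_spec()].
#' @return list with `frames` (a `pore_frames` object, axis through the box
#'   center), `truth` (list: `events` data.frame with `ion_id`, `species`,
#'   `direction`, `t_enter_ps`, `t_exit_ps`, `dwell_ps`, `via_side_pocket`;
#'   `unwrapped_z` matrix n_frames x n_ions; `times`), and `spec`.
#' @export
simulate_channel <- function(spec) {
  stopifnot(inherits(spec, "channel_spec"))
  if (length(spec$well_centers) && !spec$deterministic &&
      .max_drift_step(spec) > min(spec$well_widths) / 2)
    stop("stability error: timestep too large for the well landscape")

  n_sp <- length(spec$species)
  n_ions <- n_sp * spec$n_ions_per_species
  species_of <- rep(spec$species, each = spec$n_ions_per_species)
  nw <- length(spec$well_centers)

  init <- .with_seed(spec$seed, {
    # particle-wise draws: particle i always consumes draws 3i-2..3i, so a
    # larger ion count reuses the same initial positions for shared indices
    draw <- function(n) {
      u <- matrix(runif(3 * n), ncol = 3, byrow = TRUE) - 0.5
      sweep(u, 2, spec$box, "*")
    }
    list(ion = draw(n_ions), wat = draw(spec$n_waters))
  })
  if (n_ions == 0) init$ion <- matrix(0, 0, 3)
  if (spec$n_waters == 0) init$wat <- matrix(0, 0, 3)

  depth_mat <- matrix(0, nrow = max(n_ions, 1), ncol = max(nw, 1))
  if (n_ions && nw)
    for (i in seq_len(n_ions)) depth_mat[i, ] <- spec$well_depths[[species_of[i]]]
  pocket_on <- !is.null(spec$side_pocket)
  pocket_center <- if (pocket_on) spec$side_pocket$center else c(0, 0, 0)
  pocket_depth <- if (pocket_on && n_ions)
    as.numeric(spec$side_pocket$depth[species_of]) else rep(0, max(n_ions, 1))
  wall_z <- seq(-spec$box[3] / 2, spec$box[3] / 2, length.out = 241)
  wall_r <- spec$radial_wall(wall_z)

  out <- .langevin_core(
    n_steps = spec$n_steps, save_stride = spec$save_stride,
    dt = spec$timestep_ps, box = spec$box,
    ion_init = init$ion,
    ion_D = if (n_ions) as.numeric(spec$diffusion[species_of]) else numeric(0),
    ion_field_f = rep(spec$field_V_per_nm / .kT_volts, n_ions),
    well_center = if (nw) spec$well_centers else numeric(0),
    well_width = if (nw) spec$well_widths else numeric(0),
    well_depth = if (nw) depth_mat else matrix(0, max(n_ions, 1), 0),
    pocket_on = pocket_on, pocket_center = pocket_center,
    pocket_width = if (pocket_on) spec$side_pocket$width else 0.1,
    pocket_depth = pocket_depth,
    pocket_radius = if (pocket_on) spec$side_pocket$radius else 0,
    rep_amp = spec$repulsion$amplitude_kT_nm,
    rep_lambda = spec$repulsion$screening_nm,
    wall_z = wall_z, wall_r = wall_r, wall_k = spec$wall_k,
    water_init = init$wat, water_D = spec$water_D,
    z_upper = spec$z_upper, z_lower = spec$z_lower,
    sf_low = spec$sf_window[1], sf_high = spec$sf_window[2],
    pathway_memory = spec$pathway_memory,
    deterministic = spec$deterministic, seed = spec$seed)

  resname <- c(K = "POT", Na = "SOD")
  role <- c(K = "ion_K", Na = "ion_Na")
  atoms <- data.frame(
    atom_id = seq_len(n_ions + spec$n_waters),
    element = c(toupper(species_of), rep("O", spec$n_waters)),
    residue_name = c(resname[species_of], rep("SOL", spec$n_waters)),
    residue_seq = seq_len(n_ions + spec$n_waters),
    chain_id = "X",
    role = c(role[species_of], rep("water_O", spec$n_waters)),
    stringsAsFactors = FALSE)
  atoms$element[atoms$element == "NA"] <- "NA"   # sodium element symbol

  frames <- pore_frames(times = out$times,
                        box = matrix(spec$box, length(out$times), 3, byrow = TRUE),
                        xyz = out$positions,   # already n_atoms x 3 x n_frames
                        atoms = atoms)
  ev <- out$events
  events <- data.frame(
    ion_id = as.integer(ev[, "ion"]),
    species = if (nrow(ev)) species_of[as.integer(ev[, "ion"])] else character(0),
    direction = ifelse(ev[, "direction"] > 0, "outward", "inward"),
    t_enter_ps = ev[, "t_enter_ps"], t_exit_ps = ev[, "t_exit_ps"],
    dwell_ps = ev[, "t_exit_ps"] - ev[, "t_enter_ps"],
    via_side_pocket = ev[, "via_side_pocket"] > 0,
    stringsAsFactors = FALSE)
  list(frames = frames,
       truth = list(events = events, unwrapped_z = out$unwrapped_z,
                    times = out$times),
       spec = spec)
}

#' Plant a single-frame hydration scene with known shell composition
#'
#' Places exactly the requested numbers of water and protein oxygens strictly
#' inside the ion's first hydration shell (margin 0.05 nm) and decoy oxygens
#' strictly outside it, so shell-counting code can be checked against planted
#' truth.  Positions are wrapped into the periodic box, so an ion near a box
#' face exercises the minimum-image convention.
#'
#' @param ion_species `"K"` or `"Na"`.
#' @param n_water_in_shell,n_protein_O_in_shell planted in-shell counts.
#' @param shell_radius nm.
#' @param n_decoys oxygens placed outside the shell (alternating water and
#'   protein).
#' @param box box lengths (nm).
#' @param ion_position ion position in centered box coordinates (default
#'   origin); place near a face to force image wrapping.
#' @param min_sep minimum atom separation (nm); infeasible packings raise a
#'   packing error.
#' @param margin clearance (nm) kept on both sides of the shell boundary.
#' @param seed RNG seed.
#' @return a single-frame `pore_frames` object; the ion is atom 1.
#' @export
plant_hydration_scene <- function(ion_species, n_water_in_shell,
                                  n_protein_O_in_shell, shell_radius,
                                  n_decoys = 0, box = c(4, 4, 4),
                                  ion_position = c(0, 0, 0),
                                  min_sep = 0.05, margin = 0.05, seed = 1) {
  stopifnot(n_water_in_shell >= 0, n_protein_O_in_shell >= 0,
            shell_radius > 0, n_decoys >= 0)
  n_in <- n_water_in_shell + n_protein_O_in_shell
  r_lo <- 0.15
  if (shell_radius - margin <= r_lo && n_in > 0)
    stop("packing error: shell too small for in-shell atoms")
  # crude feasibility bound: spheres of radius min_sep/2 into the shell volume
  if (n_in > 0) {
    vol <- 4 / 3 * pi * ((shell_radius - margin)^3 - r_lo^3)
    if (n_in * (min_sep^3) > vol)
      stop("packing error: too many atoms for the shell volume")
  }
  wrap <- function(p) sweep(p, 2, box, function(x, L) x - L * round(x / L))
  .with_seed(seed, {
    place <- function(n, rmin, rmax) {
      pts <- matrix(0, 0, 3)
      tries <- 0
      while (nrow(pts) < n) {
        tries <- tries + 1
        if (tries > 20000) stop("packing error: could not place atoms")
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        r <- runif(1, rmin, rmax)
        cand <- ion_position + r * u
        ok <- TRUE
        if (nrow(pts) > 0) {
          d <- sweep(pts, 2, cand)
          d <- d - matrix(box, nrow(pts), 3, byrow = TRUE) * round(sweep(d, 2, box, "/"))
          ok <- all(sqrt(rowSums(d^2)) >= min_sep)
        }
        if (ok) pts <- rbind(pts, cand)
      }
      pts
    }
    inside <- place(n_in, r_lo, shell_radius - margin)
    rmax_out <- min(box) / 2 - 0.01
    if (n_decoys > 0 && shell_radius + margin >= rmax_out)
      stop("packing error: no room outside the shell in this box")
    outside <- place(n_decoys, shell_radius + margin, rmax_out)
    coords <- rbind(matrix(ion_position, 1, 3), inside, outside)
    coords <- wrap(coords)
    roles <- c(if (ion_species == "K") "ion_K" else "ion_Na",
               rep("water_O", n_water_in_shell),
               rep("protein", n_protein_O_in_shell),
               rep(c("water_O", "protein"), length.out = n_decoys))
    resn <- c(if (ion_species == "K") "POT" else "SOD",
              rep("SOL", n_water_in_shell), rep("THR", n_protein_O_in_shell),
              rep(c("SOL", "THR"), length.out = n_decoys))
    atoms <- data.frame(atom_id = seq_len(nrow(coords)),
                        element = c(toupper(ion_species), rep("O", nrow(coords) - 1)),
                        residue_name = resn, residue_seq = seq_len(nrow(coords)),
                        chain_id = "X", role = roles, stringsAsFactors = FALSE)
    pore_frames(times = 0, box = matrix(box, 1, 3),
                xyz = array(coords, dim = c(nrow(coords), 3, 1)), atoms = atoms)
  })
}

#' Analytic scaffold geometries for pore-profile validation
#'
#' Builds rings of atoms whose accessible (inscribed-sphere) radius equals a
#' known analytic profile exactly: ring radius = target radius + vdW radius
#' of the placed element.  `"cylinder"` has a constant target radius;
#' `"hourglass"` tapers parabolically from `r_max` at the ends to `r_waist`
#' at the mid-plane.
#'
#' @param kind `"cylinder"` or `"hourglass"`.
#' @param radius target accessible radius (nm) for the cylinder.
#' @param r_max,r_waist end and waist target radii (nm) for the hourglass.
#' @param length axial extent (nm), centered on z = 0.
#' @param dz ring spacing (nm).
#' @param n_per_ring atoms per ring.
#' @param element placed element (vdW radius from [vdw_radius_table()]).
#' @param box box lengths (nm).
#' @return a single-frame `pore_frames` scaffold (role `protein`) plus the
#'   analytic profile in attribute `target_profile` (data.frame z, radius).
#' @export
ideal_geometry <- function(kind = c("cylinder", "hourglass"), radius = 0.5,
                           r_max = 0.8, r_waist = 0.3, length = 3,
                           dz = 0.1, n_per_ring = 24, element = "O",
                           box = c(6, 6, 8)) {
  kind <- match.arg(kind)
  vdw <- vdw_radius_table()[[element]]
  if (is.null(vdw)) stop("element not in vdW table: ", element)
  z <- seq(-length / 2, length / 2, by = dz)
  target <- if (kind == "cylinder") rep(radius, base::length(z))
            else r_waist + (r_max - r_waist) * (2 * abs(z) / length)^2
  if (any(target <= vdw)) stop("target radius must exceed the vdW radius")
  ang <- seq(0, 2 * pi, length.out = n_per_ring + 1)[-(n_per_ring + 1)]
  coords <- do.call(rbind, lapply(seq_along(z), function(i) {
    rr <- target[i] + vdw
    # stagger alternate rings so slices are bounded from all azimuths
    a <- ang + if (i %% 2 == 0) pi / n_per_ring else 0
    cbind(rr * cos(a), rr * sin(a), z[i])
  }))
  atoms <- data.frame(atom_id = seq_len(nrow(coords)), element = element,
                      residue_name = "SCF", residue_seq = rep(seq_along(z), each = n_per_ring),
                      chain_id = "S", role = "protein", stringsAsFactors = FALSE)
  fr <- pore_frames(times = 0, box = matrix(box, 1, 3),
                    xyz = array(coords, dim = c(nrow(coords), 3, 1)),
                    atoms = atoms)
  attr(fr, "target_profile") <- data.frame(z = z, radius = target)
  fr
}
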