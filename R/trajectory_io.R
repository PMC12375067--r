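#' In-memory trajectory container for pore analysis
#'
#' A `pore_frames` object holds an axis-aware trajectory for a fixed atom
#' subset: frame times (ps), per-frame orthorhombic box lengths (nm), a
#' coordinate array and an atom table with per-atom roles
#' (`ion_K`, `ion_Na`, `ion_Cl`, `water_O`, `protein`, `lipid`, `other`).
#' All coordinates are in nm; the axial sign convention is +z toward the
#' extracellular side and is recorded in every file written.
#'
#' @param times numeric vector of frame times in ps, strictly increasing.
#' @param box numeric matrix `n_frames x 3` of box lengths (nm), all > 0.
#' @param xyz numeric array `c(n_atoms, 3, n_frames)` of coordinates (nm).
#' @param atoms data.frame with columns `atom_id`, `element`, `residue_name`,
#'   `residue_seq`, `chain_id`, `role`.
#' @param axis_origin,axis_direction pore-axis anchor point (nm) and unit
#'   vector; defaults place the axis along box z through the origin.
#' @return an object of class `pore_frames`.
#' @export
pore_frames <- function(times, box, xyz, atoms,
                        axis_origin = c(0, 0, 0),
                        axis_direction = c(0, 0, 1)) {
  times <- as.numeric(times)
  if (is.null(dim(box))) box <- matrix(box, nrow = length(times), ncol = 3, byrow = TRUE)
  box <- as.matrix(box)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (any(box <= 0)) stop("all box lengths must be positive")
  d <- dim(xyz)
  if (length(d) != 3 || d[2] != 3 || d[3] != length(times) || nrow(box) != length(times))
    stop("xyz must be an n_atoms x 3 x n_frames array matching times/box")
  if (!all(is.finite(range(xyz)))) stop("positions must be finite")
  need <- c("atom_id", "element", "residue_name", "residue_seq", "chain_id", "role")
  if (!all(need %in% names(atoms))) stop("atom table missing columns: ",
                                         paste(setdiff(need, names(atoms)), collapse = ", "))
  if (nrow(atoms) != d[1]) stop("atom table rows must match xyz atom count")
  if (anyDuplicated(atoms$atom_id)) stop("atom_id must be unique")
  av <- abs(sqrt(sum(axis_direction^2)) - 1)
  if (av > 1e-8) stop("axis_direction must have unit norm")
  structure(list(times = times, box = box, xyz = xyz,
                 atoms = as.data.frame(atoms),
                 axis_origin = as.numeric(axis_origin),
                 axis_direction = as.numeric(axis_direction)),
            class = "pore_frames")
}

#' @export
print.pore_frames <- function(x, ...) {
  cat(sprintf("pore_frames: %d frames, %d atoms, t = %.1f..%.1f ps\n",
              length(x$times), dim(x$xyz)[1], min(x$times), max(x$times)))
  cat(sprintf("  axis origin (%.3f, %.3f, %.3f) nm, direction (%.2f, %.2f, %.2f); %s\n",
              x$axis_origin[1], x$axis_origin[2], x$axis_origin[3],
              x$axis_direction[1], x$axis_direction[2], x$axis_direction[3],
              .axis_convention))
  print(table(x$atoms$role))
  invisible(x)
}

.n_frames <- function(frames) length(frames$times)
.n_atoms <- function(frames) dim(frames$xyz)[1]

# atom indices carrying a role (or any of several roles)
.atom_idx <- function(frames, role) which(frames$atoms$role %in% role)

.species_role <- function(species) {
  switch(toupper(species), K = "ion_K", NA_ = "ion_Na", `NA` = "ion_Na",
         CL = "ion_Cl", stop("unknown ion species: ", species))
}

# axial coordinate (relative to axis_origin, along axis_direction) for a set
# of atoms: matrix n_frames x n_atoms
.z_rel <- function(frames, idx) {
  u <- frames$axis_direction
  if (isTRUE(all.equal(u, c(0, 0, 1)))) {
    z <- frames$xyz[idx, 3, , drop = FALSE]
    t(matrix(z, nrow = length(idx))) - frames$axis_origin[3]
  } else {
    o <- frames$axis_origin
    zz <- apply(frames$xyz[idx, , , drop = FALSE], 3, function(m)
      (m[, 1] - o[1]) * u[1] + (m[, 2] - o[2]) * u[2] + (m[, 3] - o[3]) * u[3])
    t(matrix(zz, nrow = length(idx)))
  }
}

# radial distance from the pore axis: matrix n_frames x n_atoms
.r_rel <- function(frames, idx) {
  o <- frames$axis_origin; u <- frames$axis_direction
  if (isTRUE(all.equal(u, c(0, 0, 1)))) {
    dx <- t(matrix(frames$xyz[idx, 1, , drop = FALSE], nrow = length(idx))) - o[1]
    dy <- t(matrix(frames$xyz[idx, 2, , drop = FALSE], nrow = length(idx))) - o[2]
    sqrt(dx^2 + dy^2)
  } else {
    rr <- apply(frames$xyz[idx, , , drop = FALSE], 3, function(m) {
      d <- sweep(m, 2, o)
      ax <- d %*% u
      sqrt(pmax(rowSums(d^2) - ax^2, 0))
    })
    t(matrix(rr, nrow = length(idx)))
  }
}

.xyz_frame <- function(frames, t) frames$xyz[, , t, drop = TRUE]

#' Default residue/element role-assignment rules
#'
#' Covers common force-field naming: K/POT/K+ for potassium, NA/SOD/Na+ for
#' sodium, CL/CLA/Cl- for chloride, SOL/TIP3/TIP/WAT/HOH water (oxygen only),
#' the 20 standard amino-acid residue names for protein, and common
#' phospholipids.  Extend or replace any component to match other topologies.
#'
#' @return a list with components `ion_map` (named character: residue name ->
#'   role), `water_residues`, `protein_residues`, `lipid_residues`.
#' @export
default_selection_rules <- function() {
  list(
    ion_map = c(K = "ion_K", POT = "ion_K", `K+` = "ion_K",
                `NA` = "ion_Na", SOD = "ion_Na", `NA+` = "ion_Na",
                CL = "ion_Cl", CLA = "ion_Cl", `CL-` = "ion_Cl"),
    water_residues = c("SOL", "TIP3", "TIP", "WAT", "HOH", "SPC"),
    protein_residues = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                         "GLY", "HIS", "HSD", "HSE", "HSP", "ILE", "LEU",
                         "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
                         "TYR", "VAL"),
    lipid_residues = c("POPC", "POPE", "POPS", "DPPC", "DOPC", "CHL1")
  )
}

#' Assign atom roles from residue names and elements
#'
#' @param atoms atom table (see [pore_frames()]) without or with a `role`
#'   column; it is (re)computed.
#' @param rules selection rules as from [default_selection_rules()].
#' @return the atom table with `role` filled in.
#' @export
assign_roles <- function(atoms, rules = default_selection_rules()) {
  rn <- toupper(atoms$residue_name)
  el <- toupper(atoms$element)
  role <- rep("other", nrow(atoms))
  role[rn %in% rules$protein_residues] <- "protein"
  role[rn %in% rules$lipid_residues] <- "lipid"
  hit <- rn %in% names(rules$ion_map)
  role[hit] <- unname(rules$ion_map[rn[hit]])
  role[rn %in% rules$water_residues & el == "O"] <- "water_O"
  atoms$role <- role
  atoms
}

# element from an atom name: strip digits/primes, recognize two-letter ions
.guess_element <- function(name) {
  nm <- toupper(gsub("[0-9'\"]", "", trimws(name)))
  two <- c("CL", "NA", "MG", "CA", "ZN", "FE", "BR")
  ifelse(nm %in% two, nm, substr(nm, 1, 1))
}

#' Read a GRO structure file
#'
#' Fixed-column Gromos87 format; coordinates are already in nm.
#'
#' @param path file path.
#' @return list with `atoms` (atom table, roles unassigned) and `xyz`
#'   (n_atoms x 3 matrix, nm) and `box` (length-3, nm).
#' @export
read_gro <- function(path) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[2]))
  al <- ln[3:(2 + n)]
  resseq <- as.integer(substr(al, 1, 5))
  resname <- trimws(substr(al, 6, 10))
  aname <- trimws(substr(al, 11, 15))
  xyz <- cbind(as.numeric(substr(al, 21, 28)),
               as.numeric(substr(al, 29, 36)),
               as.numeric(substr(al, 37, 44)))
  box <- as.numeric(strsplit(trimws(ln[3 + n]), "\\s+")[[1]])[1:3]
  atoms <- data.frame(atom_id = seq_len(n), element = .guess_element(aname),
                      residue_name = resname, residue_seq = resseq,
                      chain_id = "A", role = "other",
                      stringsAsFactors = FALSE)
  list(atoms = atoms, xyz = xyz, box = box)
}

#' Load a topology plus optional trajectory into a `pore_frames` object
#'
#' Topologies: GRO (native nm) or PDB (via bio3d, converted from Angstrom).
#' Trajectories: DCD (via bio3d, Angstrom converted to nm) or the package's
#' JSON trajectory dialect (see [write_frames()]).  Without a trajectory the
#' topology's single frame is returned.
#'
#' @param topology_path path to a .gro or .pdb file.
#' @param trajectory_path optional path to a .dcd or .json trajectory.
#' @param selection_rules role-assignment rules, see
#'   [default_selection_rules()].
#' @param box box lengths (nm) to use when the topology provides none (PDB
#'   without CRYST1).
#' @param dt_ps frame spacing assumed for DCD files (which store no times).
#' @return a `pore_frames` object with roles assigned.
#' @export
load_trajectory <- function(topology_path, trajectory_path = NULL,
                            selection_rules = default_selection_rules(),
                            box = NULL, dt_ps = 1) {
  ext <- tolower(tools::file_ext(topology_path))
  if (ext == "gro") {
    g <- read_gro(topology_path)
    atoms <- g$atoms; xyz0 <- g$xyz; box0 <- g$box
  } else if (ext == "pdb") {
    p <- bio3d::read.pdb(topology_path)
    a <- p$atom
    atoms <- data.frame(atom_id = seq_len(nrow(a)),
                        element = ifelse(is.na(a$elesy) | a$elesy == "",
                                         .guess_element(a$elety), toupper(a$elesy)),
                        residue_name = a$resid, residue_seq = a$resno,
                        chain_id = ifelse(is.na(a$chain), "A", a$chain),
                        role = "other", stringsAsFactors = FALSE)
    xyz0 <- cbind(a$x, a$y, a$z) / 10   # Angstrom -> nm
    box0 <- if (!is.null(box)) box else c(10, 10, 10)
  } else stop("unsupported topology format: ", ext)
  if (!is.null(box)) box0 <- box
  atoms <- assign_roles(atoms, selection_rules)

  if (is.null(trajectory_path)) {
    xyz <- array(xyz0, dim = c(nrow(atoms), 3, 1))
    return(pore_frames(times = 0, box = matrix(box0, 1, 3), xyz = xyz,
                       atoms = atoms))
  }
  text <- tolower(tools::file_ext(trajectory_path))
  if (text == "json") {
    fr <- read_frames(trajectory_path)
    if (dim(fr$xyz)[1] != nrow(atoms))
      stop("format error: trajectory has ", dim(fr$xyz)[1],
           " atoms but topology has ", nrow(atoms))
    fr$atoms <- atoms
    return(fr)
  }
  if (text == "dcd") {
    m <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
    nf <- nrow(m)
    if (ncol(m) != 3 * nrow(atoms))
      stop("format error: trajectory has ", ncol(m) / 3,
           " atoms but topology has ", nrow(atoms))
    xyz <- array(0, dim = c(nrow(atoms), 3, nf))
    for (t in seq_len(nf))
      xyz[, , t] <- matrix(m[t, ], ncol = 3, byrow = TRUE) / 10
    return(pore_frames(times = (seq_len(nf) - 1) * dt_ps,
                       box = matrix(box0, nf, 3, byrow = TRUE),
                       xyz = xyz, atoms = atoms))
  }
  stop("unsupported trajectory format: ", text)
}

#' Write / read the internal JSON trajectory dialect
#'
#' A self-contained single-file dialect holding `time` (ps), `box` (nm),
#' `positions` (nm), the atom table and the axial sign convention.  Numbers
#' are written at full precision, so a write/read round trip reproduces the
#' object bit-exactly.
#'
#' @param frames a `pore_frames` object.
#' @param path output/input file path.
#' @return `write_frames`: the path, invisibly; `read_frames`: a
#'   `pore_frames` object.
#' @export
write_frames <- function(frames, path) {
  obj <- list(format = "poreflux-traj", version = 1L,
              axis_convention = .axis_convention,
              time = frames$times, box = frames$box,
              atom_table = frames$atoms,
              axis_origin = frames$axis_origin,
              axis_direction = frames$axis_direction,
              dim = dim(frames$xyz),
              positions = as.numeric(frames$xyz))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "poreflux-traj"))
    stop("format error: not a poreflux trajectory file")
  xyz <- array(as.numeric(obj$positions), dim = obj$dim)
  box <- obj$box
  storage.mode(box) <- "double"
  pore_frames(times = as.numeric(obj$time), box = box, xyz = xyz,
              atoms = obj$atom_table, axis_origin = as.numeric(obj$axis_origin),
              axis_direction = as.numeric(obj$axis_direction))
}

#' Define the pore-axis coordinate frame
#'
#' Sets `axis_origin` to the centroid of a reference selection (time-averaged
#' by default) and the axis direction to box z, or to the selection's
#' principal axis when requested.  Downstream axial coordinates are reported
#' relative to this origin, positive toward the extracellular side.
#'
#' @param frames a `pore_frames` object.
#' @param reference_selection integer atom indices (e.g. filter backbone
#'   atoms of all four subunits); must be non-empty.
#' @param mode `"z"` (default, box z axis) or `"principal"`.
#' @param frame `"average"` to use the time-averaged centroid, or a frame
#'   index.
#' @return the `pore_frames` object with axis fields set.
#' @export
define_pore_axis <- function(frames, reference_selection,
                             mode = c("z", "principal"), frame = "average") {
  mode <- match.arg(mode)
  if (length(reference_selection) == 0) stop("selection error: empty reference")
  sub <- frames$xyz[reference_selection, , , drop = FALSE]
  if (identical(frame, "average")) {
    cen <- apply(sub, 2, mean)
    pts <- apply(sub, c(1, 2), mean)
  } else {
    cen <- colMeans(matrix(sub[, , frame], ncol = 3))
    pts <- matrix(sub[, , frame], ncol = 3)
  }
  if (mode == "z") {
    u <- c(0, 0, 1)
  } else {
    pc <- sweep(pts, 2, colMeans(pts))
    ev <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)
    if (ev$values[2] < 1e-12)
      stop("geometry error: reference selection is degenerate (collinear)")
    u <- ev$vectors[, 1]
    if (u[3] < 0) u <- -u   # keep +axis toward extracellular (+z)
  }
  frames$axis_origin <- as.numeric(cen)
  frames$axis_direction <- u / sqrt(sum(u^2))
  frames
}

#' Remove periodic jumps from ion axial coordinates
#'
#' Makes every ion's z-series continuous: an inter-frame jump larger than
#' half the box height is corrected by a whole box length, so periodic
#' re-entries are not mistaken for traversals.  Non-axial coordinates are
#' untouched.  Idempotent.
#'
#' @param frames a `pore_frames` object (axis along box z).
#' @param roles atom roles to unwrap (default: all ion roles).
#' @return the `pore_frames` object with continuous ion z-series.
#' @export
unwrap_axial <- function(frames, roles = c("ion_K", "ion_Na", "ion_Cl")) {
  idx <- .atom_idx(frames, roles)
  nf <- .n_frames(frames)
  if (length(idx) == 0 || nf < 2) return(frames)
  Lz <- frames$box[-1, 3]
  z <- t(matrix(frames$xyz[idx, 3, ], nrow = length(idx)))  # frames x atoms
  dz <- z[-1, , drop = FALSE] - z[-nf, , drop = FALSE]
  dzc <- dz - Lz * round(dz / Lz)                # Lz recycles down columns
  if (any(abs(dzc) > Lz))
    stop("sampling-too-sparse error: axial jump exceeds box height after correction")
  cum <- apply(dzc, 2, cumsum)
  zu <- rbind(z[1, ], sweep(matrix(cum, ncol = length(idx)), 2, z[1, ], "+"))
  frames$xyz[idx, 3, ] <- t(zu)
  frames
}

#' Kabsch superposition of two coordinate sets
#'
#' Least-squares rigid fit of `mobile` onto `reference` (proper rotation,
#' determinant +1) with the residual RMSD.
#'
#' @param mobile,reference numeric `n x 3` matrices, n >= 3, in nm.
#' @return list with `rotation` (3x3), `translation` (length 3) such that
#'   `mobile %*% t(rotation) + translation` best matches `reference`, and
#'   `rmsd_after_fit` (nm).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || nrow(mobile) < 3)
    stop("geometry error: need equal atom counts >= 3")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  s <- svd(crossprod(A, B))         # A^T B = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr - (R %*% cm)),
       rmsd_after_fit = rmsd)
}

#' Per-atom root-mean-square fluctuation
#'
#' Each frame is superposed on the first frame using `fit_selection`; RMSF of
#' each measured atom is the square root of the time-averaged squared
#' deviation from its time-averaged (fitted) position.
#'
#' @param frames a `pore_frames` object with >= 2 frames.
#' @param fit_selection,measure_selection integer atom indices.
#' @return data.frame with `atom_id`, `residue_seq`, `rmsf_nm`.
#' @export
rmsf_per_atom <- function(frames, fit_selection, measure_selection) {
  if (length(fit_selection) == 0 || length(measure_selection) == 0)
    stop("selection error: empty selection")
  nf <- .n_frames(frames)
  if (nf < 2) stop("need >= 2 frames")
  ref <- matrix(frames$xyz[fit_selection, , 1], ncol = 3)
  fitted <- array(0, dim = c(length(measure_selection), 3, nf))
  for (t in seq_len(nf)) {
    fit <- kabsch_superpose(matrix(frames$xyz[fit_selection, , t], ncol = 3), ref)
    m <- matrix(frames$xyz[measure_selection, , t], ncol = 3)
    fitted[, , t] <- sweep(m %*% t(fit$rotation), 2, -fit$translation)
  }
  mean_pos <- apply(fitted, c(1, 2), mean)
  dev2 <- sapply(seq_len(nf), function(t) rowSums((matrix(fitted[, , t], ncol = 3) - mean_pos)^2))
  dev2 <- matrix(dev2, nrow = length(measure_selection))
  data.frame(atom_id = frames$atoms$atom_id[measure_selection],
             residue_seq = frames$atoms$residue_seq[measure_selection],
             rmsf_nm = sqrt(rowMeans(dev2)))
}
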