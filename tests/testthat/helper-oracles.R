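# Independent oracles and fixture builders shared across the suite.

# Brute-force traversal oracle: a per-frame state machine over every ion's
# region sequence, written independently of detect_events (which walks
# run-length-compressed segments).  z: matrix n_frames x n_ions of
# continuous (unwrapped) axial coordinates.
oracle_detect_events <- function(z, times, atom_ids, z_upper, z_lower, Lz) {
  n <- ncol(z)
  seg <- floor((z - z_lower) / Lz) + floor((z - z_upper) / Lz) + 2
  inside <- seg %% 2 != 0
  last_out <- rep(NA_real_, n)
  pending <- rep(FALSE, n)
  entry <- rep(NA_real_, n)
  tent <- rep(NA_real_, n)
  rows <- list()
  for (t in seq_along(times)) {
    s <- seg[t, ]
    ins <- inside[t, ]
    new_in <- ins & !pending
    if (any(new_in)) {
      pending[new_in] <- TRUE
      entry[new_in] <- last_out[new_in]
      tent[new_in] <- times[t]
    }
    ex <- !ins & pending
    if (any(ex)) {
      for (k in which(ex)) {
        if (!is.na(entry[k]) && s[k] != entry[k]) {
          rows[[length(rows) + 1]] <- data.frame(
            ion_id = atom_ids[k],
            direction = if (s[k] > entry[k]) "outward" else "inward",
            t_enter_ps = tent[k], t_exit_ps = times[t])
        }
      }
      pending[ex] <- FALSE
    }
    out_now <- !ins
    last_out[out_now] <- s[out_now]
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ion_id = integer(0), direction = character(0),
               t_enter_ps = numeric(0), t_exit_ps = numeric(0))
  ev[order(ev$t_exit_ps, ev$ion_id), , drop = FALSE]
}

# 27-image shell-count oracle: enumerates all periodic images explicitly
# instead of using the minimum-image formula.
oracle_shell_count_27 <- function(center, pts, box, radius) {
  if (nrow(pts) == 0) return(0L)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  n <- 0L
  for (i in seq_len(nrow(pts))) {
    d2 <- apply(shifts, 1, function(s)
      sum((pts[i, ] + s * box - center)^2))
    if (min(d2) <= radius^2) n <- n + 1L
  }
  n
}

# two-sided permutation p-value for a difference in means
oracle_perm_pvalue <- function(a, b, n_perm = 10000, seed = 42) {
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  n1 <- length(a)
  set.seed(seed)
  stat <- replicate(n_perm, {
    idx <- sample.int(length(pool), n1)
    mean(pool[idx]) - mean(pool[-idx])
  })
  mean(abs(stat) >= abs(obs) - 1e-12)
}

# single-ion trajectory fixture: a pore_frames object following a given
# z-series (x = y = 0), optionally with extra static water atoms
make_ion_frames <- function(z_series, box = c(4, 4, 10), dt = 100,
                            species = "K", xy = NULL) {
  nf <- length(z_series)
  xyz <- array(0, dim = c(1, 3, nf))
  xyz[1, 3, ] <- z_series
  if (!is.null(xy)) { xyz[1, 1, ] <- xy[, 1]; xyz[1, 2, ] <- xy[, 2] }
  atoms <- data.frame(atom_id = 1L, element = toupper(species),
                      residue_name = if (species == "K") "POT" else "SOD",
                      residue_seq = 1L, chain_id = "X",
                      role = paste0("ion_", species), stringsAsFactors = FALSE)
  pore_frames(times = (seq_len(nf) - 1) * dt,
              box = matrix(box, nf, 3, byrow = TRUE), xyz = xyz, atoms = atoms)
}

# multi-atom static frame fixture from a coordinate matrix and role vector
make_static_frames <- function(coords, roles, box = c(6, 6, 12), n_frames = 1,
                               elements = NULL) {
  n <- nrow(coords)
  if (is.null(elements))
    elements <- ifelse(roles %in% c("water_O", "protein"), "O", "K")
  xyz <- array(0, dim = c(n, 3, n_frames))
  for (t in seq_len(n_frames)) xyz[, , t] <- coords
  atoms <- data.frame(atom_id = seq_len(n), element = elements,
                      residue_name = ifelse(roles == "water_O", "SOL",
                                     ifelse(roles == "protein", "GLY", "POT")),
                      residue_seq = seq_len(n), chain_id = "X", role = roles,
                      stringsAsFactors = FALSE)
  pore_frames(times = (seq_len(n_frames) - 1) * 10,
              box = matrix(box, n_frames, 3, byrow = TRUE), xyz = xyz,
              atoms = atoms)
}

# default boundary fixture used across permeation tests
simple_bounds <- function(z_upper = 2, z_lower = -2, ...) {
  boundary_spec(z_upper = z_upper, z_lower = z_lower,
                sf_window = c(z_upper - 1.2, z_upper - 0.2),
                pore_window = c(z_lower, z_upper),
                gate_window = c(z_lower + 0.3, z_lower + 0.7), ...)
}
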