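# Pore geometry: largest-inscribed-sphere radius profiles along the axis
# (multi-start derivative-free optimization per slice), gate metrics
# (opposing-residue distances, gate water counts), and block-averaged
# correlation of time series.

#' Van der Waals radius table (nm)
#'
#' Bondi-style radii; unknown elements fall back to the declared default
#' with a warning.  Supply a custom table to match other radius sets.
#'
#' @param default fallback radius (nm) for unlisted elements.
#' @return named list of radii with attribute `default`.
#' @export
vdw_radius_table <- function(default = 0.170) {
  structure(list(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
                 P = 0.180, K = 0.275, `NA` = 0.227, CL = 0.175),
            default = default)
}

.vdw_of <- function(elements, table) {
  el <- toupper(elements)
  r <- unlist(table[el], use.names = FALSE)
  miss <- !(el %in% names(table))
  if (any(miss)) {
    warning("unknown elements in vdW table, using default: ",
            paste(unique(el[miss]), collapse = ", "))
    out <- numeric(length(el))
    out[!miss] <- unlist(table[el[!miss]], use.names = FALSE)
    out[miss] <- attr(table, "default")
    return(out)
  }
  r
}

#' Pore-radius profile of one frame (largest inscribed sphere)
#'
#' At each z-sample the pore radius is the largest sphere centered in that
#' plane that touches no atom's van der Waals surface:
#' `radius(z) = max over centers c of min over atoms a of (|c - a| - vdw(a))`,
#' found by multi-start Nelder-Mead seeded from the previous slice's center.
#' Negative optima are clamped to zero; slices with no candidate atoms, or
#' where the optimizer escapes the structure, are marked as gaps (`NA`).
#'
#' @param frames a `pore_frames` object with protein atoms.
#' @param z_range axial range (nm) to profile.
#' @param dz sample spacing (nm).
#' @param table a [vdw_radius_table()].
#' @param frame frame index.
#' @param slab_half half-width (nm) of the z-slab of candidate atoms per
#'   slice.
#' @param n_starts multistart count (previous center plus jittered starts).
#' @param r_cap radii above this (nm) are treated as gaps (default: the
#'   optimizer escaped; a quarter of the smaller lateral box length).
#' @return data.frame with `z_nm`, `radius_nm`, `cx_nm`, `cy_nm`, `gap`.
#' @export
pore_radius_profile <- function(frames, z_range, dz = 0.05,
                                table = vdw_radius_table(), frame = 1,
                                slab_half = 1.0, n_starts = 5,
                                r_cap = NULL) {
  prot <- .atom_idx(frames, "protein")
  if (!length(prot)) stop("selection error: no protein atoms")
  if (is.null(r_cap)) r_cap <- min(frames$box[frame, 1:2]) / 4
  pos <- matrix(frames$xyz[prot, , frame], ncol = 3)
  pos <- sweep(pos, 2, frames$axis_origin)
  vdw <- .vdw_of(frames$atoms$element[prot], table)
  zs <- seq(z_range[1], z_range[2], by = dz)
  res <- data.frame(z_nm = zs, radius_nm = NA_real_, cx_nm = NA_real_,
                    cy_nm = NA_real_, gap = TRUE)
  prev <- c(0, 0)
  jit <- rbind(c(0, 0), c(0.1, 0), c(-0.1, 0), c(0, 0.1), c(0, -0.1),
               c(0.07, 0.07), c(-0.07, -0.07))
  for (i in seq_along(zs)) {
    z <- zs[i]
    cand <- which(abs(pos[, 3] - z) <= slab_half)
    if (!length(cand)) { prev <- c(0, 0); next }
    px <- pos[cand, 1]; py <- pos[cand, 2]; pz <- pos[cand, 3]; pv <- vdw[cand]
    clearance <- function(c2) {
      min(sqrt((c2[1] - px)^2 + (c2[2] - py)^2 + (z - pz)^2) - pv)
    }
    best <- NULL
    for (s in seq_len(min(n_starts, nrow(jit)))) {
      o <- optim(prev + jit[s, ], function(p) -clearance(p),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 400))
      if (is.null(best) || o$value < best$value) best <- o
    }
    r <- -best$value
    if (r > r_cap) { prev <- c(0, 0); next }   # escaped: gap, not fabricated
    res$radius_nm[i] <- max(r, 0)
    res$cx_nm[i] <- best$par[1]; res$cy_nm[i] <- best$par[2]
    res$gap[i] <- FALSE
    prev <- best$par
  }
  res
}

#' Time-averaged pore-radius profile
#'
#' @param frames a `pore_frames` object.
#' @param stride use every `stride`-th frame.
#' @param ... passed to [pore_radius_profile()].
#' @inheritParams pore_radius_profile
#' @return data.frame with `z_nm`, `radius_mean_nm`, `radius_sd_nm`,
#'   `n_frames`.
#' @export
profile_over_time <- function(frames, z_range, dz = 0.05, stride = 1, ...) {
  stopifnot(stride >= 1)
  ts <- seq(1, .n_frames(frames), by = stride)
  profs <- lapply(ts, function(t)
    pore_radius_profile(frames, z_range = z_range, dz = dz, frame = t, ...)$radius_nm)
  m <- do.call(cbind, profs)
  data.frame(z_nm = seq(z_range[1], z_range[2], by = dz),
             radius_mean_nm = rowMeans(m, na.rm = TRUE),
             radius_sd_nm = apply(m, 1, sd, na.rm = TRUE),
             n_frames = length(ts))
}

#' Gate metrics: opposing-residue distances and gate water counts
#'
#' For four gate atoms (one per subunit) with declared opposing pairs,
#' reports both diagonal distances, their minimum, and the number of water
#' oxygens inside the gate region (z-slab intersected with a radial cutoff)
#' per frame.
#'
#' @param frames a `pore_frames` object.
#' @param gate_atoms atom ids of the four gate atoms.
#' @param opposing_pairs list of two index pairs into `gate_atoms` declaring
#'   the diagonals (honored as declared, not nearest-neighbor).
#' @param bounds a [boundary_spec()] with a `gate_window`.
#' @return data.frame with `t_ps`, `d1_nm`, `d2_nm`, `d_opposing_min_nm`,
#'   `n_gate_waters`.
#' @export
gate_metrics <- function(frames, gate_atoms,
                         opposing_pairs = list(c(1, 3), c(2, 4)), bounds) {
  if (length(gate_atoms) != 4) stop("config error: need exactly 4 gate atoms")
  if (length(opposing_pairs) != 2) stop("config error: declare both opposing pairs")
  if (is.null(bounds$gate_window)) stop("config error: bounds lack a gate_window")
  ai <- match(gate_atoms, frames$atoms$atom_id)
  if (anyNA(ai)) stop("config error: unknown gate atom id")
  wat <- .atom_idx(frames, "water_O")
  Lz <- frames$box[1, 3]
  nf <- .n_frames(frames)
  d1 <- d2 <- numeric(nf); nw <- integer(nf)
  for (t in seq_len(nf)) {
    p <- matrix(frames$xyz[ai, , t], ncol = 3)
    d1[t] <- sqrt(sum((p[opposing_pairs[[1]][1], ] - p[opposing_pairs[[1]][2], ])^2))
    d2[t] <- sqrt(sum((p[opposing_pairs[[2]][1], ] - p[opposing_pairs[[2]][2], ])^2))
    if (length(wat)) {
      zw <- .wrap_z(frames$xyz[wat, 3, t] - frames$axis_origin[3], Lz)
      rw <- sqrt((frames$xyz[wat, 1, t] - frames$axis_origin[1])^2 +
                   (frames$xyz[wat, 2, t] - frames$axis_origin[2])^2)
      nw[t] <- sum(zw >= bounds$gate_window[1] & zw <= bounds$gate_window[2] &
                     rw <= bounds$gate_radial_cutoff)
    }
  }
  data.frame(t_ps = frames$times, d1_nm = d1, d2_nm = d2,
             d_opposing_min_nm = pmin(d1, d2), n_gate_waters = nw)
}

#' Block-averaged correlation of two time series
#'
#' Reduces both series to means over non-overlapping blocks (suppressing
#' autocorrelation), then reports the Pearson correlation of the block
#' means.  The incomplete trailing block is dropped.
#'
#' @param series_a,series_b equal-length numeric series.
#' @param dt_ns sampling interval (ns).
#' @param block_ns block length (ns); the study convention is 20 ns.
#' @return list with `r`, `r2`, `n_blocks`, and `block_means` (data.frame
#'   `a`, `b`).
#' @export
block_correlation <- function(series_a, series_b, dt_ns, block_ns = 20) {
  if (length(series_a) != length(series_b))
    stop("config error: series lengths differ")
  per <- max(1L, round(block_ns / dt_ns))
  n_blocks <- floor(length(series_a) / per)
  if (n_blocks < 3) stop("insufficient-data error: need >= 3 complete blocks")
  take <- seq_len(n_blocks * per)
  am <- colMeans(matrix(series_a[take], nrow = per))
  bm <- colMeans(matrix(series_b[take], nrow = per))
  r <- cor(am, bm)
  list(r = r, r2 = r^2, n_blocks = n_blocks,
       block_means = data.frame(a = am, b = bm))
}
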