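# Volume-normalized ion occupancy: 1D profiles along the pore axis, 2D
# (z, r) maps normalized by the annular bin volume so an azimuthally uniform
# distribution appears flat in r, and mean simultaneous ion counts in the
# filter and pore regions (the knock-on bookkeeping).

# wrapped axial and radial coordinates for a species: list(z, r), each
# n_frames x n_ions
.ion_zr <- function(frames, species) {
  idx <- .atom_idx(frames, .species_role(species))
  if (length(idx) == 0) stop("selection error: no ions of species ", species)
  Lz <- frames$box[1, 3]
  list(z = .wrap_z(.z_rel(frames, idx), Lz), r = .r_rel(frames, idx), idx = idx)
}

.occupancy_map <- function(dimension, z_edges, r_edges, counts, density,
                           n_frames, species) {
  structure(list(dimension = dimension, z_edges = z_edges, r_edges = r_edges,
                 counts = counts, density = density, n_frames = n_frames,
                 species = species),
            class = "occupancy_map")
}

#' One-dimensional ion occupancy profile along the pore axis
#'
#' Ion-frame counts per z-bin inside a radial cutoff, normalized by frame
#' count and cylindrical bin volume (`pi r_cut^2 dz`), giving mean ions per
#' nm^3 per frame.  Multiply by 1e-3 for the ions-per-0.001-nm^3 convention,
#' or by 1e-6 for ions per 0.001 Angstrom^3.
#'
#' @param frames a `pore_frames` object.
#' @param species ion species.
#' @param z_range axial window (nm), inside the box.
#' @param bin_width z-bin width (nm).
#' @param radial_cutoff radial cutoff (nm).
#' @return an `occupancy_map` with `density` in ions/nm^3; the identity
#'   `sum(density * bin_volume) = mean in-region ion count per frame` holds
#'   by construction.
#' @export
occupancy_1d <- function(frames, species, z_range, bin_width = 0.05,
                         radial_cutoff = 1.2) {
  stopifnot(bin_width > 0, radial_cutoff > 0)
  Lz <- frames$box[1, 3]
  if (z_range[1] < -Lz / 2 || z_range[2] > Lz / 2)
    stop("config error: z_range outside the box")
  zr <- .ion_zr(frames, species)
  edges <- seq(z_range[1], z_range[2], by = bin_width)
  if (tail(edges, 1) < z_range[2]) edges <- c(edges, z_range[2])
  sel <- zr$r <= radial_cutoff & zr$z >= edges[1] & zr$z <= tail(edges, 1)
  bin <- findInterval(zr$z[sel], edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  vol <- pi * radial_cutoff^2 * diff(edges)
  nf <- .n_frames(frames)
  .occupancy_map("z", edges, NULL, counts, counts / (nf * vol), nf, species)
}

#' Two-dimensional (z, r) ion occupancy map
#'
#' Counts in (z, r) bins with r the distance from the pore axis; the density
#' is normalized by the annular bin volume `2 pi r_mid dr dz` (identical to
#' the exact annulus `pi (r_out^2 - r_in^2) dz` at mid-point radius), so an
#' azimuthally uniform ion distribution appears flat in r.
#'
#' @inheritParams occupancy_1d
#' @param r_max radial extent (nm).
#' @param dz,dr bin widths (nm); `dr` must be smaller than `r_max`.
#' @return an `occupancy_map` with matrices `counts` and `density`
#'   (z bins x r bins).
#' @export
occupancy_2d <- function(frames, species, z_range, r_max = 1.2, dz = 0.05,
                         dr = 0.025) {
  if (dr >= r_max) stop("config error: dr must be smaller than r_max")
  Lz <- frames$box[1, 3]
  if (z_range[1] < -Lz / 2 || z_range[2] > Lz / 2)
    stop("config error: z_range outside the box")
  zr <- .ion_zr(frames, species)
  z_edges <- seq(z_range[1], z_range[2], by = dz)
  if (tail(z_edges, 1) < z_range[2]) z_edges <- c(z_edges, z_range[2])
  r_edges <- seq(0, r_max, by = dr)
  if (tail(r_edges, 1) < r_max) r_edges <- c(r_edges, r_max)
  sel <- zr$r <= r_max & zr$z >= z_edges[1] & zr$z <= tail(z_edges, 1)
  zb <- findInterval(zr$z[sel], z_edges, rightmost.closed = TRUE)
  rb <- findInterval(zr$r[sel], r_edges, rightmost.closed = TRUE)
  nz <- length(z_edges) - 1; nr <- length(r_edges) - 1
  counts <- matrix(tabulate((rb - 1) * nz + zb, nbins = nz * nr), nz, nr)
  r_mid <- (r_edges[-1] + r_edges[-length(r_edges)]) / 2
  vol <- outer(diff(z_edges), 2 * pi * r_mid * diff(r_edges))
  nf <- .n_frames(frames)
  .occupancy_map("z_r", z_edges, r_edges, counts, counts / (nf * vol), nf,
                 species)
}

#' Bin volumes of an occupancy map (nm^3)
#'
#' @param map an `occupancy_map`.
#' @param radial_cutoff the radial cutoff used for a 1D map.
#' @return vector or matrix of bin volumes matching `map$density`.
#' @export
bin_volumes <- function(map, radial_cutoff = 1.2) {
  if (map$dimension == "z") pi * radial_cutoff^2 * diff(map$z_edges)
  else outer(diff(map$z_edges),
             pi * (map$r_edges[-1]^2 - map$r_edges[-length(map$r_edges)]^2))
}

#' Long-format export of an occupancy map
#'
#' @param map an `occupancy_map`.
#' @return data.frame with `z_nm` (and `r_nm` for 2D maps) bin centers and
#'   `density` (ions/nm^3).
#' @export
occupancy_table <- function(map) {
  z_mid <- (map$z_edges[-1] + map$z_edges[-length(map$z_edges)]) / 2
  if (map$dimension == "z")
    return(data.frame(z_nm = z_mid, density = as.numeric(map$density)))
  r_mid <- (map$r_edges[-1] + map$r_edges[-length(map$r_edges)]) / 2
  data.frame(z_nm = rep(z_mid, times = length(r_mid)),
             r_nm = rep(r_mid, each = length(z_mid)),
             density = as.numeric(map$density))
}

#' Mean simultaneous ion counts in the filter, pore and binding regions
#'
#' Per-frame ion counts inside each region (z-window and radial cutoff; the
#' side pocket is a sphere), averaged over time per run, then summarized
#' across runs.  Multiple simultaneous ions in the filter are the signature
#' of knock-on conduction.
#'
#' @param frames a `pore_frames` object.
#' @param bounds a [boundary_spec()].
#' @param species ion species.
#' @param runs optional factor/vector assigning each frame to a run
#'   (default: a single run).
#' @return data.frame with `region`, `species`, `mean_ions`,
#'   `sd_across_runs`, `n_runs`.
#' @export
site_occupancy <- function(frames, bounds, species, runs = NULL) {
  zr <- .ion_zr(frames, species)
  nf <- .n_frames(frames)
  if (is.null(runs)) runs <- rep(1L, nf)
  stopifnot(length(runs) == nf)
  regions <- c(bounds$sites,
               list(SF = bounds$sf_window, pore = bounds$pore_window))
  per_frame <- lapply(regions, function(w)
    rowSums(zr$z >= w[1] & zr$z <= w[2] & zr$r <= bounds$radial_cutoff))
  if (length(bounds$side_pocket_regions)) {
    box <- frames$box[1, ]
    idx <- zr$idx
    inp <- matrix(FALSE, nf, length(idx))
    for (p in bounds$side_pocket_regions) {
      for (k in seq_along(idx)) {
        pts <- cbind(frames$xyz[idx[k], 1, ] - frames$axis_origin[1],
                     frames$xyz[idx[k], 2, ] - frames$axis_origin[2],
                     .wrap_z(frames$xyz[idx[k], 3, ] - frames$axis_origin[3],
                             box[3]))
        inp[, k] <- inp[, k] | .min_image_dist(pts, p$center, box) <= p$radius
      }
    }
    per_frame$side_pocket <- rowSums(inp)
  }
  out <- lapply(names(per_frame), function(rn) {
    by_run <- tapply(per_frame[[rn]], runs, mean)
    data.frame(region = rn, species = species, mean_ions = mean(by_run),
               sd_across_runs = if (length(by_run) > 1) sd(by_run) else 0,
               n_runs = length(by_run))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
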