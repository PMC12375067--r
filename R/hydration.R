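# First-hydration-shell composition: how many water versus protein oxygens
# coordinate a permeating cation, resolved along the pore axis.  Shell radii
# follow the first minimum of the ion-oxygen pair distribution:
# 0.31 nm for Na+, 0.34 nm for K+.

#' Hydration-shell parameters
#'
#' @param shell_radius named per-species first-shell radii (nm); defaults
#'   are the canonical 0.31 nm (Na) and 0.34 nm (K).
#' @return a `hydration_params` list.  The shell boundary is closed: an
#'   oxygen exactly at the radius is counted.
#' @export
hydration_params <- function(shell_radius = c(Na = 0.31, K = 0.34)) {
  if (any(shell_radius <= 0)) stop("config error: shell radii must be > 0")
  structure(list(shell_radius = shell_radius), class = "hydration_params")
}

# oxygen atom indices by origin
.oxygen_idx <- function(frames) {
  list(water = .atom_idx(frames, "water_O"),
       protein = which(frames$atoms$role == "protein" &
                         toupper(frames$atoms$element) == "O"))
}

#' Count first-shell water and protein oxygens around one ion
#'
#' Center-to-center distances under the minimum-image convention of the
#' frame's periodic box; the shell boundary is closed (distance equal to the
#' radius counts).
#'
#' @param frames a `pore_frames` object.
#' @param ion_id atom id of the ion.
#' @param params a [hydration_params()].
#' @param frame frame index.
#' @return named integer vector `c(n_water_O, n_protein_O)`.
#' @export
first_shell_count <- function(frames, ion_id, params = hydration_params(),
                              frame = 1) {
  ai <- which(frames$atoms$atom_id == ion_id)
  if (length(ai) != 1) stop("unknown ion id: ", ion_id)
  species <- switch(frames$atoms$role[ai], ion_K = "K", ion_Na = "Na",
                    stop("config error: atom ", ion_id, " is not a K/Na ion"))
  radius <- params$shell_radius[[species]]
  if (is.null(radius) || is.na(radius))
    stop("config error: no shell radius configured for ", species)
  box <- frames$box[frame, ]
  pos <- frames$xyz[, , frame, drop = TRUE]
  ox <- .oxygen_idx(frames)
  cnt <- function(idx) {
    if (!length(idx)) return(0L)
    sum(.min_image_dist(pos[idx, , drop = FALSE], pos[ai, ], box) <= radius)
  }
  c(n_water_O = cnt(ox$water), n_protein_O = cnt(ox$protein))
}

#' Hydration profile along the pore axis
#'
#' Every (ion, frame) observation contributes its first-shell water and
#' protein oxygen counts to the z-bin of the ion's axial position; per-bin
#' means and the across-run SD of the total are reported.  Total equals
#' water plus protein in every bin exactly.
#'
#' @param frames a `pore_frames` object.
#' @param species ion species.
#' @param params a [hydration_params()].
#' @param z_edges z-bin edges (nm); observations outside the range are
#'   counted and reported with a warning, not silently dropped.
#' @param runs optional per-frame run assignment.
#' @return data.frame with `z_nm` (bin centers), `mean_water_O`,
#'   `mean_protein_O`, `mean_total_O`, `sd_total_across_runs`, `n_obs`.
#' @export
hydration_profile <- function(frames, species, params = hydration_params(),
                              z_edges = seq(-2, 2, by = 0.05), runs = NULL) {
  idx <- .atom_idx(frames, .species_role(species))
  if (!length(idx)) stop("selection error: no ions of species ", species)
  radius <- params$shell_radius[[species]]
  nf <- .n_frames(frames)
  if (is.null(runs)) runs <- rep(1L, nf)
  ox <- .oxygen_idx(frames)
  Lz <- frames$box[1, 3]
  nb <- length(z_edges) - 1
  run_ids <- sort(unique(runs))
  acc <- array(0, dim = c(nb, 3, length(run_ids)),
               dimnames = list(NULL, c("w", "p", "n"), NULL))
  n_outside <- 0L
  for (t in seq_len(nf)) {
    box <- frames$box[t, ]
    pos <- frames$xyz[, , t, drop = TRUE]
    ri <- match(runs[t], run_ids)
    for (k in idx) {
      zw <- .wrap_z(pos[k, 3] - frames$axis_origin[3], Lz)
      b <- findInterval(zw, z_edges, rightmost.closed = TRUE)
      if (b < 1 || b > nb) { n_outside <- n_outside + 1L; next }
      nw <- if (length(ox$water))
        sum(.min_image_dist(pos[ox$water, , drop = FALSE], pos[k, ], box) <= radius) else 0
      np <- if (length(ox$protein))
        sum(.min_image_dist(pos[ox$protein, , drop = FALSE], pos[k, ], box) <= radius) else 0
      acc[b, "w", ri] <- acc[b, "w", ri] + nw
      acc[b, "p", ri] <- acc[b, "p", ri] + np
      acc[b, "n", ri] <- acc[b, "n", ri] + 1
    }
  }
  if (n_outside > 0)
    warning(n_outside, " ion-frame observations fell outside the z bins")
  n_tot <- rowSums(acc[, "n", , drop = FALSE])
  mean_w <- ifelse(n_tot > 0, rowSums(acc[, "w", , drop = FALSE]) / n_tot, NA)
  mean_p <- ifelse(n_tot > 0, rowSums(acc[, "p", , drop = FALSE]) / n_tot, NA)
  per_run_tot <- sapply(seq_along(run_ids), function(ri)
    ifelse(acc[, "n", ri] > 0, (acc[, "w", ri] + acc[, "p", ri]) / acc[, "n", ri], NA))
  per_run_tot <- matrix(per_run_tot, nrow = nb)
  sd_tot <- if (length(run_ids) > 1) apply(per_run_tot, 1, sd, na.rm = TRUE)
            else rep(0, nb)
  data.frame(z_nm = (z_edges[-1] + z_edges[-length(z_edges)]) / 2,
             mean_water_O = mean_w, mean_protein_O = mean_p,
             mean_total_O = mean_w + mean_p,
             sd_total_across_runs = sd_tot, n_obs = as.integer(n_tot))
}
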