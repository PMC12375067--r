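#' Region boundaries for permeation and occupancy analysis
#'
#' Defines the z-planes and radial windows carving the system into
#' extracellular bulk (above `z_upper`), pore interior, and intracellular
#' bulk (below `z_lower`), plus the selectivity-filter window, the gate
#' window, the named filter binding regions and the off-axis side-pocket
#' spheres.  All coordinates are pore-axis coordinates in nm
#' (+z extracellular).
#'
#' @param z_upper,z_lower traversal boundaries (nm): above the extracellular
#'   filter mouth and below the gate.
#' @param sf_window,pore_window,gate_window z-windows (nm); the pore window
#'   must contain both the filter and gate windows.
#' @param radial_cutoff radial cutoff (nm) for pore/filter membership.
#' @param gate_radial_cutoff radial cutoff (nm) for gate-water counting.
#' @param side_pocket_regions list of `list(center = c(x, y, z), radius)`
#'   spheres (nm).
#' @param pathway_memory ps; how far back before first filter entry a pocket
#'   visit still marks the entry pathway as `side_pocket`.
#' @param sites named list of z-windows for the filter binding regions
#'   (S_intra, S_central, S_extra).
#' @return a `boundary_spec` list.
#' @export
boundary_spec <- function(z_upper, z_lower, sf_window, pore_window,
                          gate_window = NULL, radial_cutoff = 1.2,
                          gate_radial_cutoff = 0.6,
                          side_pocket_regions = list(),
                          pathway_memory = 200, sites = list()) {
  if (!(z_lower < sf_window[1] && sf_window[1] < sf_window[2] &&
        sf_window[2] <= z_upper))
    stop("config error: need z_lower < sf_window < z_upper")
  if (!(pore_window[1] <= sf_window[1] && pore_window[2] >= sf_window[2]))
    stop("config error: pore_window must contain sf_window")
  if (!is.null(gate_window) &&
      !(pore_window[1] <= gate_window[1] && pore_window[2] >= gate_window[2]))
    stop("config error: pore_window must contain gate_window")
  if (pathway_memory <= 0) stop("config error: pathway_memory must be > 0")
  if (radial_cutoff <= 0 || gate_radial_cutoff <= 0)
    stop("config error: radial cutoffs must be > 0")
  for (p in side_pocket_regions)
    if (p$radius <= 0) stop("config error: pocket radii must be > 0")
  structure(list(z_upper = z_upper, z_lower = z_lower,
                 sf_window = sf_window, pore_window = pore_window,
                 gate_window = gate_window, radial_cutoff = radial_cutoff,
                 gate_radial_cutoff = gate_radial_cutoff,
                 side_pocket_regions = side_pocket_regions,
                 pathway_memory = pathway_memory, sites = sites),
            class = "boundary_spec")
}

#' Boundaries matching a synthetic channel spec
#'
#' @param spec a [channel_spec()].
#' @param gate_window gate z-window (nm).
#' @return a [boundary_spec()] whose traversal boundaries, filter window,
#'   pocket sphere and pathway memory match the generator's ground truth.
#' @export
boundaries_from_spec <- function(spec, gate_window = c(-1.4, -1.0)) {
  pockets <- if (!is.null(spec$side_pocket))
    list(list(center = spec$side_pocket$center,
              radius = spec$side_pocket$radius)) else list()
  sites <- if (length(spec$well_centers) == 3)
    list(S_intra = spec$well_centers[1] + c(-0.15, 0.15),
         S_central = spec$well_centers[2] + c(-0.15, 0.15),
         S_extra = spec$well_centers[3] + c(-0.15, 0.15)) else list()
  boundary_spec(z_upper = spec$z_upper, z_lower = spec$z_lower,
                sf_window = spec$sf_window,
                pore_window = c(spec$z_lower, spec$z_upper),
                gate_window = gate_window,
                side_pocket_regions = pockets,
                pathway_memory = spec$pathway_memory,
                sites = sites)
}

# Segment index on the boundary-tiled axis (periodic images of the pore
# interval): odd = inside [z_lower, z_upper] (mod Lz), even = outside.  Works
# on unwrapped coordinates, so repeated traversals through periodic images
# are counted individually.
.axial_seg <- function(z, zlo, zup, Lz) {
  floor((z - zlo) / Lz) + floor((z - zup) / Lz) + 2
}

.wrap_z <- function(z, Lz) z - Lz * round(z / Lz)

#' Detect completed ion traversals of the pore
#'
#' Per-ion three-state bookkeeping on the axial coordinate: an ion that
#' enters the pore interval through one boundary and exits through the other
#' yields one event; re-exit through the entry boundary cancels the pending
#' traversal.  Intermediate excursions that do not cross a boundary are
#' ignored.  Crossings are resolved at frame resolution.  Detection operates
#' on continuous (unwrapped) ion z-series: wrapped input is unwrapped
#' internally (equivalently, pass frames through [unwrap_axial()] first —
#' the correction is idempotent); periodic images of the pore are tiled
#' along the unwrapped axis so every repeat traversal is counted.
#'
#' @param frames a `pore_frames` object.
#' @param bounds a [boundary_spec()].
#' @param species `"K"`, `"Na"` or `"Cl"`.
#' @return data.frame of events: `ion_id`, `species`, `direction`
#'   (`"inward"` toward -z, `"outward"` toward +z), `t_enter_ps` (first frame
#'   inside), `t_exit_ps` (first frame beyond the far boundary), `dwell_ps`,
#'   `entry_pathway` (`NA` until [classify_entry_pathway()]).  The boundary
#'   values used are echoed in attribute `boundaries`.
#' @export
detect_events <- function(frames, bounds, species = "K") {
  stopifnot(inherits(bounds, "boundary_spec"))
  Lz <- frames$box[1, 3]
  if (bounds$z_upper - bounds$z_lower >= Lz)
    stop("config error: boundaries span the whole box")
  if (max(abs(c(bounds$z_upper, bounds$z_lower))) > Lz / 2)
    stop("config error: boundaries outside the box")
  idx <- .atom_idx(frames, .species_role(species))
  times <- frames$times
  out <- vector("list", length(idx))
  if (length(idx)) {
    z <- .z_rel(frames, idx)                # frames x ions
    # make each ion's z-series continuous (identity on already-unwrapped
    # input, removes periodic re-entry jumps on wrapped input)
    if (nrow(z) > 1) {
      dz <- z[-1, , drop = FALSE] - z[-nrow(z), , drop = FALSE]
      dzc <- dz - Lz * round(dz / Lz)
      z <- rbind(z[1, ], sweep(matrix(apply(dzc, 2, cumsum), ncol = ncol(z)),
                               2, z[1, ], "+"))
    }
    seg <- .axial_seg(z, bounds$z_lower, bounds$z_upper, Lz)
    for (k in seq_along(idx)) {
      out[[k]] <- .walk_segments(seg[, k], times,
                                 ion_id = frames$atoms$atom_id[idx[k]])
    }
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(ion_id = integer(0), direction = character(0),
                     t_enter_ps = numeric(0), t_exit_ps = numeric(0))
  ev <- ev[order(ev$t_exit_ps, ev$ion_id), , drop = FALSE]
  res <- data.frame(ion_id = ev$ion_id, species = rep(species, nrow(ev)),
                    direction = ev$direction, t_enter_ps = ev$t_enter_ps,
                    t_exit_ps = ev$t_exit_ps,
                    dwell_ps = ev$t_exit_ps - ev$t_enter_ps,
                    entry_pathway = rep(NA_character_, nrow(ev)),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "boundaries") <- bounds
  attr(res, "axis_convention") <- .axis_convention
  res
}

# state machine over the run-length-compressed segment sequence of one ion
.walk_segments <- function(seg, times, ion_id) {
  r <- rle(seg)
  v <- r$values
  first_i <- cumsum(c(1, r$lengths[-length(r$lengths)]))
  last_i <- cumsum(r$lengths)
  events <- list()
  last_out <- NA_real_; pending <- FALSE; entry_out <- NA_real_
  t_enter <- NA_real_; t_prev <- times[1]
  for (j in seq_along(v)) {
    # decompose multi-segment jumps into instantaneous intermediate visits
    vis_vals <- v[j]
    if (j > 1 && abs(v[j] - v[j - 1]) > 1) {
      step <- sign(v[j] - v[j - 1])
      vis_vals <- seq(v[j - 1] + step, v[j], by = step)
    }
    for (m in seq_along(vis_vals)) {
      s <- vis_vals[m]
      real_run <- (m == length(vis_vals))
      t_first <- times[first_i[j]]
      if (s %% 2 != 0) {            # inside the pore interval
        if (!pending) {
          pending <- TRUE
          entry_out <- last_out
          t_enter <- if (real_run) t_first else t_prev
        }
      } else {                      # outside
        if (pending) {
          if (!is.na(entry_out) && s != entry_out) {
            t_exit <- t_first
            te <- if (t_enter < t_exit) t_enter else t_prev
            events[[length(events) + 1]] <-
              data.frame(ion_id = ion_id,
                         direction = if (s > entry_out) "outward" else "inward",
                         t_enter_ps = te, t_exit_ps = t_exit)
          }
          pending <- FALSE
        }
        last_out <- s
      }
    }
    t_prev <- times[last_i[j]]
  }
  if (length(events)) do.call(rbind, events) else NULL
}

#' Dwell-time distribution of permeation events
#'
#' @param events events from [detect_events()].
#' @param species optional species filter.
#' @param bin_width_ns histogram bin width (ns).
#' @return list with `dwell_ns` (all dwell times), `mean_ns`, `sd_ns`, `n`,
#'   and `histogram` (data.frame `mid_ns`, `count`).  An empty event list
#'   gives an empty distribution with a warning.
#' @export
dwell_times <- function(events, species = NULL, bin_width_ns = 0.5) {
  ev <- events
  if (!is.null(species)) ev <- ev[ev$species == species, , drop = FALSE]
  if (nrow(ev) == 0) {
    warning("no events: empty dwell-time distribution")
    return(list(dwell_ns = numeric(0), mean_ns = NA_real_, sd_ns = NA_real_,
                n = 0L, histogram = data.frame(mid_ns = numeric(0),
                                               count = integer(0))))
  }
  d <- ev$dwell_ps / 1000
  breaks <- seq(0, max(d) + bin_width_ns, by = bin_width_ns)
  counts <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  list(dwell_ns = d, mean_ns = mean(d), sd_ns = if (length(d) > 1) sd(d) else 0,
       n = length(d), histogram = data.frame(mid_ns = mids, count = counts))
}

# minimum-image distance of points (n x 3, centered coords) to a center
.min_image_dist <- function(pts, center, box) {
  d <- sweep(pts, 2, center)
  d <- d - matrix(box, nrow(d), 3, byrow = TRUE) *
    round(d / matrix(box, nrow(d), 3, byrow = TRUE))
  sqrt(rowSums(d^2))
}

#' Classify entry pathways of permeation events
#'
#' An event is `side_pocket` when the ion was inside any pocket sphere at
#' some time within `pathway_memory` before its first entry into the filter
#' window during the traversal; otherwise `on_axis`.  Also reports the
#' pathway split among completed traversals and, independently, among all
#' filter-entry episodes (an ion entering the filter from the extracellular
#' side, whether or not it completes a traversal).
#'
#' @param frames the `pore_frames` object the events came from (full 3D
#'   coordinates retained).
#' @param events events from [detect_events()].
#' @param bounds a [boundary_spec()] with non-empty `side_pocket_regions`.
#' @return list with `events` (entry_pathway filled in), `fractions`
#'   (per species/direction: events, side-pocket events, fraction), and
#'   `sf_entries` (per species: filter-entry episodes and pocket fraction).
#' @export
classify_entry_pathway <- function(frames, events, bounds) {
  if (length(bounds$side_pocket_regions) == 0)
    stop("config error: no side-pocket regions defined")
  if (bounds$pathway_memory <= 0) stop("config error: pathway_memory must be > 0")
  box <- frames$box[1, ]
  times <- frames$times
  pathway <- rep("on_axis", nrow(events))
  for (e in seq_len(nrow(events))) {
    ai <- which(frames$atoms$atom_id == events$ion_id[e])
    sel <- which(times >= events$t_enter_ps[e] & times <= events$t_exit_ps[e])
    if (!length(sel)) next
    zw <- .wrap_z(frames$xyz[ai, 3, sel] - frames$axis_origin[3], box[3])
    in_sf <- zw >= bounds$sf_window[1] & zw <= bounds$sf_window[2]
    if (!any(in_sf)) next
    t_sf <- times[sel[which(in_sf)[1]]]
    win <- which(times >= t_sf - bounds$pathway_memory & times <= t_sf)
    pts <- cbind(frames$xyz[ai, 1, win] - frames$axis_origin[1],
                 frames$xyz[ai, 2, win] - frames$axis_origin[2],
                 .wrap_z(frames$xyz[ai, 3, win] - frames$axis_origin[3], box[3]))
    for (p in bounds$side_pocket_regions) {
      if (any(.min_image_dist(pts, p$center, box) <= p$radius)) {
        pathway[e] <- "side_pocket"
        break
      }
    }
  }
  events$entry_pathway <- pathway
  fr <- do.call(rbind, lapply(split(seq_len(nrow(events)),
                                    list(events$species, events$direction),
                                    drop = TRUE), function(ii) {
    data.frame(species = events$species[ii[1]],
               direction = events$direction[ii[1]],
               n_events = length(ii),
               n_side_pocket = sum(events$entry_pathway[ii] == "side_pocket"),
               fraction = mean(events$entry_pathway[ii] == "side_pocket"))
  }))
  if (is.null(fr)) fr <- data.frame(species = character(0), direction = character(0),
                                    n_events = integer(0), n_side_pocket = integer(0),
                                    fraction = numeric(0))
  rownames(fr) <- NULL
  sf_entries <- .sf_entry_counter(frames, bounds)
  list(events = events, fractions = fr, sf_entries = sf_entries)
}

# filter-entry episodes (from the extracellular side) and their pocket
# fraction, independent of traversal completion
.sf_entry_counter <- function(frames, bounds) {
  box <- frames$box[1, ]
  times <- frames$times
  res <- list()
  for (role in c("ion_K", "ion_Na")) {
    idx <- .atom_idx(frames, role)
    if (!length(idx)) next
    n_entry <- 0L; n_pocket <- 0L
    for (ai in idx) {
      zw <- .wrap_z(frames$xyz[ai, 3, ] - frames$axis_origin[3], box[3])
      in_sf <- zw >= bounds$sf_window[1] & zw <= bounds$sf_window[2]
      above <- zw > bounds$sf_window[2]
      starts <- which(in_sf[-1] & above[-length(above)]) + 1L
      if (!length(starts)) next
      pts_all <- cbind(frames$xyz[ai, 1, ] - frames$axis_origin[1],
                       frames$xyz[ai, 2, ] - frames$axis_origin[2], zw)
      in_pocket <- rep(FALSE, length(times))
      for (p in bounds$side_pocket_regions)
        in_pocket <- in_pocket | .min_image_dist(pts_all, p$center, box) <= p$radius
      for (s in starts) {
        n_entry <- n_entry + 1L
        win <- times >= times[s] - bounds$pathway_memory & times <= times[s]
        if (any(in_pocket & win)) n_pocket <- n_pocket + 1L
      }
    }
    res[[role]] <- data.frame(species = sub("ion_", "", role),
                              n_sf_entries = n_entry,
                              n_via_pocket = n_pocket,
                              fraction = if (n_entry) n_pocket / n_entry else NA_real_)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(species = character(0),
                                      n_sf_entries = integer(0),
                                      n_via_pocket = integer(0),
                                      fraction = numeric(0))
  rownames(out) <- NULL
  out
}
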