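# Statistical comparisons and the pipeline driver: two-tailed unpaired
# Student's t tests with the study's significance labels, Gaussian kernel
# density estimates, and a YAML-configured end-to-end run over the synthetic
# generator with a reproducibility manifest.

#' Significance label for a p-value
#'
#' Thresholds: ns for p > 0.05, `*` for p <= 0.05, `**` for p <= 0.01,
#' `***` for p <= 0.001.
#'
#' @param p p-value in `[0, 1]`.
#' @return one of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
significance_label <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns"
}

#' Two-tailed unpaired Student's t test
#'
#' Pooled-variance (classic Student's) t statistic with
#' `df = n1 + n2 - 2` and a two-tailed p-value; Welch's correction is
#' available as a sensitivity check.
#'
#' @param sample_a,sample_b numeric samples, each of size >= 2.
#' @param welch use Welch's unequal-variance form instead.
#' @return list with `t_statistic`, `degrees_of_freedom`, `p_two_tailed`,
#'   `n1`, `n2`, `significance_label`.
#' @export
students_t_unpaired <- function(sample_a, sample_b, welch = FALSE) {
  n1 <- length(sample_a); n2 <- length(sample_b)
  if (n1 < 2 || n2 < 2) stop("need >= 2 observations per sample")
  pooled <- ((n1 - 1) * var(sample_a) + (n2 - 1) * var(sample_b)) / (n1 + n2 - 2)
  if (pooled == 0) stop("degenerate-sample error: zero pooled variance")
  ht <- t.test(sample_a, sample_b, var.equal = !welch, paired = FALSE,
               alternative = "two.sided")
  list(t_statistic = unname(ht$statistic),
       degrees_of_freedom = unname(ht$parameter),
       p_two_tailed = ht$p.value, n1 = n1, n2 = n2,
       significance_label = significance_label(ht$p.value))
}

#' Gaussian kernel density estimate on an explicit grid
#'
#' Scott's-rule bandwidth by default; the density is renormalized to unit
#' trapezoidal mass on the grid (the default grid spans the data plus three
#' bandwidths, which clips a small Gaussian tail mass).
#'
#' @param samples numeric sample with >= 2 distinct values.
#' @param grid_range range of the evaluation grid (default: data range
#'   plus/minus 3 bandwidths).
#' @param n_grid grid size.
#' @param bandwidth kernel bandwidth; default Scott's rule.
#' @return list with `grid`, `density`, `bandwidth`, `n_samples`.
#' @export
kde_distribution <- function(samples, grid_range = NULL, n_grid = 512,
                             bandwidth = NULL) {
  if (length(unique(samples)) < 2)
    stop("bandwidth-zero error: need >= 2 distinct samples")
  if (is.null(bandwidth)) bandwidth <- bw.nrd(samples)
  if (is.null(grid_range))
    grid_range <- range(samples) + c(-3, 3) * bandwidth
  grid <- seq(grid_range[1], grid_range[2], length.out = n_grid)
  dens <- vapply(grid, function(g)
    mean(dnorm(g, mean = samples, sd = bandwidth)), numeric(1))
  mass <- sum(diff(grid) * (dens[-1] + dens[-n_grid]) / 2)
  list(grid = grid, density = dens / mass, bandwidth = bandwidth,
       n_samples = length(samples))
}

#' Run the full synthetic-channel analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order over one or more
#' synthetic runs: trajectory generation, event detection and pathway
#' classification, segment conductance, occupancy maps and site occupancy,
#' hydration profile, and dwell-time statistics.  All stage outputs are
#' written as CSV files plus a single `manifest.json` recording every
#' parameter, boundary value, seed and package version used, sufficient to
#' replay the run.
#'
#' @param config a YAML file path or an equivalent named list.  Recognized
#'   keys: `seed`; `synth` (overrides for [channel_spec()], plus `n_runs`);
#'   `boundaries` (overrides for [boundaries_from_spec()]); `stages`
#'   (subset of `events`, `conductance`, `occupancy`, `hydration`,
#'   `dwell`); `conductance: segment_ns, discard`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config error: configuration must be a YAML map")
  known <- c("seed", "synth", "boundaries", "stages", "conductance",
             "occupancy", "hydration")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("config error: unknown keys: ", paste(bad, collapse = ", "))
  stages <- cfg$stages %||% c("events", "conductance", "occupancy", "dwell")
  if ("conductance" %in% stages && !("events" %in% stages))
    stop("dependency error: stage 'conductance' requires stage 'events'")
  if ("dwell" %in% stages && !("events" %in% stages))
    stop("dependency error: stage 'dwell' requires stage 'events'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seed <- cfg$seed %||% 1L
  synth <- cfg$synth %||% list()
  n_runs <- synth$n_runs %||% 1L
  synth$n_runs <- NULL
  spec_args <- synth
  spec_args$seed <- seed
  spec <- do.call(channel_spec, spec_args)
  bounds <- do.call(boundaries_from_spec,
                    c(list(spec = spec), cfg$boundaries %||% list()))
  run_ns <- spec$n_steps * spec$timestep_ps / 1000
  voltage <- field_voltage(spec$field_V_per_nm, spec$box[3])
  if (abs(voltage) < 1e-12 && "conductance" %in% stages)
    stop("undefined-conductance error: zero voltage in conductance stage")

  all_events <- list()
  sims <- list()
  for (r in seq_len(n_runs)) {
    spec_r <- spec; spec_r$seed <- as.integer(seed + 1000L * (r - 1L))
    sim <- simulate_channel(spec_r)
    sims[[r]] <- sim
    if ("events" %in% stages) {
      fr <- unwrap_axial(sim$frames)
      ev <- do.call(rbind, lapply(spec$species, function(sp)
        detect_events(fr, bounds, species = sp)))
      if (nrow(ev) && length(bounds$side_pocket_regions))
        ev <- classify_entry_pathway(sim$frames, ev, bounds)$events
      if (nrow(ev)) ev$run <- r
      all_events[[r]] <- ev
    }
  }
  manifest <- list(package = "poreflux",
                   version = as.character(utils::packageVersion("poreflux")),
                   axis_convention = .axis_convention, seed = seed,
                   n_runs = n_runs, voltage_mV = voltage,
                   run_length_ns = run_ns,
                   spec = spec[setdiff(names(spec), "radial_wall")],
                   boundaries = bounds[setdiff(names(bounds), NULL)],
                   stages = stages)

  if ("events" %in% stages) {
    ev <- do.call(rbind, all_events)
    write.csv(ev, file.path(out_dir, "events.csv"), row.names = FALSE)
    manifest$n_events <- nrow(ev)
  }
  if ("conductance" %in% stages) {
    cc <- cfg$conductance %||% list()
    est <- lapply(spec$species, function(sp) {
      evs <- ev[ev$species == sp, , drop = FALSE]
      segment_conductance(evs, voltage_mV = voltage,
                          segment_ns = cc$segment_ns %||% max(run_ns / 10, 1),
                          n_discard = cc$discard %||% 1,
                          run_length_ns = run_ns)
    })
    names(est) <- spec$species
    per <- do.call(rbind, lapply(spec$species, function(sp)
      cbind(species = sp, est[[sp]]$per_segment)))
    write.csv(per, file.path(out_dir, "conductance_segments.csv"),
              row.names = FALSE)
    manifest$conductance <- lapply(est, function(e)
      list(mean_pS = e$mean_pS, sd_pS = e$sd_pS, n_segments = e$n_segments))
  }
  if ("occupancy" %in% stages) {
    oc <- cfg$occupancy %||% list()
    zr <- c(bounds$z_lower, bounds$z_upper)
    maps <- lapply(spec$species, function(sp)
      occupancy_1d(sims[[1]]$frames, sp, z_range = zr,
                   bin_width = oc$bin_width %||% 0.05,
                   radial_cutoff = bounds$radial_cutoff))
    tab <- do.call(rbind, lapply(seq_along(spec$species), function(i)
      cbind(species = spec$species[i], occupancy_table(maps[[i]]))))
    write.csv(tab, file.path(out_dir, "occupancy_1d.csv"), row.names = FALSE)
    site <- do.call(rbind, lapply(spec$species, function(sp)
      site_occupancy(sims[[1]]$frames, bounds, sp)))
    write.csv(site, file.path(out_dir, "site_occupancy.csv"), row.names = FALSE)
  }
  if ("hydration" %in% stages) {
    hp <- do.call(rbind, lapply(spec$species, function(sp)
      cbind(species = sp, hydration_profile(sims[[1]]$frames, sp))))
    write.csv(hp, file.path(out_dir, "hydration_profile.csv"), row.names = FALSE)
  }
  if ("dwell" %in% stages && nrow(ev)) {
    dw <- lapply(spec$species, function(sp) dwell_times(ev, species = sp))
    names(dw) <- spec$species
    manifest$dwell_ns <- lapply(dw, function(d)
      list(mean = d$mean_ns, sd = d$sd_ns, n = d$n))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
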