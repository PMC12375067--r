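# Voltage and conductance: applied-field voltage (V = E Lz), transmembrane
# voltage from a charge-density profile by double integration of the 1D
# Poisson equation, and event-stream -> conductance conversion with the
# segment scheme (per-run segments, leading equilibration segments
# discarded) and 20-ns instantaneous windows.

#' Transmembrane voltage of a uniform applied field
#'
#' `V = E * Lz`, reported in mV with sign.
#'
#' @param E_V_per_nm applied field along the pore axis (V/nm).
#' @param Lz_nm box height (nm).
#' @return voltage in mV.
#' @export
field_voltage <- function(E_V_per_nm, Lz_nm) {
  if (Lz_nm <= 0) stop("usage error: Lz must be positive")
  E_V_per_nm * Lz_nm * 1000
}

.cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

#' Voltage profile from a charge-density profile (Poisson double integration)
#'
#' Integrates the one-dimensional Poisson equation
#' `d2V/dz2 = -rho(z) / eps0` twice, with `V` and `dV/dz` zero at the lower
#' box face, and reports the transmembrane voltage as the difference between
#' the mean potentials in the two bulk plateau windows.
#'
#' @param z_nm bin centers covering the full box (nm).
#' @param rho_e_nm3 charge density per bin (e/nm^3, per unit cross-sectional
#'   area).
#' @param plateau_lower,plateau_upper z-windows (nm) of the two bulk
#'   plateaus.
#' @return list with `z_nm`, `V_mV` (profile) and `delta_mV`
#'   (upper minus lower plateau).
#' @export
charge_density_voltage <- function(z_nm, rho_e_nm3, plateau_lower,
                                   plateau_upper) {
  if (length(z_nm) != length(rho_e_nm3) || length(z_nm) < 3)
    stop("config error: density profile must cover the box")
  z_m <- z_nm * 1e-9
  rho <- rho_e_nm3 * .e_charge * 1e27          # C/m^3
  E_field <- .cumtrapz(z_m, rho) / .eps0       # V/m, E(z0) = 0
  V <- -.cumtrapz(z_m, E_field)                # V, V(z0) = 0
  lo <- z_nm >= plateau_lower[1] & z_nm <= plateau_lower[2]
  hi <- z_nm >= plateau_upper[1] & z_nm <= plateau_upper[2]
  if (!any(lo) || !any(hi)) stop("config error: empty plateau window")
  list(z_nm = z_nm, V_mV = V * 1000,
       delta_mV = (mean(V[hi]) - mean(V[lo])) * 1000)
}

#' Segment-resolved conductance from a permeation event stream
#'
#' Each run is divided into consecutive segments of `segment_ns`; the
#' leading `n_discard` segments of every run are dropped as equilibration.
#' Events are assigned to segments by their completion time (`t_exit`); the
#' per-segment net count (voltage-favored minus opposed traversals) is
#' converted to conductance `g = n e / (t |V|)` in pS, and the mean and SD
#' are pooled over all retained segments of all runs.  Segments without
#' events count as zero-conductance segments.
#'
#' @param events events from [detect_events()]; an optional `run` column
#'   tags multi-run input (default: one run).
#' @param voltage_mV transmembrane voltage (nonzero); positive voltage
#'   favors outward (+z) cation traversals.
#' @param segment_ns segment length (ns).
#' @param n_discard leading segments discarded per run.
#' @param run_length_ns length of each run (ns); scalar or per-run vector.
#' @param count `"net"` (direction-resolved, default) or `"gross"`.
#' @return a `conductance_estimate`: list with `per_segment` (run, segment,
#'   t0_ns, t1_ns, n_net, n_gross, g_pS), `mean_pS`, `sd_pS`, `n_segments`,
#'   `voltage_mV`.
#' @export
segment_conductance <- function(events, voltage_mV, segment_ns = 100,
                                n_discard = 1, run_length_ns,
                                count = c("net", "gross")) {
  count <- match.arg(count)
  if (voltage_mV == 0) stop("undefined-conductance error: voltage is zero")
  if (segment_ns <= 0 || n_discard < 0) stop("config error: bad segment scheme")
  run <- if ("run" %in% names(events)) events$run else rep(1L, nrow(events))
  runs <- sort(unique(run))
  if (length(runs) == 0) runs <- 1L
  if (length(run_length_ns) == 1) run_length_ns <- rep(run_length_ns, length(runs))
  favored <- if (voltage_mV > 0) "outward" else "inward"
  seg_rows <- list()
  for (ri in seq_along(runs)) {
    n_seg <- floor(run_length_ns[ri] / segment_ns)
    keep <- seq_len(n_seg)
    keep <- keep[keep > n_discard]
    ev <- events[run == runs[ri], , drop = FALSE]
    t_ns <- ev$t_exit_ps / 1000
    seg_of <- floor(t_ns / segment_ns) + 1
    for (s in keep) {
      ii <- which(seg_of == s)
      n_fav <- sum(ev$direction[ii] == favored)
      n_opp <- length(ii) - n_fav
      seg_rows[[length(seg_rows) + 1]] <-
        data.frame(run = runs[ri], segment = s, t0_ns = (s - 1) * segment_ns,
                   t1_ns = s * segment_ns, n_net = n_fav - n_opp,
                   n_gross = length(ii))
    }
  }
  per <- do.call(rbind, seg_rows)
  if (is.null(per)) stop("config error: no retained segments")
  n_used <- if (count == "net") per$n_net else per$n_gross
  per$g_pS <- n_used * .e_charge /
    (segment_ns * 1e-9 * abs(voltage_mV) / 1000) * 1e12
  structure(list(per_segment = per, mean_pS = mean(per$g_pS),
                 sd_pS = if (nrow(per) > 1) sd(per$g_pS) else 0,
                 n_segments = nrow(per), voltage_mV = voltage_mV,
                 count = count),
            class = "conductance_estimate")
}

#' @export
print.conductance_estimate <- function(x, ...) {
  cat(sprintf("conductance: %.2f +/- %.2f pS at %+.0f mV (%d segments, %s counts)\n",
              x$mean_pS, x$sd_pS, x$voltage_mV, x$n_segments, x$count))
  invisible(x)
}

#' Instantaneous conductance over consecutive windows
#'
#' Net permeation counts in consecutive non-overlapping windows of the given
#' width, converted to pS.
#'
#' @param events events from [detect_events()].
#' @param voltage_mV transmembrane voltage (nonzero).
#' @param window_ns window width (ns); the study convention is 20 ns.
#' @param total_ns trajectory length (ns).
#' @return data.frame with `t_mid_ns`, `n_net`, `g_pS`.
#' @export
instantaneous_conductance <- function(events, voltage_mV, window_ns = 20,
                                      total_ns) {
  if (voltage_mV == 0) stop("undefined-conductance error: voltage is zero")
  if (window_ns <= 0) stop("config error: window must be positive")
  n_win <- floor(total_ns / window_ns)
  favored <- if (voltage_mV > 0) "outward" else "inward"
  t_ns <- events$t_exit_ps / 1000
  win_of <- floor(t_ns / window_ns) + 1
  n_net <- vapply(seq_len(n_win), function(w) {
    ii <- which(win_of == w)
    sum(events$direction[ii] == favored) - sum(events$direction[ii] != favored)
  }, integer(1))
  data.frame(t_mid_ns = (seq_len(n_win) - 0.5) * window_ns, n_net = n_net,
             g_pS = n_net * .e_charge /
               (window_ns * 1e-9 * abs(voltage_mV) / 1000) * 1e12)
}

#' Current-voltage relationship from conductance estimates
#'
#' `I(V) = g(V) * V` per voltage condition with the SD propagated; flags
#' (but does not enforce) non-monotone current.
#'
#' @param estimates list of `conductance_estimate` objects at distinct
#'   voltages (>= 2).
#' @return data.frame with `V_mV`, `g_pS`, `sd_pS`, `I_pA`, `sd_I_pA`;
#'   attribute `monotone` flags whether I is non-decreasing in V.
#' @export
iv_curve <- function(estimates) {
  if (length(estimates) < 2) stop("usage error: need >= 2 voltages")
  V <- vapply(estimates, function(e) e$voltage_mV, numeric(1))
  if (anyDuplicated(V)) stop("config error: duplicate voltage keys")
  g <- vapply(estimates, function(e) e$mean_pS, numeric(1))
  s <- vapply(estimates, function(e) e$sd_pS / sqrt(max(e$n_segments, 1)), numeric(1))
  o <- order(V)
  out <- data.frame(V_mV = V[o], g_pS = g[o], sd_pS = s[o],
                    I_pA = g[o] * V[o] / 1000, sd_I_pA = s[o] * abs(V[o]) / 1000)
  attr(out, "monotone") <- !is.unsorted(out$I_pA)
  out
}
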