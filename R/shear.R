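#' Wall shear stress from flow and area
#'
#' For the power-law profile the wall velocity gradient gives a shear
#' magnitude `mu * (gamma + 2) * |Ubar| / R` with `Ubar = Q/A` and
#' `R = sqrt(A/pi)`. The returned stress carries the sign of the local flow
#' so that the oscillatory shear index can detect reversal.
#'
#' @param Q volumetric flow, mL/s (vectorized).
#' @param A lumen area, cm2 (> 0).
#' @param props [fluid_properties()].
#' @return Signed wall shear stress, dyn/cm2.
#' @export
wall_shear_stress <- function(Q, A, props = fluid_properties()) {
  if (any(A <= 0)) stop("area must be positive")
  sign(Q) * props$mu * (props$gamma + 2) * abs(Q / A) / sqrt(A / pi)
}

# trapezoid rule on possibly non-uniform t
trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Time-averaged wall shear stress
#'
#' `TAWSS = (1/T) * integral over one cycle of |tau| dt`, by trapezoidal
#' quadrature on the solver clock.
#'
#' @param tau signed shear series over one cycle, dyn/cm2.
#' @param t sample times, s (same length as `tau`, spanning one cycle).
#' @return TAWSS, dyn/cm2.
#' @export
tawss <- function(tau, t) {
  if (length(tau) == 0L) stop("empty shear series")
  stopifnot(length(tau) == length(t))
  trapz(t, abs(tau)) / (t[length(t)] - t[1])
}

#' Oscillatory shear index
#'
#' `OSI = 0.5 * (1 - |mean(tau)| / mean(|tau|))`, with both means as time
#' integrals over one cycle; 0 for unidirectional shear, 0.5 for zero-mean
#' fully oscillatory shear. An identically zero series is reported as 0 with
#' attribute `undefined = TRUE`.
#'
#' @inheritParams tawss
#' @return OSI in `[0, 0.5]`.
#' @export
osi <- function(tau, t) {
  if (length(tau) == 0L) stop("empty shear series")
  stopifnot(length(tau) == length(t))
  denom <- trapz(t, abs(tau))
  if (denom == 0) {
    return(structure(0, undefined = TRUE))
  }
  val <- 0.5 * (1 - abs(trapz(t, tau)) / denom)
  min(max(val, 0), 0.5)
}

#' Shear field of a solution
#'
#' Evaluates the signed wall shear stress at every grid node and stored time
#' of a [simulate_to_periodic()] solution.
#'
#' @param sol a `solution_field`.
#' @param props [fluid_properties()] used in the simulation.
#' @return Object of class `shear_field`: per-vessel matrices `tau(t, x)`
#'   aligned with the solution grids.
#' @export
shear_field <- function(sol, props = fluid_properties()) {
  vessels <- lapply(sol$vessels, function(v) {
    list(id = v$id, name = v$name, extralobar = v$extralobar,
         length = v$length, x = v$x,
         tau = wall_shear_stress(v$Q, v$A, props))
  })
  structure(list(t = sol$t, vessels = vessels, T = sol$T),
            class = "shear_field")
}

#' Network shear summary and the combined physiomarker phi
#'
#' Computes per-segment TAWSS and OSI (per-node values averaged along the
#' segment axis), reports extralobar vessels singly and the unweighted mean
#' over intralobar segments, and evaluates
#' `phi = 100 * (network length with TAWSS < tau_low and OSI > osi_high) /
#' (total length)`, where each grid node carries its local share of segment
#' length.
#'
#' @param shear a [shear_field()].
#' @param net the `vessel_network` the solution was computed on.
#' @param tau_low low-shear threshold, dyn/cm2 (default 5).
#' @param osi_high high-oscillation threshold (default 0.05).
#' @param intralobar_weighting `"segment"` (unweighted mean over segments,
#'   default) or `"length"` (length-weighted).
#' @return List of class `shear_summary` with `per_segment` (data frame),
#'   `extralobar` (named TAWSS/OSI for MPA/LPA/RPA), `intralobar`
#'   (mean TAWSS/OSI), and `phi` (percent).
#' @export
summarize_network <- function(shear, net, tau_low = 5, osi_high = 0.05,
                              intralobar_weighting = c("segment", "length")) {
  if (tau_low <= 0 || osi_high <= 0) stop("thresholds must be positive")
  intralobar_weighting <- match.arg(intralobar_weighting)
  t <- shear$t
  rows <- list()
  flagged_len <- 0
  total_len <- 0
  for (v in shear$vessels) {
    nt <- length(t)
    nx <- length(v$x)
    node_tawss <- vapply(seq_len(nx), function(j) tawss(v$tau[, j], t), numeric(1))
    node_osi <- vapply(seq_len(nx), function(j) as.numeric(osi(v$tau[, j], t)),
                       numeric(1))
    # node length weights: half-cells at segment ends
    dx <- v$length / (nx - 1)
    w <- rep(dx, nx); w[c(1, nx)] <- dx / 2
    hit <- node_tawss < tau_low & node_osi > osi_high
    flagged_len <- flagged_len + sum(w[hit])
    total_len <- total_len + sum(w)
    rows[[length(rows) + 1L]] <- data.frame(
      id = v$id, name = v$name, extralobar = v$extralobar, length = v$length,
      tawss = mean(node_tawss), osi = mean(node_osi),
      frac_low_tawss_high_osi = sum(w[hit]) / sum(w))
  }
  per_segment <- do.call(rbind, rows)
  ex <- per_segment[per_segment$extralobar, , drop = FALSE]
  extral <- stats::setNames(
    lapply(seq_len(nrow(ex)), function(i) list(tawss = ex$tawss[i], osi = ex$osi[i])),
    ex$name)
  intr <- per_segment[!per_segment$extralobar, , drop = FALSE]
  if (nrow(intr) > 0) {
    wgt <- if (intralobar_weighting == "length") intr$length else rep(1, nrow(intr))
    intralobar <- list(tawss = stats::weighted.mean(intr$tawss, wgt),
                       osi = stats::weighted.mean(intr$osi, wgt))
  } else {
    intralobar <- list(tawss = NA_real_, osi = NA_real_)
  }
  structure(list(per_segment = per_segment, extralobar = extral,
                 intralobar = intralobar,
                 phi = 100 * flagged_len / total_len,
                 thresholds = list(tau_low = tau_low, osi_high = osi_high)),
            class = "shear_summary")
}

#' @export
print.shear_summary <- function(x, ...) {
  cat(sprintf("<shear_summary> %d segments, intralobar TAWSS %.2f dyn/cm2, OSI %.3f, phi %.1f%%\n",
              nrow(x$per_segment), x$intralobar$tawss, x$intralobar$osi, x$phi))
  invisible(x)
}

#' Write shear metrics to disk
#'
#' Emits `metrics.csv` (per-segment table) and `summary.json` (extralobar,
#' intralobar and phi values with thresholds and units).
#'
#' @param summary a `shear_summary`.
#' @param dir output directory.
#' @param seed optional generating seed recorded in the JSON.
#' @return `dir`, invisibly.
#' @export
export_metrics <- function(summary, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- summary$per_segment
  names(df) <- c("id", "name", "extralobar", "length_cm", "tawss_dyn_cm2",
                 "osi", "frac_low_tawss_high_osi")
  utils::write.csv(df, file.path(dir, "metrics.csv"), row.names = FALSE)
  out <- list(units = list(tawss = "dyn/cm2", osi = "dimensionless", phi = "percent"),
              seed = seed, thresholds = summary$thresholds,
              extralobar = summary$extralobar, intralobar = summary$intralobar,
              phi = summary$phi)
  jsonlite::write_json(out, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
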