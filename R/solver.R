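#' Fluid properties
#'
#' Blood density, dynamic viscosity and the power-law velocity-profile
#' exponent. The defaults (1.03 g/mL, 0.03 Poise, gamma = 9) give the
#' nearly flat profile appropriate for the high Womersley numbers of the
#' proximal pulmonary arteries.
#'
#' @param rho density, g/mL.
#' @param mu dynamic viscosity, Poise (dyn*s/cm2).
#' @param gamma power-law exponent (>= 2; gamma = 2 is the parabolic
#'   Poiseuille profile).
#' @return Object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1.03, mu = 0.03, gamma = 9) {
  stopifnot(rho > 0, mu > 0, gamma >= 2)
  structure(list(rho = rho, mu = mu, gamma = gamma),
            class = "fluid_properties")
}

#' Simulation configuration
#'
#' @param dx_target spatial resolution target, cm (each segment gets a
#'   uniform grid with at least 5 nodes and `dx <= dx_target`).
#' @param cfl_number Courant number in (0, 1); the time step is
#'   `cfl_number * min(dx / (|u| + c))`, re-verified every step.
#' @param max_cycles maximum number of cardiac cycles to run.
#' @param periodicity_tol relative tolerance on the end-of-cycle pressure
#'   field between consecutive cycles.
#' @param T cardiac cycle length, s.
#' @param store_points approximate number of time samples retained per cycle
#'   in the returned solution (full resolution is used internally).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(dx_target = 0.1, cfl_number = 0.5, max_cycles = 30,
                       periodicity_tol = 1e-3, T = 0.5, store_points = 400) {
  stopifnot(dx_target > 0, cfl_number > 0, cfl_number < 1,
            max_cycles >= 1, periodicity_tol > 0, T > 0)
  structure(list(dx_target = dx_target, cfl_number = cfl_number,
                 max_cycles = max_cycles, periodicity_tol = periodicity_tol,
                 T = T, store_points = store_points),
            class = "sim_config")
}

#' Inflow waveform
#'
#' Periodic volumetric inflow prescribed at the MPA inlet. Samples are
#' assumed uniformly spaced over one period with the first sample at t = 0;
#' the first and last samples must agree (periodic closure). The solver
#' resamples the waveform to its own clock through a Fourier series
#' (FFT-based band-limited interpolation).
#'
#' @param samples flow samples over one period including both endpoints, mL/s.
#' @param T period, s.
#' @return Object of class `inflow_waveform`.
#' @export
inflow_waveform <- function(samples, T) {
  stopifnot(T > 0, length(samples) >= 8, all(is.finite(samples)))
  if (abs(samples[1] - samples[length(samples)]) >
      1e-8 * (max(abs(samples)) + 1)) {
    stop("inflow waveform must be periodic (first sample == last sample)")
  }
  structure(list(samples = samples, T = T), class = "inflow_waveform")
}

# FFT band-limited resampling of one period (y excludes the repeated
# endpoint) onto n_out uniform points.
resample_periodic <- function(y, n_out) {
  n <- length(y)
  Y <- stats::fft(y)
  half <- floor(n / 2)
  Y2 <- complex(n_out)
  Y2[1] <- Y[1]
  if (half >= 1) {
    k <- seq_len(half - if (n %% 2 == 0) 1L else 0L)
    if (length(k) > 0) {
      Y2[1 + k] <- Y[1 + k]
      Y2[n_out + 1 - k] <- Y[n + 1 - k]
    }
    if (n %% 2 == 0) {  # split the Nyquist bin
      Y2[1 + half] <- Y[1 + half] / 2
      Y2[n_out + 1 - half] <- Y[1 + half] / 2
    }
  }
  Re(stats::fft(Y2, inverse = TRUE)) / n
}

#' Power-law axial velocity profile
#'
#' `u(r) = Ubar * ((gamma + 2)/gamma) * (1 - (r/R)^gamma)`: satisfies the
#' no-slip condition at the wall and integrates to the cross-sectional mean
#' `Ubar`.
#'
#' @param Ubar cross-sectional mean velocity, cm/s.
#' @param r radial coordinate(s), cm, `0 <= r <= R`.
#' @param R lumen radius, cm.
#' @param gamma power-law exponent.
#' @return Axial velocity at `r`, cm/s.
#' @export
velocity_profile <- function(Ubar, r, R, gamma = 9) {
  if (any(r > R) || any(r < 0)) stop("requires 0 <= r <= R")
  Ubar * ((gamma + 2) / gamma) * (1 - (r / R)^gamma)
}

# Build per-segment wall table aligned with net$segments.
#' Wall model table for a network
#'
#' @param net a `vessel_network`.
#' @param stiffness `Eh/r0` in dyn/cm2; scalar (uniform) or one value per
#'   segment in id order. Defaults to the per-segment `stiffness` column.
#' @param Pdia diastolic reference pressure, dyn/cm2.
#' @return Data frame with columns `id`, `stiffness`, `Adia`, `Pdia`.
#' @export
make_walls <- function(net, stiffness = NULL, Pdia = 0) {
  s <- net$segments
  if (is.null(stiffness)) stiffness <- s$stiffness
  if (length(stiffness) == 1L) stiffness <- rep(stiffness, nrow(s))
  stopifnot(length(stiffness) == nrow(s), all(stiffness > 0))
  data.frame(id = s$id, stiffness = stiffness, Adia = pi * s$r0^2,
             Pdia = rep(Pdia, nrow(s)))
}

# Assemble compiled-solver arguments; returns a context list.
solver_context <- function(net, walls, windkessels, inflow, props, config) {
  s <- net$segments
  nv <- nrow(s)
  stopifnot(nrow(walls) == nv, all(walls$id == s$id))
  n_nodes <- pmax(5L, as.integer(ceiling(s$length / config$dx_target)) + 1L)
  dx <- s$length / (n_nodes - 1)
  kid1 <- kid2 <- rep(-1L, nv)
  for (i in seq_len(nv)) {
    ch <- which(!is.na(s$parent) & s$parent == s$id[i])
    if (length(ch) == 2L) { kid1[i] <- ch[1] - 1L; kid2[i] <- ch[2] - 1L }
    else if (length(ch) != 0L) stop("non-bifurcating junction at segment ", s$id[i])
  }
  terms <- terminal_segments(net)
  if (!setequal(names(windkessels), as.character(terms))) {
    stop("windkessels must be a named list covering exactly the terminal ids")
  }
  wk_index <- rep(-1L, nv)
  wk_params <- matrix(0, length(terms), 5)
  for (k in seq_along(terms)) {
    wk <- windkessels[[as.character(terms[k])]]
    wk_params[k, ] <- c(wk$Rp, wk$Rd, wk$C, wk$Pout, wk$Pout)  # Pc0 = Pout
    wk_index[which(s$id == terms[k])] <- k - 1L
  }
  stopifnot(abs(inflow$T - config$T) < 1e-9 * config$T)
  dense <- resample_periodic(inflow$samples[-length(inflow$samples)], 2048L)
  list(n_nodes = n_nodes, dx = dx, f = walls$stiffness, Adia = walls$Adia,
       Pdia = walls$Pdia, child1 = kid1, child2 = kid2,
       root = which(s$id == net$root_id) - 1L, wk_index = wk_index,
       wk_params = wk_params, inflow_dense = dense, terms = terms,
       segments = s, props = props, config = config)
}

run_solver <- function(ctx, max_cycles, ptol, init_state = NULL) {
  raw <- .solve_network_cpp(ctx$n_nodes, ctx$dx, ctx$f, ctx$Adia, ctx$Pdia,
                            ctx$child1, ctx$child2, ctx$root, ctx$wk_index,
                            ctx$wk_params, ctx$inflow_dense,
                            ctx$config$T, ctx$props$rho, ctx$props$mu,
                            ctx$props$gamma, ctx$config$cfl_number,
                            as.integer(max_cycles), ptol,
                            as.integer(ctx$config$store_points), init_state)
  s <- ctx$segments
  vessels <- vector("list", nrow(s))
  for (i in seq_len(nrow(s))) {
    wall <- wall_model(ctx$f[i], ctx$Adia[i], ctx$Pdia[i])
    A <- raw$A[[i]]
    vessels[[i]] <- list(
      id = s$id[i], name = s$name[i], extralobar = s$extralobar[i],
      length = s$length[i],
      x = seq(0, s$length[i], length.out = ctx$n_nodes[i]),
      A = A, Q = raw$Q[[i]], P = tube_law_pressure(A, wall),
      Pmax = raw$Pmax[[i]], Pmin = raw$Pmin[[i]],
      Amax = raw$Amax[[i]], Amin = raw$Amin[[i]])
  }
  names(vessels) <- as.character(s$id)
  structure(list(
    t = raw$t, vessels = vessels, converged = raw$converged,
    cycles = raw$cycles, periodicity_err = raw$periodicity_err,
    dt = raw$dt, max_junction_residual = raw$max_junction_residual,
    inflow_volume = raw$inflow_volume,
    outlet_volumes = stats::setNames(raw$outlet_volumes, ctx$terms),
    Pc = stats::setNames(raw$Pc, ctx$terms),
    T = ctx$config$T, root_id = s$id[ctx$root + 1]),
    class = "solution_field")
}

#' Advance the network one cardiac cycle
#'
#' Runs exactly one cycle of the two-step Lax-Wendroff scheme from the
#' supplied (or cold-start) state. Mostly useful for scheme-level testing;
#' see [simulate_to_periodic()] for production runs.
#'
#' @param net a `vessel_network`.
#' @param walls wall table from [make_walls()].
#' @param windkessels named list of [windkessel3()] per terminal id.
#' @param inflow an [inflow_waveform()].
#' @param props [fluid_properties()].
#' @param config [sim_config()].
#' @param initial_state optional list with `A`, `Q` (per-vessel node vectors)
#'   and `Pc` (per-terminal capacitor pressures); defaults to the diastolic
#'   rest state (`A = Adia`, `Q = 0`, `Pc = Pout`).
#' @return A `solution_field` covering the cycle.
#' @export
lax_wendroff_cycle <- function(net, walls, windkessels, inflow,
                               props = fluid_properties(),
                               config = sim_config(),
                               initial_state = NULL) {
  ctx <- solver_context(net, walls, windkessels, inflow, props, config)
  run_solver(ctx, max_cycles = 1L, ptol = 0, init_state = initial_state)
}

#' Simulate to a periodic steady state
#'
#' Repeats cardiac cycles from the diastolic rest state (`A = Adia`,
#' `Q = 0`, capacitor pressures at `Pout`) until the end-of-cycle pressure
#' field changes by less than `config$periodicity_tol` (relative) between
#' consecutive cycles, or `config$max_cycles` is reached (in which case a
#' warning is recorded in the returned object and the final cycle is still
#' returned).
#'
#' @inheritParams lax_wendroff_cycle
#' @param initial_state optional starting state (see [lax_wendroff_cycle()]
#'   and [solution_end_state()]); the periodicity criterion defines the
#'   returned cycle either way, but a warm state near the attractor saves
#'   transient cycles (used heavily during calibration).
#' @return A `solution_field` for the final cycle, with convergence
#'   diagnostics (`converged`, `cycles`, `periodicity_err`,
#'   `max_junction_residual`, per-cycle volume audit).
#' @export
simulate_to_periodic <- function(net, walls, windkessels, inflow,
                                 props = fluid_properties(),
                                 config = sim_config(),
                                 initial_state = NULL) {
  ctx <- solver_context(net, walls, windkessels, inflow, props, config)
  sol <- run_solver(ctx, max_cycles = ctx$config$max_cycles,
                    ptol = ctx$config$periodicity_tol,
                    init_state = initial_state)
  if (!sol$converged) {
    warning(sprintf("periodicity not reached in %d cycles (err %.2e)",
                    sol$cycles, sol$periodicity_err))
  }
  sol
}

#' @export
print.solution_field <- function(x, ...) {
  cat(sprintf(paste0("<solution_field> %d vessels, %d time samples, ",
                     "%d cycles (%s), periodicity err %.2e\n"),
              length(x$vessels), length(x$t), x$cycles,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$periodicity_err))
  invisible(x)
}

#' End-of-cycle state of a solution
#'
#' Packs the final stored state (per-vessel `A`, `Q` node vectors and the
#' terminal capacitor pressures) into the `initial_state` format accepted by
#' the solvers, for warm-starting subsequent runs.
#'
#' @param sol a `solution_field`.
#' @return List with `A`, `Q` (per-vessel lists in id order) and `Pc`.
#' @export
solution_end_state <- function(sol) {
  nt <- length(sol$t)
  list(A = lapply(unname(sol$vessels), function(v) v$A[nt, ]),
       Q = lapply(unname(sol$vessels), function(v) v$Q[nt, ]),
       Pc = unname(sol$Pc))
}

#' Extract a time series from a solution field
#'
#' @param sol a `solution_field`.
#' @param id segment id (or name).
#' @param quantity one of `"Q"`, `"P"`, `"A"`.
#' @param station `"inlet"`, `"mid"` or `"outlet"` (node position).
#' @return Numeric vector over `sol$t`.
#' @export
solution_series <- function(sol, id, quantity = c("Q", "P", "A"),
                            station = c("mid", "inlet", "outlet")) {
  quantity <- match.arg(quantity)
  station <- match.arg(station)
  ves <- sol$vessels[[as.character(id)]]
  if (is.null(ves)) {  # try by name
    hit <- which(vapply(sol$vessels, function(v) identical(v$name, id), logical(1)))
    if (length(hit) != 1L) stop("unknown vessel: ", id)
    ves <- sol$vessels[[hit]]
  }
  n <- ncol(ves[[quantity]])
  j <- switch(station, inlet = 1L, outlet = n, mid = as.integer(ceiling(n / 2)))
  ves[[quantity]][, j]
}

# Interpolate a stored periodic series onto arbitrary cycle times.
interp_cycle <- function(t_stored, y, t_new, T) {
  tt <- t_new %% T
  stats::approx(t_stored, y, xout = tt, rule = 2)$y
}

#' Export a solution field to per-segment CSV
#'
#' Writes one CSV per segment (`segment_<id>.csv`) with columns
#' `x_cm, t_s, P_mmHg, Q_mL_s, A_cm2`, plus a `solution_meta.json` recording
#' units and diagnostics.
#'
#' @param sol a `solution_field`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_solution <- function(sol, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ves in sol$vessels) {
    grid <- expand.grid(t_s = sol$t, x_cm = ves$x)
    df <- data.frame(x_cm = grid$x_cm, t_s = grid$t_s,
                     P_mmHg = cgs_to_mmhg(as.vector(ves$P)),
                     Q_mL_s = as.vector(ves$Q),
                     A_cm2 = as.vector(ves$A))
    utils::write.csv(df, file.path(dir, sprintf("segment_%d.csv", ves$id)),
                     row.names = FALSE)
  }
  meta <- list(units = list(x = "cm", t = "s", P = "mmHg", Q = "mL/s", A = "cm2"),
               converged = sol$converged, cycles = sol$cycles,
               periodicity_err = sol$periodicity_err, dt = sol$dt,
               max_junction_residual = sol$max_junction_residual)
  jsonlite::write_json(meta, file.path(dir, "solution_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
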