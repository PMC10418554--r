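#' Calibration data container
#'
#' Scalar MPA pressure/area targets plus LPA/RPA flow time series sampled on
#' a common grid over one cardiac cycle. Flow series can be flagged as
#' recomputed (e.g. the left-lung flow reconstructed as `Q_MPA - Q_RPA` when
#' imaging signal is lost).
#'
#' @param Psys,Pdia systolic/diastolic MPA pressure, mmHg (`Psys > Pdia`).
#' @param Asys,Adia systolic/diastolic MPA area, cm2 (`Asys >= Adia`).
#' @param t sample times over one cycle, s (N >= 16).
#' @param Q_LPA,Q_RPA flow series on `t`, mL/s.
#' @param Q_MPA optional MPA (inlet) flow series on `t`, mL/s.
#' @param recomputed logical flags, e.g. `c(LPA = TRUE, RPA = FALSE)`.
#' @return Object of class `calibration_data`.
#' @export
calibration_data <- function(Psys, Pdia, Asys, Adia, t, Q_LPA, Q_RPA,
                             Q_MPA = NULL,
                             recomputed = c(LPA = FALSE, RPA = FALSE)) {
  if (Psys <= Pdia) stop("requires Psys > Pdia")
  if (Asys < Adia) stop("requires Asys >= Adia")
  if (length(t) < 16L) stop("need at least 16 time samples")
  stopifnot(length(Q_LPA) == length(t), length(Q_RPA) == length(t))
  structure(list(Psys = Psys, Pdia = Pdia, Asys = Asys, Adia = Adia,
                 t = t, Q_LPA = Q_LPA, Q_RPA = Q_RPA, Q_MPA = Q_MPA,
                 recomputed = recomputed),
            class = "calibration_data")
}

#' Recompute the left-lung flow from MPA and RPA series
#'
#' Pointwise `Q_LPA = Q_MPA - Q_RPA`, used when the left-lung imaging signal
#' is unreliable (severe obstruction). Series must share their time grid; no
#' silent resampling is performed.
#'
#' @param Q_MPA,Q_RPA flow series on a common grid, mL/s.
#' @return The reconstructed left flow series (attribute `recomputed = TRUE`).
#' @export
recompute_left_flow <- function(Q_MPA, Q_RPA) {
  if (length(Q_MPA) != length(Q_RPA)) {
    stop("flow series have mismatched grids (lengths ",
         length(Q_MPA), " vs ", length(Q_RPA), ")")
  }
  structure(Q_MPA - Q_RPA, recomputed = TRUE)
}

#' Scale Windkessel parameters by global factors
#'
#' Applies `theta = (rp, rd, c)` uniformly: every terminal's `Rp` is
#' multiplied by `rp`, `Rd` by `rd`, `C` by `c`.
#'
#' @param windkessels named list of [windkessel3()].
#' @param theta numeric length-3 vector `(rp, rd, c)`, all > 0.
#' @return Scaled named list.
#' @export
scale_windkessels <- function(windkessels, theta) {
  stopifnot(length(theta) == 3, all(theta > 0))
  lapply(windkessels, function(w)
    windkessel3(w$Rp * theta[1], w$Rd * theta[2], w$C * theta[3], w$Pout))
}

#' Model context for calibration
#'
#' Bundles everything needed to forward-simulate the network under scaled
#' Windkessel parameters and extract the model counterparts of the
#' calibration data: MPA pressure/area extrema at the inlet node and
#' LPA/RPA flow at mid-vessel.
#'
#' @param net a `vessel_network`.
#' @param walls wall table ([make_walls()]).
#' @param windkessels nominal Windkessel set ([nominal_windkessels()]).
#' @param inflow an [inflow_waveform()].
#' @param props [fluid_properties()].
#' @param config [sim_config()].
#' @param lpa_id,rpa_id segment ids (or names, default `"LPA"`/`"RPA"`) whose
#'   mid-vessel flow is compared to the data series.
#' @return Object of class `model_context`.
#' @export
model_context <- function(net, walls, windkessels, inflow,
                          props = fluid_properties(), config = sim_config(),
                          lpa_id = "LPA", rpa_id = "RPA") {
  find_id <- function(key) {
    s <- net$segments
    if (key %in% s$name) return(s$id[s$name == key][1])
    if (key %in% s$id) return(as.integer(key))
    stop("unknown segment: ", key)
  }
  structure(list(net = net, walls = walls, windkessels = windkessels,
                 inflow = inflow, props = props, config = config,
                 lpa_id = find_id(lpa_id), rpa_id = find_id(rpa_id)),
            class = "model_context")
}

# Forward simulation under theta; returns model observables or NULL on failure.
# `init_state` is an optional fixed (theta-independent) warm-start state; the
# periodicity stopping rule makes the returned cycle init-independent up to
# the periodicity tolerance.
model_observables <- function(theta, ctx, data_t, relax = 10,
                              init_state = NULL) {
  cfg <- ctx$config
  cfg$periodicity_tol <- cfg$periodicity_tol * relax
  if (relax > 1) {  # optimization path: trim output copying
    cfg$store_points <- max(150L, 2L * length(data_t))
  }
  sol <- tryCatch(
    suppressWarnings(simulate_to_periodic(ctx$net, ctx$walls,
                                          scale_windkessels(ctx$windkessels, theta),
                                          ctx$inflow, ctx$props, cfg,
                                          initial_state = init_state)),
    error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  root <- sol$vessels[[as.character(sol$root_id)]]
  qs <- function(id) {
    y <- solution_series(sol, id, "Q", "mid")
    interp_cycle(sol$t, y, data_t, sol$T)
  }
  list(Psys = cgs_to_mmhg(root$Pmax[1]), Pdia = cgs_to_mmhg(root$Pmin[1]),
       Asys = root$Amax[1], Adia = root$Amin[1],
       Q_LPA = qs(ctx$lpa_id), Q_RPA = qs(ctx$rpa_id), sol = sol)
}

# Residual vector whose sum of squares is the three-block cost:
# pressure block (mmHg), area block (cm2), flow block weighted 1/N ((mL/s)^2).
calibration_residuals <- function(theta, data, ctx,
                                  weighting = c("absolute", "relative"),
                                  relax = 10, init_state = NULL) {
  weighting <- match.arg(weighting)
  obs <- model_observables(theta, ctx, data$t, relax, init_state)
  if (is.null(obs)) return(NULL)
  N <- length(data$t)
  r <- c(obs$Psys - data$Psys, obs$Pdia - data$Pdia,
         obs$Asys - data$Asys, obs$Adia - data$Adia,
         (obs$Q_LPA - data$Q_LPA) / sqrt(N),
         (obs$Q_RPA - data$Q_RPA) / sqrt(N))
  if (weighting == "relative") {
    sc <- c(data$Psys, data$Psys, data$Adia, data$Adia,
            rep(max(abs(data$Q_LPA)), N), rep(max(abs(data$Q_RPA)), N))
    r <- r / sc
  }
  structure(r, obs = obs)
}

#' Calibration cost (multi-target sum of squares)
#'
#' The three-block objective
#' `S(theta) = sum_j (P_j^c - P_j)^2 + sum_j (A_j^c - A_j)^2 +
#'  (1/N) sum_k sum_i (Q_k^c(t_i) - Q_k(t_i))^2`
#' with `j in {sys, dia}` for MPA pressure (mmHg) and area (cm2) and
#' `k in {LPA, RPA}` flow series (mL/s). The default evaluates the blocks
#' literally in those units; `weighting = "relative"` normalizes each block
#' by its data scale. A failed simulation returns a large finite sentinel so
#' optimizers can continue.
#'
#' @param theta scaling factors `(rp, rd, c)`.
#' @param data a [calibration_data()].
#' @param ctx a [model_context()].
#' @param weighting `"absolute"` (literal units, default) or `"relative"`.
#' @param relax factor by which the periodicity tolerance is relaxed during
#'   optimization (default 10; use 1 for final evaluation).
#' @return Nonnegative scalar cost.
#' @export
calibration_cost <- function(theta, data, ctx,
                             weighting = c("absolute", "relative"),
                             relax = 10) {
  r <- calibration_residuals(theta, data, ctx, weighting, relax)
  if (is.null(r)) return(1e12)
  sum(r^2)
}

# Box-constrained Levenberg-Marquardt on a residual function.
lm_box <- function(resid_fn, theta0, lower, upper, max_iter = 25,
                   ftol = 1e-6, min_cost = 1e-12) {
  theta <- pmin(pmax(theta0, lower), upper)
  r <- resid_fn(theta)
  n_eval <- 1L
  if (is.null(r)) {
    return(list(theta = theta, cost = 1e12, n_eval = n_eval, converged = FALSE))
  }
  cost <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    if (cost < min_cost) { converged <- TRUE; break }
    J <- matrix(0, length(r), length(theta))
    h <- 1e-4 * pmax(abs(theta), 0.1)
    ok <- TRUE
    for (k in seq_along(theta)) {
      thk <- theta
      thk[k] <- if (theta[k] + h[k] <= upper[k]) theta[k] + h[k] else theta[k] - h[k]
      rk <- resid_fn(thk); n_eval <- n_eval + 1L
      if (is.null(rk)) { ok <- FALSE; break }
      J[, k] <- (rk - r) / (thk[k] - theta[k])
    }
    if (!ok) break
    g <- crossprod(J, r)
    H <- crossprod(J)
    improved <- FALSE
    for (tries in 1:8) {
      step <- tryCatch(
        solve(H + lambda * diag(diag(H) + 1e-12, length(theta)), -g),
        error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      cand <- pmin(pmax(theta + as.vector(step), lower), upper)
      rc <- resid_fn(cand); n_eval <- n_eval + 1L
      cc <- if (is.null(rc)) Inf else sum(rc^2)
      if (is.finite(cc) && cc < cost) {
        rel <- (cost - cc) / max(cost, 1e-300)
        theta <- cand; r <- rc; cost <- cc
        lambda <- max(lambda / 10, 1e-12)
        improved <- TRUE
        if (rel < ftol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) { converged <- TRUE; break }  # local minimum within box
    if (converged) break
  }
  list(theta = theta, cost = cost, n_eval = n_eval, converged = converged)
}

#' Multi-start Windkessel calibration
#'
#' Infers the global scaling factors `theta = (rp, rd, c)` by
#' box-constrained nonlinear least squares (Levenberg-Marquardt with
#' forward-difference Jacobians) from `n_starts` log-uniform random starting
#' points in `start_range^3`, seeded for reproducibility. The lowest-cost
#' converged point is re-simulated at the full periodicity tolerance and
#' reported together with per-start trajectories and flow-series R^2 values.
#'
#' @inheritParams calibration_cost
#' @param n_starts number of randomized starts (default 10).
#' @param seed RNG seed for the start draws.
#' @param bounds optimizer box, default `c(0.1, 10)` per component.
#' @param start_range range of the log-uniform start distribution,
#'   default `c(0.25, 4)`.
#' @param max_iter Levenberg-Marquardt iteration cap per start.
#' @param ftol relative cost-improvement threshold declaring a start
#'   converged.
#' @param min_cost absolute cost below which a start stops immediately
#'   (useful for noise-free data, where the attainable floor is set by the
#'   solver's periodicity tolerance).
#' @param warm_start if `TRUE` (default), optimizer evaluations start from
#'   the end state of one nominal-parameter reference simulation instead of
#'   the diastolic rest state. The reference state is fixed and
#'   theta-independent, so the cost landscape and reproducibility are
#'   unaffected; transient cycles are saved on every evaluation. The
#'   reported optimum is always re-simulated from the cold start at full
#'   tolerance.
#' @return Object of class `calibration_result`: `theta` (best estimate),
#'   `cost`, `starts` (per-start data frame), `r2` (LPA/RPA), `scalars`
#'   (model-vs-data table), `solution` (full-tolerance solution at the
#'   optimum).
#' @export
calibrate_windkessels <- function(data, ctx, n_starts = 10, seed = 1,
                                  weighting = c("absolute", "relative"),
                                  bounds = c(0.1, 10), start_range = c(0.25, 4),
                                  max_iter = 25, ftol = 1e-6,
                                  min_cost = 1e-12, warm_start = TRUE) {
  weighting <- match.arg(weighting)
  set.seed(seed)
  starts <- matrix(exp(stats::runif(3 * n_starts, log(start_range[1]),
                                    log(start_range[2]))),
                   ncol = 3, byrow = TRUE)
  colnames(starts) <- c("rp", "rd", "c")
  warm <- NULL
  if (warm_start) {
    ref <- model_observables(c(1, 1, 1), ctx, data$t)
    if (!is.null(ref)) warm <- solution_end_state(ref$sol)
  }
  resid_fn <- function(th) calibration_residuals(th, data, ctx, weighting,
                                                 init_state = warm)
  fits <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    fits[[i]] <- lm_box(resid_fn, starts[i, ], rep(bounds[1], 3),
                        rep(bounds[2], 3), max_iter = max_iter,
                        ftol = ftol, min_cost = min_cost)
  }
  costs <- vapply(fits, `[[`, numeric(1), "cost")
  if (all(costs >= 1e12)) {
    stop("all calibration starts failed; per-start costs: ",
         paste(signif(costs, 3), collapse = ", "))
  }
  best <- fits[[which.min(costs)]]
  # final evaluation at full periodicity tolerance
  rbest <- calibration_residuals(best$theta, data, ctx, weighting, relax = 1)
  obs <- attr(rbest, "obs")
  start_tab <- data.frame(
    start_rp = starts[, 1], start_rd = starts[, 2], start_c = starts[, 3],
    rp = vapply(fits, function(f) f$theta[1], numeric(1)),
    rd = vapply(fits, function(f) f$theta[2], numeric(1)),
    c = vapply(fits, function(f) f$theta[3], numeric(1)),
    cost = costs,
    n_eval = vapply(fits, `[[`, integer(1), "n_eval"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  scalars <- data.frame(
    quantity = c("Psys_mmHg", "Pdia_mmHg", "Asys_cm2", "Adia_cm2"),
    data = c(data$Psys, data$Pdia, data$Asys, data$Adia),
    model = c(obs$Psys, obs$Pdia, obs$Asys, obs$Adia))
  structure(list(
    theta = stats::setNames(as.numeric(best$theta), c("rp", "rd", "c")),
    cost = sum(rbest^2),
    starts = start_tab,
    r2 = list(LPA = r_squared(obs$Q_LPA, data$Q_LPA),
              RPA = r_squared(obs$Q_RPA, data$Q_RPA)),
    scalars = scalars,
    solution = obs$sol,
    weighting = weighting, seed = seed),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> theta = (%.4f, %.4f, %.4f), cost %.4g, R2 LPA %.3f / RPA %.3f\n",
              x$theta[1], x$theta[2], x$theta[3], x$cost,
              as.numeric(x$r2$LPA), as.numeric(x$r2$RPA)))
  invisible(x)
}

#' Coefficient of determination for a fitted series
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` about the data mean. A constant
#' data series makes `R^2` undefined; `NA` is returned with attribute
#' `undefined = TRUE`.
#'
#' @param model,data equal-length numeric series.
#' @return Scalar R^2 (possibly negative for fits worse than the mean).
#' @export
r_squared <- function(model, data) {
  stopifnot(length(model) == length(data))
  ss_tot <- sum((data - mean(data))^2)
  if (ss_tot == 0) return(structure(NA_real_, undefined = TRUE))
  1 - sum((data - model)^2) / ss_tot
}
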