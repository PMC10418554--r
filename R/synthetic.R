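#' Generate a structured bifurcating pulmonary tree
#'
#' Builds an MPA root with LPA/RPA children (flagged extralobar) followed by
#' self-similar bifurcations: daughter radii are
#' `r_parent * radius_ratio * (1 +/- asymmetry)` (left daughter the larger)
#' and segment lengths are `length_radius_ratio * r`. With
#' `radius_ratio ~ 0.79` the area growth approximates Murray's law
#' (`2 * 0.79^3 ~ 0.99`).
#'
#' @param generations number of bifurcation generations below the root
#'   (>= 1; `generations = g` gives `2^(g+1) - 1` segments and `2^g`
#'   terminals).
#' @param r_root MPA reference radius, cm.
#' @param radius_ratio daughter/parent radius ratio in (0, 1).
#' @param length_radius_ratio segment length as a multiple of its radius.
#' @param asymmetry relative left/right radius asymmetry in [0, 1).
#' @param seed accepted for interface uniformity; the construction is
#'   deterministic.
#' @return A `vessel_network`.
#' @export
generate_tree <- function(generations = 3, r_root = sqrt(1.75 / pi),
                          radius_ratio = 0.79, length_radius_ratio = 5,
                          asymmetry = 0, seed = NULL) {
  stopifnot(generations >= 1, radius_ratio > 0, radius_ratio < 1,
            asymmetry >= 0, asymmetry < 1, r_root > 0, length_radius_ratio > 0)
  rows <- list()
  add <- function(id, name, parent, r, extral) {
    rows[[id]] <<- data.frame(id = id, name = name, parent = parent,
                              length = length_radius_ratio * r, r0 = r,
                              extralobar = extral, stringsAsFactors = FALSE)
  }
  add(1L, "MPA", NA_integer_, r_root, TRUE)
  frontier <- data.frame(id = 1L, r = r_root, gen = 0L, side = "M",
                         stringsAsFactors = FALSE)
  next_id <- 2L
  while (nrow(frontier) > 0 && frontier$gen[1] < generations) {
    newf <- list()
    for (i in seq_len(nrow(frontier))) {
      p <- frontier[i, ]
      rl <- p$r * radius_ratio * (1 + asymmetry)
      rr <- p$r * radius_ratio * (1 - asymmetry)
      if (min(rl, rr) < 0.01) {
        stop("generated radius below 0.01 cm; use fewer generations or a larger root")
      }
      gen <- p$gen + 1L
      for (side in c("L", "R")) {
        r <- if (side == "L") rl else rr
        nm <- if (gen == 1L) paste0(side, "PA")
              else paste0(if (p$side == "M") side else p$side,
                          next_id)  # lobe prefix + unique id
        add(next_id, nm, p$id, r, gen == 1L)
        newf[[length(newf) + 1L]] <- data.frame(
          id = next_id, r = r, gen = gen,
          side = if (gen == 1L) side else p$side, stringsAsFactors = FALSE)
        next_id <- next_id + 1L
      }
    }
    frontier <- do.call(rbind, newf)
  }
  vessel_network(do.call(rbind, rows))
}

#' Ids of all descendants of a segment
#'
#' @param net a `vessel_network`.
#' @param id ancestor segment id (or name).
#' @return Integer vector of descendant ids (excluding `id` itself).
#' @export
descendants <- function(net, id) {
  s <- net$segments
  if (is.character(id)) id <- s$id[s$name == id][1]
  out <- integer(0)
  frontier <- id
  repeat {
    kids <- s$id[!is.na(s$parent) & s$parent %in% frontier]
    if (length(kids) == 0L) break
    out <- c(out, kids)
    frontier <- kids
  }
  sort(out)
}

#' Generate a pulsatile inflow waveform
#'
#' Half-sine ejection over `systole_fraction * T`, zero flow in diastole,
#' scaled so the cycle integral equals the stroke volume; the peak flow is
#' `(pi/2) * SV / (systole_fraction * T)`.
#'
#' @param T cycle length, s.
#' @param stroke_volume mL per beat (> 0).
#' @param systole_fraction fraction of the cycle spent in ejection, in (0,1).
#' @param n number of samples over the closed period (default 129).
#' @param seed accepted for interface uniformity; deterministic.
#' @return An [inflow_waveform()].
#' @export
generate_inflow <- function(T = 0.5, stroke_volume = 15,
                            systole_fraction = 0.4, n = 129L, seed = NULL) {
  stopifnot(T > 0, systole_fraction > 0, systole_fraction < 1)
  if (stroke_volume <= 0) stop("stroke volume must be positive")
  ts <- systole_fraction * T
  qpk <- pi * stroke_volume / (2 * ts)
  t <- seq(0, T, length.out = n)
  q <- ifelse(t < ts, qpk * sin(pi * t / ts), 0)
  q[n] <- q[1]
  inflow_waveform(q, T)
}

default_subject_config <- function() {
  list(
    generations = 3L,          # 15 segments, 8 terminals
    r_root = sqrt(1.75 / pi),  # cm; canine MPA diastolic area 1.75 cm2
    radius_ratio = 0.79, length_radius_ratio = 5, asymmetry = 0,
    T = 0.5,                   # s (HR 120/min, canine under anesthesia)
    stroke_volume = 15,        # mL -> mean MPA flow 30 mL/s
    systole_fraction = 0.4,
    Psys = 30, Pdia = 15,      # mmHg targets -> mPAP 20 mmHg
    Ppcw = 5,                  # mmHg
    stiffness = 1.5e5,         # dyn/cm2 (~112.5 mmHg), PWV ~ 3 m/s
    noise_sd = 0.02,           # multiplicative flow noise
    N = 64L,                   # measurement samples per cycle
    true_theta = c(rp = 1, rd = 1, c = 1),
    dx_target = 0.1, cfl_number = 0.5, max_cycles = 30,
    periodicity_tol = 1e-3)
}

subject_sim_config <- function(cfg) {
  sim_config(dx_target = cfg$dx_target, cfl_number = cfg$cfl_number,
             max_cycles = cfg$max_cycles,
             periodicity_tol = cfg$periodicity_tol, T = cfg$T)
}

# Sample mid-vessel flow series on the measurement grid with optional
# multiplicative Gaussian noise (RNG state is consumed in a fixed order).
measure_flows <- function(sol, ids, t_meas, noise_sd) {
  out <- lapply(ids, function(id) {
    y <- interp_cycle(sol$t, solution_series(sol, id, "Q", "mid"), t_meas, sol$T)
    if (noise_sd > 0) y <- y * (1 + noise_sd * stats::rnorm(length(y)))
    y
  })
  names(out) <- names(ids)
  out
}

extract_measurements <- function(subject, sol, noise_sd, recompute_left = FALSE) {
  cfg <- subject$config
  t_meas <- (seq_len(cfg$N) - 1) / cfg$N * cfg$T
  root <- sol$vessels[[as.character(sol$root_id)]]
  s <- subject$network$segments
  ids <- c(LPA = s$id[s$name == "LPA"], RPA = s$id[s$name == "RPA"])
  fl <- measure_flows(sol, ids, t_meas, noise_sd)
  q_mpa <- interp_cycle(seq(0, cfg$T, length.out = length(subject$inflow$samples)),
                        subject$inflow$samples, t_meas, cfg$T)
  if (noise_sd > 0) q_mpa <- q_mpa * (1 + noise_sd * stats::rnorm(length(q_mpa)))
  if (recompute_left) {
    q_lpa <- recompute_left_flow(q_mpa, fl$RPA)
    rec <- c(LPA = TRUE, RPA = FALSE)
  } else {
    q_lpa <- fl$LPA
    rec <- c(LPA = FALSE, RPA = FALSE)
  }
  calibration_data(Psys = cgs_to_mmhg(root$Pmax[1]),
                   Pdia = cgs_to_mmhg(root$Pmin[1]),
                   Asys = root$Amax[1], Adia = root$Amin[1],
                   t = t_meas, Q_LPA = as.numeric(q_lpa), Q_RPA = fl$RPA,
                   Q_MPA = q_mpa, recomputed = rec)
}

#' Generate a baseline synthetic subject
#'
#' Builds a structured tree, assigns a uniform wall stiffness, constructs
#' nominal Windkessels from the target mean pressures and flow (resistance
#' from the pressure gradient, compliance from the closed-form diastolic
#' decay), perturbs them by `true_theta` to form the ground truth,
#' forward-simulates to periodicity, and extracts noisy pseudo-measurements
#' `{Psys, Pdia, Asys, Adia, Q_LPA(t), Q_RPA(t)}`.
#'
#' The defaults describe a ~12 kg canine under anesthesia: cycle length
#' 0.5 s, stroke volume 15 mL (mean flow 30 mL/s), target MPA pressures
#' 30/15 mmHg (mPAP 20), wedge pressure 5 mmHg, MPA diastolic area 1.75 cm2
#' and uniform `Eh/r0 = 1.5e5 dyn/cm2` (~112.5 mmHg).
#'
#' @param config named list overriding entries of the default generator
#'   configuration (see Details in the methods vignette).
#' @param seed integer seed controlling the start-point and noise draws;
#'   identical `(config, seed)` give identical subjects.
#' @return Object of class `synthetic_subject`.
#' @export
make_baseline_subject <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(default_subject_config(), config)
  set.seed(seed)
  net <- generate_tree(cfg$generations, cfg$r_root, cfg$radius_ratio,
                       cfg$length_radius_ratio, cfg$asymmetry)
  inflow <- generate_inflow(cfg$T, cfg$stroke_volume, cfg$systole_fraction)
  walls <- make_walls(net, stiffness = cfg$stiffness,
                      Pdia = mmhg_to_cgs(cfg$Pdia))
  qbar <- cfg$stroke_volume / cfg$T
  pvr <- total_pvr(mean_pa_pressure(cfg$Psys, cfg$Pdia), cfg$Ppcw, qbar)
  Td <- (1 - cfg$systole_fraction) * cfg$T
  ctot <- total_compliance_from_decay(cfg$Psys, cfg$Pdia, cfg$Ppcw, Td, pvr)
  wk_nom <- nominal_windkessels(net, resistance_mmhg_to_cgs(pvr),
                                compliance_mmhg_to_cgs(ctot),
                                mu = fluid_properties()$mu,
                                Pout = mmhg_to_cgs(cfg$Ppcw))
  wk_true <- scale_windkessels(wk_nom, cfg$true_theta)
  subject <- structure(list(
    network = net, walls = walls, windkessels_nominal = wk_nom,
    windkessels_true = wk_true, inflow = inflow,
    props = fluid_properties(), sim = subject_sim_config(cfg),
    scenario = "baseline", true_theta = cfg$true_theta,
    config = cfg, seed = seed, baseline_seed = seed),
    class = "synthetic_subject")
  sol <- simulate_to_periodic(net, walls, wk_true, inflow,
                              subject$props, subject$sim)
  subject$solution <- sol
  subject$measurements <- extract_measurements(subject, sol, cfg$noise_sd)
  subject
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> scenario %s, %d segments, seed %d, theta* = (%.3g, %.3g, %.3g)\n",
              x$scenario, nrow(x$network$segments), x$seed,
              x$true_theta[1], x$true_theta[2], x$true_theta[3]))
  invisible(x)
}

#' Impose a CTEPH state on a baseline subject
#'
#' Emulates chronic thromboembolic obstruction with left-lung dominance:
#' left-lung terminal resistances (`Rp`, `Rd`) are multiplied by `severity`
#' and right-lung terminals by `1 + (1 - left_fraction) * (severity - 1)`;
#' compliances are divided by the same per-outlet factor (stiffer distal
#' beds are less compliant); all wall stiffnesses are multiplied by
#' `stiffening`. The subject is re-simulated and pseudo-measurements are
#' regenerated with the left-lung flow series reconstructed as
#' `Q_MPA - Q_RPA` (flagged recomputed), exercising the same signal-loss
#' workaround the measurement pipeline needs on severely obstructed lungs.
#'
#' @param subject a baseline `synthetic_subject`.
#' @param severity resistance multiplier for the obstructed (left) lung
#'   (>= 1).
#' @param left_fraction fraction of the added obstruction borne by the left
#'   lung, in [0, 1].
#' @param stiffening multiplier on all wall stiffnesses (>= 1).
#' @param seed seed for the re-drawn measurement noise.
#' @return A CTEPH-state `synthetic_subject` (field `baseline_seed` links it
#'   to its ancestor).
#' @export
apply_cteph <- function(subject, severity = 5, left_fraction = 0.8,
                        stiffening = 2, seed = subject$seed + 1000L) {
  if (!inherits(subject, "synthetic_subject") || subject$scenario != "baseline") {
    stop("apply_cteph expects a baseline synthetic_subject")
  }
  if (severity < 1) stop("severity must be >= 1")
  stopifnot(left_fraction >= 0, left_fraction <= 1, stiffening >= 1)
  net <- subject$network
  s <- net$segments
  left <- descendants(net, "LPA")
  right <- descendants(net, "RPA")
  terms <- terminal_segments(net)
  f_left <- severity
  f_right <- 1 + (1 - left_fraction) * (severity - 1)
  wk <- subject$windkessels_true
  for (id in terms) {
    fct <- if (id %in% left) f_left else if (id %in% right) f_right else 1
    w <- wk[[as.character(id)]]
    wk[[as.character(id)]] <- windkessel3(w$Rp * fct, w$Rd * fct,
                                          w$C / fct, w$Pout)
  }
  walls <- subject$walls
  walls$stiffness <- walls$stiffness * stiffening
  out <- subject
  out$windkessels_true <- wk
  out$walls <- walls
  out$scenario <- "cteph"
  out$seed <- seed
  out$cteph <- list(severity = severity, left_fraction = left_fraction,
                    stiffening = stiffening)
  set.seed(seed)
  sol <- simulate_to_periodic(net, walls, wk, subject$inflow,
                              subject$props, subject$sim)
  out$solution <- sol
  out$measurements <- extract_measurements(out, sol, subject$config$noise_sd,
                                           recompute_left = TRUE)
  out
}

#' Write a synthetic subject to disk
#'
#' Emits `network.json`, `parameters.json` (ground-truth Windkessels and
#' wall stiffnesses), `inflow.csv` and `calibration_data.json` in the
#' package text formats.
#'
#' @param subject a `synthetic_subject`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_subject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_network(subject$network, file.path(dir, "network.json"))
  wk <- subject$windkessels_true
  params <- list(
    units = list(R = "dyn*s/cm5", C = "cm5/dyn", P = "dyn/cm2",
                 stiffness = "dyn/cm2"),
    seed = subject$seed, scenario = subject$scenario,
    true_theta = as.list(subject$true_theta),
    windkessels = lapply(wk, function(w) w[c("Rp", "Rd", "C", "Pout")]),
    stiffness = stats::setNames(as.list(subject$walls$stiffness),
                                subject$walls$id))
  jsonlite::write_json(params, file.path(dir, "parameters.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  infl <- subject$inflow
  utils::write.csv(
    data.frame(t_s = seq(0, infl$T, length.out = length(infl$samples)),
               Q_mL_s = infl$samples),
    file.path(dir, "inflow.csv"), row.names = FALSE)
  save_calibration_data(subject$measurements, file.path(dir, "calibration_data.json"),
                        seed = subject$seed)
  invisible(dir)
}
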