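#' Read / write calibration data
#'
#' JSON with a units header, scalar targets in mmHg/cm2, the measurement
#' time grid and LPA/RPA (and optionally MPA) flow series in mL/s.
#'
#' @param data a [calibration_data()].
#' @param path file path.
#' @param seed optional generating seed recorded in the file.
#' @return `load_calibration_data` returns a `calibration_data`;
#'   `save_calibration_data` returns `path` invisibly.
#' @export
save_calibration_data <- function(data, path, seed = NULL) {
  doc <- list(
    format = "pulsetree-calibration-data",
    units = list(P = "mmHg", A = "cm2", Q = "mL/s", t = "s"),
    seed = seed,
    Psys_mmHg = data$Psys, Pdia_mmHg = data$Pdia,
    Asys_cm2 = data$Asys, Adia_cm2 = data$Adia,
    t_s = data$t, Q_LPA_mL_s = data$Q_LPA, Q_RPA_mL_s = data$Q_RPA,
    Q_MPA_mL_s = data$Q_MPA,
    recomputed = as.list(data$recomputed))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_calibration_data
#' @export
load_calibration_data <- function(path) {
  if (!file.exists(path)) stop("calibration data file not found: ", path)
  doc <- jsonlite::fromJSON(path)
  calibration_data(Psys = doc$Psys_mmHg, Pdia = doc$Pdia_mmHg,
                   Asys = doc$Asys_cm2, Adia = doc$Adia_cm2,
                   t = doc$t_s, Q_LPA = doc$Q_LPA_mL_s, Q_RPA = doc$Q_RPA_mL_s,
                   Q_MPA = doc$Q_MPA_mL_s,
                   recomputed = unlist(doc$recomputed))
}

#' Run the end-to-end study pipeline
#'
#' Orchestrates subject/load -> analytic wall stiffness -> nominal
#' Windkessel construction -> multi-start calibration -> final simulation at
#' the optimum -> shear metrics, writing `result.json`, `metrics.csv`,
#' `summary.json` and a run log to the output directory. Given identical
#' config and seed, outputs are identical.
#'
#' @param config list with entries: either `subject` (a
#'   `synthetic_subject`) or `network`/`data`/`inflow` (paths or objects);
#'   `Ppcw` (mmHg, wedge pressure; defaults to 5 for a loaded subject);
#'   `seed`; `n_starts`; `weighting` (`"absolute"`/`"relative"`);
#'   `thresholds` (list `tau_low`, `osi_high`); `sim` (a [sim_config()]
#'   or `NULL`); `out_dir` (or `NULL` for no file output).
#' @return Report list of class `pipeline_report` (theta, cost, R^2,
#'   stiffness, Windkessel totals, shear summary, phi, scalar fit table,
#'   seed, timings).
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  seed <- if (is.null(config$seed)) 1L else config$seed
  thr <- utils::modifyList(list(tau_low = 5, osi_high = 0.05),
                           if (is.null(config$thresholds)) list() else config$thresholds)
  if (!is.null(config$subject)) {
    sub <- config$subject
    net <- sub$network
    data <- sub$measurements
    inflow <- sub$inflow
    props <- sub$props
    sim <- if (is.null(config$sim)) sub$sim else config$sim
    Ppcw <- sub$config$Ppcw
    subject_id <- sub$baseline_seed
    scenario <- sub$scenario
  } else {
    if (is.null(config$network) || is.null(config$data) || is.null(config$inflow)) {
      stop("config must provide either a subject or network + data + inflow")
    }
    net <- if (inherits(config$network, "vessel_network")) config$network
           else load_network(config$network)
    data <- if (inherits(config$data, "calibration_data")) config$data
            else load_calibration_data(config$data)
    if (inherits(config$inflow, "inflow_waveform")) {
      inflow <- config$inflow
    } else {
      df <- utils::read.csv(config$inflow)
      inflow <- inflow_waveform(df$Q_mL_s, df$t_s[length(df$t_s)])
    }
    props <- fluid_properties()
    sim <- if (is.null(config$sim)) sim_config(T = inflow$T) else config$sim
    Ppcw <- if (is.null(config$Ppcw)) 5 else config$Ppcw
    subject_id <- NA
    scenario <- if (is.null(config$scenario)) "loaded" else config$scenario
  }
  # 1. geometry: rescale the MPA to the measured diastolic area, then the
  #    analytic wall stiffness from MPA systole (uniform across the network)
  net <- scale_extralobar_areas(net, c(MPA = data$Adia))
  ehr0 <- stiffness_from_systole(data$Psys, data$Pdia, data$Asys, data$Adia)
  walls <- make_walls(net, stiffness = mmhg_to_cgs(ehr0),
                      Pdia = mmhg_to_cgs(data$Pdia))
  # 2. nominal Windkessels from mean pressures and mean MPA flow, with the
  #    total conductance apportioned by the measured lung flow split
  mpap <- mean_pa_pressure(data$Psys, data$Pdia)
  qbar <- trapz(seq(0, inflow$T, length.out = length(inflow$samples)),
                inflow$samples) / inflow$T
  pvr <- total_pvr(mpap, Ppcw, qbar)
  Td <- diastolic_duration(inflow)
  ctot <- total_compliance_from_decay(data$Psys, data$Pdia, Ppcw, Td, pvr)
  ql <- mean(data$Q_LPA); qr <- mean(data$Q_RPA)
  split <- c(LPA = ql, RPA = qr) / (ql + qr)
  wk_nom <- nominal_windkessels(net, resistance_mmhg_to_cgs(pvr),
                                compliance_mmhg_to_cgs(ctot),
                                mu = props$mu, Pout = mmhg_to_cgs(Ppcw),
                                flow_split = split)
  # 3. calibration
  ctx <- model_context(net, walls, wk_nom, inflow, props, sim)
  n_starts <- if (is.null(config$n_starts)) 10L else config$n_starts
  weighting <- if (is.null(config$weighting)) "absolute" else config$weighting
  calib <- calibrate_windkessels(data, ctx, n_starts = n_starts, seed = seed,
                                 weighting = weighting)
  # 4. metrics on the full-tolerance solution at the optimum
  sol <- calib$solution
  shear <- shear_field(sol, props)
  summ <- summarize_network(shear, net, tau_low = thr$tau_low,
                            osi_high = thr$osi_high)
  wk_hat <- scale_windkessels(wk_nom, calib$theta)
  RT <- vapply(wk_hat, function(w) w$Rp + w$Rd, numeric(1))
  report <- structure(list(
    subject_id = subject_id, scenario = scenario, seed = seed,
    theta = calib$theta, cost = calib$cost, r2 = calib$r2,
    scalars = calib$scalars,
    stiffness_mmHg = ehr0,
    wk_totals = list(
      Rp_total = parallel_resistance(vapply(wk_hat, `[[`, numeric(1), "Rp")),
      Rd_total = parallel_resistance(vapply(wk_hat, `[[`, numeric(1), "Rd")),
      C_total = total_compliance(vapply(wk_hat, `[[`, numeric(1), "C")),
      RT_parallel = parallel_resistance(RT)),
    shear = summ, phi = summ$phi,
    convergence = list(cycles = sol$cycles, converged = sol$converged,
                       periodicity_err = sol$periodicity_err,
                       max_junction_residual = sol$max_junction_residual),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    export_metrics(summ, config$out_dir, seed = seed)
    res <- report
    res$shear <- NULL
    res$elapsed_s <- NULL  # keep result.json byte-reproducible
    res$scalars <- as.list(stats::setNames(report$scalars$model,
                                           report$scalars$quantity))
    res$units <- list(stiffness = "mmHg", R = "dyn*s/cm5", C = "cm5/dyn",
                      tawss = "dyn/cm2", phi = "percent")
    jsonlite::write_json(res, file.path(config$out_dir, "result.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    log_lines <- c(
      sprintf("pulsetree %s", as.character(utils::packageVersion("pulsetree"))),
      sprintf("R %s", R.version.string),
      sprintf("seed %d", seed),
      sprintf("scenario %s", scenario),
      sprintf("elapsed %.1f s", report$elapsed_s))
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }
  report
}

# Diastolic duration of an inflow waveform: time with (near-)zero flow.
diastolic_duration <- function(inflow) {
  q <- inflow$samples
  thr <- 0.02 * max(abs(q))
  frac <- mean(abs(q) <= thr)
  max(frac, 0.05) * inflow$T
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_report> scenario %s: theta=(%.3f, %.3f, %.3f), ",
                     "Eh/r0 %.1f mmHg, phi %.1f%%\n"),
              x$scenario, x$theta[1], x$theta[2], x$theta[3],
              x$stiffness_mmHg, x$phi))
  invisible(x)
}

#' Paired baseline-vs-CTEPH comparison
#'
#' Emits differences (CTEPH - baseline) and ratios for the wall stiffness,
#' Windkessel totals, per-region TAWSS/OSI and the combined physiomarker
#' phi, for two pipeline reports from the same subject lineage.
#'
#' @param baseline,cteph `pipeline_report`s sharing `subject_id`.
#' @return Data frame with columns `quantity`, `baseline`, `cteph`,
#'   `delta`, `ratio`.
#' @export
compare_states <- function(baseline, cteph) {
  if (!identical(baseline$subject_id, cteph$subject_id)) {
    stop("reports come from different subjects (ids ",
         baseline$subject_id, " vs ", cteph$subject_id, ")")
  }
  grab <- function(rep) {
    ex <- rep$shear$extralobar
    c(stiffness_mmHg = rep$stiffness_mmHg,
      Rp_total = rep$wk_totals$Rp_total,
      Rd_total = rep$wk_totals$Rd_total,
      C_total = rep$wk_totals$C_total,
      tawss_MPA = ex$MPA$tawss, tawss_LPA = ex$LPA$tawss,
      tawss_RPA = ex$RPA$tawss,
      tawss_intralobar = rep$shear$intralobar$tawss,
      osi_MPA = ex$MPA$osi, osi_LPA = ex$LPA$osi, osi_RPA = ex$RPA$osi,
      osi_intralobar = rep$shear$intralobar$osi,
      phi = rep$phi)
  }
  b <- grab(baseline)
  ct <- grab(cteph)
  data.frame(quantity = names(b), baseline = as.numeric(b),
             cteph = as.numeric(ct), delta = as.numeric(ct - b),
             ratio = as.numeric(ifelse(b != 0, ct / b, NA)))
}
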