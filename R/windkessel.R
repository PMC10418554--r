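#' Three-element Windkessel (RCR) outflow model
#'
#' Lumped representation of the vasculature downstream of a terminal
#' segment: proximal resistance `Rp`, distal resistance `Rd`, compliance `C`
#' and distal reference pressure `Pout` (set to the mean wedge pressure).
#' All values in CGS (dyn*s/cm5, cm5/dyn, dyn/cm2).
#'
#' @param Rp,Rd resistances, dyn*s/cm5 (> 0).
#' @param C compliance, cm5/dyn (> 0).
#' @param Pout distal reference pressure, dyn/cm2.
#' @return Object of class `windkessel3`.
#' @export
windkessel3 <- function(Rp, Rd, C, Pout = 0) {
  stopifnot(Rp > 0, Rd > 0, C > 0)
  structure(list(Rp = Rp, Rd = Rd, C = C, Pout = Pout), class = "windkessel3")
}

#' Mean pulmonary artery pressure from systolic/diastolic values
#'
#' The standard catheterization estimate `(Psys + 2 Pdia) / 3`.
#'
#' @param Psys,Pdia systolic and diastolic pressure (any single unit;
#'   Psys >= Pdia).
#' @return Mean pressure in the same unit.
#' @export
mean_pa_pressure <- function(Psys, Pdia) {
  if (any(Psys < Pdia)) stop("requires Psys >= Pdia")
  (Psys + 2 * Pdia) / 3
}

#' Total pulmonary vascular resistance
#'
#' `(mean PA pressure - mean wedge pressure) / mean MPA flow`.
#'
#' @param Ppa mean pulmonary artery pressure.
#' @param Ppcw mean pulmonary capillary wedge pressure (same unit as `Ppa`).
#' @param Qbar mean MPA flow.
#' @return Resistance in (pressure unit)*s/(flow unit), e.g. mmHg*s/mL.
#' @export
total_pvr <- function(Ppa, Ppcw, Qbar) {
  if (any(Ppa <= Ppcw)) stop("requires mean PA pressure > wedge pressure")
  if (any(Qbar <= 0)) stop("requires positive mean flow")
  (Ppa - Ppcw) / Qbar
}

#' Total compliance from the diastolic pressure decay
#'
#' Models the MPA pressure fall from systole to diastole as a
#' mono-exponential RC decay towards the wedge pressure with time constant
#' `R_total * C_total`; solving
#' `Pdia - Ppcw = (Psys - Ppcw) exp(-Td / (R C))` for `C` gives the closed
#' form used here. If a sampled diastolic pressure trace is supplied, a
#' least-squares mono-exponential fit is used instead.
#'
#' @param Psys,Pdia,Ppcw pressures (one consistent unit).
#' @param Td diastolic duration, s.
#' @param R_total total resistance, (pressure unit)*s/mL.
#' @param trace optional list with `t` (s) and `P` (pressure) sampled over
#'   diastole; overrides the scalar closed form.
#' @return Total compliance in mL/(pressure unit).
#' @export
total_compliance_from_decay <- function(Psys, Pdia, Ppcw, Td, R_total,
                                        trace = NULL) {
  if (Pdia <= Ppcw) stop("requires Pdia > wedge pressure")
  if (Psys <= Pdia) stop("requires Psys > Pdia")
  stopifnot(Td > 0, R_total > 0)
  if (is.null(trace)) {
    return(Td / (R_total * log((Psys - Ppcw) / (Pdia - Ppcw))))
  }
  stopifnot(length(trace$t) == length(trace$P), length(trace$t) >= 3)
  # linearized LS fit of log(P - Ppcw) = log(P0 - Ppcw) - t/tau
  y <- log(trace$P - Ppcw)
  fit <- stats::lm(y ~ trace$t)
  tau <- -1 / stats::coef(fit)[[2]]
  if (tau <= 0) stop("diastolic trace does not decay")
  tau / R_total
}

#' Parallel resistance and summed compliance
#'
#' Circuit-theory combination rules for terminal Windkessel elements:
#' resistances in parallel combine as `1 / sum(1/R)`, capacitors in
#' parallel add.
#'
#' @param R,C numeric vectors of positive resistances / compliances.
#' @return Combined scalar value.
#' @export
parallel_resistance <- function(R) {
  if (length(R) == 0L) stop("empty resistance list")
  stopifnot(all(R > 0))
  1 / sum(1 / R)
}

#' @rdname parallel_resistance
#' @export
total_compliance <- function(C) {
  if (length(C) == 0L) stop("empty compliance list")
  stopifnot(all(C > 0))
  sum(C)
}

#' Nominal Windkessel construction
#'
#' Distributes a measured total resistance and compliance over the terminal
#' segments of a network. Each terminal receives a total resistance
#' proportional to its cumulative root-to-terminal Poiseuille resistance,
#' uniformly rescaled so that the parallel combination equals `R_total`;
#' proximal and distal parts are split equally (`Rp = Rd = RT/2`).
#' Compliances are distributed proportionally to terminal conductance
#' `1/RT` (so outlet time constants stay comparable) and sum to `C_total`.
#'
#' When measured branch flows are available, `flow_split` apportions the
#' total conductance between the lungs before the within-lung Poiseuille
#' distribution: each named extralobar branch (e.g. LPA/RPA) receives a lung
#' resistance `R_total / share`, so the parallel total still equals
#' `R_total` while left/right asymmetry (e.g. after thromboembolic
#' obstruction) is reflected in the nominal parameters. This mirrors the
#' role of the measured (or reconstructed) lung flow series in subject
#' calibration.
#'
#' @param net a `vessel_network`.
#' @param R_total total resistance, dyn*s/cm5.
#' @param C_total total compliance, cm5/dyn.
#' @param mu dynamic viscosity, Poise.
#' @param Pout distal reference pressure (mean wedge pressure), dyn/cm2.
#' @param flow_split optional named vector of mean-flow fractions per
#'   extralobar daughter branch (e.g. `c(LPA = 0.3, RPA = 0.7)`, summing
#'   to 1); terminals under each branch share that lung's resistance.
#' @return Named list (terminal id -> `windkessel3`), id-sorted.
#' @export
nominal_windkessels <- function(net, R_total, C_total, mu = 0.03, Pout = 0,
                                flow_split = NULL) {
  stopifnot(R_total > 0, C_total > 0)
  pr <- path_resistances(net, mu)
  if (length(pr) == 0L) stop("network has no terminal segments")
  if (is.null(flow_split)) {
    kappa <- R_total * sum(1 / pr)
    RT <- kappa * pr
  } else {
    if (abs(sum(flow_split) - 1) > 1e-8) stop("flow_split must sum to 1")
    RT <- pr
    assigned <- rep(FALSE, length(pr))
    for (nm in names(flow_split)) {
      ids <- c(descendants(net, nm),
               net$segments$id[net$segments$name == nm])
      in_lung <- names(pr) %in% as.character(ids)
      if (!any(in_lung)) stop("flow_split branch has no terminals: ", nm)
      assigned <- assigned | in_lung
      R_lung <- R_total / flow_split[[nm]]
      RT[in_lung] <- R_lung * sum(1 / pr[in_lung]) * pr[in_lung]
    }
    if (!all(assigned)) {
      stop("flow_split does not cover all terminals: ",
           paste(names(pr)[!assigned], collapse = ", "))
    }
  }
  w <- (1 / RT) / sum(1 / RT)
  Ci <- C_total * w
  out <- lapply(seq_along(RT), function(i) {
    windkessel3(Rp = RT[[i]] / 2, Rd = RT[[i]] / 2, C = Ci[[i]], Pout = Pout)
  })
  names(out) <- names(pr)
  out
}

#' One implicit-Euler step of the RCR outlet
#'
#' Integrates the Windkessel capacitor state `dPc/dt = (Q - (Pc - Pout)/Rd)/C`
#' with an implicit Euler step and returns the proximal boundary pressure
#' `P = Pc + Q * Rp`. This is the reference (R-level) form of the update
#' embedded in the compiled solver's outlet closure.
#'
#' @param Q boundary flow, mL/s.
#' @param Pc_prev capacitor pressure at the previous step, dyn/cm2.
#' @param wk a `windkessel3`.
#' @param dt time step, s (> 0).
#' @return List with `P` (boundary pressure) and `Pc` (updated capacitor
#'   pressure), dyn/cm2.
#' @export
windkessel_outlet_step <- function(Q, Pc_prev, wk, dt) {
  stopifnot(dt > 0)
  Pc <- (Pc_prev + (dt / wk$C) * (Q + wk$Pout / wk$Rd)) / (1 + dt / (wk$Rd * wk$C))
  list(P = Pc + Q * wk$Rp, Pc = Pc)
}
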