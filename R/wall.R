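#' Linear-elastic tube law
#'
#' Thin-walled, linearly elastic, isotropic cylinder closure relating
#' transmural pressure to lumen area:
#' \deqn{P(A) = \frac{4}{3}\,\frac{Eh}{r_0}\left(\sqrt{A/A_{dia}} - 1\right) + P_{dia}}
#' The composite stiffness `Eh/r0` captures both structural and
#' load-dependent stiffening and is the wall physiomarker reported by the
#' package. All arguments in CGS (dyn/cm2, cm2).
#'
#' @param stiffness composite wall stiffness `Eh/r0` in dyn/cm2 (> 0).
#' @param Adia lumen area at diastolic pressure, cm2 (> 0).
#' @param Pdia diastolic reference pressure, dyn/cm2.
#' @return `wall_model` returns a list of class `wall_model`.
#' @export
wall_model <- function(stiffness, Adia, Pdia) {
  stopifnot(stiffness > 0, Adia > 0)
  structure(list(stiffness = stiffness, Adia = Adia, Pdia = Pdia),
            class = "wall_model")
}

#' @rdname wall_model
#' @param A lumen area, cm2 (> 0); vectorized.
#' @param wall a `wall_model`.
#' @export
tube_law_pressure <- function(A, wall) {
  if (any(A <= 0)) stop("area must be positive")
  (4 / 3) * wall$stiffness * (sqrt(A / wall$Adia) - 1) + wall$Pdia
}

#' @rdname wall_model
#' @param P transmural pressure, dyn/cm2; vectorized. Must lie above the
#'   collapse limit `Pdia - (4/3) Eh/r0`.
#' @export
tube_law_area <- function(P, wall) {
  root <- 1 + 3 * (P - wall$Pdia) / (4 * wall$stiffness)
  if (any(root <= 0)) {
    stop("pressure in collapse regime of the tube law (root <= 0)")
  }
  wall$Adia * root^2
}

#' Analytic wall stiffness from systolic/diastolic pressure and area
#'
#' Inverts the tube law at the systolic state, giving
#' `Eh/r0 = 3 (Psys - Pdia) / (4 (sqrt(Asys/Adia) - 1))`.
#' Units are preserved: pass pressures in mmHg to get `Eh/r0` in mmHg, or
#' in dyn/cm2 to get dyn/cm2.
#'
#' @param Psys,Pdia systolic and diastolic pressure (Psys > Pdia).
#' @param Asys,Adia systolic and diastolic lumen area in cm2 (Asys > Adia).
#' @return Composite stiffness `Eh/r0` in the pressure units supplied.
#' @export
stiffness_from_systole <- function(Psys, Pdia, Asys, Adia) {
  if (Psys <= Pdia) stop("requires Psys > Pdia")
  if (Asys <= Adia) stop("no distension measured: requires Asys > Adia")
  3 * (Psys - Pdia) / (4 * (sqrt(Asys / Adia) - 1))
}
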