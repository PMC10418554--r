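#' Unit conversion helpers
#'
#' The package works internally in CGS units (cm, s, g, dyn/cm2). Pressures
#' cross the user interface in mmHg and flows in mL/s; these helpers convert
#' pressures and lumped-parameter values between the two systems using
#' 1 mmHg = 1333.22 dyn/cm2.
#'
#' @param x numeric vector to convert.
#' @return Converted numeric vector.
#' @examples
#' mmhg_to_cgs(1)      # 1333.22
#' cgs_to_mmhg(1333.22)
#' @name units
NULL

#' @rdname units
#' @export
MMHG <- 1333.22

#' @rdname units
#' @export
mmhg_to_cgs <- function(x) x * MMHG

#' @rdname units
#' @export
cgs_to_mmhg <- function(x) x / MMHG

#' @rdname units
#' @export
resistance_mmhg_to_cgs <- function(x) x * MMHG  # mmHg*s/mL -> dyn*s/cm5

#' @rdname units
#' @export
compliance_mmhg_to_cgs <- function(x) x / MMHG  # mL/mmHg -> cm5/dyn
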