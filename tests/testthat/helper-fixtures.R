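# Shared fixtures, built once per test run (all generated in code; no files).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

# 7-segment, two-generation tree as a plain segment table
seven_segment_table <- function() {
  data.frame(
    id = 1:7,
    name = c("MPA", "LPA", "RPA", "L4", "L5", "R6", "R7"),
    parent = c(NA, 1L, 1L, 2L, 2L, 3L, 3L),
    length = c(3, 2.5, 2.5, 2, 2, 2, 2),
    r0 = c(0.75, 0.6, 0.6, 0.45, 0.45, 0.45, 0.45),
    extralobar = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

seven_segment_net <- function() fixture("net7", function() {
  vessel_network(seven_segment_table())
})

# small, fast subject for solver/calibration tests (noise-free)
toy_subject <- function() fixture("toy_subject", function() {
  make_baseline_subject(
    config = list(generations = 2, noise_sd = 0, dx_target = 0.2), seed = 42)
})

# the default synthetic subject and its CTEPH state (the study-replica fixture)
default_subject <- function() fixture("default_subject", function() {
  make_baseline_subject(seed = 42)
})

default_cteph <- function() fixture("default_cteph", function() {
  apply_cteph(default_subject())
})

# single uniform vessel with a matched Windkessel, for analytic oracles
single_vessel_net <- function(L = 2, r0 = sqrt(1 / pi)) {
  vessel_network(data.frame(id = 1, name = "MPA", parent = NA, length = L,
                            r0 = r0, extralobar = TRUE))
}
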