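test_that("structured tree generator obeys its construction rules", {
  net <- generate_tree(generations = 2)
  expect_equal(nrow(net$segments), 7L)
  expect_length(terminal_segments(net), 4L)
  expect_equal(net$segments$name[1:3], c("MPA", "LPA", "RPA"))
  expect_equal(sum(net$segments$extralobar), 3L)
  # asymmetry 0: left and right subtrees mirror-identical
  l <- net$segments[descendants(net, "LPA"), ]
  r <- net$segments[descendants(net, "RPA"), ]
  expect_equal(l$r0, r$r0)
  expect_equal(l$length, r$length)
  # asymmetric daughters
  neta <- generate_tree(2, asymmetry = 0.1)
  kids <- neta$segments[2:3, ]
  expect_equal(kids$r0[1] / kids$r0[2], 1.1 / 0.9, tolerance = 1e-12)
  # radius floor (0.05 * 0.79^7 < 0.01 cm)
  expect_error(generate_tree(7, r_root = 0.05), "fewer generations")
  # lengths proportional to radii
  expect_equal(net$segments$length, 5 * net$segments$r0)
})

test_that("half-sine inflow integrates to the stroke volume", {
  infl <- generate_inflow(T = 0.5, stroke_volume = 15, systole_fraction = 0.4)
  t <- seq(0, 0.5, length.out = length(infl$samples))
  expect_equal(pulsetree:::trapz(t, infl$samples), 15, tolerance = 1e-3)
  expect_equal(mean(infl$samples[-1]), 15 / 0.5, tolerance = 1e-2)
  expect_equal(max(infl$samples), (pi / 2) * 15 / (0.4 * 0.5), tolerance = 1e-3)
  expect_equal(infl$samples[1], infl$samples[length(infl$samples)])
  expect_error(generate_inflow(stroke_volume = -1), "positive")
})

test_that("baseline subject has physiologic pressure ordering and is deterministic", {
  sub <- default_subject()
  m <- sub$measurements
  expect_gt(m$Psys, mean_pa_pressure(m$Psys, m$Pdia))
  expect_gt(mean_pa_pressure(m$Psys, m$Pdia), m$Pdia)
  expect_gt(m$Pdia, sub$config$Ppcw)
  expect_gt(m$Asys, m$Adia)
  expect_true(sub$solution$converged)
  # byte-for-byte determinism
  s1 <- make_baseline_subject(config = list(generations = 2, dx_target = 0.2),
                              seed = 11)
  s2 <- make_baseline_subject(config = list(generations = 2, dx_target = 0.2),
                              seed = 11)
  expect_identical(s1, s2)
  # a different seed changes the noise draws
  s3 <- make_baseline_subject(config = list(generations = 2, dx_target = 0.2),
                              seed = 12)
  expect_false(identical(s1$measurements$Q_LPA, s3$measurements$Q_LPA))
})

test_that("noise-free subject is self-consistent at the true factors", {
  toy <- toy_subject()
  ctx <- model_context(toy$network, toy$walls, toy$windkessels_nominal,
                       toy$inflow, toy$props, toy$sim)
  expect_lt(calibration_cost(toy$true_theta, toy$measurements, ctx, relax = 1),
            1e-16)
})

test_that("stiffness pipeline closure: measured systole returns the true Eh/r0", {
  sub <- default_subject()
  m <- sub$measurements
  est <- stiffness_from_systole(m$Psys, m$Pdia, m$Asys, m$Adia)
  expect_equal(est, cgs_to_mmhg(sub$config$stiffness), tolerance = 0.03)
})

test_that("CTEPH transform scales the stated parameters and directions", {
  toy <- toy_subject()
  # identity severity/stiffening leaves parameters and solution unchanged
  same <- apply_cteph(toy, severity = 1, left_fraction = 0.8, stiffening = 1)
  expect_equal(same$windkessels_true, toy$windkessels_true)
  expect_equal(same$walls, toy$walls)
  expect_equal(same$measurements$Psys, toy$measurements$Psys)
  expect_true(same$measurements$recomputed[["LPA"]])
  expect_error(apply_cteph(toy, severity = 0.5), "severity")
  # left-dominant obstruction shifts flow to the right lung
  ct <- apply_cteph(toy, severity = 5, left_fraction = 0.8, stiffening = 2)
  share <- function(m) mean(m$Q_LPA) / (mean(m$Q_LPA) + mean(m$Q_RPA))
  expect_lt(share(ct$measurements), share(toy$measurements))
  # resistances scaled by the stated factors, compliances inversely
  left_term <- intersect(descendants(toy$network, "LPA"),
                         terminal_segments(toy$network))[1]
  key <- as.character(left_term)
  expect_equal(ct$windkessels_true[[key]]$Rd,
               5 * toy$windkessels_true[[key]]$Rd)
  expect_equal(ct$windkessels_true[[key]]$C,
               toy$windkessels_true[[key]]$C / 5)
  # stiffening alone raises pulse pressure
  stiff <- apply_cteph(toy, severity = 1, left_fraction = 0.8, stiffening = 2)
  pp <- function(m) m$Psys - m$Pdia
  expect_gt(pp(stiff$measurements), pp(toy$measurements))
})

test_that("subject export writes the four artifact files", {
  toy <- toy_subject()
  dir <- withr::local_tempdir()
  export_subject(toy, dir)
  expect_setequal(list.files(dir),
                  c("network.json", "parameters.json", "inflow.csv",
                    "calibration_data.json"))
  net <- load_network(file.path(dir, "network.json"))
  expect_equal(net$segments$r0, toy$network$segments$r0)
  par <- jsonlite::fromJSON(file.path(dir, "parameters.json"))
  expect_equal(par$units$R, "dyn*s/cm5")
})
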