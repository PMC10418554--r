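test_that("wall shear stress follows the power-law wall gradient", {
  expect_equal(wall_shear_stress(0, 1), 0)
  expect_equal(wall_shear_stress(20, 1), 0.03 * 11 * 20 / sqrt(1 / pi),
               tolerance = 1e-12)
  expect_equal(wall_shear_stress(20, 1), 11.70, tolerance = 1e-3)
  # tau ~ A^(-3/2) at fixed Q
  expect_equal(wall_shear_stress(20, 2) / wall_shear_stress(20, 1), 2^(-1.5),
               tolerance = 1e-12)
  # signed by flow direction
  expect_equal(wall_shear_stress(-20, 1), -wall_shear_stress(20, 1))
  expect_error(wall_shear_stress(1, -1), "positive")
})

test_that("TAWSS quadrature matches closed forms", {
  t <- seq(0, 0.8, length.out = 2001)
  expect_equal(tawss(rep(5, length(t)), t), 5)
  a <- 7.3
  expect_equal(tawss(a * sin(2 * pi * t / 0.8), t), (2 / pi) * a,
               tolerance = 1e-4)
  expect_equal(tawss(-3 * sin(2 * pi * t / 0.8), t),
               3 * tawss(sin(2 * pi * t / 0.8), t), tolerance = 1e-12)
  expect_error(tawss(numeric(0), numeric(0)), "empty")
})

test_that("OSI closed forms and bounds hold", {
  t <- seq(0, 1, length.out = 4001)
  expect_equal(as.numeric(osi(abs(sin(2 * pi * t)) + 1, t)), 0)  # unidirectional
  expect_equal(as.numeric(osi(sin(2 * pi * t), t)), 0.5, tolerance = 1e-6)
  # +2 for 3T/4 then -2 for T/4: OSI = 0.5 (1 - 1/2) = 0.25
  tau <- ifelse(t < 0.75, 2, -2)
  expect_equal(as.numeric(osi(tau, t)), 0.25, tolerance = 1e-3)
  # identically zero series flagged undefined
  z <- osi(rep(0, 10), seq(0, 1, length.out = 10))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "undefined"))
  # bounds + TAWSS >= |mean| on random series
  set.seed(4)
  for (i in 1:50) {
    tt <- seq(0, 1, length.out = 64)
    tau <- rnorm(64, mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
    o <- as.numeric(osi(tau, tt))
    expect_gte(o, 0); expect_lte(o, 0.5)
    expect_gte(tawss(tau, tt), abs(pulsetree:::trapz(tt, tau)))
  }
})

test_that("network summary computes phi as flagged length share", {
  t <- seq(0, 0.5, length.out = 101)
  mk <- function(id, tau_fun) {
    x <- seq(0, 1, length.out = 11)
    list(id = id, name = paste0("V", id), extralobar = FALSE, length = 1,
         x = x, tau = outer(tau_fun(t), rep(1, 11)))
  }
  # three segments healthy, one with low TAWSS + high OSI everywhere
  field <- structure(list(
    t = t, T = 0.5,
    vessels = list(mk(1, function(t) rep(10, length(t))),
                   mk(2, function(t) rep(10, length(t))),
                   mk(3, function(t) rep(10, length(t))),
                   mk(4, function(t) 2 * sign(sin(4 * pi * t))))),
    class = "shear_field")
  ss <- summarize_network(field, NULL)
  expect_equal(ss$phi, 25)
  expect_equal(ss$per_segment$osi[1:3], rep(0, 3))
  # all high TAWSS, zero OSI -> phi 0
  field0 <- structure(list(t = t, T = 0.5,
                           vessels = list(mk(1, function(t) rep(10, length(t))))),
                      class = "shear_field")
  expect_equal(summarize_network(field0, NULL)$phi, 0)
  # raising tau_low can only increase phi
  expect_gte(summarize_network(field, NULL, tau_low = 12)$phi, ss$phi)
  expect_error(summarize_network(field, NULL, tau_low = -1), "positive")
})

test_that("steady simulation gives OSI 0 and TAWSS matching the analytic shear", {
  net <- single_vessel_net(L = 2, r0 = sqrt(1 / pi))
  walls <- make_walls(net, stiffness = 1e7, Pdia = mmhg_to_cgs(10))
  wk <- list("1" = windkessel3(400, 400, 1e-4, Pout = mmhg_to_cgs(10)))
  infl <- inflow_waveform(rep(20, 65), T = 0.5)
  sol <- simulate_to_periodic(net, walls, wk, infl,
                              config = sim_config(periodicity_tol = 1e-6))
  sf <- shear_field(sol)
  ss <- summarize_network(sf, net)
  expect_equal(ss$per_segment$osi, 0)
  A <- mean(sol$vessels[["1"]]$A[length(sol$t), ])
  expect_equal(ss$per_segment$tawss, wall_shear_stress(20, A), tolerance = 0.01)
})

test_that("metrics export writes csv and json with thresholds", {
  toy <- toy_subject()
  ss <- summarize_network(shear_field(toy$solution, toy$props), toy$network)
  dir <- withr::local_tempdir()
  export_metrics(ss, dir, seed = 42)
  df <- utils::read.csv(file.path(dir, "metrics.csv"))
  expect_equal(nrow(df), 7L)
  js <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(js$thresholds$tau_low, 5)
  expect_equal(js$phi, ss$phi)
})
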