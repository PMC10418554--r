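test_that("hemodynamic summary formulas match their definitions", {
  expect_equal(mean_pa_pressure(30, 15), 20)
  expect_equal(mean_pa_pressure(17, 17), 17)
  expect_error(mean_pa_pressure(51, 60), "Psys >= Pdia")
  expect_equal(total_pvr(20, 5, 25), 0.6)
  expect_equal(resistance_mmhg_to_cgs(0.6), 799.932, tolerance = 1e-6)
  expect_error(total_pvr(5, 20, 25), "wedge")
  expect_error(total_pvr(20, 5, 0), "flow")
})

test_that("tube law and its inverse are exact inverses", {
  wall <- wall_model(stiffness = mmhg_to_cgs(150), Adia = 1,
                     Pdia = mmhg_to_cgs(10))
  expect_equal(tube_law_pressure(1, wall), mmhg_to_cgs(10))        # A = Adia
  expect_equal(cgs_to_mmhg(tube_law_pressure(1.21, wall)), 30)     # printed case
  expect_equal(tube_law_area(mmhg_to_cgs(30), wall), 1.21, tolerance = 1e-12)
  expect_equal(tube_law_area(wall$Pdia, wall), wall$Adia)
  # monotone increasing in A
  A <- seq(0.3, 3, length.out = 50)
  expect_true(all(diff(tube_law_pressure(A, wall)) > 0))
  # round trip on random states, random walls
  set.seed(2)
  for (i in 1:20) {
    w <- wall_model(runif(1, 2e4, 5e5), runif(1, 0.2, 3), runif(1, 0, 3e4))
    P <- runif(5, w$Pdia - 0.5 * w$stiffness, w$Pdia + w$stiffness)
    expect_equal(tube_law_pressure(tube_law_area(P, w), w), P,
                 tolerance = 1e-12)
  }
  expect_error(tube_law_area(wall$Pdia - 2 * wall$stiffness, wall), "collapse")
})

test_that("analytic stiffness inverts the tube law at systole", {
  expect_equal(stiffness_from_systole(30, 10, 1.21, 1.0), 150, tolerance = 1e-12)
  # forward substitution reproduces Psys
  set.seed(3)
  for (i in 1:20) {
    f <- runif(1, 3e4, 6e5); Adia <- runif(1, 0.3, 3)
    Pdia <- runif(1, 5e3, 3e4); Asys <- Adia * runif(1, 1.05, 1.6)
    w <- wall_model(f, Adia, Pdia)
    Psys <- tube_law_pressure(Asys, w)
    expect_equal(stiffness_from_systole(Psys, Pdia, Asys, Adia), f,
                 tolerance = 1e-10)
  }
  # vanishing pulse pressure drives stiffness to zero
  expect_lt(stiffness_from_systole(10 + 1e-9, 10, 1.21, 1.0), 1e-7)
  expect_error(stiffness_from_systole(30, 10, 1.0, 1.0), "distension")
})

test_that("total compliance follows the diastolic decay closed form", {
  expect_equal(total_compliance_from_decay(30, 15, 5, Td = 0.4, R_total = 0.6),
               0.4 / (0.6 * log(2.5)), tolerance = 1e-12)
  expect_error(total_compliance_from_decay(30, 5, 5, 0.4, 0.6), "wedge")
  # trace route: forward-simulate a decay with known tau = R*C, recover C
  R <- 0.6; C_true <- 0.9; tau <- R * C_true
  t <- seq(0, 0.35, length.out = 40)
  P <- 5 + (30 - 5) * exp(-t / tau)
  C_est <- total_compliance_from_decay(30, min(P), 5, Td = 0.35, R_total = R,
                                       trace = list(t = t, P = P))
  expect_equal(C_est, C_true, tolerance = 0.01)
})

test_that("parallel/summed combination rules hold", {
  expect_equal(parallel_resistance(c(2, 2)), 1)
  expect_equal(parallel_resistance(5), 5)
  expect_equal(total_compliance(c(0.3, 0.7)), 1.0)
  expect_error(parallel_resistance(numeric(0)), "empty")
  expect_error(total_compliance(numeric(0)), "empty")
})

test_that("nominal Windkessels conserve totals and follow path resistance", {
  # single terminal: gets everything
  net1 <- single_vessel_net()
  wk1 <- nominal_windkessels(net1, R_total = 800, C_total = 5e-4, Pout = 10)
  expect_equal(wk1[["1"]]$Rp, 400)
  expect_equal(wk1[["1"]]$Rd, 400)
  expect_equal(wk1[["1"]]$C, 5e-4)
  # two identical terminals: each takes 2 R_total, half the compliance
  sym <- vessel_network(data.frame(
    id = 1:3, name = c("MPA", "LPA", "RPA"), parent = c(NA, 1L, 1L),
    length = c(3, 2, 2), r0 = c(0.7, 0.5, 0.5), extralobar = TRUE))
  wks <- nominal_windkessels(sym, 800, 5e-4)
  expect_equal(wks[["2"]]$Rp + wks[["2"]]$Rd, 1600)
  expect_equal(wks[["3"]]$C, 2.5e-4)
  # asymmetric 1:4 path resistances: RT ratio 1:4, parallel total preserved
  asym <- vessel_network(data.frame(
    id = 1:3, name = c("MPA", "LPA", "RPA"), parent = c(NA, 1L, 1L),
    length = c(1e-9, 1, 4), r0 = c(0.7, 0.5, 0.5), extralobar = TRUE))
  wka <- nominal_windkessels(asym, 800, 5e-4)
  RT <- vapply(wka, function(w) w$Rp + w$Rd, numeric(1))
  expect_equal(unname(RT[["3"]] / RT[["2"]]), 4, tolerance = 1e-6)
  expect_equal(parallel_resistance(RT), 800, tolerance = 1e-10 * 800)
  # conservation at 1e-10 on a deeper tree, and monotone in path resistance
  net <- generate_tree(3, asymmetry = 0.2)
  wk <- nominal_windkessels(net, 1234.5, 6.7e-4)
  RT <- vapply(wk, function(w) w$Rp + w$Rd, numeric(1))
  Cs <- vapply(wk, `[[`, numeric(1), "C")
  expect_equal(parallel_resistance(RT), 1234.5, tolerance = 1e-10)
  expect_equal(total_compliance(Cs), 6.7e-4, tolerance = 1e-10)
  pr <- path_resistances(net)
  expect_equal(order(RT), order(pr))
  expect_error(nominal_windkessels(net, -1, 1), "R_total")
})

test_that("flow-split apportioning preserves the parallel total", {
  net <- generate_tree(2)
  wk <- nominal_windkessels(net, 900, 4e-4,
                            flow_split = c(LPA = 0.3, RPA = 0.7))
  RT <- vapply(wk, function(w) w$Rp + w$Rd, numeric(1))
  expect_equal(parallel_resistance(RT), 900, tolerance = 1e-10)
  left <- as.character(intersect(descendants(net, "LPA"), terminal_segments(net)))
  expect_equal(parallel_resistance(RT[left]), 900 / 0.3, tolerance = 1e-8)
  expect_equal(total_compliance(vapply(wk, `[[`, numeric(1), "C")), 4e-4,
               tolerance = 1e-10)
})

test_that("windkessel outlet step obeys the steady circuit law", {
  wk <- windkessel3(Rp = resistance_mmhg_to_cgs(0.1),
                    Rd = resistance_mmhg_to_cgs(0.5),
                    C = compliance_mmhg_to_cgs(1), Pout = mmhg_to_cgs(5))
  Pc <- wk$Pout
  dt <- wk$Rd * wk$C / 100
  for (i in 1:3000) {
    st <- windkessel_outlet_step(10, Pc, wk, dt)
    Pc <- st$Pc
  }
  expect_equal(cgs_to_mmhg(st$P), 5 + 10 * 0.6, tolerance = 1e-6)
})
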