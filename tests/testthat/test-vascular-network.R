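test_that("seven-segment tree validates and exposes its structure", {
  net <- seven_segment_net()
  expect_length(validate_network(net), 0)
  expect_equal(terminal_segments(net), c(4L, 5L, 6L, 7L))
  expect_equal(nrow(net$segments), 7L)  # 2^(g+1)-1 for g = 2
  # 3-generation tree: 15 segments, 8 terminals
  net3 <- generate_tree(generations = 3)
  expect_equal(nrow(net3$segments), 15L)
  expect_length(terminal_segments(net3), 8L)
  # single-vessel degenerate tree
  net1 <- single_vessel_net()
  expect_equal(terminal_segments(net1), 1L)
  # terminal count invariant for strict bifurcating trees
  for (g in 1:4) {
    n <- generate_tree(generations = g)
    expect_equal(length(terminal_segments(n)), (nrow(n$segments) + 1) / 2)
  }
})

test_that("structural violations are itemized", {
  tab <- seven_segment_table()
  # a third child under segment 2
  bad <- rbind(tab, data.frame(id = 8L, name = "X", parent = 2L, length = 1,
                               r0 = 0.3, extralobar = FALSE))
  expect_error(vessel_network(bad), "children")
  net <- vessel_network(bad, validate = FALSE)
  expect_match(validate_network(net), "has 3 children", all = FALSE)
  # disconnected segment (parent loop outside the root's tree)
  tab2 <- rbind(tab, data.frame(id = c(8L, 9L), name = c("X", "Y"),
                                parent = c(9L, 8L), length = 1, r0 = 0.3,
                                extralobar = FALSE))
  net2 <- vessel_network(tab2, root_id = 1L, validate = FALSE)
  expect_match(validate_network(net2), "unreachable from root", all = FALSE)
  # nonpositive radius
  tab3 <- tab; tab3$r0[4] <- -0.1
  net3 <- vessel_network(tab3, validate = FALSE)
  expect_match(validate_network(net3), "nonpositive radius", all = FALSE)
})

test_that("JSON and CSV serialization round-trip losslessly", {
  net <- seven_segment_net()
  for (ext in c("json", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    save_network(net, path)
    back <- load_network(path)
    expect_equal(back$segments, net$segments)
    expect_equal(back$root_id, net$root_id)
  }
  # malformed file: missing radius column
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = 1, name = "MPA", parent = NA,
                              length_cm = 2, extralobar = TRUE),
                   path, row.names = FALSE)
  expect_error(load_network(path), "radius_cm")
  expect_error(load_network("no/such/file.json"), "not found")
})

test_that("the shipped example network loads and validates", {
  path <- system.file("extdata", "example_network.json", package = "pulsetree")
  net <- load_network(path)
  expect_length(validate_network(net), 0)
  expect_equal(nrow(net$segments), 7L)
  expect_equal(net$segments$name[1], "MPA")
})

test_that("extralobar areas rescale to measured diastolic values", {
  net <- seven_segment_net()
  scaled <- scale_extralobar_areas(net, c(MPA = 1.75))
  expect_equal(scaled$segments$r0[1], sqrt(1.75 / pi), tolerance = 1e-12)
  expect_equal(scaled$segments$r0[1], 0.7463, tolerance = 1e-4)
  expect_equal(scaled$segments$r0[-1], net$segments$r0[-1])  # others untouched
  # identity: measured area equal to current pi r0^2
  same <- scale_extralobar_areas(net, c(LPA = pi * 0.6^2))
  expect_equal(same$segments, net$segments)
  # empty map is a no-op
  expect_equal(scale_extralobar_areas(net, list()), net)
  expect_error(scale_extralobar_areas(net, c(XPA = 1)), "unknown")
  expect_error(scale_extralobar_areas(net, c(MPA = -1)), "positive")
})

test_that("Poiseuille resistance follows 8 mu L / (pi r^4)", {
  seg <- list(length = 2, r0 = 0.2)
  expect_equal(poiseuille_resistance(seg, mu = 0.03), 0.48 / (pi * 0.0016),
               tolerance = 1e-12)
  expect_equal(poiseuille_resistance(list(length = 1, r0 = 0.1), mu = 0.03),
               763.94, tolerance = 1e-4)
  # r^-4 scaling
  expect_equal(poiseuille_resistance(list(length = 2, r0 = 0.4), mu = 0.03),
               poiseuille_resistance(seg, mu = 0.03) / 16)
  # strict monotonicity over random positive inputs
  set.seed(1)
  for (i in 1:25) {
    L <- runif(1, 0.5, 5); r <- runif(1, 0.05, 1); mu <- runif(1, 0.01, 0.1)
    base <- poiseuille_resistance(list(length = L, r0 = r), mu)
    expect_lt(poiseuille_resistance(list(length = L, r0 = r * 1.1), mu), base)
    expect_gt(poiseuille_resistance(list(length = L * 1.1, r0 = r), mu), base)
    expect_gt(poiseuille_resistance(list(length = L, r0 = r), mu * 1.1), base)
  }
})

test_that("path resistance accumulates along root-to-terminal paths", {
  net1 <- single_vessel_net()
  expect_equal(unname(path_resistances(net1)[1]),
               poiseuille_resistance(net1$segments[1, ]))
  net <- seven_segment_net()
  pr <- path_resistances(net)
  seg <- net$segments
  manual <- poiseuille_resistance(seg[1, ]) + poiseuille_resistance(seg[2, ]) +
    poiseuille_resistance(seg[4, ])
  expect_equal(pr[["4"]], manual, tolerance = 1e-12)
})
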