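blood <- fluid_properties()

test_that("the tree requires its full anatomy", {
  expect_error(venous_tree(list(vessel_segment("SSS", 100, 5))), "missing segment")
  segs <- make_linear_tree()$segments
  segs$extra <- vessel_segment("XX", 10, 5)
  expect_error(venous_tree(unname(segs)), "unknown segment")
})

test_that("a symmetric tree splits flow exactly in half", {
  sol <- solve_tree(make_linear_tree(), 600)
  expect_equal(sol$left_fraction, 0.5, tolerance = 1e-9)
  left <- sol$segments$flow[sol$segments$segment == "TS-L"]
  right <- sol$segments$flow[sol$segments$segment == "TS-R"]
  expect_equal(left, right, tolerance = 1e-9)
})

test_that("an occluded branch receives vanishing flow", {
  sol <- solve_tree(make_linear_tree(d_left = 6, d_right = 0.4), 400)
  expect_gt(sol$left_fraction, 0.999)
})

test_that("mass is conserved at every node", {
  tr <- calibrate_tree(average_tree())
  for (Q in c(200, 900, 2000)) {
    sol <- solve_tree(tr, Q)
    seg <- sol$segments
    q <- function(nm) seg$flow[seg$segment == nm]
    # inlets sum to the total
    expect_equal(q("SSS") + q("StS"), Q, tolerance = 1e-12 * Q)
    # torcula outflow equals inflow
    expect_equal(q("TS-L") + q("TS-R"), Q, tolerance = 1e-12 * Q)
    # series chains carry identical flow
    expect_equal(q("TS-L"), q("IJV-L"), tolerance = 1e-12 * Q)
    expect_equal(q("TS-R"), q("IJV-R"), tolerance = 1e-12 * Q)
  }
})

test_that("both parallel paths drop the same pressure", {
  tr <- calibrate_tree(average_tree())
  sol <- solve_tree(tr, 1400)
  seg <- sol$segments
  dl <- sum(seg$drop[seg$segment %in% c("TS-L", "PSS-L", "DSS-L", "IJV-L")])
  dr <- sum(seg$drop[seg$segment %in% c("TS-R", "PSS-R", "DSS-R", "IJV-R")])
  expect_equal(dl, dr, tolerance = 1e-8)
})

test_that("linear networks reproduce the electrical circuit closed form", {
  mu <- blood$viscosity
  for (dr in c(6, 7.5)) {
    tr <- make_linear_tree(d_left = 6, d_right = dr)
    Q_total <- 300   # keeps every segment laminar
    sol <- solve_tree(tr, Q_total, straight_fraction = 0.30, fluid = blood)
    RL <- branch_resistance(tr, c("TS-L", "PSS-L", "DSS-L", "IJV-L"), mu)
    RR <- branch_resistance(tr, c("TS-R", "PSS-R", "DSS-R", "IJV-R"), mu)
    # current divider: the left branch takes R_R / (R_L + R_R) of the flow
    expect_equal(sol$left_fraction, RR / (RL + RR), tolerance = 1e-9)
    # system drop: SSS series resistance plus the parallel combination
    Q_si <- mlmin_to_m3s(Q_total)
    Q_sss <- Q_si / 1.30
    R_sss <- branch_resistance(tr, "SSS", mu)
    drop_pa <- R_sss * Q_sss + (RL * RR / (RL + RR)) * Q_si
    expect_equal(sol$drop, pa_to_mmhg(drop_pa), tolerance = 1e-9)
  }
})

test_that("the system drop is increasing and convex in flow", {
  tr <- calibrate_tree(average_tree())
  drops <- flow_sweep(tr)$drop
  expect_true(all(diff(drops) > 0))
  expect_true(all(diff(diff(drops)) > -1e-9))
})

test_that("calibration hits its anchor and is a fixed point", {
  tr <- calibrate_tree(average_tree(), 620, 4.5)
  expect_equal(solve_tree(tr, 620)$drop, 4.5, tolerance = 1e-6)
  # calibrating an already-matching tree returns scale ~1 relative
  d0 <- solve_tree(tr, 620)$drop
  tr2 <- calibrate_tree(tr, 620, d0)
  expect_equal(attr(tr2, "k_scale") / attr(tr, "k_scale"), 1, tolerance = 1e-6)
})

test_that("calibration below the friction floor is infeasible", {
  expect_error(calibrate_tree(average_tree(), 620, 0.01), "infeasible")
})

test_that("a calibrated average tree exceeds the IIH drop at 2000 mL/min", {
  tr <- calibrate_tree(average_tree())
  expect_gt(solve_tree(tr, 2000)$drop, 8.3)
})

test_that("doubling all diameters strictly decreases every sweep drop", {
  tr <- average_tree()
  segs2 <- lapply(tr$segments, function(s)
    vessel_segment(s$name, m_to_mm(s$length), 2 * m_to_mm(s$diameter),
                   bends = s$bends, extra_K = s$extra_K))
  tr2 <- venous_tree(segs2)
  flows <- c(400, 1000, 1600)
  d1 <- flow_sweep(tr, flows)$drop
  d2 <- flow_sweep(tr2, flows)$drop
  expect_true(all(d2 < d1))
})

test_that("tree JSON round trip preserves the geometry", {
  tr <- calibrate_tree(average_tree())
  p <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tr, p)
  back <- read_tree_json(p)
  for (nm in names(tr$segments)) {
    expect_equal(back$segments[[nm]]$length, tr$segments[[nm]]$length)
    expect_equal(back$segments[[nm]]$diameter, tr$segments[[nm]]$diameter)
    expect_equal(back$segments[[nm]]$k_scale, tr$segments[[nm]]$k_scale)
    expect_equal(back$segments[[nm]]$bends, tr$segments[[nm]]$bends)
  }
  expect_equal(solve_tree(back, 620)$drop, 4.5, tolerance = 1e-6)
})
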