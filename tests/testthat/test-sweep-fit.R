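test_that("the default sweep produces ten points on the standard grid", {
  expect_equal(default_flow_grid(), seq(200, 2000, by = 200))
  tr <- calibrate_tree(average_tree())
  cv <- flow_sweep(tr)
  expect_s3_class(cv, "pressure_flow_curve")
  expect_equal(nrow(cv), 10L)
  cv1 <- flow_sweep(tr, flows = 600)
  expect_equal(nrow(cv1), 1L)
  expect_error(pq_fit(cv1), "at least 3")
})

test_that("curve validation rejects malformed input", {
  expect_error(pressure_flow_curve(c(1, 2), c(1, 2, 3)), "lengths differ")
  expect_error(pressure_flow_curve(c(2, 1, 3), c(1, 2, 3)), "increasing")
  expect_error(pressure_flow_curve(c(-1, 1, 2), 1:3), "positive")
})

test_that("a noiseless laminar sweep is fitted exactly", {
  # pure friction + bends at low flows: drop is exactly a*Q + b*Q^2
  tr <- make_linear_tree()
  cv <- flow_sweep(tr, flows = seq(50, 500, by = 50))
  fit <- pq_fit(cv)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("exactly linear data yields b ~ 0 and r = 1", {
  Q <- seq(200, 2000, by = 200)
  fit <- pq_fit(pressure_flow_curve(Q, 0.002 * Q))
  expect_equal(fit$b, 0, tolerance = 1e-12)
  expect_equal(fit$a, 0.002, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
})

test_that("fit matches an independent normal-equations solve", {
  set.seed(3)
  Q <- default_flow_grid()
  P <- (0.003 * Q + 1.5e-6 * Q^2) * (1 + rnorm(10, 0, 0.02))
  fit <- pq_fit(pressure_flow_curve(Q, P))
  # oracle: solve X'X beta = X'y directly
  X <- cbind(Q, Q^2)
  beta <- solve(t(X) %*% X, t(X) %*% P)
  expect_equal(fit$a, beta[1L], tolerance = 1e-9)
  expect_equal(fit$b, beta[2L], tolerance = 1e-9)
})

test_that("true coefficients are recovered within 15% at 2% noise", {
  a0 <- 0.003; b0 <- 1.5e-6
  rec <- sapply(1:20, function(s) {
    d <- generate_surrogate(surrogate_spec(a = a0, b = b0, sigma_p = 0.02,
                                           seed = s))[[1L]]
    cf <- coef(pq_fit(d$curve))
    c(cf[["a"]], cf[["b"]])
  })
  expect_lt(abs(median(rec[1L, ]) - a0) / a0, 0.15)
  expect_lt(abs(median(rec[2L, ]) - b0) / b0, 0.15)
})

test_that("duplicate flows are rejected as rank-deficient", {
  expect_error(pq_fit(data.frame(flow = c(200, 200, 400), drop = c(1, 1.1, 2))),
               "rank-deficient|duplicate")
})

test_that("a concave curve triggers the b < 0 warning", {
  Q <- c(200, 600, 1000, 1400)
  expect_warning(pq_fit(pressure_flow_curve(Q, sqrt(Q))), "b < 0")
})

test_that("Pearson r is invariant under unit rescaling of the drops", {
  tr <- calibrate_tree(average_tree())
  cv <- flow_sweep(tr)
  set.seed(8)
  noisy <- pressure_flow_curve(cv$flow, cv$drop * (1 + rnorm(10, 0, 0.03)))
  r_mmhg <- pq_fit(noisy)$r
  scaled <- pressure_flow_curve(noisy$flow, mmhg_to_pa(noisy$drop))
  expect_equal(pq_fit(scaled)$r, r_mmhg, tolerance = 1e-12)
})

test_that("threshold_flow inverts the fitted curve", {
  Q <- default_flow_grid()
  # constructed root: pure quadratic hitting 8.3 at exactly 2000
  b <- 8.3 / 2000^2
  fit <- pq_fit(pressure_flow_curve(Q, b * Q^2))
  expect_equal(threshold_flow(fit, 8.3), 2000, tolerance = 1e-6)
  # generic back-substitution
  fit2 <- pq_fit(pressure_flow_curve(Q, 0.002 * Q + 2e-6 * Q^2))
  q8 <- threshold_flow(fit2, 8.3)
  expect_equal(predict(fit2, q8), 8.3, tolerance = 1e-9)
  expect_error(threshold_flow(fit2, -1), "> 0")
})

test_that("a shallow linear model never reaches the threshold in range", {
  Q <- default_flow_grid()
  fit <- pq_fit(pressure_flow_curve(Q, 0.0036 * Q))   # 7.2 mmHg at 2000
  expect_equal(threshold_flow(fit, 8.3, max_flow = 2000), Inf)
  expect_true(is.finite(threshold_flow(fit, 8.3)))    # unbounded range: finite
})

test_that("threshold flow is strictly decreasing in the quadratic coefficient", {
  Q <- default_flow_grid()
  th <- sapply(c(1e-6, 2e-6, 4e-6, 8e-6), function(b)
    threshold_flow(pq_fit(pressure_flow_curve(Q, 0.002 * Q + b * Q^2)), 8.3))
  expect_true(all(diff(th) < 0))
})

test_that("hyperemia arithmetic separates the linear and quadratic models", {
  cmp <- compare_hyperemia_models()
  lin <- cmp[cmp$model == "linear", ]
  expect_equal(lin$increase, 1.575, tolerance = 1e-12)
  expect_equal(lin$increase_rounded, 1.6)
  expect_false(lin$induces_iih)
  # factor 1: no increase
  expect_equal(compare_hyperemia_models(factor = 1)$increase, 0)
  # pure quadratic: drop scales by factor^2
  Q <- default_flow_grid()
  fitq <- pq_fit(pressure_flow_curve(Q, 2e-6 * Q^2))
  cmpq <- compare_hyperemia_models(fitq, baseline_drop = 4.5, factor = 1.35)
  quad <- cmpq[cmpq$model == "quadratic", ]
  expect_equal(quad$increase, 4.5 * (1.35^2 - 1), tolerance = 1e-6)
  # +3.70 mmHg: just short of the 3.8 mmHg requirement at exactly 35%
  expect_false(quad$induces_iih)
  expect_gt(quad$increase, lin$increase)
})

test_that("curve CSV round trip preserves the data", {
  cv <- pressure_flow_curve(c(200, 400, 600), c(0.8, 2.1, 4.0))
  p <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cv, p)
  back <- read_curve_csv(p)
  expect_equal(back$flow, cv$flow)
  expect_equal(back$drop, cv$drop)
})

test_that("pq_fit methods are coherent", {
  tr <- calibrate_tree(average_tree())
  fit <- pq_fit(flow_sweep(tr))
  expect_equal(unname(coef(fit)[["a"]]), fit$a)
  expect_equal(fitted(fit) + residuals(fit), fit$curve$drop, tolerance = 1e-12)
  expect_equal(predict(fit, fit$curve$flow), fitted(fit))
  s <- summary(fit)
  expect_s3_class(s, "summary.pq_fit")
  expect_output(print(fit), "Pearson r")
})
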