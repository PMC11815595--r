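test_that("RK4 reproduces the exponential closed form", {
  out <- integrate_rk4(function(t, y) c(x = 0.3 * y[["x"]]), c(x = 7),
                       0, 1, 0.01)
  expect_equal(out$x[nrow(out)], 7 * exp(0.3), tolerance = 1e-9)
  # zero vector field: state constant
  outz <- integrate_rk4(function(t, y) c(a = 0, b = 0), c(a = 2, b = -1),
                        0, 5, 0.1)
  expect_true(all(outz$a == 2) && all(outz$b == -1))
})

test_that("RK4 global error shrinks ~16x on step halving (4th order)", {
  err <- vapply(c(0.02, 0.01), function(h) {
    out <- integrate_rk4(function(t, y) c(x = 0.9 * y[["x"]]), c(x = 1),
                         0, 2, h)
    abs(out$x[nrow(out)] - exp(0.9 * 2))
  }, numeric(1))
  expect_gt(err[1] / err[2], 13)
  expect_lt(err[1] / err[2], 19)
})

test_that("RK4 validates steps and flags non-finite derivatives", {
  expect_error(integrate_rk4(function(t, y) c(x = 1), c(x = 0), 0, 1, -0.1),
               "dt")
  expect_error(integrate_rk4(function(t, y) c(x = 1), c(x = 0), 1, 1, 0.1),
               "tf")
  expect_error(
    integrate_rk4(function(t, y) c(x = if (t > 0.5) NaN else 1), c(x = 0),
                  0, 1, 0.1),
    "non-finite derivative at t")
})

test_that("batch trajectories deplete substrates monotonically", {
  tr <- simulate_batch(p_ms, "monod_sigmoid", init_std, tf = 20, dt = 0.01)
  expect_true(all(diff(tr$sucrose_g_L) <= 1e-12))
  expect_true(all(diff(tr$kno3_g_L) <= 1e-12))
  expect_true(all(diff(tr$biomass_gDW_L) >= -1e-12))
  expect_true(all(tr$biomass_gDW_L >= 0) && all(tr$sucrose_g_L >= 0) &&
                all(tr$kno3_g_L >= 0))
  # nitrate-limited plateau stays below the conservation bound
  # x0 + Y2 * s2(0) = 7 + 7.71 * 2.1
  plateau <- tr$biomass_gDW_L[nrow(tr)]
  expect_lt(plateau, 7 + 7.71 * 2.1)
  expect_gt(plateau, 0.9 * (7 + 7.71 * 2.1))
})

test_that("without maintenance both substrate pools are first integrals", {
  tr <- simulate_batch(p_nomaint, "monod_sigmoid", init_std, tf = 12,
                       dt = 0.01)
  c1 <- tr$biomass_gDW_L + unclass(p_nomaint)[["y_xs1"]] * tr$sucrose_g_L
  c2 <- tr$biomass_gDW_L + unclass(p_nomaint)[["y_xs2"]] * tr$kno3_g_L
  expect_lt(max(abs(c1 - c1[1])) / c1[1], 1e-6)
  expect_lt(max(abs(c2 - c2[1])) / c2[1], 1e-6)
})

test_that("growth requires both substrates", {
  tr <- simulate_batch(p_ms, "monod_sigmoid", culture_state(7, 0, 2.1, 1.2),
                       tf = 5, dt = 0.01)
  expect_equal(tr$biomass_gDW_L, rep(7, nrow(tr)))
})

test_that("trajectory output is step-size independent at the default", {
  a <- simulate_batch(p_ms, "monod_sigmoid", init_std, tf = 20, dt = 0.01)
  b <- simulate_batch(p_ms, "monod_sigmoid", init_std, tf = 20, dt = 0.005)
  xa <- a$biomass_gDW_L[nrow(a)]
  xb <- b$biomass_gDW_L[nrow(b)]
  expect_lt(abs(xa - xb) / xb, 1e-5)
})

test_that("specialised core agrees with the generic RK4 over batch_rhs", {
  rhs <- function(t, st) batch_rhs(p_ms, "monod_sigmoid", st)
  gen <- integrate_rk4(rhs, unclass(init_std), 0, 10, 0.05)
  spec <- simulate_batch(p_ms, "monod_sigmoid", init_std, tf = 10, dt = 0.05)
  expect_equal(gen$x[nrow(gen)], spec$biomass_gDW_L[nrow(spec)],
               tolerance = 1e-10)
  expect_equal(gen$s1[nrow(gen)], spec$sucrose_g_L[nrow(spec)],
               tolerance = 1e-10)
})

test_that("batch integration agrees with an adaptive reference solver", {
  rhs <- function(t, st, parms) {
    list(unname(batch_rhs(p_ms, "monod_sigmoid",
                          c(x = st[[1]], s1 = max(st[[2]], 0),
                            s2 = max(st[[3]], 0), v = st[[4]]))))
  }
  ref <- deSolve::ode(unclass(init_std), c(0, 10), rhs, NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-10)
  mine <- simulate_batch(p_ms, "monod_sigmoid", init_std, tf = 10, dt = 0.01)
  expect_equal(mine$biomass_gDW_L[nrow(mine)], unname(ref[nrow(ref), "x"]),
               tolerance = 1e-5)
})

test_that("fed-batch with zero flow is the batch trajectory", {
  feed0 <- feed_strategy(1.2, 10, 17, flow = 0, feed_s1 = 250, feed_s2 = 15)
  fb <- simulate_fedbatch(p_ms, "monod_sigmoid", feed0, dt = 0.01)
  b <- simulate_batch(p_ms, "monod_sigmoid", vo_initial_state(1.2), tf = 17,
                      dt = 0.01)
  expect_equal(fb$biomass_gDW_L[nrow(fb)], b$biomass_gDW_L[nrow(b)],
               tolerance = 1e-12)
  expect_equal(fb$volume_L, rep(1.2, nrow(fb)))
})

test_that("fed-batch volume grows linearly through the feed window", {
  fb <- simulate_fedbatch(p_ms, "monod_sigmoid", vo_feed_strategy(),
                          dt = 0.01)
  expect_equal(fb$volume_L[nrow(fb)], 1.2 + 0.072 * 7, tolerance = 1e-9)
  before <- fb$volume_L[fb$time_d <= 10]
  expect_true(all(abs(before - 1.2) < 1e-12))
})

test_that("total biomass obeys d(VX)/dt = mu V X along a fed-batch run", {
  fb <- simulate_fedbatch(p_ms, "monod_sigmoid", vo_feed_strategy(),
                          dt = 0.01)
  vx <- fb$volume_L * fb$biomass_gDW_L
  mu <- specific_growth_rate(p_ms, "monod_sigmoid", fb$sucrose_g_L,
                             fb$kno3_g_L)
  dt <- diff(fb$time_d)
  lhs <- diff(vx) / dt
  mid <- (mu * vx)[-length(vx)] / 2 + (mu * vx)[-1] / 2
  expect_lt(max(abs(lhs - mid) / max(vx)), 1e-3)
})

test_that("substrate totals account for uptake plus feed inflow", {
  fb <- simulate_fedbatch(p_ms, "monod_sigmoid", vo_feed_strategy(),
                          dt = 0.01)
  in_window <- fb$time_d > 10 & fb$time_d < 17
  vs1 <- fb$volume_L * fb$sucrose_g_L
  mu <- specific_growth_rate(p_ms, "monod_sigmoid", fb$sucrose_g_L,
                             fb$kno3_g_L)
  p <- unclass(p_ms)
  expected <- -(mu / p[["y_xs1"]] + p[["m_s1"]]) * fb$biomass_gDW_L *
    fb$volume_L + 0.072 * 250
  dvdt <- diff(vs1) / diff(fb$time_d)
  midexp <- (expected[-length(expected)] + expected[-1]) / 2
  idx <- which(in_window[-1] & in_window[-length(in_window)] &
                 fb$sucrose_g_L[-1] > 0.5)
  expect_lt(max(abs(dvdt[idx] - midexp[idx])), 0.5)
})

test_that("trajectory CSV writer emits the standard header", {
  tr <- simulate_batch(p_ms, "monod_sigmoid", init_std, tf = 2, dt = 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  expect_identical(readLines(path, n = 1),
                   "time_d,biomass_gDW_L,sucrose_g_L,kno3_g_L,volume_L")
})
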