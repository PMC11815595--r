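test_that("Luong factor matches hand arithmetic and clamps at the ceiling", {
  expect_identical(luong_factor(0, 179.24, 0.60), 1)
  expect_identical(luong_factor(179.24, 179.24, 0.60), 0)
  expect_identical(luong_factor(200, 179.24, 0.60), 0)
  # frozen hand evaluation of (1 - 45.6/179.24)^0.60
  expect_equal(luong_factor(45.6, 179.24, 0.60), 0.838496, tolerance = 1e-6)
  expect_error(luong_factor(-1, 10, 1), "non-negative")
  expect_error(luong_factor(1, 0, 1), "positive")
  expect_error(luong_factor(1, 10, -1), "non-negative")
})

test_that("specific growth rate reproduces the hand-evaluated kernel", {
  expect_identical(specific_growth_rate(p_ms, "monod_sigmoid", 0, 2.1), 0)
  # nitrate at its ceiling forces zero growth
  expect_identical(specific_growth_rate(p_ms, "monod_sigmoid", 45.6, 16.14), 0)
  # frozen: 0.37 * 45.6/(45.6+14.16) * Hill(2.1; 0.17, 2.74) * Luong terms
  expect_equal(specific_growth_rate(p_ms, "monod_sigmoid", 45.6, 2.1),
               0.203723, tolerance = 1e-5)
  expect_error(specific_growth_rate(p_ms, "monod_sigmoid", -1, 1),
               "non-negative")
})

test_that("growth rate is bounded by [0, mu_max] and zero at/above ceilings", {
  grid <- expand.grid(s1 = c(0, 1, 20, 45.6, 100, 179.24, 250),
                      s2 = c(0, 0.1, 2.1, 8, 16.14, 30))
  for (m in c("monod", "monod_sigmoid", "sigmoid")) {
    p <- vo_batch_params(m)
    mu <- mapply(function(a, b) specific_growth_rate(p, m, a, b),
                 grid$s1, grid$s2)
    expect_true(all(mu >= 0))
    expect_true(all(mu <= unclass(p)[["mu_max"]] + 1e-12))
    at_ceiling <- grid$s1 >= unclass(p)[["s_m1"]] |
      grid$s2 >= unclass(p)[["s_m2"]]
    expect_true(all(mu[at_ceiling] == 0))
  }
})

test_that("growth rate rises with substrate below the inhibition onset", {
  s1 <- seq(0, 10, by = 0.5)  # far below s_m1, Monod-dominated region
  mu <- specific_growth_rate(p_ms, "monod_sigmoid", s1, 2.1)
  expect_true(all(diff(mu) > 0))
  s2 <- seq(0, 0.5, by = 0.05)
  mu2 <- specific_growth_rate(p_ms, "monod_sigmoid", 45.6, s2)
  expect_true(all(diff(mu2) > 0))
})

test_that("Hill exponents of one collapse the kernels onto Monod", {
  p1 <- as_kinetic_params(replace(unclass(p_ms), c("n1", "n2"), 1))
  s1 <- c(1, 10, 45.6, 120)
  s2 <- c(0.1, 1, 2.1, 10)
  expect_equal(specific_growth_rate(p1, "monod_sigmoid", s1, s2),
               specific_growth_rate(p1, "monod", s1, s2))
  expect_equal(specific_growth_rate(p1, "sigmoid", s1, s2),
               specific_growth_rate(p1, "monod", s1, s2))
})

test_that("uptake rates follow -(mu/Y + m) x with maintenance consuming", {
  expect_equal(uptake_rates(p_ms, mu = 0, x = 0),
               c(ds1_dt = 0, ds2_dt = 0))
  # maintenance-only: -m_s * x with the published maintenance coefficients
  expect_equal(uptake_rates(p_ms, mu = 0, x = 10),
               c(ds1_dt = -0.6, ds2_dt = -2.88e-3))
  p <- kinetic_params(y_xs1 = 0.5, y_xs2 = 1, mu_max = 1, k_s1 = 1, k_s2 = 1)
  expect_equal(uptake_rates(p, mu = 0.2, x = 10)[["ds1_dt"]], -4)
  expect_error(uptake_rates(p_ms, mu = -1, x = 1), "non-negative")
})

test_that("batch vector field: dead culture is stationary, yields cancel", {
  d0 <- batch_rhs(p_ms, "monod_sigmoid", culture_state(0, 45.6, 2.1, 1.2))
  expect_equal(unname(d0), c(0, 0, 0, 0))
  # with zero maintenance, d(x + Y1 s1)/dt = 0 along the field
  st <- culture_state(7, 45.6, 2.1, 1.5)
  d <- batch_rhs(p_nomaint, "monod_sigmoid", st)
  expect_equal(d[["x"]] + unclass(p_nomaint)[["y_xs1"]] * d[["s1"]], 0,
               tolerance = 1e-12)
  expect_equal(d[["x"]] + unclass(p_nomaint)[["y_xs2"]] * d[["s2"]], 0,
               tolerance = 1e-12)
  # dx/dt = mu * x at the inoculation state (frozen mu oracle)
  expect_equal(batch_rhs(p_ms, "monod_sigmoid", st)[["x"]], 7 * 0.203723,
               tolerance = 1e-4)
})

test_that("fed-batch field reduces to batch at zero flow and dilutes mass", {
  st <- culture_state(10, 20, 1, 1.2)
  feed0 <- feed_strategy(1.2, 10, 17, flow = 0, feed_s1 = 250, feed_s2 = 15)
  expect_equal(fedbatch_rhs(p_ms, "monod_sigmoid", st, feed0, t = 12),
               batch_rhs(p_ms, "monod_sigmoid", st))
  feed <- feed_strategy(1.2, 10, 17, flow = 0.072, feed_s1 = 250,
                        feed_s2 = 15)
  d <- fedbatch_rhs(p_ms, "monod_sigmoid", st, feed, t = 12)
  # D = F/V = 0.072/1.2 = 0.06; total biomass obeys d(VX)/dt = mu V X
  mu <- specific_growth_rate(p_ms, "monod_sigmoid", 20, 1)
  v <- 1.2
  expect_equal(v * d[["x"]] + 10 * d[["v"]], mu * v * 10, tolerance = 1e-12)
  expect_equal(d[["x"]], mu * 10 - 0.06 * 10)
  # outside the window the feed is off
  expect_equal(fedbatch_rhs(p_ms, "monod_sigmoid", st, feed, t = 5),
               batch_rhs(p_ms, "monod_sigmoid", st))
})

test_that("constructors reject unphysical inputs", {
  expect_error(kinetic_params(y_xs1 = 0, y_xs2 = 1, mu_max = 1,
                              k_s1 = 1, k_s2 = 1), "positive")
  expect_error(culture_state(-1, 1, 1, 1), "non-negative")
  expect_error(culture_state(1, 1, 1, 0), "positive")
  expect_error(feed_strategy(1.2, 10, 9, 0.1, 250, 15), "t_feed_start")
  expect_error(model_type("hill"), "unknown model")
})

test_that("free-parameter counts follow the kernels", {
  expect_identical(n_free_parameters("monod"), 11L)
  expect_identical(n_free_parameters("monod_sigmoid"), 12L)
  expect_identical(n_free_parameters("sigmoid"), 13L)
  expect_false("n2" %in% free_parameters("monod"))
  expect_false("n1" %in% free_parameters("monod_sigmoid"))
})
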