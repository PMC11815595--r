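make_point_data <- function(time_d, species, value, reps = 1) {
  tibble::tibble(time_d = rep(time_d, reps), species = species,
                 replicate = seq_len(reps), value = value)
}

test_that("objective is zero on self-generated data and follows weights", {
  spec <- synthetic_spec(p_ms, "monod_sigmoid", noise_cv = 0, seed = 1)
  dat <- generate_batch_dataset(spec)
  expect_lt(objective(p_ms, "monod_sigmoid", dat, dt = 0.1), 1e-8)

  # single species, two points, one residual of 2: definition check.
  # The model predicts constant biomass 7 when sucrose is absent.
  dat1 <- tibble::tibble(time_d = c(0, 1), species = "biomass",
                         replicate = 1L, value = c(7, 9))
  init0 <- culture_state(7, 0, 2.1, 1)
  expect_equal(objective(p_ms, "monod_sigmoid", dat1, init = init0,
                         weights = c(biomass = 1)), 4)
  expect_equal(objective(p_ms, "monod_sigmoid", dat1, init = init0,
                         weights = c(biomass = 2)), 1)
})

test_that("objective is invariant to row order", {
  spec <- synthetic_spec(p_ms, "monod_sigmoid", noise_cv = 0.05, seed = 3)
  dat <- generate_batch_dataset(spec)
  shuffled <- dat[sample(nrow(dat)), ]
  expect_equal(objective(p_ms, "monod_sigmoid", dat, dt = 0.1),
               objective(p_ms, "monod_sigmoid", shuffled, dt = 0.1))
})

test_that("default weights are the per-species maxima", {
  dat <- dplyr::bind_rows(
    make_point_data(c(0, 1), "biomass", c(5, 20)),
    make_point_data(c(0, 1), "sucrose", c(45, 10)))
  expect_equal(default_weights(dat), c(biomass = 20, sucrose = 45))
})

test_that("Rosenbrock search solves convex, bound and banana problems", {
  bowl <- rosenbrock_minimize(function(x) sum((x - c(1, -2))^2),
                              c(4, 4), lower = -5, upper = 5)
  expect_equal(bowl$par, c(1, -2), tolerance = 1e-4)
  expect_true(bowl$converged)

  # minimum outside the box: iterates end on the boundary
  edge <- rosenbrock_minimize(function(x) sum((x - 10)^2), c(0, 0),
                              lower = -5, upper = 5)
  expect_equal(edge$par, c(5, 5), tolerance = 1e-6)

  banana <- rosenbrock_minimize(
    function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2,
    c(-1.2, 1), lower = -5, upper = 5, max_eval = 20000, tol = 1e-10)
  expect_lt(banana$value, 1e-6)
})

test_that("optimizer trace improves monotonically and tolerates NaN", {
  out <- rosenbrock_minimize(function(x) {
    if (x[1] > 2.5) NaN else sum(x^2)
  }, c(2, 2), lower = -3, upper = 3)
  expect_true(all(diff(out$trace$best) <= 0))
  expect_lt(out$value, 1e-8)
  expect_lte(out$value, sum(c(2, 2)^2))
})

test_that("fit recovers the truth from noise-free data with an oracle start", {
  spec <- synthetic_spec(p_ms, "monod_sigmoid", noise_cv = 0, seed = 11)
  dat <- generate_batch_dataset(spec)
  fit <- fit_model(dat, "monod_sigmoid", n_restarts = 1, seed = 5, dt = 0.1,
                   max_eval = 300, start = p_ms)
  expect_lt(fit$objective, 1e-8)
  expect_equal(unclass(fit$params)[["mu_max"]], 0.37, tolerance = 1e-3)
  expect_identical(fit$p, 12L)
})

test_that("fits are reproducible given the seed and report model size", {
  spec <- synthetic_spec(p_ms, "monod_sigmoid", noise_cv = 0.05, seed = 21)
  dat <- generate_batch_dataset(spec)
  f1 <- fit_model(dat, "monod_sigmoid", n_restarts = 2, seed = 9, dt = 0.2,
                  max_eval = 150)
  f2 <- fit_model(dat, "monod_sigmoid", n_restarts = 2, seed = 9, dt = 0.2,
                  max_eval = 150)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$p, 12L)
  f3 <- fit_model(dat, "sigmoid", n_restarts = 1, seed = 9, dt = 0.2,
                  max_eval = 50)
  expect_identical(f3$p, 13L)
  expect_error(fit_model(dat, "monod_sigmoid"), "seed")
})

test_that("tidy and glance summarise a fit", {
  spec <- synthetic_spec(p_ms, "monod_sigmoid", noise_cv = 0, seed = 2)
  dat <- generate_batch_dataset(spec)
  fit <- fit_model(dat, "monod_sigmoid", n_restarts = 0, seed = 1, dt = 0.2,
                   max_eval = 50, start = p_ms)
  td <- tidy(fit)
  expect_identical(nrow(td), 12L)
  expect_true(all(c("term", "estimate", "at_bound") %in% names(td)))
  g <- glance(fit)
  expect_identical(g$df, g$n - g$p)
  expect_equal(g$variance, g$objective / g$df)
})

test_that("specific growth rate is read off log-linear windows", {
  t <- 0:10
  expect_equal(as.numeric(estimate_mu_series(t, 7 * exp(0.3 * t))), 0.3,
               tolerance = 1e-10)
  expect_equal(as.numeric(estimate_mu_series(t, rep(5, 11))), 0)
  expect_error(estimate_mu_series(t, c(rep(1, 10), -1)), "positive")
  expect_error(estimate_mu_series(0:2, 1:3), "4")

  # saturating growth curve: the window picker should find the early
  # exponential phase and match the analytic rate there within 5%
  tr <- simulate_batch(p_ms, "monod_sigmoid", init_std, tf = 20, dt = 0.01)
  times <- seq(0, 20, by = 1)
  x <- approx(tr$time_d, tr$biomass_gDW_L, times)$y
  mu_hat <- estimate_mu_series(times, x)
  win <- attr(mu_hat, "window")
  wt <- times[win[1]:win[2]]
  s1 <- mean(approx(tr$time_d, tr$sucrose_g_L, wt)$y)
  s2 <- mean(approx(tr$time_d, tr$kno3_g_L, wt)$y)
  mu_ref <- specific_growth_rate(p_ms, "monod_sigmoid", s1, s2)
  expect_equal(as.numeric(mu_hat), mu_ref, tolerance = 0.05)
})

test_that("time-course validation catches malformed data", {
  expect_error(as_timecourse(tibble::tibble(time_d = 1, value = 2)),
               "lacks column")
  bad <- tibble::tibble(time_d = c(0, 1), species = "biomass",
                        replicate = 1L, value = c(1, -2))
  expect_error(as_timecourse(bad), "row")
  expect_error(as_timecourse(tibble::tibble(
    time_d = c(0, 1), species = "glucose", replicate = 1L, value = 1)),
    "unknown species")
})
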