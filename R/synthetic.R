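#' Specification of a synthetic batch experiment
#'
#' Describes the simulated counterpart of the kinetic experiments: a batch
#' culture sampled every `sampling_interval` days for `horizon` days in
#' `replicates` replicates, with multiplicative Gaussian measurement noise
#' of coefficient of variation `noise_cv`. Defaults mirror the study design
#' (daily sampling for 20 d, triplicates); the 5 percent CV is a
#' conservative stand-in for the reported triplicate scatter (roughly 4
#' percent on final biomass).
#'
#' @param true_params Ground-truth [kinetic_params()].
#' @param model Model type label.
#' @param init Inoculation [culture_state()].
#' @param sampling_interval Sampling interval, d.
#' @param horizon Experiment duration, d.
#' @param replicates Replicates per time point (>= 1).
#' @param noise_cv Noise coefficient of variation (>= 0).
#' @param seed Integer seed (mandatory).
#' @return A list of class `vk_synth_spec`.
#' @export
synthetic_spec <- function(true_params, model = "monod_sigmoid",
                           init = vo_initial_state(), sampling_interval = 1,
                           horizon = 20, replicates = 3, noise_cv = 0.05,
                           seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for synthetic data generation", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (replicates < 1) stop("need >= 1 replicate", call. = FALSE)
  if (sampling_interval <= 0 || horizon <= sampling_interval) {
    stop("need 0 < sampling_interval < horizon", call. = FALSE)
  }
  validate_state(init)
  structure(list(true_params = as_kinetic_params(true_params),
                 model = model_type(model), init = init,
                 sampling_interval = sampling_interval, horizon = horizon,
                 replicates = replicates, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "vk_synth_spec")
}

#' Generate a noisy synthetic batch time-course dataset
#'
#' Simulates the ground-truth trajectory, samples all three species on the
#' regular grid, and perturbs each measurement with multiplicative Gaussian
#' noise (`sd = noise_cv * value`), truncated at zero. Deterministic given
#' the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param dt Integration step for the ground-truth simulation, d.
#' @return A long-format time-course tibble (`time_d`, `species`,
#'   `replicate`, `value`) with the ground truth attached as attributes
#'   `true_params` and `model`.
#' @export
generate_batch_dataset <- function(spec, dt = 0.01) {
  stopifnot(inherits(spec, "vk_synth_spec"))
  tr <- simulate_batch(spec$true_params, spec$model, spec$init,
                       tf = spec$horizon, dt = dt)
  times <- seq(0, spec$horizon, by = spec$sampling_interval)
  clean <- tidyr::expand_grid(time_d = times,
                              species = c("biomass", "sucrose", "kno3"),
                              replicate = seq_len(spec$replicates))
  clean$value <- dplyr::case_when(
    clean$species == "biomass" ~
      interp_trajectory(tr, "biomass_gDW_L", clean$time_d),
    clean$species == "sucrose" ~
      interp_trajectory(tr, "sucrose_g_L", clean$time_d),
    TRUE ~ interp_trajectory(tr, "kno3_g_L", clean$time_d)
  )
  clean$value <- pmax(clean$value, 0)  # spline undershoot near depletion
  noisy <- with_seed(spec$seed, {
    eps <- stats::rnorm(nrow(clean), mean = 0, sd = 1)
    pmax(clean$value * (1 + spec$noise_cv * eps), 0)
  })
  out <- dplyr::mutate(clean, value = noisy)
  out <- as_timecourse(out)
  attr(out, "true_params") <- spec$true_params
  attr(out, "model") <- spec$model
  out
}

#' Simulated substrate-inhibition series
#'
#' Emulates the shake-flask inhibition experiments: one batch per initial
#' substrate level (sucrose levels at the reference nitrate concentration
#' and vice versa), sampled every `sampling_interval` days, with the
#' specific growth rate estimated from each simulated biomass curve via
#' [estimate_mu_series()] — the same reduction applied to the flask data,
#' rather than evaluating the growth law analytically.
#'
#' @param params A [kinetic_params()] vector.
#' @param model Model type label.
#' @param s1_levels Initial sucrose levels, g L^-1 (default the experimental
#'   set 45, 75, 105, 145).
#' @param s2_levels Initial KNO3 levels, g L^-1 (default 2, 4, 8, 12).
#' @param ref_state Reference [culture_state()] supplying the inoculum and
#'   the non-varied substrate concentration.
#' @param sampling_interval Sampling interval, d (default 2, as in the flask
#'   harvests).
#' @param horizon Duration, d.
#' @param dt Integration step, d.
#' @return A tibble `substrate`, `level`, `mu_hat` (d^-1).
#' @export
generate_inhibition_series <- function(params, model,
                                       s1_levels = c(45, 75, 105, 145),
                                       s2_levels = c(2, 4, 8, 12),
                                       ref_state = vo_initial_state(),
                                       sampling_interval = 2, horizon = 20,
                                       dt = 0.01) {
  if (any(s1_levels <= 0) || any(s2_levels <= 0)) {
    stop("substrate levels must be positive", call. = FALSE)
  }
  one <- function(substrate, level) {
    st <- ref_state
    if (substrate == "sucrose") st[["s1"]] <- level else st[["s2"]] <- level
    tr <- simulate_batch(params, model, culture_state(st[["x"]], st[["s1"]],
                                                      st[["s2"]], st[["v"]]),
                         tf = horizon, dt = dt)
    times <- seq(0, horizon, by = sampling_interval)
    x <- pmax(interp_trajectory(tr, "biomass_gDW_L", times), 1e-12)
    tibble::tibble(substrate = substrate, level = level,
                   mu_hat = as.numeric(estimate_mu_series(times, x)))
  }
  dplyr::bind_rows(
    purrr::map_dfr(s1_levels, ~ one("sucrose", .x)),
    purrr::map_dfr(s2_levels, ~ one("kno3", .x))
  )
}

#' Parameter-recovery simulation study
#'
#' Generates noisy synthetic batch datasets at each noise level, refits the
#' model to each, and reports per-parameter relative errors together with
#' bias and RMSE summaries. The ground truth is always included among the
#' optimizer starting points so that the noise-free case recovers the truth
#' to integrator tolerance.
#'
#' @param true_params Ground-truth [kinetic_params()].
#' @param model Model type label.
#' @param noise_levels Numeric vector of noise CVs (e.g. `c(0, 0.02, 0.05)`).
#' @param n_reps Replicate datasets per noise level.
#' @param seed Integer seed driving the whole study.
#' @param init Inoculation state.
#' @param n_restarts Random restarts per fit (on top of the truth start).
#' @param max_eval Objective-evaluation budget per start.
#' @param dt Integration step used in fitting, d.
#' @return A list with `results` (one row per noise level x rep x free
#'   parameter: `noise_cv`, `rep`, `parameter`, `true`, `estimated`,
#'   `rel_error`, `objective`, `fit_ok`) and `summary` (bias and RMSE of the
#'   relative error per noise level and parameter).
#' @export
recovery_experiment <- function(true_params, model, noise_levels = c(0, 0.02, 0.05),
                                n_reps = 1, seed, init = vo_initial_state(),
                                n_restarts = 2, max_eval = 600, dt = 0.1) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  if (n_reps < 1) stop("need n_reps >= 1", call. = FALSE)
  true_params <- as_kinetic_params(true_params)
  free <- free_parameters(model)
  grid <- tidyr::expand_grid(noise_cv = noise_levels, rep = seq_len(n_reps))
  results <- purrr::pmap_dfr(grid, function(noise_cv, rep) {
    sub_seed <- (seed + 7919L * rep + round(1e4 * noise_cv)) %% .Machine$integer.max
    spec <- synthetic_spec(true_params, model, init, noise_cv = noise_cv,
                           seed = sub_seed)
    dat <- generate_batch_dataset(spec)
    fit <- tryCatch(
      fit_model(dat, model, init = init, n_restarts = n_restarts,
                seed = sub_seed, dt = dt, max_eval = max_eval,
                start = true_params),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(noise_cv = noise_cv, rep = rep, parameter = free,
                            true = unclass(true_params)[free],
                            estimated = NA_real_, rel_error = NA_real_,
                            objective = NA_real_, fit_ok = FALSE))
    }
    est <- unclass(fit$params)[free]
    tru <- unclass(true_params)[free]
    tibble::tibble(noise_cv = noise_cv, rep = rep, parameter = free,
                   true = unname(tru), estimated = unname(est),
                   rel_error = unname((est - tru) / tru),
                   objective = fit$objective, fit_ok = TRUE)
  })
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$noise_cv, .data$parameter),
    bias = mean(.data$rel_error),
    rmse = sqrt(mean(.data$rel_error^2)),
    n_ok = sum(.data$fit_ok),
    .groups = "drop")
  list(results = results, summary = summary)
}
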