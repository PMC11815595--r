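#' Validate a time-course dataset
#'
#' The tabular exchange format used throughout the package: one row per
#' measurement with columns `time_d`, `species` (one of `biomass`,
#' `sucrose`, `kno3`), `replicate`, `value`.
#'
#' @param data A data frame in long time-course format.
#' @return The validated tibble (rows ordered by species, time, replicate).
#' @export
as_timecourse <- function(data) {
  req <- c("time_d", "species", "replicate", "value")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("time-course data lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_sp <- setdiff(unique(data$species), c("biomass", "sucrose", "kno3"))
  if (length(bad_sp)) {
    stop("unknown species: ", paste(bad_sp, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(data$value)) || any(data$value < 0)) {
    bad <- which(!is.finite(data$value) | data$value < 0)
    stop("negative or non-finite measurement at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(data$time_d < 0)) stop("times must be non-negative", call. = FALSE)
  counts <- dplyr::count(dplyr::distinct(data, .data$species, .data$time_d),
                         .data$species)
  if (any(counts$n < 2)) {
    stop("each species needs measurements at >= 2 time points", call. = FALSE)
  }
  dplyr::arrange(tibble::as_tibble(data), .data$species, .data$time_d,
                 .data$replicate)
}

#' Default weights for the least-squares objective
#'
#' One weight per species: the maximum observed value of that species, so
#' that residuals of biomass (tens of g DW L^-1) and nitrate (a few g L^-1)
#' contribute on comparable scales.
#'
#' @param data A time-course dataset.
#' @return Named numeric vector of weights, one per species present.
#' @export
default_weights <- function(data) {
  data <- as_timecourse(data)
  w <- dplyr::summarise(dplyr::group_by(data, .data$species),
                        w = max(.data$value), .groups = "drop")
  stats::setNames(w$w, w$species)
}

#' Weighted least-squares objective for a candidate parameter vector
#'
#' Simulates a batch trajectory from `init`, interpolates the predicted
#' concentrations at the measurement times, and returns
#' `sum_ij ((c_ij - chat_ij) / W_j)^2` over all measurements i of all
#' species j.
#'
#' @param params A [kinetic_params()] vector.
#' @param model Model type label.
#' @param data Time-course dataset (long format, see [as_timecourse()]).
#' @param init Inoculation [culture_state()].
#' @param dt Integration step for the model prediction, d.
#' @param weights Named per-species weights; default [default_weights()].
#' @return The weighted SSE (dimensionless scalar, >= 0).
#' @export
objective <- function(params, model, data, init = vo_initial_state(),
                      dt = 0.1, weights = NULL) {
  data <- as_timecourse(data)
  if (is.null(weights)) weights <- default_weights(data)
  if (any(weights <= 0)) stop("weights must be strictly positive",
                              call. = FALSE)
  make_objective_fn(data, model, init, dt, weights)(params)
}

# Pre-digest the dataset into per-species numeric vectors and return a lean
# weighted-SSE closure; this is the function the optimizer hammers.
make_objective_fn <- function(data, model, init, dt, weights) {
  tf <- max(data$time_d)
  per_species <- lapply(split(data, data$species), function(d) {
    list(species = d$species[1], times = d$time_d, values = d$value,
         w2 = weights[[d$species[1]]]^2)
  })
  function(params) {
    core <- sim_core(params, model, init, tf, dt, feed = NULL)
    total <- 0
    for (sp in per_species) {
      col <- switch(sp$species, biomass = 1L, sucrose = 2L, kno3 = 3L)
      pred <- stats::spline(core$time, core$states[, col], xout = sp$times,
                            method = "fmm")$y
      total <- total + sum((sp$values - pred)^2) / sp$w2
    }
    total
  }
}

col_for_species <- c(biomass = "biomass_gDW_L", sucrose = "sucrose_g_L",
                     kno3 = "kno3_g_L")

objective_residuals <- function(trajectory, data, weights) {
  dplyr::bind_rows(lapply(split(data, data$species), function(d) {
    sp <- d$species[1]
    pred <- interp_trajectory(trajectory, col_for_species[[sp]], d$time_d)
    dplyr::mutate(d, predicted = pred,
                  residual = .data$value - pred,
                  wres = (.data$value - pred) / weights[[sp]])
  }))
}

#' Rosenbrock rotating-directions minimisation under box bounds
#'
#' The classic derivative-free method: trial steps along an orthonormal
#' direction set, step expansion (x3) on success and reversal-contraction
#' (x -0.5) on failure; once every direction has seen at least one success
#' followed by a failure, the direction set is re-orthogonalised
#' (Gram-Schmidt) around the stage's total displacement and the cycle
#' restarts. Trial points are projected onto the box, so iterates stay
#' feasible. Terminates when all step sizes fall below `tol` or the
#' evaluation budget is exhausted.
#'
#' @param f Scalar objective; `NaN` returns are treated as failed steps.
#' @param x0 Numeric start, within bounds.
#' @param lower,upper Box bounds (recycled to `length(x0)`).
#' @param step0 Initial step sizes as a fraction of the box width (or
#'   absolute for unbounded directions).
#' @param tol Convergence tolerance on the step sizes.
#' @param max_eval Budget of objective evaluations.
#' @return A list with elements `par`, `value`, `trace` (tibble of best
#'   value per evaluation), `evaluations` and `converged`.
#' @export
#' @examples
#' out <- rosenbrock_minimize(function(x) sum((x - 2)^2), c(0, 0),
#'                            lower = -5, upper = 5)
#' out$par
rosenbrock_minimize <- function(f, x0, lower = -Inf, upper = Inf,
                                step0 = 0.1, tol = 1e-8, max_eval = 5000) {
  n <- length(x0)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (any(x0 < lower - 1e-12) || any(x0 > upper + 1e-12)) {
    stop("x0 must lie within the bounds", call. = FALSE)
  }
  clip <- function(x) pmin(pmax(x, lower), upper)
  x <- clip(x0)
  width <- ifelse(is.finite(upper - lower), upper - lower, 1)
  h0 <- step0 * width
  h <- h0
  dirs <- diag(n)

  evals <- 0L
  fx <- f(x)
  evals <- evals + 1L
  if (!is.finite(fx)) stop("objective not finite at the start", call. = FALSE)
  best_trace <- numeric(max_eval + 1L)
  best_trace[1] <- fx

  success <- rep(FALSE, n)   # at least one success in this stage
  failed <- rep(FALSE, n)    # failure after a success
  lambda <- rep(0, n)        # accumulated successful displacement per direction
  x_stage <- x

  while (evals < max_eval && any(abs(h) > tol)) {
    for (i in seq_len(n)) {
      if (evals >= max_eval) break
      xt <- clip(x + h[i] * dirs[, i])
      moved <- any(xt != x)
      ft <- if (moved) f(xt) else Inf  # projection pinned at the bound
      if (moved) evals <- evals + 1L
      if (is.na(ft)) ft <- Inf
      if (ft <= fx) {
        lambda[i] <- lambda[i] + h[i]
        x <- xt
        fx <- ft
        h[i] <- sign(h[i]) * min(3 * abs(h[i]), max(width))
        success[i] <- TRUE
      } else {
        h[i] <- -0.5 * h[i]
        if (success[i]) failed[i] <- TRUE
      }
      best_trace[evals] <- fx
    }
    if (all(success & failed)) {
      # stage complete: rebuild directions around the total displacement
      a <- matrix(0, n, n)
      for (i in seq_len(n)) {
        a[, i] <- dirs[, i:n, drop = FALSE] %*% lambda[i:n]
      }
      move <- a[, 1]
      if (sqrt(sum(move^2)) > 1e-14) {
        new_dirs <- matrix(0, n, n)
        for (i in seq_len(n)) {
          v <- a[, i]
          if (i > 1) {
            proj <- new_dirs[, seq_len(i - 1), drop = FALSE]
            v <- v - proj %*% crossprod(proj, a[, i])
          }
          nv <- sqrt(sum(v^2))
          new_dirs[, i] <- if (nv > 1e-14) v / nv else dirs[, i]
        }
        dirs <- new_dirs
      }
      h <- pmax(abs(h0) * 1e-3, pmin(abs(h), abs(h0)))
      success[] <- FALSE
      failed[] <- FALSE
      lambda[] <- 0
      x_stage <- x
    }
  }
  trace <- tibble::tibble(evaluation = seq_len(evals),
                          best = cummin(best_trace[seq_len(evals)]))
  list(par = x, value = fx, trace = trace, evaluations = evals,
       converged = all(abs(h) <= tol))
}

#' Fit a growth model to time-course data
#'
#' Weighted least-squares estimation of the model's free parameters under
#' the box bounds, by Rosenbrock search from `n_restarts` Latin-hypercube
#' starting points (plus the box midpoint). Deterministic given `seed`.
#' Parameters the chosen kernel does not use (`n1`, `n2` under Monod) are
#' held at 1 and not searched.
#'
#' @param data Time-course dataset (long format).
#' @param model Model type label.
#' @param bounds Bounds tibble (`parameter`, `lower`, `upper`); defaults to
#'   [vo_parameter_bounds()].
#' @param init Inoculation [culture_state()].
#' @param n_restarts Number of Latin-hypercube starts.
#' @param seed Integer seed (required: the multi-start is stochastic).
#' @param dt Integration step used inside the objective, d.
#' @param weights Optional named per-species weights.
#' @param max_eval Objective-evaluation budget per start.
#' @param start Optional extra starting parameter vector(s) (a `vk_params`
#'   or list of them), searched in addition to the random starts.
#' @return A `vk_fit` object; see [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
fit_model <- function(data, model, bounds = vo_parameter_bounds(),
                      init = vo_initial_state(), n_restarts = 20, seed,
                      dt = 0.1, weights = NULL, max_eval = 800,
                      start = NULL) {
  if (missing(seed) || is.null(seed)) {
    stop("fit_model() is stochastic; an integer seed is required",
         call. = FALSE)
  }
  data <- as_timecourse(data)
  model <- model_type(model)
  bounds <- validate_bounds(bounds)
  if (is.null(weights)) weights <- default_weights(data)
  free <- free_parameters(model)
  lo <- stats::setNames(bounds$lower, bounds$parameter)[free]
  hi <- stats::setNames(bounds$upper, bounds$parameter)[free]

  full_par <- function(theta) {
    p <- stats::setNames(rep(1, 13), param_names())
    p[free] <- theta
    as_kinetic_params(p)
  }
  obj_fn <- make_objective_fn(data, model, init, dt, weights)
  obj <- function(theta) {
    tryCatch(obj_fn(full_par(theta)), error = function(e) NaN)
  }

  starts <- if (n_restarts >= 1) {
    with_seed(seed, {
      u <- lhs::randomLHS(n_restarts, length(free))
      lapply(seq_len(n_restarts), function(i) lo + u[i, ] * (hi - lo))
    })
  } else {
    list()
  }
  starts <- c(starts, list((lo + hi) / 2))
  if (!is.null(start)) {
    extra <- if (inherits(start, "vk_params") || is.numeric(start)) {
      list(start)
    } else {
      start
    }
    starts <- c(starts, lapply(extra, function(s) {
      pmin(pmax(unclass(as_kinetic_params(s))[free], lo), hi)
    }))
  }

  runs <- lapply(starts, function(x0) {
    tryCatch(rosenbrock_minimize(obj, x0, lo, hi, max_eval = max_eval),
             error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all optimisation restarts failed", call. = FALSE)
  runs <- runs[ok]
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]

  params <- full_par(best$par)
  tr <- simulate_batch(params, model, init, tf = max(data$time_d), dt = dt)
  resid <- objective_residuals(tr, data, weights)
  structure(list(
    params = params,
    model_type = model,
    objective = best$value,
    n = nrow(data),
    p = length(free),
    residuals = resid,
    weights = weights,
    bounds = bounds,
    init = init,
    dt = dt,
    n_restarts = n_restarts,
    seed = seed,
    evaluations = sum(vapply(runs, `[[`, integer(1), "evaluations")),
    converged = best$converged,
    trace = best$trace
  ), class = "vk_fit")
}

#' @export
print.vk_fit <- function(x, ...) {
  cat(sprintf("<model fit: %s | weighted SSE %.4g | n %d, p %d, df %d>\n",
              x$model_type, x$objective, x$n, x$p, x$n - x$p))
  print(x$params)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a model fit into a parameter table
#'
#' @param x A `vk_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter (`term`, `estimate`,
#'   `lower`, `upper`, `at_bound`).
#' @export
tidy.vk_fit <- function(x, ...) {
  free <- free_parameters(x$model_type)
  b <- x$bounds[match(free, x$bounds$parameter), ]
  est <- unclass(x$params)[free]
  tibble::tibble(
    term = free,
    estimate = unname(est),
    lower = b$lower,
    upper = b$upper,
    at_bound = est <= b$lower + 1e-10 | est >= b$upper - 1e-10
  )
}

#' One-row fit summary
#'
#' @param x A `vk_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `objective`, `n`, `p`, `df`, `variance`,
#'   `n_restarts`, `seed`, `converged`.
#' @export
glance.vk_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model_type,
    objective = x$objective,
    n = x$n,
    p = x$p,
    df = x$n - x$p,
    variance = model_variance(x$objective, x$n, x$p),
    n_restarts = x$n_restarts,
    seed = x$seed,
    converged = x$converged
  )
}

#' Estimate the specific growth rate from a biomass series
#'
#' Fits `ln(x)` against `t` over every contiguous window of at least
#' `min_window` points and returns the slope of the window with the highest
#' R-squared: the best-fit exponential phase. This mirrors how flask growth
#' curves are reduced to a single specific growth rate per condition.
#'
#' @param time Sampling times, d (strictly increasing, >= 4 points).
#' @param biomass Biomass concentrations, g DW L^-1 (all positive).
#' @param min_window Minimum window length (points).
#' @return The estimated specific growth rate, d^-1, with attributes
#'   `window` (index range used) and `r_squared`.
#' @export
#' @examples
#' t <- 0:10
#' estimate_mu_series(t, 7 * exp(0.3 * t))  # 0.3
estimate_mu_series <- function(time, biomass, min_window = 4) {
  if (length(time) < 4 || length(biomass) != length(time)) {
    stop("need >= 4 aligned (time, biomass) points", call. = FALSE)
  }
  if (any(biomass <= 0)) stop("biomass must be positive", call. = FALSE)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing",
                                 call. = FALSE)
  ly <- log(biomass)
  n <- length(time)
  best <- list(slope = 0, r2 = -Inf, win = c(1L, n))
  for (i in seq_len(n - min_window + 1L)) {
    for (j in seq(i + min_window - 1L, n)) {
      tt <- time[i:j]
      yy <- ly[i:j]
      sxx <- sum((tt - mean(tt))^2)
      syy <- sum((yy - mean(yy))^2)
      sxy <- sum((tt - mean(tt)) * (yy - mean(yy)))
      if (syy < 1e-20) next  # flat window: no growth signal
      r2 <- sxy^2 / (sxx * syy)
      if (r2 > best$r2) best <- list(slope = sxy / sxx, r2 = r2,
                                     win = c(i, j))
    }
  }
  if (!is.finite(best$r2)) {  # constant series everywhere
    return(structure(0, window = c(1L, n), r_squared = NA_real_))
  }
  structure(best$slope, window = best$win, r_squared = best$r2)
}

# run code under a temporary RNG state, restoring the caller's
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
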