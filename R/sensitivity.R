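#' Absolute parameter sensitivity by central differences
#'
#' `dF/dP ~ (f(P + h) - f(P - h)) / (2 h)` with `h = rel_step * P` (or
#' `fallback_step` when the parameter value is zero).
#'
#' @param response Function mapping a [kinetic_params()] vector to a scalar
#'   model response (for the standard ranking: biomass concentration at a
#'   reference time).
#' @param params The parameter vector at which to evaluate.
#' @param name Parameter to perturb.
#' @param rel_step Relative perturbation (default 0.01 = 1 percent).
#' @param fallback_step Absolute step used when the parameter is 0.
#' @return The absolute sensitivity, response units per parameter unit.
#' @export
absolute_sensitivity <- function(response, params, name, rel_step = 0.01,
                                 fallback_step = 1e-6) {
  p <- unclass(as_kinetic_params(params))
  if (!name %in% names(p)) stop("unknown parameter '", name, "'",
                                call. = FALSE)
  h <- if (p[[name]] != 0) rel_step * p[[name]] else fallback_step
  up <- p; up[[name]] <- p[[name]] + h
  dn <- p; dn[[name]] <- max(p[[name]] - h, 0)
  h_eff <- (up[[name]] - dn[[name]]) / 2
  f_up <- tryCatch(response(as_kinetic_params(up)), error = function(e) {
    stop("response failed at perturbed ", name, ": ", conditionMessage(e),
         call. = FALSE)
  })
  f_dn <- tryCatch(response(as_kinetic_params(dn)), error = function(e) {
    stop("response failed at perturbed ", name, ": ", conditionMessage(e),
         call. = FALSE)
  })
  (f_up - f_dn) / (2 * h_eff)
}

#' Relative parameter sensitivity (elasticity)
#'
#' `RPS = P * (dF/dP) / F`: the dimensionless elasticity of the response to
#' the parameter, used for ranking parameters across different units.
#'
#' @param aps Absolute sensitivity (from [absolute_sensitivity()]).
#' @param p_value The parameter value.
#' @param f_value The response value (non-zero).
#' @return The relative sensitivity (dimensionless).
#' @export
relative_sensitivity <- function(aps, p_value, f_value) {
  if (f_value == 0) stop("response value is zero: relative sensitivity undefined",
                         call. = FALSE)
  p_value * aps / f_value
}

#' Ranked local sensitivity table for a growth model
#'
#' Perturbs each free parameter of the chosen kernel by `rel_step` (central
#' differences) around `params`, taking the simulated biomass concentration
#' at `t_ref` as the model response, and ranks parameters by the magnitude
#' of their relative sensitivity.
#'
#' @param params A [kinetic_params()] vector (typically a fitted one).
#' @param model Model type label.
#' @param init Inoculation [culture_state()].
#' @param t_ref Response time, d (default: end of the 20-day batch).
#' @param rel_step Relative perturbation.
#' @param dt Integration step, d.
#' @return A tibble `parameter`, `value`, `aps`, `rps`, `rank`, ordered by
#'   decreasing `abs(rps)`.
#' @export
#' @examples
#' sensitivity_table(vo_batch_params(), "monod_sigmoid", t_ref = 20,
#'                   dt = 0.05)
sensitivity_table <- function(params, model, init = vo_initial_state(),
                              t_ref = 20, rel_step = 0.01, dt = 0.01) {
  model <- model_type(model)
  params <- as_kinetic_params(params)
  response <- function(p) {
    tr <- simulate_batch(p, model, init, tf = t_ref, dt = dt)
    tr$biomass_gDW_L[nrow(tr)]
  }
  f0 <- response(params)
  free <- free_parameters(model)
  tbl <- purrr::map_dfr(free, function(nm) {
    aps <- absolute_sensitivity(response, params, nm, rel_step)
    tibble::tibble(parameter = nm,
                   value = unclass(params)[[nm]],
                   aps = aps,
                   rps = relative_sensitivity(aps, unclass(params)[[nm]], f0))
  })
  tbl <- dplyr::arrange(tbl, dplyr::desc(abs(.data$rps)))
  tbl$rank <- seq_len(nrow(tbl))
  structure(tbl, response = f0, t_ref = t_ref,
            class = c("vk_sensitivity", class(tbl)))
}
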