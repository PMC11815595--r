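#' Kinetic parameter vector for dual-substrate growth models
#'
#' Builds the full 13-parameter vector used by every growth kernel in the
#' package. Units follow the package-wide convention: time in days,
#' concentrations in g L^-1, biomass in g DW L^-1.
#'
#' @param y_xs1 Biomass yield on sucrose, g DW (g sucrose)^-1.
#' @param y_xs2 Biomass yield on potassium nitrate, g DW (g KNO3)^-1.
#' @param mu_max Maximum specific growth rate, d^-1.
#' @param k_s1 Sucrose half-saturation constant, g L^-1.
#' @param k_s2 Potassium nitrate half-saturation constant, g L^-1.
#' @param m_s1 Maintenance coefficient on sucrose, g sucrose (g DW)^-1 d^-1.
#' @param m_s2 Maintenance coefficient on KNO3, g KNO3 (g DW)^-1 d^-1.
#' @param s_m1 Sucrose inhibition ceiling (growth stops at or above), g L^-1.
#' @param s_m2 KNO3 inhibition ceiling, g L^-1.
#' @param n1,n2 Sigmoid (Hill-type) cooperativity exponents for sucrose and
#'   KNO3 limitation terms (dimensionless). `n1` is only used by the pure
#'   Sigmoid model, `n2` by the Sigmoid and Monod-Sigmoid models.
#' @param n3,n4 Luong inhibition exponents for sucrose and KNO3
#'   (dimensionless).
#'
#' @return A named numeric vector of class `vk_params` with the 13 fields in
#'   canonical order.
#' @export
#' @examples
#' p <- kinetic_params(y_xs1 = 0.5, y_xs2 = 7.71, mu_max = 0.37,
#'                     k_s1 = 14.16, k_s2 = 0.17)
#' p["mu_max"]
kinetic_params <- function(y_xs1, y_xs2, mu_max, k_s1, k_s2,
                           m_s1 = 0, m_s2 = 0,
                           s_m1 = Inf, s_m2 = Inf,
                           n1 = 1, n2 = 1, n3 = 1, n4 = 1) {
  p <- c(y_xs1 = y_xs1, y_xs2 = y_xs2, mu_max = mu_max,
         k_s1 = k_s1, k_s2 = k_s2, m_s1 = m_s1, m_s2 = m_s2,
         s_m1 = s_m1, s_m2 = s_m2, n1 = n1, n2 = n2, n3 = n3, n4 = n4)
  validate_params(p)
  structure(p, class = "vk_params")
}

param_names <- function() {
  c("y_xs1", "y_xs2", "mu_max", "k_s1", "k_s2", "m_s1", "m_s2",
    "s_m1", "s_m2", "n1", "n2", "n3", "n4")
}

validate_params <- function(p) {
  if (!is.numeric(p) || !all(param_names() %in% names(p))) {
    stop("parameter vector must contain the 13 named kinetic parameters",
         call. = FALSE)
  }
  p <- p[param_names()]
  if (any(!is.finite(p) & !(names(p) %in% c("s_m1", "s_m2") & is.infinite(p)))) {
    stop("kinetic parameters must be finite (inhibition ceilings may be Inf)",
         call. = FALSE)
  }
  if (any(p < 0)) stop("kinetic parameters must be non-negative", call. = FALSE)
  if (p[["y_xs1"]] <= 0 || p[["y_xs2"]] <= 0) {
    stop("yield coefficients must be strictly positive", call. = FALSE)
  }
  if (p[["s_m1"]] <= 0 || p[["s_m2"]] <= 0) {
    stop("inhibition ceilings must be strictly positive", call. = FALSE)
  }
  invisible(p)
}

#' Coerce a named numeric vector to a kinetic parameter vector
#'
#' @param x Named numeric vector containing all 13 parameter fields.
#' @return A `vk_params` vector in canonical field order.
#' @export
as_kinetic_params <- function(x) {
  x <- unclass(x)
  validate_params(x)
  structure(x[param_names()], class = "vk_params")
}

#' @export
print.vk_params <- function(x, ...) {
  cat("<kinetic parameters>\n")
  print(signif(unclass(x), 4))
  invisible(x)
}

# ---- model types -----------------------------------------------------------

MODEL_TYPES <- c("monod", "monod_sigmoid", "sigmoid")

#' Validate a growth-model type label
#'
#' Three dual-substrate growth kernels are supported, all multiplied by the
#' Luong inhibition factors for both substrates:
#' * `"monod"`: Monod limitation in both substrates.
#' * `"monod_sigmoid"`: Monod in sucrose, Sigmoid (Hill) in nitrate.
#' * `"sigmoid"`: Sigmoid limitation in both substrates.
#'
#' @param model Character scalar, one of `"monod"`, `"monod_sigmoid"`,
#'   `"sigmoid"` (case-insensitive).
#' @return The normalised model label.
#' @export
model_type <- function(model) {
  m <- tolower(as.character(model)[1])
  if (!m %in% MODEL_TYPES) {
    stop("unknown model type '", model, "'; expected one of ",
         paste(MODEL_TYPES, collapse = ", "), call. = FALSE)
  }
  m
}

#' Free parameters of a growth model
#'
#' The Monod kernel uses neither Hill exponent, the Monod-Sigmoid kernel uses
#' `n2` only, and the Sigmoid kernel uses both `n1` and `n2`; every kernel
#' uses the yields, maintenance terms, half-saturations and the Luong ceiling
#' pairs. Hence 11, 12 and 13 free parameters respectively.
#'
#' @param model Model type label.
#' @return Character vector of free parameter names.
#' @export
free_parameters <- function(model) {
  model <- model_type(model)
  base <- setdiff(param_names(), c("n1", "n2"))
  switch(model,
    monod = base,
    monod_sigmoid = c(base, "n2"),
    sigmoid = c(base, "n1", "n2")
  )
}

#' Number of free parameters of a growth model
#' @param model Model type label.
#' @return Integer count (11, 12 or 13).
#' @export
n_free_parameters <- function(model) length(free_parameters(model))

# ---- published reference values -------------------------------------------

#' Published batch parameter estimates for Viola odorata suspensions
#'
#' Parameter vectors estimated from batch shake-flask/bioreactor cultivations
#' of *Viola odorata* cell suspensions on optimised MS medium (inoculum
#' 7 g DW L^-1, sucrose 45.6 g L^-1, KNO3 2.1 g L^-1), one vector per growth
#' kernel. These serve as defaults for replication runs, sensitivity ranking
#' and fed-batch design.
#'
#' @param model Model type label.
#' @return A `vk_params` vector.
#' @export
#' @examples
#' vo_batch_params("monod_sigmoid")
vo_batch_params <- function(model = "monod_sigmoid") {
  model <- model_type(model)
  switch(model,
    monod = kinetic_params(
      y_xs1 = 0.51, y_xs2 = 7.86, mu_max = 0.40, k_s1 = 29.93, k_s2 = 0.17,
      m_s1 = 5.08e-2, m_s2 = 1.95e-5, s_m1 = 85.93, s_m2 = 3.67,
      n3 = 3.68, n4 = 2.16),
    monod_sigmoid = kinetic_params(
      y_xs1 = 0.50, y_xs2 = 7.71, mu_max = 0.37, k_s1 = 14.16, k_s2 = 0.17,
      m_s1 = 0.06, m_s2 = 2.88e-4, s_m1 = 179.24, s_m2 = 16.14,
      n2 = 2.74, n3 = 0.60, n4 = 1.07),
    sigmoid = kinetic_params(
      y_xs1 = 0.47, y_xs2 = 7.76, mu_max = 0.37, k_s1 = 13.51, k_s2 = 0.01,
      m_s1 = 0.04, m_s2 = 2.34e-5, s_m1 = 155.00, s_m2 = 18.85,
      n1 = 4.07, n2 = 1.64, n3 = 0.37, n4 = 1.75)
  )
}

#' Published objective (weighted SSE) values of the batch fits
#'
#' @return Named numeric vector, one weighted-SSE value per model type.
#' @export
vo_batch_objectives <- function() {
  c(monod = 2.068, monod_sigmoid = 2.053, sigmoid = 2.037)
}

#' Default box bounds for parameter estimation
#'
#' The estimation bounds used for the *V. odorata* batch fits, chosen from
#' the observed data ranges and related suspension-culture literature.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @export
vo_parameter_bounds <- function() {
  tibble::tibble(
    parameter = param_names(),
    lower = c(0.1, 0.1, 0.1, 1e-3, 1e-3, 1e-7, 1e-7, 44.9, 2,
              1e-3, 1e-3, 1e-3, 1e-3),
    upper = c(1, 10, 1, 44.9, 2, 0.1, 0.1, 200, 20, 5, 5, 5, 5)
  )
}

validate_bounds <- function(bounds) {
  stopifnot(is.data.frame(bounds),
            all(c("parameter", "lower", "upper") %in% names(bounds)))
  if (!setequal(bounds$parameter, param_names())) {
    stop("bounds must cover exactly the 13 kinetic parameters", call. = FALSE)
  }
  if (any(bounds$lower > bounds$upper)) {
    stop("lower bounds must not exceed upper bounds", call. = FALSE)
  }
  bounds[match(param_names(), bounds$parameter), ]
}

# ---- culture state ---------------------------------------------------------

#' Instantaneous culture state
#'
#' @param x Biomass concentration, g DW L^-1.
#' @param s1 Sucrose concentration, g L^-1.
#' @param s2 Potassium nitrate concentration, g L^-1.
#' @param v Broth volume, L.
#' @return Named numeric vector of class `vk_state`.
#' @export
#' @examples
#' culture_state(7, 45.6, 2.1, 1.2)
culture_state <- function(x, s1, s2, v = 1) {
  st <- c(x = x, s1 = s1, s2 = s2, v = v)
  validate_state(st)
  structure(st, class = "vk_state")
}

validate_state <- function(st) {
  if (!all(c("x", "s1", "s2", "v") %in% names(st))) {
    stop("culture state needs fields x, s1, s2, v", call. = FALSE)
  }
  if (any(!is.finite(st))) stop("culture state must be finite", call. = FALSE)
  if (st[["x"]] < 0 || st[["s1"]] < 0 || st[["s2"]] < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (st[["v"]] <= 0) stop("broth volume must be positive", call. = FALSE)
  invisible(st)
}

#' Default batch inoculation state for the V. odorata runs
#'
#' Inoculum 7 g DW L^-1 in optimised medium (45.6 g L^-1 sucrose,
#' 2.1 g L^-1 KNO3).
#'
#' @param v Broth volume, L (default 1.2, the fed-batch starting volume).
#' @return A `vk_state` vector.
#' @export
vo_initial_state <- function(v = 1.2) culture_state(7, 45.6, 2.1, v)
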