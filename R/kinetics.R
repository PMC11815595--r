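#' Luong substrate-inhibition factor
#'
#' The multiplicative inhibition term `(1 - s/s_m)^n`, which drives the
#' specific growth rate to zero as the substrate concentration `s` approaches
#' the ceiling `s_m`. At or above the ceiling the base would be negative and
#' fractional powers undefined; the factor is defined as exactly 0 there,
#' matching the physical reading that growth has stopped.
#'
#' @param s Substrate concentration, g L^-1 (vectorised).
#' @param s_m Inhibition ceiling, g L^-1 (> 0).
#' @param n Dimensionless exponent (>= 0).
#' @return Numeric in `[0, 1]`, same length as `s`.
#' @export
#' @examples
#' luong_factor(45.6, 179.24, 0.60)
luong_factor <- function(s, s_m, n) {
  if (any(s < 0)) stop("substrate concentration must be non-negative",
                       call. = FALSE)
  if (!is.finite(s_m) && !is.infinite(s_m)) stop("s_m must be numeric",
                                                 call. = FALSE)
  if (s_m <= 0) stop("inhibition ceiling s_m must be positive", call. = FALSE)
  if (n < 0) stop("Luong exponent n must be non-negative", call. = FALSE)
  ifelse(s >= s_m, 0, (1 - s / s_m)^n)
}

# Monod or Hill-type limitation term; n = 1 recovers Monod exactly.
limitation <- function(s, k, n = 1) {
  if (n == 1) return(s / (s + k))
  sn <- s^n
  sn / (sn + k^n)
}

#' Specific growth rate under a dual-substrate kernel with Luong inhibition
#'
#' Computes `mu = mu_max * lim1(s1) * lim2(s2) * luong(s1) * luong(s2)` where
#' the limitation terms are Monod `s/(s+K)` or Sigmoid `s^n/(s^n+K^n)`
#' according to the model type, and the Luong factors use the `(s_m1, n3)`
#' and `(s_m2, n4)` pairs.
#'
#' @param params A [kinetic_params()] vector.
#' @param model Model type label (see [model_type()]).
#' @param s1 Sucrose concentration, g L^-1 (vectorised).
#' @param s2 Potassium nitrate concentration, g L^-1 (vectorised).
#' @return Specific growth rate mu in d^-1, bounded by `[0, mu_max]`.
#' @export
#' @examples
#' specific_growth_rate(vo_batch_params("monod_sigmoid"), "monod_sigmoid",
#'                      s1 = 45.6, s2 = 2.1)
specific_growth_rate <- function(params, model, s1, s2) {
  model <- model_type(model)
  p <- unclass(params)
  if (any(s1 < 0) || any(s2 < 0)) {
    stop("substrate concentrations must be non-negative", call. = FALSE)
  }
  f1 <- switch(model,
    monod = limitation(s1, p[["k_s1"]]),
    monod_sigmoid = limitation(s1, p[["k_s1"]]),
    sigmoid = limitation(s1, p[["k_s1"]], p[["n1"]])
  )
  f2 <- switch(model,
    monod = limitation(s2, p[["k_s2"]]),
    monod_sigmoid = limitation(s2, p[["k_s2"]], p[["n2"]]),
    sigmoid = limitation(s2, p[["k_s2"]], p[["n2"]])
  )
  p[["mu_max"]] * f1 * f2 *
    luong_factor(s1, p[["s_m1"]], p[["n3"]]) *
    luong_factor(s2, p[["s_m2"]], p[["n4"]])
}

#' Substrate uptake rates
#'
#' Volumetric accumulation rates of both substrates,
#' `ds/dt = -(mu / Y + m) * x`: growth-linked consumption plus maintenance,
#' both proportional to biomass.
#'
#' @param params A [kinetic_params()] vector.
#' @param mu Specific growth rate, d^-1.
#' @param x Biomass concentration, g DW L^-1.
#' @return Named numeric `c(ds1_dt, ds2_dt)` in g L^-1 d^-1 (both <= 0).
#' @export
uptake_rates <- function(params, mu, x) {
  p <- unclass(params)
  if (p[["y_xs1"]] <= 0 || p[["y_xs2"]] <= 0) {
    stop("yield coefficients must be strictly positive", call. = FALSE)
  }
  if (mu < 0 || x < 0) stop("mu and x must be non-negative", call. = FALSE)
  c(ds1_dt = -(mu / p[["y_xs1"]] + p[["m_s1"]]) * x,
    ds2_dt = -(mu / p[["y_xs2"]] + p[["m_s2"]]) * x)
}

#' Batch culture vector field
#'
#' Right-hand side of the batch balance equations: `dx/dt = mu x`, substrate
#' uptake as in [uptake_rates()], constant volume. When a substrate is
#' depleted (`s <= 0`) its consumption (including maintenance) is switched
#' off so concentrations cannot go negative.
#'
#' @param params A [kinetic_params()] vector.
#' @param model Model type label.
#' @param state A [culture_state()] vector.
#' @return Named derivative vector `c(x, s1, s2, v)` in units per day.
#' @export
batch_rhs <- function(params, model, state) {
  fedbatch_rhs(params, model, state, feed = NULL, t = 0)
}

#' Fed-batch culture vector field with dilution terms
#'
#' During the feed window the broth is diluted at rate `D = F/V`:
#' `dx/dt = mu x - D x`, `ds/dt = -(mu/Y + m) x + D (S0 - s)`, `dv/dt = F`.
#' Outside the window (or with `feed = NULL`) the field reduces exactly to
#' the batch equations.
#'
#' @param params A [kinetic_params()] vector.
#' @param model Model type label.
#' @param state A [culture_state()] vector.
#' @param feed A [feed_strategy()] or `NULL` for batch operation.
#' @param t Time, d (decides whether the feed is on).
#' @return Named derivative vector `c(x, s1, s2, v)`.
#' @export
fedbatch_rhs <- function(params, model, state, feed, t) {
  st <- unclass(state)
  if (st[["v"]] <= 0) stop("broth volume must be positive", call. = FALSE)
  x <- st[["x"]]
  s1 <- max(st[["s1"]], 0)
  s2 <- max(st[["s2"]], 0)
  mu <- specific_growth_rate(params, model, s1, s2)
  up <- uptake_rates(params, mu, x)
  flow <- 0
  f_s1 <- 0
  f_s2 <- 0
  if (!is.null(feed) && t >= feed$t_feed_start && t < feed$t_end) {
    flow <- feed$flow
    f_s1 <- feed$feed_s1
    f_s2 <- feed$feed_s2
  }
  d_rate <- flow / st[["v"]]
  ds1 <- up[["ds1_dt"]] + d_rate * (f_s1 - s1)
  ds2 <- up[["ds2_dt"]] + d_rate * (f_s2 - s2)
  # depletion guard: no consumption from an empty pool, inflow still counts
  if (st[["s1"]] <= 0 && up[["ds1_dt"]] < 0) ds1 <- d_rate * (f_s1 - s1)
  if (st[["s2"]] <= 0 && up[["ds2_dt"]] < 0) ds2 <- d_rate * (f_s2 - s2)
  c(x = mu * x - d_rate * x, s1 = ds1, s2 = ds2, v = flow)
}

#' Fed-batch feed strategy
#'
#' The control vector of a fed-batch run: starting volume, feed window,
#' volumetric flow and feed-bottle concentrations. Feeding runs from
#' `t_feed_start` until `t_end`, which is also the harvest time used for
#' productivity.
#'
#' @param v0 Initial broth volume, L.
#' @param t_feed_start Day feeding starts.
#' @param t_end Day feeding stops and the culture is harvested.
#' @param flow Feed flow rate, L d^-1.
#' @param feed_s1 Sucrose concentration in the feed bottle, g L^-1.
#' @param feed_s2 KNO3 concentration in the feed bottle, g L^-1.
#' @return A list of class `vk_feed`.
#' @export
#' @examples
#' # the experimentally validated strategy
#' feed_strategy(v0 = 1.2, t_feed_start = 10, t_end = 17, flow = 0.072,
#'               feed_s1 = 250, feed_s2 = 15)
feed_strategy <- function(v0, t_feed_start, t_end, flow, feed_s1, feed_s2) {
  if (v0 <= 0) stop("initial volume must be positive", call. = FALSE)
  if (t_feed_start < 0 || t_end <= t_feed_start) {
    stop("need 0 <= t_feed_start < t_end", call. = FALSE)
  }
  if (flow < 0) stop("feed flow must be non-negative", call. = FALSE)
  if (feed_s1 < 0 || feed_s2 < 0) {
    stop("feed concentrations must be non-negative", call. = FALSE)
  }
  structure(list(v0 = v0, t_feed_start = t_feed_start, t_end = t_end,
                 flow = flow, feed_s1 = feed_s1, feed_s2 = feed_s2),
            class = "vk_feed")
}

#' The experimentally validated fed-batch strategy for V. odorata
#'
#' Batch phase to day 10, then feeding of 250 g L^-1 sucrose /
#' 15 g L^-1 KNO3 at 0.072 L d^-1 until harvest on day 17, starting from
#' 1.2 L.
#'
#' @return A `vk_feed` strategy.
#' @export
vo_feed_strategy <- function() {
  feed_strategy(v0 = 1.2, t_feed_start = 10, t_end = 17, flow = 0.072,
                feed_s1 = 250, feed_s2 = 15)
}
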