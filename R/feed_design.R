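#' Default fed-batch design grid
#'
#' The in-silico screening ranges for the five controls: feed start day 5-15
#' (integer days), feed sucrose 45-400 g L^-1, feed KNO3 2-30 g L^-1, flow
#' 0.014-1.44 L d^-1 and starting volume 0.8-1.5 L. The default level counts
#' (11 x 8 x 8 x 6 x 7) enumerate 29,568 candidate strategies.
#'
#' @return Named list of level vectors for `t_feed_start`, `feed_s1`,
#'   `feed_s2`, `flow`, `v0`.
#' @export
default_design_grid <- function() {
  list(
    t_feed_start = 5:15,
    feed_s1 = seq(45, 400, length.out = 8),
    feed_s2 = seq(2, 30, length.out = 8),
    flow = seq(0.014, 1.44, length.out = 6),
    v0 = seq(0.8, 1.5, length.out = 7)
  )
}

#' Enumerate a full factorial grid of feed strategies
#'
#' Cartesian product of the level vectors, in lexicographic order (first
#' control varying slowest), with a fixed harvest/feed-end day.
#'
#' @param grid Named list of level vectors (see [default_design_grid()]).
#' @param t_end Harvest day shared by all strategies (default 17).
#' @return A tibble with one row per strategy and columns `t_feed_start`,
#'   `feed_s1`, `feed_s2`, `flow`, `v0`, `t_end`.
#' @export
#' @examples
#' nrow(enumerate_grid())  # 29568
enumerate_grid <- function(grid = default_design_grid(), t_end = 17) {
  req <- c("t_feed_start", "feed_s1", "feed_s2", "flow", "v0")
  if (!all(req %in% names(grid))) {
    stop("grid needs levels for: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  for (nm in req) {
    if (length(grid[[nm]]) < 1) stop("empty levels for ", nm, call. = FALSE)
    if (is.unsorted(grid[[nm]])) {
      stop("levels for ", nm, " must be non-decreasing", call. = FALSE)
    }
  }
  if (any(grid$t_feed_start >= t_end)) {
    stop("all feed start days must precede t_end", call. = FALSE)
  }
  out <- tidyr::expand_grid(
    t_feed_start = grid$t_feed_start,
    feed_s1 = grid$feed_s1,
    feed_s2 = grid$feed_s2,
    flow = grid$flow,
    v0 = grid$v0
  )
  out$t_end <- t_end
  out
}

#' Evaluate a single fed-batch strategy
#'
#' Simulates the strategy and scores it: final biomass concentration,
#' productivity (final biomass / harvest day) and feasibility. A strategy is
#' infeasible when the broth volume exceeds the reactor working-volume
#' ceiling or when either substrate crosses its Luong inhibition ceiling at
#' any point of the dense trajectory (growth would stall).
#'
#' @param params A [kinetic_params()] vector.
#' @param model Model type label.
#' @param strategy A [feed_strategy()] or a one-row data frame with the
#'   strategy columns.
#' @param constraints List with `v_max` (working-volume ceiling, L; default
#'   2.4 L, the stirred-tank working volume).
#' @param init Optional initial [culture_state()] (default: standard
#'   inoculum at the strategy's `v0`).
#' @param dt Integration step, d (default 0.05: design screening resolution).
#' @return One-row tibble: strategy controls plus `final_biomass`,
#'   `productivity`, `final_volume`, `feasible`, `reason`.
#' @export
evaluate_strategy <- function(params, model, strategy,
                              constraints = list(v_max = 2.4),
                              init = NULL, dt = 0.05) {
  feed <- if (inherits(strategy, "vk_feed")) {
    strategy
  } else {
    feed_strategy(v0 = strategy$v0, t_feed_start = strategy$t_feed_start,
                  t_end = strategy$t_end, flow = strategy$flow,
                  feed_s1 = strategy$feed_s1, feed_s2 = strategy$feed_s2)
  }
  v_max <- constraints$v_max %||% 2.4
  p <- unclass(as_kinetic_params(params))
  res <- tryCatch(
    simulate_fedbatch(params, model, feed, init = init, dt = dt),
    error = function(e) e)
  base <- tibble::tibble(
    v0 = feed$v0, t_feed_start = feed$t_feed_start, t_end = feed$t_end,
    flow = feed$flow, feed_s1 = feed$feed_s1, feed_s2 = feed$feed_s2)
  if (inherits(res, "error")) {
    return(dplyr::mutate(base, final_biomass = NA_real_,
                         productivity = NA_real_, final_volume = NA_real_,
                         feasible = FALSE,
                         reason = paste("simulation failed:",
                                        conditionMessage(res))))
  }
  last <- res[nrow(res), ]
  reasons <- character()
  if (last$volume_L > v_max + 1e-9) {
    reasons <- c(reasons, sprintf("final volume %.3g L exceeds ceiling %.3g L",
                                  last$volume_L, v_max))
  }
  if (any(res$sucrose_g_L >= p[["s_m1"]])) {
    reasons <- c(reasons, "sucrose crosses its inhibition ceiling")
  }
  if (any(res$kno3_g_L >= p[["s_m2"]])) {
    reasons <- c(reasons, "nitrate crosses its inhibition ceiling")
  }
  dplyr::mutate(base,
    final_biomass = last$biomass_gDW_L,
    productivity = last$biomass_gDW_L / feed$t_end,
    final_volume = last$volume_L,
    feasible = length(reasons) == 0,
    reason = if (length(reasons)) paste(reasons, collapse = "; ") else "")
}

#' Exhaustive in-silico fed-batch design
#'
#' Evaluates every strategy in the grid, drops infeasible ones, keeps those
#' beating the batch baseline productivity, and ranks the survivors by
#' productivity (ties: earlier harvest, then less total feed mass).
#'
#' @param params A [kinetic_params()] vector.
#' @param model Model type label.
#' @param grid Strategy tibble from [enumerate_grid()].
#' @param constraints List with `v_max` (see [evaluate_strategy()]).
#' @param batch_baseline Batch productivity to beat, g DW L^-1 d^-1. If
#'   `NULL`, computed by simulating a batch at the same harvest day from the
#'   standard inoculation state.
#' @param init Optional initial state override passed to every evaluation.
#' @param dt Integration step, d.
#' @return A tibble of feasible, above-baseline strategies ranked by
#'   productivity, with a `rank` column; attributes `batch_baseline` and
#'   `n_evaluated`. Warns when nothing beats the baseline.
#' @export
design_fedbatch <- function(params, model, grid = enumerate_grid(),
                            constraints = list(v_max = 2.4),
                            batch_baseline = NULL, init = NULL, dt = 0.05) {
  if (nrow(grid) == 0) stop("empty strategy grid", call. = FALSE)
  if (is.null(batch_baseline)) {
    t_end <- grid$t_end[1]
    st <- init %||% vo_initial_state()
    tr <- simulate_batch(params, model, st, tf = t_end, dt = dt)
    batch_baseline <- tr$biomass_gDW_L[nrow(tr)] / t_end
  }
  results <- purrr::pmap_dfr(grid, function(...) {
    row <- tibble::tibble(...)
    evaluate_strategy(params, model, row, constraints, init = init, dt = dt)
  })
  kept <- dplyr::filter(results, .data$feasible,
                        .data$productivity > batch_baseline)
  if (nrow(kept) == 0) {
    warning("no feasible strategy beats the batch baseline productivity",
            call. = FALSE)
  }
  kept <- dplyr::arrange(kept, dplyr::desc(.data$productivity), .data$t_end,
                         .data$flow * (.data$t_end - .data$t_feed_start) *
                           (.data$feed_s1 + .data$feed_s2))
  kept$rank <- seq_len(nrow(kept))
  structure(kept, batch_baseline = batch_baseline,
            n_evaluated = nrow(results))
}
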