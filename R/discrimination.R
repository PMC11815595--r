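#' Residual variance of a fitted model
#'
#' `sse / (n - p)`: the weighted residual sum of squares divided by the
#' residual degrees of freedom.
#'
#' @param sse Weighted sum of squared errors (>= 0).
#' @param n Number of data points.
#' @param p Number of free model parameters (`n > p`).
#' @return The model variance.
#' @export
#' @examples
#' model_variance(2.053, 34, 12)  # 0.093 at 3 decimals
model_variance <- function(sse, n, p) {
  if (sse < 0) stop("sse must be non-negative", call. = FALSE)
  if (n <= p) stop("need more data points than parameters (n > p)",
                   call. = FALSE)
  sse / (n - p)
}

#' Upper critical value of the F distribution
#'
#' @param alpha Significance level (0 < alpha < 1).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return The upper-alpha quantile of F(df1, df2).
#' @export
#' @examples
#' critical_f(0.05, 1, 21)   # 4.325
#' critical_f(0.05, 21, 22)  # 2.059
critical_f <- function(alpha, df1, df2) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1",
                               call. = FALSE)
  stats::qf(1 - alpha, df1, df2)
}

fit_summary <- function(x, label = NULL) {
  if (inherits(x, "vk_fit")) {
    list(sse = x$objective, n = x$n, p = x$p,
         label = label %||% x$model_type)
  } else if (is.list(x) && all(c("sse", "n", "p") %in% names(x))) {
    list(sse = x$sse, n = x$n, p = x$p, label = label %||% "model")
  } else {
    stop("expected a vk_fit or a list with sse, n, p", call. = FALSE)
  }
}

new_discrimination <- function(method, f, df, crit, alpha, preferred, rule) {
  structure(list(method = method, f_statistic = f, df = df,
                 critical_value = crit, alpha = alpha,
                 preferred_model = preferred, decision_rule = rule),
            class = "vk_discrimination")
}

#' @export
print.vk_discrimination <- function(x, ...) {
  cat(sprintf("<%s F-test>\n  F = %.4g on (%d, %d) df; critical %.4g at alpha %.2g\n  preferred: %s\n  %s\n",
              x$method, x$f_statistic, x$df[1], x$df[2], x$critical_value,
              x$alpha, x$preferred_model, x$decision_rule))
  invisible(x)
}

#' Tidy an F-test result
#' @param x A `vk_discrimination`.
#' @param ... Unused.
#' @return One-row tibble with the statistic, df, critical value and verdict.
#' @export
tidy.vk_discrimination <- function(x, ...) {
  tibble::tibble(method = x$method, f_statistic = x$f_statistic,
                 df1 = x$df[1], df2 = x$df[2],
                 critical_value = x$critical_value, alpha = x$alpha,
                 preferred_model = x$preferred_model)
}

#' Variance-ratio F-test between two fitted models
#'
#' Compares the residual variances of two fits of the same data:
#' `F = var_L / var_S` with the larger variance in the numerator (so F >= 1
#' by construction), using unrounded variances. The numerator degrees of
#' freedom are those of the larger-variance model. If F falls below the
#' critical value the variances are statistically indistinguishable and the
#' model with fewer parameters is preferred.
#'
#' @param fit_a,fit_b `vk_fit` objects, or lists with `sse`, `n`, `p` (and
#'   optionally a name via `labels`).
#' @param alpha Significance level.
#' @param labels Optional length-2 character labels for the two models.
#' @return A `vk_discrimination` result.
#' @export
f_test_variance <- function(fit_a, fit_b, alpha = 0.05, labels = NULL) {
  a <- fit_summary(fit_a, labels[1])
  b <- fit_summary(fit_b, labels[2])
  if (a$n != b$n) stop("both fits must use the same data (equal n)",
                       call. = FALSE)
  va <- model_variance(a$sse, a$n, a$p)
  vb <- model_variance(b$sse, b$n, b$p)
  if (min(va, vb) <= 0) stop("zero residual variance: F ratio undefined",
                             call. = FALSE)
  larger <- if (va >= vb) a else b
  smaller <- if (va >= vb) b else a
  f <- max(va, vb) / min(va, vb)
  df <- c(larger$n - larger$p, smaller$n - smaller$p)
  crit <- critical_f(alpha, df[1], df[2])
  simpler <- if (a$p <= b$p) a$label else b$label
  preferred <- if (f < crit) simpler else smaller$label
  rule <- if (f < crit) {
    sprintf("F < critical: variances indistinguishable; prefer the simpler model (%s)", simpler)
  } else {
    sprintf("F >= critical: prefer the smaller-variance model (%s)", smaller$label)
  }
  new_discrimination("variance-ratio", f, df, crit, alpha, preferred, rule)
}

#' Nested-SSE F-test between a smaller and a larger model
#'
#' `F = ((sse_a - sse_b) / (p2 - p1)) / (sse_b / (n - p2))` where model A has
#' `p1` parameters and model B the larger `p2`. When F is below the critical
#' value at `(p2 - p1, n - p2)` degrees of freedom the extra parameters do
#' not buy a significant SSE reduction and the smaller model is preferred.
#'
#' @param sse_a SSE of the smaller model (p1 parameters).
#' @param sse_b SSE of the larger model (p2 parameters).
#' @param p1,p2 Parameter counts, `p2 > p1`.
#' @param n Number of data points, `n > p2`.
#' @param alpha Significance level.
#' @param labels Optional length-2 labels (smaller, larger).
#' @return A `vk_discrimination` result.
#' @export
#' @examples
#' f_test_nested(2.053, 2.037, 12, 13, 34)  # F = 0.165
f_test_nested <- function(sse_a, sse_b, p1, p2, n, alpha = 0.05,
                          labels = c("smaller", "larger")) {
  if (p2 <= p1) stop("p2 must exceed p1", call. = FALSE)
  if (n <= p2) stop("need n > p2", call. = FALSE)
  if (sse_a < 0 || sse_b < 0) stop("SSE must be non-negative", call. = FALSE)
  if (sse_b <= 0) stop("larger model has zero SSE: F undefined",
                       call. = FALSE)
  f <- ((sse_a - sse_b) / (p2 - p1)) / (sse_b / (n - p2))
  df <- c(p2 - p1, n - p2)
  crit <- critical_f(alpha, df[1], df[2])
  preferred <- if (f < crit) labels[1] else labels[2]
  rule <- if (f < crit) {
    "F < critical: extra parameters not justified; prefer the smaller model"
  } else {
    "F >= critical: the larger model fits significantly better"
  }
  new_discrimination("nested-SSE", f, df, crit, alpha, preferred, rule)
}

#' Plausibility screen on fitted inhibition ceilings
#'
#' Compares the fitted Luong ceilings against experimentally observed
#' complete-inhibition concentrations (for *V. odorata*: sucrose around
#' 140 g L^-1, KNO3 around 12 g L^-1). A fit whose ceiling deviates by more
#' than `rel_tol` relative from the observation fails the screen, the way a
#' Monod fit with a sucrose ceiling of 85.9 g L^-1 is rejected against an
#' observed 140 g L^-1.
#'
#' @param fit A `vk_fit` or a `vk_params` vector.
#' @param observed_sm1 Observed sucrose inhibition ceiling, g L^-1.
#' @param observed_sm2 Observed KNO3 inhibition ceiling, g L^-1.
#' @param rel_tol Allowed relative deviation (default 0.3).
#' @return A tibble with one row per substrate: `substrate`, `fitted`,
#'   `observed`, `rel_deviation`, `pass`; attribute `pass` gives the overall
#'   verdict.
#' @export
screen_inhibition_ceiling <- function(fit, observed_sm1 = 140,
                                      observed_sm2 = 12, rel_tol = 0.3) {
  params <- if (inherits(fit, "vk_fit")) fit$params else as_kinetic_params(fit)
  if (observed_sm1 <= 0 || observed_sm2 <= 0) {
    stop("observed ceilings must be positive", call. = FALSE)
  }
  tbl <- tibble::tibble(
    substrate = c("sucrose", "kno3"),
    fitted = c(params[["s_m1"]], params[["s_m2"]]),
    observed = c(observed_sm1, observed_sm2)
  )
  tbl$rel_deviation <- abs(tbl$fitted - tbl$observed) / tbl$observed
  tbl$pass <- tbl$rel_deviation <= rel_tol
  structure(tbl, pass = all(tbl$pass))
}

#' Rank competing fitted models by the published discrimination protocol
#'
#' First eliminates fits whose sucrose (carbon-source) inhibition ceiling
#' deviates from the experimentally observed complete-inhibition
#' concentration by more than `rel_tol` relative — the elimination rule the
#' batch study applies before any statistics. The survivors are then
#' compared by pairwise variance-ratio F-tests (and, for pairs of different
#' size, the nested-SSE F-test), preferring models with fewer parameters
#' whenever the tests cannot tell them apart.
#'
#' @param fits Named list of `vk_fit` objects.
#' @param alpha Significance level.
#' @param observed_sm1 Observed sucrose inhibition ceiling, g L^-1.
#' @param rel_tol Screen tolerance on the relative deviation.
#' @return A list with `screen` (per-model ceiling verdicts), `tests`
#'   (tibble of pairwise test rows) and `preferred` (the selected model
#'   label).
#' @export
discriminate_models <- function(fits, alpha = 0.05, observed_sm1 = 140,
                                rel_tol = 0.3) {
  stopifnot(is.list(fits), length(fits) >= 2)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$model_type, character(1))
  }
  screen <- purrr::map_dfr(names(fits), function(nm) {
    sm1 <- unclass(fits[[nm]]$params)[["s_m1"]]
    dev <- abs(sm1 - observed_sm1) / observed_sm1
    tibble::tibble(model = nm, fitted_sm1 = sm1, observed_sm1 = observed_sm1,
                   rel_deviation = dev, pass = dev <= rel_tol)
  })
  surv <- screen$model[screen$pass]
  if (length(surv) == 0) surv <- names(fits)  # screen everything out: compare all
  if (length(surv) == 1) {
    return(list(screen = screen,
                tests = tibble::tibble(),
                preferred = surv))
  }
  pairs <- utils::combn(surv, 2, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(pr) {
    fa <- fits[[pr[1]]]
    fb <- fits[[pr[2]]]
    rows <- tidy(f_test_variance(fa, fb, alpha, labels = pr))
    if (fa$p != fb$p) {
      sm <- if (fa$p < fb$p) fa else fb
      lg <- if (fa$p < fb$p) fb else fa
      lb <- if (fa$p < fb$p) pr else rev(pr)
      rows <- dplyr::bind_rows(rows,
        tidy(f_test_nested(sm$objective, lg$objective, sm$p, lg$p, sm$n,
                           alpha, labels = lb)))
    }
    rows
  })
  votes <- table(tests$preferred_model)
  preferred <- names(votes)[which.max(votes)]
  list(screen = screen, tests = tests, preferred = preferred)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
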