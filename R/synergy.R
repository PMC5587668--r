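# Chou-Talalay median-effect / combination-index analysis.
#
# The median-effect model of one agent's dose-response is
#   fa / fu = (d / Dm)^m,   fu = 1 - fa,
# i.e. fa = 1 / (1 + (Dm/d)^m). On log scales it is a straight line,
#   log10(fa/fu) = m * log10(d) - m * log10(Dm),
# which is fitted by ordinary least squares. The combination index of a
# dose pair (d1, d2) producing fraction affected fa is
#   CI = d1/Dx1 + d2/Dx2            (mutually exclusive form, default)
# with Dx_i = dose of agent i alone producing fa; the nonexclusive form adds
# (d1*d2)/(Dx1*Dx2). CI < 1 synergy, = 1 additivity, > 1 antagonism.

#' Median-effect linearizing transform
#'
#' Maps a dose-response point to the coordinates of the median-effect plot:
#' `x = log10(dose)`, `y = log10(fa / (1 - fa))`. Exact and invertible on
#' `dose > 0`, `0 < fa < 1`.
#'
#' @param dose positive dose(s), in the agent's units.
#' @param fa fraction(s) affected, strictly inside (0, 1).
#' @return list with numeric vectors `x` and `y`.
#' @export
median_effect_transform <- function(dose, fa) {
  if (!all(is.finite(dose)) || any(dose <= 0))
    abort("dose must be finite and > 0", "tilscreen_validation_error")
  if (!all(is.finite(fa)) || any(fa <= 0) || any(fa >= 1))
    abort("fa must lie strictly inside (0, 1); clamp_fa() can pre-clamp",
          "tilscreen_validation_error")
  list(x = log10(dose), y = log10(fa / (1 - fa)))
}

#' Clamp fractions affected away from 0 and 1
#'
#' The median-effect transform is undefined at fa = 0 or 1, and ingestion
#' rejects such values. This utility clamps to `[eps, 1 - eps]` for users who
#' explicitly choose to keep saturated observations; it is never applied
#' automatically.
#'
#' @param fa numeric vector of fractions.
#' @param eps clamp margin (default 0.005).
#' @return clamped vector.
#' @export
clamp_fa <- function(fa, eps = 0.005) {
  stopifnot_scalar_number(eps, "eps", positive = TRUE)
  pmin(pmax(fa, eps), 1 - eps)
}

#' Fit the median-effect model of one agent
#'
#' Ordinary least squares on the median-effect plot: slope `m`
#' (sigmoidicity), `Dm = 10^(-intercept/m)` (dose giving 50% effect), and
#' `r`, the Pearson correlation of the linearized coordinates. The fit is
#' unweighted, following the classical procedure.
#'
#' @param dose positive doses (>= 2 distinct values).
#' @param fa fractions affected in (0, 1), same length as `dose`.
#' @param agent_id identifier carried into the model object.
#' @return object of class `medeff_model`: list with `agent_id`, `Dm`, `m`,
#'   `r`, `n_points`, `dose_range`.
#' @export
#' @examples
#' d <- c(10, 50, 100, 500, 1000)
#' fa <- 1 / (1 + (100 / d)^1.5)
#' fit_median_effect(d, fa, "drugA")
fit_median_effect <- function(dose, fa, agent_id = "agent") {
  if (length(dose) != length(fa) || length(dose) < 2L)
    abort("need >= 2 (dose, fa) points of one agent",
          "tilscreen_validation_error")
  tr <- median_effect_transform(dose, fa)
  if (length(unique(tr$x)) < 2L)
    abort("all doses identical: degenerate design, cannot fit a slope",
          "tilscreen_degenerate_design_error")
  x <- tr$x; y <- tr$y
  sxx <- sum((x - mean(x))^2)
  m <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b0 <- mean(y) - m * mean(x)
  if (!is.finite(m) || m <= 0)
    abort(sprintf(
      "non-monotone response: fitted slope m = %.4g <= 0 for agent %s",
      m, agent_id),
      "tilscreen_nonmonotone_error", slope = m, intercept = b0)
  r <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)
  structure(list(agent_id = agent_id,
                 Dm = 10^(-b0 / m),
                 m = m,
                 r = r,
                 n_points = length(dose),
                 dose_range = range(dose)),
            class = "medeff_model")
}

#' Construct a median-effect model from known parameters
#'
#' Builds a `medeff_model` directly from `(Dm, m)` without fitting — used
#' when the parameters are known (simulation ground truth) rather than
#' estimated.
#'
#' @param Dm dose giving 50% effect (> 0).
#' @param m sigmoidicity (> 0).
#' @param agent_id identifier.
#' @param dose_range nominal dose range covered (default `Dm * c(0.1, 10)`),
#'   used only for extrapolation flagging.
#' @return object of class `medeff_model` (with `r = 1`, `n_points = 0`).
#' @export
medeff_model <- function(Dm, m, agent_id = "agent",
                         dose_range = Dm * c(0.1, 10)) {
  stopifnot_scalar_number(Dm, "Dm", positive = TRUE)
  stopifnot_scalar_number(m, "m", positive = TRUE)
  structure(list(agent_id = agent_id, Dm = Dm, m = m, r = 1,
                 n_points = 0L, dose_range = dose_range),
            class = "medeff_model")
}

#' @export
print.medeff_model <- function(x, ...) {
  cat(sprintf(
    "Median-effect model [%s]: Dm = %.6g, m = %.4g, r = %.4f (n = %d)\n",
    x$agent_id, x$Dm, x$m, x$r, x$n_points))
  invisible(x)
}

#' Fraction affected at a dose (forward median-effect equation)
#'
#' @param model a `medeff_model`.
#' @param dose positive dose(s).
#' @return fraction(s) affected in (0, 1).
#' @export
effect_at_dose <- function(model, dose) {
  stopifnot(inherits(model, "medeff_model"))
  if (!all(is.finite(dose)) || any(dose <= 0))
    abort("dose must be > 0", "tilscreen_validation_error")
  1 / (1 + (model$Dm / dose)^model$m)
}

#' Dose producing a given effect (inverse median-effect equation)
#'
#' `Dx = Dm * (fa / (1 - fa))^(1/m)`.
#'
#' @param model a `medeff_model`.
#' @param fa target fraction(s) affected in (0, 1).
#' @return positive dose(s).
#' @export
dose_for_effect <- function(model, fa) {
  stopifnot(inherits(model, "medeff_model"))
  if (!all(is.finite(fa)) || any(fa <= 0) || any(fa >= 1))
    abort("fa must lie strictly inside (0, 1)", "tilscreen_validation_error")
  model$Dm * (fa / (1 - fa))^(1 / model$m)
}

#' Chou-Talalay combination index
#'
#' For each combination measurement (d1, d2, fa), computes the single-agent
#' iso-effective doses Dx1, Dx2 at `fa` and the combination index. The
#' default `exclusive` form is `CI = d1/Dx1 + d2/Dx2`; the `nonexclusive`
#' form adds `(d1*d2)/(Dx1*Dx2)`. Classification uses a tolerance band
#' around 1: `CI < 1 - tol` synergy, `|CI - 1| <= tol` additivity,
#' `CI > 1 + tol` antagonism. Measurements whose Dx requires extrapolating
#' more than two decades beyond an agent's fitted dose range are flagged
#' `extrapolated`, not rejected.
#'
#' @param model1,model2 `medeff_model` fits for the two agents.
#' @param combos data.frame with columns `d1, d2, fa` (`d1, d2 >= 0`,
#'   `d1 + d2 > 0`, `0 < fa < 1`).
#' @param form `"exclusive"` (default) or `"nonexclusive"`.
#' @param tol additivity tolerance around CI = 1 (default 0.05).
#' @return data.frame `fa, d1, d2, Dx1, Dx2, ci, classification, flag`.
#' @export
#' @examples
#' m <- fit_median_effect(c(10, 100, 1000), 1 / (1 + (100 / c(10, 100, 1000))))
#' combination_index(m, m, data.frame(d1 = 50, d2 = 50, fa = 0.5))
combination_index <- function(model1, model2, combos, form = c("exclusive",
                              "nonexclusive"), tol = 0.05) {
  form <- match.arg(form)
  stopifnot_scalar_number(tol, "tol")
  combos <- validate_combos(combos)
  Dx1 <- dose_for_effect(model1, combos$fa)
  Dx2 <- dose_for_effect(model2, combos$fa)
  ci <- combos$d1 / Dx1 + combos$d2 / Dx2
  if (form == "nonexclusive")
    ci <- ci + (combos$d1 * combos$d2) / (Dx1 * Dx2)
  classification <- ifelse(ci < 1 - tol, "synergy",
                           ifelse(ci > 1 + tol, "antagonism", "additivity"))
  flag <- ifelse(extrapolates(model1, Dx1) | extrapolates(model2, Dx2),
                 "extrapolated", "ok")
  data.frame(fa = combos$fa, d1 = combos$d1, d2 = combos$d2,
             Dx1 = Dx1, Dx2 = Dx2, ci = ci,
             classification = classification, flag = flag,
             stringsAsFactors = FALSE)
}

validate_combos <- function(combos) {
  if (!is.data.frame(combos) || !all(c("d1", "d2", "fa") %in% names(combos)))
    abort("`combos` must be a data.frame with columns d1, d2, fa",
          "tilscreen_validation_error")
  if (nrow(combos) == 0L)
    abort("combination table is empty", "tilscreen_empty_input_error")
  if (any(!is.finite(combos$d1)) || any(!is.finite(combos$d2)) ||
      any(combos$d1 < 0) || any(combos$d2 < 0) ||
      any(combos$d1 + combos$d2 <= 0))
    abort("doses must be finite, >= 0, with d1 + d2 > 0",
          "tilscreen_validation_error")
  if (any(!is.finite(combos$fa)) || any(combos$fa <= 0) ||
      any(combos$fa >= 1))
    abort("combination fa must lie strictly inside (0, 1)",
          "tilscreen_validation_error")
  combos
}

# Dx more than 2 decades outside the fitted dose range?
extrapolates <- function(model, Dx) {
  lo <- log10(model$dose_range[1L]) - 2
  hi <- log10(model$dose_range[2L]) + 2
  log10(Dx) < lo | log10(Dx) > hi
}

#' Isobologram coordinates
#'
#' Normalized dose pairs `(x, y) = (d1/Dx1, d2/Dx2)` for each combination
#' measurement, grouped by effect level `fa`. For each point `x + y` equals
#' the (exclusive-form) combination index, so points below the unit diagonal
#' `x + y = 1` indicate synergy.
#'
#' @inheritParams combination_index
#' @return plot-ready data.frame `fa, d1, d2, x, y, ci`.
#' @export
isobologram <- function(model1, model2, combos) {
  ci <- combination_index(model1, model2, combos, form = "exclusive")
  out <- data.frame(fa = ci$fa, d1 = ci$d1, d2 = ci$d2,
                    x = ci$d1 / ci$Dx1, y = ci$d2 / ci$Dx2, ci = ci$ci)
  out[order(out$fa, out$x), , drop = FALSE]
}
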