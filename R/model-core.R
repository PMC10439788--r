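#' Trait-dependent vital rates
#'
#' The biomarker level `v` is a heritable quantitative trait with functional
#' fitness consequences. Production confers a proliferation advantage,
#' `r(v) = r0 (v/v0)^beta_r`, at an exponential survival cost,
#' `delta(v) = delta0 exp(beta_delta (v - v0))`. Both are strictly increasing
#' in `v` and anchored at the baseline trait `v0`.
#'
#' @param v biomarker level(s), strictly positive.
#' @param p a [model_params()] object.
#' @return Rate(s), same length as `v`.
#' @examples
#' p <- model_params()
#' intrinsic_growth(1, p)  # r0
#' natural_death(1, p)     # delta0
#' @export
intrinsic_growth <- function(v, p) {
  check_trait(v)
  p$r0 * (v / p$v0)^p$beta_r
}

#' @rdname intrinsic_growth
#' @export
natural_death <- function(v, p) {
  check_trait(v)
  p$delta0 * exp(p$beta_delta * (v - p$v0))
}

check_trait <- function(v, what = "biomarker level") {
  if (any(!is.finite(v)) || any(v <= 0))
    stop(what, " must be strictly positive", call. = FALSE)
  invisible(v)
}

#' Competition coefficient between two biomarker strategies
#'
#' Logistic-type kernel describing the competition a focal cell with trait
#' `v_focal` experiences from a cell with trait `v_other`:
#' `a = a_max * e^x / (a_max + e^x - 1)` with `x = beta_a (v_other - v_focal)`.
#' It equals 1 between equal strategies, falls as the focal cell's own
#' production rises (higher producers are better competitors), rises with
#' the competitor's production, and is bounded in (0, a_max).
#'
#' @param v_focal focal cell's biomarker level.
#' @param v_other competitor's biomarker level.
#' @param p a [model_params()] object.
#' @return Dimensionless coefficient(s) in (0, a_max).
#' @export
competition_coeff <- function(v_focal, v_other, p) {
  check_trait(v_focal)
  check_trait(v_other)
  x <- exp(p$beta_a * (v_other - v_focal))
  p$a_max * x / (p$a_max + x - 1)
}

# d a(v, u) / dv at v = u, in closed form: -beta_a (a_max - 1) / a_max.
competition_self_deriv <- function(p) {
  -p$beta_a * (p$a_max - 1) / p$a_max
}

#' Therapy effectiveness functions
#'
#' Chemotherapy adds a death rate that decays exponentially with the
#' biomarker (production confers resistance),
#' `E_C(v) = zeta_C exp(-m_C (v - v0))`. Targeted therapy attacks the
#' biomarker itself, so its added death rate grows as a power of the trait,
#' `E_T(v) = zeta_T (v/v0)^m_T`: very effective against high producers,
#' nearly inert against low producers.
#'
#' @param v biomarker level(s), strictly positive.
#' @param p a [model_params()] object.
#' @return Added death rate(s).
#' @examples
#' p <- model_params()
#' chemo_effect(1, p)     # zeta_C
#' targeted_effect(2, p)  # zeta_T * 2^m_T
#' @export
chemo_effect <- function(v, p) {
  check_trait(v)
  p$zeta_C * exp(-p$m_C * (v - p$v0))
}

#' @rdname chemo_effect
#' @export
targeted_effect <- function(v, p) {
  check_trait(v)
  p$zeta_T * (v / p$v0)^p$m_T
}

# total therapy-induced death rate under a treatment state
therapy_death <- function(v, trt, p) {
  out <- 0
  if (trt$tau_C == 1) out <- out + chemo_effect(v, p)
  if (trt$tau_T == 1) out <- out + targeted_effect(v, p)
  out
}

#' Fitness-generating function
#'
#' Per-capita growth rate `G(v, u, C)` of a rare focal strategy `v` in a
#' monomorphic resident population with strategy `u` at density `C`:
#'
#' `G = r(v) (1 - a(v, u) C / K) - delta(v) - E_C(v) tau_C - E_T(v) tau_T`
#'
#' @param v focal biomarker level.
#' @param u resident biomarker level.
#' @param C resident population density, non-negative.
#' @param trt a [treatment_state()].
#' @param p a [model_params()] object.
#' @return Per-capita growth rate of the focal strategy.
#' @examples
#' p <- model_params()
#' fitness(1, 1, 0, no_therapy(), p)    # r0 - delta0
#' fitness(1, 1, 0.6, no_therapy(), p)  # 0: resident at equilibrium
#' @export
fitness <- function(v, u, C, trt, p) {
  check_trait(v, "focal trait")
  check_trait(u, "resident trait")
  if (any(C < 0)) stop("density C must be non-negative", call. = FALSE)
  intrinsic_growth(v, p) * (1 - competition_coeff(v, u, p) * C / p$K) -
    natural_death(v, p) - therapy_death(v, trt, p)
}

#' Selection gradient
#'
#' Analytic derivative of the fitness-generating function in its focal
#' argument, evaluated at the resident strategy (`v = u`). Its sign gives
#' the direction of trait evolution under the given treatment environment;
#' multiplied by the evolvability `k` it gives the rate. The evolvability
#' itself does not enter the gradient.
#'
#' @param u resident biomarker level.
#' @param C resident density, non-negative.
#' @param trt a [treatment_state()].
#' @param p a [model_params()] object.
#' @return Gradient value(s) (fitness per marker unit), same length as `u`.
#' @export
selection_gradient <- function(u, C, trt, p) {
  check_trait(u, "resident trait")
  if (any(C < 0)) stop("density C must be non-negative", call. = FALSE)
  dr <- p$r0 * p$beta_r / p$v0 * (u / p$v0)^(p$beta_r - 1)
  ddelta <- p$delta0 * p$beta_delta * exp(p$beta_delta * (u - p$v0))
  grad <- dr * (1 - C / p$K) -
    intrinsic_growth(u, p) * competition_self_deriv(p) * C / p$K -
    ddelta
  if (trt$tau_C == 1) grad <- grad - (-p$m_C * chemo_effect(u, p))
  if (trt$tau_T == 1) grad <- grad - p$m_T / u * targeted_effect(u, p)
  grad
}

#' Equilibrium population density of a monomorphic population
#'
#' Setting the fitness of the resident against itself to zero gives
#' `C*(v) = K (1 - (delta(v) + E(v)) / r(v))`, where `E` is the total
#' therapy-induced death rate under the (constant) treatment state. When
#' total death exceeds growth the population cannot persist and the
#' equilibrium clamps to 0, so sweeps over harsh therapy remain defined.
#' With no therapy the curve attains its maximum at the baseline `v0`.
#'
#' @param v biomarker level(s), strictly positive.
#' @param trt a [treatment_state()]; defaults to no therapy.
#' @param p a [model_params()] object.
#' @return Equilibrium density `C*` (vectorised over `v`), clamped at 0.
#' @examples
#' p <- model_params()
#' equilibrium_pop(1, no_therapy(), p)  # 0.6
#' @export
equilibrium_pop <- function(v, trt = no_therapy(), p = model_params()) {
  check_trait(v)
  pmax(0, p$K * (1 - (natural_death(v, p) + therapy_death(v, trt, p)) /
                   intrinsic_growth(v, p)))
}
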