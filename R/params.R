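#' Model parameters for the biomarker competition game
#'
#' Constructs and validates the full parameter set governing growth, death,
#' competition, therapy effectiveness and evolvability. Defaults are the
#' baseline simulation values; any subset may be overridden by name.
#'
#' @param K carrying capacity (maximum community density).
#' @param r0 baseline intrinsic growth rate at `v = v0` (per model-time unit).
#' @param beta_r exponent of the growth benefit of biomarker production.
#' @param v0 baseline biomarker level; growth, death and the two therapy
#'   effectiveness functions are all anchored at this trait value.
#' @param delta0 baseline natural death rate at `v = v0`.
#' @param beta_delta coefficient of the exponential death cost of production.
#' @param a_max maximum competition coefficient; must exceed 1 so that the
#'   competition kernel is strictly monotone in its exponent argument.
#' @param beta_a competitive benefit coefficient of biomarker production.
#' @param zeta_C chemotherapy intensity (added death rate at `v = v0`).
#' @param m_C chemotherapy resistance coefficient: how fast chemotherapy
#'   effectiveness decays as the biomarker rises.
#' @param zeta_T targeted-therapy intensity (added death rate at `v = v0`).
#' @param m_T targeted-therapy sensitivity exponent: how steeply targeted
#'   effectiveness grows with the biomarker.
#' @param k evolvability: heritable-variation scale converting the selection
#'   gradient into a rate of trait change.
#'
#' @return An object of class `bmg_params` (a named list).
#' @examples
#' p <- model_params()
#' p_strong <- model_params(zeta_C = 0.12, zeta_T = 0.04)
#' @export
model_params <- function(K = 1, r0 = 0.05, beta_r = 1, v0 = 1,
                         delta0 = 0.02, beta_delta = 1,
                         a_max = 2, beta_a = 0.5,
                         zeta_C = 0.03, m_C = 1,
                         zeta_T = 0.01, m_T = 5,
                         k = 0.01) {
  p <- list(K = K, r0 = r0, beta_r = beta_r, v0 = v0,
            delta0 = delta0, beta_delta = beta_delta,
            a_max = a_max, beta_a = beta_a,
            zeta_C = zeta_C, m_C = m_C,
            zeta_T = zeta_T, m_T = m_T, k = k)
  p <- validate_params(p)
  structure(p, class = "bmg_params")
}

validate_params <- function(p) {
  for (nm in names(p)) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  p[] <- lapply(p, as.numeric)
  # k may be exactly zero (frozen trait); everything else is a strictly
  # positive rate or scale
  strict <- setdiff(names(p), "k")
  for (nm in strict) {
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive (got ",
           p[[nm]], ")", call. = FALSE)
  }
  if (p$k < 0)
    stop("parameter 'k' must be non-negative (got ", p$k, ")", call. = FALSE)
  if (p$a_max <= 1)
    stop("parameter 'a_max' must exceed 1 (got ", p$a_max, ")", call. = FALSE)
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced, re-validated.
#'
#' @param p a `bmg_params` object.
#' @param ... named scalar overrides, e.g. `update_params(p, k = 0.5)`.
#' @return A new `bmg_params` object.
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "bmg_params"))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p[names(dots)] <- dots
  p <- validate_params(p)
  structure(p, class = "bmg_params")
}

#' @export
print.bmg_params <- function(x, ...) {
  cat("Biomarker-game model parameters:\n")
  vals <- unlist(x)
  print(vals)
  invisible(x)
}

#' Treatment state
#'
#' A pair of on/off indicators for chemotherapy (`tau_C`) and targeted
#' therapy (`tau_T`) at an instant. Both off is allowed; both on is permitted
#' by the equations though no built-in protocol produces it.
#'
#' @param tau_C chemotherapy indicator, exactly 0 or 1.
#' @param tau_T targeted-therapy indicator, exactly 0 or 1.
#' @return An object of class `bmg_treatment`.
#' @seealso [no_therapy()], [chemo_on()], [targeted_on()]
#' @export
treatment_state <- function(tau_C = 0, tau_T = 0) {
  if (!tau_C %in% c(0, 1) || !tau_T %in% c(0, 1))
    stop("treatment indicators must each be exactly 0 or 1", call. = FALSE)
  structure(list(tau_C = tau_C, tau_T = tau_T), class = "bmg_treatment")
}

#' @rdname treatment_state
#' @export
no_therapy <- function() treatment_state(0, 0)

#' @rdname treatment_state
#' @export
chemo_on <- function() treatment_state(1, 0)

#' @rdname treatment_state
#' @export
targeted_on <- function() treatment_state(0, 1)

#' @export
print.bmg_treatment <- function(x, ...) {
  lab <- if (x$tau_C == 1 && x$tau_T == 1) "chemotherapy + targeted"
         else if (x$tau_C == 1) "chemotherapy"
         else if (x$tau_T == 1) "targeted therapy"
         else "no therapy"
  cat("Treatment state:", lab, "\n")
  invisible(x)
}

treatment_label <- function(trt) {
  if (trt$tau_C == 1 && trt$tau_T == 1) "both"
  else if (trt$tau_C == 1) "chemo"
  else if (trt$tau_T == 1) "targeted"
  else "none"
}

treatment_from_label <- function(label) {
  switch(label,
         none = no_therapy(),
         chemo = chemo_on(),
         targeted = targeted_on(),
         both = treatment_state(1, 1),
         stop("unknown treatment label '", label, "'", call. = FALSE))
}
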