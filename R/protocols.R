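#' Therapy protocol specification
#'
#' Declarative description of a treatment schedule. Fixed variants list
#' phases as (treatment, duration-in-weeks) pairs; adaptive variants carry a
#' switching threshold evaluated at discrete physician visits: the
#' total-marker rule gives chemotherapy while `v * C < T` and targeted
#' therapy while `v * C > T`; the mean-marker rule compares `v` against `M`
#' the same way. Exact equality at the threshold resolves to chemotherapy
#' (the "below" branch) so the rule is deterministic.
#'
#' @param variant one of `"none"`, `"chemo_only"`, `"targeted_only"`,
#'   `"sequential"`, `"adaptive_total"`, `"adaptive_mean"`.
#' @param phases for fixed variants, a data frame with columns `treatment`
#'   (`"none"`, `"chemo"`, `"targeted"`) and `weeks`; defaults to the
#'   standard preset phases of the variant (8 untreated weeks before
#'   diagnosis, then 16-week therapy blocks).
#' @param threshold for adaptive variants: total-marker threshold `T`
#'   (`adaptive_total`) or mean-marker threshold `M` (`adaptive_mean`).
#' @param visit_interval weeks between physician visits (decisions change
#'   only at visits).
#' @param horizon total protocol length in weeks.
#' @param off_threshold optional lower bound for adaptive variants: when the
#'   monitored quantity falls below it, all therapy is withheld. `NULL`
#'   (default) gives pure chemo/targeted switching; no built-in preset
#'   uses it.
#' @param lead_in untreated weeks before the first therapy decision of an
#'   adaptive protocol (the pre-diagnosis period; default 8, matching the
#'   untreated first phase of the fixed presets). Ignored for fixed
#'   variants, whose phases encode it explicitly.
#' @param decision_delay delay (weeks) between measurement and applied
#'   decision; fixed at 0 here, kept as an explicit field for forward
#'   compatibility.
#' @return A `bmg_protocol` object.
#' @examples
#' protocol_spec("sequential")
#' protocol_spec("adaptive_mean", threshold = 1.2, horizon = 100)
#' @export
protocol_spec <- function(variant = c("none", "chemo_only", "targeted_only",
                                      "sequential", "adaptive_total",
                                      "adaptive_mean"),
                          phases = NULL, threshold = NULL,
                          visit_interval = 1, horizon = NULL,
                          off_threshold = NULL, lead_in = 8,
                          decision_delay = 0) {
  variant <- match.arg(variant)
  adaptive <- variant %in% c("adaptive_total", "adaptive_mean")

  if (adaptive) {
    if (is.null(threshold) || threshold <= 0)
      stop("adaptive variants need a strictly positive threshold",
           call. = FALSE)
    if (visit_interval <= 0)
      stop("visit_interval must be positive", call. = FALSE)
    if (lead_in < 0)
      stop("lead_in must be non-negative", call. = FALSE)
    if (is.null(horizon)) horizon <- 100
    phases <- NULL
  } else {
    lead_in <- NULL
    if (is.null(phases)) phases <- default_phases(variant)
    if (!is.data.frame(phases) ||
        !all(c("treatment", "weeks") %in% names(phases)))
      stop("phases must be a data frame with columns treatment, weeks",
           call. = FALSE)
    if (any(phases$weeks <= 0))
      stop("phase durations must be positive", call. = FALSE)
    bad <- setdiff(phases$treatment, c("none", "chemo", "targeted"))
    if (length(bad))
      stop("unknown phase treatment(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    horizon <- sum(phases$weeks)
    threshold <- NULL
  }
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  if (decision_delay != 0)
    stop("decision delays are not implemented; decision_delay must be 0",
         call. = FALSE)

  structure(list(variant = variant, phases = phases, threshold = threshold,
                 visit_interval = visit_interval, horizon = horizon,
                 off_threshold = off_threshold, lead_in = lead_in,
                 decision_delay = decision_delay),
            class = "bmg_protocol")
}

default_phases <- function(variant) {
  switch(variant,
    none = data.frame(treatment = "none", weeks = 24),
    chemo_only = data.frame(treatment = c("none", "chemo"),
                            weeks = c(8, 16)),
    targeted_only = data.frame(treatment = c("none", "targeted"),
                               weeks = c(8, 16)),
    sequential = data.frame(treatment = c("none", "chemo", "targeted"),
                            weeks = c(8, 16, 16)),
    stop("variant '", variant, "' has no default phases", call. = FALSE))
}

#' @export
print.bmg_protocol <- function(x, ...) {
  cat("Therapy protocol:", x$variant, "| horizon", x$horizon, "weeks\n")
  if (!is.null(x$phases)) {
    cum <- cumsum(c(0, x$phases$weeks))
    for (i in seq_len(nrow(x$phases)))
      cat(sprintf("  [%g, %g) weeks: %s\n", cum[i], cum[i + 1],
                  x$phases$treatment[i]))
  } else {
    cat("  threshold:", x$threshold, "| visits every", x$visit_interval,
        "week(s) | lead-in", x$lead_in, "week(s)\n")
  }
  invisible(x)
}

#' Named protocol presets
#'
#' Packaged scenarios: 16-week monotherapy after an 8-week untreated
#' (pre-diagnosis) period, the sequential evolutionary trap
#' (8 weeks none, 16 chemotherapy, 16 targeted), and the low/medium/high
#' threshold adaptive protocols (total-marker thresholds 0.4 / 0.5 / 0.6,
#' mean-marker thresholds 0.8 / 1.2 / 1.6, weekly visits, 100-week horizon).
#'
#' @param name preset name; see `protocol_presets()` for the list.
#' @return A `bmg_protocol` object.
#' @examples
#' protocol_preset("sequential_trap")
#' protocol_presets()
#' @export
protocol_preset <- function(name) {
  presets <- list(
    chemo_16wk = function() protocol_spec("chemo_only"),
    targeted_16wk = function() protocol_spec("targeted_only"),
    sequential_trap = function() protocol_spec("sequential"),
    adaptive_total_low = function()
      protocol_spec("adaptive_total", threshold = 0.4),
    adaptive_total_med = function()
      protocol_spec("adaptive_total", threshold = 0.5),
    adaptive_total_high = function()
      protocol_spec("adaptive_total", threshold = 0.6),
    adaptive_mean_low = function()
      protocol_spec("adaptive_mean", threshold = 0.8),
    adaptive_mean_med = function()
      protocol_spec("adaptive_mean", threshold = 1.2),
    adaptive_mean_high = function()
      protocol_spec("adaptive_mean", threshold = 1.6)
  )
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; see protocol_presets()",
         call. = FALSE)
  presets[[name]]()
}

#' @rdname protocol_preset
#' @export
protocol_presets <- function() {
  c("chemo_16wk", "targeted_16wk", "sequential_trap",
    "adaptive_total_low", "adaptive_total_med", "adaptive_total_high",
    "adaptive_mean_low", "adaptive_mean_med", "adaptive_mean_high")
}

#' Build the schedule of a fixed-phase protocol
#'
#' Converts week-denominated phases into a partition of model time with one
#' constant treatment per interval. Model time is abstract; week durations
#' convert at `time_units_per_week`. The conversion rescales speed only,
#' never equilibria or ESS values; the default of 100 calibrates a 16-week
#' therapy block to contain both the ecological relaxation and the trait
#' evolution the protocols rely on.
#'
#' @param spec a fixed-variant [protocol_spec()].
#' @param time_units_per_week model-time units per week.
#' @return A `bmg_schedule`: data frame with columns `start`, `end`,
#'   `tau_C`, `tau_T` partitioning `[0, horizon]`.
#' @export
build_fixed_schedule <- function(spec, time_units_per_week = 100) {
  stopifnot(inherits(spec, "bmg_protocol"))
  if (is.null(spec$phases))
    stop("build_fixed_schedule requires a fixed-phase protocol; use ",
         "run_adaptive() for adaptive variants", call. = FALSE)
  cum <- cumsum(c(0, spec$phases$weeks)) * time_units_per_week
  trts <- lapply(spec$phases$treatment, treatment_from_label)
  new_schedule(start = cum[-length(cum)], end = cum[-1],
               tau_C = vapply(trts, `[[`, numeric(1), "tau_C"),
               tau_T = vapply(trts, `[[`, numeric(1), "tau_T"),
               time_units_per_week = time_units_per_week)
}

new_schedule <- function(start, end, tau_C, tau_T, time_units_per_week) {
  df <- data.frame(start = start, end = end, tau_C = tau_C, tau_T = tau_T)
  if (any(df$end <= df$start))
    stop("schedule intervals must have positive length", call. = FALSE)
  if (any(df$tau_C + df$tau_T > 1))
    stop("at most one therapy may be active per interval", call. = FALSE)
  structure(df, time_units_per_week = time_units_per_week,
            class = c("bmg_schedule", "data.frame"))
}

#' Threshold decision rule of an adaptive protocol
#'
#' Applies the switching rule to an observed state: for `adaptive_total`,
#' chemotherapy iff `v * C <= T`, otherwise targeted therapy; for
#' `adaptive_mean`, chemotherapy iff `v <= M`. If `off_threshold` is set and
#' the monitored quantity falls below it, no therapy is given. The rule is a
#' pure function of the state, so re-evaluating it between visits never
#' changes the applied treatment.
#'
#' @param state list or named vector with elements `C` and `v`.
#' @param spec an adaptive [protocol_spec()].
#' @return A [treatment_state()].
#' @examples
#' sp <- protocol_spec("adaptive_total", threshold = 0.5)
#' adaptive_decision(list(C = 0.6, v = 1), sp)  # vC = 0.6 > 0.5: targeted
#' @export
adaptive_decision <- function(state, spec) {
  stopifnot(inherits(spec, "bmg_protocol"))
  if (!spec$variant %in% c("adaptive_total", "adaptive_mean"))
    stop("adaptive_decision requires an adaptive protocol variant",
         call. = FALSE)
  obs <- if (spec$variant == "adaptive_total") state$v * state$C else state$v
  if (!is.null(spec$off_threshold) && obs < spec$off_threshold)
    return(no_therapy())
  if (obs <= spec$threshold) chemo_on() else targeted_on()
}

#' Run an adaptive (threshold-triggered) therapy protocol
#'
#' After the untreated lead-in (the pre-diagnosis period), integrates the
#' monomorphic dynamics visit by visit: at diagnosis and at every subsequent
#' visit the decision rule is evaluated on the current state, and the chosen
#' treatment is held constant until the next visit. The trajectory is
#' continuous in `C` and `v` across switches; only the vector field jumps.
#' A run in which the treatment never switches cannot set an evolutionary
#' trap and is flagged as degenerate (attribute `degenerate`).
#'
#' @param params a [model_params()] object.
#' @param spec an adaptive [protocol_spec()].
#' @param init named vector `c(C = ..., v = ...)` at time 0.
#' @param time_units_per_week model-time units per week.
#' @param rtol,atol,sample_dt solver options as in [simulate_monomorphic()].
#' @return A `bmg_trajectory` with attributes `n_switches` and `degenerate`.
#' @export
run_adaptive <- function(params, spec, init = c(C = 0.1, v = 1),
                         time_units_per_week = 100,
                         rtol = 1e-8, atol = 1e-10, sample_dt = 0.25) {
  stopifnot(inherits(params, "bmg_params"), inherits(spec, "bmg_protocol"))
  if (!spec$variant %in% c("adaptive_total", "adaptive_mean"))
    stop("run_adaptive requires an adaptive protocol variant", call. = FALSE)

  lead <- spec$lead_in * time_units_per_week
  n_visits <- ceiling(spec$horizon / spec$visit_interval)
  bounds <- lead +
    pmin(seq_len(n_visits) * spec$visit_interval, spec$horizon) *
    time_units_per_week
  starts <- c(lead, utils::head(bounds, -1))

  state <- init
  traj <- NULL
  decisions <- integer(0)
  if (lead > 0) {
    sch0 <- new_schedule(0, lead, 0, 0, time_units_per_week)
    traj <- simulate_monomorphic(params, sch0, init = state,
                                 rtol = rtol, atol = atol,
                                 sample_dt = sample_dt)
    n <- length(traj$times)
    state <- c(C = traj$C[n], v = traj$v[n])
  }
  for (i in seq_len(n_visits)) {
    trt <- adaptive_decision(list(C = state[["C"]], v = state[["v"]]), spec)
    decisions <- c(decisions, trt$tau_C + 2L * trt$tau_T)
    sch <- new_schedule(starts[i], bounds[i], trt$tau_C, trt$tau_T,
                        time_units_per_week)
    seg <- tryCatch(
      simulate_monomorphic(params, sch, init = state,
                           rtol = rtol, atol = atol, sample_dt = sample_dt),
      error = function(e)
        stop("adaptive run failed at visit ", i, ": ", conditionMessage(e),
             call. = FALSE))
    # shift segment times from 0-origin back to absolute protocol time
    seg$times <- seg$times - seg$times[1] + starts[i]
    traj <- if (is.null(traj)) seg else append_trajectory(traj, seg)
    n <- length(seg$times)
    state <- c(C = seg$C[n], v = seg$v[n])
  }

  # switches are changes between successive visit decisions; the onset of
  # therapy after the untreated lead-in is not a switch
  n_sw <- sum(diff(decisions) != 0)
  attr(traj, "n_switches") <- n_sw
  attr(traj, "degenerate") <- n_sw == 0L
  attr(traj, "protocol") <- spec
  traj
}

append_trajectory <- function(a, b) {
  keep <- -1L  # drop duplicated junction point
  new_trajectory(c(a$times, b$times[keep]),
                 c(a$C, b$C[keep]),
                 c(a$v, b$v[keep]),
                 c(a$tau_C, b$tau_C[keep]),
                 c(a$tau_T, b$tau_T[keep]),
                 time_units_per_week = attr(a, "time_units_per_week"))
}

#' Chemotherapy-targeted therapy balance point
#'
#' The biomarker level at which the two therapies are equally effective,
#' i.e. the root of `E_C(v) - E_T(v)`. Thresholds near this balance produce
#' frequent treatment switching; thresholds far from it leave time for
#' evolutionary traps.
#'
#' @param p a [model_params()] object.
#' @param bracket trait interval containing a sign change of `E_C - E_T`.
#' @return The balance trait `v_b`, with `|E_C(v_b) - E_T(v_b)| <= 1e-12`.
#' @examples
#' balance_point(model_params())  # about 1.2
#' @export
balance_point <- function(p, bracket = c(0.1, 5)) {
  f <- function(v) chemo_effect(v, p) - targeted_effect(v, p)
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("E_C - E_T does not change sign on the bracket [",
         bracket[1], ", ", bracket[2], "]", call. = FALSE)
  root <- stats::uniroot(f, bracket, tol = 1e-14)$root
  # polish with Newton steps so the residual itself is at machine level
  for (i in 1:5) {
    fr <- f(root)
    if (abs(fr) <= 1e-13) break
    dfr <- -p$m_C * chemo_effect(root, p) -
      p$m_T / root * targeted_effect(root, p)
    root <- root - fr / dfr
  }
  if (abs(f(root)) > 1e-12)
    stop("balance point root-finding did not converge", call. = FALSE)
  root
}
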