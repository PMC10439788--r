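#' Bias of total-biomarker readouts of therapeutic efficacy
#'
#' Compares the proportional change of the true population size with the
#' proportional change of the total biomarker `v * C` across the therapy
#' window of a fixed protocol (first instant therapy turns on to the final
#' instant of the last therapy phase). When the trait evolves upward under
#' chemotherapy, total marker shrinks less than the population and a
#' marker-based readout *underestimates* efficacy; targeted therapy drives
#' the trait down, so the marker-based readout *overestimates* efficacy.
#' With evolvability zero the two ratios agree exactly.
#'
#' @param spec a fixed-variant [protocol_spec()] containing at least one
#'   therapy phase.
#' @param params a [model_params()] object.
#' @param init,time_units_per_week,... passed to [simulate_monomorphic()].
#' @return A one-row data frame: `protocol`, `pop_ratio` (`C_end/C_start`),
#'   `marker_ratio` (`(vC)_end/(vC)_start`) and `bias_direction` in
#'   `{"underestimate", "overestimate", "none"}`.
#' @examples
#' efficacy_bias(protocol_preset("chemo_16wk"), model_params())
#' @export
efficacy_bias <- function(spec, params, init = c(C = 0.1, v = 1),
                          time_units_per_week = 100, ...) {
  stopifnot(inherits(spec, "bmg_protocol"))
  if (is.null(spec$phases))
    stop("efficacy_bias requires a fixed-phase protocol", call. = FALSE)
  on_therapy <- spec$phases$treatment != "none"
  if (!any(on_therapy))
    stop("protocol has no therapy phase; the therapy window is undefined",
         call. = FALSE)
  sch <- build_fixed_schedule(spec, time_units_per_week)
  traj <- simulate_monomorphic(params, sch, init = init, ...)

  cum <- cumsum(c(0, spec$phases$weeks)) * time_units_per_week
  t_on <- cum[min(which(on_therapy))]
  t_off <- cum[max(which(on_therapy)) + 1]
  i0 <- which.min(abs(traj$times - t_on))
  i1 <- which.min(abs(traj$times - t_off))

  pop_ratio <- traj$C[i1] / traj$C[i0]
  marker_ratio <- traj$total_marker[i1] / traj$total_marker[i0]
  tol <- 1e-9
  bias <- if (marker_ratio > pop_ratio * (1 + tol)) "underestimate"
          else if (marker_ratio < pop_ratio * (1 - tol)) "overestimate"
          else "none"
  data.frame(protocol = spec$variant, pop_ratio = pop_ratio,
             marker_ratio = marker_ratio, bias_direction = bias)
}

#' Evaluate the sequential evolutionary trap against monotherapies
#'
#' Simulates the chemotherapy-only, targeted-only and sequential
#' (chemotherapy then targeted) protocols from a common initial state and
#' reports the population minimum of each full trajectory. Chemotherapy
#' first selects for high biomarker production, which maximises
#' vulnerability to the subsequent targeted phase — the evolutionary trap —
#' so with appreciable trait motion within the phases the sequential
#' minimum falls below both monotherapy minima.
#'
#' @param params a [model_params()] object.
#' @param init,time_units_per_week,... passed to [simulate_monomorphic()].
#' @return Data frame with columns `protocol`, `min_C`, `t_min` (time of
#'   the minimum) and `final_v`.
#' @examples
#' trap_evaluation(update_params(model_params(), k = 0.5))
#' @export
trap_evaluation <- function(params, init = c(C = 0.1, v = 1),
                            time_units_per_week = 100, ...) {
  variants <- c("chemo_only", "targeted_only", "sequential")
  rows <- lapply(variants, function(vr) {
    sch <- build_fixed_schedule(protocol_spec(vr), time_units_per_week)
    traj <- simulate_monomorphic(params, sch, init = init, ...)
    i <- which.min(traj$C)
    data.frame(protocol = vr, min_C = traj$C[i], t_min = traj$times[i],
               final_v = traj$v[length(traj$v)])
  })
  do.call(rbind, rows)
}

#' Sweep adaptive-therapy thresholds
#'
#' Runs an adaptive protocol over a list of thresholds and records the
#' population minimum and switch count of each run. The minimum is taken
#' from diagnosis onward: the untreated lead-in describes tumour growth
#' before any therapy decision and would otherwise mask the protocols'
#' differences with the common starting density. Runs whose treatment
#' never switches cannot set a trap and are excluded from the admissible
#' set (flagged, not dropped from the table).
#'
#' @param variant `"adaptive_total"` or `"adaptive_mean"`.
#' @param thresholds numeric vector of threshold values to sweep.
#' @param params a [model_params()] object.
#' @param horizon protocol horizon in weeks.
#' @param visit_interval weeks between visits.
#' @param init,time_units_per_week,... passed to [run_adaptive()].
#' @return A `bmg_sweep` data frame: `threshold`, `min_C`, `n_switches`,
#'   `admissible`; the parameter snapshot is stored in the `params`
#'   attribute so each row is reproducible.
#' @export
threshold_sweep <- function(variant = c("adaptive_total", "adaptive_mean"),
                            thresholds, params, horizon = 100,
                            visit_interval = 1,
                            init = c(C = 0.1, v = 1),
                            time_units_per_week = 100, ...) {
  variant <- match.arg(variant)
  rows <- lapply(thresholds, function(th) {
    spec <- protocol_spec(variant, threshold = th,
                          visit_interval = visit_interval, horizon = horizon)
    traj <- run_adaptive(params, spec, init = init,
                         time_units_per_week = time_units_per_week, ...)
    post <- traj$times >= spec$lead_in * time_units_per_week
    data.frame(threshold = th, min_C = min(traj$C[post]),
               n_switches = attr(traj, "n_switches"),
               admissible = !attr(traj, "degenerate"))
  })
  out <- do.call(rbind, rows)
  if (!any(out$admissible))
    stop("no threshold in the sweep produces a treatment switch; ",
         "the admissible set is empty", call. = FALSE)
  structure(out, params = params, variant = variant,
            class = c("bmg_sweep", "data.frame"))
}

#' Sensitivity of the trap minimum to competition and evolvability
#'
#' Runs the sequential-trap protocol across a range of values of the
#' competitive benefit `beta_a` or the evolvability `k`, at low
#' (`zeta_C = 0.03`, `zeta_T = 0.01`) or high (`zeta_C = 0.12`,
#' `zeta_T = 0.04`) therapy intensity, and records the population minimum
#' for each value.
#'
#' @param param `"beta_a"` or `"k"`.
#' @param values positive parameter values to sweep.
#' @param intensity `"low"` or `"high"` therapy intensity.
#' @param params baseline [model_params()]; the swept field and the
#'   intensity pair are overridden per run.
#' @param init,time_units_per_week,... passed to [simulate_monomorphic()].
#' @return A `bmg_sweep` data frame: `value`, `min_C`; the swept name,
#'   intensity and baseline snapshot are stored as attributes.
#' @export
sensitivity_sweep <- function(param = c("beta_a", "k"), values,
                              intensity = c("low", "high"),
                              params = model_params(),
                              init = c(C = 0.1, v = 1),
                              time_units_per_week = 100, ...) {
  param <- match.arg(param)
  intensity <- match.arg(intensity)
  if (any(values < 0) || (param == "beta_a" && any(values <= 0)))
    stop("swept values must be positive", call. = FALSE)
  zeta <- if (intensity == "high") c(zeta_C = 0.12, zeta_T = 0.04)
          else c(zeta_C = 0.03, zeta_T = 0.01)
  base <- update_params(params, zeta_C = zeta[["zeta_C"]],
                        zeta_T = zeta[["zeta_T"]])
  sch <- build_fixed_schedule(protocol_spec("sequential"),
                              time_units_per_week)
  rows <- lapply(values, function(val) {
    p_i <- do.call(update_params, c(list(base), stats::setNames(val, param)))
    traj <- simulate_monomorphic(p_i, sch, init = init, ...)
    data.frame(value = val, min_C = min(traj$C))
  })
  out <- do.call(rbind, rows)
  structure(out, params = base, param = param, intensity = intensity,
            class = c("bmg_sweep", "data.frame"))
}
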