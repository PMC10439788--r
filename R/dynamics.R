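#' Simulate the coupled ecological-evolutionary dynamics
#'
#' Integrates the monomorphic system
#' `dC/dt = G(v, v, C) C` and `dv/dt = k * dG/dv|v=u`
#' piecewise over the intervals of a treatment [schedule]: treatment is
#' constant within each interval and the integrator restarts at every
#' breakpoint, so no discontinuity is ever integrated across.
#'
#' @param params a [model_params()] object.
#' @param schedule a `bmg_schedule`, e.g. from [build_fixed_schedule()].
#' @param init named numeric vector `c(C = ..., v = ...)`: population density
#'   and mean biomarker level at time 0.
#' @param rtol,atol relative and absolute solver tolerances (lsoda).
#' @param sample_dt output sampling step in model-time units; dense enough
#'   to locate population minima accurately.
#' @return A `bmg_trajectory`: time series of density `C`, mean marker `v`,
#'   total marker `v * C`, and the active treatment indicators.
#' @examples
#' p <- model_params()
#' sch <- build_fixed_schedule(protocol_spec("sequential"))
#' tr <- simulate_monomorphic(p, sch)
#' min(tr$C)
#' @export
simulate_monomorphic <- function(params, schedule,
                                 init = c(C = 0.1, v = 1),
                                 rtol = 1e-8, atol = 1e-10,
                                 sample_dt = 0.25) {
  stopifnot(inherits(params, "bmg_params"), inherits(schedule, "bmg_schedule"))
  if (!all(c("C", "v") %in% names(init)))
    stop("init must be a named vector with elements C and v", call. = FALSE)
  if (init[["C"]] < 0 || init[["v"]] <= 0)
    stop("init requires C >= 0 and v > 0", call. = FALSE)

  # Integrate log-density: d(log C)/dt = G(v, v, C). The deep population
  # crashes of trap protocols reach minima many orders of magnitude below
  # any absolute tolerance; in log scale they are resolved to the relative
  # tolerance throughout, and non-negativity holds by construction.
  rhs <- function(t, y, parms) {
    C <- exp(y[1])
    v <- max(y[2], 1e-12)
    trt <- parms$trt
    dlogC <- fitness(v, v, C, trt, params)
    dv <- params$k * selection_gradient(v, C, trt, params)
    list(c(dlogC, dv))
  }
  if (init[["C"]] == 0)
    stop("init C must be strictly positive (a population of density 0 ",
         "stays extinct)", call. = FALSE)

  state <- c(log(init[["C"]]), init[["v"]])
  times_all <- numeric(0)
  C_all <- numeric(0)
  v_all <- numeric(0)
  tauC_all <- numeric(0)
  tauT_all <- numeric(0)

  for (i in seq_len(nrow(schedule))) {
    t0 <- schedule$start[i]
    t1 <- schedule$end[i]
    trt <- treatment_state(schedule$tau_C[i], schedule$tau_T[i])
    times <- segment_times(t0, t1, sample_dt)
    sol <- try(deSolve::lsoda(y = state, times = times, func = rhs,
                              parms = list(trt = trt),
                              rtol = rtol, atol = atol), silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < length(times))
      stop(sprintf("integration failed on interval [%g, %g]", t0, t1),
           call. = FALSE)
    keep <- if (length(times_all)) -1L else seq_len(nrow(sol))
    times_all <- c(times_all, sol[keep, 1])
    C_all <- c(C_all, exp(sol[keep, 2]))
    v_all <- c(v_all, sol[keep, 3])
    tauC_all <- c(tauC_all, rep(trt$tau_C, length(sol[keep, 1])))
    tauT_all <- c(tauT_all, rep(trt$tau_T, length(sol[keep, 1])))
    state <- c(sol[nrow(sol), 2], sol[nrow(sol), 3])
  }

  new_trajectory(times_all, C_all, v_all, tauC_all, tauT_all,
                 time_units_per_week = attr(schedule, "time_units_per_week"))
}

segment_times <- function(t0, t1, dt) {
  n <- max(2L, ceiling((t1 - t0) / dt) + 1L)
  seq(t0, t1, length.out = n)
}

new_trajectory <- function(times, C, v, tau_C, tau_T,
                           time_units_per_week = NULL) {
  structure(list(times = times, C = C, v = v,
                 total_marker = v * C,
                 tau_C = tau_C, tau_T = tau_T),
            time_units_per_week = time_units_per_week,
            class = "bmg_trajectory")
}

#' @export
as.data.frame.bmg_trajectory <- function(x, ...) {
  data.frame(time = x$times, C = x$C, v = x$v,
             total_marker = x$total_marker,
             tau_C = x$tau_C, tau_T = x$tau_T)
}

#' @export
print.bmg_trajectory <- function(x, ...) {
  cat("Eco-evolutionary trajectory:", length(x$times), "time points on [",
      format(min(x$times)), ",", format(max(x$times)), "]\n")
  cat(sprintf("  C: start %.4g, min %.4g, end %.4g\n",
              x$C[1], min(x$C), x$C[length(x$C)]))
  cat(sprintf("  v: start %.4g, range [%.4g, %.4g], end %.4g\n",
              x$v[1], min(x$v), max(x$v), x$v[length(x$v)]))
  sw <- treatment_switches(x)
  cat("  treatment switches:", length(sw), "\n")
  invisible(x)
}

#' @export
summary.bmg_trajectory <- function(object, ...) {
  i_min <- which.min(object$C)
  out <- list(
    min_C = object$C[i_min],
    t_min = object$times[i_min],
    final_C = object$C[length(object$C)],
    final_v = object$v[length(object$v)],
    n_switches = length(treatment_switches(object))
  )
  class(out) <- "summary.bmg_trajectory"
  out
}

#' @export
print.summary.bmg_trajectory <- function(x, ...) {
  cat(sprintf("population minimum %.6g at t = %.4g\n", x$min_C, x$t_min))
  cat(sprintf("final state: C = %.6g, v = %.6g; %d treatment switch(es)\n",
              x$final_C, x$final_v, x$n_switches))
  invisible(x)
}

# indices at which the applied treatment changes
treatment_switches <- function(traj) {
  code <- traj$tau_C + 2 * traj$tau_T
  which(diff(code) != 0)
}

#' Plot a trajectory
#'
#' Three stacked panels: population density, mean biomarker, and total
#' biomarker, with chemotherapy and targeted-therapy periods shaded.
#'
#' @param x a `bmg_trajectory`.
#' @param ... passed to the panel `plot()` calls.
#' @export
plot.bmg_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1, 1))
  on.exit(graphics::par(op))
  panels <- list(
    list(y = x$C, ylab = "population density C"),
    list(y = x$v, ylab = "mean biomarker v"),
    list(y = x$total_marker, ylab = "total biomarker vC")
  )
  for (pn in panels) {
    plot(x$times, pn$y, type = "l", xlab = "model time", ylab = pn$ylab, ...)
    shade_treatment(x)
    graphics::lines(x$times, pn$y)
  }
  invisible(x)
}

shade_treatment <- function(traj) {
  usr <- graphics::par("usr")
  runs <- rle(traj$tau_C + 2 * traj$tau_T)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  for (j in seq_along(runs$values)) {
    if (runs$values[j] == 0) next
    col <- if (runs$values[j] == 1) grDevices::adjustcolor("grey40", 0.25)
           else grDevices::adjustcolor("red", 0.2)
    graphics::rect(traj$times[starts[j]], usr[3], traj$times[ends[j]], usr[4],
                   col = col, border = NA)
  }
}

#' Simulate a polymorphic community of fixed biomarker types
#'
#' Integrates the multi-type Lotka-Volterra competition system
#' `dC_i/dt = r(v_i) C_i (1 - sum_j a(v_i, v_j) C_j / K) - delta(v_i) C_i`
#' with therapy entering as the additional per-capita death
#' `E_C(v_i) tau_C + E_T(v_i) tau_T`, the unique extension consistent with
#' the fitness-generating function. Types have fixed traits (no mutation);
#' this system serves as the mechanistic cross-check for the monomorphic
#' approximation and for invasion-fitness signs.
#'
#' @param params a [model_params()] object.
#' @param traits numeric vector of distinct biomarker levels, all positive.
#' @param densities initial densities, non-negative, same length.
#' @param schedule a `bmg_schedule`.
#' @param rtol,atol solver tolerances.
#' @param sample_dt output sampling step.
#' @return A list of class `bmg_poly_trajectory` with `times`, the density
#'   matrix `C` (time x type), per-type `traits`, aggregate `total` density
#'   and density-weighted `mean_v`.
#' @examples
#' p <- model_params()
#' sch <- build_fixed_schedule(protocol_spec("none"))
#' out <- simulate_polymorphic(p, traits = c(1, 1.2),
#'                             densities = c(0.6, 1e-6), sch)
#' @export
simulate_polymorphic <- function(params, traits, densities, schedule,
                                 rtol = 1e-8, atol = 1e-10,
                                 sample_dt = 0.25) {
  stopifnot(inherits(params, "bmg_params"), inherits(schedule, "bmg_schedule"))
  check_trait(traits, "trait vector")
  if (length(traits) != length(densities))
    stop("traits and densities must have the same length", call. = FALSE)
  if (anyDuplicated(traits))
    stop("traits must be distinct", call. = FALSE)
  if (any(densities < 0))
    stop("densities must be non-negative", call. = FALSE)

  n <- length(traits)
  r_i <- intrinsic_growth(traits, params)
  d_i <- natural_death(traits, params)
  # competition matrix A[i, j] = a(v_i, v_j): effect of type j on type i
  A <- outer(traits, traits,
             function(vi, vj) competition_coeff(vi, vj, params))

  rhs <- function(t, y, parms) {
    C <- pmax(y, 0)
    extra <- parms$extra_death
    dC <- r_i * C * (1 - as.vector(A %*% C) / params$K) - d_i * C - extra * C
    list(dC)
  }

  state <- densities
  times_all <- numeric(0)
  C_all <- NULL
  tauC_all <- numeric(0)
  tauT_all <- numeric(0)

  for (i in seq_len(nrow(schedule))) {
    trt <- treatment_state(schedule$tau_C[i], schedule$tau_T[i])
    extra <- therapy_death(traits, trt, params)
    if (length(extra) == 1L) extra <- rep(extra, n)
    times <- segment_times(schedule$start[i], schedule$end[i], sample_dt)
    sol <- try(deSolve::lsoda(y = state, times = times, func = rhs,
                              parms = list(extra_death = extra),
                              rtol = rtol, atol = atol), silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < length(times))
      stop(sprintf("integration failed on interval [%g, %g]",
                   schedule$start[i], schedule$end[i]), call. = FALSE)
    keep <- if (length(times_all)) -1L else seq_len(nrow(sol))
    times_all <- c(times_all, sol[keep, 1])
    Cm <- pmax(sol[keep, -1, drop = FALSE], 0)
    C_all <- rbind(C_all, Cm)
    tauC_all <- c(tauC_all, rep(trt$tau_C, length(sol[keep, 1])))
    tauT_all <- c(tauT_all, rep(trt$tau_T, length(sol[keep, 1])))
    state <- pmax(sol[nrow(sol), -1], 0)
  }

  total <- rowSums(C_all)
  mean_v <- ifelse(total > 0, as.vector(C_all %*% traits) / total, NA_real_)
  structure(list(times = times_all, C = unname(C_all), traits = traits,
                 total = total, mean_v = mean_v,
                 tau_C = tauC_all, tau_T = tauT_all),
            class = "bmg_poly_trajectory")
}

#' @export
print.bmg_poly_trajectory <- function(x, ...) {
  cat("Polymorphic trajectory:", length(x$traits), "types,",
      length(x$times), "time points\n")
  cat("  traits:", paste(format(x$traits), collapse = ", "), "\n")
  cat(sprintf("  total density: start %.4g, end %.4g\n",
              x$total[1], x$total[length(x$total)]))
  invisible(x)
}

#' Write a trajectory to CSV or JSON
#'
#' Format follows the file extension. CSV columns are
#' `time, C, v, total_marker, tau_C, tau_T` in plain decimal notation with
#' 12 significant digits; JSON holds the same records at full precision.
#'
#' @param traj a `bmg_trajectory`.
#' @param path output file path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "columns", digits = NA)
  } else {
    df[] <- lapply(df, function(x)
      format(x, digits = 12, scientific = FALSE, trim = TRUE))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
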