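# Independent numerical oracles used across the suite. These deliberately
# avoid the package's analytic code paths so that agreement is evidence,
# not tautology.

# central finite difference of the fitness function in its focal argument
fd_gradient <- function(u, C, trt, p, h = 1e-6) {
  (fitness(u + h, u, C, trt, p) - fitness(u - h, u, C, trt, p)) / (2 * h)
}

# plain bisection root-finder
bisect <- function(f, lo, hi, tol = 1e-13, maxit = 200) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

phase_label <- function(trt) {
  if (trt$tau_C == 1) "chemo" else if (trt$tau_T == 1) "targeted" else "none"
}

# schedule holding one treatment constant for `len` model-time units
constant_schedule <- function(len, trt) {
  spec <- protocol_spec("none",
                        phases = data.frame(treatment = phase_label(trt),
                                            weeks = len))
  build_fixed_schedule(spec, time_units_per_week = 1)
}

# initial per-capita growth rate of a rare mutant against a resident at its
# ecological equilibrium, measured from a short two-type Lotka-Volterra
# integration rather than from the fitness function
invasion_growth_ode <- function(v_res, v_mut, trt, p, len = 2) {
  C_res <- equilibrium_pop(v_res, trt, p)
  stopifnot(C_res > 0)
  out <- simulate_polymorphic(p, traits = c(v_res, v_mut),
                              densities = c(C_res, 1e-6),
                              constant_schedule(len, trt),
                              sample_dt = len / 4)
  n <- length(out$times)
  log(out$C[n, 2] / out$C[1, 2]) / (out$times[n] - out$times[1])
}
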