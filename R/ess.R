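#' Solve for the evolutionarily stable strategy under a constant treatment
#'
#' The ESS is the trait where the fitness-generating function attains its
#' maximum in the focal argument at the resident value, with the resident at
#' its ecological equilibrium. The two conditions `G = 0` and
#' `dG/dv|v=u = 0` reduce to one dimension: since `a(v, v) = 1`, solving
#' `G = 0` for the density gives
#' `C = K (1 - (delta(v) + E(v)) / r(v))` exactly, which is substituted
#' into the selection gradient; the gradient root is then found by bracketed
#' scalar root-finding. The second-order (maximum) condition is verified by
#' checking the gradient changes sign from positive to negative across the
#' root.
#'
#' @param trt a [treatment_state()].
#' @param p a [model_params()] object.
#' @param bracket trait interval searched for the gradient root.
#' @return A `bmg_ess` list: `v_ess`, `C_ess`, the residuals `G` and
#'   `gradient` at the solution, and the `treatment` label.
#' @examples
#' solve_ess(no_therapy(), model_params())   # v* about 1.48
#' solve_ess(chemo_on(), model_params())     # v* about 1.97
#' @export
solve_ess <- function(trt = no_therapy(), p = model_params(),
                      bracket = c(0.1, 5)) {
  g <- function(v) {
    C <- equilibrium_pop(v, trt, p)
    selection_gradient(v, C, trt, p)
  }
  glo <- g(bracket[1]); ghi <- g(bracket[2])
  if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0)
    stop("no sign change of the reduced selection gradient on the bracket [",
         bracket[1], ", ", bracket[2], "]", call. = FALSE)
  v_star <- stats::uniroot(g, bracket, tol = 1e-13)$root
  # Newton polish on the 1-D root so |gradient| reaches machine level
  h <- 1e-6
  for (i in 1:8) {
    gv <- g(v_star)
    if (abs(gv) <= 1e-12) break
    dg <- (g(v_star + h) - g(v_star - h)) / (2 * h)
    v_star <- v_star - gv / dg
  }
  C_star <- equilibrium_pop(v_star, trt, p)
  if (C_star <= 0)
    stop("gradient root has non-positive equilibrium density; ",
         "the population cannot persist under this treatment", call. = FALSE)
  # second-order condition: selection pushes toward v* from both sides
  eps <- 1e-4
  if (!(g(v_star - eps) > 0 && g(v_star + eps) < 0))
    stop("gradient root is not a fitness maximum (fails the ESS ",
         "second-order condition)", call. = FALSE)
  structure(list(v_ess = v_star, C_ess = C_star,
                 G = fitness(v_star, v_star, C_star, trt, p),
                 gradient = selection_gradient(v_star, C_star, trt, p),
                 treatment = treatment_label(trt)),
            class = "bmg_ess")
}

#' @export
print.bmg_ess <- function(x, ...) {
  cat(sprintf("ESS under %s: v* = %.4f, C* = %.4f (|G| = %.1e, |dG/dv| = %.1e)\n",
              x$treatment, x$v_ess, x$C_ess, abs(x$G), abs(x$gradient)))
  invisible(x)
}

#' ESS table across the three treatment conditions
#'
#' Convenience wrapper running [solve_ess()] with therapy off, under
#' constant chemotherapy, and under constant targeted therapy.
#'
#' @param p a [model_params()] object.
#' @param bracket passed to [solve_ess()].
#' @return Data frame with columns `treatment`, `v_ess`, `C_ess`.
#' @examples
#' ess_table(model_params())
#' @export
ess_table <- function(p = model_params(), bracket = c(0.1, 5)) {
  trts <- list(none = no_therapy(), chemo = chemo_on(),
               targeted = targeted_on())
  rows <- lapply(names(trts), function(nm) {
    e <- solve_ess(trts[[nm]], p, bracket)
    data.frame(treatment = nm, v_ess = e$v_ess, C_ess = e$C_ess)
  })
  do.call(rbind, rows)
}

#' Pairwise invasibility plot grid
#'
#' Sign of the invasion fitness of a rare mutant against each resident on a
#' grid, with the resident held at its ecological equilibrium under the
#' given treatment:
#' `s(v_mut, v_res) = G(v_mut, v_res, C*(v_res))`. Signs within `1e-12` of
#' zero map to 0, so the diagonal is identically 0. Residents whose
#' equilibrium density is zero cannot define an invasion environment; their
#' columns are flagged `NA` rather than silently skipped.
#'
#' @param trt a [treatment_state()].
#' @param p a [model_params()] object.
#' @param resident_grid,mutant_grid strictly increasing trait grids
#'   (defaults: 200 points on `[0.25, 2.5]`).
#' @return A `bmg_pip` list: the grids, the `invasion_sign` matrix
#'   (mutant rows x resident columns) with entries in `{-1, 0, 1, NA}`, and
#'   the logical vector `resident_viable`.
#' @examples
#' pip <- pip_grid(no_therapy(), model_params(),
#'                 resident_grid = seq(0.5, 2.5, length.out = 50),
#'                 mutant_grid = seq(0.5, 2.5, length.out = 50))
#' @export
pip_grid <- function(trt = no_therapy(), p = model_params(),
                     resident_grid = seq(0.25, 2.5, length.out = 200),
                     mutant_grid = seq(0.25, 2.5, length.out = 200)) {
  if (is.unsorted(resident_grid, strictly = TRUE) ||
      is.unsorted(mutant_grid, strictly = TRUE))
    stop("trait grids must be strictly increasing", call. = FALSE)
  C_star <- equilibrium_pop(resident_grid, trt, p)
  viable <- C_star > 0
  sgn <- matrix(NA_real_, nrow = length(mutant_grid),
                ncol = length(resident_grid))
  for (j in which(viable)) {
    s <- fitness(mutant_grid, resident_grid[j], C_star[j], trt, p)
    sgn[, j] <- ifelse(abs(s) < 1e-12, 0, sign(s))
  }
  structure(list(resident_values = resident_grid,
                 mutant_values = mutant_grid,
                 invasion_sign = sgn,
                 resident_viable = viable,
                 treatment = treatment_label(trt)),
            class = "bmg_pip")
}

#' @export
print.bmg_pip <- function(x, ...) {
  cat(sprintf("Pairwise invasibility grid (%s): %d mutants x %d residents\n",
              x$treatment, length(x$mutant_values),
              length(x$resident_values)))
  n_flag <- sum(!x$resident_viable)
  if (n_flag)
    cat("  ", n_flag, "resident(s) with zero equilibrium flagged NA\n")
  invisible(x)
}

#' @export
plot.bmg_pip <- function(x, ...) {
  graphics::image(x$resident_values, x$mutant_values,
                  t(x$invasion_sign),
                  col = c("black", "grey50", "red"),
                  xlab = "resident biomarker", ylab = "mutant biomarker",
                  ...)
  graphics::abline(0, 1, col = "white", lty = 2)
  invisible(x)
}

#' Write a PIP sign matrix to CSV
#'
#' @param pip a `bmg_pip` object.
#' @param path output file path; rows are mutant values, columns resident
#'   values (named `res_<value>`).
#' @return `path`, invisibly.
#' @export
write_pip <- function(pip, path) {
  df <- as.data.frame(pip$invasion_sign)
  names(df) <- paste0("res_", format(pip$resident_values, trim = TRUE))
  df <- cbind(mutant = pip$mutant_values, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Equilibrium population size as a function of the biomarker
#'
#' Elementwise [equilibrium_pop()] over a trait grid: the curve whose
#' maximum (with therapy off) sits at the baseline `v0`, the group optimum.
#' Competition drives the ESS above that optimum — a cellular tragedy of
#' the commons — so the equilibrium density at the ESS is strictly below
#' the curve's maximum.
#'
#' @param trt a [treatment_state()].
#' @param p a [model_params()] object.
#' @param grid trait grid.
#' @return Data frame with columns `v` and `C_star`.
#' @export
equilibrium_curve <- function(trt = no_therapy(), p = model_params(),
                              grid = seq(0.25, 2.5, length.out = 200)) {
  data.frame(v = grid, C_star = equilibrium_pop(grid, trt, p))
}
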