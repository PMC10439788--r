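p <- model_params()

test_that("frozen trait reduces to logistic approach of the closed-form
           equilibrium", {
  pk0 <- update_params(p, k = 0)
  sch <- constant_schedule(3000, no_therapy())
  tr <- simulate_monomorphic(pk0, sch, init = c(C = 0.1, v = 1),
                             sample_dt = 1)
  n <- length(tr$times)
  expect_equal(tr$v[n], 1, tolerance = 1e-10)
  expect_equal(tr$C[n], equilibrium_pop(1, no_therapy(), p),
               tolerance = 1e-6)
  # trajectory container invariants
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$C >= 0))
  expect_identical(tr$total_marker, tr$v * tr$C)
})

test_that("with evolution on, the trait converges to the treatment-specific
           attractor", {
  long <- 60000
  tr_none <- simulate_monomorphic(p, constant_schedule(long, no_therapy()),
                                  init = c(C = 0.1, v = 1), sample_dt = 20)
  expect_equal(tr_none$v[length(tr_none$v)], 1.48, tolerance = 0.01)
  tr_chemo <- simulate_monomorphic(p, constant_schedule(long, chemo_on()),
                                   init = c(C = 0.1, v = 1), sample_dt = 20)
  expect_equal(tr_chemo$v[length(tr_chemo$v)], 1.96, tolerance = 0.01)
})

test_that("single- and near-degenerate polymorphic runs collapse to the
           monomorphic dynamics", {
  sch <- constant_schedule(2000, no_therapy())
  pk0 <- update_params(p, k = 0)
  mono <- simulate_monomorphic(pk0, sch, init = c(C = 0.1, v = 1),
                               sample_dt = 1)
  poly1 <- simulate_polymorphic(p, traits = 1, densities = 0.1, sch,
                                sample_dt = 1)
  expect_equal(poly1$total, mono$C, tolerance = 1e-7)
  # two effectively identical types behave as one pooled population
  poly2 <- simulate_polymorphic(p, traits = c(1, 1 + 1e-9),
                                densities = c(0.05, 0.05), sch,
                                sample_dt = 1)
  expect_equal(poly2$total, mono$C, tolerance = 1e-6)
  expect_true(all(poly2$C >= 0))
})

test_that("two-type integration corroborates the invasion fitness sign of
           the G-function", {
  # mutant above a low-trait resident invades without therapy
  g <- invasion_growth_ode(1, 1.2, no_therapy(), p)
  expect_gt(g, 0)
  expect_gt(fitness(1.2, 1, equilibrium_pop(1, no_therapy(), p),
                    no_therapy(), p), 0)
  # no mutant on a coarse grid invades the no-therapy ESS resident
  ess <- solve_ess(no_therapy(), p)
  for (vm in seq(0.5, 2.5, by = 0.25)) {
    if (abs(vm - ess$v_ess) < 0.05) next
    expect_lt(invasion_growth_ode(ess$v_ess, vm, no_therapy(), p), 0)
  }
})

test_that("monomorphic trait drift direction matches a tightly clustered
           two-type population", {
  cases <- list(list(v = 1.0, trt = no_therapy()),
                list(v = 1.8, trt = no_therapy()),
                list(v = 1.2, trt = chemo_on()),
                list(v = 1.0, trt = targeted_on()))
  eps <- 0.01
  for (cs in cases) {
    C0 <- max(equilibrium_pop(cs$v, cs$trt, p), 0.05)
    sch <- constant_schedule(5, cs$trt)
    out <- simulate_polymorphic(p, traits = c(cs$v - eps, cs$v + eps),
                                densities = c(C0 / 2, C0 / 2), sch,
                                sample_dt = 1)
    n <- length(out$times)
    drift <- out$mean_v[n] - out$mean_v[1]
    grad <- selection_gradient(cs$v, C0, cs$trt, p)
    expect_equal(sign(drift), sign(grad))
  }
})

test_that("invalid inputs and degenerate initial states are rejected", {
  sch <- constant_schedule(10, no_therapy())
  expect_error(simulate_monomorphic(p, sch, init = c(C = 0, v = 1)),
               "positive")
  expect_error(simulate_monomorphic(p, sch, init = c(C = 0.1, v = -1)))
  expect_error(simulate_polymorphic(p, traits = c(1, 1),
                                    densities = c(0.1, 0.1), sch),
               "distinct")
  expect_error(simulate_polymorphic(p, traits = c(1, 2),
                                    densities = c(0.1, -0.1), sch),
               "non-negative")
  expect_error(simulate_polymorphic(p, traits = c(1, 2),
                                    densities = 0.1, sch), "length")
})
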