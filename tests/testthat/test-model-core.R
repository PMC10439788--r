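p <- model_params()

test_that("growth and death rates are anchored at baseline and increasing", {
  expect_equal(intrinsic_growth(1, p), 0.05)
  expect_equal(intrinsic_growth(2, p), 0.10)
  expect_equal(intrinsic_growth(1.48, p), 0.074)
  expect_equal(natural_death(1, p), 0.02)
  expect_equal(natural_death(1.96, p), 0.02 * exp(0.96))
  # vanishing death cost: rate flat in v
  p_flat <- update_params(p, beta_delta = 1e-12)
  expect_equal(natural_death(3, p_flat), 0.02, tolerance = 1e-10)
  v <- seq(0.25, 3, length.out = 40)
  expect_true(all(diff(intrinsic_growth(v, p)) > 0))
  expect_true(all(diff(natural_death(v, p)) > 0))
  expect_error(intrinsic_growth(0, p), "positive")
  expect_error(natural_death(-1, p), "positive")
})

test_that("competition kernel is self-neutral, monotone, and bounded", {
  v <- seq(0.3, 3, length.out = 25)
  expect_equal(competition_coeff(v, v, p), rep(1, length(v)))
  expect_equal(competition_coeff(0.7, 0.7, p), 1)
  # experienced competition falls with own trait, rises with competitor's
  expect_true(all(diff(competition_coeff(v, 1, p)) < 0))
  expect_true(all(diff(competition_coeff(1, v, p)) > 0))
  # saturation limits
  expect_lt(competition_coeff(60, 1, p), 1e-8)
  expect_equal(competition_coeff(1, 60, p), p$a_max, tolerance = 1e-8)
  expect_true(all(competition_coeff(v, rev(v), p) > 0 &
                  competition_coeff(v, rev(v), p) < p$a_max))
  # closed-form self-derivative against a central finite difference
  h <- 1e-6
  fd <- (competition_coeff(1 + h, 1, p) - competition_coeff(1 - h, 1, p)) /
    (2 * h)
  expect_equal(fd, -p$beta_a * (p$a_max - 1) / p$a_max, tolerance = 1e-8)
  expect_equal(fd, -0.25, tolerance = 1e-8)
})

test_that("therapy effectiveness functions move oppositely in the trait", {
  expect_equal(chemo_effect(1, p), 0.03)
  expect_equal(chemo_effect(1.96, p), 0.03 * exp(-0.96))
  expect_equal(targeted_effect(1, p), 0.01)
  expect_equal(targeted_effect(0.72, p), 0.01 * 0.72^5)
  expect_equal(targeted_effect(2, p), 0.32)
  v <- seq(0.25, 3, length.out = 50)
  expect_true(all(diff(chemo_effect(v, p)) < 0))
  expect_true(all(diff(targeted_effect(v, p)) > 0))
  # resistance exponent off: chemotherapy equally effective at any trait
  p_m0 <- update_params(p, m_C = 1e-15)
  expect_equal(chemo_effect(2.5, p_m0), 0.03, tolerance = 1e-12)
})

test_that("fitness-generating function reproduces its closed-form anchors", {
  expect_equal(fitness(1, 1, 0, no_therapy(), p), 0.03)
  expect_equal(fitness(1, 1, 0.6, no_therapy(), p), 0, tolerance = 1e-15)
  expect_equal(fitness(1, 1, 0, treatment_state(1, 1), p), -0.01)
  expect_error(fitness(1, 1, -0.1, no_therapy(), p), "non-negative")
})

test_that("analytic selection gradient agrees with the finite-difference
           oracle across treatments", {
  expect_equal(selection_gradient(1, 0.6, no_therapy(), p), 0.0075)
  set.seed(7)
  trts <- list(no_therapy(), chemo_on(), targeted_on())
  for (i in 1:100) {
    u <- runif(1, 0.3, 2.5)
    C <- runif(1, 0, 0.9)
    trt <- trts[[1 + i %% 3]]
    an <- selection_gradient(u, C, trt, p)
    fd <- fd_gradient(u, C, trt, p)
    expect_equal(an, fd, tolerance = 1e-6)
  }
  # the gradient is independent of the evolvability scale
  expect_identical(selection_gradient(1.3, 0.4, chemo_on(), p),
                   selection_gradient(1.3, 0.4, chemo_on(),
                                      update_params(p, k = 0.9)))
})

test_that("equilibrium density: closed form, group optimum, clamping", {
  expect_equal(equilibrium_pop(1, no_therapy(), p), 0.6, tolerance = 1e-14)
  # no-therapy curve attains its maximum at the baseline trait
  grid <- seq(0.5, 2, by = 1e-3)
  curve <- equilibrium_pop(grid, no_therapy(), p)
  expect_lt(abs(grid[which.max(curve)] - p$v0), 1.5e-3)
  # combined therapy at baseline exceeds growth: clamps to zero
  expect_equal(equilibrium_pop(1, treatment_state(1, 1), p), 0)
  # resident fitness vanishes at its own equilibrium for every viable state
  for (trt in list(no_therapy(), chemo_on(), targeted_on())) {
    Cs <- equilibrium_pop(1.2, trt, p)
    if (Cs > 0)
      expect_lt(abs(fitness(1.2, 1.2, Cs, trt, p)), 1e-12)
  }
})
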