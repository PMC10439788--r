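p <- model_params()

test_that("fixed schedules place phase boundaries at cumulative week marks", {
  sch <- build_fixed_schedule(protocol_spec("sequential"),
                              time_units_per_week = 100)
  expect_equal(sch$start, c(0, 800, 2400))
  expect_equal(sch$end, c(800, 2400, 4000))
  expect_equal(sch$tau_C, c(0, 1, 0))
  expect_equal(sch$tau_T, c(0, 0, 1))

  sch_c <- build_fixed_schedule(protocol_spec("chemo_only"),
                                time_units_per_week = 100)
  expect_equal(sch_c$end, c(800, 2400))
  expect_equal(sch_c$tau_C, c(0, 1))

  sch_0 <- build_fixed_schedule(protocol_spec("none"))
  expect_equal(nrow(sch_0), 1L)
  expect_equal(sch_0$tau_C + sch_0$tau_T, 0)

  expect_error(
    build_fixed_schedule(protocol_spec("adaptive_mean", threshold = 1)),
    "adaptive")
  # at most one active therapy per interval, for every preset
  for (nm in protocol_presets()) {
    spec <- protocol_preset(nm)
    if (is.null(spec$phases)) next
    sch_i <- build_fixed_schedule(spec)
    expect_true(all(sch_i$tau_C + sch_i$tau_T <= 1))
  }
})

test_that("threshold decision rule follows the stated inequalities with a
           chemotherapy tie-break", {
  sp_tot <- protocol_spec("adaptive_total", threshold = 0.5)
  expect_equal(adaptive_decision(list(C = 0.6, v = 1), sp_tot)$tau_T, 1)
  expect_equal(adaptive_decision(list(C = 0.3, v = 1), sp_tot)$tau_C, 1)
  # exact equality resolves to chemotherapy
  expect_equal(adaptive_decision(list(C = 0.5, v = 1), sp_tot)$tau_C, 1)
  sp_mean <- protocol_spec("adaptive_mean", threshold = 1.2)
  expect_equal(adaptive_decision(list(C = 0.6, v = 0.9), sp_mean)$tau_C, 1)
  expect_equal(adaptive_decision(list(C = 0.6, v = 1.3), sp_mean)$tau_T, 1)
  # unbounded threshold: chemotherapy at every visit
  sp_inf <- protocol_spec("adaptive_total", threshold = Inf)
  expect_equal(adaptive_decision(list(C = 10, v = 10), sp_inf)$tau_C, 1)
  expect_error(adaptive_decision(list(C = 1, v = 1),
                                 protocol_spec("sequential")), "adaptive")
  # optional withhold-below mode
  sp_off <- protocol_spec("adaptive_total", threshold = 0.5,
                          off_threshold = 0.1)
  off <- adaptive_decision(list(C = 0.05, v = 1), sp_off)
  expect_equal(off$tau_C + off$tau_T, 0)
})

test_that("adaptive runs switch only at visits and stay continuous in
           state across switches", {
  spec <- protocol_spec("adaptive_mean", threshold = 1.6, horizon = 60)
  tr <- run_adaptive(p, spec, sample_dt = 0.5)
  expect_gt(attr(tr, "n_switches"), 0)
  expect_false(attr(tr, "degenerate"))
  expect_true(all(diff(tr$times) > 0))
  # applied treatment changes only at multiples of the visit interval
  code <- tr$tau_C + 2 * tr$tau_T
  sw_t <- tr$times[which(diff(code) != 0)]
  expect_true(all(abs(sw_t / 100 - round(sw_t / 100)) < 1e-9))
  # no lead-in treatment before diagnosis
  expect_true(all(code[tr$times < spec$lead_in * 100] == 0))
  # decision rule is a pure function of state: re-applying it at each
  # visit's recorded state reproduces the treatment applied next
  visits <- (spec$lead_in + seq(0, spec$horizon - 1)) * 100
  for (tv in visits[seq(1, length(visits), by = 7)]) {
    i <- which.min(abs(tr$times - tv))
    dec <- adaptive_decision(list(C = tr$C[i], v = tr$v[i]), spec)
    j <- min(i + 1, length(code))
    expect_equal(dec$tau_C + 2 * dec$tau_T, code[j])
  }
})

test_that("a threshold no trajectory ever crosses is flagged degenerate", {
  spec <- protocol_spec("adaptive_mean", threshold = 10, horizon = 20)
  tr <- run_adaptive(p, spec, sample_dt = 1)
  expect_true(attr(tr, "degenerate"))
  expect_equal(attr(tr, "n_switches"), 0L)
})

test_that("balance point equalises the two effectiveness functions and
           matches an independent bisection", {
  vb <- balance_point(p)
  expect_lte(abs(chemo_effect(vb, p) - targeted_effect(vb, p)), 1e-12)
  vb_oracle <- bisect(function(v) chemo_effect(v, p) - targeted_effect(v, p),
                      0.5, 3)
  expect_equal(vb, vb_oracle, tolerance = 1e-9)
  expect_gt(vb, 1.0); expect_lt(vb, 1.5)
  # stronger chemotherapy pushes the balance to higher trait values
  vb_hi <- balance_point(update_params(p, zeta_C = 0.06))
  expect_gt(vb_hi, vb)
  expect_error(balance_point(p, bracket = c(2, 3)), "sign")
})

test_that("protocol constructor enforces its invariants", {
  expect_error(protocol_spec("adaptive_mean"), "threshold")
  expect_error(protocol_spec("adaptive_mean", threshold = -1), "threshold")
  expect_error(protocol_spec("sequential",
                             phases = data.frame(treatment = "chemo",
                                                 weeks = -2)), "positive")
  expect_error(protocol_spec("sequential",
                             phases = data.frame(treatment = "radio",
                                                 weeks = 2)), "radio")
  expect_error(protocol_preset("no_such"), "preset")
})
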