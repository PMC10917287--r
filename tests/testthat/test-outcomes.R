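test_that("discount factors follow (1+r)^(-t/12)", {
  expect_identical(discount_factor(0, 0.03, 1), 1)
  expect_equal(discount_factor(12, 0.03, 1), 1 / 1.03, tolerance = 1e-12)
  expect_equal(discount_factor(24, 0.03, 1), 1 / 1.03^2, tolerance = 1e-12)
  expect_error(discount_factor(-1, 0.03), "cycle")
  expect_error(discount_factor(1, -1.5), "annual_rate")
})

test_that("hand accumulation: one alive state, utility 0.8, no discounting", {
  p <- make_geom_params(p_death = 0, utility = 0.8, discount = 0, horizon = 12)
  r <- accumulate(run_cohort("soc", p), p)
  expect_equal(r$qaly_total, 0.8, tolerance = 1e-12)
  expect_equal(r$ly_total, 1.0, tolerance = 1e-12)
  expect_equal(r$cost_total, 0)
})

test_that("a trace entirely in the dead state accrues nothing", {
  p <- make_geom_params(horizon = 12)
  occ <- array(0, dim = c(13, 2, 2),
               dimnames = list(0:12, c("alive", "dead"),
                               c("on_drug", "discontinued")))
  occ[, "dead", "discontinued"] <- 1
  tr <- structure(occ, class = "ckd_trace", arm = "soc", cycle_months = 1)
  r <- accumulate(tr, p)
  expect_identical(r$cost_total, 0)
  expect_identical(r$qaly_total, 0)
  expect_identical(r$ly_total, 0)
})

test_that("drug cost switches to the comparator price after discontinuation", {
  # immortal cohort, intervention drug 120/yr vs comparator 0: with
  # discontinuation d per cycle the on-drug fraction at cycle t is (1-d)^t
  p <- make_geom_params(p_death = 0, drug_annual = 120, horizon = 24,
                        disc_rate = 0.1)
  p$costs$drug_annual$soc$mean <- 0
  r <- accumulate(run_cohort("dapagliflozin", p), p)
  expect_equal(r$cost_by_category$drug, 10 * sum(0.9^(0:23)), tolerance = 1e-12)
})

test_that("accumulated totals are internally consistent on the fixture", {
  p <- fixture_params()
  for (arm in c("dapagliflozin", "soc")) {
    r <- accumulate(run_cohort(arm, p), p)
    cats <- r$cost_by_category
    expect_equal(r$cost_total,
                 cats$drug + sum(unlist(cats$state_mgmt)) + cats$dialysis +
                   cats$transplant + cats$adverse_events,
                 tolerance = 1e-6)
    expect_lte(r$qaly_total, r$ly_total)
  }
})

test_that("discounting can only shrink totals; rate 0 leaves them unchanged", {
  p <- fixture_params()
  p0 <- p; p0$econ$annual_discount <- 0
  r <- accumulate(run_cohort("soc", p), p)
  r0 <- accumulate(run_cohort("soc", p0), p0)
  expect_lt(r$cost_total, r0$cost_total)
  expect_lt(r$qaly_total, r0$qaly_total)
  expect_equal(r$ly_total, r0$ly_total)   # life years reported undiscounted
})

test_that("compare computes ICER/NMB identities and is antisymmetric", {
  p <- fixture_params()
  a <- accumulate(run_cohort("dapagliflozin", p), p)
  s <- accumulate(run_cohort("soc", p), p)
  ce <- compare(a, s, p$econ)
  expect_equal(ce$nmb, p$econ$wtp_per_qaly * ce$d_qaly - ce$d_cost)
  expect_equal(ce$icer, ce$d_cost / ce$d_qaly)
  expect_identical(ce$dominant, ce$d_cost < 0 && ce$d_qaly > 0)

  rev <- compare(s, a, p$econ)
  expect_equal(rev$d_cost, -ce$d_cost)
  expect_equal(rev$d_qaly, -ce$d_qaly)
  expect_equal(rev$d_ly, -ce$d_ly)

  self <- compare(s, s, p$econ)
  expect_identical(self$d_cost, 0)
  expect_false(self$icer_defined)
  expect_true(is.na(self$icer))
  expect_identical(self$nmb, 0)
})

test_that("USD conversion and budget impact do plain arithmetic", {
  expect_identical(to_usd(0, 4.14), 0)
  expect_identical(to_usd(4.14, 4.14), 1)
  expect_equal(to_usd(81814, 4.14, round = FALSE), 81814 / 4.14)
  expect_error(to_usd(1, 0), "fx")

  expect_identical(budget_impact(0, -3650), 0)
  expect_identical(budget_impact(1, -3650), 3650)
  expect_equal(budget_impact(3.72e6, -3650), 1.3578e10)
  expect_error(budget_impact(-1, 0), "n_treated")
})

test_that("results CSV mirrors the cost-category breakdown", {
  p <- fixture_params()
  m <- run_model(p, horizon = 120)
  f <- withr::local_tempfile(fileext = ".csv")
  out <- write_results(m, f)
  back <- read.csv(f)
  expect_identical(back$outcome, out$outcome)
  tot <- back[back$outcome == "total_cost_rm", ]
  parts <- back[grepl("_rm$", back$outcome) &
                  !back$outcome %in% c("total_cost_rm", "nmb_rm",
                                       "icer_rm_per_qaly"), ]
  expect_equal(sum(parts$incremental), tot$incremental, tolerance = 1e-6)
})
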