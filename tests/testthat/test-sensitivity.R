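test_that("beta and gamma method-of-moments fits invert exactly", {
  expect_equal(fit_beta(0.5, 0.1), c(alpha = 12, beta = 12), tolerance = 1e-12)
  # the published dialysis utility 0.85 (SE 0.17)
  # hand: k = 0.85*0.15/0.17^2 - 1 = 3.4117647..., alpha = 0.85k, beta = 0.15k
  ab <- fit_beta(0.85, 0.17)
  expect_equal(unname(ab), c(2.9, 0.5117647058823529), tolerance = 1e-9)

  expect_equal(fit_gamma(100, 20), c(shape = 25, scale = 4), tolerance = 1e-12)
  gs <- fit_gamma(44731.40, 1118.29)
  expect_equal(unname(gs["shape"]), (44731.40 / 1118.29)^2, tolerance = 1e-9)
  expect_equal(unname(gs["scale"]), 1118.29^2 / 44731.40, tolerance = 1e-9)
  expect_equal(fit_gamma(50, 50), c(shape = 1, scale = 50), tolerance = 1e-12)

  # property: reconstructed first two moments equal the inputs to 1e-9
  set.seed(1)
  for (i in 1:50) {
    m <- runif(1, 0.01, 0.99)
    se <- runif(1, 1e-4, 0.9) * sqrt(m * (1 - m))
    ab <- fit_beta(m, se)
    expect_equal(ab[["alpha"]] / sum(ab), m, tolerance = 1e-9)
    expect_equal(sqrt(prod(ab) / (sum(ab)^2 * (sum(ab) + 1))), se,
                 tolerance = 1e-9)
    mu <- runif(1, 1, 1e5); s <- runif(1, 1e-3, 2) * mu
    gs <- fit_gamma(mu, s)
    expect_equal(gs[["shape"]] * gs[["scale"]], mu, tolerance = 1e-9)
    expect_equal(sqrt(gs[["shape"]]) * gs[["scale"]], s, tolerance = 1e-9)
  }

  expect_error(fit_beta(0.5, 0.5), "infeasible")
  expect_error(fit_beta(1, 0.1), "mean")
  expect_error(fit_gamma(0, 1), "must be > 0")
})

test_that("sample_parameter_set is deterministic, degenerate at zero SE, unbiased", {
  base <- fixture_params()
  expect_identical(sample_parameter_set(zero_se_params(base), 1),
                   zero_se_params(base))

  s1 <- sample_parameter_set(base, 42)
  s2 <- sample_parameter_set(base, 42)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_parameter_set(base, 43)))

  # rows stay stochastic after cell-wise sampling + renormalisation
  for (arm in c("dapagliflozin", "soc"))
    expect_equal(rowSums(s1$matrices[[arm]]$phase2), rep(1, 10),
                 tolerance = 1e-12, ignore_attr = TRUE)

  # law of large numbers on the dialysis cost (scaled to 2,000 draws to
  # keep the suite fast; bound 3 SE/sqrt(n))
  n <- 2000
  draws <- vapply(seq_len(n), function(i)
    sample_parameter_set(base, i)$costs$dialysis_annual$mean, 0)
  expect_lt(abs(mean(draws) - 44731.40), 3 * 1118.29 / sqrt(n))
})

test_that("PSA: degenerate run equals the base case and seeds reproduce", {
  base <- fixture_params()
  z <- zero_se_params(base)
  psa1 <- run_psa(z, n_iter = 1, seed = 9, horizon = 120)
  det <- run_model(z, horizon = 120)$ce
  expect_equal(psa1$draws$d_cost, det$d_cost, tolerance = 1e-12)
  expect_equal(psa1$draws$d_qaly, det$d_qaly, tolerance = 1e-12)
  expect_equal(psa1$draws$nmb, det$nmb, tolerance = 1e-12)

  a <- run_psa(base, n_iter = 25, seed = 7, horizon = 120)
  b <- run_psa(base, n_iter = 25, seed = 7, horizon = 120)
  expect_identical(a$draws, b$draws)
  expect_identical(a$n_failed, 0L)
  # per-draw NMB recomputable from the increments
  expect_equal(a$draws$nmb,
               base$econ$wtp_per_qaly * a$draws$d_qaly - a$draws$d_cost,
               tolerance = 1e-9)
})

test_that("PSA on an identical-arms world is a coin flip on NMB sign", {
  p <- null_effect_params()
  psa <- run_psa(p, n_iter = 200, seed = 5, horizon = 120)
  expect_lt(abs(mean(psa$draws$d_qaly)), 3 * sd(psa$draws$d_qaly) / sqrt(200))
  frac <- fraction_below_wtp(psa, p$econ$wtp_per_qaly)
  expect_gt(frac, 0.35); expect_lt(frac, 0.65)
})

test_that("fraction_below_wtp counts dominant draws and excludes ties", {
  dom <- data.frame(d_cost = c(-10, -5), d_qaly = c(0.1, 0.2))
  expect_identical(fraction_below_wtp(dom, 46000), 1)
  mix <- data.frame(d_cost = c(-1, 1), d_qaly = c(0, 0))   # nmb = +1, -1
  expect_identical(fraction_below_wtp(mix, 46000), 0.5)
  tie <- data.frame(d_cost = 0, d_qaly = 0)
  expect_identical(fraction_below_wtp(tie, 46000), 0)
  expect_error(fraction_below_wtp(data.frame(), 46000), "draws")
})

test_that("CEAC is consistent with fraction_below_wtp and monotone", {
  draws <- data.frame(d_cost = c(-100, 200, 300, -50),
                      d_qaly = c(0.01, 0.02, 0.01, 0.03))
  psa <- structure(list(draws = draws), class = "ckd_psa")
  expect_identical(ceac(psa, 46000)$probability,
                   fraction_below_wtp(psa, 46000))
  # all cost-saving draws are acceptable at WTP 0
  neg <- structure(list(draws = data.frame(d_cost = c(-1, -2),
                                           d_qaly = c(0.1, -0.1))),
                   class = "ckd_psa")
  expect_identical(ceac(neg, 0)$probability, 1)
  # hand-counted: at wtp 0 only negative-cost draws; at 1e5 all positive-qaly
  grid <- c(0, 2e4, 1e5)
  cc <- ceac(psa, grid)
  expect_equal(cc$probability, c(0.5, 0.75, 1))
  expect_true(all(diff(cc$probability) >= 0))   # all d_qaly > 0
  expect_error(ceac(psa, numeric(0)), "grid")
})

test_that("parameter paths resolve, set, and clip matrix cells", {
  p <- fixture_params()
  expect_equal(param_get(p, "costs$dialysis_annual$mean"), 44731.40)
  p2 <- param_set(p, "costs$dialysis_annual$mean", 50000)
  expect_equal(param_get(p2, "costs$dialysis_annual$mean"), 50000)

  v <- param_get(p, "matrices$soc$phase1[5,6]")
  p3 <- param_set(p, "matrices$soc$phase1[5,6]", v * 2)
  expect_equal(rowSums(p3$matrices$soc$phase1), rep(1, 10),
               tolerance = 1e-12, ignore_attr = TRUE)
  p4 <- param_set(p, "matrices$soc$phase1[5,6]", 7)   # clipped to 1
  expect_lte(max(p4$matrices$soc$phase1), 1)
  expect_error(param_get(p, "costs$nope$mean"), "cannot resolve")
  expect_error(param_set(p, "costs$nope$mean", 1), "cannot resolve")
})

test_that("one-way DSA widths equal explicit reruns and sort deterministically", {
  p <- make_geom_params(p_death = 0.02, utility = 0.8, discount = 0.03,
                        horizon = 120, drug_annual = 120, disc_rate = 0)
  p$costs$drug_annual$soc$mean <- 0
  # make the arms differ so NMB responds to the death probability
  m <- p$matrices$dapagliflozin$phase1
  m["alive", "dead"] <- 0.015; m["alive", "alive"] <- 0.985
  p$matrices$dapagliflozin$phase1 <- m
  p$matrices$dapagliflozin$phase2 <- m
  p <- validate_parameter_set(p)

  spec <- data.frame(path = c("matrices$soc$phase1[1,2]",
                              "costs$drug_annual$dapagliflozin$mean"),
                     low = c(0.018, 96), high = c(0.022, 144))
  tor <- run_dsa(p, spec)

  # hand recomputation: two explicit reruns per parameter
  for (i in seq_len(nrow(tor))) {
    lo <- run_model(param_set(p, tor$path[i], tor$low[i]))$ce$nmb
    hi <- run_model(param_set(p, tor$path[i], tor$high[i]))$ce$nmb
    expect_equal(tor$nmb_low[i], lo, tolerance = 1e-9)
    expect_equal(tor$nmb_high[i], hi, tolerance = 1e-9)
    expect_equal(tor$width[i], abs(hi - lo), tolerance = 1e-9)
  }
  expect_true(all(diff(tor$width) <= 0))

  # zero-width range degenerates to the base case
  base_nmb <- run_model(p)$ce$nmb
  z <- run_dsa(p, data.frame(path = "costs$drug_annual$dapagliflozin$mean",
                             low = 120, high = 120))
  expect_equal(z$nmb_low, base_nmb, tolerance = 1e-9)
  expect_equal(z$width, 0)

  # row order of the spec does not change the result
  tor_rev <- run_dsa(p, spec[2:1, ])
  expect_equal(as.data.frame(tor), as.data.frame(tor_rev), tolerance = 1e-12)
})
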