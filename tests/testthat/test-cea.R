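arm_results_fixture <- data.frame(
  arm = c("OMT", "PCI", "CABG"),
  cost = c(10, 20, 30),
  qaly = c(1, 2, 3),
  stringsAsFactors = FALSE
)

test_that("strategy mixes are weighted averages of arm results", {
  expect_equal(
    unname(evaluate_mix(strategy_mix("cabg", c(CABG = 1)), arm_results_fixture)),
    c(30, 3))
  eq <- strategy_mix("equal", c(OMT = 1, PCI = 1, CABG = 1) / 3)
  expect_equal(unname(evaluate_mix(eq, arm_results_fixture)), c(20, 2))
  w <- c(OMT = 0.819, PCI = 0.135, CABG = 0.046)
  cur <- evaluate_mix(strategy_mix("current", w), arm_results_fixture)
  expect_equal(cur[["cost"]], sum(w * arm_results_fixture$cost),
               tolerance = 1e-12)
  expect_equal(cur[["qaly"]], sum(w * arm_results_fixture$qaly),
               tolerance = 1e-12)
  expect_error(strategy_mix("bad", c(OMT = 0.5, PCI = 0.4)), "sum")
  expect_error(evaluate_mix(strategy_mix("x", c(Other = 1)),
                            arm_results_fixture), "no arm results")
})

test_that("evaluate_mix is linear: a mix of mixes is the convex combination", {
  w1 <- c(OMT = 1)
  w2 <- c(PCI = 0.5, CABG = 0.5)
  lam <- 0.3
  blended <- strategy_mix("b", c(OMT = lam * 1, PCI = (1 - lam) * 0.5,
                                 CABG = (1 - lam) * 0.5))
  r1 <- evaluate_mix(strategy_mix("1", w1), arm_results_fixture)
  r2 <- evaluate_mix(strategy_mix("2", w2), arm_results_fixture)
  rb <- evaluate_mix(blended, arm_results_fixture)
  expect_equal(rb, lam * r1 + (1 - lam) * r2, tolerance = 1e-12)
})

# a small PSA shared by the remaining blocks
small_psa <- local({
  model <- build_model()
  cfg <- engine_config(seed = 99)
  run_psa(model, default_strategies(), cfg, n_draws = 60)
})

test_that("PSA is deterministic under a fixed seed and varies otherwise", {
  model <- build_model()
  cfg <- engine_config(seed = 99)
  again <- run_psa(model, default_strategies(), cfg, n_draws = 60)
  expect_identical(small_psa$draws, again$draws)
  expect_gt(var(small_psa$draws$cost[small_psa$draws$strategy == "all_omt"]), 0)
})

test_that("an all-fixed parameter set yields a zero-variance PSA", {
  pars <- default_parameters()
  pars$params <- lapply(pars$params, function(s) {
    fixed_spec(unname(spec_moments(s)[["mean"]]))
  })
  model <- build_model(default_model_structure(), pars)
  psa <- run_psa(model, default_strategies(), engine_config(seed = 5),
                 n_draws = 20)
  for (s in unique(psa$draws$strategy)) {
    expect_equal(var(psa$draws$cost[psa$draws$strategy == s]), 0)
    expect_equal(var(psa$draws$qaly[psa$draws$strategy == s]), 0)
  }
})

test_that("incremental summaries obey the NMB identities", {
  ce <- incremental_summary(small_psa, "recommended", "current_practice")
  expect_equal(ce$nmb, 80000 * ce$delta_qaly - ce$delta_cost,
               tolerance = 1e-9)
  # per-draw affine-in-lambda identity at three thresholds
  for (wtp in c(0, 40000, 120000)) {
    cew <- incremental_summary(small_psa, "recommended", "current_practice",
                               wtp = wtp)
    expect_equal(cew$deltas$nmb,
                 wtp * cew$deltas$delta_qaly - cew$deltas$delta_cost,
                 tolerance = 1e-9)
  }
  ce0 <- incremental_summary(small_psa, "all_pci", "current_practice",
                             wtp = 0)
  expect_equal(ce0$deltas$nmb, -ce0$deltas$delta_cost)
  # probabilities lie in [0, 1] and intervals bracket their central values
  expect_true(all(c(ce$p_cost_saving, ce$p_qaly_gain, ce$p_cost_effective)
                  %in% c(0, 1) |
                  (c(ce$p_cost_saving, ce$p_qaly_gain, ce$p_cost_effective)
                   >= 0 &
                   c(ce$p_cost_saving, ce$p_qaly_gain, ce$p_cost_effective)
                   <= 1)))
  expect_lte(ce$delta_qaly_ui[1], ce$delta_qaly_ui[2])
})

test_that("self-comparison gives zero deltas and zero probabilities", {
  ce <- incremental_summary(small_psa, "current_practice", "current_practice")
  expect_equal(ce$delta_cost, 0)
  expect_equal(ce$delta_qaly, 0)
  expect_equal(ce$nmb, 0)
  expect_equal(ce$p_cost_saving, 0)
  expect_equal(ce$p_cost_effective, 0)
})

test_that("hand-computed incremental example: C 100->90, Q 1->1.2", {
  draws <- data.frame(
    draw = c(1L, 1L), strategy = c("base", "alt"),
    cost = c(100, 90), qaly = c(1, 1.2), stringsAsFactors = FALSE)
  psa <- structure(list(draws = draws, n_draws = 1L, seed = 1L,
                        wtp_threshold = 80000), class = "cad_psa")
  ce <- incremental_summary(psa, "alt", "base")
  expect_equal(ce$delta_cost, -10)
  expect_equal(ce$delta_qaly, 0.2, tolerance = 1e-12)
  expect_equal(ce$nmb, 80000 * 0.2 + 10, tolerance = 1e-9)
  expect_equal(ce$nmb, 16010, tolerance = 1e-9)
})

test_that("the acceptability curve matches its breakeven threshold", {
  draws <- data.frame(
    draw = c(1L, 1L), strategy = c("base", "alt"),
    cost = c(100, 90), qaly = c(1, 0.999), stringsAsFactors = FALSE)
  psa <- structure(list(draws = draws, n_draws = 1L, seed = 1L,
                        wtp_threshold = 80000), class = "cad_psa")
  # dC = -10, dQ = -0.001: cost-effective strictly below lambda = 10,000
  curve <- ceac(psa, "alt", "base", wtp_grid = c(0, 5000, 9999, 10001, 20000))
  expect_equal(curve$p_cost_effective, c(1, 1, 1, 0, 0))
  # lambda = 0 point equals the probability of saving costs
  ce <- incremental_summary(psa, "alt", "base")
  expect_equal(ceac(psa, "alt", "base", wtp_grid = c(0, 1))$p_cost_effective[1],
               ce$p_cost_saving)
  expect_error(ceac(psa, "alt", "base", wtp_grid = numeric()), "non-empty")
  expect_error(ceac(psa, "alt", "base", wtp_grid = c(5, 1)), "increasing")
})

test_that("acceptability is nondecreasing when QALYs are gained at a cost", {
  set.seed(12)
  n <- 50
  draws <- rbind(
    data.frame(draw = 1:n, strategy = "base", cost = 100, qaly = 1),
    data.frame(draw = 1:n, strategy = "alt",
               cost = 100 + runif(n, 10, 500),
               qaly = 1 + runif(n, 0.01, 0.4))
  )
  psa <- structure(list(draws = draws, n_draws = n, seed = 12L,
                        wtp_threshold = 80000), class = "cad_psa")
  ce <- incremental_summary(psa, "alt", "base")
  expect_true(all(ce$deltas$delta_qaly > 0))
  expect_true(all(ce$deltas$delta_cost > 0))
  curve <- ceac(psa, "alt", "base", wtp_grid = seq(0, 160000, 10000))
  expect_true(all(diff(curve$p_cost_effective) >= 0))
  expect_equal(curve$p_cost_effective[1], 0)   # all draws cost more at wtp 0
})

test_that("population scaling multiplies per-patient results through", {
  sc <- population_scale(list(delta_cost = -1743, delta_qaly = 0.23),
                         6000, 80000)
  expect_equal(sc[["annual_qaly_change"]], 1380)
  expect_equal(sc[["annual_cost_change"]], -10458000)
  expect_equal(sc[["annual_qaly_value"]], 110400000)
  expect_error(population_scale(list(delta_cost = 0, delta_qaly = 0),
                                -1, 80000), ">= 0")
})
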