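test_that("model assembly validates structure, parameters and rows", {
  model <- build_model()
  expect_s3_class(model, "cad_model")
  expect_true(model$states$absorbing[model$states$name == "Dead"])
  expect_equal(unname(rowSums(model$transitions)), rep(1, 9), tolerance = 1e-12)
  # a transition outside the configured diagram is rejected
  st <- default_model_structure()
  pars <- default_parameters()
  bad <- pars$transitions
  bad["StablePCI", c("StablePCI", "OMT")] <- c(0.95, 0.032)
  bad["StablePCI", "Dead"] <- 0.018
  expect_error(build_model(st, default_parameters(bad)),
               "StablePCI -> OMT")
  # a non-stochastic row is named
  bad2 <- pars$transitions
  bad2["OMT", "OMT"] <- 0.5
  expect_error(build_model(st, default_parameters(bad2)), "row 'OMT'")
  # a missing parameter spec is named
  pars2 <- default_parameters()
  pars2$params$u_omt <- NULL
  expect_error(build_model(st, pars2), "u_omt")
})

test_that("mortality adjustment steps by block and rescales the row", {
  cfg <- engine_config()
  row <- c(A = 0.60, B = 0.35, Dead = 0.05)
  # no increment inside the first block
  for (c in 1:10) expect_equal(adjust_mortality(row, c, cfg), row)
  # second block: death +0.01, live entries scaled by 0.94/0.95
  adj <- adjust_mortality(row, 11, cfg)
  expect_equal(adj[["Dead"]], 0.06)
  expect_equal(adj[["A"]], 0.60 * 0.94 / 0.95)
  expect_equal(sum(adj), 1, tolerance = 1e-12)
  # absorbing cap
  dead_row <- c(A = 0, B = 0, Dead = 1)
  expect_equal(adjust_mortality(dead_row, 15, cfg), dead_row)
  # cap when the increment overshoots
  big <- engine_config(mortality_increment = 0.97, mortality_block = 1)
  capped <- adjust_mortality(row, 3, big)
  expect_equal(capped[["Dead"]], 1)
  expect_equal(sum(capped), 1, tolerance = 1e-12)
  # rate mode adds on the hazard scale
  rcfg <- engine_config(mortality_increment = 0.01, mortality_mode = "rate")
  radj <- adjust_mortality(row, 11, rcfg)
  expect_equal(radj[["Dead"]], 1 - 0.95 * exp(-0.01), tolerance = 1e-12)
})

test_that("cohort propagation equals the matrix-power oracle", {
  cfg <- engine_config(n_cycles = 5, cohort_size = 1000,
                       mortality_increment = 0)
  model <- random_model(2, seed = 4)
  trace <- run_cohort(model, "S1", cfg)
  matpow <- function(m, k) Reduce(`%*%`, replicate(k, m, simplify = FALSE))
  start <- c(1000, 0, 0)
  for (c in 1:5) {
    expect_equal(unname(trace$occupancy[c + 1, ]),
                 as.numeric(start %*% matpow(model$transitions, c)),
                 tolerance = 1e-10)
  }
})

test_that("occupancy is conserved and death is monotone", {
  cfg <- engine_config(n_cycles = 20)
  for (seed in 1:5) {
    model <- random_model(2 + (seed %% 4), seed = seed)
    trace <- run_cohort(model, "S1", cfg)
    expect_equal(unname(rowSums(trace$occupancy)),
                 rep(cfg$cohort_size, 21), tolerance = 1e-8)
    expect_true(all(trace$occupancy >= -1e-12))
    expect_true(all(diff(trace$occupancy[, "Dead"]) >= -1e-10))
  }
})

test_that("discount factors follow mid-point compounding", {
  cfg <- engine_config()
  expect_equal(discount_factor(2, cfg), 1.03^(-0.75), tolerance = 1e-15)
  cfg0 <- engine_config(annual_discount_rate = 0)
  expect_equal(discount_factor(1:20, cfg0), rep(1, 20))
  expect_true(all(diff(discount_factor(1:20, cfg)) < 0))
  cend <- engine_config(half_cycle_correction = FALSE)
  expect_equal(discount_factor(2, cend), 1.03^(-1))
})

test_that("a decade of perfect health accrues exactly 10 QALYs undiscounted", {
  model <- single_alive_model()
  cfg <- engine_config(annual_discount_rate = 0, mortality_increment = 0)
  out <- evaluate_arm(model, "Alive", cfg)
  expect_equal(out$total_qaly, 20 * 0.5, tolerance = 1e-12)
  expect_equal(out$total_cost, 0)
})

test_that("discounted half-cycle QALYs match the geometric closed form", {
  model <- single_alive_model()
  cfg <- engine_config(mortality_increment = 0)
  out <- evaluate_arm(model, "Alive", cfg)
  expect_equal(out$total_qaly, sum(0.5 * 1.03^(-(1:20 - 0.5) / 2)),
               tolerance = 1e-12)
})

test_that("null utilities and costs accrue nothing", {
  model <- single_alive_model(utility = 0)
  out <- evaluate_arm(model, "Alive", engine_config())
  expect_equal(out$total_qaly, 0)
  expect_equal(out$total_cost, 0)
})

test_that("entry costs charge new entrants and the cycle-0 placement", {
  states <- c("A", "Proc", "Dead")
  m <- rbind(c(0.5, 0.5, 0), c(0, 0.9, 0.1), c(0, 0, 1))
  dimnames(m) <- list(states, states)
  structure_cfg <- list(states = states, absorbing = "Dead",
                        allowed = list(A = states, Proc = states,
                                       Dead = "Dead"),
                        arms = list(A = "A", Proc = "Proc"))
  pars <- list(
    params = list(entry = fixed_spec(1000), u = fixed_spec(0.5)),
    state_map = data.frame(state = states,
                           per_cycle = c("", "", ""),
                           entry = c("", "entry", ""),
                           utility = c("u", "u", ""),
                           stringsAsFactors = FALSE),
    transitions = m
  )
  model <- build_model(structure_cfg, pars)
  cfg <- engine_config(n_cycles = 1, cohort_size = 100,
                       annual_discount_rate = 0, mortality_increment = 0)
  # starting in the procedure state: entry cost at time 0, undiscounted
  out <- evaluate_arm(model, "Proc", cfg)
  expect_equal(out$entry_cost_time0, 100 * 1000)
  # starting in A: half the cohort enters Proc during cycle 1
  out_a <- evaluate_arm(model, "A", cfg)
  expect_equal(out_a$total_cost, 0.5 * 1000, tolerance = 1e-12)
  # self-transitions are not new entries
  cfg2 <- engine_config(n_cycles = 2, cohort_size = 100,
                        annual_discount_rate = 0, mortality_increment = 0)
  out2 <- evaluate_arm(model, "Proc", cfg2)
  # cycle 1 and 2 entrants into Proc are zero (only stayers remain)
  expect_equal(out2$total_cost, 1000, tolerance = 1e-12)
})

test_that("utility and discount monotonicity hold", {
  cfg <- engine_config()
  model <- random_model(3, seed = 8)
  base <- evaluate_arm(model, "S1", cfg)$total_qaly
  up <- model
  up$states$utility[1] <- min(1, up$states$utility[1] + 0.1)
  expect_gte(evaluate_arm(up, "S1", cfg)$total_qaly, base)
  hi <- engine_config(annual_discount_rate = 0.06)
  expect_lte(evaluate_arm(model, "S1", hi)$total_qaly, base)
})

test_that("half-cycle correction averages adjacent occupancy vectors", {
  # one live state decaying to death: compare against a hand trapezoid
  states <- c("A", "Dead")
  m <- rbind(c(0.8, 0.2), c(0, 1)); dimnames(m) <- list(states, states)
  structure_cfg <- list(states = states, absorbing = "Dead",
                        allowed = list(A = states, Dead = "Dead"),
                        arms = list(A = "A"))
  pars <- list(params = list(u = fixed_spec(1)),
               state_map = data.frame(state = states, per_cycle = "",
                                      entry = "", utility = c("u", ""),
                                      stringsAsFactors = FALSE),
               transitions = m)
  model <- build_model(structure_cfg, pars)
  cfg <- engine_config(n_cycles = 3, cohort_size = 1,
                       annual_discount_rate = 0, mortality_increment = 0)
  out <- evaluate_arm(model, "A", cfg)
  occ <- c(1, 0.8, 0.64, 0.512)
  expect_equal(out$total_qaly,
               sum(0.5 * (head(occ, -1) + tail(occ, -1)) / 2),
               tolerance = 1e-12)
  cfg_nohcc <- engine_config(n_cycles = 3, cohort_size = 1,
                             annual_discount_rate = 0,
                             mortality_increment = 0,
                             half_cycle_correction = FALSE)
  out2 <- evaluate_arm(model, "A", cfg_nohcc)
  expect_equal(out2$total_qaly, sum(0.5 * occ[-1]), tolerance = 1e-12)
})
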