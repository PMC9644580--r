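# Shared fixtures: small models and ground truths built in code.

# a random valid model over k transient states plus one absorbing state
random_model <- function(k, seed, with_costs = TRUE) {
  set.seed(seed)
  states <- c(paste0("S", seq_len(k)), "Dead")
  n <- k + 1L
  m <- matrix(0, n, n, dimnames = list(states, states))
  for (i in seq_len(k)) {
    w <- stats::rgamma(n, shape = 1)
    m[i, ] <- w / sum(w)
  }
  m[n, n] <- 1
  structure_cfg <- list(
    states = states, absorbing = "Dead",
    allowed = c(stats::setNames(lapply(seq_len(k), function(i) states),
                                states[seq_len(k)]),
                list(Dead = "Dead")),
    arms = list(A = states[1])
  )
  params <- list(
    params = c(
      stats::setNames(lapply(seq_len(k), function(i) {
        if (with_costs) gamma_from_mean_sd(100 * i, 10 * i) else fixed_spec(0)
      }), paste0("c", seq_len(k))),
      stats::setNames(lapply(seq_len(k), function(i) {
        beta_from_mean_sd(0.5 + 0.4 * i / k, 0.05)
      }), paste0("u", seq_len(k)))
    ),
    state_map = data.frame(
      state = states,
      per_cycle = c(paste0("c", seq_len(k)), ""),
      entry = rep("", n),
      utility = c(paste0("u", seq_len(k)), ""),
      stringsAsFactors = FALSE
    ),
    transitions = m
  )
  build_model(structure_cfg, params)
}

# one-state model: a single alive state, unit utility, configurable cost
single_alive_model <- function(per_cycle_cost = 0, utility = 1) {
  structure_cfg <- list(
    states = "Alive", absorbing = character(0),
    allowed = list(Alive = "Alive"),
    arms = list(Alive = "Alive")
  )
  params <- list(
    params = list(
      cost = if (per_cycle_cost > 0) fixed_spec(per_cycle_cost) else fixed_spec(0),
      u = fixed_spec(utility)
    ),
    state_map = data.frame(state = "Alive", per_cycle = "cost",
                           entry = "", utility = "u",
                           stringsAsFactors = FALSE),
    transitions = matrix(1, 1, 1, dimnames = list("Alive", "Alive"))
  )
  build_model(structure_cfg, params)
}

# tiny ground truth over 3 states for generator tests
toy_truth <- function(n_patients, n_cycles, seed = 1L,
                      m = rbind(c(0.7, 0.2, 0.1),
                                c(0.1, 0.7, 0.2),
                                c(0, 0, 1)),
                      start = c(0.5, 0.5, 0)) {
  states <- c("A", "B", "Dead")
  dimnames(m) <- list(states, states)
  ground_truth(states, m, start, n_patients = n_patients,
               n_cycles = n_cycles, seed = seed)
}
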