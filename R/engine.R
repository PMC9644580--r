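#' Engine configuration
#'
#' Study-condition defaults: 6-month cycles (0.5 years), 20 cycles over 10
#' years, a cohort of 10,000 patients, a 3% annual discount rate applied
#' to future costs and health benefits, half-cycle correction on, a
#' background mortality increment of 0.01 added to the death probability
#' every 10 cycles (a configurable stand-in for an external life-table
#' adjustment), and a willingness-to-pay threshold of SGD $80,000 per
#' QALY, anchored to per-capita GDP.
#'
#' @param cycle_length cycle length in years.
#' @param n_cycles number of cycles.
#' @param cohort_size cohort scale for the occupancy trace.
#' @param annual_discount_rate annual rate in \[0, 1).
#' @param half_cycle_correction average adjacent occupancy vectors and
#'   discount at cycle mid-points (life-table method).
#' @param mortality_increment probability (or rate, see `mortality_mode`)
#'   added to death per completed block of cycles.
#' @param mortality_block cycles per mortality block.
#' @param mortality_mode `"probability"` adds the increment to the death
#'   probability directly; `"rate"` adds it on the hazard scale.
#' @param wtp_threshold willingness to pay per QALY (SGD).
#' @param seed integer seed used by stochastic stages (PSA).
#' @return object of class `cad_engine_config`.
#' @export
engine_config <- function(cycle_length = 0.5, n_cycles = 20L,
                          cohort_size = 10000, annual_discount_rate = 0.03,
                          half_cycle_correction = TRUE,
                          mortality_increment = 0.01, mortality_block = 10L,
                          mortality_mode = c("probability", "rate"),
                          wtp_threshold = 80000, seed = 1L) {
  mortality_mode <- match.arg(mortality_mode)
  if (cycle_length <= 0) stop("cycle_length must be > 0")
  if (annual_discount_rate < 0 || annual_discount_rate >= 1) {
    stop("annual_discount_rate must be in [0, 1)")
  }
  if (mortality_increment < 0 || mortality_increment > 1) {
    stop("mortality_increment must be in [0, 1]")
  }
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("n_cycles must be >= 1")
  if (cohort_size <= 0) stop("cohort_size must be > 0")
  structure(
    list(cycle_length = cycle_length, n_cycles = n_cycles,
         cohort_size = cohort_size,
         annual_discount_rate = annual_discount_rate,
         half_cycle_correction = isTRUE(half_cycle_correction),
         mortality_increment = mortality_increment,
         mortality_block = as.integer(mortality_block),
         mortality_mode = mortality_mode,
         wtp_threshold = wtp_threshold, seed = as.integer(seed)),
    class = "cad_engine_config"
  )
}

#' State definitions table
#'
#' @param name state names.
#' @param per_cycle_cost recurring cost per 6-month cycle (SGD), e.g.
#'   medication.
#' @param entry_cost one-time cost charged on entry into the state (SGD),
#'   e.g. a procedure bill.
#' @param utility health-utility weight in \[0, 1\].
#' @param absorbing logical; an absorbing state must have zero costs and
#'   zero utility.
#' @return data.frame of class `cad_states`.
#' @export
state_table <- function(name, per_cycle_cost = 0, entry_cost = 0,
                        utility = 0, absorbing = FALSE) {
  df <- data.frame(name = as.character(name),
                   per_cycle_cost = as.numeric(per_cycle_cost),
                   entry_cost = as.numeric(entry_cost),
                   utility = as.numeric(utility),
                   absorbing = as.logical(absorbing),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$name)) stop("duplicate state names")
  if (any(df$per_cycle_cost < 0) || any(df$entry_cost < 0)) {
    stop("costs must be nonnegative")
  }
  if (any(df$utility < 0 | df$utility > 1)) stop("utility must be in [0, 1]")
  bad <- df$absorbing & (df$per_cycle_cost != 0 | df$entry_cost != 0 |
                           df$utility != 0)
  if (any(bad)) {
    stop("absorbing state '", df$name[bad][1],
         "' must have zero costs and zero utility")
  }
  class(df) <- c("cad_states", "data.frame")
  df
}

#' Assemble and validate a Markov model
#'
#' Combines a structure configuration (states, allowed transitions,
#' starting arms) with parameter values (transition probabilities, costs,
#' utilities) into a validated model. Any transition carrying positive
#' probability must be an allowed edge of the structure; disallowed
#' transitions are structural zeros. Every row must be stochastic within
#' `1e-9` after assembly.
#'
#' @param structure list with elements `states` (character),
#'   `absorbing` (death state name), `allowed` (named list: origin ->
#'   permitted destinations) and `arms` (named list: arm -> start state).
#'   See [default_model_structure()].
#' @param parameters list with `transitions` (row-stochastic matrix or a
#'   [estimate_transition_matrix()] result), `params` (named list of
#'   `cad_dist` specs) and `state_map` (data.frame mapping each state to
#'   its cost/utility parameter names). See [default_parameters()].
#' @return object of class `cad_model`: `states` (a [state_table()]),
#'   `transitions`, `arms`, `structure`, `parameters`.
#' @export
build_model <- function(structure = default_model_structure(),
                        parameters = default_parameters()) {
  st <- structure$states
  tr <- parameters$transitions
  if (inherits(tr, "cad_transition_estimate")) tr <- tr$probabilities
  tr <- as.matrix(tr)
  if (is.null(rownames(tr))) dimnames(tr) <- list(st, st)
  if (!setequal(rownames(tr), st) || !setequal(colnames(tr), st)) {
    stop("transition matrix states do not match the structure's state list")
  }
  tr <- tr[st, st, drop = FALSE]
  if (anyNA(tr)) {
    miss <- rownames(tr)[apply(is.na(tr), 1, any)]
    stop("missing transition probabilities for state(s): ",
         paste(miss, collapse = ", "))
  }
  assert_stochastic_rows(tr)
  for (from in st) {
    ok <- unique(c(structure$allowed[[from]],
                   if (length(structure$absorbing) &&
                         from %in% structure$absorbing) from))
    bad <- setdiff(colnames(tr)[tr[from, ] > 0], ok)
    if (length(bad)) {
      stop(sprintf("transition %s -> %s is not allowed by the model structure",
                   from, bad[1]))
    }
  }
  states <- states_from_parameters(structure, parameters)
  bad_arm <- vapply(structure$arms, function(a) !a %in% st, logical(1))
  if (any(bad_arm)) {
    stop("arm start state not in the state list: ",
         paste(unlist(structure$arms[bad_arm]), collapse = ", "))
  }
  structure(
    list(states = states, transitions = tr, arms = structure$arms,
         structure = structure, parameters = parameters),
    class = "cad_model"
  )
}

#' @export
print.cad_model <- function(x, ...) {
  cat("Cohort Markov model:", nrow(x$states), "states, arms:",
      paste(names(x$arms), collapse = ", "), "\n")
  invisible(x)
}

# Build the state table from parameter point values (spec means); sampled
# values can be injected via `overrides` (named numeric) during PSA.
states_from_parameters <- function(structure, parameters, overrides = NULL) {
  val <- function(pname) {
    if (is.null(pname) || is.na(pname) || pname == "") return(0)
    if (!is.null(overrides) && pname %in% names(overrides)) {
      return(unname(overrides[[pname]]))
    }
    spec <- parameters$params[[pname]]
    if (is.null(spec)) stop("missing parameter spec: ", pname)
    unname(spec_moments(spec)[["mean"]])
  }
  sm <- parameters$state_map
  missing_states <- setdiff(structure$states, sm$state)
  if (length(missing_states)) {
    stop("state_map lacks cost/utility mapping for state(s): ",
         paste(missing_states, collapse = ", "))
  }
  sm <- sm[match(structure$states, sm$state), ]
  state_table(
    name = sm$state,
    per_cycle_cost = vapply(sm$per_cycle, val, numeric(1)),
    entry_cost = vapply(sm$entry, val, numeric(1)),
    utility = vapply(sm$utility, val, numeric(1)),
    absorbing = sm$state %in% structure$absorbing
  )
}

#' Mortality-adjusted transition row
#'
#' Adds the stepped background mortality increment to a row's death
#' probability: `mortality_increment * floor((cycle - 1) / mortality_block)`
#' in probability mode (cycles 1-10 get no increment at the defaults,
#' cycles 11-20 get +0.01). Non-death entries are rescaled by the factor
#' restoring a unit row sum; the death probability is capped at 1, in
#' which case all other entries become 0.
#'
#' @param row named stochastic probability vector.
#' @param cycle cycle index (>= 1).
#' @param config a [engine_config()].
#' @param dead_state name of the death entry in `row`.
#' @return adjusted stochastic row.
#' @export
adjust_mortality <- function(row, cycle, config, dead_state = "Dead") {
  if (!dead_state %in% names(row)) return(row)
  blocks <- floor((cycle - 1) / config$mortality_block)
  if (blocks <= 0 || config$mortality_increment == 0) return(row)
  p0 <- row[[dead_state]]
  if (p0 >= 1) return(row)
  p1 <- if (config$mortality_mode == "rate") {
    # additive on the hazard scale for one cycle
    1 - (1 - p0) * exp(-config$mortality_increment * blocks)
  } else {
    p0 + config$mortality_increment * blocks
  }
  p1 <- min(p1, 1)
  out <- row * ((1 - p1) / (1 - p0))
  out[[dead_state]] <- p1
  out
}

# full-matrix version used by the propagation loop
adjust_mortality_matrix <- function(m, cycle, config, dead_state) {
  if (!dead_state %in% rownames(m)) return(m)
  for (s in rownames(m)) {
    if (s == dead_state) next
    m[s, ] <- adjust_mortality(m[s, ], cycle, config, dead_state)
  }
  m
}

#' Discount factor for a cycle's flows
#'
#' `(1 + r)^(-t)` with `t` the cycle's mid-point in years when half-cycle
#' correction is on (`t = (cycle - 0.5) * cycle_length`), else the
#' cycle-end time. The annual rate compounds across cycles; there is no
#' per-cycle simple-rate approximation.
#'
#' @param cycle cycle index (>= 1; vectorised).
#' @param config a [engine_config()].
#' @return discount factor(s) in (0, 1\].
#' @export
#' @examples
#' discount_factor(2, engine_config())  # 1.03^(-0.75)
discount_factor <- function(cycle, config) {
  t <- if (config$half_cycle_correction) {
    (cycle - 0.5) * config$cycle_length
  } else {
    cycle * config$cycle_length
  }
  (1 + config$annual_discount_rate)^(-t)
}

#' Propagate a cohort through the model
#'
#' Deterministic expectation propagation (not microsimulation): the whole
#' cohort starts in `start_state`, and occupancy at cycle `c + 1` is the
#' occupancy at `c` times the mortality-adjusted transition matrix for
#' that cycle. The 10,000-patient default sets the trace scale only.
#'
#' @param model a [build_model()] result.
#' @param start_state state (or arm name) the cohort starts in; a named
#'   numeric vector over states may be given for a mixed start.
#' @param config a [engine_config()].
#' @return object of class `cad_trace` with `occupancy`
#'   ((n_cycles + 1) x n_states matrix, rows summing to `cohort_size`),
#'   `start_state`, and the `config` used.
#' @export
run_cohort <- function(model, start_state, config = engine_config()) {
  stopifnot(inherits(model, "cad_model"))
  st <- model$states$name
  dead <- st[model$states$absorbing]
  dead <- if (length(dead)) dead[1] else NA_character_
  occ0 <- stats::setNames(numeric(length(st)), st)
  if (is.numeric(start_state)) {
    if (!setequal(names(start_state), st) &&
        !all(names(start_state) %in% st)) {
      stop("names of the start vector must be model states")
    }
    occ0[names(start_state)] <- start_state
    occ0 <- occ0 / sum(occ0) * config$cohort_size
  } else {
    if (start_state %in% names(model$arms)) {
      start_state <- model$arms[[start_state]]
    }
    if (!start_state %in% st) stop("unknown start state: ", start_state)
    occ0[start_state] <- config$cohort_size
  }
  occ <- matrix(0, config$n_cycles + 1L, length(st),
                dimnames = list(0:config$n_cycles, st))
  occ[1L, ] <- occ0
  for (c in seq_len(config$n_cycles)) {
    m <- if (is.na(dead)) model$transitions else {
      adjust_mortality_matrix(model$transitions, c, config, dead)
    }
    occ[c + 1L, ] <- occ[c, , drop = FALSE] %*% m
  }
  structure(list(occupancy = occ, start_state = start_state, config = config),
            class = "cad_trace")
}

#' @export
print.cad_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1L
  cat("Cohort trace:", n, "cycles,", ncol(x$occupancy), "states, start:",
      if (is.character(x$start_state)) x$start_state else "mixed", "\n")
  invisible(x)
}

#' Accumulate discounted costs and QALYs from a trace
#'
#' For each cycle `c >= 1` the effective occupancy is the mean of the
#' occupancy vectors at `c - 1` and `c` when half-cycle correction is on
#' (life-table / trapezoidal method), else the end-of-cycle occupancy.
#' Cycle QALYs are effective occupancy times utility times the cycle
#' length in years; recurring costs use the per-cycle state costs;
#' one-time entry costs attach to the expected flow of new entrants into
#' each state during the cycle. All cycle flows are multiplied by
#' [discount_factor()]. Patients placed in a procedure state at cycle 0
#' incur its entry cost at time 0, undiscounted. Totals are per patient
#' (divided by the cohort size).
#'
#' @param trace a [run_cohort()] result.
#' @param model the model the trace was run on.
#' @param config a [engine_config()]; defaults to the trace's own.
#' @return list with `total_cost`, `total_qaly` (per patient) and
#'   `per_cycle` (data.frame of discounted cycle accruals for the whole
#'   cohort).
#' @export
accumulate_outcomes <- function(trace, model, config = trace$config) {
  stopifnot(inherits(trace, "cad_trace"), inherits(model, "cad_model"))
  occ <- trace$occupancy
  st <- model$states$name
  if (!identical(colnames(occ), st)) {
    stop("trace and model state dimensions do not match")
  }
  u <- model$states$utility
  cc <- model$states$per_cycle_cost
  ec <- model$states$entry_cost
  dead <- st[model$states$absorbing]
  dead <- if (length(dead)) dead[1] else NA_character_
  n_cycles <- nrow(occ) - 1L
  cost_cycle <- qaly_cycle <- numeric(n_cycles)
  for (c in seq_len(n_cycles)) {
    eff <- if (config$half_cycle_correction) {
      (occ[c, ] + occ[c + 1L, ]) / 2
    } else {
      occ[c + 1L, ]
    }
    m <- if (is.na(dead)) model$transitions else {
      adjust_mortality_matrix(model$transitions, c, config, dead)
    }
    flow <- occ[c, , drop = FALSE] %*% m   # before netting out stayers
    stay <- occ[c, ] * diag(m)
    entrants <- pmax(as.numeric(flow) - stay, 0)
    df <- discount_factor(c, config)
    qaly_cycle[c] <- sum(eff * u) * config$cycle_length * df
    cost_cycle[c] <- (sum(eff * cc) + sum(entrants * ec)) * df
  }
  entry0 <- sum(occ[1L, ] * ec)   # starting placements pay entry at time 0
  total_cost <- (sum(cost_cycle) + entry0) / config$cohort_size
  total_qaly <- sum(qaly_cycle) / config$cohort_size
  list(
    total_cost = total_cost, total_qaly = total_qaly,
    per_cycle = data.frame(
      cycle = seq_len(n_cycles),
      discounted_cost = cost_cycle,
      discounted_qaly = qaly_cycle
    ),
    entry_cost_time0 = entry0
  )
}

#' Evaluate one starting arm end to end
#'
#' Convenience wrapper: [run_cohort()] then [accumulate_outcomes()].
#'
#' @inheritParams run_cohort
#' @return list with `trace`, `total_cost`, `total_qaly`, `per_cycle`.
#' @export
evaluate_arm <- function(model, start_state, config = engine_config()) {
  trace <- run_cohort(model, start_state, config)
  out <- accumulate_outcomes(trace, model, config)
  c(list(trace = trace), out)
}
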