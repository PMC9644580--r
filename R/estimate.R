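#' Estimate one transition-matrix row from patient histories
#'
#' Tallies consecutive observation pairs (cycle `c` in `from_state`, cycle
#' `c + 1` in each destination), pooled over patients and cycles, and
#' returns the maximum-likelihood proportions -- the share of patients in a
#' state who moved to each destination in one cycle. The raw tallies
#' double as Dirichlet count evidence for sensitivity analysis.
#'
#' @param histories data.frame with `patient_id`, `cycle`, `state`.
#' @param from_state state whose outgoing row is estimated.
#' @param state_list full ordered state vector (columns of the row).
#' @param pseudo_count nonnegative value added to each Dirichlet cell
#'   (default 0; does not affect the point estimate).
#' @return object of class `cad_transition_row`: `from_state`,
#'   `to_states`, `counts`, `probabilities`, `dirichlet`.
#' @export
estimate_transition_row <- function(histories, from_state, state_list,
                                    pseudo_count = 0) {
  stopifnot(all(c("patient_id", "cycle", "state") %in% names(histories)))
  if (!from_state %in% state_list) stop("from_state not in state_list")
  unknown <- setdiff(unique(histories$state), state_list)
  if (length(unknown)) {
    stop("histories contain states missing from state_list: ",
         paste(unknown, collapse = ", "))
  }
  h <- histories[order(histories$patient_id, histories$cycle), , drop = FALSE]
  n <- nrow(h)
  same <- h$patient_id[-n] == h$patient_id[-1L] &
    h$cycle[-1L] == h$cycle[-n] + 1L
  from <- h$state[-n][same]
  to <- h$state[-1L][same]
  if (!from_state %in% h$state) {
    stop(sprintf("state '%s' absent from the histories", from_state))
  }
  sel <- from == from_state
  if (!any(sel)) {
    stop(sprintf(
      "state '%s' observed only at final cycles: no successor pairs to count",
      from_state))
  }
  counts <- vapply(state_list, function(s) sum(to[sel] == s), numeric(1))
  structure(
    list(from_state = from_state, to_states = state_list, counts = counts,
         probabilities = counts / sum(counts),
         dirichlet = dirichlet_spec(counts, pseudo_count = pseudo_count)),
    class = "cad_transition_row"
  )
}

#' Estimate a full transition matrix from histories
#'
#' Applies [estimate_transition_row()] to every non-absorbing state; the
#' absorbing state keeps its unit row. The default estimator pools all
#' cycles (time-homogeneous, matching a single per-state proportion); set
#' `by_cycle = TRUE` for a cycle-stratified list of matrices.
#'
#' @inheritParams estimate_transition_row
#' @param state_list ordered state vector.
#' @param absorbing_state name of the death state.
#' @param by_cycle if `TRUE`, return one estimate per transition cycle.
#' @return class `cad_transition_estimate`: `states`, `counts` (matrix),
#'   `probabilities` (row-stochastic matrix), `rows` (list of
#'   `cad_transition_row`). With `by_cycle = TRUE`, a list of per-cycle
#'   estimates named by origin cycle.
#' @export
estimate_transition_matrix <- function(histories, state_list,
                                       absorbing_state = "Dead",
                                       pseudo_count = 0, by_cycle = FALSE) {
  if (!absorbing_state %in% state_list) {
    stop("absorbing_state must be in state_list")
  }
  if (by_cycle) {
    cycles <- sort(unique(histories$cycle))
    cycles <- cycles[cycles < max(cycles)]
    out <- lapply(cycles, function(c0) {
      sub <- histories[histories$cycle %in% c(c0, c0 + 1L), , drop = FALSE]
      estimate_transition_matrix(sub, state_list, absorbing_state,
                                 pseudo_count, by_cycle = FALSE)
    })
    names(out) <- cycles
    return(out)
  }
  live <- setdiff(state_list, absorbing_state)
  rows <- lapply(live, function(s) {
    tryCatch(
      estimate_transition_row(histories, s, state_list, pseudo_count),
      error = function(e) NULL
    )
  })
  names(rows) <- live
  k <- length(state_list)
  counts <- matrix(0, k, k, dimnames = list(state_list, state_list))
  probs <- matrix(NA_real_, k, k, dimnames = list(state_list, state_list))
  for (s in live) {
    if (is.null(rows[[s]])) next
    counts[s, ] <- rows[[s]]$counts
    probs[s, ] <- rows[[s]]$probabilities
  }
  probs[absorbing_state, ] <- 0
  probs[absorbing_state, absorbing_state] <- 1
  structure(
    list(states = state_list, counts = counts, probabilities = probs,
         rows = rows, absorbing_state = absorbing_state),
    class = "cad_transition_estimate"
  )
}

#' @export
print.cad_transition_estimate <- function(x, ...) {
  cat("Transition estimate over", length(x$states), "states;",
      sum(x$counts), "observed transitions\n")
  print(round(x$probabilities, 4))
  invisible(x)
}

#' Rescale a probability between time horizons
#'
#' Converts a probability observed over one horizon to another via the
#' cumulative-incidence relation `1 - (1 - p)^(t_target / t_source)`,
#' which assumes a constant event rate (exponential decay of event-free
#' survival) across the horizon. Used, e.g., to turn 5-year event-free
#' proportions into 6-month cycle probabilities.
#'
#' Limiting behaviour: `p = 1` maps to 1 for any positive target horizon
#' (a certain event stays certain under a constant-rate assumption).
#'
#' @param p_source probability in \[0, 1\] (vectorised).
#' @param horizon_source,horizon_target positive horizons in the same time
#'   unit.
#' @return probability over `horizon_target`.
#' @export
#' @examples
#' rescale_probability(64 / 70, 5, 0.5)   # 5-year -> 6-month, ~0.218
rescale_probability <- function(p_source, horizon_source, horizon_target) {
  if (any(!is.finite(horizon_source)) || any(horizon_source <= 0) ||
      any(!is.finite(horizon_target)) || any(horizon_target <= 0)) {
    stop("horizons must be positive")
  }
  if (any(p_source < 0 | p_source > 1)) stop("p_source must be in [0, 1]")
  1 - (1 - p_source)^(horizon_target / horizon_source)
}

#' Summarise billing costs per patient-period for one OMT group
#'
#' Aggregates the per-record medication amounts of one cost group and
#' returns their sample mean and standard deviation (n - 1 denominator; a
#' single record has SD 0 by convention).
#'
#' @param billing data.frame from [generate_billing()] (or the same
#'   schema).
#' @param group one of the medication cost groups present in `billing`.
#' @return named numeric vector `c(mean =, sd =, n =)`.
#' @export
summarize_costs <- function(billing, group) {
  stopifnot(all(c("group", "amount") %in% names(billing)))
  x <- billing$amount[billing$group == group]
  if (!length(x)) stop(sprintf("no billing records for group '%s'", group))
  s <- if (length(x) == 1L) 0 else stats::sd(x)
  c(mean = mean(x), sd = s, n = length(x))
}
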