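#' Simulate line-level patient state histories
#'
#' Realises the Markov chain described by a [ground_truth()] for each
#' patient: a start state is drawn from the start distribution, then the
#' chain is stepped once per 6-month cycle. Records stop at entry into the
#' absorbing death state (the death observation itself is emitted once;
#' nothing afterwards), mirroring how a clinical repository stops billing
#' at death. Optional administrative censoring truncates each patient's
#' follow-up at a uniform time over the observation window, emulating an
#' extraction-window cut-off.
#'
#' @param truth a `cad_ground_truth`.
#' @param censoring if `TRUE`, each patient is additionally censored at a
#'   cycle drawn uniformly from 1..n_cycles (observations after it are
#'   dropped). Default `FALSE`.
#' @return a data.frame with columns `patient_id`, `cycle`, `state`,
#'   ordered by patient then cycle; cycle indices start at 0.
#' @export
#' @examples
#' gt <- default_ground_truth(n_patients = 100, n_cycles = 4, seed = 7)
#' h <- generate_histories(gt)
#' head(h)
generate_histories <- function(truth, censoring = FALSE) {
  stopifnot(inherits(truth, "cad_ground_truth"))
  states <- truth$states
  m <- truth$transition_matrix
  dead <- truth$absorbing_state
  n <- truth$n_patients
  with_seed(truth$seed, {
    cur <- sample(states, n, replace = TRUE, prob = truth$start_distribution)
    path <- matrix(NA_character_, nrow = n, ncol = truth$n_cycles + 1L)
    path[, 1L] <- cur
    for (c in seq_len(truth$n_cycles)) {
      nxt <- cur
      for (s in states[states != dead]) {
        idx <- which(cur == s)
        if (length(idx)) {
          nxt[idx] <- sample(states, length(idx), replace = TRUE, prob = m[s, ])
        }
      }
      nxt[cur == dead] <- dead
      path[, c + 1L] <- nxt
      cur <- nxt
    }
    censor_at <- if (censoring) {
      sample.int(truth$n_cycles, n, replace = TRUE)
    } else {
      rep.int(truth$n_cycles, n)
    }
    # last emitted cycle: min(first entry into death, censoring time)
    first_dead <- apply(path == dead, 1L, function(z) {
      i <- which(z)[1L]
      if (is.na(i)) Inf else i - 1L
    })
    last <- pmin(first_dead, censor_at)
    keep_len <- last + 1L
    data.frame(
      patient_id = rep(sprintf("P%06d", seq_len(n)), times = keep_len),
      cycle = unlist(lapply(keep_len, function(k) 0:(k - 1L)), use.names = FALSE),
      state = unlist(lapply(seq_len(n), function(i) path[i, seq_len(keep_len[i])]),
                     use.names = FALSE),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate billing records for simulated histories
#'
#' One medication record is emitted per patient-period spent in a
#' non-absorbing, non-procedure state, with the amount drawn from a gamma
#' law matching the patient's OMT cost group: `no-intervention` before any
#' procedure, `post-stent` after a stent procedure, `post-bypass` after
#' bypass grafting (the most recent procedure decides the group). Each
#' occupation of a procedure state additionally emits a one-time record in
#' a distinct `procedure-*` group carrying the procedure cost, so
#' billing-derived and configuration-derived costing can be cross-checked.
#'
#' @param histories data.frame as returned by [generate_histories()].
#' @param cost_params data.frame `group`, `mean`, `sd` (SGD per 6 months);
#'   see [default_cost_groups()].
#' @param seed integer seed for the gamma draws.
#' @param procedure_states named character vector mapping procedure state
#'   names to procedure type (`"stent"` or `"bypass"`).
#' @param procedure_costs named numeric vector of one-time procedure costs
#'   (set to `NULL` to omit procedure rows).
#' @param absorbing_state name of the death state (no billing there).
#' @return data.frame with columns `patient_id`, `period`, `group`,
#'   `amount`.
#' @export
generate_billing <- function(histories,
                             cost_params = default_cost_groups(),
                             seed = 1L,
                             procedure_states = c(PCI = "stent", RePCI = "stent",
                                                  CABG = "bypass"),
                             procedure_costs = default_procedure_costs(),
                             absorbing_state = "Dead") {
  stopifnot(all(c("patient_id", "cycle", "state") %in% names(histories)))
  if (any(cost_params$sd <= 0)) stop("cost group SD must be > 0")
  if (any(cost_params$mean <= 0)) stop("cost group mean must be > 0")
  h <- histories[order(histories$patient_id, histories$cycle), , drop = FALSE]
  if (nrow(h) == 0L) {
    return(data.frame(patient_id = character(), period = integer(),
                      group = character(), amount = numeric(),
                      stringsAsFactors = FALSE))
  }
  proc_type <- procedure_states[h$state]           # NA for non-procedure states
  # most recent procedure type carried forward within each patient
  grp <- rep(NA_character_, nrow(h))
  new_patient <- c(TRUE, h$patient_id[-1L] != h$patient_id[-nrow(h)])
  run <- cumsum(new_patient)
  grp <- unlist(tapply(proc_type, run, function(p) {
    out <- character(length(p))
    cur <- "no-intervention"
    for (i in seq_along(p)) {
      if (!is.na(p[i])) cur <- paste0("post-", p[i])
      out[i] <- cur
    }
    out
  }, simplify = FALSE), use.names = FALSE)
  med <- is.na(proc_type) & h$state != absorbing_state
  with_seed(seed, {
    amounts <- numeric(sum(med))
    gmed <- grp[med]
    for (g in cost_params$group) {
      idx <- which(gmed == g)
      if (!length(idx)) next
      row <- cost_params[cost_params$group == g, ]
      spec <- gamma_from_mean_sd(row$mean, row$sd)
      amounts[idx] <- stats::rgamma(length(idx), shape = spec$shape,
                                    scale = spec$scale)
    }
    out <- data.frame(
      patient_id = h$patient_id[med], period = h$cycle[med],
      group = gmed, amount = amounts, stringsAsFactors = FALSE
    )
    pr <- which(!is.na(proc_type))
    if (!is.null(procedure_costs) && length(pr)) {
      out <- rbind(out, data.frame(
        patient_id = h$patient_id[pr], period = h$cycle[pr],
        group = paste0("procedure-", proc_type[pr]),
        amount = unname(procedure_costs[h$state[pr]]),
        stringsAsFactors = FALSE
      ))
    }
    out <- out[order(out$patient_id, out$period, out$group), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write histories or billing records to CSV
#'
#' Plain CSV with the canonical headers (`patient_id,cycle,state` and
#' `patient_id,period,group,amount`); identical inputs produce
#' byte-identical files.
#'
#' @param x data.frame from [generate_histories()] or [generate_billing()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @param what `"histories"` or `"billing"`, to validate the header.
#' @export
read_records_csv <- function(path, what = c("histories", "billing")) {
  what <- match.arg(what)
  if (!file.exists(path)) stop("records file does not exist: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (what == "histories") c("patient_id", "cycle", "state")
          else c("patient_id", "period", "group", "amount")
  if (!all(need %in% names(x))) {
    stop(sprintf("%s file must have columns %s", what,
                 paste(need, collapse = ", ")))
  }
  x
}
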