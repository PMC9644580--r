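#' A starting-treatment strategy mix
#'
#' @param name strategy label.
#' @param weights named nonnegative vector of starting-arm fractions,
#'   summing to 1 within 1e-9.
#' @return object of class `cad_strategy`.
#' @export
strategy_mix <- function(name, weights) {
  if (is.null(names(weights)) || any(names(weights) == "")) {
    stop("strategy weights must be named by arm")
  }
  if (any(weights < 0)) stop("strategy weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) {
    stop(sprintf("strategy '%s': weights sum to %.12f, not 1", name,
                 sum(weights)))
  }
  structure(list(name = name, weights = weights), class = "cad_strategy")
}

#' @export
print.cad_strategy <- function(x, ...) {
  cat(sprintf("Strategy '%s': %s\n", x$name,
              paste(sprintf("%s %.1f%%", names(x$weights), 100 * x$weights),
                    collapse = ", ")))
  invisible(x)
}

#' Combine per-arm results under a strategy mix
#'
#' The strategy's (cost, QALY) per patient is the weight-weighted average
#' of the arm results; the operation is linear, so a mix of mixes equals
#' the corresponding convex combination of results.
#'
#' @param mix a [strategy_mix()].
#' @param arm_results data.frame with columns `arm`, `cost`, `qaly`
#'   (one row per starting arm, a single parameter draw).
#' @return named numeric vector `c(cost =, qaly =)`.
#' @export
evaluate_mix <- function(mix, arm_results) {
  stopifnot(inherits(mix, "cad_strategy"),
            all(c("arm", "cost", "qaly") %in% names(arm_results)))
  w <- mix$weights
  missing_arm <- setdiff(names(w)[w > 0], arm_results$arm)
  if (length(missing_arm)) {
    stop("no arm results for: ", paste(missing_arm, collapse = ", "))
  }
  i <- match(names(w), arm_results$arm)
  keep <- !is.na(i)
  c(cost = sum(w[keep] * arm_results$cost[i[keep]]),
    qaly = sum(w[keep] * arm_results$qaly[i[keep]]))
}

#' Probabilistic sensitivity analysis
#'
#' For each of `n_draws` draws, every cost and utility parameter is
#' sampled once from its distribution, each starting arm is evaluated
#' deterministically under that draw, and every strategy is scored with
#' the same draw (common random numbers across strategies). By default
#' only cost and utility parameters vary; transition rows can additionally
#' be drawn from their Dirichlet count evidence with
#' `include_transitions = TRUE`.
#'
#' @param model a [build_model()] result.
#' @param strategies named list of [strategy_mix()] objects.
#' @param config a [engine_config()]; its `seed` drives all sampling.
#' @param n_draws number of parameter draws.
#' @param include_transitions sample transition rows from Dirichlet count
#'   evidence (requires `model$parameters$transitions` to be a
#'   `cad_transition_estimate`).
#' @return object of class `cad_psa`: `draws` (data.frame `draw`,
#'   `strategy`, `cost`, `qaly`), `arm_draws` (same per arm), `n_draws`,
#'   `seed`, `wtp_threshold`.
#' @export
run_psa <- function(model, strategies = default_strategies(),
                    config = engine_config(), n_draws = 1000L,
                    include_transitions = FALSE) {
  stopifnot(inherits(model, "cad_model"))
  n_draws <- as.integer(n_draws)
  params <- model$parameters$params
  est <- model$parameters$transitions
  if (include_transitions && !inherits(est, "cad_transition_estimate")) {
    stop("include_transitions requires Dirichlet count evidence ",
         "(a cad_transition_estimate) in the model parameters")
  }
  arms <- names(model$arms)
  with_seed(config$seed, {
    # one matrix of sampled values per parameter, draws in rows
    samples <- lapply(params, sample_spec, n = n_draws)
    tr_rows <- NULL
    if (include_transitions) {
      live <- setdiff(model$structure$states, model$structure$absorbing)
      tr_rows <- lapply(live, function(s) {
        if (is.null(est$rows[[s]])) return(NULL)
        sample_spec(est$rows[[s]]$dirichlet, n = n_draws)
      })
      names(tr_rows) <- live
    }
    arm_draws <- vector("list", n_draws)
    for (d in seq_len(n_draws)) {
      ov <- vapply(samples, function(v) v[d], numeric(1))
      m <- model
      m$states <- states_from_parameters(model$structure, model$parameters,
                                         overrides = ov)
      if (include_transitions) {
        tr <- model$transitions
        for (s in names(tr_rows)) {
          if (!is.null(tr_rows[[s]])) tr[s, ] <- tr_rows[[s]][d, ]
        }
        m$transitions <- tr
      }
      res <- lapply(arms, function(a) {
        out <- evaluate_arm(m, a, config)
        c(cost = out$total_cost, qaly = out$total_qaly)
      })
      arm_draws[[d]] <- data.frame(
        draw = d, arm = arms,
        cost = vapply(res, `[[`, numeric(1), "cost"),
        qaly = vapply(res, `[[`, numeric(1), "qaly"),
        stringsAsFactors = FALSE
      )
    }
  })
  cost_mat <- do.call(rbind, lapply(arm_draws, function(ad) {
    stats::setNames(ad$cost, ad$arm)
  }))
  qaly_mat <- do.call(rbind, lapply(arm_draws, function(ad) {
    stats::setNames(ad$qaly, ad$arm)
  }))
  arm_draws <- do.call(rbind, arm_draws)
  draws <- do.call(rbind, lapply(names(strategies), function(nm) {
    s <- strategies[[nm]]
    per_draw <- t(apply(cbind(seq_len(n_draws)), 1, function(d) {
      evaluate_mix(s, data.frame(arm = colnames(cost_mat),
                                 cost = cost_mat[d, ], qaly = qaly_mat[d, ],
                                 stringsAsFactors = FALSE))
    }))
    data.frame(draw = seq_len(n_draws), strategy = nm,
               cost = per_draw[, "cost"], qaly = per_draw[, "qaly"],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(
    list(draws = draws, arm_draws = arm_draws, n_draws = n_draws,
         seed = config$seed, wtp_threshold = config$wtp_threshold),
    class = "cad_psa"
  )
}

#' @export
print.cad_psa <- function(x, ...) {
  cat("PSA:", x$n_draws, "draws x",
      length(unique(x$draws$strategy)), "strategies (seed", x$seed, ")\n")
  agg <- stats::aggregate(cbind(cost, qaly) ~ strategy, data = x$draws, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Incremental cost-effectiveness summary versus a base strategy
#'
#' Per-draw differences in cost and QALYs against the base strategy, their
#' means and equal-tailed 95% percentile uncertainty intervals, the net
#' monetary benefit `NMB = wtp * dQALY - dCost`, and decision
#' probabilities: the fraction of draws that save costs (`dCost < 0`),
#' gain health (`dQALY > 0`) and are cost-effective (`NMB > 0`). Strict
#' inequalities: a delta of exactly zero counts as neither saving nor
#' effective, so comparing a strategy with itself yields zero deltas and
#' zero probabilities.
#'
#' @param psa a [run_psa()] result.
#' @param strategy,base strategy names present in the PSA.
#' @param wtp willingness-to-pay threshold (SGD per QALY); defaults to the
#'   threshold the PSA was configured with.
#' @param level uncertainty-interval level (default 0.95, equal-tailed
#'   percentile).
#' @return object of class `cad_ce_result` with means, interval bounds,
#'   probabilities and the per-draw `deltas` data.frame.
#' @export
incremental_summary <- function(psa, strategy, base = "current_practice",
                                wtp = psa$wtp_threshold, level = 0.95) {
  stopifnot(inherits(psa, "cad_psa"))
  d <- psa$draws
  for (nm in c(strategy, base)) {
    if (!nm %in% d$strategy) stop("strategy not in PSA: ", nm)
  }
  a <- d[d$strategy == strategy, ]
  b <- d[d$strategy == base, ]
  a <- a[order(a$draw), ]; b <- b[order(b$draw), ]
  delta_cost <- a$cost - b$cost
  delta_qaly <- a$qaly - b$qaly
  nmb <- wtp * delta_qaly - delta_cost
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  pct <- function(x) stats::quantile(x, qs, names = FALSE, type = 7)
  structure(
    list(
      strategy = strategy, base = base, wtp = wtp, level = level,
      delta_cost = mean(delta_cost), delta_cost_ui = pct(delta_cost),
      delta_qaly = mean(delta_qaly), delta_qaly_ui = pct(delta_qaly),
      nmb = mean(nmb), nmb_ui = pct(nmb),
      p_cost_saving = mean(delta_cost < 0),
      p_qaly_gain = mean(delta_qaly > 0),
      p_cost_effective = mean(nmb > 0),
      deltas = data.frame(draw = a$draw, delta_cost = delta_cost,
                          delta_qaly = delta_qaly, nmb = nmb)
    ),
    class = "cad_ce_result"
  )
}

#' @export
print.cad_ce_result <- function(x, ...) {
  cat(sprintf("%s vs %s (WTP %s/QALY)\n", x$strategy, x$base,
              format(x$wtp, big.mark = ",")))
  cat(sprintf("  dCost %10.0f (%.0f to %.0f)\n", x$delta_cost,
              x$delta_cost_ui[1], x$delta_cost_ui[2]))
  cat(sprintf("  dQALY %10.3f (%.3f to %.3f)\n", x$delta_qaly,
              x$delta_qaly_ui[1], x$delta_qaly_ui[2]))
  cat(sprintf("  NMB   %10.0f (%.0f to %.0f)\n", x$nmb,
              x$nmb_ui[1], x$nmb_ui[2]))
  cat(sprintf("  P(saves cost) %.3f  P(gains QALYs) %.3f  P(cost-effective) %.3f\n",
              x$p_cost_saving, x$p_qaly_gain, x$p_cost_effective))
  invisible(x)
}

#' Table of all strategies versus a base
#'
#' One row per non-base strategy with mean incremental cost, QALYs, NMB
#' and their 95% uncertainty intervals -- the standard changes-to-costs-
#' QALYs-and-NMB comparison table.
#'
#' @inheritParams incremental_summary
#' @return data.frame with columns `strategy`, `delta_cost`,
#'   `delta_cost_lo`, `delta_cost_hi`, `delta_qaly`, `delta_qaly_lo`,
#'   `delta_qaly_hi`, `nmb`, `nmb_lo`, `nmb_hi`, `p_cost_saving`,
#'   `p_qaly_gain`, `p_cost_effective`.
#' @export
comparison_table <- function(psa, base = "current_practice",
                             wtp = psa$wtp_threshold) {
  others <- setdiff(unique(psa$draws$strategy), base)
  rows <- lapply(others, function(s) {
    ce <- incremental_summary(psa, s, base, wtp)
    data.frame(
      strategy = s,
      delta_cost = ce$delta_cost, delta_cost_lo = ce$delta_cost_ui[1],
      delta_cost_hi = ce$delta_cost_ui[2],
      delta_qaly = ce$delta_qaly, delta_qaly_lo = ce$delta_qaly_ui[1],
      delta_qaly_hi = ce$delta_qaly_ui[2],
      nmb = ce$nmb, nmb_lo = ce$nmb_ui[1], nmb_hi = ce$nmb_ui[2],
      p_cost_saving = ce$p_cost_saving, p_qaly_gain = ce$p_qaly_gain,
      p_cost_effective = ce$p_cost_effective,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which
#' the strategy's net monetary benefit against the base is strictly
#' positive. At a threshold of zero this equals the probability of saving
#' costs.
#'
#' @inheritParams incremental_summary
#' @param wtp_grid nonnegative, increasing vector of thresholds.
#' @return data.frame `wtp`, `p_cost_effective`.
#' @export
ceac <- function(psa, strategy, base = "current_practice",
                 wtp_grid = seq(0, 160000, by = 5000)) {
  if (!length(wtp_grid)) stop("wtp_grid must be non-empty")
  if (any(wtp_grid < 0) || is.unsorted(wtp_grid, strictly = TRUE)) {
    stop("wtp_grid must be nonnegative and strictly increasing")
  }
  ce <- incremental_summary(psa, strategy, base, wtp = 0)
  dq <- ce$deltas$delta_qaly
  dc <- ce$deltas$delta_cost
  p <- vapply(wtp_grid, function(l) mean(l * dq - dc > 0), numeric(1))
  data.frame(wtp = wtp_grid, p_cost_effective = p)
}

#' Cost-effectiveness plane samples
#'
#' Per-draw incremental (QALY, cost) pairs for each strategy against the
#' base, ready for plotting.
#'
#' @inheritParams comparison_table
#' @return data.frame `draw`, `strategy`, `delta_qaly`, `delta_cost`.
#' @export
ce_plane <- function(psa, base = "current_practice") {
  others <- setdiff(unique(psa$draws$strategy), base)
  out <- do.call(rbind, lapply(others, function(s) {
    ce <- incremental_summary(psa, s, base, wtp = 0)
    data.frame(draw = ce$deltas$draw, strategy = s,
               delta_qaly = ce$deltas$delta_qaly,
               delta_cost = ce$deltas$delta_cost,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Scale per-patient incremental results to a treated population
#'
#' Multiplies the per-patient incremental cost and QALYs by the annual
#' number of treated patients and values the annual QALY gain at the
#' willingness-to-pay threshold.
#'
#' @param ce a [incremental_summary()] result (or a list with
#'   `delta_cost` and `delta_qaly`).
#' @param patients_per_year annual number of treated patients (>= 0).
#' @param wtp willingness to pay per QALY.
#' @return named numeric vector `annual_cost_change`,
#'   `annual_qaly_change`, `annual_qaly_value`.
#' @export
#' @examples
#' population_scale(list(delta_cost = -1743, delta_qaly = 0.23), 6000, 80000)
population_scale <- function(ce, patients_per_year, wtp) {
  if (patients_per_year < 0) stop("patients_per_year must be >= 0")
  c(annual_cost_change = ce$delta_cost * patients_per_year,
    annual_qaly_change = ce$delta_qaly * patients_per_year,
    annual_qaly_value = ce$delta_qaly * patients_per_year * wtp)
}
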