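#' Default model structure (states, allowed transitions, arms)
#'
#' Encodes the three treatment-journey diagrams as config-level data, not
#' code, so users can adapt the topology: medication-only patients may
#' stay, move to a procedure, or die; each procedure state feeds its
#' maintenance, stable and repeat-procedure states; stable states only
#' persist or die. Arms name the starting state of each policy component.
#'
#' @return list with `states`, `absorbing`, `allowed`, `arms`.
#' @export
default_model_structure <- function() {
  list(
    states = model_state_names(),
    absorbing = "Dead",
    allowed = list(
      OMT = c("OMT", "PCI", "CABG", "Dead"),
      PCI = c("PostPCI", "StablePCI", "RePCI", "CABG", "Dead"),
      CABG = c("PostCABG", "StableCABG", "RePCI", "Dead"),
      RePCI = c("PostPCI", "StablePCI", "Dead"),
      PostPCI = c("PostPCI", "RePCI", "CABG", "StablePCI", "Dead"),
      PostCABG = c("PostCABG", "RePCI", "StableCABG", "Dead"),
      StablePCI = c("StablePCI", "Dead"),
      StableCABG = c("StableCABG", "Dead"),
      Dead = "Dead"
    ),
    arms = list(OMT = "OMT", PCI = "PCI", CABG = "CABG")
  )
}

#' Default cost and utility parameter set
#'
#' Sampling distributions for every cost and utility parameter, with the
#' mapping from model states to parameters. Costs (SGD) are gamma laws
#' parameterised by mean/SD: 6-month medication costs for the three OMT
#' groups ($129.86/36.06 without intervention, $147.68/14.29 after stent,
#' $96.65/30.03 after bypass) and one-time procedure costs (PCI
#' $26,261.18/4,908.53; CABG $35,756.64/4,419.17; a repeat PCI is costed
#' as a PCI). Utilities are beta laws re-derived by method of moments from
#' their mean/SD (OMT 0.69/0.12, PCI 0.72/0.22, Re-PCI 0.70/0.16, stable
#' PCI 0.87/0.03, CABG 0.82/0.03, stable CABG 0.84/0.04); the
#' post-procedure maintenance states reuse the OMT utility.
#'
#' @param transitions transition matrix or
#'   [estimate_transition_matrix()] result; defaults to
#'   [default_transition_matrix()].
#' @return list with `params` (named list of [gamma_from_mean_sd()] /
#'   [beta_from_mean_sd()] specs), `state_map` (data.frame: `state`,
#'   `per_cycle`, `entry`, `utility`) and `transitions`.
#' @export
default_parameters <- function(transitions = default_transition_matrix()) {
  params <- list(
    med_cost_no_intervention = gamma_from_mean_sd(129.86, 36.06),
    med_cost_post_stent = gamma_from_mean_sd(147.68, 14.29),
    med_cost_post_bypass = gamma_from_mean_sd(96.65, 30.03),
    proc_cost_pci = gamma_from_mean_sd(26261.18, 4908.53),
    proc_cost_cabg = gamma_from_mean_sd(35756.64, 4419.17),
    u_omt = beta_from_mean_sd(0.69, 0.12),
    u_pci = beta_from_mean_sd(0.72, 0.22),
    u_repci = beta_from_mean_sd(0.70, 0.16),
    u_stable_pci = beta_from_mean_sd(0.87, 0.03),
    u_cabg = beta_from_mean_sd(0.82, 0.03),
    u_stable_cabg = beta_from_mean_sd(0.84, 0.04)
  )
  state_map <- data.frame(
    state = model_state_names(),
    per_cycle = c("med_cost_no_intervention",     # OMT
                  "med_cost_post_stent",          # PCI (procedure cycle)
                  "med_cost_post_bypass",         # CABG (procedure cycle)
                  "med_cost_post_stent",          # RePCI
                  "med_cost_post_stent",          # PostPCI
                  "med_cost_post_bypass",         # PostCABG
                  "med_cost_post_stent",          # StablePCI
                  "med_cost_post_bypass",         # StableCABG
                  ""),                            # Dead
    entry = c("", "proc_cost_pci", "proc_cost_cabg", "proc_cost_pci",
              "", "", "", "", ""),
    utility = c("u_omt", "u_pci", "u_cabg", "u_repci", "u_omt", "u_omt",
                "u_stable_pci", "u_stable_cabg", ""),
    stringsAsFactors = FALSE
  )
  list(params = params, state_map = state_map, transitions = transitions)
}

#' Starting-treatment policies under comparison
#'
#' A strategy is a mix of starting arms. The five shipped policies are
#' data, not code: current practice (81.9% OMT, 13.5% PCI, 4.6% CABG),
#' the three single-treatment policies, and the recommended policy of 86%
#' OMT and 14% CABG with no stent PCI as a starting treatment.
#'
#' @return named list of [strategy_mix()] objects.
#' @export
default_strategies <- function() {
  list(
    current_practice = strategy_mix("current_practice",
                                    c(OMT = 0.819, PCI = 0.135, CABG = 0.046)),
    all_cabg = strategy_mix("all_cabg", c(CABG = 1)),
    all_omt = strategy_mix("all_omt", c(OMT = 1)),
    all_pci = strategy_mix("all_pci", c(PCI = 1)),
    recommended = strategy_mix("recommended", c(OMT = 0.86, CABG = 0.14))
  )
}
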