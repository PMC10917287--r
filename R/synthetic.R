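#' Synthetic model specification
#'
#' Describes a complete synthetic world: monthly worsening and death
#' probabilities per CKD state under standard of care, renal-replacement
#' dynamics, a multiplicative treatment effect on the per-cycle worsening
#' probabilities (default 0.61, a hazard-ratio-like factor on progression),
#' and cost/utility magnitudes.  Defaults are calibrated so the SoC arm
#' lives about 9.5 undiscounted years with about 6 of them in CKD stages
#' 1--3b over a 40-year monthly horizon; they are a documented stand-in,
#' not trial estimates.
#'
#' @param worsen named monthly probabilities of progressing one stage
#'   (ckd1..ckd5; ckd5 progresses to dialysis).
#' @param death named monthly all-cause death probabilities per alive state.
#' @param tx_rate monthly probability of transplant from dialysis.
#' @param graft_fail monthly probability of graft failure (transplant
#'   maintenance back to dialysis).
#' @param effect multiplicative factor in (0, 1] applied to the worsening
#'   probabilities in the intervention arm.
#' @param n_eff pseudo sample size used for binomial standard errors of the
#'   transition probabilities, `se = sqrt(p(1-p)/n_eff)` (trial-sized
#'   precision).
#' @param init_dist baseline distribution over states (defaults concentrate
#'   on CKD 2--4, the enrolled population).
#' @param discontinuation_rate constant per-cycle treatment discontinuation
#'   probability (stand-in; not reported).
#' @param ae_rates per-cycle adverse-event rates by arm (stand-ins; the
#'   informing publication names the events but not the rates).
#' @param equal_drug_cost if `TRUE`, both arms get the comparator's drug
#'   price (used for null-effect constructions).
#' @param horizon_cycles model horizon in monthly cycles.
#' @param seed stored for provenance; the generator itself is
#'   deterministic.
#' @return An object of class `ckd_synth_spec`.
#' @export
synth_spec <- function(
    worsen = c(ckd1 = 0.006, ckd2 = 0.007, ckd3a = 0.009, ckd3b = 0.011,
               ckd4 = 0.013, ckd5 = 0.030),
    death = c(ckd1 = 0.0028, ckd2 = 0.0033, ckd3a = 0.0045, ckd3b = 0.0065,
              ckd4 = 0.0105, ckd5 = 0.0175, dialysis = 0.0275,
              tx_init = 0.0225, tx_maint = 0.0063),
    tx_rate = 0.0045,
    graft_fail = 0.0020,
    effect = 0.61,
    n_eff = 2000,
    init_dist = c(ckd1 = 0, ckd2 = 0.11, ckd3a = 0.31, ckd3b = 0.33,
                  ckd4 = 0.25, ckd5 = 0, dialysis = 0, tx_init = 0,
                  tx_maint = 0, dead = 0),
    discontinuation_rate = 0.004,
    ae_rates = list(
      volume_depletion = c(dapagliflozin = 0.0020, soc = 0.0014),
      severe_hypoglycaemia = c(dapagliflozin = 0.0011, soc = 0.0022),
      fracture = c(dapagliflozin = 0.0014, soc = 0.0011),
      diabetic_ketoacidosis = c(dapagliflozin = 0.00002, soc = 0.00007),
      amputation = c(dapagliflozin = 0.00055, soc = 0.00060)),
    equal_drug_cost = FALSE,
    horizon_cycles = 480L,
    seed = NULL) {
  if (effect <= 0 || effect > 1)
    stop("synth_spec: effect must be in (0, 1]")
  structure(list(worsen = worsen, death = death, tx_rate = tx_rate,
                 graft_fail = graft_fail, effect = effect, n_eff = n_eff,
                 init_dist = init_dist,
                 discontinuation_rate = discontinuation_rate,
                 ae_rates = ae_rates, equal_drug_cost = equal_drug_cost,
                 horizon_cycles = as.integer(horizon_cycles), seed = seed),
            class = "ckd_synth_spec")
}

# published cost table (2022 RM): drug acquisition, per-stage management,
# renal replacement therapy and adverse-event unit costs, with SEs
published_costs <- function(equal_drug_cost = FALSE) {
  list(
    drug_annual = list(
      dapagliflozin = list(mean = if (equal_drug_cost) 46.32 else 463.55,
                           se = 0.01),
      soc = list(mean = 46.32, se = 0.01)),
    state_mgmt_annual = list(
      ckd1 = list(mean = 343.91, se = 46.00),
      ckd2 = list(mean = 484.07, se = 29.52),
      ckd3a = list(mean = 425.63, se = 54.45),
      ckd3b = list(mean = 1287.52, se = 82.39),
      ckd4 = list(mean = 1726.12, se = 27.84),
      ckd5 = list(mean = 3194.31, se = 11909.60)),
    dialysis_annual = list(mean = 44731.40, se = 1118.29),
    transplant_initial_once = list(mean = 117805.11, se = 1982.69),
    transplant_maint_annual = list(mean = 25281.64, se = 632.04),
    ae_unit_cost = list(
      volume_depletion = list(mean = 1330.90, se = 350.32),
      severe_hypoglycaemia = list(mean = 8802.57, se = 462.78),
      fracture = list(mean = 7862.22, se = 391.31),
      # priced identically to a severe hypoglycaemic event
      diabetic_ketoacidosis = list(mean = 8802.57, se = 462.78),
      amputation = list(mean = 6868.35, se = 459.94)))
}

published_utilities <- function() {
  list(
    state_utility = list(
      ckd1 = list(mean = 0.93, se = 0.005),
      ckd2 = list(mean = 0.87, se = 0.005),
      ckd3a = list(mean = 0.88, se = 0.002),
      ckd3b = list(mean = 0.88, se = 0.002),
      ckd4 = list(mean = 0.87, se = 0.003),
      ckd5 = list(mean = 0.85, se = 0.009),
      dialysis = list(mean = 0.85, se = 0.17),
      tx_init = list(mean = 0.95, se = 0.05),
      tx_maint = list(mean = 0.95, se = 0.05)),
    ae_decrement = list(
      volume_depletion = list(mean = 0.05, se = 0.01),
      severe_hypoglycaemia = list(mean = 0.19, se = 0.00),
      fracture = list(mean = 0.072, se = 0.031),
      diabetic_ketoacidosis = list(mean = 0.01, se = 0.01),
      amputation = list(mean = 0.266, se = 0.05)))
}

build_soc_matrix <- function(spec, states, effect = 1) {
  sid <- states$id
  S <- length(sid)
  M <- matrix(0, S, S, dimnames = list(sid, sid))
  nxt <- c(ckd1 = "ckd2", ckd2 = "ckd3a", ckd3a = "ckd3b", ckd3b = "ckd4",
           ckd4 = "ckd5", ckd5 = "dialysis")
  for (s in names(nxt)) {
    w <- spec$worsen[[s]] * effect
    d <- spec$death[[s]]
    if (w + d > 1)
      stop("gen_parameter_set: row ", s, ": probabilities sum over 1")
    M[s, nxt[[s]]] <- w
    M[s, "dead"] <- d
    M[s, s] <- 1 - w - d
  }
  if (spec$tx_rate + spec$death[["dialysis"]] > 1)
    stop("gen_parameter_set: row dialysis: probabilities sum over 1")
  M["dialysis", "tx_init"] <- spec$tx_rate
  M["dialysis", "dead"] <- spec$death[["dialysis"]]
  M["dialysis", "dialysis"] <- 1 - spec$tx_rate - spec$death[["dialysis"]]
  M["tx_init", "dead"] <- spec$death[["tx_init"]]
  M["tx_init", "tx_maint"] <- 1 - spec$death[["tx_init"]]
  M["tx_maint", "dialysis"] <- spec$graft_fail
  M["tx_maint", "dead"] <- spec$death[["tx_maint"]]
  M["tx_maint", "tx_maint"] <- 1 - spec$graft_fail - spec$death[["tx_maint"]]
  M["dead", "dead"] <- 1
  M
}

binom_se <- function(m, n_eff, dead) {
  se <- sqrt(m * (1 - m) / n_eff)
  se[m == 0 | m == 1] <- 0
  se[dead, ] <- 0
  se
}

#' Generate a complete parameter set from a synthetic specification
#'
#' Standard-of-care matrices place each state's worsening mass on the next
#' worse state and its death mass on the dead state, with the remainder
#' staying put; the intervention arm multiplies the worsening probabilities
#' by the treatment-effect factor, the stay probability absorbing the
#' difference.  Phase 1 equals phase 2.  Costs and utilities use the
#' published magnitudes; transition SEs are binomial at `n_eff`.
#'
#' @param spec a `ckd_synth_spec`.
#' @return A validated `ckd_parameters` object.
#' @export
#' @examples
#' p <- gen_parameter_set(synth_spec(effect = 1))  # null treatment effect
#' all.equal(p$matrices$dapagliflozin$phase1, p$matrices$soc$phase1)
gen_parameter_set <- function(spec = synth_spec()) {
  states <- default_states()
  soc <- build_soc_matrix(spec, states, effect = 1)
  dapa <- build_soc_matrix(spec, states, effect = spec$effect)
  dd <- dead_id(states)
  matrices <- list(
    dapagliflozin = list(phase1 = dapa, phase2 = dapa,
                         phase1_se = binom_se(dapa, spec$n_eff, dd),
                         phase2_se = binom_se(dapa, spec$n_eff, dd)),
    soc = list(phase1 = soc, phase2 = soc,
               phase1_se = binom_se(soc, spec$n_eff, dd),
               phase2_se = binom_se(soc, spec$n_eff, dd)))
  aes <- lapply(names(spec$ae_rates), function(nm)
    list(name = nm, rate_per_cycle = spec$ae_rates[[nm]],
         duration_cycles = 1L))
  econ <- list(annual_discount = 0.03, cycle_length_months = 1,
               wtp_per_qaly = 46000, fx_rm_per_usd = 4.14,
               horizon_cycles = spec$horizon_cycles,
               discontinuation_rate_per_cycle = spec$discontinuation_rate)
  parameter_set(states, matrices,
                published_costs(spec$equal_drug_cost), published_utilities(),
                aes, econ, spec$init_dist)
}

#' Maximum-likelihood transition-matrix estimate from simulated paths
#'
#' Row-normalised transition counts over consecutive cycle pairs.  Rows for
#' states never observed as a source are returned as `NA` and flagged in
#' the `"unvisited"` attribute.
#'
#' @param paths integer matrix `n x (cycles+1)` of state indices (e.g. the
#'   `"paths"` attribute of [microsim_oracle()] with `keep_paths = TRUE`).
#' @param n_states number of states.
#' @return Estimated transition matrix with attributes `n_transitions`
#'   (per-row observation counts) and `unvisited` (row indices with no
#'   observations).
#' @export
recover_matrix <- function(paths, n_states) {
  from <- as.vector(paths[, -ncol(paths), drop = FALSE])
  to <- as.vector(paths[, -1, drop = FALSE])
  counts <- matrix(0, n_states, n_states)
  tab <- table(factor(from, levels = 1:n_states),
               factor(to, levels = 1:n_states))
  counts[] <- as.numeric(tab)
  n_row <- rowSums(counts)
  est <- counts / ifelse(n_row > 0, n_row, NA)
  unvisited <- which(n_row == 0)
  est[unvisited, ] <- NA_real_
  structure(est, n_transitions = n_row, unvisited = unvisited)
}
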