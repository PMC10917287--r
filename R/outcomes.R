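#' Per-cycle discount factor
#'
#' Discrete discounting of the annual rate compounded at the cycle length:
#' `(1 + rate)^(-cycle * cycle_months / 12)`.  Cycle 0 has factor 1.
#'
#' @param cycle cycle number(s), >= 0.
#' @param annual_rate annual discount rate (default 0.03).
#' @param cycle_months cycle length in months.
#' @return Numeric discount factor(s).
#' @export
discount_factor <- function(cycle, annual_rate = 0.03, cycle_months = 1) {
  if (annual_rate <= -1) stop("discount_factor: annual_rate must be > -1")
  if (any(cycle < 0)) stop("discount_factor: cycle must be >= 0")
  (1 + annual_rate)^(-cycle * cycle_months / 12)
}

#' Accumulate discounted costs, QALYs and life years over a cohort trace
#'
#' Rewards accrue to the state occupied at cycle start (cycles 0..H-1), all
#' cost and QALY terms discounted; life years are reported undiscounted.
#' Cost categories: drug acquisition (the arm's drug while on treatment,
#' the comparator's after discontinuation, and only in pre-RRT states),
#' per-stage disease management, dialysis, transplant (one-off surgery cost
#' on entry into the transient transplant state plus monthly maintenance),
#' and adverse events (expected value: per-cycle event rate x unit cost over
#' alive occupancy).  Adverse-event utility decrements combine
#' multiplicatively with the state utility:
#' `u * prod(1 - rate_i * decrement_i)`.
#'
#' @param trace a `ckd_trace` from [run_cohort()] or [microsim_oracle()].
#' @param params the `ckd_parameters` used to produce it.
#' @return An object of class `ckd_arm_result` with fields `cost_total`,
#'   `cost_by_category`, `qaly_total`, `ly_total`, `time_in_subset`.
#' @export
accumulate <- function(trace, params) {
  arm <- attr(trace, "arm")
  arm <- match.arg(arm, ARMS)
  st <- params$states
  sid <- st$id
  H <- dim(trace)[1] - 1
  cm <- params$econ$cycle_length_months
  df <- discount_factor(0:(H - 1), params$econ$annual_discount, cm)

  occ_on <- trace[seq_len(H), sid, "on_drug", drop = FALSE][, , 1]
  occ_off <- trace[seq_len(H), sid, "discontinued", drop = FALSE][, , 1]
  if (H == 1) { occ_on <- matrix(occ_on, 1); occ_off <- matrix(occ_off, 1)
                colnames(occ_on) <- colnames(occ_off) <- sid }

  stage_ids <- ckd_stage_ids(st)
  for (s in c(stage_ids, st$id[st$category %in%
        c("dialysis", "transplant_maintenance")])) {
    if (is.null(params$utilities$state_utility[[s]]))
      stop("accumulate: no utility for reachable state ", s)
  }

  # per-state monthly management cost
  mgmt <- stats::setNames(numeric(length(sid)), sid)
  for (s in stage_ids)
    mgmt[s] <- annual_to_cycle_cost(params$costs$state_mgmt_annual[[s]]$mean, cm)
  dial_id <- st$id[st$category == "dialysis"]
  txi_id <- st$id[st$category == "transplant_initial"]
  txm_id <- st$id[st$category == "transplant_maintenance"]
  dial_m <- annual_to_cycle_cost(params$costs$dialysis_annual$mean, cm)
  txm_m <- annual_to_cycle_cost(params$costs$transplant_maint_annual$mean, cm)
  txi_once <- params$costs$transplant_initial_once$mean

  occ_all <- occ_on + occ_off
  disc_occ <- df * occ_all                      # H x S, discounted occupancy

  cost_stage <- vapply(stage_ids, function(s) sum(disc_occ[, s]) * mgmt[s], 0)
  cost_dial <- if (length(dial_id) > 0) sum(disc_occ[, dial_id]) * dial_m else 0
  # the transplant state is transient, so all of its occupancy is new entry
  cost_tx <- (if (length(txi_id) > 0) sum(disc_occ[, txi_id]) * txi_once else 0) +
    (if (length(txm_id) > 0) sum(disc_occ[, txm_id]) * txm_m else 0)

  drug_states <- sid[st$drug_cost_applies]
  drug_m <- vapply(ARMS, function(a)
    annual_to_cycle_cost(params$costs$drug_annual[[a]]$mean, cm), 0)
  cost_drug <- sum(df * rowSums(occ_on[, drug_states, drop = FALSE])) * drug_m[[arm]] +
    sum(df * rowSums(occ_off[, drug_states, drop = FALSE])) * drug_m[["soc"]]

  # adverse events: expected cost and multiplicative utility factor, by
  # status (discontinued patients carry the comparator's event rates)
  alive <- alive_ids(st)
  ae_cost_rate <- c(on_drug = 0, discontinued = 0)
  ae_ufac <- c(on_drug = 1, discontinued = 1)
  for (ae in params$adverse_events) {
    unit <- params$costs$ae_unit_cost[[ae$name]]$mean
    dec <- params$utilities$ae_decrement[[ae$name]]$mean
    r_on <- ae$rate_per_cycle[[if (arm == "soc") "soc" else arm]]
    r_off <- ae$rate_per_cycle[["soc"]]
    ae_cost_rate <- ae_cost_rate + c(r_on, r_off) * unit
    ae_ufac <- ae_ufac * (1 - c(r_on, r_off) * dec)
  }
  alive_on <- rowSums(occ_on[, alive, drop = FALSE])
  alive_off <- rowSums(occ_off[, alive, drop = FALSE])
  cost_ae <- sum(df * alive_on) * ae_cost_rate[["on_drug"]] +
    sum(df * alive_off) * ae_cost_rate[["discontinued"]]

  u <- stats::setNames(numeric(length(sid)), sid)
  for (s in alive) u[s] <- params$utilities$state_utility[[s]]$mean
  util_cycle <- (occ_on %*% u) * ae_ufac[["on_drug"]] +
    (occ_off %*% u) * ae_ufac[["discontinued"]]
  qaly <- sum(df * util_cycle) * cm / 12
  ly <- sum(alive_on + alive_off) * cm / 12

  ckd13b <- intersect(c("ckd1", "ckd2", "ckd3a", "ckd3b"), sid)
  res <- list(
    arm = arm,
    cost_by_category = list(
      drug = unname(cost_drug),
      state_mgmt = as.list(cost_stage),
      dialysis = unname(cost_dial),
      transplant = unname(cost_tx),
      adverse_events = unname(cost_ae)
    ),
    qaly_total = qaly,
    ly_total = ly,
    time_in_subset = list(
      ckd1_3b = if (length(ckd13b) > 0) state_time(trace, ckd13b) else NA_real_,
      dialysis = if (length(dial_id) > 0) state_time(trace, dial_id) else NA_real_
    ),
    residual_alive = sum(trace[H + 1, alive, ])
  )
  res$cost_total <- cost_drug + sum(cost_stage) + cost_dial + cost_tx + cost_ae
  structure(res, class = "ckd_arm_result")
}

#' @export
print.ckd_arm_result <- function(x, ...) {
  cat("<ckd_arm_result>", x$arm, "\n")
  cat(sprintf("  total cost RM %.0f | QALY %.2f | LY %.2f\n",
              x$cost_total, x$qaly_total, x$ly_total))
  invisible(x)
}

#' Convert Ringgit to US dollars
#'
#' @param rm amount in RM.
#' @param fx exchange rate, RM per USD.
#' @param round round to the nearest unit (the reporting convention);
#'   set `FALSE` for the raw quotient.
#' @return Amount in USD.
#' @export
to_usd <- function(rm, fx = 4.14, round = TRUE) {
  if (fx <= 0) stop("to_usd: fx must be > 0")
  out <- rm / fx
  if (round) round(out) else out
}

#' Compare two arm results
#'
#' @param intervention,comparator `ckd_arm_result` objects from the same
#'   settings.
#' @param econ the economic settings (for WTP and FX).
#' @return A `ckd_ce_result` with incremental cost, QALYs and life years,
#'   ICER (`NA` with `icer_defined = FALSE` when the QALY increment is 0),
#'   net monetary benefit `wtp * d_qaly - d_cost`, cost per life year,
#'   dominance flag and unrounded USD views.
#' @export
compare <- function(intervention, comparator, econ) {
  d_cost <- intervention$cost_total - comparator$cost_total
  d_qaly <- intervention$qaly_total - comparator$qaly_total
  d_ly <- intervention$ly_total - comparator$ly_total
  icer_defined <- d_qaly != 0
  structure(list(
    d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly,
    icer = if (icer_defined) d_cost / d_qaly else NA_real_,
    icer_defined = icer_defined,
    nmb = econ$wtp_per_qaly * d_qaly - d_cost,
    cost_per_ly = if (d_ly != 0) d_cost / d_ly else NA_real_,
    dominant = d_cost < 0 && d_qaly > 0,
    wtp = econ$wtp_per_qaly,
    fx = econ$fx_rm_per_usd,
    usd = list(d_cost = d_cost / econ$fx_rm_per_usd,
               icer = if (icer_defined) d_cost / d_qaly / econ$fx_rm_per_usd
                      else NA_real_,
               nmb = (econ$wtp_per_qaly * d_qaly - d_cost) / econ$fx_rm_per_usd)
  ), class = "ckd_ce_result")
}

#' @export
print.ckd_ce_result <- function(x, ...) {
  cat("<ckd_ce_result>\n")
  cat(sprintf("  d_cost RM %.0f | d_QALY %.3f | d_LY %.3f\n",
              x$d_cost, x$d_qaly, x$d_ly))
  if (x$icer_defined)
    cat(sprintf("  ICER RM %.0f/QALY | NMB RM %.0f%s\n", x$icer, x$nmb,
                if (x$dominant) " | DOMINANT" else ""))
  else cat(sprintf("  ICER undefined (d_QALY = 0) | NMB RM %.0f\n", x$nmb))
  invisible(x)
}

#' Aggregate budget impact of a per-patient cost difference
#'
#' @param n_treated number of people treated.
#' @param d_cost_per_patient incremental cost per patient (negative =
#'   saving).
#' @return Aggregate saving in RM: `n_treated * (-d_cost_per_patient)`
#'   (negative when the intervention costs more).
#' @export
budget_impact <- function(n_treated, d_cost_per_patient) {
  if (n_treated < 0) stop("budget_impact: n_treated must be >= 0")
  n_treated * (-d_cost_per_patient)
}

#' Run both arms and compare
#'
#' Convenience wrapper: run the cohort for both arms, accumulate outcomes
#' and compare dapagliflozin + SoC against SoC.
#'
#' @param params a `ckd_parameters` object.
#' @param horizon optional horizon override in cycles.
#' @return A list with `arms` (named `ckd_arm_result`s) and `ce`
#'   (`ckd_ce_result`).
#' @export
#' @examples
#' p <- load_parameters(fixture_path())
#' run_model(p, horizon = 120)$ce
run_model <- function(params, horizon = params$econ$horizon_cycles) {
  arms <- lapply(stats::setNames(ARMS, ARMS), function(a)
    accumulate(run_cohort(a, params, horizon), params))
  list(arms = arms,
       ce = compare(arms$dapagliflozin, arms$soc, params$econ))
}

#' Write cost-effectiveness results as CSV
#'
#' One row per outcome (cost categories, life years, QALYs, NMB, ICER) with
#' RM and USD columns for each arm and the increment; USD rounded to the
#' nearest unit, RM kept at full precision.
#'
#' @param model output of [run_model()].
#' @param path output CSV path.
#' @return The results data.frame, invisibly.
#' @export
write_results <- function(model, path) {
  a <- model$arms$dapagliflozin; s <- model$arms$soc; ce <- model$ce
  fx <- ce$fx
  row <- function(outcome, x_int, x_soc, money = TRUE) {
    d <- x_int - x_soc
    data.frame(outcome = outcome,
               dapagliflozin = x_int, soc = x_soc, incremental = d,
               dapagliflozin_usd = if (money) to_usd(x_int, fx) else NA,
               soc_usd = if (money) to_usd(x_soc, fx) else NA,
               incremental_usd = if (money) to_usd(d, fx) else NA)
  }
  stages <- names(a$cost_by_category$state_mgmt)
  out <- rbind(
    row("total_cost_rm", a$cost_total, s$cost_total),
    row("drug_acquisition_rm", a$cost_by_category$drug, s$cost_by_category$drug),
    do.call(rbind, lapply(stages, function(st)
      row(paste0("mgmt_", st, "_rm"),
          a$cost_by_category$state_mgmt[[st]], s$cost_by_category$state_mgmt[[st]]))),
    row("dialysis_rm", a$cost_by_category$dialysis, s$cost_by_category$dialysis),
    row("transplant_rm", a$cost_by_category$transplant, s$cost_by_category$transplant),
    row("adverse_events_rm", a$cost_by_category$adverse_events,
        s$cost_by_category$adverse_events),
    row("life_years", a$ly_total, s$ly_total, money = FALSE),
    row("qalys", a$qaly_total, s$qaly_total, money = FALSE)
  )
  out <- rbind(out,
    data.frame(outcome = c("nmb_rm", "icer_rm_per_qaly"),
               dapagliflozin = NA, soc = NA,
               incremental = c(ce$nmb, ce$icer),
               dapagliflozin_usd = NA, soc_usd = NA,
               incremental_usd = c(to_usd(ce$nmb, fx),
                                   if (ce$icer_defined) to_usd(ce$icer, fx) else NA)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
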