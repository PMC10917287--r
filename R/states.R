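#' Default CKD health-state table
#'
#' The model's ten ordered health states: CKD stages 1--5 (eGFR bands),
#' dialysis, the transient transplant-surgery state, transplant maintenance,
#' and absorbing death.  Drug acquisition cost stops once renal replacement
#' therapy begins, reflecting the practice of withdrawing the drug at
#' dialysis.
#'
#' @return A data.frame with one row per state and columns `id`, `label`,
#'   `egfr_band`, `category`, `absorbing`, `drug_cost_applies`.
#' @export
#' @examples
#' default_states()
default_states <- function() {
  data.frame(
    id = c("ckd1", "ckd2", "ckd3a", "ckd3b", "ckd4", "ckd5",
           "dialysis", "tx_init", "tx_maint", "dead"),
    label = c("CKD stage 1", "CKD stage 2", "CKD stage 3a", "CKD stage 3b",
              "CKD stage 4", "CKD stage 5 (pre-RRT)", "Dialysis",
              "Transplant (initial cycle)", "Transplant (maintenance)",
              "Dead"),
    egfr_band = c(">90 ml/min per 1.73 m^2", "60-89 ml/min per 1.73 m^2",
                  "45-59 ml/min per 1.73 m^2", "30-44 ml/min per 1.73 m^2",
                  "15-29 ml/min per 1.73 m^2", "<15 ml/min per 1.73 m^2",
                  NA, NA, NA, NA),
    category = c("ckd_stage_1", "ckd_stage_2", "ckd_stage_3a", "ckd_stage_3b",
                 "ckd_stage_4", "ckd_stage_5", "dialysis",
                 "transplant_initial", "transplant_maintenance", "dead"),
    absorbing = c(rep(FALSE, 9), TRUE),
    drug_cost_applies = c(rep(TRUE, 6), FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
ckd_stage_ids <- function(states) {
  states$id[grepl("^ckd_stage", states$category)]
}

#' @keywords internal
alive_ids <- function(states) states$id[states$category != "dead"]

#' @keywords internal
dead_id <- function(states) states$id[states$category == "dead"]

# validate the state table itself; stops with the offending field path
validate_states <- function(states) {
  required <- c("id", "label", "category", "absorbing", "drug_cost_applies")
  miss <- setdiff(required, names(states))
  if (length(miss) > 0)
    stop("states: missing column(s) ", paste(miss, collapse = ", "))
  if (anyDuplicated(states$id))
    stop("states$id: duplicated state id")
  dead <- states$category == "dead"
  if (sum(dead) != 1L || !states$absorbing[dead])
    stop("states: exactly one state must have category 'dead' and absorbing = TRUE")
  no_drug <- c("dialysis", "transplant_initial", "transplant_maintenance", "dead")
  bad <- states$id[states$category %in% no_drug & states$drug_cost_applies]
  if (length(bad) > 0)
    stop("states$drug_cost_applies must be FALSE for ", paste(bad, collapse = ", "),
         " (treatment stops at renal replacement therapy)")
  invisible(states)
}
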