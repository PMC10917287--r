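#' @title Model parameter container
#' @description
#' A `ckd_parameters` object bundles everything the cohort engine needs:
#' the state table, per-arm two-phase monthly transition matrices with
#' standard errors, cost and utility inputs, adverse-event specifications,
#' economic settings and the baseline state distribution.  Costs are in
#' 2022 Malaysian Ringgit (RM) per year unless stated otherwise; the engine
#' converts annual amounts to per-cycle amounts internally.
#'
#' @name ckd_parameters
NULL

ARMS <- c("dapagliflozin", "soc")
STATUSES <- c("on_drug", "discontinued")
AE_NAMES <- c("volume_depletion", "severe_hypoglycaemia", "fracture",
              "diabetic_ketoacidosis", "amputation")

#' Convert an annual amount to a per-cycle amount
#'
#' @param annual non-negative annual amount (e.g. RM/year).
#' @param cycle_months cycle length in months.
#' @return `annual * cycle_months / 12`.
#' @export
#' @examples
#' annual_to_cycle_cost(463.55, 1)  # monthly drug cost
annual_to_cycle_cost <- function(annual, cycle_months = 1) {
  if (any(annual < 0)) stop("annual_to_cycle_cost: annual amount must be >= 0")
  annual * cycle_months / 12
}

#' Validate and renormalise a row-stochastic matrix
#'
#' Rows whose sums deviate from 1 by at most `tolerance` are renormalised
#' exactly; larger deviations or negative entries are errors naming the row.
#'
#' @param m square numeric matrix of probabilities.
#' @param tolerance maximum tolerated absolute row-sum deviation from 1.
#' @param label name used in error messages.
#' @return The renormalised matrix (rows sum to 1 exactly, within machine
#'   precision).
#' @export
validate_matrix <- function(m, tolerance = 1e-6, label = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(label, ": must be a square matrix")
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(label, ": negative entry at row ", neg[1, 1], ", col ", neg[1, 2])
  if (any(m > 1 + tolerance))
    stop(label, ": entry greater than 1")
  rs <- rowSums(m)
  off <- which(abs(rs - 1) > tolerance)
  if (length(off) > 0)
    stop(label, ": row ", off[1],
         if (!is.null(rownames(m))) paste0(" (", rownames(m)[off[1]], ")") else "",
         " sums to ", format(rs[off[1]]), ", outside tolerance ", tolerance)
  m / rs
}

#' Construct a validated parameter set
#'
#' Low-level constructor; most users will call [load_parameters()] or
#' [gen_parameter_set()] instead.  All invariants are checked and violations
#' reported with the offending field path.
#'
#' @param states state table as from [default_states()].
#' @param matrices named list (`dapagliflozin`, `soc`), each a list with
#'   `phase1`, `phase2` (monthly transition matrices; phase 1 covers cycles
#'   1--4, phase 2 cycles 5 onward) and `phase1_se`, `phase2_se`.
#' @param costs,utilities,adverse_events,econ,init_dist see
#'   [ckd_parameters].
#' @return An object of class `ckd_parameters`.
#' @export
parameter_set <- function(states, matrices, costs, utilities, adverse_events,
                          econ, init_dist) {
  p <- structure(
    list(states = states, matrices = matrices, costs = costs,
         utilities = utilities, adverse_events = adverse_events,
         econ = econ, init_dist = init_dist),
    class = "ckd_parameters")
  validate_parameter_set(p)
}

#' Validate a parameter set
#'
#' @param p a `ckd_parameters` object (or bare list with the same fields).
#' @param tolerance row-sum tolerance passed to [validate_matrix()].
#' @return The validated object (matrices renormalised), invisibly classed
#'   `ckd_parameters`.
#' @export
validate_parameter_set <- function(p, tolerance = 1e-6) {
  validate_states(p$states)
  sid <- p$states$id
  S <- length(sid)
  dd <- dead_id(p$states)

  miss_arm <- setdiff(ARMS, names(p$matrices))
  if (length(miss_arm) > 0)
    stop("matrices: missing arm(s) ", paste(miss_arm, collapse = ", "))
  for (arm in ARMS) {
    for (ph in c("phase1", "phase2")) {
      m <- p$matrices[[arm]][[ph]]
      if (is.null(m)) stop("matrices$", arm, "$", ph, ": missing")
      if (!identical(dim(m), c(S, S)))
        stop("matrices$", arm, "$", ph, ": dimensions do not match state list")
      if (is.null(rownames(m))) dimnames(m) <- list(sid, sid)
      m <- m[sid, sid]
      m <- validate_matrix(m, tolerance, paste0("matrices$", arm, "$", ph))
      if (!isTRUE(all.equal(m[dd, ], as.numeric(sid == dd),
                            check.attributes = FALSE, tolerance = 1e-12)))
        stop("matrices$", arm, "$", ph, ": dead row must be the identity row")
      # transplant-surgery state is transient: it may only empty into
      # maintenance or death
      ti <- p$states$id[p$states$category == "transplant_initial"]
      tm <- p$states$id[p$states$category == "transplant_maintenance"]
      if (length(ti) == 1) {
        ok_targets <- c(tm, dd)
        leak <- setdiff(sid[m[ti, ] > 0], ok_targets)
        if (length(leak) > 0)
          stop("matrices$", arm, "$", ph, ": transient state ", ti,
               " transitions to ", paste(leak, collapse = ", "))
      }
      p$matrices[[arm]][[ph]] <- m
      se <- p$matrices[[arm]][[paste0(ph, "_se")]]
      if (is.null(se)) {
        se <- matrix(0, S, S, dimnames = list(sid, sid))
      } else {
        if (!identical(dim(se), c(S, S)))
          stop("matrices$", arm, "$", ph, "_se: dimensions do not match state list")
        if (is.null(rownames(se))) dimnames(se) <- list(sid, sid)
        se <- se[sid, sid]
        if (any(se < 0)) stop("matrices$", arm, "$", ph, "_se: negative SE")
      }
      p$matrices[[arm]][[paste0(ph, "_se")]] <- se
    }
  }

  # costs: every mean/se pair non-negative
  check_ms <- function(x, path) {
    if (is.null(x$mean) || is.null(x$se))
      stop(path, ": needs fields mean and se")
    if (x$mean < 0 || x$se < 0) stop(path, ": mean and se must be >= 0")
  }
  for (arm in ARMS)
    check_ms(p$costs$drug_annual[[arm]], paste0("costs$drug_annual$", arm))
  for (s in ckd_stage_ids(p$states))
    check_ms(p$costs$state_mgmt_annual[[s]], paste0("costs$state_mgmt_annual$", s))
  check_ms(p$costs$dialysis_annual, "costs$dialysis_annual")
  check_ms(p$costs$transplant_initial_once, "costs$transplant_initial_once")
  check_ms(p$costs$transplant_maint_annual, "costs$transplant_maint_annual")
  for (ae in AE_NAMES)
    check_ms(p$costs$ae_unit_cost[[ae]], paste0("costs$ae_unit_cost$", ae))

  # utilities in [0, 1]; decrements in [0, 1)
  for (s in alive_ids(p$states)) {
    u <- p$utilities$state_utility[[s]]
    if (is.null(u)) stop("utilities$state_utility$", s, ": missing")
    if (u$mean < 0 || u$mean > 1)
      stop("utilities$state_utility$", s, ": mean outside [0, 1]")
    if (u$se < 0) stop("utilities$state_utility$", s, ": negative se")
  }
  for (ae in AE_NAMES) {
    d <- p$utilities$ae_decrement[[ae]]
    if (is.null(d)) stop("utilities$ae_decrement$", ae, ": missing")
    if (d$mean < 0 || d$mean >= 1)
      stop("utilities$ae_decrement$", ae, ": mean outside [0, 1)")
  }

  # adverse events: one-cycle transient events with non-negative rates
  for (ae in p$adverse_events) {
    if (!ae$name %in% AE_NAMES)
      stop("adverse_events: unknown event '", ae$name, "'")
    if (any(unlist(ae$rate_per_cycle[ARMS]) < 0))
      stop("adverse_events$", ae$name, ": rate_per_cycle must be >= 0")
    if (!identical(as.integer(ae$duration_cycles), 1L))
      stop("adverse_events$", ae$name, ": duration_cycles must be 1 (transient event)")
  }

  e <- p$econ
  if (e$annual_discount < 0 || e$annual_discount >= 1)
    stop("econ$annual_discount: must be in [0, 1)")
  if (e$wtp_per_qaly <= 0) stop("econ$wtp_per_qaly: must be > 0")
  if (e$fx_rm_per_usd <= 0) stop("econ$fx_rm_per_usd: must be > 0")
  if (e$horizon_cycles < 1) stop("econ$horizon_cycles: must be >= 1")
  if (e$discontinuation_rate_per_cycle < 0 || e$discontinuation_rate_per_cycle >= 1)
    stop("econ$discontinuation_rate_per_cycle: must be in [0, 1)")

  v <- p$init_dist
  if (is.null(names(v)) || !setequal(names(v), sid))
    stop("init_dist: must be named by the state ids")
  v <- v[sid]
  if (any(v < 0)) stop("init_dist: negative entry")
  if (abs(sum(v) - 1) > 1e-8) stop("init_dist: does not sum to 1")
  if (v[dd] != 0) stop("init_dist: mass on the dead state")
  p$init_dist <- v / sum(v)

  p
}

#' @export
print.ckd_parameters <- function(x, ...) {
  cat("<ckd_parameters>\n")
  cat("  states:", nrow(x$states), paste0("(", paste(x$states$id, collapse = ", "), ")"), "\n")
  cat("  arms  :", paste(names(x$matrices), collapse = ", "), "\n")
  cat("  horizon:", x$econ$horizon_cycles, "monthly cycles;",
      "discount", x$econ$annual_discount * 100, "%/yr;",
      "WTP RM", format(x$econ$wtp_per_qaly, big.mark = ","), "/QALY\n")
  cat("  discontinuation:", x$econ$discontinuation_rate_per_cycle, "per cycle\n")
  invisible(x)
}

# ---- serialisation -------------------------------------------------------

matrix_file <- function(arm, ph, se = FALSE)
  paste0("matrix_", arm, "_", ph, if (se) "_se", ".csv")

write_matrix_csv <- function(m, path) {
  df <- data.frame(state = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$state
  storage.mode(m) <- "double"
  m
}

#' Write a parameter set to a configuration directory
#'
#' Writes `config.json` plus one CSV per transition matrix (mean and SE,
#' named `matrix_<arm>_<phase>[_se].csv`, with state ids as header row and
#' first column).  [load_parameters()] reads the same layout back.
#'
#' @param p a `ckd_parameters` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_parameters <- function(p, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (arm in ARMS) for (ph in c("phase1", "phase2")) {
    write_matrix_csv(p$matrices[[arm]][[ph]], file.path(dir, matrix_file(arm, ph)))
    write_matrix_csv(p$matrices[[arm]][[paste0(ph, "_se")]],
                     file.path(dir, matrix_file(arm, ph, se = TRUE)))
  }
  cfg <- list(
    states = p$states,
    costs = p$costs,
    utilities = p$utilities,
    adverse_events = lapply(p$adverse_events, function(a)
      list(name = a$name, rate_per_cycle = as.list(a$rate_per_cycle),
           duration_cycles = a$duration_cycles)),
    econ = p$econ,
    init_dist = as.list(p$init_dist)
  )
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load and validate a parameter set from a configuration directory
#'
#' @param path a directory containing `config.json` and the matrix CSVs, or
#'   the path of the `config.json` itself.
#' @param tolerance row-sum tolerance for matrix validation.
#' @return A validated `ckd_parameters` object.
#' @export
#' @examples
#' p <- load_parameters(system.file("extdata", "dapa_ckd_fixture",
#'                                  package = "ckdcea"))
#' p
load_parameters <- function(path, tolerance = 1e-6) {
  if (dir.exists(path)) {
    dir <- path
  } else {
    dir <- dirname(path)
  }
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path)) stop("load_parameters: no config.json at ", dir)
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = FALSE)
  states <- do.call(rbind, lapply(cfg$states, function(r)
    data.frame(id = r$id, label = r$label,
               egfr_band = if (is.null(r$egfr_band)) NA_character_
                           else r$egfr_band,
               category = r$category,
               absorbing = isTRUE(r$absorbing),
               drug_cost_applies = isTRUE(r$drug_cost_applies),
               stringsAsFactors = FALSE)))

  # scalar lists come back as lists of lists; coerce mean/se leaves to numeric
  fix_ms <- function(x) lapply(x, function(v) {
    if (is.list(v) && all(c("mean", "se") %in% names(v)))
      list(mean = as.numeric(v$mean), se = as.numeric(v$se))
    else if (is.list(v)) fix_ms(v) else v
  })
  costs <- fix_ms(cfg$costs)
  utilities <- fix_ms(cfg$utilities)

  aes <- lapply(cfg$adverse_events, function(a)
    list(name = a$name,
         rate_per_cycle = vapply(a$rate_per_cycle[ARMS], as.numeric, 0),
         duration_cycles = as.integer(a$duration_cycles)))

  matrices <- list()
  for (arm in ARMS) {
    matrices[[arm]] <- list()
    for (ph in c("phase1", "phase2"))
      matrices[[arm]][[ph]] <- read_matrix_csv(file.path(dir, matrix_file(arm, ph)))
    for (ph in c("phase1", "phase2")) {
      sef <- file.path(dir, matrix_file(arm, ph, se = TRUE))
      if (file.exists(sef))
        matrices[[arm]][[paste0(ph, "_se")]] <- read_matrix_csv(sef)
    }
  }

  p <- structure(list(
    states = states,
    matrices = matrices,
    costs = costs,
    utilities = utilities,
    adverse_events = aes,
    econ = lapply(cfg$econ, as.numeric),
    init_dist = unlist(cfg$init_dist)
  ), class = "ckd_parameters")
  validate_parameter_set(p, tolerance)
}

#' Path to the packaged parameter fixture
#'
#' The packaged fixture transcribes the published cost and utility tables
#' exactly; its transition matrices and baseline distribution are a
#' documented SYNTHETIC stand-in calibrated so the standard-of-care arm has
#' a life expectancy of about 9.5 years with about 6 years spent in CKD
#' stages 1--3b.  It is not the trial's supplementary data.
#'
#' @return Directory path of the fixture.
#' @export
fixture_path <- function() {
  system.file("extdata", "dapa_ckd_fixture", package = "ckdcea", mustWork = TRUE)
}
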