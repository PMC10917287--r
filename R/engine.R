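#' Transition matrix in force for a given arm, cycle and treatment status
#'
#' Phase 1 matrices apply during cycles 1--4 (the initial eGFR-dip period),
#' phase 2 from cycle 5 onward.  Patients who have discontinued treatment
#' (and the whole comparator arm) move under the standard-of-care matrix of
#' the matching phase.
#'
#' @param arm `"dapagliflozin"` or `"soc"`.
#' @param cycle cycle number, >= 1.
#' @param status `"on_drug"` or `"discontinued"`.
#' @param params a `ckd_parameters` object.
#' @return The monthly transition matrix to apply during `cycle`.
#' @export
effective_matrix <- function(arm, cycle, status, params) {
  arm <- match.arg(arm, ARMS)
  status <- match.arg(status, STATUSES)
  if (cycle < 1) stop("effective_matrix: cycle must be >= 1")
  ph <- if (cycle <= 4) "phase1" else "phase2"
  use_arm <- if (arm == "soc" || status == "discontinued") "soc" else arm
  params$matrices[[use_arm]][[ph]]
}

new_trace <- function(occ, arm, cycle_months) {
  structure(occ, class = "ckd_trace", arm = arm, cycle_months = cycle_months)
}

#' Run the Markov cohort simulation for one arm
#'
#' The cohort starts in the baseline distribution (in the `on_drug` stratum
#' for the intervention arm; entirely `discontinued` -- i.e. on comparator
#' dynamics and costs -- for the SoC arm).  Each cycle applies, in order:
#' (1) the constant per-cycle discontinuation probability, moving on-drug
#' mass in non-dead states to the discontinued stratum, then (2) the
#' stratum's effective transition matrix.  No half-cycle correction is
#' applied; rewards downstream accrue to the state occupied at cycle start.
#'
#' @param arm `"dapagliflozin"` or `"soc"`.
#' @param params a `ckd_parameters` object.
#' @param horizon number of monthly cycles (default `econ$horizon_cycles`).
#' @return A `ckd_trace`: an array `(horizon + 1) x states x status` of
#'   occupancy fractions, rows labelled by cycle 0..horizon.
#' @export
#' @examples
#' p <- load_parameters(fixture_path())
#' tr <- run_cohort("soc", p, horizon = 120)
#' state_time(tr, c("ckd2", "ckd3a"))
run_cohort <- function(arm, params, horizon = params$econ$horizon_cycles) {
  arm <- match.arg(arm, ARMS)
  if (horizon < 1) stop("run_cohort: horizon must be >= 1")
  sid <- params$states$id
  S <- length(sid)
  dd <- dead_id(params$states)
  disc <- params$econ$discontinuation_rate_per_cycle

  occ <- array(0, dim = c(horizon + 1, S, 2),
               dimnames = list(0:horizon, sid, STATUSES))
  if (arm == "soc") {
    occ[1, , "discontinued"] <- params$init_dist
  } else {
    occ[1, , "on_drug"] <- params$init_dist
  }

  for (t in seq_len(horizon)) {
    on <- occ[t, , "on_drug"]
    off <- occ[t, , "discontinued"]
    if (disc > 0 && any(on > 0)) {
      mv <- on * disc
      mv[dd] <- 0            # the dead cannot discontinue
      on <- on - mv
      off <- off + mv
    }
    occ[t + 1, , "on_drug"] <-
      as.numeric(on %*% effective_matrix(arm, t, "on_drug", params))
    occ[t + 1, , "discontinued"] <-
      as.numeric(off %*% effective_matrix(arm, t, "discontinued", params))
  }
  new_trace(occ, arm, params$econ$cycle_length_months)
}

#' @export
print.ckd_trace <- function(x, ...) {
  H <- dim(x)[1] - 1
  cat("<ckd_trace> arm =", attr(x, "arm"), ", cycles 0..", H, "\n")
  dd <- grep("dead", colnames(x))
  cat("  dead at horizon:", round(sum(x[H + 1, dd, ]), 4), "\n")
  invisible(x)
}

#' Per-individual microsimulation oracle
#'
#' Simulates `n` independent individual trajectories under exactly the same
#' effective matrices and discontinuation rule as [run_cohort()], by
#' categorical sampling.  Used to validate the cohort engine: since
#' individuals are i.i.d., the empirical occupancy of each state at each
#' cycle is Binomial(n, p) around the cohort trace value p.
#'
#' @inheritParams run_cohort
#' @param n number of simulated individuals.
#' @param seed RNG seed.
#' @param keep_paths if `TRUE`, attach the integer state-index path matrix
#'   (`n x (horizon+1)`) as attribute `"paths"` (used by [recover_matrix()]).
#' @return A `ckd_trace` of empirical occupancy fractions.
#' @export
microsim_oracle <- function(arm, params, n, seed = 1L,
                            horizon = params$econ$horizon_cycles,
                            keep_paths = FALSE) {
  arm <- match.arg(arm, ARMS)
  if (n < 1) stop("microsim_oracle: n must be >= 1")
  set.seed(seed)
  sid <- params$states$id
  S <- length(sid)
  dd_i <- match(dead_id(params$states), sid)
  disc <- params$econ$discontinuation_rate_per_cycle

  state <- sample.int(S, n, replace = TRUE, prob = params$init_dist)
  on_drug <- rep(arm != "soc", n)

  occ <- array(0, dim = c(horizon + 1, S, 2),
               dimnames = list(0:horizon, sid, STATUSES))
  tally <- function(t) {
    for (k in 1:2) {
      sel <- if (k == 1) on_drug else !on_drug
      if (any(sel)) occ[t, , k] <<- tabulate(state[sel], nbins = S) / n
    }
  }
  tally(1)
  paths <- if (keep_paths) matrix(NA_integer_, n, horizon + 1) else NULL
  if (keep_paths) paths[, 1] <- state

  for (t in seq_len(horizon)) {
    if (disc > 0) {
      cand <- which(on_drug & state != dd_i)
      if (length(cand) > 0)
        on_drug[cand[stats::runif(length(cand)) < disc]] <- FALSE
    }
    new_state <- state
    for (k in 1:2) {
      status <- STATUSES[k]
      M <- effective_matrix(arm, t, status, params)
      sel <- if (k == 1) on_drug else !on_drug
      for (s in unique(state[sel])) {
        idx <- which(sel & state == s)
        if (s == dd_i) next                       # absorbing
        new_state[idx] <- sample.int(S, length(idx), replace = TRUE,
                                     prob = M[s, ])
      }
    }
    state <- new_state
    tally(t + 1)
    if (keep_paths) paths[, t + 1] <- state
  }
  tr <- new_trace(occ, arm, params$econ$cycle_length_months)
  if (keep_paths) attr(tr, "paths") <- paths
  tr
}

#' Undiscounted expected time spent in a subset of states
#'
#' Sums occupancy over cycles 0..H-1 (state at cycle start accrues that
#' cycle) and converts to years.
#'
#' @param trace a `ckd_trace`.
#' @param states character vector of state ids.
#' @return Expected years in the subset.
#' @export
state_time <- function(trace, states) {
  if (length(states) == 0) stop("state_time: empty state subset")
  unknown <- setdiff(states, colnames(trace))
  if (length(unknown) > 0)
    stop("state_time: unknown state id(s) ", paste(unknown, collapse = ", "))
  H <- dim(trace)[1] - 1
  cm <- attr(trace, "cycle_months")
  sum(trace[seq_len(H), states, , drop = FALSE]) * cm / 12
}

#' Write / read a cohort trace as long-format CSV
#'
#' Columns `cycle`, `state`, `status`, `occupancy`; values are written in
#' full precision (`format(..., digits = 17)`) so the file re-reads
#' bit-exactly.
#'
#' @param trace a `ckd_trace`.
#' @param path output CSV path.
#' @return `path` invisibly ([write_trace()]); a `ckd_trace`
#'   ([read_trace()]).
#' @export
write_trace <- function(trace, path) {
  H <- dim(trace)[1] - 1
  sid <- colnames(trace)
  df <- expand.grid(cycle = 0:H, state = sid, status = STATUSES,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$occupancy <- as.vector(trace)
  df$occupancy <- vapply(df$occupancy, function(x) format(x, digits = 17), "")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param arm,cycle_months metadata to attach on read.
#' @export
read_trace <- function(path, arm = NA_character_, cycle_months = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cycles <- sort(unique(df$cycle))
  sid <- unique(df$state)
  occ <- array(0, dim = c(length(cycles), length(sid), 2),
               dimnames = list(cycles, sid, STATUSES))
  occ[cbind(match(df$cycle, cycles), match(df$state, sid),
            match(df$status, STATUSES))] <- df$occupancy
  new_trace(occ, arm, cycle_months)
}
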