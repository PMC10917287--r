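#' Method-of-moments beta fit
#'
#' Solves `alpha = m*k`, `beta = (1-m)*k` with `k = m(1-m)/se^2 - 1`, the
#' standard moment match used for probabilities and utilities in
#' probabilistic sensitivity analysis.
#'
#' @param mean mean in (0, 1).
#' @param se standard error with `se^2 < mean * (1 - mean)`.
#' @return Named vector `c(alpha, beta)`.
#' @export
#' @examples
#' fit_beta(0.5, 0.1)   # alpha = beta = 12
fit_beta <- function(mean, se) {
  if (mean <= 0 || mean >= 1) stop("fit_beta: mean must be in (0, 1)")
  if (se <= 0) stop("fit_beta: se must be > 0")
  v <- se^2
  if (v >= mean * (1 - mean))
    stop("fit_beta: infeasible moments, se^2 >= mean*(1-mean)")
  k <- mean * (1 - mean) / v - 1
  c(alpha = mean * k, beta = (1 - mean) * k)
}

#' Method-of-moments gamma fit
#'
#' `shape = mean^2/se^2`, `scale = se^2/mean`; the standard moment match
#' for cost parameters.
#'
#' @param mean positive mean.
#' @param se positive standard error.
#' @return Named vector `c(shape, scale)`.
#' @export
#' @examples
#' fit_gamma(100, 20)   # shape 25, scale 4
fit_gamma <- function(mean, se) {
  if (mean <= 0 || se <= 0) stop("fit_gamma: mean and se must be > 0")
  c(shape = mean^2 / se^2, scale = se^2 / mean)
}

# draw one probability-like value; passthrough when degenerate
draw_beta <- function(mean, se, path) {
  if (se == 0 || mean <= 0 || mean >= 1) return(mean)
  ab <- tryCatch(fit_beta(mean, se),
                 error = function(e) stop("sample_parameter_set: ", path, ": ",
                                          conditionMessage(e)))
  stats::rbeta(1, ab["alpha"], ab["beta"])
}

draw_gamma <- function(mean, se, path) {
  if (se == 0 || mean == 0) return(mean)
  gs <- tryCatch(fit_gamma(mean, se),
                 error = function(e) stop("sample_parameter_set: ", path, ": ",
                                          conditionMessage(e)))
  stats::rgamma(1, shape = gs["shape"], scale = gs["scale"])
}

#' Draw one probabilistic parameter set
#'
#' Transition probabilities, state utilities and adverse-event decrements
#' are drawn cell-wise from beta distributions matched to their mean and SE
#' (cells with SE 0 or boundary means pass through unchanged), then each
#' matrix row is renormalised to sum 1.  Costs are drawn from gamma
#' distributions.  With all SEs zero the base object is returned unchanged.
#'
#' @param base a `ckd_parameters` object.
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @return A `ckd_parameters` object with sampled values.
#' @export
sample_parameter_set <- function(base, seed = 1L) {
  set.seed(seed)
  p <- base
  sid <- p$states$id
  dd <- dead_id(p$states)
  changed <- FALSE

  for (arm in ARMS) for (ph in c("phase1", "phase2")) {
    m <- p$matrices[[arm]][[ph]]
    se <- p$matrices[[arm]][[paste0(ph, "_se")]]
    if (all(se == 0)) next
    changed <- TRUE
    for (i in seq_along(sid)) {
      if (sid[i] == dd) next
      row <- m[i, ]
      for (j in seq_along(sid)) {
        if (se[i, j] > 0 && row[j] > 0 && row[j] < 1)
          row[j] <- draw_beta(m[i, j], se[i, j],
                              sprintf("matrices$%s$%s[%d,%d]", arm, ph, i, j))
      }
      m[i, ] <- row / sum(row)
    }
    p$matrices[[arm]][[ph]] <- m
  }

  for (s in names(p$utilities$state_utility)) {
    u <- p$utilities$state_utility[[s]]
    if (u$se > 0) {
      p$utilities$state_utility[[s]]$mean <-
        draw_beta(u$mean, u$se, paste0("utilities$state_utility$", s))
      changed <- TRUE
    }
  }
  for (ae in names(p$utilities$ae_decrement)) {
    d <- p$utilities$ae_decrement[[ae]]
    if (d$se > 0) {
      p$utilities$ae_decrement[[ae]]$mean <-
        draw_beta(d$mean, d$se, paste0("utilities$ae_decrement$", ae))
      changed <- TRUE
    }
  }

  draw_cost <- function(x, path) {
    if (x$se > 0) {
      changed <<- TRUE
      x$mean <- draw_gamma(x$mean, x$se, path)
    }
    x
  }
  for (arm in ARMS)
    p$costs$drug_annual[[arm]] <-
      draw_cost(p$costs$drug_annual[[arm]], paste0("costs$drug_annual$", arm))
  for (s in names(p$costs$state_mgmt_annual))
    p$costs$state_mgmt_annual[[s]] <-
      draw_cost(p$costs$state_mgmt_annual[[s]], paste0("costs$state_mgmt_annual$", s))
  p$costs$dialysis_annual <- draw_cost(p$costs$dialysis_annual, "costs$dialysis_annual")
  p$costs$transplant_initial_once <-
    draw_cost(p$costs$transplant_initial_once, "costs$transplant_initial_once")
  p$costs$transplant_maint_annual <-
    draw_cost(p$costs$transplant_maint_annual, "costs$transplant_maint_annual")
  for (ae in names(p$costs$ae_unit_cost))
    p$costs$ae_unit_cost[[ae]] <-
      draw_cost(p$costs$ae_unit_cost[[ae]], paste0("costs$ae_unit_cost$", ae))

  if (!changed) return(base)
  p
}

#' Probabilistic sensitivity analysis
#'
#' For each iteration a parameter set is drawn with
#' [sample_parameter_set()] under its own sub-seed (derived once from the
#' master seed, so iteration k's draws do not depend on how many iterations
#' are run), both arms are simulated, and the incremental cost, QALYs and
#' net monetary benefit are recorded.  Iterations whose sampling or
#' simulation fails are counted, not silently dropped.
#'
#' @param base a `ckd_parameters` object (means and SEs define the
#'   distributions).
#' @param n_iter number of Monte Carlo iterations (the analysis default is
#'   1,000).
#' @param seed master seed.
#' @param horizon optional horizon override in cycles.
#' @return A `ckd_psa` object: data.frame `draws` (`iter`, `d_cost`,
#'   `d_qaly`, `nmb`), plus `n_iter`, `seed`, `wtp`, `n_failed`.
#' @export
run_psa <- function(base, n_iter = 1000L, seed = 1L,
                    horizon = base$econ$horizon_cycles) {
  if (n_iter < 1) stop("run_psa: n_iter must be >= 1")
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
  wtp <- base$econ$wtp_per_qaly
  out <- vector("list", n_iter)
  n_failed <- 0L
  for (i in seq_len(n_iter)) {
    res <- tryCatch({
      ps <- sample_parameter_set(base, iter_seeds[i])
      m <- run_model(ps, horizon)
      c(m$ce$d_cost, m$ce$d_qaly, m$ce$nmb)
    }, error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    out[[i]] <- data.frame(iter = i, d_cost = res[1], d_qaly = res[2],
                           nmb = res[3])
  }
  draws <- do.call(rbind, out)
  structure(list(draws = draws, n_iter = n_iter, seed = seed, wtp = wtp,
                 n_failed = n_failed),
            class = "ckd_psa")
}

#' @export
print.ckd_psa <- function(x, ...) {
  cat("<ckd_psa>", nrow(x$draws), "draws (", x$n_failed, "failed ) seed", x$seed, "\n")
  cat(sprintf("  mean d_cost RM %.0f | mean d_QALY %.3f | P(CE at RM %s/QALY) = %.3f\n",
              mean(x$draws$d_cost), mean(x$draws$d_qaly),
              format(x$wtp, big.mark = ","), fraction_below_wtp(x, x$wtp)))
  invisible(x)
}

#' Fraction of PSA draws cost-effective at a threshold
#'
#' Share of iterations with positive net monetary benefit at `wtp`
#' (dominant draws count; ties at exactly 0 do not).
#'
#' @param draws a `ckd_psa` object or a data.frame with `d_cost`, `d_qaly`.
#' @param wtp willingness-to-pay threshold (RM/QALY).
#' @return Fraction in `[0, 1]`.
#' @export
fraction_below_wtp <- function(draws, wtp) {
  d <- if (inherits(draws, "ckd_psa")) draws$draws else draws
  if (is.null(d) || nrow(d) == 0) stop("fraction_below_wtp: no draws")
  mean(wtp * d$d_qaly - d$d_cost > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' @param draws a `ckd_psa` object.
#' @param wtp_grid non-empty vector of thresholds.
#' @return data.frame with columns `wtp`, `probability`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (length(wtp_grid) == 0) stop("ceac: empty wtp grid")
  data.frame(wtp = wtp_grid,
             probability = vapply(wtp_grid,
                                  function(w) fraction_below_wtp(draws, w), 0))
}

# ---- parameter paths -----------------------------------------------------

# parse "matrices$soc$phase1[3,4]" into list parts + optional [i,j]
parse_path <- function(path) {
  idx <- NULL
  m <- regmatches(path, regexec("^(.*)\\[([0-9]+),([0-9]+)\\]$", path))[[1]]
  if (length(m) == 4) {
    path <- m[2]
    idx <- as.integer(m[3:4])
  }
  list(keys = strsplit(path, "$", fixed = TRUE)[[1]], idx = idx)
}

#' Get / set a parameter by path
#'
#' Paths use `$`-separated keys into the parameter list, with an optional
#' matrix index, e.g. `"costs$dialysis_annual$mean"`,
#' `"utilities$state_utility$dialysis$mean"`,
#' `"matrices$soc$phase1[3,4]"`, `"econ$discontinuation_rate_per_cycle"`.
#'
#' @param params a `ckd_parameters` object.
#' @param path parameter path string.
#' @param value replacement value ([param_set()]).
#' @return The value ([param_get()]) or the modified, re-validated
#'   parameter set ([param_set()]).  When a matrix cell is set, the value
#'   is clipped to `[0, 1]` and the row renormalised.
#' @export
param_get <- function(params, path) {
  pp <- parse_path(path)
  x <- params
  for (k in pp$keys) {
    if (is.null(x[[k]])) stop("param_get: cannot resolve '", path, "' at '", k, "'")
    x <- x[[k]]
  }
  if (!is.null(pp$idx)) x <- x[pp$idx[1], pp$idx[2]]
  x
}

#' @rdname param_get
#' @export
param_set <- function(params, path, value) {
  pp <- parse_path(path)
  if (is.null(pp$idx)) {
    expr <- paste0("params", paste0("[['", pp$keys, "']]", collapse = ""))
    if (is.null(eval(parse(text = expr))))
      stop("param_set: cannot resolve '", path, "'")
    eval(parse(text = paste0(expr, " <- value")))
  } else {
    expr <- paste0("params", paste0("[['", pp$keys, "']]", collapse = ""))
    m <- eval(parse(text = expr))
    if (!is.matrix(m)) stop("param_set: '", path, "' is not a matrix")
    i <- pp$idx[1]; j <- pp$idx[2]
    m[i, j] <- min(max(value, 0), 1)
    m[i, ] <- m[i, ] / sum(m[i, ])
    eval(parse(text = paste0(expr, " <- m")))
  }
  validate_parameter_set(params, tolerance = 1e-6)
}

#' Default one-way sensitivity-analysis specification
#'
#' One row per varied parameter with its low/high values: mean +/- SE where
#' an SE is available, otherwise +/-10% for probabilities and utilities and
#' +/-20% for costs.  Utilities are capped at 1 and probabilities kept in
#' `[0, 1]`.
#'
#' @param params a `ckd_parameters` object.
#' @return data.frame with columns `path`, `low`, `high`.
#' @export
dsa_default_spec <- function(params) {
  rows <- list()
  add <- function(path, mean, se, kind) {
    if (is.null(se) || se == 0) {
      f <- if (kind == "cost") 0.20 else 0.10
      lo <- mean * (1 - f); hi <- mean * (1 + f)
    } else {
      lo <- mean - se; hi <- mean + se
    }
    if (kind %in% c("prob", "util")) {
      lo <- max(lo, 0); hi <- min(hi, 1)
    } else lo <- max(lo, 0)
    rows[[length(rows) + 1]] <<- data.frame(path = path, low = lo, high = hi)
  }
  for (arm in ARMS) {
    x <- params$costs$drug_annual[[arm]]
    add(paste0("costs$drug_annual$", arm, "$mean"), x$mean, x$se, "cost")
  }
  for (s in names(params$costs$state_mgmt_annual)) {
    x <- params$costs$state_mgmt_annual[[s]]
    add(paste0("costs$state_mgmt_annual$", s, "$mean"), x$mean, x$se, "cost")
  }
  for (nm in c("dialysis_annual", "transplant_initial_once",
               "transplant_maint_annual")) {
    x <- params$costs[[nm]]
    add(paste0("costs$", nm, "$mean"), x$mean, x$se, "cost")
  }
  for (ae in names(params$costs$ae_unit_cost)) {
    x <- params$costs$ae_unit_cost[[ae]]
    add(paste0("costs$ae_unit_cost$", ae, "$mean"), x$mean, x$se, "cost")
  }
  for (s in names(params$utilities$state_utility)) {
    x <- params$utilities$state_utility[[s]]
    add(paste0("utilities$state_utility$", s, "$mean"), x$mean, x$se, "util")
  }
  for (ae in names(params$utilities$ae_decrement)) {
    x <- params$utilities$ae_decrement[[ae]]
    add(paste0("utilities$ae_decrement$", ae, "$mean"), x$mean, x$se, "util")
  }
  add("econ$discontinuation_rate_per_cycle",
      params$econ$discontinuation_rate_per_cycle, 0, "prob")
  do.call(rbind, rows)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the full deterministic model at each parameter's low and high
#' value and records net monetary benefit and ICER at both ends.  The
#' tornado is built on NMB, which stays well-behaved when the QALY
#' increment crosses zero; ICERs are reported alongside.  Output is sorted
#' by descending NMB width, ties broken by parameter path.
#'
#' @param base a `ckd_parameters` object.
#' @param spec data.frame with columns `path`, `low`, `high`; defaults to
#'   [dsa_default_spec()].
#' @param horizon optional horizon override in cycles.
#' @return A `ckd_dsa` data.frame with columns `path`, `low`, `high`,
#'   `nmb_low`, `nmb_high`, `icer_low`, `icer_high`, `width`, plus
#'   attribute `base_nmb`.
#' @export
run_dsa <- function(base, spec = dsa_default_spec(base),
                    horizon = base$econ$horizon_cycles) {
  base_ce <- run_model(base, horizon)$ce
  one <- function(path, value) {
    ce <- run_model(param_set(base, path, value), horizon)$ce
    c(nmb = ce$nmb, icer = if (ce$icer_defined) ce$icer else NA_real_)
  }
  res <- lapply(seq_len(nrow(spec)), function(i) {
    lo <- one(spec$path[i], spec$low[i])
    hi <- one(spec$path[i], spec$high[i])
    data.frame(path = spec$path[i], low = spec$low[i], high = spec$high[i],
               nmb_low = lo[["nmb"]], nmb_high = hi[["nmb"]],
               icer_low = lo[["icer"]], icer_high = hi[["icer"]],
               width = abs(hi[["nmb"]] - lo[["nmb"]]))
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$width, out$path), ]
  rownames(out) <- NULL
  structure(out, class = c("ckd_dsa", "data.frame"),
            base_nmb = base_ce$nmb, base_icer = base_ce$icer)
}
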