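# Sensitivity analyses: one-way deterministic (tornado) and
# probabilistic (cost-effectiveness plane, CEAC).

# fast path: cohort totals without validation or trace, for the many
# model evaluations inside OWSA/PSA loops
.cohort_totals <- function(params, arm, H) {
  st <- params$settings
  cycles <- H * st$cycles_per_year
  core <- .core_per_cycle(.matrix_core(params, arm), st$cycles_per_year)
  qs <- .cycle_qx(params, cycles)
  occ <- matrix(0, cycles + 1L, 9)
  occ[1, 1] <- 1
  rec_inflow <- numeric(cycles + 1L)
  for (t in seq_len(cycles)) {
    M <- .engine_matrix(core, qs[t])
    occ[t + 1L, ] <- occ[t, ] %*% M
    rec_inflow[t + 1L] <- occ[t, 3] * M[3, 7] + occ[t, 4] * M[4, 8]
  }
  acc <- .accrue(occ, rec_inflow, .econ_core(params, arm))
  list(cost_total = sum(acc$cost), qaly = acc$qaly)
}

.icer_value <- function(params, H) {
  ic <- compute_icer(.cohort_totals(params, "combination", H),
                     .cohort_totals(params, "monotherapy", H))
  ic$icer
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' For every ranged parameter, sets it to its low and then its high bound
#' with all other parameters at base, recomputes the ICER with the
#' deterministic cohort engine, and sorts the table by the absolute ICER
#' spread, largest first — the order of the bars of a tornado diagram.
#'
#' @param params A validated `bph_parameters` object.
#' @param ranges Data frame with columns `target`, `low`, `high`;
#'   defaults to the ranges shipped in `params$owsa_ranges`.
#' @param horizon_years Optional horizon override.
#' @return A `bph_tornado` data frame: `target`, `low`, `high`,
#'   `icer_low`, `icer_high`, `spread`, sorted by `spread` descending,
#'   with the base-case ICER as attribute `base_icer`.
#' @export
run_owsa <- function(params, ranges = NULL, horizon_years = NULL) {
  .stop_if_invalid(params)
  if (is.null(ranges)) ranges <- params$owsa_ranges
  H <- if (is.null(horizon_years)) params$settings$horizon_years
       else as.integer(horizon_years)

  base_icer <- .icer_value(params, H)
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    target <- ranges$target[i]
    base <- get_parameter(params, target)
    if (ranges$low[i] > base || ranges$high[i] < base)
      stop(sprintf("range for %s [%g, %g] does not bracket base value %g",
                   target, ranges$low[i], ranges$high[i], base),
           call. = FALSE)
    at <- function(v) {
      p2 <- set_parameter(params, target, v)
      rep <- validate_parameters(p2)
      if (nrow(rep) > 0)
        stop(sprintf("range bound %g for %s violates an invariant: %s",
                     v, target, rep$message[1]), call. = FALSE)
      .icer_value(p2, H)
    }
    lo <- at(ranges$low[i]); hi <- at(ranges$high[i])
    data.frame(target = target, low = ranges$low[i], high = ranges$high[i],
               icer_low = lo, icer_high = hi, spread = abs(hi - lo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  structure(out, base_icer = base_icer, horizon_years = H,
            class = c("bph_tornado", "data.frame"))
}

#' @export
print.bph_tornado <- function(x, ...) {
  cat(sprintf("one-way sensitivity analysis, %d-year horizon; base ICER %.0f\n",
              attr(x, "horizon_years"), attr(x, "base_icer")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

# effective gamma rate: rederived from the printed mean when available
.gamma_rate <- function(dist_row) {
  if (!is.na(dist_row$mean_override)) dist_row$shape_alpha / dist_row$mean_override
  else dist_row$shape_beta_or_rate
}

#' Sample parameter draws for probabilistic sensitivity analysis
#'
#' Draws `n` joint parameter sets from the model's distribution table:
#' beta for probabilities and efficacies, gamma for costs (rates
#' rederived from the published means; see
#' [default_psa_distributions()]).  Unsampled fields stay at their base
#' values.  Draws that would violate a structural invariant (possible in
#' `"residual"` row mode, where sampled exits can sum past one) are
#' resampled and counted.
#'
#' @param params A validated `bph_parameters` object.
#' @param n Number of draws (`n = 0` gives an empty table).
#' @param seed Integer seed.
#' @return Data frame of `n` rows, one column per sampled target, with
#'   attribute `resampled` (number of redrawn rows).  Use
#'   [apply_parameter_draw()] to materialize a draw as a full parameter
#'   set.
#' @export
sample_psa_parameters <- function(params, n, seed) {
  .stop_if_invalid(params)
  pd <- params$psa_distributions
  set.seed(as.integer(seed))
  draw_all <- function(m) {
    cols <- lapply(seq_len(nrow(pd)), function(i) {
      row <- pd[i, ]
      if (row$family == "beta")
        stats::rbeta(m, row$shape_alpha, row$shape_beta_or_rate)
      else
        stats::rgamma(m, shape = row$shape_alpha, rate = .gamma_rate(row))
    })
    names(cols) <- pd$target
    as.data.frame(cols)
  }
  draws <- draw_all(n)
  resampled <- 0L
  if (n > 0) {
    bad <- .invalid_draws(draws, params)
    it <- 0L
    while (any(bad) && it < 100L) {
      resampled <- resampled + sum(bad)
      draws[bad, ] <- draw_all(sum(bad))
      bad <- .invalid_draws(draws, params)
      it <- it + 1L
    }
    if (any(bad))
      stop("could not draw valid parameter sets after 100 resampling rounds",
           call. = FALSE)
  }
  structure(draws, resampled = resampled)
}

# rows whose sampled values break a row-feasibility invariant
.invalid_draws <- function(draws, params) {
  tr <- params$transitions
  g <- function(nm) if (nm %in% names(draws)) draws[[nm]] else
    get_parameter(params, nm)
  if (identical(params$options$row_mode, "residual")) {
    bad <- (g("p_bph_to_turp") + g("p_bph_to_aur") > 1) |
           (g("p_medical_to_second_turp") + tr$p_medical_to_aur > 1)
  } else {
    bad <- rep(FALSE, nrow(draws))
  }
  bad
}

#' Materialize one PSA draw as a full parameter set
#'
#' @param params Base `bph_parameters`.
#' @param draw One-row data frame (or named list/vector) of sampled
#'   values, as one row of [sample_psa_parameters()] output.
#' @return A `bph_parameters` object with the sampled fields replaced.
#' @export
apply_parameter_draw <- function(params, draw) {
  for (nm in names(draw)) params <- set_parameter(params, nm, draw[[nm]])
  params
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: for each of `n` joint parameter draws, both
#' arms are run with the deterministic cohort engine on the same drawn
#' parameters (so each draw yields one incremental cost and one
#' incremental QALY — pure parameter uncertainty), and the incremental
#' pair is classified on the cost-effectiveness plane.  A nested mode
#' running the microsimulation inside each draw is available via
#' `engine = "microsim"`.
#'
#' @param params A validated `bph_parameters` object.
#' @param n Number of parameter draws.
#' @param horizon_years Optional horizon override.
#' @param seed Integer seed (drives both the draws and, in nested mode,
#'   the inner runs).
#' @param engine Inner engine; `"cohort"` (default) or `"microsim"`.
#' @param n_patients Patients per inner run in nested mode.
#' @return A `bph_psa` data frame with one row per draw: arm-level
#'   discounted cost and QALYs, `delta_cost`, `delta_qaly`, `quadrant`;
#'   attributes `seed`, `horizon_years`, `resampled`, `wtp_grid`.
#' @export
run_psa <- function(params, n = 10000, horizon_years = NULL, seed,
                    engine = c("cohort", "microsim"), n_patients = 1000) {
  if (missing(seed) || is.null(seed))
    stop("probabilistic sensitivity analysis requires a seed", call. = FALSE)
  engine <- match.arg(engine)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  H <- if (is.null(horizon_years)) params$settings$horizon_years
       else as.integer(horizon_years)
  draws <- sample_psa_parameters(params, n, seed)

  cost_c <- numeric(n); qaly_c <- numeric(n)
  cost_m <- numeric(n); qaly_m <- numeric(n)
  targets <- names(draws)
  groups <- vapply(targets, function(nm) .find_group(params, nm), character(1))
  for (i in seq_len(n)) {
    p_i <- params
    for (k in seq_along(targets))
      p_i[[groups[k]]][[targets[k]]] <- draws[i, k]
    if (engine == "cohort") {
      rc <- .cohort_totals(p_i, "combination", H)
      rm_ <- .cohort_totals(p_i, "monotherapy", H)
    } else {
      rc <- run_microsimulation(p_i, "combination", n_patients,
                                seed = seed + 2L * i, horizon_years = H,
                                keep_log = FALSE)
      rm_ <- run_microsimulation(p_i, "monotherapy", n_patients,
                                 seed = seed + 2L * i + 1L, horizon_years = H,
                                 keep_log = FALSE)
    }
    cost_c[i] <- rc$cost_total; qaly_c[i] <- rc$qaly
    cost_m[i] <- rm_$cost_total; qaly_m[i] <- rm_$qaly
  }
  dc <- cost_c - cost_m; dq <- qaly_c - qaly_m
  out <- data.frame(
    draw = seq_len(n),
    cost_combination = cost_c, qaly_combination = qaly_c,
    cost_monotherapy = cost_m, qaly_monotherapy = qaly_m,
    delta_cost = dc, delta_qaly = dq,
    quadrant = classify_quadrant(dc, dq))
  structure(out, seed = as.integer(seed), horizon_years = H,
            resampled = attr(draws, "resampled"),
            wtp_grid = params$settings$wtp_grid,
            class = c("bph_psa", "data.frame"))
}

#' Quadrant shares of a PSA scatter
#'
#' @param scatter A `bph_psa` data frame.
#' @return Named numeric vector of the NE/SE/NW/SW fractions (sums to 1).
#' @export
quadrant_shares <- function(scatter) {
  tab <- table(scatter$quadrant)
  stats::setNames(as.vector(tab) / nrow(scatter), names(tab))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that combination
#' therapy is cost-effective: the fraction of draws with strictly
#' positive incremental net monetary benefit (a draw with incremental NMB
#' exactly zero counts as not cost-effective).  At `wtp = 0` this reduces
#' to the fraction of cost-saving draws.
#'
#' @param scatter A `bph_psa` data frame (non-empty).
#' @param wtp_grid Willingness-to-pay grid (USD/QALY); defaults to the
#'   grid carried by the scatter.
#' @return A `bph_ceac` data frame: `wtp`, `probability`.
#' @export
compute_ceac <- function(scatter, wtp_grid = NULL) {
  if (is.null(scatter) || nrow(scatter) == 0)
    stop("empty scatter: nothing to compute a CEAC from", call. = FALSE)
  if (is.null(wtp_grid)) wtp_grid <- attr(scatter, "wtp_grid")
  if (is.null(wtp_grid)) stop("no willingness-to-pay grid", call. = FALSE)
  prob <- vapply(wtp_grid, function(w)
    mean(net_monetary_benefit(scatter$delta_cost, scatter$delta_qaly, w) > 0),
    numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("bph_ceac", "data.frame"))
}
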