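# Simulation engines: deterministic cohort trace and seeded
# individual-level microsimulation, sharing one accrual routine for
# discounted costs, QALYs and episode counts.

#' Discount factor for a cycle
#'
#' Cycle-start discounting: `(1 + rate)^(-cycle_index)`, so cycle 0 is
#' undiscounted.
#'
#' @param cycle_index Cycle index (>= 0); vectorized.
#' @param annual_rate Annual discount rate (>= 0), applied to both costs
#'   and outcomes.
#' @return Numeric discount factor(s).
#' @examples
#' discount_factor(1, 0.03)  # 0.9708738
#' @export
discount_factor <- function(cycle_index, annual_rate) {
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0", call. = FALSE)
  if (annual_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle_index)
}

# economic scalars used by the accrual routine
.econ_core <- function(params, arm) {
  arm <- .match_arm(arm)
  co <- params$costs; u <- params$utilities; st <- params$settings
  list(
    r = st$discount_rate,
    cpy = st$cycles_per_year,
    c_drug = if (arm == "combination") co$annual_drug_combination
             else co$annual_drug_tamsulosin,
    c_bph = co$annual_bph_management,
    c_aur = co$aur_episode,
    c_turp = co$turp_procedure,
    c_med = co$annual_medical_intervention,
    c_fu = co$recovery_followup,
    u9 = c(u$u_bph, u$u_aur, u$u_turp, u$u_turp, u$u_medical, u$u_medical,
           u$u_recovery, u$u_recovery, u$u_death),
    drug_alive = identical(params$options$drug_accrual, "alive"),
    hcc = isTRUE(params$options$half_cycle_correction))
}

# per-cycle background mortality for every transition of a run
.cycle_qx <- function(params, cycles) {
  st <- params$settings
  ages <- st$cohort_start_age + (seq_len(cycles) - 1) / st$cycles_per_year
  qx <- .lookup_qx(params$life_table, ages)
  if (st$cycles_per_year > 1) qx <- 1 - (1 - qx)^(1 / st$cycles_per_year)
  qx
}

# per-cycle progression probabilities when running sub-annual cycles
.core_per_cycle <- function(core, cpy) {
  if (cpy == 1) return(core)
  for (f in c("p_bt", "p_ba", "p_mt", "p_rm", "p_rep_med"))
    core[[f]] <- 1 - (1 - core[[f]])^(1 / cpy)
  core
}

# Accrual over an occupancy path.
# occ: (cycles+1) x 9 matrix of state occupancy fractions, rows t = 0..C;
# rec_inflow: length cycles+1 vector, arrivals into RECOVERY from the
# surgical states at each time point (index t+1 = arrivals at time t).
.accrue <- function(occ, rec_inflow, econ) {
  cycles <- nrow(occ) - 1L
  tp <- 0:cycles
  df <- (1 + econ$r)^(-tp / econ$cpy)
  w <- if (econ$hcc) c(0.5, rep(1, cycles - 1), 0.5)
       else c(rep(1, cycles), 0)
  wdf <- w * df
  per_year <- 1 / econ$cpy     # membership accruals are annual rates

  o_bph <- occ[, 1]; o_aur <- occ[, 2]
  o_surg <- occ[, 3] + occ[, 4]
  o_med <- occ[, 5] + occ[, 6]
  alive <- 1 - occ[, 9]

  cost <- c(
    drug = sum(wdf * econ$c_drug * per_year *
                 (if (econ$drug_alive) alive else o_bph)),
    bph = sum(wdf * econ$c_bph * per_year * o_bph),
    aur = sum(wdf * econ$c_aur * o_aur),
    turp = sum(wdf * econ$c_turp * o_surg),
    medical = sum(wdf * (econ$c_med * per_year * o_med +
                           econ$c_fu * rec_inflow)))
  qaly <- sum(wdf * per_year * (occ %*% econ$u9))
  episodes <- c(
    bph = sum(o_bph[seq_len(cycles)]) * per_year,
    aur = sum(o_aur[seq_len(cycles)]),
    turp = sum(o_surg[seq_len(cycles)]),
    deaths = occ[cycles + 1L, 9])
  list(cost = cost, qaly = qaly, episodes = episodes,
       cycle_cost = wdf * (econ$c_drug * per_year *
                             (if (econ$drug_alive) alive else o_bph) +
                           econ$c_bph * per_year * o_bph +
                           econ$c_aur * o_aur + econ$c_turp * o_surg +
                           econ$c_med * per_year * o_med +
                           econ$c_fu * rec_inflow),
       cycle_qaly = wdf * per_year * as.vector(occ %*% econ$u9))
}

.new_result <- function(arm, engine, horizon_years, acc, n_patients = NA,
                        trace = NULL, seed = NA) {
  structure(list(
    arm = arm, engine = engine, horizon_years = horizon_years,
    n_patients = n_patients, seed = seed,
    cost_total = sum(acc$cost), cost = acc$cost,
    qaly = acc$qaly, episodes = acc$episodes,
    trace = trace), class = "bph_result")
}

#' @export
print.bph_result <- function(x, ...) {
  cat(sprintf("%s arm, %s engine, %d-year horizon\n",
              x$arm, x$engine, x$horizon_years))
  cat(sprintf("  discounted cost per patient: %.2f USD\n", x$cost_total))
  cat(sprintf("    %s\n", paste(sprintf("%s %.2f", names(x$cost), x$cost),
                                collapse = ", ")))
  cat(sprintf("  discounted QALYs per patient: %.4f\n", x$qaly))
  cat(sprintf("  episodes: BPH person-years %.3f, AUR %.4f, TURP %.4f, deaths %.4f\n",
              x$episodes["bph"], x$episodes["aur"], x$episodes["turp"],
              x$episodes["deaths"]))
  invisible(x)
}

#' Run the deterministic cohort model
#'
#' Propagates the full cohort's state occupancy through the per-cycle
#' transition matrices and accumulates discounted costs (decomposed as
#' drug, BPH management, AUR episodes, TURP procedures, medical
#' intervention), discounted QALYs, and undiscounted episode counts.
#' Everyone starts in the BPH state; the cohort ages through the life
#' table as cycles advance.
#'
#' @param params A validated `bph_parameters` object.
#' @param arm `"combination"` or `"monotherapy"`.
#' @param horizon_years Optional override of `params$settings$horizon_years`.
#' @param trace Keep the per-cycle occupancy trace (default `TRUE`).
#' @return A `bph_result` with components `cost_total`, `cost`
#'   (category breakdown), `qaly`, `episodes` (BPH person-years, AUR
#'   episodes, TURP procedures, cumulative deaths) and, if requested,
#'   `trace`: a tidy data frame (cycle, state, occupancy) over the seven
#'   reporting states plus per-cycle discounted cost and QALY increments
#'   in `attr(trace, "cycle_summary")`.
#' @examples
#' p <- base_case_parameters()
#' run_cohort(p, "monotherapy")
#' @export
run_cohort <- function(params, arm, horizon_years = NULL, trace = TRUE) {
  .stop_if_invalid(params)
  arm <- .match_arm(arm)
  st <- params$settings
  H <- if (is.null(horizon_years)) st$horizon_years else as.integer(horizon_years)
  cycles <- H * st$cycles_per_year
  core <- .core_per_cycle(.matrix_core(params, arm), st$cycles_per_year)
  qs <- .cycle_qx(params, cycles)

  occ <- matrix(0, cycles + 1L, 9)
  occ[1, 1] <- 1
  rec_inflow <- numeric(cycles + 1L)
  for (t in seq_len(cycles)) {
    M <- .engine_matrix(core, qs[t])
    o <- occ[t, ] %*% M
    if (any(o < -1e-12) || abs(sum(o) - 1) > 1e-9)
      stop("internal-consistency error: occupancy left the simplex at cycle ",
           t, call. = FALSE)
    occ[t + 1L, ] <- o
    rec_inflow[t + 1L] <- occ[t, 3] * M[3, 7] + occ[t, 4] * M[4, 8]
  }

  acc <- .accrue(occ, rec_inflow, .econ_core(params, arm))
  tr <- NULL
  if (trace) {
    rep_states <- bph_states()
    agg <- cbind(occ[, 1], occ[, 2], occ[, 3], occ[, 4],
                 occ[, 5] + occ[, 6], occ[, 7] + occ[, 8], occ[, 9])
    tr <- data.frame(
      cycle = rep(0:cycles, times = 7),
      state = factor(rep(rep_states, each = cycles + 1L), levels = rep_states),
      occupancy = as.vector(agg))
    attr(tr, "cycle_summary") <- data.frame(
      cycle = 0:cycles, cost = acc$cycle_cost, qaly = acc$cycle_qaly)
  }
  .new_result(arm, "cohort", H, acc, trace = tr)
}

#' Run the individual-level microsimulation
#'
#' Walks `n_patients` independent patients through the chain by sampling
#' each transition, then accumulates the same discounted outcomes as the
#' cohort engine.  Identical seeds give bit-identical results; by the law
#' of large numbers the means converge to the cohort model's values at
#' rate \eqn{O(n^{-1/2})}.
#'
#' @param params A validated `bph_parameters` object.
#' @param arm `"combination"` or `"monotherapy"`.
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed; required, so every stochastic run is
#'   reproducible.
#' @param horizon_years Optional horizon override.
#' @param keep_log Keep the per-patient event log (state of every patient
#'   at every cycle; default `TRUE`).
#' @return A `bph_result` (engine `"microsim"`); when `keep_log = TRUE`
#'   the integer state-path matrix is attached as `$event_log` with the
#'   engine state names as an attribute.
#' @export
run_microsimulation <- function(params, arm,
                                n_patients = params$settings$n_microsim_patients,
                                seed, horizon_years = NULL, keep_log = TRUE) {
  if (missing(seed) || is.null(seed))
    stop("microsimulation requires an explicit seed", call. = FALSE)
  .stop_if_invalid(params)
  arm <- .match_arm(arm)
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  st <- params$settings
  H <- if (is.null(horizon_years)) st$horizon_years else as.integer(horizon_years)
  cycles <- H * st$cycles_per_year
  core <- .core_per_cycle(.matrix_core(params, arm), st$cycles_per_year)
  qs <- .cycle_qx(params, cycles)

  set.seed(as.integer(seed))
  log <- matrix(1L, n_patients, cycles + 1L)
  cur <- rep(1L, n_patients)
  for (t in seq_len(cycles)) {
    M <- .engine_matrix(core, qs[t])
    nxt <- cur
    for (s in 1:8) {              # death (9) is absorbing
      idx <- which(cur == s)
      if (length(idx))
        nxt[idx] <- sample.int(9, length(idx), replace = TRUE, prob = M[s, ])
    }
    nxt[cur == 9L] <- 9L
    log[, t + 1L] <- nxt
    cur <- nxt
  }
  attr(log, "states") <- .engine_states

  res <- accumulate_outcomes(log, params, arm)
  res$engine <- "microsim"
  res$n_patients <- n_patients
  res$seed <- as.integer(seed)
  if (keep_log) res$event_log <- log
  res
}

#' Accumulate discounted outcomes from an event log
#'
#' Recomputes a `bph_result` from a stored per-patient state-path matrix
#' alone, using the same accrual rules as the engines; re-running it on
#' the same log is idempotent.
#'
#' @param event_log Integer matrix (patients x time points) of engine
#'   state indices, as produced by [run_microsimulation()].
#' @param params The parameter set the log was generated under.
#' @param arm Arm name.
#' @param per_patient If `TRUE`, attach a per-patient data frame of
#'   discounted cost and QALY (`$per_patient`).
#' @return A `bph_result`.
#' @export
accumulate_outcomes <- function(event_log, params, arm, per_patient = FALSE) {
  arm <- .match_arm(arm)
  if (!is.matrix(event_log) || any(event_log < 1) || any(event_log > 9))
    stop("event log must be a matrix of engine state indices 1..9",
         call. = FALSE)
  st <- params$settings
  cycles <- ncol(event_log) - 1L
  if (cycles %% st$cycles_per_year != 0)
    stop("event log length is not a whole number of years", call. = FALSE)
  H <- cycles %/% st$cycles_per_year
  n <- nrow(event_log)

  occ <- vapply(1:9, function(s) colMeans(event_log == s), numeric(cycles + 1L))
  if (cycles == 0) occ <- matrix(occ, 1L, 9)
  from_surg <- event_log[, seq_len(cycles), drop = FALSE] %in% c(3L, 4L)
  to_rec <- event_log[, seq_len(cycles) + 1L, drop = FALSE] %in% c(7L, 8L)
  rec_in <- matrix(from_surg & to_rec, n, cycles)
  rec_inflow <- c(0, colMeans(rec_in))

  econ <- .econ_core(params, arm)
  acc <- .accrue(occ, rec_inflow, econ)
  res <- .new_result(arm, "microsim", H, acc, n_patients = n)

  if (per_patient) {
    tp <- 0:cycles
    wdf <- (if (econ$hcc) c(0.5, rep(1, cycles - 1), 0.5)
            else c(rep(1, cycles), 0)) * (1 + econ$r)^(-tp / econ$cpy)
    per_year <- 1 / econ$cpy
    cost9 <- c(econ$c_bph * per_year, econ$c_aur, econ$c_turp, econ$c_turp,
               econ$c_med * per_year, econ$c_med * per_year, 0, 0, 0)
    drug9 <- if (econ$drug_alive) c(rep(econ$c_drug * per_year, 8), 0)
             else c(econ$c_drug * per_year, rep(0, 8))
    state_cost <- cost9 + drug9
    cost_i <- numeric(n); qaly_i <- numeric(n)
    for (t in 0:cycles) {
      s_t <- event_log[, t + 1L]
      cost_i <- cost_i + wdf[t + 1L] * state_cost[s_t]
      qaly_i <- qaly_i + wdf[t + 1L] * per_year * econ$u9[s_t]
    }
    if (econ$c_fu != 0 && cycles > 0)
      cost_i <- cost_i + as.vector(rec_in %*% wdf[-1]) * econ$c_fu
    res$per_patient <- data.frame(cost = cost_i, qaly = qaly_i)
  }
  res
}

#' Per-patient event counts from a microsimulation log
#'
#' Tunnel states (AUR, TURP, repeat TURP) are left after exactly one
#' cycle, so each cycle spent there is one event.
#'
#' @param event_log State-path matrix from [run_microsimulation()].
#' @return Data frame with one row per patient: BPH cycles, AUR episodes,
#'   TURP procedures (first + repeat), and death indicator.
#' @export
patient_event_counts <- function(event_log) {
  data.frame(
    bph_cycles = rowSums(event_log == 1L),
    aur = rowSums(event_log == 2L),
    turp = rowSums(event_log == 3L | event_log == 4L),
    died = event_log[, ncol(event_log)] == 9L)
}
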