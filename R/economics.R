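# Incremental cost-effectiveness computation and willingness-to-pay
# decision rules.

#' Incremental cost-effectiveness ratio of combination vs monotherapy
#'
#' Deltas are combination minus monotherapy.  The ICER is the numeric
#' ratio \eqn{\Delta C / \Delta E} whenever \eqn{\Delta E \ne 0};
#' the dominance label is `"dominant"` when the combination is no more
#' costly and more effective, `"dominated"` when it is no less costly and
#' less effective, `"undefined"` when \eqn{\Delta E = 0}, and `"icer"`
#' otherwise.
#'
#' @param result_combination,result_monotherapy `bph_result` objects (or
#'   any lists with `cost_total` and `qaly`) from identical settings and
#'   horizon.
#' @return A `bph_icer` list: `delta_cost`, `delta_qaly`, `icer` (numeric
#'   or `NA` when undefined), `label`, `arm_totals`, and the per-category
#'   cost deltas when both results carry breakdowns.
#' @examples
#' compute_icer(list(cost_total = 3679, qaly = 3.0664),
#'              list(cost_total = 2905, qaly = 3))$icer   # 774 / 0.0664
#' @export
compute_icer <- function(result_combination, result_monotherapy) {
  rc <- result_combination; rm_ <- result_monotherapy
  if (!is.null(rc$horizon_years) && !is.null(rm_$horizon_years) &&
      rc$horizon_years != rm_$horizon_years)
    stop("results come from different horizons", call. = FALSE)
  dc <- rc$cost_total - rm_$cost_total
  dq <- rc$qaly - rm_$qaly
  icer <- if (dq != 0) dc / dq else NA_real_
  label <- if (dq == 0) "undefined"
           else if (dc <= 0 && dq > 0) "dominant"
           else if (dc >= 0 && dq < 0) "dominated"
           else "icer"
  delta_cost_by_category <- if (!is.null(rc$cost) && !is.null(rm_$cost))
    rc$cost - rm_$cost else NULL
  structure(list(
    delta_cost = dc, delta_qaly = dq, icer = icer, label = label,
    delta_cost_by_category = delta_cost_by_category,
    arm_totals = data.frame(
      arm = c("combination", "monotherapy"),
      cost = c(rc$cost_total, rm_$cost_total),
      qaly = c(rc$qaly, rm_$qaly))), class = "bph_icer")
}

#' @export
print.bph_icer <- function(x, ...) {
  cat(sprintf("incremental cost %.2f USD, incremental QALY %.4f\n",
              x$delta_cost, x$delta_qaly))
  if (x$label == "icer")
    cat(sprintf("ICER: %.0f USD per QALY gained\n", x$icer))
  else
    cat("ICER:", x$label,
        if (!is.na(x$icer)) sprintf("(ratio %.0f)", x$icer) else "", "\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = wtp * qaly - cost`; at willingness-to-pay `wtp` a strategy with
#' higher NMB is preferred, and a positive incremental NMB is equivalent
#' to the ICER lying below `wtp` when the QALY gain is positive.
#'
#' @param cost Discounted cost (USD); vectorized.
#' @param qaly Discounted QALYs; vectorized.
#' @param wtp Willingness to pay per QALY (USD, >= 0).
#' @return Net monetary benefit in USD.
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("willingness-to-pay must be >= 0", call. = FALSE)
  wtp * qaly - cost
}

#' Classify a point on the cost-effectiveness plane
#'
#' Sign-based quadrant of the incremental (cost, QALY) pair: NE (more
#' costly, more effective), SE (less costly, more effective: cost-saving),
#' NW (more costly, less effective), SW (less costly, less effective).
#' Exact zeros are assigned to the positive side and flagged as ties.
#'
#' @param delta_cost,delta_qaly Incremental cost and QALYs; vectorized.
#' @return Factor with levels NE, SE, NW, SW and a logical `"tie"`
#'   attribute marking points on an axis.
#' @export
classify_quadrant <- function(delta_cost, delta_qaly) {
  north <- delta_cost >= 0
  east <- delta_qaly >= 0
  q <- ifelse(north & east, "NE",
       ifelse(!north & east, "SE",
       ifelse(north & !east, "NW", "SW")))
  structure(factor(q, levels = c("NE", "SE", "NW", "SW")),
            tie = delta_cost == 0 | delta_qaly == 0)
}

#' Willingness-to-pay reference thresholds
#'
#' Named constants used in the analysis: one and three times Hong Kong's
#' 2017 GDP per capita, the WHO-CHOICE reference points.  Both are
#' exposed; neither is endorsed as "the" threshold.
#'
#' @return Named numeric vector (USD per QALY).
#' @export
wtp_thresholds <- function() {
  c(gdp_per_capita_hk_2017 = 45887, three_gdp_per_capita_hk_2017 = 137661)
}

#' Base-case results table for both arms
#'
#' Runs both arms at one or more horizons and lays the results out as the
#' standard base-case report: per-category discounted costs, episode
#' counts, QALYs and the ICER, with a combination column, a monotherapy
#' column and their difference.
#'
#' @param params A validated `bph_parameters` object.
#' @param horizons Integer vector of horizons in years.
#' @param engine `"cohort"` (deterministic) or `"microsim"`.
#' @param n_patients,seed Microsimulation size and seed (required for the
#'   microsim engine).
#' @return A data frame with columns `horizon`, `item`, `combination`,
#'   `monotherapy`, `difference`.
#' @export
basecase_table <- function(params, horizons = c(4L, 35L),
                           engine = c("cohort", "microsim"),
                           n_patients = params$settings$n_microsim_patients,
                           seed = NULL) {
  engine <- match.arg(engine)
  out <- list()
  for (H in horizons) {
    run1 <- function(arm)
      if (engine == "cohort") run_cohort(params, arm, H, trace = FALSE)
      else run_microsimulation(params, arm, n_patients, seed = seed,
                               horizon_years = H, keep_log = FALSE)
    rc <- run1("combination"); rm_ <- run1("monotherapy")
    ic <- compute_icer(rc, rm_)
    items <- c("Drug", "BPH", "AUR", "TURP", "Medical intervention",
               "BPH episodes", "AUR episodes", "TURP episodes", "Death",
               "QALY", "ICER")
    cc <- c(rc$cost, rc$episodes, rc$qaly, NA)
    cm <- c(rm_$cost, rm_$episodes, rm_$qaly, NA)
    dd <- c(cc[1:10] - cm[1:10], ic$icer)
    out[[length(out) + 1]] <- data.frame(
      horizon = H, item = items, combination = unname(cc),
      monotherapy = unname(cm), difference = unname(dd))
  }
  do.call(rbind, out)
}
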