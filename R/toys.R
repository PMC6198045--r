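# Synthetic fixtures: toy chains with closed-form solutions used as
# independent oracles for the engines, and random valid parameter sets
# for property testing.

#' Closed-form expected discounted cycles in the start state
#'
#' For a chain whose start state is left with constant probability
#' `1 - p_stay` per cycle (all exits absorbing), the expected discounted
#' occupancy summed over `horizon_cycles` cycles is the geometric series
#' \deqn{\sum_{t=0}^{H-1} \left(\frac{p_{stay}}{1+r}\right)^t,}
#' evaluated in closed form.  This is the oracle the cohort engine is
#' verified against on toy models.
#'
#' @param p_stay Per-cycle probability of remaining in the start state.
#' @param rate Discount rate (>= 0).
#' @param horizon_cycles Number of cycles (>= 1).
#' @return The expected discounted start-state cycles.
#' @examples
#' closed_form_occupancy(0.5, 0, 3)     # 1.75
#' closed_form_occupancy(0.9, 0.03, 2)  # 1 + 0.9 / 1.03
#' @export
closed_form_occupancy <- function(p_stay, rate, horizon_cycles) {
  if (p_stay < 0 || p_stay > 1) stop("p_stay must be in [0, 1]", call. = FALSE)
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  if (horizon_cycles < 1) stop("horizon must be >= 1 cycle", call. = FALSE)
  x <- p_stay / (1 + rate)
  if (abs(x - 1) < 1e-15) return(as.numeric(horizon_cycles))
  (1 - x^horizon_cycles) / (1 - x)
}

#' Build an analytically solvable toy model
#'
#' Degenerates the full parameter set into a chain with a closed-form
#' solution.  With `n_states = 2` the cohort stays in BPH with
#' probability `p_stay` and otherwise dies (all exit mass routed to the
#' absorbing death state through the life table), so discounted QALYs are
#' exactly `utility * closed_form_occupancy(p_stay, rate, horizon)` and
#' likewise for the per-cycle cost.  With `n_states = 3` an additional
#' transient flow through AUR (which returns to BPH) is enabled with
#' probability `p_move`, still analytically solvable by propagating the
#' 3 x 3 chain directly.
#'
#' @param n_states 2 or 3.
#' @param p_stay Per-cycle stay probability of the start state.
#' @param p_move For `n_states = 3`: per-cycle probability of visiting the
#'   transient AUR state.
#' @param utility Utility of the start state (all other alive utilities 0).
#' @param cost Annual cost accrued in the start state.
#' @param horizon Horizon in years.
#' @param rate Discount rate.
#' @return A validated `bph_parameters` object.
#' @export
make_toy_model <- function(n_states = 2, p_stay = 0.8, p_move = 0.1,
                           utility = 1, cost = 0, horizon = 4, rate = 0) {
  if (!n_states %in% c(2, 3))
    stop("no closed form available: n_states must be 2 or 3", call. = FALSE)
  p <- base_case_parameters()
  # route all exit mass from BPH to death via a flat life table
  q <- 1 - p_stay - if (n_states == 3) p_move else 0
  if (q < 0) stop("p_stay + p_move must be <= 1", call. = FALSE)
  lt <- p$life_table
  lt$qx <- rep(q, nrow(lt))   # constant hazard, independent of age
  p$life_table <- structure(lt, class = class(p$life_table))
  p$transitions$p_bph_stay <- 1
  p$transitions$p_bph_to_turp <- 0
  # the engine scales alive transitions by (1 - q), so the configured
  # AUR exit is inflated to make the marginal flow exactly p_move
  p$transitions$p_bph_to_aur <- if (n_states == 3)
    p_move / max(1 - q, 1e-12) else 0
  p$transitions$p_aur_to_turp <- 0        # AUR returns to BPH
  p$efficacy$rrr_aur <- 0; p$efficacy$rrr_turp <- 0
  p$costs <- lapply(p$costs, function(x) 0)
  p$costs$annual_bph_management <- cost
  p$utilities <- list(u_bph = utility, u_aur = 0, u_turp = 0,
                      u_medical = 0, u_recovery = 0, u_death = 0)
  p$settings$discount_rate <- rate
  p$settings$horizon_years <- as.integer(horizon)
  p$options$drug_accrual <- "bph"   # drug cost is zero anyway; keep exact
  p$options$row_mode <- "residual"  # toy probabilities are literal
  p$owsa_ranges <- NULL             # base ranges no longer bracket the toy
  p$psa_distributions <- NULL
  .stop_if_invalid(p)
  p
}

#' Generate random valid parameter sets
#'
#' Draws each ranged parameter uniformly within its published low/high
#' bounds (all other fields at base) and returns full parameter sets;
#' every draw passes [validate_parameters()].  Used as the input
#' generator for property-style tests of matrix construction and the
#' engines.
#'
#' @param seed Integer seed.
#' @param n Number of parameter sets.
#' @return List of `n` validated `bph_parameters` objects.
#' @export
generate_random_parameters <- function(seed, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  base <- base_case_parameters()
  rg <- base$owsa_ranges
  draws <- matrix(stats::runif(n * nrow(rg), rg$low, rg$high),
                  nrow = nrow(rg), ncol = n)
  lapply(seq_len(n), function(i) {
    p <- base
    for (k in seq_len(nrow(rg)))
      p <- set_parameter(p, rg$target[k], draws[k, i])
    rep <- validate_parameters(p)
    if (nrow(rep) > 0)
      stop("generator produced an invalid draw: ", rep$message[1],
           call. = FALSE)
    p
  })
}
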