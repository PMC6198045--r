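# Transition-matrix construction: treatment effects, competing-risk
# combination with background mortality, and the per-arm per-cycle
# row-stochastic matrix over the expanded nine-state chain.

#' Apply a relative risk reduction to a transition probability
#'
#' The combination arm's effect on disease progression is modelled as a
#' relative risk reduction (RRR) applied to the monotherapy transition:
#' the treated probability is `base_prob * (1 - rrr)`.
#'
#' @param base_prob Monotherapy (baseline) transition probability in
#'   \[0, 1\]; vectorized.
#' @param rrr Relative risk reduction in \[0, 1\]: 0 means no effect,
#'   1 complete protection.
#' @return The treated transition probability.
#' @examples
#' apply_efficacy(0.004, 0.676)  # 0.001296
#' @export
apply_efficacy <- function(base_prob, rrr) {
  if (any(base_prob < 0 | base_prob > 1) || any(is.na(base_prob)))
    stop("base_prob must be in [0, 1]", call. = FALSE)
  if (any(rrr < 0 | rrr > 1) || any(is.na(rrr)))
    stop("rrr must be in [0, 1]", call. = FALSE)
  base_prob * (1 - rrr)
}

#' Combine state exits with background mortality as competing risks
#'
#' Given the exit probabilities of a health state (conditional on
#' surviving the cycle) and the probability of background all-cause death,
#' returns the full row fragment: state-specific transitions are scaled by
#' the survival probability, and the death entry receives the background
#' mortality combined with any state-specific (e.g. 30-day surgical)
#' mortality by the competing-risk product rule
#' \eqn{p_{death} = 1 - (1 - p_{state})(1 - p_{bg})}.
#'
#' @param exit_probs Named numeric vector of exit probabilities, summing
#'   to at most 1; the remainder is the self-loop.
#' @param p_bg_death Background death probability for the cycle.
#' @param state_mortality State-specific mortality (default 0).
#' @return A list with components `exits` (scaled exit probabilities),
#'   `p_death`, and `p_stay` (the residual self-loop); the three sum to 1.
#' @examples
#' combine_with_background_mortality(c(RECOVERY = 0.882), 0.01,
#'                                   state_mortality = 0.0237)
#' @export
combine_with_background_mortality <- function(exit_probs, p_bg_death,
                                              state_mortality = 0) {
  if (sum(exit_probs) > 1 + 1e-12)
    stop("exit probabilities sum to more than 1", call. = FALSE)
  if (p_bg_death < 0 || p_bg_death > 1)
    stop("background death probability must be in [0, 1]", call. = FALSE)
  p_death <- 1 - (1 - state_mortality) * (1 - p_bg_death)
  exits <- exit_probs * (1 - p_death)
  list(exits = exits,
       p_death = p_death,
       p_stay = (1 - p_death) * max(0, 1 - sum(exit_probs)))
}

# Timescale conversion: printed monthly probability -> annual-cycle
# probability.  Applied to progression probabilities only; conditional
# splits and mortality fractions are cycle-length free.
.annualize <- function(p) 1 - (1 - p)^12

# Extract the cycle-invariant "core" of the chain for one arm: effective
# per-cycle exit probabilities after timescale conversion, row-mode
# handling and treatment effect.  The engines and the PSA loop work from
# this structure; build_transition_matrix() is its public face.
.matrix_core <- function(params, arm) {
  arm <- .match_arm(arm)
  tr <- params$transitions
  monthly <- identical(params$options$probability_timescale, "monthly")
  renorm <- identical(params$options$row_mode, "renormalize") && !monthly

  cv <- if (monthly) .annualize else identity
  p_bt <- cv(tr$p_bph_to_turp)
  p_ba <- cv(tr$p_bph_to_aur)
  p_rm <- cv(tr$p_recovery_to_medical)
  p_mt <- cv(tr$p_medical_to_second_turp)
  p_ma <- cv(tr$p_medical_to_aur)
  p_pm <- cv(tr$p_repeat_to_medical)

  if (renorm) {
    tot <- tr$p_bph_stay + p_bt + p_ba
    p_bt <- p_bt / tot; p_ba <- p_ba / tot
    tot <- tr$p_medical_stay + p_mt + p_ma
    p_mt <- p_mt / tot
    tot <- tr$p_recovery_stay + p_rm
    p_rm <- p_rm / tot
  }
  if (p_bt + p_ba > 1)
    stop("BPH row: explicit exits exceed 1", call. = FALSE)
  if (p_mt > 1) stop("MEDICAL_INTERVENTION row: exits exceed 1", call. = FALSE)

  if (arm == "combination") {
    p_bt <- apply_efficacy(p_bt, params$efficacy$rrr_turp)
    p_ba <- apply_efficacy(p_ba, params$efficacy$rrr_aur)
  }

  list(arm = arm,
       p_bt = p_bt, p_ba = p_ba,
       p_aur_turp = tr$p_aur_to_turp,
       sm_turp = tr$p_turp_30day_mortality,
       p_turp_rep = tr$p_turp_to_repeat,
       p_turp_med = tr$p_turp_to_medical,
       sm_rep = tr$p_repeat_turp_mortality,
       p_rep_med = p_pm,
       p_mt = p_mt, p_rm = p_rm)
}

# 9x9 engine matrix for one cycle given background mortality q
.engine_matrix <- function(core, q) {
  M <- matrix(0, 9, 9, dimnames = list(.engine_states, .engine_states))
  s <- 1 - q
  # BPH
  M[1, 3] <- core$p_bt * s
  M[1, 2] <- core$p_ba * s
  M[1, 1] <- (1 - core$p_bt - core$p_ba) * s
  M[1, 9] <- q
  # AUR tunnel: to surgery or back to BPH
  M[2, 3] <- core$p_aur_turp * s
  M[2, 1] <- (1 - core$p_aur_turp) * s
  M[2, 9] <- q
  # TURP tunnel: competing 30-day surgical death, survivors split
  dth <- 1 - (1 - core$sm_turp) * s
  M[3, 4] <- core$p_turp_rep * (1 - dth)
  M[3, 5] <- core$p_turp_med * (1 - dth)
  M[3, 7] <- (1 - core$p_turp_rep - core$p_turp_med) * (1 - dth)
  M[3, 9] <- dth
  # repeat TURP tunnel: all survivors recover unless needing medication
  dth <- 1 - (1 - core$sm_rep) * s
  M[4, 6] <- core$p_rep_med * (1 - dth)
  M[4, 8] <- (1 - core$p_rep_med) * (1 - dth)
  M[4, 9] <- dth
  # medical intervention, one TURP so far: second TURP possible
  M[5, 4] <- core$p_mt * s
  M[5, 5] <- (1 - core$p_mt) * s
  M[5, 9] <- q
  # medical intervention after the second TURP: no further surgery
  M[6, 6] <- s
  M[6, 9] <- q
  # recovery rows
  M[7, 5] <- core$p_rm * s
  M[7, 7] <- (1 - core$p_rm) * s
  M[7, 9] <- q
  M[8, 6] <- core$p_rm * s
  M[8, 8] <- (1 - core$p_rm) * s
  M[8, 9] <- q
  M[9, 9] <- 1
  M
}

#' Build the per-arm transition matrix for one cycle
#'
#' Constructs the row-stochastic transition matrix of the chain for the
#' given arm and cohort age.  The matrix is over the expanded nine-state
#' chain: `MEDICAL_INTERVENTION` and `RECOVERY` each appear twice,
#' subscripted by the number of TURP procedures already received, which
#' encodes the at-most-two-TURPs rule structurally (the post-second-TURP
#' copies have no surgical exit).  The `"report_state"` attribute maps the
#' nine engine states onto the seven reporting states.
#'
#' In the combination arm the BPH exit probabilities toward TURP and AUR
#' are reduced by [apply_efficacy()]; background mortality at the given
#' age enters every alive row by the competing-risk product rule.
#'
#' @param params A validated `bph_parameters` object.
#' @param arm `"combination"` or `"monotherapy"`.
#' @param cohort_age Attained cohort age (years) for the cycle's
#'   background mortality lookup.
#' @return A 9 x 9 row-stochastic matrix with state dimnames and
#'   attributes `arm`, `age`, `report_state`.
#' @examples
#' p <- base_case_parameters()
#' M <- build_transition_matrix(p, "monotherapy", 66)
#' rowSums(M)
#' @export
build_transition_matrix <- function(params, arm, cohort_age) {
  core <- .matrix_core(params, arm)
  q <- .lookup_qx(params$life_table, cohort_age)
  M <- .engine_matrix(core, q)
  if (any(M < 0) || any(abs(rowSums(M) - 1) > 1e-12))
    stop("internal error: transition matrix is not row-stochastic",
         call. = FALSE)
  attr(M, "arm") <- core$arm
  attr(M, "age") <- cohort_age
  attr(M, "report_state") <- unname(.engine_to_report[.engine_states])
  M
}

#' Write per-cycle transition matrices for audit
#'
#' Dumps the transition matrix of every cycle of a run to CSV, one file
#' per arm per cycle, with named state rows and columns.
#'
#' @param params A `bph_parameters` object.
#' @param arm Arm name.
#' @param horizon_years Number of annual cycles to dump.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_matrix_audit <- function(params, arm, horizon_years, dir) {
  arm <- .match_arm(arm)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (t in seq_len(horizon_years) - 1L) {
    age <- params$settings$cohort_start_age + t
    M <- build_transition_matrix(params, arm, age)
    path <- file.path(dir, sprintf("matrix_%s_cycle%02d.csv", arm, t))
    utils::write.csv(as.data.frame(M), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
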