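# Health-state and arm definitions shared across the package.
#
# The reporting model has seven states.  Internally the engines run on an
# expanded nine-state chain in which MEDICAL_INTERVENTION and RECOVERY are
# split by the number of TURP procedures already received, so that the
# "at most two TURPs per patient" rule is a structural property of the
# chain rather than a bookkeeping patch.

#' Health states of the BPH progression model
#'
#' Returns the seven reporting health states: symptomatic BPH (the unique
#' start state), acute urinary retention (AUR, a one-cycle tunnel state),
#' TURP surgery, repeat TURP surgery, long-term medical intervention,
#' post-surgical recovery, and death (absorbing; pooled surgical and
#' all-cause mortality).
#'
#' @return Character vector of the seven state names.
#' @export
bph_states <- function() {
  c("BPH", "AUR", "TURP", "REPEAT_TURP", "MEDICAL_INTERVENTION",
    "RECOVERY", "DEATH")
}

#' Treatment arms
#'
#' The two strategies compared: daily single-dose dutasteride/tamsulosin
#' (`"combination"`) and daily tamsulosin 0.4 mg alone (`"monotherapy"`).
#'
#' @return Character vector of the two arm names.
#' @export
bph_arms <- function() c("combination", "monotherapy")

# Engine (expanded) states.  MEDICAL_1/RECOVERY_1 follow a first TURP (a
# second TURP is still possible); MEDICAL_2/RECOVERY_2 follow a repeat
# TURP (no further surgery is allowed).
.engine_states <- c("BPH", "AUR", "TURP", "REPEAT_TURP",
                    "MEDICAL_1", "MEDICAL_2",
                    "RECOVERY_1", "RECOVERY_2", "DEATH")

# map engine state -> reporting state
.engine_to_report <- c(
  BPH = "BPH", AUR = "AUR", TURP = "TURP", REPEAT_TURP = "REPEAT_TURP",
  MEDICAL_1 = "MEDICAL_INTERVENTION", MEDICAL_2 = "MEDICAL_INTERVENTION",
  RECOVERY_1 = "RECOVERY", RECOVERY_2 = "RECOVERY", DEATH = "DEATH")

.match_arm <- function(arm) {
  match.arg(tolower(arm), bph_arms())
}
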