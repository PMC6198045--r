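# Background all-cause mortality stand-in.
#
# The published model takes all-cause mortality from the territory's life
# table, which is not reproduced in print.  The stand-in is a Gompertz
# hazard mu(a) = b * exp(c * a), discretized to annual death
# probabilities q(a) = 1 - exp(-mu(a)), with the level b calibrated in
# closed form so that the cumulative background mortality of the starting
# cohort over the first four years matches a target.

#' Gompertz life-table stand-in for background mortality
#'
#' Builds an annual life table from a Gompertz hazard
#' \eqn{\mu(a) = b e^{ca}}.  The slope `c` is fixed at a value typical of
#' late-adult male mortality; the level `b` is solved so that the 4-year
#' cumulative probability of background death starting at `start_age`
#' equals `calibration_target`:
#' \deqn{b = -\log(1 - \mathrm{target}) / \sum_{a} e^{c a},}
#' the sum running over the four ages `start_age .. start_age + 3`.
#'
#' The default target (0.0538 from age 66) was chosen so that total
#' 4-year deaths in the monotherapy arm — background plus 30-day surgical
#' mortality — come out near the published 0.0577; the resulting annual
#' probabilities (about 0.012 at 66) are in the range of male all-cause
#' mortality at these ages.
#'
#' @param start_age Cohort starting age in years (>= 50, the model
#'   population's entry criterion).
#' @param calibration_target 4-year cumulative background mortality of
#'   the starting cohort, in \[0, 1).
#' @param slope Gompertz slope `c` per year of age.
#' @param max_age Last tabulated age; probabilities are capped at 1.
#' @return A data frame of class `bph_life_table` with columns `age`
#'   (integer, 50..`max_age`) and `qx` (annual death probability),
#'   carrying the fitted `b` and `slope` as attributes.
#' @examples
#' lt <- build_life_table_standin()
#' lt$qx[lt$age == 66]
#' @export
build_life_table_standin <- function(start_age = 66,
                                     calibration_target = 0.0538,
                                     slope = 0.085,
                                     max_age = 110) {
  if (start_age < 50)
    stop("start_age must be >= 50 (model population)", call. = FALSE)
  if (calibration_target < 0 || calibration_target >= 1)
    stop("calibration target must lie in [0, 1): unreachable with a ",
         "positive Gompertz hazard", call. = FALSE)
  if (slope <= 0) stop("Gompertz slope must be positive", call. = FALSE)

  b <- -log(1 - calibration_target) /
    sum(exp(slope * (start_age + 0:3)))
  ages <- 50:max_age
  qx <- 1 - exp(-b * exp(slope * ages))
  structure(
    data.frame(age = ages, qx = pmin(qx, 1)),
    b = b, slope = slope,
    class = c("bph_life_table", "data.frame"))
}

# annual background death probability at (possibly fractional) age;
# ages beyond the table reuse the last entry
.lookup_qx <- function(life_table, age) {
  idx <- findInterval(floor(age), life_table$age)
  idx[idx < 1] <- 1
  idx[idx > nrow(life_table)] <- nrow(life_table)
  life_table$qx[idx]
}
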