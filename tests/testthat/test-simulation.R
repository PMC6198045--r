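test_that("discounting follows the cycle-start convention", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(0:5, 0), rep(1, 6))
  expect_error(discount_factor(1, -0.01), "discount")
  expect_error(discount_factor(-1, 0.03), "cycle_index")
})

test_that("cohort engine matches the geometric closed form on 2-state toys", {
  cases <- expand.grid(p_stay = c(1, 0.9, 0.5, 0.2),
                       rate = c(0, 0.03, 0.1),
                       horizon = c(1, 4, 10))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    toy <- make_toy_model(2, p_stay = cs$p_stay, utility = 0.7, cost = 100,
                          horizon = cs$horizon, rate = cs$rate)
    res <- run_cohort(toy, "monotherapy", trace = FALSE)
    cf <- closed_form_occupancy(cs$p_stay, cs$rate, cs$horizon)
    expect_equal(res$qaly, 0.7 * cf, tolerance = 1e-9)
    expect_equal(res$cost_total, 100 * cf, tolerance = 1e-9)
  }
  # the degenerate absorbing case: utility 1, horizon 4, no discounting
  toy <- make_toy_model(2, p_stay = 1, utility = 1, horizon = 4, rate = 0)
  expect_equal(run_cohort(toy, "monotherapy")$qaly, 4, tolerance = 1e-12)
})

test_that("cohort engine matches direct propagation on the 3-state toy", {
  p_stay <- 0.7; p_move <- 0.2; rate <- 0.03; H <- 6
  toy <- make_toy_model(3, p_stay = p_stay, p_move = p_move, utility = 0.8,
                        horizon = H, rate = rate)
  # independent oracle: propagate the 3x3 chain (BPH, AUR, dead) directly;
  # AUR returns to BPH among survivors of the constant hazard q
  q <- 1 - p_stay - p_move
  A <- rbind(c(p_stay, p_move, q),
             c(1 - q, 0, q),
             c(0, 0, 1))
  o <- c(1, 0, 0); qaly <- 0
  for (t in 0:(H - 1)) {
    qaly <- qaly + (1 + rate)^(-t) * 0.8 * o[1]
    o <- as.vector(o %*% A)
  }
  res <- run_cohort(toy, "monotherapy", trace = FALSE)
  expect_equal(res$qaly, qaly, tolerance = 1e-9)
})

test_that("cohort occupancy stays on the simplex with non-decreasing deaths", {
  res <- run_cohort(base_case_parameters(), "combination", 35)
  tr <- res$trace
  sums <- tapply(tr$occupancy, tr$cycle, sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-9)
  dead <- tr$occupancy[tr$state == "DEATH"]
  expect_true(all(diff(dead) >= -1e-12))
  expect_true(all(tr$occupancy >= -1e-12))
})

test_that("microsimulation is seed-reproducible and converges to the cohort", {
  p <- base_case_parameters()
  a <- run_microsimulation(p, "combination", 2000, seed = 99)
  b <- run_microsimulation(p, "combination", 2000, seed = 99)
  expect_identical(a$cost_total, b$cost_total)
  expect_identical(a$qaly, b$qaly)
  expect_identical(a$event_log, b$event_log)
  c_ <- run_microsimulation(p, "combination", 2000, seed = 100)
  expect_false(identical(a$cost_total, c_$cost_total))

  # law of large numbers against the deterministic cohort values
  co <- run_cohort(p, "monotherapy", trace = FALSE)
  ms <- run_microsimulation(p, "monotherapy", 200000, seed = 5)
  pp <- accumulate_outcomes(ms$event_log, p, "monotherapy",
                            per_patient = TRUE)$per_patient
  n <- nrow(pp)
  expect_lt(abs(ms$qaly - co$qaly), 3 * sd(pp$qaly) / sqrt(n))
  expect_lt(abs(ms$cost_total - co$cost_total), 3 * sd(pp$cost) / sqrt(n))
})

test_that("microsimulation error shrinks like one over root n on a toy", {
  toy <- make_toy_model(2, p_stay = 0.8, utility = 1, horizon = 4, rate = 0)
  truth <- run_cohort(toy, "monotherapy", trace = FALSE)$qaly
  err_at <- function(n) {
    errs <- vapply(1:8, function(s)
      abs(run_microsimulation(toy, "monotherapy", n, seed = 300 + s,
                              keep_log = FALSE)$qaly - truth), numeric(1))
    mean(errs)
  }
  e3 <- err_at(1000); e4 <- err_at(10000); e5 <- err_at(100000)
  # mean absolute error over seeds shrinks with n, consistent with the
  # root-n rate (the 100-fold n step should shrink it far more than 2x)
  expect_lt(e4, e3)
  expect_lt(e5, e3 / 2)
})

test_that("no simulated path contains a third TURP procedure", {
  p <- base_case_parameters()
  for (arm in bph_arms()) {
    ms <- run_microsimulation(p, arm, 10000, seed = 21, horizon_years = 35)
    ev <- patient_event_counts(ms$event_log)
    expect_lte(max(ev$turp), 2)
  }
})

test_that("outcome accumulation from a stored log is exact and idempotent", {
  p <- base_case_parameters()
  p$settings$discount_rate <- 0

  # one patient spending four cycles in BPH: drug cost is 4 x 55.79
  log1 <- matrix(1L, 1, 5)
  res <- accumulate_outcomes(log1, p, "monotherapy")
  expect_equal(unname(res$cost["drug"]), 4 * 55.79)
  expect_equal(unname(res$cost["bph"]), 4 * 471)
  expect_equal(res$qaly, 4 * 0.876)

  # immediate death after the first cycle: only cycle-0 accruals
  log2 <- matrix(c(1L, 9L, 9L, 9L, 9L), 1, 5)
  res2 <- accumulate_outcomes(log2, p, "monotherapy")
  expect_equal(res2$cost_total, 55.79 + 471)
  expect_equal(res2$qaly, 0.876)
  expect_equal(unname(res2$episodes["deaths"]), 1)

  # idempotence on a real log
  ms <- run_microsimulation(base_case_parameters(), "combination", 500,
                            seed = 8)
  again <- accumulate_outcomes(ms$event_log, base_case_parameters(),
                               "combination")
  expect_equal(again$cost_total, ms$cost_total)
  expect_equal(again$qaly, ms$qaly)
  expect_error(accumulate_outcomes(matrix(12L, 1, 5), p, "monotherapy"),
               "state indices")
})

test_that("utilities all one with no death give QALYs equal to the horizon", {
  toy <- make_toy_model(2, p_stay = 1, utility = 1, horizon = 7, rate = 0)
  expect_equal(run_cohort(toy, "monotherapy")$qaly, 7, tolerance = 1e-12)
})

test_that("outcomes respond monotonically to parameters", {
  p <- base_case_parameters()
  base_c <- run_cohort(p, "combination", trace = FALSE)
  base_m <- run_cohort(p, "monotherapy", trace = FALSE)

  up_u <- set_parameter(p, "u_bph", 0.9)
  expect_gte(run_cohort(up_u, "combination", trace = FALSE)$qaly, base_c$qaly)

  up_c <- set_parameter(p, "turp_procedure", 8000)
  expect_gte(run_cohort(up_c, "monotherapy", trace = FALSE)$cost_total,
             base_m$cost_total)

  up_e <- set_parameter(p, "rrr_turp", 0.9)
  expect_lte(run_cohort(up_e, "combination", trace = FALSE)$episodes[["turp"]],
             base_c$episodes[["turp"]])

  # discounting can only shrink totals
  p0 <- p; p0$settings$discount_rate <- 0
  und <- run_cohort(p0, "monotherapy", trace = FALSE)
  expect_gte(und$cost_total, base_m$cost_total)
  expect_gte(und$qaly, base_m$qaly)
})

test_that("a stochastic run demands an explicit seed", {
  expect_error(run_microsimulation(base_case_parameters(), "monotherapy", 10),
               "seed")
})

test_that("alternative readings behave as documented", {
  p <- base_case_parameters()
  base4 <- cohort_icer(p, 4)

  # the residual row reading produces roughly four-fold fewer surgical
  # events and a several-fold larger ICER than the renormalized default
  pr <- p; pr$options$row_mode <- "residual"
  res4 <- cohort_icer(pr, 4)
  ep_ren <- run_cohort(p, "monotherapy", 4, trace = FALSE)$episodes[["turp"]]
  ep_res <- run_cohort(pr, "monotherapy", 4, trace = FALSE)$episodes[["turp"]]
  expect_gt(ep_ren, 2 * ep_res)
  expect_gt(res4$icer, 3 * base4$icer)

  # restricting drug accrual to the BPH state roughly halves the
  # lifetime monotherapy drug cost relative to all-alive accrual
  pb <- p; pb$options$drug_accrual <- "bph"
  drug_alive <- run_cohort(p, "monotherapy", 35, trace = FALSE)$cost[["drug"]]
  drug_bph <- run_cohort(pb, "monotherapy", 35, trace = FALSE)$cost[["drug"]]
  expect_lt(drug_bph, 0.65 * drug_alive)
})
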