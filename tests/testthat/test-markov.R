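test_that("relative risk reduction scales transition probabilities", {
  expect_equal(apply_efficacy(0.004, 0.676), 0.001296)
  expect_equal(apply_efficacy(0.3, 0), 0.3)
  expect_equal(apply_efficacy(0.3, 1), 0)
  expect_error(apply_efficacy(1.2, 0.5), "base_prob")
  expect_error(apply_efficacy(0.5, -0.1), "rrr")
})

test_that("background mortality combines with exits as competing risks", {
  ex <- c(TURP = 0.2, AUR = 0.1)
  same <- combine_with_background_mortality(ex, 0)
  expect_equal(same$exits, ex)
  expect_equal(same$p_death, 0)

  all_dead <- combine_with_background_mortality(ex, 1)
  expect_equal(all_dead$p_death, 1)
  expect_equal(sum(all_dead$exits), 0)

  # surgical 30-day mortality and background death, product rule
  comb <- combine_with_background_mortality(c(x = 0.5), 0.01,
                                            state_mortality = 0.0237)
  expect_equal(comb$p_death, 1 - (1 - 0.0237) * (1 - 0.01))
  expect_equal(comb$exits[["x"]] + comb$p_death + comb$p_stay, 1)

  expect_error(combine_with_background_mortality(c(0.7, 0.5), 0), "sum")
})

test_that("transition entries match the configured inputs before mortality", {
  # residual reading: printed probabilities are literal
  p <- params_no_mortality("residual")
  Mm <- build_transition_matrix(p, "monotherapy", 66)
  expect_equal(Mm["BPH", "AUR"], 0.004)
  expect_equal(Mm["BPH", "TURP"], 0.021)
  Mc <- build_transition_matrix(p, "combination", 66)
  expect_equal(Mc["BPH", "TURP"], 0.021 * (1 - 0.706))   # 0.006174
  expect_equal(Mc["BPH", "AUR"], 0.004 * (1 - 0.676))

  # renormalized reading: stay-weight rescaling
  pr <- params_no_mortality("renormalize")
  Mr <- build_transition_matrix(pr, "monotherapy", 66)
  expect_equal(Mr["BPH", "TURP"], 0.021 / (0.345 + 0.021 + 0.004))
  expect_equal(Mr["BPH", "AUR"], 0.004 / (0.345 + 0.021 + 0.004))

  # monthly-to-annual conversion
  pm <- params_no_mortality("residual")
  pm$options$probability_timescale <- "monthly"
  Mmth <- build_transition_matrix(pm, "monotherapy", 66)
  expect_equal(Mmth["BPH", "AUR"], 1 - (1 - 0.004)^12)
})

test_that("matrices are row-stochastic with absorbing death on random draws", {
  draws <- generate_random_parameters(seed = 424, n = 20)
  for (p in draws[1:10]) p$options$row_mode <- "residual"
  for (p in draws) {
    for (arm in bph_arms()) {
      M <- build_transition_matrix(p, arm, sample(66:90, 1))
      expect_true(all(M >= 0))
      expect_equal(unname(rowSums(M)), rep(1, 9), tolerance = 1e-12)
      expect_equal(M["DEATH", "DEATH"], 1)
      # death stays absorbing under repeated multiplication
      Mn <- M %*% M %*% M %*% M
      expect_equal(Mn["DEATH", "DEATH"], 1, tolerance = 1e-12)
      expect_equal(unname(rowSums(Mn)), rep(1, 9), tolerance = 1e-10)
    }
  }
})

test_that("zero efficacy makes the two arms identical", {
  p <- base_case_parameters()
  p$efficacy$rrr_aur <- 0
  p$efficacy$rrr_turp <- 0
  Mc <- build_transition_matrix(p, "combination", 70)
  Mm <- build_transition_matrix(p, "monotherapy", 70)
  attr(Mc, "arm") <- attr(Mm, "arm")
  expect_equal(Mc, Mm)
})

test_that("matrix audit dump writes one readable file per cycle", {
  dir <- withr::local_tempdir()
  paths <- write_matrix_audit(base_case_parameters(), "monotherapy", 3, dir)
  expect_length(paths, 3)
  M <- read.csv(paths[1], row.names = 1)
  expect_equal(dim(M), c(9, 9))
  expect_equal(unname(rowSums(M)), rep(1, 9), tolerance = 1e-9)
})
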