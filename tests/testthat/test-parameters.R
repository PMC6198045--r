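test_that("base case reproduces the published inputs and is deterministic", {
  p <- base_case_parameters()
  expect_equal(p$transitions$p_bph_to_turp, 0.021)
  expect_equal(p$transitions$p_bph_to_aur, 0.004)
  expect_equal(p$transitions$p_aur_to_turp, 0.8)
  expect_equal(p$transitions$p_turp_30day_mortality, 0.0237)
  expect_equal(p$efficacy$rrr_aur, 0.676)
  expect_equal(p$efficacy$rrr_turp, 0.706)
  expect_equal(p$costs$annual_drug_combination, 464.97)
  expect_equal(p$costs$annual_drug_tamsulosin, 55.79)
  expect_equal(p$costs$turp_procedure, 6334)
  expect_equal(p$utilities$u_bph, 0.876)
  expect_equal(p$utilities$u_aur, 0.25)
  expect_equal(p$utilities$u_death, 0)
  expect_equal(p$settings$discount_rate, 0.03)
  expect_equal(p$settings$cohort_start_age, 66L)
  # every ranged / distributed input is carried along
  expect_equal(nrow(p$owsa_ranges), 23)
  expect_equal(nrow(p$psa_distributions), 11)
  expect_setequal(p$psa_distributions$family[p$psa_distributions$target ==
                    "aur_episode"], "gamma")
  # bit-identical across calls
  expect_identical(p, base_case_parameters())
})

test_that("configuration loading overlays the base case and round-trips", {
  p <- base_case_parameters()
  expect_equal(load_parameters(text = ""), p)

  p2 <- load_parameters(text = "rrr_aur: 0.527")
  expect_equal(p2$efficacy$rrr_aur, 0.527)
  p2$efficacy$rrr_aur <- p$efficacy$rrr_aur
  expect_equal(p2, p)

  # nested group syntax
  p3 <- load_parameters(text = "costs:\n  turp_procedure: 5000")
  expect_equal(p3$costs$turp_procedure, 5000)

  # load -> write -> load is the identity
  p4 <- load_parameters(text = "u_bph: 0.9\np_bph_to_turp: 0.03")
  expect_equal(load_parameters(text = write_parameters(p4)), p4)
})

test_that("bad configurations are rejected with informative errors", {
  expect_error(load_parameters(text = "p_bph_to_aur: 1.5"),
               "p_bph_to_aur")
  expect_error(load_parameters(text = "no_such_field: 1"), "unknown")
  expect_error(load_parameters(text = "a: [1, 2\n"), "parse error")
  expect_error(load_parameters(), "text or file")
})

test_that("validation reports every violated invariant and names fields", {
  p <- base_case_parameters()
  expect_equal(nrow(validate_parameters(p)), 0)

  p1 <- p
  p1$transitions$p_bph_to_turp <- 0.9
  p1$transitions$p_bph_to_aur <- 0.3
  rep1 <- validate_parameters(p1)
  expect_true(any(grepl("BPH", rep1$field)))

  p2 <- p
  p2$costs$turp_procedure <- -10
  rep2 <- validate_parameters(p2)
  expect_true("turp_procedure" %in% rep2$field)

  p3 <- p
  p3$transitions$p_medical_to_aur <- 0.1
  expect_true("p_medical_to_aur" %in% validate_parameters(p3)$field)

  p4 <- p
  p4$utilities$u_recovery <- 1.2
  expect_true("u_recovery" %in% validate_parameters(p4)$field)
})

test_that("life-table stand-in is calibrated, monotone, and handles edge cases", {
  lt <- build_life_table_standin()
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))
  expect_false(is.unsorted(lt$qx))
  q66 <- lt$qx[lt$age == 66]
  q80 <- lt$qx[lt$age == 80]
  expect_gte(q80, q66)
  # 4-year cumulative background mortality from the start age
  cum4 <- 1 - prod(1 - lt$qx[lt$age %in% 66:69])
  expect_gt(cum4, 0.03)
  expect_lt(cum4, 0.07)

  # zero hazard: survival 1
  lt0 <- build_life_table_standin(calibration_target = 0)
  expect_true(all(lt0$qx == 0))

  expect_error(build_life_table_standin(calibration_target = 1),
               "unreachable")
  expect_error(build_life_table_standin(start_age = 40), ">= 50")
})
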