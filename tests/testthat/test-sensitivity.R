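test_that("one-way analysis reproduces the base ICER at degenerate ranges", {
  p <- base_case_parameters()
  base_icer <- cohort_icer(p, 4)$icer
  ranges <- data.frame(
    target = c("annual_drug_combination", "rrr_turp", "u_bph"),
    low = c(464.97, 0.706, 0.876), high = c(464.97, 0.706, 0.876))
  tor <- run_owsa(p, ranges)
  expect_equal(tor$spread, rep(0, 3))
  expect_equal(tor$icer_low, rep(base_icer, 3))
  expect_equal(attr(tor, "base_icer"), base_icer)
})

test_that("the tornado table is sorted by spread and rejects bad ranges", {
  p <- base_case_parameters()
  tor <- run_owsa(p)
  expect_equal(nrow(tor), nrow(p$owsa_ranges))
  expect_false(is.unsorted(rev(tor$spread)))
  expect_error(
    run_owsa(p, data.frame(target = "u_bph", low = 0.9, high = 0.95)),
    "bracket")
  expect_error(
    run_owsa(p, data.frame(target = "p_bph_to_aur", low = 0.004, high = 1.5)),
    "invariant")
})

test_that("repeated one-way runs are bit-identical", {
  p <- base_case_parameters()
  r <- p$owsa_ranges[c(2, 13, 19), ]
  expect_identical(as.data.frame(run_owsa(p, r)),
                   as.data.frame(run_owsa(p, r)))
})

test_that("parameter sampling matches the distribution moments and the seed", {
  p <- base_case_parameters()
  d1 <- sample_psa_parameters(p, 10000, seed = 31)
  d2 <- sample_psa_parameters(p, 10000, seed = 31)
  expect_identical(d1, d2)
  expect_equal(nrow(sample_psa_parameters(p, 0, seed = 1)), 0)

  # beta(1.77, 0.85): mean alpha / (alpha + beta), the published efficacy
  m <- mean(d1$rrr_aur)
  se <- sd(d1$rrr_aur) / sqrt(nrow(d1))
  expect_lt(abs(m - 1.77 / (1.77 + 0.85)), 3 * se)

  # gamma with rederived rate: mean equals the published mean
  m2 <- mean(d1$turp_procedure)
  se2 <- sd(d1$turp_procedure) / sqrt(nrow(d1))
  expect_lt(abs(m2 - 6334), 3 * se2)

  # a draw materializes into a valid parameter set
  pi1 <- apply_parameter_draw(p, d1[1, ])
  expect_equal(nrow(validate_parameters(pi1)), 0)
  expect_equal(pi1$transitions$p_bph_to_turp, d1$p_bph_to_turp[1])
})

test_that("distribution families are tied to their parameter roles", {
  p <- base_case_parameters()
  bad <- p
  bad$psa_distributions$family[bad$psa_distributions$target ==
                                 "turp_procedure"] <- "beta"
  expect_gt(nrow(validate_parameters(bad)), 0)
})

test_that("the probabilistic analysis is reproducible and coherent", {
  p <- base_case_parameters()
  s1 <- run_psa(p, n = 300, seed = 17)
  s2 <- run_psa(p, n = 300, seed = 17)
  expect_identical(as.data.frame(s1), as.data.frame(s2))

  sh <- quadrant_shares(s1)
  expect_equal(sum(sh), 1)
  expect_equal(s1$delta_cost, s1$cost_combination - s1$cost_monotherapy)

  # a different seed moves shares only within Monte-Carlo noise
  s3 <- run_psa(p, n = 300, seed = 18)
  p_ne <- quadrant_shares(s1)[["NE"]]
  se_ne <- sqrt(p_ne * (1 - p_ne) / 300)
  expect_lt(abs(quadrant_shares(s3)[["NE"]] - p_ne), 4 * se_ne + 1e-9)
})

test_that("a no-effect null collapses the incremental QALYs", {
  p <- base_case_parameters()
  p$efficacy$rrr_aur <- 0
  p$efficacy$rrr_turp <- 0
  pd <- p$psa_distributions
  p$psa_distributions <- pd[!pd$target %in% c("rrr_aur", "rrr_turp"), ]
  s <- run_psa(p, n = 100, seed = 3)
  expect_true(all(abs(s$delta_qaly) < 1e-9))
  # the drug-price difference keeps costs apart, so no draw is
  # cost-effective at any willingness to pay
  expect_true(all(s$delta_cost > 0))
  expect_equal(compute_ceac(s, c(0, 45887, 1e6))$probability, rep(0, 3))
  expect_true(all(attr(classify_quadrant(s$delta_cost, s$delta_qaly), "tie")))
})

test_that("the acceptability curve agrees with draw-by-draw net benefit", {
  p <- base_case_parameters()
  s <- run_psa(p, n = 500, seed = 23)
  grid <- c(0, 10000, 45887, 137661)
  ce <- compute_ceac(s, grid)
  expect_true(all(ce$probability >= 0 & ce$probability <= 1))
  expect_equal(ce$probability[ce$wtp == 0], mean(s$delta_cost < 0))

  # two-path equivalence: arm-level NMB comparison per draw
  for (i in seq_along(grid)) {
    nmb_c <- net_monetary_benefit(s$cost_combination, s$qaly_combination,
                                  grid[i])
    nmb_m <- net_monetary_benefit(s$cost_monotherapy, s$qaly_monotherapy,
                                  grid[i])
    expect_equal(ce$probability[i], mean(nmb_c - nmb_m > 0))
  }
  expect_error(compute_ceac(s[0, ], grid), "empty")
})

test_that("the default willingness-to-pay grid covers the reported thresholds", {
  g <- base_case_parameters()$settings$wtp_grid
  expect_true(all(c(20000, 40000, 45887, 137661) %in% g))
})
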