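# Dose-response fitting, Cheng-Prusoff, Monte-Carlo uncertainty, Boltzmann
# melt fitting and the thermal-shift significance call.

test_that("noiseless dose-response curves are recovered exactly", {
  conc <- 1e-6 * 10^seq(-1.5, 1.5, length.out = 9)
  resp <- 1 / (1 + conc / 1e-6)
  fit <- fit_dose_response(conc, resp)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 1e-6, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-4)
  # model midpoint identity: response at [I] = IC50 is exactly 0.5
  expect_equal(1 / (1 + (fit$ic50 / fit$ic50)^fit$hill), 0.5)
})

test_that("dose-response input contracts are enforced", {
  conc <- 1e-6 * 10^seq(-1, 1, length.out = 6)
  expect_error(fit_dose_response(conc[1:4], rep(0.5, 4)), "at least 5")
  expect_error(fit_dose_response(rev(conc), rep(0.5, 6)),
               "strictly increasing")
  expect_warning(fit_dose_response(conc, seq(0.1, 0.9, length.out = 6)),
                 "not clearly decreasing")
})

test_that("cheng_prusoff identities hold", {
  cond_eq <- assay_conditions(substrate_conc = 1e-3, km = 1e-3)
  expect_equal(cheng_prusoff(1000e-9, cond_eq), 500e-9)      # [S] = Km
  cond_lo <- assay_conditions(substrate_conc = 1e-12, km = 1e-3)
  expect_equal(cheng_prusoff(1e-6, cond_lo), 1e-6, tolerance = 1e-8)
  cond <- assay_conditions(substrate_conc = 1e-3, km = 0.5e-3)
  expect_equal(cheng_prusoff(2000, cond), 2000 / 3, tolerance = 1e-12)
  # strictly decreasing in [S]/Km
  ratios <- c(0.1, 0.5, 1, 2, 10)
  kis <- sapply(ratios, function(r) {
    cheng_prusoff(1, assay_conditions(substrate_conc = r, km = 1))
  })
  expect_true(all(diff(kis) < 0))
  expect_error(cheng_prusoff(1e-6, assay_conditions()), "Km is required")
})

test_that("monte_carlo_ki propagates noise honestly", {
  cond <- assay_conditions(substrate_conc = 1e-3, km = 1e-3)
  dat <- simulate_dose_response(2e-6, hill = 1, rel_noise = 0, seed = 1)
  mc0 <- monte_carlo_ki(dat$concentration_M, dat$response, cond,
                        n_cycles = 20, rel_noise = 0, seed = 5)
  expect_equal(mc0$ki_sd, 0)
  expect_equal(mc0$ki_mean, mc0$ki, tolerance = 1e-6)
  expect_equal(mc0$ki, 1e-6, tolerance = 1e-4)   # IC50/2 at [S] = Km

  mc5 <- monte_carlo_ki(dat$concentration_M, dat$response, cond,
                        n_cycles = 60, rel_noise = 0.05, seed = 5)
  mc10 <- monte_carlo_ki(dat$concentration_M, dat$response, cond,
                         n_cycles = 60, rel_noise = 0.10, seed = 5)
  expect_gt(mc5$ki_sd, 0)
  expect_gt(mc10$ki_sd, mc5$ki_sd)   # more noise, more spread
  # deterministic under seed
  mc5b <- monte_carlo_ki(dat$concentration_M, dat$response, cond,
                         n_cycles = 60, rel_noise = 0.05, seed = 5)
  expect_identical(mc5$ki_sd, mc5b$ki_sd)
})

test_that("fits are invariant to data-point order", {
  dat <- simulate_dose_response(5e-7, hill = 1.2, rel_noise = 0.05, seed = 3)
  f1 <- fit_dose_response(dat$concentration_M, dat$response)
  # reordering must be rejected upstream (strictly increasing contract),
  # so invariance is checked through a sorted permutation of duplicates
  mc <- simulate_melt_curve(55, seed = 4)
  perm <- sample(nrow(mc))
  t1 <- fit_boltzmann_tm(mc$temperature_C, mc$fluorescence)
  t2 <- fit_boltzmann_tm(mc$temperature_C[perm], mc$fluorescence[perm])
  expect_equal(t1$tm, t2$tm, tolerance = 1e-8)
  expect_true(f1$converged)
})

test_that("Boltzmann melt fits recover Tm and flag edge cases", {
  mc <- simulate_melt_curve(55, slope = 2, rel_noise = 0, seed = 1)
  fit <- fit_boltzmann_tm(mc$temperature_C, mc$fluorescence)
  expect_true(fit$converged)
  expect_equal(fit$tm, 55, tolerance = 0.01)
  expect_equal(fit$slope, 2, tolerance = 0.01)
  expect_false(fit$at_edge)
  # model midpoint identity on the fitted curve
  mid <- fit$plateau_low +
    (fit$plateau_high - fit$plateau_low) / (1 + exp(0))
  expect_equal(mid, (fit$plateau_high + fit$plateau_low) / 2)

  edge <- simulate_melt_curve(67.6, slope = 1.5, rel_noise = 0, seed = 2)
  efit <- fit_boltzmann_tm(edge$temperature_C, edge$fluorescence)
  expect_true(efit$at_edge)

  expect_error(fit_boltzmann_tm(seq(30, 39), runif(10)), "at least 10")
})

test_that("thermal-shift significance follows the 3-SD rule", {
  call <- delta_tm_call(50.5, c(50.0, 50.1, 49.9))
  expect_equal(call$delta_tm, 0.5)
  expect_equal(call$reference_sd, 0.1)
  expect_true(call$significant)            # 0.5 > 3 x 0.1

  call0 <- delta_tm_call(50.0, c(50.0, 50.1, 49.9))
  expect_false(call0$significant)
  # zero-SD reference: any non-zero shift is significant
  call_sd0 <- delta_tm_call(50.2, c(50, 50, 50))
  expect_true(call_sd0$significant)
  expect_error(delta_tm_call(50, c(50, 50.1)), "at least 3")
})
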