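# Weighted least-squares fitting: residuals, chi-squared, self-consistency,
# recovery of the generating geometry, uncertainty sanity.

fx_gv <- table1_fixtures()$GV

test_that("residuals are zero at truth and one at one-sigma offsets", {
  prof <- simulate_profile(fx_gv$particle, fx_gv$stacking, fx_gv$ip,
                           beamline_config(noise_rel = 0))
  r0 <- profile_residuals(prof, fx_gv$particle, fx_gv$stacking, fx_gv$ip)
  expect_lt(max(abs(r0)), 1e-8)
  # shift the data by exactly one sigma
  sig <- 0.01 * prof$intensity
  prof1 <- saxs_profile(prof$q, prof$intensity + sig, sig)
  r1 <- profile_residuals(prof1, fx_gv$particle, fx_gv$stacking, fx_gv$ip)
  expect_equal(r1, rep(1, length(r1)), tolerance = 1e-10)
  # windowing and direct recomputation
  win <- c(0.5, 1.5)
  rw <- profile_residuals(prof1, fx_gv$particle, fx_gv$stacking, fx_gv$ip,
                          q_window = win)
  keep <- prof1$q >= win[1] & prof1$q <= win[2]
  expect_equal(length(rw), sum(keep))
  direct <- (prof1$intensity[keep] -
               model_intensity(prof1$q[keep], fx_gv$particle,
                               fx_gv$stacking, fx_gv$ip)) / sig[keep]
  expect_equal(rw, direct)
  expect_error(profile_residuals(prof1, fx_gv$particle, fx_gv$stacking,
                                 fx_gv$ip, q_window = c(5, 6)),
               "empty q window")
})

test_that("reduced chi-squared follows its definition", {
  expect_equal(reduced_chi2(rep(0, 100), 5), 0)
  expect_equal(reduced_chi2(rep(1, 100), 9), 100 / 91)
  expect_error(reduced_chi2(rep(1, 5), 5), "degrees of freedom")
})

test_that("noise-free self-fit recovers the generating parameters", {
  prof <- simulate_profile(fx_gv$particle, fx_gv$stacking, fx_gv$ip,
                           beamline_config(noise_rel = 0))
  fit <- suppressWarnings(fit_profile(prof, fit_config(n_starts = 1)))
  expect_true(fit$converged)
  expect_lt(fit$reduced_chi2, 1e-6)
  expect_lt(abs(fit$derived$outer_diameter_nm / 84.8 - 1), 1e-3)
  expect_lt(abs(fit$derived$multilayer_percent / 72 - 1), 1e-3)
  expect_lt(abs(fit$derived$n_layers / 2.3 - 1), 1e-3)
  expect_lt(abs(fit$parameters[["repeat_distance"]] / 6.3 - 1), 1e-3)
  # accepted optimizer steps never increase the objective
  expect_true(all(diff(fit$rsstrace) <= 1e-12 * fit$rsstrace[1]))
})

test_that("fit object methods are coherent", {
  prof <- simulate_profile(fx_gv$particle, fx_gv$stacking, fx_gv$ip,
                           beamline_config(rng_seed = 3))
  fit <- suppressWarnings(fit_profile(prof, fit_config(n_starts = 2,
                                                       rng_seed = 3)))
  expect_s3_class(fit, "saxs_fit")
  expect_named(coef(fit))
  expect_equal(dim(vcov(fit)), c(length(fit$free), length(fit$free)))
  expect_equal(length(fitted(fit)), sum(fit$window))
  expect_equal(length(residuals(fit)), sum(fit$window))
  expect_equal(fitted(fit),
               predict(fit, q = prof$q[fit$window]), tolerance = 1e-8)
  expect_output(print(fit), "outer diameter")
  expect_output(print(summary(fit)), "Reduced chi")
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "saxs_profile")
  # deterministic refit under the same config
  refit <- suppressWarnings(fit_profile(prof, fit_config(n_starts = 2,
                                                         rng_seed = 3)))
  expect_identical(coef(fit), coef(refit))
})

test_that("unilamellar convention: fixed f = 0 reports no layer number", {
  fx3 <- table1_fixtures()$LM3
  prof <- simulate_profile(fx3$particle, fx3$stacking, fx3$ip,
                           beamline_config(rng_seed = 4))
  cfg <- fit_config(free = c("core_radius_mean", "rho_core", "rho_tail",
                             "rho_polar_out", "scale", "background"),
                    fixed = list(multilayer_fraction = 0), n_starts = 2)
  fit <- suppressWarnings(fit_profile(prof, cfg))
  expect_true(is.na(fit$derived$n_layers))
  expect_equal(fit$derived$multilayer_percent, 0)
  expect_lt(abs(fit$derived$outer_diameter_nm / 67.2 - 1), 0.02)
})

test_that("recovery study reproduces the generating geometry", {
  truths <- list(GV = c(d = 84.8, f = 72, N = 2.3),
                 LM1 = c(d = 82.5, f = 40, N = 1.2),
                 LM2 = c(d = 97.1, f = 55, N = 2.2),
                 LM3 = c(d = 67.2, f = 0, N = NA),
                 LM4 = c(d = 57.4, f = 69, N = 1.7))
  for (fixture in names(truths)) {
    res <- recovery_results(fixture)
    s <- attr(res, "summary")
    tr <- truths[[fixture]]
    # outer diameter: median relative error < 2% for every formulation
    expect_lt(abs(s$median_outer_diameter_nm / tr[["d"]] - 1), 0.02,
              label = paste(fixture, "diameter"))
    expect_gte(s$n_converged, 18)
  }
  # multilayer % and N_av where the two are jointly identifiable (N > 2)
  for (fixture in c("GV", "LM2")) {
    s <- recovery_summary(fixture)
    tr <- truths[[fixture]]
    expect_lt(abs(s$median_multilayer_percent - tr[["f"]]), 10,
              label = paste(fixture, "multilayer"))
    expect_lt(abs(s$median_n_layers - tr[["N"]]), 0.3,
              label = paste(fixture, "N_av"))
  }
  # for N_av in (1, 2] the likelihood depends on (f, N) only through the
  # lamellar amplitude f (N - 1); that product is the recoverable quantity
  for (fixture in c("LM1", "LM4")) {
    res <- recovery_results(fixture)
    tr <- truths[[fixture]]
    prod_hat <- median(res$multilayer_percent / 100 * (res$n_layers - 1))
    prod_true <- tr[["f"]] / 100 * (tr[["N"]] - 1)
    tol <- 0.1 * (tr[["N"]] - 1) + 0.3 * tr[["f"]] / 100
    expect_lt(abs(prod_hat - prod_true), tol,
              label = paste(fixture, "lamellar amplitude"))
  }
})

test_that("reported 1-sigma intervals cover the truth at a sane rate", {
  res <- recovery_results("GV")
  cover <- abs(res$outer_diameter_nm - 84.8) <= res$outer_diameter_unc
  expect_gte(mean(cover), 0.5)
})

test_that("fit configuration is validated", {
  expect_error(fit_config(free = "nope"), "unknown free parameter")
  expect_error(fit_config(n_starts = 0), "n_starts")
  expect_error(fit_config(q_window = c(2, 1)), "q_window")
})
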