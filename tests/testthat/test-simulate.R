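# Orchestrated runs: reproducibility, conservation, controls, scans.

test_that("a run is a deterministic function of (config, seed)", {
  p <- small_params()
  a <- run_simulation(p, dt = 0.5, t_total = 300, t_equil = 150, seed = 9)
  b <- run_simulation(p, dt = 0.5, t_total = 300, t_equil = 150, seed = 9)
  expect_identical(a$ts, b$ts)
  expect_identical(a$final, b$final)
  c <- run_simulation(p, dt = 0.5, t_total = 300, t_equil = 150, seed = 10)
  expect_false(identical(a$ts$s1, c$ts$s1))
})

test_that("polarity factors are conserved exactly in every recorded frame", {
  p <- small_params()
  for (mode in c("normal", "homogenized", "feedback_cut")) {
    r <- run_simulation(sim_config(p, dt = 0.5, t_total = 250, seed = 2,
                                   mode = mode))
    tot <- r$ts$C_free + r$ts$C_m + r$ts$C_membrane
    expect_true(all(tot == p$pf$C_total))
  }
  # the position-tracking transport variant conserves too
  rt <- run_simulation(sim_config(p, dt = 0.5, t_total = 250, seed = 2,
                                  transport = "track"))
  expect_true(all(rt$ts$C_free + rt$ts$C_m + rt$ts$C_membrane ==
                    p$pf$C_total))
})

test_that("an empty pool yields an undefined order parameter", {
  p <- small_params(C = 0)
  r <- run_simulation(p, dt = 0.5, t_total = 200, seed = 1)
  expect_true(all(is.na(r$ts$s1)))
  expect_true(all(r$ts$C_membrane == 0))
  expect_gt(r$summary$s1_undefined_frames, 0)
})

test_that("configuration guards reject unstable step sizes", {
  p <- small_params()
  expect_error(sim_config(p, dt = 5, t_total = 100), "time step too large")
  pk <- p; pk$pf$k_u <- 2.5
  expect_error(sim_config(pk, dt = 0.5, t_total = 100),
               "k_u \\* dt")
  expect_error(sim_config(p, dt = 0.5, t_total = 100, t_equil = 200),
               "t_equil")
})

test_that("homogenized control sits on the finite-number counting floor", {
  p <- default_params(C_total = 20000, M = 200, l_half = 30)
  r <- run_homogenized(p, dt = 1, t_total = 1500, t_equil = 750, seed = 3)
  floor_exp <- sqrt(pi / (4 * r$summary$C_membrane_mean))
  expect_equal(r$summary$s1_mean, floor_exp, tolerance = 0.2)
})

test_that("delivery flux obeys the mean-field kernel in refresh transport", {
  p <- default_params(C_total = 20000, M = 200, l_half = 30)
  r <- run_simulation(p, dt = 1, t_total = 3000, t_equil = 1000, seed = 4,
                      mode = "feedback_cut")
  expect_equal(r$summary$delivery_flux, r$summary$delivery_flux_meanfield,
               tolerance = 0.03)
  # and membrane turnover balances delivery in the stationary state
  expect_equal(r$summary$delivery_flux, r$summary$unbinding_flux,
               tolerance = 0.05)
})

test_that("time-step halving leaves stationary pools unchanged (weak check)", {
  p <- small_params(C = 3000, M = 50, l_half = 7.5)
  pools <- function(dtv) {
    x <- vapply(1:3, function(s)
      run_simulation(p, dt = dtv, t_total = 2000, t_equil = 1000,
                     seed = 20 + s)$summary$C_membrane_mean, numeric(1))
    c(mean(x), stats::sd(x) / sqrt(3))
  }
  a <- pools(1); b <- pools(0.5)
  expect_lt(abs(a[1] - b[1]),
            2 * sqrt(a[2]^2 + b[2]^2) + 0.02 * a[1])
})

test_that("abundance scans label, aggregate and noise-correct", {
  p <- small_params(C = 3000, M = 50, l_half = 7.5)
  sc <- scan_abundance(p, C_values = c(1500, 3000), n_seeds = 2, seed0 = 5,
                       noise = TRUE, noise_t_total = 400,
                       dt = 1, t_total = 800, t_equil = 400)
  expect_equal(nrow(sc), 2)
  expect_true(all(diff(sc$gamma) >= 0))
  expect_equal(sc$gamma, gamma_from_C(p, c(1500, 3000)), tolerance = 1e-9)
  expect_true(all(is.finite(sc$s1_mean)))
  expect_equal(sc$s1_corrected, sc$s1_mean - sc$s1_noise)
})

test_that("ensemble statistics refuse runs from different configurations", {
  p <- small_params()
  r1 <- run_simulation(p, dt = 1, t_total = 200, seed = 1)
  r2 <- run_simulation(p, dt = 1, t_total = 200, seed = 2)
  es <- ensemble_stats(list(r1, r2))
  expect_equal(es$n, 2)
  p2 <- small_params(C = 2500)
  r3 <- run_simulation(p2, dt = 1, t_total = 200, seed = 3)
  expect_error(ensemble_stats(list(r1, r3)), "heterogeneous")
})
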