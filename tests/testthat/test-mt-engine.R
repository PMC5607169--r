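# Stochastic microtubule population dynamics against the mean-field oracle.

test_that("single-step update rules: firing, capping, flooring", {
  mt <- ref_mt_long(M = 10)
  fb <- ref_fb()
  st <- new_mt_state(10)
  # zero-probability limit: nothing happens from the empty state
  mt0 <- mt; mt0$r_nuc <- 1e-300
  out <- step_mts(st, mt0, fb, local_gamma = 0, dt = 1)
  expect_identical(out$status, st$status)
  expect_identical(out$length, st$length)
  # growth caps exactly at R and pauses
  st2 <- list(status = rep(1L, 10), length = rep(mt$R - mt$v_plus / 2, 10))
  mtg <- mt; mtg$r_cat <- 1e-300
  out2 <- step_mts(st2, mtg, fb, 0, dt = 1)
  expect_true(all(out2$status == 3L))
  expect_true(all(out2$length == mt$R))
  # shrink floors exactly at 0 and empties
  st3 <- list(status = rep(2L, 10), length = rep(mt$v_minus / 2, 10))
  mts <- mt; mts$r_res <- 1e-300
  out3 <- step_mts(st3, mts, fb, 0, dt = 1)
  expect_true(all(out3$status == 0L))
  expect_true(all(out3$length == 0))
  # rate bound on the time step is enforced
  expect_error(step_mts(st, mt, fb, 0, dt = 10), "time step too large")
  expect_error(step_mts(st, mt, fb, -1, dt = 1), "non-negative")
  # lengths remain inside [0, R] over many steps, with the state-length
  # equivalences (empty <=> 0, paused <=> R) intact
  s <- new_mt_state(50)
  set.seed(2)
  mtb <- mt_params(M = 50)
  ok_range <- ok_empty <- ok_paused <- TRUE
  for (i in 1:400) {
    s <- step_mts(s, mtb, fb, local_gamma = 1, dt = 1)
    ok_range <- ok_range && all(s$length >= 0 & s$length <= 3)
    ok_empty <- ok_empty && all((s$length == 0) == (s$status == 0L))
    ok_paused <- ok_paused && all((s$status == 3L) == (s$length == 3))
  }
  expect_true(ok_range)
  expect_true(ok_empty)
  expect_true(ok_paused)
})

test_that("long-run occupancies agree with the mean-field solution", {
  fb <- ref_fb()
  mt <- ref_mt_long(M = 400)
  sim <- simulate_mts(mt, fb, gamma = 1, dt = 0.25, t_total = 3e4,
                      t_equil = 1e4, seed = 7)
  st <- mt_stats(sim)
  expect_equal(sum(st$occ), 1, tolerance = 1e-12)
  mf <- mt_meanfield(mt, fb, 1)
  z <- (st$occ - c(mf$P_empty, mf$P_grow, mf$P_shrink, mf$P_bound)) /
    st$occ_se
  expect_true(all(abs(z) < 4))
  # empirical boundary-reach factor: arrival flux over nucleation flux
  expect_equal(st$mu_b_hat, mf$mu_b, tolerance = 0.05)
})

test_that("boundary residence times are exponential at clamped densities", {
  # fast-release parameters so that a short run collects many episodes
  mt <- mt_params(v_plus = 0.04, v_minus = 0.08, r_cat = 0.004,
                  r_res = 0.0016, r_nuc = 0.2, M = 300)
  fb <- feedback_params(r_u0 = 0.05, r_uinf = 0.01, p = 5, c_star = 100)
  for (g in c(0, Inf)) {
    rate <- if (g == 0) fb$r_u0 else fb$r_uinf
    sim <- simulate_mts(mt, fb, gamma = g, dt = 0.1, t_total = 2e4,
                        t_equil = 2e3, seed = 5, max_residence = 4000)
    res <- mt_stats(sim)$residence
    expect_gt(length(res), 500)
    ks <- suppressWarnings(stats::ks.test(res, "pexp", rate))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("life-cycle simulation recovers the stationary mean length", {
  for (mt in list(ref_mt_short(), ref_mt_long())) {
    r <- simulate_mt_lifecycles(2e4, mt, seed = 3)
    expect_lt(abs(r$mean_length - 1 / lambda_decay(mt)), 4 * r$se)
    expect_lt(r$se / r$mean_length, 0.02)
  }
  expect_error(simulate_mt_lifecycles(
    1e3, suppressWarnings(mt_params(r_cat = 1e-4, r_res = 0.01)), seed = 1),
    "diverges")
})
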