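# Polarity-factor pools: binding equilibrium, transport, membrane step.

test_that("binding equilibrium hits the saturation target and conserves", {
  set.seed(1)
  M <- 20
  pf <- new_pf_state(12000, M)
  lengths <- rep(7.5, M)            # l_tot = 150
  out <- equilibrate_binding(pf, lengths, l_half = 150)
  expect_length(out$bound_site, 6000)     # half saturation
  expect_equal(out$C_free, 6000)
  expect_true(all(out$bound_pos >= 0 &
                    out$bound_pos <= lengths[out$bound_site]))
  # no microtubules: everything stays free
  out0 <- equilibrate_binding(pf, rep(0, M), l_half = 150)
  expect_length(out0$bound_site, 0)
  expect_equal(out0$C_free, 12000)
  # infinite-affinity limit binds the whole interior pool
  outi <- equilibrate_binding(pf, lengths, l_half = 1e-12)
  expect_length(outi$bound_site, 12000)
  # surplus unbinds when the arbor shrinks
  out2 <- equilibrate_binding(out, lengths / 3, l_half = 150)
  expect_length(out2$bound_site, round(12000 * 50 / 200))
  expect_equal(out2$C_free + length(out2$bound_site), 12000)
  # stranded particles fall off a shrunken microtubule first
  out3 <- equilibrate_binding(out, c(rep(0.5, M)), l_half = 1e9)
  expect_true(all(out3$bound_pos <= 0.5))
  expect_error(equilibrate_binding(pf, lengths, l_half = -1), "negative")
  # refresh mode reaches the same target with fresh positions
  out4 <- equilibrate_binding(out, lengths, l_half = 150, refresh = TRUE)
  expect_length(out4$bound_site, 6000)
  expect_equal(out4$C_free, 6000)
})

test_that("transport delivers at paused tips and drops elsewhere", {
  M <- 8
  mt_state <- list(status = c(3L, 1L, rep(0L, M - 2)),
                   length = c(3, 1.5, rep(0, M - 2)))
  pf <- new_pf_state(10, M)
  pf$C_free <- 8L
  pf$bound_site <- c(1L, 2L)
  pf$bound_pos <- c(3 - 0.4, 1.5 - 0.4)   # both within v_m*dt of the tip
  out <- transport_and_deliver(pf, mt_state, v_m = 0.81, dt = 1)
  expect_equal(out$memb[1], 1)            # delivered at the paused site
  expect_equal(sum(out$memb), 1)
  expect_equal(out$C_free, 9)             # fell off the growing tip
  expect_length(out$bound_site, 0)
  # a particle short of the tip just advances
  pf2 <- new_pf_state(10, M)
  pf2$C_free <- 9L; pf2$bound_site <- 1L; pf2$bound_pos <- 1
  out2 <- transport_and_deliver(pf2, mt_state, v_m = 0.81, dt = 1)
  expect_equal(out2$bound_pos, 1.81)
  expect_equal(sum(out2$memb), 0)
})

test_that("membrane step: unbinding thins the pool at rate k_u", {
  M <- 40
  q <- segment_offset_probs(M, 0.02)
  set.seed(8)
  pf <- new_pf_state(5000, M)
  pf$C_free <- 0L
  pf$memb <- rep(125L, M)
  # zero unbinding and near-zero diffusion leave the counts untouched
  q0 <- segment_offset_probs(M, 1e-9)
  out <- membrane_step(pf, k_u = 0, dt = 1, offset_probs = q0)
  expect_identical(out$memb, pf$memb)
  expect_error(membrane_step(pf, k_u = 1, dt = 1, offset_probs = q),
               "configuration error")
  # exponential decay of the total with delivery switched off:
  # binomial thinning, checked against its own 3-SE band
  k_u <- 0.07; dt <- 0.5; n_steps <- 60
  cur <- pf
  for (i in seq_len(n_steps)) cur <- membrane_step(cur, k_u, dt, q)
  expected <- 5000 * (1 - k_u * dt)^n_steps
  se <- sqrt(5000 * (1 - k_u * dt)^n_steps *
               (1 - (1 - k_u * dt)^n_steps))
  expect_lt(abs(sum(cur$memb) - expected), 3 * se)
  expect_equal(sum(cur$memb) + cur$C_free, 5000)   # exact conservation
})

test_that("smoothed density averages neighbours and integrates back", {
  counts <- c(9, 0, 0, 3, 6, 0)
  M <- length(counts)
  dth <- 2 * pi / M
  c_m <- smooth_density(counts)
  expect_equal(c_m[1], (0 + 9 + 0) / (3 * dth))
  expect_equal(c_m[2], (9 + 0 + 0) / (3 * dth))
  expect_equal(c_m[6], (6 + 0 + 9) / (3 * dth))   # cyclic
  expect_equal(sum(c_m) * dth, sum(counts), tolerance = 1e-12)
  set.seed(3)
  cnt <- rpois(200, 40)
  expect_equal(sum(smooth_density(cnt)) * 2 * pi / 200, sum(cnt),
               tolerance = 1e-9)
})
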