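# Closed-form layer: dose-response, mean-field steady state, dispersion
# relation, phase boundaries and the isotropic self-consistency map.

test_that("dose-response and release rate follow the Hill form", {
  expect_equal(sigma_hill(0, 5), 1)
  expect_equal(sigma_hill(1, 5), 0.5)
  # at the activation threshold gamma = (p-1)^(-1/p) the weight is (p-1)/p
  p <- 5
  expect_equal(sigma_hill((p - 1)^(-1 / p), p), (p - 1) / p, tolerance = 1e-12)
  expect_true(all(diff(sigma_hill(seq(0, 4, 0.1), 3)) < 0))
  expect_error(sigma_hill(-0.1, 5), "non-negative")
  expect_error(sigma_hill(1, 1), "exceed 1")

  fb <- feedback_params(r_u0 = 0.04, r_uinf = 0.004, p = 5, c_star = 100)
  expect_equal(release_rate(0, fb), fb$r_u0)
  expect_equal(release_rate(1e12, fb), fb$r_uinf, tolerance = 1e-6)
  expect_equal(release_rate(fb$c_star, fb), (fb$r_u0 + fb$r_uinf) / 2)
  cb <- seq(0, 500, 10)
  expect_true(all(diff(release_rate(cb, fb)) < 0))
  expect_error(release_rate(-1, fb), "non-negative")
})

test_that("mean-field MT population matches the flux-balance closed forms", {
  fb <- ref_fb()
  # unconfined mean lengths 1/lambda for the two reference speed pairs
  expect_equal(1 / lambda_decay(ref_mt_short()), 1.785714, tolerance = 1e-6)
  expect_equal(1 / lambda_decay(ref_mt_long()), 2.513966, tolerance = 1e-6)
  # boundary-reach factors e^(-lambda R)
  mfs <- mt_meanfield(ref_mt_short(), fb, gamma = 1)
  mfl <- mt_meanfield(ref_mt_long(), fb, gamma = 1)
  expect_equal(mfs$mu_b, exp(-1.68), tolerance = 1e-6)
  expect_equal(mfl$mu_b, 0.3032, tolerance = 1e-3)
  # probabilities are a distribution, exactly
  for (g in c(0, 0.5, 1.288, 10, Inf)) {
    mf <- mt_meanfield(ref_mt_long(), fb, g)
    expect_equal(mf$P_empty + mf$P_grow + mf$P_shrink + mf$P_bound, 1,
                 tolerance = 1e-12)
    expect_true(all(c(mf$P_empty, mf$P_grow, mf$P_shrink, mf$P_bound) >= 0))
    expect_true(mf$l_tot >= 0 && mf$l_tot <= mf$mt$M * mf$mt$R)
  }
  # saturated limit pauses more and grows the arbor
  expect_gt(mt_meanfield(ref_mt_long(), fb, Inf)$P_bound,
            mt_meanfield(ref_mt_long(), fb, 0)$P_bound)
})

test_that("unbounded growth is rejected by theory but flagged at construction", {
  expect_warning(mt <- mt_params(v_plus = 0.1, v_minus = 0.045,
                                 r_cat = 0.0016, r_res = 0.0078),
                 "bounded-growth violated")
  expect_error(mt_meanfield(mt, ref_fb(), 1), "unsupported regime")
  expect_error(eta_param(mt, ref_fb()))
})

test_that("eta matches the composite closed form and its calibration", {
  mt <- ref_mt_long()
  # an independently specified rate pair known to give eta = 0.322
  fb2 <- feedback_params(r_u0 = 0.03369, r_uinf = 0.2 * 0.03369)
  expect_equal(eta_param(mt, fb2), 0.322, tolerance = 1e-3)
  # calibration round-trip at several targets
  for (eta in c(0.15, 0.322, 0.6)) {
    fb <- calibrate_feedback(mt, eta = eta, rho = 0.1)
    expect_equal(eta_param(mt, fb), eta, tolerance = 1e-10)
  }
  expect_error(calibrate_feedback(mt, eta = 0.05, rho = 0.5), "infeasible")
  # degenerate feedback contrast
  fbd <- feedback_params(r_u0 = 0.02, r_uinf = 0.02)
  expect_error(eta_param(mt, fbd), "undefined")
})

test_that("dispersion relation reproduces its closed-form limits", {
  # spot values at the reference (p, eta)
  expect_equal(omega_squared(1.288, 5, 0.322), 0.583, tolerance = 2e-3)
  expect_equal(omega_squared(1.853, 5, 0.322), -0.428, tolerance = 2e-3)
  expect_equal(omega_squared(Inf, 5, 0), 4)        # sup = p - 1
  expect_equal(omega_squared((5 - 1)^(-1 / 5), 5, 0), 0, tolerance = 1e-12)
  for (p in c(2, 3, 5, 8)) {
    # eta -> 0: positivity threshold at gamma_min = (p-1)^(-1/p),
    # supremum p - 1 approached at large gamma
    gmin <- (p - 1)^(-1 / p)
    expect_equal(omega_squared(gmin, p, 0), 0, tolerance = 1e-9)
    expect_lt(omega_squared(gmin * (1 - 1e-4), p, 0), 0)
    expect_gt(omega_squared(gmin * (1 + 1e-4), p, 0), 0)
    expect_equal(omega_squared(1e6, p, 0), p - 1, tolerance = 1e-9)
    # eta_max = (p-1)^2/(4p): positive Omega^2 exists iff eta below it
    eta_max <- (p - 1)^2 / (4 * p)
    gg <- exp(seq(log(1e-3), log(1e5), length.out = 20001))
    expect_gt(max(omega_squared(gg, p, eta_max * (1 - 1e-6))), 0)
    expect_lt(max(omega_squared(gg, p, eta_max * (1 + 1e-6))), 0)
    # and the analytic supremum dominates the grid
    crit <- polarization_criteria(p, eta_max / 2)
    expect_gte(crit$omega_sq_sup + 1e-12,
               max(omega_squared(gg, p, eta_max / 2)))
    expect_equal(crit$eta_max, eta_max)
    expect_equal(crit$gamma_min, gmin)
  }
  # mode bound: 3D unipolar mode at eta -> 0 gives delta_max = (p-1)/2
  expect_equal(polarization_criteria(5, 0, dim = 3, mode_n = 1)$delta_max, 2)
  expect_equal(polarization_criteria(5, 0, dim = 2, mode_n = 1)$delta_max, 4)
  expect_equal(polarization_criteria(3, 0, dim = 3, mode_n = 2)$lap_eig, 6)
})

test_that("phase boundary brackets the polarized window", {
  # reference case: roots bracket the printed polarized/saturated snapshots
  r <- phase_boundary(p = 5, eta = 0.322, delta = 0.286, dim = 2, mode_n = 1)
  expect_length(r, 2)
  expect_gt(r[1], 0.90); expect_lt(r[1], 0.95)
  expect_gt(r[2], 1.40); expect_lt(r[2], 1.50)
  # the roots solve the marginal condition to high accuracy
  expect_equal(omega_squared(r, 5, 0.322), rep(0.286, 2), tolerance = 1e-8)
  # infeasible eta: empty
  expect_length(phase_boundary(5, 0.9, 0.1), 0)
  # delta -> 0 converges to the zeros of Omega^2
  z <- phase_boundary(5, 0.322, 1e-12)
  expect_equal(omega_squared(z, 5, 0.322), c(0, 0), tolerance = 1e-9)
  # window shrinks to a point as eta approaches eta_max (continuation)
  prev_width <- Inf
  for (f in c(0.5, 0.9, 0.99, 0.999)) {
    rr <- phase_boundary(5, 0.8 * f, 1e-9)
    expect_length(rr, 2)
    expect_lt(diff(rr), prev_width)
    prev_width <- diff(rr)
  }
  expect_lt(prev_width, 0.05)
  # eta = 0: single (lower) root, the upper boundary receding to infinity
  r0 <- phase_boundary(5, 0, 0.5)
  expect_length(r0, 1)
  expect_equal(omega_squared(r0, 5, 0), 0.5, tolerance = 1e-8)
})

test_that("isotropic self-consistency map behaves and matches the reference labels", {
  p <- default_params(C_total = 37000)
  # empty pool and no delivery collapse to the trivial fixed point
  p0 <- p; p0$pf$C_total <- 0L
  expect_equal(isotropic_solution(p0)$roots$C_b, 0)
  pv <- p; pv$pf$v_m <- 1e-12
  expect_lt(isotropic_solution(pv)$roots$gamma[1], 1e-6)
  # gamma label is non-decreasing in the total abundance
  Cs <- seq(5000, 60000, length.out = 8)
  expect_true(all(diff(gamma_from_C(p, Cs)) >= 0))
  # the three reference abundances map onto the snapshot densities
  g <- gamma_from_C(p, c(30000, 37000, 50000))
  expect_equal(g, c(0.923, 1.288, 1.853), tolerance = 0.01)
  # interior pools are consistent at the fixed point
  iso <- isotropic_solution(p)$roots[1, ]
  expect_equal(iso$C_b + iso$C_int, 37000, tolerance = 1e-6)
  expect_equal(iso$C_m, iso$C_int * iso$l_tot / (p$pf$l_half + iso$l_tot),
               tolerance = 1e-6)
  expect_true(iso$stable)
})

test_that("isotropic solution is invariant under M <-> l_half compensation", {
  for (C in c(30000, 37000, 50000)) {
    a <- default_params(C_total = C, M = 1000, l_half = 150)
    b <- default_params(C_total = C, M = 100, l_half = 15)
    ga <- isotropic_solution(a)$roots$gamma[1]
    gb <- isotropic_solution(b)$roots$gamma[1]
    expect_equal(ga, gb, tolerance = 1e-9)
  }
})

test_that("numerical linearization of the membrane balance recovers Omega^2", {
  for (C in c(30000, 37000, 50000)) {
    p <- default_params(C_total = C, M = 400, l_half = 60)
    chk <- omega_squared_numeric(p, mode_n = 1)
    expect_lt(chk$residual, 1e-8)
    expect_equal(chk$omega_sq_numeric, chk$omega_sq_analytic,
                 tolerance = 1e-6)
  }
  # higher modes see the same reaction eigenvalue
  p <- default_params(C_total = 37000, M = 400, l_half = 60)
  chk2 <- omega_squared_numeric(p, mode_n = 3)
  expect_equal(chk2$omega_sq_numeric, chk2$omega_sq_analytic,
               tolerance = 1e-6)
})

test_that("dispersion table flags the unstable window", {
  tab <- dispersion_table(5, 0.322, 0.286, gamma = seq(0.5, 2, 0.005))
  r <- phase_boundary(5, 0.322, 0.286)
  expect_identical(tab$polarized, tab$gamma > r[1] & tab$gamma < r[2])
})
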