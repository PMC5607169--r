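# Canonical parameter sets and independent oracles shared across tests.

# reference dynamic-instability speed pairs (short and long mean length)
ref_mt_short <- function(M = 1000) mt_params(v_plus = 0.013, v_minus = 0.040,
                                             M = M)
ref_mt_long <- function(M = 1000) mt_params(v_plus = 0.018, v_minus = 0.045,
                                            M = M)

# feedback calibrated on the long-length set (the reference configuration)
ref_fb <- function() calibrate_feedback(mt_params())

# a deliberately small system for fast orchestration tests
small_params <- function(C = 2000, M = 50, l_half = 7.5)
  default_params(C_total = C, M = M, l_half = l_half)

# Independent oracle for diffusion on the circle: the wrapped normal of
# variance 2*Ddt as a sum of Gaussian images (the dual representation of
# the heat kernel used by circle_diffusion_cdf()).
wrapped_normal_cdf <- function(q, Ddt, kmax = 50) {
  s <- sqrt(2 * Ddt)
  acc <- numeric(length(q))
  for (k in -kmax:kmax)
    acc <- acc + stats::pnorm((q - 2 * pi * k) / s) -
      stats::pnorm(-2 * pi * k / s)
  acc
}
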