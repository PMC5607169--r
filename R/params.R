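# Parameter containers for the microtubule / polarity-factor model.

#' Microtubule dynamic-instability parameters
#'
#' Bundles the microscopic parameters of the two-state dynamic-instability
#' model together with the cell geometry: growth speed `v_plus` and shrink
#' speed `v_minus` (um/s), catastrophe rate `r_cat` and rescue rate `r_res`
#' (1/s), the firing rate `r_nuc` (1/s) of an empty nucleation site, the cell
#' radius `R` (um) and the number `M` of single-microtubule nucleation sites
#' on the central centrosome.
#'
#' In the bounded-growth regime the decay constant
#' \eqn{\lambda = r_{cat}/v_+ - r_{res}/v_-} is positive and the unconfined
#' stationary length distribution is exponential with mean \eqn{1/\lambda}.
#' `lambda <= 0` (unbounded growth) is accepted -- the cell boundary still
#' caps all lengths in simulation -- but triggers a "bounded-growth violated"
#' warning because the closed-form mean-field theory does not apply there.
#'
#' @param R cell radius (um).
#' @param v_plus,v_minus growth and shrink speeds (um/s).
#' @param r_cat,r_res catastrophe and rescue rates (1/s).
#' @param r_nuc nucleation firing rate per empty site (1/s).
#' @param M number of nucleation sites (integer, at least 3).
#' @return an object of class `mt_params`.
#' @seealso [lambda_decay()], [mt_meanfield()]
#' @export
#' @examples
#' mt <- mt_params(v_plus = 0.013, v_minus = 0.040)
#' 1 / lambda_decay(mt)  # mean unconfined MT length (um)
mt_params <- function(R = 3, v_plus = 0.018, v_minus = 0.045,
                      r_cat = 0.0078, r_res = 0.0016, r_nuc = 0.05,
                      M = 1000) {
  stopifnot(is.numeric(R), R > 0, v_plus > 0, v_minus > 0,
            r_cat > 0, r_res > 0, r_nuc > 0,
            length(M) == 1, M >= 3, M == as.integer(M))
  x <- structure(list(R = R, v_plus = v_plus, v_minus = v_minus,
                      r_cat = r_cat, r_res = r_res, r_nuc = r_nuc,
                      M = as.integer(M)),
                 class = "mt_params")
  if (lambda_decay(x) <= 0)
    warning("bounded-growth violated: r_cat/v_plus - r_res/v_minus <= 0; ",
            "closed-form mean-field results are unavailable for this set ",
            "(simulated lengths are still capped at R)", call. = FALSE)
  x
}

#' Length-distribution decay constant
#'
#' \eqn{\lambda = r_{cat}/v_+ - r_{res}/v_-} (1/um). Positive in the
#' bounded-growth regime, where the unconfined mean length is `1/lambda`.
#'
#' @param mt an [mt_params()] object.
#' @return numeric scalar (1/um).
#' @export
lambda_decay <- function(mt) mt$r_cat / mt$v_plus - mt$r_res / mt$v_minus

#' Feedback (dose-response) parameters
#'
#' The boundary release rate of a stalled microtubule interpolates between
#' `r_u0` (no polarity factor present) and the lower saturated value `r_uinf`
#' through a Hill dose-response in the local membrane density, with Hill
#' coefficient `p` and density scale `c_star` (polarity factors per radian of
#' boundary).
#'
#' @param r_u0 release rate at zero polarity-factor density (1/s).
#' @param r_uinf saturated release rate (1/s), `0 < r_uinf <= r_u0`.
#' @param p Hill coefficient (> 1).
#' @param c_star density scale (PF per radian). The default corresponds to a
#'   full-circle scale of `2*pi*c_star = 20000` polarity factors.
#' @return an object of class `feedback_params`.
#' @seealso [release_rate()], [calibrate_feedback()]
#' @export
feedback_params <- function(r_u0, r_uinf, p = 5, c_star = 20000 / (2 * pi)) {
  stopifnot(r_u0 > 0, r_uinf > 0, r_uinf <= r_u0, p > 1, c_star > 0)
  structure(list(r_u0 = r_u0, r_uinf = r_uinf, p = p, c_star = c_star),
            class = "feedback_params")
}

#' Polarity-factor transport and membrane parameters
#'
#' @param v_m plus-end-directed transport speed along a microtubule (um/s).
#' @param k_u membrane unbinding (recycling) rate (1/s).
#' @param D_ang angular membrane diffusion constant (rad^2/s). The
#'   mean-square angular displacement before unbinding is
#'   `delta = D_ang/k_u`.
#' @param l_half microtubule-binding affinity half-length (um): with total
#'   microtubule length `l_tot`, a fraction `l_tot/(l_half + l_tot)` of the
#'   interior pool is microtubule-bound at equilibrium.
#' @param C_total conserved total number of polarity factors (count).
#' @return an object of class `pf_params`.
#' @export
pf_params <- function(v_m = 0.81, k_u = 0.07, D_ang = 0.02,
                      l_half = 150, C_total = 37000) {
  stopifnot(v_m > 0, k_u > 0, D_ang > 0, l_half > 0,
            C_total >= 0, C_total == as.integer(C_total))
  structure(list(v_m = v_m, k_u = k_u, D_ang = D_ang,
                 l_half = l_half, C_total = as.integer(C_total)),
            class = "pf_params")
}

#' Full model parameter bundle
#'
#' @param mt an [mt_params()] object.
#' @param fb a [feedback_params()] object.
#' @param pf a [pf_params()] object.
#' @return an object of class `model_params`.
#' @export
model_params <- function(mt = mt_params(), fb = calibrate_feedback(mt),
                         pf = pf_params()) {
  stopifnot(inherits(mt, "mt_params"), inherits(fb, "feedback_params"),
            inherits(pf, "pf_params"))
  structure(list(mt = mt, fb = fb, pf = pf), class = "model_params")
}

#' Calibrate the feedback rates to a target competition parameter
#'
#' The absolute boundary-release rates are not independently constrained by
#' the dimensionless theory; what matters is the competition parameter
#' `eta` and the ratio `rho = r_uinf/r_u0`. Given a microtubule parameter
#' set, this solves the closed-form expression for `eta` for `r_u0`:
#' \deqn{r_{u0} = \frac{\mu_b r_{nuc}}{(1+\mu_i)\,(\eta(1-\rho) - \rho)}}
#' and sets `r_uinf = rho * r_u0`. The default `eta = 0.322`, `rho = 0.1`
#' reproduces the reference abundance-to-density mapping of the isotropic
#' state (see the methods vignette).
#'
#' @param mt an [mt_params()] object.
#' @param eta target competition parameter (> 0).
#' @param rho ratio `r_uinf/r_u0` in (0, 1); must satisfy
#'   `eta * (1 - rho) > rho`.
#' @param p,c_star passed to [feedback_params()].
#' @return a [feedback_params()] object.
#' @export
#' @examples
#' fb <- calibrate_feedback(mt_params(), eta = 0.322, rho = 0.1)
#' fb$r_u0
calibrate_feedback <- function(mt, eta = 0.322, rho = 0.1, p = 5,
                               c_star = 20000 / (2 * pi)) {
  stopifnot(inherits(mt, "mt_params"), eta > 0, rho > 0, rho < 1)
  lam <- lambda_decay(mt)
  if (lam <= 0)
    stop("calibrate_feedback() requires the bounded-growth regime (lambda > 0)")
  mu_b <- exp(-lam * mt$R)
  mu_i <- mt$r_nuc * (1 / mt$v_plus + 1 / mt$v_minus) * (1 - mu_b) / lam
  denom <- eta * (1 - rho) - rho
  if (denom <= 0)
    stop("infeasible calibration: need eta * (1 - rho) > rho")
  r_u0 <- mu_b * mt$r_nuc / ((1 + mu_i) * denom)
  feedback_params(r_u0 = r_u0, r_uinf = rho * r_u0, p = p, c_star = c_star)
}

#' Reference parameter set
#'
#' The full default parameter bundle: cell radius 3 um, dynamic-instability
#' speeds 0.018/0.045 um/s, catastrophe/rescue 0.0078/0.0016 1/s, nucleation
#' 0.05 1/s, transport 0.81 um/s, membrane unbinding 0.07 1/s, angular
#' diffusion 0.02 rad^2/s (so `delta = 0.286`), density scale
#' `2*pi*c_star = 20000`, and feedback rates calibrated to `eta = 0.322`
#' with `rho = 0.1`.
#'
#' @param C_total total polarity-factor count.
#' @param M number of nucleation sites (and membrane segments).
#' @param l_half binding half-length (um). When scaling `M` down, scale
#'   `l_half` down by the same factor to keep the effective delivery rate
#'   invariant.
#' @param eta,rho calibration targets, see [calibrate_feedback()].
#' @param D_ang angular diffusion constant (rad^2/s).
#' @param p Hill coefficient.
#' @param ... further overrides passed to [mt_params()].
#' @return a [model_params()] bundle.
#' @export
default_params <- function(C_total = 37000, M = 1000, l_half = 150,
                           eta = 0.322, rho = 0.1, D_ang = 0.02, p = 5, ...) {
  mt <- mt_params(M = M, ...)
  fb <- calibrate_feedback(mt, eta = eta, rho = rho, p = p)
  pf <- pf_params(D_ang = D_ang, l_half = l_half, C_total = C_total)
  model_params(mt, fb, pf)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Microtubule polarity model parameters\n")
  cat(sprintf("  cell: R = %g um, M = %d nucleation sites\n", x$mt$R, x$mt$M))
  cat(sprintf("  MT:   v+ = %g, v- = %g um/s; r_cat = %g, r_res = %g, r_nuc = %g 1/s\n",
              x$mt$v_plus, x$mt$v_minus, x$mt$r_cat, x$mt$r_res, x$mt$r_nuc))
  lam <- lambda_decay(x$mt)
  if (lam > 0)
    cat(sprintf("        lambda = %.4g 1/um (mean free length %.4g um)\n",
                lam, 1 / lam))
  cat(sprintf("  feedback: r_u0 = %.4g, r_uinf = %.4g 1/s; p = %g; 2*pi*c* = %g\n",
              x$fb$r_u0, x$fb$r_uinf, x$fb$p, 2 * pi * x$fb$c_star))
  cat(sprintf("  PF:   v_m = %g um/s, k_u = %g 1/s, D = %g rad^2/s (delta = %.4g)\n",
              x$pf$v_m, x$pf$k_u, x$pf$D_ang, x$pf$D_ang / x$pf$k_u))
  cat(sprintf("        l_half = %g um, C_total = %d\n",
              x$pf$l_half, x$pf$C_total))
  if (lam > 0)
    cat(sprintf("  eta = %.4g\n", eta_param(x$mt, x$fb)))
  invisible(x)
}
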