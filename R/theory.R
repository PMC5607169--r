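# Mean-field steady state, dispersion relation and phase boundaries.

#' Hill dose-response function
#'
#' \eqn{\sigma(\gamma) = 1/(1 + \gamma^p)}: the weight interpolating the
#' boundary release rate between its zero-density and saturated values.
#' Strictly decreasing in `gamma` with range (0, 1].
#'
#' @param gamma reduced polarity-factor density (dimensionless, >= 0; may be
#'   `Inf`).
#' @param p Hill coefficient (> 1).
#' @return numeric vector of the same length as `gamma`.
#' @export
sigma_hill <- function(gamma, p) {
  if (any(gamma < 0, na.rm = TRUE)) stop("gamma must be non-negative")
  if (p <= 1) stop("Hill coefficient p must exceed 1")
  1 / (1 + gamma^p)
}

#' Boundary release rate of a stalled microtubule
#'
#' \eqn{r_u(c_b) = (r_{u0} - r_{u\infty})\,\sigma(c_b/c_*) + r_{u\infty}},
#' monotone decreasing in the local membrane density `c_b` and bounded in
#' `[r_uinf, r_u0]`.
#'
#' @param c_b local membrane density (polarity factors per radian, >= 0).
#' @param fb a [feedback_params()] object.
#' @return release rate(s) (1/s).
#' @export
release_rate <- function(c_b, fb) {
  if (any(c_b < 0, na.rm = TRUE)) stop("membrane density must be non-negative")
  (fb$r_u0 - fb$r_uinf) * sigma_hill(c_b / fb$c_star, fb$p) + fb$r_uinf
}

# Vectorised per-site mean-field quantities at fixed reduced density gamma.
# Returns state probabilities, per-site expected MT length and r_u(gamma).
mf_site <- function(mt, fb, gamma) {
  lam <- lambda_decay(mt)
  if (lam <= 0)
    stop("unsupported regime: mean-field closed forms require lambda > 0")
  mu_b <- exp(-lam * mt$R)
  mu_i <- mt$r_nuc * (1 / mt$v_plus + 1 / mt$v_minus) * (1 - mu_b) / lam
  r_u <- ifelse(is.infinite(gamma), fb$r_uinf, release_rate(gamma * fb$c_star, fb))
  A <- mt$r_nuc * mu_b / r_u
  P_empty <- 1 / (1 + mu_i + A)
  phi <- mt$r_nuc * P_empty                     # per-site nucleation flux (1/s)
  P_grow <- phi * (1 - mu_b) / (lam * mt$v_plus)
  P_shrink <- phi * (1 - mu_b) / (lam * mt$v_minus)
  P_bound <- P_empty * A
  l_int <- phi * (1 / mt$v_plus + 1 / mt$v_minus) *
    (1 - (1 + lam * mt$R) * mu_b) / lam^2
  list(lambda = lam, mu_b = mu_b, mu_i = mu_i, r_u = r_u,
       P_empty = P_empty, P_grow = P_grow, P_shrink = P_shrink,
       P_bound = P_bound, l_site = l_int + mt$R * P_bound)
}

#' Competition parameter eta
#'
#' \deqn{\eta = \frac{r_{u\infty}/r_{u0} + \mu_b r_{nuc}/((1+\mu_i) r_{u0})}
#'                  {1 - r_{u\infty}/r_{u0}}}
#' with the boundary-reach factor \eqn{\mu_b = e^{-\lambda R}} and interior
#' time factor \eqn{\mu_i = r_{nuc}(1/v_+ + 1/v_-)(1 - e^{-\lambda R})/\lambda}.
#' Small `eta` means stabilised boundary microtubules enjoy a large
#' competitive advantage.
#'
#' @param mt an [mt_params()] object (bounded-growth regime required).
#' @param fb a [feedback_params()] object with `r_uinf < r_u0`.
#' @return numeric scalar (> 0).
#' @export
eta_param <- function(mt, fb) {
  if (fb$r_uinf >= fb$r_u0)
    stop("eta is undefined for r_uinf = r_u0 (no feedback contrast)")
  s <- mf_site(mt, fb, gamma = 0)
  rho <- fb$r_uinf / fb$r_u0
  (rho + s$mu_b * mt$r_nuc / ((1 + s$mu_i) * fb$r_u0)) / (1 - rho)
}

#' Mean-field steady state of the microtubule population
#'
#' Solves the stationary two-state transport equations for a single
#' nucleation site with boundary pausing at radius `R` and
#' density-dependent release, at a fixed reduced membrane density `gamma`.
#' Zero net radial flux forces \eqn{v_+ m_+(r) = v_- m_-(r)} and an
#' exponential profile \eqn{m_\pm(r) \propto e^{-\lambda r}}, from which the
#' state probabilities, the per-site and total expected microtubule length
#' and the composite parameters \eqn{\mu_b}, \eqn{\mu_i}, \eqn{\eta} follow
#' in closed form.
#'
#' @param mt an [mt_params()] object; requires `lambda_decay(mt) > 0`.
#' @param fb a [feedback_params()] object.
#' @param gamma reduced membrane density (scalar, >= 0, may be `Inf`).
#' @return an object of class `mt_meanfield`: a list with the stationary
#'   state probabilities `P_empty`, `P_grow`, `P_shrink`, `P_bound` (which
#'   sum to one exactly), the total expected length `l_tot` (um, all `M`
#'   sites), `mean_length_free = 1/lambda`, `mu_b`, `mu_i`, `eta` and the
#'   input `gamma`.
#' @export
#' @examples
#' mt <- mt_params(v_plus = 0.013, v_minus = 0.040)
#' mf <- mt_meanfield(mt, calibrate_feedback(mt), gamma = 1)
#' mf$mean_length_free  # 1/lambda = 1.786 um
mt_meanfield <- function(mt, fb, gamma) {
  stopifnot(length(gamma) == 1, gamma >= 0)
  s <- mf_site(mt, fb, gamma)
  structure(list(gamma = gamma,
                 P_empty = s$P_empty, P_grow = s$P_grow,
                 P_shrink = s$P_shrink, P_bound = s$P_bound,
                 l_site = s$l_site, l_tot = mt$M * s$l_site,
                 mean_length_free = 1 / s$lambda,
                 mu_b = s$mu_b, mu_i = s$mu_i, r_u = s$r_u,
                 eta = if (fb$r_uinf < fb$r_u0) eta_param(mt, fb) else NA_real_,
                 mt = mt, fb = fb),
            class = "mt_meanfield")
}

#' @export
print.mt_meanfield <- function(x, ...) {
  cat(sprintf("Mean-field MT population at gamma = %g\n", x$gamma))
  cat(sprintf("  P(empty, grow, shrink, paused) = %.4f %.4f %.4f %.4f\n",
              x$P_empty, x$P_grow, x$P_shrink, x$P_bound))
  cat(sprintf("  l_tot = %.4g um (%d sites); free mean length = %.4g um\n",
              x$l_tot, x$mt$M, x$mean_length_free))
  cat(sprintf("  mu_b = %.4g, mu_i = %.4g, eta = %.4g\n",
              x$mu_b, x$mu_i, x$eta))
  invisible(x)
}

#' Squared angular wavenumber of the membrane perturbation equation
#'
#' Linearising the membrane reaction-diffusion balance around the isotropic
#' state (perturbations of the global pools vanish for mode numbers
#' `n >= 1`) yields a Helmholtz equation whose squared wavenumber is
#' \deqn{\Omega^2(\gamma) = \frac{p\,\gamma^p}
#'   {(1+\gamma^p)\,(1 + \eta\,(1+\gamma^p))} - 1
#'   \;=\; \gamma \,\frac{d \ln m_b}{d\gamma} - 1.}
#' A mode with Laplacian eigenvalue `L` (`n^2` on the circle,
#' `n(n+1)` on the sphere) is unstable -- i.e. the system polarises -- when
#' \eqn{\Omega^2 > L\,\delta} with `delta = D_ang/k_u`.
#'
#' @param gamma reduced mean membrane density (vectorised, >= 0, may be
#'   `Inf`).
#' @param p Hill coefficient (> 1).
#' @param eta competition parameter (>= 0; `eta = 0` is the limit of
#'   maximally advantaged boundary microtubules).
#' @return numeric vector.
#' @seealso [polarization_criteria()], [phase_boundary()],
#'   [omega_squared_numeric()]
#' @export
omega_squared <- function(gamma, p, eta) {
  if (any(gamma < 0, na.rm = TRUE)) stop("gamma must be non-negative")
  if (p <= 1) stop("Hill coefficient p must exceed 1")
  if (eta < 0) stop("eta must be non-negative")
  x <- gamma^p
  out <- p * x / ((1 + x) * (1 + eta * (1 + x))) - 1
  inf <- is.infinite(x)
  if (any(inf)) out[inf] <- if (eta > 0) -1 else p - 1
  out
}

# Laplacian eigenvalue of angular mode n in dimension dim (2: circle,
# 3: sphere).
lap_eigenvalue <- function(mode_n, dim = 2) {
  stopifnot(mode_n >= 1, mode_n == as.integer(mode_n), dim %in% c(2, 3))
  if (dim == 2) mode_n^2 else mode_n * (mode_n + 1)
}

# Supremum of omega_squared over gamma at fixed (p, eta).
omega_squared_sup <- function(p, eta) {
  if (eta == 0) return(p - 1)
  x_star <- sqrt(1 + 1 / eta)          # maximiser of Omega^2 in x = gamma^p
  p * x_star / ((1 + x_star) * (1 + eta * (1 + x_star))) - 1
}

#' Necessary conditions for spontaneous polarization
#'
#' Computes the closed-form feasibility bounds on the four effective
#' parameters: `eta_max = (p-1)^2/(4p)`, the zero-`eta` activation threshold
#' `gamma_min = (p-1)^(-1/p)`, `p_min = 1`, and the mode-dependent bound
#' `delta_max = sup_gamma Omega^2 / L` with Laplacian eigenvalue `L` (for the
#' unipolar spherical mode `n = 1`, `dim = 3`, at `eta -> 0` this is
#' `(p-1)/2`).
#'
#' @param p Hill coefficient (> 1).
#' @param eta competition parameter (>= 0).
#' @param delta mean-square angular displacement before unbinding
#'   (`D_ang/k_u`); `NA` to report bounds only.
#' @param dim 2 (circle) or 3 (sphere).
#' @param mode_n angular mode number (>= 1).
#' @return a list with `eta_max`, `gamma_min`, `p_min`, `lap_eig`,
#'   `omega_sq_sup`, `delta_max` and the boolean `feasible`.
#' @export
polarization_criteria <- function(p, eta = 0, delta = NA, dim = 2, mode_n = 1) {
  stopifnot(p > 1, eta >= 0)
  lap <- lap_eigenvalue(mode_n, dim)
  sup <- omega_squared_sup(p, eta)
  res <- list(eta_max = (p - 1)^2 / (4 * p),
              gamma_min = (p - 1)^(-1 / p),
              p_min = 1,
              lap_eig = lap,
              omega_sq_sup = sup,
              delta_max = max(sup, 0) / lap)
  res$feasible <- (eta < res$eta_max) &&
    (is.na(delta) || delta < res$delta_max)
  res
}

#' Phase boundary: roots of the marginal-stability condition
#'
#' Solves \eqn{\Omega^2(\gamma) = L\,\delta} for `gamma`, where `L` is the
#' Laplacian eigenvalue of the requested mode. `Omega^2` is unimodal in
#' `gamma`, so there are 0, 1 or 2 solutions; two roots delimit the
#' reentrant polarization window.
#'
#' @param p Hill coefficient (> 1).
#' @param eta competition parameter (>= 0).
#' @param delta mean-square angular displacement before unbinding (>= 0).
#' @param dim,mode_n mode selection: Laplacian eigenvalue `mode_n^2` on the
#'   circle (`dim = 2`) or `mode_n*(mode_n+1)` on the sphere (`dim = 3`).
#' @param tol relative root tolerance.
#' @return a sorted numeric vector of roots (possibly empty). With `eta = 0`
#'   the upper boundary recedes to infinite density and only the lower root
#'   is returned.
#' @export
#' @examples
#' phase_boundary(p = 5, eta = 0.322, delta = 0.286)
phase_boundary <- function(p, eta, delta, dim = 2, mode_n = 1, tol = 1e-10) {
  stopifnot(p > 1, eta >= 0, delta >= 0)
  target <- lap_eigenvalue(mode_n, dim) * delta
  f <- function(lx) omega_squared(exp(lx / p), p, eta) - target
  # maximiser in x = gamma^p
  x_star <- if (eta == 0) Inf else sqrt(1 + 1 / eta)
  if (is.finite(x_star)) {
    if (omega_squared(x_star^(1 / p), p, eta) < target) return(numeric(0))
    lx_star <- log(x_star)
  }
  roots <- numeric(0)
  # lower root: Omega^2 -> -1 as gamma -> 0
  lo <- if (is.finite(x_star)) lx_star else log(1e3)
  while (f(lo) < 0 && lo < 700) lo <- lo + 1   # eta = 0: walk up to the sup
  if (f(lo) >= 0) {
    lo_left <- lo - 1
    while (f(lo_left) > 0) lo_left <- lo_left - 5
    r <- stats::uniroot(f, c(lo_left, lo), tol = tol * 1e-2)$root
    roots <- c(roots, exp(r / p))
    # upper root only exists for eta > 0
    if (is.finite(x_star)) {
      hi <- lx_star + 1
      while (f(hi) > 0) hi <- hi + 5
      r2 <- stats::uniroot(f, c(lx_star, hi), tol = tol * 1e-2)$root
      roots <- c(roots, exp(r2 / p))
    }
  }
  sort(roots)
}

#' Isotropic steady state: membrane pool self-consistency
#'
#' The isotropic steady state balances membrane unbinding against delivery:
#' \deqn{k_u C_b = v_m \frac{C_m}{l_{tot}} M_b(\bar\gamma),}
#' with \eqn{C_m = C_{int}\, l_{tot}/(l_{1/2}+l_{tot})},
#' \eqn{C_{int} = C - C_b}, \eqn{\bar\gamma = C_b/(2\pi c_*)} and
#' \eqn{M_b = M P_{bound}(\bar\gamma)}. All fixed points of the net membrane
#' flux on `[0, C_total]` are located by a sign-change scan followed by
#' bisection, and classified by the sign of the flux derivative (negative =
#' locally stable). Starting from an empty membrane the simulation relaxes
#' to the first root, which is used to label an abundance `C` with its
#' reduced density `gamma` (see [gamma_from_C()]).
#'
#' @param params a [model_params()] bundle.
#' @param n_grid number of scan points for root bracketing.
#' @return an object of class `isotropic_solution`: a list whose `roots`
#'   element is a data frame with one row per fixed point (`C_b`, `gamma`,
#'   `C_int`, `C_m`, `C_free`, `l_tot`, `M_paused`, `stable`).
#' @export
isotropic_solution <- function(params, n_grid = 512) {
  mt <- params$mt; fb <- params$fb; pf <- params$pf
  C <- pf$C_total
  net <- function(C_b) {
    g <- C_b / (2 * pi * fb$c_star)
    s <- mf_site(mt, fb, g)
    l_tot <- mt$M * s$l_site
    C_int <- C - C_b
    influx <- pf$v_m * C_int / (pf$l_half + l_tot) * mt$M * s$P_bound
    influx - pf$k_u * C_b
  }
  describe <- function(C_b) {
    g <- C_b / (2 * pi * fb$c_star)
    s <- mf_site(mt, fb, g)
    l_tot <- mt$M * s$l_site
    C_int <- C - C_b
    C_m <- C_int * l_tot / (pf$l_half + l_tot)
    h <- max(C, 1) * 1e-7
    dnet <- (net(min(C_b + h, C)) - net(max(C_b - h, 0))) /
      (min(C_b + h, C) - max(C_b - h, 0))
    data.frame(C_b = C_b, gamma = g, C_int = C_int, C_m = C_m,
               C_free = C_int - C_m, l_tot = l_tot,
               M_paused = mt$M * s$P_bound, stable = dnet < 0)
  }
  if (C == 0)
    return(structure(list(roots = describe(0), params = params),
                     class = "isotropic_solution"))
  grid <- seq(0, C, length.out = n_grid)
  v <- vapply(grid, net, numeric(1))
  if (v[1] < 0)
    stop("internal error: net influx at empty membrane should be positive")
  roots <- numeric(0)
  if (v[1] == 0) roots <- 0   # v_m = 0 edge: no delivery at all
  sgn <- sign(v)
  for (i in seq_len(n_grid - 1)) {
    if (sgn[i] != 0 && sgn[i + 1] != 0 && sgn[i] != sgn[i + 1]) {
      r <- stats::uniroot(net, c(grid[i], grid[i + 1]), tol = 1e-10 * max(C, 1))
      roots <- c(roots, r$root)
    } else if (sgn[i + 1] == 0 && i + 1 < n_grid) {
      roots <- c(roots, grid[i + 1])
    }
  }
  if (length(roots) == 0)
    stop("internal error: no isotropic fixed point found")
  structure(list(roots = do.call(rbind, lapply(roots, describe)),
                 params = params),
            class = "isotropic_solution")
}

#' @export
print.isotropic_solution <- function(x, ...) {
  cat(sprintf("Isotropic steady state(s) for C_total = %d\n",
              x$params$pf$C_total))
  print(x$roots, row.names = FALSE)
  invisible(x)
}

#' Label abundances with their isotropic reduced membrane density
#'
#' Maps total polarity-factor numbers `C` to the reduced density
#' `gamma = C_b/(2 pi c_star)` of the isotropic fixed point reached from an
#' empty membrane (the first, stable root). `gamma` is non-decreasing in
#' `C`.
#'
#' @param params a [model_params()] bundle (its `C_total` is ignored).
#' @param C vector of total polarity-factor counts.
#' @return numeric vector of reduced densities.
#' @export
gamma_from_C <- function(params, C) {
  vapply(C, function(Ci) {
    p <- params
    p$pf$C_total <- as.integer(round(Ci))
    isotropic_solution(p)$roots$gamma[1]
  }, numeric(1))
}

#' Numerical linearization cross-check of the dispersion relation
#'
#' Independently recomputes `Omega^2` by discretising the membrane balance
#' on the `M` boundary segments, perturbing the isotropic fixed point with a
#' discrete cosine mode, and projecting the centred finite difference of the
#' reaction part (unbinding plus delivery, with all global pools recomputed
#' from the perturbed field) back onto the mode. Agreement with
#' [omega_squared()] validates the analytic linearization, in which
#' perturbations of the global pools drop out for `n >= 1`.
#'
#' @param params a [model_params()] bundle.
#' @param mode_n angular mode number (>= 1).
#' @param eps_rel relative perturbation amplitude for the finite difference.
#' @return a list with `omega_sq_numeric`, `omega_sq_analytic`, `gamma` (the
#'   isotropic root used) and `residual` (isotropic balance residual, should
#'   be ~0).
#' @export
omega_squared_numeric <- function(params, mode_n = 1, eps_rel = 1e-4) {
  mt <- params$mt; fb <- params$fb; pf <- params$pf
  iso <- isotropic_solution(params)
  C_b <- iso$roots$C_b[1]
  gbar <- iso$roots$gamma[1]
  M <- mt$M
  theta <- 2 * pi * (seq_len(M) - 1) / M
  dtheta <- 2 * pi / M
  reaction <- function(cvec) {      # per-radian densities on the M segments
    g <- cvec / fb$c_star
    s <- mf_site(mt, fb, g)
    l_tot <- sum(s$l_site)
    C_int <- pf$C_total - sum(cvec) * dtheta
    C_m <- C_int * l_tot / (pf$l_half + l_tot)
    Kb <- pf$v_m * (C_m / l_tot) * (M / (2 * pi)) * s$P_bound
    Kb - pf$k_u * cvec
  }
  cbar <- rep(C_b / (2 * pi), M)
  v <- cos(mode_n * theta)
  eps <- eps_rel * max(C_b / (2 * pi), 1)
  dF <- (reaction(cbar + eps * v) - reaction(cbar - eps * v)) / (2 * eps)
  omega_num <- sum(dF * v) / (pf$k_u * (M / 2))
  list(omega_sq_numeric = omega_num,
       omega_sq_analytic = omega_squared(gbar, fb$p, eta_param(mt, fb)),
       gamma = gbar,
       residual = max(abs(reaction(cbar))) / max(pf$k_u * C_b / (2 * pi), 1))
}

#' Dispersion table for export
#'
#' Evaluates `Omega^2` on a grid of reduced densities and flags where the
#' selected mode is unstable (`Omega^2 > L * delta`).
#'
#' @param p,eta dispersion parameters.
#' @param delta mean-square angular displacement before unbinding.
#' @param gamma grid of reduced densities.
#' @param dim,mode_n mode selection.
#' @return a data frame with columns `gamma`, `omega_sq`, `polarized`.
#' @export
dispersion_table <- function(p, eta, delta,
                             gamma = seq(0, 3, by = 0.01),
                             dim = 2, mode_n = 1) {
  om <- omega_squared(gamma, p, eta)
  data.frame(gamma = gamma, omega_sq = om,
             polarized = om > lap_eigenvalue(mode_n, dim) * delta)
}
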