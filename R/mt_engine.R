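# Stochastic microtubule population dynamics.
#
# The per-step update rules live in two places: step_mts() is the readable
# vectorised R reference used directly in unit tests, and the compiled
# engine (src/engine.cpp) applies identical rules inside the full
# simulation loop. Equivalence is enforced by the mean-field oracle tests.

MT_EMPTY <- 0L
MT_GROWING <- 1L
MT_SHRINKING <- 2L
MT_PAUSED <- 3L

#' Create an empty microtubule population state
#'
#' All `M` nucleation sites start empty; site `i` points along the fixed
#' direction `2*pi*(i-1)/M`.
#'
#' @param M number of nucleation sites.
#' @return a list with integer `status` (0 empty, 1 growing, 2 shrinking,
#'   3 paused) and numeric `length` (um), each of length `M`.
#' @export
new_mt_state <- function(M) {
  list(status = rep(MT_EMPTY, M), length = numeric(M))
}

# Guard: the fixed-step scheme needs all event probabilities well below 1.
check_dt_rates <- function(mt, fb, dt) {
  rmax <- max(mt$r_nuc, mt$r_cat, mt$r_res, fb$r_u0)
  if (dt * rmax >= 0.1)
    stop(sprintf(paste0("time step too large: dt * max rate = %.3g ",
                        "(must be < 0.1); reduce dt"), dt * rmax))
  invisible(TRUE)
}

#' One fixed-time-step update of the microtubule population
#'
#' Per site, the stochastic state transition (probability `1 - exp(-r*dt)`
#' for a rate-`r` event) is decided first and the length then moves
#' according to the new state: growing tips advance by `v_plus*dt` and stall
#' at the boundary (`length = R`, paused), shrinking tips retreat by
#' `v_minus*dt` and vanish at zero length. A paused microtubule switches to
#' shrinking with the density-dependent release rate evaluated at its
#' site's local (smoothed) membrane density.
#'
#' @param state a [new_mt_state()] list.
#' @param mt an [mt_params()] object.
#' @param fb a [feedback_params()] object.
#' @param local_gamma per-site reduced membrane density (scalar or length
#'   `M`; may be `Inf` for the saturated limit).
#' @param dt time step (s); `dt * max(rates)` must stay below 0.1.
#' @return the updated state.
#' @export
step_mts <- function(state, mt, fb, local_gamma, dt) {
  check_dt_rates(mt, fb, dt)
  if (any(local_gamma < 0)) stop("local_gamma must be non-negative")
  M <- length(state$status)
  g <- rep_len(local_gamma, M)
  st <- state$status
  len <- state$length
  u <- stats::runif(M)
  r_u <- ifelse(is.infinite(g), fb$r_uinf, release_rate(g * fb$c_star, fb))
  # transitions first ...
  new_st <- st
  new_st[st == MT_EMPTY & u < 1 - exp(-mt$r_nuc * dt)] <- MT_GROWING
  new_st[st == MT_GROWING & u < 1 - exp(-mt$r_cat * dt)] <- MT_SHRINKING
  new_st[st == MT_SHRINKING & u < 1 - exp(-mt$r_res * dt)] <- MT_GROWING
  new_st[st == MT_PAUSED & u < 1 - exp(-r_u * dt)] <- MT_SHRINKING
  # ... then the length move under the new state
  gr <- new_st == MT_GROWING
  sh <- new_st == MT_SHRINKING
  len[gr] <- len[gr] + mt$v_plus * dt
  len[sh] <- len[sh] - mt$v_minus * dt
  hit <- len >= mt$R
  new_st[hit] <- MT_PAUSED
  len[hit] <- mt$R
  gone <- len <= 0
  new_st[gone] <- MT_EMPTY
  len[gone] <- 0
  list(status = new_st, length = len)
}

#' Long-run microtubule population statistics at fixed membrane density
#'
#' Runs the compiled fixed-step engine for an isolated microtubule
#' population (no polarity-factor transport; the reduced membrane density is
#' clamped at `gamma`), then summarises the post-equilibration trajectory.
#'
#' @param mt an [mt_params()] object.
#' @param fb a [feedback_params()] object.
#' @param gamma clamped reduced density (scalar, >= 0 or `Inf`).
#' @param dt time step (s).
#' @param t_total,t_equil total and discarded simulated time (s).
#' @param n_batches number of batches for batch-means standard errors.
#' @param seed RNG seed.
#' @param max_residence maximum number of boundary residence durations to
#'   collect (post-equilibration).
#' @return an object of class `mt_sim` with elements `occ` (batch matrix of
#'   state occupancies), `l_tot` (batch means), `arrivals`, `nucleations`
#'   and `residence` (s).
#' @seealso [mt_stats()]
#' @export
simulate_mts <- function(mt, fb, gamma, dt = 0.5, t_total = 4e4,
                         t_equil = t_total / 4, n_batches = 16, seed = 1,
                         max_residence = 5000) {
  check_dt_rates(mt, fb, dt)
  stopifnot(t_equil < t_total, length(gamma) == 1, gamma >= 0)
  r_u <- if (is.infinite(gamma)) fb$r_uinf else
    release_rate(gamma * fb$c_star, fb)
  set.seed(seed)
  res <- run_mts_cpp(mt$M, mt$R, mt$v_plus, mt$v_minus, mt$r_cat, mt$r_res,
                     mt$r_nuc, r_u, dt, as.integer(round(t_total / dt)),
                     as.integer(round(t_equil / dt)), n_batches,
                     max_residence)
  res$gamma <- gamma
  res$dt <- dt
  res$mt <- mt
  colnames(res$occ) <- c("empty", "growing", "shrinking", "paused")
  class(res) <- "mt_sim"
  res
}

#' Summary statistics of a microtubule-population trajectory
#'
#' Time-averaged occupancy fractions and total length with batch-means
#' standard errors, the boundary-arrival flux, and the empirical
#' boundary-reach factor `mu_b` (arrival flux over nucleation flux, equal to
#' `exp(-lambda*R)` in the mean-field limit).
#'
#' @param sim a [simulate_mts()] result.
#' @return a list with `occ` (means), `occ_se`, `l_tot`, `l_tot_se`,
#'   `arrival_flux` (events/s, whole population), `mu_b_hat` and the raw
#'   `residence` sample.
#' @export
mt_stats <- function(sim) {
  if (!inherits(sim, "mt_sim")) stop("expected a simulate_mts() result")
  nb <- nrow(sim$occ)
  if (nb < 2) stop("need at least two batches")
  list(occ = colMeans(sim$occ),
       occ_se = apply(sim$occ, 2, stats::sd) / sqrt(nb),
       l_tot = mean(sim$l_tot),
       l_tot_se = stats::sd(sim$l_tot) / sqrt(nb),
       arrival_flux = sim$arrivals / sim$measured_time,
       mu_b_hat = if (sim$nucleations > 0)
         sim$arrivals / sim$nucleations else NA_real_,
       residence = sim$residence)
}

#' Exact life-cycle simulation of unconfined microtubules
#'
#' Event-driven (continuous-time, no time-step discretisation) simulation
#' of independent microtubule life cycles without a confining boundary:
#' nucleate at zero length, alternate exponential growth and shrinkage
#' phases, absorb at zero length. The stationary mean length of the
#' population of existing microtubules is the renewal-reward ratio
#' `E[integral of length dt] / E[lifetime]`, which in the bounded-growth
#' regime equals `1/lambda`.
#'
#' @param n number of independent life cycles.
#' @param mt an [mt_params()] object (only the speeds and rates are used;
#'   `lambda_decay(mt) > 0` required for a finite mean).
#' @param seed RNG seed (optional).
#' @return a list with `mean_length` (um), its delta-method standard error
#'   `se`, and `n`.
#' @export
#' @examples
#' mt <- mt_params(v_plus = 0.013, v_minus = 0.040)
#' simulate_mt_lifecycles(2000, mt, seed = 1)$mean_length  # about 1.79 um
simulate_mt_lifecycles <- function(n, mt, seed = NULL) {
  stopifnot(n >= 2)
  if (lambda_decay(mt) <= 0)
    stop("unconfined mean length diverges for lambda <= 0")
  if (!is.null(seed)) set.seed(seed)
  A <- numeric(n)    # per-cycle integral of length over time (um * s)
  Tt <- numeric(n)   # per-cycle lifetime (s)
  len <- numeric(n)
  active <- rep(TRUE, n)
  while (any(active)) {
    i <- which(active)
    # growth phase: duration to catastrophe
    tau <- stats::rexp(length(i), mt$r_cat)
    A[i] <- A[i] + len[i] * tau + mt$v_plus * tau^2 / 2
    Tt[i] <- Tt[i] + tau
    len[i] <- len[i] + mt$v_plus * tau
    # shrink phase: rescue vs absorption at zero length
    tau_r <- stats::rexp(length(i), mt$r_res)
    t0 <- len[i] / mt$v_minus
    died <- tau_r >= t0
    id <- i[died]; ir <- i[!died]
    A[id] <- A[id] + len[id] * t0[died] - mt$v_minus * t0[died]^2 / 2
    Tt[id] <- Tt[id] + t0[died]
    len[id] <- 0
    active[id] <- FALSE
    tr <- tau_r[!died]
    A[ir] <- A[ir] + len[ir] * tr - mt$v_minus * tr^2 / 2
    Tt[ir] <- Tt[ir] + tr
    len[ir] <- len[ir] - mt$v_minus * tr
  }
  mhat <- sum(A) / sum(Tt)
  # delta-method SE of the ratio estimator
  resid <- A - mhat * Tt
  se <- sqrt(stats::var(resid) / n) / mean(Tt)
  list(mean_length = mhat, se = se, n = n)
}
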