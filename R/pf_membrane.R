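# Polarity-factor bookkeeping: interior pool, fast-equilibrium microtubule
# binding, plus-end transport, membrane lattice diffusion and recycling.
#
# As in mt_engine.R these R implementations are the testable reference for
# the rules applied by the compiled simulation loop. A polarity factor is in
# exactly one of three pools at any time -- free interior, microtubule-bound
# (with a radial position), or membrane (binned into the M boundary
# segments, each particle sitting at its segment centre) -- and the integer
# total is conserved exactly.

#' Create a polarity-factor pool state
#'
#' All polarity factors start free in the cell interior.
#'
#' @param C_total conserved total count.
#' @param M number of membrane segments.
#' @return a list with `C_free` (count), `bound_site`/`bound_pos` (parallel
#'   vectors: nucleation-site index and radial position of each
#'   microtubule-bound particle) and `memb` (integer counts per segment).
#' @export
new_pf_state <- function(C_total, M) {
  list(C_free = as.integer(C_total), bound_site = integer(0),
       bound_pos = numeric(0), memb = integer(M))
}

pf_total <- function(pf) pf$C_free + length(pf$bound_site) + sum(pf$memb)

#' Smoothed local membrane density
#'
#' The local density at segment `m` averages the segment and its two cyclic
#' neighbours: `c_m = (C[m-1] + C[m] + C[m+1]) / (3 * dtheta)` (polarity
#' factors per radian). The smoothed densities integrate back to the total
#' membrane count.
#'
#' @param counts integer per-segment counts.
#' @return numeric vector of densities (per radian).
#' @export
smooth_density <- function(counts) {
  M <- length(counts)
  dtheta <- 2 * pi / M
  left <- counts[c(M, seq_len(M - 1))]
  right <- counts[c(seq_len(M - 1) + 1, 1)]
  (left + counts + right) / (3 * dtheta)
}

#' Fast binding equilibrium with the instantaneous microtubule configuration
#'
#' Interior polarity factors bind microtubules on a time scale much shorter
#' than the microtubule dynamics, so every step the microtubule-bound count
#' is reset to the equilibrium target
#' `C_m = round(C_int * l_tot / (l_half + l_tot))` with
#' `C_int = C_free + C_m` the whole interior pool. Surplus bound particles
#' unbind (uniformly chosen); deficit particles bind at positions uniform on
#' the total microtubule length (i.e. per microtubule proportional to its
#' length). Particles left stranded above a shrunken tip fall off first.
#' In-transit positions of particles that remain bound are preserved.
#'
#' @param pf a [new_pf_state()] pool state.
#' @param lengths per-site microtubule lengths (um).
#' @param l_half affinity half-length (um).
#' @param refresh redraw all bound positions from the equilibrium
#'   distribution (fast-exchange limit used by the default `"refresh"`
#'   transport mode of [sim_config()]) instead of preserving in-transit
#'   positions.
#' @return the updated pool state.
#' @export
equilibrate_binding <- function(pf, lengths, l_half, refresh = FALSE) {
  if (l_half < 0 || any(lengths < 0)) stop("negative inputs")
  if (refresh && length(pf$bound_site)) {
    pf$C_free <- pf$C_free + length(pf$bound_site)
    pf$bound_site <- integer(0)
    pf$bound_pos <- numeric(0)
  }
  # fall off microtubules that shrank below the particle position
  if (length(pf$bound_site)) {
    off <- pf$bound_pos > lengths[pf$bound_site]
    pf$C_free <- pf$C_free + sum(off)
    pf$bound_site <- pf$bound_site[!off]
    pf$bound_pos <- pf$bound_pos[!off]
  }
  l_tot <- sum(lengths)
  C_m <- length(pf$bound_site)
  C_int <- pf$C_free + C_m
  target <- if (l_tot > 0) round(C_int * l_tot / (l_half + l_tot)) else 0
  target <- min(target, C_int)
  if (target < C_m) {
    drop <- sample.int(C_m, C_m - target)
    pf$C_free <- pf$C_free + (C_m - target)
    pf$bound_site <- pf$bound_site[-drop]
    pf$bound_pos <- pf$bound_pos[-drop]
  } else if (target > C_m) {
    k <- target - C_m
    x <- stats::runif(k) * l_tot
    cum <- cumsum(lengths)
    site <- findInterval(x, cum) + 1L
    pos <- x - c(0, cum)[site]
    pos <- pmin(pos, lengths[site])
    pf$bound_site <- c(pf$bound_site, site)
    pf$bound_pos <- c(pf$bound_pos, pos)
    pf$C_free <- pf$C_free - k
  }
  pf
}

#' Plus-end transport and boundary delivery
#'
#' Every microtubule-bound polarity factor advances towards the plus end by
#' `v_m * dt`. A particle passing the current tip is removed from the
#' microtubule: if that microtubule is paused at the boundary the particle
#' is delivered into the membrane segment containing the site direction,
#' otherwise it simply falls off back into the free interior pool.
#'
#' @param pf pool state.
#' @param mt_state a microtubule state ([new_mt_state()] layout).
#' @param v_m transport speed (um/s).
#' @param dt time step (s).
#' @return the updated pool state.
#' @export
transport_and_deliver <- function(pf, mt_state, v_m, dt) {
  if (!length(pf$bound_site)) return(pf)
  pf$bound_pos <- pf$bound_pos + v_m * dt
  passed <- pf$bound_pos > mt_state$length[pf$bound_site]
  if (any(passed)) {
    site <- pf$bound_site[passed]
    paused <- mt_state$status[site] == MT_PAUSED
    if (any(paused))
      pf$memb <- pf$memb + tabulate(site[paused], nbins = length(pf$memb))
    pf$C_free <- pf$C_free + sum(!paused)
    pf$bound_site <- pf$bound_site[!passed]
    pf$bound_pos <- pf$bound_pos[!passed]
  }
  pf
}

#' Membrane diffusion and unbinding step
#'
#' Each membrane polarity factor independently unbinds with probability
#' `k_u * dt` (returning to the free interior pool) or otherwise moves by a
#' displacement drawn from the exact circle-diffusion law, applied at
#' segment resolution via the cyclic offset distribution of
#' [segment_offset_probs()].
#'
#' @param pf pool state.
#' @param k_u unbinding rate (1/s).
#' @param dt time step (s); `k_u * dt` must be below 1.
#' @param offset_probs cyclic offset distribution (length `M`), from
#'   [segment_offset_probs()].
#' @return the updated pool state.
#' @export
membrane_step <- function(pf, k_u, dt, offset_probs) {
  if (k_u * dt >= 1)
    stop("configuration error: k_u * dt must be below 1")
  M <- length(pf$memb)
  n <- sum(pf$memb)
  if (n == 0) return(pf)
  seg <- rep.int(seq_len(M), pf$memb)
  u <- stats::runif(n)
  unbind <- u < k_u * dt
  pf$C_free <- pf$C_free + sum(unbind)
  seg <- seg[!unbind]
  if (length(seg)) {
    off <- findInterval(stats::runif(length(seg)), cumsum(offset_probs)) # 0..M-1
    seg <- ((seg - 1L + off) %% M) + 1L
    pf$memb <- tabulate(seg, nbins = M)
  } else {
    pf$memb <- integer(M)
  }
  pf
}
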