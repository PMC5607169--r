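# Diffusion on the circle: exact CDF and inverse-CDF sampling.

# Number of Fourier terms needed so that the dropped weights are < 1e-16.
wrapped_nmax <- function(Ddt) max(1L, as.integer(ceiling(sqrt(36.85 / Ddt))))

#' Cumulative distribution of diffusion on the unit circle
#'
#' The angular displacement after a diffusion time with mean-square angle
#' `2 * Ddt` has, on `[0, 2*pi)`, the cumulative probability
#' \deqn{P(\delta\theta) = \frac{\delta\theta}{2\pi}
#'   + \frac{1}{\pi}\sum_{n\ge 1} \frac{e^{-n^2 D\Delta t}}{n}
#'     \sin(n\,\delta\theta).}
#' The series is truncated once \eqn{e^{-n^2 D\Delta t} < 10^{-16}}.
#'
#' @param theta displacement(s) in radians, in `[0, 2*pi]`.
#' @param Ddt dimensionless diffusion time `D_ang * dt` (rad^2), > 0.
#' @return cumulative probabilities; `P(0) = 0`, `P(2*pi) = 1`.
#' @export
circle_diffusion_cdf <- function(theta, Ddt) {
  stopifnot(Ddt > 0, all(theta >= -1e-12), all(theta <= 2 * pi + 1e-12))
  n <- seq_len(wrapped_nmax(Ddt))
  w <- exp(-n^2 * Ddt) / n
  base <- theta / (2 * pi)
  corr <- vapply(theta, function(th) sum(w * sin(n * th)), numeric(1))
  base + corr / pi
}

#' Inverse-CDF sampling of circle diffusion displacements
#'
#' Inverts [circle_diffusion_cdf()] by bisection to absolute tolerance `tol`
#' for each supplied uniform variate, yielding exact (to tolerance) samples
#' of the angular displacement on `[0, 2*pi)`. For large `Ddt` the
#' distribution approaches the uniform; for small `Ddt` it approaches a
#' narrow wrapped normal of variance `2 * Ddt`.
#'
#' @param u uniform variates in `[0, 1)`, or a single integer `n` together
#'   with `n_is_count = TRUE` to draw that many fresh uniforms.
#' @param Ddt dimensionless diffusion time `D_ang * dt` (> 0).
#' @param tol absolute bisection tolerance (radians).
#' @param n_is_count interpret `u` as a sample count.
#' @return numeric vector of displacements in `[0, 2*pi)`.
#' @export
#' @examples
#' set.seed(1)
#' dth <- sample_wrapped_displacement(1000, Ddt = 0.01, n_is_count = TRUE)
sample_wrapped_displacement <- function(u, Ddt, tol = 1e-10,
                                        n_is_count = FALSE) {
  stopifnot(Ddt > 0, tol > 0)
  if (n_is_count) u <- stats::runif(u)
  if (any(u < 0 | u >= 1)) stop("uniform variates must lie in [0, 1)")
  sample_wrapped_cpp(u, Ddt, tol)
}

#' Segment-offset distribution for membrane diffusion
#'
#' With the membrane divided into `M` equal segments and every polarity
#' factor represented at its segment centre, one diffusion update moves a
#' particle by a whole number of segments. Offset `k` (cyclic) occurs when
#' the continuous displacement falls in
#' `[(k - 1/2) * dtheta, (k + 1/2) * dtheta)`, so the exact offset
#' probabilities are differences of [circle_diffusion_cdf()] at the bin
#' edges (the `k = 0` bin wraps around zero). They telescope to one.
#'
#' @param M number of segments.
#' @param Ddt dimensionless diffusion time per step (> 0).
#' @return numeric vector of length `M`; element `k + 1` is the probability
#'   of a cyclic offset of `k` segments.
#' @export
segment_offset_probs <- function(M, Ddt) {
  stopifnot(M >= 3, Ddt > 0)
  dtheta <- 2 * pi / M
  edges <- (seq_len(M) - 0.5) * dtheta          # upper edge of bins 0..M-1
  P <- circle_diffusion_cdf(edges, Ddt)
  q <- c(P[1] + (1 - P[M]), diff(P))
  q <- pmax(q, 0)
  q / sum(q)
}
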