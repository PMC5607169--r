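# Conversion between the affinity half-length and the lattice binding
# density convention (one binding site per tubulin dimer, 13 protofilaments,
# 8 nm dimer length).

TUBULIN_DIMER_LENGTH <- 0.008   # um
N_PROTOFILAMENTS <- 13

#' Lattice binding density from the affinity half-length
#'
#' The microtubule lattice offers `N = 13 * l_tot / l_dimer` dimers; at
#' binding equilibrium `C_m = C_int * l_tot / (l_half + l_tot)` polarity
#' factors are bound, so the binding density (bound ligands per lattice
#' residue) is
#' \deqn{\nu = \frac{C_m}{N} = \frac{C_{int}\, l_{dimer}}
#'   {13\,(l_{1/2} + l_{tot})}.}
#'
#' @param l_half affinity half-length (um, > 0).
#' @param C_int interior polarity-factor count (> 0).
#' @param l_tot total microtubule length (um, > 0).
#' @return binding density `nu` (dimensionless).
#' @seealso [lhalf_from_nu()], [affinity_record()]
#' @export
nu_from_lhalf <- function(l_half, C_int, l_tot) {
  stopifnot(l_half > 0, C_int > 0, l_tot > 0)
  C_int * TUBULIN_DIMER_LENGTH / (N_PROTOFILAMENTS * (l_half + l_tot))
}

#' Affinity half-length from the lattice binding density
#'
#' Inverse of [nu_from_lhalf()]:
#' \eqn{l_{1/2} = C_{int}\,l_{dimer}/(13\,\nu) - l_{tot}}.
#'
#' @param nu binding density (> 0).
#' @param C_int interior polarity-factor count.
#' @param l_tot total microtubule length (um).
#' @return affinity half-length (um).
#' @export
lhalf_from_nu <- function(nu, C_int, l_tot) {
  stopifnot(nu > 0, C_int > 0, l_tot > 0)
  C_int * TUBULIN_DIMER_LENGTH / (N_PROTOFILAMENTS * nu) - l_tot
}

#' Full affinity conversion record
#'
#' @param l_half affinity half-length (um).
#' @param C_int interior polarity-factor count.
#' @param l_tot total microtubule length (um).
#' @return a list with the inputs, the available dimer count `N`, the bound
#'   count `C_m` and the binding density `nu`.
#' @export
affinity_record <- function(l_half, C_int, l_tot) {
  nu <- nu_from_lhalf(l_half, C_int, l_tot)
  list(l_half = l_half, C_int = C_int, l_tot = l_tot,
       l_dimer = TUBULIN_DIMER_LENGTH,
       n_protofilaments = N_PROTOFILAMENTS,
       N = N_PROTOFILAMENTS * l_tot / TUBULIN_DIMER_LENGTH,
       C_m = C_int * l_tot / (l_half + l_tot),
       nu = nu)
}
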