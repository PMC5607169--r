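# Polar order parameter, drift correction and ensemble statistics.

#' Polar order parameter S1
#'
#' \eqn{S_1 = \sqrt{\langle\cos\theta\rangle^2 +
#' \langle\sin\theta\rangle^2}}, the resultant length of the
#' count-weighted mean unit vector of the membrane distribution, with every
#' particle placed at its segment-centre angle. 0 for a perfectly isotropic
#' distribution, 1 when all polarity factors sit in a single segment. For
#' finitely many particles an isotropic state has the finite-number floor
#' \eqn{E[S_1] \approx \sqrt{\pi/(4N)}}.
#'
#' @param counts integer vector of per-segment membrane counts (segment `m`
#'   is centred on angle `2*pi*(m-1)/length(counts)`).
#' @return numeric scalar in `[0, 1]`, or `NA` for an empty membrane.
#' @export
order_parameter_s1 <- function(counts) {
  N <- sum(counts)
  if (N < 1) return(NA_real_)
  M <- length(counts)
  theta <- 2 * pi * (seq_len(M) - 1) / M
  sqrt(sum(counts * cos(theta))^2 + sum(counts * sin(theta))^2) / N
}

#' Phase-drift correction of boundary histograms
#'
#' A polarized patch performs a slow random walk around the boundary, which
#' would smear a naive time average. Each frame's phase is extracted as the
#' argument of its first circular Fourier mode and the histogram is
#' cyclically shifted (to the nearest segment) so that the phase sits at
#' angle zero before averaging.
#'
#' @param frames matrix of per-frame segment counts (frames in rows).
#' @return a list with the aligned mean `profile`, the number of frames
#'   `n_used`, and the per-frame `phase` (radians; `NA` for skipped frames).
#'   Frames with zero first-mode amplitude are skipped with a warning.
#' @export
drift_correct <- function(frames) {
  frames <- rbind(frames)
  M <- ncol(frames)
  theta <- 2 * pi * (seq_len(M) - 1) / M
  dtheta <- 2 * pi / M
  z <- frames %*% cbind(cos(theta), sin(theta))
  amp <- sqrt(rowSums(z^2))
  ok <- amp > 1e-8 * pmax(rowSums(abs(frames)), 1)
  if (!all(ok))
    warning(sum(!ok), " frame(s) with zero first-mode amplitude skipped")
  if (!any(ok)) stop("no frame with a defined phase")
  phase <- ifelse(ok, atan2(z[, 2], z[, 1]), NA_real_)
  aligned <- t(vapply(which(ok), function(i) {
    shift <- round(phase[i] / dtheta) %% M
    idx <- ((seq_len(M) - 1 + shift) %% M) + 1
    frames[i, idx]
  }, numeric(M)))
  list(profile = colMeans(aligned), n_used = sum(ok), phase = phase)
}

#' Ensemble statistics of the order parameter
#'
#' Mean and standard error of the per-run time-averaged order parameter over
#' independent runs.
#'
#' @param x either a numeric vector of per-run time-averaged `S1` values or
#'   a list of [run_simulation()] results (which must share a
#'   configuration).
#' @return a list with `mean`, `sem` and `n`.
#' @export
ensemble_stats <- function(x) {
  if (is.list(x) && !is.numeric(x)) {
    if (length(x) >= 2) {
      cfg <- lapply(x, function(r) r$config[c("params", "dt", "t_total",
                                              "t_equil", "mode",
                                              "transport")])
      if (!all(vapply(cfg[-1], identical, logical(1), y = cfg[[1]])))
        stop("runs have heterogeneous configurations")
    }
    x <- vapply(x, function(r) r$summary$s1_mean, numeric(1))
  }
  if (length(x) < 2) stop("need at least two runs")
  list(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x))
}
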