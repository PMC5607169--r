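# Orchestration of seeded particle-based runs and abundance scans.

#' Simulation configuration
#'
#' Bundles a parameter set with the run controls. Runs start from an empty
#' state (no active microtubules, all polarity factors free in the
#' interior); measurements are taken after discarding the equilibration
#' window `t_equil` (default: the first half of the run).
#'
#' @param params a [model_params()] bundle.
#' @param dt time step (s). Must satisfy `dt * max(rates) < 0.1` and
#'   `k_u * dt < 1`.
#' @param t_total simulated duration (s).
#' @param t_equil equilibration time discarded from summaries (s).
#' @param seed integer RNG seed; a run is a deterministic function of
#'   `(config, seed)`.
#' @param mode `"normal"`, `"homogenized"` or `"feedback_cut"`. The
#'   homogenized control redistributes the membrane pool uniformly
#'   (multinomially) after every step, preserving its total: the recorded
#'   order parameter is then the pure counting-noise floor,
#'   `E[S1] ~ sqrt(pi/(4 C_membrane))`. The feedback-cut control instead
#'   shows every microtubule the spatially uniform mean membrane density
#'   while the membrane field itself evolves freely: polarization feedback
#'   is severed, but the order parameter retains the
#'   discrete-microtubule delivery noise, giving the no-feedback baseline
#'   against which small-`M` runs are judged (see the methods vignette).
#' @param transport `"refresh"` (default) or `"track"`. In the
#'   fast-exchange limit assumed by the binding equilibrium, every bound
#'   polarity factor unbinds and rebinds many times per step, so `"refresh"`
#'   redraws all bound positions from the equilibrium (uniform on the total
#'   microtubule length) each step; the boundary delivery flux then equals
#'   the mean-field law `v_m * c_m * m_b` exactly. `"track"` instead
#'   preserves in-transit positions between steps; uniform injection plus
#'   plus-end advection then piles bound particles up towards the tips and
#'   enhances delivery above the mean-field law (see the methods vignette).
#' @param record_interval interval between recorded frames (s).
#' @param record_frames also store every recorded membrane histogram (for
#'   [drift_correct()]).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(params, dt = 0.05, t_total = 2000,
                       t_equil = t_total / 2, seed = 1,
                       mode = c("normal", "homogenized", "feedback_cut"),
                       transport = c("refresh", "track"),
                       record_interval = max(dt, t_total / 400),
                       record_frames = FALSE) {
  mode <- match.arg(mode)
  transport <- match.arg(transport)
  stopifnot(inherits(params, "model_params"), dt > 0, t_total > dt,
            t_equil >= 0, t_equil < t_total,
            seed == as.integer(seed))
  check_dt_rates(params$mt, params$fb, dt)
  if (params$pf$k_u * dt >= 1)
    stop("configuration error: k_u * dt must be below 1")
  structure(list(params = params, dt = dt, t_total = t_total,
                 t_equil = t_equil, seed = as.integer(seed), mode = mode,
                 transport = transport,
                 record_interval = max(record_interval, dt),
                 record_frames = record_frames),
            class = "sim_config")
}

#' Run one seeded particle-based simulation
#'
#' Executes the fixed-time-step loop: microtubule update (with local
#' smoothed membrane densities feeding the boundary-release rates), fast
#' binding equilibrium, plus-end transport and boundary delivery, membrane
#' diffusion/unbinding, optional homogenization, and recording. Exact
#' integer conservation of the polarity-factor total is asserted at every
#' step.
#'
#' @param config a [sim_config()] object (or a [model_params()] bundle, in
#'   which case the remaining arguments are forwarded to [sim_config()]).
#' @param ... forwarded to [sim_config()] when `config` is a parameter
#'   bundle.
#' @return an object of class `sim_result`: `ts` (data frame with columns
#'   `time`, `s1`, `C_free`, `C_m`, `C_membrane`, `l_tot`, `M_paused`),
#'   `hist_mean` (post-equilibration mean boundary histogram), `frames`
#'   (matrix or `NULL`), `final` state, the `config`, and `summary`
#'   (post-equilibration time averages, including `s1_mean`).
#' @export
#' @examples
#' p <- default_params(C_total = 2000, M = 50, l_half = 7.5)
#' r <- run_simulation(p, dt = 0.5, t_total = 200, seed = 1)
#' r$summary$s1_mean
run_simulation <- function(config, ...) {
  if (inherits(config, "model_params")) config <- sim_config(config, ...)
  stopifnot(inherits(config, "sim_config"))
  p <- config$params
  n_steps <- as.integer(round(config$t_total / config$dt))
  record_every <- max(1L, as.integer(round(config$record_interval / config$dt)))
  equil_steps <- as.integer(round(config$t_equil / config$dt))
  q <- segment_offset_probs(p$mt$M, p$pf$D_ang * config$dt)
  raw <- run_sim_cpp(p$mt$M, p$mt$R, p$mt$v_plus, p$mt$v_minus,
                     p$mt$r_cat, p$mt$r_res, p$mt$r_nuc,
                     p$fb$r_u0, p$fb$r_uinf, p$fb$p, p$fb$c_star,
                     p$pf$v_m, p$pf$k_u, p$pf$l_half, p$pf$C_total,
                     config$dt, n_steps, record_every, equil_steps,
                     config$mode == "homogenized", q, config$record_frames,
                     config$transport == "refresh",
                     config$mode == "feedback_cut", config$seed)
  ts <- data.frame(time = raw$time, s1 = raw$s1, C_free = raw$C_free,
                   C_m = raw$C_m, C_m_eq = raw$C_m_eq,
                   C_membrane = raw$C_membrane,
                   l_tot = raw$l_tot, M_paused = raw$M_paused)
  post <- ts[ts$time > config$t_equil, , drop = FALSE]
  s1_ok <- post$s1[!is.na(post$s1)]
  # heuristic stationarity check: first vs second half of the measurement
  # window, flagged when the means disagree by more than 3 naive SEs
  equil_flag <- FALSE
  if (length(s1_ok) >= 8) {
    h <- split(s1_ok, rep(1:2, each = ceiling(length(s1_ok) / 2),
                          length.out = length(s1_ok)))
    se2 <- stats::var(h[[1]]) / length(h[[1]]) +
      stats::var(h[[2]]) / length(h[[2]])
    equil_flag <- is.finite(se2) && se2 > 0 &&
      abs(mean(h[[1]]) - mean(h[[2]])) > 3 * sqrt(se2)
  }
  summary <- list(
    s1_mean = if (length(s1_ok)) mean(s1_ok) else NA_real_,
    s1_sd = if (length(s1_ok) > 1) stats::sd(s1_ok) else NA_real_,
    s1_undefined_frames = sum(is.na(post$s1)),
    equilibration_suspect = equil_flag,
    C_membrane_mean = mean(post$C_membrane),
    C_m_mean = mean(post$C_m),
    l_tot_mean = mean(post$l_tot),
    M_paused_mean = mean(post$M_paused),
    gamma_measured = mean(post$C_membrane) / (2 * pi * p$fb$c_star),
    # realised boundary delivery flux vs the mean-field law of the
    # effective binding rate, K_b integrated over the boundary:
    # v_m * (C_m / l_tot) * M_paused
    delivery_flux = raw$events[["delivered"]] / raw$events[["measured_time"]],
    delivery_flux_meanfield = mean(p$pf$v_m * post$C_m_eq / post$l_tot *
                                     post$M_paused),
    falloff_flux = raw$events[["falloff"]] / raw$events[["measured_time"]],
    unbinding_flux = raw$events[["unbound"]] / raw$events[["measured_time"]])
  structure(list(ts = ts, hist_mean = raw$hist_mean,
                 frames = raw$frames, final = raw$final,
                 config = config, summary = summary),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Particle simulation (%s mode): C = %d, M = %d, seed = %d\n",
              cfg$mode, cfg$params$pf$C_total, cfg$params$mt$M, cfg$seed))
  cat(sprintf("  t = %g s (dt = %g, equilibration %g s discarded)\n",
              cfg$t_total, cfg$dt, cfg$t_equil))
  cat(sprintf("  time-averaged S1 = %.4f; <C_membrane> = %.0f (gamma = %.3f)\n",
              x$summary$s1_mean, x$summary$C_membrane_mean,
              x$summary$gamma_measured))
  invisible(x)
}

#' Homogenized noise-floor run
#'
#' Convenience wrapper for `run_simulation(..., mode = "homogenized")`: the
#' membrane pool is redistributed uniformly (multinomially) over the
#' segments after every step, keeping its total fixed, so the recorded
#' order parameter is the finite-particle-number noise floor of a forced
#' isotropic state.
#'
#' @inheritParams run_simulation
#' @export
run_homogenized <- function(config, ...) {
  if (inherits(config, "model_params"))
    config <- sim_config(config, ..., mode = "homogenized")
  else config$mode <- "homogenized"
  run_simulation(config)
}

#' Abundance scan of the order parameter
#'
#' Runs the simulation over a grid of total polarity-factor numbers with
#' several seeds per value, labels each abundance with the reduced density
#' `gamma` of its isotropic fixed point (as obtained from
#' [isotropic_solution()]), and aggregates the per-run time-averaged order
#' parameter into mean and standard error. Optionally a homogenized
#' noise-floor run set is subtracted (plain subtraction of mean curves).
#'
#' @param params a [model_params()] template (its `C_total` is replaced).
#' @param C_values vector of total polarity-factor counts.
#' @param n_seeds number of independent seeds per value (>= 2).
#' @param seed0 base seed; run `s` at value `i` uses
#'   `seed0 + 1000 * i + s`.
#' @param noise also run a no-polarization control at each abundance.
#' @param noise_mode which control: `"homogenized"` (pure counting noise;
#'   equilibrates on the fast membrane-recycling time scale, so
#'   `noise_t_total` may be much shorter) or `"feedback_cut"` (retains
#'   microtubule delivery noise; needs durations comparable to the normal
#'   runs). See [sim_config()].
#' @param noise_t_total,noise_t_equil duration of the control runs (s).
#' @param ... run controls forwarded to [sim_config()] (`dt`, `t_total`,
#'   `t_equil`, ...).
#' @return a data frame with one row per abundance: `C`, `gamma`,
#'   `s1_mean`, `s1_sem`, and when `noise = TRUE` also `s1_noise`,
#'   `s1_noise_sem` and the noise-subtracted `s1_corrected`.
#' @export
scan_abundance <- function(params, C_values, n_seeds = 4, seed0 = 1,
                           noise = TRUE,
                           noise_mode = c("homogenized", "feedback_cut"),
                           noise_t_total = NULL,
                           noise_t_equil = NULL, ...) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(n_seeds >= 2)
  gam <- gamma_from_C(params, C_values)
  rows <- lapply(seq_along(C_values), function(i) {
    p <- params
    p$pf$C_total <- as.integer(round(C_values[i]))
    s1 <- vapply(seq_len(n_seeds), function(s) {
      run_simulation(sim_config(p, seed = seed0 + 1000L * i + s, ...))$
        summary$s1_mean
    }, numeric(1))
    row <- data.frame(C = C_values[i], gamma = gam[i],
                      s1_mean = mean(s1),
                      s1_sem = stats::sd(s1) / sqrt(n_seeds))
    if (noise) {
      nargs <- list(...)
      if (!is.null(noise_t_total)) {
        nargs$t_total <- noise_t_total
        nargs$t_equil <- if (is.null(noise_t_equil)) noise_t_total / 2 else
          noise_t_equil
      }
      ns <- vapply(seq_len(n_seeds), function(s) {
        cfg <- do.call(sim_config,
                       c(list(params = p, seed = seed0 + 1000L * i + 500L + s,
                              mode = noise_mode), nargs))
        run_simulation(cfg)$summary$s1_mean
      }, numeric(1))
      row$s1_noise <- mean(ns)
      row$s1_noise_sem <- stats::sd(ns) / sqrt(n_seeds)
      row$s1_corrected <- row$s1_mean - row$s1_noise
    }
    row
  })
  do.call(rbind, rows)
}
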