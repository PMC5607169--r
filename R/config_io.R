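# Structured-text (YAML) configuration files and shipped fixtures.

config_schema <- list(
  microtubules = c("R", "v_plus", "v_minus", "r_cat", "r_res", "r_nuc", "M"),
  feedback = c("r_u0", "r_uinf", "p", "c_star_full_circle"),
  polarity_factor = c("v_m", "k_u", "D", "d_is_angular", "l_half", "C_total"),
  simulation = c("dt", "t_total", "t_equil", "seed", "mode",
                 "record_interval"),
  scan = c("C_values", "n_seeds")
)
config_optional <- c("polarity_factor:d_is_angular", "simulation",
                     "simulation:t_equil", "simulation:mode",
                     "simulation:record_interval", "scan")

#' Load and validate a model configuration file
#'
#' Reads a YAML configuration with sections `microtubules`, `feedback`,
#' `polarity_factor` and (optionally) `simulation` and `scan`. All physical
#' quantities carry the units documented in [mt_params()],
#' [feedback_params()] and [pf_params()]; the feedback density scale is
#' given as the full-circle value `c_star_full_circle = 2*pi*c_star`.
#' Unknown keys are rejected and missing required keys are reported by
#' name.
#'
#' The membrane diffusion entry `D` is interpreted as the angular diffusion
#' constant (rad^2/s) when `d_is_angular` is true (the default), so that
#' `delta = D/k_u` directly; with `d_is_angular: false` it is read as a
#' translational membrane constant (um^2/s) and divided by `R^2`.
#'
#' @param path path to a YAML file.
#' @param verbose emit a message with the resolved `delta` and `eta`.
#' @return a list with `params` (a [model_params()] bundle), `sim` (run
#'   controls or `NULL`), `scan` (or `NULL`), and the resolved `delta` and
#'   `eta`.
#' @seealso [save_config()], [make_fixtures()]
#' @export
load_config <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  for (sec in names(raw))
    if (!sec %in% names(config_schema))
      stop("unknown configuration section: ", sec)
  for (sec in names(config_schema)) {
    required_sec <- !sec %in% config_optional
    if (is.null(raw[[sec]])) {
      if (required_sec) stop("missing configuration section: ", sec)
      next
    }
    for (key in names(raw[[sec]]))
      if (!key %in% config_schema[[sec]])
        stop("unknown key in section '", sec, "': ", key)
    for (key in config_schema[[sec]])
      if (is.null(raw[[sec]][[key]]) &&
          !paste0(sec, ":", key) %in% config_optional && sec != "scan")
        stop("missing key in section '", sec, "': ", key)
  }
  m <- raw$microtubules; f <- raw$feedback; q <- raw$polarity_factor
  mt <- mt_params(R = m$R, v_plus = m$v_plus, v_minus = m$v_minus,
                  r_cat = m$r_cat, r_res = m$r_res, r_nuc = m$r_nuc,
                  M = m$M)
  fb <- feedback_params(r_u0 = f$r_u0, r_uinf = f$r_uinf, p = f$p,
                        c_star = f$c_star_full_circle / (2 * pi))
  d_ang <- if (isFALSE(q$d_is_angular)) q$D / mt$R^2 else q$D
  pf <- pf_params(v_m = q$v_m, k_u = q$k_u, D_ang = d_ang,
                  l_half = q$l_half, C_total = q$C_total)
  params <- model_params(mt, fb, pf)
  delta <- pf$D_ang / pf$k_u
  eta <- if (fb$r_uinf < fb$r_u0 && lambda_decay(mt) > 0)
    eta_param(mt, fb) else NA_real_
  if (verbose)
    message(sprintf("loaded %s: delta = %.4g, eta = %.4g", path, delta, eta))
  list(params = params, sim = raw$simulation, scan = raw$scan,
       delta = delta, eta = eta)
}

#' Write a model configuration file
#'
#' Inverse of [load_config()]: `load_config(save_config(params, path))`
#' restores an identical parameter bundle.
#'
#' @param params a [model_params()] bundle.
#' @param path output path (YAML).
#' @param sim optional named list of run controls (`dt`, `t_total`, ...).
#' @param scan optional named list with `C_values` and `n_seeds`.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path, sim = NULL, scan = NULL) {
  stopifnot(inherits(params, "model_params"))
  cfg <- list(
    microtubules = params$mt[c("R", "v_plus", "v_minus", "r_cat", "r_res",
                               "r_nuc", "M")],
    feedback = list(r_u0 = params$fb$r_u0, r_uinf = params$fb$r_uinf,
                    p = params$fb$p,
                    c_star_full_circle = 2 * pi * params$fb$c_star),
    polarity_factor = list(v_m = params$pf$v_m, k_u = params$pf$k_u,
                           D = params$pf$D_ang, d_is_angular = TRUE,
                           l_half = params$pf$l_half,
                           C_total = params$pf$C_total))
  if (!is.null(sim)) cfg$simulation <- sim
  if (!is.null(scan)) cfg$scan <- scan
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Write the reference fixture configurations
#'
#' Emits the shipped study configurations into a directory:
#' * `fig5_low.yaml`, `fig5_mid.yaml`, `fig5_high.yaml` -- the three
#'   abundance regimes (`C = 30000, 37000, 50000`; isotropic, polarized,
#'   saturated) at `M = 1000`, `l_half = 150` um, `p = 5`,
#'   `delta = 0.286`, feedback calibrated to `eta = 0.322`;
#' * `fig6_m1000.yaml` / `fig6_m100.yaml` -- the microtubule-number
#'   compensation pair (`M = 1000, l_half = 150` vs `M = 100,
#'   l_half = 15`);
#' * `fig4_scan.yaml` -- an abundance scan grid at full scale;
#' * `scaled_scan.yaml` -- the desk-scale scan (`M = 200, l_half = 30`)
#'   used by the package's own validation runs.
#'
#' @param dir output directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim_default <- list(dt = 1, t_total = 20000, t_equil = 10000, seed = 1,
                      mode = "normal", record_interval = 20)
  pth <- character(0)
  emit <- function(name, C, M, l_half, sim = sim_default, scan = NULL) {
    p <- default_params(C_total = C, M = M, l_half = l_half)
    fp <- file.path(dir, name)
    save_config(p, fp, sim = sim, scan = scan)
    pth <<- c(pth, fp)
  }
  emit("fig5_low.yaml", 30000, 1000, 150)
  emit("fig5_mid.yaml", 37000, 1000, 150)
  emit("fig5_high.yaml", 50000, 1000, 150)
  emit("fig6_m1000.yaml", 37000, 1000, 150)
  emit("fig6_m100.yaml", 37000, 100, 15)
  emit("fig4_scan.yaml", 37000, 1000, 150,
       scan = list(C_values = c(20000, 25000, 30000, 33000, 36000, 39000,
                                42000, 46000, 50000, 60000),
                   n_seeds = 8))
  emit("scaled_scan.yaml", 37000, 200, 30,
       scan = list(C_values = c(30000, 37000, 50000), n_seeds = 4))
  invisible(pth)
}
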