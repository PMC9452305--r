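#' Simulation configuration
#'
#' Bundles every tunable of the synthetic experiment generator. Defaults
#' emulate the volumetric NTS preparation the pipeline targets: a
#' 509.12 x 509.12 x 320 um field sampled as 5 planes of 512 x 512 pixels at
#' 1.25 volumes/s, ~2,800 nuclear-labelled neurons, organ response domains a
#' few tens of um apart, ~90% single-organ selectivity among responders, and
#' a mix of rapidly and slowly adapting kinetics.
#'
#' @param n_neurons number of neurons to simulate.
#' @param fov_um numeric length-3, field extent in um (x, y, z).
#' @param n_planes number of imaging planes spanning the z extent.
#' @param frame_rate_hz volumetric acquisition rate (volumes/s).
#' @param img_px lateral image size in pixels (square images).
#' @param organs named list; one entry per organ with fields `centroid`
#'   (length-3, um) and `spread` (um, isotropic Gaussian SD of the domain).
#' @param frac_selective fraction of all neurons tuned to exactly one organ.
#' @param frac_multi fraction of all neurons tuned to two or more organs.
#'   `frac_selective + frac_multi <= 1`; the remainder are non-responders.
#' @param frac_rapid fraction of responders with rapidly adapting kinetics.
#' @param kernel_rise_s,kernel_decay_s calcium-indicator rise/decay time
#'   constants in seconds (difference-of-exponentials kernel).
#' @param adapt_tau_s time constant (s) of within-stimulus adaptation for the
#'   rapid class.
#' @param amp_meanlog,amp_sdlog,amp_min log-normal parameters and floor of
#'   per-neuron peak response amplitude (dF/F units).
#' @param hill_n,ec50 Hill exponent and per-organ half-saturation volumes
#'   (named numeric, ul) of the saturating dose-response map for distensions.
#' @param noise_sd per-frame dF/F noise SD added to traces.
#' @param drift_rate fractional photobleaching per minute of raw fluorescence.
#' @param baseline_f0 mean raw baseline fluorescence (arbitrary units).
#' @param suppression list of cross-inhibition rules, each a list with fields
#'   `suppressed`, `suppressor` (organ labels), `fraction` (of neurons tuned
#'   to the suppressed organ that are sensitive), and `strength` in \[0,1\]
#'   (fractional amplitude loss at saturating co-stimulus intensity).
#' @param nucleus_radius_px rendered nuclear radius (Gaussian sigma, px).
#' @param render_background,render_noise_sd rendered-image background level
#'   and additive pixel noise SD (arbitrary units).
#' @param min_sep_um minimum in-plane (x, y) distance between somata (um);
#'   0 disables the dart-throwing separation constraint.
#' @param edge_margin_um lateral margin (um) kept free of somata at the FOV
#'   border (edge ROIs are not analysable in real recordings).
#' @param seed integer seed; all generator randomness flows from it.
#' @return a list of class `viscmap_sim_config`.
#' @export
sim_config <- function(n_neurons = 2800,
                       fov_um = c(509.12, 509.12, 320),
                       n_planes = 5,
                       frame_rate_hz = 1.25,
                       img_px = 512,
                       organs = list(
                         stomach = list(centroid = c(225, 255, 160), spread = 40),
                         duodenum = list(centroid = c(285, 255, 160), spread = 40)
                       ),
                       frac_selective = 0.54,
                       frac_multi = 0.06,
                       frac_rapid = 0.5,
                       kernel_rise_s = 0.3,
                       kernel_decay_s = 1.5,
                       adapt_tau_s = 8,
                       amp_meanlog = log(1.0),
                       amp_sdlog = 0.35,
                       amp_min = 0.4,
                       hill_n = 1.5,
                       ec50 = c(stomach = 300, duodenum = 100,
                                jejunum = 100, larynx = 50),
                       noise_sd = 0.1,
                       drift_rate = 0.02,
                       baseline_f0 = 100,
                       suppression = list(
                         list(suppressed = "duodenum", suppressor = "stomach",
                              fraction = 0.3, strength = 0.7)
                       ),
                       nucleus_radius_px = 3,
                       render_background = 20,
                       render_noise_sd = 2,
                       min_sep_um = 0,
                       edge_margin_um = 0,
                       seed = 1L) {
  cfg <- list(n_neurons = as.integer(n_neurons), fov_um = as.numeric(fov_um),
              n_planes = as.integer(n_planes),
              frame_rate_hz = as.numeric(frame_rate_hz),
              img_px = as.integer(img_px), organs = organs,
              frac_selective = frac_selective, frac_multi = frac_multi,
              frac_rapid = frac_rapid, kernel_rise_s = kernel_rise_s,
              kernel_decay_s = kernel_decay_s, adapt_tau_s = adapt_tau_s,
              amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
              amp_min = amp_min, hill_n = hill_n, ec50 = ec50,
              noise_sd = noise_sd, drift_rate = drift_rate,
              baseline_f0 = baseline_f0, suppression = suppression,
              nucleus_radius_px = nucleus_radius_px,
              render_background = render_background,
              render_noise_sd = render_noise_sd,
              min_sep_um = min_sep_um,
              edge_margin_um = edge_margin_um, seed = as.integer(seed))
  class(cfg) <- "viscmap_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$frac_selective, cfg$frac_multi, cfg$frac_rapid)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$frac_selective + cfg$frac_multi > 1 + 1e-12)
    stop("frac_selective + frac_multi must be <= 1")
  if (cfg$n_neurons < 1) stop("at least one neuron must be requested")
  if (cfg$n_planes < 1) stop("n_planes must be >= 1")
  if (cfg$frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  if (length(cfg$fov_um) != 3 || any(cfg$fov_um <= 0))
    stop("fov_um must be three positive extents")
  if (length(cfg$organs) < 1) stop("at least one organ must be configured")
  if (is.null(names(cfg$organs)) || any(names(cfg$organs) == ""))
    stop("organs must be a named list")
  for (o in names(cfg$organs)) {
    oc <- cfg$organs[[o]]
    if (length(oc$centroid) != 3)
      stop("organ '", o, "': centroid must be length 3 (um)")
    if (any(oc$centroid < 0 | oc$centroid > cfg$fov_um))
      stop("organ '", o, "': centroid outside the FOV")
    if (oc$spread <= 0) stop("organ '", o, "': spread must be positive")
  }
  for (s in cfg$suppression) {
    if (!all(c("suppressed", "suppressor", "fraction", "strength") %in%
             names(s)))
      stop("each suppression rule needs suppressed/suppressor/fraction/strength")
    if (s$fraction < 0 || s$fraction > 1 || s$strength < 0 || s$strength > 1)
      stop("suppression fraction and strength must lie in [0, 1]")
  }
  invisible(cfg)
}

#' @rdname sim_config
#' @param path YAML file path.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$ec50 <- unlist(y$ec50)
  do.call(sim_config, y)
}

#' @rdname sim_config
#' @param cfg a `viscmap_sim_config` to write.
#' @export
write_sim_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$ec50 <- as.list(y$ec50)
  yaml::write_yaml(y, path)
  invisible(path)
}

# micrometres per pixel in x/y, and plane spacing in z
um_per_px <- function(cfg) cfg$fov_um[1:2] / cfg$img_px
plane_spacing_um <- function(cfg) cfg$fov_um[3] / cfg$n_planes
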