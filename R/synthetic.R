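#' Saturating dose-response map for distension stimuli
#'
#' Response amplitude scales with distension volume through a Hill-type
#' saturation, so graded volumes of the same organ produce graded responses.
#' Chemical stimuli are not dose-scaled (intensity is a label).
#'
#' @param intensity stimulus intensity (ul for distension).
#' @param organ organ label (selects the half-saturation volume).
#' @param cfg a [sim_config()].
#' @return scaling factor in (0, 1].
#' @keywords internal
hill_scale <- function(intensity, organ, cfg) {
  ec <- cfg$ec50[[organ]]
  if (is.null(ec) || is.na(ec)) ec <- stats::median(cfg$ec50)
  intensity^cfg$hill_n / (intensity^cfg$hill_n + ec^cfg$hill_n)
}

#' Synthesize a noiseless dF/F trace for one neuron
#'
#' Builds the deterministic response trace implied by a neuron's per-stimulus
#' peak amplitudes and adaptation class. Slowly adapting neurons rise with the
#' indicator rise time and sustain a plateau for the stimulus duration;
#' rapidly adapting neurons rise at onset and relax toward baseline during
#' the stimulus with time constant `adapt_tau_s`. After stimulus offset both
#' classes decay with the indicator decay time. Each stimulus's unit shape is
#' peak-normalized before scaling, so the trace maximum within a stimulus
#' window equals the requested amplitude exactly.
#'
#' @param amplitudes numeric vector of peak dF/F amplitudes, one per protocol
#'   row (order matches the protocol); all `>= 0`.
#' @param kinetic_class `"rapid"` or `"slow"`.
#' @param protocol a [stimulus_protocol()].
#' @param cfg a [sim_config()].
#' @param n_frames trace length; defaults to [protocol_length()].
#' @return numeric vector of noiseless dF/F, zero away from transients.
#' @export
synthesize_trace <- function(amplitudes, kinetic_class, protocol, cfg,
                             n_frames = protocol_length(protocol)) {
  if (!kinetic_class %in% c("rapid", "slow"))
    stop("unknown kinetic class: '", kinetic_class, "'")
  if (length(amplitudes) != nrow(protocol))
    stop("need one amplitude per protocol event")
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  dt <- 1 / cfg$frame_rate_hz
  trace <- numeric(n_frames)
  for (s in seq_len(nrow(protocol))) {
    a <- amplitudes[s]
    if (a == 0) next
    on <- protocol$onset_frame[s]   # 0-based
    off <- protocol$offset_frame[s]
    idx <- (on + 1):n_frames        # 1-based frames from onset on
    tt <- (seq_along(idx)) * dt     # time since onset at each frame
    rise <- 1 - exp(-tt / cfg$kernel_rise_s)
    shape <- if (kinetic_class == "slow") rise
             else rise * exp(-tt / cfg$adapt_tau_s)
    stim_len <- off - on
    if (length(shape) > stim_len) {
      post <- (stim_len + 1):length(shape)
      t_post <- (seq_along(post)) * dt
      shape[post] <- shape[stim_len] * exp(-t_post / cfg$kernel_decay_s)
    }
    shape <- shape / max(shape[seq_len(min(stim_len, length(shape)))])
    shape[shape < 1e-4] <- 0
    trace[idx] <- trace[idx] + a * shape
  }
  trace
}

draw_positions <- function(cfg, organ_of_neuron) {
  n <- cfg$n_neurons
  pos <- matrix(NA_real_, n, 3)
  max_try <- 200L
  lo <- c(rep(cfg$edge_margin_um, 2), 0)
  hi <- cfg$fov_um - c(rep(cfg$edge_margin_um, 2), 0) - 1e-9
  for (i in seq_len(n)) {
    org <- organ_of_neuron[i]
    for (try in seq_len(max_try)) {
      p <- if (is.na(org)) stats::runif(3, lo, hi) else {
        oc <- cfg$organs[[org]]
        q <- stats::rnorm(3, oc$centroid, oc$spread)
        pmin(pmax(q, lo), hi)
      }
      # separation enforced in-plane: somata on one plane must not overlap
      if (cfg$min_sep_um <= 0 || i == 1) break
      prev <- pos[seq_len(i - 1), 1:2, drop = FALSE]
      d2 <- (prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2
      if (min(d2) >= cfg$min_sep_um^2) break
      if (try == max_try)
        warning("min_sep_um constraint could not be satisfied for neuron ", i)
    }
    pos[i, ] <- p
  }
  pos
}

#' Generate a complete synthetic experiment with ground truth
#'
#' Draws neuron positions from per-organ Gaussian spatial domains, assigns
#' organ tuning (selective / multi-organ / non-responder), adaptation
#' kinetics, per-stimulus response amplitudes with saturating dose
#' dependence, and cross-organ suppression sensitivity; synthesizes noiseless
#' dF/F traces; and converts them to raw fluorescence with photobleaching
#' drift and Gaussian noise:
#' `F = baseline * (1 + drift(t)) * (1 + dF/F_true) + noise`.
#'
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param protocol a [stimulus_protocol()]; every organ it references must be
#'   configured in `cfg$organs`.
#' @param n_frames recording length; defaults to fitting the protocol plus a
#'   20-frame tail.
#' @return list with elements `neurons` (NeuronSet data frame), `truth`
#'   (`viscmap_ground_truth`), `fluor` (`viscmap_fluor`: raw fluorescence
#'   matrix neurons x frames plus frame rate), and `protocol`.
#' @export
generate_experiment <- function(cfg, protocol,
                                n_frames = protocol_length(protocol)) {
  validate_sim_config(cfg)
  validate_protocol(protocol, n_frames)
  missing_org <- setdiff(unique(protocol$organ), names(cfg$organs))
  if (length(missing_org))
    stop("protocol organ(s) absent from config: ",
         paste(missing_org, collapse = ", "))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_neurons
    organs <- names(cfg$organs)
    n_stim <- nrow(protocol)

    # tuning category per neuron: selective / multi / none
    u <- stats::runif(n)
    category <- ifelse(u < cfg$frac_selective, "selective",
                ifelse(u < cfg$frac_selective + cfg$frac_multi,
                       "multi_organ", "none"))
    if (any(category == "multi_organ") && length(organs) < 2)
      stop("frac_multi > 0 requires at least two configured organs")
    tuning <- vector("list", n)
    for (i in seq_len(n)) {
      tuning[[i]] <- switch(category[i],
        selective = sample(organs, 1),
        multi_organ = sample(organs, 2),
        none = character(0))
    }
    home_organ <- vapply(tuning, function(x)
      if (length(x)) x[1] else NA_character_, character(1))

    pos <- draw_positions(cfg, home_organ)
    spacing <- plane_spacing_um(cfg)
    plane <- pmin(cfg$n_planes - 1L,
                  pmax(0L, as.integer(round(pos[, 3] / spacing))))

    responder <- category != "none"
    kinetic <- rep("none", n)
    kinetic[responder] <- ifelse(stats::runif(sum(responder)) < cfg$frac_rapid,
                                 "rapid", "slow")

    # per-neuron base amplitude, dose-scaled per stimulus of a tuned organ
    base_amp <- pmax(stats::rlnorm(n, cfg$amp_meanlog, cfg$amp_sdlog),
                     cfg$amp_min)
    amp <- matrix(0, n, n_stim,
                  dimnames = list(NULL, protocol$stim_id))
    dose <- vapply(seq_len(n_stim), function(s)
      if (protocol$modality[s] == "stretch")
        hill_scale(protocol$intensity[s], protocol$organ[s], cfg) else 1,
      numeric(1))
    for (i in which(responder))
      for (s in seq_len(n_stim))
        if (protocol$organ[s] %in% tuning[[i]])
          amp[i, s] <- base_amp[i] * dose[s]

    # cross-organ suppression sensitivity
    suppressed_by <- vector("list", n)
    for (rule in cfg$suppression) {
      cand <- which(vapply(tuning, function(x) rule$suppressed %in% x,
                           logical(1)))
      hit <- cand[stats::runif(length(cand)) < rule$fraction]
      for (i in hit)
        suppressed_by[[i]] <- c(suppressed_by[[i]], rule$suppressor)
    }

    # effective amplitudes: multiplicative suppression during simultaneous
    # presentation, dose-dependent in the suppressor's intensity
    eff_amp_for <- function(i) {
      a <- amp[i, ]
      for (rule in cfg$suppression) {
        if (!(rule$suppressor %in% suppressed_by[[i]])) next
        for (s in seq_len(n_stim)) {
          if (protocol$organ[s] != rule$suppressed || a[s] == 0) next
          ov <- which(protocol$organ == rule$suppressor &
                      protocol$onset_frame < protocol$offset_frame[s] &
                      protocol$offset_frame > protocol$onset_frame[s])
          if (!length(ov)) next
          co <- max(vapply(ov, function(k)
            if (protocol$modality[k] == "stretch")
              hill_scale(protocol$intensity[k], protocol$organ[k], cfg) else 1,
            numeric(1)))
          a[s] <- a[s] * (1 - rule$strength * co)
        }
      }
      a
    }

    dff_true <- matrix(0, n, n_frames)
    for (i in which(responder))
      dff_true[i, ] <- synthesize_trace(eff_amp_for(i), kinetic[i],
                                        protocol, cfg, n_frames)

    baseline <- cfg$baseline_f0 * stats::runif(n, 0.8, 1.2)
    t_min <- (seq_len(n_frames) - 1) / cfg$frame_rate_hz / 60
    drift <- 1 - cfg$drift_rate * t_min
    noise <- matrix(stats::rnorm(n * n_frames, 0, cfg$noise_sd), n, n_frames) *
      baseline
    F <- sweep(1 + dff_true, 2, drift, `*`) * baseline + noise

    neurons <- data.frame(
      neuron_id = seq_len(n),
      x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
      plane = plane, stringsAsFactors = FALSE)
    class(neurons) <- c("viscmap_neurons", "data.frame")

    truth <- list(
      neurons = data.frame(
        neuron_id = seq_len(n),
        tuning = vapply(tuning, paste, character(1), collapse = ","),
        selectivity = category,
        kinetic_class = kinetic,
        suppressed_by = vapply(suppressed_by, function(x)
          paste(unique(x), collapse = ","), character(1)),
        base_amplitude = base_amp * responder,
        stringsAsFactors = FALSE),
      amplitude = amp,
      responsive = amp > 0)
    class(truth) <- "viscmap_ground_truth"

    fluor <- list(F = F, frame_rate_hz = cfg$frame_rate_hz)
    class(fluor) <- "viscmap_fluor"

    list(neurons = neurons, truth = truth, fluor = fluor,
         protocol = protocol, dff_true = dff_true)
  })
}

#' Render a synthetic experiment as an image stack
#'
#' Each neuron is drawn as a 2D Gaussian nucleus on its nearest imaging
#' plane, with peak intensity equal to its raw fluorescence at that frame,
#' on a constant background with additive Gaussian pixel noise.
#'
#' @param neurons NeuronSet data frame (`x_um`, `y_um`, `plane`).
#' @param fluor a `viscmap_fluor` (raw fluorescence, neurons x frames).
#' @param cfg a [sim_config()]; `img_px`, `nucleus_radius_px`,
#'   `render_background` and `render_noise_sd` control the rendering.
#' @param seed optional seed for the pixel noise (defaults to `cfg$seed + 1`).
#' @return a `viscmap_movie`: list with `data` array
#'   `[row, col, plane, frame]`, pixel size, and plane count.
#' @export
render_movie <- function(neurons, fluor, cfg, seed = cfg$seed + 1L) {
  H <- W <- cfg$img_px
  upp <- um_per_px(cfg)
  if (any(neurons$x_um < 0 | neurons$x_um > cfg$fov_um[1] |
          neurons$y_um < 0 | neurons$y_um > cfg$fov_um[2]))
    stop("neuron position outside the FOV cannot be rendered")
  n_frames <- ncol(fluor$F)
  r <- cfg$nucleus_radius_px
  half <- ceiling(3 * r)
  gx <- outer((-half:half)^2, (-half:half)^2, `+`)
  patch <- exp(-gx / (2 * r^2))
  # 0-based pixel coordinates: col from x, row from y
  pc <- round(neurons$x_um / upp[1])
  pr <- round(neurons$y_um / upp[2])
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    data <- array(stats::rnorm(H * W * cfg$n_planes * n_frames,
                               cfg$render_background, cfg$render_noise_sd),
                  dim = c(H, W, cfg$n_planes, n_frames))
    for (i in seq_len(nrow(neurons))) {
      rows <- (pr[i] - half):(pr[i] + half) + 1L
      cols <- (pc[i] - half):(pc[i] + half) + 1L
      ok_r <- rows >= 1 & rows <= H
      ok_c <- cols >= 1 & cols <= W
      p <- neurons$plane[i] + 1L
      data[rows[ok_r], cols[ok_c], p, ] <-
        data[rows[ok_r], cols[ok_c], p, ] +
        outer(patch[ok_r, ok_c, drop = FALSE], fluor$F[i, ])
    }
    movie <- list(data = data, um_per_px = upp,
                  n_planes = cfg$n_planes, frame_rate_hz = cfg$frame_rate_hz,
                  plane_spacing_um = plane_spacing_um(cfg))
    class(movie) <- "viscmap_movie"
    movie
  })
}

#' Write / read a movie as a multi-page TIFF
#'
#' Pages are ordered frame-major (all planes of frame 1, then frame 2, ...).
#' Values are stored as 32-bit float after division by `scale`, which is
#' written into the page order's first page description implicitly via the
#' sidecar-free convention: the caller passes the same `scale` and
#' `n_planes` when reading back.
#'
#' @param movie a `viscmap_movie`.
#' @param path output TIFF path.
#' @param scale divisor applied before writing (default: movie maximum).
#' @return `scale`, invisibly (needed to restore raw units on read).
#' @export
write_movie_tiff <- function(movie, path, scale = max(movie$data)) {
  d <- movie$data / scale
  pages <- list()
  k <- 0L
  for (f in seq_len(dim(d)[4]))
    for (p in seq_len(dim(d)[3])) {
      k <- k + 1L
      pages[[k]] <- d[, , p, f]
    }
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  invisible(scale)
}

#' @rdname write_movie_tiff
#' @param n_planes planes per volume used when writing.
#' @param um_per_px,frame_rate_hz,plane_spacing_um acquisition metadata to
#'   attach to the restored movie.
#' @export
read_movie_tiff <- function(path, n_planes, scale = 1,
                            um_per_px = c(1, 1), frame_rate_hz = 1.25,
                            plane_spacing_um = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  n_frames <- length(pages) / n_planes
  if (n_frames != round(n_frames))
    stop("page count is not a multiple of n_planes")
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  data <- array(0, c(H, W, n_planes, n_frames))
  k <- 0L
  for (f in seq_len(n_frames))
    for (p in seq_len(n_planes)) {
      k <- k + 1L
      data[, , p, f] <- pages[[k]] * scale
    }
  movie <- list(data = data, um_per_px = um_per_px, n_planes = n_planes,
                frame_rate_hz = frame_rate_hz,
                plane_spacing_um = plane_spacing_um)
  class(movie) <- "viscmap_movie"
  movie
}
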