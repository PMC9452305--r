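#' Compute dF/F from raw fluorescence
#'
#' `dF/F = (F_t - F0) / F0`, with `F0` the mean raw fluorescence over a
#' baseline window (by convention the 24-s pre-stimulus period of the first
#' stimulus; 30 frames at 1.25 volumes/s).
#'
#' @param fluor a `viscmap_fluor` (raw fluorescence, neurons x frames), or a
#'   bare matrix.
#' @param baseline_window integer vector of 1-based frame indices.
#' @return a `viscmap_dff`: list with `dff` matrix, `frame_rate_hz`,
#'   `detrended` flag.
#' @export
compute_dff <- function(fluor, baseline_window) {
  F <- if (inherits(fluor, "viscmap_fluor")) fluor$F else fluor
  rate <- if (inherits(fluor, "viscmap_fluor")) fluor$frame_rate_hz else NA
  if (!length(baseline_window)) stop("baseline window is empty")
  if (any(baseline_window < 1 | baseline_window > ncol(F)))
    stop("baseline window outside the recording")
  F0 <- rowMeans(F[, baseline_window, drop = FALSE])
  bad <- which(F0 <= 0)
  if (length(bad))
    stop("baseline fluorescence F0 <= 0 for neuron(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; dF/F is undefined")
  dff <- sweep(sweep(F, 1, F0, `-`), 1, F0, `/`)
  out <- list(dff = dff, frame_rate_hz = rate, detrended = FALSE)
  class(out) <- "viscmap_dff"
  out
}

#' Remove slow non-stationary trends from a dF/F trace
#'
#' Fits a linear trend to the frames outside all stimulus-driven windows
#' (each stimulus window extended by `pad_frames` to let transients decay)
#' and subtracts it, removing photobleaching-like drift. When `exclude` is
#' set (duodenal chemical perfusion runs, where slow real responses would be
#' mistaken for a trend) the trace is returned unchanged.
#'
#' @param trace numeric dF/F vector.
#' @param protocol a [stimulus_protocol()] (may be `NULL`: whole trace used).
#' @param exclude logical; `TRUE` skips detrending.
#' @param pad_frames frames appended to each stimulus window when choosing
#'   trend-fit frames.
#' @return the detrended trace.
#' @export
detrend_trace <- function(trace, protocol = NULL, exclude = FALSE,
                          pad_frames = 20L) {
  if (exclude) return(trace)
  n <- length(trace)
  in_stim <- rep(FALSE, n)
  if (!is.null(protocol))
    for (s in seq_len(nrow(protocol))) {
      a <- protocol$onset_frame[s] + 1L
      b <- min(n, protocol$offset_frame[s] + pad_frames)
      in_stim[a:b] <- TRUE
    }
  fit_idx <- which(!in_stim)
  if (length(fit_idx) < 2) {
    warning("no stimulus-free frames; trend fitted on the whole trace")
    fit_idx <- seq_len(n)
  }
  t_all <- seq_len(n)
  co <- stats::coef(stats::lm.fit(cbind(1, fit_idx), trace[fit_idx]))
  trace - (co[1] + co[2] * t_all)
}

#' Apply dF/F detrending across a matrix
#'
#' @param dff a `viscmap_dff`.
#' @inheritParams detrend_trace
#' @return the `viscmap_dff` with detrended traces and `detrended = TRUE`
#'   (unless `exclude`).
#' @export
detrend_dff <- function(dff, protocol = NULL, exclude = FALSE,
                        pad_frames = 20L) {
  if (!exclude) {
    dff$dff <- t(apply(dff$dff, 1, detrend_trace, protocol = protocol,
                       exclude = FALSE, pad_frames = pad_frames))
    dff$detrended <- TRUE
  }
  dff
}

#' Per-stimulus baseline statistics and response threshold
#'
#' For one neuron's dF/F trace and one stimulus event, computes the
#' pre-stimulus baseline mean `F0` and SD `s0` over a 24-s window, the
#' response threshold `theta = F0 + 2.5 * s0`, and the short-window
#' statistics used by the persistence criteria: `F0_m`/`s0_m` over the 7
#' frames before onset (mechanical) and `F0_c`/`s0_c` over the 25 frames
#' before onset (chemical). All statistics live in dF/F units (the trace is
#' already baseline-normalized and detrended, so `F0` is close to zero);
#' this is the only reading under which comparing in-window dF/F against
#' `theta` is dimensionally coherent.
#'
#' @param trace numeric dF/F vector.
#' @param stimulus one-row slice of a [stimulus_protocol()].
#' @param frame_rate_hz acquisition rate; fixes the 24-s window length.
#' @return list of class `viscmap_baseline`: `F0`, `s0`, `theta`, `F0_m`,
#'   `s0_m`, `F0_c`, `s0_c`, plus the window lengths used.
#' @export
baseline_stats <- function(trace, stimulus, frame_rate_hz = 1.25) {
  onset <- stimulus$onset_frame   # 0-based; frames before onset: 1..onset
  n_long <- round(24 * frame_rate_hz)
  need <- if (stimulus$modality == "chemical") max(n_long, 25L) else n_long
  if (onset < need)
    stop("stimulus '", stimulus$stim_id %||% stimulus$organ,
         "': only ", onset, " pre-stimulus frames; ", need, " required")
  win_long <- (onset - n_long + 1):onset
  win7 <- (onset - 7 + 1):onset
  win25 <- (onset - 25 + 1):onset
  F0 <- mean(trace[win_long]); s0 <- stats::sd(trace[win_long])
  out <- list(F0 = F0, s0 = s0, theta = F0 + 2.5 * s0,
              F0_m = mean(trace[win7]), s0_m = stats::sd(trace[win7]),
              F0_c = mean(trace[win25]), s0_c = stats::sd(trace[win25]),
              n_long = n_long)
  class(out) <- "viscmap_baseline"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
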