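#' Stimulus protocols
#'
#' A stimulus protocol is an ordered table of stimulation events, one row per
#' event, with columns `organ` (character), `modality` (`"stretch"` or
#' `"chemical"`), `intensity` (numeric; microlitres for distension, a
#' concentration code for perfusions), and half-open frame windows
#' `onset_frame`/`offset_frame` in 0-based volume indices.
#'
#' @param organ character vector of organ labels.
#' @param modality character vector, each `"stretch"` or `"chemical"`.
#' @param intensity numeric vector of stimulus intensities.
#' @param onset_frame,offset_frame integer vectors of 0-based volume indices;
#'   each event occupies `[onset_frame, offset_frame)`.
#' @param n_frames optional recording length; when given, events must fit.
#' @return a `data.frame` of class `viscmap_protocol`, ordered by onset.
#' @examples
#' stimulus_protocol("stomach", "stretch", 600, 50, 100)
#' @export
stimulus_protocol <- function(organ, modality, intensity,
                              onset_frame, offset_frame, n_frames = NULL) {
  p <- data.frame(
    organ = as.character(organ),
    modality = as.character(modality),
    intensity = as.numeric(intensity),
    onset_frame = as.integer(onset_frame),
    offset_frame = as.integer(offset_frame),
    stringsAsFactors = FALSE
  )
  validate_protocol(p, n_frames)
  p <- p[order(p$onset_frame), , drop = FALSE]
  rownames(p) <- NULL
  p$stim_id <- make.unique(paste(p$organ, p$modality, p$intensity, sep = "_"))
  class(p) <- c("viscmap_protocol", "data.frame")
  p
}

validate_protocol <- function(p, n_frames = NULL) {
  req <- c("organ", "modality", "intensity", "onset_frame", "offset_frame")
  miss <- setdiff(req, names(p))
  if (length(miss))
    stop("protocol is missing column(s): ", paste(miss, collapse = ", "))
  bad_mod <- !p$modality %in% c("stretch", "chemical")
  if (any(bad_mod))
    stop("unknown modality in protocol row(s) ",
         paste(which(bad_mod), collapse = ", "),
         " (must be 'stretch' or 'chemical')")
  bad <- !(p$onset_frame < p$offset_frame)
  if (any(bad))
    stop("protocol row(s) ", paste(which(bad), collapse = ", "),
         ": onset_frame must be < offset_frame")
  if (any(p$onset_frame < 0))
    stop("protocol onset_frame must be >= 0")
  if (!is.null(n_frames) && any(p$offset_frame > n_frames))
    stop("protocol events extend beyond the recording (n_frames = ",
         n_frames, ")")
  invisible(p)
}

#' Default stimulation protocol used by the synthetic experiments
#'
#' Graded 40-s balloon distensions of the stomach (150, 300, 600, 900 ul) and
#' duodenum (90, 115, 140 ul) at 1.25 volumes/s, with a 24-s-plus pre-stimulus
#' lead-in before every onset so baseline windows are always available.
#'
#' @param frame_rate_hz acquisition rate in volumes per second.
#' @param stim_s stimulus duration in seconds.
#' @param gap_s inter-stimulus interval in seconds.
#' @return a `viscmap_protocol`.
#' @export
default_protocol <- function(frame_rate_hz = 1.25, stim_s = 40, gap_s = 80) {
  stim_f <- round(stim_s * frame_rate_hz)
  gap_f <- round(gap_s * frame_rate_hz)
  organs <- c(rep("stomach", 4), rep("duodenum", 3))
  vols <- c(150, 300, 600, 900, 90, 115, 140)
  onsets <- gap_f + (seq_along(vols) - 1L) * (stim_f + gap_f)
  stimulus_protocol(organs, rep("stretch", length(vols)), vols,
                    onsets, onsets + stim_f)
}

#' Number of frames needed to play out a protocol
#'
#' Includes a post-offset tail (20 frames by default) so chemical response
#' windows never truncate.
#' @param protocol a `viscmap_protocol`.
#' @param tail_frames frames appended after the last offset.
#' @export
protocol_length <- function(protocol, tail_frames = 20L) {
  max(protocol$offset_frame) + as.integer(tail_frames)
}

#' @rdname stimulus_protocol
#' @param path file path (CSV).
#' @export
read_protocol <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  stimulus_protocol(p$organ, p$modality, p$intensity,
                    p$onset_frame, p$offset_frame)
}

#' @rdname stimulus_protocol
#' @param protocol a `viscmap_protocol` to write.
#' @export
write_protocol <- function(protocol, path) {
  utils::write.csv(as.data.frame(protocol)[, c("organ", "modality",
    "intensity", "onset_frame", "offset_frame")], path, row.names = FALSE)
  invisible(path)
}
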