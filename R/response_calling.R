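longest_run <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Centered moving average with shrinking edge windows
#'
#' @param x numeric vector.
#' @param w window width (odd; default 5 frames).
#' @return smoothed vector, same length.
#' @export
moving_average <- function(x, w = 5L) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  # shifted-column means (not cumsum differences) so identical local
  # patterns smooth to bit-identical values anywhere in the trace
  M <- vapply(-half:half, function(k) {
    idx <- seq_len(n) + k
    v <- rep(NA_real_, n)
    ok <- idx >= 1L & idx <= n
    v[ok] <- x[idx[ok]]
    v
  }, numeric(n))
  rowMeans(M, na.rm = TRUE)
}

# 1-based in-window frame indices for a stimulus and modality
response_window <- function(stimulus, n_frames, post_frames = 20L) {
  a <- stimulus$onset_frame + 1L
  b <- stimulus$offset_frame
  if (stimulus$modality == "chemical") {
    b2 <- b + post_frames
    if (b2 > n_frames)
      warning("chemical response window truncated at the recording end")
    b <- min(b2, n_frames)
  }
  a:b
}

#' Mechanical response criterion
#'
#' A neuron responds to a distension if, within the stimulation window,
#' its dF/F (1) exceeds `theta` for more than three continuous frames and
#' (2) exceeds both `F0_m + 2 * s0_m` (the 7-frame pre-onset statistics) and
#' `theta` for at least two continuous frames. "More than three" is strict:
#' a 3-frame run fails, a 4-frame run passes.
#'
#' @param trace dF/F vector.
#' @param stats a [baseline_stats()] result for this stimulus.
#' @param stimulus one-row protocol slice.
#' @return list: `responsive`, `n_run_theta`, `n_run_bound`, `bound`.
#' @export
call_mechanical_response <- function(trace, stats, stimulus) {
  win <- (stimulus$onset_frame + 1L):stimulus$offset_frame
  if (length(win) < 4L) {
    warning("stimulus window shorter than 4 frames; cannot be responsive")
    return(list(responsive = FALSE, n_run_theta = 0L, n_run_bound = 0L,
                bound = NA_real_))
  }
  x <- trace[win]
  bound <- max(stats$F0_m + 2 * stats$s0_m, stats$theta)
  r1 <- longest_run(x > stats$theta)
  r2 <- longest_run(x > bound)
  list(responsive = r1 >= 4L && r2 >= 2L,
       n_run_theta = r1, n_run_bound = r2, bound = bound)
}

#' Chemical response criterion
#'
#' Evaluated over the stimulation window plus the 20 frames after offset:
#' dF/F must exceed `theta` for more than four continuous frames and exceed
#' both `F0_c + 2 * s0_c` (25-frame pre-onset statistics) and `theta` for at
#' least two continuous frames.
#'
#' @inheritParams call_mechanical_response
#' @param n_frames recording length (bounds the post-offset window).
#' @param post_frames frames appended after offset (default 20).
#' @return list as in [call_mechanical_response()].
#' @export
call_chemical_response <- function(trace, stats, stimulus,
                                   n_frames = length(trace),
                                   post_frames = 20L) {
  win <- response_window(stimulus, n_frames, post_frames)
  if (length(win) < 5L)
    return(list(responsive = FALSE, n_run_theta = 0L, n_run_bound = 0L,
                bound = NA_real_))
  x <- trace[win]
  bound <- max(stats$F0_c + 2 * stats$s0_c, stats$theta)
  r1 <- longest_run(x > stats$theta)
  r2 <- longest_run(x > bound)
  list(responsive = r1 >= 5L && r2 >= 2L,
       n_run_theta = r1, n_run_bound = r2, bound = bound)
}

#' Response magnitude
#'
#' Maximum of the 5-frame moving-averaged dF/F over the response window
#' (stimulation period for mechanical stimuli; plus the 20 post-offset
#' frames for chemical), minus `theta`. Reported unfloored; clamp at zero at
#' presentation time if desired.
#'
#' @inheritParams call_chemical_response
#' @param smooth_w moving-average width in frames.
#' @return numeric magnitude (dF/F units).
#' @export
response_magnitude <- function(trace, stats, stimulus,
                               n_frames = length(trace), smooth_w = 5L,
                               post_frames = 20L) {
  win <- if (stimulus$modality == "chemical")
    response_window(stimulus, n_frames, post_frames)
  else (stimulus$onset_frame + 1L):stimulus$offset_frame
  if (!length(win)) stop("empty response window")
  sm <- moving_average(trace, smooth_w)
  max(sm[win]) - stats$theta
}

#' Call responses for every neuron x stimulus
#'
#' Applies [baseline_stats()], the modality-appropriate persistence
#' criterion, and [response_magnitude()] across a dF/F matrix.
#'
#' @param dff a `viscmap_dff` (detrended) or bare matrix.
#' @param protocol a [stimulus_protocol()].
#' @param frame_rate_hz acquisition rate (taken from `dff` when available).
#' @param exclusions optional data frame (`neuron_id`, `stim_id`) of
#'   manually excluded responses (set to not-responsive, magnitude `NA`).
#' @return a long `data.frame` (class `viscmap_responses`): one row per
#'   neuron x stimulus with `responsive`, `magnitude`, `theta`, and
#'   run-length diagnostics.
#' @export
call_responses <- function(dff, protocol, frame_rate_hz = NULL,
                           exclusions = NULL) {
  M <- if (inherits(dff, "viscmap_dff")) dff$dff else dff
  rate <- frame_rate_hz %||%
    (if (inherits(dff, "viscmap_dff")) dff$frame_rate_hz else 1.25)
  n <- nrow(M); n_frames <- ncol(M)
  out <- vector("list", nrow(protocol))
  for (s in seq_len(nrow(protocol))) {
    stim <- protocol[s, , drop = FALSE]
    rows <- lapply(seq_len(n), function(i) {
      st <- baseline_stats(M[i, ], stim, rate)
      cl <- if (stim$modality == "chemical")
        call_chemical_response(M[i, ], st, stim, n_frames)
      else call_mechanical_response(M[i, ], st, stim)
      data.frame(neuron_id = i, stim_id = stim$stim_id,
                 organ = stim$organ, modality = stim$modality,
                 intensity = stim$intensity,
                 responsive = cl$responsive,
                 magnitude = response_magnitude(M[i, ], st, stim, n_frames),
                 theta = st$theta,
                 n_run_theta = cl$n_run_theta,
                 n_run_bound = cl$n_run_bound,
                 stringsAsFactors = FALSE)
    })
    out[[s]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (!is.null(exclusions) && nrow(exclusions)) {
    key <- paste(res$neuron_id, res$stim_id)
    ex <- paste(exclusions$neuron_id, exclusions$stim_id)
    hit <- key %in% ex
    res$responsive[hit] <- FALSE
    res$magnitude[hit] <- NA_real_
  }
  rownames(res) <- NULL
  class(res) <- c("viscmap_responses", "data.frame")
  res
}

#' Classify adaptation kinetics by k-means
#'
#' Clusters onset-aligned, peak-normalized response traces with k-means
#' (k = 2, 10 restarts under a fixed seed) and labels the cluster whose mean
#' trace has the larger late-window/early-window amplitude ratio as
#' `"slow"` (sustained) and the other as `"rapid"` (onset-transient).
#'
#' @param traces matrix (responders x frames), onset-aligned windows.
#' @param k number of clusters (2).
#' @param seed RNG seed for the k-means restarts.
#' @return character vector of labels, `"rapid"`/`"slow"`; all `"none"` when
#'   fewer than 2 traces, all `"slow"` when the traces are indistinguishable.
#' @export
classify_kinetics <- function(traces, k = 2L, seed = 1L) {
  n <- nrow(traces)
  if (is.null(n) || n < 2) return(rep("none", if (is.null(n)) 0 else n))
  pk <- apply(abs(traces), 1, max)
  pk[pk == 0] <- 1
  X <- traces / pk
  if (nrow(unique(X)) < k) return(rep("slow", n))
  km <- withr::with_seed(seed, stats::kmeans(X, centers = k, nstart = 10))
  tw <- ncol(X)
  third <- max(1L, floor(tw / 3))
  ratio <- vapply(seq_len(k), function(j) {
    ctr <- km$centers[j, ]
    late <- mean(ctr[(tw - third + 1):tw])
    early <- mean(ctr[seq_len(third)])
    late / (abs(early) + 1e-9)
  }, numeric(1))
  slow_cluster <- which.max(ratio)
  ifelse(km$cluster == slow_cluster, "slow", "rapid")
}

#' Field-of-view inclusion filters
#'
#' @param fov_tables named list of `viscmap_responses` tables, one per FOV.
#' @param mode `"glucose"` (>= 5 neurons responsive to every stimulus),
#'   `"standard"` (>= 2 responsive to all stimuli analysed), or
#'   `"spatial_pairs"` (>= 2 selectively tuned neurons per stimulus of a
#'   pair).
#' @param stimuli stimulus ids to require (default: all present).
#' @param profiles for `"spatial_pairs"`: named list (per FOV) of
#'   [build_tuning_profiles()] tables.
#' @param pair for `"spatial_pairs"`: the two stimulus ids compared.
#' @return character vector of included FOV names.
#' @export
filter_fovs <- function(fov_tables, mode = c("standard", "glucose",
                                             "spatial_pairs"),
                        stimuli = NULL, profiles = NULL, pair = NULL) {
  mode <- match.arg(mode)
  min_n <- switch(mode, glucose = 5L, standard = 2L, spatial_pairs = 2L)
  keep <- vapply(names(fov_tables), function(fv) {
    tab <- fov_tables[[fv]]
    stims <- stimuli %||% unique(tab$stim_id)
    if (mode == "spatial_pairs") {
      if (is.null(profiles) || is.null(pair))
        stop("spatial_pairs mode needs `profiles` and `pair`")
      prof <- profiles[[fv]]
      sel_ids <- prof$neuron_id[prof$selectivity == "selective"]
      cnt <- vapply(pair, function(s)
        sum(tab$responsive & tab$stim_id == s & tab$neuron_id %in% sel_ids),
        numeric(1))
      return(all(cnt >= min_n))
    }
    cnt <- vapply(stims, function(s)
      sum(tab$responsive[tab$stim_id == s]), numeric(1))
    length(cnt) > 0 && all(cnt >= min_n)
  }, logical(1))
  names(fov_tables)[keep]
}
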