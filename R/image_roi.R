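#' Detect neuronal nuclei by normalized cross-correlation
#'
#' Cross-correlates a mean (time-averaged) image against a Gaussian kernel
#' whose size approximates an average nucleus, thresholds the correlation
#' map, labels connected components, filters them by area, and reports
#' centroids. Overlapping/adjacent detections are resolved greedily by
#' keeping the higher-correlation peak.
#'
#' @param mean_image 2D numeric matrix (rows = y, cols = x).
#' @param kernel_radius_px Gaussian sigma of the nucleus template, pixels.
#' @param corr_threshold correlation threshold in \[0, 1).
#' @param min_area_px,max_area_px inclusive component-area bounds.
#' @param um_per_px length-2 pixel size (x, y) in um.
#' @param plane 0-based plane index attached to the detections.
#' @param plane_spacing_um z distance between planes (um).
#' @return a `viscmap_rois`: list with `table` (one row per ROI:
#'   `roi_id`, `plane`, 0-based centroid pixel coordinates, centroid in um,
#'   `area_px`, `peak_corr`) and `masks` (per-ROI list of `plane` and a
#'   two-column 1-based `pixels` matrix). A constant image yields zero ROIs.
#' @export
detect_nuclei <- function(mean_image, kernel_radius_px = 3,
                          corr_threshold = 0.5,
                          min_area_px = 20, max_area_px = 400,
                          um_per_px = c(1, 1), plane = 0L,
                          plane_spacing_um = 1) {
  if (length(dim(mean_image)) != 2)
    stop("mean_image must be a 2D matrix")
  if (!all(is.finite(mean_image))) stop("mean_image must be finite")
  if (kernel_radius_px < 1) stop("kernel_radius_px must be >= 1")

  half <- ceiling(3 * kernel_radius_px)
  ax <- (-half:half)^2
  kern <- exp(-outer(ax, ax, `+`) / (2 * kernel_radius_px^2))
  k0 <- kern - mean(kern)
  n_k <- length(kern)
  box <- matrix(1, nrow(kern), ncol(kern))

  num <- EBImage::filter2(mean_image, k0, boundary = "replicate")
  s1 <- EBImage::filter2(mean_image, box, boundary = "replicate")
  s2 <- EBImage::filter2(mean_image^2, box, boundary = "replicate")
  local_var <- pmax(s2 - s1^2 / n_k, 0)
  denom <- sqrt(local_var) * sqrt(sum(k0^2))
  ncc <- ifelse(denom > 1e-9 * max(denom, 1e-300), num / denom, 0)
  ncc[!is.finite(ncc)] <- 0

  lab <- EBImage::bwlabel(ncc > corr_threshold)
  n_comp <- max(lab)
  if (n_comp == 0) return(empty_rois())

  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  areas <- tabulate(comp, n_comp)
  keep <- which(areas >= min_area_px & areas <= max_area_px)
  if (!length(keep)) return(empty_rois())

  rows <- split(idx[, 1], comp)
  cols <- split(idx[, 2], comp)
  peak <- vapply(split(ncc[idx], comp), max, numeric(1))

  tab <- data.frame(
    comp = keep,
    row_px = vapply(keep, function(k) mean(rows[[as.character(k)]]) - 1,
                    numeric(1)),
    col_px = vapply(keep, function(k) mean(cols[[as.character(k)]]) - 1,
                    numeric(1)),
    area_px = areas[keep],
    peak_corr = peak[as.character(keep)])

  # greedy non-maximum suppression on centroid proximity
  ord <- order(-tab$peak_corr)
  kept <- integer(0)
  for (j in ord) {
    if (length(kept)) {
      d <- sqrt((tab$row_px[kept] - tab$row_px[j])^2 +
                (tab$col_px[kept] - tab$col_px[j])^2)
      if (min(d) < kernel_radius_px) next
    }
    kept <- c(kept, j)
  }
  tab <- tab[sort(kept), , drop = FALSE]

  masks <- lapply(tab$comp, function(k)
    list(plane = as.integer(plane),
         pixels = cbind(row = rows[[as.character(k)]],
                        col = cols[[as.character(k)]])))
  tab$roi_id <- seq_len(nrow(tab))
  tab$plane <- as.integer(plane)
  tab$x_um <- tab$col_px * um_per_px[1]
  tab$y_um <- tab$row_px * um_per_px[2]
  tab$z_um <- as.numeric(plane) * plane_spacing_um
  tab$comp <- NULL
  rownames(tab) <- NULL
  out <- list(table = tab, masks = masks)
  class(out) <- "viscmap_rois"
  out
}

empty_rois <- function() {
  out <- list(table = data.frame(row_px = numeric(0), col_px = numeric(0),
                                 area_px = integer(0), peak_corr = numeric(0),
                                 roi_id = integer(0), plane = integer(0),
                                 x_um = numeric(0), y_um = numeric(0),
                                 z_um = numeric(0)),
              masks = list())
  class(out) <- "viscmap_rois"
  out
}

#' Detect nuclei on every plane of a movie
#'
#' Averages the movie over time per plane and runs [detect_nuclei()] on each
#' mean image; ROI ids are renumbered to be unique across planes.
#'
#' @param movie a `viscmap_movie`.
#' @param ... passed to [detect_nuclei()].
#' @return a combined `viscmap_rois`.
#' @export
detect_nuclei_stack <- function(movie, ...) {
  per_plane <- lapply(seq_len(movie$n_planes), function(p) {
    mi <- rowMeans(movie$data[, , p, , drop = FALSE], dims = 2)
    detect_nuclei(mi, um_per_px = movie$um_per_px, plane = p - 1L,
                  plane_spacing_um = movie$plane_spacing_um, ...)
  })
  tab <- do.call(rbind, lapply(per_plane, `[[`, "table"))
  masks <- do.call(c, lapply(per_plane, `[[`, "masks"))
  if (nrow(tab)) {
    tab$roi_id <- seq_len(nrow(tab))
    rownames(tab) <- NULL
  }
  out <- list(table = tab, masks = masks)
  class(out) <- "viscmap_rois"
  out
}

#' Extract per-ROI fluorescence time series
#'
#' `F[i, t]` is the mean over the i-th mask's pixels of frame `t` on the
#' mask's plane, in mask order.
#'
#' @param movie a `viscmap_movie`.
#' @param rois a `viscmap_rois` (or a bare list of masks).
#' @return a `viscmap_fluor`: raw fluorescence matrix (ROIs x frames) plus
#'   frame rate.
#' @export
extract_fluorescence <- function(movie, rois) {
  masks <- if (inherits(rois, "viscmap_rois")) rois$masks else rois
  d <- dim(movie$data)
  n_frames <- d[4]
  F <- matrix(NA_real_, length(masks), n_frames)
  if (length(masks)) {
    planes_used <- sort(unique(vapply(masks, `[[`, integer(1), "plane")))
    if (any(planes_used < 0 | planes_used >= movie$n_planes))
      stop("mask references a plane absent from the movie")
    flat <- lapply(seq_len(movie$n_planes), function(p)
      matrix(movie$data[, , p, ], d[1] * d[2], n_frames))
    for (i in seq_along(masks)) {
      m <- masks[[i]]
      px <- m$pixels
      if (!nrow(px)) stop("mask ", i, " is empty")
      if (any(px[, 1] < 1 | px[, 1] > d[1] | px[, 2] < 1 | px[, 2] > d[2]))
        stop("mask ", i, " has pixels outside the frame")
      lin <- (px[, 2] - 1L) * d[1] + px[, 1]
      F[i, ] <- colMeans(flat[[m$plane + 1L]][lin, , drop = FALSE])
    }
  }
  out <- list(F = F, frame_rate_hz = movie$frame_rate_hz)
  class(out) <- "viscmap_fluor"
  out
}
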