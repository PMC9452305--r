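shift_mat <- function(m, dr, dc) {
  out <- matrix(0, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rd <- rs + dr; cd <- cs + dc
  ok_r <- rd >= 1 & rd <= nrow(m); ok_c <- cd >= 1 & cd <= ncol(m)
  out[rs[ok_r], cs[ok_c]] <- m[rd[ok_r], cd[ok_c]]
  out
}

#' Canny edge map
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and two-threshold hysteresis (weak edges
#' are kept only in components containing a strong edge). Thresholds are
#' fractions of the maximum gradient magnitude.
#'
#' @param img 2D numeric matrix.
#' @param edge_low,edge_high hysteresis thresholds as fractions of the peak
#'   gradient magnitude (`0 < edge_low <= edge_high < 1`).
#' @param sigma smoothing SD in pixels.
#' @return logical edge matrix.
#' @export
canny_edges <- function(img, edge_low = 0.1, edge_high = 0.3, sigma = 1) {
  if (length(dim(img)) != 2) stop("img must be a 2D matrix")
  sm <- EBImage::gblur(img, sigma)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # d/d(col)
  gx <- EBImage::filter2(sm, sx, boundary = "replicate")
  gy <- EBImage::filter2(sm, t(sx), boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  sector <- (floor((ang + 22.5) / 45) %% 4)  # 0:E-W 1:NE 2:N-S 3:NW
  offs <- list(c(0, 1), c(-1, 1), c(1, 0), c(1, 1))
  nms <- mag
  for (s in 0:3) {
    o <- offs[[s + 1]]
    nb <- pmax(shift_mat(mag, o[1], o[2]), shift_mat(mag, -o[1], -o[2]))
    nms[sector == s & mag < nb] <- 0
  }
  strong <- nms >= edge_high * mx
  weak <- nms >= edge_low * mx
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong & lab > 0])
  lab > 0 & lab %in% keep
}

#' Detect axonal boutons as filled edge-bounded regions
#'
#' Applies [canny_edges()] to a (bleed-through-corrected) green-channel
#' image, fills the closed regions the edges bound, labels connected
#' components, filters them by area, and returns centroids (0-based pixel
#' coordinates and um).
#'
#' @inheritParams canny_edges
#' @param min_area minimum filled-region area in pixels.
#' @param um_per_px length-2 pixel size (x, y) in um.
#' @return data frame: `bouton_id`, `row_px`, `col_px` (0-based centroids),
#'   `x_um`, `y_um`, `area_px`; empty when no closed regions exist.
#' @export
detect_boutons <- function(img, edge_low = 0.1, edge_high = 0.3,
                           min_area = 5, sigma = 1, um_per_px = c(1, 1)) {
  edges <- canny_edges(img, edge_low, edge_high, sigma)
  empty <- data.frame(bouton_id = integer(0), row_px = numeric(0),
                      col_px = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), area_px = integer(0))
  if (!any(edges)) return(empty)
  # close single-pixel diagonal gaps in the thinned edge rings, fill the
  # enclosed regions, then erode back to the original footprint
  brush <- EBImage::makeBrush(3, "box")
  closed_edges <- EBImage::dilate(edges * 1, brush)
  filled <- EBImage::erode(EBImage::fillHull(closed_edges), brush) > 0
  interior <- filled & !edges
  if (!any(interior)) return(empty)
  lab <- EBImage::bwlabel(filled)
  # a closed region must have interior pixels, not just the edge itself
  closed <- unique(lab[interior])
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  keepers <- intersect(closed, which(tabulate(comp, max(lab)) >= min_area))
  if (!length(keepers)) return(empty)
  rows <- split(idx[, 1], comp); cols <- split(idx[, 2], comp)
  out <- data.frame(
    row_px = vapply(keepers, function(k)
      mean(rows[[as.character(k)]]) - 1, numeric(1)),
    col_px = vapply(keepers, function(k)
      mean(cols[[as.character(k)]]) - 1, numeric(1)),
    area_px = tabulate(comp, max(lab))[keepers])
  out$x_um <- out$col_px * um_per_px[1]
  out$y_um <- out$row_px * um_per_px[2]
  out <- out[order(out$row_px, out$col_px), , drop = FALSE]
  out$bouton_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("bouton_id", "row_px", "col_px", "x_um", "y_um", "area_px")]
}
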