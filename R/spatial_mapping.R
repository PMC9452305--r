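#' Centroid-referenced coordinates
#'
#' Subtracts, within each FOV, the centroid of the reference-labelled points
#' from every point's position, so point patterns can be pooled across
#' animals. FOVs lacking the reference label are dropped with a warning.
#'
#' @param points data frame with columns `x_um`, `y_um`, `z_um` (optional),
#'   `label`, and optionally `fov_id` (single FOV assumed when absent).
#' @param reference_label the label whose per-FOV centroid becomes the origin.
#' @return the data frame with positions shifted, dropped FOVs removed.
#' @export
relative_positions <- function(points, reference_label) {
  if (!"fov_id" %in% names(points)) points$fov_id <- 1L
  cols <- intersect(c("x_um", "y_um", "z_um"), names(points))
  out <- lapply(split(points, points$fov_id), function(fv) {
    ref <- fv$label == reference_label
    if (!any(ref)) {
      warning("FOV ", fv$fov_id[1], " has no '", reference_label,
              "' points; dropped")
      return(NULL)
    }
    for (cc in cols) fv[[cc]] <- fv[[cc]] - mean(fv[[cc]][ref])
    fv
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

si_aggregates <- function(D, ix, iy) {
  sxx <- sum(D[ix, ix])
  syy <- sum(D[iy, iy])
  sxy <- (sum(D[c(ix, iy), c(ix, iy)]) - sxx - syy) / 2
  c(sxx = sxx, syy = syy, sxy = sxy)
}

# all permutations of 1..n as rows (n small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k)) # insert k first, remap remainder
  }))
}

#' Permutation-normalized spatial segregation index
#'
#' Quantifies the spatial segregation of two labelled point groups. For each
#' point, the mean distance to the other group minus the mean distance to
#' its own group (self excluded) is computed; the average of these
#' differences over all points is the numerator. The denominator is the same
#' construction with a `+` sign (mean cross-distance plus mean
#' within-distance, halved) averaged over random permutations of the group
#' labels. SI > 0 indicates segregated groups, SI near 0 intermingled, and
#' SI < 0 interleaved/anti-clustered.
#'
#' When `(n + m)! <= exhaustive_limit` the permutation average is computed
#' exactly by enumerating every label assignment; otherwise
#' `n_permutations` uniform random permutations are drawn (with
#' replacement across draws) under `seed`.
#'
#' @param X,Y numeric matrices of point coordinates (rows = points); by
#'   default only the first two columns (in-plane x, y) are used.
#' @param n_permutations number of random permutations for the null.
#' @param seed RNG seed for the permutation draws.
#' @param permutations optional integer matrix (one permutation of
#'   `1:(n + m)` per row) overriding random generation — used to share draws
#'   with an external oracle.
#' @param dims how many leading coordinate columns to use (2 = in-plane,
#'   3 = volumetric).
#' @param exhaustive_limit enumerate all permutations when `(n + m)!` is at
#'   or below this bound.
#' @return list of class `viscmap_si`: `SI`, `numerator`, `denominator`,
#'   `n_permutations`, `exhaustive`, `seed`, `n`, `m`.
#' @export
segregation_index <- function(X, Y, n_permutations = 1000, seed = 1L,
                              permutations = NULL, dims = 2,
                              exhaustive_limit = 10000) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- nrow(Y)
  if (n < 2 || m < 2)
    stop("segregation index needs at least 2 points per group ",
         "(within-group mean distance undefined)")
  d_use <- seq_len(min(dims, ncol(X)))
  Z <- rbind(X[, d_use, drop = FALSE], Y[, d_use, drop = FALSE])
  if (!all(is.finite(Z))) stop("positions must be finite")
  D <- as.matrix(stats::dist(Z))
  N <- n + m

  wx <- 1 / m + 1 / n
  ag0 <- si_aggregates(D, seq_len(n), n + seq_len(m))
  numerator <- (wx * ag0["sxy"] - ag0["sxx"] / (n - 1) -
                ag0["syy"] / (m - 1)) / N

  exhaustive <- FALSE
  if (is.null(permutations)) {
    if (factorial(N) <= exhaustive_limit) {
      permutations <- all_permutations(N)
      exhaustive <- TRUE
    } else {
      permutations <- withr::with_seed(seed, t(replicate(n_permutations,
                                                         sample.int(N))))
    }
  }
  denom_terms <- apply(permutations, 1, function(sg) {
    ag <- si_aggregates(D, sg[seq_len(n)], sg[n + seq_len(m)])
    (wx * ag["sxy"] + ag["sxx"] / (n - 1) + ag["syy"] / (m - 1)) / (2 * N)
  })
  denominator <- mean(denom_terms)
  if (denominator <= 0) stop("degenerate point set: null denominator <= 0")
  out <- list(SI = unname(numerator / denominator),
              numerator = unname(numerator), denominator = denominator,
              n_permutations = nrow(permutations), exhaustive = exhaustive,
              seed = seed, n = n, m = m)
  class(out) <- "viscmap_si"
  out
}

#' Pool segregation indices across FOVs
#'
#' The mean of the per-FOV numerators is divided by the mean of the per-FOV
#' permutation denominators (numerators and denominators are averaged before
#' the division, not the per-FOV ratios).
#'
#' @param results list of `viscmap_si` objects, one per FOV.
#' @return list: pooled `SI`, `numerator`, `denominator`, `n_fovs`.
#' @export
pool_segregation <- function(results) {
  if (!length(results)) stop("no per-FOV results to pool")
  num <- mean(vapply(results, `[[`, numeric(1), "numerator"))
  den <- mean(vapply(results, `[[`, numeric(1), "denominator"))
  list(SI = num / den, numerator = num, denominator = den,
       n_fovs = length(results))
}

#' Observed vs frequency-preserving shuffled pairwise distances
#'
#' Collects all pairwise distances between same-labelled points and between
#' differently labelled points, then repeats the computation after randomly
#' reassigning labels within each FOV while preserving the observed label
#' frequencies — a null that controls for regional variation in point
#' density. FOVs in which either group is empty are skipped with a warning.
#'
#' @param points data frame with `x_um`, `y_um` (optionally `z_um`,
#'   `fov_id`) and a two-level `label` column.
#' @param n_shuffles number of label reassignments.
#' @param seed RNG seed.
#' @param dims coordinate dimensions used (2 = in-plane).
#' @return list: `observed` and `shuffled`, each with numeric `within` and
#'   `cross` distance vectors (shuffled distances pooled over shuffles), and
#'   `n_shuffles`.
#' @export
pairwise_distance_shuffle_test <- function(points, n_shuffles = 100,
                                           seed = 1L, dims = 2) {
  if (!"fov_id" %in% names(points)) points$fov_id <- 1L
  labs <- unique(points$label)
  if (length(labs) != 2) stop("exactly two labels are required")
  cols <- c("x_um", "y_um", "z_um")[seq_len(dims)]
  gather <- function(D, lab) {
    same <- outer(lab, lab, `==`)
    ut <- upper.tri(D)
    list(within = D[ut & same], cross = D[ut & !same])
  }
  obs_w <- obs_c <- sh_w <- sh_c <- list()
  withr::with_seed(seed, {
    for (fv in split(points, points$fov_id)) {
      if (!all(labs %in% fv$label)) {
        warning("FOV ", fv$fov_id[1], " lacks one label group; skipped")
        next
      }
      D <- as.matrix(stats::dist(as.matrix(fv[, cols, drop = FALSE])))
      g <- gather(D, fv$label)
      obs_w <- c(obs_w, list(g$within)); obs_c <- c(obs_c, list(g$cross))
      for (k in seq_len(n_shuffles)) {
        gs <- gather(D, sample(fv$label))
        sh_w <- c(sh_w, list(gs$within)); sh_c <- c(sh_c, list(gs$cross))
      }
    }
  })
  list(observed = list(within = unlist(obs_w), cross = unlist(obs_c)),
       shuffled = list(within = unlist(sh_w), cross = unlist(sh_c)),
       n_shuffles = n_shuffles)
}

#' Neuron-to-bouton spatial comparison
#'
#' Same contract as [pairwise_distance_shuffle_test()] with structure
#' classes (neuron vs bouton) as the two labels: within = neuron-to-neuron
#' and bouton-to-bouton distances, cross = neuron-to-bouton.
#'
#' @param neurons,boutons data frames or matrices with `x_um`, `y_um`
#'   columns (>= 2 rows each).
#' @inheritParams pairwise_distance_shuffle_test
#' @export
bouton_neuron_segregation <- function(neurons, boutons, n_shuffles = 100,
                                      seed = 1L, dims = 2) {
  as_df <- function(p, lab) {
    p <- as.data.frame(p)
    if (!"x_um" %in% names(p)) names(p)[1:2] <- c("x_um", "y_um")
    p$label <- lab
    p[, c("x_um", "y_um", intersect("z_um", names(p)), "label")]
  }
  if (nrow(as.data.frame(neurons)) < 2 || nrow(as.data.frame(boutons)) < 2)
    stop("need at least 2 neurons and 2 boutons")
  pts <- rbind(as_df(neurons, "neuron"), as_df(boutons, "bouton"))
  pairwise_distance_shuffle_test(pts, n_shuffles, seed, dims)
}

#' Enrichment index
#'
#' Contrasts the response frequency of a Cre-labelled class against its
#' complement: `(P_cre_pos - P_cre_neg) / (P_cre_pos + P_cre_neg)`, in
#' \[-1, 1\]. Returns `NA` with a warning when both frequencies are zero.
#'
#' @param p_cre_pos,p_cre_neg response fractions (or percentages, any common
#'   scale) of Cre-positive and Cre-negative neurons; non-negative.
#' @export
enrichment_index <- function(p_cre_pos, p_cre_neg) {
  if (any(c(p_cre_pos, p_cre_neg) < 0)) stop("fractions must be >= 0")
  tot <- p_cre_pos + p_cre_neg
  out <- ifelse(tot > 0, (p_cre_pos - p_cre_neg) / tot, NA_real_)
  if (anyNA(out)) warning("both response fractions zero; index undefined")
  out
}

#' Kernel-density raster of a labelled point pattern
#'
#' 2D Gaussian kernel density of the points carrying `label`, normalized to
#' integrate to 1 over the grid, so per-label rasters are individually
#' scaled.
#'
#' @param points data frame with `x_um`, `y_um`, `label`.
#' @param label which label to rasterize.
#' @param bandwidth_um Gaussian kernel SD in um.
#' @param grid_n grid resolution per axis.
#' @param lims `c(xmin, xmax, ymin, ymax)`; default pads the data range by
#'   three bandwidths.
#' @return list `x`, `y`, `z` (density raster, integrates to 1).
#' @export
density_map <- function(points, label, bandwidth_um = 15, grid_n = 101,
                        lims = NULL) {
  p <- points[points$label == label, , drop = FALSE]
  if (!nrow(p)) stop("no points with label '", label, "'")
  pad <- 3 * bandwidth_um
  lims <- lims %||% c(range(p$x_um) + c(-pad, pad),
                      range(p$y_um) + c(-pad, pad))
  # MASS::kde2d uses a kernel SD of h/4
  kd <- MASS::kde2d(p$x_um, p$y_um, h = 4 * bandwidth_um, n = grid_n,
                    lims = lims)
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  kd$z <- kd$z / (sum(kd$z) * dx * dy)
  kd
}
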