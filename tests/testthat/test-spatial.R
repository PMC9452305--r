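test_that("optimized SI equals the literal brute-force transcription", {
  withr::with_seed(17, {
    for (r in 1:10) {
      n <- sample(2:12, 1); m <- sample(2:12, 1)
      X <- matrix(stats::runif(2 * n, 0, 100), n)
      Y <- matrix(stats::runif(2 * m, 0, 100), m)
      P <- t(replicate(25, sample.int(n + m)))
      fast <- segregation_index(X, Y, permutations = P)
      slow <- brute_force_si(X, Y, P)
      expect_lt(abs(fast$SI - slow$SI) / abs(slow$SI), 1e-10)
      expect_lt(abs(fast$numerator - slow$numerator) /
                max(abs(slow$numerator), 1e-12), 1e-10)
    }
  })
})

test_that("interleaved 1D points give SI = -0.3 by exhaustive enumeration", {
  si <- segregation_index(matrix(c(0, 2)), matrix(c(1, 3)), dims = 1)
  expect_true(si$exhaustive)
  expect_equal(si$SI, -0.3, tolerance = 1e-12)
  expect_lt(si$SI, 0)
})

test_that("well-separated clusters give large positive SI", {
  cl <- two_clusters(20, 20, 1000, 10, seed = 5)
  si <- segregation_index(cl$X, cl$Y, seed = 5)
  expect_gt(si$SI, 0.5)
})

test_that("randomly labelled common-distribution points give SI near 0", {
  sis <- vapply(1:30, function(r) {
    cl <- two_clusters(25, 25, 0, 30, seed = 100 + r)
    segregation_index(cl$X, cl$Y, n_permutations = 200, seed = r)$SI
  }, numeric(1))
  expect_lt(abs(mean(sis)), 2 * stats::sd(sis) / sqrt(length(sis)) + 0.01)
})

test_that("SI is symmetric and geometry-invariant", {
  cl <- two_clusters(12, 15, 80, 20, seed = 3)
  P <- withr::with_seed(2, t(replicate(50, sample.int(27))))
  base <- segregation_index(cl$X, cl$Y, permutations = P)$SI
  # symmetry in X and Y: swap groups, remap the shared permutations
  Pm <- ifelse(P <= 12, P + 15, P - 12)   # Z index -> swapped-Z index
  Psw <- cbind(Pm[, 13:27], Pm[, 1:12])   # permuted Y slots become X slots
  swap <- segregation_index(cl$Y, cl$X, permutations = Psw)$SI
  expect_equal(swap, base, tolerance = 1e-12)
  # translation, rotation, uniform scaling
  th <- 0.7; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  tf <- function(M) 3.2 * (M %*% Rm) + rep(c(55, -40), each = nrow(M))
  inv <- segregation_index(tf(cl$X), tf(cl$Y), permutations = P)$SI
  expect_equal(inv, base, tolerance = 1e-9)
})

test_that("SI increases monotonically with cluster separation", {
  seps <- c(0, 25, 50, 100, 200)
  sis <- vapply(seps, function(s) {
    cl <- two_clusters(50, 50, s, 25, seed = 7)
    segregation_index(cl$X, cl$Y, seed = 7)$SI
  }, numeric(1))
  expect_true(all(diff(sis) > 0))
})

test_that("SI rejects degenerate groups and pools by mean num/denom", {
  expect_error(segregation_index(matrix(1, 1, 2), matrix(1:4, 2)),
               "at least 2")
  r1 <- segregation_index(two_clusters(10, 10, 50, 10, 1)$X,
                          two_clusters(10, 10, 50, 10, 1)$Y,
                          n_permutations = 50, seed = 1)
  r2 <- segregation_index(two_clusters(10, 10, 150, 10, 2)$X,
                          two_clusters(10, 10, 150, 10, 2)$Y,
                          n_permutations = 50, seed = 2)
  pool <- pool_segregation(list(r1, r2))
  expect_equal(pool$SI,
               mean(c(r1$numerator, r2$numerator)) /
               mean(c(r1$denominator, r2$denominator)))
  expect_false(isTRUE(all.equal(pool$SI, mean(c(r1$SI, r2$SI)))))
})

test_that("relative positions are centroid-referenced per FOV", {
  pts <- data.frame(fov_id = c(1, 1, 1, 2, 2),
                    x_um = c(0, 10, 20, 5, 15), y_um = c(0, 10, 20, 5, 15),
                    z_um = 0,
                    label = c("ref", "ref", "other", "other", "other"))
  expect_warning(out <- relative_positions(pts, "ref"), "dropped")
  expect_equal(nrow(out), 3)
  expect_equal(mean(out$x_um[out$label == "ref"]), 0)
  shifted <- pts[pts$fov_id == 1, ]
  shifted$x_um <- shifted$x_um + 50; shifted$y_um <- shifted$y_um + 50
  expect_equal(relative_positions(shifted, "ref")[, c("x_um", "y_um")],
               suppressWarnings(relative_positions(pts, "ref"))[
                 , c("x_um", "y_um")])
  one <- data.frame(x_um = 7, y_um = 9, z_um = 0, label = "ref")
  out1 <- relative_positions(one, "ref")
  expect_equal(unlist(out1[, c("x_um", "y_um")]), c(x_um = 0, y_um = 0))
})

test_that("frequency-preserving shuffles match mixed labels, not segregated", {
  mixed <- withr::with_seed(4, data.frame(
    x_um = stats::runif(60, 0, 100), y_um = stats::runif(60, 0, 100),
    label = sample(rep(c("A", "B"), 30))))
  r <- pairwise_distance_shuffle_test(mixed, n_shuffles = 20, seed = 2)
  ks <- suppressWarnings(stats::ks.test(r$observed$within,
                                        r$shuffled$within))$statistic
  expect_lt(unname(ks), 0.1)

  cl <- two_clusters(30, 30, 300, 15, seed = 6)
  seg <- data.frame(x_um = c(cl$X[, 1], cl$Y[, 1]),
                    y_um = c(cl$X[, 2], cl$Y[, 2]),
                    label = rep(c("A", "B"), each = 30))
  rs <- pairwise_distance_shuffle_test(seg, n_shuffles = 20, seed = 2)
  expect_lt(mean(rs$observed$within), mean(rs$shuffled$within))
  expect_gt(mean(rs$observed$cross), mean(rs$shuffled$cross))
})

test_that("degenerate shuffle inputs follow the contract", {
  two <- data.frame(x_um = c(0, 30), y_um = c(0, 40),
                    label = c("A", "B"))
  r <- pairwise_distance_shuffle_test(two, n_shuffles = 5, seed = 1)
  expect_length(r$observed$within, 0)
  expect_equal(r$observed$cross, 50)
  multi <- rbind(cbind(two, fov_id = 1),
                 data.frame(x_um = 1, y_um = 1, label = "A", fov_id = 2))
  expect_warning(pairwise_distance_shuffle_test(multi, 5, 1), "skipped")
})

test_that("bouton-neuron comparison mirrors the label shuffle contract", {
  nn <- two_clusters(15, 15, 0, 20, seed = 8)$X
  same <- bouton_neuron_segregation(nn, nn + stats::rnorm(30, 0, 0.1),
                                    n_shuffles = 10, seed = 3)
  ks <- suppressWarnings(stats::ks.test(same$observed$cross,
                                        same$observed$within))$statistic
  expect_lt(unname(ks), 0.2)
  far <- bouton_neuron_segregation(nn, nn + 200, n_shuffles = 10, seed = 3)
  expect_gt(mean(far$observed$cross), mean(far$shuffled$cross))
  expect_error(bouton_neuron_segregation(nn, nn[1, , drop = FALSE]),
               "at least 2")
})

test_that("enrichment index identities", {
  expect_equal(enrichment_index(0.3, 0.3), 0)
  expect_equal(enrichment_index(0.4, 0), 1)
  expect_equal(enrichment_index(0, 0.4), -1)
  expect_warning(expect_true(is.na(enrichment_index(0, 0))), "undefined")
  expect_error(enrichment_index(-0.1, 0.2), ">= 0")
})

test_that("density maps integrate to one and localize their points", {
  pts <- data.frame(x_um = 50, y_um = 70, label = "A")
  dm <- density_map(pts, "A", bandwidth_um = 10, grid_n = 81)
  dx <- diff(dm$x[1:2]); dy <- diff(dm$y[1:2])
  expect_equal(sum(dm$z) * dx * dy, 1, tolerance = 0.01)
  pk <- which(dm$z == max(dm$z), arr.ind = TRUE)
  expect_lt(abs(dm$x[pk[1]] - 50), 2)
  expect_lt(abs(dm$y[pk[2]] - 70), 2)
  expect_error(density_map(pts, "B"), "no points")
})

test_that("two synthetic domains 60 um apart separate in density argmax", {
  cl <- two_clusters(200, 200, 60, 25, seed = 12)
  pts <- data.frame(x_um = c(cl$X[, 1], cl$Y[, 1]),
                    y_um = c(cl$X[, 2], cl$Y[, 2]),
                    label = rep(c("A", "B"), each = 200))
  lims <- c(-120, 120, -120, 120)
  da <- density_map(pts, "A", 15, 121, lims)
  db <- density_map(pts, "B", 15, 121, lims)
  pa <- which(da$z == max(da$z), arr.ind = TRUE)
  pb <- which(db$z == max(db$z), arr.ind = TRUE)
  sep <- sqrt((da$x[pa[1]] - db$x[pb[1]])^2 + (da$y[pa[2]] - db$y[pb[2]])^2)
  expect_lt(abs(sep - 60), 15)
})

disk_image <- function(H, W, centers, radius) {
  img <- matrix(0, H, W)
  for (k in seq_len(nrow(centers))) {
    rr <- outer((seq_len(H) - 1 - centers[k, 1])^2,
                (seq_len(W) - 1 - centers[k, 2])^2, `+`)
    img[rr <= radius^2] <- 1
  }
  img
}

test_that("bouton detection finds filled disks and ignores blanks", {
  expect_equal(nrow(detect_boutons(matrix(0, 64, 64))), 0L)
  one <- disk_image(64, 64, cbind(30, 40), 5)
  b1 <- detect_boutons(one, min_area = 5)
  expect_equal(nrow(b1), 1L)
  expect_lt(abs(b1$row_px - 30), 1)
  expect_lt(abs(b1$col_px - 40), 1)
  two <- disk_image(96, 96, rbind(c(25, 25), c(70, 70)), 5)
  expect_equal(nrow(detect_boutons(two, min_area = 5)), 2L)
})
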