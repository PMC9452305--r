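# Independent oracles and small fixture builders used across the suite.

# Literal transcription of the segregation-index definition: per-point mean
# cross-group distance minus mean own-group distance (self excluded),
# averaged; divided by the label-permutation average of the "+"-signed
# construction. Inner sums are evaluated directly from coordinates.
brute_force_si <- function(X, Y, permutations) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- nrow(Y)
  Z <- rbind(X, Y)
  dmean <- function(p, Q) mean(sqrt(rowSums((Q - rep(p, each = nrow(Q)))^2)))
  num <- 0
  for (i in seq_len(n))
    num <- num + dmean(X[i, ], Y) -
      mean(sqrt(rowSums((X[-i, , drop = FALSE] -
                         rep(X[i, ], each = n - 1))^2)))
  for (k in seq_len(m))
    num <- num + dmean(Y[k, ], X) -
      mean(sqrt(rowSums((Y[-k, , drop = FALSE] -
                         rep(Y[k, ], each = m - 1))^2)))
  num <- num / (n + m)
  den_terms <- numeric(nrow(permutations))
  for (r in seq_len(nrow(permutations))) {
    sg <- permutations[r, ]
    Xs <- Z[sg[seq_len(n)], , drop = FALSE]
    Ys <- Z[sg[n + seq_len(m)], , drop = FALSE]
    tot <- 0
    for (i in seq_len(n))
      tot <- tot + dmean(Xs[i, ], Ys) +
        mean(sqrt(rowSums((Xs[-i, , drop = FALSE] -
                           rep(Xs[i, ], each = n - 1))^2)))
    for (k in seq_len(m))
      tot <- tot + dmean(Ys[k, ], Xs) +
        mean(sqrt(rowSums((Ys[-k, , drop = FALSE] -
                           rep(Ys[k, ], each = m - 1))^2)))
    den_terms[r] <- tot / (2 * (n + m))
  }
  list(SI = num / mean(den_terms), numerator = num,
       denominator = mean(den_terms))
}

# two Gaussian clusters in 2D, centred +/- sep/2 on x
two_clusters <- function(n, m, sep, spread, seed) {
  withr::with_seed(seed, list(
    X = cbind(rnorm(n, -sep / 2, spread), rnorm(n, 0, spread)),
    Y = cbind(rnorm(m, sep / 2, spread), rnorm(m, 0, spread))))
}

# protocol with a single stimulus, 30+ frame lead-in
single_stim_protocol <- function(organ = "stomach", modality = "stretch",
                                 intensity = 600, onset = 40L,
                                 dur = 50L) {
  stimulus_protocol(organ, modality, intensity, onset, onset + dur)
}

# a small quiet configuration used by unit tests
quiet_config <- function(...) {
  args <- list(
    n_neurons = 50, n_planes = 1, fov_um = c(200, 200, 20), img_px = 128,
    organs = list(stomach = list(centroid = c(70, 100, 10), spread = 25),
                  duodenum = list(centroid = c(130, 100, 10), spread = 25)),
    noise_sd = 0, drift_rate = 0, seed = 42)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# render-and-recover matching: nearest true neuron for each detection
match_centroids <- function(detected_px, true_px, tol_px = 2) {
  if (!nrow(detected_px)) return(0L)
  hits <- 0L
  used <- rep(FALSE, nrow(true_px))
  for (i in seq_len(nrow(detected_px))) {
    d <- sqrt((true_px[, 1] - detected_px[i, 1])^2 +
              (true_px[, 2] - detected_px[i, 2])^2)
    j <- which.min(replace(d, used, Inf))
    if (length(j) && d[j] <= tol_px) { hits <- hits + 1L; used[j] <- TRUE }
  }
  hits
}

# protocol realizing the measurement order S1, D1, M1, S2, D2, M2 (the mix
# trials are simultaneous stomach + duodenum events sharing a window)
suppression_protocol <- function(stim_f = 50L, gap_f = 60L) {
  on <- function(k) 40L + (k - 1L) * (stim_f + gap_f)
  stimulus_protocol(
    organ = c("stomach", "duodenum", "stomach", "duodenum",
              "stomach", "duodenum", "stomach", "duodenum"),
    modality = "stretch",
    intensity = c(600, 140, 600, 140, 600, 140, 600, 140),
    onset_frame = c(on(1), on(2), on(3), on(3), on(4), on(5), on(6), on(6)),
    offset_frame = c(on(1), on(2), on(3), on(3), on(4), on(5), on(6), on(6)) +
      stim_f)
}

suppression_trial_ids <- function(proto) {
  ids <- proto$stim_id
  mix_d <- ids[proto$organ == "duodenum"][c(2, 4)]
  c(d_S1 = ids[1], d_D1 = ids[2], d_M1 = mix_d[1],
    d_S2 = ids[5], d_D2 = ids[6], d_M2 = mix_d[2])
}

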