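# trace with `k` consecutive suprathreshold frames inside the window
pulse_trace <- function(n, onset, k, height = 1, start_in = 5) {
  tr <- rep(0, n)
  tr[(onset + start_in):(onset + start_in + k - 1)] <- height
  tr
}

mech_stim <- function() single_stim_protocol(onset = 40, dur = 50)[1, ]
chem_stim <- function() {
  stimulus_protocol("duodenum", "chemical", 1, 40, 90)[1, ]
}

test_that("mechanical persistence criterion is strict at 3 vs 4 frames", {
  stim <- mech_stim()
  flat <- rep(0, 130)
  st <- baseline_stats(flat, stim, 1.25)
  expect_false(call_mechanical_response(flat, st, stim)$responsive)

  tr3 <- pulse_trace(130, 40, 3)
  tr4 <- pulse_trace(130, 40, 4)
  # baselines identical (zeros): theta = 0; ">" is strict so zeros never count
  expect_false(call_mechanical_response(tr3, st, stim)$responsive)
  expect_true(call_mechanical_response(tr4, st, stim)$responsive)
})

test_that("both mechanical bounds must hold simultaneously", {
  stim <- mech_stim()
  # a noisy 7-frame pre-onset window raises the local 2-SD bound above theta
  tr <- rep(0, 130)
  tr[34:40] <- c(0.15, -0.15, 0.15, -0.15, 0.15, -0.15, 0.15)
  st <- baseline_stats(tr, stim, 1.25)
  bound2 <- st$F0_m + 2 * st$s0_m
  tr[46:52] <- (st$theta + bound2) / 2      # above theta, below local bound
  expect_gt(bound2, st$theta)
  expect_false(call_mechanical_response(tr, st, stim)$responsive)
  tr[46:52] <- bound2 + 0.1
  expect_true(call_mechanical_response(tr, st, stim)$responsive)
})

test_that("chemical criterion needs 5 frames and sees post-offset frames", {
  stim <- chem_stim()
  n <- 140
  st <- baseline_stats(rep(0, n), stim, 1.25)
  tr4 <- pulse_trace(n, 90, 4, start_in = 3)   # entirely after offset
  tr6 <- pulse_trace(n, 90, 6, start_in = 3)
  expect_false(call_chemical_response(tr4, st, stim, n)$responsive)
  expect_true(call_chemical_response(tr6, st, stim, n)$responsive)
  # outside the +20 window it must not count
  tr_late <- pulse_trace(n, 90, 6, start_in = 25)
  expect_false(call_chemical_response(tr_late, st, stim, n)$responsive)
})

test_that("short windows can never be responsive", {
  stim <- stimulus_protocol("stomach", "stretch", 600, 40, 43)[1, ]
  tr <- pulse_trace(100, 40, 3, start_in = 1)
  st <- baseline_stats(rep(0, 100), stim, 1.25)
  expect_warning(res <- call_mechanical_response(tr, st, stim), "shorter")
  expect_false(res$responsive)
})

test_that("response magnitude is the smoothed in-window peak minus theta", {
  stim <- mech_stim()
  st <- list(theta = 0.1)
  const <- rep(0.1, 130)
  expect_equal(response_magnitude(const, st, stim), 0)

  spike <- pulse_trace(130, 40, 1, height = 1)
  expect_equal(response_magnitude(spike, list(theta = 0), stim), 1 / 5)

  cfg <- quiet_config()
  p <- single_stim_protocol(onset = 40, dur = 50)
  tr <- synthesize_trace(0.8, "slow", p, cfg)
  stb <- baseline_stats(tr, p[1, ], 1.25)
  mag <- response_magnitude(tr, stb, p[1, ])
  expect_lt(abs(mag - (0.8 - stb$theta)) / 0.7, 0.05)
})

test_that("adding a positive offset inside the window never kills a call", {
  stim <- mech_stim()
  withr::with_seed(8, {
    for (r in 1:20) {
      tr <- c(stats::rnorm(40, 0, 0.05),
              stats::rnorm(60, 0.2, 0.1), rep(0, 30))
      st <- baseline_stats(tr, stim, 1.25)
      before <- call_mechanical_response(tr, st, stim)$responsive
      tr2 <- tr
      tr2[41:90] <- tr2[41:90] + 0.5
      after <- call_mechanical_response(tr2, st, stim)$responsive
      expect_true(!before || after)
    }
  })
})

kinetic_templates <- function(n_each, noise_sd = 0, seed = 1) {
  cfg <- quiet_config()
  p <- single_stim_protocol(onset = 40, dur = 50)
  nf <- protocol_length(p)
  slow <- synthesize_trace(1, "slow", p, cfg, nf)[41:100]
  rapid <- synthesize_trace(1, "rapid", p, cfg, nf)[41:100]
  withr::with_seed(seed, {
    X <- rbind(
      matrix(rep(slow, n_each), n_each, byrow = TRUE),
      matrix(rep(rapid, n_each), n_each, byrow = TRUE)) +
      matrix(stats::rnorm(2 * n_each * 60, 0, noise_sd), 2 * n_each)
    list(X = X, truth = rep(c("slow", "rapid"), each = n_each))
  })
}

test_that("k-means kinetics: noiseless templates are perfectly labelled", {
  tp <- kinetic_templates(50)
  expect_identical(classify_kinetics(tp$X, seed = 4), tp$truth)
})

test_that("k-means kinetics handles degenerate inputs", {
  expect_identical(classify_kinetics(matrix(1, 1, 10)), "none")
  same <- matrix(rep(c(0, 1, 1, 1), 5), 5, 4, byrow = TRUE)
  expect_identical(classify_kinetics(same), rep("slow", 5))
})

test_that("k-means labels are invariant to trace order", {
  tp <- kinetic_templates(30, noise_sd = 0.1, seed = 2)
  lab <- classify_kinetics(tp$X, seed = 4)
  perm <- withr::with_seed(9, sample(nrow(tp$X)))
  lab_p <- classify_kinetics(tp$X[perm, ], seed = 4)
  expect_identical(lab_p, lab[perm])
})

test_that("FOV filters implement the inclusion thresholds", {
  mk <- function(counts, stims = names(counts)) {
    do.call(rbind, lapply(stims, function(s) data.frame(
      neuron_id = seq_len(10), stim_id = s, organ = "stomach",
      modality = "stretch", intensity = 1,
      responsive = seq_len(10) <= counts[[s]],
      magnitude = 1, theta = 0)))
  }
  fovs <- list(
    none = mk(c(a = 0, b = 0)),
    glu_fail = mk(c(a = 5, b = 5, c = 4)),
    glu_pass = mk(c(a = 5, b = 6, c = 5)),
    std_edge = mk(c(a = 2, b = 2))
  )
  expect_false("none" %in% filter_fovs(fovs, "standard"))
  expect_false("none" %in% filter_fovs(fovs[1:2], "glucose"))
  expect_false("glu_fail" %in% filter_fovs(fovs, "glucose"))
  expect_true("glu_pass" %in% filter_fovs(fovs, "glucose"))
  expect_true("std_edge" %in% filter_fovs(fovs["std_edge"], "standard"))
  expect_error(filter_fovs(fovs, "cheese"))
})

test_that("spatial_pairs mode needs two selectively tuned neurons per side", {
  tab <- data.frame(
    neuron_id = rep(1:4, 2), stim_id = rep(c("A", "B"), each = 4),
    organ = rep(c("stomach", "duodenum"), each = 4),
    modality = "stretch", intensity = 1,
    responsive = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    magnitude = 1, theta = 0)
  prof <- data.frame(neuron_id = 1:4,
                     selectivity = c("selective", "selective",
                                     "selective", "multi_organ"))
  inc <- filter_fovs(list(f1 = tab), "spatial_pairs",
                     profiles = list(f1 = prof), pair = c("A", "B"))
  expect_false("f1" %in% inc)    # B has only one selective responder
  prof$selectivity[4] <- "selective"
  inc2 <- filter_fovs(list(f1 = tab), "spatial_pairs",
                      profiles = list(f1 = prof), pair = c("A", "B"))
  expect_true("f1" %in% inc2)
})
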