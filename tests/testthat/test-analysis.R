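make_rec <- function(data, fs = 250) {
  manual_recording(data, fs, onsets = 0L, codes = 2L)
}

test_that("preprocessing removes DC, attenuates mains, flags wild channels", {
  fs <- 250
  n <- fs * 20
  t <- (0:(n - 1)) / fs
  set.seed(21)
  base <- matrix(rnorm(n * 24, sd = 5), ncol = 24)
  dimnames(base) <- list(NULL, montage_labels())
  base[, "CZ"] <- 40                      # DC-offset-only channel
  base[, "PZ"] <- base[, "PZ"] + 30 * sin(2 * pi * 50 * t)  # mains
  base[, "F3"] <- rnorm(n, sd = 500)      # 100x noise channel
  rec <- make_rec(base, fs)

  # with rejection disabled the DC-only channel filters to flat zero
  pre_all <- preprocess(rec, remove_bad = FALSE)
  expect_lt(max(abs(pre_all$CZ[fs:(n - fs)])), 1e-6)
  # 50 Hz is outside the 1-30 Hz passband by at least 40 dB
  a_before <- fit_sine_amplitude(base[, "PZ"], fs, 50)
  a_after <- fit_sine_amplitude(pre_all$PZ, fs, 50)
  expect_lt(a_after / a_before, 10^(-40 / 20))
  # with rejection on, the flat and the wild channel are removed
  pre <- preprocess(rec)
  expect_setequal(attr(pre, "bad_channels"), c("CZ", "F3"))
  expect_false("F3" %in% recording_channels(pre))
  # a recording where every channel is flat aborts
  flat <- make_rec(matrix(1, nrow = 500, ncol = 24), fs)
  expect_error(preprocess(flat), "all channels")
})

test_that("epoching cuts 15-s windows inside condition blocks", {
  fs <- 250
  # two 120-s blocks: closed then open
  data <- matrix(rnorm(240 * fs * 24), ncol = 24)
  rec <- manual_recording(data, fs, onsets = c(0L, 120L * fs),
                          codes = c(2L, 1L))
  ep <- epoch_recording(rec)
  expect_equal(sum(ep$condition == "eyes_closed"), 8)  # 120 / 15
  expect_equal(sum(ep$condition == "eyes_open"), 8)
  expect_equal(dim(ep$signal[[1]]), c(24, 15 * fs))
  # epochs never span a condition boundary
  expect_true(all(ep$start_s[ep$condition == "eyes_closed"] + 15 <= 120))
  # a 14-s block yields nothing, with a warning
  rec14 <- manual_recording(matrix(rnorm(14 * fs * 24), ncol = 24), fs,
                            onsets = 0L, codes = 2L)
  expect_warning(expect_error(epoch_recording(rec14), "no complete"),
                 "shorter")
})

test_that("epoch rejection removes only above-threshold epochs, keeps order", {
  fs <- 250
  data <- matrix(rnorm(120 * fs * 24, sd = 10), ncol = 24)
  # plant a 300 uV blink-like transient in what will be epoch 3
  data[(2 * 15 * fs + 100):(2 * 15 * fs + 200), 1] <- 300
  rec <- make_rec(data, fs)
  ep <- epoch_recording(rec)
  kept <- reject_bad_epochs(ep, ptp_threshold_uV = 250)
  expect_equal(attr(kept, "n_rejected"), 1)
  expect_false(3 %in% kept$epoch)
  expect_equal(kept$epoch, sort(kept$epoch))
  # infinite threshold is the identity
  all_kept <- reject_bad_epochs(ep, ptp_threshold_uV = Inf)
  expect_equal(nrow(all_kept), nrow(ep))
  expect_error(reject_bad_epochs(ep, ptp_threshold_uV = 0), "all epochs")
})

test_that("Hanning PSD: pure-tone peak, zero input, Parseval, resolution", {
  fs <- 250
  t <- (0:(15 * fs - 1)) / fs
  tone <- matrix(sin(2 * pi * 10 * t), ncol = 24, nrow = length(t))
  ep <- epoch_recording(make_rec(tone, fs))
  psd <- compute_psd(ep)
  expect_equal(psd$freqs[2] - psd$freqs[1], 1 / 15, tolerance = 1e-9)
  expect_true(all(psd$power >= 0))
  peak <- psd$freqs[which.max(psd$power[1, ])]
  expect_lt(abs(peak - 10), 1 / 30 + 1e-9)
  # zero signal: zero power
  ep0 <- epoch_recording(make_rec(matrix(0, length(t), 24), fs))
  expect_true(all(compute_psd(ep0)$power == 0))
  # white noise: integrated density recovers the variance (Parseval)
  set.seed(33)
  wn <- matrix(rnorm(8 * 15 * fs * 24), ncol = 24)
  epw <- epoch_recording(manual_recording(wn, fs, 0L, 2L))
  psdw <- compute_psd(epw)
  total <- band_power(psdw, 0, fs / 2 + 1)
  expect_equal(mean(total$power), 1, tolerance = 0.05)
})

test_that("band power integrates [low, high) and is additive below the total", {
  fs <- 250
  set.seed(34)
  wn <- matrix(rnorm(2 * 15 * fs * 24), ncol = 24)
  psd <- compute_psd(epoch_recording(manual_recording(wn, fs, 0L, 2L)))
  bands <- eeg_bands()
  parts <- purrr::pmap_dbl(bands, function(band, low, high)
    mean(band_power(psd, low, high)$power))
  total <- mean(band_power(psd, 1, 30)$power)
  expect_lte(sum(parts), total + 1e-12)
  expect_gt(sum(parts), 0.9 * total)  # near-contiguous bands
  expect_error(band_power(psd, 10, 10.01), "fewer than two")
})

# synthetic band-power table with a planted effect
planted_bp <- function(seed, effect_channels = character(0), ratio = 1,
                       n_each = 20) {
  set.seed(seed)
  labels <- montage_labels()
  tidyr::expand_grid(condition = c("eyes_closed", "eyes_open"),
                     epoch = seq_len(n_each), channel = labels) |>
    dplyr::mutate(
      epoch = epoch + ifelse(condition == "eyes_open", n_each, 0),
      power = stats::rlnorm(dplyr::n()) *
        ifelse(condition == "eyes_closed" & channel %in% effect_channels,
               ratio, 1))
}

test_that("cluster test finds a planted occipital effect and is seed-stable", {
  bp <- planted_bp(41, c("O1", "O2", "OZ", "POZ"), ratio = 5)
  ct <- cluster_permutation_test(bp, n_perm = 500, seed = 99)
  top <- ct$clusters[1, ]
  expect_equal(top$direction, "closed>open")
  expect_true(all(c("O1", "O2", "OZ", "POZ") %in% top$channels[[1]]))
  expect_lt(top$p_value, 0.01)
  ct2 <- cluster_permutation_test(bp, n_perm = 500, seed = 99)
  expect_identical(tidy(ct), tidy(ct2))
  ct3 <- cluster_permutation_test(bp, n_perm = 500, seed = 100)
  expect_false(identical(ct$null_max, ct3$null_max))
})

test_that("clusters never span non-adjacent channels", {
  # plant the same strong effect on two far-apart channels
  bp <- planted_bp(43, c("FP1", "O2"), ratio = 8)
  ct <- cluster_permutation_test(bp, n_perm = 200, seed = 1)
  adj <- montage_adjacency()
  for (chs in ct$clusters$channels) {
    members <- montage_labels() %in% chs
    expect_true(oracle_is_connected(adj, members))
  }
  # FP1 and O2 are not adjacent, so they cannot share a cluster
  expect_false(any(vapply(ct$clusters$channels, function(chs)
    all(c("FP1", "O2") %in% chs), logical(1))))
})

test_that("cluster test input validation", {
  bp <- planted_bp(44)
  expect_error(cluster_permutation_test(bp[bp$epoch %in% c(1, 21), ]),
               "at least 2 epochs")
  tiny_adj <- montage_adjacency()[1:4, 1:4]
  expect_error(cluster_permutation_test(bp, adjacency = tiny_adj),
               "cover all channels")
})
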