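cfg10 <- codec_config(bit_length = 10, fs_out = 250)

test_that("single-frame encoding follows the shift/clip arithmetic", {
  st <- codec_reset(cfg10, n_channels = 1)
  # d = 1000 at s = 0: forced clip to the 10-bit max 511
  r <- encode_frame(st, 1000, cfg10)
  expect_equal(r$deltas, 511)
  expect_equal(r$state$r, 511)
  # d = 1000 at s = 2: q = 250, reconstruction exact
  st2 <- codec_reset(cfg10, n_channels = 1)
  st2$s <- 2L
  r2 <- encode_frame(st2, 1000, cfg10)
  expect_equal(r2$deltas, 250)
  expect_equal(r2$state$r, 1000)
  # zero difference: q = 0, reconstruction unchanged, A decays
  st3 <- r2$state
  A_before <- st3$A
  r3 <- encode_frame(st3, 1000, cfg10)
  expect_equal(r3$deltas, 0)
  expect_equal(r3$state$r, 1000)
  expect_equal(r3$state$A, (1 - cfg10$ema_lambda) * A_before)
})

test_that("rounding is half-away-from-zero and symmetric", {
  st <- codec_reset(cfg10, n_channels = 4)
  st$s <- rep(2L, 4)
  r <- encode_frame(st, c(6, -6, 5, -5), cfg10)
  expect_equal(r$deltas, c(2, -2, 1, -1))  # 6/4 = 1.5 -> 2; 5/4 = 1.25 -> 1
})

test_that("shift selection: zero case, worked value, monotonicity, adequacy", {
  expect_equal(update_shift(0, 10), 0L)
  expect_equal(update_shift(0, 16), 0L)
  # A = 4096, headroom 8: bitlength(32768) = 16, s = 16 - 9 = 7, and that
  # shift is adequate while s - 1 is not
  s <- update_shift(4096, 10, headroom = 8)
  expect_equal(s, 7L)
  expect_gte(2^s * (2^9 - 1), 8 * 4096)
  expect_lt(2^(s - 1) * (2^9 - 1), 8 * 4096)
  # monotone non-decreasing in A; bounded by 15
  A <- sort(c(0, exp(seq(0, log(1e8), length.out = 400))))
  for (n in c(10, 14, 16)) {
    sv <- update_shift(A, n)
    expect_true(all(diff(sv) >= 0))
    expect_true(all(sv >= 0 & sv <= 15))
  }
})

test_that("fresh states are reproducible and the first frame differs from zero", {
  expect_identical(codec_reset(cfg10), codec_reset(cfg10))
  st <- codec_reset(cfg10, n_channels = 1)
  r <- encode_frame(st, 137, cfg10)
  expect_equal(r$deltas, 137)   # difference from the zero initial value
})

test_that("closed loop: encoder and decoder reconstructions agree at every sample", {
  cfg <- codec_config(bit_length = 10, fs_out = 250)
  set.seed(31)
  x <- round(cumsum(rnorm(1200, 0, 120)))
  enc <- codec_reset(cfg, n_channels = 1)
  dec <- decoder_reset(cfg, n_channels = 1)
  for (t in seq_along(x)) {
    if ((t - 1) %% 250 == 0) {
      s <- update_shift(enc$A, cfg$bit_length, cfg$headroom)
      enc$s <- s
      dec <- decoder_apply_shifts(dec, s)
    }
    r <- encode_frame(enc, x[t], cfg)
    enc <- r$state
    r2 <- decode_frame(dec, r$deltas, cfg)
    dec <- r2$state
    expect_identical(dec$r, enc$r)
  }
})

test_that("decoder refuses to run before synchronization", {
  dec <- decoder_reset(cfg10, n_channels = 1)
  expect_error(decode_frame(dec, 0, cfg10), class = "eegstream_unsynchronized")
})

test_that("without clipping the per-sample error is bounded by half an LSB step", {
  cfg <- codec_config(bit_length = 10, fs_out = 250)
  set.seed(52)
  # gentle Gaussian differences: shift settles low, no clipping
  x <- matrix(round(cumsum(rnorm(5000, 0, 60))), ncol = 1)[, rep(1, 24)]
  frames <- tibble::as_tibble(as.data.frame(x))
  names(frames) <- montage_labels()
  frames$time_s <- (seq_len(nrow(x)) - 1) / 250
  frames$trigger <- 0L
  attr(frames, "fs_reported") <- 250L
  attr(frames, "gain") <- 8L
  stream <- telemetry_encode(frames, cfg)
  expect_equal(sum(attr(stream, "clipped")), 0)
  dec <- telemetry_decode(stream)
  err <- abs(x[, 1] - dec$OZ)
  s_at <- attr(dec, "shift_at")[, match("OZ", montage_labels())]
  expect_true(all(err <= pmax(2^(s_at - 1), 0) + 1e-9))
})

test_that("EMA converges geometrically on constant-magnitude differences", {
  cfg <- codec_config(bit_length = 16, fs_out = 250, ema_lambda = 0.1)
  st <- codec_reset(cfg, n_channels = 1)
  st$s <- 15L  # huge shift: q = 0, so d stays constant at D
  D <- 7
  for (k in 1:40) {
    r <- encode_frame(st, D, cfg)
    st <- r$state
    expect_equal(st$A, D * (1 - 0.9^k), tolerance = 1e-12)
  }
})

test_that("a dropped packet leaves a persistent reconstruction offset", {
  cfg <- codec_config(bit_length = 16, fs_out = 250)
  set.seed(8)
  x <- round(cumsum(rnorm(400, 0, 50)))
  enc <- codec_reset(cfg, n_channels = 1)
  dec_ok <- decoder_apply_shifts(decoder_reset(cfg, n_channels = 1), 0L)
  dec_lossy <- decoder_apply_shifts(decoder_reset(cfg, n_channels = 1), 0L)
  offset <- numeric(length(x))
  for (t in seq_along(x)) {
    r <- encode_frame(enc, x[t], cfg)
    enc <- r$state
    a <- decode_frame(dec_ok, r$deltas, cfg)
    dec_ok <- a$state
    if (t != 100) {      # packet 100 never reaches the lossy decoder
      b <- decode_frame(dec_lossy, r$deltas, cfg)
      dec_lossy <- b$state
    }
    offset[t] <- dec_ok$r - dec_lossy$r
  }
  expect_true(all(offset[1:99] == 0))
  expect_true(all(offset[100:400] == offset[100]))
  expect_false(offset[100] == 0)
})

test_that("R scalar codec and C++ stream codec are the same algorithm", {
  cfg <- codec_config(bit_length = 14, fs_out = 250)
  set.seed(12)
  cm <- matrix(as.integer(round(cumsum(rnorm(600 * 24, 0, 200)))), ncol = 24)
  frames <- tibble::as_tibble(as.data.frame(cm))
  names(frames) <- montage_labels()
  frames$time_s <- (seq_len(600) - 1) / 250
  frames$trigger <- 0L
  attr(frames, "fs_reported") <- 250L
  attr(frames, "gain") <- 8L
  decoded <- telemetry_decode(telemetry_encode(frames, cfg))
  enc <- codec_reset(cfg)
  recon <- matrix(0, 600, 24)
  for (t in 1:600) {
    if ((t - 1) %% 250 == 0) enc$s <- update_shift(enc$A, cfg$bit_length,
                                                   cfg$headroom)
    r <- encode_frame(enc, cm[t, ], cfg)
    enc <- r$state
    recon[t, ] <- enc$r   # closed loop: encoder r == decoder r
  }
  expect_equal(unname(as.matrix(decoded[montage_labels()])), recon,
               ignore_attr = TRUE)
})

test_that("shift adaptation keeps the clipping rate under 1% on Gaussian input", {
  set.seed(77)
  cm <- vapply(seq_len(24), function(c)
    as.integer(round(cumsum(rnorm(30000, 0, 300)))), integer(30000))
  frames <- tibble::as_tibble(as.data.frame(cm))
  names(frames) <- montage_labels()
  frames$time_s <- (seq_len(nrow(cm)) - 1) / 250
  frames$trigger <- 0L
  attr(frames, "fs_reported") <- 250L
  attr(frames, "gain") <- 8L
  stream <- telemetry_encode(frames, codec_config(bit_length = 10, fs_out = 250))
  clip_rate <- sum(attr(stream, "clipped")) / (nrow(cm) * 24)
  expect_lt(clip_rate, 0.01)
})
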