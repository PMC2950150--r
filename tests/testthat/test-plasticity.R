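test_that("spike-pair rule handles empty and singleton trains", {
  cfg <- rule_config()
  empty <- spike_train(numeric(0), 1)
  one <- spike_train(0.5, 1)
  expect_identical(pairwise_weight_change(empty, one, toy_dog, cfg), 0)
  expect_identical(pairwise_weight_change(one, empty, toy_dog, cfg), 0)
  expect_identical(pairwise_weight_change_fft(empty, one, toy_dog, cfg), 0)
  # a single coincident pair contributes exactly P(0)
  expect_equal(pairwise_weight_change(one, one, toy_dog, cfg),
               eval_profile(toy_dog, 0))
  cfg5 <- rule_config(beta = 5)
  expect_equal(pairwise_weight_change(one, one, toy_dog, cfg5),
               5 * eval_profile(toy_dog, 0))
})

test_that("spike train and config validation", {
  expect_error(spike_train(c(0.2, 0.1), 1), "increasing")
  expect_error(spike_train(c(0.2, 1.5), 1), "lie in")
  expect_error(rule_config(beta = 0), "positive")
  expect_error(
    pairwise_weight_change(spike_train(0.1, 1), spike_train(0.2, 1),
                           toy_dog, rule_config(pair_window = 99)),
    "exceeds profile support")
})

test_that("windowed direct sum equals the unwindowed brute force", {
  cfg <- rule_config()  # pair_window = profile support
  for (s in 1:10) {
    v <- random_train(50, 5, 100 + s)
    c1 <- random_train(50, 5, 200 + s)
    expect_equal(pairwise_weight_change(v, c1, toy_dog, cfg),
                 brute_force_dw(v, c1, toy_dog))
  }
})

test_that("FFT rule agrees with the direct sum within the binning bound", {
  cfg <- rule_config()
  # max |P'| for the toy profile bounds the per-pair binning error
  grad_max <- max(abs(diff(tabulate_profile(toy_dog)$value))) /
    toy_dog$grid_step
  worst <- 0
  for (s in 1:100) {
    v <- random_train(20, 2, 300 + s)
    c1 <- random_train(20, 2, 400 + s)
    d <- pairwise_weight_change(v, c1, toy_dog, cfg)
    f <- pairwise_weight_change_fft(v, c1, toy_dog, cfg)
    n_pairs <- length(istdpsim:::window_pair_lags(v$times, c1$times,
                                                 toy_dog$support))
    expect_lt(abs(d - f), grad_max * cfg$grid_step * n_pairs)
    worst <- max(worst, abs(d - f))
  }
  expect_gt(worst, 0)  # the two paths are genuinely distinct computations
})

test_that("halving the grid shrinks the FFT binning error", {
  errs <- sapply(c(2e-3, 1e-3, 5e-4), function(h) {
    mean(sapply(1:30, function(s) {
      v <- random_train(25, 2, 500 + s)
      c1 <- random_train(25, 2, 600 + s)
      abs(pairwise_weight_change(v, c1, toy_dog, rule_config()) -
          pairwise_weight_change_fft(v, c1, toy_dog,
                                     rule_config(grid_step = h)))
    }))
  })
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], 0.5 * errs[1])  # first-order convergence
})

test_that("a grid that cannot resolve the dip is refused", {
  v <- random_train(5, 1, 1)
  c1 <- random_train(5, 1, 2)
  expect_error(
    pairwise_weight_change_fft(v, c1, toy_dog, rule_config(grid_step = 5e-3)),
    "grid too coarse")
})

test_that("rate rule: zero deviations, sinusoid convention, sign flip", {
  cfg <- rule_config()
  flat <- rate_signal(30, rep(0, 5000), 1e-3)
  out <- rate_weight_change(flat, flat, toy_dog, cfg)
  expect_identical(out$total, 0)
  # in-phase unit sinusoids: rate = -lambda(f)/2 (beta = 1)
  f0 <- 2
  t <- (seq_len(5000) - 0.5) * 1e-3
  s <- rate_signal(0, sin(2 * pi * f0 * t), 1e-3)
  rw <- rate_weight_change(s, s, toy_dog, cfg, boundary = "periodic")
  lam <- learning_rate_function(toy_dog, f0, method = "closed_form")$values
  expect_equal(rw$rate, -lam / 2, tolerance = 1e-4)
  # anti-phase flips the sign exactly
  s2 <- rate_signal(0, -sin(2 * pi * f0 * t), 1e-3)
  rw2 <- rate_weight_change(s, s2, toy_dog, cfg, boundary = "periodic")
  expect_equal(rw2$total, -rw$total)
  # beta scaling
  rwb <- rate_weight_change(s, s, toy_dog, rule_config(beta = 2),
                            boundary = "periodic")
  expect_equal(rwb$total, 2 * rw$total)
})

test_that("rate rule rejects mismatched sampling", {
  a <- rate_signal(0, rep(0, 100), 1e-3)
  b <- rate_signal(0, rep(0, 101), 1e-3)
  d <- rate_signal(0, rep(0, 100), 2e-3)
  expect_error(rate_weight_change(a, b, toy_dog, rule_config()), "sampling")
  expect_error(rate_weight_change(a, d, toy_dog, rule_config()), "sampling")
})

test_that("weight change is additive over a partition of one train", {
  cfg <- rule_config()
  v <- random_train(60, 5, 11)
  c1 <- random_train(40, 5, 12)
  idx <- with_seed_test(13, sample(c(TRUE, FALSE), 60, replace = TRUE))
  v1 <- spike_train(v$times[idx], 5)
  v2 <- spike_train(v$times[!idx], 5)
  expect_equal(pairwise_weight_change(v1, c1, toy_dog, cfg) +
                 pairwise_weight_change(v2, c1, toy_dog, cfg),
               pairwise_weight_change(v, c1, toy_dog, cfg))
})

test_that("balanced profile gives no mean drift for independent Poisson input", {
  cfg <- rule_config()
  dws <- sapply(1:30, function(s) {
    v <- poisson_encode(rate_signal(30, rep(0, 20000), 1e-3), 1000 + s)
    c1 <- poisson_encode(rate_signal(30, rep(0, 20000), 1e-3), 2000 + s)
    pairwise_weight_change_fft(v, c1, toy_dog, cfg)
  })
  se <- sd(dws) / sqrt(length(dws))
  expect_lt(abs(mean(dws)), 3 * se)
})

test_that("correlation sign determines the direction of plasticity", {
  cfg <- rule_config()
  sp <- modulation_spec(30, 20, 3, duration = 20)
  dw_in <- sapply(1:8, function(s) {
    pr <- make_correlated_pair(sp, sp, 0, s)
    pairwise_weight_change_fft(pr$v, pr$c, toy_dog, cfg)
  })
  dw_anti <- sapply(1:8, function(s) {
    pr <- make_correlated_pair(sp, sp, pi, s)
    pairwise_weight_change_fft(pr$v, pr$c, toy_dog, cfg)
  })
  expect_lt(mean(dw_in), 0)   # positive correlation -> LTD
  expect_gt(mean(dw_anti), 0) # negative correlation -> LTP
})

test_that("ISI histogram counts qualifying pairs in centred bins", {
  one <- spike_train(0.5, 1)
  h <- isi_histogram(one, one, bin_width = 0.01, max_lag = 0.2)
  expect_equal(sum(h$count), 1)
  expect_equal(h$count[h$tau == 0], 1)
  # totals equal the number of pairs within the lag window
  v <- random_train(40, 5, 21)
  c1 <- random_train(40, 5, 22)
  h2 <- isi_histogram(v, c1, 0.02, 0.5)
  lags <- outer(v$times, c1$times, "-")
  expect_equal(sum(h2$count), sum(abs(lags) <= 0.5 + 0.01))
  expect_error(isi_histogram(v, c1, 0.02, 9), "duration")
  expect_error(isi_histogram(v, c1, 0, 0.5), "positive")
})

test_that("independent homogeneous Poisson trains give a flat histogram", {
  v <- poisson_encode(rate_signal(30, rep(0, 50000), 1e-3), 31)
  c1 <- poisson_encode(rate_signal(30, rep(0, 50000), 1e-3), 32)
  h <- isi_histogram(v, c1, 0.01, 0.25)
  expected <- 30 * 30 * 50 * 0.01  # rate_v * rate_c * T * bin
  expect_lt(max(abs(h$count - expected)), 5 * sqrt(expected))
  # flat relative to its own level (the overall scale fluctuates with the
  # realised spike counts, so compare bins against the empirical mean)
  expect_lt(max(abs(h$count - mean(h$count))), 5 * sqrt(mean(h$count)))
})

test_that("in-phase 3 Hz modulation shapes the ISI histogram", {
  sp <- modulation_spec(30, 20, 3, duration = 50)
  pr <- make_correlated_pair(sp, sp, 0, 77)
  h <- isi_histogram(pr$v, pr$c, 0.01, 0.5)
  # peak at zero ISI: central bins exceed bins half a cycle away
  central <- mean(h$count[abs(h$tau) <= 0.04])
  trough <- mean(h$count[abs(abs(h$tau) - 1 / 6) <= 0.04])
  expect_gt(central, trough)
  # modulation at the input frequency: strong 3 Hz Fourier component
  dev <- h$count - mean(h$count)
  amp3 <- abs(sum(dev * exp(-2i * pi * 3 * h$tau)))
  amp_bg <- max(sapply(c(1.3, 2.1, 4.2, 5.6), function(f)
    abs(sum(dev * exp(-2i * pi * f * h$tau)))))
  expect_gt(amp3, amp_bg)
})
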