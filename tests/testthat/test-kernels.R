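test_that("DoG profile solves the LTP amplitude from the area condition", {
  p <- make_dog_profile(-1, 0.010, 0.100)
  expect_equal(p$amp_ltp, 0.1)
  a <- profile_areas(p)
  expect_lt(abs(a$total), 1e-9 * (a$positive - a$negative))
  # dip dominates at coincidence
  expect_equal(eval_profile(p, 0), -0.9)
  expect_lt(eval_profile(p, 0), 0)
  # numeric area on the tabulation grid is consistent with the closed form
  tab <- tabulate_profile(p)
  expect_lt(abs(sum(tab$value) * p$grid_step),
            1e-6 * sum(abs(tab$value)) * p$grid_step)
  # LTP somewhere positive at large |tau| within support
  expect_gt(max(tab$value), 0)
})

test_that("imbalance scales the positive component area", {
  p <- make_dog_profile(-1, 0.010, 0.100, imbalance = 0.10)
  a <- profile_areas(p)
  expect_equal(a$positive / abs(a$negative), 1.10)
  expect_equal(a$total, 0.10 * abs(a$negative))
  pn <- make_dog_profile(-1, 0.010, 0.100, imbalance = -0.05)
  an <- profile_areas(pn)
  expect_equal(an$positive / abs(an$negative), 0.95)
})

test_that("invalid profile parameters are rejected", {
  expect_error(make_dog_profile(-1, 0.1, 0.01), "width ordering")
  expect_error(make_dog_profile(1, 0.01, 0.1), "negative")
  expect_error(make_doe_profile(-1, 0.2, 0.1), "width ordering")
})

test_that("DoE profiles balance and respect symmetry choices", {
  p <- make_doe_profile(-1, 0.010, 0.100)
  expect_equal(p$amp_ltp, 0.1)
  expect_equal(profile_areas(p)$total, 0)
  tau <- seq(0.001, 0.4, by = 0.007)
  expect_equal(eval_profile(p, tau), eval_profile(p, -tau))
  pa <- make_doe_profile(-1, 0.010, 0.100, antisymmetric = TRUE)
  expect_true(all(eval_profile(pa, tau) < 0))   # LTD branch
  expect_true(all(eval_profile(pa, -tau) > 0))  # LTP branch
  expect_equal(profile_areas(pa)$total, 0)
  lr <- learning_rate_function(pa, 0, method = "closed_form")
  expect_equal(lr$values, 0)
})

test_that("balanced profiles have zero learning rate at DC", {
  doe <- make_doe_profile(-0.5, 0.008, 0.150)
  for (p in list(toy_dog, vor_p, doe)) {
    lr0 <- learning_rate_function(p, 0, method = "closed_form")$values
    expect_lt(abs(lr0), 1e-12)
  }
  # numeric transform: smooth Gaussian kernels integrate to machine noise
  for (p in list(toy_dog, vor_p)) {
    expect_lt(abs(learning_rate_function(p, 0)$values),
              1e-9 * peak_learning_rate(p)$value)
  }
  # the exponential kernel has a cusp at tau = 0, so grid quadrature is
  # second order: residual bounded by h^2/6 * |amp_ltd|/tau_ltd
  lr0n <- learning_rate_function(doe, 0)$values
  expect_lt(abs(lr0n), doe$grid_step^2 / 6 * abs(doe$amp_ltd) / doe$tau_ltd *
                        1.1)
})

test_that("numeric transform matches the closed-form DoG pair", {
  fs <- exp(seq(log(0.01), log(50), length.out = 25))
  for (p in list(toy_dog, vor_p)) {
    num <- learning_rate_function(p, fs)
    cf <- learning_rate_function(p, fs, method = "closed_form")
    expect_lt(max(abs(num$values - cf$values)) / max(abs(cf$values)), 1e-6)
    expect_lt(num$imag_residue, 1e-9)
  }
})

test_that("transform of too-coarse a grid is refused", {
  expect_error(learning_rate_function(toy_dog, c(1, 600)), "Nyquist")
})

test_that("a near-delta LTD dip with wide shallow LTP is all-pass", {
  p <- make_dog_profile(-1, 3e-4, 10)
  fs <- seq(0.5, 20, by = 0.5)
  lam <- learning_rate_function(p, fs, method = "closed_form")$values
  expect_lt(max(lam) / min(lam) - 1, 1e-3)  # flat above zero frequency
  expect_lt(abs(learning_rate_function(p, 0, method = "closed_form")$values),
            1e-12)
})

test_that("learning rate scales linearly with profile amplitude", {
  p1 <- make_dog_profile(-1, 0.012, 0.090)
  p3 <- make_dog_profile(-3, 0.012, 0.090)
  fs <- c(0.1, 1, 5, 20)
  expect_equal(learning_rate_function(p3, fs, method = "closed_form")$values,
               3 * learning_rate_function(p1, fs, method = "closed_form")$values)
  expect_equal(learning_rate_function(p3, fs)$values,
               3 * learning_rate_function(p1, fs)$values)
})

test_that("bandpass calibration enforces its edge constraints", {
  p <- vor_p
  lr <- learning_rate_function(p, c(0.3, 10), method = "closed_form")
  pk <- peak_learning_rate(p, method = "closed_form")
  expect_equal(lr$values / pk$value, c(0.2, 0.2), tolerance = 1e-7)
  expect_equal(eval_profile(p, 0), -1)  # normalised dip
  # idempotence: re-solving from the same constraints reproduces the widths
  p2 <- calibrate_bandpass(0.3, 10, 0.2)
  expect_equal(p2$sigma_ltd, p$sigma_ltd, tolerance = 1e-8)
  expect_equal(p2$sigma_ltp, p$sigma_ltp, tolerance = 1e-8)
})

test_that("narrowing the passband widens the LTD dip", {
  wide_band <- vor_p
  narrow_band <- calibrate_bandpass(0.3, 5, 0.2)
  expect_gt(dip_halfwidth(narrow_band, 0.2), dip_halfwidth(wide_band, 0.2))
})

test_that("dip half-width matches the Gaussian closed form", {
  # nearly pure Gaussian dip: lobes 500x wider, amplitude ~ 1/500
  p <- make_dog_profile(-1, 0.0136, 6.8, support = 3)
  expect_equal(dip_halfwidth(p, 0.2), 0.0136 * sqrt(2 * log(5)),
               tolerance = 0.005)
  expect_equal(dip_halfwidth(p, 1), 0)
  expect_error(dip_halfwidth(p, 0), "depth_fraction")
  flat <- make_tabulated_profile(seq(-0.1, 0.1, by = 0.001),
                                 rep(1, 201))
  expect_error(dip_halfwidth(flat, 0.2), "no LTD dip")
})

test_that("constrained profile has a 20 ms dip half-width", {
  expect_equal(dip_halfwidth(constrained_p, 0.2), 0.020, tolerance = 1e-6)
  expect_equal(eval_profile(constrained_p, 0), -1)
  expect_lt(abs(profile_areas(constrained_p)$total), 1e-12)
})

test_that("profiles serialise and round-trip through JSON and CSV", {
  tmp <- tempfile(fileext = ".json")
  for (p in list(toy_dog,
                 make_doe_profile(-2, 0.008, 0.120, imbalance = 0.05,
                                  antisymmetric = TRUE))) {
    write_profile_json(p, tmp)
    q <- read_profile_json(tmp)
    expect_equal(unclass(q), unclass(p))
  }
  csv <- tempfile(fileext = ".csv")
  write_profile_csv(toy_dog, csv)
  d <- read.csv(csv)
  expect_named(d, c("tau_ms", "P"))
  tab <- tabulate_profile(toy_dog)
  expect_equal(d$P, tab$value)
  expect_equal(d$tau_ms, tab$tau * 1000)
})

test_that("timing uncertainty maps to its Nyquist frequency", {
  expect_identical(timing_nyquist(0.020), 25)
  expect_equal(timing_nyquist(0.010), 50)
  expect_error(timing_nyquist(0), "positive")
})
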