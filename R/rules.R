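#' Spike train container
#'
#' Ordered event times over a finite observation window with a shared time
#' origin at 0.
#'
#' @param times event times (s), strictly increasing, in `[0, duration)`.
#' @param duration observation window length (s).
#' @return object of class `spike_train`.
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  if (length(times) > 0) {
    if (any(times < 0) || any(times >= duration))
      stop("spike times must lie in [0, duration)")
    if (is.unsorted(times, strictly = TRUE))
      stop("spike times must be strictly increasing")
  }
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike train: %d spikes over %.3g s (mean rate %.3g sp/s)\n",
              length(x$times), x$duration,
              length(x$times) / x$duration))
  invisible(x)
}

#' Rate signal container
#'
#' A tonic (baseline) firing rate plus a uniformly sampled time-varying
#' deviation; the rate-coded form of the vestibular and cerebellar inputs.
#' Samples are taken at bin centres `t0 + (i - 1/2) * dt`.
#'
#' @param tonic baseline rate (spikes/s), >= 0.
#' @param deviation rate deviation from tonic at each sample (spikes/s; may
#'   be negative).
#' @param dt sampling step (s).
#' @param t0 window start time (s).
#' @return object of class `rate_signal`.
#' @export
rate_signal <- function(tonic, deviation, dt, t0 = 0) {
  if (tonic < 0) stop("tonic rate must be nonnegative")
  if (dt <= 0) stop("dt must be positive")
  structure(list(tonic = tonic, deviation = as.numeric(deviation),
                 dt = dt, t0 = t0),
            class = "rate_signal")
}

#' Sample times of a rate signal
#' @param x a `rate_signal`.
#' @export
rate_times <- function(x) {
  stopifnot(inherits(x, "rate_signal"))
  x$t0 + (seq_along(x$deviation) - 0.5) * x$dt
}

#' @export
print.rate_signal <- function(x, ...) {
  cat(sprintf(
    "rate signal: tonic %.3g sp/s, %d samples at %.3g ms (%.3g s)\n",
    x$tonic, length(x$deviation), 1000 * x$dt,
    length(x$deviation) * x$dt))
  invisible(x)
}

#' Learning-rule configuration
#'
#' @param beta learning-rate scale (weight change per unit pair
#'   contribution), > 0. Sets the absolute magnitude of plasticity; profile
#'   shapes are normalised separately.
#' @param pair_window maximum inter-spike interval considered (s); `NULL`
#'   uses the profile's support at the point of use.
#' @param grid_step binning step (s) for the transform-based rule path.
#' @export
rule_config <- function(beta = 1, pair_window = NULL, grid_step = 1e-3) {
  if (beta <= 0) stop("beta must be positive")
  if (grid_step <= 0) stop("grid_step must be positive")
  structure(list(beta = beta, pair_window = pair_window,
                 grid_step = grid_step),
            class = "rule_config")
}

resolve_window <- function(config, profile) {
  w <- if (is.null(config$pair_window)) profile$support else config$pair_window
  if (w > profile$support + 1e-12)
    stop("pair_window exceeds profile support")
  w
}

# all inter-spike intervals tv - tc with |.| <= W, by windowed expansion
window_pair_lags <- function(tv, tc, W) {
  if (length(tv) == 0 || length(tc) == 0) return(numeric(0))
  lo <- findInterval(tv - W, tc) + 1
  hi <- findInterval(tv + W, tc)
  n_i <- pmax(hi - lo + 1, 0)
  keep <- n_i > 0
  if (!any(keep)) return(numeric(0))
  idx_c <- sequence(n_i[keep]) + rep(lo[keep] - 1, n_i[keep])
  idx_v <- rep(which(keep), n_i[keep])
  tv[idx_v] - tc[idx_c]
}

#' Spike-pair weight change (direct sum)
#'
#' Applies the iSTDP rule to a pair of spike trains: the weight change is
#' `beta` times the sum over all vestibular/cerebellar spike pairs of
#' `P(t_v - t_c)`, restricted to pairs closer than the pair window.
#' Direct O(Nv * Nc) evaluation within the window.
#'
#' @param v_spikes,c_spikes vestibular and cerebellar [spike_train()]s with
#'   a common time origin.
#' @param profile an `istdp_profile`.
#' @param config a [rule_config()].
#' @return total weight change (dimensionless). Empty trains give 0.
#' @export
pairwise_weight_change <- function(v_spikes, c_spikes, profile, config) {
  stopifnot(inherits(v_spikes, "spike_train"),
            inherits(c_spikes, "spike_train"))
  W <- resolve_window(config, profile)
  lags <- window_pair_lags(v_spikes$times, c_spikes$times, W)
  if (length(lags) == 0) return(0)
  config$beta * sum(eval_profile(profile, lags))
}

#' Spike-pair weight change (transform path)
#'
#' Bins both trains onto the rule grid, forms the cross-correlogram with
#' the FFT (convolution theorem), and weights it by the tabulated profile.
#' Agrees with [pairwise_weight_change()] up to first-order binning error in
#' `grid_step`.
#'
#' @inheritParams pairwise_weight_change
#' @export
pairwise_weight_change_fft <- function(v_spikes, c_spikes, profile, config) {
  stopifnot(inherits(v_spikes, "spike_train"),
            inherits(c_spikes, "spike_train"))
  h <- config$grid_step
  dip <- switch(profile$kind, dog = profile$sigma_ltd,
                doe = profile$tau_ltd, tabulated = NA_real_)
  if (!is.na(dip) && h > dip / 5 + 1e-12)
    stop(sprintf(
      "grid too coarse: grid_step %.3g s does not resolve the LTD dip (%.3g s); need <= dip/5",
      h, dip))
  if (length(v_spikes$times) == 0 || length(c_spikes$times) == 0) return(0)
  W <- resolve_window(config, profile)
  cl <- cross_lag_counts(v_spikes, c_spikes, h, as.integer(round(W / h)))
  config$beta * sum(cl$counts * eval_profile(profile, cl$lags * h))
}

# binned cross-correlogram via the convolution theorem:
# counts[m] = number of spike pairs with binned lag tv - tc = lags[m] * h
cross_lag_counts <- function(v_spikes, c_spikes, h, K) {
  D <- max(v_spikes$duration, c_spikes$duration)
  n <- as.integer(ceiling(D / h))
  xv <- tabulate(pmin(floor(v_spikes$times / h), n - 1) + 1, nbins = n)
  xc <- tabulate(pmin(floor(c_spikes$times / h), n - 1) + 1, nbins = n)
  L <- 2^ceiling(log2(n + K + 1))
  X <- stats::fft(c(xv, rep(0, L - n)))
  Y <- stats::fft(c(xc, rep(0, L - n)))
  cc <- Re(stats::fft(X * Conj(Y), inverse = TRUE)) / L
  # cc[m + 1] counts pairs at lag m*h for m >= 0; negative lags wrap from the end
  list(lags = c(0:K, -(K:1)),
       counts = c(cc[1:(K + 1)], cc[(L - K + 1):L]))
}

#' Firing-rate weight change
#'
#' The rate-coded form of the rule: the weight change over the common
#' window is `beta` times the double integral of
#' `v(t) c(s) P(t - s)`, evaluated as a discrete convolution of the
#' vestibular deviation with the profile followed by integration against the
#' cerebellar deviation. Equivalently `-beta * <c * (k conv v)>` with kernel
#' `k = -P`. Tonic components are excluded: only deviations from tonic
#' drive learning.
#'
#' @param v,c [rate_signal()]s with identical sampling (same `dt`, length).
#' @param profile an `istdp_profile`.
#' @param config a [rule_config()]; `beta` scales the result.
#' @param boundary `"zero"` treats the signals as zero outside the window
#'   (isolated presentation); `"periodic"` wraps them (steady-state
#'   sinusoids).
#' @return list with `total` (cumulative weight change over the window) and
#'   `rate` (`total` divided by the window length).
#' @export
rate_weight_change <- function(v, c, profile, config,
                               boundary = c("zero", "periodic")) {
  stopifnot(inherits(v, "rate_signal"), inherits(c, "rate_signal"))
  boundary <- match.arg(boundary)
  if (abs(v$dt - c$dt) > 1e-12 ||
      length(v$deviation) != length(c$deviation))
    stop("v and c must share sampling (equal dt and length)")
  h <- v$dt
  n <- length(v$deviation)
  W <- resolve_window(config, profile)
  K <- as.integer(round(W / h))
  kern <- eval_profile(profile, seq(-K, K) * h)
  if (boundary == "zero") {
    L <- 2^ceiling(log2(n + 2 * K + 1))
  } else {
    if (n < 2 * K + 1)
      stop("periodic boundary needs window length >= profile window")
    L <- n
  }
  wrap <- c(kern[(K + 1):(2 * K + 1)], rep(0, L - (2 * K + 1)), kern[1:K])
  V <- stats::fft(c(v$deviation, rep(0, L - n)))
  Pw <- stats::fft(wrap)
  # z[i] = sum_j v[j] P((j - i) h): cross-correlation of v with P
  z <- Re(stats::fft(V * Conj(Pw), inverse = TRUE))[1:n] / L
  total <- config$beta * h^2 * sum(c$deviation * z)
  list(total = total, rate = total / (n * h))
}

#' Inter-spike-interval histogram between two trains
#'
#' Counts all vestibular-minus-cerebellar spike-time differences within
#' `max_lag`, in bins of `bin_width` centred on integer multiples of the
#' bin width (so lag 0 falls at the centre of the middle bin).
#'
#' @inheritParams pairwise_weight_change
#' @param bin_width histogram bin width (s), > 0.
#' @param max_lag maximum |lag| retained (s); must not exceed the shorter
#'   train duration.
#' @return data.frame with columns `tau` (bin centre, s) and `count`.
#' @export
isi_histogram <- function(v_spikes, c_spikes, bin_width, max_lag) {
  stopifnot(inherits(v_spikes, "spike_train"),
            inherits(c_spikes, "spike_train"))
  if (bin_width <= 0) stop("bin_width must be positive")
  if (max_lag > min(v_spikes$duration, c_spikes$duration))
    stop("max_lag exceeds the shorter train duration")
  M <- floor(max_lag / bin_width)
  lags <- window_pair_lags(v_spikes$times, c_spikes$times,
                           (M + 0.5) * bin_width)
  idx <- round(lags / bin_width)
  idx <- idx[abs(idx) <= M]
  counts <- tabulate(idx + M + 1, nbins = 2 * M + 1)
  data.frame(tau = seq(-M, M) * bin_width, count = counts)
}
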