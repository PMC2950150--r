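#' Weight trajectory container
#'
#' @param times sample times (s).
#' @param weights synaptic weight (or cumulative weight change) at `times`.
#' @param metadata named list of provenance (protocol, profile parameters,
#'   seeds, ...).
#' @export
weight_trajectory <- function(times, weights, metadata = list()) {
  if (is.unsorted(times)) stop("times must be increasing")
  structure(list(times = times, weights = weights, metadata = metadata),
            class = "weight_trajectory")
}

#' @export
print.weight_trajectory <- function(x, ...) {
  cat(sprintf(
    "weight trajectory: %d samples over %.3g s, final value %.4g\n",
    length(x$times), max(x$times) - min(x$times),
    x$weights[length(x$weights)]))
  invisible(x)
}

#' Soft-saturation configuration
#'
#' @param w_max maximum weight (normalised to 1).
#' @param w_init initial weight as a fraction of `w_max`, in `[0, 1]`.
#' @param enabled if `FALSE`, updates are applied unmodified.
#' @export
saturation_config <- function(w_max = 1, w_init = 0.95, enabled = TRUE) {
  if (w_init < 0 || w_init > 1) stop("w_init must lie in [0, 1]")
  structure(list(w_max = w_max, w_init = w_init, enabled = enabled),
            class = "saturation_config")
}

#' Soft weight saturation
#'
#' Standard soft-bounds rule: potentiation is scaled by the remaining
#' headroom `(1 - w/w_max)` and depression by the current fraction
#' `w/w_max`, keeping the weight smoothly inside `[0, w_max]`.
#'
#' @param dw proposed weight change(s).
#' @param w current weight, in `[0, w_max]`.
#' @param config a [saturation_config()].
#' @return adjusted weight change(s).
#' @export
soft_saturate <- function(dw, w, config = saturation_config()) {
  if (w < 0 || w > config$w_max)
    stop("weight outside [0, w_max]")
  if (!isTRUE(config$enabled)) return(dw)
  ifelse(dw > 0, dw * (1 - w / config$w_max), dw * (w / config$w_max))
}

#' Simulate an induction protocol
#'
#' Computes the per-presentation weight change with the firing-rate form of
#' the learning rule and applies it sequentially over all presentations,
#' optionally through the soft-saturation rule. Presentations are treated
#' as independent (no cross-presentation spike pairs), so without
#' saturation the trajectory is exactly linear in presentation number.
#'
#' @param protocol a [protocol()].
#' @param profile an `istdp_profile`.
#' @param config a [rule_config()].
#' @param saturation a [saturation_config()] or `NULL` for unbounded
#'   cumulative weight change starting from 0.
#' @param pulse_rate_gain,event_rate_area passed to [protocol_to_rates()].
#' @return a [weight_trajectory()] sampled once per presentation; with
#'   saturation the weights are absolute (starting at `w_init * w_max`),
#'   otherwise cumulative change from 0.
#' @export
simulate_protocol <- function(protocol, profile, config = rule_config(),
                              saturation = NULL, pulse_rate_gain = 50,
                              event_rate_area = 1) {
  rr <- protocol_to_rates(protocol, pulse_rate_gain, event_rate_area,
                          config$grid_step)
  dw1 <- rate_weight_change(rr$v, rr$c, profile, config)$total
  n <- protocol$n_presentations
  times <- seq(0, n) * protocol$presentation_period
  if (is.null(saturation) || !isTRUE(saturation$enabled)) {
    w <- c(0, cumsum(rep(dw1, n)))
  } else {
    w <- numeric(n + 1)
    w[1] <- saturation$w_init * saturation$w_max
    for (k in seq_len(n)) {
      w[k + 1] <- min(max(w[k] + soft_saturate(dw1, w[k], saturation), 0),
                      saturation$w_max)
    }
  }
  weight_trajectory(times, w,
    metadata = list(protocol = protocol$name, dw_per_presentation = dw1,
                    beta = config$beta))
}

#' Calibrate beta so PR-0 depresses the weight to a target fraction
#'
#' Under soft saturation, solves for the learning-rate scale at which the
#' PR-0 protocol drives the weight from `w_init * w_max` down to
#' `target_fraction * w_max` by the end of its 30 presentations.
#'
#' @param profile an `istdp_profile`.
#' @param saturation a [saturation_config()].
#' @param target_fraction final weight as a fraction of `w_max`.
#' @inheritParams simulate_protocol
#' @return calibrated `beta`.
#' @export
calibrate_pr0_beta <- function(profile, saturation = saturation_config(),
                               target_fraction = 0.5,
                               pulse_rate_gain = 50, event_rate_area = 1) {
  prot <- build_pr_protocol("PR0")
  final_w <- function(beta) {
    tr <- simulate_protocol(prot, profile, rule_config(beta = beta),
                            saturation, pulse_rate_gain, event_rate_area)
    tr$weights[length(tr$weights)]
  }
  target <- target_fraction * saturation$w_max
  stats::uniroot(function(lb) final_w(exp(lb)) - target,
                 lower = log(1e-8), upper = log(1), tol = 1e-12)$root |>
    exp()
}

#' Stochastic sinusoidal learning (spike-pair rule)
#'
#' Draws `n_segments` independent pairs of Poisson-coded sinusoidal inputs
#' and applies the spike-pair iSTDP rule to each, recording the cumulative
#' weight change within each segment (attributed to vestibular spike
#' times, on a uniform checkpoint grid) and the ensemble mean.
#'
#' @param spec_v,spec_c [modulation_spec()]s sharing frequency and duration.
#' @param profile an `istdp_profile`.
#' @param config a [rule_config()].
#' @param n_segments number of segment pairs.
#' @param phase_lag cerebellar phase offset (radians); 0 = in phase.
#' @param seed master seed.
#' @param checkpoint checkpoint spacing (s) for the within-segment curves.
#' @return list with `times`, `trajectories` (checkpoints x segments
#'   matrix of cumulative weight change), `ensemble_mean`, and `totals`
#'   (per-segment final weight change).
#' @export
simulate_sinusoidal_learning <- function(spec_v, spec_c, profile,
                                         config = rule_config(),
                                         n_segments = 20, phase_lag = 0,
                                         seed = NULL, checkpoint = 1) {
  W <- resolve_window(config, profile)
  ck <- seq(checkpoint, spec_v$duration, by = checkpoint)
  traj <- matrix(0, length(ck), n_segments)
  totals <- numeric(n_segments)
  for (s in seq_len(n_segments)) {
    pr <- make_correlated_pair(spec_v, spec_c, phase_lag,
                               sub_seed(seed, s))
    tv <- pr$v$times; tc <- pr$c$times
    lags <- window_pair_lags(tv, tc, W)
    if (length(lags) > 0) {
      # attribute each pair to its vestibular spike time
      lo <- findInterval(tv - W, tc) + 1
      hi <- findInterval(tv + W, tc)
      n_i <- pmax(hi - lo + 1, 0)
      t_pair <- rep(tv, n_i)
      contrib <- config$beta * eval_profile(profile, lags)
      ord <- order(t_pair)
      cum <- cumsum(contrib[ord])
      idx <- findInterval(ck, t_pair[ord])
      traj[, s] <- ifelse(idx > 0, cum[pmax(idx, 1)], 0)
      totals[s] <- cum[length(cum)]
    }
  }
  list(times = ck, trajectories = traj,
       ensemble_mean = rowMeans(traj), totals = totals)
}

#' Empirical learning-rate curve from spiking simulations
#'
#' Estimates the effective learning rate per modulation frequency from
#' in-phase Poisson-coded sinusoidal input pairs: for each frequency the
#' mean spike-pair weight change over `n_segments` independent segment
#' pairs is converted to a rate via `lambda_hat = -2 dW / (beta T)`, whose
#' expectation is `m_v * m_c * lambda(f)` for modulation depths `m_v`,
#' `m_c`. The modulation-normalised curve (`norm`) estimates `lambda(f)`
#' itself and is directly comparable to the theoretical transform.
#'
#' @param profile an `istdp_profile`.
#' @param spec_v template [modulation_spec()] for the vestibular input (its
#'   `freq` is overridden per evaluation frequency).
#' @param spec_c template for the cerebellar input; defaults to `spec_v`.
#' @param freqs evaluation frequencies (Hz).
#' @param config a [rule_config()].
#' @param n_segments segment pairs per frequency.
#' @param seed master seed. Using the same master seed for two modulation
#'   settings yields common random numbers, which sharpens comparisons of
#'   peak learning rates between settings.
#' @param edge_correct if `TRUE` (default), pair counts at lag tau are
#'   reweighted by `T / (T - |tau|)`, the standard cross-correlogram edge
#'   correction, so the estimator is unbiased for the infinite-duration
#'   learning rate; the raw learning rule itself never applies this.
#' @return list with `freqs`, `raw` (mean rate estimate per frequency),
#'   `se_raw`, `norm`, `se_norm`, `theory` (closed-form or numeric
#'   `lambda(f)`), `peak_raw`, `peak_freq`.
#' @export
estimate_learning_rate <- function(profile, spec_v, spec_c = spec_v,
                                   freqs, config = rule_config(),
                                   n_segments = 20, seed = NULL,
                                   edge_correct = TRUE) {
  raw <- se <- numeric(length(freqs))
  h <- config$grid_step
  K <- as.integer(round(min(profile$support, spec_v$duration / 2) / h))
  for (i in seq_along(freqs)) {
    sv <- spec_v; sv$freq <- freqs[i]
    sc <- spec_c; sc$freq <- freqs[i]
    Tdur <- spec_v$duration
    pk <- eval_profile(profile, seq(-K, K) * h)[c((K + 1):(2 * K + 1), 1:K)]
    lag_w <- if (edge_correct) {
      lt <- abs(c(0:K, -(K:1))) * h
      pk * Tdur / (Tdur - lt)
    } else pk
    dws <- vapply(seq_len(n_segments), function(s) {
      pr <- make_correlated_pair(sv, sc, 0, sub_seed(seed, i * 1000 + s))
      cl <- cross_lag_counts(pr$v, pr$c, h, K)
      config$beta * sum(cl$counts * lag_w)
    }, numeric(1))
    est <- -2 * dws / (config$beta * spec_v$duration)
    raw[i] <- mean(est)
    se[i] <- stats::sd(est) / sqrt(n_segments)
  }
  mm <- spec_v$depth * spec_c$depth
  theory <- tryCatch(lambda_closed_form(profile, freqs),
                     error = function(e)
                       learning_rate_function(profile, freqs)$values)
  k <- which.max(raw)
  list(freqs = freqs, raw = raw, se_raw = se,
       norm = if (mm > 0) raw / mm else raw * NA,
       se_norm = if (mm > 0) se / mm else se * NA,
       theory = theory, peak_raw = raw[k], peak_freq = freqs[k])
}

#' Closed-loop gain-transfer configuration
#'
#' Parameters of the cortex-to-brainstem consolidation loop: a sinusoidal
#' head-velocity signal drives the vestibular input; the cerebellar input
#' carries the corrective signal that cancels the current gain error
#' (cerebellar cortical learning is assumed fast and accurate relative to
#' brainstem learning), encoded as `depth_c` spikes/s per unit fractional
#' gain error.
#'
#' @param target_gain desired brainstem gain w*.
#' @param tonic_v,tonic_c tonic rates (spikes/s).
#' @param depth_v vestibular modulation depth (spikes/s).
#' @param depth_c cerebellar modulation depth per unit fractional gain
#'   error (spikes/s).
#' @param freq head-movement frequency (Hz).
#' @param imbalance relative LTP area excess of the plasticity profile
#'   (recorded for provenance; the profile passed to the simulator governs).
#' @param beta learning-rate scale; `NULL` selects a scale at which the
#'   balanced loop reaches 95% of its asymptote within half the default
#'   number of steps (brainstem learning slow relative to cortex).
#' @param n_steps learning iterations.
#' @param segment_duration seconds of input per iteration.
#' @param w_init initial weight.
#' @param seed master seed.
#' @export
closed_loop_config <- function(target_gain = 0.5, tonic_v = 50,
                               tonic_c = 50, depth_v = 40, depth_c = 40,
                               freq = 3, imbalance = 0, beta = NULL,
                               n_steps = 150, segment_duration = 50,
                               w_init = 0, seed = NULL) {
  if (any(c(tonic_v, tonic_c, depth_v, depth_c) < 0))
    stop("rates and depths must be nonnegative")
  if (freq <= 0) stop("freq must be positive")
  structure(list(target_gain = target_gain, tonic_v = tonic_v,
                 tonic_c = tonic_c, depth_v = depth_v, depth_c = depth_c,
                 freq = freq, imbalance = imbalance, beta = beta,
                 n_steps = n_steps, segment_duration = segment_duration,
                 w_init = w_init, seed = seed),
            class = "closed_loop_config")
}

# default beta: exponential approach rate kappa per step = 0.05
closed_loop_beta <- function(config, profile) {
  if (!is.null(config$beta)) return(config$beta)
  lam <- lambda_closed_form(
    if (profile$kind == "dog")
      make_dog_profile(profile$amp_ltd, profile$sigma_ltd,
                       profile$sigma_ltp, 0)
    else profile,
    config$freq)
  kappa <- 0.05
  2 * kappa * config$target_gain /
    (config$segment_duration * lam * config$depth_v * config$depth_c)
}

#' Closed-loop brainstem learning simulation
#'
#' Iterates slow iSTDP learning of the brainstem weight w inside the
#' behavioural loop: at each step the cerebellar modulation is set to the
#' corrective signal implied by the current weight error
#' (`(w - w*) / w*`, scaled to `depth_c` spikes/s per unit), one segment
#' pair is Poisson-encoded, and the spike-pair rule updates w. With a
#' balanced profile the fixed point is w = w*; an LTP/LTD imbalance shifts
#' the stable limiting weight, producing a gain-transfer error.
#'
#' @param config a [closed_loop_config()].
#' @param profile an `istdp_profile` (its imbalance drives the error).
#' @return a [weight_trajectory()] with metadata including
#'   `final_gain_error` (percent, relative to the balanced-case weight
#'   w*), `w_final` (mean weight over the final third of the run), and
#'   `beta`.
#' @export
simulate_closed_loop <- function(config, profile) {
  stopifnot(inherits(config, "closed_loop_config"))
  beta <- closed_loop_beta(config, profile)
  rc <- rule_config(beta = beta)
  wstar <- config$target_gain
  dt <- 1e-3
  n <- round(config$segment_duration / dt)
  t <- (seq_len(n) - 0.5) * dt
  s_mod <- sin(2 * pi * config$freq * t)
  v_rate <- rate_signal(config$tonic_v, config$depth_v * s_mod, dt)
  w <- numeric(config$n_steps + 1)
  w[1] <- config$w_init
  clip_warned <- FALSE
  for (k in seq_len(config$n_steps)) {
    amp_c <- config$depth_c * (w[k] - wstar) / wstar
    if (!clip_warned && abs(amp_c) > config$tonic_c) {
      warning("corrective cerebellar modulation exceeds tonic rate; clipping")
      clip_warned <- TRUE
    }
    c_rate <- rate_signal(config$tonic_c, amp_c * s_mod, dt)
    sv <- poisson_encode(v_rate, sub_seed(config$seed, 2 * k))
    sc <- poisson_encode(c_rate, sub_seed(config$seed, 2 * k + 1))
    w[k + 1] <- w[k] + pairwise_weight_change_fft(sv, sc, profile, rc)
    if (abs(w[k + 1]) > 10 * abs(wstar))
      stop(sprintf(
        "closed-loop instability: |w| exceeded 10x target at step %d (imbalance %.3g)",
        k, profile$imbalance))
  }
  tail_n <- max(1, floor(config$n_steps / 3))
  w_final <- mean(w[(length(w) - tail_n + 1):length(w)])
  err <- 100 * (w_final - wstar) / wstar
  weight_trajectory(
    seq(0, config$n_steps) * config$segment_duration, w,
    metadata = list(final_gain_error = err, w_final = w_final,
                    beta = beta, imbalance = profile$imbalance,
                    seed = config$seed))
}

#' Analytic closed-loop equilibrium gain error
#'
#' Closed-form fixed point of the loop in [simulate_closed_loop()]: the
#' drift from the tonic-rate imbalance term balances the corrective
#' correlated-modulation term, giving a fractional weight error
#' \deqn{(w - w^*)/w^* = \frac{2\, r_{0v} r_{0c}\, \int P}
#'   {m_v\, m_c\, \lambda(f)}}
#' where `int P` is the profile's total area (epsilon times the LTD
#' component area) and `lambda(f)` its learning rate at the loop frequency.
#' With `profile = NULL` the idealised all-pass profile is assumed
#' (`int P / lambda = epsilon` from `config$imbalance`), giving
#' `200 * eps * r0v * r0c / (m_v * m_c)` percent.
#'
#' @param config a [closed_loop_config()].
#' @param profile an `istdp_profile`, or `NULL` for the idealised profile.
#' @return gain error in percent.
#' @export
analytic_closed_loop_error <- function(config, profile = NULL) {
  stopifnot(inherits(config, "closed_loop_config"))
  if (config$depth_v <= 0 || config$depth_c <= 0)
    stop("modulation depths must be positive for a fixed point to exist")
  ratio <- if (is.null(profile)) {
    config$imbalance
  } else {
    profile_areas(profile)$total / lambda_closed_form(profile, config$freq)
  }
  200 * config$tonic_v * config$tonic_c * ratio /
    (config$depth_v * config$depth_c)
}
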