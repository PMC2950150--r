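#' Run code with a private, reproducible RNG stream
#'
#' Saves and restores `.Random.seed` so package simulations are replayable
#' from a seed without disturbing the caller's RNG state. A `NULL` seed
#' uses (and advances) the global stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic substream seeds, kept below 2^31 - 1
sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k * 104729) %%
               2147483647)
}

#' Specification of a sinusoidally modulated firing rate
#'
#' Describes the rate-coded vestibular or cerebellar input used throughout
#' the in-vivo simulations: a tonic rate plus a sinusoidal modulation.
#'
#' @param tonic baseline rate r0 (spikes/s), >= 0.
#' @param depth peak modulation m (spikes/s), >= 0.
#' @param freq modulation frequency (Hz).
#' @param phase phase (radians).
#' @param duration segment length (s), > 0.
#' @param seed integer seed used when the spec is Poisson-encoded, or `NULL`.
#' @export
modulation_spec <- function(tonic, depth, freq, phase = 0, duration = 50,
                            seed = NULL) {
  if (tonic < 0 || depth < 0) stop("tonic and depth must be nonnegative")
  if (duration <= 0) stop("duration must be positive")
  structure(list(tonic = tonic, depth = depth, freq = freq, phase = phase,
                 duration = duration, seed = seed),
            class = "modulation_spec")
}

#' Sinusoidal rate signal from a modulation spec
#'
#' Samples `r(t) = tonic + depth * sin(2 pi freq t + phase)` on a uniform
#' grid. The deviation is stored unclipped; the Poisson encoding path clips
#' the total rate at zero, and the fraction of samples that would be
#' clipped is reported in the `clipped_fraction` attribute.
#'
#' @param spec a [modulation_spec()].
#' @param dt sampling step (s).
#' @return a [rate_signal()] with attribute `clipped_fraction`.
#' @export
sinusoidal_rate <- function(spec, dt = 1e-3) {
  stopifnot(inherits(spec, "modulation_spec"))
  n <- round(spec$duration / dt)
  t <- (seq_len(n) - 0.5) * dt
  dev <- spec$depth * sin(2 * pi * spec$freq * t + spec$phase)
  out <- rate_signal(spec$tonic, dev, dt)
  attr(out, "clipped_fraction") <- mean(spec$tonic + dev < 0)
  out
}

#' Poisson-encode a rate signal into a spike train
#'
#' Inhomogeneous Poisson sampling by per-bin Bernoulli draws: the
#' probability of a spike in a short interval dt is `r * dt`. The sampling
#' grid is refined automatically so that `max(r) * dt <= 0.1`; negative
#' instantaneous rates are clipped to zero. Reproducible given `seed`.
#'
#' @param rate a [rate_signal()].
#' @param seed integer seed or `NULL`.
#' @return a [spike_train()] over the signal's window.
#' @export
poisson_encode <- function(rate, seed = NULL) {
  stopifnot(inherits(rate, "rate_signal"))
  r <- pmax(rate$tonic + rate$deviation, 0)
  dt <- rate$dt
  m <- max(1L, as.integer(ceiling(max(r, 0) * dt / 0.1)))
  rf <- rep(r, each = m)
  dtf <- dt / m
  with_seed(seed, {
    hit <- stats::runif(length(rf)) < rf * dtf
    times <- (which(hit) - 0.5) * dtf
    spike_train(times, length(rate$deviation) * dt)
  })
}

#' Generate a correlated pair of Poisson spike trains
#'
#' Two independent Poisson encodings of sinusoidal rates sharing a common
#' frequency, with the cerebellar phase offset by `phase_lag` relative to
#' the vestibular phase (0 = in phase, pi = anti-phase). Independent
#' substreams derived from `seed` drive the two encodings, so the trains
#' share rate modulation but no spike-level structure.
#'
#' @param spec_v,spec_c [modulation_spec()]s with equal `freq` and
#'   `duration`.
#' @param phase_lag cerebellar phase offset (radians).
#' @param seed master seed; substreams are derived per train.
#' @param dt sampling step (s) for the underlying rate signals.
#' @return list with elements `v` and `c`, both [spike_train()]s.
#' @export
make_correlated_pair <- function(spec_v, spec_c, phase_lag = 0, seed = NULL,
                                 dt = 1e-3) {
  stopifnot(inherits(spec_v, "modulation_spec"),
            inherits(spec_c, "modulation_spec"))
  if (abs(spec_v$freq - spec_c$freq) > 1e-12 ||
      abs(spec_v$duration - spec_c$duration) > 1e-12)
    stop("spec_v and spec_c must share freq and duration")
  spec_c2 <- spec_c
  spec_c2$phase <- spec_v$phase + phase_lag
  rv <- sinusoidal_rate(spec_v, dt)
  rc <- sinusoidal_rate(spec_c2, dt)
  list(v = poisson_encode(rv, sub_seed(seed, 1)),
       c = poisson_encode(rc, sub_seed(seed, 2)))
}
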