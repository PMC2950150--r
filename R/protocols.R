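#' In-vitro induction protocols
#'
#' A protocol is a repeated pairing schedule of excitatory (vestibular
#' afferent) events and injected current pulses within one presentation
#' window. Pulse amplitudes are in normalised units: +1 is the standard
#' hyperpolarising pulse (mimicking an IPSP, i.e. increased inhibitory
#' input), negative amplitudes are depolarisations (decreased inhibitory
#' input).
#'
#' @param name label.
#' @param excitatory_events event times within one presentation (s).
#' @param inhibitory_pulses list of pulses, each `list(onset, duration,
#'   amplitude)`.
#' @param presentation_period seconds between presentation onsets.
#' @param n_presentations number of presentations, >= 1.
#' @export
protocol <- function(name, excitatory_events, inhibitory_pulses,
                     presentation_period, n_presentations) {
  if (n_presentations < 1) stop("n_presentations must be >= 1")
  ev <- as.numeric(excitatory_events)
  if (any(ev < 0) || any(ev >= presentation_period))
    stop("excitatory events must lie within one presentation period")
  for (p in inhibitory_pulses) {
    if (p$onset < 0 || p$onset + p$duration > presentation_period)
      stop("pulse extends outside the presentation period")
  }
  structure(list(name = name, excitatory_events = ev,
                 inhibitory_pulses = inhibitory_pulses,
                 presentation_period = presentation_period,
                 n_presentations = n_presentations),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf(
    "protocol %s: %d events, %d pulse(s), %d presentations every %.3g s\n",
    x$name, length(x$excitatory_events), length(x$inhibitory_pulses),
    x$n_presentations, x$presentation_period))
  invisible(x)
}

#' Input-spike-timing (iST) induction protocol
#'
#' One vestibular afferent stimulus paired with a 20 ms hyperpolarising
#' pulse of unit amplitude, repeated (by default 1000 presentations at
#' 0.5 s intervals). `Ts` is the stimulus time relative to pulse onset:
#' `Ts = 0` puts the stimulus at pulse onset, `Ts = 0.020` at pulse end
#' (the peak of membrane hyperpolarisation), negative values place it
#' before the pulse. The pulse is positioned mid-window so negative `Ts`
#' stays inside the presentation.
#'
#' @param Ts stimulus time relative to pulse onset (s).
#' @param n_presentations number of presentations.
#' @param period presentation period (s).
#' @param pulse_duration hyperpolarising pulse duration (s).
#' @return a [protocol()].
#' @export
build_ist_protocol <- function(Ts, n_presentations = 1000, period = 0.5,
                               pulse_duration = 0.020) {
  onset <- period / 2
  protocol(name = sprintf("iST Ts=%g ms", 1000 * Ts),
           excitatory_events = onset + Ts,
           inhibitory_pulses = list(list(onset = onset,
                                         duration = pulse_duration,
                                         amplitude = 1)),
           presentation_period = period,
           n_presentations = n_presentations)
}

#' Pause-rebound (PR) induction protocols
#'
#' A 130 Hz regular vestibular train over 550 ms (72 events) paired with
#' 250 ms current pulses, 30 presentations at 5 s intervals:
#' * `PR0` -- hyperpolarisation (0--250 ms, amplitude +1);
#' * `PR1` -- hyperpolarisation followed by a 250 ms depolarisation of
#'   equal amplitude;
#' * `PR2` -- hyperpolarisation followed by a 125 ms depolarisation of
#'   twice the amplitude (equal pulse areas);
#' * `PR3` -- 250 ms depolarisation only.
#'
#' @param variant one of `"PR0"`, `"PR1"`, `"PR2"`, `"PR3"`.
#' @return a [protocol()].
#' @export
build_pr_protocol <- function(variant = c("PR0", "PR1", "PR2", "PR3")) {
  variant <- match.arg(variant)
  events <- seq(0, 0.550, by = 1 / 130)
  pulses <- switch(variant,
    PR0 = list(list(onset = 0, duration = 0.250, amplitude = 1)),
    PR1 = list(list(onset = 0, duration = 0.250, amplitude = 1),
               list(onset = 0.250, duration = 0.250, amplitude = -1)),
    PR2 = list(list(onset = 0, duration = 0.250, amplitude = 1),
               list(onset = 0.250, duration = 0.125, amplitude = -2)),
    PR3 = list(list(onset = 0, duration = 0.250, amplitude = -1)))
  protocol(name = variant, excitatory_events = events,
           inhibitory_pulses = pulses,
           presentation_period = 5, n_presentations = 30)
}

#' Rate-signal representation of one protocol presentation
#'
#' Maps the schedule to the firing-rate form of the learning rule: current
#' pulses become proportional cerebellar rate deviations
#' (hyperpolarisation, i.e. stronger inhibitory drive, is a positive
#' deviation; depolarisation negative), and each excitatory event becomes a
#' vestibular rate impulse of fixed area on the sampling grid.
#'
#' @param protocol a [protocol()].
#' @param pulse_rate_gain cerebellar rate deviation per unit pulse
#'   amplitude (spikes/s).
#' @param event_rate_area area of each vestibular rate impulse (spikes).
#' @param sample_step sampling step (s).
#' @return list with [rate_signal()]s `v` and `c` covering one presentation.
#' @export
protocol_to_rates <- function(protocol, pulse_rate_gain = 50,
                              event_rate_area = 1, sample_step = 1e-3) {
  stopifnot(inherits(protocol, "protocol"))
  if (pulse_rate_gain <= 0 || event_rate_area <= 0)
    stop("gains must be positive")
  n <- round(protocol$presentation_period / sample_step)
  vdev <- numeric(n)
  idx <- pmin(floor(protocol$excitatory_events / sample_step) + 1, n)
  for (i in idx) vdev[i] <- vdev[i] + event_rate_area / sample_step
  cdev <- numeric(n)
  for (p in protocol$inhibitory_pulses) {
    from <- floor(p$onset / sample_step) + 1
    to <- max(from, ceiling((p$onset + p$duration) / sample_step))
    cdev[from:to] <- cdev[from:to] + pulse_rate_gain * p$amplitude
  }
  list(v = rate_signal(0, vdev, sample_step),
       c = rate_signal(0, cdev, sample_step))
}

#' Spiking representation of one protocol presentation
#'
#' Excitatory events become literal vestibular spikes; the cerebellar
#' channel is Poisson-encoded from `tonic_c` plus the pulse-proportional
#' rate deviation (clipped at zero). A nonzero `tonic_c` is needed to
#' express depolarisations (rate decreases) in spikes. Because tonic
#' inhibitory firing continues between presentations, the cerebellar
#' window is padded by `pad` seconds of tonic-rate spiking on both sides
#' (set it to the profile support): every event then sees the full pair
#' window of tonic spikes, and a balanced profile draws no net drift from
#' the tonic stream.
#'
#' @inheritParams protocol_to_rates
#' @param tonic_c cerebellar tonic rate (spikes/s).
#' @param pad tonic padding (s) added before and after the presentation on
#'   the cerebellar channel; event and pulse times shift by `pad`.
#' @param seed RNG seed for the Poisson encoding.
#' @return list of [spike_train()]s `v` and `c` on the padded time base.
#' @export
protocol_spike_trains <- function(protocol, pulse_rate_gain = 50,
                                  tonic_c = 0, pad = 0, seed = NULL,
                                  sample_step = 1e-3) {
  rr <- protocol_to_rates(protocol, pulse_rate_gain, 1, sample_step)
  npad <- round(pad / sample_step)
  dev <- c(rep(0, npad), rr$c$deviation, rep(0, npad))
  cr <- rate_signal(tonic_c, dev, sample_step)
  list(v = spike_train(protocol$excitatory_events + npad * sample_step,
                       protocol$presentation_period + 2 * npad * sample_step),
       c = poisson_encode(cr, seed))
}

#' Serialise / deserialise a protocol as JSON
#' @param protocol a [protocol()].
#' @param path file path.
#' @export
write_protocol_json <- function(protocol, path) {
  stopifnot(inherits(protocol, "protocol"))
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  protocol(x$name, unlist(x$excitatory_events),
           lapply(x$inhibitory_pulses, function(p)
             list(onset = p$onset, duration = p$duration,
                  amplitude = p$amplitude)),
           x$presentation_period, x$n_presentations)
}
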