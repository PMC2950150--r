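#' iSTDP profiles and their frequency-domain learning rates
#'
#' An iSTDP profile P(tau) gives the change in vestibular synaptic weight
#' caused by a single pair of input spikes -- one on the excitatory
#' (vestibular) stream, one on the inhibitory (cerebellar/Purkinje) stream --
#' as a function of the inter-spike interval tau = t_vestibular - t_cerebellar.
#' The anti-Hebbian form has a narrow LTD dip at coincidence (P(0) < 0)
#' balanced by broad shallow LTP lobes, so that tonic uncorrelated inputs
#' produce no net drift (zero total area). The associated convolution kernel
#' is k(tau) = -P(tau); the effective learning rate at head-movement frequency
#' f is the real part of the Fourier transform of k.
#'
#' @name istdp_profile
#' @keywords internal
NULL

new_istdp_profile <- function(kind, params, imbalance, antisymmetric = FALSE,
                              grid_step = 1e-3, support = NULL) {
  # Gaussian tails die at ~7 sigma; exponential tails need ~25 time
  # constants for the truncated area to be negligible at 1e-9 scale
  width <- switch(kind,
    dog = 7 * params$sigma_ltp,
    doe = 25 * params$tau_ltp,
    tabulated = max(abs(params$tau)))
  if (is.null(support)) support <- max(1, width)
  structure(
    c(list(kind = kind), params,
      list(imbalance = imbalance, antisymmetric = antisymmetric,
           grid_step = grid_step, support = support)),
    class = "istdp_profile")
}

#' Construct a difference-of-Gaussians iSTDP profile
#'
#' Builds the time-symmetric bandpass profile
#' \deqn{P(\tau) = a_D e^{-\tau^2/2\sigma_D^2} + a_P e^{-\tau^2/2\sigma_P^2}}
#' with `amp_ltd` = \eqn{a_D < 0} (narrow LTD dip) and the LTP amplitude
#' \eqn{a_P} solved from the area condition: the area of the positive Gaussian
#' equals `(1 + imbalance)` times the magnitude of the negative Gaussian's
#' area. With `imbalance = 0` the total area is exactly zero, so tonic
#' uncorrelated inputs cause no weight drift.
#'
#' @param amp_ltd LTD dip amplitude (weight change per pair at tau = 0 from
#'   the dip component alone); must be negative.
#' @param sigma_ltd LTD dip width (s); must be positive and smaller than
#'   `sigma_ltp`.
#' @param sigma_ltp LTP lobe width (s).
#' @param imbalance relative excess of LTP area over LTD area (0 = balanced).
#' @param grid_step tabulation step (s) used by grid-based operations.
#' @param support half-width (s) of the window outside which the tabulated
#'   profile is treated as zero; defaults to `max(1, 7 * sigma_ltp)` so the
#'   truncated tail area is negligible.
#' @return An object of class `istdp_profile`.
#' @examples
#' p <- make_dog_profile(-1, 0.010, 0.100)
#' eval_profile(p, 0)          # dip at coincidence
#' profile_areas(p)$total      # 0: balanced
#' @export
make_dog_profile <- function(amp_ltd, sigma_ltd, sigma_ltp, imbalance = 0,
                             grid_step = 1e-3, support = NULL) {
  if (!is.numeric(amp_ltd) || amp_ltd >= 0)
    stop("`amp_ltd` must be negative (LTD at coincidence)")
  if (sigma_ltd <= 0 || sigma_ltp <= sigma_ltd)
    stop("width ordering violated: need 0 < sigma_ltd < sigma_ltp")
  amp_ltp <- abs(amp_ltd) * (sigma_ltd / sigma_ltp) * (1 + imbalance)
  new_istdp_profile("dog",
    list(amp_ltd = amp_ltd, sigma_ltd = sigma_ltd,
         amp_ltp = amp_ltp, sigma_ltp = sigma_ltp),
    imbalance, FALSE, grid_step, support)
}

#' Construct a difference-of-exponentials iSTDP profile
#'
#' Exponential analogue of [make_dog_profile()]. With
#' `antisymmetric = FALSE` both the LTD dip and the LTP lobes are two-sided
#' (even in tau); with `antisymmetric = TRUE` the LTD branch occupies
#' tau > 0 and the LTP branch tau < 0, resembling classical causal STDP
#' windows. The LTP amplitude is solved from the same area condition as for
#' the DoG profile (component areas `2*a*tau`, or `a*tau` one-sided).
#'
#' @param amp_ltd LTD amplitude, negative.
#' @param tau_ltd,tau_ltp LTD / LTP time constants (s), `tau_ltp > tau_ltd`.
#' @param imbalance relative LTP area excess.
#' @param antisymmetric if `TRUE`, one-sided branches (LTD for tau >= 0,
#'   LTP for tau < 0).
#' @inheritParams make_dog_profile
#' @return An `istdp_profile`.
#' @export
make_doe_profile <- function(amp_ltd, tau_ltd, tau_ltp, imbalance = 0,
                             antisymmetric = FALSE,
                             grid_step = 1e-3, support = NULL) {
  if (!is.numeric(amp_ltd) || amp_ltd >= 0)
    stop("`amp_ltd` must be negative (LTD at coincidence)")
  if (tau_ltd <= 0 || tau_ltp <= tau_ltd)
    stop("width ordering violated: need 0 < tau_ltd < tau_ltp")
  amp_ltp <- abs(amp_ltd) * (tau_ltd / tau_ltp) * (1 + imbalance)
  new_istdp_profile("doe",
    list(amp_ltd = amp_ltd, tau_ltd = tau_ltd,
         amp_ltp = amp_ltp, tau_ltp = tau_ltp),
    imbalance, antisymmetric, grid_step, support)
}

#' Construct a tabulated iSTDP profile from (tau, value) samples
#'
#' For profiles without a parametric form. `tau` must be a uniform,
#' symmetric grid; values outside its range are treated as zero.
#'
#' @param tau sample times (s), uniformly spaced, spanning negative and
#'   positive lags.
#' @param values profile values at `tau`.
#' @export
make_tabulated_profile <- function(tau, values) {
  if (length(tau) != length(values)) stop("tau and values lengths differ")
  h <- diff(tau)
  if (length(h) < 1 || max(abs(h - h[1])) > 1e-9 * h[1])
    stop("tau must be a uniform grid")
  new_istdp_profile("tabulated", list(tau = tau, values = values),
                    imbalance = NA_real_, grid_step = h[1],
                    support = max(abs(tau)))
}

#' Evaluate an iSTDP profile at inter-spike intervals
#'
#' @param profile an `istdp_profile`.
#' @param tau inter-spike intervals tau = t_vestibular - t_cerebellar (s).
#' @return numeric vector of per-pair weight changes; zero outside the
#'   profile's support window.
#' @export
eval_profile <- function(profile, tau) {
  stopifnot(inherits(profile, "istdp_profile"))
  out <- switch(profile$kind,
    dog = profile$amp_ltd * exp(-tau^2 / (2 * profile$sigma_ltd^2)) +
          profile$amp_ltp * exp(-tau^2 / (2 * profile$sigma_ltp^2)),
    doe = if (profile$antisymmetric) {
      ifelse(tau >= 0,
             profile$amp_ltd * exp(-tau / profile$tau_ltd),
             profile$amp_ltp * exp(tau / profile$tau_ltp))
    } else {
      profile$amp_ltd * exp(-abs(tau) / profile$tau_ltd) +
      profile$amp_ltp * exp(-abs(tau) / profile$tau_ltp)
    },
    tabulated = {
      idx <- round((tau - profile$tau[1]) / profile$grid_step) + 1
      v <- rep(0, length(tau))
      ok <- idx >= 1 & idx <= length(profile$values) &
            abs(tau - (profile$tau[1] + (idx - 1) * profile$grid_step)) <
              profile$grid_step
      v[ok] <- profile$values[idx[ok]]
      v
    })
  out[abs(tau) > profile$support] <- 0
  out
}

#' Closed-form LTP/LTD component areas of a parametric profile
#'
#' Returns the (untruncated) areas of the positive and negative components
#' and their sum. For a balanced profile the total is exactly zero; with
#' imbalance eps, `positive = (1 + eps) * abs(negative)`.
#'
#' @param profile an `istdp_profile`.
#' @return list with elements `negative` (signed, < 0), `positive`, `total`.
#' @export
profile_areas <- function(profile) {
  stopifnot(inherits(profile, "istdp_profile"))
  switch(profile$kind,
    dog = {
      neg <- profile$amp_ltd * profile$sigma_ltd * sqrt(2 * pi)
      pos <- profile$amp_ltp * profile$sigma_ltp * sqrt(2 * pi)
      list(negative = neg, positive = pos, total = pos + neg)
    },
    doe = {
      k <- if (profile$antisymmetric) 1 else 2
      neg <- k * profile$amp_ltd * profile$tau_ltd
      pos <- k * profile$amp_ltp * profile$tau_ltp
      list(negative = neg, positive = pos, total = pos + neg)
    },
    tabulated = {
      v <- profile$values
      h <- profile$grid_step
      list(negative = sum(v[v < 0]) * h, positive = sum(v[v > 0]) * h,
           total = sum(v) * h)
    })
}

#' Tabulate a profile on its grid
#'
#' @param profile an `istdp_profile`.
#' @return data.frame with columns `tau` (s) and `value`.
#' @export
tabulate_profile <- function(profile) {
  stopifnot(inherits(profile, "istdp_profile"))
  n <- round(profile$support / profile$grid_step)
  tau <- seq(-n, n) * profile$grid_step
  data.frame(tau = tau, value = eval_profile(profile, tau))
}

# Closed-form lambda(f) = Re FT of kernel k = -P, for parametric kinds.
lambda_closed_form <- function(profile, freqs) {
  w <- 2 * pi * freqs
  switch(profile$kind,
    dog = -(profile$amp_ltd * profile$sigma_ltd * sqrt(2 * pi) *
              exp(-profile$sigma_ltd^2 * w^2 / 2) +
            profile$amp_ltp * profile$sigma_ltp * sqrt(2 * pi) *
              exp(-profile$sigma_ltp^2 * w^2 / 2)),
    doe = {
      k <- if (profile$antisymmetric) 1 else 2
      -(k * profile$amp_ltd * profile$tau_ltd / (1 + w^2 * profile$tau_ltd^2) +
        k * profile$amp_ltp * profile$tau_ltp / (1 + w^2 * profile$tau_ltp^2))
    },
    stop("no closed-form transform for kind '", profile$kind, "'"))
}

#' Frequency-dependent learning rate of an iSTDP profile
#'
#' Computes the effective learning rate lambda(f) for sinusoidally modulated
#' inputs at head-movement frequency f, defined as the real part of the
#' Fourier transform of the convolution kernel k(tau) = -P(tau). For a
#' balanced profile lambda(0) = 0, so tonic (DC) activity drives no
#' learning; the profile acts as a bandpass filter on input correlations.
#'
#' The default path evaluates the transform numerically from the tabulated
#' kernel (trapezoidal quadrature on the profile grid); for `dog` and `doe`
#' kinds `method = "closed_form"` uses the analytic Gaussian / Lorentzian
#' Fourier pairs instead.
#'
#' @param profile an `istdp_profile`.
#' @param freqs evaluation frequencies (Hz), all >= 0.
#' @param method `"numeric"` (tabulated transform) or `"closed_form"`.
#' @return object of class `learning_rate_function`: list with `freqs`,
#'   `values`, `peak_freq`, `peak_value`, and `imag_residue` (relative
#'   magnitude of the imaginary part left by the numeric transform).
#' @export
learning_rate_function <- function(profile, freqs,
                                   method = c("numeric", "closed_form")) {
  stopifnot(inherits(profile, "istdp_profile"))
  method <- match.arg(method)
  if (any(freqs < 0)) stop("freqs must be nonnegative")
  f_ny <- 1 / (2 * profile$grid_step)
  if (method == "numeric" && max(freqs) > f_ny)
    stop(sprintf(
      "grid too coarse: max frequency %.3g Hz exceeds grid Nyquist %.3g Hz",
      max(freqs), f_ny))
  if (method == "closed_form") {
    values <- lambda_closed_form(profile, freqs)
    resid <- 0
  } else {
    tab <- tabulate_profile(profile)
    k <- -tab$value
    h <- profile$grid_step
    re <- vapply(freqs, function(f) sum(k * cos(2 * pi * f * tab$tau)) * h,
                 numeric(1))
    im <- vapply(freqs, function(f) sum(k * sin(2 * pi * f * tab$tau)) * h,
                 numeric(1))
    values <- re
    scale <- max(abs(re), .Machine$double.eps)
    resid <- max(abs(im)) / scale
  }
  pk <- peak_learning_rate(profile, method = method)
  structure(list(freqs = freqs, values = values,
                 peak_freq = pk$freq, peak_value = pk$value,
                 imag_residue = resid),
            class = "learning_rate_function")
}

#' Peak of the learning-rate function
#'
#' Locates the maximum of lambda(f) over f in (0, Nyquist of the profile
#' grid) by golden-section search on log-frequency.
#'
#' @inheritParams learning_rate_function
#' @return list with `freq` (Hz) and `value`.
#' @export
peak_learning_rate <- function(profile, method = c("numeric", "closed_form")) {
  method <- match.arg(method)
  lam <- if (method == "closed_form" || profile$kind == "tabulated") {
    if (profile$kind == "tabulated") {
      tab_k <- -profile$values
      h <- profile$grid_step
      function(f) sum(tab_k * cos(2 * pi * f * profile$tau)) * h
    } else {
      function(f) lambda_closed_form(profile, f)
    }
  } else {
    tab <- tabulate_profile(profile)
    k <- -tab$value
    h <- profile$grid_step
    function(f) sum(k * cos(2 * pi * f * tab$tau)) * h
  }
  f_hi <- min(1 / (2 * profile$grid_step), 100)
  opt <- stats::optimize(function(lf) lam(exp(lf)),
                         lower = log(1e-3), upper = log(f_hi), maximum = TRUE,
                         tol = 1e-10)
  list(freq = exp(opt$maximum), value = opt$objective)
}

#' Calibrate a balanced DoG profile to a learning-rate passband
#'
#' Solves the two width parameters (sigma_ltd, sigma_ltp) of a balanced
#' difference-of-Gaussians profile so that the learning rate falls to
#' `edge_fraction` of its maximum at both band edges `f_lo` and `f_hi`
#' (the VOR-adaptation constraint uses 0.3 and 10 Hz at 20%). Newton
#' iteration on (log sigma_ltd, log sigma_ltp) with the closed-form
#' transform; the returned profile is scaled so that min P = -1.
#'
#' @param f_lo,f_hi lower and upper band-edge frequencies (Hz), 0 < f_lo < f_hi.
#' @param edge_fraction fraction of peak learning rate at the edges, in (0, 1).
#' @param grid_step,support passed to [make_dog_profile()].
#' @return calibrated balanced `istdp_profile` (kind `dog`).
#' @export
calibrate_bandpass <- function(f_lo = 0.3, f_hi = 10, edge_fraction = 0.2,
                               grid_step = 1e-3, support = NULL) {
  if (!(f_lo > 0 && f_hi > f_lo)) stop("need 0 < f_lo < f_hi")
  if (!(edge_fraction > 0 && edge_fraction < 1))
    stop("edge_fraction must be in (0, 1)")
  # balanced lambda up to amplitude: sD * (exp(-(sD w)^2/2) - exp(-(sP w)^2/2))
  lam <- function(f, sD, sP) {
    w <- 2 * pi * f
    sD * (exp(-(sD * w)^2 / 2) - exp(-(sP * w)^2 / 2))
  }
  lam_peak <- function(sD, sP) {
    wst <- sqrt(2 * log(sP^2 / sD^2) / (sP^2 - sD^2))
    lam(wst / (2 * pi), sD, sP)
  }
  resid <- function(p) {
    sD <- exp(p[1]); sP <- exp(p[2])
    m <- lam_peak(sD, sP)
    c(lam(f_lo, sD, sP) / m - edge_fraction,
      lam(f_hi, sD, sP) / m - edge_fraction)
  }
  # initial guess: dip scale from the upper edge, lobes from the lower edge
  p <- log(c(0.3 / f_hi, 0.1 / f_lo))
  converged <- FALSE
  trace <- character(0)
  for (it in seq_len(200)) {
    r <- resid(p)
    if (max(abs(r)) < 1e-10) { converged <- TRUE; break }
    J <- matrix(0, 2, 2)
    h <- 1e-7
    for (j in 1:2) {
      ph <- p; ph[j] <- ph[j] + h
      J[, j] <- (resid(ph) - r) / h
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    # damping: halve until residual does not blow up
    lambda_damp <- 1
    repeat {
      pn <- p + lambda_damp * step
      rn <- tryCatch(resid(pn), error = function(e) rep(Inf, 2))
      if (all(is.finite(rn)) && max(abs(rn)) < max(abs(r)) * (1 - 1e-4) ||
          lambda_damp < 1e-6) break
      lambda_damp <- lambda_damp / 2
    }
    trace <- c(trace, sprintf("it %d: resid %.3g", it, max(abs(r))))
    p <- pn
  }
  if (!converged)
    stop("calibration failed to converge; attempts:\n",
         paste(utils::tail(trace, 5), collapse = "\n"))
  sD <- exp(p[1]); sP <- exp(p[2])
  # scale so min P = -1: with amp_ltd = -a, min P = -a (1 - sD/sP)
  a <- 1 / (1 - sD / sP)
  make_dog_profile(-a, sD, sP, imbalance = 0,
                   grid_step = grid_step, support = support)
}

#' The VOR-calibrated iSTDP profile
#'
#' Balanced DoG profile whose learning rate falls to 20% of maximum at
#' 0.3 and 10 Hz, the frequency band over which VOR gain adaptation is
#' transferred to the brainstem.
#'
#' @inheritParams make_dog_profile
#' @export
vor_calibrated_profile <- function(grid_step = 1e-3, support = NULL) {
  calibrate_bandpass(0.3, 10, 0.2, grid_step = grid_step, support = support)
}

#' The experimentally constrained iSTDP profile
#'
#' Balanced DoG profile whose LTD dip half-width at 20% of maximum depth is
#' `halfwidth` (default 20 ms, the value consistent with the in-vitro timing
#' sweep), with the LTP lobe width kept at the VOR-calibrated value: the
#' slice data constrain only the dip, corresponding to better high-frequency
#' learning, while the low-frequency edge of the passband is unchanged.
#' Scaled so min P = -1.
#'
#' @param halfwidth dip half-width at 20% of maximum depth (s).
#' @param imbalance relative LTP area excess.
#' @inheritParams make_dog_profile
#' @export
constrained_profile <- function(halfwidth = 0.020, imbalance = 0,
                                grid_step = 1e-3, support = NULL) {
  vor <- calibrate_bandpass(0.3, 10, 0.2, grid_step = grid_step)
  sP <- vor$sigma_ltp
  hw_of <- function(sD) {
    p <- make_dog_profile(-1, sD, sP, grid_step = grid_step)
    dip_halfwidth(p, 0.2)
  }
  sD <- stats::uniroot(function(s) hw_of(s) - halfwidth,
                       c(halfwidth / 4, halfwidth * 2), tol = 1e-12)$root
  a <- 1 / (1 - (sD / sP) * (1 + imbalance))
  make_dog_profile(-a, sD, sP, imbalance = imbalance,
                   grid_step = grid_step, support = support)
}

#' Half-width of the LTD dip at a fractional depth
#'
#' Returns half of the full width of the region where
#' `P(tau) <= depth_fraction * min(P)`, i.e. where the dip is at least
#' `depth_fraction` of its maximum depth (depth measured from zero). The
#' profile must have its unique minimum at tau = 0.
#'
#' @param profile an `istdp_profile` with P(0) < 0.
#' @param depth_fraction fraction of maximum depth, in (0, 1]; 1 gives 0.
#' @return half-width (s).
#' @export
dip_halfwidth <- function(profile, depth_fraction = 0.2) {
  stopifnot(inherits(profile, "istdp_profile"))
  p0 <- eval_profile(profile, 0)
  if (p0 >= 0) stop("profile has no LTD dip at tau = 0")
  if (depth_fraction <= 0 || depth_fraction > 1)
    stop("depth_fraction must be in (0, 1]")
  if (depth_fraction == 1) return(0)
  level <- depth_fraction * p0
  f <- function(tau) eval_profile(profile, tau) - level
  # bracket: march outward until the profile rises above the level
  hi <- profile$grid_step
  while (f(hi) < 0 && hi < profile$support) hi <- hi * 2
  if (f(hi) < 0)
    stop("profile never rises above the requested depth level within support")
  stats::uniroot(f, c(0, min(hi, profile$support)), tol = 1e-12)$root
}

#' Nyquist frequency implied by a spike-timing uncertainty window
#'
#' A timing uncertainty of `window` seconds in the LTD interaction limits
#' faithful transfer of input correlations to frequencies below
#' 1 / (2 * window); the in-vitro bound of 20 ms corresponds to 25 Hz.
#'
#' @param window timing uncertainty (s).
#' @return frequency (Hz).
#' @export
timing_nyquist <- function(window = 0.020) {
  if (window <= 0) stop("window must be positive")
  1 / (2 * window)
}

#' @export
print.istdp_profile <- function(x, ...) {
  cat("iSTDP profile (", x$kind,
      if (isTRUE(x$antisymmetric)) ", antisymmetric" else "", ")\n", sep = "")
  if (x$kind == "dog")
    cat(sprintf("  LTD: amp %.4g, sigma %.4g ms | LTP: amp %.4g, sigma %.4g ms\n",
                x$amp_ltd, 1000 * x$sigma_ltd, x$amp_ltp, 1000 * x$sigma_ltp))
  if (x$kind == "doe")
    cat(sprintf("  LTD: amp %.4g, tau %.4g ms | LTP: amp %.4g, tau %.4g ms\n",
                x$amp_ltd, 1000 * x$tau_ltd, x$amp_ltp, 1000 * x$tau_ltp))
  if (!is.na(x$imbalance))
    cat(sprintf("  imbalance: %.3g | grid %.3g ms | support +/- %.3g s\n",
                x$imbalance, 1000 * x$grid_step, x$support))
  invisible(x)
}

#' @export
print.learning_rate_function <- function(x, ...) {
  cat(sprintf(
    "learning-rate function: %d frequencies, peak %.4g at %.3g Hz\n",
    length(x$freqs), x$peak_value, x$peak_freq))
  invisible(x)
}

#' Write / read an iSTDP profile as JSON
#'
#' Parametric profiles round-trip exactly; tabulated profiles store their
#' grid. CSV export writes the tabulated profile as two columns
#' (`tau_ms`, `P`).
#'
#' @param profile an `istdp_profile`.
#' @param path file path.
#' @export
write_profile_json <- function(profile, path) {
  stopifnot(inherits(profile, "istdp_profile"))
  fields <- unclass(profile)
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$kind)) stop("not a profile JSON: missing 'kind'")
  imb <- if (is.null(x$imbalance)) NA_real_ else x$imbalance
  switch(x$kind,
    dog = make_dog_profile(x$amp_ltd, x$sigma_ltd, x$sigma_ltp, imb,
                           grid_step = x$grid_step, support = x$support),
    doe = make_doe_profile(x$amp_ltd, x$tau_ltd, x$tau_ltp, imb,
                           antisymmetric = isTRUE(x$antisymmetric),
                           grid_step = x$grid_step, support = x$support),
    tabulated = make_tabulated_profile(x$tau, x$values),
    stop("unknown profile kind: ", x$kind))
}

#' @rdname write_profile_json
#' @export
write_profile_csv <- function(profile, path) {
  tab <- tabulate_profile(profile)
  utils::write.csv(data.frame(tau_ms = tab$tau * 1000, P = tab$value),
                   path, row.names = FALSE)
  invisible(path)
}
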