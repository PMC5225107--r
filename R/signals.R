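#' Perturbation signal specification
#'
#' Describes a filtered-white-noise perturbation signal: Gaussian white noise
#' of a given one-sided spectral density shaped by an ordered chain of
#' low-pass filters, with linear onset/offset ramps so the deployed signal
#' starts and ends at zero.
#'
#' @param kind `"visual"` (scene angle, deg) or `"motor"` (motor position, cm).
#' @param psd_level One-sided spectral density of the source white noise
#'   (deg^2/Hz or cm^2/Hz).
#' @param filter_chain List of stages, each `list(family, order, cutoff)`
#'   with `family` one of `"firstorder"`, `"butter"` and `cutoff` in Hz.
#' @param duration Signal duration in seconds.
#' @param ramp Ramp duration in seconds at each end (`duration > 2*ramp`).
#' @param rate Sampling rate in samples/second.
#' @return An object of class `"perturbation_spec"`.
#' @export
perturbation_spec <- function(kind = c("visual", "motor"), psd_level,
                              filter_chain, duration, ramp, rate) {
  kind <- match.arg(kind)
  stopifnot(psd_level >= 0, duration > 2 * ramp, ramp >= 0, rate > 0)
  for (st in filter_chain) {
    if (!all(c("family", "order", "cutoff") %in% names(st)))
      stop("each filter stage needs `family`, `order`, `cutoff`")
    if (st$cutoff <= 0) stop("filter cutoffs must be > 0")
  }
  structure(list(kind = kind, psd_level = psd_level,
                 filter_chain = filter_chain, duration = duration,
                 ramp = ramp, rate = rate),
            class = "perturbation_spec")
}

#' Visual-scene perturbation specification
#'
#' White noise with one-sided spectral density 150 deg^2/Hz shaped by a
#' first-order low-pass at 0.02 Hz and a second-order Butterworth low-pass at
#' 5 Hz; 250-s signals with 5-s ramps.
#'
#' @param rate Sampling rate (samples/second).
#' @param duration,ramp Signal and ramp durations in seconds.
#' @return A `"perturbation_spec"`.
#' @export
visual_perturbation_spec <- function(rate = 120, duration = 250, ramp = 5) {
  perturbation_spec(
    kind = "visual", psd_level = 150,
    filter_chain = list(
      list(family = "firstorder", order = 1L, cutoff = 0.02),
      list(family = "butter", order = 2L, cutoff = 5)),
    duration = duration, ramp = ramp, rate = rate)
}

#' Motor-position perturbation specification
#'
#' White noise with one-sided spectral density 1.1 cm^2/Hz shaped by an
#' eighth-order Butterworth low-pass at 4 Hz.
#'
#' @inheritParams visual_perturbation_spec
#' @return A `"perturbation_spec"`.
#' @export
motor_perturbation_spec <- function(rate = 120, duration = 250, ramp = 5) {
  perturbation_spec(
    kind = "motor", psd_level = 1.1,
    filter_chain = list(list(family = "butter", order = 8L, cutoff = 4)),
    duration = duration, ramp = ramp, rate = rate)
}

# causal digital realization of one filter stage
apply_stage <- function(x, stage, rate) {
  nyq <- rate / 2
  if (stage$cutoff >= nyq)
    stop(sprintf("filter stage (%s, order %d, %g Hz) has cutoff above the Nyquist frequency %g Hz",
                 stage$family, stage$order, stage$cutoff, nyq))
  if (identical(stage$family, "firstorder")) {
    # bilinear transform matched (prewarped) at the cutoff
    K <- tan(pi * stage$cutoff / rate)
    b <- c(K, K) / (1 + K)
    a <- c(1, (K - 1) / (K + 1))
    out <- x
    for (i in seq_len(stage$order))
      out <- as.numeric(signal::filter(signal::Arma(b = b, a = a), out))
    out
  } else if (identical(stage$family, "butter")) {
    bt <- signal::butter(stage$order, stage$cutoff / nyq, type = "low")
    as.numeric(signal::filter(bt, x))
  } else {
    stop("unknown filter family: ", stage$family)
  }
}

#' Generate a filtered-white-noise perturbation signal
#'
#' Draws Gaussian white noise with per-sample variance `psd_level * rate / 2`
#' (the one-sided spectral-density convention, making the shaped spectrum
#' independent of the sampling rate), passes it through the causal digital
#' filter chain, and multiplies the first and last `ramp` seconds by linear
#' ramps reaching zero at the endpoints.
#'
#' @param spec A `"perturbation_spec"`.
#' @param seed Integer seed; the signal is deterministic given the seed.
#' @return A `"phirf_ts"` (units deg or cm according to `spec$kind`).
#' @export
generate_perturbation <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "perturbation_spec"))
  hi <- max(vapply(spec$filter_chain, function(s) s$cutoff, numeric(1)))
  if (hi > spec$rate / 4)
    stop("sampling rate too low: highest cutoff must be <= rate/4")
  if (!is.null(seed)) set.seed(seed)
  n <- round(spec$duration * spec$rate)
  x <- stats::rnorm(n, sd = sqrt(spec$psd_level * spec$rate / 2))
  for (st in spec$filter_chain) x <- apply_stage(x, st, spec$rate)
  t <- (seq_len(n) - 1) / spec$rate
  if (spec$ramp > 0) {
    w <- pmin(1, t / spec$ramp, (spec$duration - 1 / spec$rate - t) / spec$ramp)
    x <- x * pmax(w, 0)
  }
  units <- if (spec$kind == "visual") "deg" else "cm"
  ts <- time_series(x, spec$rate, 0, units)
  attr(ts, "ramp") <- spec$ramp
  ts
}

#' Surface EMG envelope
#'
#' Zero-lag forward-backward 4th-order Butterworth high-pass at 20 Hz,
#' full-wave rectification, then zero-lag forward-backward 4th-order
#' Butterworth low-pass at 10 Hz.  The forward-backward cascades introduce
#' no net phase shift, so envelope peaks stay aligned with burst centers.
#'
#' @param raw A `"phirf_ts"` of raw EMG at >= 200 samples/s.
#' @param highpass,lowpass Cutoffs in Hz.
#' @return A `"phirf_ts"` envelope (same units).
#' @export
emg_envelope <- function(raw, highpass = 20, lowpass = 10) {
  stopifnot(inherits(raw, "phirf_ts"))
  if (raw$rate < 200)
    stop("emg_envelope(): sampling rate must be >= 200 samples/s for the 20-Hz high-pass")
  hp <- signal::butter(4, highpass / (raw$rate / 2), type = "high")
  lp <- signal::butter(4, lowpass / (raw$rate / 2), type = "low")
  v <- as.numeric(signal::filtfilt(hp, raw$values))
  v <- abs(v)
  v <- as.numeric(signal::filtfilt(lp, v))
  time_series(v, raw$rate, raw$start, raw$units, raw$valid)
}

#' Marker track (sagittal plane)
#'
#' @param ap Anterior-posterior coordinates in cm (positive anterior).
#' @param vert Vertical coordinates in cm (positive up).
#' @param rate Sampling rate (samples/second).
#' @param label Marker label.
#' @return An object of class `"marker_track"`.
#' @export
marker_track <- function(ap, vert, rate, label = "") {
  stopifnot(length(ap) == length(vert), rate > 0)
  structure(list(ap = as.numeric(ap), vert = as.numeric(vert),
                 rate = rate, label = label),
            class = "marker_track")
}

#' Sagittal trunk orientation from two spine markers
#'
#' Angle of the lower-to-upper spine marker vector (e.g. L1 to T1) relative
#' to vertical, in degrees; positive is forward rotation (flexion), zero when
#' the upper marker is directly above the lower one.  Samples where the two
#' markers coincide are marked invalid.
#'
#' @param l1,t1 `"marker_track"` objects with equal rates and lengths.
#' @return A `"phirf_ts"` in degrees.
#' @export
trunk_orientation <- function(l1, t1) {
  stopifnot(inherits(l1, "marker_track"), inherits(t1, "marker_track"))
  if (l1$rate != t1$rate || length(l1$ap) != length(t1$ap))
    stop("trunk_orientation(): marker tracks must share rate and length")
  dap <- t1$ap - l1$ap
  dv <- t1$vert - l1$vert
  coincident <- dap == 0 & dv == 0
  ang <- atan2(dap, dv) * 180 / pi
  ang[coincident] <- NA_real_
  valid <- !coincident & is.finite(ang)
  ang[!valid] <- 0
  time_series(ang, l1$rate, 0, "deg", valid)
}

#' Anterior-posterior displacement of a marker
#'
#' @param l1 A `"marker_track"`.
#' @return A `"phirf_ts"` in cm, positive anterior.
#' @export
ap_displacement <- function(l1) {
  stopifnot(inherits(l1, "marker_track"))
  time_series(l1$ap, l1$rate, 0, "cm", is.finite(l1$ap))
}
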