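#' Welch PSD and double-frequency CSD in the phase domain
#'
#' Splits the phase-domain record into Hann-tapered segments of
#' `window_cycles` cycles starting at integer phases, advanced by
#' `(1 - overlap) * window_cycles` cycles, and averages the input power
#' spectral density `p_uu(f1)` and the double-frequency cross-spectral
#' densities `p_uz(f1, f1 + k)` for mode offsets `k = -k_max..k_max`.
#' In the phase domain the system period is exactly one cycle, so a mode
#' offset of k corresponds to exactly `k * window_cycles` frequency bins.
#' Segments containing any invalid sample are skipped.  Scaling follows the
#' Welch convention: the one-sided PSD integrates to the signal variance.
#'
#' @param pds A `"phase_domain"` object (typically deviations from
#'   [cycle_mean()]).
#' @param input Name of the input channel in `pds$channels`.
#' @param outputs Names of output channels; defaults to all non-input
#'   channels plus the phase-rate deviation `".q"`.
#' @param window_cycles Window length in cycles (default 40).
#' @param overlap Fractional overlap (default 0.5).
#' @param k_max Largest mode offset (default 10).
#' @param f_max Largest analysis frequency `f1` in cycles^-1 (default 10).
#' @return An object of class `"spectral_estimate"`.
#' @export
welch_psd_csd <- function(pds, input, outputs = NULL, window_cycles = 40,
                          overlap = 0.5, k_max = 10, f_max = 10) {
  stopifnot(inherits(pds, "phase_domain"))
  if (!input %in% names(pds$channels)) stop("input channel not found: ", input)
  if (is.null(outputs))
    outputs <- c(setdiff(names(pds$channels), input), ".q")
  spc <- round(1 / pds$dphi)
  L <- window_cycles * spc
  fs <- spc                               # samples per cycle = phase-domain rate
  df <- 1 / window_cycles
  if (f_max + k_max > fs / 2)
    stop("f_max + k_max exceeds the phase-domain Nyquist frequency")
  nf <- floor(f_max / df) + 1L            # bins 0 .. f_max
  hop <- round((1 - overlap) * window_cycles) * spc
  if (hop < 1L) stop("overlap too large")
  N <- length(pds$grid)
  if (N < L) stop("record shorter than one full window")
  starts <- seq(1L, N - L + 1L, by = hop)

  u <- pds$channels[[input]]
  zs <- lapply(outputs, function(nm) if (nm == ".q") pds$q else pds$channels[[nm]])
  names(zs) <- outputs

  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / L)   # periodic Hann
  wss <- sum(w^2)
  modes <- (-k_max):k_max
  Suu <- numeric(nf)
  Suz <- array(0 + 0i, dim = c(nf, length(modes), length(outputs)),
               dimnames = list(NULL, as.character(modes), outputs))
  nseg <- 0L
  idx <- seq_len(nf)
  for (s in starts) {
    sel <- s:(s + L - 1L)
    if (!all(pds$valid[sel])) next
    useg <- u[sel]
    # per-segment mean removal: a segment-mean offset maps exactly onto the
    # FFT bins 0 and +/-1 of the Hann window and would corrupt the lowest
    # analysis frequencies, which carry the permanent phase-shift content
    U <- stats::fft(w * (useg - mean(useg)))
    Suu <- Suu + Re(U[idx] * Conj(U[idx]))
    Uc <- Conj(U[idx])
    for (j in seq_along(outputs)) {
      zseg <- zs[[j]][sel]
      Z <- stats::fft(w * (zseg - mean(zseg)))
      for (ki in seq_along(modes)) {
        shift <- modes[ki] * window_cycles
        zi <- ((idx - 1L + shift) %% L) + 1L
        Suz[, ki, j] <- Suz[, ki, j] + Uc * Z[zi]
      }
    }
    nseg <- nseg + 1L
  }
  if (nseg == 0L) stop("no complete valid window in the record")
  scale <- 2 / (fs * wss * nseg)
  structure(list(f1 = (idx - 1L) * df, df = df,
                 p_uu = Suu * scale, p_uz = Suz * scale,
                 n_segments = nseg, window_cycles = window_cycles,
                 overlap = overlap, dphi = pds$dphi, k_max = k_max,
                 f_max = f_max, input = input, outputs = outputs,
                 units = pds$units, T_bar = pds$T_bar, f0 = pds$f0),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral estimate> %d segments of %d cycles, f1 up to %g cycles^-1, modes -%d..%d\n",
              x$n_segments, x$window_cycles, x$f_max, x$k_max, x$k_max))
  invisible(x)
}

#' Pool spectral estimates across trials
#'
#' Segment-count-weighted average of the PSD and CSD arrays; grids and mode
#' sets must be identical.
#'
#' @param estimates List of `"spectral_estimate"` objects.
#' @return A pooled `"spectral_estimate"`.
#' @export
pool_spectra <- function(estimates) {
  stopifnot(length(estimates) >= 1L)
  ref <- estimates[[1]]
  wts <- vapply(estimates, function(e) e$n_segments, numeric(1))
  for (e in estimates[-1]) {
    if (length(e$f1) != length(ref$f1) || any(e$f1 != ref$f1) ||
        e$k_max != ref$k_max || !identical(e$outputs, ref$outputs) ||
        e$window_cycles != ref$window_cycles)
      stop("pool_spectra(): estimates have mismatched grids or modes")
  }
  out <- ref
  W <- sum(wts)
  out$p_uu <- Reduce(`+`, lapply(seq_along(estimates),
                                 function(i) estimates[[i]]$p_uu * wts[i])) / W
  out$p_uz <- Reduce(`+`, lapply(seq_along(estimates),
                                 function(i) estimates[[i]]$p_uz * wts[i])) / W
  out$n_segments <- as.integer(W)
  out$T_bar <- sum(vapply(seq_along(estimates),
                          function(i) estimates[[i]]$T_bar * wts[i], numeric(1))) / W
  out$f0 <- 1 / out$T_bar
  out
}

#' Harmonic transfer function modes from pooled spectra
#'
#' Computes `H_{z,k}(f1) = p_uz(f1, f1 + k) / p_uu(f1)` on the analysis band.
#' Bins where the input PSD falls below `floor_frac` times the band median
#' are marked invalid; the DC bin is filled by constant extrapolation from
#' the first band bin (transfer functions are continuous at 0).  Values at
#' negative `f1` follow from the conjugate-symmetry relation
#' `H_{z,-k}(-f1) = Conj(H_{z,k}(f1))` and are filled in by [htf_to_irf()].
#'
#' @param se A `"spectral_estimate"`.
#' @param floor_frac PSD floor as a fraction of the band median (default 1e-6).
#' @return An object of class `"htf_estimate"`: complex array `H`
#'   `[freq, mode, channel]` plus grids and metadata.
#' @export
compute_htf <- function(se, floor_frac = 1e-6) {
  stopifnot(inherits(se, "spectral_estimate"))
  band <- se$f1 > 0
  floor_val <- floor_frac * stats::median(se$p_uu[band])
  ok <- se$p_uu > floor_val
  ok[!band] <- FALSE   # the DC bin is dominated by window means; extrapolate it
  if (mean(!ok[band]) > 0.10)
    warning(sprintf("compute_htf(): input PSD below floor on %.0f%% of the band",
                    100 * mean(!ok[band])))
  H <- se$p_uz
  for (j in seq_len(dim(H)[3]))
    for (ki in seq_len(dim(H)[2]))
      H[, ki, j] <- ifelse(ok, H[, ki, j] / se$p_uu, NA_complex_)
  # constant extrapolation into the DC bin and any floored bin
  for (j in seq_len(dim(H)[3])) {
    for (ki in seq_len(dim(H)[2])) {
      col <- H[, ki, j]
      bad <- !is.finite(Re(col))
      if (any(bad) && any(!bad)) {
        good_idx <- which(!bad)
        col[bad] <- col[vapply(which(bad), function(i)
          good_idx[which.min(abs(good_idx - i))], integer(1))]
        H[, ki, j] <- col
      }
    }
  }
  structure(list(H = H, f1 = se$f1, df = se$df, modes = (-se$k_max):se$k_max,
                 k_max = se$k_max, window_cycles = se$window_cycles,
                 dphi = se$dphi, f_max = se$f_max, outputs = se$outputs,
                 input = se$input, units = se$units,
                 T_bar = se$T_bar, f0 = se$f0, n_segments = se$n_segments),
            class = "htf_estimate")
}

#' @export
print.htf_estimate <- function(x, ...) {
  cat(sprintf("<HTF estimate> modes -%d..%d on f1 in (0, %g] cycles^-1 (df = %g); channels: %s\n",
              x$k_max, x$k_max, x$f_max, x$df,
              paste(x$outputs, collapse = ", ")))
  invisible(x)
}
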