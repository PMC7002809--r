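#' Time-intensity curve
#'
#' A time-intensity curve (TIC) is one voxel's (or a VOI aggregate's) signal
#' intensity sampled at the dynamic acquisition times. At least six samples
#' are required so that a three-segment piecewise-linear model with two
#' samples per segment can be hosted.
#'
#' @param times Numeric vector of acquisition times in seconds, strictly
#'   increasing.
#' @param signal Numeric vector of signal intensities (arbitrary units),
#'   same length as `times`.
#' @return An object of class `tic`: a list with elements `times` and
#'   `signal`.
#' @export
tic <- function(times, signal) {
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) != length(signal)) {
    stop("`times` and `signal` must have the same length", call. = FALSE)
  }
  if (length(times) < 6L) {
    stop("a time-intensity curve needs at least 6 samples ",
         "(two per piecewise segment)", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(signal))) {
    stop("non-finite values in time-intensity curve", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  structure(list(times = times, signal = signal), class = "tic")
}

#' Ground-truth kinetic parameters for one voxel or region
#'
#' Generative counterpart of the three-region TIC model: a flat baseline
#' until contrast arrival, a linear washin up to the peak, and a linear
#' washout afterwards.
#'
#' @param baseline_signal Pre-contrast signal level (a.u.).
#' @param onset_time Contrast arrival time (s); the baseline/washin
#'   breakpoint.
#' @param peak_time Time of peak enhancement (s); the washin/washout
#'   breakpoint. Must exceed `onset_time`.
#' @param msd_true True maximum signal difference, i.e. peak enhancement
#'   above baseline (a.u., non-negative).
#' @param wos_true True washout slope (a.u./s, signed; typically negative).
#' @param noise_sd Standard deviation of additive i.i.d. Gaussian
#'   measurement noise (a.u., non-negative).
#' @return An object of class `kinetic_truth`.
#' @export
kinetic_truth <- function(baseline_signal, onset_time, peak_time,
                          msd_true, wos_true, noise_sd = 0) {
  if (onset_time >= peak_time) {
    stop("`onset_time` must be smaller than `peak_time`", call. = FALSE)
  }
  if (msd_true < 0) stop("`msd_true` must be non-negative", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(list(baseline_signal = baseline_signal,
                 onset_time = onset_time, peak_time = peak_time,
                 msd_true = msd_true, wos_true = wos_true,
                 noise_sd = noise_sd),
            class = "kinetic_truth")
}

#' Evaluate the noiseless piecewise-linear TIC model
#'
#' @param truth A [kinetic_truth()] object.
#' @param times Numeric vector of times (s).
#' @return Numeric vector of noiseless signal values.
#' @keywords internal
piecewise_signal <- function(truth, times) {
  wis <- truth$msd_true / (truth$peak_time - truth$onset_time)
  s <- rep(truth$baseline_signal, length(times))
  rise <- times > truth$onset_time & times <= truth$peak_time
  fall <- times > truth$peak_time
  s[rise] <- truth$baseline_signal + wis * (times[rise] - truth$onset_time)
  s[fall] <- truth$baseline_signal + truth$msd_true +
    truth$wos_true * (times[fall] - truth$peak_time)
  s
}

#' Generate a synthetic time-intensity curve
#'
#' Samples the noiseless three-segment model at the given acquisition times
#' and adds i.i.d. Gaussian noise. The acquisition must include at least two
#' pre-onset (baseline) samples, mirroring protocols that collect two
#' baseline volumes before contrast injection.
#'
#' @param truth A [kinetic_truth()] object.
#' @param times Strictly increasing acquisition times (s).
#' @param seed Optional integer seed for the noise draw.
#' @return A [tic()] object.
#' @export
generate_tic <- function(truth, times, seed = NULL) {
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (sum(times <= truth$onset_time) < 2L) {
    stop("need at least 2 baseline samples at or before `onset_time`",
         call. = FALSE)
  }
  s <- piecewise_signal(truth, times)
  if (truth$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    s <- s + stats::rnorm(length(s), sd = truth$noise_sd)
  }
  tic(times, s)
}
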