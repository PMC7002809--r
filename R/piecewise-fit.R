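#' Fit the three-segment piecewise-linear TIC model
#'
#' Exhaustively searches all breakpoint pairs on the sampling grid. The
#' curve is split at sample indices `(i, j)` into a baseline segment
#' (samples `1..i`, fitted as a constant), a washin segment (samples
#' `i..j`, ordinary least-squares line) and a washout segment (samples
#' `j..n`, OLS line); the breakpoint samples belong to both adjacent
#' segments. Each segment must contain at least two samples. The pair
#' minimising the total sum of squared errors is returned; exact SSE ties
#' are broken towards the smallest onset, then the smallest peak, so the
#' fit is deterministic.
#'
#' Continuity between segments is deliberately not enforced: each segment
#' is fitted independently, which keeps the estimator linear per candidate
#' pair and is the simplest faithful reading of an unconstrained piecewise
#' linear fit.
#'
#' @param x A [tic()] object.
#' @return An object of class `piecewise_fit`: list with `baseline_level`,
#'   `t_onset`, `t_peak`, `onset_index`, `peak_index`, `washin_slope`,
#'   `washin_intercept`, `washout_slope`, `washout_intercept`, `sse` and
#'   `degenerate` (TRUE when the curve is constant).
#' @export
fit_piecewise <- function(x) {
  stopifnot(inherits(x, "tic"))
  f <- fit_piecewise_matrix(x$times, matrix(x$signal, ncol = 1))
  structure(list(baseline_level = f$baseline_level[1],
                 t_onset = f$t_onset[1], t_peak = f$t_peak[1],
                 onset_index = f$onset_index[1], peak_index = f$peak_index[1],
                 washin_slope = f$washin_slope[1],
                 washin_intercept = f$washin_intercept[1],
                 washout_slope = f$washout_slope[1],
                 washout_intercept = f$washout_intercept[1],
                 sse = f$sse[1], degenerate = f$degenerate[1]),
            class = "piecewise_fit")
}

# OLS of Y rows `idx` against times[idx], vectorised over columns of Y.
# Returns slope, intercept and SSE per column.
.seg_ols <- function(times, Y, idx) {
  x <- times[idx]
  m <- length(idx)
  Ys <- Y[idx, , drop = FALSE]
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- colSums(xc * Ys) / sxx
  intercept <- colMeans(Ys) - slope * mean(x)
  fitted <- outer(x, slope) + rep(intercept, each = m)
  sse <- colSums((Ys - fitted)^2)
  list(slope = slope, intercept = intercept, sse = sse)
}

#' Piecewise fit of many curves sharing one time grid
#'
#' Engine behind [fit_piecewise()]: fits every column of `Y` at once so
#' whole-VOI fitting stays fast. Candidate onsets `i` run over `2..n-2`
#' and peaks `j` over `i+1..n-1` (two samples per segment).
#'
#' @param times Acquisition times (s), length `n >= 6`.
#' @param Y Numeric matrix, `n` rows (frames) by `V` columns (voxels).
#' @return List of per-column vectors (see [fit_piecewise()]).
#' @export
fit_piecewise_matrix <- function(times, Y) {
  n <- length(times)
  if (n < 6L) stop("need at least 6 frames", call. = FALSE)
  if (nrow(Y) != n) stop("nrow(Y) must equal length(times)", call. = FALSE)
  V <- ncol(Y)

  # baseline SSE for every candidate onset i (constant fit on 1..i)
  base_mean <- vector("list", n)
  base_sse <- vector("list", n)
  cs <- apply(Y, 2, cumsum)
  cs2 <- apply(Y^2, 2, cumsum)
  if (V == 1L) { cs <- matrix(cs, ncol = 1); cs2 <- matrix(cs2, ncol = 1) }
  for (i in 2:(n - 2)) {
    mu <- cs[i, ] / i
    base_mean[[i]] <- mu
    base_sse[[i]] <- pmax(0, cs2[i, ] - i * mu^2)
  }
  # washout fit for every candidate peak j (line on j..n)
  wo <- vector("list", n)
  for (j in 3:(n - 1)) wo[[j]] <- .seg_ols(times, Y, j:n)

  best_sse <- rep(Inf, V)
  bi <- integer(V); bj <- integer(V)
  for (i in 2:(n - 2)) {
    s1 <- base_sse[[i]]
    for (j in (i + 1):(n - 1)) {
      s2 <- .seg_ols(times, Y, i:j)$sse
      tot <- s1 + s2 + wo[[j]]$sse
      upd <- tot < best_sse
      if (any(upd)) {
        best_sse[upd] <- tot[upd]
        bi[upd] <- i
        bj[upd] <- j
      }
    }
  }

  # recompute the winning segments' parameters per voxel
  baseline <- numeric(V); wis <- numeric(V); wii <- numeric(V)
  wos <- numeric(V); woi <- numeric(V)
  for (i in unique(bi)) {
    sel <- bi == i
    baseline[sel] <- base_mean[[i]][sel]
    for (j in unique(bj[sel])) {
      s <- sel & bj == j
      w <- .seg_ols(times, Y[, s, drop = FALSE], i:j)
      wis[s] <- w$slope
      wii[s] <- w$intercept
      wos[s] <- wo[[j]]$slope[s]
      woi[s] <- wo[[j]]$intercept[s]
    }
  }
  degen <- apply(Y, 2, function(v) max(v) == min(v))
  list(baseline_level = baseline,
       t_onset = times[bi], t_peak = times[bj],
       onset_index = bi, peak_index = bj,
       washin_slope = wis, washin_intercept = wii,
       washout_slope = wos, washout_intercept = woi,
       sse = best_sse, degenerate = degen)
}

#' Semiquantitative kinetic parameters from a piecewise fit
#'
#' Derives the kinetic descriptors: maximum signal difference (MSD, fitted
#' washin value at the peak minus the baseline level, floored at zero),
#' time to peak (TTP, the washin/washout breakpoint), washin and washout
#' slopes (WIS, WOS) and intercepts, and the trapezoidal areas under the
#' baseline-subtracted observed curve over the washin, washout and
#' combined intervals.
#'
#' @param fit A `piecewise_fit` from [fit_piecewise()].
#' @param x The [tic()] that was fitted.
#' @return Named numeric vector with elements
#'   `msd, ttp, wis, wos, washin_intercept, washout_intercept,
#'   auc_washin, auc_washout, auc_total`.
#' @export
semiquant_params <- function(fit, x) {
  stopifnot(inherits(fit, "piecewise_fit"), inherits(x, "tic"))
  peak_val <- fit$washin_slope * fit$t_peak + fit$washin_intercept
  msd <- max(0, peak_val - fit$baseline_level)
  i <- fit$onset_index
  j <- fit$peak_index
  n <- length(x$times)
  excess <- x$signal - fit$baseline_level
  auc_in <- pracma::trapz(x$times[i:j], excess[i:j])
  auc_out <- pracma::trapz(x$times[j:n], excess[j:n])
  c(msd = msd, ttp = fit$t_peak,
    wis = fit$washin_slope, wos = fit$washout_slope,
    washin_intercept = fit$washin_intercept,
    washout_intercept = fit$washout_intercept,
    auc_washin = auc_in, auc_washout = auc_out,
    auc_total = auc_in + auc_out)
}

#' Names of the semiquantitative kinetic parameters
#' @return Character vector of the nine per-examination kinetic parameters.
#' @export
semiquant_names <- function() {
  c("msd", "ttp", "wis", "wos", "washin_intercept", "washout_intercept",
    "auc_washin", "auc_washout", "auc_total")
}

#' Extract per-voxel time-intensity curves from a dynamic series
#'
#' @param series A [dynamic_series()].
#' @param mask A [voi_mask()] aligned to the series.
#' @return A list with `voxels` (V x 3 integer matrix of array indices) and
#'   `curves` (a list of [tic()] objects, one per VOI voxel, in the same
#'   order).
#' @export
extract_tics <- function(series, mask) {
  Y <- voi_signal_matrix(series, mask)
  idx <- attr(Y, "voxels")
  curves <- lapply(seq_len(ncol(Y)), function(v) tic(series$frame_times, Y[, v]))
  list(voxels = idx, curves = curves)
}

# frames x voxels signal matrix for the VOI, with voxel indices attached
voi_signal_matrix <- function(series, mask) {
  stopifnot(inherits(series, "dynamic_series"), inherits(mask, "voi_mask"))
  if (!identical(dim(mask$mask), dim(series$signal)[1:3])) {
    stop("mask and series grids are not aligned", call. = FALSE)
  }
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty VOI mask", call. = FALSE)
  n <- length(series$frame_times)
  if (n < 6L) stop("need at least 6 frames", call. = FALSE)
  flat <- matrix(series$signal, ncol = n)  # voxels x frames
  lin <- which(as.vector(mask$mask))
  Y <- t(flat[lin, , drop = FALSE])        # frames x voxels
  attr(Y, "voxels") <- idx
  Y
}

#' Fit all VOI voxels and tabulate their kinetic parameters
#'
#' @param series A [dynamic_series()].
#' @param mask A [voi_mask()].
#' @return Data frame, one row per VOI voxel, columns [semiquant_names()].
#' @export
voi_semiquant_table <- function(series, mask) {
  Y <- voi_signal_matrix(series, mask)
  times <- series$frame_times
  f <- fit_piecewise_matrix(times, Y)
  n <- length(times)
  V <- ncol(Y)
  peak_val <- f$washin_slope * f$t_peak + f$washin_intercept
  msd <- pmax(0, peak_val - f$baseline_level)
  auc_in <- numeric(V); auc_out <- numeric(V)
  for (v in seq_len(V)) {
    i <- f$onset_index[v]; j <- f$peak_index[v]
    excess <- Y[, v] - f$baseline_level[v]
    auc_in[v] <- pracma::trapz(times[i:j], excess[i:j])
    auc_out[v] <- pracma::trapz(times[j:n], excess[j:n])
  }
  data.frame(msd = msd, ttp = f$t_peak, wis = f$washin_slope,
             wos = f$washout_slope, washin_intercept = f$washin_intercept,
             washout_intercept = f$washout_intercept,
             auc_washin = auc_in, auc_washout = auc_out,
             auc_total = auc_in + auc_out)
}

#' VOI-representative kinetic parameters
#'
#' The representative value of each parameter over the VOI is the voxelwise
#' median; the sample standard deviation and the range (maximum minus
#' minimum) are reported alongside. For a single-voxel VOI the SD and range
#' are zero.
#'
#' @param params Data frame of per-voxel parameters (e.g. from
#'   [voi_semiquant_table()]).
#' @return Data frame with rows `median`, `sd`, `range` and one column per
#'   parameter.
#' @export
voi_representative <- function(params) {
  if (!is.data.frame(params) || nrow(params) == 0L) {
    stop("`params` must be a non-empty data frame", call. = FALSE)
  }
  med <- vapply(params, stats::median, numeric(1))
  sdv <- vapply(params, function(v) if (length(v) > 1L) stats::sd(v) else 0,
                numeric(1))
  rng <- vapply(params, function(v) max(v) - min(v), numeric(1))
  out <- rbind(median = med, sd = sdv, range = rng)
  as.data.frame(out)
}
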