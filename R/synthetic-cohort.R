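#' Configuration of a synthetic DCE-MRI cohort
#'
#' Defines the acquisition grid, tumour geometry, patient-level kinetic
#' distributions and treatment-effect factors used by [generate_cohort()].
#' Defaults emulate the structure of public breast DCE-MRI therapy-response
#' collections: 25 dynamic frames at 16 s spacing with baseline frames
#' before contrast arrival, an ellipsoidal tumour VOI with spatially
#' heterogeneous kinetics, 15 pCR and 30 non-pCR patients, and a treatment
#' effect that suppresses enhancement far more strongly in pCR patients.
#'
#' Treatment-effect factors multiply each patient's pre-treatment kinetic
#' parameters, so a factor `f` yields a ground-truth percentage change of
#' `(1 - f) * 100`. The defaults (`0.10`/`0.11` for pCR, `0.92`/`0.94` for
#' non-pCR) give ground-truth group median percentage changes of about 90
#' and 89 (pCR) versus 8 and 6 (non-pCR) for MSD and WOS, hence a
#' Standardised Index of Shape near 125 in responders and near 10 in
#' non-responders. In responders a small fraction of VOI voxels
#' (`residual_focus_fraction_pcr`) keeps its pre-treatment kinetics,
#' modelling scattered residual enhancing foci; this leaves the VOI median
#' (and hence the ground-truth percentage change) untouched but changes the
#' spatial texture of the post-treatment arterial phase.
#'
#' @param n_pcr,n_nonpcr Number of patients per response group.
#' @param n_frames Number of dynamic frames.
#' @param frame_interval Temporal resolution (s); must lie in `[10, 30]`.
#' @param grid_shape Integer length-3 grid size (voxels).
#' @param voi_semiaxes Length-3 semi-axes of the ellipsoidal VOI (voxels).
#' @param voxel_spacing Voxel size (mm).
#' @param effect_msd_pcr,effect_wos_pcr,effect_msd_nonpcr,effect_wos_nonpcr
#'   Multiplicative post/pre treatment factors in `(0, 2]`.
#' @param effect_sdlog Lognormal patient-to-patient jitter (sdlog) applied
#'   to the group effect factors.
#' @param shrink_pcr,shrink_nonpcr Linear scale factor in `(0, 1]` applied
#'   to the VOI semi-axes of the post-treatment examination; responding
#'   tumours shrink markedly after the first cycle while non-responders
#'   barely change size.
#' @param residual_focus_fraction_pcr,residual_focus_fraction_nonpcr
#'   Fraction of VOI voxels forming scattered residual enhancing foci
#'   (off by default).
#' @param residual_focus_effect Effect factor applied inside residual
#'   foci instead of the group factor (partial response of the foci).
#' @param heterogeneity_lengthscale_pre,heterogeneity_lengthscale_post
#'   Gaussian-random-field smoothing lengthscale (voxels); smaller values
#'   give rougher, higher-entropy tumours. `Inf` gives a homogeneous VOI.
#'   The post value applies to phantoms generated on their own; within a
#'   cohort the post-treatment examination reuses the patient's
#'   pre-treatment field (scaled by the effect factors) so that pre and
#'   post share their spatial structure.
#' @param heterogeneity_amplitude Relative amplitude of the field
#'   modulating the per-voxel kinetic magnitudes.
#' @param baseline_signal Pre-contrast signal level (a.u.).
#' @param baseline_sdlog Lognormal patient variability of the baseline.
#' @param msd_median,msd_sdlog Lognormal distribution of the patient-level
#'   maximum signal difference (a.u.).
#' @param wos_magnitude_median,wos_sdlog Lognormal distribution of the
#'   washout slope magnitude (a.u./s); the slope itself is negative.
#' @param onset_time Contrast arrival time (s); kept on the frame grid.
#' @param peak_frames Candidate peak-time frame indices (0-based) sampled
#'   per patient; kept on the frame grid so that noiseless fits are exact.
#' @param noise_sd Gaussian measurement noise SD (a.u.).
#' @param seed Integer root seed for the whole cohort.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_pcr = 15, n_nonpcr = 30,
                          n_frames = 25, frame_interval = 16,
                          grid_shape = c(24, 24, 12),
                          voi_semiaxes = c(6.5, 6.5, 4.5),
                          voxel_spacing = c(1, 1, 1),
                          effect_msd_pcr = 0.10, effect_wos_pcr = 0.11,
                          effect_msd_nonpcr = 0.92, effect_wos_nonpcr = 0.94,
                          effect_sdlog = 0.10,
                          shrink_pcr = 0.50, shrink_nonpcr = 0.95,
                          residual_focus_fraction_pcr = 0.04,
                          residual_focus_fraction_nonpcr = 0,
                          residual_focus_effect = 0.25,
                          heterogeneity_lengthscale_pre = 1,
                          heterogeneity_lengthscale_post = 1,
                          heterogeneity_amplitude = 0.35,
                          baseline_signal = 100, baseline_sdlog = 0.05,
                          msd_median = 150, msd_sdlog = 0.25,
                          wos_magnitude_median = 0.2, wos_sdlog = 0.3,
                          onset_time = 48,
                          peak_frames = 7:10,
                          noise_sd = 2, seed = 1L) {
  cfg <- list(n_pcr = n_pcr, n_nonpcr = n_nonpcr, n_frames = n_frames,
              frame_interval = frame_interval, grid_shape = grid_shape,
              voi_semiaxes = voi_semiaxes, voxel_spacing = voxel_spacing,
              effect_msd_pcr = effect_msd_pcr, effect_wos_pcr = effect_wos_pcr,
              effect_msd_nonpcr = effect_msd_nonpcr,
              effect_wos_nonpcr = effect_wos_nonpcr,
              effect_sdlog = effect_sdlog,
              shrink_pcr = shrink_pcr, shrink_nonpcr = shrink_nonpcr,
              residual_focus_fraction_pcr = residual_focus_fraction_pcr,
              residual_focus_fraction_nonpcr = residual_focus_fraction_nonpcr,
              residual_focus_effect = residual_focus_effect,
              heterogeneity_lengthscale_pre = heterogeneity_lengthscale_pre,
              heterogeneity_lengthscale_post = heterogeneity_lengthscale_post,
              heterogeneity_amplitude = heterogeneity_amplitude,
              baseline_signal = baseline_signal, baseline_sdlog = baseline_sdlog,
              msd_median = msd_median, msd_sdlog = msd_sdlog,
              wos_magnitude_median = wos_magnitude_median,
              wos_sdlog = wos_sdlog, onset_time = onset_time,
              peak_frames = peak_frames, noise_sd = noise_sd,
              seed = as.integer(seed))
  if (n_pcr < 1 || n_nonpcr < 1) stop("group sizes must be positive",
                                      call. = FALSE)
  if (frame_interval < 10 || frame_interval > 30) {
    stop("`frame_interval` must lie in [10, 30] s", call. = FALSE)
  }
  eff <- c(effect_msd_pcr, effect_wos_pcr, effect_msd_nonpcr,
           effect_wos_nonpcr)
  if (any(eff <= 0 | eff > 2)) {
    stop("effect factors must lie in (0, 2]", call. = FALSE)
  }
  if (any(c(shrink_pcr, shrink_nonpcr) <= 0 |
          c(shrink_pcr, shrink_nonpcr) > 1)) {
    stop("shrink factors must lie in (0, 1]", call. = FALSE)
  }
  if (n_frames < 6) stop("need at least 6 frames", call. = FALSE)
  if (any(grid_shape < 2 * ceiling(voi_semiaxes) + 1)) {
    stop("`grid_shape` cannot accommodate `voi_semiaxes`", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' Acquisition time grid of a cohort configuration
#' @param config A [cohort_config()].
#' @return Numeric vector of frame times (s), starting at 0.
#' @export
frame_time_grid <- function(config) {
  (seq_len(config$n_frames) - 1) * config$frame_interval
}

#' Axis-aligned ellipsoidal VOI mask
#'
#' @param grid_shape Integer length-3 grid size.
#' @param semiaxes Length-3 semi-axes (voxels).
#' @param centre Ellipsoid centre in voxel coordinates (defaults to the
#'   grid centre).
#' @return A [voi_mask()].
#' @export
ellipsoid_mask <- function(grid_shape, semiaxes, centre = (grid_shape + 1) / 2) {
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  d <- ((g$x - centre[1]) / semiaxes[1])^2 +
       ((g$y - centre[2]) / semiaxes[2])^2 +
       ((g$z - centre[3]) / semiaxes[3])^2
  voi_mask(array(d <= 1, dim = grid_shape))
}

# Separable Gaussian smoothing of a 3-D array (replicated edges);
# `sd` may be a per-axis length-3 vector for anisotropic smoothing.
.smooth_gauss3 <- function(a, sd) {
  sd <- rep_len(sd, 3)
  smooth_dim <- function(a, dim) {
    if (sd[dim] <= 0) return(a)
    r <- max(1L, ceiling(3 * sd[dim]))
    k <- stats::dnorm(-r:r, sd = sd[dim])
    k <- k / sum(k)
    n <- base::dim(a)[dim]
    idx <- function(i) pmin(pmax(i, 1L), n)  # replicate padding
    out <- array(0, base::dim(a))
    for (o in -r:r) {
      w <- k[o + r + 1]
      src <- idx(seq_len(n) + o)
      out <- out + w * switch(dim,
        a[src, , , drop = FALSE],
        a[, src, , drop = FALSE],
        a[, , src, drop = FALSE])
    }
    out
  }
  for (d in 1:3) a <- smooth_dim(a, d)
  a
}

#' Gaussian random field on a 3-D grid
#'
#' White Gaussian noise smoothed with a separable Gaussian kernel of the
#' given lengthscale, then standardised to zero mean and unit variance over
#' the grid. `lengthscale = Inf` returns a constant zero field (the
#' homogeneous limit); `lengthscale = 0` returns standardised white noise.
#'
#' @param grid_shape Integer length-3 grid size.
#' @param lengthscale Smoothing kernel SD (voxels).
#' @param seed Optional integer seed.
#' @return 3-D numeric array.
#' @export
gaussian_random_field <- function(grid_shape, lengthscale, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(is.infinite(lengthscale))) return(array(0, grid_shape))
  z <- array(stats::rnorm(prod(grid_shape)), grid_shape)
  z <- .smooth_gauss3(z, lengthscale)
  (z - mean(z)) / stats::sd(z)
}

#' Per-voxel kinetic ground truth over a VOI
#'
#' Builds the per-voxel kinetic maps for one examination: patient-level
#' magnitudes modulated by a Gaussian random field (clipped so modulation
#' stays positive at zero).
#'
#' @param mask A [voi_mask()].
#' @param field 3-D modulation field (zero mean, unit variance), as from
#'   [gaussian_random_field()].
#' @param amplitude Relative modulation amplitude.
#' @param baseline_signal,onset_time,peak_time Scalars shared by all voxels.
#' @param msd,wos Patient-level maximum signal difference and washout
#'   slope; modulated per voxel.
#' @param noise_sd Measurement noise SD.
#' @return An object of class `truth_field`: per-voxel arrays `msd_map`,
#'   `wos_map` plus the scalar fields.
#' @export
truth_field <- function(mask, field, amplitude, baseline_signal,
                        onset_time, peak_time, msd, wos, noise_sd) {
  mod <- pmax(0, 1 + amplitude * field)
  structure(list(msd_map = msd * mod * mask$mask,
                 wos_map = wos * mod * mask$mask,
                 baseline_signal = baseline_signal,
                 onset_time = onset_time, peak_time = peak_time,
                 noise_sd = noise_sd),
            class = "truth_field")
}

#' Generate a 4-D dynamic phantom from a ground-truth field
#'
#' Every VOI voxel follows its local three-segment kinetic model;
#' background voxels stay at the baseline level. I.i.d. Gaussian noise is
#' added everywhere.
#'
#' @param truth A [truth_field()].
#' @param mask The [voi_mask()] the truth was built on.
#' @param times Acquisition times (s).
#' @param voxel_spacing Voxel size (mm).
#' @param seed Optional integer seed for the noise draw.
#' @return A [dynamic_series()].
#' @export
generate_phantom <- function(truth, mask, times, voxel_spacing = c(1, 1, 1),
                             seed = NULL) {
  if (!any(mask$mask)) stop("empty VOI mask", call. = FALSE)
  if (sum(times <= truth$onset_time) < 2L) {
    stop("need at least 2 baseline samples at or before `onset_time`",
         call. = FALSE)
  }
  dims <- dim(mask$mask)
  n <- length(times)
  wis_map <- truth$msd_map / (truth$peak_time - truth$onset_time)
  sig <- array(truth$baseline_signal, c(dims, n))
  for (f in seq_len(n)) {
    t <- times[f]
    if (t <= truth$onset_time) next
    enh <- if (t <= truth$peak_time) {
      wis_map * (t - truth$onset_time)
    } else {
      truth$msd_map + truth$wos_map * (t - truth$peak_time)
    }
    sig[, , , f] <- truth$baseline_signal + enh
  }
  if (truth$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sig <- sig + array(stats::rnorm(length(sig), sd = truth$noise_sd),
                       dim(sig))
  }
  dynamic_series(sig, times, voxel_spacing)
}

# scale a truth field by treatment-effect factors; residual foci respond
# with the (weaker) focal effect factor instead
.apply_effect <- function(truth, mask, f_msd, f_wos, focus_fraction,
                          focus_effect = 1) {
  post <- truth
  fac_msd <- array(f_msd, dim(truth$msd_map))
  fac_wos <- array(f_wos, dim(truth$wos_map))
  if (focus_fraction > 0) {
    lin <- which(as.vector(mask$mask))
    n_focus <- round(focus_fraction * length(lin))
    if (n_focus > 0) {
      foci <- sample(lin, n_focus)
      fac_msd[foci] <- focus_effect
      fac_wos[foci] <- focus_effect
    }
  }
  post$msd_map <- truth$msd_map * fac_msd
  post$wos_map <- truth$wos_map * fac_wos
  post
}

#' Generate a synthetic therapy-response cohort
#'
#' Draws patient-level kinetics from lognormal distributions, builds the
#' pre-treatment examination on a heterogeneous ellipsoidal VOI, and
#' derives the post-treatment examination by scaling the same ground-truth
#' field with the response group's effect factors (with patient-level
#' jitter, clamped to `(0.01, 2]`), shrinking the VOI by the group's
#' linear shrink factor, and optionally sparing a configured fraction of
#' residual enhancing foci. The ground-truth percentage changes of MSD and
#' WOS, and the Standardised Index of Shape they imply, are recorded per
#' patient.
#'
#' All randomness flows from `config$seed`; the same configuration always
#' reproduces the same cohort.
#'
#' @param config A [cohort_config()].
#' @return A list of patient records (class `synthetic_cohort`), each with
#'   `patient_id`, `label`, `exam_pre`, `exam_post` (lists with `series`
#'   and `mask`), `truth_pre`, `truth_post` and `delta_true` (named vector
#'   `delta_msd`, `delta_wos`, `sis`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  times <- frame_time_grid(config)
  mask <- ellipsoid_mask(config$grid_shape, config$voi_semiaxes)
  labels <- c(rep("pCR", config$n_pcr), rep("non-pCR", config$n_nonpcr))
  n <- length(labels)
  cohort <- vector("list", n)
  for (p in seq_len(n)) {
    lab <- labels[p]
    pcr <- lab == "pCR"
    baseline <- config$baseline_signal *
      stats::rlnorm(1, 0, config$baseline_sdlog)
    msd <- stats::rlnorm(1, log(config$msd_median), config$msd_sdlog)
    wos <- -stats::rlnorm(1, log(config$wos_magnitude_median),
                          config$wos_sdlog)
    peak_time <- times[sample(config$peak_frames, 1) + 1L]
    field <- gaussian_random_field(config$grid_shape,
                                   config$heterogeneity_lengthscale_pre)
    pre <- truth_field(mask, field, config$heterogeneity_amplitude,
                       baseline, config$onset_time, peak_time,
                       msd, wos, config$noise_sd)
    jitter <- function(f) {
      min(2, max(0.01, f * stats::rlnorm(1, 0, config$effect_sdlog)))
    }
    f_msd <- jitter(if (pcr) config$effect_msd_pcr else config$effect_msd_nonpcr)
    f_wos <- jitter(if (pcr) config$effect_wos_pcr else config$effect_wos_nonpcr)
    focus <- if (pcr) config$residual_focus_fraction_pcr else
      config$residual_focus_fraction_nonpcr
    shrink <- if (pcr) config$shrink_pcr else config$shrink_nonpcr
    mask_post <- ellipsoid_mask(config$grid_shape,
                                config$voi_semiaxes * shrink)
    post <- .apply_effect(pre, mask, f_msd, f_wos, focus,
                          config$residual_focus_effect)
    post$msd_map <- post$msd_map * mask_post$mask
    post$wos_map <- post$wos_map * mask_post$mask
    exam_pre <- generate_phantom(pre, mask, times, config$voxel_spacing)
    exam_post <- generate_phantom(post, mask_post, times,
                                  config$voxel_spacing)
    d_msd <- (1 - f_msd) * 100
    d_wos <- (1 - f_wos) * 100
    cohort[[p]] <- list(
      patient_id = sprintf("SYN-%03d", p), label = lab,
      exam_pre = list(series = exam_pre, mask = mask),
      exam_post = list(series = exam_post, mask = mask_post),
      truth_pre = pre, truth_post = post,
      delta_true = c(delta_msd = d_msd, delta_wos = d_wos,
                     sis = compute_sis(d_msd, d_wos)))
  }
  structure(cohort, class = c("synthetic_cohort", "list"))
}

#' Write a synthetic cohort to disk
#'
#' Writes each examination as NIfTI-1 volume + mask + JSON timing sidecar,
#' the configuration as YAML, and a manifest CSV holding patient ids,
#' labels, file paths and the ground-truth percentage changes.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param config The [cohort_config()] used (stored as `config.yaml`).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(pat) {
    id <- pat$patient_id
    paths <- list()
    for (phase in c("pre", "post")) {
      ex <- pat[[paste0("exam_", phase)]]
      base <- file.path(dir, paste0(id, "_", phase))
      write_examination(ex$series, ex$mask,
                        paste0(base, "_dce.nii.gz"),
                        paste0(base, "_mask.nii.gz"),
                        paste0(base, "_timing.json"))
      paths[[paste0(phase, "_volume")]] <- paste0(id, "_", phase, "_dce.nii.gz")
      paths[[paste0(phase, "_mask")]] <- paste0(id, "_", phase, "_mask.nii.gz")
      paths[[paste0(phase, "_timing")]] <- paste0(id, "_", phase, "_timing.json")
    }
    data.frame(patient_id = id, label = pat$label,
               pre_volume = paths$pre_volume, pre_mask = paths$pre_mask,
               pre_timing = paths$pre_timing,
               post_volume = paths$post_volume, post_mask = paths$post_mask,
               post_timing = paths$post_timing,
               delta_msd_true = pat$delta_true[["delta_msd"]],
               delta_wos_true = pat$delta_true[["delta_wos"]],
               sis_true = pat$delta_true[["sis"]],
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE)
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  }
  invisible(manifest)
}
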