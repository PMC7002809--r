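#' Dynamic contrast-enhanced series
#'
#' Container for one DCE-MRI examination: a 4-D signal array `(x, y, z,
#' frame)` with per-frame acquisition times and voxel spacing.
#'
#' @param signal 4-D numeric array, arbitrary units.
#' @param frame_times Strictly increasing acquisition times (s), one per
#'   frame.
#' @param voxel_spacing Numeric length-3 vector of voxel dimensions (mm).
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(signal, frame_times, voxel_spacing = c(1, 1, 1)) {
  if (length(dim(signal)) != 4L) stop("`signal` must be 4-D", call. = FALSE)
  frame_times <- as.numeric(frame_times)
  if (dim(signal)[4] != length(frame_times)) {
    stop("frame count (", dim(signal)[4], ") does not match timing vector ",
         "length (", length(frame_times), ")", call. = FALSE)
  }
  if (any(diff(frame_times) <= 0)) {
    stop("`frame_times` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(signal))) {
    stop("non-finite voxel values in dynamic series", call. = FALSE)
  }
  structure(list(signal = signal, frame_times = frame_times,
                 voxel_spacing = as.numeric(voxel_spacing)),
            class = "dynamic_series")
}

#' Tumour volume-of-interest mask
#'
#' @param mask 3-D logical (or numeric, binarised at values strictly
#'   greater than 0) array on the same grid as the dynamic series.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(mask) {
  if (length(dim(mask)) != 3L) stop("`mask` must be 3-D", call. = FALSE)
  m <- array(mask > 0, dim = dim(mask))
  structure(list(mask = m), class = "voi_mask")
}

#' Map a Miller-Payne grade to the response label
#'
#' Grade 5 (no residual invasive cancer) is a pathological complete
#' response; grades 1-4 are scored as non-pCR.
#'
#' @param grade Integer grade in 1..5.
#' @return `"pCR"` or `"non-pCR"`.
#' @export
miller_payne_to_label <- function(grade) {
  if (length(grade) != 1L || is.na(grade) || grade != as.integer(grade) ||
      grade < 1 || grade > 5) {
    stop("Miller-Payne grade must be an integer in 1..5", call. = FALSE)
  }
  if (grade == 5) "pCR" else "non-pCR"
}

#' Write one examination to disk
#'
#' The 4-D volume and the binary mask are written as NIfTI-1 files; the
#' frame times go to a JSON sidecar (key `frame_times_s`) because NIfTI-1
#' carries no reliable 4-D timing convention.
#'
#' @param series A [dynamic_series()].
#' @param mask A [voi_mask()].
#' @param volume_path,mask_path,timing_path Output paths (`.nii`/`.nii.gz`
#'   for the arrays, `.json` for the timing sidecar).
#' @return Invisibly, a named list of the three paths.
#' @export
write_examination <- function(series, mask, volume_path, mask_path,
                              timing_path) {
  sp <- series$voxel_spacing
  vol <- RNifti::asNifti(series$signal)
  RNifti::pixdim(vol) <- c(sp, 1)
  RNifti::writeNifti(vol, volume_path)
  msk <- RNifti::asNifti(array(as.integer(mask$mask), dim = dim(mask$mask)))
  RNifti::pixdim(msk) <- sp
  RNifti::writeNifti(msk, mask_path)
  jsonlite::write_json(list(frame_times_s = series$frame_times),
                       timing_path, digits = NA)
  invisible(list(volume = volume_path, mask = mask_path,
                 timing = timing_path))
}

#' Read one examination from disk
#'
#' @param volume_path NIfTI-1 4-D dynamic volume.
#' @param mask_path NIfTI-1 mask, same spatial grid; binarised at `> 0`.
#' @param timing_path JSON sidecar with key `frame_times_s`.
#' @return A list with elements `series` ([dynamic_series()]) and `mask`
#'   ([voi_mask()]).
#' @export
read_examination <- function(volume_path, mask_path, timing_path) {
  for (p in c(volume_path, mask_path, timing_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  vol <- RNifti::readNifti(volume_path)
  msk <- RNifti::readNifti(mask_path)
  if (length(dim(vol)) != 4L) {
    stop("volume must be 4-D: ", volume_path, call. = FALSE)
  }
  if (!identical(dim(msk)[1:3], dim(vol)[1:3])) {
    stop("mask grid ", paste(dim(msk), collapse = "x"),
         " does not align with volume grid ",
         paste(dim(vol)[1:3], collapse = "x"), call. = FALSE)
  }
  timing <- jsonlite::read_json(timing_path, simplifyVector = TRUE)
  ft <- as.numeric(timing$frame_times_s)
  if (length(ft) != dim(vol)[4]) {
    stop("timing vector length (", length(ft), ") does not match frame ",
         "count (", dim(vol)[4], ")", call. = FALSE)
  }
  sp <- RNifti::pixdim(vol)[1:3]
  list(series = dynamic_series(array(as.numeric(vol), dim = dim(vol)), ft, sp),
       mask = voi_mask(array(as.numeric(msk), dim = dim(msk))))
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `patient_id, label, pre_volume,
#' pre_mask, pre_timing, post_volume, post_mask, post_timing` (paths
#' relative to the manifest's directory or absolute).
#'
#' @param manifest_csv Path to the manifest.
#' @param load Logical; if `TRUE` (default) the examinations are read into
#'   memory, otherwise only paths and labels are returned.
#' @return A list of patient records: each a list with `patient_id`,
#'   `label`, and (when `load = TRUE`) `exam_pre` / `exam_post` as returned
#'   by [read_examination()].
#' @export
read_cohort <- function(manifest_csv, load = TRUE) {
  man <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  if (nrow(man) == 0L) {
    warning("empty cohort manifest: ", manifest_csv)
    return(list())
  }
  need <- c("patient_id", "label", "pre_volume", "pre_mask", "pre_timing",
            "post_volume", "post_mask", "post_timing")
  miss <- setdiff(need, names(man))
  if (length(miss)) {
    stop("manifest lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(man$patient_id)) {
    stop("duplicate patient_id in manifest", call. = FALSE)
  }
  if (!all(man$label %in% c("pCR", "non-pCR"))) {
    stop("labels must be 'pCR' or 'non-pCR'", call. = FALSE)
  }
  root <- dirname(manifest_csv)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(root, p))
  lapply(seq_len(nrow(man)), function(r) {
    rec <- list(patient_id = man$patient_id[r], label = man$label[r])
    if (load) {
      rec$exam_pre <- read_examination(resolve(man$pre_volume[r]),
                                       resolve(man$pre_mask[r]),
                                       resolve(man$pre_timing[r]))
      rec$exam_post <- read_examination(resolve(man$post_volume[r]),
                                        resolve(man$post_mask[r]),
                                        resolve(man$post_timing[r]))
    } else {
      rec$paths <- man[r, setdiff(need, c("patient_id", "label"))]
    }
    rec
  })
}
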