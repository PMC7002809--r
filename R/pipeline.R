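#' Combined kinetic + texture feature vector of one examination
#'
#' VOI-representative (voxelwise median) semiquantitative kinetic
#' parameters concatenated with the 50-feature texture panel.
#'
#' @param exam List with `series` ([dynamic_series()]) and `mask`
#'   ([voi_mask()]).
#' @param n_levels Gray levels for texture quantisation.
#' @return Named numeric vector of 59 features.
#' @export
examination_features <- function(exam, n_levels = 32) {
  per_voxel <- voi_semiquant_table(exam$series, exam$mask)
  rep_row <- unlist(voi_representative(per_voxel)["median", ])
  names(rep_row) <- semiquant_names()
  tex <- full_feature_vector(exam$series, exam$mask, n_levels)
  attributes(tex)$degenerate <- NULL
  c(rep_row, tex)
}

#' Analyse a cohort in memory
#'
#' Runs the full study flow on a list of patient records: per-examination
#' kinetic and texture features, per-patient percentage changes with SIS,
#' and the group-comparison and diagnostic tables. Patients whose
#' processing fails are skipped with a warning; the run aborts if more
#' than `max_failure_fraction` of patients fail, so cohort statistics can
#' never be computed on a silently shrunken sample.
#'
#' @param patients List of records with `patient_id`, `label`, `exam_pre`,
#'   `exam_post` (e.g. from [generate_cohort()] or [read_cohort()]).
#' @param n_levels Texture quantisation levels.
#' @param alpha Significance level for Bonferroni flags.
#' @param eps Near-zero guard for percentage changes.
#' @param max_failure_fraction Abort threshold (default 0.2).
#' @return List with `features_pre`, `features_post`, `deltas` (data
#'   frames; one row per analysed patient), `labels`, `patient_ids`,
#'   `failed` (ids) and `tables` (from [build_tables()]).
#' @export
analyze_cohort <- function(patients, n_levels = 32, alpha = 0.05,
                           eps = 1e-9, max_failure_fraction = 0.2) {
  if (!length(patients)) stop("empty cohort", call. = FALSE)
  rows_pre <- list(); rows_post <- list(); rows_delta <- list()
  labels <- character(0); ids <- character(0); failed <- character(0)
  for (pat in patients) {
    res <- tryCatch({
      pre <- examination_features(pat$exam_pre, n_levels)
      post <- examination_features(pat$exam_post, n_levels)
      list(pre = pre, post = post,
           delta = patient_delta_vector(pre, post, eps))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("patient ", pat$patient_id, " skipped: ",
              conditionMessage(res))
      failed <- c(failed, pat$patient_id)
      next
    }
    rows_pre[[pat$patient_id]] <- res$pre
    rows_post[[pat$patient_id]] <- res$post
    rows_delta[[pat$patient_id]] <- res$delta
    labels <- c(labels, pat$label)
    ids <- c(ids, pat$patient_id)
  }
  if (length(failed) > max_failure_fraction * length(patients)) {
    stop("more than ", round(100 * max_failure_fraction),
         "% of patients failed (", length(failed), "/", length(patients),
         "); aborting", call. = FALSE)
  }
  as_df <- function(rows) {
    df <- as.data.frame(do.call(rbind, rows))
    rownames(df) <- NULL
    df
  }
  deltas <- as_df(rows_delta)
  list(features_pre = as_df(rows_pre), features_post = as_df(rows_post),
       deltas = deltas, labels = labels, patient_ids = ids, failed = failed,
       tables = build_tables(deltas, labels, alpha))
}

#' Simulate a cohort and write it to disk
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @return The manifest path, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  cohort <- generate_cohort(config)
  write_cohort(cohort, out_dir, config)
}

#' Analyse a cohort manifest and write all report tables
#'
#' Reads the cohort, runs [analyze_cohort()] and writes
#' `features_pre.csv`, `features_post.csv`, `deltas.csv`, `table1.csv`
#' (group summary), `table2.csv` (diagnostic accuracy; metrics and cutoffs
#' additionally rounded to 2 decimals in the printed columns) and a
#' full-precision `report.json`.
#'
#' @param manifest_csv Cohort manifest path.
#' @param out_dir Output directory.
#' @inheritParams analyze_cohort
#' @return The [analyze_cohort()] result, invisibly.
#' @export
run_analyze <- function(manifest_csv, out_dir, n_levels = 32, alpha = 0.05,
                        eps = 1e-9) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  root <- dirname(manifest_csv)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(root, p))
  patients <- lapply(seq_len(nrow(man)), function(r) {
    list(patient_id = man$patient_id[r], label = man$label[r], row = man[r, ])
  })
  # wrap reading inside the per-patient fail-soft path
  loaded <- lapply(patients, function(pat) {
    pat$exam_pre <- tryCatch(
      read_examination(resolve(pat$row$pre_volume), resolve(pat$row$pre_mask),
                       resolve(pat$row$pre_timing)),
      error = function(e) e)
    pat$exam_post <- tryCatch(
      read_examination(resolve(pat$row$post_volume),
                       resolve(pat$row$post_mask),
                       resolve(pat$row$post_timing)),
      error = function(e) e)
    pat
  })
  bad <- vapply(loaded, function(p) inherits(p$exam_pre, "error") ||
                  inherits(p$exam_post, "error"), logical(1))
  for (p in loaded[bad]) {
    msgs <- c(if (inherits(p$exam_pre, "error"))
      conditionMessage(p$exam_pre),
      if (inherits(p$exam_post, "error")) conditionMessage(p$exam_post))
    warning("patient ", p$patient_id, " skipped: ",
            paste(msgs, collapse = "; "))
  }
  if (sum(bad) > 0.2 * length(loaded)) {
    stop("more than 20% of patients failed to load; aborting",
         call. = FALSE)
  }
  res <- analyze_cohort(loaded[!bad], n_levels, alpha, eps)
  wr <- function(df, name, ids = TRUE) {
    if (ids) df <- cbind(patient_id = res$patient_ids,
                         label = res$labels, df)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(res$features_pre, "features_pre.csv")
  wr(res$features_post, "features_post.csv")
  wr(res$deltas, "deltas.csv")
  t1 <- res$tables$group_summary
  utils::write.csv(t1, file.path(out_dir, "table1.csv"), row.names = FALSE)
  t2 <- res$tables$diagnostics
  printed <- c("roc_auc", "sensitivity", "specificity", "ppv", "npv",
               "accuracy", "cutoff")
  t2[printed] <- lapply(t2[printed], round_half_up, 2)
  utils::write.csv(t2, file.path(out_dir, "table2.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_levels = n_levels, alpha = alpha,
         n_patients = length(res$patient_ids),
         failed = res$failed,
         bonferroni_m = res$tables$bonferroni_m,
         group_summary = res$tables$group_summary,
         diagnostics = res$tables$diagnostics),
    file.path(out_dir, "report.json"), digits = NA, auto_unbox = TRUE)
  invisible(res)
}

#' SIS from a pair of time-intensity curve tables
#'
#' Reads two CSV files with `time,signal` columns (pre- and
#' post-treatment curves), fits the piecewise model to each, and returns
#' the ten semiquantitative parameters per examination together with the
#' percentage changes of MSD and WOS and the SIS.
#'
#' @param pre_csv,post_csv Paths to the TIC tables.
#' @param eps Near-zero guard for the percentage changes.
#' @return List with `params_pre`, `params_post` (named vectors),
#'   `delta_msd`, `delta_wos`, `sis`.
#' @export
sis_from_tic_tables <- function(pre_csv, post_csv, eps = 1e-9) {
  read_tic <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("time", "signal") %in% names(df))) {
      stop("TIC table must have `time` and `signal` columns: ", path,
           call. = FALSE)
    }
    tic(df$time, df$signal)
  }
  one <- function(path) {
    x <- read_tic(path)
    semiquant_params(fit_piecewise(x), x)
  }
  p1 <- one(pre_csv)
  p2 <- one(post_csv)
  d_msd <- percent_change(p1[["msd"]], p2[["msd"]], eps)
  d_wos <- percent_change(p1[["wos"]], p2[["wos"]], eps)
  list(params_pre = p1, params_post = p2,
       delta_msd = d_msd, delta_wos = d_wos,
       sis = compute_sis(d_msd, d_wos))
}
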