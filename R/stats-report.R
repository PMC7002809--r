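#' Two-group Kruskal-Wallis test
#'
#' Tie-corrected rank H statistic with a chi-square (1 df) p-value, as
#' provided by [stats::kruskal.test()].
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @return List with `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  kt <- stats::kruskal.test(list(x, y))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Bonferroni significance flags
#'
#' @param p Vector of p-values.
#' @param alpha Family-wise significance level (default 0.05).
#' @param m Number of comparisons (default `length(p)`).
#' @return Logical vector: `p < alpha / m`.
#' @export
bonferroni_flags <- function(p, alpha = 0.05, m = length(p)) {
  if (!length(p)) return(logical(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  !is.na(p) & p < alpha / m
}

# normalise labels to logical positive (pCR) indicator
.as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels == "pCR"
}

#' ROC area under the curve
#'
#' The tie-corrected Mann-Whitney probability that a positive (pCR) score
#' exceeds a negative one, with ties counted one half. Orientation is
#' fixed: higher score means more likely pCR.
#'
#' @param scores Numeric scores.
#' @param labels `"pCR"`/`"non-pCR"` (or logical, `TRUE` = positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- .as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Diagnostic metrics from a confusion matrix
#'
#' @param tp,fp,tn,fn Non-negative integer counts; `tp + fn > 0` and
#'   `tn + fp > 0`.
#' @return List with full-precision `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy` (PPV/NPV `NA`-flagged on zero denominators), their
#'   2-decimal `rounded` counterparts (half-up rounding, the convention of
#'   printed clinical tables), and the counts.
#' @export
diagnostic_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || tp + fn == 0 || tn + fp == 0) {
    stop("invalid confusion counts", call. = FALSE)
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  acc <- (tp + tn) / sum(counts)
  full <- c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
            accuracy = acc)
  list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
       accuracy = acc, rounded = round_half_up(full, 2), counts = counts)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, as printed clinical
#' tables do (R's `round()` rounds ties to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Youden-optimal cutoff and diagnostic report
#'
#' Classifies positive when `score >= cutoff`, evaluates the Youden index
#' `J = sensitivity + specificity - 1` at every observed score value, and
#' returns the maximising cutoff. Ties on `J` are broken towards the
#' highest specificity, then the smallest cutoff, so reports are
#' deterministic. When all scores are identical the single candidate has
#' `J = 0` and the report is flagged degenerate.
#'
#' @inheritParams roc_auc
#' @return List with `cutoff`, `youden_j`, `auc`, `degenerate` and the
#'   fields of [diagnostic_metrics()] at the chosen cutoff.
#' @export
youden_cutoff <- function(scores, labels) {
  pos <- .as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  cands <- sort(unique(scores))
  best <- NULL
  for (cut in cands) {
    pred <- scores >= cut
    tp <- sum(pred & pos); fp <- sum(pred & !pos)
    fn <- n1 - tp; tn <- n0 - fp
    j <- tp / n1 + tn / n0 - 1
    spec <- tn / n0
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12)) {
      best <- list(cut = cut, j = j, spec = spec,
                   tp = tp, fp = fp, tn = tn, fn = fn)
    }
  }
  dm <- diagnostic_metrics(best$tp, best$fp, best$tn, best$fn)
  c(list(cutoff = best$cut, youden_j = best$j,
         auc = roc_auc(scores, labels),
         degenerate = length(cands) == 1L), dm)
}

#' Group-comparison and diagnostic tables for a cohort delta table
#'
#' For every percentage-change feature: per-group (pCR, non-pCR, total)
#' median, SD and range (max - min), the Kruskal-Wallis p-value and its
#' Bonferroni flag (family size = number of features tested); and the ROC
#' AUC, Youden-optimal cutoff and the derived diagnostic metrics.
#' Undefined (NA) changes are excluded feature-wise with a recorded count.
#' Rows are ordered textural features first, then dynamic parameters, with
#' SIS last.
#'
#' @param delta_table Data frame: one row per patient, one column per
#'   percentage-change feature (plus `sis`).
#' @param labels Patient labels (`"pCR"`/`"non-pCR"`), one per row.
#' @param alpha Significance level for the Bonferroni flags.
#' @return List with data frames `group_summary` (Table 1 analogue) and
#'   `diagnostics` (Table 2 analogue), plus `n_excluded` per feature.
#' @export
build_tables <- function(delta_table, labels, alpha = 0.05) {
  pos <- .as_positive(labels)
  if (sum(pos) < 2 || sum(!pos) < 2) {
    stop("need at least 2 patients per group", call. = FALSE)
  }
  feats <- names(delta_table)
  dynamic <- c(semiquant_names(), "sis")
  feats <- c(setdiff(feats, dynamic), intersect(dynamic, feats))
  gs <- list(); dg <- list(); excl <- integer(0)
  for (f in feats) {
    v <- delta_table[[f]]
    ok <- !is.na(v)
    excl[f] <- sum(!ok)
    vv <- v[ok]; pp <- pos[ok]
    if (sum(pp) < 2 || sum(!pp) < 2 || length(unique(vv)) < 1) {
      next
    }
    kw <- kruskal_wallis(vv[pp], vv[!pp])
    stat3 <- function(x) c(median = stats::median(x),
                           sd = if (length(x) > 1) stats::sd(x) else 0,
                           range = max(x) - min(x))
    gs[[f]] <- data.frame(feature = f,
                          t(c(pcr = stat3(vv[pp]), nonpcr = stat3(vv[!pp]),
                              total = stat3(vv))),
                          kruskal_p = kw$p_value,
                          stringsAsFactors = FALSE)
    yj <- youden_cutoff(vv, pp)
    dg[[f]] <- data.frame(feature = f, kruskal_p = kw$p_value,
                          roc_auc = yj$auc, cutoff = yj$cutoff,
                          sensitivity = yj$sensitivity,
                          specificity = yj$specificity,
                          ppv = yj$ppv, npv = yj$npv,
                          accuracy = yj$accuracy,
                          tp = yj$counts[["tp"]], fp = yj$counts[["fp"]],
                          tn = yj$counts[["tn"]], fn = yj$counts[["fn"]],
                          stringsAsFactors = FALSE)
  }
  group_summary <- do.call(rbind, gs)
  diagnostics <- do.call(rbind, dg)
  rownames(group_summary) <- rownames(diagnostics) <- NULL
  group_summary$bonferroni_significant <-
    bonferroni_flags(group_summary$kruskal_p, alpha,
                     m = nrow(group_summary))
  list(group_summary = group_summary, diagnostics = diagnostics,
       n_excluded = excl, bonferroni_m = nrow(group_summary),
       alpha = alpha)
}
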