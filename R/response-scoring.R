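#' Standardised Index of Shape coefficients
#'
#' Fixed weights of the SIS linear combination of the percentage changes
#' of maximum signal difference and washout slope.
#' @return Named numeric vector `c(msd = 0.7780, wos = 0.6157)`.
#' @export
sis_coefficients <- function() c(msd = 0.7780, wos = 0.6157)

#' Pre-to-post percentage change
#'
#' `delta = (v1 - v2) / v1 * 100`: a post-treatment decrease yields a
#' positive change. When the pre-treatment value is within `eps` of zero
#' the change is undefined and `NA` is returned (flagged), so downstream
#' cohort statistics can exclude it explicitly.
#'
#' @param v1 Pre-treatment value.
#' @param v2 Post-treatment value.
#' @param eps Near-zero guard on `|v1|` (default `1e-9`).
#' @return Percentage change (vectorised); `NA` where undefined.
#' @export
percent_change <- function(v1, v2, eps = 1e-9) {
  out <- ifelse(!is.na(v1) & !is.na(v2) & abs(v1) >= eps,
                (v1 - v2) / v1 * 100, NA_real_)
  as.numeric(out)
}

#' Standardised Index of Shape
#'
#' Linear combination of the percentage changes of maximum signal
#' difference and washout slope: `0.7780 * delta_msd + 0.6157 * delta_wos`
#' (both in percent). Undefined when either change is undefined.
#'
#' @param delta_msd,delta_wos Percentage changes (%).
#' @param coefficients Optional replacement weights (named `msd`, `wos`).
#' @return SIS in percent; `NA` if either input is `NA`.
#' @export
compute_sis <- function(delta_msd, delta_wos,
                        coefficients = sis_coefficients()) {
  unname(coefficients[["msd"]] * delta_msd +
           coefficients[["wos"]] * delta_wos)
}

#' Per-patient percentage-change vector with SIS
#'
#' Applies [percent_change()] feature-wise to matched pre/post
#' representative feature vectors and appends the SIS computed from the
#' `msd` and `wos` entries.
#'
#' @param pre,post Named numeric vectors with identical key sets
#'   (semiquantitative parameters and/or texture features).
#' @param eps Near-zero guard passed to [percent_change()].
#' @return Named numeric vector of percentage changes plus `sis`.
#' @export
patient_delta_vector <- function(pre, post, eps = 1e-9) {
  if (!setequal(names(pre), names(post)) || is.null(names(pre))) {
    stop("`pre` and `post` must share the same feature names", call. = FALSE)
  }
  post <- post[names(pre)]
  d <- percent_change(as.numeric(pre), as.numeric(post), eps)
  names(d) <- names(pre)
  sis <- if (all(c("msd", "wos") %in% names(d))) {
    compute_sis(d[["msd"]], d[["wos"]])
  } else {
    NA_real_
  }
  c(d, sis = sis)
}
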