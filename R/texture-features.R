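#' The 13 unique 3-D neighbour directions
#'
#' Offsets covering every axis, face-diagonal and corner direction up to
#' sign, used to pool GLCM and GLRLM matrices over orientations.
#'
#' @return 13 x 3 integer matrix of (dx, dy, dz) offsets.
#' @export
texture_directions <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# all 26 neighbour offsets (both signs)
.offsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# paired linear indices (centre, neighbour) for one offset, within bounds
.shift_pairs <- function(dims, d) {
  rng <- function(n, o) {
    from <- max(1, 1 - o); to <- min(n, n - o)
    if (from > to) integer(0) else seq.int(from, to)
  }
  xs <- rng(dims[1], d[1]); ys <- rng(dims[2], d[2]); zs <- rng(dims[3], d[3])
  if (!length(xs) || !length(ys) || !length(zs)) {
    return(cbind(integer(0), integer(0)))
  }
  g <- expand.grid(x = xs, y = ys, z = zs)
  a <- g$x + dims[1] * (g$y - 1L) + dims[1] * dims[2] * (g$z - 1L)
  b <- (g$x + d[1]) + dims[1] * (g$y + d[2] - 1L) +
    dims[1] * dims[2] * (g$z + d[3] - 1L)
  cbind(a, b)
}

#' Select the arterial-phase frame of a dynamic series
#'
#' The arterial (early post-contrast) frame is the first frame whose
#' VOI-mean enhancement over the pre-contrast baseline (mean of the first
#' two frames) reaches 50% of the maximum VOI-mean enhancement. A series
#' with no enhancement falls back to the last frame with a warning.
#'
#' @param series A [dynamic_series()].
#' @param mask A [voi_mask()].
#' @return The selected 3-D volume, with attribute `frame_index`.
#' @export
select_arterial_frame <- function(series, mask) {
  n <- length(series$frame_times)
  if (n < 3L) stop("need at least 3 frames", call. = FALSE)
  lin <- which(as.vector(mask$mask))
  if (!length(lin)) stop("empty VOI mask", call. = FALSE)
  flat <- matrix(series$signal, ncol = n)
  m <- colMeans(flat[lin, , drop = FALSE])
  enh <- m - mean(m[1:2])
  if (max(enh) <= 0) {
    warning("no VOI enhancement detected; falling back to the last frame")
    idx <- n
  } else {
    idx <- which(enh >= 0.5 * max(enh))[1]
  }
  vol <- series$signal[, , , idx, drop = TRUE]
  attr(vol, "frame_index") <- idx
  vol
}

#' Equal-width gray-level quantisation of a VOI
#'
#' Bins the VOI intensities into `n_levels` equal-width bins between the
#' VOI minimum and maximum; the maximum maps to level `n_levels`. Voxels
#' outside the mask get level 0. A constant VOI maps entirely to level 1
#' and is flagged degenerate.
#'
#' @param volume 3-D numeric array.
#' @param mask A [voi_mask()].
#' @param n_levels Number of gray levels (>= 2); default 32.
#' @return An object of class `quantized_voi`: list with `levels` (integer
#'   array, 0 outside the VOI), `n_levels`, `bin_edges` and `degenerate`.
#' @export
quantize_voi <- function(volume, mask, n_levels = 32) {
  if (n_levels < 2) stop("`n_levels` must be at least 2", call. = FALSE)
  stopifnot(inherits(mask, "voi_mask"))
  if (!identical(dim(volume), dim(mask$mask))) {
    stop("volume and mask grids are not aligned", call. = FALSE)
  }
  v <- volume[mask$mask]
  if (!length(v)) stop("empty VOI mask", call. = FALSE)
  mn <- min(v); mx <- max(v)
  degenerate <- mx <= mn
  lev <- array(0L, dim(volume))
  if (degenerate) {
    lev[mask$mask] <- 1L
    edges <- seq(mn, mn + 1, length.out = n_levels + 1)
  } else {
    w <- (mx - mn) / n_levels
    lev[mask$mask] <- as.integer(pmin(n_levels, floor((v - mn) / w) + 1))
    edges <- seq(mn, mx, length.out = n_levels + 1)
  }
  structure(list(levels = lev, n_levels = as.integer(n_levels),
                 bin_edges = edges, degenerate = degenerate),
            class = "quantized_voi")
}

# mark names as undefined (NA) and remember the flags
.flagged <- function(x, flags) {
  attr(x, "degenerate") <- flags
  x
}

#' First-order intensity statistics of a VOI
#'
#' Statistics of the raw (unquantised) VOI intensities: mean, mode (bin
#' centre of the most frequent quantised level), median, sample SD, median
#' absolute deviation (unscaled), range (max - min), excess kurtosis,
#' skewness and interquartile range. Skewness and kurtosis of a constant
#' VOI are undefined and returned as `NA` (flagged).
#'
#' @param volume 3-D numeric array.
#' @param mask A [voi_mask()].
#' @param n_levels Quantisation used for the mode.
#' @return Named numeric vector of 9 features (prefix `fo_`), with
#'   attribute `degenerate` naming any undefined entries.
#' @export
first_order_features <- function(volume, mask, n_levels = 32) {
  v <- volume[mask$mask]
  if (!length(v)) stop("empty VOI mask", call. = FALSE)
  q <- quantize_voi(volume, mask, n_levels)
  counts <- tabulate(q$levels[mask$mask], nbins = q$n_levels)
  ml <- which.max(counts)
  mode_val <- (q$bin_edges[ml] + q$bin_edges[ml + 1]) / 2
  sk <- e1071::skewness(v)
  ku <- e1071::kurtosis(v)
  flags <- character(0)
  if (!is.finite(sk)) { sk <- NA_real_; flags <- c(flags, "fo_skewness") }
  if (!is.finite(ku)) { ku <- NA_real_; flags <- c(flags, "fo_kurtosis") }
  out <- c(fo_mean = mean(v), fo_mode = mode_val,
           fo_median = stats::median(v),
           fo_sd = if (length(v) > 1) stats::sd(v) else 0,
           fo_mad = stats::median(abs(v - stats::median(v))),
           fo_range = max(v) - min(v),
           fo_kurtosis = ku, fo_skewness = sk,
           fo_iqr = unname(stats::IQR(v)))
  .flagged(out, flags)
}

#' Pooled gray-level co-occurrence matrix
#'
#' Co-occurrences of quantised levels between in-VOI voxel pairs at
#' distance 1, accumulated over the given directions, symmetrised and
#' normalised to a joint probability.
#'
#' @param q A [quantize_voi()] result.
#' @param directions Matrix of direction offsets (default all 13).
#' @return `n_levels x n_levels` probability matrix (sums to 1), or all
#'   zeros when no valid pair exists.
#' @export
glcm_matrix <- function(q, directions = texture_directions()) {
  ng <- q$n_levels
  L <- q$levels
  dims <- dim(L)
  counts <- matrix(0, ng, ng)
  for (k in seq_len(nrow(directions))) {
    pr <- .shift_pairs(dims, directions[k, ])
    a <- L[pr[, 1]]; b <- L[pr[, 2]]
    sel <- a > 0L & b > 0L
    if (!any(sel)) next
    tab <- tabulate((a[sel] - 1L) * ng + b[sel], nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
  }
  counts <- counts + t(counts)
  tot <- sum(counts)
  if (tot > 0) counts / tot else counts
}

#' GLCM texture features
#'
#' Nine features from the direction-pooled co-occurrence matrix: energy,
#' contrast, entropy (bits, with 0 log 0 = 0), homogeneity, correlation,
#' dissimilarity, autocorrelation, sum average and variance. Correlation
#' is undefined (flagged `NA`) when the marginal variance is zero.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector (prefix `glcm_`).
#' @export
glcm_features <- function(q, directions = texture_directions()) {
  P <- glcm_matrix(q, directions)
  ng <- q$n_levels
  nm <- paste0("glcm_", c("energy", "contrast", "entropy", "homogeneity",
                          "correlation", "dissimilarity", "autocorrelation",
                          "sum_average", "variance"))
  if (sum(P) == 0) {
    return(.flagged(stats::setNames(rep(NA_real_, 9), nm), nm))
  }
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)                       # symmetric: px == py
  mu <- sum(seq_len(ng) * px)
  sigma2 <- sum((seq_len(ng) - mu)^2 * px)
  pos <- P > 0
  entropy <- -sum(P[pos] * log2(P[pos]))
  flags <- character(0)
  correlation <- if (sigma2 > 0) {
    (sum(i * j * P) - mu^2) / sigma2
  } else {
    flags <- "glcm_correlation"
    NA_real_
  }
  out <- stats::setNames(c(
    sum(P^2), sum((i - j)^2 * P), entropy, sum(P / (1 + abs(i - j))),
    correlation, sum(abs(i - j) * P), sum(i * j * P), sum((i + j) * P),
    sigma2), nm)
  .flagged(out, flags)
}

# run-length matrix for one direction: maximal runs of equal level
.glrlm_one <- function(L, dims, d, ng, max_len) {
  # run starts: in-VOI voxels whose predecessor (pos - d) is absent/different
  pred <- array(0L, dims)
  pr <- .shift_pairs(dims, -d)
  pred[pr[, 1]] <- L[pr[, 2]]
  starts <- which(L > 0L & pred != L, arr.ind = TRUE)
  R <- matrix(0, ng, max_len)
  if (nrow(starts) == 0L) return(R)
  lin0 <- starts[, 1] + dims[1] * (starts[, 2] - 1L) +
    dims[1] * dims[2] * (starts[, 3] - 1L)
  lvl <- L[lin0]
  len <- rep(1L, nrow(starts))
  cur <- starts
  active <- seq_len(nrow(starts))
  while (length(active)) {
    nxt <- cur[active, , drop = FALSE] +
      matrix(d, length(active), 3, byrow = TRUE)
    inb <- nxt[, 1] >= 1 & nxt[, 1] <= dims[1] &
      nxt[, 2] >= 1 & nxt[, 2] <= dims[2] &
      nxt[, 3] >= 1 & nxt[, 3] <= dims[3]
    ok <- inb
    if (any(inb)) {
      lin <- nxt[inb, 1] + dims[1] * (nxt[inb, 2] - 1L) +
        dims[1] * dims[2] * (nxt[inb, 3] - 1L)
      ok[inb] <- L[lin] == lvl[active[inb]]
    }
    keep <- active[ok]
    if (!length(keep)) break
    cur[keep, ] <- nxt[ok, , drop = FALSE]
    len[keep] <- len[keep] + 1L
    active <- keep
  }
  tab <- tabulate((len - 1L) * ng + lvl, nbins = ng * max_len)
  R + matrix(tab, ng, max_len, byrow = FALSE)
}

#' Pooled gray-level run-length matrix
#'
#' Maximal runs of equal quantised level along each direction, restricted
#' to the VOI, summed over directions.
#'
#' @inheritParams glcm_matrix
#' @return `n_levels x max_run_length` count matrix.
#' @export
glrlm_matrix <- function(q, directions = texture_directions()) {
  dims <- dim(q$levels)
  max_len <- max(dims)
  R <- matrix(0, q$n_levels, max_len)
  for (k in seq_len(nrow(directions))) {
    R <- R + .glrlm_one(q$levels, dims, directions[k, ], q$n_levels, max_len)
  }
  R
}

#' GLRLM texture features
#'
#' Thirteen run-length features including long-run emphasis (LRE), from
#' the direction-pooled run-length matrix. Run percentage is normalised by
#' the number of directions so it stays in (0, 1].
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector (prefix `glrlm_`).
#' @export
glrlm_features <- function(q, directions = texture_directions()) {
  R <- glrlm_matrix(q, directions)
  np <- sum(q$levels > 0L)
  .rl_family(R, np * nrow(directions), "glrlm_",
             c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
               "srlge", "srhge", "lrlge", "lrhge", "glv", "rlv"))
}

# shared feature formulas for run-length and size-zone matrices;
# M is gray-level x (run length | zone size) counts
.rl_family <- function(M, np_norm, prefix, suffixes) {
  Nr <- sum(M)
  nm <- paste0(prefix, suffixes)
  if (Nr == 0) return(.flagged(stats::setNames(rep(NA_real_, 13), nm), nm))
  g <- seq_len(nrow(M))
  r <- seq_len(ncol(M))
  p <- M / Nr
  gm <- matrix(g, nrow(M), ncol(M))
  rm <- matrix(r, nrow(M), ncol(M), byrow = TRUE)
  mug <- sum(gm * p)
  mur <- sum(rm * p)
  out <- stats::setNames(c(
    sum(p / rm^2), sum(p * rm^2),
    sum(rowSums(M)^2) / Nr, sum(colSums(M)^2) / Nr,
    Nr / np_norm,
    sum(p / gm^2), sum(p * gm^2),
    sum(p / (gm^2 * rm^2)), sum(p * gm^2 / rm^2),
    sum(p * rm^2 / gm^2), sum(p * gm^2 * rm^2),
    sum(p * (gm - mug)^2), sum(p * (rm - mur)^2)), nm)
  .flagged(out, character(0))
}

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal quantised level inside the
#' VOI; the zone-size matrix feeds the standard 13-feature family
#' (small/large-zone emphases, gray-level and zone-size non-uniformities,
#' zone percentage, low/high gray-level emphases and variances).
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector (prefix `glszm_`).
#' @export
glszm_features <- function(q) {
  z <- glszm_zones(q)
  np <- sum(q$levels > 0L)
  max_s <- max(z$size)
  M <- matrix(0, q$n_levels, max_s)
  for (k in seq_along(z$size)) {
    M[z$level[k], z$size[k]] <- M[z$level[k], z$size[k]] + 1
  }
  .rl_family(M, np, "glszm_",
             c("sze", "lze", "gln", "zsn", "zp", "lgze", "hgze",
               "szlge", "szhge", "lzlge", "lzhge", "glv", "zsv"))
}

#' Connected equal-level zones of a quantised VOI
#'
#' @param q A [quantize_voi()] result.
#' @return List with integer vectors `level` and `size`, one entry per
#'   26-connected zone.
#' @export
glszm_zones <- function(q) {
  L <- q$levels
  dims <- dim(L)
  lin <- which(as.vector(L) > 0L)
  vid <- integer(length(L))
  vid[lin] <- seq_along(lin)
  edges <- list()
  for (k in seq_len(nrow(texture_directions()))) {
    pr <- .shift_pairs(dims, texture_directions()[k, ])
    sel <- L[pr[, 1]] > 0L & L[pr[, 2]] > 0L & L[pr[, 1]] == L[pr[, 2]]
    if (any(sel)) {
      edges[[length(edges) + 1]] <- cbind(vid[pr[sel, 1]], vid[pr[sel, 2]])
    }
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(e))
  }
  comp <- igraph::components(g)
  lev <- L[lin]
  list(level = as.integer(tapply(lev, comp$membership, function(v) v[1])),
       size = as.integer(comp$csize))
}

#' Neighbourhood gray-tone difference features
#'
#' From the NGTDM over 26-connected in-VOI neighbourhoods: coarseness,
#' contrast, busyness, complexity and strength. For a single-level VOI the
#' busyness denominator vanishes; busyness is then reported as 0 and
#' flagged degenerate, and contrast/strength are flagged `NA`.
#'
#' @param q A [quantize_voi()] result.
#' @return Named numeric vector (prefix `ngtdm_`).
#' @export
ngtdm_features <- function(q) {
  L <- q$levels
  dims <- dim(L)
  ng <- q$n_levels
  nb_sum <- array(0, dims)
  nb_cnt <- array(0L, dims)
  for (k in seq_len(nrow(.offsets26()))) {
    pr <- .shift_pairs(dims, .offsets26()[k, ])
    inm <- L[pr[, 2]] > 0L
    a <- pr[inm, 1]
    tmp <- numeric(length(L)); tmp[a] <- tmp[a] + L[pr[inm, 2]]
    # accumulate via indexing (duplicates impossible within one offset)
    nb_sum <- nb_sum + array(tmp, dims)
    tmpc <- integer(length(L)); tmpc[a] <- 1L
    nb_cnt <- nb_cnt + array(tmpc, dims)
  }
  valid <- L > 0L & nb_cnt > 0L
  N <- sum(valid)
  nm <- paste0("ngtdm_", c("coarseness", "contrast", "busyness",
                           "complexity", "strength"))
  if (N == 0) return(.flagged(stats::setNames(rep(NA_real_, 5), nm), nm))
  abar <- nb_sum[valid] / nb_cnt[valid]
  lv <- L[valid]
  s <- vapply(seq_len(ng), function(i) sum(abs(i - abar)[lv == i]),
              numeric(1))
  ni <- tabulate(lv, nbins = ng)
  p <- ni / N
  occ <- which(p > 0)
  ngp <- length(occ)
  flags <- character(0)
  ps <- sum(p * s)
  coarseness <- if (ps > 0) 1 / ps else { flags <- c(flags, nm[1]); NA_real_ }
  if (ngp >= 2) {
    pi_ <- p[occ]; ii <- occ
    dmat <- outer(ii, ii, "-")
    contrast <- sum(outer(pi_, pi_) * dmat^2) / (ngp * (ngp - 1)) * sum(s) / N
    denom_b <- sum(abs(outer(ii * pi_, ii * pi_, "-")))
    busyness <- ps / denom_b
    psmat <- outer(pi_ * s[occ], pi_ * s[occ], "+")
    pp <- outer(pi_, pi_, "+")
    off <- dmat != 0
    complexity <- sum((abs(dmat[off]) * psmat[off]) / pp[off]) / N
    strength <- if (sum(s) > 0) sum(pp[off] * dmat[off]^2) / sum(s) else {
      flags <- c(flags, nm[5]); NA_real_
    }
  } else {
    contrast <- NA_real_
    busyness <- 0
    complexity <- NA_real_
    strength <- NA_real_
    flags <- c(flags, nm[2], nm[3], nm[4], nm[5])
  }
  .flagged(stats::setNames(c(coarseness, contrast, busyness, complexity,
                             strength), nm), flags)
}

#' Names of the 50-feature texture panel
#' @return Character vector of the frozen, documented panel order.
#' @export
texture_panel_names <- function() {
  c(paste0("fo_", c("mean", "mode", "median", "sd", "mad", "range",
                    "kurtosis", "skewness", "iqr")),
    paste0("glcm_", c("energy", "contrast", "entropy", "homogeneity",
                      "correlation", "dissimilarity", "autocorrelation",
                      "sum_average", "variance")),
    paste0("glrlm_", c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                       "srlge", "srhge", "lrlge", "lrhge", "glv", "rlv")),
    paste0("glszm_", c("sze", "lze", "gln", "zsn", "zp", "lgze", "hgze",
                       "szlge", "szhge", "lzlge", "lzhge", "glv", "zsv")),
    paste0("ngtdm_", c("coarseness", "contrast", "busyness", "complexity",
                       "strength")),
    "volume_mm3")
}

#' Full 50-feature texture vector of one examination
#'
#' Selects the arterial-phase frame, quantises the VOI and assembles the
#' full panel: 9 first-order + 9 GLCM + 13 GLRLM + 13 GLSZM + 5 NGTDM
#' features plus the VOI volume (voxel count x voxel volume). Optionally a
#' first-order histogram entropy (`hist_entropy`, bits over the quantised
#' level histogram) is appended as an auxiliary 51st value outside the
#' frozen panel.
#'
#' @param series A [dynamic_series()].
#' @param mask A [voi_mask()].
#' @param n_levels Gray levels for quantisation (default 32).
#' @param include_hist_entropy Append the auxiliary histogram entropy.
#' @return Named numeric vector with exactly the [texture_panel_names()]
#'   keys (plus `hist_entropy` if requested); attribute `degenerate` lists
#'   undefined entries (carried as `NA`).
#' @export
full_feature_vector <- function(series, mask, n_levels = 32,
                                include_hist_entropy = FALSE) {
  vol <- select_arterial_frame(series, mask)
  q <- quantize_voi(vol, mask, n_levels)
  parts <- list(first_order_features(vol, mask, n_levels),
                glcm_features(q), glrlm_features(q), glszm_features(q),
                ngtdm_features(q))
  flags <- unlist(lapply(parts, attr, "degenerate"))
  out <- unlist(lapply(parts, function(p) { attributes(p)$degenerate <- NULL; p }))
  out <- c(out, volume_mm3 = sum(mask$mask) * prod(series$voxel_spacing))
  out <- out[texture_panel_names()]
  if (include_hist_entropy) {
    h <- tabulate(q$levels[mask$mask], nbins = q$n_levels)
    ph <- h[h > 0] / sum(h)
    out <- c(out, hist_entropy = -sum(ph * log2(ph)))
  }
  .flagged(out, flags)
}
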