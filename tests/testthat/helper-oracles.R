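# Literal-definition brute-force oracles. These deliberately re-derive
# every quantity by direct enumeration, independently of the package's
# vectorised implementations.

oracle_dims <- function(L) dim(L)

# co-occurrence counts by looping over every voxel and direction
oracle_glcm <- function(L, ng, directions = sisdce::texture_directions()) {
  dims <- dim(L)
  counts <- matrix(0, ng, ng)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      a <- L[x, y, z]
      if (a == 0) next
      for (k in seq_len(nrow(directions))) {
        d <- directions[k, ]
        xx <- x + d[1]; yy <- y + d[2]; zz <- z + d[3]
        if (xx < 1 || xx > dims[1] || yy < 1 || yy > dims[2] ||
            zz < 1 || zz > dims[3]) next
        b <- L[xx, yy, zz]
        if (b == 0) next
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  if (sum(counts) > 0) counts / sum(counts) else counts
}

oracle_glcm_entropy <- function(L, ng) {
  P <- oracle_glcm(L, ng)
  p <- P[P > 0]
  if (!length(p)) return(NA_real_)
  -sum(p * log2(p))
}

# run-length matrix: walk every maximal run explicitly
oracle_glrlm <- function(L, ng, directions = sisdce::texture_directions()) {
  dims <- dim(L)
  max_len <- max(dims)
  R <- matrix(0, ng, max_len)
  inb <- function(p) all(p >= 1) && all(p <= dims)
  for (k in seq_len(nrow(directions))) {
    d <- directions[k, ]
    for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
      for (z in seq_len(dims[3])) {
        lv <- L[x, y, z]
        if (lv == 0) next
        prev <- c(x, y, z) - d
        if (inb(prev) && L[prev[1], prev[2], prev[3]] == lv) next  # not a start
        len <- 1
        cur <- c(x, y, z) + d
        while (inb(cur) && L[cur[1], cur[2], cur[3]] == lv) {
          len <- len + 1
          cur <- cur + d
        }
        R[lv, len] <- R[lv, len] + 1
      }
  }
  R
}

oracle_lre <- function(L, ng) {
  R <- oracle_glrlm(L, ng)
  r2 <- matrix(seq_len(ncol(R))^2, nrow(R), ncol(R), byrow = TRUE)
  sum(R * r2) / sum(R)
}

# size zones by literal flood fill over the 26-neighbourhood
oracle_glszm_zones <- function(L) {
  dims <- dim(L)
  seen <- array(FALSE, dims)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  zones <- list()
  inb <- function(p) all(p >= 1) && all(p <= dims)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      if (L[x, y, z] == 0 || seen[x, y, z]) next
      lv <- L[x, y, z]
      queue <- list(c(x, y, z))
      seen[x, y, z] <- TRUE
      size <- 0
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        size <- size + 1
        for (o in seq_len(nrow(offs))) {
          q <- p + offs[o, ]
          if (inb(q) && !seen[q[1], q[2], q[3]] &&
              L[q[1], q[2], q[3]] == lv) {
            seen[q[1], q[2], q[3]] <- TRUE
            queue[[length(queue) + 1]] <- q
          }
        }
      }
      zones[[length(zones) + 1]] <- c(level = lv, size = size)
    }
  do.call(rbind, zones)
}

oracle_glszm_features <- function(L, ng) {
  zs <- oracle_glszm_zones(L)
  np <- sum(L > 0)
  max_s <- max(zs[, "size"])
  M <- matrix(0, ng, max_s)
  for (r in seq_len(nrow(zs))) {
    M[zs[r, "level"], zs[r, "size"]] <- M[zs[r, "level"], zs[r, "size"]] + 1
  }
  Nz <- sum(M)
  p <- M / Nz
  g <- matrix(seq_len(ng), ng, max_s)
  s <- matrix(seq_len(max_s), ng, max_s, byrow = TRUE)
  mug <- sum(g * p); mus <- sum(s * p)
  c(sze = sum(p / s^2), lze = sum(p * s^2),
    gln = sum(rowSums(M)^2) / Nz, zsn = sum(colSums(M)^2) / Nz,
    zp = Nz / np,
    lgze = sum(p / g^2), hgze = sum(p * g^2),
    szlge = sum(p / (g^2 * s^2)), szhge = sum(p * g^2 / s^2),
    lzlge = sum(p * s^2 / g^2), lzhge = sum(p * g^2 * s^2),
    glv = sum(p * (g - mug)^2), zsv = sum(p * (s - mus)^2))
}

# NGTDM by looping over every voxel's 26-neighbourhood
oracle_ngtdm_busyness <- function(L, ng) {
  dims <- dim(L)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  s <- numeric(ng); nn <- integer(ng); N <- 0
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      lv <- L[x, y, z]
      if (lv == 0) next
      vals <- c()
      for (o in seq_len(nrow(offs))) {
        q <- c(x, y, z) + offs[o, ]
        if (all(q >= 1) && all(q <= dims) && L[q[1], q[2], q[3]] > 0) {
          vals <- c(vals, L[q[1], q[2], q[3]])
        }
      }
      if (!length(vals)) next
      N <- N + 1
      nn[lv] <- nn[lv] + 1L
      s[lv] <- s[lv] + abs(lv - mean(vals))
    }
  p <- nn / N
  occ <- which(p > 0)
  if (length(occ) < 2) return(0)
  denom <- 0
  for (i in occ) for (j in occ) if (i != j) {
    denom <- denom + abs(i * p[i] - j * p[j])
  }
  sum(p * s) / denom
}

# pairwise-count AUC
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}

# exhaustive threshold scan including +/- Inf, rule: positive if score >= cut
oracle_best_youden <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  best <- -Inf
  for (cut in c(-Inf, sort(unique(scores)), Inf)) {
    pred <- scores >= cut
    j <- sum(pred & pos) / n1 + sum(!pred & !pos) / n0 - 1
    if (j > best) best <- j
  }
  best
}

# tie-corrected two-group Kruskal-Wallis H by the rank formula
oracle_kw_h <- function(x, y) {
  v <- c(x, y)
  N <- length(v)
  r <- rank(v)
  R1 <- sum(r[seq_along(x)]); R2 <- sum(r[-seq_along(x)])
  h <- 12 / (N * (N + 1)) *
    (R1^2 / length(x) + R2^2 / length(y)) - 3 * (N + 1)
  ties <- table(v)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) 0 else h / corr
}

# exact permutation p for the Kruskal-Wallis H at small n
oracle_kw_perm_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  h_obs <- oracle_kw_h(x, y)
  splits <- utils::combn(length(v), n1)
  hs <- apply(splits, 2, function(idx) oracle_kw_h(v[idx], v[-idx]))
  mean(hs >= h_obs - 1e-12)
}

# brute-force piecewise fit via lm() per candidate breakpoint pair
oracle_piecewise <- function(times, signal) {
  n <- length(times)
  best <- NULL
  for (i in 2:(n - 2)) for (j in (i + 1):(n - 1)) {
    s1 <- sum((signal[1:i] - mean(signal[1:i]))^2)
    f2 <- stats::lm(signal[i:j] ~ times[i:j])
    f3 <- stats::lm(signal[j:n] ~ times[j:n])
    sse <- s1 + sum(stats::resid(f2)^2) + sum(stats::resid(f3)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(sse = sse, i = i, j = j)
    }
  }
  best
}

# random quantised test volume with its mask implied by levels > 0
random_quantized <- function(dims, ng, p_mask = 0.8) {
  L <- array(0L, dims)
  sel <- stats::runif(prod(dims)) < p_mask
  L[sel] <- sample.int(ng, sum(sel), replace = TRUE)
  structure(list(levels = L, n_levels = as.integer(ng),
                 bin_edges = seq(0, ng, length.out = ng + 1),
                 degenerate = FALSE),
            class = "quantized_voi")
}

make_quantized <- function(L, ng) {
  structure(list(levels = L, n_levels = as.integer(ng),
                 bin_edges = seq(0, ng, length.out = ng + 1),
                 degenerate = FALSE),
            class = "quantized_voi")
}
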