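test_that("equal-width quantisation follows the binning contract", {
  m <- voi_mask(array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2)))
  vol <- array(c(0, 1, 2, 3, 0, 0, 0, 0), c(2, 2, 2))
  q <- quantize_voi(vol, m, 2)
  expect_identical(q$levels[m$mask], c(1L, 1L, 2L, 2L))

  const <- quantize_voi(array(7, c(2, 2, 2)), m, 8)
  expect_true(const$degenerate)
  expect_true(all(const$levels[m$mask] == 1L))

  set.seed(2)
  mm <- voi_mask(array(TRUE, c(6, 6, 6)))
  vv <- array(stats::runif(216), c(6, 6, 6))
  q32 <- quantize_voi(vv, mm, 32)
  lv <- q32$levels[mm$mask]
  expect_equal(min(lv), 1L)
  expect_equal(max(lv), 32L)
  expect_error(quantize_voi(vv, mm, 1), "n_levels")
})

test_that("first-order statistics match hand values and flag degeneracy", {
  m <- voi_mask(array(c(rep(TRUE, 5), rep(FALSE, 3)), c(2, 2, 2)))
  vol <- array(c(1, 2, 3, 4, 5, 0, 0, 0), c(2, 2, 2))
  f <- first_order_features(vol, m)
  expect_equal(f[["fo_mean"]], 3)
  expect_equal(f[["fo_median"]], 3)
  expect_equal(f[["fo_range"]], 4)
  expect_equal(f[["fo_iqr"]], unname(stats::IQR(1:5)))

  fc <- first_order_features(array(7, c(2, 2, 2)), m)
  expect_equal(fc[["fo_sd"]], 0)
  expect_equal(fc[["fo_mad"]], 0)
  expect_equal(fc[["fo_range"]], 0)
  expect_true(is.na(fc[["fo_skewness"]]))
  expect_true(is.na(fc[["fo_kurtosis"]]))
  expect_setequal(attr(fc, "degenerate"), c("fo_skewness", "fo_kurtosis"))

  set.seed(42)
  big <- voi_mask(array(TRUE, c(25, 20, 20)))
  gvol <- array(stats::rnorm(10000), c(25, 20, 20))
  fg <- first_order_features(gvol, big)
  expect_lt(abs(fg[["fo_skewness"]]), 0.05)
  expect_lt(abs(fg[["fo_kurtosis"]]), 0.1)
})

test_that("GLCM entropy matches hand-enumerated cases", {
  m1 <- make_quantized(array(1L, c(3, 3, 2)), 4)
  expect_equal(glcm_features(m1)[["glcm_entropy"]], 0)

  strip <- array(0L, c(4, 1, 1))
  strip[, 1, 1] <- c(1L, 2L, 1L, 2L)
  qs <- make_quantized(strip, 2)
  expect_equal(glcm_features(qs)[["glcm_entropy"]], 1.0)
})

test_that("GLRLM and NGTDM match hand-computed single instances", {
  strip <- array(0L, c(1, 1, 4))
  strip[1, 1, ] <- 1L
  q <- make_quantized(strip, 2)
  one_dir <- matrix(c(0, 0, 1), 1)
  expect_equal(glrlm_features(q, directions = one_dir)[["glrlm_lre"]], 16)

  alt <- array(0L, c(1, 1, 4))
  alt[1, 1, ] <- c(1L, 2L, 1L, 2L)
  qa <- make_quantized(alt, 2)
  expect_equal(glrlm_features(qa, directions = one_dir)[["glrlm_lre"]], 1)

  centre <- array(1L, c(3, 3, 1))
  centre[2, 2, 1] <- 2L
  qc <- make_quantized(centre, 2)
  # p1 = 8/9, p2 = 1/9; s1 = 4/3 + 4/5, s2 = 1 -> busyness = 813/540
  expect_equal(ngtdm_features(qc)[["ngtdm_busyness"]], 813 / 540,
               tolerance = 1e-12)
  expect_equal(oracle_ngtdm_busyness(centre, 2), 813 / 540,
               tolerance = 1e-12)
})

test_that("GLSZM handles constant and multi-blob volumes", {
  const <- make_quantized(array(1L, c(2, 2, 2)), 2)
  expect_equal(glszm_features(const)[["glszm_sze"]], 1 / 64)

  two <- array(0L, c(9, 1, 1))
  two[1:3, 1, 1] <- 1L
  two[5:9, 1, 1] <- 1L
  z <- glszm_zones(make_quantized(two, 2))
  expect_setequal(z$size, c(3, 5))
  expect_equal(z$level, c(1L, 1L))
})

test_that("texture families match brute-force enumeration oracles", {
  set.seed(314)
  for (rep in 1:50) {
    dims <- sample(3:6, 3, replace = TRUE)
    ng <- sample(2:6, 1)
    q <- random_quantized(dims, ng, p_mask = stats::runif(1, 0.5, 1))
    if (!any(q$levels > 0)) next
    L <- q$levels
    expect_equal(glcm_features(q)[["glcm_entropy"]],
                 oracle_glcm_entropy(L, ng), tolerance = 1e-10)
    expect_equal(glrlm_features(q)[["glrlm_lre"]], oracle_lre(L, ng),
                 tolerance = 1e-10)
    expect_equal(ngtdm_features(q)[["ngtdm_busyness"]],
                 oracle_ngtdm_busyness(L, ng), tolerance = 1e-10)
    gz <- glszm_features(q)
    oz <- oracle_glszm_features(L, ng)
    expect_equal(unname(gz[paste0("glszm_", names(oz))]), unname(oz),
                 tolerance = 1e-10)
  }
})

test_that("entropy is invariant to gray-level relabelling and rotation", {
  set.seed(5)
  for (rep in 1:5) {
    ng <- 5
    q <- random_quantized(c(5, 5, 4), ng)
    perm <- sample(ng)
    L2 <- q$levels
    L2[L2 > 0] <- perm[L2[L2 > 0]]
    q2 <- make_quantized(L2, ng)
    expect_equal(glcm_features(q)[["glcm_entropy"]],
                 glcm_features(q2)[["glcm_entropy"]], tolerance = 1e-12)

    rotz <- function(a) {
      b <- aperm(a, c(2, 1, 3))
      b[rev(seq_len(dim(b)[1])), , , drop = FALSE]
    }
    qr <- make_quantized(rotz(q$levels), ng)
    expect_equal(glcm_features(q)[["glcm_entropy"]],
                 glcm_features(qr)[["glcm_entropy"]], tolerance = 1e-12)
    expect_equal(glrlm_features(q)[["glrlm_lre"]],
                 glrlm_features(qr)[["glrlm_lre"]], tolerance = 1e-12)
  }
})

test_that("arterial-frame selection follows the half-maximum rule", {
  mask <- ellipsoid_mask(c(8, 8, 6), c(2.5, 2.5, 1.5))
  times <- seq(0, 384, by = 16)
  # monotone linear rise: first frame at or past half-max of the final level
  n <- length(times)
  sig <- array(rep(seq(0, 100, length.out = n), each = 8 * 8 * 6),
               c(8, 8, 6, n))
  series <- dynamic_series(sig + 100, times)
  vol <- select_arterial_frame(series, mask)
  enh <- seq(0, 100, length.out = n) - mean(seq(0, 100, length.out = n)[1:2])
  expect_equal(attr(vol, "frame_index"), which(enh >= 0.5 * max(enh))[1])

  flat <- dynamic_series(array(100, c(8, 8, 6, n)), times)
  expect_warning(v2 <- select_arterial_frame(flat, mask), "enhancement")
  expect_equal(attr(v2, "frame_index"), n)

  field <- gaussian_random_field(c(8, 8, 6), 1, seed = 3)
  tf <- truth_field(mask, field, 0.35, 100, 48, 128, 150, -0.2, 0)
  ph <- generate_phantom(tf, mask, times)
  v3 <- select_arterial_frame(ph, mask)
  expect_lte(attr(v3, "frame_index"), which(times == 128))
})

test_that("the full panel has exactly the 50 documented features", {
  cfg <- cohort_config(n_pcr = 1, n_nonpcr = 1, seed = 6,
                       grid_shape = c(12, 12, 8),
                       voi_semiaxes = c(3.5, 3.5, 2.5))
  ex <- generate_cohort(cfg)[[1]]$exam_pre
  fv <- full_feature_vector(ex$series, ex$mask)
  expect_length(fv, 50)
  expect_identical(names(fv), texture_panel_names())
  fv2 <- full_feature_vector(ex$series, ex$mask)
  expect_identical(unclass(fv), unclass(fv2))

  fv51 <- full_feature_vector(ex$series, ex$mask,
                              include_hist_entropy = TRUE)
  expect_length(fv51, 51)

  # constant VOI: degenerate values across the heterogeneity families
  const <- dynamic_series(array(100, c(12, 12, 8, 25)),
                          seq(0, 384, by = 16))
  suppressWarnings(fvc <- full_feature_vector(const, ex$mask))
  expect_equal(fvc[["glcm_entropy"]], 0)
  expect_equal(fvc[["ngtdm_busyness"]], 0)
  expect_true("ngtdm_busyness" %in% attr(fvc, "degenerate"))
})
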