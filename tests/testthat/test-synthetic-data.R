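test_that("noiseless TIC generation follows the closed-form model", {
  tr <- kinetic_truth(baseline_signal = 100, onset_time = 40,
                      peak_time = 100, msd_true = 150, wos_true = -0.2)
  x <- generate_tic(tr, seq(0, 400, by = 20))
  expect_equal(x$signal[x$times == 100], 250)
  expect_equal(x$signal[x$times == 400], 250 - 0.2 * 300)
  expect_true(all(x$signal[x$times <= 40] == 100))

  flat <- kinetic_truth(100, 40, 100, msd_true = 0, wos_true = 0)
  xf <- generate_tic(flat, seq(0, 400, by = 20))
  expect_equal(xf$signal, rep(100, 21))
})

test_that("TIC noise matches the stated Gaussian model", {
  tr <- kinetic_truth(100, 40, 100, 150, -0.2, noise_sd = 5)
  times <- seq(0, 400, by = 20)
  clean <- generate_tic(kinetic_truth(100, 40, 100, 150, -0.2), times)$signal
  set.seed(99)
  resid <- unlist(lapply(1:500, function(i) {
    generate_tic(tr, times)$signal - clean
  }))
  expect_gt(length(resid), 10000)
  expect_lt(abs(stats::sd(resid) - 5) / 5, 0.02)
})

test_that("TIC generation rejects invalid sampling", {
  tr <- kinetic_truth(100, 40, 100, 150, -0.2)
  expect_error(generate_tic(tr, c(0, 20, 20, 60, 80, 100, 120)),
               "increasing")
  expect_error(generate_tic(tr, seq(30, 430, by = 20)), "baseline")
})

test_that("homogeneous-limit phantom gives one shared TIC and is deterministic", {
  mask <- ellipsoid_mask(c(10, 10, 8), c(3.5, 3.5, 2.5))
  field <- gaussian_random_field(c(10, 10, 8), Inf)
  tf <- truth_field(mask, field, amplitude = 0.35, baseline_signal = 100,
                    onset_time = 48, peak_time = 112, msd = 150,
                    wos = -0.2, noise_sd = 0)
  times <- seq(0, 384, by = 16)
  ph <- generate_phantom(tf, mask, times)
  Y <- t(matrix(ph$signal, ncol = length(times))[which(mask$mask), ])
  expect_true(all(apply(Y, 1, function(r) max(r) - min(r)) == 0))

  tfn <- truth_field(mask, field, 0.35, 100, 48, 112, 150, -0.2,
                     noise_sd = 3)
  p1 <- generate_phantom(tfn, mask, times, seed = 5)
  p2 <- generate_phantom(tfn, mask, times, seed = 5)
  expect_identical(p1$signal, p2$signal)
})

test_that("rougher random fields raise arterial-phase GLCM entropy", {
  lengthscales <- c(0.5, 1.5, 3)
  set.seed(11)
  ent <- sapply(lengthscales, function(ls) {
    mean(sapply(1:10, function(r) {
      mask <- ellipsoid_mask(c(14, 14, 10), c(5, 5, 3.5))
      field <- gaussian_random_field(c(14, 14, 10), ls)
      tf <- truth_field(mask, field, 0.35, 100, 48, 112, 150, -0.2, 0)
      ph <- generate_phantom(tf, mask, seq(0, 384, by = 16))
      vol <- select_arterial_frame(ph, mask)
      glcm_features(quantize_voi(vol, mask, 32))[["glcm_entropy"]]
    }))
  })
  expect_true(all(diff(ent) < 0))
})

test_that("cohort composition, determinism and ground-truth deltas are correct", {
  cfg <- cohort_config(n_pcr = 3, n_nonpcr = 5, seed = 4,
                       grid_shape = c(14, 14, 10),
                       voi_semiaxes = c(4.5, 4.5, 3.5))
  co <- generate_cohort(cfg)
  expect_length(co, 8)
  expect_equal(sum(sapply(co, `[[`, "label") == "pCR"), 3)
  expect_true(all(sapply(co, function(p) any(p$exam_post$mask$mask))))

  co2 <- generate_cohort(cfg)
  expect_identical(co[[5]]$exam_pre$series$signal,
                   co2[[5]]$exam_pre$series$signal)
  expect_identical(co[[2]]$delta_true, co2[[2]]$delta_true)

  # ground-truth delta algebra: factor f gives (1 - f) * 100
  cfg0 <- cohort_config(n_pcr = 2, n_nonpcr = 2, seed = 9,
                        grid_shape = c(12, 12, 8),
                        voi_semiaxes = c(3.5, 3.5, 2.5),
                        effect_msd_pcr = 0.3, effect_wos_pcr = 0.3,
                        effect_sdlog = 0, noise_sd = 0,
                        residual_focus_fraction_pcr = 0)
  co0 <- generate_cohort(cfg0)
  pcr <- co0[sapply(co0, `[[`, "label") == "pCR"]
  expect_equal(unname(sapply(pcr, function(p) p$delta_true[["delta_msd"]])),
               rep(70, 2))

  # no-effect null: all ground-truth changes vanish
  cfg1 <- cohort_config(n_pcr = 2, n_nonpcr = 2, seed = 10,
                        grid_shape = c(12, 12, 8),
                        voi_semiaxes = c(3.5, 3.5, 2.5),
                        effect_msd_pcr = 1, effect_wos_pcr = 1,
                        effect_msd_nonpcr = 1, effect_wos_nonpcr = 1,
                        effect_sdlog = 0,
                        shrink_pcr = 1, shrink_nonpcr = 1,
                        residual_focus_fraction_pcr = 0)
  co1 <- generate_cohort(cfg1)
  d <- t(sapply(co1, `[[`, "delta_true"))
  expect_equal(unname(d), matrix(0, 4, 3))
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(frame_interval = 5), "frame_interval")
  expect_error(cohort_config(effect_msd_pcr = 0), "effect factors")
  expect_error(cohort_config(effect_wos_nonpcr = 2.5), "effect factors")
  expect_error(cohort_config(n_pcr = 0), "positive")
  expect_error(cohort_config(grid_shape = c(8, 8, 6),
                             voi_semiaxes = c(6, 6, 4)), "accommodate")
})
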