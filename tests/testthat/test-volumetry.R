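# Segmentation and volume quantification: oracle equivalence on clean
# phantoms, robustness under noise and blur, conservation, and the
# reliability analyses.

test_that("segmentation recovers the ground-truth mask exactly on a clean phantom", {
  ph <- clean_vestibule()
  mask <- segment_fluid(ph$stir, ph$seeds$fluid)
  expect_identical(unclass(mask) & TRUE, ph$labels > 0)
  pmask <- segment_fluid(ph$flair, ph$seeds$perilymph)
  expect_identical(unclass(pmask) & TRUE, ph$labels == 1)
})

test_that("a background seed is rejected", {
  ph <- clean_vestibule()
  expect_error(segment_fluid(ph$stir, c(1L, 1L, 1L)), "seed outside fluid")
  expect_error(segment_fluid(ph$stir, c(0L, 1L, 1L)), "outside the image grid")
})

test_that("noisy blurred vestibule segmentation stays accurate (Dice >= 0.90)", {
  ph <- generate_phantom(phantom_spec("vestibule", seed = 21L))
  mask <- segment_fluid(ph$stir, ph$seeds$fluid)
  d <- dice(unclass(mask) & TRUE, ph$labels > 0)
  expect_gte(d, 0.90)
})

test_that("quantification is exact arithmetic with containment", {
  ph <- clean_vestibule(target_tv = 62.5, target_ep = 0.25)
  fv <- measure_phantom(ph)
  expect_equal(fv$tv, 62.5)
  expect_equal(fv$pv, 50.0)
  expect_equal(fv$ev, 12.5)
  expect_equal(fv$ep_ratio, 0.25)
  # flair mask equal to stir mask: EV = 0
  m <- ph$labels > 0
  fv2 <- quantify_volumes(m, m, 0.5)
  expect_equal(fv2$ev, 0)
  expect_equal(fv2$ep_ratio, 0)
  # flair voxels outside stir mask are clipped with a warning
  f <- m
  f[1, 1, 1] <- TRUE
  expect_warning(fv3 <- quantify_volumes(m, f, 0.5), "clipped")
  expect_equal(fv3$n_clipped, 1)
  expect_equal(fv3$tv, fv3$pv + fv3$ev)
  # empty perilymph is an error
  expect_error(quantify_volumes(m, array(FALSE, dim(m)), 0.5), "no perilymph")
})

test_that("EV + PV = TV exactly and matches the label-map oracle on clean phantoms", {
  set.seed(77)
  for (i in 1:5) {
    st <- sample(c("vestibule", "cochlea"), 1)
    ph <- generate_phantom(phantom_spec(st, target_tv = runif(1, 40, 100),
                                        target_ep = runif(1, 0.1, 0.5),
                                        blur_fwhm = 0, noise_sigma = 0))
    fv <- measure_phantom(ph)
    vv <- ph$voxel_size^3
    expect_equal(fv$tv, sum(ph$labels > 0) * vv)
    expect_equal(fv$ev, sum(ph$labels == 2) * vv)
    expect_equal(fv$tv, fv$pv + fv$ev)
  }
})

test_that("measured E/P is monotone in the target E/P", {
  eps <- c(0, 0.1, 0.2, 0.3, 0.45, 0.6)
  got <- vapply(eps, function(e) {
    measure_phantom(clean_vestibule(target_ep = e))$ep_ratio
  }, numeric(1))
  expect_true(all(diff(got) >= 0))
})

test_that("TV is reproducible across noise realizations (CV <= 5%)", {
  tvs <- vapply(1:8, function(s) {
    ph <- generate_phantom(phantom_spec("vestibule", seed = s))
    fv <- suppressWarnings(measure_phantom(ph))
    fv$tv
  }, numeric(1))
  expect_lte(sd(tvs) / mean(tvs), 0.05)
})

test_that("partial-volume TV bias at 0.8 mm voxels stays within 5%", {
  ph <- generate_phantom(phantom_spec("vestibule", voxel_size = 0.8, seed = 3L))
  fv <- measure_phantom(ph)
  expect_lt(abs(fv$tv - 59.57) / 59.57, 0.05)
})

test_that("fragmented cochlear endolymph degrades E/P recovery more than connected", {
  err <- vapply(c(FALSE, TRUE), function(frag) {
    errs <- vapply(1:4, function(s) {
      ph <- generate_phantom(phantom_spec("cochlea", seed = s,
                                          fragment_endolymph = frag))
      fv <- suppressWarnings(measure_phantom(ph))
      abs(fv$ep_ratio - 0.24)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_gt(err[2], err[1])
})

test_that("hydrops classification uses a strict threshold", {
  expect_true(classify_hydrops(0.55, 0.50))
  expect_false(classify_hydrops(0.35, 0.50))
  expect_false(classify_hydrops(0.50, 0.50))
  fv <- measure_phantom(clean_vestibule(target_ep = 0.6))
  expect_true(classify_hydrops(fv, 0.50))
})

test_that("TV deviations are centred per ear", {
  expect_equal(tv_deviations(c(93, 95, 94)), c(-1, 1, 0))
  expect_equal(tv_deviations(90), 0)
  expect_equal(tv_deviations(rep(88, 4)), rep(0, 4))
  expect_equal(sum(tv_deviations(rnorm(7, 90, 3))), 0, tolerance = 1e-10)
})

test_that("dose/delay association: exact linear, degenerate, and null type-I error", {
  df <- data.frame(pv = 10 + 2 * seq(0.1, 0.3, length.out = 20),
                   dose = seq(0.1, 0.3, length.out = 20),
                   delay_h = rep(6, 20))
  expect_error(dose_delay_association(df), "degenerate")
  df$delay_h <- runif(20, 4, 8)
  res <- dose_delay_association(df)
  expect_equal(res$r[res$predictor == "dose"], 1, tolerance = 1e-10)
  expect_equal(res$slope[res$predictor == "dose"], 2, tolerance = 1e-10)
  # PV independent of dose: p should be uniform
  set.seed(500)
  rej <- mean(replicate(200, {
    d2 <- data.frame(pv = rnorm(200, 50, 5),
                     dose = rnorm(200, 0.2, 0.01),
                     delay_h = runif(200, 4, 8))
    dose_delay_association(d2)$p[1] < 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
})
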