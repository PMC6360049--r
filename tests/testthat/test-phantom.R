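test_that("phantom construction yields a consistent labelled anatomy", {
  ph <- make_phantom(grid_dim = c(64, 64))
  expect_s3_class(ph, "petkem_phantom")
  expect_true(sum(ph$labels == ph$label_names[["aorta"]]) >= 4)
  expect_true(all(sort(unique(as.vector(ph$labels))) %in%
                    c(0L, ph$label_names)))
  expect_identical(dim(ph$labels), dim(ph$mu))
  expect_identical(dim(ph$labels), dim(ph$guidance))
  # water-like attenuation on tissue, zero in air
  expect_true(all(ph$mu[ph$labels > 0] > 0))
  expect_true(all(ph$mu[ph$labels == 0] == 0))
})

test_that("noiseless guidance image is piecewise constant per label", {
  ph <- make_phantom(grid_dim = c(64, 64), guidance_noise_sd = 0)
  for (lab in ph$label_names)
    expect_length(unique(ph$guidance[ph$labels == lab]), 1L)
  expect_true(all(ph$guidance[ph$labels == 0] == 0))
})

test_that("a 5 mm aorta at 1.56 mm spacing is 3 voxels wide in-plane", {
  ph <- make_phantom(grid_dim = c(96, 96), spacing = c(1.56, 1.56))
  # brute-force count of voxel centres inside the circle, row through centre
  seg <- ph$labels[, , 1] == ph$label_names[["aorta"]]
  widths <- apply(seg, 2, sum)
  expect_identical(max(widths), 3L)
  # oracle: voxel centres within 2.5 mm of the (snapped) centre
  xs <- (seq_len(96) - (96 + 1) / 2) * 1.56
  cx <- xs[which.min(abs(xs - 0.78))]
  expect_identical(max(widths), sum(abs(xs - cx) <= 2.5))
})

test_that("degenerate phantom configurations are rejected", {
  expect_error(make_phantom(aorta_diameter_mm = 1), "degenerate")
  expect_error(make_phantom(spacing = c(-1, 1.56)), "positive")
  expect_error(make_phantom(grid_dim = c(16, 16)), ">= 32")
})

test_that("frame scheme expansion matches the dynamic protocol", {
  fs <- make_frame_scheme()
  expect_equal(nrow(fs), 45L)
  expect_equal(sum(fs$duration), 4842)
  # contiguous, non-overlapping
  expect_equal(fs$start[-1], fs$end[-nrow(fs)])
  expect_true(all(fs$duration > 0))
  expect_equal(fs$start[1], 0)
  # singleton and conservation
  one <- make_frame_scheme(list(c(1, 10)))
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$duration), c(0, 10))
  spec <- list(c(3, 2.5), c(2, 7))
  expect_equal(sum(make_frame_scheme(spec)$duration),
               sum(vapply(spec, function(s) s[1] * s[2], numeric(1))))
  expect_error(make_frame_scheme(list()), "empty")
})

test_that("tissue curves satisfy the boundary and shape contracts", {
  expect_equal(tissue_tac("blood", t = 0), 0)
  expect_equal(tissue_tac("uptake", t = 0), 0)
  tt <- seq(0, 600, by = 0.25)
  blood <- tissue_tac("blood", t = tt)
  expect_true(all(blood >= 0))
  expect_lt(tt[which.max(blood)], 60)
  # uptake approaches its plateau (closed form: 1 - exp(-t/tau))
  p <- list(plateau = 7, tau = 50)
  t_99 <- 50 * log(100)
  expect_equal(tissue_tac("uptake", p, t_99), 7 * 0.99, tolerance = 1e-12)
  expect_lt(abs(tissue_tac("uptake", p, 1e6) - 7) / 7, 0.01)
  expect_error(tissue_tac("blood", t = -1), "negative")
})

test_that("blood curve peaks before every tissue curve maximum", {
  tacs <- default_tac_table()
  tt <- seq(0, 4842, by = 1)
  blood <- tissue_tac(tacs$aorta$model, tacs$aorta$params, tt)
  t_blood_peak <- tt[which.max(blood)]
  for (nm in setdiff(names(tacs), "aorta")) {
    organ <- tissue_tac(tacs[[nm]]$model, tacs[[nm]]$params, tt)
    expect_gt(tt[which.max(organ)], t_blood_peak)
  }
})

test_that("frame averaging matches a fine-step quadrature oracle", {
  tacs <- default_tac_table()
  got <- frame_average_tac(tacs$aorta, 24, 6)
  # independent oracle: trapezoid at 1 ms steps
  tt <- seq(24, 30, by = 0.001)
  a <- tissue_tac("blood", t = tt)
  oracle <- (sum(a) - (a[1] + a[length(a)]) / 2) / (length(tt) - 1)
  expect_lt(abs(got - oracle) / oracle, 0.001)
})

test_that("activity sampling paints frame-averaged values per tissue", {
  ph <- tiny_phantom()
  tacs <- default_tac_table()
  img <- sample_activity_image(ph, tacs, c(24, 6))
  expect_true(all(img[ph$labels == 0] == 0))
  for (nm in names(ph$label_names)) {
    sel <- ph$labels == ph$label_names[[nm]]
    expect_equal(unique(img[sel]), frame_average_tac(tacs[[nm]], 24, 6))
  }
  # monotone: if one tissue's curve dominates another, so do its voxels
  img2 <- sample_activity_image(ph, tacs, c(100, 50))
  hi <- unique(img2[ph$labels == ph$label_names[["organ_large"]]])
  lo <- unique(img2[ph$labels == ph$label_names[["organ_mid"]]])
  expect_gt(hi, lo)  # plateau 25 vs 12, same-shaped uptake
  bad <- tacs[c("aorta", "soft_tissue")]
  expect_error(sample_activity_image(ph, bad, c(0, 6)), "organ_large")
})

test_that("noiseless phantom aorta mean equals the frame-averaged blood TAC", {
  ph <- tiny_phantom()
  tacs <- default_tac_table()
  scheme <- make_frame_scheme(list(c(3, 6), c(2, 30)))
  truth <- true_idif(tacs, scheme)
  for (k in seq_len(nrow(scheme))) {
    img <- sample_activity_image(ph, tacs, scheme[k, ])
    expect_identical(mean(img[ph$labels == ph$label_names[["aorta"]]]),
                     truth[k])
  }
})
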