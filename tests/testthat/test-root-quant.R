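# Hairy-root measurement: channel extraction, background box subtraction,
# segmentation, masked means, control baseline and the corrected record.

test_that("green channel extraction preserves construction", {
  px <- array(0, dim = c(6, 6, 3))
  px[, , 1] <- 200                        # pure red image
  expect_true(all(extract_green(px) == 0))
  px[, , 2] <- 37
  expect_true(all(extract_green(px) == 37))

  res <- make_root_scene(small_root_scene(noise_sd = 0))
  g <- extract_green(res$image)
  base <- small_root_scene(noise_sd = 0)
  expect_equal(dim(g), c(96, 128))
  expect_equal(max(g), base$autofluor_baseline + base$true_signal)
})

test_that("background box subtraction clamps at zero and validates", {
  ch <- matrix(50, 40, 40)
  out <- subtract_background_box(ch, list(row = 5, col = 5,
                                          height = 10, width = 10))
  expect_true(all(out == 0))
  expect_equal(attr(out, "background_value"), 50)

  ch2 <- matrix(30, 40, 40)
  root <- matrix(FALSE, 40, 40); root[15:25, 15:25] <- TRUE
  ch2[root] <- 130
  out2 <- subtract_background_box(ch2, c(2, 2, 8, 8), root_region = root)
  expect_equal(unique(as.numeric(out2[root])), 100)
  expect_equal(unique(as.numeric(out2[!root])), 0)

  expect_error(subtract_background_box(ch2, c(35, 35, 10, 10)), "outside")
  expect_error(subtract_background_box(ch2, c(14, 14, 5, 5),
                                       root_region = root), "overlaps")
})

test_that("a box inside the halo ring absorbs the halo contribution", {
  cfg <- small_root_scene(noise_sd = 0, halo_gain = 0.3)
  res <- make_root_scene(cfg)
  g <- extract_green(res$image)
  far <- res$image$background_box
  ring <- which(extract_green(res$image) ==
                  cfg$autofluor_baseline + cfg$halo_gain * cfg$true_signal,
                arr.ind = TRUE)
  rrow <- ring[1, 1]; rcol <- ring[1, 2]
  halo_box_val <- g[rrow, rcol]
  far_val <- mean(g[far$row:(far$row + far$height - 1),
                    far$col:(far$col + far$width - 1)])
  expect_equal(far_val, cfg$autofluor_baseline)
  expect_equal(halo_box_val - far_val, cfg$halo_gain * cfg$true_signal)
})

test_that("segmentation recovers the bimodal mask and obeys fixed thresholds", {
  ch <- matrix(0, 30, 30)
  truth <- matrix(FALSE, 30, 30); truth[10:20, 12:22] <- TRUE
  ch[truth] <- 120
  m <- segment_expressing(ch, "otsu")
  expect_identical(unname(m > 0), truth)

  expect_true(all(!segment_expressing(matrix(0, 5, 5), "otsu")))
  pos <- matrix(3, 4, 4)
  expect_true(all(segment_expressing(pos, "fixed", threshold = 0)))
  expect_error(segment_expressing(pos, "fixed"), "threshold")
})

test_that("masked mean handles plain and empty masks", {
  ch <- matrix(80, 10, 10)
  expect_equal(masked_mean(ch, ch > 0), 80)
  two <- matrix(c(rep(100, 8), rep(200, 8)), 4, 4)
  expect_equal(masked_mean(two, two > 0), 150)
  expect_warning(out <- masked_mean(ch, ch > 100), "empty")
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "empty_mask"))
})

test_that("control baseline averages per-root means", {
  expect_error(control_baseline(list()), "control")
  mk <- function(seed) make_root_scene(small_root_scene(
    true_signal = 0, halo_gain = 0, noise_sd = 3, seed = seed))$image
  ctrl <- lapply(1:5, mk)
  base <- control_baseline(ctrl)
  expect_equal(base$n_control_roots, 5)
  expect_equal(base$mean_gray, mean(base$per_root))
  expect_lt(base$mean_gray, 10)  # near zero after box subtraction
})

test_that("corrected means follow the subtraction rule and recover ranks", {
  img <- make_root_scene(small_root_scene(noise_sd = 0))$image
  # arithmetic contract on the record
  m <- promoterglow:::root_gray_mean(img)$mean
  rec <- quantify_root(img, baseline = 10)
  expect_equal(rec$corrected_mean, max(0, m - 10))
  expect_equal(quantify_root(img, baseline = m)$corrected_mean, 0)
  expect_gt(rec$n_segmented_px, 0)

  # cohort with true strengths 1x/2x/4x lands in the true rank order
  cohort <- make_root_cohort(c(A = 1, B = 2, C = 4), n_events = 6,
                             ref_signal = 40, event_cv = 0.15, seed = 5)
  base <- control_baseline(cohort$controls)
  recs <- quantify_cohort(cohort$images, base)
  means <- tapply(recs$corrected_mean, recs$promoter_id, mean)
  expect_true(means[["A"]] < means[["B"]] && means[["B"]] < means[["C"]])
})

test_that("corrected mean is shift-invariant and monotone in true signal", {
  res <- make_root_scene(small_root_scene(noise_sd = 2, seed = 8))
  img <- res$image
  shifted <- img
  shifted$pixels[, , 2] <- img$pixels[, , 2] + 10   # no clipping occurs
  r1 <- quantify_root(img, baseline = 0)
  r2 <- quantify_root(shifted, baseline = 0)
  expect_equal(r1$corrected_mean, r2$corrected_mean)
  expect_equal(r1$n_segmented_px, r2$n_segmented_px)

  sigs <- c(20, 50, 90)
  cms <- vapply(sigs, function(s) {
    im <- make_root_scene(small_root_scene(true_signal = s,
                                           noise_sd = 0))$image
    quantify_root(im, baseline = 0)$corrected_mean
  }, numeric(1))
  expect_true(all(diff(cms) >= 0))

  # determinism: same image and parameters give the identical record
  expect_identical(quantify_root(img, baseline = 3),
                   quantify_root(img, baseline = 3))
})

test_that("auto_box picks a flat window clear of the root", {
  res <- make_root_scene(small_root_scene(noise_sd = 2, seed = 4))
  bx <- auto_box(res$image, size = 20)
  rows <- bx$row:(bx$row + 19); cols <- bx$col:(bx$col + 19)
  expect_false(any(res$image$root_region[rows, cols]))
  ch <- extract_green(res$image)
  expect_lt(mean(ch[rows, cols]), 25)   # medium, not root
})
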