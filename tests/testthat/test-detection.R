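mk_seg <- function(codes, dims = NULL) {
  if (is.null(dims)) dims <- c(length(codes), 1, 1)
  label_volume(array(as.integer(codes), dim = dims))
}
mk_img <- function(vals, dims = NULL) {
  if (is.null(dims)) dims <- c(length(vals), 1, 1)
  volume3d(array(as.numeric(vals), dim = dims))
}

test_that("cerebral stats: two-point oracle, CSF exclusion, degenerate cases", {
  img <- mk_img(c(260, 260, 190, 190))
  seg <- mk_seg(c(3, 3, 2, 2))
  st <- cerebral_intensity_stats(img, seg)
  expect_equal(st$mean, 225)
  expect_equal(st$sd, 35)        # population SD of the two-point distribution

  # adding CSF voxels of any value leaves the stats unchanged
  img2 <- mk_img(c(260, 260, 190, 190, 1e6, -5))
  seg2 <- mk_seg(c(3, 3, 2, 2, 1, 1))
  st2 <- cerebral_intensity_stats(img2, seg2)
  expect_equal(st2[c("mean", "sd")], st[c("mean", "sd")])

  expect_equal(cerebral_intensity_stats(mk_img(c(100, 100)),
                                        mk_seg(c(2, 3)))$sd, 0)
  expect_error(cerebral_intensity_stats(mk_img(c(100, 100)),
                                        mk_seg(c(1, 2))), "fewer than 2")
})

test_that("threshold rule: arithmetic oracle, inclusivity, alpha = 0", {
  img <- mk_img(c(260, 260, 190, 190, 340, 274, 273.999))
  seg <- mk_seg(c(3, 3, 2, 2, 3, 3, 3))
  # stats over all 7 cerebral voxels would shift; use a fixed two-point pool
  img0 <- mk_img(c(rep(260, 50), rep(190, 50), 340, 274, 273.999),
                 dims = c(103, 1, 1))
  seg0 <- mk_seg(c(rep(3, 50), rep(2, 50), 1, 1, 1), dims = c(103, 1, 1))
  st <- cerebral_intensity_stats(img0, seg0)
  expect_equal(st$mean + 1.4 * st$sd, 274)

  # same pool as candidates: a WM voxel at 340 is flagged, one at 260 is not
  seg1 <- mk_seg(c(rep(3, 50), rep(2, 50), 3, 3, 3), dims = c(103, 1, 1))
  det <- detect_wmsa(img0, seg1, detection_config(alpha = 1.4))
  st1 <- attr(det, "stats")
  vals <- as.vector(img0$data)
  expect_equal(as.numeric(det$data[vals == 340]), 1)
  expect_true(all(det$data[vals == 260] == 0))

  # inclusivity (>=) checked where the threshold is exact in floating point:
  # two-point pool, alpha = 1 puts the threshold at 225 + 35 = 260 exactly,
  # so every WM voxel sits exactly at the threshold and must be flagged
  img1 <- mk_img(c(rep(260, 50), rep(190, 50)), dims = c(100, 1, 1))
  seg2 <- mk_seg(c(rep(3, 50), rep(2, 50)), dims = c(100, 1, 1))
  det1 <- detect_wmsa(img1, seg2, detection_config(alpha = 1))
  expect_equal(attr(det1, "stats")$threshold, 260)
  v1 <- as.vector(img1$data)
  expect_true(all(det1$data[v1 == 260] == 1))   # at threshold -> flagged
  expect_true(all(det1$data[v1 == 190] == 0))

  det0 <- detect_wmsa(img0, seg1, detection_config(alpha = 0))
  expect_equal(sum(det0$data), sum(vals >= st1$mean &
                                   as.vector(seg1$labels) %in% 2:3))
})

test_that("detected mask shrinks as alpha grows, and survives affine rescale", {
  for (rep in 1:20) {
    set.seed(rep)
    n <- 400
    seg <- mk_seg(sample(0:4, n, replace = TRUE), dims = c(n, 1, 1))
    img <- mk_img(rnorm(n, 250, 40), dims = c(n, 1, 1))
    masks <- lapply(c(1.0, 1.4, 1.8), function(a)
      detect_wmsa(img, seg, detection_config(alpha = a))$data > 0.5)
    expect_true(all(masks[[2]] <= masks[[1]]))
    expect_true(all(masks[[3]] <= masks[[2]]))

    # global affine intensity rescale leaves the detection unchanged
    img_r <- mk_img(3.7 * as.vector(img$data) + 120, dims = c(n, 1, 1))
    m1 <- detect_wmsa(img, seg, detection_config(1.4))$data
    m2 <- detect_wmsa(img_r, seg, detection_config(1.4))$data
    expect_identical(m1, m2)
  }
})

test_that("wmsa_volume is the exact count-times-voxel-volume product", {
  m <- volume3d(array(0, dim = c(10, 10, 10)))
  expect_equal(wmsa_volume(m), 0)
  m$data[1:100] <- 1
  expect_equal(wmsa_volume(m), 100)
  m2 <- volume3d(array(c(rep(1, 10), rep(0, 90)), dim = c(10, 10, 1)),
                 spacing = c(0.703, 0.703, 2))
  expect_equal(round(wmsa_volume(m2), 2), 9.88)
})

test_that("regional split: counting oracle and slab invariants", {
  m <- volume3d(array(0, dim = c(8, 8, 12)))
  # 0-based landmarks: periventricular slab slices 3..6, centrum 7..8
  rs <- region_spec(3, 6)
  m$data[1:3, 1, 5] <- 1   # 3 voxels in the pv slab (slice index 4, 0-based)
  m$data[1:2, 1, 6] <- 1   # 2 more in the pv slab
  m$data[1:3, 2, 8] <- 1   # 3 voxels in the centrum slab (0-based 7)
  v <- regional_wmsa_volumes(m, rs)
  expect_equal(unname(v), c(8, 5, 3))
  expect_lte(v[["periventricular"]] + v[["centrum_semiovale"]],
             v[["entire_wm"]])

  # mask confined to the centrum slab
  m2 <- volume3d(array(0, dim = c(8, 8, 12)))
  m2$data[, , 9:10] <- 1   # 0-based slices 8..9 = centrum for midbody=7
  v2 <- regional_wmsa_volumes(m2, region_spec(2, 7))
  expect_equal(v2[["centrum_semiovale"]], v2[["entire_wm"]])
  expect_equal(v2[["periventricular"]], 0)

  expect_error(region_spec(5, 3), "frontal_horn")
  expect_error(regional_wmsa_volumes(m, region_spec(3, 11)), "above")
})

test_that("calibrate_alpha: single-element grid, exact-phantom tie-break", {
  sp <- phantom_spec(shape = c(40, 40, 40), snr = Inf, inu_level = 0, seed = 2)
  cal1 <- calibrate_alpha(list(sp), grid = 1.2)
  expect_equal(cal1$alpha, 1.2)
  expect_error(calibrate_alpha(list(sp), grid = numeric(0)), "non-empty")
  expect_error(calibrate_alpha(list(), grid = 1.2), "PhantomSpec")

  # on the exact-intensity phantom every alpha whose threshold separates WM
  # (260) from WMSA (340) is perfect; the tie-break returns the smallest
  cal <- calibrate_alpha(list(sp), grid = seq(1.0, 1.8, by = 0.1))
  tab <- cal$table
  perfect <- tab$alpha[tab$accuracy == max(tab$accuracy)]
  expect_equal(cal$alpha, min(perfect))
  expect_equal(max(tab$accuracy), 1)
})

test_that("atlas guidance beats the CSF-blind whole-brain threshold", {
  ph <- fx_noisy64()
  res <- fx_noisy64_seg()
  truth_arr <- ph$labels$labels == 4L
  truth <- volume3d(array(as.numeric(truth_arr), dim = dim(truth_arr)))
  emask <- ph$labels$labels != 0L

  guided <- detect_wmsa(res$corrected, res$seg, detection_config(1.4))
  naive_seg <- label_volume(array(ifelse(ph$labels$labels != 0L, 3L, 0L),
                                  dim = dim(truth_arr)))
  naive <- detect_wmsa(ph$image, naive_seg,
                       detection_config(1.4, candidate = "brain"))
  dice_of <- function(det) detection_metrics(
    confusion_counts(truth, det, eval_mask = emask))$dice
  expect_gt(dice_of(guided), dice_of(naive))
})
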