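test_that("identical subjects with the identity backend give the common anatomy", {
  ph <- fx_clean48()
  imgs <- list(ph$image, ph$image, ph$image)
  segs <- list(ph$labels, ph$labels, ph$labels)
  atlas <- build_atlas(imgs, segs, representative_index = 1)
  # images are z-scored over the brain mask before averaging, so the template
  # is the common image up to that affine rescale: correlation 1 in-mask
  m <- ph$labels$labels != 0L
  expect_gt(cor(atlas$template$data[m], ph$image$data[m]), 1 - 1e-12)
  # priors are the one-hot maps of the common segmentation (up to the floor)
  for (cl in c("csf", "gm", "wm")) {
    code <- c(csf = 1L, gm = 2L, wm = 3L)[[cl]]
    onehot <- ph$labels$labels == code | (cl == "wm" & ph$labels$labels == 4L)
    expect_equal(atlas$priors[[cl]]$data[m], as.numeric(onehot[m]),
                 tolerance = 1e-5)
  }
})

test_that("priors average one-hot maps voxelwise and sum to 1 in-mask", {
  lab1 <- array(0L, dim = c(8, 8, 8)); lab1[3:6, 3:6, 3:6] <- 1L  # CSF block
  lab2 <- array(0L, dim = c(8, 8, 8)); lab2[3:6, 3:6, 3:6] <- 3L  # WM block
  img <- volume3d(array(rnorm(512), dim = c(8, 8, 8)))
  atlas <- build_atlas(list(img, img),
                       list(label_volume(lab1), label_volume(lab2)),
                       representative_index = 1)
  i <- 4; j <- 4; k <- 4
  expect_equal(atlas$priors$csf$data[i, j, k], 0.5, tolerance = 1e-5)
  expect_equal(atlas$priors$wm$data[i, j, k], 0.5, tolerance = 1e-5)
  expect_equal(atlas$priors$gm$data[i, j, k], 0, tolerance = 1e-5)

  s <- atlas$priors$csf$data + atlas$priors$gm$data + atlas$priors$wm$data
  m <- atlas$mask$data > 0.5
  expect_true(all(abs(s[m] - 1) < 1e-6))
})

test_that("atlas building validates inputs and is permutation-invariant", {
  ph <- fx_clean48()
  expect_error(build_atlas(list(ph$image), list(ph$labels)), "at least 2")
  expect_error(build_atlas(list(ph$image, ph$image), list(ph$labels)),
               "length mismatch")
  expect_error(build_atlas(list(ph$image, ph$image),
                           list(ph$labels, ph$labels),
                           representative_index = 5), "out of range")

  ph2 <- generate_phantom(phantom_spec(shape = c(48, 48, 48), snr = 25,
                                       inu_level = 0, seed = 2))
  a <- build_atlas(list(ph$image, ph2$image), list(ph$labels, ph2$labels),
                   representative_index = 1)
  b <- build_atlas(list(ph2$image, ph$image), list(ph2$labels, ph$labels),
                   representative_index = 2)
  expect_equal(a$template$data, b$template$data, tolerance = 1e-12)
  expect_equal(a$priors$wm$data, b$priors$wm$data, tolerance = 1e-12)
})

test_that("suggest_representative picks the median brain volume", {
  mk <- function(n) {
    lab <- array(0L, dim = c(10, 10, 10))
    lab[seq_len(n), 1, 1] <- 3L
    label_volume(lab)
  }
  segs <- list(mk(9), mk(3), mk(6))
  expect_equal(suggest_representative(segs), 3L)
})

test_that("warped priors reproduce a subject's own segmentation (one-hot round trip)", {
  ph <- fx_clean_lesion48()
  atlas <- build_atlas(list(ph$image, ph$image), list(ph$labels, ph$labels),
                       representative_index = 1)
  mu_atlas <- warp_priors_to_subject(atlas, ph$image, backend = "identity")
  # in-mask memberships sum to 1
  m <- neowmsa:::membership_mask(mu_atlas)
  s <- mu_atlas$probs[, , , 1] + mu_atlas$probs[, , , 2] + mu_atlas$probs[, , , 3]
  expect_true(all(abs(s[m] - 1) < 1e-6))
  seg <- hard_segmentation(mu_atlas)
  expect_identical(seg$labels, pmin(ph$labels$labels, 3L))  # WMSA folds into WM
})

test_that("atlases persist to a NIfTI directory and back", {
  ph <- fx_clean48()
  atlas <- build_atlas(list(ph$image, ph$image), list(ph$labels, ph$labels),
                       representative_index = 1)
  d <- tempfile()
  save_atlas(atlas, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  a2 <- load_atlas(d)
  expect_equal(a2$subject_count, 2L)
  expect_equal(a2$template$data, atlas$template$data, tolerance = 1e-5)
  expect_equal(a2$priors$wm$data, atlas$priors$wm$data, tolerance = 1e-5)
  expect_error(load_atlas(tempfile()), "manifest")
  unlink(d, recursive = TRUE)
})
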