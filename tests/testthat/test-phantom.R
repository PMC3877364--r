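test_that("noise-free, INU-free phantom has exact class mean intensities", {
  ph <- fx_clean_lesion48()
  img <- ph$image$data
  lab <- ph$labels$labels
  expect_true(all(img[lab == 3L] == 260))   # WM
  expect_true(all(img[lab == 4L] == 340))   # WMSA
  expect_true(all(img[lab == 1L] == 400))   # CSF
  expect_true(all(img[lab == 2L] == 190))   # GM
  expect_true(all(img[lab == 0L] == 0))
})

test_that("lesion handling: empty spec, load, containment, centre errors", {
  ph0 <- fx_clean48()
  expect_equal(sum(ph0$labels$labels == 4L), 0)

  ph <- fx_clean_lesion48()
  lab <- ph$labels$labels
  nwm <- sum(lab == 3L); nles <- sum(lab == 4L)
  expect_gt(nles, 0)
  # default diffuse load ~15% of WM
  expect_gt(nles / (nwm + nles), 0.08)
  expect_lt(nles / (nwm + nles), 0.25)

  # a lesion centred in background or CSF is an argument error
  bad <- phantom_spec(shape = c(48, 48, 48),
                      lesion_spec = data.frame(cx = 1, cy = 1, cz = 1,
                                               radius_mm = 3))
  expect_error(generate_phantom(bad), "white matter")
  out <- phantom_spec(shape = c(48, 48, 48),
                      lesion_spec = data.frame(cx = 200, cy = 1, cz = 1,
                                               radius_mm = 3))
  expect_error(generate_phantom(out), "outside")
})

test_that("SNR 15 phantom recovers the WM mean within 2% (Rician bias small)", {
  sp <- phantom_spec(shape = c(48, 48, 48), snr = 15, inu_level = 0,
                     lesion_spec = data.frame(), seed = 9)
  ph <- generate_phantom(sp)
  wm <- ph$image$data[ph$labels$labels == 3L]
  expect_lt(abs(mean(wm) - 260) / 260, 0.02)
})

test_that("INU field hits its stated range exactly and is smooth", {
  f <- make_inu_field(c(64, 64, 64), 0.2, seed = 3)
  expect_equal(min(f$data), 0.9)
  expect_equal(max(f$data), 1.1)
  f0 <- make_inu_field(c(16, 16, 16), 0)
  expect_true(all(f0$data == 1))
  expect_error(make_inu_field(c(16, 16, 16), 1.2), "inu_level")

  big <- make_inu_field(c(128, 128, 128), 0.2, seed = 5)$data
  madj <- mean(abs(big[-1, , ] - big[-128, , ]))
  expect_lt(madj, 0.01)
})

test_that("Rician noise model: limits, nonnegativity, empirical SD", {
  v <- volume3d(array(300, dim = c(30, 30, 30)))
  expect_identical(add_rician_noise(v, Inf, reference_mean = 300), v)
  expect_error(add_rician_noise(v, -1, reference_mean = 300), "positive")

  n <- add_rician_noise(v, 10, seed = 4, reference_mean = 300)
  expect_true(all(n$data >= 0))
  # on a constant region of value m with snr s, sd ~ m/s within 5%
  expect_lt(abs(sd(n$data) - 30) / 30, 0.05)
})

test_that("phantoms are seed-reproducible; labels are noise-invariant", {
  sp <- phantom_spec(shape = c(32, 32, 32), snr = 12, seed = 21)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$labels$labels, b$labels$labels)

  sp2 <- phantom_spec(shape = c(32, 32, 32), snr = 12, seed = 22)
  c_ <- generate_phantom(sp2)
  expect_identical(a$labels$labels, c_$labels$labels)   # same anatomy
  expect_false(identical(a$image$data, c_$image$data))  # different noise

  # ground-truth WMSA count invariant to noise level and INU
  for (snr in c(5, Inf)) for (inu in c(0, 0.2)) {
    ph <- generate_phantom(phantom_spec(shape = c(32, 32, 32), snr = snr,
                                        inu_level = inu, seed = 21))
    expect_equal(sum(ph$labels$labels == 4L), sum(a$labels$labels == 4L))
  }
})

test_that("phantom_spec validates its fields", {
  expect_error(phantom_spec(snr = 0), "snr")
  expect_error(phantom_spec(inu_level = 1), "inu_level")
  expect_error(phantom_spec(class_means = c(csf = 400, wm = 260, gm = 190)),
               "class_means")
  expect_error(phantom_spec(shape = c(8, 8)), "shape")
})
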