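test_that("identity backend returns exact identity maps", {
  ph <- fx_clean48()
  tr <- register(ph$image, ph$image, backend = "identity")
  for (dir in c("forward", "inverse"))
    expect_identical(apply_transform(tr, ph$image, dir)$data, ph$image$data)
  expect_identical(apply_transform(tr, ph$labels)$labels, ph$labels$labels)
})

test_that("registration validates its inputs", {
  a <- toy_volume(c(4, 4, 4))
  b <- toy_volume(c(5, 4, 4))
  expect_error(register(a, b), "shape")
  c_ <- volume3d(a$data, spacing = c(2, 1, 1))
  expect_error(register(a, c_), "spacing")
  tr <- register(a, a)
  expect_error(apply_transform(tr, a, "sideways"), "arg")
})

test_that("translation backend recovers a known shift", {
  ph <- fx_clean48()
  f <- ph$image
  m <- volume3d(array(0, dim = dim(f$data)), f$spacing)
  m$data[4:48, , ] <- f$data[1:45, , ]   # moving = fixed shifted +3 in x
  tr <- register(m, f, backend = "translation")
  expect_equal(tr$params$shift_vox, c(-3, 0, 0))
  w <- apply_transform(tr, m, "forward")
  mae <- mean(abs(w$data - f$data)) / diff(range(f$data))
  expect_lt(mae, 0.05)
  # round trip through forward + inverse is exact for integer translations
  rt <- apply_transform(tr, w, "inverse")
  expect_equal(rt$data[4:48, , ], m$data[4:48, , ], tolerance = 1e-12)
})

test_that("constant maps are invariant under any transform", {
  ph <- fx_clean48()
  const <- volume3d(array(7, dim = dim(ph$image$data)))
  m <- volume3d(array(0, dim = dim(ph$image$data)))
  m$data[3:48, , ] <- ph$image$data[1:46, , ]
  tr <- register(m, ph$image, backend = "translation", max_shift = 4)
  w <- apply_transform(tr, const, "forward")
  inner <- w$data[5:44, 5:44, 5:44]   # away from out-of-grid fill
  expect_true(all(abs(inner - 7) < 1e-9))
})

test_that("demons backend: self-registration is (near) zero displacement", {
  ph <- generate_phantom(phantom_spec(shape = c(24, 24, 24), snr = Inf,
                                      inu_level = 0, seed = 3))
  tr <- register(ph$image, ph$image, backend = "demons", levels = 1,
                 iter_per_level = 5)
  expect_lt(mean(abs(tr$disp_forward)), 1e-8)
})

test_that("demons backend: warps a shifted copy back and round-trips one-hot maps", {
  ph <- generate_phantom(phantom_spec(shape = c(32, 32, 32), snr = Inf,
                                      inu_level = 0, seed = 5))
  f <- ph$image
  m <- volume3d(array(0, dim = dim(f$data)), f$spacing)
  m$data[3:32, , ] <- f$data[1:30, , ]
  tr <- register(m, f, backend = "demons", levels = 2, iter_per_level = 25)
  w <- apply_transform(tr, m, "forward")
  expect_lt(mean(abs(w$data - f$data)) / diff(range(f$data)), 0.05)

  onehot <- volume3d(array(as.numeric(ph$labels$labels == 3L),
                           dim = dim(f$data)), f$spacing)
  rt <- apply_transform(tr, apply_transform(tr, onehot, "forward"), "inverse")
  a <- onehot$data > 0.5; b <- rt$data > 0.5
  dice <- 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gte(dice, 0.9)
})

test_that("transforms serialize to displacement-field NIfTI and back", {
  ph <- fx_clean48()
  m <- volume3d(array(0, dim = dim(ph$image$data)), ph$image$spacing)
  m$data[2:48, , ] <- ph$image$data[1:47, , ]
  tr <- register(m, ph$image, backend = "translation", max_shift = 3)
  d <- tempfile()
  save_transform(tr, d)
  tr2 <- load_transform(d)
  expect_equal(tr2$backend, "translation")
  expect_equal(tr2$disp_forward, tr$disp_forward, tolerance = 1e-6)
  w1 <- apply_transform(tr, m, "forward")
  w2 <- apply_transform(tr2, m, "forward")
  expect_equal(w1$data, w2$data, tolerance = 1e-5)

  # identity transforms round trip too
  ti <- register(ph$image, ph$image)
  d2 <- tempfile()
  save_transform(ti, d2)
  expect_identical(apply_transform(load_transform(d2), ph$image)$data,
                   ph$image$data)
  unlink(c(d, d2), recursive = TRUE)
})
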