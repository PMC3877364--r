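test_that("EM recovers exact class means on a noise-free phantom with flat priors", {
  ph <- fx_clean48()
  fit <- fit_unified_gmm(ph$image, flat_priors(ph),
                         seg_config(bias_order = 0, max_iter = 40))
  expect_lt(abs(class_mean(fit, "csf") - 400) / 400, 0.01)
  expect_lt(abs(class_mean(fit, "wm") - 260) / 260, 0.01)
  expect_lt(abs(class_mean(fit, "gm") - 190) / 190, 0.01)
})

test_that("unified membership sums to 1 in-mask; log-likelihood never decreases", {
  res <- fx_noisy64_seg()
  fit <- res$fit
  mu <- fit$membership
  m <- neowmsa:::membership_mask(mu)
  s <- 0
  for (i in 1:4) s <- s + mu$probs[, , , i]
  expect_true(all(abs(s[m] - 1) < 1e-6))
  ll <- fit$loglik
  expect_true(all(diff(ll) >= -1e-8 * abs(ll[-length(ll)])))
})

test_that("with no INU in the data, the estimated bias field is flat within 2%", {
  ph <- generate_phantom(phantom_spec(shape = c(48, 48, 48), snr = 20,
                                      inu_level = 0, seed = 13))
  res <- neowmsa:::segment_phantom(ph)
  m <- ph$labels$labels != 0L
  b <- res$fit$bias$data[m]
  b <- b / mean(b)   # global scale is absorbed by the mixture means
  expect_lt(max(abs(b - 1)), 0.02)
})

test_that("joint membership matches hand-computed values and exponent identities", {
  mk <- function(p1) {
    arr <- array(0, dim = c(1, 1, 1, 2))
    arr[1, 1, 1, ] <- c(p1, 1 - p1)
    membership_map(arr, c("csf", "gm"), role = "unified")
  }
  u <- mk(0.8); a <- mk(0.5)
  j <- joint_membership(u, a, fusion_params(1, 1))
  expect_equal(as.numeric(j$probs[1, 1, 1, ]), c(0.8, 0.2), tolerance = 1e-9)

  u2 <- mk(0.6); a2 <- mk(0.9)
  j2 <- joint_membership(u2, a2, fusion_params(1, 1))
  expect_equal(as.numeric(j2$probs[1, 1, 1, ]), c(0.54, 0.04) / 0.58,
               tolerance = 1e-9)

  # q = 0 reduces to the unified membership exactly
  j3 <- joint_membership(u2, a2, fusion_params(1, 0))
  expect_identical(as.numeric(j3$probs), as.numeric(u2$probs))
})

test_that("fusion properties: uniform atlas neutral, one-hot atlas decisive", {
  res <- fx_noisy64_seg()
  mu <- res$fit$membership
  d <- dim(mu$probs)[1:3]
  m <- neowmsa:::membership_mask(mu)

  unif <- array(0, dim = c(d, 4))
  for (i in 1:4) { s <- array(0, dim = d); s[m] <- 0.25; unif[, , , i] <- s }
  mu_unif <- membership_map(unif, mu$classes, role = "atlas")
  j <- joint_membership(mu, mu_unif, fusion_params(1, 1))
  expect_equal(j$probs[m], mu$probs[m], tolerance = 1e-9)

  onehot <- array(0, dim = c(d, 4))
  wm_i <- match("wm", mu$classes)
  s <- array(0, dim = d); s[m] <- 1; onehot[, , , wm_i] <- s
  mu_onehot <- membership_map(onehot, mu$classes, role = "atlas")
  j2 <- joint_membership(mu, mu_onehot, fusion_params(1, 1))
  seg <- hard_segmentation(j2)
  has_wm_support <- mu$probs[, , , wm_i] > 1e-12
  expect_true(all(seg$labels[m & has_wm_support] == 3L))
})

test_that("class-set and grid mismatches are argument errors", {
  arr2 <- array(0.5, dim = c(2, 2, 2, 2))
  arr3 <- array(1 / 3, dim = c(2, 2, 2, 3))
  a <- membership_map(arr2, c("csf", "gm"))
  b <- membership_map(arr3, c("csf", "gm", "wm"))
  expect_error(joint_membership(a, b), "class sets")
  c_ <- membership_map(array(0.5, dim = c(3, 2, 2, 2)), c("csf", "gm"))
  expect_error(joint_membership(a, c_), "grid")
  expect_error(fusion_params(0, 0), "p \\+ q")
})

test_that("hard segmentation: one-hot identity, tie rule, 'other' to background", {
  d <- c(2, 2, 1)
  arr <- array(0, dim = c(d, 4))
  cls <- c("csf", "gm", "wm", "other")
  arr[1, 1, 1, ] <- c(1, 0, 0, 0)       # pure CSF
  arr[2, 1, 1, ] <- c(0.5, 0.5, 0, 0)   # CSF/GM tie -> CSF (lower code)
  arr[1, 2, 1, ] <- c(0, 0.2, 0.75, 0.05)
  arr[2, 2, 1, ] <- c(0, 0, 0.1, 0.9)   # other -> background
  seg <- hard_segmentation(membership_map(arr, cls))
  expect_equal(as.vector(seg$labels), c(1L, 1L, 3L, 0L))
})

test_that("joint segmentation agrees with ground truth on a lesion-free phantom", {
  ph <- generate_phantom(phantom_spec(shape = c(48, 48, 48), snr = 15,
                                      inu_level = 0.2,
                                      lesion_spec = data.frame(), seed = 31))
  res <- neowmsa:::segment_phantom(ph)
  m <- ph$labels$labels != 0L
  agree <- mean(res$seg$labels[m] == ph$labels$labels[m])
  expect_gte(agree, 0.95)
})

test_that("degenerate inputs are rejected", {
  ph <- fx_clean48()
  pri <- flat_priors(ph)
  expect_error(fit_unified_gmm(ph$image, pri,
                               mask = array(FALSE, dim = dim(ph$image$data))),
               "empty mask")
  expect_error(seg_config(tol = 0), "tol")
  expect_error(seg_config(gaussians_per_class = c(gm = 0, wm = 2, csf = 2,
                                                  other = 5)), "counts")
})
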