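# Shared fixtures, built in code and cached for the test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# noise-free, INU-free, lesion-free 48^3 phantom (exact class intensities)
fx_clean48 <- function() fixture("clean48", function()
  generate_phantom(phantom_spec(shape = c(48, 48, 48), snr = Inf,
                                inu_level = 0, lesion_spec = data.frame(),
                                seed = 1)))

# noise-free, INU-free phantom with the default diffuse lesions
fx_clean_lesion48 <- function() fixture("clean_lesion48", function()
  generate_phantom(phantom_spec(shape = c(48, 48, 48), snr = Inf,
                                inu_level = 0, seed = 1)))

# SNR 15, 20% INU, default lesions (the realistic case), 64^3
fx_noisy64 <- function() fixture("noisy64", function()
  generate_phantom(phantom_spec(shape = c(64, 64, 64), snr = 15,
                                inu_level = 0.2, seed = 7)))

# full segmentation of the noisy phantom via the calibration path
fx_noisy64_seg <- function() fixture("noisy64_seg", function()
  neowmsa:::segment_phantom(fx_noisy64()))

# flat (uniform in-mask) csf/gm/wm priors for a phantom
flat_priors <- function(ph) {
  d <- dim(ph$image$data)
  m <- ph$labels$labels != 0L
  arr <- array(0, dim = c(d, 3))
  for (i in 1:3) {
    s <- array(0, dim = d)
    s[m] <- 1 / 3
    arr[, , , i] <- s
  }
  membership_map(arr, c("csf", "gm", "wm"), role = "atlas",
                 spacing = ph$image$spacing, affine = ph$image$affine)
}

# weight-averaged mean intensity of a fitted tissue class
class_mean <- function(fit, class) {
  p <- fit$params$classes[[class]]
  sum(p$weights * p$means)
}

# tiny deterministic scalar volume
toy_volume <- function(dims = c(6, 5, 4), spacing = c(1, 1, 1), seed = 42) {
  set.seed(seed)
  volume3d(array(stats::rnorm(prod(dims)), dim = dims), spacing = spacing)
}
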