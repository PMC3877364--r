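# Procedural preterm-brain phantom: nested ellipsoid anatomy with ventricles,
# diffuse WMSA lesions carved from WM, a smooth multiplicative INU field and
# Rician noise at a stated SNR.  The phantom is the calibration/validation
# substrate for the alpha-threshold detector.

#' Phantom specification
#'
#' Defaults encode the simulation world used for calibration: T2-weighted
#' class mean intensities CSF 400, WM 260, GM 190, WMSA 340 (neonatal T2:
#' WM brighter than GM), an INU field spanning 0.9--1.1 at the default 20%
#' level, and diffuse periventricular + centrum semiovale lesions occupying
#' roughly 15% of the white matter (moderate diffuse DEHSI).
#'
#' @param shape integer length-3 grid dimensions (default 96^3).
#' @param spacing voxel size in mm (isotropic scalar or length-3).
#' @param class_means named numeric: mean intensity for `csf`, `wm`, `gm`,
#'   `wmsa` (arbitrary T2 units, all > 0).
#' @param snr signal-to-noise ratio: mean brain signal divided by the noise
#'   standard deviation; `Inf` for noise-free.
#' @param inu_level fractional intensity nonuniformity range (0.2 = field in
#'   0.9--1.1); must satisfy `0 <= inu_level < 1`.
#' @param lesion_spec data frame with columns `cx, cy, cz` (0-based voxel
#'   centre) and `radius_mm`, or `NULL` for the default diffuse lesion set,
#'   or an empty data frame for a lesion-free phantom.
#' @param seed integer seed controlling INU and noise realizations.
#' @return An object of class `PhantomSpec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 96),
                         spacing = 1,
                         class_means = c(csf = 400, wm = 260, gm = 190,
                                         wmsa = 340),
                         snr = 15,
                         inu_level = 0.2,
                         lesion_spec = NULL,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("shape must be 3 integers >= 16")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  req <- c("csf", "wm", "gm", "wmsa")
  if (!all(req %in% names(class_means)) || any(class_means[req] <= 0))
    stop("class_means must name positive csf, wm, gm, wmsa intensities")
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop("snr must be a positive number (Inf allowed)")
  if (!is.numeric(inu_level) || inu_level < 0 || inu_level >= 1)
    stop("inu_level must lie in [0, 1)")
  if (is.null(lesion_spec))
    lesion_spec <- default_lesion_spec(shape, spacing)
  lesion_spec <- as.data.frame(lesion_spec)
  if (nrow(lesion_spec) > 0 &&
      !all(c("cx", "cy", "cz", "radius_mm") %in% names(lesion_spec)))
    stop("lesion_spec needs columns cx, cy, cz, radius_mm")
  structure(list(shape = shape, spacing = spacing,
                 class_means = class_means[req], snr = snr,
                 inu_level = inu_level, lesion_spec = lesion_spec,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# Ellipsoid anatomy parameters, as fractions of the grid half-extent (brain)
# and of the WM compartment semi-axes (ventricles, lesions).  Fixed once; all
# phantom geometry derives from these.
PHANTOM_GEOM <- list(
  brain_frac = c(0.875, 0.75, 0.667),   # brain semi-axes / half-extent
  csf_shell  = 0.055,                   # peripheral CSF shell (fraction)
  gm_shell   = 0.19,                    # cortical GM shell (fraction)
  vent_off   = c(0.29, 0.0, -0.08),     # ventricle centres / WM semi-axes
  vent_semi  = c(0.18, 0.55, 0.31)      # ventricle semi-axes / WM semi-axes
)

phantom_geometry <- function(shape, spacing) {
  half <- shape * spacing / 2
  ctr <- (shape - 1) / 2 * spacing
  brain <- PHANTOM_GEOM$brain_frac * half
  gm_outer <- brain * (1 - PHANTOM_GEOM$csf_shell)
  wm_outer <- brain * (1 - PHANTOM_GEOM$gm_shell)
  vents <- lapply(c(-1, 1), function(s) {
    list(centre = ctr + c(s, 1, 1) * PHANTOM_GEOM$vent_off * wm_outer,
         semi = PHANTOM_GEOM$vent_semi * wm_outer)
  })
  list(centre = ctr, brain = brain, gm_outer = gm_outer, wm_outer = wm_outer,
       vents = vents)
}

#' Default diffuse WMSA lesion set
#'
#' Four large periventricular blobs plus two centrum semiovale blobs, sized so
#' that after carving to the WM compartment they occupy roughly 15% of WM at
#' the default geometry.
#'
#' @param shape,spacing as in [phantom_spec()].
#' @return data frame with columns `cx, cy, cz, radius_mm`.
#' @export
default_lesion_spec <- function(shape, spacing = 1) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  g <- phantom_geometry(as.integer(shape), spacing)
  a <- g$wm_outer
  rmin <- min(a)
  mm <- rbind(
    g$centre + c( 0.45,  0.42, 0) * a,
    g$centre + c(-0.45,  0.42, 0) * a,
    g$centre + c( 0.45, -0.42, 0) * a,
    g$centre + c(-0.45, -0.42, 0) * a,
    g$centre + c( 0.26,  0.0,  0.52) * a,
    g$centre + c(-0.26,  0.0,  0.52) * a)
  data.frame(cx = mm[, 1] / spacing[1], cy = mm[, 2] / spacing[2],
             cz = mm[, 3] / spacing[3],
             radius_mm = c(rep(0.36 * rmin, 4), rep(0.30 * rmin, 2)))
}

#' Generate a simulated preterm T2-weighted brain with WMSA ground truth
#'
#' Builds the label volume (nested ellipsoids: peripheral CSF shell, cortical
#' GM, WM interior, ventricular CSF, plus WMSA blobs carved from WM), assigns
#' each voxel its class mean intensity, applies the multiplicative INU field,
#' then Rician noise.  Ground-truth labels are fixed before any intensity
#' corruption.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `image` (`Volume3D`), `labels` (`LabelVolume`),
#'   and `inu` (the applied INU field, `Volume3D`).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "PhantomSpec")) stop("spec must be a PhantomSpec")
  d <- spec$shape; sp <- spec$spacing
  g <- phantom_geometry(d, sp)
  gr <- voxel_grid(d)
  x <- gr[, 1] * sp[1] - g$centre[1]
  y <- gr[, 2] * sp[2] - g$centre[2]
  z <- gr[, 3] * sp[3] - g$centre[3]
  inside <- function(semi, off = c(0, 0, 0)) {
    ((x - off[1]) / semi[1])^2 + ((y - off[2]) / semi[2])^2 +
      ((z - off[3]) / semi[3])^2 <= 1
  }
  lab <- integer(prod(d))
  lab[inside(g$brain)] <- TISSUE_CODES[["csf"]]
  lab[inside(g$gm_outer)] <- TISSUE_CODES[["gm"]]
  lab[inside(g$wm_outer)] <- TISSUE_CODES[["wm"]]
  for (v in g$vents)
    lab[inside(v$semi, v$centre - g$centre)] <- TISSUE_CODES[["csf"]]
  wm_pre <- lab == TISSUE_CODES[["wm"]]
  ls <- spec$lesion_spec
  if (nrow(ls) > 0) {
    for (i in seq_len(nrow(ls))) {
      cmm <- c(ls$cx[i] * sp[1], ls$cy[i] * sp[2], ls$cz[i] * sp[3]) - g$centre
      cidx <- round(c(ls$cx[i], ls$cy[i], ls$cz[i]))
      if (any(cidx < 0) || any(cidx > d - 1))
        stop(sprintf("lesion %d centre outside the volume", i))
      if (!wm_pre[1 + cidx[1] + d[1] * (cidx[2] + d[2] * cidx[3])])
        stop(sprintf("lesion %d centre does not lie in white matter", i))
      ball <- (x - cmm[1])^2 + (y - cmm[2])^2 + (z - cmm[3])^2 <=
        ls$radius_mm[i]^2
      lab[ball & wm_pre] <- TISSUE_CODES[["wmsa"]]
    }
  }
  labels <- label_volume(array(lab, dim = d), spacing = sp)

  # intensity lookup by label code: 0 bg, 1 csf, 2 gm, 3 wm, 4 wmsa
  lut <- c(0,spec$class_means[["csf"]], spec$class_means[["gm"]],
           spec$class_means[["wm"]], spec$class_means[["wmsa"]])
  img <- array(lut[lab + 1L], dim = d)
  inu <- make_inu_field(d, spec$inu_level, seed = spec$seed)
  img <- img * inu$data
  vol <- volume3d(img, spacing = sp)
  if (is.finite(spec$snr)) {
    ref <- mean(img[lab != 0L])
    vol <- add_rician_noise(vol, snr = spec$snr, seed = spec$seed + 1L,
                            reference_mean = ref)
  }
  list(image = vol, labels = labels, inu = inu)
}

#' Smooth multiplicative intensity-nonuniformity field
#'
#' Gaussian-smoothed white noise, affinely rescaled so the field minimum and
#' maximum are exactly `1 - inu_level/2` and `1 + inu_level/2`.
#'
#' @param shape grid dimensions.
#' @param inu_level fractional range (0.2 gives 0.9--1.1); `0` gives a
#'   constant field of 1.
#' @param seed integer seed.
#' @param fwhm_frac smoothing kernel FWHM as a fraction of the grid extent
#'   per axis (default 1/4).
#' @return A `Volume3D` INU field.
#' @export
make_inu_field <- function(shape, inu_level, seed = 1L, fwhm_frac = 0.25) {
  shape <- as.integer(shape)
  if (inu_level < 0 || inu_level >= 1) stop("inu_level must lie in [0, 1)")
  if (inu_level == 0)
    return(volume3d(array(1, dim = shape)))
  # the field is band-limited far below voxel scale, so synthesize it on a
  # coarse grid (>= 4 samples per FWHM) and upsample trilinearly
  ds <- max(1L, min(as.integer(floor(fwhm_frac * min(shape) / 4)),
                    as.integer(min(shape) %/% 24)))
  cs <- if (ds > 1L) as.integer(floor((shape - 1) / ds)) + 2L else shape
  field <- with_seed(seed, array(stats::rnorm(prod(cs)), dim = cs))
  sigma <- fwhm_frac * shape / 2.3548 / ds
  field <- gaussian_smooth3d(field, sigma)
  if (ds > 1L) {
    g <- voxel_grid(shape)
    pts <- cbind(g[, 1] / ds, g[, 2] / ds, g[, 3] / ds)
    field <- array(sample_array3d(field, pts, "linear"), dim = shape)
  }
  rng <- range(field)
  lo <- 1 - inu_level / 2; hi <- 1 + inu_level / 2
  if (rng[2] - rng[1] < .Machine$double.eps) {
    field[] <- 1
  } else {
    field <- lo + (field - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
  }
  volume3d(field)
}

#' Add Rician noise to a volume
#'
#' Each output voxel is `sqrt((v + n1)^2 + n2^2)` with `n1`, `n2` independent
#' zero-mean Gaussians of standard deviation `reference_mean / snr` (the
#' magnitude-MRI noise model).
#'
#' @param vol a `Volume3D`.
#' @param snr positive SNR; `Inf` returns the input unchanged.
#' @param seed integer seed.
#' @param reference_mean mean signal used to set the noise SD (caller
#'   supplies, typically the mean over the brain mask).
#' @return A `Volume3D` with non-negative intensities.
#' @export
add_rician_noise <- function(vol, snr, seed = 1L, reference_mean) {
  if (!inherits(vol, "Volume3D")) stop("vol must be a Volume3D")
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop("snr must be positive")
  if (is.infinite(snr)) return(vol)
  if (missing(reference_mean) || !is.finite(reference_mean) ||
      reference_mean <= 0)
    stop("reference_mean must be a positive finite number")
  sigma <- reference_mean / snr
  n <- length(vol$data)
  noisy <- with_seed(seed, {
    n1 <- stats::rnorm(n, sd = sigma)
    n2 <- stats::rnorm(n, sd = sigma)
    sqrt((as.numeric(vol$data) + n1)^2 + n2^2)
  })
  volume3d(array(noisy, dim = dim(vol$data)), spacing = vol$spacing,
           affine = vol$affine)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
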