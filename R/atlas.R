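# Group-averaged probabilistic atlas: two-pass template averaging plus
# averaged tissue probability maps, and warping of the priors into an
# individual subject's space (the inverse-transform dataflow).

#' Construct / validate a probabilistic atlas object
#'
#' @param template `Volume3D` averaged anatomy.
#' @param priors named list of `Volume3D` probability maps for `csf`, `gm`,
#'   `wm`; each in \[0,1\] and summing to 1 (within 1e-6) at every in-mask
#'   voxel.
#' @param mask `Volume3D` binary template brain mask.
#' @param subject_count number of subjects averaged.
#' @param meta list of provenance fields stored in the manifest.
#' @return An object of class `ProbabilisticAtlas`.
#' @export
probabilistic_atlas <- function(template, priors, mask, subject_count,
                                meta = list()) {
  stopifnot(inherits(template, "Volume3D"))
  if (!all(c("csf", "gm", "wm") %in% names(priors)))
    stop("priors must name csf, gm and wm maps")
  for (p in priors) {
    stop_if_grid_mismatch(template, p, "template and priors")
    if (min(p$data) < -1e-9 || max(p$data) > 1 + 1e-9)
      stop("prior probabilities must lie in [0,1]")
  }
  s <- priors$csf$data + priors$gm$data + priors$wm$data
  m <- mask$data > 0.5
  if (any(abs(s[m] - 1) > 1e-6))
    stop("priors must sum to 1 at every in-mask voxel")
  structure(list(template = template, priors = priors[c("csf", "gm", "wm")],
                 mask = mask, subject_count = as.integer(subject_count),
                 meta = meta),
            class = "ProbabilisticAtlas")
}

#' @export
print.ProbabilisticAtlas <- function(x, ...) {
  cat(sprintf("<ProbabilisticAtlas %s, %d subjects, spacing %s mm>\n",
              paste(dim(x$template$data), collapse = "x"), x$subject_count,
              paste(signif(x$template$spacing, 3), collapse = "x")))
  invisible(x)
}

#' Suggest a representative subject
#'
#' Deterministic proxy for the manual "representative anatomy" choice: the
#' subject whose brain-mask volume is the cohort median (lower median for
#' even cohorts).
#'
#' @param segmentations list of `LabelVolume`.
#' @return integer index into `segmentations`.
#' @export
suggest_representative <- function(segmentations) {
  vols <- vapply(segmentations, function(s)
    sum(s$labels != 0L) * prod(s$spacing), numeric(1))
  ord <- order(vols)
  ord[ceiling(length(vols) / 2)]
}

#' Build a probabilistic atlas from segmented subject images
#'
#' Two-pass template construction: every subject is registered to the chosen
#' representative and the warped images averaged into a tentative template;
#' every subject is then registered to that tentative template and averaged
#' again into the final template.  The pass-2 transforms are applied to each
#' subject's one-hot tissue maps (WMSA ground truth, if present, counts as
#' WM: the atlas encodes CSF/GM/WM only) and averaged into the priors, which
#' are floored at `prior_floor` and renormalized voxelwise inside the
#' template brain mask.  Images are z-scored over their brain mask before
#' averaging, so subjects with different intensity scales average sensibly.
#'
#' @param images list of `Volume3D` (>= 2).
#' @param segmentations list of matching `LabelVolume`.
#' @param representative_index index of the representative subject (see
#'   [suggest_representative()]).
#' @param backend registration backend name, see [register()].
#' @param target_mm working isotropic resolution (default 1 mm).
#' @param prior_floor floor applied to priors before renormalization.
#' @return A `ProbabilisticAtlas`.
#' @export
build_atlas <- function(images, segmentations,
                        representative_index = suggest_representative(segmentations),
                        backend = "identity", target_mm = 1,
                        prior_floor = 1e-6) {
  if (length(images) < 2L) stop("atlas construction needs at least 2 subjects")
  if (length(images) != length(segmentations))
    stop("images and segmentations must pair up (length mismatch)")
  if (representative_index < 1 || representative_index > length(images))
    stop("representative_index out of range")
  images <- lapply(images, resample_isotropic, target_mm = target_mm)
  segmentations <- lapply(segmentations, resample_isotropic,
                          target_mm = target_mm)
  for (i in seq_along(images))
    stop_if_grid_mismatch(images[[i]], segmentations[[i]],
                          sprintf("subject %d image/segmentation", i))
  zimgs <- mapply(function(im, seg) {
    m <- seg$labels != 0L
    if (!any(m)) stop("a subject has an empty brain mask")
    mu <- mean(im$data[m]); sd <- stats::sd(im$data[m])
    if (!is.finite(sd) || sd == 0) sd <- 1
    volume3d((im$data - mu) / sd, im$spacing, im$affine)
  }, images, segmentations, SIMPLIFY = FALSE)

  rep_img <- zimgs[[representative_index]]
  pass1 <- lapply(zimgs, function(im) {
    tr <- register(im, rep_img, backend = backend)
    apply_transform(tr, im, "forward")$data
  })
  tentative <- volume3d(Reduce(`+`, pass1) / length(pass1),
                        rep_img$spacing, rep_img$affine)

  n <- length(zimgs)
  acc_img <- 0
  acc_prior <- list(csf = 0, gm = 0, wm = 0)
  acc_mask <- 0
  for (i in seq_len(n)) {
    tr <- register(zimgs[[i]], tentative, backend = backend)
    acc_img <- acc_img + apply_transform(tr, zimgs[[i]], "forward")$data
    lab <- segmentations[[i]]$labels
    onehot <- list(csf = lab == TISSUE_CODES[["csf"]],
                   gm  = lab == TISSUE_CODES[["gm"]],
                   wm  = lab == TISSUE_CODES[["wm"]] |
                         lab == TISSUE_CODES[["wmsa"]])
    for (cl in names(onehot)) {
      v <- volume3d(array(as.numeric(onehot[[cl]]), dim = dim(lab)),
                    segmentations[[i]]$spacing, segmentations[[i]]$affine)
      acc_prior[[cl]] <- acc_prior[[cl]] +
        apply_transform(tr, v, "forward", interpolation = "linear")$data
    }
    mk <- volume3d(array(as.numeric(lab != 0L), dim = dim(lab)),
                   segmentations[[i]]$spacing, segmentations[[i]]$affine)
    acc_mask <- acc_mask + apply_transform(tr, mk, "forward",
                                           interpolation = "linear")$data
  }
  template <- volume3d(acc_img / n, tentative$spacing, tentative$affine)
  mask_arr <- (acc_mask / n) > 0.5
  priors <- lapply(acc_prior, function(a) a / n)
  priors <- normalize_priors(priors, mask_arr, prior_floor)
  priors <- lapply(priors, volume3d, spacing = template$spacing,
                   affine = template$affine)
  probabilistic_atlas(template, priors,
                      volume3d(array(as.numeric(mask_arr), dim = dim(mask_arr)),
                               template$spacing, template$affine),
                      subject_count = n,
                      meta = list(backend = backend, target_mm = target_mm,
                                  representative_index = representative_index,
                                  intensity_normalization = "zscore-brainmask",
                                  prior_floor = prior_floor))
}

# floor priors in-mask, renormalize voxelwise; outside mask set to 0
normalize_priors <- function(priors, mask_arr, floor = 1e-6) {
  s <- 0
  priors <- lapply(priors, function(a) {
    a <- pmax(pmin(a, 1), 0)
    a[mask_arr] <- pmax(a[mask_arr], floor)
    a[!mask_arr] <- 0
    a
  })
  for (a in priors) s <- s + a
  s[s == 0] <- 1
  lapply(priors, function(a) a / s)
}

#' Warp atlas priors into a subject's space
#'
#' Registers the subject image to the atlas template and applies the inverse
#' transform to each tissue probability map, yielding subject-space spatial
#' priors (the atlas membership function).
#'
#' @param atlas a `ProbabilisticAtlas`.
#' @param subject `Volume3D` at atlas resolution and grid shape.
#' @param backend registration backend name.
#' @param prior_floor floor before renormalization.
#' @return A `MembershipMap` with role `"atlas"` and classes csf/gm/wm.
#' @export
warp_priors_to_subject <- function(atlas, subject, backend = "identity",
                                   prior_floor = 1e-6) {
  if (!inherits(atlas, "ProbabilisticAtlas")) stop("atlas must be a ProbabilisticAtlas")
  if (!inherits(subject, "Volume3D")) stop("subject must be a Volume3D")
  tr <- tryCatch(register(subject, atlas$template, backend = backend),
                 error = function(e)
                   stop(sprintf("registration to atlas failed: %s",
                                conditionMessage(e))))
  warped <- lapply(atlas$priors, function(p)
    apply_transform(tr, p, "inverse", interpolation = "linear")$data)
  wmask <- apply_transform(tr, atlas$mask, "inverse",
                           interpolation = "nearest")$data > 0.5
  warped <- normalize_priors(warped, wmask, prior_floor)
  arr <- array(0, dim = c(dim(subject$data), 3))
  for (i in 1:3) arr[, , , i] <- warped[[c("csf", "gm", "wm")[i]]]
  membership_map(arr, classes = c("csf", "gm", "wm"), role = "atlas",
                 spacing = subject$spacing, affine = subject$affine)
}

#' One-hot (optionally smoothed) prior maps from a label volume
#'
#' Builds subject-space spatial priors directly from a tissue segmentation:
#' one-hot CSF/GM/WM maps (WMSA counts as WM), optionally Gaussian-smoothed
#' to emulate atlas-like soft priors, floored and renormalized in-mask.
#' This is the prior source for the phantom calibration study, where the
#' anatomy is known and spatial normalization error is deliberately excluded.
#'
#' @param labels a `LabelVolume`.
#' @param smooth_mm Gaussian smoothing FWHM in mm (0 = hard one-hot priors).
#' @param prior_floor floor before renormalization.
#' @return A `MembershipMap` with role `"atlas"`.
#' @export
make_prior_maps <- function(labels, smooth_mm = 0, prior_floor = 1e-6) {
  if (!inherits(labels, "LabelVolume")) stop("labels must be a LabelVolume")
  lab <- labels$labels
  mask_arr <- lab != 0L
  onehot <- list(csf = as.numeric(lab == 1L),
                 gm  = as.numeric(lab == 2L),
                 wm  = as.numeric(lab == 3L | lab == 4L))
  onehot <- lapply(onehot, array, dim = dim(lab))
  if (smooth_mm > 0) {
    sigma_vox <- smooth_mm / 2.3548 / labels$spacing
    onehot <- lapply(onehot, gaussian_smooth3d, sigma_vox = sigma_vox)
  }
  pri <- normalize_priors(onehot, mask_arr, prior_floor)
  arr <- array(0, dim = c(dim(lab), 3))
  for (i in 1:3) arr[, , , i] <- pri[[c("csf", "gm", "wm")[i]]]
  membership_map(arr, classes = c("csf", "gm", "wm"), role = "atlas",
                 spacing = labels$spacing, affine = labels$affine)
}

#' Save an atlas as a directory of NIfTI files plus a JSON manifest
#' @param atlas a `ProbabilisticAtlas`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_atlas <- function(atlas, dir) {
  if (!inherits(atlas, "ProbabilisticAtlas")) stop("atlas must be a ProbabilisticAtlas")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(atlas$template, file.path(dir, "template.nii.gz"))
  write_nifti(atlas$mask, file.path(dir, "mask.nii.gz"))
  for (cl in names(atlas$priors))
    write_nifti(atlas$priors[[cl]], file.path(dir, sprintf("prior_%s.nii.gz", cl)))
  manifest <- c(list(subject_count = atlas$subject_count,
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                atlas$meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load an atlas saved by [save_atlas()]
#' @param dir atlas directory.
#' @return A `ProbabilisticAtlas`.
#' @export
load_atlas <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path))
    stop(sprintf("not an atlas directory (missing manifest.json): %s", dir))
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  template <- read_nifti(file.path(dir, "template.nii.gz"))
  mask <- read_nifti(file.path(dir, "mask.nii.gz"))
  priors <- lapply(c(csf = "csf", gm = "gm", wm = "wm"), function(cl)
    read_nifti(file.path(dir, sprintf("prior_%s.nii.gz", cl))))
  meta <- manifest[setdiff(names(manifest), c("subject_count", "created"))]
  probabilistic_atlas(template, priors, mask,
                      subject_count = manifest$subject_count, meta = meta)
}
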