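# Spatial normalization behind a pluggable backend contract.
#
# The atlas workflow only requires an invertible transform object that can
# warp volumes in either direction (the reciprocity that diffeomorphic
# registration provides).  Three backends are shipped: "identity",
# "translation" (integer shift by FFT cross-correlation) and "demons"
# (a lightweight multi-resolution Gaussian-regularized demons).  All expose
# the same Transform contract and displacement-field serialization.

#' @rdname register
#' @export
registration_backends <- function() c("identity", "translation", "demons")

new_transform <- function(backend, params, disp_fwd, disp_inv, spacing, affine,
                          tolerance) {
  structure(list(backend = backend, params = params,
                 disp_forward = disp_fwd, disp_inverse = disp_inv,
                 spacing = spacing, affine = affine, tolerance = tolerance),
            class = "Transform")
}

#' @export
print.Transform <- function(x, ...) {
  cat(sprintf("<Transform backend=%s, round-trip tolerance %.3g>\n",
              x$backend, x$tolerance))
  invisible(x)
}

#' Register a moving volume to a fixed volume
#'
#' Returns a `Transform` whose forward map resamples the moving volume onto
#' the fixed grid and whose inverse map goes back.  Both images must share
#' grid shape and spacing (resample first if needed).
#'
#' @param moving,fixed `Volume3D` objects on the same grid.
#' @param backend one of `"identity"`, `"translation"`, `"demons"`.
#' @param ... backend options: `max_shift` (translation, voxels, default 1/4
#'   of the grid), `levels`, `iter_per_level`, `smooth_sigma` (demons).
#' @return A `Transform`.
#' @export
register <- function(moving, fixed, backend = "identity", ...) {
  if (!inherits(moving, "Volume3D") || !inherits(fixed, "Volume3D"))
    stop("moving and fixed must be Volume3D objects")
  if (!identical(dim(moving$data), dim(fixed$data)))
    stop("moving and fixed must share grid shape (resample first)")
  if (max(abs(moving$spacing - fixed$spacing)) > 1e-6)
    stop("moving and fixed must share voxel spacing (resample first)")
  backend <- match.arg(backend, registration_backends())
  switch(backend,
    identity = new_transform("identity", list(), NULL, NULL,
                             fixed$spacing, fixed$affine, tolerance = 0),
    translation = register_translation(moving, fixed, ...),
    demons = register_demons(moving, fixed, ...))
}

register_translation <- function(moving, fixed, max_shift = NULL, ...) {
  d <- dim(fixed$data)
  if (is.null(max_shift)) max_shift <- pmax(2L, d %/% 4L)
  max_shift <- rep_len(as.integer(max_shift), 3L)
  # circular cross-correlation via FFT; argmax over the allowed shift window
  fm <- stats::fft(moving$data)
  ff <- stats::fft(fixed$data)
  cc <- Re(stats::fft(Conj(fm) * ff, inverse = TRUE)) / prod(d)
  # cc[s+1] = sum_u moving(u) * fixed(u + s)  (circular, 0-based s)
  shifts <- lapply(1:3, function(ax) {
    s <- c(0:(d[ax] - 1))
    ifelse(s > d[ax] / 2, s - d[ax], s)
  })
  allow <- array(TRUE, dim = d)
  for (ax in 1:3) {
    ok <- abs(shifts[[ax]]) <= max_shift[ax]
    allow <- sweep(allow, ax, ok, `&`)
  }
  cc[!allow] <- -Inf
  best <- arrayInd(which.max(cc), d)
  t_vox <- sapply(1:3, function(ax) shifts[[ax]][best[ax]])
  # fixed(u) ~ moving(u - t) => forward warp samples moving at u - t
  disp_fwd <- constant_disp(d, -t_vox)
  disp_inv <- constant_disp(d, t_vox)
  new_transform("translation", list(shift_vox = t_vox), disp_fwd, disp_inv,
                fixed$spacing, fixed$affine, tolerance = 1e-6)
}

constant_disp <- function(d, t_vox) {
  disp <- array(0, dim = c(d, 3))
  for (ax in 1:3) disp[, , , ax] <- t_vox[ax]
  disp
}

register_demons <- function(moving, fixed, levels = 2, iter_per_level = 30,
                            smooth_sigma = 1.5, step = 2, ...) {
  rng <- max(fixed$data) - min(fixed$data)
  if (rng <= 0) rng <- 1
  d <- dim(fixed$data)
  disp <- NULL
  for (lev in seq(levels, 1)) {
    f <- 2^(lev - 1)
    dl <- pmax(8L, as.integer(ceiling(d / f)))
    fx <- shrink_array(fixed$data, dl)
    mv <- shrink_array(moving$data, dl)
    disp <- if (is.null(disp)) array(0, dim = c(dl, 3)) else
      upsample_disp(disp, dl)
    g <- voxel_grid(dl)
    for (it in seq_len(iter_per_level)) {
      pts <- g + matrix(disp, ncol = 3)
      w <- array(sample_array3d(mv, pts, "linear"), dim = dl)
      diffi <- fx - w
      grad <- array_gradient(w)
      gmag2 <- grad[, , , 1]^2 + grad[, , , 2]^2 + grad[, , , 3]^2
      denom <- gmag2 + (diffi / (step * rng / 10))^2
      denom[denom < 1e-12] <- 1e-12
      fac <- diffi / denom
      upd <- array(0, dim = c(dl, 3))
      for (ax in 1:3) {
        u <- fac * grad[, , , ax]
        u[abs(u) > 2] <- sign(u[abs(u) > 2]) * 2   # cap per-iteration step
        upd[, , , ax] <- gaussian_smooth3d(u, smooth_sigma)
      }
      disp <- disp + upd
      for (ax in 1:3)
        disp[, , , ax] <- gaussian_smooth3d(disp[, , , ax], smooth_sigma / 2)
    }
    if (!all(dl == d) && lev == 1) disp <- upsample_disp(disp, d)
  }
  if (!all(dim(disp)[1:3] == d)) disp <- upsample_disp(disp, d)
  disp_inv <- invert_disp(disp)
  new_transform("demons",
                list(levels = levels, iter_per_level = iter_per_level,
                     smooth_sigma = smooth_sigma),
                disp, disp_inv, fixed$spacing, fixed$affine, tolerance = 0.15)
}

shrink_array <- function(arr, dl) {
  d <- dim(arr)
  if (all(dl == d)) return(arr)
  g <- voxel_grid(dl)
  sc <- (d - 1) / pmax(dl - 1, 1)
  pts <- cbind(g[, 1] * sc[1], g[, 2] * sc[2], g[, 3] * sc[3])
  array(sample_array3d(arr, pts, "linear"), dim = dl)
}

upsample_disp <- function(disp, dnew) {
  dold <- dim(disp)[1:3]
  out <- array(0, dim = c(dnew, 3))
  g <- voxel_grid(dnew)
  sc_idx <- (dold - 1) / pmax(dnew - 1, 1)
  sc_val <- (dnew - 1) / pmax(dold - 1, 1)
  pts <- cbind(g[, 1] * sc_idx[1], g[, 2] * sc_idx[2], g[, 3] * sc_idx[3])
  for (ax in 1:3)
    out[, , , ax] <- array(sample_array3d(disp[, , , ax], pts, "linear"),
                           dim = dnew) * sc_val[ax]
  out
}

array_gradient <- function(arr) {
  d <- dim(arr)
  g <- array(0, dim = c(d, 3))
  g[2:(d[1] - 1), , , 1] <- (arr[3:d[1], , ] - arr[1:(d[1] - 2), , ]) / 2
  g[, 2:(d[2] - 1), , 2] <- (arr[, 3:d[2], ] - arr[, 1:(d[2] - 2), ]) / 2
  g[, , 2:(d[3] - 1), 3] <- (arr[, , 3:d[3]] - arr[, , 1:(d[3] - 2)]) / 2
  g
}

# fixed-point inversion of a displacement field: v(u) = -disp(u + v(u))
invert_disp <- function(disp, iters = 15) {
  d <- dim(disp)[1:3]
  g <- voxel_grid(d)
  v <- matrix(0, nrow = nrow(g), ncol = 3)
  dmat <- matrix(disp, ncol = 3)
  for (it in seq_len(iters)) {
    pts <- g + v
    for (ax in 1:3)
      v[, ax] <- -sample_array3d(array(dmat[, ax], dim = d), pts, "linear")
  }
  array(v, dim = c(d, 3))
}

#' Apply a transform to a volume
#'
#' @param t a `Transform` from [register()].
#' @param vol `Volume3D` or `LabelVolume` on the transform's grid.
#' @param direction `"forward"` (moving -> fixed space) or `"inverse"`.
#' @param interpolation `"linear"` or `"nearest"`; defaults to linear for
#'   scalar volumes and nearest for labels.
#' @return Warped volume of the same type as `vol`.
#' @export
apply_transform <- function(t, vol, direction = c("forward", "inverse"),
                            interpolation = NULL) {
  if (!inherits(t, "Transform")) stop("t must be a Transform")
  direction <- match.arg(direction)
  if (!inherits(vol, c("Volume3D", "LabelVolume")))
    stop("vol must be a Volume3D or LabelVolume")
  is_lab <- inherits(vol, "LabelVolume")
  if (is.null(interpolation)) interpolation <- if (is_lab) "nearest" else "linear"
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  disp <- if (direction == "forward") t$disp_forward else t$disp_inverse
  arr <- vol_data(vol)
  if (is.null(disp)) {
    out <- arr
  } else {
    d <- dim(arr)
    if (!all(dim(disp)[1:3] == d))
      stop("volume grid does not match the transform's grid")
    pts <- voxel_grid(d) + matrix(disp, ncol = 3)
    out <- array(sample_array3d(arr, pts, interpolation), dim = d)
  }
  if (is_lab)
    label_volume(array(as.integer(round(out)), dim = dim(arr)),
                 vol$spacing, vol$affine)
  else
    volume3d(out, vol$spacing, vol$affine)
}

#' Serialize a transform as displacement-field NIfTI files
#'
#' Writes one scalar NIfTI per displacement component and direction
#' (`fwd_dx` ... `inv_dz`, in voxel units) plus a JSON manifest.
#'
#' @param t a `Transform`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_transform <- function(t, dir) {
  if (!inherits(t, "Transform")) stop("t must be a Transform")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comp <- c("dx", "dy", "dz")
  for (dn in c("forward", "inverse")) {
    disp <- t[[paste0("disp_", dn)]]
    if (is.null(disp)) next
    for (ax in 1:3)
      write_nifti(volume3d(disp[, , , ax], t$spacing, t$affine),
                  file.path(dir, sprintf("%s_%s.nii.gz",
                                         substr(dn, 1, 3), comp[ax])))
  }
  meta <- list(backend = t$backend, params = t$params,
               tolerance = t$tolerance, spacing = t$spacing,
               identity = is.null(t$disp_forward))
  jsonlite::write_json(meta, file.path(dir, "transform.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a transform saved by [save_transform()]
#' @param dir directory written by [save_transform()].
#' @return A `Transform`.
#' @export
load_transform <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "transform.json"),
                              simplifyVector = TRUE)
  if (isTRUE(meta$identity)) {
    return(new_transform(meta$backend, meta$params, NULL, NULL,
                         as.numeric(meta$spacing), diag(4), meta$tolerance))
  }
  read_disp <- function(prefix) {
    comps <- lapply(c("dx", "dy", "dz"), function(cn)
      read_nifti(file.path(dir, sprintf("%s_%s.nii.gz", prefix, cn))))
    d <- dim(comps[[1]]$data)
    disp <- array(0, dim = c(d, 3))
    for (ax in 1:3) disp[, , , ax] <- comps[[ax]]$data
    list(disp = disp, spacing = comps[[1]]$spacing,
         affine = comps[[1]]$affine)
  }
  fwd <- read_disp("for")
  inv <- read_disp("inv")
  new_transform(meta$backend, meta$params, fwd$disp, inv$disp,
                fwd$spacing, fwd$affine, meta$tolerance)
}
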