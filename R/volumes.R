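# Core volumetric containers and resampling.
#
# Conventions (fixed package-wide): voxel indices are 0-based in all geometry
# computations; the third array axis is axial (inferior -> superior); the
# affine maps 0-based voxel indices to RAS world coordinates in mm.

#' Construct a 3-D scalar volume
#'
#' A `Volume3D` is a 3-D numeric array together with its voxel spacing (mm)
#' and a 4x4 voxel-to-world affine (RAS convention, 0-based voxel indices).
#'
#' @param data 3-D numeric array of intensities (all values finite).
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(c(spacing, 1))`.
#' @return An object of class `Volume3D`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as_array3d(data)
  if (!all(is.finite(data))) stop("Volume3D data must be finite everywhere")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- check_affine(affine)
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "Volume3D")
}

#' Construct a 3-D tissue label volume
#'
#' Integer tissue codes: 0 background, 1 CSF, 2 GM, 3 WM, 4 WMSA.
#'
#' @param labels 3-D array of integer codes in 0..4.
#' @param spacing,affine as in [volume3d()].
#' @return An object of class `LabelVolume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), affine = NULL) {
  labels <- as_array3d(labels)
  if (any(is.na(labels)) || any(labels != round(labels)))
    stop("labels must be integral and non-missing")
  if (any(labels < 0 | labels > 4))
    stop("label codes must lie in {0 (bg), 1 (CSF), 2 (GM), 3 (WM), 4 (WMSA)}")
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- check_affine(affine)
  structure(list(labels = labels, spacing = spacing, affine = affine),
            class = "LabelVolume")
}

#' @export
print.Volume3D <- function(x, ...) {
  cat(sprintf("<Volume3D %s, spacing %s mm, range [%.4g, %.4g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.LabelVolume <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:4,
                      labels = c("bg", "CSF", "GM", "WM", "WMSA")))
  cat(sprintf("<LabelVolume %s, spacing %s mm>\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  print(tab)
  invisible(x)
}

# standard class codes, used throughout
TISSUE_CODES <- c(bg = 0L, csf = 1L, gm = 2L, wm = 3L, wmsa = 4L)

as_array3d <- function(x) {
  x <- unclass(x)
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop("expected a rank-3 array")
  storage.mode(x) <- if (is.integer(x)) "integer" else "double"
  x
}

check_affine <- function(a) {
  a <- as.matrix(a)
  if (!all(dim(a) == c(4, 4)) || any(!is.finite(a)))
    stop("affine must be a finite 4x4 matrix")
  if (!isTRUE(all.equal(a[4, ], c(0, 0, 0, 1))))
    stop("last affine row must be (0,0,0,1)")
  a
}

vol_data <- function(vol) if (inherits(vol, "LabelVolume")) vol$labels else vol$data

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(vol_data(a)), dim(vol_data(b))) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop(sprintf("%s must share grid (dim/spacing/affine)", what))
  invisible(TRUE)
}

#' Trilinear / nearest sampling of a 3-D array at fractional voxel coordinates
#'
#' Coordinates are 0-based; points outside the grid return `fill`.
#'
#' @param arr 3-D array.
#' @param coords n x 3 matrix of 0-based voxel coordinates.
#' @param method "linear" or "nearest".
#' @param fill value for out-of-grid points.
#' @param clamp if `TRUE`, out-of-grid coordinates are clamped to the grid
#'   edge (edge replication) instead of returning `fill`; used by resampling,
#'   where the target grid's outermost voxel centres can sit up to half a
#'   voxel beyond the source centres.
#' @return numeric vector of length n.
#' @keywords internal
sample_array3d <- function(arr, coords, method = c("linear", "nearest"),
                           fill = 0, clamp = FALSE) {
  method <- match.arg(method)
  d <- dim(arr)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  if (clamp) {
    x <- pmin.int(pmax.int(x, 0), d[1] - 1)
    y <- pmin.int(pmax.int(y, 0), d[2] - 1)
    z <- pmin.int(pmax.int(z, 0), d[3] - 1)
  }
  out <- rep.int(as.numeric(fill), nrow(coords))
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  if (method == "nearest") {
    ii <- as.integer(pmin.int(pmax.int(round(x), 0), d[1] - 1))
    jj <- as.integer(pmin.int(pmax.int(round(y), 0), d[2] - 1))
    kk <- as.integer(pmin.int(pmax.int(round(z), 0), d[3] - 1))
    out[inside] <- arr[1L + ii + d[1] * (jj + d[2] * kk)]
    return(out)
  }
  x0 <- pmin.int(floor(x), d[1] - 2); y0 <- pmin.int(floor(y), d[2] - 2)
  z0 <- pmin.int(floor(z), d[3] - 2)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  d1 <- d[1]; d12 <- d[1] * d[2]
  base <- 1L + as.integer(x0) + as.integer(d1) * as.integer(y0) +
    as.integer(d12) * as.integer(z0)
  gx <- 1 - fx
  c00 <- arr[base]                  * gx + arr[base + 1L]             * fx
  c10 <- arr[base + d1]             * gx + arr[base + d1 + 1L]        * fx
  c01 <- arr[base + d12]            * gx + arr[base + d12 + 1L]       * fx
  c11 <- arr[base + d12 + d1]       * gx + arr[base + d12 + d1 + 1L]  * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

# full 0-based index grid for given dims, as an n x 3 matrix
voxel_grid <- function(d) {
  cbind(rep_len(0:(d[1] - 1), prod(d)),
        rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]),
        rep(0:(d[3] - 1), each = d[1] * d[2]))
}

#' Resample a volume to isotropic resolution
#'
#' Scalar volumes are interpolated trilinearly, label volumes by nearest
#' neighbour.  The occupied world extent is preserved to within one voxel.
#'
#' @param vol a `Volume3D` or `LabelVolume`.
#' @param target_mm target isotropic voxel size in mm (> 0).
#' @return Same type as `vol`, with spacing `(target_mm, target_mm, target_mm)`.
#' @export
resample_isotropic <- function(vol, target_mm) {
  if (!inherits(vol, c("Volume3D", "LabelVolume")))
    stop("vol must be a Volume3D or LabelVolume")
  if (!is.numeric(target_mm) || length(target_mm) != 1L ||
      !is.finite(target_mm) || target_mm <= 0)
    stop("target_mm must be a single positive number")
  arr <- vol_data(vol)
  d <- dim(arr)
  if (max(abs(vol$spacing - target_mm)) < 1e-9) return(vol)
  scale <- target_mm / vol$spacing
  nd <- pmax(2L, as.integer(ceiling(d * vol$spacing / target_mm)))
  g <- voxel_grid(nd)
  src <- cbind(g[, 1] * scale[1], g[, 2] * scale[2], g[, 3] * scale[3])
  is_lab <- inherits(vol, "LabelVolume")
  vals <- sample_array3d(arr, src, method = if (is_lab) "nearest" else "linear",
                         clamp = TRUE)
  new_affine <- vol$affine %*% diag(c(scale, 1))
  out <- array(vals, dim = nd)
  if (is_lab)
    label_volume(out, spacing = rep(target_mm, 3), affine = new_affine)
  else
    volume3d(out, spacing = rep(target_mm, 3), affine = new_affine)
}

#' Binary brain mask from a label volume
#'
#' @param labels a `LabelVolume`.
#' @return A `Volume3D` with value 1 where the label is non-background.
#' @export
brain_mask <- function(labels) {
  if (!inherits(labels, "LabelVolume")) stop("labels must be a LabelVolume")
  volume3d(array(as.numeric(labels$labels != 0L), dim = dim(labels$labels)),
           spacing = labels$spacing, affine = labels$affine)
}

#' Separable Gaussian smoothing of a 3-D array
#'
#' Edge handling is by edge replication; `sigma_vox` is in voxels per axis.
#'
#' @keywords internal
gaussian_smooth3d <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, as.integer(ceiling(3 * s)))
    k <- exp(-0.5 * ((-half:half) / s)^2)
    k <- k / sum(k)
    arr <- smooth_axis(arr, ax, k, half)
  }
  arr
}

smooth_axis <- function(arr, ax, k, half) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  dp <- dim(a)
  m <- matrix(a, nrow = dp[1])
  # replicate-pad along the filtered axis so stats::filter has full support
  mp <- rbind(m[rep(1L, half), , drop = FALSE], m,
              m[rep(nrow(m), half), , drop = FALSE])
  f <- stats::filter(mp, k, sides = 2)
  f <- f[(half + 1):(half + dp[1]), , drop = FALSE]
  a <- array(as.numeric(f), dim = dp)
  aperm(a, order(perm))
}
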