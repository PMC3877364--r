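# Intensity-model tissue membership: per-class Gaussian mixtures combined
# with spatial priors by Bayes' rule, a shared smooth multiplicative bias
# field modelled on a 3-D discrete-cosine basis (log-intensity domain), and
# the joint probabilistic fusion of the intensity-model membership with
# warped atlas priors.

#' Per-voxel class membership map
#'
#' @param probs 4-D array `x * y * z * class` of probabilities; inside the
#'   brain mask each voxel's probabilities sum to 1 (within 1e-6), outside
#'   they may be all zero.
#' @param classes character vector naming the 4th-dimension slices (subset of
#'   `csf`, `gm`, `wm`, `other`).
#' @param role one of `"unified"`, `"atlas"`, `"joint"`.
#' @param spacing,affine grid geometry.
#' @return An object of class `MembershipMap`.
#' @export
membership_map <- function(probs, classes, role = c("unified", "atlas", "joint"),
                           spacing = c(1, 1, 1), affine = NULL) {
  role <- match.arg(role)
  if (length(dim(probs)) != 4L || dim(probs)[4] != length(classes))
    stop("probs must be a 4-D array with one slice per class")
  if (!all(classes %in% c("csf", "gm", "wm", "other")) ||
      anyDuplicated(classes))
    stop("classes must be distinct names among csf, gm, wm, other")
  if (min(probs) < -1e-9 || max(probs) > 1 + 1e-9)
    stop("membership probabilities must lie in [0,1]")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(probs = probs, classes = classes, role = role,
                 spacing = spacing, affine = check_affine(affine)),
            class = "MembershipMap")
}

#' @export
print.MembershipMap <- function(x, ...) {
  cat(sprintf("<MembershipMap [%s] %s, classes: %s>\n", x$role,
              paste(dim(x$probs)[1:3], collapse = "x"),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

membership_mask <- function(mm) {
  s <- 0
  for (i in seq_along(mm$classes)) s <- s + mm$probs[, , , i]
  s > 0.5
}

#' Append an "other" class to a csf/gm/wm membership map
#'
#' The atlas priors cover CSF/GM/WM; the intensity model also carries an
#' `other` class.  This gives the atlas map a small flat `other` prior so the
#' two class sets match for fusion.
#'
#' @param mm a `MembershipMap` without an `other` class.
#' @param weight flat prior mass assigned to `other` in-mask (default 0.02).
#' @return A `MembershipMap` with classes `csf, gm, wm, other`.
#' @export
add_other_class <- function(mm, weight = 0.02) {
  if ("other" %in% mm$classes) return(mm)
  m <- membership_mask(mm)
  d <- dim(mm$probs)[1:3]
  arr <- array(0, dim = c(d, length(mm$classes) + 1))
  for (i in seq_along(mm$classes))
    arr[, , , i] <- mm$probs[, , , i] * (1 - weight)
  oth <- array(0, dim = d); oth[m] <- weight
  arr[, , , length(mm$classes) + 1] <- oth
  membership_map(arr, c(mm$classes, "other"), role = mm$role,
                 spacing = mm$spacing, affine = mm$affine)
}

#' Segmentation configuration
#'
#' Defaults follow the unified-segmentation convention: 3 Gaussians for GM,
#' 2 for WM, 2 for CSF and 5 for everything else; a 4x4x4 discrete-cosine
#' bias basis (DC term excluded, so the mixture means carry the global
#' scale); EM stops when the relative log-likelihood change drops below
#' `tol`.
#'
#' @param gaussians_per_class named integer vector (`gm`, `wm`, `csf`,
#'   `other`), all >= 1.
#' @param bias_order per-axis DCT basis order (0 disables bias estimation).
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance (> 0).
#' @param var_floor_frac variance floor, as a fraction of the in-mask
#'   intensity range (guards degenerate noise-free fits).
#' @return An object of class `SegmentationConfig`.
#' @export
seg_config <- function(gaussians_per_class = c(gm = 3L, wm = 2L, csf = 2L,
                                               other = 5L),
                       bias_order = 4L, max_iter = 50L, tol = 1e-5,
                       var_floor_frac = 1e-3) {
  req <- c("csf", "gm", "wm", "other")
  if (!all(req %in% names(gaussians_per_class)) ||
      any(gaussians_per_class[req] < 1))
    stop("gaussians_per_class must name csf, gm, wm, other with counts >= 1")
  if (tol <= 0) stop("tol must be > 0")
  if (bias_order < 0 || max_iter < 1) stop("invalid bias_order or max_iter")
  structure(list(gaussians_per_class = as.integer(gaussians_per_class[req]) |>
                   stats::setNames(req),
                 bias_order = as.integer(bias_order),
                 max_iter = as.integer(max_iter), tol = tol,
                 var_floor_frac = var_floor_frac),
            class = "SegmentationConfig")
}

#' Fusion parameters
#'
#' Exponents controlling the relative contribution of the intensity-model
#' membership (`p`) and the atlas membership (`q`) in the joint membership.
#' Both default to 1 (equal weights).
#'
#' @param p,q non-negative reals with `p + q > 0`.
#' @return An object of class `FusionParams`.
#' @export
fusion_params <- function(p = 1, q = 1) {
  if (p < 0 || q < 0 || p + q <= 0)
    stop("p and q must be non-negative with p + q > 0")
  structure(list(p = p, q = q), class = "FusionParams")
}

# 3-D DCT basis (tensor products of per-axis cosines, DC term removed),
# evaluated at the given 0-based voxel coordinates. Returns n x (order^3 - 1).
dct_basis <- function(coords, d, order) {
  ax_basis <- lapply(1:3, function(ax) {
    v <- coords[, ax]
    m <- matrix(0, nrow = length(v), ncol = order)
    for (k in 0:(order - 1))
      m[, k + 1] <- cos(pi * k * (v + 0.5) / d[ax])
    m
  })
  nb <- order^3 - 1
  X <- matrix(0, nrow = nrow(coords), ncol = nb)
  col <- 0L
  for (kz in 0:(order - 1)) for (ky in 0:(order - 1)) for (kx in 0:(order - 1)) {
    if (kx == 0 && ky == 0 && kz == 0) next
    col <- col + 1L
    X[, col] <- ax_basis[[1]][, kx + 1] * ax_basis[[2]][, ky + 1] *
      ax_basis[[3]][, kz + 1]
  }
  X
}

# Deterministic component initialization: sample quantiles of the masked
# intensities, read off rank segments that encode the neonatal T2 brightness
# ordering GM < WM < CSF.  The segments are deliberately asymmetric: WM's
# upper end reaches into the hyperintense band so its second Gaussian can
# capture WMSA, and CSF's segment sits at the very top of the distribution.
INIT_SEGMENTS <- list(gm = c(0.05, 0.28), wm = c(0.45, 0.80),
                      csf = c(0.92, 0.99), other = c(0.02, 0.98))

init_gmm_params <- function(y, classes, K) {
  sd_glob <- stats::sd(y)
  if (!is.finite(sd_glob) || sd_glob == 0) sd_glob <- max(abs(y), 1) * 0.01
  params <- list()
  for (j in seq_along(classes)) {
    cl <- classes[j]
    k <- K[j]
    seg <- INIT_SEGMENTS[[cl]]
    probs <- if (k == 1) mean(seg) else seq(seg[1], seg[2], length.out = k)
    mu <- stats::quantile(y, probs, type = 1, names = FALSE)
    # tissue classes start tight so components stay in their intensity band;
    # "other" stays broad as the catch-all
    sd0 <- if (cl == "other") sd_glob else sd_glob / 3
    params[[cl]] <- list(weights = rep(1 / k, k), means = mu,
                         vars = rep(sd0^2, k))
  }
  params
}

#' Fit the prior-guided Gaussian mixture with bias-field correction
#'
#' EM over per-class Gaussian mixtures.  The E-step combines class
#' likelihoods with the spatial priors by Bayes' rule; the M-step updates
#' component weights, means and variances in closed form and then re-fits the
#' shared log-domain bias field by weighted least squares on the DCT basis.
#' A bias update is only accepted if it does not decrease the penalized
#' log-likelihood, so the objective is non-decreasing across iterations.
#' Initialization is deterministic (prior-weighted intensity quantiles), so
#' the fit needs no seed.
#'
#' @param image `Volume3D`, masked (non-brain voxels 0) or accompanied by
#'   `mask`.
#' @param priors `MembershipMap` of spatial priors (role "atlas"); classes
#'   csf/gm/wm (an `other` channel is added internally) or csf/gm/wm/other.
#' @param cfg a [seg_config()].
#' @param mask optional logical array; defaults to the priors' support.
#' @return A list of class `UnifiedFit`:
#'   `params` (per-class weights/means/vars + `bias_coef`),
#'   `membership` (`MembershipMap`, role "unified"),
#'   `bias` (`Volume3D`, 1 outside the mask),
#'   `corrected` (`Volume3D`, bias-corrected intensities),
#'   `loglik` (trace), `converged`, `n_iter`.
#' @export
fit_unified_gmm <- function(image, priors, cfg = seg_config(), mask = NULL) {
  if (!inherits(image, "Volume3D")) stop("image must be a Volume3D")
  if (!inherits(priors, "MembershipMap")) stop("priors must be a MembershipMap")
  if (!identical(dim(image$data), dim(priors$probs)[1:3]))
    stop("image and priors must share grid")
  if (!"other" %in% priors$classes) priors <- add_other_class(priors)
  classes <- c("csf", "gm", "wm", "other")
  pidx <- match(classes, priors$classes)
  if (any(is.na(pidx))) stop("priors must cover classes csf, gm, wm")
  if (is.null(mask)) mask <- membership_mask(priors)
  mask <- mask & is.finite(image$data)
  n <- sum(mask)
  if (n == 0) stop("empty mask: no voxels to segment")
  d <- dim(image$data)
  midx <- which(mask)
  y <- as.numeric(image$data[midx])
  # strictly positive intensities are required for the log-domain bias model
  ypos_floor <- max(stats::quantile(y[y > 0], 0.001, names = FALSE), 1e-6)
  y <- pmax(y, ypos_floor)
  P <- matrix(0, nrow = n, ncol = 4)
  for (j in 1:4) P[, j] <- priors$probs[, , , pidx[j]][midx]
  P <- P / pmax(rowSums(P), 1e-12)

  K <- cfg$gaussians_per_class[classes]
  params <- init_gmm_params(y, classes, K)
  ncomp <- sum(K)
  comp_class <- rep(seq_along(classes), times = K)

  use_bias <- cfg$bias_order > 0
  if (use_bias) {
    coords <- voxel_grid(d)[midx, , drop = FALSE]
    X <- dct_basis(coords, d, cfg$bias_order)
    nb <- ncol(X)
  }
  bcoef <- if (use_bias) rep(0, ncol(X)) else numeric(0)
  logb <- rep(0, n)

  rng_y <- diff(range(y))
  var_floor <- max((cfg$var_floor_frac * rng_y)^2, 1e-12)

  comp_dens <- function(x, params) {
    # n x ncomp matrix of prior-weighted component densities
    dens <- matrix(0, nrow = n, ncol = ncomp)
    cc <- 0L
    for (j in seq_along(classes)) {
      pj <- params[[classes[j]]]
      for (k in seq_len(K[j])) {
        cc <- cc + 1L
        dens[, cc] <- P[, j] * pj$weights[k] *
          stats::dnorm(x, pj$means[k], sqrt(pj$vars[k]))
      }
    }
    dens
  }
  loglik_of <- function(logb_, params) {
    x <- y * exp(-logb_)
    dens <- comp_dens(x, params)
    tot <- rowSums(dens)
    sum(log(pmax(tot, 1e-300))) - sum(logb_)
  }

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(cfg$max_iter)) {
    x <- y * exp(-logb)
    dens <- comp_dens(x, params)
    tot <- rowSums(dens)
    ll <- sum(log(pmax(tot, 1e-300))) - sum(logb)
    R <- dens / pmax(tot, 1e-300)

    # M-step: closed-form Gaussian updates
    cc <- 0L
    for (j in seq_along(classes)) {
      pj <- params[[classes[j]]]
      rsum_class <- 0
      for (k in seq_len(K[j])) rsum_class <- rsum_class + sum(R[, cc + k])
      for (k in seq_len(K[j])) {
        r <- R[, cc + k]
        rs <- sum(r)
        if (rs > 1e-8) {
          mu <- sum(r * x) / rs
          v <- sum(r * (x - mu)^2) / rs
          pj$means[k] <- mu
          pj$vars[k] <- max(v, var_floor)
          pj$weights[k] <- rs / max(rsum_class, 1e-300)
        } else {
          pj$weights[k] <- rs / max(rsum_class, 1e-300)
        }
      }
      pj$weights <- pj$weights / sum(pj$weights)
      params[[classes[j]]] <- pj
      cc <- cc + K[j]
    }

    # bias M-step: log-domain weighted least squares, guarded so the
    # objective cannot decrease
    if (use_bias) {
      mu_vec <- unlist(lapply(params[classes], `[[`, "means"))
      var_vec <- unlist(lapply(params[classes], `[[`, "vars"))
      mu_hat <- as.numeric(R %*% mu_vec)
      mu_hat <- pmax(mu_hat, ypos_floor)
      w <- as.numeric(R %*% (mu_vec^2 / var_vec))
      t_i <- log(y) - log(mu_hat)
      bc_new <- tryCatch(
        solve(crossprod(X, X * w) + diag(1e-8 * mean(w), nb),
              crossprod(X, w * t_i)),
        error = function(e) NULL)
      if (!is.null(bc_new)) {
        logb_new <- as.numeric(X %*% bc_new)
        if (loglik_of(logb_new, params) >= loglik_of(logb, params)) {
          bcoef <- as.numeric(bc_new)
          logb <- logb_new
        }
      }
    }

    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < cfg$tol * (abs(ll_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  if (!converged)
    warning(sprintf("EM did not converge within %d iterations", cfg$max_iter))

  # final memberships at the converged parameters
  x <- y * exp(-logb)
  dens <- comp_dens(x, params)
  tot <- pmax(rowSums(dens), 1e-300)
  probs <- array(0, dim = c(d, 4))
  cc <- 0L
  for (j in seq_along(classes)) {
    pr <- rowSums(dens[, cc + seq_len(K[j]), drop = FALSE]) / tot
    slab <- array(0, dim = d)
    slab[midx] <- pr
    probs[, , , j] <- slab
    cc <- cc + K[j]
  }
  bias_arr <- array(1, dim = d)
  bias_arr[midx] <- exp(logb)
  corr_arr <- array(0, dim = d)
  corr_arr[midx] <- x
  gmm <- structure(list(classes = params, bias_coef = bcoef,
                        bias_order = cfg$bias_order), class = "GMMParams")
  structure(list(
    params = gmm,
    membership = membership_map(probs, classes, role = "unified",
                                spacing = image$spacing, affine = image$affine),
    bias = volume3d(bias_arr, image$spacing, image$affine),
    corrected = volume3d(corr_arr, image$spacing, image$affine),
    loglik = ll_trace, converged = converged, n_iter = length(ll_trace)),
    class = "UnifiedFit")
}

#' @export
print.GMMParams <- function(x, ...) {
  for (cl in names(x$classes)) {
    p <- x$classes[[cl]]
    cat(sprintf("%-6s means: %s | sds: %s | weights: %s\n", cl,
                paste(signif(p$means, 4), collapse = ", "),
                paste(signif(sqrt(p$vars), 4), collapse = ", "),
                paste(signif(p$weights, 3), collapse = ", ")))
  }
  invisible(x)
}

#' Joint probabilistic membership (intensity model x atlas fusion)
#'
#' Per voxel and class:
#' `mu_joint(j) = mu_unified(j)^p * mu_atlas(j)^q / sum_c mu_unified(c)^p * mu_atlas(c)^q`.
#' Where the denominator underflows (all products zero), the voxel falls back
#' to the unified membership; the count of such voxels is attached as
#' attribute `n_fallback`.
#'
#' @param mu_unified,mu_atlas `MembershipMap`s with identical class sets and
#'   grids.
#' @param fp a [fusion_params()].
#' @return A `MembershipMap` with role `"joint"`.
#' @export
joint_membership <- function(mu_unified, mu_atlas, fp = fusion_params()) {
  if (!inherits(mu_unified, "MembershipMap") ||
      !inherits(mu_atlas, "MembershipMap"))
    stop("memberships must be MembershipMap objects")
  if (!identical(sort(mu_unified$classes), sort(mu_atlas$classes)))
    stop("class sets of the two memberships do not match")
  if (!identical(dim(mu_unified$probs)[1:3], dim(mu_atlas$probs)[1:3]))
    stop("memberships must share grid")
  if (!inherits(fp, "FusionParams")) fp <- do.call(fusion_params, as.list(fp))
  classes <- mu_unified$classes
  aidx <- match(classes, mu_atlas$classes)
  d <- dim(mu_unified$probs)[1:3]
  ncl <- length(classes)
  num <- array(0, dim = c(d, ncl))
  for (i in seq_len(ncl))
    num[, , , i] <- mu_unified$probs[, , , i]^fp$p *
      mu_atlas$probs[, , , aidx[i]]^fp$q
  den <- array(0, dim = d)
  for (i in seq_len(ncl)) den <- den + num[, , , i]
  inmask <- membership_mask(mu_unified)
  bad <- inmask & (den < 1e-300 | !is.finite(den))
  den[den < 1e-300 | !is.finite(den)] <- 1
  out <- array(0, dim = c(d, ncl))
  for (i in seq_len(ncl)) {
    slab <- num[, , , i] / den
    if (any(bad)) slab[bad] <- mu_unified$probs[, , , i][bad]
    out[, , , i] <- slab
  }
  res <- membership_map(out, classes, role = "joint",
                        spacing = mu_unified$spacing,
                        affine = mu_unified$affine)
  attr(res, "n_fallback") <- sum(bad)
  res
}

#' Hard segmentation by per-voxel argmax
#'
#' Ties are broken toward the lowest tissue code; the `other` class maps to
#' background (code 0).  Voxels with no membership mass are background.
#'
#' @param mu a `MembershipMap`.
#' @return A `LabelVolume` with codes 0 (bg/other), 1 (CSF), 2 (GM), 3 (WM).
#' @export
hard_segmentation <- function(mu) {
  if (!inherits(mu, "MembershipMap")) stop("mu must be a MembershipMap")
  code_of <- c(other = 0L, csf = 1L, gm = 2L, wm = 3L)
  present <- intersect(names(code_of), mu$classes)  # ascending code order
  d <- dim(mu$probs)[1:3]
  m <- matrix(0, nrow = prod(d), ncol = length(present))
  for (i in seq_along(present))
    m[, i] <- mu$probs[, , , match(present[i], mu$classes)]
  pick <- max.col(m, ties.method = "first")  # first max = lowest code
  lab <- code_of[present][pick]
  lab[rowSums(m) < 0.5] <- 0L
  label_volume(array(as.integer(lab), dim = d), mu$spacing, mu$affine)
}
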