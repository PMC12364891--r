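#' Multiscale vesselness parameters
#'
#' Scales are Gaussian standard deviations in mm (converted to voxels per
#' axis via the volume's voxel size, so anisotropic grids are handled
#' consistently). `alpha_f` weighs the plate-vs-line discriminator,
#' `beta_f` the blob discriminator, and `c_f` the structure-vs-noise term;
#' when `c_f` is `NULL` it defaults, per scale, to half the maximum
#' Hessian Frobenius norm. Bright-on-dark polarity is assumed (vessels
#' brighter than tissue, as for inflow contrast at 7T).
#'
#' @param scales positive ascending numeric vector of Gaussian sigmas (mm).
#' @param alpha_f,beta_f positive discriminator weights.
#' @param c_f structure-noise weight, or `NULL` for the per-scale default.
#' @return A list of class `hv_vesselness_params`.
#' @export
vesselness_params <- function(scales = c(0.5, 0.75, 1.0, 1.5),
                              alpha_f = 0.5, beta_f = 0.5, c_f = NULL) {
  if (!length(scales) || any(scales <= 0) || is.unsorted(scales, strictly = FALSE))
    stop("vesselness_params: scales must be nonempty, positive, ascending", call. = FALSE)
  if (alpha_f <= 0 || beta_f <= 0)
    stop("vesselness_params: alpha_f and beta_f must be positive", call. = FALSE)
  structure(list(scales = as.numeric(scales), alpha_f = alpha_f,
                 beta_f = beta_f, c_f = c_f),
            class = "hv_vesselness_params")
}

# --- separable Gaussian-derivative filtering ------------------------------

# correlation weights for order-0/1/2 Gaussian derivative at sigma (voxels),
# moment-corrected so polynomial responses are exact: order 0 sums to 1,
# order 1 responds 1 to f(x)=x, order 2 responds 2 to f(x)=x^2.
gaussian_deriv_kernel <- function(sigma, order) {
  r <- max(2L, ceiling(4 * sigma))
  t <- seq.int(-r, r)
  g <- exp(-t^2 / (2 * sigma^2))
  switch(as.character(order),
    "0" = g / sum(g),
    "1" = { w <- t * g; w / sum(t * w) },
    "2" = { mu <- sum(t^2 * g) / sum(g)
            w <- (t^2 - mu) * g
            2 * w / sum(t^2 * w) },
    stop("order must be 0, 1 or 2"))
}

# correlate `a` with 1D weights along `axis`, reflection boundary
conv1d_axis <- function(a, w, axis) {
  d <- dim(a)
  r <- (length(w) - 1L) %/% 2L
  n <- d[axis]
  idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  args <- list(a, seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  args[[axis + 1L]] <- idx
  ap <- do.call(`[`, args)
  out <- array(0, d)
  take <- function(off) {
    args2 <- list(ap, seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    args2[[axis + 1L]] <- seq_len(n) + r + off
    do.call(`[`, args2)
  }
  for (k in seq_along(w)) {
    off <- k - r - 1L
    out <- out + w[k] * take(off)
  }
  out
}

# Gaussian-derivative filter with per-axis derivative orders (mm units)
gaussian_filter3 <- function(arr, sigma_mm, voxel_size, orders) {
  out <- arr
  for (ax in 1:3) {
    sv <- sigma_mm / voxel_size[ax]
    w <- gaussian_deriv_kernel(sv, orders[ax])
    out <- conv1d_axis(out, w, ax)
    if (orders[ax] > 0) out <- out / voxel_size[ax]^orders[ax]
  }
  out
}

#' Scale-normalized Hessian eigenvalues of a volume
#'
#' Computes the six second Gaussian derivatives at scale `sigma` (mm),
#' multiplies by `sigma^2` (gamma-normalization so responses are
#' comparable across scales), and returns the per-voxel eigenvalues of
#' the symmetric Hessian ordered by increasing magnitude
#' `|lambda1| <= |lambda2| <= |lambda3|`.
#'
#' @param volume an [hv_volume].
#' @param sigma positive Gaussian scale in mm.
#' @return A list with 3D arrays `l1`, `l2`, `l3`.
#' @export
hessian_eigenvalues <- function(volume, sigma) {
  stopifnot(inherits(volume, "hv_volume"))
  if (!is.numeric(sigma) || sigma <= 0)
    stop("hessian_eigenvalues: sigma must be positive", call. = FALSE)
  a <- volume$data; vs <- volume$voxel_size
  s2 <- sigma^2
  h11 <- s2 * gaussian_filter3(a, sigma, vs, c(2, 0, 0))
  h22 <- s2 * gaussian_filter3(a, sigma, vs, c(0, 2, 0))
  h33 <- s2 * gaussian_filter3(a, sigma, vs, c(0, 0, 2))
  h12 <- s2 * gaussian_filter3(a, sigma, vs, c(1, 1, 0))
  h13 <- s2 * gaussian_filter3(a, sigma, vs, c(1, 0, 1))
  h23 <- s2 * gaussian_filter3(a, sigma, vs, c(0, 1, 1))
  eig <- sym3_eigenvalues(h11, h22, h33, h12, h13, h23)
  d <- dim(a)
  lapply(eig, function(x) array(x, d))
}

# closed-form eigenvalues of symmetric 3x3 matrices, vectorized over
# voxels; returns them ordered by increasing |lambda|
sym3_eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  a11 <- as.vector(a11); a22 <- as.vector(a22); a33 <- as.vector(a33)
  a12 <- as.vector(a12); a13 <- as.vector(a13); a23 <- as.vector(a23)
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  ok <- p > .Machine$double.eps * (abs(q) + 1)
  ps <- ifelse(ok, p, 1)
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1 <- ifelse(ok, e1, q); e2 <- ifelse(ok, e2, q); e3 <- ifelse(ok, e3, q)
  # sorting network on |lambda|
  l1 <- e1; l2 <- e2; l3 <- e3
  sw <- abs(l1) > abs(l2); tmp <- l1; l1 <- ifelse(sw, l2, l1); l2 <- ifelse(sw, tmp, l2)
  sw <- abs(l2) > abs(l3); tmp <- l2; l2 <- ifelse(sw, l3, l2); l3 <- ifelse(sw, tmp, l3)
  sw <- abs(l1) > abs(l2); tmp <- l1; l1 <- ifelse(sw, l2, l1); l2 <- ifelse(sw, tmp, l2)
  list(l1 = l1, l2 = l2, l3 = l3)
}

#' Vesselness response from ordered Hessian eigenvalues
#'
#' The tubular-structure measure
#' `V = (1 - exp(-Ra^2 / 2 alpha^2)) * exp(-Rb^2 / 2 beta^2) *
#'      (1 - exp(-S^2 / 2 c^2))`
#' with `Ra = |l2|/|l3|` (plate vs line), `Rb = |l1|/sqrt(|l2 l3|)`
#' (blob deviation) and `S = sqrt(l1^2 + l2^2 + l3^2)` (second-order
#' structure energy); zero wherever `l2 >= 0` or `l3 >= 0` (bright-vessel
#' polarity).
#'
#' @param eigs list `l1`, `l2`, `l3` from [hessian_eigenvalues()].
#' @param params a [vesselness_params()] object.
#' @return Array of vesselness values in `[0, 1]`, same shape.
#' @export
frangi_response <- function(eigs, params = vesselness_params()) {
  l1 <- eigs$l1; l2 <- eigs$l2; l3 <- eigs$l3
  v <- array(0, dim = if (is.null(dim(l1))) length(l1) else dim(l1))
  sel <- which(l2 < 0 & l3 < 0)
  if (!length(sel)) return(v)
  S2_all <- l1^2 + l2^2 + l3^2
  cf <- params$c_f
  if (is.null(cf)) cf <- sqrt(max(S2_all)) / 2
  if (cf <= 0) cf <- 1  # structureless input; term vanishes anyway
  Ra2 <- (l2[sel] / l3[sel])^2
  Rb2 <- l1[sel]^2 / abs(l2[sel] * l3[sel])
  v[sel] <- (1 - exp(-Ra2 / (2 * params$alpha_f^2))) *
    exp(-Rb2 / (2 * params$beta_f^2)) *
    (1 - exp(-S2_all[sel] / (2 * cf^2)))
  v
}

#' Multiscale Frangi vesselness
#'
#' Voxelwise maximum of [frangi_response()] over `params$scales`, with
#' the argmax scale recorded as attribute `"scale"` of the returned
#' volume's data.
#'
#' @param volume an [hv_volume] (typically the enhanced volume).
#' @param params a [vesselness_params()].
#' @return An [hv_volume] of vesselness in `[0, 1]`; `attr(v$data, "scale")`
#'   holds the per-voxel best scale (mm).
#' @export
multiscale_vesselness <- function(volume, params = vesselness_params()) {
  stopifnot(inherits(volume, "hv_volume"), inherits(params, "hv_vesselness_params"))
  best <- array(0, dim(volume$data))
  best_scale <- array(NA_real_, dim(volume$data))
  for (s in params$scales) {
    eigs <- hessian_eigenvalues(volume, s)
    v <- frangi_response(eigs, params)
    upd <- v > best
    best[upd] <- v[upd]
    best_scale[upd] <- s
  }
  out <- hv_volume(best, volume$voxel_size, volume$affine)
  attr(out$data, "scale") <- best_scale
  out
}
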