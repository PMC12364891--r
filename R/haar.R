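#' Parameters of the Haar-coefficient vessel enhancement
#'
#' Thresholds partition coefficient magnitudes into four bands:
#' above `alpha1` (strong image structure, kept as is), `[alpha2, alpha1]`
#' (weak structure, amplified by `gamma1`), `[beta, alpha2)` (near-noise,
#' amplified by `gamma2`), below `beta` (noise, zeroed). The defaults are
#' the published operating point for 7T T1w vessel enhancement on
#' intensities normalized to `[0, intensity_scale_max]`:
#' alpha1 = 60, alpha2 = 30, beta = 10, gamma1 = 40, gamma2 = 0.5 * gamma1.
#'
#' @param alpha1,alpha2,beta coefficient-magnitude thresholds for normal
#'   structure, weak structure and noise; require `0 <= beta < alpha2 < alpha1`.
#' @param gamma1,gamma2 positive gains for the weak-structure and near-noise
#'   bands.
#' @param cube_size odd cube edge length (voxels), >= 3.
#' @param intensity_scale_max target maximum of the pre-enhancement
#'   intensity normalization.
#' @return A list of class `hv_enhance_params`.
#' @export
enhance_params <- function(alpha1 = 60, alpha2 = 30, beta = 10,
                           gamma1 = 40, gamma2 = 0.5 * gamma1,
                           cube_size = 7L, intensity_scale_max = 255) {
  if (!(beta >= 0 && beta < alpha2 && alpha2 < alpha1))
    stop("enhance_params: need 0 <= beta < alpha2 < alpha1", call. = FALSE)
  if (gamma1 <= 0 || gamma2 <= 0)
    stop("enhance_params: gains must be positive", call. = FALSE)
  cube_size <- as.integer(cube_size)
  if (cube_size < 3L || cube_size %% 2L == 0L)
    stop("enhance_params: cube_size must be odd and >= 3", call. = FALSE)
  if (intensity_scale_max <= 0)
    stop("enhance_params: intensity_scale_max must be positive", call. = FALSE)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, beta = beta,
                 gamma1 = gamma1, gamma2 = gamma2, cube_size = cube_size,
                 intensity_scale_max = intensity_scale_max),
            class = "hv_enhance_params")
}

#' The orthonormal 8-point Haar transform matrix
#'
#' Rows are the Haar basis: the first row is the constant (DC) vector,
#' subsequent rows hold differences at successively finer scales. The
#' matrix is orthonormal, so `H %*% t(H)` is the identity and the inverse
#' transform is `t(H)`.
#'
#' @return An 8x8 numeric matrix.
#' @export
haar_matrix_8 <- function() {
  H <- rbind(
    c( 1,  1,  1,  1,  1,  1,  1,  1),
    c( 1,  1,  1,  1, -1, -1, -1, -1),
    c( 1,  1, -1, -1,  0,  0,  0,  0),
    c( 0,  0,  0,  0,  1,  1, -1, -1),
    c( 1, -1,  0,  0,  0,  0,  0,  0),
    c( 0,  0,  1, -1,  0,  0,  0,  0),
    c( 0,  0,  0,  0,  1, -1,  0,  0),
    c( 0,  0,  0,  0,  0,  0,  1, -1)
  )
  H / sqrt(rowSums(H^2))
}

#' Piecewise amplification of a Haar detail coefficient
#'
#' Applies the four-band rule to coefficient magnitudes, preserving sign:
#' identity above `alpha1`; `gamma1 * c` for magnitudes in
#' `[alpha2, alpha1]`; `gamma2 * c` for `[beta, alpha2)`; zero below
#' `beta`. Magnitudes exactly at `alpha2` take the stronger (`gamma1`)
#' gain and magnitudes exactly at `beta` are retained in the `gamma2`
#' band, so every magnitude maps to exactly one branch.
#'
#' @param c_h numeric vector of coefficients.
#' @param params an [enhance_params()] object.
#' @return Numeric vector of enhanced coefficients, same shape.
#' @export
enhance_coefficient <- function(c_h, params = enhance_params()) {
  stopifnot(inherits(params, "hv_enhance_params"))
  m <- abs(c_h)
  gain <- ifelse(m > params$alpha1, 1,
          ifelse(m >= params$alpha2, params$gamma1,
          ifelse(m >= params$beta,   params$gamma2, 0)))
  gain * c_h
}

#' Affine intensity normalization
#'
#' Rescales intensities so the minimum maps to 0 and the maximum to
#' `params$intensity_scale_max` (255 by default), the scale the
#' enhancement thresholds are calibrated for. Monotone; errors on a
#' constant volume (degenerate dynamic range).
#'
#' @param volume an [hv_volume].
#' @param params an [enhance_params()] (only `intensity_scale_max` used).
#' @return A rescaled [hv_volume].
#' @export
normalize_intensity <- function(volume, params = enhance_params()) {
  stopifnot(inherits(volume, "hv_volume"))
  rng <- range(volume$data)
  if (diff(rng) <= 0)
    stop("normalize_intensity: constant volume has no dynamic range", call. = FALSE)
  out <- (volume$data - rng[1]) / diff(rng) * params$intensity_scale_max
  hv_volume(out, volume$voxel_size, volume$affine)
}

# reflection padding of a 3D array by `p` voxels on every face
reflect_pad <- function(a, p) {
  d <- dim(a)
  idx <- lapply(d, function(n) {
    # reflect without repeating the edge sample (NumPy-style "reflect")
    c(rev(seq_len(p) + 1L), seq_len(n), n - seq_len(p))
  })
  a[idx[[1]], idx[[2]], idx[[3]]]
}

#' Haar-transform vessel enhancement of a 3D volume
#'
#' For every voxel, a reference cube of `cube_size`^3 voxels is paired
#' with its 7 companion cubes at offsets {0,1}^3 (the 2x2x2 corner of the
#' surrounding 3x3x3 cube neighborhood). For each intra-cube position the
#' 8 samples across cubes are Haar-transformed with [haar_matrix_8()];
#' the 7 detail coefficients pass through [enhance_coefficient()] while
#' the DC coefficient is left untouched (preserving tissue background),
#' then the inverse transform is applied and the reference-cube
#' contribution accumulated. Overlapping contributions are averaged.
#' Borders are handled by reflection padding, cropped after enhancement.
#'
#' The input is expected on the `[0, intensity_scale_max]` scale produced
#' by [normalize_intensity()]; a constant volume is a fixed point.
#'
#' @param volume an [hv_volume], intensity-normalized.
#' @param params an [enhance_params()].
#' @return An enhanced [hv_volume] of identical shape.
#' @export
enhance_volume <- function(volume, params = enhance_params()) {
  stopifnot(inherits(volume, "hv_volume"), inherits(params, "hv_enhance_params"))
  d <- dim(volume$data)
  cs <- params$cube_size
  if (any(d < cs + 1L))
    stop("enhance_volume: grid must exceed cube_size + 1 per axis", call. = FALSE)
  half <- cs %/% 2L
  pad <- cs                       # room for offsets in [-half, half + 1]
  a <- reflect_pad(volume$data, pad)
  dp <- dim(a)
  H <- haar_matrix_8()
  tH <- t(H)

  # cube-offset vectors {0,1}^3, reference first
  offs <- as.matrix(expand.grid(o1 = 0:1, o2 = 0:1, o3 = 0:1))

  # centers: all padded voxels whose full stencil (offset + intra-cube
  # position) stays in bounds; a rectangular sub-grid, so linear index
  # arithmetic below never wraps
  cr <- lapply(dp, function(n) seq.int(half + 1L, n - half - 1L))
  nst <- c(dp[1], dp[1] * dp[2])
  centers_idx <- as.vector(
    outer(outer(cr[[1]], (cr[[2]] - 1L) * nst[1], "+"),
          (cr[[3]] - 1L) * nst[2], "+"))
  off_lin <- function(v) v[1] + v[2] * nst[1] + v[3] * nst[2]
  cube_off <- apply(offs, 1L, off_lin)

  av <- as.vector(a)
  acc <- numeric(length(av))
  g1 <- params$gamma1; g2 <- params$gamma2
  a1 <- params$alpha1; a2 <- params$alpha2; b0 <- params$beta

  intra <- expand.grid(d1 = -half:half, d2 = -half:half, d3 = -half:half)
  nctr <- length(centers_idx)
  S <- matrix(0, nctr, 8L)
  for (r in seq_len(nrow(intra))) {
    dlin <- off_lin(as.numeric(intra[r, ]))
    base <- centers_idx + dlin
    for (j in 1:8) S[, j] <- av[base + cube_off[j]]
    C <- S %*% tH                 # coefficients, columns = basis index
    det <- C[, 2:8]
    mg <- abs(det)
    gain <- ifelse(mg > a1, 1, ifelse(mg >= a2, g1, ifelse(mg >= b0, g2, 0)))
    C[, 2:8] <- det * gain
    # reference-cube (offset 0) component of the inverse transform
    rec <- C %*% H[, 1L]
    acc[base] <- acc[base] + rec
  }
  acc <- acc / nrow(intra)        # every retained voxel receives cube_size^3 contributions
  out <- array(acc, dim = dp)[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])]
  hv_volume(out, volume$voxel_size, volume$affine)
}
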