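#' Specify a vessel phantom
#'
#' Defines a 3D digital phantom emulating the inflow contrast of 7T
#' MPRAGE: bright tubular vessels over tissue background, two
#' hippocampus ellipsoids, a white-matter slab and a cerebellum-tagged
#' exclusion slab, all with ground-truth masks. Defaults: 48^3 grid at
#' 0.75 mm isotropic, vessel intensity 1.6x the WM mean, supply-trunk
#' tubes of radius 2.5 voxels (~1.9 mm) approaching each hippocampus, and
#' noise sigma set from `snr`, defined as the vessel-over-WM contrast
#' `wm_mean * (vessel_to_wm_ratio - 1)` divided by sigma (default SNR 20,
#' i.e. sigma = 4.5 at the default intensities).
#'
#' @param grid_shape length-3 integer grid size.
#' @param voxel_size voxel edge lengths, mm.
#' @param background_mean,wm_mean tissue intensities (arbitrary units).
#' @param vessel_to_wm_ratio vessel intensity as a multiple of `wm_mean`.
#' @param snr tube contrast over noise sigma; used when `noise_sigma` is
#'   `NULL`. `snr = Inf` (or `noise_sigma = 0`) gives a noiseless render.
#' @param noise_sigma Gaussian noise SD; overrides `snr` when given.
#' @param tubes list of tubes, each `list(points = k x 3 matrix of voxel
#'   coordinates, radius = voxels, side = "left"|"right")`.
#' @param distractors like `tubes` but with no side; must lie >= 10
#'   voxels from both hippocampi.
#' @param hippo_centers,hippo_axes per-side ellipsoid centers and
#'   semi-axes (voxels).
#' @param edge_sigma_vox Gaussian blur of the tube indicator outside the
#'   lumen, in voxels, emulating sub-voxel partial-volume edges.
#' @param seed integer RNG seed for the noise draw.
#' @return A list of class `hv_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         voxel_size = c(0.75, 0.75, 0.75),
                         background_mean = 80, wm_mean = 150,
                         vessel_to_wm_ratio = 1.6,
                         snr = 20, noise_sigma = NULL,
                         tubes = NULL, distractors = NULL,
                         hippo_centers = list(left = c(14, 32, 20),
                                              right = c(34, 32, 20)),
                         hippo_axes = list(left = c(5, 7, 5),
                                           right = c(5, 7, 5)),
                         edge_sigma_vox = 0.25,
                         seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(tubes)) {
    tubes <- list(
      list(points = rbind(c(14, 8, 16), c(14, 16, 18), c(14, 24, 20)),
           radius = 2.5, side = "left"),
      list(points = rbind(c(34, 8, 16), c(34, 16, 18), c(34, 24, 20)),
           radius = 2.5, side = "right"))
  }
  if (is.null(distractors)) {
    distractors <- list(
      list(points = rbind(c(8, 4, 8), c(24, 4, 8), c(40, 4, 8)), radius = 2))
  }
  vessel_contrast <- wm_mean * (vessel_to_wm_ratio - 1)
  if (is.null(noise_sigma)) {
    noise_sigma <- if (is.infinite(snr)) 0 else vessel_contrast / snr
  }
  if (noise_sigma < 0) stop("phantom_spec: noise_sigma must be >= 0", call. = FALSE)
  spec <- structure(list(
    grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
    background_mean = background_mean, wm_mean = wm_mean,
    vessel_to_wm_ratio = vessel_to_wm_ratio, noise_sigma = noise_sigma,
    tubes = tubes, distractors = distractors,
    hippo_centers = hippo_centers, hippo_axes = hippo_axes,
    edge_sigma_vox = edge_sigma_vox,
    seed = as.integer(seed)), class = "hv_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

ellipsoid_mask <- function(d, center, axes) {
  x <- (seq_len(d[1]) - center[1]) / axes[1]
  y <- (seq_len(d[2]) - center[2]) / axes[2]
  z <- (seq_len(d[3]) - center[3]) / axes[3]
  outer(outer(x^2, y^2, "+"), z^2, "+") <= 1
}

# min distance (voxels) from each ellipsoid surface sample to a point set
ellipsoid_gap <- function(center, axes, pts) {
  # conservative: distance from ellipsoid center minus the max semi-axis
  dmin <- min(sqrt(colSums((t(pts) - center)^2)))
  dmin - max(axes)
}

validate_phantom_spec <- function(spec) {
  d <- spec$grid_shape
  for (tb in c(spec$tubes, spec$distractors)) {
    p <- tb$points
    if (any(p - tb$radius < 1) || any(sweep(p + tb$radius, 2, d, ">")))
      stop("phantom: tube exits the grid", call. = FALSE)
  }
  for (tb in spec$tubes) {
    side <- tb$side
    if (!side %in% c("left", "right"))
      stop("phantom: tubes must be tagged 'left' or 'right'", call. = FALSE)
    ctr <- spec$hippo_centers[[side]]; ax <- spec$hippo_axes[[side]]
    endpt <- tb$points[nrow(tb$points), ]
    # ellipsoid implicit value at the endpoint; <= ~1 voxel outside surface
    val <- sum(((endpt - ctr) / ax)^2)
    if (val > ((max(ax) + 1.5) / max(ax))^2)
      stop("phantom: ", side, " tube does not terminate within ~1 voxel of its hippocampus",
           call. = FALSE)
  }
  for (db in spec$distractors) {
    for (side in c("left", "right")) {
      if (ellipsoid_gap(spec$hippo_centers[[side]], spec$hippo_axes[[side]],
                        db$points) < 10)
        stop("phantom: distractor closer than 10 voxels to the ", side,
             " hippocampus", call. = FALSE)
    }
  }
  invisible(spec)
}

# rasterize a polyline tube: voxels within `radius` of the densely
# sampled centerline
render_tube <- function(d, points, radius) {
  # sample the polyline every 0.25 voxel
  segs <- lapply(seq_len(nrow(points) - 1L), function(i) {
    p0 <- points[i, ]; p1 <- points[i + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.25) + 1L))
    cbind(p0[1] + t * (p1[1] - p0[1]),
          p0[2] + t * (p1[2] - p0[2]),
          p0[3] + t * (p1[3] - p0[3]))
  })
  pts <- unique(do.call(rbind, segs))
  mask <- array(FALSE, d)
  r <- radius
  ri <- ceiling(r)
  for (k in seq_len(nrow(pts))) {
    c0 <- pts[k, ]
    xs <- max(1, floor(c0[1] - ri)):min(d[1], ceiling(c0[1] + ri))
    ys <- max(1, floor(c0[2] - ri)):min(d[2], ceiling(c0[2] + ri))
    zs <- max(1, floor(c0[3] - ri)):min(d[3], ceiling(c0[3] + ri))
    dx2 <- (xs - c0[1])^2; dy2 <- (ys - c0[2])^2; dz2 <- (zs - c0[3])^2
    sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    mask[xs, ys, zs] <- mask[xs, ys, zs] | sub
  }
  mask
}

#' Render a phantom with ground truth
#'
#' Builds the T1w-like volume, the aseg-style label map (hippocampi 17/53,
#' cerebral WM 2/41, cerebellum slab 47), the pure-WM mask and the truth
#' vessel masks. Vessels are rendered with a hard radius then given
#' partial-volume edges by sub-voxel Gaussian smoothing of the indicator
#' outside the lumen (interior voxels keep the exact vessel intensity
#' `wm_mean * vessel_to_wm_ratio`). Gaussian noise is added with the
#' spec's seed; the render is a pure function of the spec.
#'
#' @param spec an [phantom_spec()].
#' @return A list of class `hv_phantom`: `t1w` ([hv_volume]), `labelmap`
#'   ([hv_labelmap]), `wm_mask`, `vessel_truth_left`, `vessel_truth_right`,
#'   `vessel_truth_distractor` ([hv_mask]), and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "hv_phantom_spec"))
  d <- spec$grid_shape
  labels <- array(0L, d)

  # white-matter slab in upper z, split into left/right hemicodes
  wm_z <- seq.int(max(1L, d[3] - 14L), d[3] - 2L)
  xl <- seq_len(d[1] %/% 2)
  labels[xl, , wm_z] <- 2L
  labels[setdiff(seq_len(d[1]), xl), , wm_z] <- 41L
  # cerebellum-style exclusion slab at low y / low z
  labels[, seq_len(6L), seq_len(12L)] <- 47L
  # hippocampi override
  hl <- ellipsoid_mask(d, spec$hippo_centers$left, spec$hippo_axes$left)
  hr <- ellipsoid_mask(d, spec$hippo_centers$right, spec$hippo_axes$right)
  labels[hl] <- 17L
  labels[hr] <- 53L

  tissue <- array(spec$background_mean, d)
  tissue[labels %in% c(2L, 41L)] <- spec$wm_mean
  # hippocampal GM is kept isointense with the surrounding parenchyma:
  # at this field/sequence the parcellation, not intensity, delineates it

  truth_l <- array(FALSE, d); truth_r <- array(FALSE, d)
  for (tb in spec$tubes) {
    m <- render_tube(d, tb$points, tb$radius)
    if (tb$side == "left") truth_l <- truth_l | m else truth_r <- truth_r | m
  }
  truth_d <- array(FALSE, d)
  for (db in spec$distractors) truth_d <- truth_d | render_tube(d, db$points, db$radius)
  # hippocampus tissue is not vessel truth
  truth_l <- truth_l & !(hl | hr)
  truth_r <- truth_r & !(hl | hr)

  vessel_int <- spec$wm_mean * spec$vessel_to_wm_ratio
  hard <- (truth_l | truth_r | truth_d) * 1
  f <- if (spec$edge_sigma_vox > 0) {
    pmax(hard, gaussian_filter3(hard, spec$edge_sigma_vox * spec$voxel_size[1],
                                spec$voxel_size, c(0, 0, 0)))
  } else hard
  img <- tissue + (vessel_int - tissue) * f

  if (spec$noise_sigma > 0) {
    img <- with_local_seed(spec$seed, function()
      img + array(stats::rnorm(prod(d), 0, spec$noise_sigma), d))
  }

  wm <- labels %in% c(2L, 41L)
  # pure-WM mask: erode the slab margin by excluding slab boundary voxels
  wm_core <- array(FALSE, d)
  if (length(wm_z) > 4L) {
    wm_core[2:(d[1] - 1), 2:(d[2] - 1), wm_z[3:(length(wm_z) - 2)]] <- TRUE
  }
  wm_core <- wm_core & wm

  list(
    t1w = hv_volume(img, spec$voxel_size),
    labelmap = hv_labelmap(labels),
    wm_mask = hv_mask(wm_core),
    vessel_truth_left = hv_mask(truth_l),
    vessel_truth_right = hv_mask(truth_r),
    vessel_truth_distractor = hv_mask(truth_d),
    spec = spec
  ) -> out
  class(out) <- "hv_phantom"
  out
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b [hv_mask] objects or logical arrays on the same grid.
#' @return `2|A n B| / (|A| + |B|)`; `NA` when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "hv_mask")) a <- a$mask
  if (inherits(b, "hv_mask")) b <- b$mask
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
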