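#' Threshold a vesselness map and apply anatomical exclusion
#'
#' Keeps voxels whose vesselness exceeds `frac` of the map maximum
#' (default 5%), then removes voxels whose parcellation label belongs to
#' the excluded regions (white matter, cerebellum, temporal,
#' supramarginal, orbitofrontal by default) — inflow contrast also
#' brightens non-arterial structures there.
#'
#' @param vesselness an [hv_volume] of vesselness values.
#' @param labelmap an [hv_labelmap] on the same grid.
#' @param frac fraction of the maximum vesselness, in (0, 1).
#' @param excluded_regions integer label codes to remove
#'   (default [default_excluded_codes()]).
#' @return An [hv_mask] of candidate vessel voxels.
#' @export
threshold_and_exclude <- function(vesselness, labelmap,
                                  frac = 0.05,
                                  excluded_regions = default_excluded_codes()) {
  stopifnot(inherits(vesselness, "hv_volume"), inherits(labelmap, "hv_labelmap"))
  if (!(frac > 0 && frac < 1))
    stop("threshold_and_exclude: frac must be in (0, 1)", call. = FALSE)
  check_same_grid(vesselness, labelmap, "vesselness", "labelmap")
  vmax <- max(vesselness$data)
  if (vmax <= 0) {
    warning("threshold_and_exclude: all-zero vesselness; returning empty mask",
            call. = FALSE)
    return(hv_mask(array(FALSE, dim(vesselness$data))))
  }
  m <- vesselness$data > frac * vmax
  m[labelmap$labels %in% excluded_regions] <- FALSE
  hv_mask(m)
}

# linear-offset table for a (2k+1)^3 neighborhood minus the center
neighbor_offsets <- function(connectivity = 26L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  else if (connectivity != 26L)
    stop("connectivity must be 6 or 26", call. = FALSE)
  as.matrix(g)
}

#' Label connected components of a 3D binary mask
#'
#' Sparse implementation: foreground voxels become graph vertices, voxels
#' adjacent under the chosen connectivity become edges, and component
#' membership is read off the graph. Suited to vessel masks, which occupy
#' a small fraction of the grid.
#'
#' @param mask 3D logical array or [hv_mask].
#' @param connectivity 6 or 26 (default).
#' @return Integer array of the same shape: 0 for background, 1..K
#'   component ids otherwise.
#' @export
label_components <- function(mask, connectivity = 26L) {
  if (inherits(mask, "hv_mask")) mask <- mask$mask
  d <- dim(mask)
  idx <- which(mask)
  out <- array(0L, d)
  if (!length(idx)) return(out)
  rank <- array(0L, d)
  rank[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)
  offs <- neighbor_offsets(connectivity)
  # each unordered pair once: offsets lexicographically positive
  pos <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
          (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  ef <- integer(0); et <- integer(0)
  for (r in seq_len(nrow(pos))) {
    ok <- co[, 1] + pos[r, 1] >= 1 & co[, 1] + pos[r, 1] <= d[1] &
          co[, 2] + pos[r, 2] >= 1 & co[, 2] + pos[r, 2] <= d[2] &
          co[, 3] + pos[r, 3] >= 1 & co[, 3] + pos[r, 3] <= d[3]
    nb <- idx[ok] + pos[r, 1] + pos[r, 2] * d[1] + pos[r, 3] * d[1] * d[2]
    nb_rank <- rank[nb]
    hit <- nb_rank > 0L
    ef <- c(ef, rank[idx[ok]][hit]); et <- c(et, nb_rank[hit])
  }
  g <- igraph::make_graph(rbind(ef, et), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}

# one-voxel binary dilation under 26-connectivity, by shifting
dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  offs <- neighbor_offsets(26L)
  for (r in seq_len(nrow(offs))) {
    sx <- offs[r, 1]; sy <- offs[r, 2]; sz <- offs[r, 3]
    src <- list(seq.int(max(1, 1 - sx), min(d[1], d[1] - sx)),
                seq.int(max(1, 1 - sy), min(d[2], d[2] - sy)),
                seq.int(max(1, 1 - sz), min(d[3], d[3] - sz)))
    dst <- list(src[[1]] + sx, src[[2]] + sy, src[[3]] + sz)
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] | mask[src[[1]], src[[2]], src[[3]]]
  }
  out
}

#' Hippocampus-connected vessel components per hemisphere
#'
#' Connected components of the candidate vessel mask (26-connectivity by
#' default) that touch — overlap or are adjacent to, operationalized as
#' overlapping the 1-voxel-dilated hippocampus mask — the left or right
#' hippocampus are kept for that side; components touching neither are
#' dropped. A component touching both hippocampi is assigned to the side
#' with greater contact; an exact tie assigns it to both and flags it for
#' QC.
#'
#' @param vessel_mask an [hv_mask] of candidate vessel voxels.
#' @param labelmap an [hv_labelmap] containing hippocampus codes.
#' @param connectivity 6 or 26.
#' @param left_code,right_code hippocampus label codes (aseg 17 / 53).
#' @return List with `left`, `right` ([hv_mask]), and `qc_ties`
#'   (component ids assigned to both sides).
#' @export
hippocampal_components <- function(vessel_mask, labelmap, connectivity = 26L,
                                   left_code = 17L, right_code = 53L) {
  stopifnot(inherits(vessel_mask, "hv_mask"), inherits(labelmap, "hv_labelmap"))
  check_same_grid(vessel_mask, labelmap, "vessel mask", "labelmap")
  if (!any(labelmap$labels == left_code) || !any(labelmap$labels == right_code))
    stop("hippocampal_components: hippocampus labels (", left_code, ", ",
         right_code, ") not present in label map", call. = FALSE)
  comp <- label_components(vessel_mask, connectivity)
  d <- dim(comp)
  left_h <- dilate1(labelmap$labels == left_code)
  right_h <- dilate1(labelmap$labels == right_code)
  k <- max(comp)
  left_mask <- array(FALSE, d); right_mask <- array(FALSE, d)
  ties <- integer(0)
  if (k > 0) {
    contact_l <- tabulate(comp[left_h & comp > 0L], nbins = k)
    contact_r <- tabulate(comp[right_h & comp > 0L], nbins = k)
    for (ci in seq_len(k)) {
      cl <- contact_l[ci]; cr <- contact_r[ci]
      if (cl == 0 && cr == 0) next
      if (cl > cr) left_mask[comp == ci] <- TRUE
      else if (cr > cl) right_mask[comp == ci] <- TRUE
      else {  # exact tie: assign to both, flag
        left_mask[comp == ci] <- TRUE
        right_mask[comp == ci] <- TRUE
        ties <- c(ties, ci)
      }
    }
  }
  list(left = hv_mask(left_mask), right = hv_mask(right_mask), qc_ties = ties)
}

#' Vessel voxel counts and volumes
#'
#' @param left,right [hv_mask] objects on the same grid.
#' @param voxel_size length-3 voxel edge lengths in mm.
#' @return A tibble with one row per side plus totals: `side`, `n_voxels`,
#'   `volume_mm3`.
#' @export
vessel_metrics <- function(left, right, voxel_size = c(0.75, 0.75, 0.75)) {
  stopifnot(inherits(left, "hv_mask"), inherits(right, "hv_mask"))
  check_same_grid(left, right, "left mask", "right mask")
  vv <- prod(voxel_size)
  nl <- sum(left$mask); nr <- sum(right$mask)
  tibble::tibble(
    side = c("left", "right", "total"),
    n_voxels = c(nl, nr, nl + nr),
    volume_mm3 = c(nl, nr, nl + nr) * vv
  )
}

#' Normalize a T1w volume to the white-matter mean
#'
#' Divides all intensities by the mean intensity inside the pure-WM mask,
#' so the WM mean of the output is exactly 1 and all vessel SI values are
#' dimensionless multiples of WM signal. Scale-invariant: rescaling the
#' input globally leaves the output unchanged.
#'
#' @param t1w an [hv_volume].
#' @param wm_mask a nonempty [hv_mask] of pure white matter.
#' @return The normalized [hv_volume].
#' @export
normalize_si <- function(t1w, wm_mask) {
  stopifnot(inherits(t1w, "hv_volume"), inherits(wm_mask, "hv_mask"))
  check_same_grid(t1w, wm_mask, "t1w", "wm mask")
  if (!any(wm_mask$mask))
    stop("normalize_si: empty WM mask", call. = FALSE)
  mu <- mean(t1w$data[wm_mask$mask])
  if (!is.finite(mu) || mu <= 0)
    stop("normalize_si: non-positive WM mean intensity", call. = FALSE)
  hv_volume(t1w$data / mu, t1w$voxel_size, t1w$affine)
}

#' Mean normalized signal intensity within a mask
#'
#' @param norm a WM-normalized [hv_volume] from [normalize_si()].
#' @param mask an [hv_mask]; an empty mask yields `NA` (missing), not 0.
#' @return Scalar mean SI, or `NA_real_`.
#' @export
mean_vessel_si <- function(norm, mask) {
  stopifnot(inherits(norm, "hv_volume"), inherits(mask, "hv_mask"))
  check_same_grid(norm, mask, "volume", "mask")
  if (!any(mask$mask)) return(NA_real_)
  mean(norm$data[mask$mask])
}

#' Lateralization index
#'
#' `LI = (right - left) / (right + left)`, bounded in `[-1, 1]` for
#' non-negative inputs; 0 under perfect symmetry, positive for rightward
#' dominance. Undefined (returns `NA`) when both sides are 0. Vectorized.
#'
#' @param right,left non-negative scalars or vectors.
#' @return Numeric LI value(s).
#' @export
lateralization_index <- function(right, left) {
  if (any(right < 0, na.rm = TRUE) || any(left < 0, na.rm = TRUE))
    stop("lateralization_index: inputs must be non-negative", call. = FALSE)
  s <- right + left
  out <- (right - left) / s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}
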