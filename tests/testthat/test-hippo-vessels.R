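make_lab <- function(d = c(20, 20, 20)) {
  lab <- array(0L, d)
  lab[3:6, 3:6, 3:6] <- 17L      # left hippocampus block
  lab[14:17, 3:6, 3:6] <- 53L    # right hippocampus block
  lab
}

test_that("thresholding keeps voxels above the max-referenced fraction", {
  d <- c(8, 8, 8)
  v <- array(0, d); v[1:64] <- seq(0, 100, length.out = 64)
  lab <- hv_labelmap(array(0L, d), c(none = 0L))
  m <- threshold_and_exclude(hv_volume(v), lab, frac = 0.05)
  expect_identical(m$mask, array(v > 5, d))
  # monotone nesting of thresholds
  m99 <- threshold_and_exclude(hv_volume(v), lab, frac = 0.99)
  expect_true(all(m$mask[m99$mask]))
  expect_error(threshold_and_exclude(hv_volume(v), lab, frac = 1.5), "frac")
  # all-zero vesselness: warning + empty mask
  expect_warning(m0 <- threshold_and_exclude(hv_volume(array(0, d)), lab), "empty")
  expect_false(any(m0$mask))
})

test_that("excluded-region labels are removed from the candidate mask", {
  d <- c(20, 8, 8)
  v <- array(0, d); v[3:18, 4, 4] <- 100       # tube along x
  lab <- array(0L, d); lab[11:20, , ] <- 2L    # WM slab over half
  m <- threshold_and_exclude(hv_volume(v), hv_labelmap(lab), frac = 0.05,
                             excluded_regions = 2L)
  expect_true(all(which(m$mask, arr.ind = TRUE)[, 1] <= 10))
  expect_equal(sum(m$mask), 8)  # only the non-WM half survives
})

test_that("components are assigned to the hippocampus they touch", {
  d <- c(20, 20, 20)
  lab <- hv_labelmap(make_lab(d))
  vm <- array(FALSE, d)
  vm[4, 7:14, 4] <- TRUE          # tube ending 1 voxel from left block
  vm[15, 7:14, 4] <- TRUE         # tube ending 1 voxel from right block
  vm[10, 18, 18] <- TRUE          # distractor speck far from both
  res <- hippocampal_components(hv_mask(vm), lab)
  expect_equal(sum(res$left$mask), 8)
  expect_equal(sum(res$right$mask), 8)
  expect_true(all(which(res$left$mask, arr.ind = TRUE)[, 1] == 4))
  expect_true(all(which(res$right$mask, arr.ind = TRUE)[, 1] == 15))
  expect_false(res$left$mask[10, 18, 18] || res$right$mask[10, 18, 18])
  expect_length(res$qc_ties, 0)
  # masks disjoint and contained in the candidate set
  expect_false(any(res$left$mask & res$right$mask))
  expect_true(all(vm[res$left$mask | res$right$mask]))
  expect_error(hippocampal_components(hv_mask(vm), hv_labelmap(array(0L, d), c(n = 0L))),
               "hippocampus")
})

test_that("connected component labeling respects connectivity", {
  d <- c(10, 10, 10)
  m <- array(FALSE, d)
  m[2, 2, 2] <- TRUE; m[3, 3, 3] <- TRUE   # corner-adjacent pair
  m[8, 8, 8] <- TRUE                        # isolated voxel
  c26 <- label_components(m, 26L)
  expect_equal(max(c26), 2L)
  expect_equal(c26[2, 2, 2], c26[3, 3, 3])
  c6 <- label_components(m, 6L)
  expect_equal(max(c6), 3L)
  expect_false(c6[2, 2, 2] == c6[3, 3, 3])
})

test_that("vessel metrics convert counts to mm^3 exactly", {
  d <- c(10, 10, 10)
  l <- array(FALSE, d); l[1:100] <- TRUE
  r <- array(FALSE, d)
  met <- vessel_metrics(hv_mask(l), hv_mask(r), c(0.75, 0.75, 0.75))
  expect_equal(met$volume_mm3[met$side == "left"], 42.1875)
  expect_equal(met$n_voxels[met$side == "right"], 0)
  expect_equal(met$volume_mm3[met$side == "right"], 0)
  expect_equal(met$n_voxels[met$side == "total"], 100)
})

test_that("WM normalization yields unit WM mean and scale invariance", {
  d <- c(8, 8, 8)
  set.seed(21)
  a <- array(stats::rnorm(prod(d), 500, 30), d)
  wm <- array(FALSE, d); wm[2:7, 2:7, 2] <- TRUE
  a[3, 3, 5] <- 820 * mean(a[wm]) / 500   # engineered vessel voxel
  v <- hv_volume(a); wmm <- hv_mask(wm)
  nv <- normalize_si(v, wmm)
  expect_equal(mean(nv$data[wm]), 1, tolerance = 1e-12)
  # doubling all intensities changes nothing
  nv2 <- normalize_si(hv_volume(2 * a), wmm)
  expect_equal(nv2$data, nv$data, tolerance = 1e-10)
  # a voxel at 1.64x the WM mean reads 1.64
  expect_equal(nv$data[3, 3, 5], 820 / 500, tolerance = 1e-6)
  expect_error(normalize_si(v, hv_mask(array(FALSE, d))), "empty")
  neg <- hv_volume(a - 10 * mean(a[wm]))
  expect_error(normalize_si(neg, wmm), "non-positive")
})

test_that("mean vessel SI averages the mask and is missing when empty", {
  d <- c(4, 4, 4)
  a <- array(1, d); a[1, 1, 1] <- 1.5; a[2, 1, 1] <- 2.5
  m <- array(FALSE, d); m[1:2, 1, 1] <- TRUE
  v <- hv_volume(a)
  expect_equal(mean_vessel_si(v, hv_mask(m)), 2.0)
  expect_equal(mean_vessel_si(v, hv_mask(array(a == 1, d))), 1.0)
  expect_true(is.na(mean_vessel_si(v, hv_mask(array(FALSE, d)))))
})

test_that("lateralization index is bounded, antisymmetric and exact", {
  expect_equal(lateralization_index(7, 7), 0)
  expect_equal(lateralization_index(224, 190), 34 / 414, tolerance = 1e-12)
  expect_equal(lateralization_index(1, 0), 1)
  expect_true(is.na(lateralization_index(0, 0)))
  expect_error(lateralization_index(-1, 2), "non-negative")
  rl <- with_seed(3, matrix(stats::runif(200, 0, 50), ncol = 2))
  li <- lateralization_index(rl[, 1], rl[, 2])
  expect_equal(li, -lateralization_index(rl[, 2], rl[, 1]))
  expect_true(all(li >= -1 & li <= 1))
})
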