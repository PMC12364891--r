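test_that("analytic symmetric-3x3 eigenvalues match LAPACK", {
  set.seed(31)
  for (i in 1:200) {
    M <- matrix(stats::rnorm(9, sd = sample(c(0.01, 1, 100), 1)), 3)
    M <- (M + t(M)) / 2
    ref <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    got <- hippovessel:::sym3_eigenvalues(M[1, 1], M[2, 2], M[3, 3],
                                          M[1, 2], M[1, 3], M[2, 3])
    expect_equal(sort(c(got$l1, got$l2, got$l3)), ref, tolerance = 1e-9)
    # ordering contract |l1| <= |l2| <= |l3|
    expect_true(abs(got$l1) <= abs(got$l2) + 1e-12 &&
                abs(got$l2) <= abs(got$l3) + 1e-12)
  }
})

test_that("Hessian eigenvalues recover the analytic curvature of -x^2", {
  d <- c(21, 21, 21)
  x <- seq_len(d[1]) - 11
  f <- array(rep(-x^2, times = d[2] * d[3]), d)
  v <- hv_volume(f, voxel_size = c(1, 1, 1))
  sigma <- 1.2
  eg <- hessian_eigenvalues(v, sigma)
  # interior voxel: one eigenvalue -2*sigma^2 (scale-normalized), two ~ 0
  expect_equal(eg$l3[11, 11, 11], -2 * sigma^2, tolerance = 1e-6)
  expect_equal(eg$l1[11, 11, 11], 0, tolerance = 1e-6)
  expect_equal(eg$l2[11, 11, 11], 0, tolerance = 1e-6)
  expect_error(hessian_eigenvalues(v, -1), "sigma")
})

test_that("constant volumes have zero Hessian eigenvalues everywhere", {
  v <- hv_volume(array(42, c(10, 10, 10)), voxel_size = c(1, 1, 1))
  eg <- hessian_eigenvalues(v, 1)
  expect_equal(max(abs(eg$l3)), 0, tolerance = 1e-10)
})

test_that("an isotropic Gaussian blob has three equal negative eigenvalues at center", {
  d <- c(25, 25, 25)
  g <- function(i) exp(-(i - 13)^2 / (2 * 9))
  f <- 100 * outer(outer(g(1:25), g(1:25)), g(1:25))
  v <- hv_volume(array(f, d), voxel_size = c(1, 1, 1))
  eg <- hessian_eigenvalues(v, 2)
  ls <- c(eg$l1[13, 13, 13], eg$l2[13, 13, 13], eg$l3[13, 13, 13])
  expect_true(all(ls < 0))
  expect_lt(diff(range(ls)) / abs(mean(ls)), 0.02)
})

test_that("vesselness closed form evaluates exactly and respects polarity", {
  prm <- vesselness_params(scales = 1, alpha_f = 0.5, beta_f = 0.5, c_f = 10)
  v <- frangi_response(list(l1 = 0, l2 = -10, l3 = -10), prm)
  expect_equal(as.numeric(v), (1 - exp(-2)) * 1 * (1 - exp(-1)), tolerance = 1e-10)
  expect_equal(as.numeric(frangi_response(list(l1 = 0, l2 = 0, l3 = 0), prm)), 0)
  expect_equal(as.numeric(frangi_response(list(l1 = 5, l2 = 6, l3 = 7), prm)), 0)
  # bounded in [0, 1]
  set.seed(4)
  eg <- list(l1 = stats::rnorm(100), l2 = stats::rnorm(100), l3 = stats::rnorm(100))
  r <- frangi_response(eg, prm)
  expect_true(all(r >= 0 & r <= 1))
  expect_true(all(r[eg$l2 >= 0 | eg$l3 >= 0] == 0))
})

# shared tube/sphere phantom for the discrimination and scale tests
tube_sphere_volume <- function() {
  d <- c(40, 40, 40)
  a <- array(0, d)
  tube <- hippovessel:::render_tube(d, rbind(c(10, 4, 10), c(10, 36, 10)), 2)
  co <- as.matrix(expand.grid(1:40, 1:40, 1:40))
  sph <- array((co[, 1] - 28)^2 + (co[, 2] - 20)^2 + (co[, 3] - 28)^2 <= 16, d)
  a[tube] <- 100; a[sph] <- 100
  sm <- hippovessel:::gaussian_filter3(a, 0.75, c(0.75, 0.75, 0.75), c(0, 0, 0))
  hv_volume(sm, voxel_size = c(0.75, 0.75, 0.75))
}

test_that("tubes dominate blobs and scale selection tracks the radius", {
  v <- tube_sphere_volume()
  ms <- multiscale_vesselness(v, vesselness_params())
  tube_resp <- ms$data[10, 20, 10]
  sph_resp <- ms$data[28, 20, 28]
  # an ideal sphere is suppressed by exp(-1/(2*beta_f^2)) = e^-2 relative
  # to an ideal tube, a ~7.4-fold separation; assert a conservative 5x
  expect_gt(tube_resp / sph_resp, 5)
  expect_true(all(ms$data >= 0 & ms$data <= 1))

  # radius-2 tube, scales {1,2,4} voxels: best scale at centerline is 2 +/- 1 step
  ms2 <- multiscale_vesselness(hv_volume(v$data, voxel_size = c(1, 1, 1)),
                               vesselness_params(scales = c(1, 2, 4)))
  sc <- attr(ms2$data, "scale")[10, 18:22, 10]
  expect_true(all(sc %in% c(1, 2)))
})

test_that("single-scale multiscale reduces to the plain response", {
  v <- tube_sphere_volume()
  prm <- vesselness_params(scales = 1.0)
  ms <- multiscale_vesselness(v, prm)
  direct <- frangi_response(hessian_eigenvalues(v, 1.0), prm)
  expect_equal(ms$data, direct, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("oblique tubes respond within 20% of axis-aligned ones", {
  d <- c(40, 40, 40)
  mk <- function(p0, p1) {
    m <- hippovessel:::render_tube(d, rbind(p0, p1), 2) * 100
    sm <- hippovessel:::gaussian_filter3(m, 0.75, c(0.75, 0.75, 0.75), c(0, 0, 0))
    multiscale_vesselness(hv_volume(sm, voxel_size = c(0.75, 0.75, 0.75)),
                          vesselness_params())
  }
  ax <- mk(c(20, 6, 20), c(20, 34, 20))
  ob <- mk(c(12, 12, 20), c(28, 28, 20))   # 45 degrees in-plane
  resp_ax <- mean(ax$data[20, 16:24, 20])
  ob_line <- vapply(16:24, function(t) ob$data[t, t, 20], numeric(1))
  expect_gt(mean(ob_line), 0.8 * resp_ax)
  expect_lt(mean(ob_line), 1.2 * resp_ax)
})

test_that("raising tube contrast never lowers centerline vesselness", {
  d <- c(32, 32, 32)
  tube <- hippovessel:::render_tube(d, rbind(c(16, 4, 16), c(16, 28, 16)), 2)
  noise <- with_seed(12, array(stats::rnorm(prod(d), 0, 2), d))
  resp <- vapply(c(20, 60, 120, 200), function(contrast) {
    a <- noise; a[tube] <- a[tube] + contrast
    sm <- hippovessel:::gaussian_filter3(a, 0.75, c(0.75, 0.75, 0.75), c(0, 0, 0))
    ms <- multiscale_vesselness(hv_volume(sm, voxel_size = c(0.75, 0.75, 0.75)),
                                vesselness_params())
    mean(ms$data[16, 10:22, 16])
  }, numeric(1))
  expect_true(all(diff(resp) >= -1e-10))
})
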