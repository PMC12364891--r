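test_that("model specification enforces hemisphere matching and transforms", {
  sp <- mediation_spec("sbp", "vessel_si_total", "hippo_vol_total")
  expect_equal(sp$hemisphere, "total")
  expect_error(mediation_spec("sbp", "vessel_si_left", "hippo_vol_right"),
               "hemisphere")
  expect_error(mediation_spec("sbp", "sbp", "hippo_vol_total"), "distinct")
})

test_that("log1p transform handles boundary values and monotonicity", {
  expect_equal(log1p_transform(0), 0)
  expect_equal(log1p_transform(exp(1) - 1), 1)
  x <- sort(with_seed(2, stats::runif(50, 0, 100)))
  expect_true(all(diff(log1p_transform(x)) > 0))
  expect_true(is.na(log1p_transform(c(1, NA))[2]))
  expect_error(log1p_transform(-0.1), "negative")
})

test_that("noiseless linear structure is recovered exactly", {
  n <- 64
  x1 <- with_seed(10, stats::rnorm(n))
  u <- rep(c(1, 1, -1, -1), n / 4)
  u <- drop(u - cbind(1, x1) %*% oracle_ols(cbind(1, x1), u))  # orthogonal to {1, x}
  df <- tibble::tibble(subject_id = as.character(1:n), x1 = x1,
                       m1 = 2 * x1 + u)
  df$y1 <- 3 * df$m1
  f <- fit_path_model(df, mediation_spec("x1", "m1", "y1", covariates = character(0)))
  expect_equal(f$a, 2, tolerance = 1e-8)
  expect_equal(f$b, 3, tolerance = 1e-8)
  expect_equal(f$c_prime, 0, tolerance = 1e-8)
  expect_equal(f$indirect, 6, tolerance = 1e-8)
  expect_equal(f$total, f$c_prime + f$indirect, tolerance = 1e-12)
})

test_that("estimates equal the normal-equations oracle with covariates", {
  dd <- make_cohort(cohort_spec(n = 300, a = 0.5, b = 0.4, c_prime = 0.1,
                                covariate_effects_y = c(icv = 0.3), seed = 14))
  tr <- attr(dd, "truth")
  f <- fit_path_model(dd, mediation_spec(tr$x, tr$m, tr$y))
  o <- oracle_path(dd, tr$x, tr$m, tr$y)
  expect_equal(f$a, o$a, tolerance = 1e-8)
  expect_equal(f$b, o$b, tolerance = 1e-8)
  expect_equal(f$c_prime, o$c_prime, tolerance = 1e-8)
  expect_equal(f$total, o$total, tolerance = 1e-8)
})

test_that("estimates land within 3 analytic SEs of the generating truth", {
  dd <- make_cohort(cohort_spec(n = 500, a = 0.5, b = 0.4, c_prime = 0.1, seed = 11))
  tr <- attr(dd, "truth")
  f <- fit_path_model(dd, mediation_spec(tr$x, tr$m, tr$y))
  # X ~ N(0,1), unit noise: se(a) ~ 1/sqrt(n); se(b) ~ 1/sqrt(n) as well
  se <- 1 / sqrt(500)
  expect_lt(abs(f$a - 0.5), 3 * se)
  expect_lt(abs(f$b - 0.4), 3 * se)
  expect_lt(abs(f$c_prime - 0.1), 3 * se * 1.2)
  expect_equal(f$n_used, 500)
})

test_that("singular designs and short tables raise informative errors", {
  dd <- make_cohort(cohort_spec(n = 50, seed = 3))
  dd$dup <- dd$sbp
  expect_error(fit_path_model(dd, mediation_spec("sbp", "dup", "hippo_vol_total")),
               "collinear")
  expect_error(fit_path_model(dd[1:5, ], mediation_spec("sbp", "vessel_si_total",
                                                        "hippo_vol_total")),
               "complete cases")
})

test_that("listwise deletion drops exactly the rows missing model variables", {
  dd <- make_cohort(cohort_spec(n = 80, seed = 4))
  dd$sbp[c(3, 9)] <- NA
  dd$icv[10] <- NA
  dd$dbp[15] <- NA   # not in this model; must not cost a row
  f <- fit_path_model(dd, mediation_spec("sbp", "vessel_si_total", "hippo_vol_total"))
  expect_equal(f$n_used, 77)
})

test_that("bootstrap is seed-reproducible and decomposition holds per draw", {
  dd <- make_cohort(cohort_spec(n = 150, seed = 5))
  tr <- attr(dd, "truth")
  sp <- mediation_spec(tr$x, tr$m, tr$y)
  b1 <- bootstrap_mediation(dd, sp, n_boot = 400, seed = 99)
  b2 <- bootstrap_mediation(dd, sp, n_boot = 400, seed = 99)
  expect_identical(b1$draws, b2$draws)
  expect_identical(b1$ci_indirect, b2$ci_indirect)
  # c = c' + a*b exactly in every bootstrap replicate
  expect_equal(b1$draws[, "total"],
               b1$draws[, "direct"] + b1$draws[, "indirect"],
               tolerance = 1e-10)
  # significance flags match the 0-outside-CI rule
  expect_identical(b1$significant_indirect,
                   unname(b1$ci_indirect[1] > 0 | b1$ci_indirect[2] < 0))
  expect_error(bootstrap_mediation(dd, sp, n_boot = 0), "n_boot")
})

test_that("the default grid enumerates 138 hemisphere-matched models", {
  g <- build_model_grid()
  expect_length(g, 138)
  expect_true(all(vapply(g, inherits, logical(1), "hv_mediation_spec")))
  ms <- vapply(g, function(s) s$m, character(1))
  ys <- vapply(g, function(s) s$y, character(1))
  expect_true(all(sub(".*_", "", ms) == sub(".*_", "", ys)))
  # insulin and IL-6 models carry the log1p transform
  tr <- vapply(g, function(s) s$transform_x, character(1))
  xs <- vapply(g, function(s) s$x, character(1))
  expect_true(all(tr[xs %in% c("insulin", "il6")] == "log1p"))
  expect_true(all(tr[!xs %in% c("insulin", "il6")] == "none"))
  # degenerate single-cell grid
  g1 <- build_model_grid(systemic = "sbp", hemispheres = "total", mediators = "vessel_si")
  expect_length(g1, 1)
  expect_error(build_model_grid(systemic = c("sbp", "sbp")), "duplicate")
})

test_that("grid runner returns one row per model and confirms only significant ones", {
  dd <- make_cohort(cohort_spec(n = 120, a = 0.8, b = 0.8, seed = 6))
  grid <- build_model_grid(systemic = c("sdnn", "sbp", "glucose"),
                           hemispheres = "total")
  res <- run_grid(dd, grid, n_boot = 300, confirm_boot = 600, seed = 42)
  expect_s3_class(res, "hv_grid_result")
  expect_equal(nrow(res), length(grid))
  expect_false(any(res$failed))
  any_sig <- res$significant_indirect | res$significant_direct | res$significant_total
  expect_identical(res$confirmed, any_sig)
  expect_true(all(is.na(res$confirm_ci_indirect_low[!res$confirmed])))
  expect_true(all(is.finite(res$confirm_ci_indirect_low[res$confirmed])))
  # the engineered sdnn model must be found
  expect_true(res$significant_indirect[res$x == "sdnn" & res$m == "vessel_si_total"])
  # derived per-model seeds are deterministic
  res2 <- run_grid(dd, grid, n_boot = 300, confirm_boot = 600, seed = 42)
  expect_identical(res$ci_indirect_low, res2$ci_indirect_low)
})

test_that("grid-level null false-positive rate is near the nominal level", {
  dd <- make_cohort(cohort_spec(n = 191, a = 0, c_prime = 0, seed = 77))
  res <- run_grid(dd, build_model_grid(), n_boot = 500, confirm_boot = 0, seed = 8)
  fp <- mean(res$significant_indirect)
  expect_gte(fp, 0)
  expect_lte(fp, 0.12)   # ~5% nominal; rows share columns, so wide binomial band
})

test_that("covariate adjustment removes confounder bias in the indirect effect", {
  biases <- vapply(1:30, function(i) {
    dd <- make_cohort(cohort_spec(n = 400, a = 0.5, b = 0.4,
                                  covariate_effects_m = c(icv = 0.8),
                                  covariate_effects_y = c(icv = 0.8),
                                  seed = 1000 + i))
    tr <- attr(dd, "truth")
    adj <- fit_path_model(dd, mediation_spec(tr$x, tr$m, tr$y))$indirect
    raw <- fit_path_model(dd, mediation_spec(tr$x, tr$m, tr$y,
                                             covariates = character(0)))$indirect
    c(adj - 0.2, raw - 0.2)
  }, numeric(2))
  expect_lt(abs(mean(biases[1, ])), 0.02)   # adjusted: unbiased
  expect_gt(abs(mean(biases[2, ])), 0.02)   # omitted covariates: biased
})

test_that("tidy and glance expose broom-style summaries", {
  dd <- make_cohort(cohort_spec(n = 100, seed = 9))
  tr <- attr(dd, "truth")
  sp <- mediation_spec(tr$x, tr$m, tr$y)
  f <- fit_path_model(dd, sp)
  td <- generics::tidy(f)
  expect_equal(td$term, c("a", "b", "c_prime", "indirect", "total"))
  b <- bootstrap_mediation(dd, sp, n_boot = 200, seed = 2)
  tb <- generics::tidy(b)
  expect_named(tb, c("term", "estimate", "conf.low", "conf.high", "significant"))
  gl <- generics::glance(b)
  expect_equal(gl$n_boot, 200)
})
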