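#' Specify one mediation model
#'
#' A single X -> M -> Y path model: `x` a systemic variable, `m` a vessel
#' metric column (volume or SI; total/left/right), `y` a hippocampal
#' volume column of the matching hemisphere. Covariates enter both the
#' mediator and the outcome equation. Skewed concentrations (insulin,
#' IL-6 by default) are log(1+x)-transformed before fitting.
#'
#' @param x,m,y distinct column names; the hemisphere suffix of `m` must
#'   match `y` (`total`/`left`/`right`).
#' @param covariates covariate column names (default age, sex, icv).
#' @param transform_x `"none"` or `"log1p"`.
#' @return A list of class `hv_mediation_spec`.
#' @export
mediation_spec <- function(x, m, y, covariates = c("age", "sex", "icv"),
                           transform_x = c("none", "log1p")) {
  transform_x <- match.arg(transform_x)
  if (anyDuplicated(c(x, m, y)))
    stop("mediation_spec: x, m, y must be distinct", call. = FALSE)
  hemi <- function(nm) {
    h <- sub(".*_(total|left|right)$", "\\1", nm)
    if (h == nm) NA_character_ else h
  }
  hm <- hemi(m); hy <- hemi(y)
  if (!is.na(hm) && !is.na(hy) && hm != hy)
    stop("mediation_spec: hemisphere of mediator (", hm,
         ") must match outcome (", hy, ")", call. = FALSE)
  structure(list(x = x, m = m, y = y, covariates = covariates,
                 transform_x = transform_x,
                 hemisphere = if (!is.na(hy)) hy else hm),
            class = "hv_mediation_spec")
}

#' log(1 + x) transform for skewed non-negative variables
#'
#' @param values non-negative numeric vector; `NA` stays `NA`.
#' @return `log(1 + values)`.
#' @export
log1p_transform <- function(values) {
  if (any(values < 0, na.rm = TRUE))
    stop("log1p_transform: negative input (expects concentrations >= 0)",
         call. = FALSE)
  log1p(values)
}

# design matrices for the two path equations, complete cases only
mediation_design <- function(records, spec) {
  cols <- c(spec$x, spec$m, spec$y, spec$covariates)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    stop("mediation: columns absent from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- records[cols]
  keep <- stats::complete.cases(df)
  df <- df[keep, ]
  x <- df[[spec$x]]
  if (spec$transform_x == "log1p") x <- log1p_transform(x)
  ncov <- length(spec$covariates)
  Xm <- cbind(1, x, if (ncov) as.matrix(df[spec$covariates]))
  colnames(Xm) <- c("(intercept)", spec$x, spec$covariates)
  Xy <- cbind(1, x, df[[spec$m]], if (ncov) as.matrix(df[spec$covariates]))
  colnames(Xy) <- c("(intercept)", spec$x, spec$m, spec$covariates)
  list(Xm = Xm, m = df[[spec$m]], Xy = Xy, y = df[[spec$y]],
       n = nrow(df))
}

ols_coef <- function(X, y) {
  fit <- .lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    bad <- colnames(X)[fit$pivot[seq.int(fit$rank + 1L, ncol(X))]]
    stop("singular design matrix; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  co <- numeric(ncol(X))
  co[fit$pivot] <- fit$coefficients
  names(co) <- colnames(X)
  co
}

path_from_design <- function(des, spec) {
  cm <- ols_coef(des$Xm, des$m)
  cy <- ols_coef(des$Xy, des$y)
  a <- unname(cm[spec$x])
  b <- unname(cy[spec$m])
  c_prime <- unname(cy[spec$x])
  list(a = a, b = b, c_prime = c_prime,
       indirect = a * b, total = c_prime + a * b)
}

#' Fit one mediation path model by least squares
#'
#' Two-equation recursive path model: `a` from regressing M on X and the
#' covariates; `b` and the direct effect `c'` from regressing Y on X, M
#' and the covariates. The indirect effect is `a * b` and the total
#' effect decomposes exactly as `c = c' + a * b` (the maximum-likelihood
#' solution of the saturated recursive path model). Estimates are
#' unstandardized. Rows with missing values in any model variable are
#' dropped (listwise deletion); the complete-case count is returned.
#'
#' @param records subject tibble (see [read_subject_table()]).
#' @param spec a [mediation_spec()].
#' @return A list of class `hv_path_fit`: `a`, `b`, `c_prime`, `indirect`,
#'   `total`, `n_used`, `spec`.
#' @export
fit_path_model <- function(records, spec) {
  stopifnot(inherits(spec, "hv_mediation_spec"))
  des <- mediation_design(records, spec)
  p <- ncol(des$Xy)
  if (des$n < p + 1L)
    stop("fit_path_model: only ", des$n, " complete cases for ", p,
         " parameters", call. = FALSE)
  est <- path_from_design(des, spec)
  structure(c(est, list(n_used = des$n, spec = spec)), class = "hv_path_fit")
}

#' @export
print.hv_path_fit <- function(x, ...) {
  cat(sprintf("<mediation fit> %s -> %s -> %s (n = %d)\n",
              x$spec$x, x$spec$m, x$spec$y, x$n_used))
  cat(sprintf("  a = %.4g, b = %.4g, c' = %.4g, indirect = %.4g, total = %.4g\n",
              x$a, x$b, x$c_prime, x$indirect, x$total))
  invisible(x)
}

# run fn() with a locally seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  fn()
}

#' Percentile-bootstrap mediation inference
#'
#' Resamples subjects (rows) with replacement, refits both path equations
#' jointly per resample, and forms percentile confidence intervals for
#' the indirect, direct and total effects from the empirical quantiles
#' (the 2.5th and 97.5th for the default 95% level). An effect is flagged
#' significant when 0 lies outside its interval. Degenerate resamples
#' whose design matrix is singular are rejected and redrawn; more than 1%
#' of them aborts with a reliability error. Given a seed, results are
#' reproducible bit-for-bit (Mersenne-Twister, inversion normals).
#'
#' @param records subject tibble.
#' @param spec a [mediation_spec()].
#' @param n_boot number of bootstrap iterations (>= 1000 recommended;
#'   5000 default).
#' @param seed integer RNG seed.
#' @param level confidence level in (0, 1).
#' @return A list of class `hv_mediation_boot` with the point fit,
#'   per-effect CIs, significance flags, `n_boot`, `seed`, and the
#'   redraw count.
#' @export
bootstrap_mediation <- function(records, spec, n_boot = 5000, seed = 1,
                                level = 0.95) {
  stopifnot(inherits(spec, "hv_mediation_spec"))
  if (n_boot < 1)
    stop("bootstrap_mediation: n_boot must be positive", call. = FALSE)
  if (!(level > 0 && level < 1))
    stop("bootstrap_mediation: level must be in (0, 1)", call. = FALSE)
  fit <- fit_path_model(records, spec)
  des <- mediation_design(records, spec)
  n <- des$n
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  draws <- matrix(NA_real_, n_boot, 3L,
                  dimnames = list(NULL, c("indirect", "direct", "total")))
  n_redraw <- 0L
  with_local_seed(seed, function() {
    i <- 1L
    while (i <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      est <- tryCatch(
        path_from_design(list(Xm = des$Xm[idx, , drop = FALSE], m = des$m[idx],
                              Xy = des$Xy[idx, , drop = FALSE], y = des$y[idx]),
                         spec),
        error = function(e) NULL)
      if (is.null(est)) {
        n_redraw <<- n_redraw + 1L
        if (n_redraw > max(10L, ceiling(0.01 * n_boot)))
          stop("bootstrap_mediation: more than 1% of resamples singular (",
               n_redraw, " redraws); design too fragile for resampling",
               call. = FALSE)
        next
      }
      draws[i, ] <<- c(est$indirect, est$c_prime, est$total)
      i <- i + 1L
    }
  })
  ci <- apply(draws, 2L, stats::quantile, probs = probs, names = FALSE, type = 7)
  sig <- ci[1, ] > 0 | ci[2, ] < 0
  structure(list(
    estimates = fit,
    ci_indirect = ci[, "indirect"], ci_direct = ci[, "direct"],
    ci_total = ci[, "total"],
    significant_indirect = unname(sig["indirect"]),
    significant_direct = unname(sig["direct"]),
    significant_total = unname(sig["total"]),
    n_boot = n_boot, seed = seed, level = level, n_redraw = n_redraw,
    draws = draws
  ), class = "hv_mediation_boot")
}

#' @export
print.hv_mediation_boot <- function(x, ...) {
  print(x$estimates)
  f <- function(nm, ci, sig)
    cat(sprintf("  %-8s CI [%.4g, %.4g]%s\n", nm, ci[1], ci[2],
                if (sig) " *" else ""))
  f("indirect", x$ci_indirect, x$significant_indirect)
  f("direct", x$ci_direct, x$significant_direct)
  f("total", x$ci_total, x$significant_total)
  cat(sprintf("  %d bootstrap iterations, seed %d\n", x$n_boot, x$seed))
  invisible(x)
}

#' Build the full mediation model grid
#'
#' Crosses the systemic variables with the three hippocampal volume
#' measures (total, left, right) and the two vessel mediator metrics
#' (volume, SI), pairing mediator and outcome hemisphere-wise. With the
#' default 23 systemic variables this yields 23 x 3 x 2 = 138 models.
#' Default transforms ([log1p_variables()]) are applied.
#'
#' @param systemic character vector of systemic variable names.
#' @param hemispheres subset of `c("total", "left", "right")`.
#' @param mediators subset of `c("vessel_vol", "vessel_si")`.
#' @param covariates covariate names for every model.
#' @param log1p_vars variables receiving the log(1+x) transform.
#' @return A list of [mediation_spec()] objects.
#' @export
build_model_grid <- function(systemic = systemic_variables(),
                             hemispheres = c("total", "left", "right"),
                             mediators = c("vessel_vol", "vessel_si"),
                             covariates = c("age", "sex", "icv"),
                             log1p_vars = log1p_variables()) {
  if (anyDuplicated(systemic))
    stop("build_model_grid: duplicate systemic variable names", call. = FALSE)
  grid <- expand.grid(x = systemic, hemi = hemispheres, med = mediators,
                      stringsAsFactors = FALSE)
  purrr::pmap(grid, function(x, hemi, med) {
    mediation_spec(
      x = x,
      m = paste0(med, "_", hemi),
      y = paste0("hippo_vol_", hemi),
      covariates = covariates,
      transform_x = if (x %in% log1p_vars) "log1p" else "none"
    )
  })
}

# deterministic per-model seed derived from the master seed
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 7919 * as.double(index)) %% 2147483647)
}

#' Run the mediation grid with bootstrap confirmation
#'
#' Fits and bootstraps every model in the grid; rows significant for any
#' effect at `n_boot` iterations are re-tested at `confirm_boot`
#' iterations (50,000 by default) and both results are retained. Failed
#' models become rows with `failed = TRUE` rather than being dropped.
#' Per-model seeds are deterministic functions of `(seed, model index)`.
#'
#' @param records subject tibble.
#' @param grid list of [mediation_spec()] (default [build_model_grid()]).
#' @param n_boot first-pass bootstrap iterations.
#' @param confirm_boot confirmation iterations for significant rows.
#' @param seed master integer seed.
#' @param level confidence level.
#' @return A tibble of class `hv_grid_result`, one row per model.
#' @export
run_grid <- function(records, grid = build_model_grid(), n_boot = 5000,
                     confirm_boot = 50000, seed = 1, level = 0.95) {
  if (!length(grid)) stop("run_grid: empty grid", call. = FALSE)
  rows <- purrr::imap(grid, function(spec, i) {
    sd_i <- derive_seed(seed, i)
    res <- tryCatch(
      bootstrap_mediation(records, spec, n_boot = n_boot, seed = sd_i,
                          level = level),
      error = function(e) e)
    if (inherits(res, "error")) {
      return(tibble::tibble(
        spec_id = i, x = spec$x, m = spec$m, y = spec$y,
        hemisphere = spec$hemisphere %||% NA_character_,
        transform_x = spec$transform_x,
        a = NA_real_, b = NA_real_, c_prime = NA_real_,
        indirect = NA_real_, total = NA_real_, n_used = NA_integer_,
        ci_indirect_low = NA_real_, ci_indirect_high = NA_real_,
        ci_direct_low = NA_real_, ci_direct_high = NA_real_,
        ci_total_low = NA_real_, ci_total_high = NA_real_,
        significant_indirect = NA, significant_direct = NA,
        significant_total = NA, n_boot = n_boot, seed = sd_i,
        confirmed = FALSE,
        confirm_ci_indirect_low = NA_real_, confirm_ci_indirect_high = NA_real_,
        confirm_significant_indirect = NA,
        failed = TRUE, error = conditionMessage(res)))
    }
    est <- res$estimates
    any_sig <- isTRUE(res$significant_indirect) ||
      isTRUE(res$significant_direct) || isTRUE(res$significant_total)
    conf <- NULL
    if (any_sig && confirm_boot > n_boot) {
      conf <- bootstrap_mediation(records, spec, n_boot = confirm_boot,
                                  seed = derive_seed(sd_i, 1L), level = level)
    }
    tibble::tibble(
      spec_id = i, x = spec$x, m = spec$m, y = spec$y,
      hemisphere = spec$hemisphere %||% NA_character_,
      transform_x = spec$transform_x,
      a = est$a, b = est$b, c_prime = est$c_prime,
      indirect = est$indirect, total = est$total, n_used = est$n_used,
      ci_indirect_low = res$ci_indirect[1], ci_indirect_high = res$ci_indirect[2],
      ci_direct_low = res$ci_direct[1], ci_direct_high = res$ci_direct[2],
      ci_total_low = res$ci_total[1], ci_total_high = res$ci_total[2],
      significant_indirect = res$significant_indirect,
      significant_direct = res$significant_direct,
      significant_total = res$significant_total,
      n_boot = n_boot, seed = sd_i,
      confirmed = !is.null(conf),
      confirm_ci_indirect_low = if (is.null(conf)) NA_real_ else conf$ci_indirect[1],
      confirm_ci_indirect_high = if (is.null(conf)) NA_real_ else conf$ci_indirect[2],
      confirm_significant_indirect = if (is.null(conf)) NA else conf$significant_indirect,
      failed = FALSE, error = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hv_grid_result", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mediation fit or bootstrap result
#'
#' @param x an `hv_path_fit` or `hv_mediation_boot`.
#' @param ... unused.
#' @return A tibble with one row per path term (broom convention).
#' @exportS3Method generics::tidy
#' @export
tidy.hv_path_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c_prime", "indirect", "total"),
    estimate = c(x$a, x$b, x$c_prime, x$indirect, x$total)
  )
}

#' @rdname tidy.hv_path_fit
#' @exportS3Method generics::tidy
#' @export
tidy.hv_mediation_boot <- function(x, ...) {
  est <- x$estimates
  tibble::tibble(
    term = c("indirect", "direct", "total"),
    estimate = c(est$indirect, est$c_prime, est$total),
    conf.low = c(x$ci_indirect[1], x$ci_direct[1], x$ci_total[1]),
    conf.high = c(x$ci_indirect[2], x$ci_direct[2], x$ci_total[2]),
    significant = c(x$significant_indirect, x$significant_direct,
                    x$significant_total)
  )
}

#' @rdname tidy.hv_path_fit
#' @exportS3Method generics::glance
#' @export
glance.hv_mediation_boot <- function(x, ...) {
  tibble::tibble(n_used = x$estimates$n_used, n_boot = x$n_boot,
                 level = x$level, seed = x$seed, n_redraw = x$n_redraw)
}
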