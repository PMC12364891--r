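#' Specify a simulated cohort with known mediation structure
#'
#' Draws a subject table whose target X -> M -> Y triple follows the
#' linear path model
#' `M = mu_m + a X + gamma_m' C + e_m`, `Y = mu_y + b M + c' X + gamma_y' C + e_y`,
#' with covariates C = (age, sex, ICV; standardized inside the generator)
#' and independent Gaussian noise. All remaining systemic and imaging
#' columns are drawn with realistic marginals but no structural relation
#' to the target, so the stored truth supports closed-loop parameter
#' recovery. Demographics emulate a midlife community cohort: n = 191,
#' age uniform on 30-59 years, 115/191 female (sex coded 1), ICV normal.
#' Hemisphere asymmetries default to the group means reported for this
#' population (hippocampal volume 3730/3620 mm^3, vessel volume 224/190
#' mm^3, vessel SI 1.64/1.61).
#'
#' @param n number of subjects (>= 10).
#' @param x target systemic variable name.
#' @param mediator `"vessel_si"` or `"vessel_vol"`.
#' @param hemisphere `"total"`, `"left"` or `"right"`.
#' @param a,b,c_prime true path coefficients.
#' @param covariate_effects_m,covariate_effects_y named vectors with
#'   entries `age`, `sex`, `icv`: loadings of the standardized covariates
#'   on M and Y.
#' @param noise_sd_m,noise_sd_y positive noise SDs.
#' @param rho_x pairwise correlation imposed across the Gaussian systemic
#'   variables (shared-factor construction); 0 keeps them independent.
#' @param seed integer RNG seed.
#' @return A list of class `hv_cohort_spec`.
#' @export
cohort_spec <- function(n = 191, x = "sdnn",
                        mediator = c("vessel_si", "vessel_vol"),
                        hemisphere = c("total", "left", "right"),
                        a = 0.5, b = 0.4, c_prime = 0.1,
                        covariate_effects_m = c(age = 0, sex = 0, icv = 0),
                        covariate_effects_y = c(age = 0, sex = 0, icv = 0),
                        noise_sd_m = 1, noise_sd_y = 1,
                        rho_x = 0, seed = 1L) {
  mediator <- match.arg(mediator)
  hemisphere <- match.arg(hemisphere)
  if (n < 10) stop("cohort_spec: n must be >= 10", call. = FALSE)
  if (noise_sd_m <= 0 || noise_sd_y <= 0)
    stop("cohort_spec: noise SDs must be positive", call. = FALSE)
  if (!x %in% systemic_variables())
    stop("cohort_spec: unknown systemic variable ", x, call. = FALSE)
  ce <- function(v) {
    out <- c(age = 0, sex = 0, icv = 0)
    out[names(v)] <- v
    out
  }
  structure(list(n = as.integer(n), x = x, mediator = mediator,
                 hemisphere = hemisphere, a = a, b = b, c_prime = c_prime,
                 covariate_effects_m = ce(covariate_effects_m),
                 covariate_effects_y = ce(covariate_effects_y),
                 noise_sd_m = noise_sd_m, noise_sd_y = noise_sd_y,
                 rho_x = rho_x, seed = as.integer(seed)),
            class = "hv_cohort_spec")
}

# reference marginals for the imaging columns (group mean, SD)
cohort_reference_means <- function() {
  list(hippo = c(left = 3620, right = 3730, sd = 405),
       vessel_vol = c(left = 190, right = 224, sd_left = 91, sd_right = 108),
       vessel_si = c(left = 1.61, right = 1.64, sd = 0.28))
}

#' Simulate a cohort table
#'
#' @param spec an [cohort_spec()].
#' @return A subject tibble (schema of [read_subject_table()], totals
#'   included) with the generating truth stored in `attr(, "truth")`.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "hv_cohort_spec"))
  n <- spec$n
  ref <- cohort_reference_means()
  with_local_seed(spec$seed, function() {
    age <- stats::runif(n, 30, 59)
    sex <- stats::rbinom(n, 1, 115 / 191)          # 1 = female
    icv <- stats::rnorm(n, 1.5e6, 1.5e5)
    Cs <- cbind(age = (age - 44.5) / 8.4,
                sex = (sex - 115 / 191) / 0.49,
                icv = (icv - 1.5e6) / 1.5e5)

    sysv <- systemic_variables()
    shared <- stats::rnorm(n)
    Xmat <- sapply(sysv, function(v) {
      if (v %in% log1p_variables()) {
        base <- if (v == "insulin") stats::rlnorm(n, log(10), 0.6)
                else stats::rlnorm(n, log(1.5), 0.6)
        base
      } else if (spec$rho_x > 0) {
        sqrt(spec$rho_x) * shared + sqrt(1 - spec$rho_x) * stats::rnorm(n)
      } else stats::rnorm(n)
    })
    colnames(Xmat) <- sysv

    xv <- Xmat[, spec$x]
    xt <- if (spec$x %in% log1p_variables()) log1p(xv) else xv

    m_struct <- spec$a * xt + drop(Cs %*% spec$covariate_effects_m) +
      stats::rnorm(n, 0, spec$noise_sd_m)

    df <- tibble::tibble(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      age = age, sex = sex, icv = icv)
    for (v in sysv) df[[v]] <- Xmat[, v]

    # unstructured imaging columns at realistic marginals
    df$vessel_vol_left <- pmax(1, stats::rnorm(n, ref$vessel_vol["left"],
                                               ref$vessel_vol["sd_left"]))
    df$vessel_vol_right <- pmax(1, stats::rnorm(n, ref$vessel_vol["right"],
                                                ref$vessel_vol["sd_right"]))
    df$vessel_si_left <- stats::rnorm(n, ref$vessel_si["left"], ref$vessel_si["sd"])
    df$vessel_si_right <- stats::rnorm(n, ref$vessel_si["right"], ref$vessel_si["sd"])

    med_base <- if (spec$mediator == "vessel_si")
      mean(ref$vessel_si[c("left", "right")]) else
      sum(ref$vessel_vol[c("left", "right")])

    if (spec$hemisphere == "total") {
      if (spec$mediator == "vessel_si") {
        asym <- (ref$vessel_si["right"] - ref$vessel_si["left"]) / 2
        mid <- med_base + m_struct
        df$vessel_si_left <- mid - asym + stats::rnorm(n, 0, 0.01)
        df$vessel_si_right <- mid + asym + stats::rnorm(n, 0, 0.01)
        # equal vessel volumes => volume-weighted total SI == mid + small dev
        w <- pmax(1, stats::rnorm(n, 207, 60))
        df$vessel_vol_left <- w
        df$vessel_vol_right <- w
      } else {
        tot <- pmax(2, med_base + m_struct)
        wfrac <- stats::rnorm(n, unname(ref$vessel_vol["left"]) /
                                 (ref$vessel_vol["left"] + ref$vessel_vol["right"]), 0.01)
        df$vessel_vol_left <- tot * wfrac
        df$vessel_vol_right <- tot * (1 - wfrac)
      }
    } else {
      side_col <- paste0(spec$mediator, "_", spec$hemisphere)
      side_mu <- if (spec$mediator == "vessel_si")
        ref$vessel_si[spec$hemisphere] else ref$vessel_vol[spec$hemisphere]
      df[[side_col]] <- unname(side_mu) + m_struct
    }

    # observable mediator column (totals not derivable yet: hippocampal
    # columns are generated below, after the outcome structure)
    m_obs <- if (spec$hemisphere == "total") {
      if (spec$mediator == "vessel_vol") df$vessel_vol_left + df$vessel_vol_right
      else (df$vessel_si_left * df$vessel_vol_left +
            df$vessel_si_right * df$vessel_vol_right) /
           (df$vessel_vol_left + df$vessel_vol_right)
    } else df[[paste0(spec$mediator, "_", spec$hemisphere)]]

    y_struct <- spec$b * (m_obs - mean(m_obs)) + spec$c_prime * xt +
      drop(Cs %*% spec$covariate_effects_y) + stats::rnorm(n, 0, spec$noise_sd_y)

    if (spec$hemisphere == "total") {
      tot <- sum(ref$hippo[c("left", "right")]) + y_struct
      frac <- stats::rnorm(n, unname(ref$hippo["left"]) /
                              sum(ref$hippo[c("left", "right")]), 0.002)
      df$hippo_vol_left <- tot * frac
      df$hippo_vol_right <- tot * (1 - frac)
    } else {
      other <- setdiff(c("left", "right"), spec$hemisphere)
      df[[paste0("hippo_vol_", spec$hemisphere)]] <-
        unname(ref$hippo[spec$hemisphere]) + y_struct
      df[[paste0("hippo_vol_", other)]] <-
        stats::rnorm(n, ref$hippo[other], ref$hippo["sd"])
    }

    df <- derive_totals(df)
    attr(df, "truth") <- list(
      x = spec$x, m = paste0(spec$mediator, "_", spec$hemisphere),
      y = paste0("hippo_vol_", spec$hemisphere),
      a = spec$a, b = spec$b, c_prime = spec$c_prime,
      indirect = spec$a * spec$b,
      covariate_effects_m = spec$covariate_effects_m,
      covariate_effects_y = spec$covariate_effects_y,
      transform_x = if (spec$x %in% log1p_variables()) "log1p" else "none")
    df
  })
}
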