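# Independent oracles used to freeze expected values. These deliberately
# re-derive each quantity by a different route than the package code.

# Per-center triple-loop enhancement oracle: for each cube center, extract
# the 8 companion cubes as explicit sub-arrays, transform every intra-cube
# 8-vector, re-apply the published piecewise rule written out directly,
# inverse-transform, and accumulate the reference-cube contribution with
# an explicit overlap counter.
oracle_enhance <- function(vol, params, zero_details = FALSE) {
  a <- vol$data
  d <- dim(a)
  cs <- params$cube_size; half <- cs %/% 2L; pad <- cs
  idx <- lapply(d, function(n) c(rev(seq_len(pad) + 1L), seq_len(n), n - seq_len(pad)))
  ap <- a[idx[[1]], idx[[2]], idx[[3]]]
  dp <- dim(ap)
  H <- haar_matrix_8()
  offs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  acc <- array(0, dp); cnt <- array(0, dp)
  piecewise <- function(co) {
    m <- abs(co)
    out <- ifelse(m > params$alpha1, co,
           ifelse(m >= params$alpha2, params$gamma1 * co,
           ifelse(m >= params$beta, params$gamma2 * co, 0)))
    out
  }
  for (i in (half + 1L):(dp[1] - half - 1L))
    for (j in (half + 1L):(dp[2] - half - 1L))
      for (k in (half + 1L):(dp[3] - half - 1L)) {
        S <- matrix(0, cs^3, 8L)
        for (q in 1:8) {
          o <- offs[q, ]
          S[, q] <- as.vector(ap[i + o[1] + (-half:half),
                                 j + o[2] + (-half:half),
                                 k + o[3] + (-half:half)])
        }
        C <- S %*% t(H)
        if (zero_details) C[, 2:8] <- 0 else C[, 2:8] <- piecewise(C[, 2:8])
        rec <- C %*% H[, 1]
        xs <- i + (-half:half); ys <- j + (-half:half); zs <- k + (-half:half)
        acc[xs, ys, zs] <- acc[xs, ys, zs] + array(rec, c(cs, cs, cs))
        cnt[xs, ys, zs] <- cnt[xs, ys, zs] + 1
      }
  out <- acc / cnt
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])]
}

# Brute-force OLS via the normal equations (vs the QR route in the package)
oracle_ols <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# path estimates recomputed from scratch with the normal-equations oracle
oracle_path <- function(df, x, m, y, covariates = c("age", "sex", "icv"),
                        transform_x = "none") {
  cols <- c(x, m, y, covariates)
  dd <- df[stats::complete.cases(df[cols]), cols]
  xv <- if (transform_x == "log1p") log1p(dd[[x]]) else dd[[x]]
  Xm <- cbind(1, xv, as.matrix(dd[covariates]))
  Xy <- cbind(1, xv, dd[[m]], as.matrix(dd[covariates]))
  cm <- unname(oracle_ols(Xm, dd[[m]]))
  cy <- unname(oracle_ols(Xy, dd[[y]]))
  list(a = cm[2], b = cy[3], c_prime = cy[2],
       indirect = cm[2] * cy[3], total = cy[2] + cm[2] * cy[3])
}

# small helper: draw with a local seed without touching global RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}
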