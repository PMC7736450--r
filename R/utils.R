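# Separable Gaussian smoothing of a 3D array, sigma per axis in voxels.
# Each axis is convolved through an explicitly built, row-normalized
# band matrix, so truncation at the borders renormalizes instead of
# darkening (constant fields are preserved exactly).
gaussian_smooth <- function(arr, sigma_vox) {
  d <- dim(arr)
  sigma_vox <- rep_len(sigma_vox, 3)
  smooth_axis <- function(a, k, sig) {
    if (sig <= 0 || d[k] == 1L) return(a)
    n <- d[k]
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-(i - j)^2 / (2 * sig^2)))
    K[abs(row(K) - col(K)) > ceiling(4 * sig)] <- 0
    K <- K / rowSums(K)
    if (k == 1) {
      array(K %*% matrix(a, n, prod(d[-1])), d)
    } else {
      perm <- switch(k, NULL, c(2, 1, 3), c(3, 2, 1))
      b <- aperm(a, perm)
      b <- array(K %*% matrix(b, n, length(a) / n), dim(b))
      aperm(b, perm)
    }
  }
  for (k in 1:3) arr <- smooth_axis(arr, k, sigma_vox[k])
  arr
}

# standard-normal random field smoothed to a correlation length (mm) and
# re-standardized to zero mean, unit sd
correlated_noise_field <- function(geometry, correlation_mm) {
  g <- geometry
  z <- array(stats::rnorm(prod(g$shape)), g$shape)
  if (correlation_mm > 0)
    z <- gaussian_smooth(z, correlation_mm / g$spacing)
  s <- stats::sd(z)
  if (s > 0) z <- (z - mean(z)) / s
  z
}

run_with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    set.seed(seed)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    })
  }
  force(expr)
}
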