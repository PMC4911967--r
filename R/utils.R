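# Internal helpers: seeded RNG scoping, frequency grids, separable cubic
# resampling, Fourier-domain filtering.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, restores. Keeps every
#' stochastic stage of the pipeline independently reproducible without
#' clobbering the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' A small string hash (polynomial, modulo a Mersenne prime) keeps derived
#' seeds inside the 32-bit range R requires and decorrelates stages that
#' share a master seed.
#' @noRd
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483629
  as.integer(h %% 2147483563L + 1L)
}

#' DFT sample frequencies (cycles/mm) for length `n` at spacing `d`
#' @noRd
fft_freq <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

#' Radial frequency magnitude grid for an `nr` x `nc` spectrum
#' @noRd
freq_radius <- function(nr, nc, pitch) {
  fy <- fft_freq(nr, pitch)
  fx <- fft_freq(nc, pitch)
  sqrt(outer(fy^2, fx^2, `+`))
}

#' Apply a modulation transfer function to an image in the Fourier domain
#'
#' `mtf_model` is either `NULL` (identity), `list(type = "gaussian",
#' sigma = <mm>)` giving MTF(f) = exp(-2 pi^2 sigma^2 f^2), or
#' `list(type = "tabulated", f = <cycles/mm>, mtf = <values>)` interpolated
#' radially (constant extrapolation at the ends).
#' @noRd
apply_mtf <- function(img, mtf_model, pitch) {
  if (is.null(mtf_model)) return(img)
  r <- freq_radius(nrow(img), ncol(img), pitch)
  h <- mtf_values(mtf_model, r)
  Re(stats::fft(stats::fft(img) * h, inverse = TRUE)) / length(img)
}

#' @noRd
mtf_values <- function(mtf_model, f) {
  type <- if (is.null(mtf_model$type)) "gaussian" else mtf_model$type
  switch(type,
    gaussian = exp(-2 * pi^2 * mtf_model$sigma^2 * f^2),
    tabulated = {
      y <- stats::approx(mtf_model$f, mtf_model$mtf, xout = as.vector(f),
                         rule = 2)$y
      array(y, dim = dim(f) %||% length(f))
    },
    stop("unknown MTF model type: ", type)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' md5-based short checksum of a metadata string
#' @noRd
hash_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  substr(unname(tools::md5sum(f)), 1, 12)
}

#' Reflect out-of-range 1-based indices back into [1, n]
#' @noRd
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  i <- ((i - 1L) %% p + p) %% p
  ifelse(i >= n, p - i, i) + 1L
}

#' Dense resampling operator for separable cubic (Catmull-Rom) interpolation
#'
#' Returns the matrix `W` such that `W %*% v` samples the length-`n_in`
#' signal `v` (unit-spaced, 1-based) at the fractional coordinates `coords`.
#' Out-of-range taps are reflected about the edges.
#' @noRd
resample_operator <- function(coords, n_in) {
  n_out <- length(coords)
  W <- matrix(0, n_out, n_in)
  base <- floor(coords)
  t <- coords - base
  t2 <- t * t
  t3 <- t2 * t
  w <- cbind(-0.5 * t3 + t2 - 0.5 * t,
             1.5 * t3 - 2.5 * t2 + 1,
             -1.5 * t3 + 2 * t2 + 0.5 * t,
             0.5 * t3 - 0.5 * t2)
  for (k in 0:3) {
    idx <- reflect_index(base + k - 1L, n_in)
    W[cbind(seq_len(n_out), idx)] <- W[cbind(seq_len(n_out), idx)] + w[, k + 1]
  }
  W
}

#' Sample an image at separable fractional row/column coordinates
#' @noRd
resample_image <- function(img, row_coords, col_coords) {
  Wr <- resample_operator(row_coords, nrow(img))
  Wc <- resample_operator(col_coords, ncol(img))
  Wr %*% img %*% t(Wc)
}

#' Gaussian random field with isotropic power-law spectrum
#'
#' White Gaussian noise shaped in the Fourier domain by |f|^(-exponent/2)
#' (frequencies in cycles/voxel, DC removed), normalised to zero mean and
#' unit variance. `dims` may have length 2 or 3.
#' @noRd
power_law_field <- function(dims, exponent, seed) {
  stopifnot(length(dims) %in% c(2L, 3L), exponent >= 0)
  freqs <- lapply(dims, fft_freq)
  r2 <- 0
  for (j in seq_along(dims)) {
    shape <- rep(1L, length(dims)); shape[j] <- dims[j]
    r2 <- r2 + array(rep(freqs[[j]]^2,
                         each = prod(dims[seq_len(j - 1L)])), dim = dims)
  }
  r <- sqrt(r2)
  amp <- ifelse(r > 0, r^(-exponent / 2), 0)
  x <- with_seed(seed, array(stats::rnorm(prod(dims)), dim = dims))
  y <- Re(stats::fft(stats::fft(x) * amp, inverse = TRUE)) / prod(dims)
  (y - mean(y)) / stats::sd(y)
}
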