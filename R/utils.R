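# Internal helpers shared across modules.

# Evaluate `code` under a private RNG stream. When `seed` is NULL the global
# stream is used (and advanced); otherwise the global stream is untouched.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), force(code))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    abort(sprintf("`%s` = %g is outside its allowed range.", name, x))
  }
  invisible(x)
}

assert_prob <- function(x, name) assert_scalar_num(x, name, 0, 1)

# Standard error of the mean; NA for n < 2.
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

# 2D FFT convolution, "same" output, replicate (edge) padding so a flat field
# convolved with a unit-sum kernel stays exactly flat.
conv2_same <- function(x, kernel, kernel_fft = NULL, pad = NULL) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  xp <- pad_replicate(x, kr, kc)
  nr <- nrow(xp); nc <- ncol(xp)
  if (is.null(kernel_fft)) {
    kp <- matrix(0, nr, nc)
    kp[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
    # centre the kernel at (1,1) so the convolution is unshifted
    kp <- shift_matrix(kp, -kr, -kc)
    kernel_fft <- fft(kp)
  }
  out <- Re(fft(fft(xp) * kernel_fft, inverse = TRUE)) / (nr * nc)
  out[(kr + 1L):(kr + nrow(x)), (kc + 1L):(kc + ncol(x)), drop = FALSE]
}

# Precompute the kernel FFT for repeated conv2_same calls at fixed image size.
conv2_plan <- function(dim_x, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  nr <- dim_x[1] + 2L * kr
  nc <- dim_x[2] + 2L * kc
  kp <- matrix(0, nr, nc)
  kp[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  kp <- shift_matrix(kp, -kr, -kc)
  list(kernel = kernel, kernel_fft = fft(kp))
}

conv2_apply <- function(x, plan) {
  conv2_same(x, plan$kernel, kernel_fft = plan$kernel_fft)
}

pad_replicate <- function(x, kr, kc) {
  ri <- c(rep(1L, kr), seq_len(nrow(x)), rep(nrow(x), kr))
  ci <- c(rep(1L, kc), seq_len(ncol(x)), rep(ncol(x), kc))
  x[ri, ci, drop = FALSE]
}

# Circularly shift a matrix by (dr, dc).
shift_matrix <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- ((seq_len(nr) - 1L - dr) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L - dc) %% nc) + 1L
  x[ri, ci, drop = FALSE]
}

# Binary dilation of a logical mask with a (2*margin+1) square structuring
# element; small masks only.
dilate_mask <- function(mask, margin) {
  if (margin <= 0) return(mask)
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1]; c <- idx[k, 2]
    out[max(1, r - margin):min(nr, r + margin),
        max(1, c - margin):min(nc, c + margin)] <- TRUE
  }
  out
}
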