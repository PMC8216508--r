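# Ordinal-pattern (rank-permutation) entropy and non-triviality of 2D fields.
#
# Every cell-sized window (stride 1) is reduced to the rank ordering of its
# values (ties broken by raster position), giving one of d! ordinal patterns
# for a d-pixel cell. The normalized Shannon entropy of the pattern
# distribution measures homogeneity; the entropy times the normalized
# Jensen-Shannon divergence from the uniform pattern distribution
# ("non-triviality", a statistical-complexity measure) is low for both
# perfectly ordered and fully random fields and higher for anisotropic
# structured ones.

# All permutations of 1..n in lexicographic order.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

#' Ordinal-pattern distribution of a 2D field
#'
#' Slides a `cell[1]` x `cell[2]` window over the image with stride 1; each
#' window's values, read in raster order (left-to-right, top-to-bottom), are
#' converted to their rank permutation with ties broken by raster position
#' (earlier pixels rank lower). Returns the relative frequency of each of the
#' `prod(cell)!` possible patterns.
#'
#' @param image numeric matrix, at least as large as `cell`.
#' @param cell window dimensions (rows, cols); default 2 x 2 (24 patterns).
#' @param mask optional logical matrix; windows touching any `FALSE` pixel
#'   are excluded.
#' @return Named numeric vector of pattern probabilities (sums to 1).
#' @export
ordinal_pattern_distribution <- function(image, cell = c(2L, 2L),
                                         mask = NULL) {
  image <- as.matrix(image)
  cr <- cell[1]; cc <- cell[2]
  if (nrow(image) < cr || ncol(image) < cc) {
    abort("image is smaller than the pattern cell")
  }
  nwr <- nrow(image) - cr + 1L
  nwc <- ncol(image) - cc + 1L
  d <- cr * cc

  # v[[k]]: value at raster offset k, for every window (as nwr x nwc matrix)
  v <- vector("list", d)
  keep <- matrix(TRUE, nwr, nwc)
  k <- 0L
  for (i in seq_len(cr)) {
    for (j in seq_len(cc)) {
      k <- k + 1L
      v[[k]] <- image[i:(i + nwr - 1L), j:(j + nwc - 1L), drop = FALSE]
      if (!is.null(mask)) {
        keep <- keep & mask[i:(i + nwr - 1L), j:(j + nwc - 1L), drop = FALSE]
      }
    }
  }
  if (!any(keep)) abort("no complete window lies inside the mask")

  code <- matrix(0, nwr, nwc)
  base <- d + 1
  for (i in seq_len(d)) {
    r_i <- 1
    for (j in seq_len(d)) {
      if (j == i) next
      r_i <- r_i + (v[[j]] < v[[i]]) + ((v[[j]] == v[[i]]) & (j < i))
    }
    code <- code + r_i * base^(i - 1)
  }

  perms <- all_permutations(d)
  perm_codes <- as.vector(perms %*% base^(seq_len(d) - 1))
  labels <- apply(perms, 1, paste0, collapse = "")
  counts <- tabulate(match(code[keep], perm_codes), nbins = nrow(perms))
  setNames(counts / sum(counts), labels)
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized ordinal-pattern entropy
#'
#' `H = -sum(p log p) / log(n_patterns)`, in `[0, 1]`. Constant or globally
#' monotone fields give 0; i.i.d. continuous noise approaches 1.
#'
#' @inheritParams ordinal_pattern_distribution
#' @return Entropy in `[0, 1]`.
#' @export
pattern_entropy <- function(image, cell = c(2L, 2L), mask = NULL) {
  p <- ordinal_pattern_distribution(image, cell, mask)
  shannon(p) / log(length(p))
}

# Normalized Jensen-Shannon disequilibrium between p and the uniform
# distribution over the same support; 0 at uniform, 1 at a point mass.
js_disequilibrium <- function(p) {
  n <- length(p)
  u <- rep(1 / n, n)
  jsd <- shannon((p + u) / 2) - shannon(p) / 2 - shannon(u) / 2
  q0 <- -0.5 * ((n + 1) / n * log(n + 1) - 2 * log(2 * n) + log(n))
  jsd / q0
}

#' Non-triviality (statistical complexity) of a 2D field
#'
#' `C = H * Q_JS` where `H` is the normalized ordinal-pattern entropy and
#' `Q_JS` the normalized Jensen-Shannon divergence between the pattern
#' distribution and the uniform distribution. `C = 0` for both degenerate
#' (single-pattern) and uniform pattern distributions; anisotropic structured
#' fields at intermediate entropy score higher.
#'
#' @inheritParams ordinal_pattern_distribution
#' @return Non-triviality, `>= 0`.
#' @export
pattern_nontriviality <- function(image, cell = c(2L, 2L), mask = NULL) {
  p <- ordinal_pattern_distribution(image, cell, mask)
  h <- shannon(p) / log(length(p))
  h * js_disequilibrium(p)
}

#' Entropy / non-triviality time course of a dF/F movie
#'
#' Computes H and C per frame over the bounding box of the bouton mask
#' dilated by `margin` pixels (windows touching pixels outside the dilated
#' mask are excluded). Amplitudes are changes from the pre-stimulus baseline
#' mean to the value at the frame of peak cumulative response, signed so that
#' the release-evoked decrease in entropy and increase in non-triviality are
#' both reported as positive: `H_amplitude = H_baseline - H_peak`,
#' `C_amplitude = C_peak - C_baseline`.
#'
#' @param dff a `bq_dff`.
#' @param margin dilation margin in pixels (default 2).
#' @param cell pattern cell, default 2 x 2.
#' @return A tibble `time`, `H`, `C` with an `"amplitudes"` attribute (tibble
#'   with `H_amplitude`, `C_amplitude`, `peak_frame`, baseline values).
#' @export
pattern_timecourse <- function(dff, margin = 2L, cell = c(2L, 2L)) {
  stopifnot(inherits(dff, "bq_dff"))
  region <- dilate_mask(dff$bouton_mask, margin)
  rr <- range(which(rowSums(region) > 0))
  cc_rng <- range(which(colSums(region) > 0))
  sub_mask <- region[rr[1]:rr[2], cc_rng[1]:cc_rng[2], drop = FALSE]
  n_frames <- dim(dff$dff)[1]

  h <- numeric(n_frames); cv <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    img <- dff$dff[f, rr[1]:rr[2], cc_rng[1]:cc_rng[2]]
    p <- ordinal_pattern_distribution(img, cell, sub_mask)
    h[f] <- shannon(p) / log(length(p))
    cv[f] <- h[f] * js_disequilibrium(p)
  }

  base_idx <- dff$baseline_frames
  if (length(base_idx) == 0) {
    base_idx <- which(dff$time < min(dff$stimulus_times))
  }
  traces <- trace_parameters(dff)
  post <- which(dff$time >= min(dff$stimulus_times))
  peak_frame <- post[which.max(traces$cumulative[post])]

  out <- tibble(time = dff$time, H = h, C = cv)
  attr(out, "amplitudes") <- tibble(
    H_baseline = mean(h[base_idx]), C_baseline = mean(cv[base_idx]),
    H_peak = h[peak_frame], C_peak = cv[peak_frame],
    H_amplitude = mean(h[base_idx]) - h[peak_frame],
    C_amplitude = cv[peak_frame] - mean(cv[base_idx]),
    peak_frame = peak_frame)
  class(out) <- c("bq_pattern", class(out))
  out
}

#' @rdname pattern_timecourse
#' @param x result of [pattern_timecourse()].
#' @export
pattern_amplitudes <- function(x) attr(x, "amplitudes")
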