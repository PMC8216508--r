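# Independent brute-force oracles used across test files. These deliberately
# use the slowest, most literal formulation of each quantity.

# Mean pairwise 3D distance and per-section 2D nearest-neighbour mean by
# explicit double loops.
oracle_sv_stats <- function(rec) {
  pts <- NULL
  nn <- c()
  for (s in rec$sections) {
    v <- s$vesicles
    if (nrow(v) > 0) {
      pts <- rbind(pts, cbind(v$x, v$y, (s$z_index - 0.5) * rec$section_thickness))
    }
    if (nrow(v) >= 2) {
      for (i in seq_len(nrow(v))) {
        best <- Inf
        for (j in seq_len(nrow(v))) {
          if (i == j) next
          d <- sqrt((v$x[i] - v$x[j])^2 + (v$y[i] - v$y[j])^2)
          best <- min(best, d)
        }
        nn <- c(nn, best)
      }
    }
  }
  n <- nrow(pts)
  tot <- 0
  npair <- 0
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        tot <- tot + sqrt(sum((pts[i, ] - pts[j, ])^2))
        npair <- npair + 1
      }
    }
  }
  list(mean_pair = if (npair > 0) tot / npair else NA_real_,
       mnnd = if (length(nn) > 0) mean(nn) else NA_real_)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n_a + n_b, n_a) group assignments of the pooled sample.
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_stat <- function(xa, xb) {
    sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  }
  obs <- u_stat(a, b)
  mu <- na * length(b) / 2
  splits <- utils::combn(n, na)
  cnt <- 0
  for (k in seq_len(ncol(splits))) {
    ua <- u_stat(pooled[splits[, k]], pooled[-splits[, k]])
    if (abs(ua - mu) >= abs(obs - mu) - 1e-12) cnt <- cnt + 1
  }
  cnt / ncol(splits)
}

# Two-sample KS statistic as the literal sup over all pooled points of the
# empirical CDF difference.
oracle_ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(t) {
    abs(mean(a <= t) - mean(b <= t))
  }, numeric(1)))
}

# Prominence of every local maximum by threshold flood fill. Assumes all
# pixel values are unique. For each strict local max m with value v, the
# prominence is v minus the highest level L at which the connected component
# of {pixels >= L} containing m also contains a strictly higher pixel
# (v - global min for the global max).
oracle_prominences <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  neigh <- function(r, c) {
    out <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) out <- rbind(out, c(rr, cc))
    }
    out
  }
  is_max <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    nb <- neigh(r, c)
    is_max[r, c] <- all(img[r, c] > img[nb])
  }
  levels <- sort(unique(as.vector(img)), decreasing = TRUE)
  res <- NULL
  for (r in 1:nr) for (c in 1:nc) {
    if (!is_max[r, c]) next
    v <- img[r, c]
    prom <- v - min(img)
    for (L in levels[levels < v]) {
      # flood fill >= L from (r, c)
      seen <- matrix(FALSE, nr, nc)
      stack <- list(c(r, c))
      seen[r, c] <- TRUE
      higher <- FALSE
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (img[p[1], p[2]] > v) { higher <- TRUE; break }
        nb <- neigh(p[1], p[2])
        for (k in seq_len(nrow(nb))) {
          q <- nb[k, ]
          if (!seen[q[1], q[2]] && img[q[1], q[2]] >= L) {
            seen[q[1], q[2]] <- TRUE
            stack[[length(stack) + 1]] <- q
          }
        }
      }
      if (higher) { prom <- v - L; break }
    }
    res <- rbind(res, c(r, c, v, prom))
  }
  res
}

# Build a minimal bq_traces object around a single trace, for decay fitting.
make_traces <- function(time, cumulative, stimulus_times = 0) {
  out <- tibble::tibble(
    frame = seq_along(time), time = time,
    n_active = as.numeric(cumulative > 0),
    active_area_um2 = 0, active_frac = 0,
    cumulative = cumulative, mean_amp = cumulative,
    max_amp = cumulative, no_active = cumulative == 0)
  attr(out, "stimulus_times") <- stimulus_times
  attr(out, "frame_interval") <- diff(time[1:2])
  attr(out, "pixel_size") <- 0.2
  class(out) <- c("bq_traces", class(out))
  out
}

# Union of per-frame active-pixel masks over a time window.
recovered_mask <- function(traces, t_from, t_to) {
  act <- attr(traces, "active_mask")
  idx <- which(traces$time >= t_from & traces$time < t_to)
  apply(act[idx, , , drop = FALSE], c(2, 3), any)
}

# A square-bouton reconstruction with one AZ along the bottom edge and
# vesicles at chosen distances above it; side in nm.
square_az_rec <- function(vesicle_dists, side = 2000, r = 20,
                          thickness = 70) {
  poly <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  az <- list(az_id = 1L,
             points = rbind(c(side * 0.25, 0), c(side * 0.75, 0)))
  x <- seq(side * 0.3, side * 0.7, length.out = max(length(vesicle_dists), 2))
  ves <- tibble::tibble(x = x[seq_along(vesicle_dists)],
                        y = vesicle_dists, r = r)
  reconstruction(list(list(z_index = 1L, presyn = list(poly), az = list(az),
                           mito = list(), vesicles = ves)),
                 section_thickness = thickness)
}
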