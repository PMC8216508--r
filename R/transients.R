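#' Convert a bouton movie to percent dF/F with per-pixel baseline statistics
#'
#' Each pixel trace is zero-phase low-pass filtered (2nd-order Butterworth,
#' default cutoff 100 Hz), then expressed as a change of fluorescence in
#' percent of that pixel's mean over the 50 ms preceding the first stimulus.
#' The per-pixel baseline SD of the filtered dF/F over the same window is the
#' reference for the suprathreshold ("active pixel") criterion, by default
#' 3 x SD.
#'
#' @param movie a `bq_movie` (see [fluorescence_movie()]).
#' @param threshold_k suprathreshold multiplier (default 3).
#' @param filter_cutoff low-pass cutoff in Hz; `NULL` disables filtering.
#' @param baseline_ms baseline window length before the first stimulus (ms).
#' @param filter_guard_ms trailing part of the baseline window excluded from
#'   the baseline statistics when filtering is on (ms). The zero-phase filter
#'   smears the stimulus response a few ms backwards; without the guard that
#'   smear would inflate the baseline SD. Ignored when `filter_cutoff` is
#'   `NULL`.
#' @param sd_scope `"pixel"` (default) computes the baseline SD per pixel;
#'   `"global"` uses one pooled SD for all pixels (sensitivity analysis).
#' @return A `bq_dff` object: filtered dF/F array (%), per-pixel baseline mean
#'   (a.u.) and SD (%), plus acquisition metadata.
#' @export
compute_dff <- function(movie, threshold_k = 3, filter_cutoff = 100,
                        baseline_ms = 50, filter_guard_ms = 10,
                        sd_scope = c("pixel", "global")) {
  stopifnot(inherits(movie, "bq_movie"))
  sd_scope <- match.arg(sd_scope)
  dt <- movie$frame_interval
  n_frames <- dim(movie$data)[1]
  t_frames <- (seq_len(n_frames) - 1) * dt
  t1 <- min(movie$stimulus_times)
  if (t1 < baseline_ms) {
    abort(sprintf(
      "first stimulus at %g ms: need >= %g ms of pre-stimulus baseline",
      t1, baseline_ms))
  }
  guard <- if (is.null(filter_cutoff)) 0 else filter_guard_ms
  base_idx <- which(t_frames >= t1 - baseline_ms & t_frames < t1 - guard)

  d <- dim(movie$data)
  flat <- matrix(movie$data, nrow = n_frames)  # frames x pixels
  if (!is.null(filter_cutoff)) {
    fs <- 1000 / dt
    if (filter_cutoff >= fs / 2) {
      abort("filter_cutoff must be below the Nyquist frequency")
    }
    bf <- signal::butter(2, filter_cutoff / (fs / 2), type = "low")
    # odd-reflection padding suppresses the filter's edge transients
    pad <- min(n_frames - 1L, 150L)
    flat <- apply(flat, 2, function(x) {
      xp <- c(2 * x[1] - x[(pad + 1):2], x,
              2 * x[n_frames] - x[(n_frames - 1):(n_frames - pad)])
      signal::filtfilt(bf, xp)[(pad + 1):(pad + n_frames)]
    })
  }

  base_mean <- colMeans(flat[base_idx, , drop = FALSE])
  if (any(base_mean == 0)) {
    bad <- which(base_mean == 0)[1]
    rc <- arrayInd(bad, d[2:3])
    abort(sprintf("pixel (%d, %d) has zero baseline mean", rc[1], rc[2]))
  }
  dff <- 100 * sweep(sweep(flat, 2, base_mean, "-"), 2, base_mean, "/")
  base_sd <- apply(dff[base_idx, , drop = FALSE], 2, sd)
  if (sd_scope == "global") base_sd[] <- sqrt(mean(base_sd^2))

  structure(
    list(dff = array(dff, d),
         baseline_mean = matrix(base_mean, d[2], d[3]),
         baseline_sd = matrix(base_sd, d[2], d[3]),
         threshold_k = threshold_k, filter_cutoff = filter_cutoff,
         frame_interval = dt, pixel_size = movie$pixel_size,
         stimulus_times = movie$stimulus_times,
         bouton_mask = movie$bouton_mask, time = t_frames,
         baseline_frames = base_idx),
    class = "bq_dff")
}

#' Construct a dF/F object directly
#'
#' Mainly useful for feeding synthetic dF/F fields with known baseline
#' statistics into [trace_parameters()].
#'
#' @param dff frames x rows x cols array in percent dF/F.
#' @param baseline_sd per-pixel baseline SD (%), scalar or rows x cols matrix.
#' @param frame_interval ms per frame.
#' @param pixel_size um per pixel.
#' @param stimulus_times stimulus onsets (ms).
#' @param bouton_mask logical mask; defaults to all pixels.
#' @param threshold_k suprathreshold multiplier.
#' @return A `bq_dff` object.
#' @export
dff_movie <- function(dff, baseline_sd, frame_interval, pixel_size,
                      stimulus_times = numeric(), bouton_mask = NULL,
                      threshold_k = 3) {
  d <- dim(dff)
  stopifnot(length(d) == 3)
  if (length(baseline_sd) == 1) baseline_sd <- matrix(baseline_sd, d[2], d[3])
  if (is.null(bouton_mask)) bouton_mask <- matrix(TRUE, d[2], d[3])
  structure(
    list(dff = dff, baseline_mean = matrix(NA_real_, d[2], d[3]),
         baseline_sd = baseline_sd, threshold_k = threshold_k,
         filter_cutoff = NULL, frame_interval = frame_interval,
         pixel_size = pixel_size, stimulus_times = stimulus_times,
         bouton_mask = bouton_mask,
         time = (seq_len(d[1]) - 1) * frame_interval,
         baseline_frames = integer()),
    class = "bq_dff")
}

#' Time-resolved transient parameters from a dF/F movie
#'
#' Per frame, active pixels are those whose dF/F exceeds `threshold_k` times
#' their own baseline SD. The four readouts follow the study's definitions:
#' active area (pixel count x pixel area; also as fraction of the bouton
#' mask), cumulative amplitude (sum of dF/F over active pixels, % x pixel),
#' mean amplitude and maximal amplitude over active pixels. Frames with no
#' active pixel report area and cumulative 0 and mean/max as `NA` (flagged),
#' so trace averages are not biased toward zero.
#'
#' @param dff a `bq_dff`.
#' @param bouton_mask optional logical mask overriding the one stored in
#'   `dff` (used for the fraction-of-bouton normalisation).
#' @param pixel_size optional um/pixel override.
#' @return A tibble (class `bq_traces`) with columns `frame`, `time`,
#'   `n_active`, `active_area_um2`, `active_frac`, `cumulative`, `mean_amp`,
#'   `max_amp`, `no_active` and the per-frame active-pixel masks in the
#'   `"active_mask"` attribute.
#' @export
trace_parameters <- function(dff, bouton_mask = NULL, pixel_size = NULL) {
  stopifnot(inherits(dff, "bq_dff"))
  bouton_mask <- bouton_mask %||% dff$bouton_mask
  pixel_size <- pixel_size %||% dff$pixel_size
  d <- dim(dff$dff)
  n_frames <- d[1]
  thr <- dff$threshold_k * dff$baseline_sd
  thr_arr <- array(rep(as.vector(thr), each = n_frames), d)
  active <- dff$dff > thr_arr

  flat_dff <- matrix(dff$dff, nrow = n_frames)
  flat_act <- matrix(active, nrow = n_frames)
  n_active <- rowSums(flat_act)
  masked <- flat_dff
  masked[!flat_act] <- 0
  cumulative <- rowSums(masked)
  mean_amp <- ifelse(n_active > 0, cumulative / n_active, NA_real_)
  masked[!flat_act] <- -Inf
  max_amp <- apply(masked, 1, max)
  max_amp[n_active == 0] <- NA_real_
  cumulative[n_active == 0] <- 0

  px_area <- pixel_size^2
  out <- tibble(
    frame = seq_len(n_frames),
    time = dff$time,
    n_active = n_active,
    active_area_um2 = n_active * px_area,
    active_frac = n_active / sum(bouton_mask),
    cumulative = cumulative,
    mean_amp = mean_amp,
    max_amp = max_amp,
    no_active = n_active == 0
  )
  attr(out, "active_mask") <- active
  attr(out, "stimulus_times") <- dff$stimulus_times
  attr(out, "frame_interval") <- dff$frame_interval
  attr(out, "pixel_size") <- pixel_size
  attr(out, "bouton_area_um2") <- sum(bouton_mask) * px_area
  class(out) <- c("bq_traces", class(out))
  out
}

trace_measures <- c("active_area_um2", "cumulative", "mean_amp", "max_amp")

#' Per-stimulus peaks and paired-pulse ratios
#'
#' For each stimulus, the peak of each transient readout is the maximum of
#' the trace within the window from the stimulus up to the next stimulus (or
#' `window` ms after the last one; the default window equals the 50-ms
#' interstimulus interval). The paired-pulse ratio is the second peak divided
#' by the first; a zero first peak yields `NA` with a reason.
#'
#' @param traces a `bq_traces` tibble from [trace_parameters()].
#' @param stimulus_times optional override of the stored stimulus times (ms).
#' @param window peak-search window after the last stimulus (ms).
#' @return A tibble with one row per readout: per-stimulus peak columns
#'   `peak_1`, `peak_2`, ..., `ppr`, and `ppr_note`.
#' @export
peak_and_ppr <- function(traces, stimulus_times = NULL, window = 50) {
  stimulus_times <- stimulus_times %||% attr(traces, "stimulus_times")
  if (length(stimulus_times) < 1) abort("at least one stimulus is required")
  stimulus_times <- sort(stimulus_times)
  n_stim <- length(stimulus_times)
  ends <- c(stimulus_times[-1], stimulus_times[n_stim] + window)

  peaks <- matrix(NA_real_, length(trace_measures), n_stim,
                  dimnames = list(trace_measures, NULL))
  for (s in seq_len(n_stim)) {
    in_win <- traces$time >= stimulus_times[s] & traces$time < ends[s]
    if (!any(in_win)) abort(sprintf("no frames in window of stimulus %d", s))
    for (m in trace_measures) {
      v <- traces[[m]][in_win]
      peaks[m, s] <- if (all(is.na(v))) 0 else max(v, na.rm = TRUE)
    }
  }
  out <- tibble(measure = trace_measures)
  for (s in seq_len(n_stim)) out[[paste0("peak_", s)]] <- unname(peaks[, s])
  if (n_stim >= 2) {
    p1 <- unname(peaks[, 1]); p2 <- unname(peaks[, 2])
    out$ppr <- ifelse(p1 > 0, p2 / p1, NA_real_)
    out$ppr_note <- ifelse(p1 > 0, NA_character_,
                           "first peak is zero: PPR undefined")
  } else {
    out$ppr <- NA_real_
    out$ppr_note <- "single stimulus: PPR undefined"
  }
  out
}

# Monoexponential least-squares fit y = A exp(-(t - t0)/tau) + c.
fit_monoexp <- function(t, y, offset = TRUE) {
  if (sd(y) == 0) abort("non-decaying segment: trace is constant")
  t0 <- t[1]
  c0 <- if (offset) min(y) else 0
  a0 <- max(y[1] - c0, 1e-9)
  pos <- y - c0 > a0 * 1e-3
  tau0 <- if (sum(pos) >= 2) {
    fitl <- stats::lm(log(y[pos] - c0 + a0 * 1e-6) ~ t[pos])
    -1 / min(coef(fitl)[2], -1e-6)
  } else diff(range(t)) / 3
  tau0 <- min(max(tau0, diff(range(t)) / 100), diff(range(t)) * 10)
  fml <- if (offset) y ~ A * exp(-(t - t0) / tau) + cc else
    y ~ A * exp(-(t - t0) / tau)
  fit <- NULL
  last_err <- NULL
  for (tau_try in unique(c(tau0, diff(range(t)) / 5, diff(range(t)) / 20))) {
    start <- if (offset) list(A = a0, tau = tau_try, cc = c0) else
      list(A = a0, tau = tau_try)
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = list(y = y, t = t, t0 = t0),
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) { last_err <<- conditionMessage(e); NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    abort(paste0("monoexponential fit failed (non-decaying segment?): ",
                 last_err))
  }
  cf <- coef(fit)
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0 ||
      cf[["tau"]] > 20 * diff(range(t))) {
    abort(sprintf(
      "fitted tau = %g ms is not a credible decay constant for a %g-ms segment",
      cf[["tau"]], diff(range(t))))
  }
  res <- stats::residuals(fit)
  ss_tot <- sum((y - mean(y))^2)
  list(tau = unname(cf[["tau"]]), A = unname(cf[["A"]]),
       c = if (offset) unname(cf[["cc"]]) else 0,
       r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
       resid_sd = sd(res), n = length(y), t_start = t0)
}

#' Fit the decay time constant of the cumulative transient
#'
#' Fits `A * exp(-(t - t_peak)/tau) + c` by least squares to the cumulative
#' trace from its peak after the chosen stimulus (default: the last one) to
#' the end of the recording.
#'
#' @param traces a `bq_traces` tibble.
#' @param stimulus_index which stimulus anchors the fit (default last).
#' @param measure which trace to fit (default `"cumulative"`).
#' @param offset fit an additive offset `c` (default `TRUE`).
#' @return An object of class `bq_decay_fit` with fields `tau` (ms), `A`,
#'   `c`, `r_squared`, `resid_sd`; see [glance.bq_decay_fit()].
#' @export
fit_decay_tau <- function(traces, stimulus_index = NULL,
                          measure = "cumulative", offset = TRUE) {
  stims <- sort(attr(traces, "stimulus_times"))
  if (is.null(stimulus_index)) stimulus_index <- length(stims)
  t_stim <- stims[stimulus_index]
  nxt <- if (stimulus_index < length(stims)) stims[stimulus_index + 1] else Inf
  y <- traces[[measure]]
  y[is.na(y)] <- 0
  in_win <- traces$time >= t_stim & traces$time < min(nxt, t_stim + 50)
  if (!any(in_win) || max(y[in_win]) <= 0) {
    abort("no detected peak after the chosen stimulus")
  }
  i_peak <- which(in_win)[which.max(y[in_win])]
  seg <- seq(i_peak, nrow(traces))
  fit <- fit_monoexp(traces$time[seg], y[seg], offset = offset)
  structure(c(fit, list(measure = measure, stimulus_index = stimulus_index)),
            class = "bq_decay_fit")
}

#' @export
print.bq_decay_fit <- function(x, ...) {
  cat(sprintf("<bq_decay_fit> tau = %.3g ms (A = %.3g, c = %.3g, R2 = %.3f)\n",
              x$tau, x$A, x$c, x$r_squared))
  invisible(x)
}

#' @rdname fit_decay_tau
#' @param x a `bq_decay_fit`.
#' @param ... unused.
#' @export
glance.bq_decay_fit <- function(x, ...) {
  tibble(tau = x$tau, A = x$A, c = x$c, r_squared = x$r_squared,
         resid_sd = x$resid_sd, n = x$n)
}

#' Virtual bouton diameter
#'
#' Diameter of the circle whose area equals the bouton-mask area:
#' `d = 2 * sqrt(A / pi)`.
#'
#' @param bouton_mask logical mask.
#' @param pixel_size um per pixel.
#' @return Diameter in um.
#' @export
virtual_diameter <- function(bouton_mask, pixel_size) {
  n <- sum(bouton_mask)
  if (n == 0) abort("bouton mask is empty")
  2 * sqrt(n * pixel_size^2 / pi)
}

#' Pairwise correlogram of transient parameters
#'
#' Pearson correlations with two-sided p-values between per-bouton transient
#' parameters (e.g. each amplitude versus its PPR, active area versus the
#' amplitudes, and amplitudes versus entropy / non-triviality changes).
#'
#' @param summaries a data frame with one row per bouton and numeric
#'   parameter columns.
#' @param pairs optional 2-column character matrix (or data frame) of column
#'   pairs; defaults to all unordered pairs of numeric columns.
#' @return A tibble with `param_x`, `param_y`, `n`, `r`, `p`, `note`.
#' @export
correlate_parameters <- function(summaries, pairs = NULL) {
  summaries <- as_tibble(summaries)
  num_cols <- names(summaries)[vapply(summaries, is.numeric, logical(1))]
  if (is.null(pairs)) {
    if (length(num_cols) < 2) abort("need at least two numeric columns")
    pairs <- t(utils::combn(num_cols, 2))
  }
  pairs <- as.matrix(pairs)
  if (nrow(summaries) < 3) abort("need >= 3 observations for correlograms")
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    x <- summaries[[pairs[i, 1]]]
    y <- summaries[[pairs[i, 2]]]
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(param_x = pairs[i, 1], param_y = pairs[i, 2],
                    n = length(x), r = NA_real_, p = NA_real_,
                    note = "constant column: correlation undefined"))
    }
    ct <- cor.test(x, y)
    tibble(param_x = pairs[i, 1], param_y = pairs[i, 2], n = length(x),
           r = unname(ct$estimate), p = ct$p.value, note = NA_character_)
  })
}

#' Longitudinal bleaching-normalised tracking of transient parameters
#'
#' For a time-ordered series of movies from the same bouton, reports the mean
#' baseline fluorescence and the mean baseline dF/F SD over all ROI pixels,
#' each normalised to the first timepoint, and the per-stimulus-1 peak of
#' each transient readout normalised to the mean of the pre-treatment
#' timepoints.
#'
#' @param movies list of `bq_movie` objects, one per timepoint.
#' @param timepoints strictly increasing numeric timepoints (min).
#' @param treatment_time timepoints `<= treatment_time` are the pre-treatment
#'   reference.
#' @param ... passed on to [compute_dff()].
#' @return A tidy tibble: `timepoint`, `measure`, `value`, `norm_value`.
#' @export
longitudinal_track <- function(movies, timepoints, treatment_time = 0, ...) {
  if (length(movies) < 2) abort("need >= 2 timepoints")
  if (length(timepoints) != length(movies) || is.unsorted(timepoints, strictly = TRUE)) {
    abort("timepoints must be strictly increasing, one per movie")
  }
  rows <- purrr::map2_dfr(movies, timepoints, function(mv, tp) {
    dff <- compute_dff(mv, ...)
    base_f <- mean(mv$data[dff$baseline_frames, , ])
    base_sd <- mean(dff$baseline_sd)
    pk <- peak_and_ppr(trace_parameters(dff))
    dplyr::bind_rows(
      tibble(timepoint = tp, measure = "baseline_f", value = base_f),
      tibble(timepoint = tp, measure = "baseline_sd", value = base_sd),
      tibble(timepoint = tp, measure = pk$measure, value = pk$peak_1))
  })
  first_tp <- min(timepoints)
  rows |>
    dplyr::group_by(.data$measure) |>
    dplyr::mutate(norm_value = as.numeric(dplyr::case_when(
      .data$measure %in% c("baseline_f", "baseline_sd") ~
        .data$value / .data$value[.data$timepoint == first_tp],
      TRUE ~ .data$value /
        mean(.data$value[.data$timepoint <= treatment_time])
    ))) |>
    dplyr::ungroup()
}
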