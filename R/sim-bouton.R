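#' Configuration for the synthetic bouton-movie generator
#'
#' Assembles and validates the parameters of the forward model used by
#' [simulate_bouton_movie()]. The model emulates high-speed (default 1.6 kHz)
#' single-channel two-photon movies of a single mossy fiber bouton expressing
#' a membrane-bound low-affinity glutamate sensor (Kd = 600 uM), stimulated
#' with paired pulses 50 ms apart.
#'
#' Release is quantal and site-based: each of `n_release_sites` sites releases
#' independently at each stimulus with probability `site_release_prob`.
#' Glutamate from a release event spreads as an isotropic Gaussian in the
#' image plane (sd `spatial_sigma`, truncated at 3 sigma so pixels outside the
#' footprint stay exactly at baseline) and follows a linear-rise /
#' monoexponential-decay time course. The sensor response saturates as
#' `dff_max * [Glu] / ([Glu] + sensor_kd)`.
#'
#' Per-site release probabilities and quantal cleft glutamate concentrations
#' at hippocampal mossy fiber boutons are not established quantities; the
#' defaults here (`site_release_prob = 0.5`, `glut_peak_conc = 3000` uM) are
#' placeholders: clearly suprathreshold responses with a millimolar cleft
#' peak that saturates the low-affinity sensor near release sites, and should
#' be treated as such.
#'
#' @param roi_shape integer(2), movie rows x cols in pixels (default 13 x 13,
#'   i.e. the 169-pixel high-speed ROI).
#' @param pixel_size um per pixel.
#' @param frame_rate acquisition rate in Hz.
#' @param duration movie length in ms.
#' @param stimulus_times stimulus onsets in ms (default a pair 50 ms apart).
#' @param n_release_sites number of release sites.
#' @param site_release_prob per-site, per-stimulus release probability.
#' @param quanta_per_release vesicles released per successful event.
#' @param glut_peak_conc peak cleft glutamate (uM) per quantum at the release
#'   point.
#' @param spatial_sigma Gaussian spread of cleft glutamate (um).
#' @param sensor_kd sensor dissociation constant (uM).
#' @param dff_max saturating sensor response (percent dF/F).
#' @param decay_tau glutamate decay time constant (ms).
#' @param rise_time linear rise time to peak (ms).
#' @param baseline_f baseline fluorescence (a.u.).
#' @param noise_sd Gaussian detection noise sd (a.u.).
#' @param bleach_tau monoexponential bleaching time constant (ms), or `NULL`
#'   for no bleaching.
#' @param site_positions optional n x 2 matrix of (row, col) site positions in
#'   pixels; sampled inside the bouton mask when `NULL`.
#' @param seed integer seed for the generator's private RNG stream.
#' @return A list of class `bouton_sim_config`.
#' @export
bouton_sim_config <- function(roi_shape = c(13L, 13L),
                              pixel_size = 0.2,
                              frame_rate = 1600,
                              duration = 200,
                              stimulus_times = c(60, 110),
                              n_release_sites = 4L,
                              site_release_prob = 0.5,
                              quanta_per_release = 1L,
                              glut_peak_conc = 3000,
                              spatial_sigma = 0.3,
                              sensor_kd = 600,
                              dff_max = 180,
                              decay_tau = 10,
                              rise_time = 1,
                              baseline_f = 100,
                              noise_sd = 2,
                              bleach_tau = NULL,
                              site_positions = NULL,
                              seed = NULL) {
  assert_scalar_num(frame_rate, "frame_rate", 0, strict_lower = TRUE)
  assert_scalar_num(duration, "duration", 0, strict_lower = TRUE)
  assert_prob(site_release_prob, "site_release_prob")
  assert_scalar_num(sensor_kd, "sensor_kd", 0, strict_lower = TRUE)
  assert_scalar_num(decay_tau, "decay_tau", 0, strict_lower = TRUE)
  assert_scalar_num(rise_time, "rise_time", 0, strict_lower = TRUE)
  assert_scalar_num(baseline_f, "baseline_f", 0, strict_lower = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  assert_scalar_num(spatial_sigma, "spatial_sigma", 0, strict_lower = TRUE)
  if (any(stimulus_times < 0)) abort("stimulus times must be >= 0")
  if (duration < max(stimulus_times) + 3 * decay_tau) {
    abort(sprintf(
      "duration (%g ms) must cover the last stimulus + 3 * decay_tau (%g ms)",
      duration, max(stimulus_times) + 3 * decay_tau))
  }
  structure(
    list(roi_shape = as.integer(roi_shape), pixel_size = pixel_size,
         frame_rate = frame_rate, duration = duration,
         stimulus_times = sort(stimulus_times),
         n_release_sites = as.integer(n_release_sites),
         site_release_prob = site_release_prob,
         quanta_per_release = quanta_per_release,
         glut_peak_conc = glut_peak_conc, spatial_sigma = spatial_sigma,
         sensor_kd = sensor_kd, dff_max = dff_max, decay_tau = decay_tau,
         rise_time = rise_time, baseline_f = baseline_f, noise_sd = noise_sd,
         bleach_tau = bleach_tau, site_positions = site_positions,
         seed = seed),
    class = "bouton_sim_config")
}

#' Construct a fluorescence-movie object
#'
#' @param data frames x rows x cols numeric array (a.u.).
#' @param frame_interval ms between frames.
#' @param pixel_size um per pixel.
#' @param stimulus_times stimulus onsets in ms.
#' @param bouton_mask logical rows x cols bouton contour mask.
#' @param condition_label free-text condition tag.
#' @return A `bq_movie` object.
#' @export
fluorescence_movie <- function(data, frame_interval, pixel_size,
                               stimulus_times, bouton_mask,
                               condition_label = "") {
  stopifnot(length(dim(data)) == 3)
  assert_scalar_num(frame_interval, "frame_interval", 0, strict_lower = TRUE)
  if (!any(bouton_mask)) abort("bouton_mask must contain at least one pixel")
  dur <- dim(data)[1] * frame_interval
  if (any(stimulus_times >= dur)) {
    abort("stimulus_times must fall within the movie duration")
  }
  structure(
    list(data = data, frame_interval = frame_interval,
         pixel_size = pixel_size, stimulus_times = stimulus_times,
         bouton_mask = bouton_mask, condition_label = condition_label),
    class = "bq_movie")
}

#' @export
print.bq_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<bq_movie> %d frames of %d x %d px (%.3g ms/frame, %.3g um/px), %d stimuli\n",
    d[1], d[2], d[3], x$frame_interval, x$pixel_size,
    length(x$stimulus_times)))
  invisible(x)
}

# Linear rise over rise_time, then monoexponential decay; peak value 1.
release_kernel <- function(u, rise_time, decay_tau) {
  out <- numeric(length(u))
  rising <- u >= 0 & u < rise_time
  out[rising] <- u[rising] / rise_time
  decaying <- u >= rise_time
  out[decaying] <- exp(-(u[decaying] - rise_time) / decay_tau)
  out
}

default_bouton_mask <- function(roi_shape) {
  rows <- roi_shape[1]; cols <- roi_shape[2]
  cr <- (rows + 1) / 2; cc <- (cols + 1) / 2
  r <- min(rows, cols) / 2 - 0.5
  outer(seq_len(rows), seq_len(cols),
        function(i, j) (i - cr)^2 + (j - cc)^2 <= r^2)
}

#' Simulate a single-bouton glutamate-sensor movie
#'
#' Runs the forward model described in [bouton_sim_config()] and returns the
#' noisy movie together with the generating ground truth: site positions, the
#' site x stimulus release-event matrix, the noise-free analytic dF/F movie,
#' and the per-stimulus true active mask (the union of the glutamate
#' footprints of every site that released at or before that stimulus — the
#' monoexponential tail of an earlier response keeps those pixels above a
#' zero-noise threshold in later windows).
#'
#' @param config a [bouton_sim_config()].
#' @return A list with elements `movie` (a `bq_movie`) and `truth`.
#' @export
simulate_bouton_movie <- function(config) {
  stopifnot(inherits(config, "bouton_sim_config"))
  with_rng(config$seed, simulate_bouton_movie_impl(config))
}

simulate_bouton_movie_impl <- function(cfg) {
  rows <- cfg$roi_shape[1]; cols <- cfg$roi_shape[2]
  dt <- 1000 / cfg$frame_rate
  n_frames <- floor(cfg$duration / dt)
  t_frames <- (seq_len(n_frames) - 1) * dt
  mask <- default_bouton_mask(cfg$roi_shape)

  n_sites <- cfg$n_release_sites
  sites <- cfg$site_positions
  if (is.null(sites) && n_sites > 0) {
    interior <- which(mask, arr.ind = TRUE)
    pick <- sample(nrow(interior), n_sites, replace = n_sites > nrow(interior))
    sites <- interior[pick, , drop = FALSE]
  } else if (n_sites > 0) {
    sites <- matrix(as.numeric(sites), ncol = 2)
  } else {
    sites <- matrix(numeric(0), 0, 2)
  }

  n_stim <- length(cfg$stimulus_times)
  events <- matrix(FALSE, max(n_sites, 0), n_stim)
  if (n_sites > 0 && n_stim > 0) {
    events[] <- runif(n_sites * n_stim) < cfg$site_release_prob
  }

  # Per-site spatial footprint: truncated Gaussian, exact zero beyond 3 sigma.
  sigma_px <- cfg$spatial_sigma / cfg$pixel_size
  footprints <- vector("list", n_sites)
  px_r <- matrix(seq_len(rows), rows, cols)
  px_c <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  for (j in seq_len(n_sites)) {
    d2 <- (px_r - sites[j, 1])^2 + (px_c - sites[j, 2])^2
    w <- exp(-d2 / (2 * sigma_px^2))
    w[d2 > (3 * sigma_px)^2] <- 0
    footprints[[j]] <- w
  }

  amp <- cfg$quanta_per_release * cfg$glut_peak_conc
  glu <- array(0, c(n_frames, rows, cols))
  for (s in seq_len(n_stim)) {
    k <- release_kernel(t_frames - cfg$stimulus_times[s],
                        cfg$rise_time, cfg$decay_tau)
    active <- which(events[, s])
    if (length(active) == 0) next
    fp <- Reduce(`+`, footprints[active])
    glu <- glu + outer(k, amp * fp)
  }

  dff <- cfg$dff_max * glu / (glu + cfg$sensor_kd)
  bleach <- if (is.null(cfg$bleach_tau)) rep(1, n_frames) else
    exp(-t_frames / cfg$bleach_tau)
  f <- cfg$baseline_f * (1 + dff / 100) * bleach
  if (cfg$noise_sd > 0) {
    f <- f + array(rnorm(length(f), sd = cfg$noise_sd), dim(f))
  }

  true_active <- array(FALSE, c(rows, cols, n_stim))
  released_so_far <- rep(FALSE, n_sites)
  for (s in seq_len(n_stim)) {
    released_so_far <- released_so_far | events[, s]
    for (j in which(released_so_far)) {
      true_active[, , s] <- true_active[, , s] | (footprints[[j]] > 0)
    }
  }

  movie <- fluorescence_movie(f, dt, cfg$pixel_size, cfg$stimulus_times, mask,
                              condition_label = "synthetic")
  truth <- list(site_positions = sites, events = events,
                footprints = footprints, dff = dff,
                true_active_mask = true_active,
                true_decay_tau = cfg$decay_tau,
                bleach = bleach, config = cfg)
  list(movie = movie, truth = truth)
}
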