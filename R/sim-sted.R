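#' Configuration for the synthetic gSTED field generator
#'
#' Parameters of the forward model in [simulate_sted_field()], which emulates
#' three-channel (Cav2.1 / Munc13-1 / Homer1) 2D gSTED images at 20-nm pixels.
#' Each synapse is a triad: a Cav2.1 and a Munc13-1 point source separated by
#' a draw from `separation_distribution` along a uniformly random orientation,
#' plus a Homer1 source displaced trans-synaptically (perpendicular to the
#' Cav-Munc axis) by `homer_offset`. Sources are blurred with a 2D Lorentzian
#' point spread function (default FWHM 40 nm, truncated at 10 x FWHM and
#' renormalised), then Poisson shot noise and Gaussian read noise are applied.
#'
#' @param field_size integer(2), image rows x cols in pixels.
#' @param pixel_size nm per pixel (default 20).
#' @param n_triads number of synapse triads.
#' @param separation_distribution list with `family` one of `"point"`
#'   (`value` nm), `"truncnorm"` (`mean`, `sd` nm, truncated at 0 by
#'   redrawing), or `"uniform"` (`min`, `max` nm).
#' @param homer_offset trans-synaptic Homer displacement (nm).
#' @param psf_fwhm Lorentzian PSF full width at half maximum (nm).
#' @param spot_amplitudes named numeric: peak counts for `cav`, `munc`,
#'   `homer` sources.
#' @param background mean background counts per pixel.
#' @param read_noise_sd Gaussian read noise sd (counts); `0` and
#'   `poisson = FALSE` give a noise-free field.
#' @param poisson apply Poisson shot noise.
#' @param n_distractors unmatched spots added per channel.
#' @param min_triad_sep minimum distance between triad centres (nm).
#' @param seed integer seed.
#' @return A list of class `sted_sim_config`.
#' @export
sted_sim_config <- function(field_size = c(500L, 500L),
                            pixel_size = 20,
                            n_triads = 10L,
                            separation_distribution = list(
                              family = "truncnorm", mean = 64.6, sd = 30),
                            homer_offset = 80,
                            psf_fwhm = 40,
                            spot_amplitudes = c(cav = 150, munc = 150,
                                                homer = 150),
                            background = 2,
                            read_noise_sd = 1,
                            poisson = TRUE,
                            n_distractors = 5L,
                            min_triad_sep = 600,
                            seed = NULL) {
  assert_scalar_num(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  assert_scalar_num(psf_fwhm, "psf_fwhm", 0, strict_lower = TRUE)
  assert_scalar_num(homer_offset, "homer_offset", 0)
  if (!separation_distribution$family %in% c("point", "truncnorm", "uniform")) {
    abort("unknown separation_distribution family")
  }
  structure(
    list(field_size = as.integer(field_size), pixel_size = pixel_size,
         n_triads = as.integer(n_triads),
         separation_distribution = separation_distribution,
         homer_offset = homer_offset, psf_fwhm = psf_fwhm,
         spot_amplitudes = spot_amplitudes, background = background,
         read_noise_sd = read_noise_sd, poisson = poisson,
         n_distractors = as.integer(n_distractors),
         min_triad_sep = min_triad_sep, seed = seed),
    class = "sted_sim_config")
}

#' Draw separations from a configured distribution family
#'
#' @param dist distribution spec (see [sted_sim_config()]).
#' @param n number of draws.
#' @return Nonnegative separations (nm).
#' @export
draw_separations <- function(dist, n) {
  out <- switch(dist$family,
    point = rep(dist$value, n),
    truncnorm = {
      x <- rnorm(n, dist$mean, dist$sd)
      while (any(x < 0)) {
        bad <- x < 0
        x[bad] <- rnorm(sum(bad), dist$mean, dist$sd)
      }
      x
    },
    uniform = runif(n, dist$min, dist$max),
    abort("unknown separation distribution family"))
  if (any(out < 0)) abort("negative separation drawn")
  out
}

#' Construct a STED field object
#'
#' @param channels named list of numeric matrices `cav`, `munc`, `homer`.
#' @param pixel_size nm per pixel.
#' @param region_label,condition,animal_id grouping metadata.
#' @return A `bq_sted` object.
#' @export
sted_field <- function(channels, pixel_size = 20, region_label = "",
                       condition = "", animal_id = "") {
  stopifnot(all(c("cav", "munc", "homer") %in% names(channels)))
  dims <- vapply(channels, dim, integer(2))
  if (any(dims != dims[, 1])) abort("all channels must share one shape")
  structure(list(channels = channels, pixel_size = pixel_size,
                 region_label = region_label, condition = condition,
                 animal_id = animal_id),
            class = "bq_sted")
}

#' @export
print.bq_sted <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<bq_sted> %d x %d px at %g nm/px (%s %s)\n",
              d[1], d[2], x$pixel_size, x$condition, x$region_label))
  invisible(x)
}

# 2D Lorentzian PSF kernel: I(r) = 1 / (1 + (r/gamma)^2), gamma = FWHM/2,
# truncated at trunc_factor * FWHM and renormalised to unit sum.
lorentzian_kernel <- function(fwhm_nm, pixel_size_nm, trunc_factor = 10) {
  gamma <- fwhm_nm / 2
  r_px <- ceiling(trunc_factor * fwhm_nm / pixel_size_nm)
  off <- (-r_px):r_px
  d_nm <- sqrt(outer(off^2, off^2, "+")) * pixel_size_nm
  k <- 1 / (1 + (d_nm / gamma)^2)
  k[d_nm > trunc_factor * fwhm_nm] <- 0
  k / sum(k)
}

# Add a PSF-shaped spot at continuous pixel position (row0, col0); this is
# the convolution of a point source with the truncated, unit-peak Lorentzian.
add_spot <- function(img, row0, col0, amplitude, fwhm_nm, pixel_size_nm,
                     trunc_factor = 10) {
  gamma <- fwhm_nm / 2
  r_px <- ceiling(trunc_factor * fwhm_nm / pixel_size_nm)
  rows <- max(1, floor(row0 - r_px)):min(nrow(img), ceiling(row0 + r_px))
  cols <- max(1, floor(col0 - r_px)):min(ncol(img), ceiling(col0 + r_px))
  d_nm <- sqrt(outer((rows - row0)^2, (cols - col0)^2, "+")) * pixel_size_nm
  patch <- amplitude / (1 + (d_nm / gamma)^2)
  patch[d_nm > trunc_factor * fwhm_nm] <- 0
  img[rows, cols] <- img[rows, cols] + patch
  img
}

#' Simulate a three-channel gSTED field of synapse triads
#'
#' Runs the forward model described in [sted_sim_config()].
#'
#' @param config a [sted_sim_config()].
#' @return List with `field` (a `bq_sted`) and `truth`, a tibble of true
#'   source positions (continuous pixel coordinates `*_row`, `*_col`) and the
#'   true `separation_nm` per triad.
#' @export
simulate_sted_field <- function(config) {
  stopifnot(inherits(config, "sted_sim_config"))
  with_rng(config$seed, simulate_sted_field_impl(config))
}

simulate_sted_field_impl <- function(cfg) {
  nr <- cfg$field_size[1]; nc <- cfg$field_size[2]
  px <- cfg$pixel_size
  margin_px <- (cfg$homer_offset + 250) / px  # keep triad members in-field

  centers <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(centers) < cfg$n_triads) {
    tries <- tries + 1L
    if (tries > 20000L) abort("could not place triads with min_triad_sep")
    cand <- c(runif(1, 1 + margin_px, nr - margin_px),
              runif(1, 1 + margin_px, nc - margin_px))
    if (nrow(centers) > 0) {
      dmin <- min(sqrt(rowSums(sweep(centers, 2, cand)^2))) * px
      if (dmin < cfg$min_triad_sep) next
    }
    centers <- rbind(centers, cand)
  }

  n <- cfg$n_triads
  sep_nm <- if (n > 0) draw_separations(cfg$separation_distribution, n) else
    numeric()
  theta <- runif(n, 0, 2 * pi)
  ux <- cos(theta); uy <- sin(theta)
  half_px <- sep_nm / 2 / px
  cav <- cbind(centers[, 1] - half_px * ux, centers[, 2] - half_px * uy)
  munc <- cbind(centers[, 1] + half_px * ux, centers[, 2] + half_px * uy)
  hoff_px <- cfg$homer_offset / px
  homer <- cbind(centers[, 1] - hoff_px * uy, centers[, 2] + hoff_px * ux)

  ch <- list(cav = matrix(0, nr, nc), munc = matrix(0, nr, nc),
             homer = matrix(0, nr, nc))
  amp <- cfg$spot_amplitudes
  for (i in seq_len(n)) {
    ch$cav <- add_spot(ch$cav, cav[i, 1], cav[i, 2], amp[["cav"]],
                       cfg$psf_fwhm, px)
    ch$munc <- add_spot(ch$munc, munc[i, 1], munc[i, 2], amp[["munc"]],
                        cfg$psf_fwhm, px)
    ch$homer <- add_spot(ch$homer, homer[i, 1], homer[i, 2], amp[["homer"]],
                         cfg$psf_fwhm, px)
  }
  for (name in names(ch)) {
    for (k in seq_len(cfg$n_distractors)) {
      pos <- c(runif(1, 1, nr), runif(1, 1, nc))
      ch[[name]] <- add_spot(ch[[name]], pos[1], pos[2], amp[[name]],
                             cfg$psf_fwhm, px)
    }
  }

  for (name in names(ch)) {
    img <- ch[[name]] + cfg$background
    if (cfg$poisson) img <- matrix(rpois(length(img), img), nr, nc)
    if (cfg$read_noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, cfg$read_noise_sd), nr, nc)
    }
    ch[[name]] <- pmax(img, 0)
  }

  truth <- tibble(
    triad = seq_len(n),
    cav_row = cav[, 1], cav_col = cav[, 2],
    munc_row = munc[, 1], munc_col = munc[, 2],
    homer_row = homer[, 1], homer_col = homer[, 2],
    separation_nm = sep_nm)
  list(field = sted_field(ch, pixel_size = px, condition = "synthetic"),
       truth = truth)
}
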