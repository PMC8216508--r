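#' Richardson-Lucy deconvolution with a 2D Lorentzian PSF
#'
#' Standard multiplicative Richardson-Lucy updates with a unit-sum 2D
#' Lorentzian kernel (FWHM `psf_fwhm`, truncated at 10 x FWHM and
#' renormalised). Convolutions use replicate (flat) boundary padding, so a
#' uniform image is a fixed point and total intensity is conserved to within
#' about 1%.
#'
#' @param image nonnegative numeric matrix (raw counts).
#' @param psf_fwhm PSF full width at half maximum (nm).
#' @param n_iter number of iterations (>= 1; default 30).
#' @param pixel_size nm per pixel.
#' @return Deconvolved nonnegative matrix.
#' @export
richardson_lucy_deconvolve <- function(image, psf_fwhm = 40, n_iter = 30,
                                       pixel_size = 20) {
  if (any(image < 0)) abort("image must be nonnegative (raw counts)")
  if (n_iter < 1) abort("n_iter must be >= 1")
  kernel <- lorentzian_kernel(psf_fwhm, pixel_size)
  plan <- conv2_plan(dim(image), kernel)
  eps <- 1e-12
  u <- image
  u[u <= 0] <- mean(image[image > 0]) * 1e-6 + eps
  for (i in seq_len(n_iter)) {
    est <- conv2_apply(u, plan)
    ratio <- image / pmax(est, eps)
    u <- u * conv2_apply(ratio, plan)  # kernel is symmetric
    u[u < 0] <- 0
  }
  u
}

#' Deconvolve every channel of a STED field
#'
#' @param field a `bq_sted`.
#' @inheritParams richardson_lucy_deconvolve
#' @param channels which channels to deconvolve.
#' @return A new `bq_sted` with deconvolved channels.
#' @export
deconvolve_field <- function(field, psf_fwhm = 40, n_iter = 30,
                             channels = c("cav", "munc", "homer")) {
  stopifnot(inherits(field, "bq_sted"))
  for (nm in channels) {
    field$channels[[nm]] <- richardson_lucy_deconvolve(
      field$channels[[nm]], psf_fwhm, n_iter, field$pixel_size)
  }
  field
}

#' Prominence-gated local maxima of an image
#'
#' Finds local maxima (8-connectivity) whose prominence — height above the
#' highest saddle connecting them to a higher maximum — exceeds `prominence`,
#' the same gating rule as Fiji's "Find maxima". The global maximum's
#' prominence is its height above the image minimum. Plateau maxima are
#' reported at the centroid of the plateau.
#'
#' @param channel numeric matrix.
#' @param prominence strict lower bound on prominence.
#' @return Tibble `row`, `col` (centroid, fractional for plateaus), `value`,
#'   `prominence`, sorted by decreasing value.
#' @export
find_maxima <- function(channel, prominence = 20) {
  m <- cpp_find_maxima(as.matrix(channel), as.numeric(prominence))
  out <- tibble(row = m[, 1], col = m[, 2], value = m[, 3],
                prominence = m[, 4])
  dplyr::arrange(out, dplyr::desc(.data$value))
}

#' Gate Cav-Munc maxima pairs into Homer-adjacent synapse triads
#'
#' Greedy one-to-one matching: candidate Cav2.1/Munc13-1 pairs closer than
#' `pair_radius` are visited in order of increasing distance and accepted
#' when both members are still unused and lie within `homer_radius` of a
#' common Homer1 spot.
#'
#' @param cav_maxima,munc_maxima,homer_spots tibbles with `row`, `col`
#'   (pixel coordinates, e.g. from [find_maxima()]).
#' @param pair_radius maximum Cav-Munc distance (nm).
#' @param homer_radius maximum distance of each member to the shared Homer
#'   spot (nm).
#' @param pixel_size nm per pixel.
#' @return Tibble of triads: member coordinates, `pair_dist_nm`, and the
#'   gate radii used.
#' @export
detect_triads <- function(cav_maxima, munc_maxima, homer_spots,
                          pair_radius = 250, homer_radius = 200,
                          pixel_size = 20) {
  empty <- tibble(cav_row = numeric(), cav_col = numeric(),
                  munc_row = numeric(), munc_col = numeric(),
                  homer_row = numeric(), homer_col = numeric(),
                  pair_dist_nm = numeric(),
                  pair_radius = numeric(), homer_radius = numeric())
  nc_ <- nrow(cav_maxima); nm_ <- nrow(munc_maxima); nh <- nrow(homer_spots)
  if (nc_ == 0 || nm_ == 0 || nh == 0) return(empty)

  cav <- cbind(cav_maxima$row, cav_maxima$col) * pixel_size
  munc <- cbind(munc_maxima$row, munc_maxima$col) * pixel_size
  hom <- cbind(homer_spots$row, homer_spots$col) * pixel_size

  dmat <- sqrt(outer(cav[, 1], munc[, 1], "-")^2 +
               outer(cav[, 2], munc[, 2], "-")^2)
  cand <- which(dmat <= pair_radius, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(dmat[cand]), , drop = FALSE]

  used_c <- rep(FALSE, nc_); used_m <- rep(FALSE, nm_)
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_c[i] || used_m[j]) next
    dc <- sqrt((hom[, 1] - cav[i, 1])^2 + (hom[, 2] - cav[i, 2])^2)
    dm <- sqrt((hom[, 1] - munc[j, 1])^2 + (hom[, 2] - munc[j, 2])^2)
    shared <- which(dc <= homer_radius & dm <= homer_radius)
    if (length(shared) == 0) next
    h <- shared[which.min(pmax(dc[shared], dm[shared]))]
    used_c[i] <- TRUE; used_m[j] <- TRUE
    rows[[length(rows) + 1]] <- tibble(
      cav_row = cav_maxima$row[i], cav_col = cav_maxima$col[i],
      munc_row = munc_maxima$row[j], munc_col = munc_maxima$col[j],
      homer_row = homer_spots$row[h], homer_col = homer_spots$col[h],
      pair_dist_nm = dmat[i, j],
      pair_radius = pair_radius, homer_radius = homer_radius)
  }
  if (length(rows) == 0) return(empty)
  dplyr::bind_rows(rows)
}

#' Peak-to-peak coupling distance along a line profile
#'
#' Draws the straight 1-pixel line through the two intensity maxima of a
#' triad, extends it by `extend` pixels beyond each end, samples the Cav and
#' Munc channels along it (nearest-pixel reads by default), and returns the
#' distance between the positions of the two channel maxima along the line,
#' in nm. No subpixel interpolation of the maximum position is performed.
#'
#' @param field a `bq_sted` (typically deconvolved).
#' @param triad one row of the tibble from [detect_triads()].
#' @param extend extension beyond each endpoint (pixels).
#' @param interpolate use bilinear interpolation instead of nearest-pixel
#'   reads along the line.
#' @return Distance in nm.
#' @export
measure_distance <- function(field, triad, extend = 10, interpolate = FALSE) {
  stopifnot(inherits(field, "bq_sted"))
  a <- c(triad$cav_row, triad$cav_col)
  b <- c(triad$munc_row, triad$munc_col)
  len <- sqrt(sum((b - a)^2))
  if (len == 0) return(0)
  u <- (b - a) / len
  tt <- seq(-extend, len + extend, by = 1)
  pr <- a[1] + tt * u[1]
  pc <- a[2] + tt * u[2]
  img <- field$channels
  nr <- nrow(img$cav); nc <- ncol(img$cav)

  read_line <- function(im) {
    if (interpolate) {
      r0 <- floor(pr); c0 <- floor(pc)
      ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
      v <- rep(NA_real_, length(tt))
      fr <- pr - r0; fc <- pc - c0
      i <- which(ok)
      v[i] <- im[cbind(r0[i], c0[i])] * (1 - fr[i]) * (1 - fc[i]) +
        im[cbind(r0[i] + 1, c0[i])] * fr[i] * (1 - fc[i]) +
        im[cbind(r0[i], c0[i] + 1)] * (1 - fr[i]) * fc[i] +
        im[cbind(r0[i] + 1, c0[i] + 1)] * fr[i] * fc[i]
      v
    } else {
      rr <- round(pr); cc <- round(pc)
      ok <- rr >= 1 & cc >= 1 & rr <= nr & cc <= nc
      v <- rep(NA_real_, length(tt))
      v[ok] <- im[cbind(rr[ok], cc[ok])]
      v
    }
  }
  v_cav <- read_line(img$cav)
  v_munc <- read_line(img$munc)
  if (all(is.na(v_cav)) || all(is.na(v_munc))) {
    abort("line profile exits the image with no attainable maximum")
  }
  t_cav <- tt[which.max(v_cav)]
  t_munc <- tt[which.max(v_munc)]
  abs(t_cav - t_munc) * field$pixel_size
}

#' End-to-end coupling-distance measurement on one field
#'
#' Deconvolves the Cav and Munc channels (Richardson-Lucy, Lorentzian PSF),
#' finds prominence-gated maxima in all three channels, gates Homer-adjacent
#' Cav-Munc triads, and measures the line-profile peak-to-peak distance for
#' each triad.
#'
#' @param field a raw `bq_sted`.
#' @param prominence maxima prominence threshold (default 20; the study used
#'   10 for a subset of CA1 data).
#' @param pair_radius,homer_radius triad gate radii (nm).
#' @param psf_fwhm,n_iter Richardson-Lucy settings.
#' @param deconvolve set `FALSE` to measure on the raw channels.
#' @return Tibble with one row per measured synapse: `distance_nm`, triad
#'   coordinates, and the field's grouping metadata.
#' @export
measure_coupling <- function(field, prominence = 20, pair_radius = 250,
                             homer_radius = 200, psf_fwhm = 40, n_iter = 30,
                             deconvolve = TRUE) {
  stopifnot(inherits(field, "bq_sted"))
  work <- if (deconvolve) {
    deconvolve_field(field, psf_fwhm, n_iter, channels = c("cav", "munc"))
  } else field
  cavm <- find_maxima(work$channels$cav, prominence)
  muncm <- find_maxima(work$channels$munc, prominence)
  homm <- find_maxima(work$channels$homer, prominence)
  triads <- detect_triads(cavm, muncm, homm, pair_radius, homer_radius,
                          work$pixel_size)
  if (nrow(triads) == 0) {
    return(tibble(distance_nm = numeric(), cav_row = numeric(),
                  cav_col = numeric(), munc_row = numeric(),
                  munc_col = numeric(), condition = character(),
                  region = character(), animal_id = character()))
  }
  d <- vapply(seq_len(nrow(triads)),
              function(i) measure_distance(work, triads[i, ]), numeric(1))
  dplyr::mutate(triads, distance_nm = d, condition = field$condition,
                region = field$region_label, animal_id = field$animal_id)
}

#' Aggregate per-synapse coupling distances into group summaries
#'
#' Builds 20-nm histograms from 0, cumulative frequencies, per-synapse and
#' per-animal mean +/- SEM for each group, and pairwise cross-group
#' comparisons (two-sample Kolmogorov-Smirnov on the distributions and
#' Mann-Whitney on synapse-level values).
#'
#' @param measurements tibble with `distance_nm` and grouping columns.
#' @param group name of the grouping column (default `"condition"`).
#' @param animal name of the animal-id column, or `NULL`.
#' @param bin_width histogram bin width (nm, default 20).
#' @return A list of class `bq_distance_set`: `summary`, `animal_summary`,
#'   `histogram`, `comparisons`, `data`.
#' @export
aggregate_distances <- function(measurements, group = "condition",
                                animal = "animal_id", bin_width = 20) {
  measurements <- as_tibble(measurements)
  if (any(measurements$distance_nm < 0)) abort("distances must be >= 0")
  g <- measurements[[group]]
  if (any(table(g) < 2)) {
    abort(sprintf("group '%s' has fewer than 2 synapses",
                  names(which(table(g) < 2))[1]))
  }
  summary <- measurements |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$distance_nm),
                     sem = sem(.data$distance_nm), .groups = "drop")

  animal_summary <- NULL
  if (!is.null(animal) && animal %in% names(measurements)) {
    per_animal <- measurements |>
      dplyr::group_by(group = .data[[group]],
                      animal = .data[[animal]]) |>
      dplyr::summarise(animal_mean = mean(.data$distance_nm),
                       n_synapses = dplyr::n(), .groups = "drop")
    animal_summary <- per_animal |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(n_animals = dplyr::n(),
                       mean = mean(.data$animal_mean),
                       sem = sem(.data$animal_mean), .groups = "drop")
    attr(animal_summary, "per_animal") <- per_animal
  }

  max_d <- max(measurements$distance_nm)
  breaks <- seq(0, (floor(max_d / bin_width) + 1) * bin_width, by = bin_width)
  histogram <- measurements |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::reframe({
      cnt <- graphics::hist(.data$distance_nm, breaks = breaks, right = FALSE,
                            plot = FALSE)$counts
      tibble(bin_start = breaks[-length(breaks)],
             bin_end = breaks[-1], count = cnt,
             cum_freq = cumsum(cnt) / sum(cnt))
    })

  groups <- unique(g)
  comparisons <- NULL
  if (length(groups) >= 2) {
    prs <- utils::combn(as.character(groups), 2)
    comparisons <- purrr::map_dfr(seq_len(ncol(prs)), function(k) {
      a <- measurements$distance_nm[g == prs[1, k]]
      b <- measurements$distance_nm[g == prs[2, k]]
      mw <- compare_groups(a, b)
      ks <- compare_groups(a, b, distributional = TRUE)
      dplyr::bind_rows(
        dplyr::mutate(tidy(mw), group_a = prs[1, k], group_b = prs[2, k]),
        dplyr::mutate(tidy(ks), group_a = prs[1, k], group_b = prs[2, k]))
    })
  }
  structure(list(summary = summary, animal_summary = animal_summary,
                 histogram = histogram, comparisons = comparisons,
                 data = measurements, group = group, bin_width = bin_width),
            class = "bq_distance_set")
}

#' @export
print.bq_distance_set <- function(x, ...) {
  cat("<bq_distance_set>\n")
  print(x$summary)
  if (!is.null(x$comparisons)) {
    cat("comparisons:\n")
    print(x$comparisons[, c("group_a", "group_b", "test", "p_value", "stars")])
  }
  invisible(x)
}

#' @rdname aggregate_distances
#' @param x a `bq_distance_set`.
#' @param ... unused.
#' @export
tidy.bq_distance_set <- function(x, ...) x$summary

#' @rdname aggregate_distances
#' @export
glance.bq_distance_set <- function(x, ...) {
  tibble(n_total = nrow(x$data), n_groups = nrow(x$summary),
         bin_width = x$bin_width)
}
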