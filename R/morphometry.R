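# Serial-section EM morphometry. Coordinates are nm; areas um^2, volumes
# um^3, densities per um^2/um^3 to match the study's reporting units.

largest_profile <- function(rec) {
  best <- NULL; best_area <- -Inf
  for (s in rec$sections) {
    for (p in s$presyn) {
      a <- polygon_area(p)
      if (a > best_area) { best_area <- a; best <- p }
    }
  }
  if (is.null(best) || best_area <= 0) abort("no nondegenerate presynaptic profile")
  best
}

#' Bouton complexity and presynaptic area of a 2D profile
#'
#' Complexity is the perimeter of the presynaptic bouton profile divided by
#' its area, measured on the single largest profile of the reconstruction
#' (units 1/um). A circle of radius r has complexity 2/r; by the
#' isoperimetric inequality every non-circular profile of equal area scores
#' higher.
#'
#' @param x a `bq_reconstruction`, or a single polygon (n x 2 matrix, nm).
#' @return `bouton_complexity()`: 1/um. `presyn_area()`: um^2.
#' @export
bouton_complexity <- function(x) {
  poly <- if (inherits(x, "bq_reconstruction")) largest_profile(x) else x
  a <- polygon_area(poly)
  if (a <= 0) abort("degenerate polygon: area is zero")
  (polygon_perimeter(poly) / 1e3) / (a / 1e6)
}

#' @rdname bouton_complexity
#' @export
presyn_area <- function(x) {
  poly <- if (inherits(x, "bq_reconstruction")) largest_profile(x) else x
  polygon_area(poly) / 1e6
}

#' Reconstructed presynaptic volume
#'
#' Sum over sections of presynaptic profile area times section thickness.
#'
#' @param rec a `bq_reconstruction`.
#' @return Volume in um^3.
#' @export
reconstructed_volume <- function(rec) {
  stopifnot(inherits(rec, "bq_reconstruction"))
  a <- sum(vapply(rec$sections, function(s)
    sum(vapply(s$presyn, polygon_area, numeric(1))), numeric(1)))
  a * rec$section_thickness / 1e9
}

#' Active-zone count, density and per-AZ area
#'
#' AZs are linked across sections by `az_id`; per-AZ area is the summed trace
#' length times section thickness. Density is distinct AZ count per um^3 of
#' reconstructed volume. An `az_id` appearing in non-contiguous sections is
#' kept as one AZ with a warning.
#'
#' @param rec a `bq_reconstruction`.
#' @return List with `az_count`, `az_density` (1/um^3) and tibble `az_areas`
#'   (`az_id`, `area_um2`, `n_sections`).
#' @export
az_stats <- function(rec) {
  stopifnot(inherits(rec, "bq_reconstruction"))
  rows <- list()
  for (s in rec$sections) {
    for (a in s$az) {
      rows[[length(rows) + 1]] <- tibble(
        az_id = a$az_id, z_index = s$z_index,
        length_nm = polyline_length(a$points))
    }
  }
  vol <- reconstructed_volume(rec)
  if (length(rows) == 0) {
    return(list(az_count = 0L, az_density = 0,
                az_areas = tibble(az_id = integer(), area_um2 = numeric(),
                                  n_sections = integer())))
  }
  tr <- dplyr::bind_rows(rows)
  gaps <- tr |>
    dplyr::group_by(.data$az_id) |>
    dplyr::summarise(contig = all(diff(sort(.data$z_index)) == 1))
  if (any(!gaps$contig)) {
    warn(sprintf("AZ id(s) %s appear in non-contiguous sections; treated as one AZ each",
                 paste(gaps$az_id[!gaps$contig], collapse = ", ")))
  }
  areas <- tr |>
    dplyr::group_by(.data$az_id) |>
    dplyr::summarise(
      area_um2 = sum(.data$length_nm) * rec$section_thickness / 1e6,
      n_sections = dplyr::n(), .groups = "drop")
  list(az_count = nrow(areas), az_density = nrow(areas) / vol,
       az_areas = areas)
}

# All vesicles of a reconstruction with 3D coordinates (z at mid-section).
vesicle_table <- function(rec) {
  purrr::map_dfr(rec$sections, function(s) {
    v <- s$vesicles
    if (is.null(v) || nrow(v) == 0) return(tibble())
    dplyr::mutate(as_tibble(v), z_index = s$z_index,
                  z = (s$z_index - 0.5) * rec$section_thickness)
  })
}

#' Synaptic vesicle count, density, pairwise dispersion and 2D MNND
#'
#' Density is count per um^3 of reconstructed volume. Pairwise dispersion is
#' the mean over all unordered vesicle pairs of the 3D Euclidean
#' centre-to-centre distance (z at mid-section planes) divided by the
#' reconstructed volume (nm/um^3); `dispersion = "sum"` and `"per_vesicle"`
#' variants are provided because sum, per-vesicle mean and pair mean are all
#' dimensionally consistent with the reported unit. MNND is the mean over
#' vesicles of the within-section 2D nearest-neighbour centre distance,
#' averaged across sections weighted by vesicle count.
#'
#' @param rec a `bq_reconstruction`.
#' @param dispersion `"pair_mean"` (default), `"sum"`, or `"per_vesicle"`.
#' @return Tibble: `sv_count`, `sv_density`, `pairwise_dispersion`, `mnnd`,
#'   `dispersion_note`.
#' @export
sv_stats <- function(rec, dispersion = c("pair_mean", "sum", "per_vesicle")) {
  stopifnot(inherits(rec, "bq_reconstruction"))
  dispersion <- match.arg(dispersion)
  ves <- vesicle_table(rec)
  vol <- reconstructed_volume(rec)
  n <- nrow(ves)

  disp <- NA_real_; note <- NA_character_
  if (n >= 2) {
    d3 <- stats::dist(cbind(ves$x, ves$y, ves$z))
    total <- sum(d3)
    disp <- switch(dispersion,
                   pair_mean = total / length(d3),
                   sum = total,
                   per_vesicle = 2 * total / n) / vol
  } else {
    note <- "fewer than 2 vesicles: dispersion undefined"
  }

  nn_all <- numeric(0)
  for (s in rec$sections) {
    v <- s$vesicles
    if (is.null(v) || nrow(v) < 2) next
    dm <- as.matrix(stats::dist(cbind(v$x, v$y)))
    diag(dm) <- Inf
    nn_all <- c(nn_all, apply(dm, 1, min))
  }
  mnnd <- if (length(nn_all) > 0) mean(nn_all) else NA_real_

  tibble(sv_count = n, sv_density = n / vol, pairwise_dispersion = disp,
         mnnd = mnnd, dispersion_note = note)
}

#' Classify vesicles as docked, tethered or neither
#'
#' Per vesicle, the gap is the distance from its centre to the nearest
#' AZ-bearing membrane segment of its own section minus the vesicle radius.
#' Docked: gap <= `docked_gap_max` (membrane contact, default 2 nm).
#' Tethered: not docked and centre within `tether_center_max` (default 60 nm,
#' the study's readily-releasable-pool approximation) of that membrane.
#' Densities are reported per um^3 of bouton volume and per um^2 of AZ area;
#' the RRP density is their sum.
#'
#' @param rec a `bq_reconstruction`.
#' @param docked_gap_max nm.
#' @param tether_center_max nm.
#' @return List with `vesicles` (tibble incl. `label`, `az_dist`) and
#'   `densities` (one-row tibble).
#' @export
classify_docked_tethered <- function(rec, docked_gap_max = 2,
                                     tether_center_max = 60) {
  stopifnot(inherits(rec, "bq_reconstruction"))
  vol <- reconstructed_volume(rec)
  azs <- az_stats(rec)
  rows <- purrr::map_dfr(rec$sections, function(s) {
    v <- s$vesicles
    if (is.null(v) || nrow(v) == 0) return(tibble())
    v <- dplyr::mutate(as_tibble(v), z_index = s$z_index)
    if (length(s$az) == 0) {
      return(dplyr::mutate(v, az_dist = NA_real_, label = "neither"))
    }
    dmat <- vapply(s$az, function(a)
      dist_point_polyline(v$x, v$y, a$points), numeric(nrow(v)))
    az_dist <- if (nrow(v) == 1) min(dmat) else
      apply(matrix(dmat, nrow = nrow(v)), 1, min)
    dplyr::mutate(v, az_dist = az_dist,
                  label = dplyr::case_when(
                    az_dist - .data$r <= docked_gap_max ~ "docked",
                    az_dist <= tether_center_max ~ "tethered",
                    TRUE ~ "neither"))
  })
  if (nrow(rows) == 0) {
    rows <- tibble(x = numeric(), y = numeric(), r = numeric(),
                   z_index = integer(), az_dist = numeric(),
                   label = character())
  }
  n_docked <- sum(rows$label == "docked")
  n_tethered <- sum(rows$label == "tethered")
  az_area <- sum(azs$az_areas$area_um2)
  per_az <- function(n) if (az_area > 0) n / az_area else NA_real_
  densities <- tibble(
    n_docked = n_docked, n_tethered = n_tethered,
    docked_density_volume = n_docked / vol,
    docked_density_az = per_az(n_docked),
    tethered_density_az = per_az(n_tethered),
    rrp_density_az = per_az(n_docked) + per_az(n_tethered))
  list(vesicles = rows, densities = densities)
}

#' Mitochondrial volume fraction
#'
#' Summed mitochondrial polygon area times thickness as a percentage of the
#' reconstructed presynaptic volume; 0 when no mitochondria are present.
#'
#' @param rec a `bq_reconstruction`.
#' @return Percent.
#' @export
mito_fraction <- function(rec) {
  stopifnot(inherits(rec, "bq_reconstruction"))
  a <- sum(vapply(rec$sections, function(s) {
    if (length(s$mito) == 0) return(0)
    sum(vapply(s$mito, polygon_area, numeric(1)))
  }, numeric(1)))
  100 * (a * rec$section_thickness / 1e9) / reconstructed_volume(rec)
}

#' Full morphometry of a reconstruction
#'
#' One-row tidy summary: complexity, presynaptic area, volume, AZ count /
#' density / mean area, vesicle count / density / dispersion / MNND, docked
#' and tethered densities, RRP density and mitochondrial fraction.
#'
#' @inheritParams classify_docked_tethered
#' @inheritParams sv_stats
#' @return A one-row tibble.
#' @export
morphometry <- function(rec, docked_gap_max = 2, tether_center_max = 60,
                        dispersion = "pair_mean") {
  azs <- az_stats(rec)
  sv <- sv_stats(rec, dispersion = dispersion)
  dt <- classify_docked_tethered(rec, docked_gap_max, tether_center_max)
  dplyr::bind_cols(
    tibble(bouton_id = rec$bouton_id, condition = rec$condition,
           animal_id = rec$animal_id,
           complexity = bouton_complexity(rec),
           presyn_area = presyn_area(rec),
           volume = reconstructed_volume(rec),
           az_count = azs$az_count, az_density = azs$az_density,
           mean_az_area = if (nrow(azs$az_areas) > 0)
             mean(azs$az_areas$area_um2) else NA_real_),
    sv[, c("sv_count", "sv_density", "pairwise_dispersion", "mnnd")],
    dt$densities,
    tibble(mito_fraction = mito_fraction(rec)))
}
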