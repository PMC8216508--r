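#' Configuration for the synthetic serial-section reconstruction generator
#'
#' Parameters of [simulate_reconstruction()], which emulates a manually
#' segmented serial-section (default 70 nm) reconstruction of a mossy fiber
#' bouton: a rough-edged presynaptic membrane polygon per section, active
#' zone (AZ) traces on the membrane, synaptic vesicle centres drawn from a
#' uniform or clustered (Thomas parent-offspring) point process with hard-core
#' rejection, docked and tethered vesicles at the AZs, and mitochondria
#' occupying a configured volume fraction.
#'
#' @param n_sections number of serial sections.
#' @param section_thickness nm (default 70).
#' @param bouton_area_um2 presynaptic profile area per section (um^2).
#' @param boundary_roughness relative amplitude of the radial perturbation of
#'   the profile outline (0 = circle).
#' @param n_azs number of active zones.
#' @param az_length_nm AZ trace length per section (nm).
#' @param az_sections number of consecutive sections each AZ spans.
#' @param vesicle_count free vesicles drawn from the point process.
#' @param vesicle_diameter nm (default 40).
#' @param clustering list: `type = "uniform"`, or `type = "thomas"` with
#'   `n_parents`, `offspring_sd` (nm) and optional `parent_region_scale` in
#'   (0, 1] concentrating cluster parents toward the bouton core.
#' @param hardcore_radius minimum centre-to-centre distance within a section
#'   (nm); default one vesicle diameter.
#' @param docked_per_az,tethered_per_az counts placed at each AZ.
#' @param mito_volume_fraction percent of the reconstructed volume occupied
#'   by mitochondria.
#' @param seed integer seed.
#' @return A list of class `em_sim_config`.
#' @export
em_sim_config <- function(n_sections = 8L,
                          section_thickness = 70,
                          bouton_area_um2 = 4,
                          boundary_roughness = 0.12,
                          n_azs = 4L,
                          az_length_nm = 400,
                          az_sections = 2L,
                          vesicle_count = 300L,
                          vesicle_diameter = 40,
                          clustering = list(type = "uniform"),
                          hardcore_radius = NULL,
                          docked_per_az = 3L,
                          tethered_per_az = 4L,
                          mito_volume_fraction = 10,
                          seed = NULL) {
  assert_scalar_num(section_thickness, "section_thickness", 0,
                    strict_lower = TRUE)
  assert_scalar_num(bouton_area_um2, "bouton_area_um2", 0,
                    strict_lower = TRUE)
  assert_scalar_num(mito_volume_fraction, "mito_volume_fraction", 0, 100)
  if (!clustering$type %in% c("uniform", "thomas")) {
    abort("clustering$type must be 'uniform' or 'thomas'")
  }
  structure(
    list(n_sections = as.integer(n_sections),
         section_thickness = section_thickness,
         bouton_area_um2 = bouton_area_um2,
         boundary_roughness = boundary_roughness,
         n_azs = as.integer(n_azs), az_length_nm = az_length_nm,
         az_sections = as.integer(az_sections),
         vesicle_count = as.integer(vesicle_count),
         vesicle_diameter = vesicle_diameter,
         clustering = clustering,
         hardcore_radius = hardcore_radius %||% vesicle_diameter,
         docked_per_az = as.integer(docked_per_az),
         tethered_per_az = as.integer(tethered_per_az),
         mito_volume_fraction = mito_volume_fraction, seed = seed),
    class = "em_sim_config")
}

#' Construct a reconstruction object
#'
#' @param sections list of sections, each a list with `z_index` (strictly
#'   increasing integers), `presyn` (list of n x 2 polygon vertex matrices,
#'   nm), `az` (list of `list(az_id =, points = n x 2 matrix)`), `mito`
#'   (list of polygons), `vesicles` (tibble `x`, `y`, `r` in nm).
#' @param section_thickness nm.
#' @param bouton_id,condition,animal_id metadata.
#' @return A `bq_reconstruction`.
#' @export
reconstruction <- function(sections, section_thickness = 70,
                           bouton_id = "", condition = "", animal_id = "") {
  z <- vapply(sections, function(s) s$z_index, numeric(1))
  if (is.unsorted(z, strictly = TRUE)) {
    abort("section z_index must be strictly increasing")
  }
  structure(list(sections = sections, section_thickness = section_thickness,
                 bouton_id = bouton_id, condition = condition,
                 animal_id = animal_id),
            class = "bq_reconstruction")
}

#' @export
print.bq_reconstruction <- function(x, ...) {
  nves <- sum(vapply(x$sections, function(s) nrow(s$vesicles), numeric(1)))
  cat(sprintf("<bq_reconstruction> %d sections x %g nm, %d vesicles\n",
              length(x$sections), x$section_thickness, nves))
  invisible(x)
}

# Rough closed outline: circle of the given area with low-order harmonic
# radial perturbation, rescaled to the target area.
rough_polygon <- function(area_nm2, roughness, n_vertices = 72,
                          center = c(0, 0)) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  pert <- rep(0, n_vertices)
  if (roughness > 0) {
    for (h in 2:5) {
      pert <- pert + rnorm(1, 0, roughness / 2) * cos(h * theta) +
        rnorm(1, 0, roughness / 2) * sin(h * theta)
    }
  }
  r <- sqrt(area_nm2 / pi) * pmax(1 + pert, 0.3)
  poly <- cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
  poly * sqrt(area_nm2 / polygon_area(poly))
}

# Extract a boundary arc of given length starting at arc-length `start`
# (must satisfy start + arc_length <= perimeter, so arcs never wrap the seam).
boundary_arc <- function(poly, arc_length, start = NULL) {
  closed <- rbind(poly, poly[1, , drop = FALSE])
  seg_len <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  if (is.null(start)) start <- runif(1, 0, total - arc_length)
  s_pts <- seq(start, min(start + arc_length, total), length.out = 9)
  t(vapply(s_pts, function(s) {
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- min(i, length(seg_len))
    f <- (s - cum[i]) / seg_len[i]
    closed[i, ] + f * (closed[i + 1, ] - closed[i, ])
  }, numeric(2)))
}

# Inward unit normal at the midpoint of a polyline lying on `poly`'s boundary.
inward_point <- function(arc, poly, depth) {
  mid_i <- ceiling(nrow(arc) / 2)
  tang <- arc[min(mid_i + 1, nrow(arc)), ] - arc[max(mid_i - 1, 1), ]
  tang <- tang / sqrt(sum(tang^2))
  nrm <- c(-tang[2], tang[1])
  p <- arc[mid_i, ] + depth * nrm
  if (!point_in_polygon(p[1], p[2], poly)) p <- arc[mid_i, ] - depth * nrm
  p
}

#' Simulate a serial-section bouton reconstruction
#'
#' Runs the generator described in [em_sim_config()]. The presynaptic profile
#' polygon is drawn once and reused in every section (a prism), so the
#' ground-truth volume is exact. Mitochondria are a copy of the profile
#' scaled about its centroid to the configured volume fraction. Free vesicle
#' centres respect the hard-core constraint within each section (sections are
#' 70 nm apart, beyond the default hard-core radius).
#'
#' @param config an [em_sim_config()].
#' @return List with `rec` (a `bq_reconstruction`) and `truth` (counts,
#'   volume, densities, per-AZ areas, generating parameters).
#' @export
simulate_reconstruction <- function(config) {
  stopifnot(inherits(config, "em_sim_config"))
  with_rng(config$seed, simulate_reconstruction_impl(config))
}

simulate_reconstruction_impl <- function(cfg) {
  area_nm2 <- cfg$bouton_area_um2 * 1e6
  poly <- rough_polygon(area_nm2, cfg$boundary_roughness)
  thick <- cfg$section_thickness
  n_sec <- cfg$n_sections
  r_ves <- cfg$vesicle_diameter / 2
  hc <- cfg$hardcore_radius

  # AZ layout: az k spans az_sections consecutive sections; arcs live in
  # disjoint perimeter segments so AZs never overlap on the membrane
  az_first <- sample(seq_len(max(n_sec - cfg$az_sections + 1, 1)),
                     cfg$n_azs, replace = TRUE)
  perim <- polygon_perimeter(poly)
  if (cfg$n_azs > 0 && cfg$az_length_nm * cfg$n_azs > perim) {
    abort("AZ traces do not fit on the membrane perimeter")
  }
  seg <- if (cfg$n_azs > 0) perim / cfg$n_azs else perim
  az_arcs <- lapply(seq_len(cfg$n_azs), function(k) {
    start <- (k - 1) * seg + runif(1, 0, max(seg - cfg$az_length_nm, 0))
    boundary_arc(poly, cfg$az_length_nm, start)
  })

  mito_poly <- NULL
  if (cfg$mito_volume_fraction > 0) {
    cen <- polygon_centroid(poly)
    sc <- sqrt(cfg$mito_volume_fraction / 100)
    mito_poly <- sweep(sweep(poly, 2, cen, "-") * sc, 2, cen, "+")
  }

  # docked / tethered vesicles per AZ per section; docked sit in membrane
  # contact (gap <= 0), tethered strictly inside the tether shell
  # (gap > docked_gap, centre <= 60 nm from the AZ membrane)
  arc_point <- function(arc, f) {
    idx <- 1 + f * (nrow(arc) - 1)
    lo <- floor(idx); hi <- min(ceiling(idx), nrow(arc))
    arc[lo, ] + (idx - lo) * (arc[hi, ] - arc[lo, ])
  }
  # inward unit normal from the local tangent at arc fraction f, so a vesicle
  # at base + r * normal is exactly r from the local segment (gap 0)
  arc_normal <- function(arc, poly, base, f) {
    idx <- 1 + f * (nrow(arc) - 1)
    lo <- max(floor(idx), 1); hi <- min(lo + 1, nrow(arc))
    tang <- arc[hi, ] - arc[lo, ]
    tang <- tang / sqrt(sum(tang^2))
    nrm <- c(-tang[2], tang[1])
    probe <- base + 5 * nrm
    if (!point_in_polygon(probe[1], probe[2], poly)) nrm <- -nrm
    nrm
  }
  placed <- vector("list", n_sec)
  for (s in seq_len(n_sec)) placed[[s]] <- matrix(numeric(0), 0, 3)
  n_docked <- 0L; n_tethered <- 0L
  for (k in seq_len(cfg$n_azs)) {
    secs <- az_first[k]:(az_first[k] + cfg$az_sections - 1)
    for (s in secs) {
      arc <- az_arcs[[k]]
      for (i in seq_len(cfg$docked_per_az)) {
        f <- (i - 0.5) / max(cfg$docked_per_az, 1)
        base <- arc_point(arc, f)
        p <- base + r_ves * arc_normal(arc, poly, base, f)
        placed[[s]] <- rbind(placed[[s]], c(p, r_ves))
        n_docked <- n_docked + 1L
      }
      for (i in seq_len(cfg$tethered_per_az)) {
        ok <- FALSE
        for (try in seq_len(200)) {
          f <- runif(1)
          depth <- runif(1, r_ves + 6, 56)
          base <- arc_point(arc, f)
          p <- base + depth * arc_normal(arc, poly, base, f)
          if (!point_in_polygon(p[1], p[2], poly)) next
          d_az <- dist_point_polyline(p[1], p[2], arc)
          if (d_az <= r_ves + 4 || d_az > 58) next
          prev <- placed[[s]]
          if (nrow(prev) > 0 &&
              any(sqrt((prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2) < hc)) {
            next
          }
          placed[[s]] <- rbind(placed[[s]], c(p, r_ves))
          n_tethered <- n_tethered + 1L
          ok <- TRUE
          break
        }
        if (!ok) {
          abort("could not place a tethered vesicle in the tether shell")
        }
      }
    }
  }

  # AZ polylines per section, for the free-vesicle exclusion zone
  az_by_section <- lapply(seq_len(n_sec), function(s) {
    out <- list()
    for (k in seq_len(cfg$n_azs)) {
      secs <- az_first[k]:(az_first[k] + cfg$az_sections - 1)
      if (s %in% secs) out[[length(out) + 1]] <- az_arcs[[k]]
    }
    out
  })

  # free vesicles from the configured point process, hard-core within section
  target <- cfg$vesicle_count
  max_attempts <- 400L * max(target, 1L)
  attempts <- 0L
  got <- 0L
  inner <- function() {
    if (cfg$clustering$type == "uniform") {
      s <- sample.int(n_sec, 1)
      p <- sample_in_polygon(1, poly)
      list(s = s, p = p[1, ])
    } else {
      if (is.null(parents_env$parents)) {
        np <- cfg$clustering$n_parents
        scale <- cfg$clustering$parent_region_scale %||% 1
        ppoly <- if (scale < 1) {
          cen <- polygon_centroid(poly)
          sweep(sweep(poly, 2, cen, "-") * scale, 2, cen, "+")
        } else poly
        parents_env$parents <- cbind(sample.int(n_sec, np, replace = TRUE),
                                     sample_in_polygon(np, ppoly))
      }
      pp <- parents_env$parents
      k <- sample.int(nrow(pp), 1)
      sd_off <- cfg$clustering$offspring_sd
      z <- (pp[k, 1] - 0.5) * thick + rnorm(1, 0, sd_off)
      s <- floor(z / thick) + 1
      p <- pp[k, 2:3] + rnorm(2, 0, sd_off)
      list(s = s, p = p)
    }
  }
  parents_env <- new.env()
  parents_env$parents <- NULL
  while (got < target) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(sprintf(
        "could not place %d vesicles under the hard-core constraint within %d attempts",
        target, max_attempts))
    }
    cand <- inner()
    s <- cand$s
    if (is.na(s) || s < 1 || s > n_sec) next
    if (!point_in_polygon(cand$p[1], cand$p[2], poly)) next
    # keep free vesicles out of the 60-nm tether zone of same-section AZs so
    # ground-truth docked/tethered counts stay exact
    near_az <- any(vapply(az_by_section[[s]], function(a)
      dist_point_polyline(cand$p[1], cand$p[2], a) <= 62, logical(1)))
    if (near_az) next
    prev <- placed[[s]]
    if (nrow(prev) > 0) {
      d <- sqrt((prev[, 1] - cand$p[1])^2 + (prev[, 2] - cand$p[2])^2)
      if (any(d < hc)) next
    }
    placed[[s]] <- rbind(placed[[s]], c(cand$p, r_ves))
    got <- got + 1L
  }

  sections <- lapply(seq_len(n_sec), function(s) {
    azs <- list()
    for (k in seq_len(cfg$n_azs)) {
      secs <- az_first[k]:(az_first[k] + cfg$az_sections - 1)
      if (s %in% secs) {
        azs[[length(azs) + 1]] <- list(az_id = k, points = az_arcs[[k]])
      }
    }
    ves <- placed[[s]]
    list(z_index = s,
         presyn = list(poly),
         az = azs,
         mito = if (is.null(mito_poly)) list() else list(mito_poly),
         vesicles = tibble(x = ves[, 1], y = ves[, 2], r = ves[, 3]))
  })

  rec <- reconstruction(sections, thick, bouton_id = "synthetic")
  vol_um3 <- polygon_area(poly) * thick * n_sec / 1e9
  az_area_um2 <- vapply(az_arcs, polyline_length, numeric(1)) *
    thick * cfg$az_sections / 1e6
  n_total <- got + n_docked + n_tethered
  truth <- list(
    volume_um3 = vol_um3,
    profile_area_um2 = polygon_area(poly) / 1e6,
    profile_perimeter_um = polygon_perimeter(poly) / 1e3,
    n_free = got, n_docked = n_docked, n_tethered = n_tethered,
    n_vesicles = n_total,
    sv_density = n_total / vol_um3,
    az_count = cfg$n_azs,
    az_density = cfg$n_azs / vol_um3,
    az_area_um2 = az_area_um2,
    mito_fraction = cfg$mito_volume_fraction,
    config = cfg)
  list(rec = rec, truth = truth)
}
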