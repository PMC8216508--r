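# File interchange: multi-page TIFF + JSON sidecar for movies and STED
# fields, a versioned JSON schema for reconstructions, tidy CSV for tables.
# TIFF pages are stored scaled to [0, 1]; the scale factor lives in the
# sidecar so values round-trip exactly up to float precision.

#' Write / read a bouton movie as multi-page TIFF plus JSON sidecar
#'
#' @param movie a `bq_movie`.
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path>.json` unless `sidecar` is given.
#' @param sidecar optional sidecar path.
#' @return `write_movie_tiff()` the TIFF path, invisibly;
#'   `read_movie_tiff()` a `bq_movie`.
#' @export
write_movie_tiff <- function(movie, path, sidecar = NULL) {
  stopifnot(inherits(movie, "bq_movie"))
  sidecar <- sidecar %||% paste0(path, ".json")
  scale <- max(movie$data, 1e-12)
  pages <- lapply(seq_len(dim(movie$data)[1]), function(f)
    pmax(movie$data[f, , ], 0) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(
    kind = "bouton_movie", scale = scale,
    frame_interval_ms = movie$frame_interval,
    pixel_size_um = movie$pixel_size,
    stimulus_times_ms = movie$stimulus_times,
    condition_label = movie$condition_label,
    bouton_mask = as.integer(movie$bouton_mask),  # column-major
    mask_dim = dim(movie$bouton_mask))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, sidecar = NULL) {
  sidecar <- sidecar %||% paste0(path, ".json")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  data <- array(0, c(length(pages), dim(pages[[1]])))
  for (f in seq_along(pages)) data[f, , ] <- pages[[f]] * meta$scale
  mask <- matrix(as.logical(meta$bouton_mask),
                 meta$mask_dim[1], meta$mask_dim[2])
  fluorescence_movie(data, meta$frame_interval_ms, meta$pixel_size_um,
                     meta$stimulus_times_ms, mask,
                     meta$condition_label %||% "")
}

#' Write / read a STED field as three-page TIFF plus JSON sidecar
#'
#' Pages are in channel-role order `cav`, `munc`, `homer` (also recorded in
#' the sidecar).
#'
#' @param field a `bq_sted`.
#' @inheritParams write_movie_tiff
#' @return `write_sted_tiff()` the TIFF path, invisibly; `read_sted_tiff()`
#'   a `bq_sted`.
#' @export
write_sted_tiff <- function(field, path, sidecar = NULL) {
  stopifnot(inherits(field, "bq_sted"))
  sidecar <- sidecar %||% paste0(path, ".json")
  roles <- c("cav", "munc", "homer")
  scale <- max(unlist(lapply(field$channels[roles], max)), 1e-12)
  pages <- lapply(roles, function(r) pmax(field$channels[[r]], 0) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(kind = "sted_field", scale = scale, channel_roles = roles,
               pixel_size_nm = field$pixel_size,
               region_label = field$region_label,
               condition = field$condition, animal_id = field$animal_id)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sted_tiff
#' @export
read_sted_tiff <- function(path, sidecar = NULL) {
  sidecar <- sidecar %||% paste0(path, ".json")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- setNames(lapply(pages, function(p) p * meta$scale),
                       meta$channel_roles)
  sted_field(channels, meta$pixel_size_nm, meta$region_label %||% "",
             meta$condition %||% "", meta$animal_id %||% "")
}

#' Write / read a reconstruction in the versioned JSON schema
#'
#' Schema (version 1): `{schema_version, section_thickness_nm, bouton_id,
#' condition, animal_id, sections: [{z_index, presyn: [[[x, y], ...]], az:
#' [{az_id, points: [[x, y], ...]}], mito: [...], vesicles: [{x, y, r}]}]}`;
#' all coordinates in nm.
#'
#' @param rec a `bq_reconstruction`.
#' @param path JSON path.
#' @return `write_reconstruction_json()` the path, invisibly;
#'   `read_reconstruction_json()` a `bq_reconstruction`.
#' @export
write_reconstruction_json <- function(rec, path) {
  stopifnot(inherits(rec, "bq_reconstruction"))
  poly_list <- function(p) lapply(seq_len(nrow(p)), function(i)
    c(p[i, 1], p[i, 2]))
  sections <- lapply(rec$sections, function(s) {
    list(
      z_index = s$z_index,
      presyn = lapply(s$presyn, poly_list),
      az = lapply(s$az, function(a)
        list(az_id = a$az_id, points = poly_list(a$points))),
      mito = lapply(s$mito, poly_list),
      vesicles = if (nrow(s$vesicles) == 0) list() else
        lapply(seq_len(nrow(s$vesicles)), function(i)
          list(x = s$vesicles$x[i], y = s$vesicles$y[i],
               r = s$vesicles$r[i])))
  })
  obj <- list(schema_version = 1L,
              section_thickness_nm = rec$section_thickness,
              bouton_id = rec$bouton_id, condition = rec$condition,
              animal_id = rec$animal_id, sections = sections)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reconstruction_json
#' @export
read_reconstruction_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  to_mat <- function(pts) {
    do.call(rbind, lapply(pts, function(p) c(p[[1]], p[[2]])))
  }
  sections <- lapply(obj$sections, function(s) {
    ves <- if (length(s$vesicles) == 0) {
      tibble(x = numeric(), y = numeric(), r = numeric())
    } else {
      tibble(x = vapply(s$vesicles, function(v) v$x, numeric(1)),
             y = vapply(s$vesicles, function(v) v$y, numeric(1)),
             r = vapply(s$vesicles, function(v) v$r, numeric(1)))
    }
    list(z_index = s$z_index,
         presyn = lapply(s$presyn, to_mat),
         az = lapply(s$az, function(a)
           list(az_id = a$az_id, points = to_mat(a$points))),
         mito = lapply(s$mito, to_mat),
         vesicles = ves)
  })
  reconstruction(sections, obj$section_thickness_nm,
                 obj$bouton_id %||% "", obj$condition %||% "",
                 obj$animal_id %||% "")
}

#' Export / import vesicle tables as CSV
#'
#' Columns `x_nm`, `y_nm`, `z_index`, `r_nm`.
#'
#' @param rec a `bq_reconstruction`.
#' @param path CSV path.
#' @return `write_vesicle_csv()` the path, invisibly; `read_vesicle_csv()` a
#'   tibble.
#' @export
write_vesicle_csv <- function(rec, path) {
  v <- vesicle_table(rec)
  utils::write.csv(
    data.frame(x_nm = v$x, y_nm = v$y, z_index = v$z_index, r_nm = v$r),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vesicle_csv
#' @export
read_vesicle_csv <- function(path) {
  as_tibble(utils::read.csv(path))
}
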