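#' Read a park boundary from GeoJSON
#'
#' Accepts a `Polygon` geometry (bare geometry, `Feature`, or first feature
#' of a `FeatureCollection`). Coordinates are taken as planar km when the
#' properties carry `"units": "km"` (the convention used by the synthetic
#' generator); otherwise they are treated as lon/lat degrees and projected
#' to a local km frame centred on the ring centroid.
#'
#' @param path GeoJSON file.
#' @return List with `boundary` (a [park_boundary()]) and `projection`
#'   (a [local_projection()], or `NULL` when input was already planar).
#' @export
read_boundary_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  props <- list()
  geom <- g
  if (identical(g$type, "FeatureCollection")) {
    if (!length(g$features)) stop("empty FeatureCollection")
    geom <- g$features[[1L]]$geometry
    props <- g$features[[1L]]$properties %||% list()
  } else if (identical(g$type, "Feature")) {
    geom <- g$geometry
    props <- g$properties %||% list()
  }
  if (!identical(geom$type, "Polygon"))
    stop("boundary GeoJSON must contain a Polygon geometry")
  ring <- geom$coordinates[[1L]]
  xy <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
  if (identical(props$units, "km")) {
    return(list(boundary = park_boundary(xy, source_crs = "local-km"),
                projection = NULL))
  }
  lon0 <- mean(range(xy[, 1L])); lat0 <- mean(range(xy[, 2L]))
  proj <- local_projection(lon0, lat0)
  list(boundary = park_boundary(project_lonlat(proj, xy[, 1L], xy[, 2L]),
                                source_crs = sprintf("equirect(%.4f,%.4f)", lon0, lat0)),
       projection = proj)
}

#' Write a park boundary as GeoJSON (planar km convention)
#' @param boundary a [park_boundary()].
#' @param path output file.
#' @export
write_boundary_geojson <- function(boundary, path) {
  ring <- rbind(boundary$xy, boundary$xy[1L, , drop = FALSE])
  obj <- list(type = "Feature",
              properties = list(units = "km", source_crs = boundary$source_crs),
              geometry = list(type = "Polygon",
                              coordinates = list(lapply(seq_len(nrow(ring)),
                                                        function(i) as.numeric(ring[i, ])))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read GPS search tracks from delimited text
#'
#' Expects a header `date,time,lon,lat` (projected via `projection`) or
#' `date,time,x_km,y_km` (already planar). One [track_log()] per distinct
#' date is returned; points keep file order within a day.
#'
#' @param path CSV file.
#' @param projection optional [local_projection()] for lon/lat input.
#' @return List of [track_log()].
#' @export
read_tracks <- function(path, projection = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  xy <- .resolve_xy(d, projection)
  days <- as.Date(d$date)
  lapply(split(seq_len(nrow(d)), days), function(ix) {
    track_log(days[ix[1L]], xy[ix, , drop = FALSE])
  })
}

#' Write tracks as delimited text (planar km convention)
#' @param tracks list of [track_log()].
#' @param path output CSV.
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- lapply(tracks, function(t) {
    npt <- nrow(t$xy)
    tm <- if (is.null(t$time)) seq(0, by = 10, length.out = npt) else t$time
    data.frame(date = as.character(t$day), time = tm,
               x_km = t$xy[, 1L], y_km = t$xy[, 2L])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read sighting records from delimited text
#'
#' Expects header `date,lon,lat,individual_id,sex,age_class,id_quality`
#' (or `x_km,y_km` instead of `lon,lat` for planar input).
#'
#' @param path CSV file.
#' @param projection optional [local_projection()] for lon/lat input.
#' @return Data frame with `day`, `x_km`, `y_km`, `individual_id`, `sex`,
#'   `age_class`, `id_quality`.
#' @export
read_sightings <- function(path, projection = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  xy <- .resolve_xy(d, projection)
  data.frame(day = as.Date(d$date), x_km = xy[, 1L], y_km = xy[, 2L],
             individual_id = as.character(d$individual_id),
             sex = as.character(d$sex),
             age_class = as.character(d$age_class),
             id_quality = as.character(d$id_quality),
             stringsAsFactors = FALSE)
}

#' Write sighting records as delimited text (planar km convention)
#' @param records sightings data frame (as from [read_sightings()]).
#' @param path output CSV.
#' @export
write_sightings_csv <- function(records, path) {
  out <- data.frame(date = as.character(as.Date(records$day)),
                    x_km = records$x_km, y_km = records$y_km,
                    individual_id = records$individual_id,
                    sex = records$sex,
                    age_class = records$age_class,
                    id_quality = records$id_quality)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

.resolve_xy <- function(d, projection) {
  if (all(c("x_km", "y_km") %in% names(d))) {
    cbind(d$x_km, d$y_km)
  } else if (all(c("lon", "lat") %in% names(d))) {
    if (is.null(projection))
      stop("lon/lat input needs a projection (see read_boundary_geojson)")
    project_lonlat(projection, d$lon, d$lat)
  } else stop("need columns x_km,y_km or lon,lat")
}

#' Serialise an effort matrix in long format
#' @param effort an [compute_effort()] result.
#' @param path output CSV (`trap_id`, `occasion_date`, `km`); zero cells omitted.
#' @export
write_effort_long <- function(effort, path) {
  idx <- which(effort$values > 0, arr.ind = TRUE)
  out <- data.frame(trap_id = effort$trap_ids[idx[, 1L]],
                    occasion_date = as.character(effort$occasion_dates[idx[, 2L]]),
                    km = effort$values[idx])
  out <- out[order(out$trap_id, out$occasion_date), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a capture history in long format
#' @param ch a [build_capture_history()] result.
#' @param path output CSV (`individual_id`, `sex`, `trap_id`, `occasion_date`).
#' @export
write_captures_long <- function(ch, path) {
  idx <- which(ch$y == 1L, arr.ind = TRUE)
  out <- data.frame(individual_id = ch$individual_ids[idx[, 1L]],
                    sex = ch$sexes[idx[, 1L]],
                    trap_id = ch$trap_ids[idx[, 2L]],
                    occasion_date = as.character(ch$occasion_dates[idx[, 3L]]))
  out <- out[order(out$individual_id, out$occasion_date, out$trap_id), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialise the trap table
#' @param effort an effort matrix.
#' @param path output CSV (`trap_id`, `x_km`, `y_km`).
#' @export
write_traps_csv <- function(effort, path) {
  utils::write.csv(data.frame(trap_id = effort$trap_ids,
                              x_km = effort$trap_xy[, 1L],
                              y_km = effort$trap_xy[, 2L]),
                   path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
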