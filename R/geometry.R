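#' Park boundary polygon
#'
#' Construct the boundary of the (fenced) study area as a simple closed
#' polygon in a planar metric frame with coordinates in kilometres. The
#' boundary defines the SECR state space: only grid pixels whose centroid
#' falls inside it can host an activity centre.
#'
#' @param coords two-column matrix or data frame of vertex coordinates
#'   (x_km, y_km), in order along the ring; a repeated closing vertex is
#'   tolerated and dropped.
#' @param source_crs free-text label recording the coordinate frame the
#'   vertices are expressed in (e.g. `"local-km"` or an EPSG tag).
#' @return An object of class `park_boundary` with elements `xy` (the open
#'   ring, counter-clockwise), `source_crs` and `area_km2`.
#' @examples
#' b <- park_boundary(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' b$area_km2
#' @export
park_boundary <- function(coords, source_crs = "local-km") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("boundary coordinates must have two columns")
  storage.mode(coords) <- "double"
  if (anyNA(coords)) stop("boundary coordinates contain NA")
  n <- nrow(coords)
  if (n > 1L && all(coords[1L, ] == coords[n, ])) coords <- coords[-n, , drop = FALSE]
  if (nrow(coords) < 3L) stop("boundary polygon needs at least 3 distinct vertices")
  a <- polygon_area(coords)
  if (abs(a) < 1e-9) stop("degenerate boundary polygon: area is zero")
  if (a < 0) { # store counter-clockwise
    coords <- coords[rev(seq_len(nrow(coords))), , drop = FALSE]
    a <- -a
  }
  structure(list(xy = coords, source_crs = source_crs, area_km2 = a),
            class = "park_boundary")
}

#' @export
print.park_boundary <- function(x, ...) {
  cat(sprintf("park_boundary: %d vertices, area %.2f km^2 [%s]\n",
              nrow(x$xy), x$area_km2, x$source_crs))
  invisible(x)
}

#' Signed polygon area (shoelace formula)
#'
#' @param xy two-column matrix of ring vertices (open ring, no repeated
#'   closing vertex required).
#' @return Signed area; positive for counter-clockwise rings.
#' @export
polygon_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(x * y2 - x2 * y) / 2
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' Vectorised over points; points lying exactly on an edge follow the
#' even-odd rule of the cast and may land on either side at machine
#' precision, which is immaterial for centroid retention on a continuous
#' boundary.
#'
#' @param px,py point coordinates.
#' @param xy polygon ring (open, two columns).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, xy) {
  nv <- nrow(xy)
  inside <- logical(length(px))
  x1 <- xy[, 1L]; y1 <- xy[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  for (e in seq_len(nv)) {
    crosses <- (y1[e] > py) != (y2[e] > py)
    if (any(crosses)) {
      idx <- which(crosses)
      xint <- x1[e] + (py[idx] - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
      flip <- idx[px[idx] < xint]
      inside[flip] <- !inside[flip]
    }
  }
  inside
}

#' Local planar projection for a small study area
#'
#' Longitude/latitude are mapped to kilometres on a local equirectangular
#' frame centred on a reference point. Over the extent of a single fenced
#' reserve (tens of km) the distortion relative to a transverse-Mercator
#' zone is negligible compared with the 0.5 km^2 pixel size.
#'
#' @param lon0,lat0 reference point (degrees); typically the boundary centroid.
#' @return Object of class `local_projection`.
#' @export
local_projection <- function(lon0, lat0) {
  structure(list(lon0 = lon0, lat0 = lat0,
                 kx = 111.320 * cos(lat0 * pi / 180), ky = 110.574),
            class = "local_projection")
}

#' Project longitude/latitude to local km coordinates
#'
#' @param proj a [local_projection()].
#' @param lon,lat coordinates in degrees.
#' @return Two-column matrix (x_km, y_km).
#' @export
project_lonlat <- function(proj, lon, lat) {
  cbind(x_km = (lon - proj$lon0) * proj$kx, y_km = (lat - proj$lat0) * proj$ky)
}

#' Discretise the park into candidate activity-centre pixels
#'
#' Lays a square grid of pixels of area `pixel_area_km2` over the boundary's
#' bounding box, anchored at its lower-left corner, and retains a pixel iff
#' its centroid falls inside the polygon. The retained pixels are both the
#' candidate activity centres (state space) and the potential trap cells.
#'
#' @param boundary a [park_boundary()].
#' @param pixel_area_km2 pixel area in km^2 (default 0.5).
#' @return Object of class `state_space`: `pixels` (data frame with
#'   `pixel_id`, `x_km`, `y_km`, `row`, `col`), `pixel_area_km2`,
#'   `total_area_km2` (= pixel count x pixel area), grid geometry (`origin`,
#'   `delta`, `nx`, `ny`, `id_grid`) and the boundary.
#' @examples
#' sp <- build_state_space(park_boundary(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))))
#' nrow(sp$pixels); sp$total_area_km2
#' @export
build_state_space <- function(boundary, pixel_area_km2 = 0.5) {
  stopifnot(inherits(boundary, "park_boundary"))
  if (!is.numeric(pixel_area_km2) || length(pixel_area_km2) != 1L || pixel_area_km2 <= 0)
    stop("pixel_area_km2 must be a positive scalar")
  delta <- sqrt(pixel_area_km2)
  rx <- range(boundary$xy[, 1L]); ry <- range(boundary$xy[, 2L])
  ox <- rx[1L]; oy <- ry[1L]
  nx <- max(1L, as.integer(ceiling((rx[2L] - ox) / delta - 1e-9)))
  ny <- max(1L, as.integer(ceiling((ry[2L] - oy) / delta - 1e-9)))
  cx <- ox + (seq_len(nx) - 0.5) * delta
  cy <- oy + (seq_len(ny) - 0.5) * delta
  grid <- expand.grid(col = seq_len(nx), row = seq_len(ny),
                      KEEP.OUT.ATTRS = FALSE)
  px <- cx[grid$col]; py <- cy[grid$row]
  keep <- point_in_polygon(px, py, boundary$xy)
  if (!any(keep)) stop("no pixel centroid falls inside the boundary; check units")
  pixels <- data.frame(pixel_id = seq_len(sum(keep)),
                       x_km = px[keep], y_km = py[keep],
                       row = grid$row[keep], col = grid$col[keep])
  id_grid <- matrix(NA_integer_, nrow = ny, ncol = nx)
  id_grid[cbind(pixels$row, pixels$col)] <- pixels$pixel_id
  structure(list(pixels = pixels,
                 pixel_area_km2 = pixel_area_km2,
                 total_area_km2 = nrow(pixels) * pixel_area_km2,
                 delta = delta, origin = c(ox, oy), nx = nx, ny = ny,
                 id_grid = id_grid, boundary = boundary),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("state_space: %d pixels of %.2f km^2 (total %.1f km^2), grid %d x %d\n",
              nrow(x$pixels), x$pixel_area_km2, x$total_area_km2, x$ny, x$nx))
  invisible(x)
}

#' Map planar points to state-space pixel ids
#'
#' @param space a [build_state_space()] result.
#' @param x,y coordinates in km.
#' @return Integer pixel ids; `NA` for points outside the retained grid.
#' @export
locate_pixel <- function(space, x, y) {
  col <- floor((x - space$origin[1L]) / space$delta) + 1L
  row <- floor((y - space$origin[2L]) / space$delta) + 1L
  ok <- col >= 1L & col <= space$nx & row >= 1L & row <= space$ny
  out <- rep(NA_integer_, length(x))
  out[ok] <- space$id_grid[cbind(row[ok], col[ok])]
  out
}

#' Squared distances between state-space pixels and trap pixels
#'
#' @param space state space.
#' @param trap_ids pixel ids acting as traps.
#' @return `G x J` matrix of squared distances (km^2).
#' @keywords internal
pixel_dist2 <- function(space, trap_ids) {
  gx <- space$pixels$x_km; gy <- space$pixels$y_km
  tx <- space$pixels$x_km[trap_ids]; ty <- space$pixels$y_km[trap_ids]
  outer(gx, tx, "-")^2 + outer(gy, ty, "-")^2
}
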