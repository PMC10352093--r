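#' A single day's search track
#'
#' @param day `Date` (one calendar day = one sampling occasion).
#' @param xy two-column matrix of ordered point coordinates in km.
#' @param time optional vector of timestamps (seconds or POSIXct), strictly
#'   increasing; purely descriptive, effort uses geometry only.
#' @return Object of class `track_log`.
#' @export
track_log <- function(day, xy, time = NULL) {
  day <- as.Date(day)
  if (length(day) != 1L || is.na(day)) stop("track_log needs a single valid day")
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || nrow(xy) < 1L) stop("track needs >= 1 point with (x, y)")
  storage.mode(xy) <- "double"
  if (!is.null(time)) {
    if (length(time) != nrow(xy)) stop("time and points lengths differ")
    if (nrow(xy) > 1L && any(diff(as.numeric(time)) <= 0))
      stop("timestamps must be strictly increasing within a day")
  }
  structure(list(day = day, xy = xy, time = time), class = "track_log")
}

#' Total polyline length of a track (km)
#' @param track a [track_log()].
#' @return Length in km.
#' @export
track_length <- function(track) {
  xy <- track$xy
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(diff(xy[, 1L])^2 + diff(xy[, 2L])^2))
}

# Split one segment at grid-line crossings; returns in-space length per pixel
# as a two-row accumulation into `acc` (G x K matrix), done by the caller.
# Returns list(ids, len) of pixel ids (may include NA for outside) and the
# sub-segment lengths.
.segment_pixels <- function(space, x1, y1, x2, y2) {
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (len == 0) return(NULL)
  tcut <- numeric(0)
  if (x2 != x1) {
    i1 <- (x1 - space$origin[1L]) / space$delta
    i2 <- (x2 - space$origin[1L]) / space$delta
    lo <- ceiling(min(i1, i2) + 1e-12); hi <- floor(max(i1, i2) - 1e-12)
    if (hi >= lo) tcut <- c(tcut, ((lo:hi) - i1) / (i2 - i1))
  }
  if (y2 != y1) {
    j1 <- (y1 - space$origin[2L]) / space$delta
    j2 <- (y2 - space$origin[2L]) / space$delta
    lo <- ceiling(min(j1, j2) + 1e-12); hi <- floor(max(j1, j2) - 1e-12)
    if (hi >= lo) tcut <- c(tcut, ((lo:hi) - j1) / (j2 - j1))
  }
  ts <- c(0, sort(unique(tcut[tcut > 1e-12 & tcut < 1 - 1e-12])), 1)
  tm <- (ts[-1L] + ts[-length(ts)]) / 2
  ids <- locate_pixel(space, x1 + tm * (x2 - x1), y1 + tm * (y2 - y1))
  list(ids = ids, len = diff(ts) * len)
}

#' Per-pixel per-occasion search effort from GPS tracks
#'
#' Consecutive track points form straight segments; each segment is split
#' exactly at grid-line crossings and its length apportioned to the pixel
#' containing each piece. Pieces falling outside the state space (outside
#' the fenced boundary, as discretised by retained pixels) are clipped off
#' and reported as `dropped_km`. Occasions are the ordered distinct track
#' days; traps are the pixels with nonzero effort on at least one occasion.
#'
#' @param tracks list of [track_log()] objects (several tracks may share a
#'   day; their effort accumulates).
#' @param space state space from [build_state_space()].
#' @param window optional `Date` vector of length 2; track days outside it
#'   are excluded with a warning.
#' @return Object of class `effort_matrix`: `values` (J x K km), `trap_ids`,
#'   `trap_xy`, `occasion_dates`, `total_km` (= sum(values)), `dropped_km`.
#' @export
compute_effort <- function(tracks, space, window = NULL) {
  stopifnot(inherits(space, "state_space"))
  if (inherits(tracks, "track_log")) tracks <- list(tracks)
  days <- as.Date(vapply(tracks, function(t) as.character(t$day), ""))
  if (!is.null(window)) {
    window <- as.Date(window)
    bad <- days < window[1L] | days > window[2L]
    if (any(bad)) {
      warning(sprintf("%d track day(s) outside the study window excluded", sum(bad)))
      tracks <- tracks[!bad]; days <- days[!bad]
    }
  }
  if (!length(tracks)) stop("no tracks to compute effort from")
  occ <- sort(unique(days))
  K <- length(occ)
  G <- nrow(space$pixels)
  eff <- matrix(0, nrow = G, ncol = K)
  dropped <- 0
  for (ti in seq_along(tracks)) {
    k <- match(days[ti], occ)
    xy <- tracks[[ti]]$xy
    if (nrow(xy) < 2L) next
    for (si in seq_len(nrow(xy) - 1L)) {
      sp <- .segment_pixels(space, xy[si, 1L], xy[si, 2L], xy[si + 1L, 1L], xy[si + 1L, 2L])
      if (is.null(sp)) next
      out <- is.na(sp$ids)
      if (any(out)) dropped <- dropped + sum(sp$len[out])
      if (any(!out)) {
        ids <- sp$ids[!out]; ln <- sp$len[!out]
        for (u in seq_along(ids)) eff[ids[u], k] <- eff[ids[u], k] + ln[u]
      }
    }
  }
  traps <- which(rowSums(eff) > 0)
  if (!length(traps)) stop("tracks produced no in-boundary effort")
  values <- eff[traps, , drop = FALSE]
  rownames(values) <- traps
  colnames(values) <- as.character(occ)
  structure(list(values = values,
                 trap_ids = traps,
                 trap_xy = as.matrix(space$pixels[traps, c("x_km", "y_km")]),
                 occasion_dates = occ,
                 total_km = sum(values),
                 dropped_km = dropped),
            class = "effort_matrix")
}

#' @export
print.effort_matrix <- function(x, ...) {
  cat(sprintf("effort_matrix: %d traps x %d occasions, %.1f km searched (%.2f km clipped off)\n",
              nrow(x$values), ncol(x$values), x$total_km, x$dropped_km))
  invisible(x)
}

#' Apply the field record filters to sighting records
#'
#' Detections without an unambiguous photographic identification are dropped
#' first, then detections of individuals under one year of age (cubs), whose
#' high mortality would violate demographic closure.
#'
#' @param records data frame of sightings with (at least) columns
#'   `id_quality` (`"adequate"`/`"inadequate"`) and `age_class`
#'   (`"cub_lt1"`/`"older"`).
#' @return List with `kept` (the filtered data frame, original order) and
#'   `report`: counts `total`, `dropped_unidentified`, `dropped_underage`,
#'   `kept`.
#' @examples
#' r <- data.frame(id_quality = c("adequate", "inadequate"),
#'                 age_class = c("older", "older"))
#' filter_sightings(r)$report
#' @export
filter_sightings <- function(records) {
  records <- as.data.frame(records)
  total <- nrow(records)
  if (total == 0L) {
    return(list(kept = records,
                report = list(total = 0L, dropped_unidentified = 0L,
                              dropped_underage = 0L, kept = 0L)))
  }
  idq <- as.character(records$id_quality)
  keep1 <- idq != "inadequate"
  d1 <- sum(!keep1)
  r1 <- records[keep1, , drop = FALSE]
  age <- as.character(r1$age_class)
  keep2 <- age != "cub_lt1"
  d2 <- sum(!keep2)
  kept <- r1[keep2, , drop = FALSE]
  list(kept = kept,
       report = list(total = total, dropped_unidentified = d1,
                     dropped_underage = d2, kept = nrow(kept)))
}

# Internal constructor shared by ingest and the simulator.
.new_capture_history <- function(y, individual_ids, sexes, effort) {
  stopifnot(length(dim(y)) == 3L,
            dim(y)[2L] == nrow(effort$values),
            dim(y)[3L] == ncol(effort$values))
  structure(list(y = y,
                 individual_ids = individual_ids,
                 sexes = sexes,
                 trap_ids = effort$trap_ids,
                 occasion_dates = effort$occasion_dates,
                 effort = effort),
            class = "capture_history")
}

#' Build the binary SECR capture history
#'
#' Collapses filtered sightings into the standard SCR array `y[i, j, k]`
#' (individual x trap-pixel x occasion, binary): repeated sightings of the
#' same individual in the same pixel on the same day count once. Sighting
#' pixels with no driven effort that day (opportunistic tip-offs) are added
#' to the trap set and given a small effort floor so the effort-dependent
#' detection model stays evaluable there.
#'
#' @param kept filtered sightings: data frame with `day`, `x_km`, `y_km`,
#'   `individual_id`, `sex` (`"female"`/`"male"`).
#' @param effort an [compute_effort()] result.
#' @param space the state space.
#' @param effort_floor_km effort assigned to a zero-effort pixel-day cell
#'   that holds a detection (default 0.1 km).
#' @param snap_km sightings outside the pixel grid are snapped to the
#'   nearest state-space pixel if within this distance (default 1 km),
#'   otherwise an error is raised.
#' @return Object of class `capture_history` with the binary array `y`,
#'   `individual_ids`, `sexes`, `trap_ids`, `occasion_dates` and the aligned
#'   (possibly extended and floored) `effort`.
#' @export
build_capture_history <- function(kept, effort, space, effort_floor_km = 0.1,
                                  snap_km = 1) {
  stopifnot(inherits(effort, "effort_matrix"), inherits(space, "state_space"))
  kept <- as.data.frame(kept)
  if (nrow(kept) == 0L) stop("no sighting records to build a capture history from")
  day <- as.Date(kept$day)
  k <- match(day, effort$occasion_dates)
  if (anyNA(k)) {
    bad <- which(is.na(k))
    stop(sprintf("sighting(s) on dates with no sampling occasion: rows %s (dates %s)",
                 paste(utils::head(bad, 5L), collapse = ", "),
                 paste(unique(day[bad]), collapse = ", ")))
  }
  ids <- as.character(kept$individual_id)
  if (any(ids %in% c("", "UNKNOWN", NA)))
    stop("all kept sightings must carry a known individual_id")
  sex <- as.character(kept$sex)
  if (!all(sex %in% c("female", "male")))
    stop("all kept sightings must have sex 'female' or 'male'")
  pix <- locate_pixel(space, kept$x_km, kept$y_km)
  if (anyNA(pix)) {
    miss <- which(is.na(pix))
    d2 <- outer(kept$x_km[miss], space$pixels$x_km, "-")^2 +
      outer(kept$y_km[miss], space$pixels$y_km, "-")^2
    nearest <- max.col(-d2)
    dmin <- sqrt(d2[cbind(seq_along(miss), nearest)])
    if (any(dmin > snap_km))
      stop(sprintf("%d sighting(s) more than %.2f km outside the state space",
                   sum(dmin > snap_km), snap_km))
    pix[miss] <- nearest
  }
  # individuals in order of first appearance (deterministic)
  uid <- unique(ids)
  i <- match(ids, uid)
  sex_by_id <- tapply(sex, i, function(s) unique(s), simplify = FALSE)
  conflict <- vapply(sex_by_id, length, 1L) > 1L
  if (any(conflict))
    stop(sprintf("conflicting sex records for individual(s): %s",
                 paste(uid[as.integer(names(sex_by_id))[conflict]], collapse = ", ")))
  sexes <- vapply(sex_by_id[as.character(seq_along(uid))], `[[`, "", 1L)

  # extend trap set with sighting pixels not yet searched
  extra <- setdiff(unique(pix), effort$trap_ids)
  if (length(extra)) {
    add <- matrix(0, nrow = length(extra), ncol = ncol(effort$values))
    rownames(add) <- extra
    effort$values <- rbind(effort$values, add)
    effort$trap_ids <- c(effort$trap_ids, extra)
    effort$trap_xy <- rbind(effort$trap_xy,
                            as.matrix(space$pixels[extra, c("x_km", "y_km")]))
  }
  j <- match(pix, effort$trap_ids)
  # effort floor on detection cells with zero driven effort
  zero <- effort$values[cbind(j, k)] == 0
  if (any(zero)) {
    cells <- unique(cbind(j[zero], k[zero]))
    effort$values[cells] <- effort_floor_km
  }
  n <- length(uid)
  y <- array(0L, dim = c(n, nrow(effort$values), ncol(effort$values)))
  y[cbind(i, j, k)] <- 1L
  ch <- .new_capture_history(y, uid, sexes, effort)
  ch
}

#' @export
print.capture_history <- function(x, ...) {
  s <- summarize_captures(x)
  cat(sprintf("capture_history: %d individuals (%d F / %d M), %d traps, %d occasions\n",
              s$n_individuals, s$n_females, s$n_males,
              length(x$trap_ids), length(x$occasion_dates)))
  cat(sprintf("  %d detections, %d recaptures, %.1f average spatial recaptures\n",
              s$detections, s$recaptures, s$avg_spatial_recaptures))
  invisible(x)
}

#' Summary counts of a capture history
#'
#' @param ch a [build_capture_history()] result.
#' @return List: `detections` (total 1-cells), `detections_female`,
#'   `detections_male`, `n_individuals`, `n_females`, `n_males`,
#'   `recaptures` (detections - individuals), `recaptures_female`,
#'   `recaptures_male`, and `avg_spatial_recaptures` (mean over individuals
#'   of the number of distinct trap-pixels where each was detected).
#' @export
summarize_captures <- function(ch) {
  stopifnot(inherits(ch, "capture_history"))
  per_ind <- apply(ch$y, 1L, sum)
  male <- ch$sexes == "male"
  traps_per_ind <- apply(ch$y, 1L, function(m) sum(rowSums(m) > 0))
  list(detections = sum(per_ind),
       detections_female = sum(per_ind[!male]),
       detections_male = sum(per_ind[male]),
       n_individuals = length(per_ind),
       n_females = sum(!male),
       n_males = sum(male),
       recaptures = sum(per_ind) - length(per_ind),
       recaptures_female = sum(per_ind[!male]) - sum(!male),
       recaptures_male = sum(per_ind[male]) - sum(male),
       avg_spatial_recaptures = mean(traps_per_ind))
}
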