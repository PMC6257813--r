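#' Head pose
#'
#' A time-stamped head position and orientation, the unit of all logging and
#' analysis. Coordinates are right-handed with x/y horizontal and z up; yaw
#' is measured from the +x axis, positive clockwise seen from above, so that
#' a positive relative azimuth is to the user's right.
#'
#' @param t time in seconds (non-negative).
#' @param position numeric 3-vector, meters.
#' @param yaw,pitch,roll orientation in degrees; yaw is wrapped to
#'   (-180, 180].
#' @return an object of class `nav_pose`.
#' @export
pose <- function(t = 0, position = c(0, 0, 0), yaw = 0, pitch = 0, roll = 0) {
  stopifnot(is.numeric(t), length(t) == 1, t >= 0,
            is.numeric(position), length(position) == 3)
  structure(list(t = t, position = as.numeric(position),
                 yaw = wrap_angle(yaw), pitch = pitch, roll = roll),
            class = "nav_pose")
}

#' @export
print.nav_pose <- function(x, ...) {
  cat(sprintf("<pose t=%.2fs xyz=(%.2f, %.2f, %.2f) yaw=%.1f deg>\n",
              x$t, x$position[1], x$position[2], x$position[3], x$yaw))
  invisible(x)
}

#' Scene object
#'
#' A labelled object with a position and a circular footprint. The footprint
#' radius doubles as the trigger/collision zone used by the tasks.
#'
#' @param id unique token.
#' @param label display text spoken by the object's voice (non-empty).
#' @param position numeric 3-vector, meters.
#' @param radius footprint radius in meters, > 0.
#' @return object of class `nav_object`.
#' @export
scene_object <- function(id, label = id, position, radius = 0.5) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stop("object 'id' must be a non-empty string")
  if (!is.character(label) || length(label) != 1 || !nzchar(label))
    stop("object 'label' must be non-empty")
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0)
    stop("object 'radius' must be > 0")
  if (!is.numeric(position) || length(position) != 3)
    stop("object 'position' must be a numeric 3-vector")
  structure(list(id = id, label = label, position = as.numeric(position),
                 radius = radius),
            class = "nav_object")
}

#' Occupancy grid
#'
#' A 2D boolean occupancy grid standing in for a scanned 3D mesh. Cell
#' (r, c) covers `origin + ((c-1..c), (r-1..r)) * cell_size`; row 1 is the
#' southern edge (minimum y).
#'
#' @param rows,cols grid dimensions.
#' @param cell_size cell edge length in meters (> 0), default 0.1.
#' @param origin xy of the grid's lower-left corner.
#' @param blocked logical `rows x cols` matrix (default all free) or a
#'   two-column matrix of blocked (row, col) indices.
#' @return object of class `nav_grid`.
#' @export
occupancy_grid <- function(rows, cols, cell_size = 0.1, origin = c(0, 0),
                           blocked = NULL) {
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("grid 'cell_size' must be > 0")
  stopifnot(rows >= 1, cols >= 1, length(origin) == 2)
  b <- matrix(FALSE, rows, cols)
  if (!is.null(blocked)) {
    if (is.logical(blocked)) {
      stopifnot(identical(dim(blocked), dim(b)))
      b <- blocked
    } else {
      blocked <- matrix(as.integer(blocked), ncol = 2)
      b[blocked] <- TRUE
    }
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 cell_size = cell_size, origin = as.numeric(origin),
                 blocked = b),
            class = "nav_grid")
}

grid_bounds <- function(grid) {
  # (xmin, xmax, ymin, ymax)
  c(grid$origin[1], grid$origin[1] + grid$cols * grid$cell_size,
    grid$origin[2], grid$origin[2] + grid$rows * grid$cell_size)
}

in_grid_bounds <- function(grid, position) {
  b <- grid_bounds(grid)
  position[1] >= b[1] && position[1] <= b[2] &&
    position[2] >= b[3] && position[2] <= b[4]
}

#' Which grid cell contains an xy point?
#' @noRd
grid_cell_of <- function(grid, position) {
  c(r = min(grid$rows, max(1, 1 + floor((position[2] - grid$origin[2]) / grid$cell_size))),
    c = min(grid$cols, max(1, 1 + floor((position[1] - grid$origin[1]) / grid$cell_size))))
}

grid_cell_center <- function(grid, r, c) {
  c(grid$origin[1] + (c - 0.5) * grid$cell_size,
    grid$origin[2] + (r - 0.5) * grid$cell_size)
}

#' Scene
#'
#' A world model: labelled objects, an optional obstacle occupancy grid and
#' a start zone. Object positions must lie inside the grid bounds when a
#' grid is present.
#'
#' @param objects list of [scene_object()]s with unique ids.
#' @param grid optional [occupancy_grid()].
#' @param start_zone list with `center` (3-vector) and `radius` (meters).
#' @return object of class `nav_scene`.
#' @export
scene <- function(objects = list(), grid = NULL,
                  start_zone = list(center = c(0, 0, 0), radius = 0.5)) {
  ids <- vapply(objects, function(o) o$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate object ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "nav_grid"))
    for (o in objects)
      if (!in_grid_bounds(grid, o$position))
        stop("object '", o$id, "' lies outside the grid bounds")
  }
  stopifnot(length(start_zone$center) == 3, start_zone$radius > 0)
  structure(list(objects = objects, grid = grid, start_zone = start_zone),
            class = "nav_scene")
}

#' @export
print.nav_scene <- function(x, ...) {
  cat(sprintf("<scene: %d objects%s>\n", length(x$objects),
              if (is.null(x$grid)) "" else
                sprintf(", %dx%d grid (%.2f m cells)",
                        x$grid$rows, x$grid$cols, x$grid$cell_size)))
  invisible(x)
}

scene_get_object <- function(scene, id) {
  for (o in scene$objects) if (o$id == id) return(o)
  stop("unknown object id: '", id, "'")
}

#' Guide path
#'
#' An ordered polyline of waypoints with per-waypoint turn and stairs
#' annotations. The first and last waypoint carry no turn; intermediate
#' waypoints may announce "left"/"right" turns and approaching stairs.
#'
#' @param waypoints numeric matrix, one row per waypoint, columns x, y, z
#'   (a 2-column matrix is padded with z = 0). At least 2 rows; consecutive
#'   rows must be distinct.
#' @param turn character vector of "left"/"right"/"none" per waypoint.
#' @param stairs logical vector per waypoint.
#' @param arrival_radius arrival threshold at the final waypoint, meters
#'   (default 1.2, boundary inclusive).
#' @param segment_breaks,segment_labels optional partition of the path into
#'   named legs (breaks are waypoint indices of length
#'   `length(segment_labels) + 1`, starting at 1 and ending at the last
#'   waypoint); used by the analytics to report per-segment metrics.
#' @return object of class `nav_path`.
#' @export
guide_path <- function(waypoints, turn = NULL, stairs = NULL,
                       arrival_radius = 1.2,
                       segment_breaks = NULL, segment_labels = NULL) {
  waypoints <- as.matrix(waypoints)
  if (ncol(waypoints) == 2) waypoints <- cbind(waypoints, 0)
  stopifnot(ncol(waypoints) == 3)
  n <- nrow(waypoints)
  if (n < 2) stop("a guide path needs at least 2 waypoints")
  d <- sqrt(rowSums((waypoints[-1, , drop = FALSE] -
                       waypoints[-n, , drop = FALSE])^2))
  if (any(d == 0)) stop("consecutive waypoints must be distinct")
  if (is.null(turn)) turn <- rep("none", n)
  if (is.null(stairs)) stairs <- rep(FALSE, n)
  stopifnot(length(turn) == n, all(turn %in% c("left", "right", "none")),
            length(stairs) == n, arrival_radius > 0)
  if (!is.null(segment_breaks))
    stopifnot(segment_breaks[1] == 1, segment_breaks[length(segment_breaks)] == n,
              length(segment_breaks) == length(segment_labels) + 1)
  waypoints <- unname(waypoints)
  v <- waypoints[-1, , drop = FALSE] - waypoints[-n, , drop = FALSE]
  structure(list(waypoints = waypoints, turn = turn,
                 stairs = as.logical(stairs),
                 arrival_radius = arrival_radius,
                 cumlen = c(0, cumsum(d)),
                 seg_a = waypoints[-n, , drop = FALSE],  # precomputed for
                 seg_v = v, seg_len2 = rowSums(v^2),     # fast projection
                 segment_breaks = segment_breaks,
                 segment_labels = segment_labels),
            class = "nav_path")
}

#' @export
print.nav_path <- function(x, ...) {
  cat(sprintf("<guide path: %d waypoints, %.1f m>\n",
              nrow(x$waypoints), path_total_length(x)))
  invisible(x)
}

#' Total polyline length of a guide path, meters
#' @param path a [guide_path()].
#' @export
path_total_length <- function(path) {
  path$cumlen[length(path$cumlen)]
}

#' Relative azimuth of a point from a pose
#'
#' Horizontal-plane angle from the pose's facing direction to the point,
#' wrapped to (-180, 180]. Zero means dead ahead; positive is to the user's
#' right. Elevation is ignored throughout (all aiming analyses are
#' azimuth-only).
#'
#' @param pose a [pose()].
#' @param point numeric 3-vector (or 2-vector, z ignored anyway).
#' @return degrees in (-180, 180].
#' @export
relative_azimuth <- function(pose, point) {
  dx <- point[1] - pose$position[1]
  dy <- point[2] - pose$position[2]
  if (dx == 0 && dy == 0)
    stop("azimuth undefined: point is vertically above/below the head")
  # yaw positive-clockwise from +x  =>  absolute azimuth is -atan2(dy, dx)
  wrap_angle(rad2deg(-atan2(dy, dx)) - pose$yaw)
}

#' Absolute azimuth of the direction from one xy point to another
#'
#' Same convention as [relative_azimuth()]: 0 along +x, positive clockwise
#' seen from above.
#' @param from,to numeric vectors (first two components used).
#' @return degrees in (-180, 180].
#' @export
absolute_azimuth <- function(from, to) {
  dx <- to[1] - from[1]
  dy <- to[2] - from[2]
  if (dx == 0 && dy == 0) stop("azimuth undefined: coincident points")
  wrap_angle(rad2deg(-atan2(dy, dx)))
}

#' Is a point inside the spotlight cone?
#'
#' The spotlight cone is measured in azimuth only and its boundary is
#' inclusive: a point at exactly half the aperture still speaks (avoids
#' flicker at the boundary in discrete time).
#'
#' @param pose a [pose()].
#' @param point numeric 3-vector.
#' @param aperture_deg full cone aperture in degrees, in (0, 360);
#'   default 30.
#' @return logical.
#' @export
in_spotlight <- function(pose, point, aperture_deg = 30) {
  stopifnot(aperture_deg > 0, aperture_deg < 360)
  abs(relative_azimuth(pose, point)) <= aperture_deg / 2
}

#' Left-to-right scan order of a scene's objects
#'
#' Objects sorted by ascending relative azimuth (leftmost, i.e. most
#' negative, first); ties broken lexicographically by id so the order is
#' deterministic.
#'
#' @param scene a [scene()].
#' @param pose a [pose()].
#' @return the scene's object list, reordered (empty scene gives an empty
#'   list).
#' @export
scan_order <- function(scene, pose) {
  if (length(scene$objects) == 0) return(list())
  az <- vapply(scene$objects, function(o) relative_azimuth(pose, o$position),
               numeric(1))
  ids <- vapply(scene$objects, function(o) o$id, character(1))
  scene$objects[order(az, ids, method = "radix")]
}

#' Distance to the nearest obstacle
#'
#' Euclidean (xy-plane) distance from a position to the nearest boundary of
#' any blocked grid cell; 0 inside a blocked cell, `Inf` if the scene has no
#' grid or no blocked cells.
#'
#' @param scene a [scene()].
#' @param position numeric vector (first two components used); must lie
#'   inside the grid bounds when a grid is present.
#' @return distance in meters.
#' @seealso [nearest_obstacle()] for the closest obstacle point itself.
#' @export
distance_to_nearest_obstacle <- function(scene, position) {
  nearest_obstacle(scene, position)$distance
}

#' @rdname distance_to_nearest_obstacle
#' @return `nearest_obstacle()`: list with `distance` and `point` (xy of the
#'   closest point on the blocked cell, NULL if none).
#' @export
nearest_obstacle <- function(scene, position) {
  grid <- scene$grid
  if (is.null(grid) || !any(grid$blocked))
    return(list(distance = Inf, point = NULL))
  if (!in_grid_bounds(grid, position))
    stop("position is outside the grid bounds")
  idx <- which(grid$blocked, arr.ind = TRUE)
  cs <- grid$cell_size
  # rectangle of each blocked cell; clamp the query point into it
  xlo <- grid$origin[1] + (idx[, 2] - 1) * cs
  ylo <- grid$origin[2] + (idx[, 1] - 1) * cs
  px <- pmin(pmax(position[1], xlo), xlo + cs)
  py <- pmin(pmax(position[2], ylo), ylo + cs)
  d2 <- (px - position[1])^2 + (py - position[2])^2
  k <- which.min(d2)
  list(distance = sqrt(d2[k]), point = c(px[k], py[k]))
}
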