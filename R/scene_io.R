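#' Read and write scene/path configuration files
#'
#' Scenes and guide paths share one JSON schema with keys
#' `objects[]` (`{id, label, position, radius}`),
#' `grid{cell_size, rows, cols, origin, blocked[]}` (blocked as
#' `[row, col]` pairs, 1-based),
#' `start_zone{center, radius}` and
#' `waypoints[]` (`{xyz, turn, stairs}`), plus optional `arrival_radius`,
#' `segment_breaks` and `segment_labels`. `save_scene()` followed by
#' `load_scene()` is the identity on scene and path contents.
#'
#' @param file path to a JSON file (or, for `load_scene()`, an already
#'   parsed list).
#' @return `load_scene()`: list with components `scene` ([scene()]) and
#'   `path` ([guide_path()] or NULL). `save_scene()`: the file path,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' sc <- scene(list(scene_object("chair", position = c(2, 0, 0))))
#' save_scene(sc, file = f)
#' load_scene(f)$scene
#' @export
load_scene <- function(file) {
  cfg <- if (is.character(file)) {
    jsonlite::read_json(file, simplifyVector = FALSE)
  } else if (is.list(file)) file else stop("'file' must be a path or a list")

  num3 <- function(x, what) {
    x <- unlist(x)
    if (length(x) == 2) x <- c(x, 0)
    if (!is.numeric(x) || length(x) != 3 || anyNA(x))
      stop("field '", what, "' must be a numeric 3-vector")
    x
  }

  objects <- lapply(seq_along(cfg$objects), function(i) {
    o <- cfg$objects[[i]]
    if (is.null(o$id)) stop("field 'objects[", i, "].id' is missing")
    radius <- if (is.null(o$radius)) 0.5 else o$radius
    if (!is.numeric(radius) || radius <= 0)
      stop("field 'objects[", i, "].radius' must be > 0")
    scene_object(id = o$id,
                 label = if (is.null(o$label)) o$id else o$label,
                 position = num3(o$position, paste0("objects[", i, "].position")),
                 radius = radius)
  })

  grid <- NULL
  if (!is.null(cfg$grid)) {
    g <- cfg$grid
    for (k in c("cell_size", "rows", "cols"))
      if (is.null(g[[k]])) stop("field 'grid.", k, "' is missing")
    if (g$cell_size <= 0) stop("field 'grid.cell_size' must be > 0")
    blocked <- NULL
    if (length(g$blocked))
      blocked <- do.call(rbind, lapply(g$blocked, function(rc) unlist(rc)[1:2]))
    grid <- occupancy_grid(rows = g$rows, cols = g$cols,
                           cell_size = g$cell_size,
                           origin = if (is.null(g$origin)) c(0, 0) else unlist(g$origin),
                           blocked = blocked)
  }

  start_zone <- list(center = c(0, 0, 0), radius = 0.5)
  if (!is.null(cfg$start_zone)) {
    if (is.null(cfg$start_zone$center) || is.null(cfg$start_zone$radius))
      stop("field 'start_zone' needs 'center' and 'radius'")
    if (cfg$start_zone$radius <= 0)
      stop("field 'start_zone.radius' must be > 0")
    start_zone <- list(center = num3(cfg$start_zone$center, "start_zone.center"),
                       radius = cfg$start_zone$radius)
  }

  path <- NULL
  if (length(cfg$waypoints)) {
    wps <- t(vapply(seq_along(cfg$waypoints), function(i)
      num3(cfg$waypoints[[i]]$xyz, paste0("waypoints[", i, "].xyz")),
      numeric(3)))
    turn <- vapply(cfg$waypoints, function(w)
      if (is.null(w$turn)) "none" else w$turn, character(1))
    stairs <- vapply(cfg$waypoints, function(w)
      isTRUE(w$stairs), logical(1))
    path <- guide_path(
      wps, turn = turn, stairs = stairs,
      arrival_radius = if (is.null(cfg$arrival_radius)) 1.2 else cfg$arrival_radius,
      segment_breaks = if (length(cfg$segment_breaks)) unlist(cfg$segment_breaks) else NULL,
      segment_labels = if (length(cfg$segment_labels)) unlist(cfg$segment_labels) else NULL)
  }

  list(scene = scene(objects, grid = grid, start_zone = start_zone),
       path = path)
}

#' @rdname load_scene
#' @param scene a [scene()].
#' @param path optional [guide_path()] stored alongside the scene.
#' @export
save_scene <- function(scene, path = NULL, file) {
  cfg <- list(
    objects = lapply(scene$objects, function(o)
      list(id = o$id, label = o$label, position = o$position,
           radius = o$radius)),
    start_zone = scene$start_zone
  )
  if (!is.null(scene$grid)) {
    g <- scene$grid
    blk <- which(g$blocked, arr.ind = TRUE)
    cfg$grid <- list(cell_size = g$cell_size, rows = g$rows, cols = g$cols,
                     origin = g$origin,
                     blocked = lapply(seq_len(nrow(blk)), function(i)
                       as.integer(blk[i, ])))
  }
  if (!is.null(path)) {
    cfg$waypoints <- lapply(seq_len(nrow(path$waypoints)), function(i)
      list(xyz = path$waypoints[i, ], turn = path$turn[i],
           stairs = path$stairs[i]))
    cfg$arrival_radius <- path$arrival_radius
    if (!is.null(path$segment_breaks)) {
      cfg$segment_breaks <- path$segment_breaks
      cfg$segment_labels <- path$segment_labels
    }
  }
  jsonlite::write_json(cfg, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
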