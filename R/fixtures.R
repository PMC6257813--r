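#' Bundled scene and path fixtures
#'
#' Deterministic constructors for the benchmark geometries: the 10 x 10 m
#' virtual living room with 16 labelled objects, the four-direction
#' direct-navigation arena, the five-object memory scenes (both block
#' orders, with the -7.5..+7.5 degree sonar-beep reference sector), and the
#' nine-waypoint building guide path of exactly 36.4 m polyline length
#' (lobby, stairwell with two flights, hallway).
#'
#' @return `fixture_living_room()`, `fixture_arena()`,
#'   `fixture_memory_scene()`: list with `scene` (and NULL `path`);
#'   `fixture_building_path()`: a [guide_path()].
#' @export
fixture_living_room <- function() {
  spots <- list(
    sofa = c(1.0, 8.5), `coffee table` = c(2.5, 7.0), tv = c(1.0, 5.0),
    bookshelf = c(1.0, 2.0), piano = c(3.5, 1.0), `dining table` = c(6.5, 1.5),
    chair = c(7.0, 5.0), lamp = c(9.0, 8.8), plant = c(9.0, 1.0),
    fridge = c(9.2, 4.0), desk = c(8.5, 6.5), wardrobe = c(4.0, 9.0),
    `trash bin` = c(6.0, 9.0), rug = c(5.0, 3.2), stool = c(3.0, 4.0),
    key = c(6.5, 6.8))
  objs <- lapply(names(spots), function(nm)
    scene_object(id = nm, label = nm,
                 position = c(spots[[nm]], 0),
                 radius = if (nm == "key") 0.15 else 0.5))
  grid <- occupancy_grid(rows = 100, cols = 100, cell_size = 0.1,
                         origin = c(0, 0))
  list(scene = scene(objs, grid = grid,
                     start_zone = list(center = c(5, 5, 0), radius = 0.5)),
       path = NULL)
}

#' @rdname fixture_living_room
#' @export
fixture_arena <- function() {
  objs <- lapply(c(0, 90, 180, 270), function(az)
    scene_object(id = sprintf("chair_%d", az),
                 label = "chair",
                 position = point_at_azimuth(c(0, 0, 0), az, 2),
                 radius = 0.5))
  list(scene = scene(objs,
                     start_zone = list(center = c(0, 0, 0), radius = 0.5)),
       path = NULL)
}

#' @rdname fixture_living_room
#' @param block memory-task block (1 or 2), selecting the printed
#'   left-to-right label order.
#' @export
fixture_memory_scene <- function(block = 1) {
  tc <- task_config()$memory
  stopifnot(block %in% seq_along(tc$block_labels))
  list(scene = memory_scene(tc, block), path = NULL,
       reference_sector = tc$reference_sector)
}

#' @rdname fixture_living_room
#' @export
fixture_building_path <- function() {
  flight <- sqrt(3^2 + 1.5^2)             # one stair flight, 3 m plan 1.5 m rise
  fixed <- 6 + 4 + 2 * flight + 2 + 2 + 2
  hallway <- 36.4 - fixed                 # final corridor closes to 36.4 m
  w <- rbind(c(0, 0, 0),      # 1 lobby entrance
             c(6, 0, 0),      # 2 across the lobby, turn left
             c(6, 4, 0),      # 3 foot of the stairs, turn right
             c(9, 4, 1.5),    # 4 landing between flights
             c(12, 4, 3),     # 5 top of the stairs, turn left
             c(12, 6, 3),     # 6 corner, turn left
             c(10, 6, 3),     # 7 corner, turn right
             c(10, 8, 3),     # 8 into the corridor, turn right
             c(10 + hallway, 8, 3))  # 9 office door
  guide_path(w,
             turn = c("none", "left", "right", "none", "left", "left",
                      "right", "right", "none"),
             stairs = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
                        FALSE, FALSE),
             arrival_radius = 1.2,
             segment_breaks = c(1, 3, 5, 9),
             segment_labels = c("lobby", "stairwell", "hallway"))
}

#' Regenerate the bundled fixture files
#'
#' Writes the named fixture(s) as scene/path JSON configuration files.
#' Regeneration is deterministic and idempotent; the files bundled under
#' `inst/extdata` are exactly the output of this generator.
#'
#' @param name one of `"living-room"`, `"arena"`, `"memory-block1"`,
#'   `"memory-block2"`, `"building-path"`, or `"all"`.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
fixture_generator <- function(name = "all", dir = ".") {
  known <- c("living-room", "arena", "memory-block1", "memory-block2",
             "building-path")
  names_ <- if (identical(name, "all")) known else match.arg(name, known)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names_) {
    file <- file.path(dir, paste0(gsub("-", "_", nm), ".json"))
    switch(nm,
      "living-room" = {
        fx <- fixture_living_room()
        save_scene(fx$scene, file = file)
      },
      "arena" = {
        fx <- fixture_arena()
        save_scene(fx$scene, file = file)
      },
      "memory-block1" = save_scene(fixture_memory_scene(1)$scene, file = file),
      "memory-block2" = save_scene(fixture_memory_scene(2)$scene, file = file),
      "building-path" = {
        path <- fixture_building_path()
        save_scene(scene(), path = path, file = file)
      })
    written <- c(written, file)
  }
  invisible(written)
}
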