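#' Shape classes of the building kit
#'
#' Runs are built from three classes of block: `RAMP` and `CUBE` count as one
#' coding unit each, while `DOUBLE` stands for any larger block that two cubes
#' could replace and therefore counts as two units.
#'
#' @export
shape_classes <- function() c("RAMP", "CUBE", "DOUBLE")

#' Default block colour palette
#' @export
default_palette <- function() c("red", "yellow", "blue", "green")

#' Construct a marble run
#'
#' A marble run is an ordered sequence of blocks laid left to right along an
#' adhesive strip. Each block carries a shape class and a colour.
#'
#' @param shape_class character vector of shape classes (see [shape_classes()]).
#' @param color character vector of block colours, recycled against
#'   `shape_class` if of length one.
#' @param builder identifier of the child who built the run, or
#'   `"EXPERIMENTER"` for the initial model run.
#' @param palette allowed colours; defaults to [default_palette()].
#' @return An object of class `marble_run`: a data frame with columns
#'   `shape_class` and `color`, one row per block, and a `builder` attribute.
#' @examples
#' marble_run(c("RAMP", "CUBE"), c("red", "blue"))
#' @export
marble_run <- function(shape_class, color, builder = "EXPERIMENTER",
                       palette = default_palette()) {
  shape_class <- as.character(shape_class)
  color <- as.character(color)
  if (length(color) == 1L) color <- rep(color, length(shape_class))
  stopifnot(length(shape_class) == length(color))
  bad <- setdiff(unique(shape_class), shape_classes())
  if (length(bad)) stop("unknown shape class: ", paste(bad, collapse = ", "))
  badc <- setdiff(unique(color), palette)
  if (length(badc)) stop("colour outside palette: ", paste(badc, collapse = ", "))
  run <- data.frame(shape_class = shape_class, color = color,
                    stringsAsFactors = FALSE)
  attr(run, "builder") <- builder
  class(run) <- c("marble_run", "data.frame")
  run
}

#' @export
print.marble_run <- function(x, ...) {
  cat(sprintf("<marble_run: %d blocks, builder %s>\n",
              nrow(x), attr(x, "builder")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Number of bricks in a run
#' @param run a [marble_run()].
#' @export
n_bricks <- function(run) nrow(run)

#' The experimenter's initial marble run
#'
#' The eight-block model run shown to the first child of every group. The
#' composition is configurable; the default mixes the three shape classes and
#' all four palette colours.
#'
#' @param shape_class,color block sequences; must have length 8.
#' @return A `marble_run` of 8 blocks with builder `"EXPERIMENTER"`.
#' @export
initial_run <- function(shape_class = c("RAMP", "CUBE", "DOUBLE", "CUBE",
                                        "RAMP", "DOUBLE", "CUBE", "CUBE"),
                        color = c("red", "yellow", "blue", "green",
                                  "yellow", "red", "blue", "green")) {
  if (length(shape_class) != 8L) {
    stop("the initial run must have exactly 8 blocks")
  }
  marble_run(shape_class, color, builder = "EXPERIMENTER")
}

#' Decompose a marble run into coding units
#'
#' Ramps and cubes contribute one unit; `DOUBLE` blocks contribute two
#' consecutive units of identical colour (because two cubes could replace
#' them). Unit order follows block order.
#'
#' @param run a [marble_run()]; must be non-empty.
#' @return A data frame with columns `unit_tag` and `color`, one row per unit.
#' @examples
#' decompose_to_units(marble_run(c("RAMP", "DOUBLE"), c("blue", "yellow")))
#' @export
decompose_to_units <- function(run) {
  if (!inherits(run, "marble_run")) stop("`run` must be a marble_run")
  if (nrow(run) == 0L) stop("cannot decompose an empty run")
  reps <- ifelse(run$shape_class == "DOUBLE", 2L, 1L)
  idx <- rep(seq_len(nrow(run)), reps)
  data.frame(unit_tag = run$shape_class[idx], color = run$color[idx],
             stringsAsFactors = FALSE)
}
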