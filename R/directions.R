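#' Compass direction labels for the center-out task
#'
#' The eight targets sit on a circle around the home position at the four
#' cardinal and four ordinal compass directions. Angles are measured
#' counter-clockwise from +x (East) in the home frame, so E = 0, N = 90,
#' W = 180, S = 270 degrees. The fixed index order E, NE, N, NW, W, SW, S,
#' SE (0..7) is used everywhere: probability vectors, confusion matrices and
#' tie-breaking all follow it.
#'
#' @format A character vector of the eight direction names in index order.
#' @export
DIRECTIONS <- c("E", "NE", "N", "NW", "W", "SW", "S", "SE")

#' @rdname DIRECTIONS
#' @export
DIRECTION_ANGLES_DEG <- c(E = 0, NE = 45, N = 90, NW = 135,
                          W = 180, SW = 225, S = 270, SE = 315)

#' Convert between direction names, indices and angles
#'
#' @param x direction names (character) or 0-based indices (numeric).
#' @return `direction_index()` gives 0-based indices; `direction_angle()`
#'   gives angles in degrees; `direction_label()` maps 0-based indices or
#'   angles (`from = "angle"`) back to names.
#' @export
direction_index <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  i <- match(x, DIRECTIONS)
  if (anyNA(i)) stop("unknown direction label: ", paste(x[is.na(i)], collapse = ", "))
  i - 1L
}

#' @rdname direction_index
#' @export
direction_angle <- function(x) {
  unname(DIRECTION_ANGLES_DEG[direction_index(x) + 1L])
}

#' @rdname direction_index
#' @param from either "index" (default) or "angle".
#' @export
direction_label <- function(x, from = c("index", "angle")) {
  from <- match.arg(from)
  if (from == "angle") {
    x <- as.integer(round(((x %% 360) / 45))) %% 8L
  }
  DIRECTIONS[as.integer(x) + 1L]
}

#' Circular index distance between two directions
#'
#' Distance 0 means the same direction; 4 means diametrically opposite.
#'
#' @param a,b direction names or 0-based indices.
#' @return integer in 0..4.
#' @export
direction_distance <- function(a, b) {
  d <- abs(direction_index(a) - direction_index(b))
  pmin(d, 8L - d)
}
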