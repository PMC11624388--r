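#' Barn geometry
#'
#' A `barn_geometry` describes the pen as a bounding rectangle plus named
#' polygons for the two functional areas -- `resting` (cubicles and inner
#' alleys, in the centre of the barn) and `feeding` (feed tables and outer
#' alleys, along the sides) -- and optional explicitly `excluded` polygons
#' (out-of-bounds strips, e.g. the transfer lane to the milking parlor).
#' Any point falling in no polygon is treated as excluded.
#'
#' @param bounds numeric of length 2, `c(width, height)` in metres.
#' @param resting,feeding,excluded lists of polygons; each polygon is a
#'   two-column numeric matrix of vertex coordinates in metres (closed
#'   implicitly, i.e. last vertex joins the first).
#' @param cubicle_width cubicle width in metres; two cows lying in adjacent
#'   cubicles are at most `2 * cubicle_width` apart, which motivates the
#'   default proximity radius.
#' @return an object of class `barn_geometry`.
#' @seealso [default_barn()], [read_barn_config()], [assign_functional_area()]
#' @export
barn_geometry <- function(bounds, resting, feeding, excluded = list(),
                          cubicle_width = 1.25) {
  stopifnot(is.numeric(bounds), length(bounds) == 2L, all(bounds > 0))
  as_poly <- function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    if (ncol(p) != 2L || nrow(p) < 3L)
      stop("each polygon needs >= 3 vertices with (x, y) columns")
    if (any(p[, 1] < 0 | p[, 1] > bounds[1] | p[, 2] < 0 | p[, 2] > bounds[2]))
      stop("polygon vertices must lie within the barn bounds")
    p
  }
  out <- structure(
    list(bounds = as.numeric(bounds),
         resting = lapply(resting, as_poly),
         feeding = lapply(feeding, as_poly),
         excluded = lapply(excluded, as_poly),
         cubicle_width = cubicle_width),
    class = "barn_geometry")
  out
}

#' @export
print.barn_geometry <- function(x, ...) {
  cat(sprintf("Barn geometry: %.1f x %.1f m\n", x$bounds[1], x$bounds[2]))
  cat(sprintf("  resting polygons: %d, feeding polygons: %d, excluded: %d\n",
              length(x$resting), length(x$feeding), length(x$excluded)))
  cat(sprintf("  cubicle width: %.2f m\n", x$cubicle_width))
  invisible(x)
}

rect_poly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Default synthetic freestall barn
#'
#' A synthetic single-pen freestall layout with the proportions of a
#' 74 x 33 m barn: a central resting band of cubicles and inner alleys,
#' feeding bands (feed tables and outer alleys) along both long sides, and
#' excluded border strips outside the cows' reach. The exact band widths are
#' invented; they exist to exercise the area-assignment and contact rules.
#'
#' @return a [barn_geometry()] object.
#' @export
default_barn <- function() {
  barn_geometry(
    bounds = c(74, 33),
    resting = list(rect_poly(0, 10.5, 74, 22.5)),
    feeding = list(rect_poly(0, 2, 74, 10.5), rect_poly(0, 22.5, 74, 31)),
    excluded = list(rect_poly(0, 0, 74, 2), rect_poly(0, 31, 74, 33)),
    cubicle_width = 1.25)
}

#' Read barn geometry from a YAML config file
#'
#' The config lists the bounding rectangle and named polygon groups:
#' ```yaml
#' bounds: [74, 33]
#' cubicle_width: 1.25
#' resting:
#'   - [[0, 10.5], [74, 10.5], [74, 22.5], [0, 22.5]]
#' feeding:
#'   - [[0, 2], [74, 2], [74, 10.5], [0, 10.5]]
#' excluded: []
#' ```
#'
#' @param path path to the YAML file.
#' @return a [barn_geometry()] object.
#' @export
read_barn_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  polys <- function(x) lapply(x %||% list(), function(p) do.call(rbind, p))
  barn_geometry(bounds = unlist(cfg$bounds),
                resting = polys(cfg$resting),
                feeding = polys(cfg$feeding),
                excluded = polys(cfg$excluded),
                cubicle_width = cfg$cubicle_width %||% 1.25)
}

# even-odd ray casting; vectorised over query points; boundary points count
# as inside (assignment order then resolves shared edges)
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    # points exactly on a horizontal edge
    on_edge <- (py[i] == y & py[j] == y &
                  x >= pmin(px[i], px[j]) & x <= pmax(px[i], px[j]))
    inside <- inside | on_edge
    j <- i
  }
  inside
}

in_any_polygon <- function(x, y, polys) {
  hit <- logical(length(x))
  for (p in polys) hit <- hit | point_in_polygon(x, y, p)
  hit
}

#' Assign positions to a functional area
#'
#' Tests each point against the resting polygons first, then feeding, then
#' excluded; points in no polygon are excluded. Contacts are only tallied
#' between cows assigned to the same functional area.
#'
#' @param x,y coordinates in metres (vectorised).
#' @param barn a [barn_geometry()].
#' @return character vector in `c("resting", "feeding", "excluded")`.
#' @export
assign_functional_area <- function(x, y, barn) {
  stopifnot(inherits(barn, "barn_geometry"))
  out <- rep("excluded", length(x))
  ok <- is.finite(x) & is.finite(y)
  feed <- ok & in_any_polygon(x, y, barn$feeding)
  rest <- ok & in_any_polygon(x, y, barn$resting)
  out[feed] <- "feeding"
  out[rest] <- "resting"   # resting wins shared boundaries
  out
}

# integer area codes used by the compiled tally: 0 excluded, 1 resting, 2 feeding
area_codes <- function(x, y, barn) {
  a <- assign_functional_area(x, y, barn)
  match(a, c("excluded", "resting", "feeding")) - 1L
}
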