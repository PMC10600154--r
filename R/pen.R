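#' Axis-aligned rectangular pen geometry
#'
#' Pens are modelled as axis-aligned rectangles in the local positioning
#' frame, in metres. Points on the boundary count as inside. The defaults
#' mirror commercial calf housing: 1.5 x 3.5 m straw-bedded pair pens and
#' 6 x 10 m group pens holding up to 16 calves.
#'
#' @param x_min,x_max,y_min,y_max pen extent in metres; `x_max > x_min`,
#'   `y_max > y_min`.
#' @param label housing label, `"pair"` or `"group"`.
#' @return An object of class `pen_geometry`.
#' @examples
#' pen_pair()
#' pen_group()
#' @export
pen_geometry <- function(x_min, x_max, y_min, y_max,
                         label = c("pair", "group")) {
  label <- match.arg(label)
  stopifnot(is.numeric(x_min), is.numeric(x_max),
            is.numeric(y_min), is.numeric(y_max))
  if (x_max <= x_min || y_max <= y_min) {
    stop("pen must have positive extent: require x_max > x_min and y_max > y_min")
  }
  structure(list(x_min = x_min, x_max = x_max,
                 y_min = y_min, y_max = y_max, label = label),
            class = "pen_geometry")
}

#' @rdname pen_geometry
#' @export
pen_pair <- function() pen_geometry(0, 1.5, 0, 3.5, label = "pair")

#' @rdname pen_geometry
#' @export
pen_group <- function() pen_geometry(0, 6, 0, 10, label = "group")

#' @export
print.pen_geometry <- function(x, ...) {
  cat(sprintf("<pen_geometry> %s housing: %.2f x %.2f m (area %.2f m2)\n",
              x$label, x$x_max - x$x_min, x$y_max - x$y_min, pen_area(x)))
  invisible(x)
}

#' Pen area and stocking density
#'
#' @param pen a [pen_geometry()].
#' @param n_calves number of calves housed in the pen.
#' @return Area in m2, or space allowance in m2 per calf.
#' @examples
#' stocking_density(pen_pair(), 2)   # 2.625 m2/calf
#' stocking_density(pen_group(), 16) # 3.75  m2/calf
#' @export
pen_area <- function(pen) {
  stopifnot(inherits(pen, "pen_geometry"))
  (pen$x_max - pen$x_min) * (pen$y_max - pen$y_min)
}

#' @rdname pen_area
#' @export
stocking_density <- function(pen, n_calves) {
  stopifnot(is.numeric(n_calves), length(n_calves) == 1, n_calves > 0)
  pen_area(pen) / n_calves
}

# TRUE for points inside or on the boundary of the pen
points_in_pen <- function(x, y, pen) {
  x >= pen$x_min & x <= pen$x_max & y >= pen$y_min & y <= pen$y_max
}
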