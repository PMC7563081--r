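#' Digitized anterior vertebral polylines
#'
#' A polyline is the ordered trace of the anterior margin of the cervical
#' vertebral bodies on a lateral radiograph, in image-pixel coordinates,
#' cranial to caudal. `as_polyline()` validates a data frame of points and
#' attaches the orientation flag saying which lateral side of the curve is
#' anatomically anterior.
#'
#' Orientation is expressed relative to the direction of travel from the
#' first (cranial) to the last (caudal) point, reading `(x, y)` as ordinary
#' Cartesian coordinates: `"left"` means the anterior soft tissues lie to
#' the left of that direction. After standardization the anterior side is
#' mapped to positive y, so an anteriorly convex (lordotic) spine yields a
#' positive quadratic coefficient.
#'
#' @param points A data frame (or tibble) with numeric columns `x` and `y`,
#'   one row per digitized point, cranial first.
#' @param anterior `"left"` or `"right"`: the anatomically anterior side
#'   relative to the cranial-to-caudal direction of travel.
#' @param min_points Minimum number of points required (default 5, the
#'   smallest sample that over-determines a quadratic).
#'
#' @return A tibble of class `cc_polyline` with columns `x`, `y` and an
#'   `anterior` attribute.
#' @export
#' @examples
#' pts <- data.frame(x = -6:6, y = 0.002 * (-6:6)^2)
#' as_polyline(pts)
as_polyline <- function(points, anterior = c("left", "right"), min_points = 5L) {
  anterior <- match.arg(anterior)
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points))) {
    cc_abort("invalid_value", "`points` must be a data frame with columns `x` and `y`.")
  }
  pts <- as_tibble(points)[, c("x", "y")]
  if (!is.numeric(pts$x) || !is.numeric(pts$y) || anyNA(pts$x) || anyNA(pts$y) ||
      any(!is.finite(pts$x)) || any(!is.finite(pts$y))) {
    cc_abort("invalid_value", "Polyline coordinates must be finite numerics.")
  }
  if (nrow(pts) < min_points) {
    cc_abort(
      "insufficient_points",
      sprintf("Polyline has %d points; at least %d are required.", nrow(pts), min_points)
    )
  }
  dup <- which(diff(pts$x) == 0 & diff(pts$y) == 0)
  if (length(dup) > 0) {
    cc_abort("invalid_geometry", "Polyline has identical consecutive points.")
  }
  n <- nrow(pts)
  if (pts$x[1] == pts$x[n] && pts$y[1] == pts$y[n]) {
    cc_abort("invalid_geometry", "Polyline endpoints coincide (zero-length chord).")
  }
  structure(pts, anterior = anterior, class = c("cc_polyline", class(pts)))
}

#' @export
print.cc_polyline <- function(x, ...) {
  cat(sprintf(
    "<cc_polyline> %d points, anterior side: %s\n",
    nrow(x), attr(x, "anterior")
  ))
  NextMethod()
}

polyline_anterior <- function(polyline) {
  a <- attr(polyline, "anterior")
  if (is.null(a)) "left" else a
}

#' Read and write polylines
#'
#' CSV files use the header `point_index,x,y` with 0-based indices and rows
#' in cranial-to-caudal order; the JSON form adds an `orientation` field
#' (`"left"`/`"right"`) alongside the point list.
#'
#' @param path File path.
#' @param anterior Anterior side for CSV input, where the file cannot carry
#'   it (JSON files carry their own `orientation`).
#' @return `read_polyline()` returns a [as_polyline()] object;
#'   `write_polyline()` returns `path` invisibly.
#' @export
read_polyline <- function(path, anterior = c("left", "right")) {
  anterior <- match.arg(anterior)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- as_tibble(obj$points)
    ant <- if (!is.null(obj$orientation)) obj$orientation else anterior
    return(as_polyline(pts, anterior = ant))
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("point_index", "x", "y") %in% names(df))) {
    cc_abort("invalid_value", "Polyline CSV must have columns point_index,x,y.")
  }
  df <- arrange(df, .data$point_index)
  as_polyline(df[, c("x", "y")], anterior = anterior)
}

#' @rdname read_polyline
#' @param polyline A `cc_polyline`.
#' @export
write_polyline <- function(polyline, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(
        orientation = polyline_anterior(polyline),
        points = as.data.frame(polyline[, c("x", "y")])
      ),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    out <- tibble(
      point_index = seq_len(nrow(polyline)) - 1L,
      x = polyline$x, y = polyline$y
    )
    readr::write_csv(out, path)
  }
  invisible(path)
}
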