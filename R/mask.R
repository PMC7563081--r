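#' Binary segmentation masks
#'
#' Masks are integer or logical matrices: one raster row per image row,
#' row 1 cranial, foreground (the segmented anterior vertebral line)
#' nonzero. `read_mask_png()`/`write_mask_png()` map foreground to 255 in a
#' single-channel PNG.
#'
#' @param path PNG file path.
#' @param threshold Gray level (0-1) above which a pixel is foreground.
#' @return `read_mask_png()` returns a logical matrix.
#' @export
read_mask_png <- function(path, threshold = 0.5) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > threshold
}

#' @rdname read_mask_png
#' @param mask Logical or 0/1 matrix.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

# 8-connected component labelling by BFS; masks here are line strokes of a
# few thousand pixels, so plain R is fast enough
cc_label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask)
  nc <- ncol(mask)
  cur <- 0L
  idx <- which(mask != 0)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- r + dr
          cc <- cl + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          q <- (cc - 1L) * nr + rr
          if (mask[q] != 0 && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

#' Extract the anterior vertebral polyline from a segmentation mask
#'
#' Bridges any segmenter's raster output to the geometry pipeline. The
#' largest 8-connected foreground component is reduced to one point per
#' raster row (the row-wise centroid of its foreground pixels), ordered
#' cranial to caudal (row 1 first); interior rows without foreground are
#' filled by linear interpolation. Points are returned as
#' `(x = column, y = row)`.
#'
#' @param mask Logical or 0/1 matrix, row 1 cranial.
#' @param anterior Orientation flag passed through to [as_polyline()];
#'   which side of the extracted line (relative to the cranial-to-caudal
#'   direction, Cartesian reading of `(x, y)`) is anatomically anterior.
#' @param component_min_px Components smaller than this are treated as
#'   noise; two or more components at or above it make the mask ambiguous.
#' @return A [as_polyline()] object.
#' @export
extract_anterior_polyline <- function(mask, anterior = c("left", "right"),
                                      component_min_px = 10L) {
  anterior <- match.arg(anterior)
  stopifnot(is.matrix(mask))
  if (!any(mask != 0)) cc_abort("empty_mask", "Mask has no foreground pixels.")
  lab <- cc_label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  large <- which(sizes >= component_min_px)
  if (length(large) > 1L) {
    cc_abort(
      "ambiguous_mask",
      sprintf(
        "Mask has %d foreground components of >= %d px; expected one.",
        length(large), component_min_px
      )
    )
  }
  keep <- if (length(large) == 1L) large else which.max(sizes)
  sel <- lab == keep
  rows <- which(apply(sel, 1, any))
  if (length(rows) < 5L) {
    cc_abort("insufficient_points", "Foreground component spans fewer than 5 rows.")
  }
  cent <- vapply(rows, function(r) mean(which(sel[r, ])), numeric(1))
  span <- seq(min(rows), max(rows))
  if (length(span) > length(rows)) {
    cent <- approx(rows, cent, xout = span)$y
    rows <- span
  }
  as_polyline(tibble(x = cent, y = as.numeric(rows)), anterior = anterior)
}

#' Rasterize a polyline into a binary mask
#'
#' Draws an 8-connected stroke of the given thickness along the polyline,
#' reading point coordinates as `(x = column, y = row)`. Inverse (to within
#' extraction tolerance) of [extract_anterior_polyline()].
#'
#' @param polyline A [as_polyline()] object in raster coordinates.
#' @param shape `c(n_rows, n_cols)` of the output mask.
#' @param thickness Stroke thickness in pixels (diameter).
#' @return A logical matrix.
#' @export
rasterize_polyline <- function(polyline, shape, thickness = 3) {
  if (!inherits(polyline, "cc_polyline")) polyline <- as_polyline(polyline)
  stopifnot(length(shape) == 2L, all(shape >= 1), thickness >= 1)
  if (any(polyline$x < 1) || any(polyline$x > shape[2]) ||
      any(polyline$y < 1) || any(polyline$y > shape[1])) {
    cc_abort("bounds", "Polyline does not fit inside the raster shape.")
  }
  mask <- matrix(FALSE, shape[1], shape[2])
  rad <- thickness / 2
  x <- polyline$x
  y <- polyline$y
  # flat caps: the stroke never extends past the cranial/caudal end rows,
  # so extraction sees exactly the rows the polyline spans
  row_lo <- max(1L, round(min(y)))
  row_hi <- min(shape[1], round(max(y)))
  for (i in seq_len(length(x) - 1L)) {
    seg_len <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
    ts <- seq(0, 1, length.out = max(2L, ceiling(seg_len * 2) + 1L))
    for (t in ts) {
      cx <- x[i] + t * (x[i + 1] - x[i])
      cy <- y[i] + t * (y[i + 1] - y[i])
      rr <- max(row_lo, floor(cy - rad)):min(row_hi, ceiling(cy + rad))
      cc <- max(1L, floor(cx - rad)):min(shape[2], ceiling(cx + rad))
      for (r in rr) {
        hit <- (cc - cx)^2 + (r - cy)^2 <= max(rad, 0.5)^2
        mask[r, cc[hit]] <- TRUE
      }
    }
  }
  mask
}
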