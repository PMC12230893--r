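#' Axis-aligned rectangle utilities
#'
#' All spatial objects in this package (atlas grid cells, neighbourhood income
#' polygons, functional urban area outlines) are axis-aligned rectangles in one
#' projected, planar coordinate system, stored as data frames with columns
#' `xmin`, `xmax`, `ymin`, `ymax` plus arbitrary attribute columns. Restricting
#' the geometry to rectangles keeps every overlap area exact, so area-weighted
#' overlays carry no numerical-integration error.
#'
#' @param r,a,b data frames (or single rows) with `xmin`, `xmax`, `ymin`,
#'   `ymax` columns.
#' @return `rect_area()` and `rect_intersection_area()` return numeric
#'   vectors; `rect_union_area()` a single number.
#' @name rectangles
NULL

#' @rdname rectangles
#' @export
rect_area <- function(r) {
  (r$xmax - r$xmin) * (r$ymax - r$ymin)
}

#' @rdname rectangles
#' @export
rect_intersection_area <- function(a, b) {
  w <- pmin(a$xmax, b$xmax) - pmax(a$xmin, b$xmin)
  h <- pmin(a$ymax, b$ymax) - pmax(a$ymin, b$ymin)
  pmax(w, 0) * pmax(h, 0)
}

# Clip rectangles `r` to window `win` (single row); drops empty results.
rect_clip <- function(r, win) {
  out <- data.frame(
    xmin = pmax(r$xmin, win$xmin), xmax = pmin(r$xmax, win$xmax),
    ymin = pmax(r$ymin, win$ymin), ymax = pmin(r$ymax, win$ymax)
  )
  keep <- out$xmax > out$xmin & out$ymax > out$ymin
  out[keep, , drop = FALSE]
}

#' @rdname rectangles
#' @export
rect_union_area <- function(r) {
  if (nrow(r) == 0) return(0)
  if (any(r$xmax < r$xmin) || any(r$ymax < r$ymin)) {
    stopf("invalid rectangle: max < min")
  }
  # sweep over x-breakpoints; within each slab the union of y-intervals is exact
  xs <- sort(unique(c(r$xmin, r$xmax)))
  total <- 0
  for (i in seq_len(length(xs) - 1L)) {
    x0 <- xs[i]; x1 <- xs[i + 1L]
    act <- r$xmin <= x0 & r$xmax >= x1
    if (!any(act)) next
    ys <- r[act, c("ymin", "ymax"), drop = FALSE]
    ys <- ys[order(ys$ymin), , drop = FALSE]
    cov <- 0; cur_lo <- ys$ymin[1]; cur_hi <- ys$ymax[1]
    if (nrow(ys) > 1) {
      for (j in 2:nrow(ys)) {
        if (ys$ymin[j] > cur_hi) {
          cov <- cov + (cur_hi - cur_lo)
          cur_lo <- ys$ymin[j]; cur_hi <- ys$ymax[j]
        } else {
          cur_hi <- max(cur_hi, ys$ymax[j])
        }
      }
    }
    cov <- cov + (cur_hi - cur_lo)
    total <- total + cov * (x1 - x0)
  }
  total
}
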