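# Shared internal helpers: polygon rasterisation, line drawing, seed streams.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterise a closed polygon into a pixel mask
#'
#' Pixel centers use the 0-based image convention: array element
#' `[i, j]` is the pixel at `(x, y) = (i - 1, j - 1)`. A pixel belongs to
#' the region when its center falls inside the polygon (even-odd rule);
#' this is also the rule applied to leaflet ROIs throughout the package.
#'
#' @param polygon two-column matrix or data frame of `x, y` vertex
#'   coordinates (0-based pixels); the polygon is closed implicitly.
#' @param dim image dimensions `c(width, height)` in pixels.
#' @return logical matrix of dimension `dim`.
#' @export
polygon_mask <- function(polygon, dim) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2, nrow(polygon) >= 3, length(dim) == 2)
  if (any(!is.finite(polygon))) stop("polygon vertices must be finite")
  px <- rep(seq_len(dim[1]) - 1, times = dim[2])
  py <- rep(seq_len(dim[2]) - 1, each = dim[1])
  inside <- rep(FALSE, length(px))
  n <- nrow(polygon)
  xs <- polygon[, 1]; ys <- polygon[, 2]
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, dim[1], dim[2])
}

#' Polygon area by the shoelace formula
#' @param polygon two-column matrix of vertices.
#' @return unsigned area in square pixels.
#' @keywords internal
polygon_area <- function(polygon) {
  polygon <- as.matrix(polygon)
  x <- polygon[, 1]; y <- polygon[, 2]
  n <- nrow(polygon)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Bresenham raster line between two 0-based integer pixel coordinates;
# returns a two-column matrix of 0-based pixels including both endpoints.
bresenham_line <- function(p0, p1) {
  x0 <- round(p0[1]); y0 <- round(p0[2])
  x1 <- round(p1[1]); y1 <- round(p1[2])
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  pts <- matrix(NA_integer_, dx - dy + 1L, 2)
  k <- 0L
  repeat {
    k <- k + 1L
    pts[k, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2 * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  pts[seq_len(k), , drop = FALSE]
}

# Deterministic sub-seed stream: one root seed fans out to n independent
# 31-bit seeds, so modules consume independent randomness reproducibly.
derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Standard error of the mean (reporting convention: mean +/- SEM).
sem <- function(x) stats::sd(x) / sqrt(length(x))

# An elliptical default leaflet ROI polygon for the synthetic generators;
# frac gives the semi-axes as fractions of the image dimensions.
default_ellipse_roi <- function(dim, frac = c(0.44, 0.44), n_vertices = 64) {
  frac <- rep_len(frac, 2)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  cbind(x = (dim[1] - 1) / 2 + frac[1] * dim[1] * cos(th),
        y = (dim[2] - 1) / 2 + frac[2] * dim[2] * sin(th))
}

#' Read a leaflet ROI polygon from CSV
#'
#' Expects columns `x, y` with 0-based pixel coordinates.
#' @param path CSV file path.
#' @return two-column matrix of vertices.
#' @export
read_roi <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df))) stop("ROI CSV needs columns x, y")
  as.matrix(df[, c("x", "y")])
}

#' Write a leaflet ROI polygon to CSV
#' @param polygon two-column matrix of `x, y` vertices (0-based pixels).
#' @param path output CSV path.
#' @export
write_roi <- function(polygon, path) {
  polygon <- as.matrix(polygon)
  utils::write.csv(data.frame(x = polygon[, 1], y = polygon[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}
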