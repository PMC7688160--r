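# Trichrome morphometrics: HSL pixel classification inside a leaflet ROI,
# constituent area fractions, and mean leaflet thickness (area / cusp
# length via the medial-axis skeleton).

#' Classify image pixels into stain classes within a leaflet ROI
#'
#' Each ROI pixel is labeled with the first stain window (in list order)
#' containing its HSL value; ROI pixels matching no window are
#' "background" (in trichrome practice near-white, L > 0.93, or
#' desaturated, S < 0.1); pixels outside the ROI are "outside".
#'
#' @param img RGB array `[x, y, 3]` in `[0, 1]`, or a precomputed HSL
#'   array from [rgb_to_hsl()] (set `hsl = TRUE`).
#' @param roi ROI polygon (two-column `x, y`, 0-based pixels) or a
#'   logical mask of the image dimensions.
#' @param windows list of [hsl_window()] objects (validated for
#'   non-overlap); defaults to the trichrome windows [stain_windows()].
#' @param hsl set to `TRUE` when `img` is already HSL.
#' @return integer label matrix of class `stain_labels`: 0 = outside ROI,
#'   `1..K` = window classes, `K + 1` = background; the class names are
#'   in `attr(x, "classes")`.
#' @export
classify_pixels <- function(img, roi, windows = stain_windows(), hsl = FALSE) {
  validate_windows(windows)
  d <- dim(img)
  stopifnot(length(d) == 3, d[3] == 3)
  hslimg <- if (hsl) img else rgb_to_hsl(img)
  mask <- if (is.matrix(roi) && is.logical(roi)) roi
          else polygon_mask(roi, d[1:2])
  stopifnot(all(dim(mask) == d[1:2]))
  if (!any(mask)) stop("ROI contains no pixels")
  h <- hslimg[, , 1][mask]; s <- hslimg[, , 2][mask]; l <- hslimg[, , 3][mask]
  lab <- rep.int(length(windows) + 1L, sum(mask))  # background by default
  for (k in rev(seq_along(windows)))               # first window wins
    lab[in_hsl_window(h, s, l, windows[[k]])] <- k
  out <- matrix(0L, d[1], d[2])
  out[mask] <- lab
  structure(out,
            classes = unname(c(vapply(windows, `[[`, "", "name"), "background")),
            class = c("stain_labels", class(out)))
}

#' Constituent area fractions from a stain label mask
#'
#' Fractions are ratios of class pixel counts to non-background pixels
#' within the leaflet ROI, so the non-background fractions sum to one.
#' The background fraction is reported relative to all ROI pixels.
#'
#' @param labels label mask from [classify_pixels()].
#' @return list of class `composition_result`: `fractions` (named, over
#'   non-background classes), `background_fraction`, `leaflet_area`
#'   (ROI pixels) and `counts`.
#' @export
area_fractions <- function(labels) {
  classes <- attr(labels, "classes")
  if (is.null(classes)) stop("labels must come from classify_pixels()")
  k <- length(classes) - 1L
  counts <- tabulate(labels[labels > 0L], nbins = k + 1L)
  names(counts) <- classes
  n_roi <- sum(counts)
  n_fg <- sum(counts[seq_len(k)])
  if (n_fg == 0)
    stop("undefined fractions: leaflet contains no non-background pixels")
  structure(list(fractions = counts[seq_len(k)] / n_fg,
                 background_fraction = unname(counts[k + 1L] / n_roi),
                 leaflet_area = n_roi, counts = counts),
            class = "composition_result")
}

#' @export
print.composition_result <- function(x, ...) {
  cat("<composition_result>", x$leaflet_area, "ROI px;",
      sprintf("%s %.3f", names(x$fractions), x$fractions),
      sprintf("(background %.3f)\n", x$background_fraction))
  invisible(x)
}

# --- skeletonization ---------------------------------------------------

# Zhang-Suen binary thinning. Operates on a logical matrix; border pixels
# are treated as background. Returns the 1-pixel-wide skeleton.
skeletonize <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.integer(mask)
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(x, di, dj) {  # neighbor value at offset (di, dj)
    out <- matrix(0L, nr, nc)
    ri <- max(1, 1 + di):min(nr, nr + di)
    ci <- max(1, 1 + dj):min(nc, nc + dj)
    out[ri - di, ci - dj] <- x[ri, ci]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- sh(m, 0, -1); p3 <- sh(m, 1, -1); p4 <- sh(m, 1, 0)
      p5 <- sh(m, 1, 1);  p6 <- sh(m, 0, 1);  p7 <- sh(m, -1, 1)
      p8 <- sh(m, -1, 0); p9 <- sh(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqn <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nr, nc)
      for (i in 1:8) a <- a + (seqn[[i]] == 0L & seqn[[i + 1]] == 1L)
      if (step == 1) {
        c1 <- p2 * p4 * p6; c2 <- p4 * p6 * p8
      } else {
        c1 <- p2 * p4 * p8; c2 <- p2 * p6 * p8
      }
      del <- m == 1L & b >= 2 & b <= 6 & a == 1L & c1 == 0L & c2 == 0L
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] == 1L
}

# Longest geodesic path through a skeleton (weighted graph diameter over
# 8-connected pixels; orthogonal steps weigh 1, diagonal sqrt(2)).
# Returns the path length and the two endpoint pixels.
skeleton_longest_path <- function(skel) {
  px <- which(skel, arr.ind = TRUE)
  n <- nrow(px)
  if (n <= 1) return(list(length = 0, ends = px))
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[px] <- seq_len(n)
  edges <- NULL; w <- NULL
  for (off in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    qi <- px[, 1] + off[1]; qj <- px[, 2] + off[2]
    ok <- qi >= 1 & qi <= nrow(skel) & qj >= 1 & qj <= ncol(skel)
    ok[ok] <- id[cbind(qi[ok], qj[ok])] > 0L
    if (any(ok)) {
      edges <- rbind(edges, cbind(seq_len(n)[ok], id[cbind(qi[ok], qj[ok])]))
      w <- c(w, rep(sqrt(sum(off^2)), sum(ok)))
    }
  }
  if (is.null(edges)) return(list(length = 0, ends = px[1, , drop = FALSE]))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  path <- as.integer(igraph::get_diameter(g, directed = FALSE))
  # Euclidean length of the resampled path: summing raster steps would
  # inflate oblique segments by up to 8% (octile-distance error)
  anchors <- unique(c(seq(1, length(path), by = 4), length(path)))
  pc <- px[path[anchors], , drop = FALSE]
  len <- if (nrow(pc) > 1) sum(sqrt(rowSums(diff(pc)^2))) else 0
  list(length = len,
       ends = px[c(path[1], path[length(path)]), , drop = FALSE])
}

#' Mean leaflet thickness from a binary leaflet mask
#'
#' Thickness is the total leaflet area divided by the length along the
#' cusp, with cusp length measured as the longest geodesic path through
#' the medial-axis skeleton of the mask (Zhang-Suen thinning, 8-connected
#' geodesic distance), extended at both ends by the local medial radius
#' so the measurement runs tip to tip. A user-supplied cusp polyline
#' overrides the
#' skeleton measurement. If the mask is disconnected, the largest
#' component is used with a warning.
#'
#' @param mask logical leaflet mask, or a ROI polygon plus `dim`.
#' @param cusp_line optional two-column polyline of cusp coordinates
#'   (pixels); its arc length replaces the skeleton path length.
#' @param pixel_size optional physical pixel size; when supplied the
#'   returned thickness is `pixel_size` units instead of pixels.
#' @param dim image dimensions, required when `mask` is a polygon.
#' @return list with `thickness`, `area` (px), `cusp_length` (px).
#' @examples
#' m <- matrix(FALSE, 220, 40); m[11:210, 11:30] <- TRUE
#' leaflet_thickness(m)$thickness  # ~ 20
#' @export
leaflet_thickness <- function(mask, cusp_line = NULL, pixel_size = NULL,
                              dim = NULL) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    if (is.null(dim)) stop("supply `dim` when `mask` is a polygon")
    mask <- polygon_mask(mask, dim)
  }
  if (!any(mask)) stop("empty leaflet mask")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(tab) > 1) {
    warning("disconnected leaflet mask: using largest component")
    mask <- EBImage::imageData(lab) == which.max(tab)
  }
  area <- sum(mask)
  len <- if (!is.null(cusp_line)) {
    cl <- as.matrix(cusp_line)
    sum(sqrt(rowSums(diff(cl)^2)))
  } else {
    # thinning stops the medial axis about one local radius short of each
    # cusp tip; extend the longest path by the distance-transform value
    # at its endpoints to recover tip-to-tip cusp length
    lp <- skeleton_longest_path(skeletonize(mask))
    edt <- as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1))))
    if (nrow(lp$ends) == 0) {
      # skeleton eroded away entirely (round blob with no elongation):
      # tip-to-tip length degenerates to the inscribed diameter
      2 * max(edt)
    } else {
      lp$length + sum(edt[lp$ends])
    }
  }
  if (len <= 0) stop("cusp length is zero; cannot form thickness")
  th <- area / len
  if (!is.null(pixel_size)) th <- th * pixel_size
  list(thickness = th, area = area, cusp_length = len)
}

#' Full trichrome composition of one section
#'
#' Convenience wrapper: classify pixels, compute area fractions, and
#' (optionally) leaflet thickness from the ROI mask.
#'
#' @inheritParams classify_pixels
#' @param thickness also measure leaflet thickness of the ROI mask.
#' @param pixel_size optional physical pixel size for thickness.
#' @return `composition_result` with an added `thickness` element when
#'   requested.
#' @export
quantify_trichrome <- function(img, roi, windows = stain_windows(),
                               thickness = FALSE, pixel_size = NULL) {
  labels <- classify_pixels(img, roi, windows)
  comp <- area_fractions(labels)
  if (thickness) {
    mask <- if (is.matrix(roi) && is.logical(roi)) roi
            else polygon_mask(roi, dim(img)[1:2])
    comp$thickness <- leaflet_thickness(mask, pixel_size = pixel_size)
  }
  comp
}
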