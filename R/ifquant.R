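# Immunofluorescence quantification: fuzzy c-means DAPI foreground,
# watershed + concave-point nucleus splitting, median-threshold marker
# positivity (Runx2 nuclear coverage, aSMA area fraction).

#' Fuzzy c-means foreground segmentation of a DAPI image
#'
#' Two-cluster fuzzy c-means (fuzziness m = 2) on the intensity histogram
#' of ROI pixels, with deterministic initialisation at the 25th/75th
#' intensity percentiles. Pixels whose membership in the brighter cluster
#' exceeds 0.5 — equivalently, pixels closer to the bright center — form
#' the foreground.
#'
#' @param img numeric intensity matrix (any range; 16-bit images arrive
#'   as integers).
#' @param roi ROI polygon or logical mask; `NULL` uses the whole image.
#' @param m fuzziness exponent.
#' @param tol convergence tolerance on center movement, relative to the
#'   intensity range.
#' @param max_iter iteration cap.
#' @return logical foreground mask (FALSE outside the ROI); the fitted
#'   cluster centers are in `attr(x, "centers")`.
#' @export
fcm_foreground <- function(img, roi = NULL, m = 2, tol = 1e-5, max_iter = 300) {
  stopifnot(is.matrix(img))
  mask <- if (is.null(roi)) matrix(TRUE, nrow(img), ncol(img))
          else if (is.matrix(roi) && is.logical(roi)) roi
          else polygon_mask(roi, dim(img))
  x <- img[mask]
  rng <- range(x)
  if (diff(rng) == 0)
    stop("degenerate clustering: ROI intensities are constant")
  # histogram-based: iterate over unique intensity values with counts
  vals <- sort(unique(x))
  cnt <- tabulate(match(x, vals), nbins = length(vals))
  ctr <- as.numeric(stats::quantile(x, c(0.25, 0.75), names = FALSE))
  if (ctr[1] == ctr[2]) ctr <- rng
  p <- 2 / (m - 1)
  for (it in seq_len(max_iter)) {
    d1 <- abs(vals - ctr[1]); d2 <- abs(vals - ctr[2])
    u1 <- ifelse(d1 == 0, 1, ifelse(d2 == 0, 0,
                 1 / (1 + (d1 / d2)^p)))
    u2 <- 1 - u1
    w1 <- cnt * u1^m; w2 <- cnt * u2^m
    new_ctr <- c(sum(w1 * vals) / sum(w1), sum(w2 * vals) / sum(w2))
    if (max(abs(new_ctr - ctr)) < tol * diff(rng)) { ctr <- new_ctr; break }
    ctr <- new_ctr
  }
  bright <- which.max(ctr)
  fg <- matrix(FALSE, nrow(img), ncol(img))
  fg[mask] <- abs(x - ctr[bright]) < abs(x - ctr[3 - bright])
  attr(fg, "centers") <- sort(ctr)
  fg
}

#' Split touching nuclei by watershed on the distance transform
#'
#' Markers are the regional maxima of the Euclidean distance transform
#' after h-maxima suppression (`h` pixels, default 2); the watershed of
#' the inverted distance transform, confined to the foreground, assigns
#' each foreground pixel a nucleus label. Objects smaller than
#' `min_area` are removed (an empty result is allowed).
#'
#' @param mask logical foreground mask.
#' @param h regional-maxima suppression depth in pixels.
#' @param min_area minimum nucleus area in pixels (default 25 at 20x).
#' @return integer label matrix with sequential labels (0 = background).
#' @export
watershed_split <- function(mask, h = 2, min_area = 25) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(EBImage::Image(mask * 1))
  w <- EBImage::watershed(d, tolerance = h, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(w)), nrow(mask), ncol(mask))
  drop_small_and_relabel(lab, min_area)
}

# Remove sub-min_area objects and relabel 1..K preserving order.
drop_small_and_relabel <- function(lab, min_area) {
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_area)
  lut <- integer(max(lab))
  lut[keep] <- seq_along(keep)
  lab[lab > 0L] <- lut[lab[lab > 0L]]
  lab
}

# Concave contour vertices of one 0-based contour (n x 2), CCW-oriented.
# Interior angle measured over a (2*window + 1)-point contour span;
# returns indices whose interior angle exceeds angle_deg.
concave_points <- function(contour, window = 3, angle_deg = 210) {
  n <- nrow(contour)
  if (n < 2 * window + 1) return(integer(0))
  # orient counter-clockwise (positive signed area)
  a2 <- sum(contour[, 1] * contour[c(2:n, 1), 2] -
            contour[c(2:n, 1), 1] * contour[, 2])
  if (a2 < 0) contour <- contour[n:1, , drop = FALSE]
  prv <- contour[((seq_len(n) - 1 - window) %% n) + 1, , drop = FALSE]
  nxt <- contour[((seq_len(n) - 1 + window) %% n) + 1, , drop = FALSE]
  v1 <- contour - prv
  v2 <- nxt - contour
  cross <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  dt <- v1[, 1] * v2[, 1] + v1[, 2] * v2[, 2]
  turn <- atan2(cross, dt) * 180 / pi
  idx <- which(180 - turn > angle_deg)
  if (a2 < 0) idx <- n + 1 - idx  # map back to input order
  idx
}

#' Split remaining touching nuclei at concave contour points
#'
#' For each labeled object, contour points whose interior angle exceeds
#' `angle_deg` (measured over a `2 * window + 1`-point contour span) are
#' detected; when at least two exist the object is cut along the
#' shortest chord joining two concave points whose cut yields two parts
#' each at least `min_area` pixels. At most `max_passes` passes are
#' applied (no deeper recursion), and a convex object is returned
#' unchanged, which makes the operation idempotent in practice.
#'
#' @param labels integer label matrix (e.g. from [watershed_split()]).
#' @param window contour half-window for the angle measurement.
#' @param angle_deg concavity threshold in degrees (> 180 is reflex).
#' @param min_area minimum area of each part after a cut.
#' @param max_passes number of sweeps over the objects.
#' @return relabeled integer matrix.
#' @export
concave_split <- function(labels, window = 3, angle_deg = 210,
                          min_area = 25, max_passes = 2) {
  stopifnot(is.matrix(labels))
  lab <- labels
  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    if (max(lab) == 0L) break
    contours <- EBImage::ocontour(EBImage::Image(lab))
    for (obj in seq_along(contours)) {
      if (!any(lab == obj)) next
      ct <- contours[[obj]]
      cp <- concave_points(ct, window, angle_deg)
      if (length(cp) < 2) next
      cut <- try_concave_cut(lab, obj, ct, cp, window, min_area)
      if (!is.null(cut)) { lab <- cut; changed <- TRUE }
    }
    if (!changed) break
  }
  drop_small_and_relabel(lab, min_area = 1)
}

# Attempt the shortest valid concave-pair chord cut of object `obj`.
# Returns the updated label matrix or NULL when no cut qualifies.
try_concave_cut <- function(lab, obj, contour, cp, window, min_area) {
  n <- nrow(contour)
  pairs <- t(utils::combn(cp, 2))
  # exclude pairs from the same notch (too close along the contour)
  sep <- pmin(abs(pairs[, 1] - pairs[, 2]),
              n - abs(pairs[, 1] - pairs[, 2]))
  pairs <- pairs[sep > 2 * window, , drop = FALSE]
  if (!nrow(pairs)) return(NULL)
  p1 <- contour[pairs[, 1], , drop = FALSE]
  p2 <- contour[pairs[, 2], , drop = FALSE]
  chord <- sqrt(rowSums((p1 - p2)^2))
  for (k in order(chord)) {
    line <- bresenham_line(p1[k, ], p2[k, ]) + 1L  # to 1-based indices
    inb <- line[, 1] >= 1 & line[, 1] <= nrow(lab) &
           line[, 2] >= 1 & line[, 2] <= ncol(lab)
    line <- line[inb, , drop = FALSE]
    on_obj <- lab[line] == obj
    if (!all(on_obj)) next  # chord leaves the object: invalid cut
    cut_lab <- lab
    cut_lab[line] <- 0L
    # relabel within the object's bounding box only
    obj_mask <- cut_lab == obj
    comp <- EBImage::bwlabel(EBImage::Image(obj_mask * 1))
    comp <- matrix(as.integer(EBImage::imageData(comp)), nrow(lab), ncol(lab))
    sizes <- tabulate(comp[comp > 0L])
    big <- which(sizes >= min_area)
    if (length(big) < 2) next
    # accept: largest part keeps the old label, others get new labels
    newlab <- lab
    newlab[lab == obj] <- 0L
    base <- max(lab)
    ids <- c(obj, base + seq_len(length(big) - 1L))
    for (i in seq_along(big)) newlab[comp == big[i]] <- ids[i]
    # chord pixels: assign to the nearest retained part
    for (r in seq_len(nrow(line))) {
      pt <- line[r, ]
      best <- 0L; bestd <- Inf
      for (i in seq_along(big)) {
        pxs <- which(comp == big[i], arr.ind = TRUE)
        dmin <- min((pxs[, 1] - pt[1])^2 + (pxs[, 2] - pt[2])^2)
        if (dmin < bestd) { bestd <- dmin; best <- ids[i] }
      }
      newlab[pt[1], pt[2]] <- best
    }
    return(newlab)
  }
  NULL
}

#' Segment nuclei from a DAPI image
#'
#' The full nucleus pipeline: fuzzy c-means foreground, watershed
#' splitting on the distance transform, then concave-point splitting of
#' remaining clumps (the order in which the stages are described for
#' this assay).
#'
#' @inheritParams fcm_foreground
#' @inheritParams watershed_split
#' @inheritParams concave_split
#' @return integer nucleus label matrix.
#' @export
segment_nuclei <- function(img, roi = NULL, h = 2, min_area = 25,
                           window = 3, angle_deg = 210) {
  fg <- fcm_foreground(img, roi)
  lab <- watershed_split(fg, h = h, min_area = min_area)
  concave_split(lab, window = window, angle_deg = angle_deg,
                min_area = min_area)
}

#' Median marker threshold within the leaflet
#'
#' The positivity threshold for a fluorescence marker is the median stain
#' intensity over leaflet pixels; positive pixels are those strictly
#' greater. Because the median is equivariant under strictly increasing
#' intensity transforms, the positive-pixel mask is invariant under any
#' such transform.
#'
#' @param img marker intensity matrix.
#' @param roi leaflet polygon or logical mask.
#' @return the median intensity (threshold).
#' @export
marker_threshold <- function(img, roi) {
  stopifnot(is.matrix(img))
  mask <- if (is.matrix(roi) && is.logical(roi)) roi
          else polygon_mask(roi, dim(img))
  if (!any(mask)) stop("empty ROI")
  stats::median(img[mask])
}

#' Marker-positive area fraction of the leaflet
#'
#' Ratio of positive pixels (strictly above the median threshold) to all
#' leaflet pixels — the aSMA read-out, also reused for phospho-ERK1/2.
#'
#' @inheritParams marker_threshold
#' @param threshold optional precomputed threshold; defaults to
#'   [marker_threshold()] of the same image and ROI.
#' @return fraction in `[0, 1]`.
#' @export
asma_area_fraction <- function(img, roi, threshold = NULL) {
  mask <- if (is.matrix(roi) && is.logical(roi)) roi
          else polygon_mask(roi, dim(img))
  if (!any(mask)) stop("empty ROI")
  thr <- threshold %||% stats::median(img[mask])
  mean(img[mask] > thr)
}

#' Per-nucleus marker coverage and positivity (Runx2 read-out)
#'
#' For each segmented nucleus, coverage is the fraction of its pixels
#' strictly above the marker threshold; a nucleus is positive when its
#' coverage strictly exceeds 0.5 ("greater than 50% stain coverage", so
#' exactly half is negative). Positive counts are normalised to the
#' total nucleus count.
#'
#' @param labels nucleus label matrix from [segment_nuclei()].
#' @param img marker intensity matrix.
#' @param threshold marker threshold from [marker_threshold()].
#' @return object of class `marker_quantification`: `n_nuclei`,
#'   `positive_fraction`, `threshold` and a per-nucleus `records` data
#'   frame (label, area, centroid, coverage, positive).
#' @export
runx2_positivity <- function(labels, img, threshold) {
  stopifnot(is.matrix(labels), all(dim(labels) == dim(img)))
  k <- max(labels)
  if (k == 0L) stop("undefined positivity: no nuclei segmented")
  recs <- nucleus_records(labels, img, threshold)
  structure(list(n_nuclei = k,
                 positive_fraction = mean(recs$positive),
                 threshold = threshold, records = recs),
            class = "marker_quantification")
}

#' @export
print.marker_quantification <- function(x, ...) {
  cat(sprintf("<marker_quantification> %d nuclei, %.3f positive (threshold %g)\n",
              x$n_nuclei, x$positive_fraction, x$threshold))
  invisible(x)
}

#' Per-nucleus records from a label mask
#'
#' @inheritParams runx2_positivity
#' @return data frame: `label`, `area` (px), `x`, `y` centroid (0-based
#'   pixels) and, when a marker image is supplied, `coverage` and
#'   `positive`.
#' @export
nucleus_records <- function(labels, img = NULL, threshold = NULL) {
  k <- max(labels)
  if (k == 0L)
    return(data.frame(label = integer(0), area = integer(0),
                      x = numeric(0), y = numeric(0)))
  px <- which(labels > 0L, arr.ind = TRUE)
  l <- labels[px]
  area <- tabulate(l, nbins = k)
  cx <- vapply(split(px[, 1] - 1, l), mean, 0)
  cy <- vapply(split(px[, 2] - 1, l), mean, 0)
  out <- data.frame(label = seq_len(k), area = area,
                    x = as.numeric(cx), y = as.numeric(cy))
  if (!is.null(img)) {
    stopifnot(!is.null(threshold))
    pos <- img[px] > threshold
    cov <- vapply(split(pos, l), mean, 0)
    out$coverage <- as.numeric(cov)
    out$positive <- out$coverage > 0.5
  }
  out
}
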