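# Synthetic two-channel fluorescence fields: DAPI nuclei (with a known
# number of touching pairs) plus a marker channel with planted
# per-nucleus coverage and diffuse extranuclear signal.

#' Simulate a DAPI + marker fluorescence field with known ground truth
#'
#' Nuclei are discs with radii drawn from `nucleus_radius`, placed inside
#' the leaflet ROI by rejection sampling. `n_touching_pairs` of them are
#' placed as overlapping pairs (center distance 1.6 times the radius)
#' whose union is the two-lobed shape with exactly two concave junction
#' points that the splitting algorithms target; all remaining nuclei are
#' isolated. The DAPI channel is the blurred disc indicator plus
#' truncated Gaussian noise (16-bit range). The marker channel covers the
#' requested fraction of each nucleus (pixels are marked from one side of
#' the nucleus along a random direction, so the planted coverage is exact
#' pixel-wise before blurring) plus a diffuse extranuclear component
#' covering `diffuse_marker_fraction` of the leaflet.
#'
#' @param n_nuclei total number of nuclei.
#' @param n_touching_pairs number of touching pairs (each consumes two
#'   nuclei; must be at most `n_nuclei / 2`).
#' @param nucleus_radius radius range in pixels.
#' @param marker_coverage per-nucleus marker coverage fractions in
#'   `[0, 1]` (recycled); `NULL` means no nuclear marker.
#' @param diffuse_marker_fraction fraction of leaflet area carrying
#'   diffuse marker signal.
#' @param psf_sigma Gaussian blur sigma in pixels (0 disables blurring).
#' @param noise_sd additive Gaussian noise SD in intensity units
#'   (truncated to the 16-bit range).
#' @param dim image dimensions.
#' @param roi_polygon leaflet polygon (default: centered ellipse).
#' @param seed integer seed.
#' @param max_attempts rejection-sampling cap before an infeasible
#'   packing error.
#' @return list with `dapi` and `marker` intensity matrices, `roi`
#'   polygon, `truth` data frame (per nucleus: id, x, y, radius, area,
#'   coverage, positive, pair), and `label_mask` of true nucleus labels.
#' @export
simulate_fluorescence <- function(n_nuclei = 100, n_touching_pairs = 10,
                                  nucleus_radius = c(5, 8),
                                  marker_coverage = NULL,
                                  diffuse_marker_fraction = 0.05,
                                  psf_sigma = 1, noise_sd = 300,
                                  dim = c(512, 512), roi_polygon = NULL,
                                  seed = 1, max_attempts = 20000) {
  stopifnot(n_nuclei >= 1, n_touching_pairs >= 0,
            n_touching_pairs <= n_nuclei / 2,
            length(nucleus_radius) == 2, nucleus_radius[1] > 1,
            diffuse_marker_fraction >= 0, diffuse_marker_fraction < 1)
  if (!is.null(marker_coverage)) {
    stopifnot(all(marker_coverage >= 0 & marker_coverage <= 1))
    marker_coverage <- rep_len(marker_coverage, n_nuclei)
  }
  set.seed(as.integer(seed))
  roi <- roi_polygon %||% default_ellipse_roi(dim)
  roimask <- polygon_mask(roi, dim)

  # --- placement: pairs first (larger footprint), then singles ---------
  centers <- matrix(numeric(0), 0, 2); radii <- numeric(0); pair_id <- integer(0)
  occupied_r <- numeric(0)  # exclusion radius per placed blob center
  blob_centers <- matrix(numeric(0), 0, 2)
  place <- function(footprint) {
    for (a in seq_len(max_attempts)) {
      cx <- stats::runif(1, 0, dim[1] - 1); cy <- stats::runif(1, 0, dim[2] - 1)
      i <- round(cx) + 1; j <- round(cy) + 1
      if (i < 1 || j < 1 || i > dim[1] || j > dim[2] || !roimask[i, j]) next
      # keep the footprint inside the ROI (checked at 4 compass points)
      ok <- TRUE
      for (dd in list(c(footprint, 0), c(-footprint, 0),
                      c(0, footprint), c(0, -footprint))) {
        ii <- round(cx + dd[1]) + 1; jj <- round(cy + dd[2]) + 1
        if (ii < 1 || jj < 1 || ii > dim[1] || jj > dim[2] ||
            !roimask[ii, jj]) { ok <- FALSE; break }
      }
      if (!ok) next
      if (nrow(blob_centers) &&
          any(sqrt((blob_centers[, 1] - cx)^2 + (blob_centers[, 2] - cy)^2) <
              occupied_r + footprint + 2)) next
      return(c(cx, cy))
    }
    stop("infeasible packing: could not place all nuclei in the ROI")
  }
  n_singles <- n_nuclei - 2L * n_touching_pairs
  id <- 0L
  for (p in seq_len(n_touching_pairs)) {
    r <- stats::runif(1, nucleus_radius[1], nucleus_radius[2])
    dsep <- 1.6 * r
    c0 <- place(r + dsep / 2)
    th <- stats::runif(1, 0, 2 * pi)
    off <- c(cos(th), sin(th)) * dsep / 2
    centers <- rbind(centers, c0 + off, c0 - off)
    radii <- c(radii, r, r)
    pair_id <- c(pair_id, p, p)
    blob_centers <- rbind(blob_centers, c0)
    occupied_r <- c(occupied_r, r + dsep / 2)
    id <- id + 2L
  }
  for (s in seq_len(n_singles)) {
    r <- stats::runif(1, nucleus_radius[1], nucleus_radius[2])
    c0 <- place(r)
    centers <- rbind(centers, c0)
    radii <- c(radii, r)
    pair_id <- c(pair_id, 0L)
    blob_centers <- rbind(blob_centers, c0)
    occupied_r <- c(occupied_r, r)
  }

  # --- true label mask (overlap pixels go to the nearer center) --------
  lab <- matrix(0L, dim[1], dim[2])
  bestd <- matrix(Inf, dim[1], dim[2])
  for (k in seq_len(n_nuclei)) {
    r <- radii[k]
    xr <- max(1, floor(centers[k, 1] - r)):min(dim[1], ceiling(centers[k, 1] + r) + 1)
    yr <- max(1, floor(centers[k, 2] - r)):min(dim[2], ceiling(centers[k, 2] + r) + 1)
    gx <- (xr - 1) - centers[k, 1]
    gy <- (yr - 1) - centers[k, 2]
    d2 <- outer(gx^2, gy^2, `+`)
    sel <- d2 <= r^2 & d2 < bestd[xr, yr]
    lb <- lab[xr, yr]; bd <- bestd[xr, yr]
    lb[sel] <- k; bd[sel] <- d2[sel]
    lab[xr, yr] <- lb; bestd[xr, yr] <- bd
  }

  # --- marker ground truth: directional fill to the exact pixel count --
  marked <- matrix(FALSE, dim[1], dim[2])
  realized_cov <- numeric(n_nuclei)
  if (!is.null(marker_coverage)) {
    for (k in seq_len(n_nuclei)) {
      px <- which(lab == k, arr.ind = TRUE)
      nmark <- round(marker_coverage[k] * nrow(px))
      realized_cov[k] <- nmark / nrow(px)
      if (nmark == 0) next
      th <- stats::runif(1, 0, 2 * pi)
      proj <- px[, 1] * cos(th) + px[, 2] * sin(th)
      sel <- order(proj, decreasing = TRUE)[seq_len(nmark)]
      marked[px[sel, , drop = FALSE]] <- TRUE
    }
  }
  diffuse <- matrix(FALSE, dim[1], dim[2])
  if (diffuse_marker_fraction > 0) {
    field <- matrix(stats::rnorm(prod(dim)), dim[1], dim[2])
    field <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(field), sigma = 12)))
    # diffuse signal is extranuclear; pick the quantile so the realized
    # fraction of the whole leaflet equals diffuse_marker_fraction
    cand <- roimask & lab == 0L
    want <- diffuse_marker_fraction * sum(roimask)
    if (want > sum(cand))
      stop("diffuse_marker_fraction too large for the extranuclear area")
    qv <- stats::quantile(field[cand], 1 - want / sum(cand), names = FALSE)
    diffuse <- cand & field > qv
  }

  # --- render channels -------------------------------------------------
  render <- function(im) {
    if (psf_sigma > 0)
      im <- as.matrix(EBImage::imageData(
        EBImage::gblur(EBImage::Image(im), sigma = psf_sigma)))
    if (noise_sd > 0) im <- im + stats::rnorm(length(im), 0, noise_sd)
    matrix(pmin(pmax(round(im), 0), 65535), dim[1], dim[2])
  }
  dapi <- render(800 + 14000 * (lab > 0L))
  # marker baseline structure: extranuclear leaflet tissue carries more
  # nonspecific autofluorescence (1200) than the DNA-dense nucleus
  # interior (400), so the leaflet median separates true stain from
  # unmarked nuclear pixels; outside the leaflet is darker still
  mbase <- matrix(100, dim[1], dim[2])
  mbase[roimask] <- 1200
  mbase[lab > 0L] <- 400
  marker <- render(mbase + 18000 * (marked | diffuse))

  truth <- data.frame(id = seq_len(n_nuclei),
                      x = centers[, 1], y = centers[, 2],
                      radius = radii,
                      area = tabulate(lab[lab > 0L], nbins = n_nuclei),
                      coverage = realized_cov,
                      positive = realized_cov > 0.5,
                      pair = pair_id)
  list(dapi = dapi, marker = marker, roi = roi, truth = truth,
       label_mask = lab)
}
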