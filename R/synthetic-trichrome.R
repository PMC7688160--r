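# Synthetic trichrome sections: leaflet pixels painted with HSL values
# drawn strictly inside each stain-class window, with known per-class
# pixel counts, so classification can be checked by exact recovery.

#' Simulate a trichrome-stained leaflet section with known composition
#'
#' Paints every leaflet-interior pixel by sampling an HSL value uniformly
#' inside its class window shrunk by `hsl_jitter` on each side (so that
#' 8-bit RGB quantisation cannot push a pixel out of its window), then
#' converts to 8-bit RGB. Background pixels inside the leaflet are
#' near-white (L above the 0.93 lightness cut); pixels outside the
#' leaflet are white. Class pixel counts follow `class_fractions` exactly
#' (largest-remainder rounding).
#'
#' @param class_fractions named fractions of non-background leaflet
#'   pixels per stain class; must name classes in `windows` and sum to 1.
#' @param background_fraction fraction of leaflet pixels that are
#'   background.
#' @param windows stain windows (default [stain_windows()]).
#' @param hsl_jitter per-channel half-widths `c(h =, s =, l =)` by which
#'   each window is shrunk before sampling.
#' @param dim image dimensions in pixels.
#' @param roi_polygon leaflet polygon (default: centered ellipse).
#' @param seed integer seed.
#' @return list with `image` (RGB array, 8-bit quantised values in
#'   `[0, 1]`), `roi` (polygon), and `truth` (label matrix using the
#'   [classify_pixels()] coding, per-class `counts` and `fractions`).
#' @export
simulate_trichrome <- function(class_fractions = c(collagen = 0.3, cytoplasm = 0.7),
                               background_fraction = 0,
                               windows = stain_windows(),
                               hsl_jitter = c(h = 8, s = 0.15, l = 0.15),
                               dim = c(256, 256), roi_polygon = NULL,
                               seed = 1) {
  validate_windows(windows)
  stopifnot(abs(sum(class_fractions) - 1) < 1e-9,
            all(class_fractions >= 0),
            background_fraction >= 0, background_fraction < 1)
  if (!all(names(class_fractions) %in% names(windows)))
    stop("class_fractions must name classes present in `windows`")
  set.seed(as.integer(seed))
  # default leaflet: an elongated ellipse, the aspect of a valve cusp
  roi <- roi_polygon %||% default_ellipse_roi(dim, frac = c(0.45, 0.18))
  mask <- polygon_mask(roi, dim)
  idx <- which(mask)
  n_in <- length(idx)
  n_bg <- round(background_fraction * n_in)
  n_fg <- n_in - n_bg

  # exact per-class pixel counts via largest remainder
  raw <- class_fractions * n_fg
  counts <- floor(raw)
  rem <- n_fg - sum(counts)
  if (rem > 0) {
    o <- order(raw - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }

  assign_class <- sample(rep.int(c(seq_along(class_fractions), 0L),
                                 c(counts, n_bg)))
  h <- s <- l <- numeric(n_in)
  for (k in seq_along(class_fractions)) {
    w <- windows[[names(class_fractions)[k]]]
    sel <- assign_class == k
    nk <- sum(sel)
    if (!nk) next
    span <- if (w$wraps) (360 - w$hue[1]) + w$hue[2] else diff(w$hue)
    if (span - 2 * hsl_jitter["h"] <= 0 ||
        diff(w$saturation) - 2 * hsl_jitter["s"] <= 0 ||
        diff(w$lightness) - 2 * hsl_jitter["l"] <= 0)
      stop("hsl_jitter too large: window '", w$name, "' becomes empty")
    h[sel] <- (w$hue[1] + hsl_jitter["h"] +
                 stats::runif(nk) * (span - 2 * hsl_jitter["h"])) %% 360
    s[sel] <- stats::runif(nk, w$saturation[1] + hsl_jitter["s"],
                           w$saturation[2] - hsl_jitter["s"])
    l[sel] <- stats::runif(nk, w$lightness[1] + hsl_jitter["l"],
                           w$lightness[2] - hsl_jitter["l"])
  }
  bg <- assign_class == 0L
  if (any(bg)) {
    h[bg] <- stats::runif(sum(bg), 0, 360)
    s[bg] <- stats::runif(sum(bg), 0, 0.05)
    l[bg] <- stats::runif(sum(bg), 0.95, 0.99)
  }

  img <- array(1, c(dim, 3))  # white outside leaflet
  rgbv <- hsl_to_rgb(h, s, l)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- rgbv[, ch]
    img[, , ch] <- plane
  }
  img <- round(img * 255) / 255  # 8-bit quantisation

  # truth labels use the classify_pixels() coding (window list order)
  win_idx <- match(names(class_fractions), names(windows))
  truth_labels <- matrix(0L, dim[1], dim[2])
  truth_labels[idx] <- ifelse(assign_class == 0L, length(windows) + 1L,
                              win_idx[pmax(assign_class, 1L)])
  list(image = img, roi = roi,
       truth = list(labels = truth_labels, counts = counts,
                    fractions = counts / n_fg,
                    background_fraction = if (n_in) n_bg / n_in else 0))
}
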