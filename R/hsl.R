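# RGB <-> HSL conversion (bi-hexcone definition). grDevices only provides
# HSV, and the stain windows are specified in HSL, so the conversion is
# implemented here and unit-tested against primary colors.

#' Convert an RGB image to HSL
#'
#' Uses the standard bi-hexcone HSL definition: lightness
#' `L = (max + min) / 2`, saturation `S = C / (1 - |2L - 1|)` with chroma
#' `C = max - min` (0 for achromatic pixels), and hue in degrees
#' `[0, 360)`.
#'
#' @param img numeric array `[x, y, 3]` with values in `[0, 1]`, or an
#'   `n x 3` matrix of RGB triples.
#' @return array (or matrix) of the same shape with channels H (degrees),
#'   S and L.
#' @examples
#' rgb_to_hsl(matrix(c(1, 0, 0), 1))  # primary red: H 0, S 1, L 0.5
#' @export
rgb_to_hsl <- function(img) {
  d <- dim(img)
  if (is.null(d) || !(length(d) %in% c(2, 3)))
    stop("img must be an [x, y, 3] array or an n x 3 matrix")
  if (d[length(d)] != 3) stop("img must have exactly 3 color channels")
  m <- if (length(d) == 3) matrix(img, prod(d[1:2]), 3) else as.matrix(img)
  if (min(m) < 0 || max(m) > 1) stop("RGB values must lie in [0, 1]")
  r <- m[, 1]; g <- m[, 2]; b <- m[, 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  ch <- mx - mn
  s <- ifelse(ch == 0, 0, ch / (1 - abs(2 * l - 1)))
  h <- numeric(length(r))
  i <- ch > 0 & mx == r
  h[i] <- 60 * (((g[i] - b[i]) / ch[i]) %% 6)
  i <- ch > 0 & mx == g & mx != r
  h[i] <- 60 * ((b[i] - r[i]) / ch[i] + 2)
  i <- ch > 0 & mx == b & mx != r & mx != g
  h[i] <- 60 * ((r[i] - g[i]) / ch[i] + 4)
  h <- h %% 360
  out <- cbind(h, s, l)
  if (length(d) == 3) dim(out) <- d
  out
}

#' Convert HSL values to RGB
#'
#' Inverse of [rgb_to_hsl()].
#'
#' @param h hue in degrees (wrapped modulo 360).
#' @param s,l saturation and lightness in `[0, 1]`.
#' @return `n x 3` matrix of RGB values in `[0, 1]`.
#' @export
hsl_to_rgb <- function(h, s, l) {
  stopifnot(length(h) == length(s), length(s) == length(l))
  if (min(s) < 0 || max(s) > 1 || min(l) < 0 || max(l) > 1)
    stop("s and l must lie in [0, 1]")
  h <- h %% 360
  ch <- (1 - abs(2 * l - 1)) * s
  hp <- h / 60
  x <- ch * (1 - abs(hp %% 2 - 1))
  sext <- floor(hp) %% 6
  r1 <- ifelse(sext == 0 | sext == 5, ch, ifelse(sext == 1 | sext == 4, x, 0))
  g1 <- ifelse(sext == 1 | sext == 2, ch, ifelse(sext == 0 | sext == 3, x, 0))
  b1 <- ifelse(sext == 3 | sext == 4, ch, ifelse(sext == 2 | sext == 5, x, 0))
  mlow <- l - ch / 2
  cbind(r = r1 + mlow, g = g1 + mlow, b = b1 + mlow)
}
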