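# Stain-class definitions: named HSL windows with wrap-around hue support.

#' Define a stain-class HSL window
#'
#' A pixel class is a box in HSL space. The hue interval may wrap through
#' 0 degrees: `hue = c(250, 25)` means the arc from 250 through 360/0 to
#' 25 degrees, the convention needed for red stains whose hues straddle
#' 0. All interval bounds are inclusive.
#'
#' @param name class name (e.g. `"collagen"`).
#' @param hue length-2 hue interval in degrees; `hue[1] > hue[2]` wraps
#'   through 0.
#' @param saturation,lightness length-2 intervals within `[0, 1]`.
#' @return object of class `hsl_window`.
#' @export
hsl_window <- function(name, hue, saturation = c(0.1, 1), lightness = c(0.1, 0.93)) {
  stopifnot(is.character(name), length(hue) == 2, length(saturation) == 2,
            length(lightness) == 2)
  if (any(hue < 0 | hue >= 360)) stop("hue bounds must lie in [0, 360)")
  if (saturation[1] > saturation[2] || any(saturation < 0 | saturation > 1))
    stop("saturation interval must be ordered within [0, 1]")
  if (lightness[1] > lightness[2] || any(lightness < 0 | lightness > 1))
    stop("lightness interval must be ordered within [0, 1]")
  structure(list(name = name, hue = as.numeric(hue),
                 saturation = as.numeric(saturation),
                 lightness = as.numeric(lightness),
                 wraps = hue[1] > hue[2]),
            class = "hsl_window")
}

#' @export
print.hsl_window <- function(x, ...) {
  cat(sprintf("<hsl_window> %s: H %g-%g%s, S %g-%g, L %g-%g\n", x$name,
              x$hue[1], x$hue[2], if (x$wraps) " (wraps 0)" else "",
              x$saturation[1], x$saturation[2],
              x$lightness[1], x$lightness[2]))
  invisible(x)
}

#' The Masson's trichrome stain windows
#'
#' The two HSL windows used to segment trichrome-stained aortic valve
#' sections: collagen (blue, H 150-250) and cytoplasm/myocardium (red,
#' H 250-25 wrapping through 0), both with S 0.1-1.0 and L 0.1-0.93.
#'
#' @return named list of [hsl_window()] objects.
#' @export
stain_windows <- function() {
  list(collagen  = hsl_window("collagen",  c(150, 250)),
       cytoplasm = hsl_window("cytoplasm", c(250, 25)))
}

# Hue membership with wrap; closed interval.
hue_in_window <- function(h, w) {
  h <- h %% 360
  if (w$wraps) h >= w$hue[1] | h <= w$hue[2] else h >= w$hue[1] & h <= w$hue[2]
}

#' Test HSL values against a window
#' @param h,s,l HSL vectors (hue in degrees).
#' @param window an [hsl_window()].
#' @return logical vector.
#' @export
in_hsl_window <- function(h, s, l, window) {
  hue_in_window(h, window) &
    s >= window$saturation[1] & s <= window$saturation[2] &
    l >= window$lightness[1] & l <= window$lightness[2]
}

# Decompose a window's hue set into non-wrapping arcs on [0, 360].
hue_arcs <- function(w) {
  if (w$wraps) list(c(w$hue[1], 360), c(0, w$hue[2])) else list(w$hue)
}

interval_overlap <- function(a, b) max(0, min(a[2], b[2]) - max(a[1], b[1]))

#' Validate a set of stain windows
#'
#' Rejects pairs of windows whose HSL boxes intersect with positive
#' measure. Windows that merely share a boundary (the trichrome collagen
#' and cytoplasm windows share H = 250 exactly) are allowed; a pixel on a
#' shared bound is assigned to the first matching window in list order.
#'
#' @param windows list of [hsl_window()] objects.
#' @return the validated list, invisibly; errors on overlap.
#' @export
validate_windows <- function(windows) {
  stopifnot(length(windows) >= 1,
            all(vapply(windows, inherits, TRUE, "hsl_window")))
  nm <- vapply(windows, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate window names: ", nm[duplicated(nm)][1])
  n <- length(windows)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      wi <- windows[[i]]; wj <- windows[[j]]
      h_olap <- sum(vapply(hue_arcs(wi), function(a)
        sum(vapply(hue_arcs(wj), function(b) interval_overlap(a, b), 0)), 0))
      if (h_olap > 0 &&
          interval_overlap(wi$saturation, wj$saturation) > 0 &&
          interval_overlap(wi$lightness, wj$lightness) > 0)
        stop(sprintf("stain windows '%s' and '%s' overlap in HSL space",
                     wi$name, wj$name))
    }
  }
  invisible(windows)
}

#' Read stain windows from a YAML file
#'
#' Format: a top-level mapping of class name to `{hue: [lo, hi],
#' saturation: [lo, hi], lightness: [lo, hi]}`.
#'
#' @param path YAML file.
#' @return validated list of [hsl_window()] objects.
#' @export
windows_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  ws <- lapply(names(cfg), function(nm) {
    w <- cfg[[nm]]
    hsl_window(nm, unlist(w$hue),
               unlist(w$saturation %||% c(0.1, 1)),
               unlist(w$lightness %||% c(0.1, 0.93)))
  })
  names(ws) <- names(cfg)
  validate_windows(ws)
  ws
}
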