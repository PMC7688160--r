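# Fixture builders shared across test files.

# A cardiac cycle object built directly from a velocity vector.
make_cycle <- function(v, dt = 5e-4, start = 0) {
  structure(list(start = start, end = start + length(v) * dt,
                 time = start + (seq_along(v) - 1) * dt,
                 velocity = v),
            class = "cardiac_cycle")
}

# Binary mask containing one or two discs (two discs give a touching
# pair when d < r1 + r2).
disc_mask <- function(dim, centers, radii) {
  m <- matrix(FALSE, dim[1], dim[2])
  xy <- cbind(rep(seq_len(dim[1]), dim[2]), rep(seq_len(dim[2]), each = dim[1]))
  for (k in seq_len(nrow(centers))) {
    d2 <- (xy[, 1] - centers[k, 1])^2 + (xy[, 2] - centers[k, 2])^2
    m[xy[d2 <= radii[k]^2, , drop = FALSE]] <- TRUE
  }
  m
}

# Rectangular ROI polygon covering the full image (0-based, pixel
# centers of an w x h image all inside).
full_roi <- function(dim) {
  cbind(x = c(-0.5, dim[1] - 0.5, dim[1] - 0.5, -0.5),
        y = c(-0.5, -0.5, dim[2] - 0.5, dim[2] - 0.5))
}
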