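# In-code fixtures shared across the suite.

# Minimal uniform trace from named channel vectors.
make_trace <- function(n, dt = 0.01, mode = "NM", ...) {
  chans <- list(...)
  df <- tibble::tibble(t = (seq_len(n) - 1) * dt)
  for (nm in names(chans)) df[[nm]] <- chans[[nm]]
  imu_trace(df, dt = dt, mode = mode)
}

# A static_mask with a single hand-chosen segment (for isolating the
# integration stages from the detector).
manual_mask <- function(n, i_start, i_end, dt = 0.01) {
  moving <- rep(FALSE, n)
  moving[i_start:(i_end - 1)] <- TRUE
  structure(list(
    moving = moving,
    segments = tibble::tibble(segment_id = 1L, i_start = as.integer(i_start),
                              i_end = as.integer(i_end),
                              t_start = (i_start - 1) * dt,
                              t_end = (i_end - 1) * dt,
                              duration = (i_end - i_start) * dt),
    thd_used = c(acc_y = 0.15), dt = dt, channels = "acc_y", n = n),
    class = "static_mask")
}

# Independent brute-force 3x3 convolution oracle (explicit loops, replicate
# padding) against which the vectorised kernels are checked.
conv3x3_oracle <- function(img, kernel) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    acc <- 0
    for (dy in -1:1) for (dx in -1:1) {
      yy <- min(max(y + dy, 1), h)
      xx <- min(max(x + dx, 1), w)
      acc <- acc + kernel[dy + 2, dx + 2] * img[yy, xx]
    }
    out[y, x] <- acc
  }
  out
}

# Small textured test image (single channel, 0..255).
texture_image <- function(h, w, seed = 1) {
  set.seed(seed)
  matrix(runif(h * w, 0, 255), h, w)
}
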