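# ROI sharpness indexes and frame down-selection.
#
# Frames are numeric matrices (single channel) or h x w x 3 arrays (RGB) on
# the 0..255 scale; all filtering happens on the red channel. Convolutions
# are exact shifted-matrix sums with replicate padding, so a uniform image
# scores exactly zero under every operator.

#' Acceptance thresholds for the sharpness indexes
#'
#' A frame is accepted when at least one circular ROI scores strictly above
#' the operator's threshold: 1,100,000 (Sobel), 54,000 (Laplacian), 290,000
#' (Canny; an edge map encoded 0/255, so this is ~1,137 edge pixels in a
#' 100-px-diameter ROI). Below these values the frame is taken to have been
#' acquired above 5 cm/s and is too blurred to process.
#'
#' @param sobel,laplacian,canny Positive index thresholds.
#' @return Named list of class `sharpness_thresholds`.
#' @export
sharpness_thresholds <- function(sobel = 1100000, laplacian = 54000,
                                 canny = 290000) {
  if (any(c(sobel, laplacian, canny) <= 0)) abort("Thresholds must be > 0.")
  structure(list(sobel = sobel, laplacian = laplacian, canny = canny),
            class = "sharpness_thresholds")
}

#' Default circular regions of interest
#'
#' Three 100-px-diameter circles on the central horizontal band, centred at
#' 1/4, 1/2 and 3/4 of the image width — where the branch lies in a
#' correctly framed scan.
#'
#' @param width,height Image size in pixels; both must be at least twice the
#'   ROI diameter so the circles fit.
#' @param diameter ROI diameter, pixels.
#' @return Tibble with `roi` (left/center/right), `cx`, `cy`, `diameter`.
#' @examples
#' default_rois(1920, 1080)
#' @export
default_rois <- function(width, height, diameter = 100) {
  if (diameter <= 0) abort("`diameter` must be > 0.")
  if (width < 2 * diameter || height < 2 * diameter) {
    abort(sprintf("Image %dx%d too small for %d-px ROIs (need >= %d in each dimension).",
                  width, height, diameter, 2 * diameter))
  }
  tibble(roi = c("left", "center", "right"),
         cx = c(width / 4, width / 2, 3 * width / 4),
         cy = height / 2,
         diameter = diameter)
}

# --- image helpers ---------------------------------------------------------

#' Load a frame as a 0..255 array
#'
#' @param x A PNG path, a numeric matrix or an RGB array. PNG files (0..1)
#'   are rescaled to 0..255.
#' @return Numeric matrix or h x w x 3 array on the 0..255 scale.
#' @export
load_frame <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) abort(sprintf("Frame '%s' does not exist.", x))
    img <- png::readPNG(x) * 255
    if (length(dim(img)) == 3 && dim(img)[3] >= 3) img <- img[, , 1:3]
    return(img)
  }
  if (!is.numeric(x)) abort("Frame must be a path, a matrix or an array.")
  x
}

#' Red channel of a frame
#'
#' @param img Matrix (returned unchanged) or RGB array.
#' @return Numeric matrix.
#' @export
red_channel <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3) return(img[, , 1])
  abort("`img` must be a matrix or an h x w x 3 array.")
}

# Exact 3x3 convolution with replicate (edge-clamp) padding.
conv3x3 <- function(img, kernel) {
  h <- nrow(img); w <- ncol(img)
  ir <- c(1L, seq_len(h), h)
  ic <- c(1L, seq_len(w), w)
  pad <- img[ir, ic, drop = FALSE]
  out <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    k <- kernel[dy + 1L, dx + 1L]
    if (k != 0) out <- out + k * pad[dy + seq_len(h), dx + seq_len(w), drop = FALSE]
  }
  out
}

KERNEL_SOBEL_X <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
KERNEL_SOBEL_Y <- t(KERNEL_SOBEL_X)
KERNEL_LAPLACIAN <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3, byrow = TRUE)

# Logical mask of a circular ROI; errors if the circle leaves the image.
roi_mask <- function(h, w, roi) {
  r <- roi$diameter[1] / 2
  cx <- roi$cx[1]; cy <- roi$cy[1]
  if (cx - r < 0 || cx + r > w || cy - r < 0 || cy + r > h) {
    abort("ROI circle lies (partly) outside the image.")
  }
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# --- index operators -------------------------------------------------------

#' Sobel sharpness index of one ROI
#'
#' Sum over the ROI pixels of the gradient magnitude
#' `sqrt(Sobel.x^2 + Sobel.y^2)` from the standard 3x3 horizontal and
#' vertical Sobel kernels.
#'
#' @param image Single-channel numeric matrix (red channel, 0..255).
#' @param roi One row of a [default_rois()] tibble (or a list with `cx`,
#'   `cy`, `diameter`).
#' @return Nonnegative scalar index.
#' @export
sobel_index <- function(image, roi) {
  stopifnot(is.matrix(image))
  sx <- conv3x3(image, KERNEL_SOBEL_X)
  sy <- conv3x3(image, KERNEL_SOBEL_Y)
  m <- roi_mask(nrow(image), ncol(image), roi)
  sum(sqrt(sx[m]^2 + sy[m]^2))
}

#' Laplacian sharpness index of one ROI
#'
#' Sum over the ROI of the absolute 3x3 Laplacian response. Zero on uniform
#' images and on linear intensity ramps (away from borders).
#'
#' @inheritParams sobel_index
#' @return Nonnegative scalar index.
#' @export
laplacian_index <- function(image, roi) {
  stopifnot(is.matrix(image))
  lp <- conv3x3(image, KERNEL_LAPLACIAN)
  m <- roi_mask(nrow(image), ncol(image), roi)
  sum(abs(lp[m]))
}

#' Canny edge map of a full image
#'
#' Sobel gradients, four-direction non-maximum suppression and hysteresis
#' with limits adapted to the image: lower limit one standard deviation of
#' the complete single-channel image, upper limit three standard deviations,
#' both applied to the gradient magnitude. The returned map is 0/255. A
#' constant image (sd 0) yields an all-zero map.
#'
#' @param image Single-channel numeric matrix.
#' @return Matrix of 0/255 values, same size as `image`.
#' @export
canny_edge_map <- function(image) {
  stopifnot(is.matrix(image))
  sigma <- stats::sd(image)
  if (!is.finite(sigma) || sigma == 0) return(matrix(0, nrow(image), ncol(image)))
  sx <- conv3x3(image, KERNEL_SOBEL_X)
  sy <- conv3x3(image, KERNEL_SOBEL_Y)
  mag <- sqrt(sx^2 + sy^2)
  h <- nrow(image); w <- ncol(image)

  # quantize gradient direction into 4 sectors and suppress non-maxima
  ang <- atan2(sy, sx) * 180 / pi
  ang <- ang %% 180
  sector <- integer(length(ang))
  sector[(ang >= 22.5 & ang < 67.5)] <- 1L    # diagonal /
  sector[(ang >= 67.5 & ang < 112.5)] <- 2L   # vertical gradient
  sector[(ang >= 112.5 & ang < 157.5)] <- 3L  # diagonal \
  dim(sector) <- dim(mag)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mag
  shift <- function(dy, dx) pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  n1 <- matrix(0, h, w); n2 <- n1
  for (s in 0:3) {
    idx <- sector == s
    off <- switch(as.character(s),
                  "0" = c(0L, 1L),   # gradient along x: compare left/right
                  "1" = c(1L, 1L),
                  "2" = c(1L, 0L),   # gradient along y: compare up/down
                  "3" = c(1L, -1L))
    n1[idx] <- shift(off[1], off[2])[idx]
    n2[idx] <- shift(-off[1], -off[2])[idx]
  }
  keep <- mag >= n1 & mag >= n2
  nms <- ifelse(keep, mag, 0)

  lo <- sigma; hi <- 3 * sigma
  strong <- nms > hi
  weak <- nms > lo
  if (!any(strong)) return(matrix(0, h, w))
  labels <- EBImage::bwlabel(weak)
  keep_ids <- unique(labels[strong])
  keep_ids <- keep_ids[keep_ids > 0]
  edge <- matrix(0, h, w)
  edge[labels %in% keep_ids] <- 255
  edge
}

#' Canny sharpness index of one ROI
#'
#' Sum of the 0/255 Canny edge map over the ROI, i.e. 255 times the edge
#' pixel count inside the circle.
#'
#' @inheritParams sobel_index
#' @return Nonnegative scalar index.
#' @export
canny_index <- function(image, roi) {
  stopifnot(is.matrix(image))
  edge <- canny_edge_map(image)
  m <- roi_mask(nrow(image), ncol(image), roi)
  sum(edge[m])
}

# --- per-frame scoring and selection ---------------------------------------

#' Score the sharpness indexes of one frame
#'
#' Computes the requested operators once over the red channel and evaluates
#' each ROI, returning one row per ROI.
#'
#' @param frame Path, matrix or RGB array (see [load_frame()]).
#' @param rois ROI tibble; defaults to [default_rois()] for the frame size.
#' @param operators Subset of `c("sobel", "laplacian", "canny")`.
#' @return Tibble with `roi` and one `idx_<operator>` column per operator.
#' @export
frame_sharpness <- function(frame, rois = NULL,
                            operators = c("sobel", "laplacian", "canny")) {
  operators <- match.arg(operators, several.ok = TRUE)
  img <- red_channel(load_frame(frame))
  h <- nrow(img); w <- ncol(img)
  rois <- rois %||% default_rois(w, h)
  fields <- list()
  if ("sobel" %in% operators || "canny" %in% operators) {
    sx <- conv3x3(img, KERNEL_SOBEL_X)
    sy <- conv3x3(img, KERNEL_SOBEL_Y)
    mag <- sqrt(sx^2 + sy^2)
  }
  if ("sobel" %in% operators) fields$idx_sobel <- mag
  if ("laplacian" %in% operators) {
    fields$idx_laplacian <- abs(conv3x3(img, KERNEL_LAPLACIAN))
  }
  if ("canny" %in% operators) fields$idx_canny <- canny_edge_map(img)
  out <- purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    m <- roi_mask(h, w, rois[i, ])
    vals <- purrr::map_dbl(fields, ~ sum(.x[m]))
    dplyr::bind_cols(tibble(roi = rois$roi[i]), as_tibble(as.list(vals)))
  })
  out
}

#' Frame acceptance decision
#'
#' A frame is accepted when the chosen operator's index is strictly above
#' its threshold in at least one ROI.
#'
#' @param indexes Numeric vector of per-ROI index values for `operator`.
#' @param thresholds A [sharpness_thresholds()].
#' @param operator `"sobel"`, `"laplacian"` or `"canny"`.
#' @return Logical scalar.
#' @examples
#' accept_frame(c(1.2e6, 3e5, 2e5), sharpness_thresholds(), "sobel")
#' @export
accept_frame <- function(indexes, thresholds = sharpness_thresholds(),
                         operator = c("laplacian", "sobel", "canny")) {
  operator <- match.arg(operator)
  thr <- thresholds[[operator]]
  if (is.null(thr)) abort(sprintf("Unknown operator '%s'.", operator))
  any(indexes > thr)
}

#' Select sharp frames from a trimmed scan
#'
#' Quality control first: the beginning, middle and end frames of the
#' trimmed range are scored, and if none of the three is accepted the whole
#' video is flagged for re-acquisition. Otherwise every frame is scored, the
#' accepted ones are uniformly subsampled down to the retention fraction
#' (nearest-integer count), and the selection is returned. With the nominal
#' 450-frame, all-sharp scan of a 50 cm branch and the default retention of
#' 0.2 this keeps 90 frames.
#'
#' @param frames List of frames (paths, matrices or arrays); the trimmed
#'   range of the video, in order.
#' @param thresholds A [sharpness_thresholds()].
#' @param operator Operator used for the decision (default `"laplacian"`,
#'   the cheapest kernel; the three operators discriminate equally well).
#' @param retention Fraction of accepted frames to keep (default 0.2).
#' @param rois Optional ROI tibble shared by all frames.
#' @param frame_offset Integer id of the first frame (e.g. `frame_start`
#'   from [map_to_frames()]), so reported ids index the original video.
#' @return A `frame_selection`: list with `scores` (per frame: `frame_id`,
#'   max per-ROI index, `accepted`), `selected` (integer frame ids),
#'   `reacquire` flag, `operator`, `retention`.
#' @export
select_frames <- function(frames, thresholds = sharpness_thresholds(),
                          operator = c("laplacian", "sobel", "canny"),
                          retention = 0.2, rois = NULL, frame_offset = 0L) {
  operator <- match.arg(operator)
  n <- length(frames)
  if (n == 0) abort("Empty frame range.")
  if (retention <= 0 || retention > 1) abort("`retention` must be in (0, 1].")
  idx_col <- paste0("idx_", operator)
  score_one <- function(fr) {
    sc <- frame_sharpness(fr, rois = rois, operators = operator)
    max(sc[[idx_col]])
  }
  frame_ids <- frame_offset + seq_len(n) - 1L

  qc <- unique(c(1L, as.integer(ceiling(n / 2)), n))
  qc_ok <- purrr::map_lgl(qc, function(i) {
    sc <- frame_sharpness(frames[[i]], rois = rois, operators = operator)
    accept_frame(sc[[idx_col]], thresholds, operator)
  })
  if (!any(qc_ok)) {
    return(structure(list(
      scores = tibble(frame_id = frame_ids[qc], index = NA_real_,
                      accepted = FALSE),
      selected = integer(0), reacquire = TRUE,
      operator = operator, retention = retention),
      class = "frame_selection"))
  }

  max_idx <- purrr::map_dbl(frames, score_one)
  accepted <- max_idx > thresholds[[operator]]
  acc_pos <- which(accepted)
  k <- round(length(acc_pos) * retention)
  selected <- if (k >= 1) {
    acc_pos[unique(round(seq(1, length(acc_pos), length.out = k)))]
  } else integer(0)
  structure(list(
    scores = tibble(frame_id = frame_ids, index = max_idx, accepted = accepted),
    selected = frame_ids[selected], reacquire = FALSE,
    operator = operator, retention = retention),
    class = "frame_selection")
}

#' @export
print.frame_selection <- function(x, ...) {
  if (x$reacquire) {
    cat("<frame_selection> all QC frames blurred -> re-acquisition advised\n")
  } else {
    cat(sprintf("<frame_selection> %d/%d frames accepted (%s), %d selected at retention %.2f\n",
                sum(x$scores$accepted), nrow(x$scores), x$operator,
                length(x$selected), x$retention))
  }
  invisible(x)
}

#' @rdname select_frames
#' @param x A `frame_selection`.
#' @param ... Unused.
#' @export
tidy.frame_selection <- function(x, ...) {
  dplyr::mutate(x$scores, selected = .data$frame_id %in% x$selected)
}

#' Plot per-frame sharpness scores
#'
#' @param object A `frame_selection`.
#' @param ... Unused.
#' @return A ggplot of the per-frame index with accepted/selected marks.
#' @export
autoplot.frame_selection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame_id, y = .data$index)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$accepted,
                                     shape = .data$selected)) +
    ggplot2::labs(x = "frame", y = sprintf("max ROI %s index", object$operator),
                  title = "Frame sharpness and selection")
}
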