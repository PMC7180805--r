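#' @title Gaze-weighted multi-frame image representation
#'
#' @description
#' A gaze recording (timestamped samples of gazed pixel locations with
#' dwell durations) is binned into `d4` equal-length time frames. Each
#' frame yields a fixation map: duration-weighted votes at gazed pixels,
#' smoothed with an isotropic Gaussian and floored at a small positive
#' `epsilon`. The per-frame gaze-and-image weight (GIW) matrices are
#'
#'   W_f = d4 * Wgaze_f / sum_f Wgaze_f + 1
#'
#' so that at every pixel the weights sum to `2 * d4` across frames. The
#' representation is the fourth-order tensor whose frame-`f`, channel-`c`
#' slice is the Hadamard product of image channel `c` with `W_f`; averaging
#' its frames and dividing by `2 * d4` reconstructs the image exactly.
#'
#' Coordinates are 0-based with the origin at the top-left pixel; `x` is
#' the column, `y` the row.
#'
#' @name gaze-representation
NULL

#' Construct a gaze recording
#'
#' @param x,y Gazed pixel coordinates (0-based; `x` = column, `y` = row).
#' @param onset Sample onset times in seconds, non-decreasing.
#' @param duration Dwell durations in seconds, strictly positive.
#' @param subject_id,image_id Identifiers.
#' @return A `gaze_recording`: a data frame of samples with identifier
#'   attributes.
#' @export
gaze_recording <- function(x, y, onset, duration,
                           subject_id = "s1", image_id = "img1") {
  n <- length(x)
  if (n == 0L) stop("gaze recording must contain at least one sample", call. = FALSE)
  if (length(y) != n || length(onset) != n || length(duration) != n) {
    stop("x, y, onset, duration must have equal length", call. = FALSE)
  }
  if (is.unsorted(onset)) stop("onsets must be non-decreasing", call. = FALSE)
  if (any(duration <= 0)) stop("durations must be positive", call. = FALSE)
  rec <- data.frame(x = as.numeric(x), y = as.numeric(y),
                    onset = as.numeric(onset), duration = as.numeric(duration))
  attr(rec, "subject_id") <- subject_id
  attr(rec, "image_id") <- image_id
  class(rec) <- c("gaze_recording", "data.frame")
  rec
}

#' Bin gaze samples into equal-length time frames
#'
#' The span from the first onset to the last onset plus its duration is
#' split into `d4` half-open bins; each sample goes to the bin containing
#' its midpoint `onset + duration / 2` (a midpoint exactly on a boundary
#' goes to the later bin). Samples are never split across bins.
#'
#' @param rec A [gaze_recording()].
#' @param d4 Number of frames, `>= 1`.
#' @return A list of `d4` data frames of samples (possibly empty).
#' @export
bin_gaze_to_frames <- function(rec, d4) {
  if (nrow(rec) == 0L) stop("empty gaze recording", call. = FALSE)
  d4 <- as.integer(d4)
  if (d4 < 1L) stop("`d4` must be >= 1", call. = FALSE)
  t0 <- rec$onset[1L]
  t1 <- max(rec$onset + rec$duration)
  mid <- rec$onset + rec$duration / 2
  if (t1 <= t0) {
    idx <- rep(1L, nrow(rec))
  } else {
    breaks <- seq(t0, t1, length.out = d4 + 1L)
    idx <- findInterval(mid, breaks) # boundary value -> later bin
    idx <- pmin(pmax(idx, 1L), d4)
  }
  lapply(seq_len(d4), function(f) rec[idx == f, , drop = FALSE])
}

# Separable Gaussian smoothing with half-sample symmetric (reflect)
# padding; reflection folds the kernel back at the border so total mass
# is conserved exactly.
gaussian_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  smooth_vec <- function(v) {
    n <- length(v)
    pad_lo <- v[pmin(r:1, n)]
    pad_hi <- v[pmax(n - seq_len(r) + 1L, 1L)]
    padded <- c(pad_lo, v, pad_hi)
    stats::convolve(padded, k, type = "filter")
  }
  m <- apply(m, 2L, smooth_vec)
  t(apply(m, 1L, smooth_vec))
}

#' Build per-frame fixation maps
#'
#' Each sample votes its dwell duration (or a unit count, see `weight`)
#' into its nearest pixel; the vote image is smoothed with an isotropic
#' Gaussian (reflect boundary, mass-preserving) and a positivity floor
#' `epsilon` is added everywhere so the downstream GIW normalization is
#' well defined at never-gazed pixels.
#'
#' @param bins List of per-frame sample data frames from
#'   [bin_gaze_to_frames()].
#' @param shape Image shape `c(d1, d2)` = (rows, columns).
#' @param sigma Gaussian kernel width in pixels; `"auto"` uses 2% of the
#'   image diagonal (roughly the foveal spread).
#' @param epsilon Positivity floor added to every pixel, `> 0`.
#' @param weight `"duration"` (default) weights votes by dwell time;
#'   `"count"` gives every sample unit weight.
#' @return A `fixation_map_stack`: list with `maps` (list of `d1 x d2`
#'   strictly positive matrices), `sigma`, `epsilon`.
#' @export
build_fixation_maps <- function(bins, shape, sigma = "auto", epsilon = 1e-6,
                                weight = c("duration", "count")) {
  weight <- match.arg(weight)
  d1 <- as.integer(shape[1L]); d2 <- as.integer(shape[2L])
  if (identical(sigma, "auto")) sigma <- 0.02 * sqrt(d1^2 + d2^2)
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  maps <- lapply(bins, function(b) {
    votes <- matrix(0, d1, d2)
    if (nrow(b) > 0L) {
      # nearest pixel of 0-based coordinates, clamped to the image
      col <- pmin(pmax(round(b$x), 0), d2 - 1L) + 1L
      row <- pmin(pmax(round(b$y), 0), d1 - 1L) + 1L
      w <- if (weight == "duration") b$duration else rep(1, nrow(b))
      for (i in seq_len(nrow(b))) {
        votes[row[i], col[i]] <- votes[row[i], col[i]] + w[i]
      }
      votes <- gaussian_smooth(votes, sigma)
    }
    votes + epsilon
  })
  structure(list(maps = maps, sigma = sigma, epsilon = epsilon),
            class = "fixation_map_stack")
}

#' Gaze-and-image weight (GIW) matrices
#'
#' Normalizes a stack of strictly positive fixation maps into per-frame
#' pixel weights `W_f = d4 * Wgaze_f / sum_f Wgaze_f + 1`. At every pixel
#' the weights sum to `2 * d4` across frames, and the result is invariant
#' to positive rescaling of the fixation stack.
#'
#' @param fix A `fixation_map_stack` from [build_fixation_maps()].
#' @return A `giw_stack`: list with `weights` (list of `d1 x d2`
#'   matrices) and `d4`.
#' @export
compute_giw <- function(fix) {
  maps <- fix$maps
  d4 <- length(maps)
  denom <- Reduce(`+`, maps)
  if (any(denom <= 0)) {
    stop("fixation maps must be strictly positive at every pixel", call. = FALSE)
  }
  weights <- lapply(maps, function(m) d4 * m / denom + 1)
  structure(list(weights = weights, d4 = d4), class = "giw_stack")
}

#' Build the fourth-order gaze-weighted image representation
#'
#' Frame `f`, channel `c` of the output is the Hadamard product of image
#' channel `c` with the GIW matrix `W_f`.
#'
#' @param image Numeric `d1 x d2 x 3` array with values typically in
#'   `[0, 1]`.
#' @param giw A `giw_stack` from [compute_giw()].
#' @param image_id Identifier carried along for bookkeeping.
#' @return A `gaze_image_representation`: list with `tensor`
#'   (`d1 x d2 x 3 x d4` array), `d4`, `image_id`.
#' @export
build_representation <- function(image, giw, image_id = "img1") {
  if (!is.array(image) || length(dim(image)) != 3L) {
    stop("`image` must be a d1 x d2 x channels array", call. = FALSE)
  }
  d <- dim(image)
  d4 <- giw$d4
  if (!all(vapply(giw$weights, function(w) identical(dim(w), d[1:2]), logical(1)))) {
    stop("GIW matrices and image shape differ", call. = FALSE)
  }
  tensor <- array(0, c(d, d4))
  for (f in seq_len(d4)) {
    for (ch in seq_len(d[3L])) {
      tensor[, , ch, f] <- image[, , ch] * giw$weights[[f]]
    }
  }
  structure(list(tensor = tensor, d4 = d4, image_id = image_id),
            class = "gaze_image_representation")
}

#' Reconstruct the source image from its gaze-weighted representation
#'
#' Returns `1 / (2 * d4) * sum_f frame_f`, which equals the source image
#' whenever the representation was built from a GIW stack (the per-pixel
#' frame weights sum to `2 * d4`).
#'
#' @param rep A `gaze_image_representation`.
#' @return A `d1 x d2 x 3` array.
#' @export
reconstruct_image <- function(rep) {
  d <- dim(rep$tensor)
  out <- array(0, d[1:3])
  for (f in seq_len(d[4L])) out <- out + rep$tensor[, , , f]
  out / (2 * d[4L])
}

#' Bilinearly resize an image and rescale gaze coordinates
#'
#' Used when raw images are larger than the working resolution; gaze
#' coordinates must be rescaled with the same factors.
#'
#' @param image `d1 x d2 x ch` array.
#' @param shape Target `c(d1, d2)`.
#' @return Resized array.
#' @export
resize_image <- function(image, shape) {
  d <- dim(image)
  if (d[1L] == shape[1L] && d[2L] == shape[2L]) return(image)
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("resizing requires the EBImage package", call. = FALSE)
  }
  out <- EBImage::resize(EBImage::Image(image, colormode = "Color"),
                         w = shape[1L], h = shape[2L], filter = "bilinear")
  array(EBImage::imageData(out), c(shape[1L], shape[2L], d[3L]))
}
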