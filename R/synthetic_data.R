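#' @title Synthetic scenes, scanpaths and planted-structure tensors
#'
#' @description
#' Generators that emulate the study setting end to end without
#' human-subject data: images with localized "objects" (soft blobs on a
#' noisy background), class-dependent time-varying scanpaths (a
#' two-attractor dwell/jitter process: class 0 dwells on one object
#' throughout, class 1 shifts its attention to a second object partway
#' through viewing), multi-hot labels, and — separately — tensors with
#' planted discriminant structure for exercising GTDA and LTR in
#' isolation. All generators are pure functions of their seeds.
#'
#' @name synthetic-data
NULL

#' Default scene specification
#'
#' Scenes emulate a controlled fixed-layout stimulus: the two objects
#' that serve as scanpath attractors sit at canonical positions
#' (`anchor_a`, `anchor_b`, as row/column fractions of the image) with
#' small positional jitter, so the class-dependent attention shift is
#' spatially consistent across images; any additional distractor blob
#' is placed uniformly at random. Radii and per-channel intensities are
#' random per blob.
#'
#' @param d1,d2 Image rows and columns in pixels.
#' @param n_blobs_range Range of object counts per image (the first two
#'   are the attractors).
#' @param radius_range Blob radius range in pixels.
#' @param noise_sd Background Gaussian noise standard deviation.
#' @param anchor_a,anchor_b Canonical (row, col) positions of the two
#'   attractor objects, as fractions of the image sides.
#' @param anchor_jitter Positional jitter of the anchored objects, as a
#'   fraction of the image sides.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(d1 = 32L, d2 = 32L, n_blobs_range = c(2L, 3L),
                       radius_range = c(3, 6), noise_sd = 0.05,
                       anchor_a = c(0.3, 0.3), anchor_b = c(0.7, 0.7),
                       anchor_jitter = 0.04) {
  list(d1 = as.integer(d1), d2 = as.integer(d2),
       n_blobs_range = as.integer(n_blobs_range),
       radius_range = radius_range, noise_sd = noise_sd,
       anchor_a = anchor_a, anchor_b = anchor_b,
       anchor_jitter = anchor_jitter)
}

#' Default scanpath specification
#'
#' @param sample_rate_hz Gaze sample rate.
#' @param total_s Viewing time in seconds.
#' @param jitter_sd Saccade jitter standard deviation in pixels.
#' @param switch_frac For class 1, the fraction of the viewing time
#'   after which attention shifts from the first to the second object.
#' @return A `scanpath_spec` list.
#' @export
scanpath_spec <- function(sample_rate_hz = 60, total_s = 2,
                          jitter_sd = 2, switch_frac = 0.5) {
  list(sample_rate_hz = sample_rate_hz, total_s = total_s,
       jitter_sd = jitter_sd, switch_frac = switch_frac)
}

#' Generate synthetic images with localized objects
#'
#' Each image is a noisy gray background plus 2-3 soft radial blobs
#' with random centers, radii and per-channel intensities; values are
#' clamped to `[0, 1]`.
#'
#' @param n Number of images.
#' @param spec A [scene_spec()].
#' @param seed Integer seed; the output is bit-reproducible.
#' @return List with `images` (list of `d1 x d2 x 3` arrays) and
#'   `scenes` (per-image blob records: `centers` matrix (row, col),
#'   `radii`, `intensities`).
#' @export
gen_images <- function(n, spec = scene_spec(), seed = 1L) {
  set.seed(seed)
  d1 <- spec$d1; d2 <- spec$d2
  rows <- matrix(rep(seq_len(d1), d2), d1, d2)
  cols <- matrix(rep(seq_len(d2), each = d1), d1, d2)
  images <- vector("list", n)
  scenes <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- sample(seq(spec$n_blobs_range[1L], spec$n_blobs_range[2L]), 1L)
    anchors <- rbind(spec$anchor_a, spec$anchor_b)[seq_len(min(nb, 2L)), , drop = FALSE]
    centers <- cbind(
      row = c(anchors[, 1L] + stats::rnorm(nrow(anchors), sd = spec$anchor_jitter),
              stats::runif(max(nb - 2L, 0L), 0.15, 0.85)) * d1,
      col = c(anchors[, 2L] + stats::rnorm(nrow(anchors), sd = spec$anchor_jitter),
              stats::runif(max(nb - 2L, 0L), 0.15, 0.85)) * d2)
    radii <- stats::runif(nb, spec$radius_range[1L], spec$radius_range[2L])
    intens <- matrix(stats::runif(nb * 3L, 0.3, 0.7), nb, 3L)
    img <- array(0.3, c(d1, d2, 3L))
    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(d1 * d2 * 3L, sd = spec$noise_sd),
                         c(d1, d2, 3L))
    }
    for (b in seq_len(nb)) {
      bump <- exp(-((rows - centers[b, 1L])^2 + (cols - centers[b, 2L])^2) /
                    (2 * radii[b]^2))
      for (ch in 1:3) img[, , ch] <- img[, , ch] + intens[b, ch] * bump
    }
    images[[i]] <- pmin(pmax(img, 0), 1)
    scenes[[i]] <- list(centers = centers, radii = radii, intensities = intens)
  }
  list(images = images, scenes = scenes)
}

#' Generate a class-dependent synthetic scanpath
#'
#' Class 0 dwells on the first object for the whole viewing time; class
#' 1 dwells on the first object early and shifts to the second object
#' after `switch_frac` of the viewing time. Samples jitter around the
#' current attractor with Gaussian noise and are clamped to the image.
#'
#' @param scene A scene record from [gen_images()].
#' @param class_label 0 or 1.
#' @param spec A [scanpath_spec()].
#' @param shape Image shape `c(d1, d2)` for clamping.
#' @param seed Integer seed.
#' @param subject_id,image_id Identifiers for the recording.
#' @return A [gaze_recording()].
#' @export
gen_gaze <- function(scene, class_label, spec = scanpath_spec(),
                     shape = c(32L, 32L), seed = 1L,
                     subject_id = "s1", image_id = "img1") {
  set.seed(seed)
  m <- max(1L, round(spec$sample_rate_hz * spec$total_s))
  dt <- spec$total_s / m
  onset <- (seq_len(m) - 1L) * dt
  a <- scene$centers[1L, ]
  b <- if (nrow(scene$centers) >= 2L) {
    scene$centers[2L, ]
  } else {
    c(shape[1L], shape[2L]) - a   # mirror through the image center
  }
  late <- class_label == 1L & onset >= spec$switch_frac * spec$total_s
  att_row <- ifelse(late, b[1L], a[1L])
  att_col <- ifelse(late, b[2L], a[2L])
  y <- att_row - 1 + stats::rnorm(m, sd = spec$jitter_sd)
  x <- att_col - 1 + stats::rnorm(m, sd = spec$jitter_sd)
  gaze_recording(x = pmin(pmax(x, 0), shape[2L] - 1),
                 y = pmin(pmax(y, 0), shape[1L] - 1),
                 onset = onset, duration = rep(dt, m),
                 subject_id = subject_id, image_id = image_id)
}

#' Generate a complete synthetic dataset
#'
#' Produces images, balanced binary labels for one synthetic category,
#' and one scanpath per image whose dynamics depend on the label. With
#' `out_dir` set, also writes `images/*.png`, `gaze.csv`
#' (`subject_id,image_id,x,y,onset_s,duration_s`) and `labels.csv`
#' (`image_id,category,label`) — the formats the rest of the pipeline
#' consumes.
#'
#' @param n_images Number of images.
#' @param class_balance Fraction of class-1 images.
#' @param scene A [scene_spec()]; `scan` a [scanpath_spec()].
#' @param scan Scanpath specification.
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @param category Category name written to the label file.
#' @param subject_id Subject identifier for the recordings.
#' @return List with `images`, `scenes`, `gaze` (list of recordings),
#'   `labels` (data frame `image_id, category, label`), `image_ids`.
#' @export
gen_dataset <- function(n_images = 200L, class_balance = 0.5,
                        scene = scene_spec(), scan = scanpath_spec(),
                        seed = 1L, out_dir = NULL,
                        category = "synthetic", subject_id = "s1") {
  imgs <- gen_images(n_images, scene, seed = seed)
  set.seed(seed + 1L)
  n1 <- round(n_images * class_balance)
  labels <- sample(c(rep(1L, n1), rep(0L, n_images - n1)))
  ids <- sprintf("img%04d", seq_len(n_images))
  gaze <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    gaze[[i]] <- gen_gaze(imgs$scenes[[i]], labels[i], scan,
                          shape = c(scene$d1, scene$d2),
                          seed = seed + 1000L + i,
                          subject_id = subject_id, image_id = ids[i])
  }
  label_df <- data.frame(image_id = ids, category = category, label = labels,
                         stringsAsFactors = FALSE)
  out <- list(images = imgs$images, scenes = imgs$scenes, gaze = gaze,
              labels = label_df, image_ids = ids)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_images)) {
      png::writePNG(imgs$images[[i]],
                    file.path(out_dir, "images", paste0(ids[i], ".png")))
    }
    write_gaze_csv(gaze, file.path(out_dir, "gaze.csv"))
    utils::write.csv(label_df, file.path(out_dir, "labels.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(out)
}

#' Generate tensors with planted discriminant structure
#'
#' Two modes. `"gtda"`: i.i.d. Gaussian tensors whose class-1 mean is
#' shifted by `effect * (u o e1 o e1)` for a random unit vector `u`
#' along mode 1 — ground truth for projection-recovery tests. `"ltr"`:
#' standard-normal tensors labeled from the logistic model
#' `Pr(y=1) = sigmoid(<Z, V> / noise_sd)` for a sparse coefficient
#' tensor `Z` with `sparsity` fraction of entries equal to +-1
#' (`noise_sd = 0` makes labels deterministic in the sign of the
#' logit).
#'
#' @param n Number of tensors.
#' @param dims Tensor dimensions (length 3).
#' @param effect Mean-shift magnitude (gtda mode).
#' @param noise_sd Noise level; see above for its role per mode.
#' @param sparsity Fraction of nonzero coefficients (ltr mode).
#' @param seed Integer seed.
#' @param mode `"gtda"` or `"ltr"`.
#' @return List with `tensors`, `labels`, and the planted truth (`u`
#'   for gtda; `z` for ltr).
#' @export
gen_planted_cft <- function(n, dims = c(4L, 3L, 5L), effect = 1,
                            noise_sd = 0.1, sparsity = 0.05, seed = 1L,
                            mode = c("gtda", "ltr")) {
  mode <- match.arg(mode)
  set.seed(seed)
  dims <- as.integer(dims)
  p <- prod(dims)
  if (mode == "gtda") {
    u <- stats::rnorm(dims[1L]); u <- u / sqrt(sum(u^2))
    shift <- array(0, dims)
    shift[, 1L, 1L] <- effect * u
    labels <- rep(c(0L, 1L), length.out = n)
    tensors <- lapply(seq_len(n), function(i) {
      array(stats::rnorm(p, sd = noise_sd), dims) +
        if (labels[i] == 1L) shift else 0
    })
    list(tensors = tensors, labels = labels, u = u)
  } else {
    nnz <- max(1L, round(sparsity * p))
    z <- numeric(p)
    z[sample(p, nnz)] <- sample(c(-1, 1), nnz, replace = TRUE)
    tensors <- lapply(seq_len(n), function(i) array(stats::rnorm(p), dims))
    logits <- vapply(tensors, function(v) sum(as.numeric(v) * z), numeric(1))
    labels <- if (noise_sd == 0) {
      as.integer(logits > 0)
    } else {
      stats::rbinom(n, 1L, sigmoid(logits / noise_sd))
    }
    list(tensors = tensors, labels = labels, z = array(z, dims))
  }
}
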