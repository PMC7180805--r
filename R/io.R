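#' @title File formats and artifact persistence
#'
#' @description
#' Tabular interchange formats: a gaze CSV with header
#' `subject_id,image_id,x,y,onset_s,duration_s` (0-based pixel
#' coordinates, seconds) and a labels CSV with header
#' `image_id,category,label` (label in 0/1). Images are PNG. Fitted
#' artifacts (projections, models, manifests) are persisted with base R
#' serialization alongside the configuration hash that produced them.
#'
#' @name io
NULL

#' Write gaze recordings to CSV
#'
#' @param gaze List of [gaze_recording()]s.
#' @param path Output file.
#' @export
write_gaze_csv <- function(gaze, path) {
  rows <- lapply(gaze, function(g) {
    data.frame(subject_id = attr(g, "subject_id"),
               image_id = attr(g, "image_id"),
               x = g$x, y = g$y, onset_s = g$onset, duration_s = g$duration,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gaze recordings from CSV
#'
#' @param path Gaze CSV with header
#'   `subject_id,image_id,x,y,onset_s,duration_s`.
#' @return List of [gaze_recording()]s, one per (subject, image) pair,
#'   in file order of first appearance.
#' @export
read_gaze_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "image_id", "x", "y", "onset_s", "duration_s")
  if (!all(need %in% names(df))) {
    stop(sprintf("gaze CSV must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  key <- paste(df$subject_id, df$image_id, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    gaze_recording(g$x, g$y, g$onset_s, g$duration_s,
                   subject_id = g$subject_id[1L], image_id = g$image_id[1L])
  })
}

#' Read a labels CSV
#'
#' @param path Labels CSV with header `image_id,category,label`.
#' @return Data frame with those columns, label coerced to integer.
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "category", "label")
  if (!all(need %in% names(df))) {
    stop("labels CSV must have columns image_id, category, label", call. = FALSE)
  }
  df$label <- as.integer(df$label)
  if (!all(df$label %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  df
}

#' Read a directory of PNG images
#'
#' @param dir Directory containing `<image_id>.png` files.
#' @param ids Optional image ids to read, in order; defaults to all,
#'   sorted.
#' @return Named list of `d1 x d2 x 3` arrays.
#' @export
read_images_dir <- function(dir, ids = NULL) {
  if (is.null(ids)) {
    ids <- sort(sub("\\.png$", "", list.files(dir, pattern = "\\.png$")))
  }
  out <- lapply(ids, function(id) {
    img <- png::readPNG(file.path(dir, paste0(id, ".png")))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    img[, , 1:3, drop = FALSE]
  })
  names(out) <- ids
  out
}

#' Hash a configuration list
#'
#' MD5 of the canonical JSON serialization; used to stamp artifacts so
#' that evaluation can detect config/artifact mismatches.
#'
#' @param config A list of plain values.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Save / load a pipeline artifact
#'
#' Artifacts carry the hash of the producing configuration; `load`
#' optionally verifies it.
#'
#' @param object Any R object.
#' @param path Destination file.
#' @param config Configuration list stamped into the artifact.
#' @export
save_artifact <- function(object, path, config = NULL) {
  saveRDS(list(object = object,
               config_hash = if (!is.null(config)) config_hash(config),
               package_version = as.character(utils::packageVersion("gazecft"))),
          path)
  invisible(path)
}

#' @rdname save_artifact
#' @param expected_hash If non-NULL, error unless the stored hash matches.
#' @export
load_artifact <- function(path, expected_hash = NULL) {
  if (!file.exists(path)) stop(sprintf("artifact not found: %s", path), call. = FALSE)
  art <- readRDS(path)
  if (!is.null(expected_hash) && !identical(art$config_hash, expected_hash)) {
    stop(sprintf("artifact %s was produced under a different configuration", path),
         call. = FALSE)
  }
  art$object
}

#' Write predictions to CSV
#'
#' @param pred Data frame with columns `image_id, category, subject_id,
#'   probability, label`.
#' @param path Output file.
#' @export
write_predictions_csv <- function(pred, path) {
  pred$probability <- sprintf("%.12g", pred$probability)
  utils::write.csv(pred, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
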