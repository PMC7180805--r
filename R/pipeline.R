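#' @title End-to-end classification pipeline
#'
#' @description
#' Orchestrates the full flow: gaze binning and fixation maps ->
#' gaze-weighted representation -> per-frame features from each
#' backbone -> FDA dimension unification -> CFT assembly -> GTDA ->
#' L1 logistic tensor regression -> per-category predictions and F1.
#' Models are fitted per (subject, category) pair; with a single pooled
#' subject the loop degenerates to one model per category.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' @param d4 Number of time frames.
#' @param sigma Fixation-map Gaussian width in pixels, or `"auto"` (2%
#'   of the image diagonal).
#' @param epsilon Fixation-map positivity floor.
#' @param extractors Extractor specification string, see
#'   [parse_extractors()]; order is significant.
#' @param fda_ridge Ridge for the FDA within-scatter.
#' @param gtda_dims GTDA target dimensions (length 3) or `"auto"`.
#' @param gtda_sweeps,gtda_tol Alternating-optimization controls.
#' @param lambda LTR L1 weight or `"auto"` (3-fold CV).
#' @param ltr_max_iter,ltr_tol LTR solver controls.
#' @param train_frac Fraction of images in the training split.
#' @param split_seed Seed for the train/test split and CV folds.
#' @param skip_initial_s Seconds of gaze discarded from the start of
#'   every recording (0 keeps the center-fixation onset second).
#' @return A named list.
#' @export
pipeline_config <- function(d4 = 10L, sigma = "auto", epsilon = 1e-6,
                            extractors = "toy:g=2,toy:g=3,toy:g=4",
                            fda_ridge = 1e-3,
                            gtda_dims = "auto", gtda_sweeps = 10L,
                            gtda_tol = 1e-6,
                            lambda = "auto", ltr_max_iter = 500L,
                            ltr_tol = 1e-7,
                            train_frac = 0.75, split_seed = 7L,
                            skip_initial_s = 0) {
  list(d4 = as.integer(d4), sigma = sigma, epsilon = epsilon,
       extractors = extractors, fda_ridge = fda_ridge,
       gtda_dims = gtda_dims, gtda_sweeps = as.integer(gtda_sweeps),
       gtda_tol = gtda_tol, lambda = lambda,
       ltr_max_iter = as.integer(ltr_max_iter), ltr_tol = ltr_tol,
       train_frac = train_frac, split_seed = as.integer(split_seed),
       skip_initial_s = skip_initial_s)
}

#' Build gaze-weighted representations for a set of recordings
#'
#' One representation per gaze recording (i.e. per subject-image pair);
#' the image for each recording is looked up by its `image_id` when
#' `images` is named, otherwise the lists are taken as parallel.
#'
#' @param images List of `d1 x d2 x 3` arrays, named by image id or
#'   parallel to `gaze`.
#' @param gaze List of [gaze_recording()]s.
#' @param config A [pipeline_config()].
#' @return List of `gaze_image_representation`s, parallel to `gaze`.
#' @export
represent_dataset <- function(images, gaze, config = pipeline_config()) {
  named <- !is.null(names(images))
  if (!named && length(images) != length(gaze)) {
    stop("unnamed `images` must be parallel to `gaze`", call. = FALSE)
  }
  lapply(seq_along(gaze), function(i) {
    rec <- gaze[[i]]
    img <- if (named) images[[attr(rec, "image_id")]] else images[[i]]
    if (is.null(img)) {
      stop(sprintf("no image for id '%s'", attr(rec, "image_id")), call. = FALSE)
    }
    if (config$skip_initial_s > 0) {
      keep <- rec$onset >= rec$onset[1L] + config$skip_initial_s
      if (any(keep)) rec <- rec[keep, , drop = FALSE]
    }
    bins <- bin_gaze_to_frames(rec, config$d4)
    fix <- build_fixation_maps(bins, dim(img)[1:2], sigma = config$sigma,
                               epsilon = config$epsilon)
    build_representation(img, compute_giw(fix),
                         image_id = attr(gaze[[i]], "image_id"))
  })
}

#' Fit the per-category model stack (FDA + GTDA + LTR)
#'
#' @param feature_sets List of `feature_matrix_set`s (one per training
#'   image).
#' @param labels Binary labels parallel to `feature_sets`.
#' @param config A [pipeline_config()].
#' @return A `category_model`: list with `fda` (per-backbone
#'   projections), `gtda`, `ltr`, `d1f`, `config_hash`.
#' @export
fit_category_model <- function(feature_sets, labels, config = pipeline_config()) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present", call. = FALSE)
  nb <- length(feature_sets[[1L]]$matrices)
  d1f <- min(vapply(feature_sets[[1L]]$matrices, nrow, integer(1)))
  # pooled frame-level vectors, each frame labeled with its image's label
  fda <- lapply(seq_len(nb), function(b) {
    x <- do.call(cbind, lapply(feature_sets, function(fs) fs$matrices[[b]]))
    d4 <- ncol(feature_sets[[1L]]$matrices[[b]])
    y <- rep(labels, each = d4)
    fda_fit(t(x), y, k = d1f, ridge = config$fda_ridge)
  })
  cfts <- lapply(feature_sets, build_cft, projections = fda)
  gtda <- gtda_fit(cfts, labels, target_dims = config$gtda_dims,
                   sweeps = config$gtda_sweeps, tol = config$gtda_tol)
  transformed <- lapply(cfts, gtda_transform, proj = gtda)
  ltr <- ltr_fit(transformed, labels, lambda = config$lambda,
                 max_iter = config$ltr_max_iter, tol = config$ltr_tol,
                 seed = config$split_seed)
  structure(list(fda = fda, gtda = gtda, ltr = ltr, d1f = d1f,
                 config_hash = config_hash(config)),
            class = "category_model")
}

#' Predict class probabilities with a fitted category model
#'
#' @param model A `category_model`.
#' @param feature_sets List of `feature_matrix_set`s.
#' @return Data frame with `probability` and `label` per input.
#' @export
predict_category <- function(model, feature_sets) {
  proba <- vapply(feature_sets, function(fs) {
    v <- gtda_transform(build_cft(fs, model$fda), model$gtda)
    predict_proba(v, model$ltr)
  }, numeric(1))
  data.frame(probability = proba, label = as.integer(proba > 0.5))
}

#' Run the full pipeline on an in-memory dataset
#'
#' Splits the images into train/test with `split_seed`, fits one model
#' per (subject, category) pair on the training split and evaluates F1
#' on the test split. `labels` rows are matched to images by
#' `image_id`.
#'
#' @param dataset List with `images`, `gaze`, `labels`, `image_ids`
#'   (the shape returned by [gen_dataset()]).
#' @param config A [pipeline_config()].
#' @param permute_labels If `TRUE`, training and test labels are
#'   permuted with `split_seed` (a chance-level control).
#' @return A `pipeline_result`: list with `predictions` (data frame:
#'   `image_id, category, subject_id, probability, label, truth`),
#'   `f1` ([aggregate_f1()] table), `models`, `train_ids`, `test_ids`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         permute_labels = FALSE) {
  images <- dataset$images
  if (is.null(names(images))) names(images) <- dataset$image_ids
  reps <- represent_dataset(images, dataset$gaze, config)
  extractors <- parse_extractors(config$extractors)
  feats <- lapply(reps, extract_features, extractors = extractors)
  rec_image <- vapply(dataset$gaze, attr, "", "image_id")
  rec_subject <- vapply(dataset$gaze, attr, "", "subject_id")
  ids <- dataset$image_ids
  n <- length(ids)
  set.seed(config$split_seed)
  train_ids <- ids[sort(sample(n, floor(config$train_frac * n)))]
  test_ids <- setdiff(ids, train_ids)
  if (length(test_ids) == 0L) stop("empty test split", call. = FALSE)
  subjects <- unique(rec_subject)
  categories <- unique(dataset$labels$category)
  preds <- list()
  models <- list()
  f1 <- matrix(NA_real_, length(subjects), length(categories),
               dimnames = list(subjects, categories))
  for (s in subjects) {
    for (cat in categories) {
      lab_df <- dataset$labels[dataset$labels$category == cat, ]
      img_labels <- lab_df$label[match(ids, lab_df$image_id)]
      if (permute_labels) {
        set.seed(config$split_seed + 1L)
        img_labels <- sample(img_labels)
      }
      labels <- img_labels[match(rec_image, ids)]
      tr <- which(rec_subject == s & rec_image %in% train_ids)
      te <- which(rec_subject == s & rec_image %in% test_ids)
      if (length(te) == 0L) stop("empty test split", call. = FALSE)
      model <- fit_category_model(feats[tr], labels[tr], config)
      pred <- predict_category(model, feats[te])
      pred$image_id <- rec_image[te]
      pred$category <- cat
      pred$subject_id <- s
      pred$truth <- labels[te]
      preds[[paste(s, cat)]] <- pred
      models[[paste(s, cat)]] <- model
      f1[s, cat] <- precision_recall_f1(confusion_counts(pred$truth, pred$label))["f1"]
    }
  }
  pred_df <- do.call(rbind, preds)
  rownames(pred_df) <- NULL
  pred_df <- pred_df[, c("image_id", "category", "subject_id",
                         "probability", "label", "truth")]
  structure(list(predictions = pred_df, f1 = aggregate_f1(f1),
                 models = models,
                 train_ids = train_ids, test_ids = test_ids),
            class = "pipeline_result")
}

#' Load a dataset from disk in the pipeline's file formats
#'
#' @param dir Directory containing `images/` (PNG), `gaze.csv`,
#'   `labels.csv`.
#' @return A dataset list as consumed by [run_pipeline()].
#' @export
load_dataset <- function(dir) {
  labels <- read_labels_csv(file.path(dir, "labels.csv"))
  gaze <- read_gaze_csv(file.path(dir, "gaze.csv"))
  ids <- unique(vapply(gaze, attr, "", "image_id"))
  images <- read_images_dir(file.path(dir, "images"), ids)
  list(images = images, gaze = gaze, labels = labels, image_ids = ids)
}
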