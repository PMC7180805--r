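#' @title Per-frame feature extraction and CFT assembly
#'
#' @description
#' Every frame of the gaze-weighted representation is passed through one
#' or more feature extractors ("backbones"). Because backbones emit
#' different dimensionalities, each backbone's features are projected to
#' the smallest output dimension with a supervised Fisher discriminant
#' analysis (FDA) projection fitted on pooled frame-level training
#' vectors. The unified per-frame features are stacked into the
#' composite feature tensor (CFT), a third-order array of shape
#' (unified feature dim) x (number of backbones) x (number of frames).
#' Backbone order is significant and preserved.
#'
#' @name feature-extraction
NULL

#' Construct a feature extractor
#'
#' @param name Identifier.
#' @param output_dim Length of the feature vector the extractor emits.
#' @param extract Function mapping a `d1 x d2 x ch` frame array to a
#'   numeric vector of length `output_dim`; must be deterministic.
#' @return A `feature_extractor` object.
#' @export
feature_extractor <- function(name, output_dim, extract) {
  stopifnot(is.character(name), output_dim >= 1L, is.function(extract))
  structure(list(name = name, output_dim = as.integer(output_dim),
                 extract = extract),
            class = "feature_extractor")
}

#' Deterministic grid-mean extractor
#'
#' Partitions each channel of a frame into a `g x g` grid of contiguous
#' near-equal blocks and returns the block means, concatenated over
#' channels (cells in column-major order within a channel). A cheap,
#' deterministic stand-in for a pretrained backbone: with different `g`
#' values it exercises the heterogeneous-dimension unification path.
#'
#' @param g Grid side, `>= 1`; must not exceed either image side.
#' @param channels Number of image channels the extractor expects.
#' @return A [feature_extractor()] with `output_dim = channels * g^2`.
#' @export
toy_grid_extractor <- function(g, channels = 3L) {
  g <- as.integer(g)
  if (g < 1L) stop("`g` must be >= 1", call. = FALSE)
  extract <- function(frame) {
    d <- dim(frame)
    if (g > min(d[1:2])) {
      stop(sprintf("grid side %d exceeds image side %d", g, min(d[1:2])),
           call. = FALSE)
    }
    grp <- function(n) {
      if (g == 1L) rep(1L, n) else as.integer(cut(seq_len(n), g, labels = FALSE))
    }
    row_grp <- grp(d[1L])
    col_grp <- grp(d[2L])
    out <- numeric(d[3L] * g * g)
    pos <- 1L
    for (ch in seq_len(d[3L])) {
      sl <- frame[, , ch]
      # column-major cell order within a channel
      for (cc in seq_len(g)) {
        for (rr in seq_len(g)) {
          out[pos] <- mean(sl[row_grp == rr, col_grp == cc])
          pos <- pos + 1L
        }
      }
    }
    out
  }
  feature_extractor(sprintf("toy_grid_g%d", g), channels * g * g, extract)
}

#' Parse extractor specifications like "toy:g=4"
#'
#' @param spec Comma-separated string, e.g. `"toy:g=2,toy:g=3,toy:g=4"`.
#' @param channels Channel count passed to the extractors.
#' @return List of [feature_extractor()]s in the given order.
#' @export
parse_extractors <- function(spec, channels = 3L) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1L]]
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^toy:g=([0-9]+)$", p))[[1L]]
    if (length(m) != 2L) stop(sprintf("unknown extractor spec '%s'", p), call. = FALSE)
    toy_grid_extractor(as.integer(m[2L]), channels = channels)
  })
}

#' Extract per-frame features from a representation
#'
#' @param rep A `gaze_image_representation`.
#' @param extractors Non-empty list of [feature_extractor()]s; order is
#'   preserved and significant downstream.
#' @return A `feature_matrix_set`: list with `matrices` (one
#'   `output_dim_b x d4` matrix per backbone) and `backbones` (names in
#'   order).
#' @export
extract_features <- function(rep, extractors) {
  if (length(extractors) == 0L) stop("need at least one extractor", call. = FALSE)
  d4 <- rep$d4
  matrices <- lapply(extractors, function(ex) {
    out <- matrix(NA_real_, ex$output_dim, d4)
    for (f in seq_len(d4)) {
      v <- tryCatch(ex$extract(rep$tensor[, , , f, drop = TRUE]),
                    error = function(e) {
                      stop(sprintf("extractor '%s' failed on frame %d: %s",
                                   ex$name, f, conditionMessage(e)), call. = FALSE)
                    })
      if (length(v) != ex$output_dim || !all(is.finite(v))) {
        stop(sprintf("extractor '%s' returned a bad vector on frame %d",
                     ex$name, f), call. = FALSE)
      }
      out[, f] <- v
    }
    out
  })
  structure(list(matrices = matrices,
                 backbones = vapply(extractors, `[[`, "", "name")),
            class = "feature_matrix_set")
}

#' Fit a Fisher discriminant analysis projection
#'
#' For binary labels the discriminant subspace of
#' `(S_w + ridge * I)^{-1} S_b` has rank 1; the remaining `k - 1` basis
#' vectors are the leading principal components of the total scatter
#' restricted to the orthogonal complement of the discriminant
#' direction. Columns are orthonormal.
#'
#' @param x Matrix, samples in rows (`n x input_dim`).
#' @param y Binary labels (0/1), both classes present.
#' @param k Target dimension, `<= input_dim`.
#' @param ridge Ridge added to the within-class scatter, `>= 0`.
#' @return An `fda_projection`: list with `mean` (length `input_dim`),
#'   `basis` (`input_dim x k`, orthonormal columns), `ridge`.
#' @export
fda_fit <- function(x, y, k, ridge = 1e-3) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  p <- ncol(x)
  if (k > p) stop("`k` exceeds the input dimension", call. = FALSE)
  mu <- colMeans(x)
  mu0 <- colMeans(x[y == 0L, , drop = FALSE])
  mu1 <- colMeans(x[y == 1L, , drop = FALSE])
  xc0 <- sweep(x[y == 0L, , drop = FALSE], 2L, mu0)
  xc1 <- sweep(x[y == 1L, , drop = FALSE], 2L, mu1)
  sw <- crossprod(xc0) + crossprod(xc1)
  # rank-1 discriminant direction for two classes
  w <- solve(sw + ridge * diag(p), mu1 - mu0)
  w <- w / sqrt(sum(w^2))
  basis <- matrix(w, ncol = 1L)
  if (k > 1L) {
    xc <- sweep(x, 2L, mu)
    st <- crossprod(xc)
    proj <- diag(p) - tcrossprod(w)
    st_perp <- proj %*% st %*% proj
    st_perp <- (st_perp + t(st_perp)) / 2
    ev <- eigen(st_perp, symmetric = TRUE)
    basis <- cbind(basis, ev$vectors[, seq_len(k - 1L), drop = FALSE])
    basis <- qr.Q(qr(basis))[, seq_len(k), drop = FALSE]
  }
  basis <- fix_column_signs(basis)
  structure(list(mean = mu, basis = basis, ridge = ridge),
            class = "fda_projection")
}

#' Apply an FDA projection
#'
#' @param proj An `fda_projection`.
#' @param x Matrix of samples in rows, or a single vector.
#' @return Projected samples (`n x k` matrix).
#' @export
fda_transform <- function(proj, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  sweep(as.matrix(x), 2L, proj$mean) %*% proj$basis
}

#' Assemble the composite feature tensor (CFT)
#'
#' Projects each backbone's per-frame feature matrix to the common
#' unified dimension and stacks the results: entry `(i, b, f)` is the
#' `i`-th component of the projected feature of backbone `b` at frame
#' `f`.
#'
#' @param fms A `feature_matrix_set` from [extract_features()].
#' @param projections List of `fda_projection`s, one per backbone, each
#'   mapping that backbone's dimension to the common `d1f`.
#' @return A 3-d array (`d1f x n_backbones x d4`).
#' @export
build_cft <- function(fms, projections) {
  nb <- length(fms$matrices)
  if (length(projections) != nb) {
    stop("one projection per backbone is required", call. = FALSE)
  }
  d1f <- unique(vapply(projections, function(p) ncol(p$basis), integer(1)))
  if (length(d1f) != 1L) stop("projections disagree on the unified dimension", call. = FALSE)
  d4 <- ncol(fms$matrices[[1L]])
  cft <- array(0, c(d1f, nb, d4))
  for (b in seq_len(nb)) {
    if (nrow(projections[[b]]$basis) != nrow(fms$matrices[[b]])) {
      stop(sprintf("projection %d does not match backbone dimension", b), call. = FALSE)
    }
    cft[, b, ] <- t(fda_transform(projections[[b]], t(fms$matrices[[b]])))
  }
  cft
}

# Deterministic sign convention: first entry of each column whose
# magnitude exceeds a relative tolerance is made positive.
fix_column_signs <- function(m, tol = 1e-9) {
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    nz <- which(abs(col) > tol * max(abs(col), 1e-300))
    if (length(nz) > 0L && col[nz[1L]] < 0) m[, j] <- -col
  }
  m
}
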