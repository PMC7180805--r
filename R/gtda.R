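#' @title General Tensor Discriminant Analysis
#'
#' @description
#' GTDA finds one orthonormal projection matrix per tensor mode that
#' jointly maximizes, mode by mode, the discriminability criterion
#' `tr(P_l' (S_l^b - eta_l * S_l^w) P_l)`, where `S_l^b` and `S_l^w` are
#' the between- and within-class scatter matrices of the mode-`l`
#' unfoldings of the training tensors after projecting all *other*
#' modes, and `eta_l` is the largest eigenvalue of
#' `(S_l^w)^{-1} S_l^b`. The problem is solved by alternating
#' optimization: sweeping over modes, each `P_l` is updated by a
#' symmetric eigendecomposition with the other modes' projections held
#' fixed. A small ridge proportional to `tr(S_w)/d` stabilizes the
#' within-scatter inverse (the feature dimension typically exceeds the
#' sample count).
#'
#' @name gtda
NULL

#' Class mean tensors
#'
#' @param tensors List of same-sized 3-d arrays.
#' @param labels Binary labels (0/1), both classes present.
#' @return A `class_moments`: list with `m0`, `m1` (class means), `m`
#'   (grand mean, the count-weighted average of the class means), `n0`,
#'   `n1`.
#' @export
class_means <- function(tensors, labels) {
  labels <- as.integer(labels)
  if (length(tensors) != length(labels)) stop("lengths differ", call. = FALSE)
  if (length(unique(labels)) < 2L) stop("both classes must be present", call. = FALSE)
  avg <- function(ts) Reduce(`+`, ts) / length(ts)
  m0 <- avg(tensors[labels == 0L])
  m1 <- avg(tensors[labels == 1L])
  n0 <- sum(labels == 0L); n1 <- sum(labels == 1L)
  structure(list(m0 = m0, m1 = m1, m = (n0 * m0 + n1 * m1) / (n0 + n1),
                 n0 = n0, n1 = n1),
            class = "class_moments")
}

# Project all modes except `l` by the current projections.
project_except <- function(x, projections, l) {
  for (k in setdiff(1:3, l)) {
    if (!is.null(projections[[k]])) x <- mode_product(x, projections[[k]], k)
  }
  x
}

#' Mode-l between- and within-class scatter matrices
#'
#' The class-mean deviations (between) and per-sample deviations from
#' the class mean (within) are projected along every mode except `l` by
#' the current projections, unfolded along mode `l`, and accumulated as
#' outer products. Both outputs are symmetric positive semidefinite of
#' size `d_l x d_l`.
#'
#' @param tensors List of 3-d arrays.
#' @param labels Binary labels.
#' @param moments A `class_moments` (recomputed if `NULL`).
#' @param projections List of length 3 of projection matrices (entries
#'   may be `NULL` meaning identity); only modes `!= l` are used.
#' @param l Mode whose scatters are formed.
#' @return List with `sb` and `sw`.
#' @export
mode_scatters <- function(tensors, labels, moments = NULL, projections, l) {
  labels <- as.integer(labels)
  if (is.null(moments)) moments <- class_means(tensors, labels)
  dl <- dim(tensors[[1L]])[l]
  sb <- matrix(0, dl, dl)
  for (y in 0:1) {
    my <- if (y == 0L) moments$m0 else moments$m1
    ny <- if (y == 0L) moments$n0 else moments$n1
    b <- unfold(project_except(my - moments$m, projections, l), l)
    sb <- sb + ny * tcrossprod(b)
  }
  sw <- matrix(0, dl, dl)
  for (n in seq_along(tensors)) {
    my <- if (labels[n] == 0L) moments$m0 else moments$m1
    w <- unfold(project_except(tensors[[n]] - my, projections, l), l)
    sw <- sw + tcrossprod(w)
  }
  list(sb = (sb + t(sb)) / 2, sw = (sw + t(sw)) / 2)
}

#' Solve one mode of the GTDA criterion
#'
#' `eta` is the largest eigenvalue of `(S_w + ridge I)^{-1} S_b`
#' (computed via a Cholesky whitening so the problem stays symmetric);
#' `P` collects the orthonormal eigenvectors of the symmetric matrix
#' `S_b - eta * S_w` for its `k` largest eigenvalues. When `S_b` is
#' identically zero that matrix vanishes, and `P` falls back to the
#' top-`k` eigenvectors of `-S_w` (the directions of least within-class
#' scatter). Eigenvector signs are fixed (first non-negligible entry
#' positive) for reproducibility.
#'
#' @param sb,sw Symmetric PSD scatter matrices of equal size.
#' @param k Number of projection columns, `<= nrow(sb)`.
#' @param ridge Ridge added to `sw` before inversion.
#' @return List with `p` (orthonormal `d x k`) and `eta`.
#' @export
solve_mode <- function(sb, sw, k, ridge = 0) {
  d <- nrow(sb)
  if (k > d) stop("`k` exceeds the scatter size", call. = FALSE)
  sym_tol <- 1e-8 * max(abs(sb), abs(sw), 1)
  if (max(abs(sb - t(sb))) > sym_tol || max(abs(sw - t(sw))) > sym_tol) {
    stop("scatter matrices must be symmetric", call. = FALSE)
  }
  if (max(abs(sb)) == 0) {
    eta <- 0
    target <- -sw
  } else {
    eta <- mode_eta(sb, sw, ridge)
    target <- sb - eta * sw
  }
  ev <- eigen((target + t(target)) / 2, symmetric = TRUE)
  p <- fix_column_signs(ev$vectors[, seq_len(k), drop = FALSE])
  list(p = p, eta = eta)
}

# Largest eigenvalue of (S_w + ridge I)^{-1} S_b via Cholesky whitening
# (keeps the problem symmetric); zero when S_b vanishes.
mode_eta <- function(sb, sw, ridge) {
  if (max(abs(sb)) == 0) return(0)
  d <- nrow(sw)
  swr <- sw + ridge * diag(d)
  ch <- chol(swr + 1e-12 * max(diag(swr), 1) * diag(d))
  l_mat <- t(ch)
  white <- t(forwardsolve(l_mat, t(forwardsolve(l_mat, sb))))
  max(eigen((white + t(white)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

#' Fit GTDA projections by alternating optimization
#'
#' Each `P_l` is initialized to the first `target_dims[l]` columns of
#' the identity; sweeps over modes 1..3 update each `P_l` from the
#' scatters of the other modes' current projections. Iteration stops
#' after `sweeps` sweeps or when the relative change of the summed mode
#' objectives falls below `tol`. Non-convergence is reported through the
#' objective trace, never as an error.
#'
#' @param tensors List of same-sized 3-d arrays (the training CFTs).
#' @param labels Binary labels (0/1).
#' @param target_dims Integer vector of length 3, the projected
#'   dimensions (each `<=` the corresponding input dimension), or
#'   `"auto"` to retain a 0.95 eigenvalue-energy fraction of the
#'   per-mode total scatter.
#' @param sweeps Maximum number of alternating sweeps.
#' @param tol Relative-change stopping tolerance on the objective.
#' @param ridge_scale Ridge applied to each within-scatter as
#'   `ridge_scale * tr(S_w) / d`.
#' @return A `gtda_projection_set`: list with `p` (list of 3 orthonormal
#'   matrices), `eta` (per-mode values from the last sweep),
#'   `objective_trace` (one summed objective per sweep), `target_dims`.
#' @export
gtda_fit <- function(tensors, labels, target_dims = "auto", sweeps = 10L,
                     tol = 1e-6, ridge_scale = 1e-6) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present", call. = FALSE)
  dims <- dim(tensors[[1L]])
  moments <- class_means(tensors, labels)
  if (identical(target_dims, "auto")) {
    target_dims <- vapply(1:3, function(l) {
      sc <- mode_scatters(tensors, labels, moments,
                          projections = vector("list", 3L), l = l)
      ev <- eigen(sc$sb + sc$sw, symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 0)
      if (sum(ev) == 0) return(dims[l])
      as.integer(which(cumsum(ev) / sum(ev) >= 0.95)[1L])
    }, integer(1))
  }
  target_dims <- as.integer(target_dims)
  if (any(target_dims > dims) || any(target_dims < 1L)) {
    stop("target dims must be in [1, input dims]", call. = FALSE)
  }
  projections <- lapply(1:3, function(l) diag(1, dims[l])[, seq_len(target_dims[l]), drop = FALSE])
  eta <- numeric(3L)
  # joint objective evaluated at the current iterate: scatters and eta
  # recomputed for every mode with all projections fixed
  evaluate <- function(projections) {
    total <- 0
    etas <- numeric(3L)
    for (l in 1:3) {
      sc <- mode_scatters(tensors, labels, moments, projections, l)
      ridge <- ridge_scale * sum(diag(sc$sw)) / nrow(sc$sw)
      etas[l] <- mode_eta(sc$sb, sc$sw, ridge)
      pl <- projections[[l]]
      total <- total +
        sum(diag(crossprod(pl, (sc$sb - etas[l] * sc$sw) %*% pl)))
    }
    list(obj = total, eta = etas)
  }
  trace <- numeric(0)
  prev_obj <- NA_real_
  for (s in seq_len(sweeps)) {
    snapshot <- list(p = projections, eta = eta)
    for (l in 1:3) {
      sc <- mode_scatters(tensors, labels, moments, projections, l)
      ridge <- ridge_scale * sum(diag(sc$sw)) / nrow(sc$sw)
      sol <- solve_mode(sc$sb, sc$sw, target_dims[l], ridge = ridge)
      projections[[l]] <- sol$p
    }
    ev <- evaluate(projections)
    obj <- ev$obj
    eta <- ev$eta
    # monotone acceptance: near the fixed point the re-estimated eta can
    # make the objective wobble at numerical noise level; reject a
    # decreasing sweep and stop with the previous projections
    if (!is.na(prev_obj) && obj < prev_obj) {
      projections <- snapshot$p
      eta <- snapshot$eta
      break
    }
    trace <- c(trace, obj)
    if (!is.na(prev_obj) &&
        abs(obj - prev_obj) <= tol * max(1, abs(prev_obj))) break
    prev_obj <- obj
  }
  structure(list(p = projections, eta = eta, objective_trace = trace,
                 target_dims = target_dims),
            class = "gtda_projection_set")
}

#' Apply a GTDA projection set to a tensor
#'
#' Sequential mode products along modes 1, 2, 3 (products along distinct
#' modes commute, so the order is immaterial).
#'
#' @param x 3-d array with dimensions matching the projection rows.
#' @param proj A `gtda_projection_set` (or plain list of 3 matrices).
#' @return The projected tensor, dimensions equal to the target dims.
#' @export
gtda_transform <- function(x, proj) {
  p <- if (inherits(proj, "gtda_projection_set")) proj$p else proj
  for (l in 1:3) x <- mode_product(x, p[[l]], l)
  x
}
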