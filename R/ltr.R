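#' @title L1-regularized logistic tensor regression
#'
#' @description
#' The classifier models `Pr(y = 1 | V) = sigmoid(<Z, V>)` where the
#' coefficient `Z` is a tensor of the same shape as the input tensor
#' `V` and `<.,.>` is the tensor inner product. `Z` is estimated by
#' minimizing the Bernoulli negative log-likelihood plus an L1 penalty
#' `lambda * ||Z||_1`, using accelerated proximal gradient descent
#' (FISTA) with backtracking line search, soft-thresholding prox, and
#' adaptive restart so the recorded objective is non-increasing.
#'
#' @name ltr
NULL

# log(1 + exp(t)) without overflow
log1pexp <- function(t) {
  out <- t
  small <- t <= 33
  out[small] <- log1p(exp(t[small]))
  out
}

sigmoid <- function(u) 1 / (1 + exp(-pmin(pmax(u, -700), 700)))

as_design <- function(tensors) {
  t(vapply(tensors, as.numeric, numeric(length(tensors[[1L]]))))
}

#' Construct an LTR model from a coefficient tensor
#'
#' @param z Coefficient tensor (3-d array).
#' @param intercept Scalar intercept, default 0.
#' @param lambda L1 weight recorded with the model.
#' @return An `ltr_model`.
#' @export
ltr_model <- function(z, intercept = 0, lambda = 0) {
  assert_tensor3(z)
  structure(list(z = z, intercept = intercept, lambda = lambda,
                 objective_trace = numeric(0), iterations = 0L,
                 converged = NA),
            class = "ltr_model")
}

#' Class-1 probability under an LTR model
#'
#' Returns `sigmoid(<Z, V> + b)` where `b` is the model intercept
#' (zero when fitted without one).
#'
#' @param v 3-d array matching the model's coefficient dimensions.
#' @param model An `ltr_model` from [ltr_fit()].
#' @return Probability in (0, 1), numerically stabilized.
#' @export
predict_proba <- function(v, model) {
  if (!identical(dim(v), dim(model$z))) stop("tensor dimensions differ", call. = FALSE)
  b <- if (is.null(model$intercept)) 0 else model$intercept
  sigmoid(tensor_inner(model$z, v) + b)
}

#' Penalized negative log-likelihood and its gradient
#'
#' Returns the smooth part of the LTR objective,
#' `-sum_n [y_n log s_n + (1 - y_n) log(1 - s_n)]` with
#' `s_n = sigmoid(<Z, V_n>)`, and its gradient
#' `sum_n (s_n - y_n) V_n`. The L1 term is handled by the proximal step
#' in [ltr_fit()], not here.
#'
#' @param tensors List of 3-d arrays.
#' @param labels Binary labels (0/1).
#' @param z Coefficient tensor, same dimensions as each input.
#' @param lambda L1 weight (recorded, not added to the smooth value).
#' @return List with `value` (scalar) and `gradient` (3-d array).
#' @export
penalized_nll <- function(tensors, labels, z, lambda = 0) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (!identical(dim(tensors[[1L]]), dim(z))) stop("tensor dimensions differ", call. = FALSE)
  x <- as_design(tensors)
  u <- drop(x %*% as.numeric(z))
  # -[y log s + (1-y) log(1-s)] = log1pexp(u) - y*u
  value <- sum(log1pexp(u) - labels * u)
  grad <- drop(crossprod(x, sigmoid(u) - labels))
  list(value = value, gradient = array(grad, dim(z)))
}

soft_threshold <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

#' Fit an L1-regularized logistic tensor regression model
#'
#' Minimizes the Bernoulli negative log-likelihood plus
#' `lambda * ||Z||_1` by FISTA with backtracking; `Z` starts at zero.
#' `lambda = "auto"` selects the weight from a logarithmic grid by
#' 3-fold cross-validated F1.
#'
#' @param tensors List of same-sized 3-d arrays.
#' @param labels Binary labels (0/1), both classes present.
#' @param lambda L1 weight (`>= 0`) or `"auto"`.
#' @param max_iter Iteration cap.
#' @param tol Relative-objective-change stopping tolerance.
#' @param seed Seed for the cross-validation folds when
#'   `lambda = "auto"`; ignored otherwise (the solver is deterministic).
#' @param intercept Fit an unpenalized intercept (default `TRUE`); the
#'   transformed feature tensors are generally not centered, so without
#'   one the decision boundary is forced through the origin.
#' @return An `ltr_model`: list with `z` (coefficient array),
#'   `intercept`, `lambda`, `objective_trace`, `iterations`,
#'   `converged`.
#' @export
ltr_fit <- function(tensors, labels, lambda = "auto", max_iter = 500L,
                    tol = 1e-7, seed = 1L, intercept = TRUE) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L) stop("both classes must be present", call. = FALSE)
  dims <- dim(tensors[[1L]])
  x <- as_design(tensors)
  if (identical(lambda, "auto")) {
    lambda <- cv_lambda(x, labels, dims, max_iter, tol, seed, intercept)
  }
  if (!is.numeric(lambda) || lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  fit <- fista_logistic(x, labels, lambda, max_iter, tol, intercept)
  structure(list(z = array(fit$z, dims), intercept = fit$intercept,
                 lambda = lambda,
                 objective_trace = fit$trace, iterations = fit$iterations,
                 converged = fit$converged),
            class = "ltr_model")
}

# FISTA on vectorized tensors; monotone via restart on objective
# increase. With `intercept` an unpenalized constant column is appended
# and excluded from the soft-threshold prox.
fista_logistic <- function(x, y, lambda, max_iter, tol, intercept = FALSE) {
  if (intercept) x <- cbind(x, 1)
  p <- ncol(x)
  n_pen <- if (intercept) p - 1L else p
  smooth <- function(z) {
    u <- drop(x %*% z)
    list(value = sum(log1pexp(u) - y * u),
         grad = drop(crossprod(x, sigmoid(u) - y)))
  }
  obj <- function(z, fval) fval + lambda * sum(abs(z[seq_len(n_pen)]))
  prox <- function(v, t) {
    v[seq_len(n_pen)] <- soft_threshold(v[seq_len(n_pen)], t)
    v
  }
  z <- numeric(p)
  zv <- z                     # momentum point
  t_mom <- 1
  lip <- 1
  f0 <- smooth(z)
  best <- obj(z, f0$value)
  trace <- best
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    fy <- smooth(zv)
    repeat {
      z_new <- prox(zv - fy$grad / lip, lambda / lip)
      fz <- smooth(z_new)
      dz <- z_new - zv
      if (fz$value <= fy$value + sum(fy$grad * dz) + lip / 2 * sum(dz^2) + 1e-12) break
      lip <- lip * 2
    }
    new_obj <- obj(z_new, fz$value)
    if (new_obj > best + 1e-12) {
      # restart: plain proximal step from the last accepted iterate
      fz_prev <- smooth(z)
      repeat {
        z_new <- prox(z - fz_prev$grad / lip, lambda / lip)
        fz <- smooth(z_new)
        dz <- z_new - z
        if (fz$value <= fz_prev$value + sum(fz_prev$grad * dz) +
              lip / 2 * sum(dz^2) + 1e-12) break
        lip <- lip * 2
      }
      new_obj <- obj(z_new, fz$value)
      t_mom <- 1
      zv <- z_new
    } else {
      t_new <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
      zv <- z_new + (t_mom - 1) / t_new * (z_new - z)
      t_mom <- t_new
    }
    rel <- abs(best - new_obj) / max(1, abs(best))
    z <- z_new
    best <- min(best, new_obj)
    trace <- c(trace, best)
    if (rel < tol) { converged <- TRUE; break }
  }
  list(z = z[seq_len(n_pen)],
       intercept = if (intercept) z[p] else 0,
       trace = trace, iterations = iter, converged = converged)
}

# 3-fold stratified CV over a log-spaced lambda grid, scored by F1.
cv_lambda <- function(x, y, dims, max_iter, tol, seed, intercept = FALSE,
                      grid = 10^seq(-3, 1, length.out = 9)) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in c(0, 1)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(1:3, length(idx)))
  }
  scores <- vapply(grid, function(lam) {
    f1s <- vapply(1:3, function(k) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      fit <- fista_logistic(x[tr, , drop = FALSE], y[tr], lam, max_iter, tol,
                            intercept)
      pred <- as.integer(
        sigmoid(drop(x[!tr, , drop = FALSE] %*% fit$z) + fit$intercept) > 0.5)
      cc <- confusion_counts(y[!tr], pred)
      precision_recall_f1(cc)["f1"]
    }, numeric(1))
    mean(f1s, na.rm = TRUE)
  }, numeric(1))
  grid[which.max(scores)]
}

#' Classify a tensor with a fitted LTR model
#'
#' Label 1 iff the class-1 probability exceeds 0.5; an exact tie maps to
#' class 0.
#'
#' @param v 3-d array.
#' @param model An `ltr_model`.
#' @return Integer label, 0 or 1.
#' @export
classify <- function(v, model) {
  as.integer(predict_proba(v, model) > 0.5)
}
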