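#' @title Multilinear algebra primitives
#'
#' @description
#' Third- and fourth-order tensors are represented as plain numeric R
#' arrays. The functions here fix the unfolding and mode-product
#' conventions used throughout the package:
#'
#' * `unfold(T, l)` returns the mode-`l` matricization, a matrix whose
#'   rows index mode `l` and whose columns enumerate the remaining modes
#'   with the lower-numbered remaining mode varying fastest.
#' * `mode_product(T, U, l)` contracts mode `l` of `T` against the rows
#'   of `U` so that `unfold(mode_product(T, U, l), l) == t(U) %*% unfold(T, l)`;
#'   a `d x k` projection matrix therefore shrinks mode `l` from `d` to `k`.
#'
#' Any consistent convention preserves the downstream results; this one
#' coincides with R's native column-major layout for mode 1.
#'
#' @name tensor-core
NULL

assert_tensor3 <- function(x, arg = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop(sprintf("`%s` must be a 3-dimensional numeric array", arg), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite entries", arg), call. = FALSE)
  }
  invisible(x)
}

#' Mode-l unfolding of a third-order tensor
#'
#' @param x Numeric 3-d array.
#' @param mode Integer in 1:3, the mode indexing the rows.
#' @return A matrix of dimension `dim(x)[mode]` by the product of the
#'   remaining dimensions, remaining modes ordered ascending with the
#'   lower-numbered one varying fastest along columns.
#' @examples
#' x <- array(1:24, c(2, 3, 4))
#' dim(unfold(x, 2)) # 3 x 8
#' @export
unfold <- function(x, mode) {
  assert_tensor3(x)
  if (!mode %in% 1:3) stop("`mode` must be 1, 2 or 3", call. = FALSE)
  d <- dim(x)
  perm <- c(mode, setdiff(1:3, mode))
  matrix(aperm(x, perm), nrow = d[mode])
}

#' Fold a mode-l unfolding back into a tensor
#'
#' Inverse of [unfold()]: `fold(unfold(x, m), m, dim(x))` recovers `x`.
#'
#' @param m Matrix produced by [unfold()].
#' @param mode Mode along which `m` was unfolded.
#' @param dims Target tensor dimensions (length 3).
#' @return A 3-d array with dimensions `dims`.
#' @export
fold <- function(m, mode, dims) {
  if (!mode %in% 1:3) stop("`mode` must be 1, 2 or 3", call. = FALSE)
  dims <- as.integer(dims)
  if (length(dims) != 3L) stop("`dims` must have length 3", call. = FALSE)
  if (nrow(m) != dims[mode] || ncol(m) != prod(dims[-mode])) {
    stop("matrix shape incompatible with `dims` and `mode`", call. = FALSE)
  }
  perm <- c(mode, setdiff(1:3, mode))
  arr <- array(m, dim = dims[perm])
  aperm(arr, order(perm))
}

#' Mode-l product of a tensor with a matrix
#'
#' Contracts mode `mode` of `x` (size `d`) with a `d x k` matrix `u`,
#' producing a tensor whose `mode`-th dimension is `k`. Satisfies
#' `unfold(mode_product(x, u, l), l) == t(u) %*% unfold(x, l)`.
#'
#' @param x Numeric 3-d array.
#' @param u Matrix with `nrow(u) == dim(x)[mode]`.
#' @param mode Integer in 1:3.
#' @return A 3-d array; `dim(x)` with the `mode`-th entry replaced by `ncol(u)`.
#' @export
mode_product <- function(x, u, mode) {
  assert_tensor3(x)
  if (!mode %in% 1:3) stop("`mode` must be 1, 2 or 3", call. = FALSE)
  u <- as.matrix(u)
  d <- dim(x)
  if (nrow(u) != d[mode]) {
    stop(sprintf("`u` has %d rows but mode %d has size %d", nrow(u), mode, d[mode]),
         call. = FALSE)
  }
  out_dims <- d
  out_dims[mode] <- ncol(u)
  fold(crossprod(u, unfold(x, mode)), mode, out_dims)
}

#' Tensor inner product
#'
#' Sum over all index triples of the elementwise product of two
#' same-sized third-order tensors.
#'
#' @param a,b Numeric 3-d arrays of identical dimensions.
#' @return A scalar.
#' @export
tensor_inner <- function(a, b) {
  assert_tensor3(a)
  assert_tensor3(b)
  if (!identical(dim(a), dim(b))) stop("tensor dimensions differ", call. = FALSE)
  sum(a * b)
}

#' Hadamard (elementwise) product of two matrices
#'
#' @param a,b Matrices of identical shape.
#' @return Their elementwise product.
#' @export
hadamard <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("matrix shapes differ", call. = FALSE)
  a * b
}
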