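test_that("class mean tensors average within class and weight the grand mean", {
  t1 <- array(1, c(1, 1, 1)); t3 <- array(3, c(1, 1, 1)); t5 <- array(5, c(1, 1, 1))
  cm <- class_means(list(t1, t3, t5), c(0, 0, 1))
  expect_equal(cm$m0[1], 2)
  expect_equal(cm$m1[1], 5)
  expect_equal(cm$m[1], 3)

  same <- rand_tensor(c(2, 3, 2), seed = 1)
  cm2 <- class_means(list(same, same, same), c(0, 1, 1))
  expect_equal(cm2$m0, same); expect_equal(cm2$m1, same); expect_equal(cm2$m, same)

  a <- rand_tensor(c(2, 2, 2), seed = 2); b <- rand_tensor(c(2, 2, 2), seed = 3)
  expect_equal(class_means(list(a, b), c(0, 1))$m, (a + b) / 2)
  expect_error(class_means(list(a, b), c(1, 1)), "both classes")
})

test_that("mode scatters vanish in the degenerate cases and match hand outer products", {
  id3 <- vector("list", 3)

  # identical class means -> no between-class scatter
  a <- rand_tensor(c(2, 2, 2), seed = 4)
  sc <- mode_scatters(list(a, -a, a, -a), c(0, 0, 1, 1), projections = id3, l = 1)
  expect_equal(sc$sb, matrix(0, 2, 2), tolerance = 1e-12)

  # every tensor equals its class mean -> no within-class scatter
  b <- rand_tensor(c(2, 2, 2), seed = 5)
  sc2 <- mode_scatters(list(a, a, b, b), c(0, 0, 1, 1), projections = id3, l = 1)
  expect_equal(sc2$sw, matrix(0, 2, 2), tolerance = 1e-12)

  # hand example: 2x1x1 tensors, balanced labels, zero means
  v <- function(x1, x2) array(c(x1, x2), c(2, 1, 1))
  sc3 <- mode_scatters(list(v(1, 0), v(-1, 0), v(0, 2), v(0, -2)),
                       c(0, 0, 1, 1), projections = id3, l = 1)
  expect_equal(sc3$sb, matrix(0, 2, 2), tolerance = 1e-12)
  expect_equal(sc3$sw, diag(c(2, 8)), tolerance = 1e-12)

  # symmetric PSD on random instances
  set.seed(6)
  for (i in 1:5) {
    ts <- lapply(1:6, function(j) rand_tensor(c(3, 2, 2)))
    for (l in 1:3) {
      sc <- mode_scatters(ts, c(0, 0, 0, 1, 1, 1), projections = id3, l = l)
      for (s in list(sc$sb, sc$sw)) {
        expect_equal(s, t(s), tolerance = 1e-12)
        expect_gte(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
      }
    }
  }
})

test_that("solve_mode solves the per-mode eigenproblem with fixed signs", {
  sol <- solve_mode(diag(c(4, 1)), diag(2), k = 1)
  expect_equal(sol$eta, 4, tolerance = 1e-9)
  expect_equal(sol$p, matrix(c(1, 0), 2, 1), tolerance = 1e-10)

  # degenerate between-scatter: least within-scatter directions
  sw <- matrix(c(3, 1, 1, 2), 2, 2)
  sol0 <- solve_mode(matrix(0, 2, 2), sw, k = 1)
  expect_equal(sol0$eta, 0)
  ev <- eigen(-sw, symmetric = TRUE)
  expect_equal(abs(sum(sol0$p * ev$vectors[, 1])), 1, tolerance = 1e-10)

  # joint rescaling leaves the projection unchanged
  set.seed(7)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  sb <- q %*% diag(c(3, 1, 0.2)) %*% t(q)
  sw2 <- diag(c(1, 2, 0.5))
  s1 <- solve_mode(sb, sw2, k = 2)
  s2 <- solve_mode(5 * sb, 5 * sw2, k = 2)
  expect_equal(s1$p, s2$p, tolerance = 1e-8)

  expect_error(solve_mode(matrix(c(0, 1, 0, 0), 2, 2), diag(2), k = 1),
               "symmetric")
})

test_that("full-rank GTDA is an isometry on pairwise inner products", {
  set.seed(8)
  ts <- lapply(1:10, function(i) rand_tensor(c(3, 2, 2)))
  labels <- rep(c(0, 1), 5)
  fit <- gtda_fit(ts, labels, target_dims = c(3, 2, 2))
  for (l in 1:3) {
    expect_equal(crossprod(fit$p[[l]]), diag(ncol(fit$p[[l]])), tolerance = 1e-10)
  }
  tf <- lapply(ts, gtda_transform, proj = fit)
  for (i in 1:4) {
    expect_equal(tensor_inner(tf[[i]], tf[[i + 1]]),
                 tensor_inner(ts[[i]], ts[[i + 1]]), tolerance = 1e-8)
  }
})

test_that("GTDA recovers a planted mode-1 discriminant direction", {
  hits <- 0
  for (seed in 1:10) {
    d <- gen_planted_cft(200, dims = c(4, 3, 5), effect = 1, noise_sd = 0.1,
                         seed = seed, mode = "gtda")
    fit <- gtda_fit(d$tensors, d$labels, target_dims = c(1, 1, 1))
    expect_true(all(diff(fit$objective_trace) >= -1e-8))
    for (l in 1:3) {
      expect_equal(crossprod(fit$p[[l]]), diag(1), tolerance = 1e-10)
    }
    if (abs(sum(fit$p[[1]][, 1] * d$u)) >= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("alternating GTDA matches a 1-degree rotation grid search on 2x2x1 tensors", {
  set.seed(9)
  ts <- lapply(1:12, function(i) rand_tensor(c(2, 2, 1)))
  shift <- array(c(1, 0.5, -0.3, 0.2), c(2, 2, 1))
  labels <- rep(c(0, 1), 6)
  ts <- lapply(seq_along(ts), function(i) ts[[i]] + labels[i] * shift)
  moments <- class_means(ts, labels)

  # with the third mode a singleton, every tensor is a 2x2 matrix and the
  # per-mode scatters have closed 2x2 forms; the objective below evaluates
  # the same criterion as the fit (scatters, ridged eta, trace) by direct
  # matrix arithmetic, cheap enough for the full 1-degree grid
  b_mats <- lapply(0:1, function(y) {
    my <- if (y == 0) moments$m0 else moments$m1
    (my - moments$m)[, , 1]
  })
  n_y <- c(moments$n0, moments$n1)
  d_mats <- lapply(seq_along(ts), function(i) {
    my <- if (labels[i] == 0) moments$m0 else moments$m1
    (ts[[i]] - my)[, , 1]
  })
  eigmax2 <- function(m) {
    tr <- m[1, 1] + m[2, 2]
    dt <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
    (tr + sqrt(max(tr^2 - 4 * dt, 0))) / 2
  }
  mode_obj <- function(p_self, vecs_b, vecs_d) {
    sb <- matrix(0, 2, 2); sw <- matrix(0, 2, 2)
    for (y in 1:2) sb <- sb + n_y[y] * tcrossprod(vecs_b[[y]])
    for (v in vecs_d) sw <- sw + tcrossprod(v)
    ridge <- 1e-6 * sum(diag(sw)) / 2
    swr <- sw + ridge * diag(2)
    inv <- solve(swr)
    eta <- if (max(abs(sb)) == 0) 0 else eigmax2(inv %*% sb)
    drop(crossprod(p_self, (sb - eta * sw) %*% p_self))
  }
  objective <- function(p1, p2) {
    mode_obj(p1, lapply(b_mats, function(b) b %*% p2),
             lapply(d_mats, function(d) d %*% p2)) +
      mode_obj(p2, lapply(b_mats, function(b) t(b) %*% p1),
               lapply(d_mats, function(d) t(d) %*% p1))
  }

  fit <- gtda_fit(ts, labels, target_dims = c(1, 1, 1), sweeps = 50,
                  tol = 1e-12)
  j_alt <- objective(fit$p[[1]], fit$p[[2]])

  angles <- seq(0, 179) * pi / 180
  j_grid <- -Inf
  for (th1 in angles) {
    p1 <- matrix(c(cos(th1), sin(th1)), 2, 1)
    for (th2 in angles) {
      p2 <- matrix(c(cos(th2), sin(th2)), 2, 1)
      j <- objective(p1, p2)
      if (j > j_grid) j_grid <- j
    }
  }
  expect_gte(j_alt, j_grid - 0.01 * max(abs(j_grid), 1e-8))
})

test_that("gtda_transform equals sequential contractions in any mode order", {
  x <- rand_tensor(c(3, 3, 2), seed = 10)
  ps <- list(qr.Q(qr(matrix(rnorm(9), 3, 3)))[, 1:2],
             qr.Q(qr(matrix(rnorm(9), 3, 3)))[, 1:2],
             matrix(c(1, 0), 2, 1))
  out <- gtda_transform(x, ps)
  oracle <- naive_mode_product(
    naive_mode_product(naive_mode_product(x, ps[[3]], 3), ps[[2]], 2), ps[[1]], 1)
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_equal(gtda_transform(x, list(diag(3), diag(3), diag(2))), x)
})
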