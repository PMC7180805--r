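test_that("toy grid extractor returns block means in a fixed order", {
  ex <- toy_grid_extractor(2, channels = 1)
  # 4x4 single-channel frame; cells are 2x2 blocks, column-major order
  frame <- array(matrix(1:16, 4, 4, byrow = TRUE), c(4, 4, 1))
  got <- ex$extract(frame)
  # block-mean oracle
  oracle <- c(mean(frame[1:2, 1:2, 1]), mean(frame[3:4, 1:2, 1]),
              mean(frame[1:2, 3:4, 1]), mean(frame[3:4, 3:4, 1]))
  expect_equal(got, oracle)
  expect_setequal(got, c(3.5, 5.5, 11.5, 13.5))

  const <- array(0.7, c(6, 6, 3))
  ex3 <- toy_grid_extractor(2)
  expect_equal(ex3$extract(const), rep(0.7, 12))
  expect_equal(ex3$output_dim, 12L)

  g1 <- toy_grid_extractor(1)
  frame3 <- rand_tensor(c(5, 4, 3), seed = 1)
  expect_equal(g1$extract(frame3),
               c(mean(frame3[, , 1]), mean(frame3[, , 2]), mean(frame3[, , 3])))

  expect_error(toy_grid_extractor(9)$extract(rand_tensor(c(4, 4, 3))), "exceeds")
})

test_that("extract_features maps frames to columns per backbone", {
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  fix <- rand_fixation_stack(1, c(8, 8), seed = 4)
  fix$maps <- rep(fix$maps, 3)          # uniform attention, weight 2
  rep3 <- build_representation(img, compute_giw(fix))
  fms <- extract_features(rep3, list(toy_grid_extractor(2), toy_grid_extractor(4)))

  expect_length(fms$matrices, 2)
  expect_equal(dim(fms$matrices[[1]]), c(12L, 3L))
  expect_equal(dim(fms$matrices[[2]]), c(48L, 3L))
  # identical frames -> identical columns
  expect_equal(fms$matrices[[1]][, 1], fms$matrices[[1]][, 2])
  # uniform attention doubles the raw-image features (block means are linear)
  raw <- toy_grid_extractor(2)$extract(img)
  expect_equal(fms$matrices[[1]][, 1], 2 * raw)

  expect_error(extract_features(rep3, list()), "at least one")
})

test_that("FDA finds the discriminant direction and completes orthonormally", {
  set.seed(5)
  n <- 150
  x <- rbind(matrix(rnorm(2 * n), n, 2),
             matrix(rnorm(2 * n), n, 2) + matrix(c(4, 0), n, 2, byrow = TRUE))
  y <- rep(c(0, 1), each = n)

  fisher_ratio <- function(v) {
    p0 <- x[y == 0, ] %*% v; p1 <- x[y == 1, ] %*% v
    (mean(p1) - mean(p0))^2 / (var(drop(p0)) + var(drop(p1)))
  }
  proj <- fda_fit(x, y, k = 1)
  expect_gte(fisher_ratio(proj$basis), fisher_ratio(c(1, 0)))
  expect_gte(fisher_ratio(proj$basis), fisher_ratio(c(0, 1)))

  # full-dimension projection is a rotation: pairwise distances preserved
  proj2 <- fda_fit(x, y, k = 2)
  expect_equal(crossprod(proj2$basis), diag(2), tolerance = 1e-10)
  z <- fda_transform(proj2, x[1:10, ])
  expect_equal(as.numeric(dist(z)), as.numeric(dist(x[1:10, ])),
               tolerance = 1e-8)

  # flipping the label convention leaves the subspace unchanged
  pf <- fda_fit(x, 1 - y, k = 1)
  expect_equal(abs(sum(pf$basis * proj$basis)), 1, tolerance = 1e-8)

  expect_error(fda_fit(x, rep(0, 2 * n), k = 1), "both classes")
  expect_error(fda_fit(x, y, k = 3), "exceeds")
})

test_that("CFT assembly stacks projected backbones in order", {
  # hand-assembled: 2 backbones already at d1f = 2, identity projections
  id_proj <- function(p) structure(list(mean = rep(0, p), basis = diag(p), ridge = 0),
                                   class = "fda_projection")
  m1 <- matrix(c(1, 2, 3, 4), 2, 2)    # dim 2 x d4 2
  m2 <- matrix(c(5, 6, 7, 8), 2, 2)
  fms <- structure(list(matrices = list(m1, m2), backbones = c("a", "b")),
                   class = "feature_matrix_set")
  cft <- build_cft(fms, list(id_proj(2), id_proj(2)))
  expect_equal(dim(cft), c(2L, 2L, 2L))
  expect_equal(cft[, 1, ], m1)
  expect_equal(cft[, 2, ], m2)
  for (i in 1:2) for (b in 1:2) for (f in 1:2) {
    expect_equal(cft[i, b, ], list(m1, m2)[[b]][i, ])
  }

  # permuting backbone order permutes mode-2 slices identically
  fms_rev <- structure(list(matrices = list(m2, m1), backbones = c("b", "a")),
                       class = "feature_matrix_set")
  cft_rev <- build_cft(fms_rev, list(id_proj(2), id_proj(2)))
  expect_equal(cft_rev[, 1, ], cft[, 2, ])
  expect_equal(cft_rev[, 2, ], cft[, 1, ])

  expect_error(build_cft(fms, list(id_proj(2))), "one projection per backbone")
  expect_error(build_cft(fms, list(id_proj(2), id_proj(3))), "unified dimension")
})
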