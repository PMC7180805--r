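test_that("gaze samples are binned by midpoint into half-open frames", {
  rec <- gaze_recording(x = c(1, 2), y = c(1, 2),
                        onset = c(0, 0.85), duration = c(0.2, 0.1))
  # span [0, 0.95], midpoints 0.1 and 0.9
  bins1 <- bin_gaze_to_frames(rec, 1)
  expect_length(bins1, 1)
  expect_equal(nrow(bins1[[1]]), 2)

  bins2 <- bin_gaze_to_frames(rec, 2)
  expect_equal(nrow(bins2[[1]]), 1)
  expect_equal(nrow(bins2[[2]]), 1)
  expect_equal(bins2[[1]]$x, 1)
  expect_equal(bins2[[2]]$x, 2)

  # midpoint exactly on an interior boundary goes to the later bin:
  # span [0, 2], midpoint of sample 2 = 1.0 = boundary of 2 bins
  rec2 <- gaze_recording(x = c(0, 5, 9), y = c(0, 5, 9),
                         onset = c(0, 0.9, 1.8), duration = c(0.2, 0.2, 0.2))
  bins <- bin_gaze_to_frames(rec2, 2)
  expect_equal(bins[[2]]$x, c(5, 9))

  expect_error(gaze_recording(numeric(0), numeric(0), numeric(0), numeric(0)),
               "at least one sample")
})

test_that("fixation maps vote duration, smooth mass-preservingly, and floor at epsilon", {
  shape <- c(16, 16)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      onset = numeric(0), duration = numeric(0))
  one <- data.frame(x = 7, y = 5, onset = 0, duration = 1)

  fix <- build_fixation_maps(list(empty, one, one), shape,
                             sigma = 0.8, epsilon = 1e-6)
  expect_equal(fix$maps[[1]], matrix(1e-6, 16, 16))
  # mass of a single unit vote is conserved by reflect-padding smoothing
  expect_equal(sum(fix$maps[[2]]), 1 + 1e-6 * prod(shape), tolerance = 1e-10)
  # peak at the voted pixel (0-based (7,5) -> row 6, col 8)
  expect_equal(which(fix$maps[[2]] == max(fix$maps[[2]])),
               (8 - 1) * 16 + 6)
  # identical votes give identical maps
  expect_identical(fix$maps[[2]], fix$maps[[3]])

  expect_error(build_fixation_maps(list(one), shape, sigma = -1), "sigma")
  expect_error(build_fixation_maps(list(one), shape, sigma = 1, epsilon = 0),
               "epsilon")
})

test_that("GIW matrices normalize to a per-pixel frame sum of 2*d4", {
  # identical maps -> every weight is the constant 2
  fix <- rand_fixation_stack(1, c(3, 4), seed = 1)
  fix$maps <- rep(fix$maps, 3)
  giw <- compute_giw(fix)
  for (f in 1:3) expect_equal(giw$weights[[f]], matrix(2, 3, 4))

  # hand-evaluated 1x2 example
  fix2 <- structure(list(maps = list(matrix(c(2, 1), 1), matrix(c(2, 3), 1)),
                         sigma = 1, epsilon = 1e-6),
                    class = "fixation_map_stack")
  giw2 <- compute_giw(fix2)
  expect_equal(giw2$weights[[1]], matrix(c(2, 1.5), 1))
  expect_equal(giw2$weights[[2]], matrix(c(2, 2.5), 1))
  expect_equal(giw2$weights[[1]] + giw2$weights[[2]], matrix(4, 1, 2))

  # scale invariance and per-pixel sum over random stacks
  for (seed in 1:5) {
    d4 <- c(1, 2, 5, 10, 100)[seed]
    fix <- rand_fixation_stack(d4, c(4, 5), seed = seed)
    giw <- compute_giw(fix)
    expect_equal(Reduce(`+`, giw$weights), matrix(2 * d4, 4, 5),
                 tolerance = 1e-10)
    fix_scaled <- fix
    fix_scaled$maps <- lapply(fix$maps, `*`, 37.5)
    expect_equal(compute_giw(fix_scaled)$weights, giw$weights,
                 tolerance = 1e-12)
  }
})

test_that("representation weights channels per frame and reconstructs exactly", {
  set.seed(2)
  img <- array(runif(6 * 5 * 3), c(6, 5, 3))

  # uniform attention: all weights 2, every frame is twice the image
  fix <- rand_fixation_stack(1, c(6, 5), seed = 3)
  fix$maps <- rep(fix$maps, 4)
  rep4 <- build_representation(img, compute_giw(fix))
  for (f in 1:4) expect_equal(rep4$tensor[, , , f], 2 * img)
  expect_equal(reconstruct_image(rep4), img, tolerance = 1e-10)

  # zero image stays zero
  rep0 <- build_representation(array(0, c(6, 5, 3)), compute_giw(fix))
  expect_true(all(rep0$tensor == 0))

  # random positive stacks: reconstruction identity to 1e-10
  for (seed in 1:5) {
    fix <- rand_fixation_stack(5, c(6, 5), seed = seed + 10)
    r <- build_representation(img, compute_giw(fix))
    expect_lt(max(abs(reconstruct_image(r) - img)), 1e-10)
  }

  bad <- compute_giw(rand_fixation_stack(2, c(3, 3), seed = 1))
  expect_error(build_representation(img, bad), "shape")
})
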