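make_static_stack <- function(h = 60, w = 70, n = 3, seed = 1) {
  withr::local_seed(seed)
  fr <- random_frame(h, w)
  frame_stack(rep(list(fr), n))
}

test_that("a static textured stack aligns at the identity offset", {
  st <- stabilize(make_static_stack(), template_margin_px = 10)
  expect_true(all(st$offsets$x == 10))
  expect_true(all(st$offsets$y == 10))
  expect_identical(st$template_size, c(w = 50L, h = 40L))
  templ <- make_static_stack()$frames[[1]][11:50, 11:60, , drop = FALSE]
  for (f in st$aligned$frames) expect_identical(f, templ)
})

test_that("injected integer jitter is recovered exactly", {
  for (seed in c(3, 8)) {
    sim <- jittered_texture_stack(seed, jitter_max = 6)
    st <- stabilize(sim$stack, template_margin_px = 8)
    jo <- sim$ground_truth$jitter_offsets
    expect_identical(st$offsets$x, as.integer(8 - jo$dx))
    expect_identical(st$offsets$y, as.integer(8 - jo$dy))
  }
})

test_that("stabilization output has the template size and rejects degenerate input", {
  sim <- jittered_texture_stack(2, jitter_max = 2, width = 90, height = 72,
                                n_frames = 5)
  st <- stabilize(sim$stack, template_margin_px = 5)
  expect_length(st$aligned$frames, 5)
  expect_identical(dim(st$aligned$frames[[1]]), c(72L - 10L, 90L - 10L, 3L))

  flat <- frame_stack(list(array(100L, c(30, 30, 3))))
  expect_error(stabilize(flat, 5), "untextured")
  small <- frame_stack(list(random_frame(8, 8)))
  expect_error(stabilize(small, 10), "margin")
})

test_that("min-green composite picks the lowest-G frame and keeps its full color", {
  f <- function(v) array(as.integer(v), dim = c(1, 1, 3))
  st <- frame_stack(list(f(c(200, 120, 90)), f(c(180, 80, 70)),
                         f(c(210, 200, 190))))
  cmp <- min_green_composite(st)
  expect_identical(as.integer(cmp$image), c(180L, 80L, 70L))
  expect_identical(cmp$source_frame_index[1, 1], 2L)

  single <- frame_stack(list(random_frame(9, 7)))
  expect_identical(min_green_composite(single)$image, single$frames[[1]])

  # tie on minimal G: earliest frame wins
  a <- f(c(10, 50, 30)); b <- f(c(90, 50, 70))
  cmp2 <- min_green_composite(frame_stack(list(a, b)))
  expect_identical(as.integer(cmp2$image), c(10L, 50L, 30L))
  expect_identical(cmp2$source_frame_index[1, 1], 1L)
})

test_that("composite equals the per-pixel loop oracle and dominates no frame's G", {
  withr::local_seed(11)
  for (rep in 1:5) {
    frames <- replicate(4, random_frame(12, 9), simplify = FALSE)
    cmp <- min_green_composite(frame_stack(frames))
    orc <- oracle_composite(frames)
    expect_identical(cmp$image, orc$image)
    expect_identical(cmp$source_frame_index, orc$index)
    for (f in frames) expect_true(all(cmp$image[, , 2] <= f[, , 2]))
    # invariant: image[p] comes verbatim from the recorded source frame
    for (c in 1:3) {
      picked <- mapply(function(i, j, k) frames[[k]][i, j, c],
                       row(orc$index), col(orc$index), orc$index)
      expect_identical(as.vector(cmp$image[, , c]), as.integer(picked))
    }
  }
})

test_that("flat-fielding leaves a constant image unchanged and flattens a vignette", {
  img <- array(rep(c(100L, 150L, 200L), each = 20), dim = c(4, 5, 3))
  expect_identical(flatten_illumination(img, flat_field_config(kernel_radius_px = 2)),
                   img)
  expect_equal(flat_field_config()$kernel_radius_px, 300L)

  v <- vignette_field(200, 200, 0.8)
  scene <- array(0L, c(200, 200, 3))
  for (c in 1:3) scene[, , c] <- as.integer(round(180 * v))
  out <- flatten_illumination(scene, flat_field_config(kernel_radius_px = 25))
  interior <- function(m) m[26:175, 26:175]
  cv <- function(m) sd(m) / mean(m)
  expect_gt(cv(interior(scene[, , 2] * 1.0)), 0.10)
  expect_lt(cv(interior(out[, , 2] * 1.0)), 0.01)
})

test_that("contrast enhancement preserves gamma endpoints and degenerate histograms", {
  glut <- function(v, g) round(255 * (v / 255)^g)
  expect_equal(glut(0, 0.3), 0)
  expect_equal(glut(255, 0.3), 255)
  expect_equal(glut(128, 0.3), 207)

  img <- array(77L, c(6, 6, 3))
  out <- enhance_contrast(img, contrast_config())
  expect_true(all(out[, , 1] == out[1, 1, 1]))  # constant stays constant

  # gamma-only path hits the closed form exactly
  ramp <- array(rep(0:255, length.out = 16 * 16 * 3), c(16, 16, 3))
  out2 <- enhance_contrast(as_int <- {storage.mode(ramp) <- "integer"; ramp},
                           contrast_config(apply_equalization = FALSE))
  expect_identical(as.vector(out2),
                   as.integer(floor(255 * (as.vector(ramp) / 255)^0.3 + 0.5)))
})

test_that("the preprocessing chain composes and keeps the template-crop size", {
  img <- array(123L, c(40, 50, 3))
  pp <- preprocess_video(frame_stack(list(img + array(sample(0:10, 6000, TRUE), c(40, 50, 3)))),
                         template_margin_px = 4,
                         flat = flat_field_config(kernel_radius_px = 5))
  expect_identical(dim(pp$still), c(32L, 42L, 3L))

  sim <- generate_scene(scene_config(width_px = 128, height_px = 96,
                                     n_frames = 10, n_capillaries = 3,
                                     jitter_max_px = 2, seed = 21))
  res <- preprocess_video(sim$stack, template_margin_px = 6,
                          flat = flat_field_config(kernel_radius_px = 20))
  expect_identical(dim(res$still), c(96L - 12L, 128L - 12L, 3L))
  # composite coverage: every vessel pixel that ever carried an RBC is dark
  # in the still relative to a single frame -- checked loosely via region
  # overlap: the still's dark-G pixels hit every ground-truth vessel
  gt <- crop_margin(sim$ground_truth$capillary_mask, 6)
  g <- res$still[, , 2]
  dark <- matrix(0L, nrow(g), ncol(g))
  dark[g <= quantile(g, 0.15)] <- 255L
  rc <- region_confusion(dark, gt)
  expect_equal(rc$recall, 1)
})
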