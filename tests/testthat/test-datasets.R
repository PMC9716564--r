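# Cluttered-cube dataset generation.

test_that("synth_glyphs counts, determinism and value range", {
  gl <- synth_glyphs(3, 10, seed = 1)
  expect_length(gl, 30)
  expect_equal(table(vapply(gl, `[[`, integer(1), "label")),
               table(rep(0:2, each = 10)))
  expect_identical(gl, synth_glyphs(3, 10, seed = 1))
  rng <- range(unlist(lapply(gl, `[[`, "pixels")))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  expect_error(synth_glyphs(1, 5), "n_classes")
})

test_that("glyph classes are separable by a nearest-template oracle", {
  n <- 5
  templates <- synth_glyphs(n, 1, seed = 99, jitter = FALSE)
  samples <- synth_glyphs(n, 60, seed = 7)  # 300 samples
  tm <- vapply(templates, function(t) as.numeric(t$pixels), numeric(784))
  correct <- vapply(samples, function(s) {
    sc <- cor(as.numeric(s$pixels), tm)
    (which.max(sc) - 1L) == s$label
  }, logical(1))
  expect_gte(mean(correct), 0.95)
})

test_that("make_clutter is seeded, bounded and rejects empty pools", {
  pool <- synth_glyphs(4, 5, seed = 2)
  c1 <- make_clutter(pool, seed = 5)
  expect_identical(c1, make_clutter(pool, seed = 5))
  expect_equal(dim(c1), c(28L, 28L))
  # range stays in [0,1] over many seeded draws
  ex <- range(vapply(1:200, function(s) range(make_clutter(pool, seed = s)),
                     numeric(2)))
  expect_gte(ex[1], 0); expect_lte(ex[2], 1)
  # all-zero pool gives all-zero clutter
  zp <- list(list(pixels = matrix(0, 28, 28), label = 0L))
  expect_true(all(make_clutter(zp, seed = 1) == 0))
  expect_error(make_clutter(list()), "empty")
})

test_that("colorize maps intensities onto the fg/bg colour axis", {
  g <- matrix(0, 4, 4); g[1, 1] <- 1; g[2, 2] <- 0.5
  out <- colorize(g, fg_color = c(1, 0, 0), bg_color = c(0, 0, 1))
  expect_equal(out[1, 1, ], c(1, 0, 0))          # full intensity -> fg
  expect_equal(out[3, 3, ], c(0, 0, 1))          # zero -> bg
  expect_equal(out[2, 2, ], c(0.5, 0, 0.5))      # proportional blend
  allbg <- colorize(matrix(0, 4, 4), c(1, 0, 0), c(0, 0, 1))
  expect_true(all(allbg[, , 3] == 1) && all(allbg[, , 1:2] == 0))
  expect_error(colorize(g, c(1, 0, 0), c(1, 0, 0)), "differ")
})

test_that("build_cube places one target and three shuffled clutter faces", {
  gl <- synth_glyphs(4, 2, seed = 3)
  target <- gl[[1]]
  pool <- gl[vapply(gl, `[[`, integer(1), "label") != target$label]
  cl <- lapply(1:3, function(k) make_clutter(pool, seed = k))
  sc <- build_cube(target, cl, seed = 9)
  expect_s3_class(sc, "cube_scene")
  expect_equal(sc$target_face_azimuth, 0)
  expect_equal(sc$target_class, target$label)
  # exactly one face equals the target texture
  eq <- vapply(sc$face_textures, function(tx)
    isTRUE(all.equal(tx[, , 1], target$pixels)), logical(1))
  expect_equal(sum(eq), 1L)
  expect_true(eq[1])
  # same seed -> same assignment
  sc2 <- build_cube(target, cl, seed = 9)
  expect_identical(sc$face_textures, sc2$face_textures)
  # no clutter face equals the target
  for (f in 2:4)
    expect_false(isTRUE(all.equal(sc$face_textures[[f]][, , 1], target$pixels)))
  expect_error(build_cube(target, list(matrix(0, 14, 14), cl[[2]], cl[[3]])),
               "shape")
})

test_that("RGB cubes carry three channels on every face", {
  gl <- synth_glyphs(3, 4, seed = 4)
  sp <- dataset_spec(n_classes = 3, split_sizes = c(4, 2, 2), seed = 5,
                     mode = "rgb")
  splits <- generate_split(gl, sp)
  for (sc in c(splits$train, splits$val, splits$test))
    for (tx in sc$face_textures) expect_equal(dim(tx)[3], 3L)
})

test_that("generate_split sizes, disjointness and determinism", {
  gl <- synth_glyphs(3, 50, seed = 6)
  sp <- dataset_spec(n_classes = 3, split_sizes = c(100, 20, 20), seed = 11)
  splits <- generate_split(gl, sp)
  expect_length(splits$train, 100)
  expect_length(splits$val, 20)
  expect_length(splits$test, 20)
  # all cubes have exactly one target face at azimuth 0
  for (sc in splits$test) {
    expect_equal(sc$target_face_azimuth, 0)
    expect_true(sc$target_class %in% 0:2)
  }
  # disjoint target textures across splits (compare a hash of each target)
  key <- function(sc) paste(round(sc$face_textures[[1]][, , 1], 6), collapse = ",")
  ktr <- vapply(splits$train, key, character(1))
  kte <- vapply(splits$test, key, character(1))
  expect_length(intersect(ktr, kte), 0)
  # pure function of (images, seed)
  splits2 <- generate_split(gl, sp)
  expect_identical(splits, splits2)
  expect_error(generate_split(gl[1:10], sp), "source images")
})

test_that("target classes are close to uniform across many cubes", {
  gl <- synth_glyphs(4, 80, seed = 8)
  sp <- dataset_spec(n_classes = 4, split_sizes = c(280, 20, 20), seed = 13)
  splits <- generate_split(gl, sp)
  tab <- table(vapply(splits$train, `[[`, integer(1), "target_class"))
  expect_gt(chisq.test(tab)$p.value, 1e-4)
})
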