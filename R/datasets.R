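# Cluttered-cube dataset construction. Cube faces carry 28x28 images
# (grayscale or RGB): one target image on the azimuth-0 face and composite
# clutter on the other three vertical faces. A procedural glyph generator
# stands in for handwriting/sketch image sets, so the whole pipeline runs
# from code alone; IDX/NPY loaders for external sets are out of scope here.

# ---- procedural glyphs ----------------------------------------------------

# Stroke library: each class is a distinct composition of line segments on a
# 28x28 canvas (coordinates in pixels, origin top-left). Circles/arcs are
# polylines. Ten stroke patterns are defined; n_classes selects the first n.
glyph_strokes <- function(class_id) {
  poly <- function(xs, ys) cbind(xs[-length(xs)], ys[-length(ys)], xs[-1], ys[-1])
  circ <- function(cx, cy, rad, n = 16) {
    a <- seq(0, 2 * pi, length.out = n + 1)
    poly(cx + rad * cos(a), cy + rad * sin(a))
  }
  switch(class_id + 1L,
    rbind(c(14, 5, 14, 23), c(5, 14, 23, 14)),                     # cross
    rbind(c(6, 6, 22, 22), c(22, 6, 6, 22)),                       # X
    circ(14, 14, 7),                                               # circle
    rbind(c(7, 7, 7, 21), c(14, 7, 14, 21), c(21, 7, 21, 21)),     # three bars
    poly(c(14, 22, 6, 14), c(6, 22, 22, 6)),                       # triangle
    rbind(c(6, 7, 22, 7), c(14, 7, 14, 23)),                       # T
    poly(c(6, 22, 6, 22), c(7, 7, 21, 21)),                        # Z
    rbind(c(8, 5, 8, 22), c(8, 22, 22, 22)),                       # L
    poly(c(14, 23, 14, 5, 14), c(5, 14, 23, 14, 5)),               # diamond
    poly(c(6, 14, 22), c(6, 22, 6))                                # V
  )
}

# Rasterize segments with a soft 1-px edge profile at the given stroke width.
rasterize_strokes <- function(seg, width = 1.6, size = 28L) {
  xs <- rep(seq_len(size) - 0.5, each = size)   # column coordinate
  ys <- rep(seq_len(size) - 0.5, times = size)  # row coordinate
  img <- numeric(size * size)
  for (s in seq_len(nrow(seg))) {
    ax <- seg[s, 1]; ay <- seg[s, 2]; bx <- seg[s, 3]; by <- seg[s, 4]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    tt <- if (L2 == 0) 0 else pmin(1, pmax(0, ((xs - ax) * vx + (ys - ay) * vy) / L2))
    d <- sqrt((ax + tt * vx - xs)^2 + (ay + tt * vy - ys)^2)
    img <- pmax(img, pmin(1, pmax(0, width / 2 + 0.5 - d)))
  }
  matrix(img, size, size)  # rows = y, cols = x
}

#' Procedural glyph images
#'
#' Generates labelled 28x28 grayscale images from a library of distinct
#' stroke templates (cross, X, circle, square, ...), one template per class,
#' with per-sample random affine jitter (rotation up to +/-15 degrees,
#' translation up to +/-2 px) and stroke-width noise. A download-free stand-in
#' with handwriting/sketch-like statistics for the cube datasets.
#'
#' @param n_classes number of classes (2..10).
#' @param n_per_class samples per class.
#' @param seed integer seed; the same seed reproduces the same images.
#' @param jitter set `FALSE` to get the clean class templates (used e.g. as
#'   a nearest-template classification oracle).
#' @return list of labelled images, each `list(pixels = 28x28 matrix,
#'   label = class id in 0..n_classes-1)`.
#' @export
synth_glyphs <- function(n_classes, n_per_class, seed = 1L, jitter = TRUE) {
  if (n_classes < 2 || n_classes > 10)
    stopf("synth_glyphs: n_classes must be in 2..10")
  with_seed(seed, {
    out <- vector("list", n_classes * n_per_class)
    i <- 0L
    for (cl in seq_len(n_classes) - 1L) {
      seg0 <- glyph_strokes(cl)
      for (s in seq_len(n_per_class)) {
        seg <- seg0
        wdt <- 3.2
        if (jitter) {
          ang <- stats::runif(1, -15, 15) * pi / 180
          shift <- stats::runif(2, -2, 2)
          wdt <- 3.2 + stats::runif(1, -0.3, 0.3)
          rot <- function(x, y)
            cbind(cos(ang) * (x - 14) - sin(ang) * (y - 14) + 14 + shift[1],
                  sin(ang) * (x - 14) + cos(ang) * (y - 14) + 14 + shift[2])
          a <- rot(seg[, 1], seg[, 2]); b <- rot(seg[, 3], seg[, 4])
          seg <- cbind(a, b)
        }
        i <- i + 1L
        out[[i]] <- list(pixels = rasterize_strokes(seg, wdt), label = cl)
      }
    }
    out
  })
}

# ---- clutter and colour ---------------------------------------------------

#' Composite clutter image
#'
#' Builds a nontarget texture by pasting 2-4 randomly cropped fragments
#' (8x8 to 16x16 px) of randomly chosen pool images at random positions,
#' taking the pixelwise maximum where fragments overlap; output clipped to
#' `[0, 1]`. Deterministic under `seed`.
#'
#' @param source_pool non-empty list of labelled images (as from
#'   [synth_glyphs()]); grayscale and RGB pools both work.
#' @param seed optional integer seed.
#' @return clutter image with the pool's shape and channels.
#' @export
make_clutter <- function(source_pool, seed = NULL) {
  if (length(source_pool) == 0) stopf("make_clutter: source pool is empty")
  with_seed(seed, {
    proto <- source_pool[[1]]$pixels
    d <- dim(proto)
    C <- if (length(d) == 3L) d[3] else 1L
    out <- array(0, c(28L, 28L, C))
    for (f in seq_len(sample(2:4, 1))) {
      src <- source_pool[[sample(length(source_pool), 1)]]$pixels
      if (length(dim(src)) == 2L) src <- array(src, c(dim(src), 1L))
      fs <- sample(8:16, 1)
      r0 <- sample(28L - fs + 1L, 1); c0 <- sample(28L - fs + 1L, 1)
      frag <- src[r0:(r0 + fs - 1L), c0:(c0 + fs - 1L), , drop = FALSE]
      r1 <- sample(28L - fs + 1L, 1); c1 <- sample(28L - fs + 1L, 1)
      tgt <- out[r1:(r1 + fs - 1L), c1:(c1 + fs - 1L), , drop = FALSE]
      out[r1:(r1 + fs - 1L), c1:(c1 + fs - 1L), ] <- pmax(tgt, frag)
    }
    out <- pmin(pmax(out, 0), 1)
    if (C == 1L) out <- matrix(out, 28L, 28L)
    out
  })
}

#' Colorize a grayscale image
#'
#' Pixels at or above the intensity threshold are blended from the
#' background colour toward the foreground colour in proportion to their
#' intensity; the rest become the background colour.
#'
#' @param gray 28x28 matrix (or any 2-D matrix) of intensities in `[0, 1]`.
#' @param fg_color,bg_color RGB triples in `[0, 1]`; must differ.
#' @param threshold intensity cut-off in (0, 1), default 0.2.
#' @return array `nrow x ncol x 3` in `[0, 1]`.
#' @export
colorize <- function(gray, fg_color, bg_color, threshold = 0.2) {
  if (all(fg_color == bg_color))
    stopf("colorize: foreground and background colours must differ")
  if (threshold <= 0 || threshold >= 1) stopf("colorize: threshold must be in (0,1)")
  d <- dim(gray)
  out <- array(0, c(d, 3L))
  fg_mask <- gray >= threshold
  for (ch in 1:3) {
    plane <- matrix(bg_color[ch], d[1], d[2])
    plane[fg_mask] <- bg_color[ch] + gray[fg_mask] * (fg_color[ch] - bg_color[ch])
    out[, , ch] <- plane
  }
  pmin(pmax(out, 0), 1)
}

# Fixed 8-colour palette used when colorizing whole datasets.
glyph_palette <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0),
        c(1, 0, 1), c(0, 1, 1), c(1, 1, 1), c(1, 0.5, 0))
}

# ---- cubes ----------------------------------------------------------------

#' Build a cluttered cube from a target and three clutter images
#'
#' The target texture goes on the azimuth-0 face; the three clutter textures
#' are shuffled onto the remaining vertical faces.
#'
#' @param target labelled image (`list(pixels, label)`).
#' @param clutter list of exactly 3 images (arrays/matrices, or labelled
#'   images whose `$pixels` are taken).
#' @param seed optional integer seed controlling the clutter shuffle.
#' @return a [cube_scene()] with `target_class = target$label`.
#' @export
build_cube <- function(target, clutter, seed = NULL) {
  stopifnot(length(clutter) == 3L)
  cl <- lapply(clutter, function(x) if (is.list(x)) x$pixels else x)
  as_arr <- function(x) if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
  tgt <- as_arr(target$pixels)
  cl <- lapply(cl, as_arr)
  dims <- vapply(cl, dim, integer(3))
  if (any(dims != dim(tgt)))
    stopf("build_cube: clutter shape does not match the target texture")
  ord <- with_seed(seed, sample(3L))
  cube_scene(c(list(tgt), cl[ord]), target_face_azimuth = 0,
             target_class = target$label)
}

#' Dataset specification
#'
#' @param n_classes number of target classes (default 10).
#' @param split_sizes named or positional `(train, val, test)` cube counts.
#' @param seed integer seed making generation a pure function of
#'   `(images, spec)`.
#' @param mode `"grayscale"` or `"rgb"`.
#' @return object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_classes = 10L, split_sizes = c(100L, 20L, 20L),
                         seed = 1L, mode = c("grayscale", "rgb")) {
  if (any(split_sizes <= 0)) stopf("dataset_spec: split sizes must be positive")
  structure(list(n_classes = as.integer(n_classes),
                 split_sizes = as.integer(split_sizes),
                 seed = as.integer(seed), mode = match.arg(mode)),
            class = "dataset_spec")
}

#' Generate train/validation/test cube splits
#'
#' Draws disjoint target images for the three splits, builds each cube with
#' [build_cube()] using composite clutter from other-class images, and (in
#' RGB mode) colorizes targets and clutter with seeded palette colours.
#'
#' @param images pool of labelled images (e.g. from [synth_glyphs()]).
#' @param spec a [dataset_spec()].
#' @return list with elements `train`, `val`, `test`, each a list of
#'   [cube_scene()] objects.
#' @export
generate_split <- function(images, spec) {
  total <- sum(spec$split_sizes)
  if (length(images) < total)
    stopf("generate_split: need %d source images, got %d", total, length(images))
  seeds <- derive_seeds(spec$seed, 2L + total)
  ord <- with_seed(seeds[1], sample(length(images)))
  labels <- vapply(images, `[[`, integer(1), "label")
  idx_splits <- split(ord[seq_len(total)],
                      rep(c("train", "val", "test"), spec$split_sizes))
  si <- 1L
  res <- lapply(c(train = "train", val = "val", test = "test"), function(nm) {
    lapply(idx_splits[[nm]], function(ti) {
      si <<- si + 1L
      sd <- seeds[1L + si - 1L]
      sub <- derive_seeds(sd, 6L)
      target <- images[[ti]]
      pool <- images[labels != target$label]
      cl <- lapply(1:3, function(k) make_clutter(pool, seed = sub[k]))
      if (spec$mode == "rgb") {
        pal <- glyph_palette()
        pick <- with_seed(sub[4], {
          m <- matrix(0L, 4, 2)
          for (r in 1:4) m[r, ] <- sample(nrow(pal), 2)
          m
        })
        gray2 <- function(x) if (is.matrix(x)) x else x[, , 1]
        target <- list(pixels = colorize(gray2(target$pixels),
                                         pal[pick[1, 1], ], pal[pick[1, 2], ]),
                       label = target$label)
        cl <- lapply(1:3, function(k)
          colorize(gray2(cl[[k]]), pal[pick[k + 1, 1], ], pal[pick[k + 1, 2], ]))
      }
      build_cube(target, cl, seed = sub[5])
    })
  })
  res
}
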