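# Minimal scenes: a distinctive target texture with blank clutter faces.

make_scene <- function(target = NULL, clutter = 0, C = 1L, az = 0) {
  if (is.null(target)) target <- array(1, c(28, 28, C))
  tex <- lapply(1:4, function(i) array(clutter, c(28, 28, C)))
  tex[[which(c(0, 90, 180, 270) == az)]] <- target
  cube_scene(tex, target_face_azimuth = az, target_class = 0L)
}

# A small 3-class glyph cube set shared by trainer/evaluation tests.
small_cube_set <- function(n_train = 12, n_val = 4, n_test = 4, seed = 123) {
  gl <- synth_glyphs(3, ceiling((n_train + n_val + n_test) / 3) + 2, seed = seed)
  sp <- dataset_spec(n_classes = 3, split_sizes = c(n_train, n_val, n_test),
                     seed = seed)
  generate_split(gl, sp)
}
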