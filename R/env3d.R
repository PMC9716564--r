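# Cube world: a textured cube at the origin, a camera on a horizontal
# circular orbit always looking at the centre, and a software pinhole
# renderer (perspective projection, back-face culling, bilinear texture
# sampling). Azimuth theta is in degrees; theta = 0 is directly in front of
# the azimuth-0 face; the camera position is (r sin(theta), 0, r cos(theta)).

#' Cube scene
#'
#' Four vertical face textures, one of which carries the target image; the
#' two horizontal faces are a constant fill (never visible from the
#' equatorial orbit).
#'
#' @param face_textures list of 4 texture arrays (`H x W` or `H x W x C`,
#'   values in `[0, 1]`), in azimuth order 0, 90, 180, 270 degrees.
#' @param target_face_azimuth azimuth of the target face, one of 0, 90, 180,
#'   270 (default 0).
#' @param target_class integer class id of the target image.
#' @param top_bottom_fill fill value for the horizontal faces.
#' @return object of class `cube_scene`.
#' @export
cube_scene <- function(face_textures, target_face_azimuth = 0,
                       target_class = NA_integer_, top_bottom_fill = 0) {
  stopifnot(length(face_textures) == 4L)
  face_textures <- lapply(face_textures, function(tx) {
    if (is.matrix(tx)) tx <- array(tx, c(dim(tx), 1L))
    tx
  })
  dims <- vapply(face_textures, function(tx) dim(tx), integer(3))
  if (any(dims != dims[, 1]))
    stopf("cube_scene: all four face textures must share shape and channels")
  if (!target_face_azimuth %in% c(0, 90, 180, 270))
    stopf("cube_scene: target_face_azimuth must be one of 0, 90, 180, 270")
  rng <- range(unlist(lapply(face_textures, range)))
  if (rng[1] < 0 || rng[2] > 1)
    stopf("cube_scene: texture values must lie in [0, 1]")
  structure(list(face_textures = face_textures,
                 face_azimuths = c(0, 90, 180, 270),
                 target_face_azimuth = target_face_azimuth,
                 target_class = as.integer(target_class),
                 top_bottom_fill = top_bottom_fill,
                 channels = dims[3, 1]),
            class = "cube_scene")
}

#' Render configuration
#'
#' @param view_height,view_width view size in pixels (default 75 x 100).
#' @param cube_edge cube edge length in world units (default 2: faces span
#'   `[-1, 1]`).
#' @param vertical_fov vertical field of view in degrees (default 45).
#' @param background fill value in `[0, 1]` for rays that miss the cube.
#' @return object of class `render_config`.
#' @export
render_config <- function(view_height = 75L, view_width = 100L, cube_edge = 2,
                          vertical_fov = 45, background = 0) {
  if (view_height < 1 || view_width < 1)
    stopf("render_config: view dimensions must be positive")
  if (!(vertical_fov > 0 && vertical_fov < 180))
    stopf("render_config: vertical_fov must be in (0, 180)")
  if (cube_edge <= 0) stopf("render_config: cube_edge must be positive")
  structure(list(view_height = as.integer(view_height),
                 view_width = as.integer(view_width),
                 cube_edge = cube_edge, vertical_fov = vertical_fov,
                 background = background),
            class = "render_config")
}

#' Camera pose on the orbit
#'
#' @param theta azimuth in degrees (wrapped to `[0, 360)`).
#' @param r orbit radius in world units (default 2.5).
#' @return object of class `camera_pose` with the world position
#'   `(r sin(theta), 0, r cos(theta))` and a look-at-origin contract.
#' @export
camera_pose <- function(theta, r = 2.5) {
  if (!is.finite(theta)) stopf("camera_pose: theta must be finite")
  if (r <= 0) stopf("camera_pose: r must be positive")
  theta <- wrap_theta(theta)
  th <- theta * pi / 180
  structure(list(r = r, theta = theta, phi = 0,
                 position = c(r * sin(th), 0, r * cos(th))),
            class = "camera_pose")
}

#' Advance the camera azimuth by one action
#'
#' @param theta current azimuth in degrees.
#' @param action one of `"right"`, `"left"`, `"stay"` (or action index
#'   1, 2, 3 in that order).
#' @param jump jump length in degrees (>= 0).
#' @return new azimuth in `[0, 360)`.
#' @export
step_camera <- function(theta, action, jump) {
  if (jump < 0) stopf("step_camera: jump must be >= 0")
  if (is.numeric(action)) {
    if (!action %in% 1:3) stopf("step_camera: unknown action index %s", action)
    action <- c("right", "left", "stay")[action]
  }
  switch(action,
         right = wrap_theta(theta + jump),
         left  = wrap_theta(theta - jump),
         stay  = wrap_theta(theta),
         stopf("step_camera: unknown action '%s'", action))
}

#' Signed angular offset from the target face
#'
#' Signed angular distance of the camera azimuth from the frontal azimuth of
#' the scene's target face, wrapped to `(-180, 180]`.
#'
#' @param theta camera azimuth in degrees.
#' @param scene a [cube_scene()].
#' @return signed degrees in `(-180, 180]`.
#' @export
relative_offset <- function(theta, scene) {
  d <- wrap_theta(theta - scene$target_face_azimuth)
  if (d > 180) d - 360 else d
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Bilinear texture lookup. tex: (H x W x C); rr, cc: continuous 0-based
# coordinates (vectors); returns (length(rr) x C).
tex_sample <- function(tex, rr, cc) {
  H <- dim(tex)[1]; W <- dim(tex)[2]; C <- dim(tex)[3]
  rr <- pmin(pmax(rr, 0), H - 1); cc <- pmin(pmax(cc, 0), W - 1)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  out <- matrix(0, length(rr), C)
  for (ch in seq_len(C)) {
    tx <- tex[, , ch]
    v00 <- tx[cbind(r0 + 1, c0 + 1)]; v10 <- tx[cbind(r1 + 1, c0 + 1)]
    v01 <- tx[cbind(r0 + 1, c1 + 1)]; v11 <- tx[cbind(r1 + 1, c1 + 1)]
    out[, ch] <- (1 - fr) * ((1 - fc) * v00 + fc * v01) +
                 fr * ((1 - fc) * v10 + fc * v11)
  }
  out
}

#' Render the camera view of a cube scene
#'
#' Software pinhole renderer: for every front-facing vertical face
#' (outward normal toward the camera), image rays are intersected with the
#' face plane and the face texture is sampled bilinearly; rays that hit no
#' face get the background fill. Deterministic - no RNG involved.
#'
#' @param scene a [cube_scene()].
#' @param pose a [camera_pose()].
#' @param cfg a [render_config()].
#' @return view array `view_height x view_width x C`, values in `[0, 1]`.
#' @export
render <- function(scene, pose, cfg = render_config()) {
  if (!inherits(pose, "camera_pose")) pose <- camera_pose(pose)
  H <- cfg$view_height; W <- cfg$view_width
  half <- cfg$cube_edge / 2
  p <- pose$position
  fwd <- -p / sqrt(sum(p * p))
  rightv <- cross3(fwd, c(0, 1, 0))
  rightv <- rightv / sqrt(sum(rightv * rightv))
  upv <- cross3(rightv, fwd)
  fpix <- (H / 2) / tan(cfg$vertical_fov / 2 * pi / 180)
  # pixel-centre camera coordinates (row 1 = top of view)
  jj <- rep(seq_len(W), each = H)
  ii <- rep(seq_len(H), W)
  xc <- (jj - (W + 1) / 2) / fpix
  yc <- ((H + 1) / 2 - ii) / fpix
  # ray directions d = fwd + xc*right + yc*up, one row per pixel
  dx <- fwd[1] + xc * rightv[1] + yc * upv[1]
  dy <- fwd[2] + xc * rightv[2] + yc * upv[2]
  dz <- fwd[3] + xc * rightv[3] + yc * upv[3]
  C <- scene$channels
  out <- matrix(cfg$background, H * W, C)
  for (fi in seq_along(scene$face_azimuths)) {
    az <- scene$face_azimuths[fi] * pi / 180
    n <- c(sin(az), 0, cos(az))
    ndp <- sum(n * p)
    if (ndp <= half) next                      # back-facing or edge-on
    ndd <- n[1] * dx + n[2] * dy + n[3] * dz
    tt <- (half - ndp) / ndd
    ok <- ndd < 0 & tt > 0
    if (!any(ok)) next
    hx <- p[1] + tt[ok] * dx[ok]
    hy <- p[2] + tt[ok] * dy[ok]
    hz <- p[3] + tt[ok] * dz[ok]
    tu <- c(cos(az), 0, -sin(az))              # in-plane horizontal axis
    u <- tu[1] * hx + tu[3] * hz
    v <- hy
    inface <- abs(u) <= half & abs(v) <= half
    if (!any(inface)) next
    tex <- scene$face_textures[[fi]]
    Ht <- dim(tex)[1]; Wt <- dim(tex)[2]
    uu <- u[inface]; vv <- v[inface]
    cc <- (uu + half) / (2 * half) * Wt - 0.5
    rr <- (half - vv) / (2 * half) * Ht - 0.5
    out[which(ok)[inface], ] <- tex_sample(tex, rr, cc)
  }
  array(out, c(H, W, C))
}

# Project a world point to continuous (row, col) image coordinates (1-based
# pixel centres); used only by tests as a corner-projection oracle and by
# the trace plotter.
project_point <- function(pt, pose, cfg = render_config()) {
  p <- pose$position
  fwd <- -p / sqrt(sum(p * p))
  rightv <- cross3(fwd, c(0, 1, 0))
  rightv <- rightv / sqrt(sum(rightv * rightv))
  upv <- cross3(rightv, fwd)
  fpix <- (cfg$view_height / 2) / tan(cfg$vertical_fov / 2 * pi / 180)
  d <- pt - p
  zc <- sum(d * fwd)
  c(row = (cfg$view_height + 1) / 2 - sum(d * upv) / zc * fpix,
    col = sum(d * rightv) / zc * fpix + (cfg$view_width + 1) / 2)
}
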