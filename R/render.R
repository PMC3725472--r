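#' Panoramic view parameters
#'
#' The renderer models the rat's wide visual field with an
#' equidistant-azimuth (cylindrical) projection: column `c` (0-based, of
#' `W`) looks along azimuth `heading + fov/2 - c * fov/(W-1)`, so both FoV
#' edge rays are rendered. The rat's full field of view is 320 degrees; a
#' 55 degree option matches a typical digital camera for robot work.
#'
#' @param fov Horizontal field of view in degrees, in `(0, 360]`.
#' @param width,height Frame size in pixels.
#' @param color_mode `"grayscale"`, `"color"`, or `"both"`.
#' @param wall_scale Distance (world units) at which a wall fills the frame
#'   vertically; the rendered wall span is proportional to `1/distance`.
#' @return An object of class `view_params`.
#' @export
view_params <- function(fov = 320, width = 320, height = 40,
                        color_mode = c("grayscale", "color", "both"),
                        wall_scale = 2) {
  color_mode <- match.arg(color_mode)
  if (fov <= 0 || fov > 360) stopf("fov must lie in (0, 360] degrees")
  if (width < 4 || height < 2) stopf("frame must be at least 4 x 2 pixels")
  structure(list(fov = fov, width = as.integer(width),
                 height = as.integer(height), color_mode = color_mode,
                 wall_scale = wall_scale),
            class = "view_params")
}

#' Azimuth of each rendered column
#'
#' @param view A [view_params()] object.
#' @param heading Agent heading in radians.
#' @return Radians, one per pixel column (left to right).
#' @export
column_azimuths <- function(view, heading = 0) {
  w <- view$width
  heading + deg2rad(view$fov / 2 - (0:(w - 1)) * view$fov / (w - 1))
}

#' Render the rat's-eye panoramic view at a pose
#'
#' Software raycaster: one ray per pixel column; the nearest wall hit sets
#' the vertical wall span (proportional to `1/distance`, clamped to the
#' frame) and the texture coordinate; pixels above and below the wall are
#' filled with fixed sky (200) and floor (40) levels.
#'
#' @param plan A `floorplan`.
#' @param state Pose: list or numeric with `x`, `y`, `heading` (radians).
#' @param view A [view_params()] object.
#' @param registry Texture registry (defaults to the plan's).
#' @return A `frame`: `height x width` numeric matrix (grayscale) or
#'   `height x width x 3` array (color), integer intensities 0-255, with a
#'   `pose` attribute.
#' @export
render_view <- function(plan, state, view = view_params(),
                        registry = plan$registry) {
  if (is.numeric(state)) state <- list(x = state[1], y = state[2], heading = state[3])
  color <- view$color_mode != "grayscale"
  fr <- render_view_internal(plan, state$x, state$y, state$heading, view,
                             registry, color = color)
  attr(fr, "pose") <- c(x = state$x, y = state$y, heading = state$heading)
  fr
}

render_view_internal <- function(plan, x, y, heading, view, registry, color) {
  H <- view$height; W <- view$width
  az <- column_azimuths(view, heading)
  hit <- ray_cast_many(plan, c(x, y), az)
  if (any(!is.finite(hit$distance))) {
    stopf("view at (%g, %g) hits no wall in some direction: open floor plan?",
          x, y)
  }
  segs <- plan$segments
  half <- (H / 2) * view$wall_scale / hit$distance   # half wall span, pixels
  center <- (H + 1) / 2
  top <- center - half
  bot <- center + half

  rows <- matrix(seq_len(H), H, W)
  topm <- matrix(top, H, W, byrow = TRUE)
  botm <- matrix(bot, H, W, byrow = TRUE)
  wall <- rows >= topm & rows <= botm
  v <- (rows - topm) / (botm - topm)                 # vertical texture coord

  # horizontal texture coord: tile along the wall by world length
  seg_len <- sqrt((segs$x2 - segs$x1)^2 + (segs$y2 - segs$y1)^2)[hit$segment]
  ucoord <- (hit$u * seg_len / registry$tile_width) %% 1

  tex_names <- segs$texture[hit$segment]
  nch <- if (color) 3L else 1L
  out <- array(0, dim = c(H, W, nch))
  sky <- if (color) c(200, 210, 225) else 200
  floor_col <- if (color) c(46, 40, 32) else 40
  for (k in seq_len(nch)) {
    ch <- matrix(sky[k], H, W)
    ch[rows > botm] <- floor_col[k]
    out[, , k] <- ch
  }
  for (nm in unique(tex_names)) {
    cols <- which(tex_names == nm)
    tx <- get_texture(registry, nm)
    timg <- if (color) tx$col else tx$gray
    th <- dim(timg)[1]; tw <- dim(timg)[2]
    tc <- pmin(tw, 1L + as.integer(floor(ucoord[cols] * tw)))
    sub_wall <- wall[, cols, drop = FALSE]
    sub_v <- v[, cols, drop = FALSE]
    tr <- pmin(th, pmax(1L, 1L + floor(sub_v * th)))
    tcm <- matrix(tc, H, length(cols), byrow = TRUE)
    sel <- which(sub_wall)
    for (k in seq_len(nch)) {
      page <- if (color) timg[, , k] else timg
      chan <- out[, cols, k]
      chan[sel] <- page[cbind(tr[sel], tcm[sel])]
      out[, cols, k] <- chan
    }
  }
  out <- round(out)
  if (!color) out <- out[, , 1]
  out
}

#' Convert a frame to grayscale
#'
#' Fixed luminance weights (0.299, 0.587, 0.114); 1-channel input is passed
#' through unchanged, so the operation is idempotent.
#'
#' @param frame A frame matrix/array, or a `frame_sequence`.
#' @export
to_grayscale <- function(frame) {
  if (inherits(frame, "frame_sequence")) {
    if (frame$color_mode == "grayscale") return(frame)
    a <- frame$frames
    g <- round(0.299 * a[, , 1, , drop = TRUE] + 0.587 * a[, , 2, , drop = TRUE] +
                 0.114 * a[, , 3, , drop = TRUE])
    if (length(dim(g)) == 2L) dim(g) <- c(dim(a)[1], dim(a)[2], 1L)
    frame$frames <- g
    frame$color_mode <- "grayscale"
    return(frame)
  }
  if (is.matrix(frame)) return(frame)
  pose <- attr(frame, "pose")
  g <- round(0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3])
  attr(g, "pose") <- pose
  g
}

#' Crop the central part of an image
#'
#' Used to conform arbitrary image sequences (natural movies etc.) to the
#' network's input size for generic lower-layer training. For odd size
#' differences the extra discarded pixel is taken from the left/top, i.e.
#' the retained window is biased one pixel toward the right/bottom.
#'
#' @param image Matrix or `H x W x C` array.
#' @param out_w,out_h Output size in pixels.
#' @export
crop_center <- function(image, out_w, out_h) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (out_w > w || out_h > h) {
    stopf("crop size %d x %d exceeds image size %d x %d", out_w, out_h, w, h)
  }
  r0 <- floor((h - out_h) / 2)
  c0 <- floor((w - out_w) / 2)
  rows <- (r0 + 1):(r0 + out_h)
  cols <- (c0 + 1):(c0 + out_w)
  if (length(d) == 2L) image[rows, cols, drop = FALSE]
  else image[rows, cols, , drop = FALSE]
}

#' Render the visual stream along a trajectory
#'
#' @param plan A `floorplan`.
#' @param trajectory Tibble with `x`, `y`, `heading` columns.
#' @param view A [view_params()] object.
#' @param registry Texture registry (defaults to the plan's).
#' @return A `frame_sequence`: list with `frames` (grayscale `H x W x T` or
#'   color `H x W x 3 x T` array), `pose` tibble, `view`, `color_mode`.
#' @export
render_frames <- function(plan, trajectory, view = view_params(),
                          registry = plan$registry) {
  T_ <- nrow(trajectory)
  color <- view$color_mode != "grayscale"
  H <- view$height; W <- view$width
  arr <- if (color) array(0, dim = c(H, W, 3L, T_)) else array(0, dim = c(H, W, T_))
  for (t in seq_len(T_)) {
    fr <- render_view_internal(plan, trajectory$x[t], trajectory$y[t],
                               trajectory$heading[t], view, registry, color)
    if (color) arr[, , , t] <- fr else arr[, , t] <- fr
  }
  frame_sequence(arr, pose = trajectory[, c("x", "y", "heading")], view = view)
}

#' Construct a frame sequence container
#'
#' @param frames Grayscale `H x W x T` or color `H x W x 3 x T` array.
#' @param pose Tibble with one `(x, y, heading)` row per frame (optional).
#' @param view The [view_params()] the frames were rendered with (optional).
#' @export
frame_sequence <- function(frames, pose = NULL, view = NULL) {
  nd <- length(dim(frames))
  if (!nd %in% c(3L, 4L)) stopf("frames must be an H x W x T or H x W x 3 x T array")
  color_mode <- if (nd == 4L) "color" else "grayscale"
  T_ <- dim(frames)[nd]
  if (!is.null(pose)) {
    pose <- tibble::as_tibble(pose)
    if (nrow(pose) != T_) stopf("pose table must have one row per frame")
  }
  structure(list(frames = frames, pose = pose, view = view,
                 color_mode = color_mode),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  nd <- length(d)
  cat(sprintf("<frame_sequence> %d frames of %d x %d (%s)\n",
              d[nd], d[2], d[1], x$color_mode))
  invisible(x)
}

#' Number of frames in a frame sequence
#' @param x A `frame_sequence`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "frame_sequence"))
  dim(x$frames)[length(dim(x$frames))]
}

# extract frame t as a plain matrix/array
get_frame <- function(x, t) {
  if (x$color_mode == "color") x$frames[, , , t] else x$frames[, , t]
}
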