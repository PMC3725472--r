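# Minimal deterministic raster toolkit: pixel-exact canvases for the
# wallcheck overview, trajectory overlays and plot files. Canvases are
# H x W x 3 arrays in [0, 1]; row 1 is the top of the image.

rl_canvas <- function(h, w, color = c(1, 1, 1)) {
  arr <- array(0, dim = c(h, w, 3))
  for (k in 1:3) arr[, , k] <- color[k]
  arr
}

rl_put <- function(canvas, rows, cols, color) {
  h <- dim(canvas)[1]; w <- dim(canvas)[2]
  keep <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
  rows <- rows[keep]; cols <- cols[keep]
  for (k in 1:3) canvas[cbind(rows, cols, k)] <- color[k]
  canvas
}

# draw a line by dense sampling (deterministic, no antialiasing)
rl_draw_line <- function(canvas, r1, c1, r2, c2, color = c(0, 0, 0),
                         dotted = FALSE) {
  n <- max(2L, ceiling(2 * max(abs(r2 - r1), abs(c2 - c1))))
  t <- seq(0, 1, length.out = n)
  if (dotted) t <- t[(seq_along(t) - 1) %% 8 < 4]
  rl_put(canvas, round(r1 + t * (r2 - r1)), round(c1 + t * (c2 - c1)), color)
}

rl_draw_disc <- function(canvas, r, c, radius, color) {
  span <- -radius:radius
  grid <- expand.grid(dr = span, dc = span)
  grid <- grid[grid$dr^2 + grid$dc^2 <= radius^2, ]
  rl_put(canvas, round(r + grid$dr), round(c + grid$dc), color)
}

# 3x5 bitmap font for grid labels (digits, minus, dot)
rl_font <- function() {
  glyph <- function(s) matrix(as.integer(strsplit(s, "")[[1]] == "1"), 5, 3, byrow = TRUE)
  list(
    "0" = glyph("111101101101111"), "1" = glyph("010110010010111"),
    "2" = glyph("111001111100111"), "3" = glyph("111001111001111"),
    "4" = glyph("101101111001001"), "5" = glyph("111100111001111"),
    "6" = glyph("111100111101111"), "7" = glyph("111001001001001"),
    "8" = glyph("111101111101111"), "9" = glyph("111101111001111"),
    "-" = glyph("000000111000000"), "." = glyph("000000000000010")
  )
}

rl_draw_text <- function(canvas, r, c, text, color = c(0.2, 0.2, 0.2)) {
  font <- rl_font()
  chars <- strsplit(text, "")[[1]]
  for (ch in chars) {
    g <- font[[ch]]
    if (!is.null(g)) {
      px <- which(g == 1L, arr.ind = TRUE)
      canvas <- rl_put(canvas, r + px[, 1] - 1L, c + px[, 2] - 1L, color)
    }
    c <- c + 4L
  }
  canvas
}

#' Render a top-down overview of a floor plan
#'
#' Draws all wall segments of the plan as seen from above; with
#' `raster_overlay = TRUE` a labeled coordinate grid is underlaid at
#' `grid_spacing` world units so waypoint coordinates can be read off.
#' Dangling endpoints failing the closed-loop check are marked with red
#' discs. The wall pixels are identical with and without the overlay
#' (the grid is drawn first).
#'
#' @param plan A `floorplan`.
#' @param raster_overlay Draw the labeled coordinate grid?
#' @param grid_spacing Grid spacing in world units (default: a round number
#'   near 1/10 of the larger extent).
#' @param px_per_unit Image resolution in pixels per world unit.
#' @param path Optional output PNG path.
#' @return Invisibly, the image as an `H x W x 3` array in `[0, 1]`, with
#'   attributes `grid_x`/`grid_y` giving the world coordinates of the grid
#'   lines (empty when the overlay is off).
#' @export
render_wallcheck <- function(plan, raster_overlay = TRUE, grid_spacing = NULL,
                             px_per_unit = NULL, path = NULL) {
  b <- plan$bounds
  wx <- b["xmax"] - b["xmin"]; wy <- b["ymax"] - b["ymin"]
  ext <- max(wx, wy)
  if (is.null(grid_spacing)) {
    grid_spacing <- signif(ext / 10, 1)
  }
  if (is.null(px_per_unit)) px_per_unit <- max(1, floor(560 / ext))
  pad <- 20L
  w <- as.integer(ceiling(wx * px_per_unit)) + 2L * pad
  h <- as.integer(ceiling(wy * px_per_unit)) + 2L * pad
  to_col <- function(x) pad + (x - b["xmin"]) * px_per_unit + 1
  to_row <- function(y) h - pad - (y - b["ymin"]) * px_per_unit
  img <- rl_canvas(h, w)

  gx <- gy <- numeric(0)
  if (raster_overlay) {
    gx <- seq(ceiling(b["xmin"] / grid_spacing) * grid_spacing, b["xmax"],
              by = grid_spacing)
    gy <- seq(ceiling(b["ymin"] / grid_spacing) * grid_spacing, b["ymax"],
              by = grid_spacing)
    for (x in gx) {
      img <- rl_draw_line(img, to_row(b["ymin"]), to_col(x),
                          to_row(b["ymax"]), to_col(x), color = c(0.8, 0.85, 0.95))
      img <- rl_draw_text(img, h - pad + 4L, to_col(x) - 4L,
                          formatC(x, format = "g"))
    }
    for (y in gy) {
      img <- rl_draw_line(img, to_row(y), to_col(b["xmin"]),
                          to_row(y), to_col(b["xmax"]), color = c(0.8, 0.85, 0.95))
      img <- rl_draw_text(img, to_row(y) - 2L, 2L, formatC(y, format = "g"))
    }
  }
  s <- plan$segments
  for (i in seq_len(nrow(s))) {
    col <- if (s$obstacle[i]) c(0.35, 0.25, 0.1) else c(0, 0, 0)
    img <- rl_draw_line(img, to_row(s$y1[i]), to_col(s$x1[i]),
                        to_row(s$y2[i]), to_col(s$x2[i]), color = col)
  }
  chk <- check_closed(plan)
  if (!chk$ok) {
    for (i in seq_len(nrow(chk$dangling))) {
      img <- rl_draw_disc(img, to_row(chk$dangling$y[i]),
                          to_col(chk$dangling$x[i]), 4L, c(1, 0, 0))
    }
  }
  attr(img, "grid_x") <- gx
  attr(img, "grid_y") <- gy
  attr(img, "px_per_unit") <- px_per_unit
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}

#' Render a trajectory overlay on the floor-plan overview
#'
#' Final-state summary image in the style of the simulation viewer: the
#' traversed path as a dotted line and the final pose as an arrow.
#'
#' @param plan A `floorplan`.
#' @param trajectory A trajectory tibble from [generate_trajectory()].
#' @param path Optional output PNG path.
#' @return Invisibly, the image array.
#' @export
render_trajectory_overlay <- function(plan, trajectory, path = NULL) {
  img <- render_wallcheck(plan, raster_overlay = FALSE)
  ppu <- attr(img, "px_per_unit")
  b <- plan$bounds
  h <- dim(img)[1]
  pad <- 20L
  to_col <- function(x) pad + (x - b["xmin"]) * ppu + 1
  to_row <- function(y) h - pad - (y - b["ymin"]) * ppu
  n <- nrow(trajectory)
  # dotted white-on-gray path: use mid gray so it is visible on white
  keep <- seq(1, n, by = max(1, floor(n / 4000)))
  img <- rl_put(img, round(to_row(trajectory$y[keep])),
                round(to_col(trajectory$x[keep])), c(0.55, 0.55, 0.55))
  xf <- trajectory$x[n]; yf <- trajectory$y[n]; hf <- trajectory$heading[n]
  len <- 0.04 * max(b["xmax"] - b["xmin"], b["ymax"] - b["ymin"])
  img <- rl_draw_line(img, to_row(yf), to_col(xf),
                      to_row(yf + len * sin(hf)), to_col(xf + len * cos(hf)),
                      color = c(0.9, 0, 0))
  img <- rl_draw_disc(img, to_row(yf), to_col(xf), 3L, c(0.9, 0, 0))
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}
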