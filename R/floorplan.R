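#' Enclosure floor plans
#'
#' An enclosure is a set of textured vertical wall segments in continuous 2-D
#' world coordinates (origin at the lower-left of the bounding box, y up,
#' angles counter-clockwise from +x). Boundary segments must form closed
#' loops; axis-aligned rectangular obstacles can be added inside and take
#' part in raycasting and validity checks exactly like walls.
#'
#' @name floorplan
NULL

EPS_GAP <- 1e-6

new_floorplan <- function(segments, registry) {
  segments <- tibble::as_tibble(segments)
  needed <- c("x1", "y1", "x2", "y2", "texture", "obstacle")
  stopifnot(all(needed %in% names(segments)))
  if (nrow(segments) == 0) stopf("floor plan has no wall segments")
  deg <- with(segments, abs(x1 - x2) < 1e-12 & abs(y1 - y2) < 1e-12)
  if (any(deg)) stopf("degenerate wall segment (zero length) at row %d", which(deg)[1])
  bounds <- c(
    xmin = min(segments$x1, segments$x2), xmax = max(segments$x1, segments$x2),
    ymin = min(segments$y1, segments$y2), ymax = max(segments$y1, segments$y2)
  )
  structure(
    list(segments = segments, bounds = bounds, registry = registry),
    class = "floorplan"
  )
}

#' @export
print.floorplan <- function(x, ...) {
  b <- x$bounds
  cat(sprintf("<floorplan> %d segments (%d obstacle), bounds (%g,%g)-(%g,%g)\n",
              nrow(x$segments), sum(x$segments$obstacle),
              b["xmin"], b["ymin"], b["xmax"], b["ymax"]))
  invisible(x)
}

#' @export
as_tibble.floorplan <- function(x, ...) x$segments

segment_tbl <- function(xy, registry, obstacle = FALSE, offset = 0L) {
  # xy: matrix of vertices defining a closed loop (consecutive pairs)
  n <- nrow(xy)
  idx <- seq_len(n)
  nxt <- c(idx[-1], idx[1])
  tibble::tibble(
    x1 = xy[idx, 1], y1 = xy[idx, 2],
    x2 = xy[nxt, 1], y2 = xy[nxt, 2],
    texture = vapply(idx + offset, function(i) texture_for_index(registry, i), ""),
    obstacle = obstacle
  )
}

#' Rectangular box enclosure
#'
#' @param width,height Box dimensions in world units.
#' @param registry Texture registry (defaults to the procedural set).
#' @return A `floorplan` with 4 boundary segments and corners
#'   `(0,0)`-`(width,height)`.
#' @export
make_box <- function(width, height, registry = texture_registry()) {
  assert_scalar_num(width, "width"); assert_scalar_num(height, "height")
  if (width <= 0 || height <= 0) stopf("box dimensions must be positive")
  xy <- cbind(c(0, width, width, 0), c(0, 0, height, height))
  new_floorplan(segment_tbl(xy, registry), registry)
}

#' Circular enclosure (regular polygon)
#'
#' @param radius Circle radius in world units.
#' @param n_segments Number of wall segments approximating the circle (>= 3).
#' @inheritParams make_box
#' @return A `floorplan` whose segments form a regular `n_segments`-gon
#'   inscribed in the circle, translated so the bounding box starts at (0,0).
#' @export
make_circle <- function(radius, n_segments = 60, registry = texture_registry()) {
  assert_scalar_num(radius, "radius")
  if (radius <= 0) stopf("radius must be positive")
  if (n_segments < 3) stopf("a circle needs at least 3 segments")
  th <- 2 * pi * (seq_len(n_segments) - 1) / n_segments
  xy <- cbind(radius * cos(th), radius * sin(th))
  xy <- sweep(xy, 2, apply(xy, 2, min)) # origin at lower-left of bounds
  new_floorplan(segment_tbl(xy, registry), registry)
}

#' Star maze enclosure
#'
#' `arms` corridors of width `arm_width` and side-wall length `arm_length`
#' radiate equidistantly from a central region of radius `center_radius`.
#' Each arm contributes two side walls and an end cap; adjacent arms are
#' joined by a chord wall across the central circle, giving `4 * arms`
#' segments in one closed loop.
#'
#' @param arms Number of arms (>= 3).
#' @param arm_width,arm_length,center_radius Geometry in world units.
#' @inheritParams make_box
#' @export
make_star_maze <- function(arms, arm_width, arm_length, center_radius,
                           registry = texture_registry()) {
  if (arms < 3) stopf("a star maze needs at least 3 arms")
  if (arm_width <= 0 || arm_length <= 0 || center_radius <= 0) {
    stopf("star-maze dimensions must be positive")
  }
  if (arm_width / 2 >= center_radius) {
    stopf("arm_width/2 (%g) must be smaller than center_radius (%g)",
          arm_width / 2, center_radius)
  }
  phi <- asin((arm_width / 2) / center_radius) # half-angle an arm subtends
  sep <- 2 * pi / arms
  if (2 * phi >= sep) {
    stopf(paste0("adjacent arms overlap at the center: each arm mouth spans ",
                 "%.1f deg but arms are only %.1f deg apart; reduce arm_width ",
                 "or increase center_radius"),
          rad2deg(2 * phi), rad2deg(sep))
  }
  verts <- NULL
  for (k in seq_len(arms) - 1) {
    th <- k * sep
    d <- c(cos(th), sin(th))
    inner_r <- center_radius * c(cos(th - phi), sin(th - phi)) # right mouth
    inner_l <- center_radius * c(cos(th + phi), sin(th + phi)) # left mouth
    outer_r <- inner_r + arm_length * d
    outer_l <- inner_l + arm_length * d
    # walk counter-clockwise: right mouth -> right outer -> left outer -> left mouth
    verts <- rbind(verts, inner_r, outer_r, outer_l, inner_l)
  }
  verts <- sweep(verts, 2, apply(verts, 2, min))
  new_floorplan(segment_tbl(verts, registry), registry)
}

#' Add a rectangular obstacle to a floor plan
#'
#' The obstacle is stored as a 4-segment closed loop flagged as obstacle;
#' it participates in raycasting and position validity exactly like walls.
#'
#' @param plan A `floorplan`.
#' @param x,y Lower-left corner of the obstacle.
#' @param w,h Obstacle dimensions.
#' @export
add_obstacle <- function(plan, x, y, w, h) {
  if (w <= 0 || h <= 0) stopf("obstacle dimensions must be positive")
  xy <- cbind(c(x, x + w, x + w, x), c(y, y, y + h, y + h))
  seg <- segment_tbl(xy, plan$registry, obstacle = TRUE,
                     offset = nrow(plan$segments))
  new_floorplan(dplyr::bind_rows(plan$segments, seg), plan$registry)
}

#' Check that wall segments form closed loops
#'
#' Collects all segment endpoints per group (boundary walls and each obstacle
#' are separate loops is not assumed; the check is purely on the endpoint
#' multiset) and verifies that every endpoint coincides with exactly one
#' other endpoint within a tolerance of `1e-6` world units.
#'
#' @param plan A `floorplan`.
#' @return A list with `ok` (logical) and `dangling`, a tibble of unmatched
#'   endpoints (empty when closed).
#' @export
check_closed <- function(plan) {
  s <- plan$segments
  pts <- rbind(cbind(s$x1, s$y1), cbind(s$x2, s$y2))
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  matches <- rowSums(d < EPS_GAP)
  bad <- which(matches != 1L)
  dangling <- tibble::tibble(x = pts[bad, 1], y = pts[bad, 2],
                             n_coincident = matches[bad])
  list(ok = length(bad) == 0L, dangling = dangling)
}

#' Read a floor plan from a plain-text wall-segment file
#'
#' One segment per line: `x1 y1 x2 y2 [texture_name]`, whitespace-separated;
#' `#` starts a comment. Unresolved texture names fall back to the default
#' texture. After parsing, the closed-loop gap check runs and any dangling
#' endpoints are reported as a warning.
#'
#' @param path Path to the `.txt` floor-plan file.
#' @inheritParams make_box
#' @export
load_floorplan <- function(path, registry = texture_registry()) {
  if (!file.exists(path)) stopf("floor-plan file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) < 4 || length(tok) > 5) {
      stopf("line %d of %s: expected 'x1 y1 x2 y2 [texture]', got %d fields",
            i, path, length(tok))
    }
    xy <- suppressWarnings(as.numeric(tok[1:4]))
    if (anyNA(xy)) stopf("line %d of %s: non-numeric coordinate", i, path)
    texture <- if (length(tok) == 5) tok[5] else texture_for_index(registry, length(rows) + 1L)
    if (!texture %in% names(registry$textures)) {
      texture <- names(registry$textures)[1L]
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      x1 = xy[1], y1 = xy[2], x2 = xy[3], y2 = xy[4],
      texture = texture, obstacle = FALSE
    )
  }
  if (length(rows) == 0) stopf("floor-plan file %s contains no wall segments", path)
  plan <- new_floorplan(dplyr::bind_rows(rows), registry)
  chk <- check_closed(plan)
  if (!chk$ok) {
    warnf("floor plan has %d dangling endpoint(s); first at (%g, %g)",
          nrow(chk$dangling), chk$dangling$x[1], chk$dangling$y[1])
  }
  plan
}

#' Write a floor plan to the plain-text wall-segment format
#'
#' @param plan A `floorplan`.
#' @param path Output file path.
#' @export
write_floorplan <- function(plan, path) {
  s <- plan$segments
  lines <- sprintf("%.17g %.17g %.17g %.17g %s", s$x1, s$y1, s$x2, s$y2, s$texture)
  writeLines(c("# floor plan: x1 y1 x2 y2 texture", lines), path)
  invisible(path)
}

# ---- geometry queries -------------------------------------------------------

# even-odd crossing test against all segments; obstacles make their interior
# "outside" automatically because their loop adds a second crossing.
points_inside <- function(plan, px, py) {
  s <- plan$segments
  inside <- logical(length(px))
  x1 <- s$x1; y1 <- s$y1; x2 <- s$x2; y2 <- s$y2
  for (i in seq_along(px)) {
    cross <- ((y1 > py[i]) != (y2 > py[i]))
    xin <- x1 + (py[i] - y1) / (y2 - y1) * (x2 - x1)
    inside[i] <- (sum(cross & px[i] < xin) %% 2L) == 1L
  }
  inside
}

# minimum distance from each point to any wall segment
points_wall_distance <- function(plan, px, py) {
  s <- plan$segments
  ex <- s$x2 - s$x1; ey <- s$y2 - s$y1
  len2 <- ex^2 + ey^2
  out <- numeric(length(px))
  for (i in seq_along(px)) {
    t <- pmin(1, pmax(0, ((px[i] - s$x1) * ex + (py[i] - s$y1) * ey) / len2))
    dx <- s$x1 + t * ex - px[i]
    dy <- s$y1 + t * ey - py[i]
    out[i] <- sqrt(min(dx^2 + dy^2))
  }
  out
}

#' Test whether positions are valid for the agent
#'
#' A position is valid when it lies inside the boundary loop, outside all
#' obstacles, and at least `margin` world units away from every wall
#' segment (the nearest distance the virtual rodent can approach a wall).
#'
#' @param plan A `floorplan`.
#' @param x,y Position coordinates (vectorised).
#' @param margin Minimum wall distance in world units.
#' @return Logical vector.
#' @export
is_valid_position <- function(plan, x, y, margin = 0) {
  stopifnot(length(x) == length(y))
  ok <- points_inside(plan, x, y)
  if (margin > 0 && any(ok)) {
    ok[ok] <- points_wall_distance(plan, x[ok], y[ok]) >= margin
  }
  ok
}

# Cast many rays from one origin; returns list(distance, segment, u) with one
# entry per angle. Vectorised over angles x segments.
ray_cast_many <- function(plan, origin, angles) {
  s <- plan$segments
  dx <- cos(angles); dy <- sin(angles)
  ex <- s$x2 - s$x1; ey <- s$y2 - s$y1
  rx <- s$x1 - origin[1]; ry <- s$y1 - origin[2]
  ce <- rx * ey - ry * ex                       # per segment
  denom <- outer(dx, ey) - outer(dy, ex)        # rays x segments
  cd <- outer(dy, rx) - outer(dx, ry)
  tt <- sweep(1 / denom, 2, ce, `*`)            # ray parameter
  uu <- cd / denom                              # position along segment
  bad <- !is.finite(tt) | tt <= 1e-9 | uu < -1e-9 | uu > 1 + 1e-9
  tt[bad] <- Inf
  hit <- max.col(-tt, ties.method = "first")
  idx <- cbind(seq_along(angles), hit)
  dist <- tt[idx]
  list(distance = dist, segment = hit, u = pmin(1, pmax(0, uu[idx])))
}

#' Cast a single ray against all wall segments
#'
#' @param plan A `floorplan`.
#' @param origin Numeric `(x, y)`, strictly inside the enclosure.
#' @param angle Ray direction in radians (counter-clockwise from +x).
#' @return A list with `distance` (world units), `segment` (row index into
#'   `plan$segments`), and `u`, the normalised hit position along the
#'   segment in `[0, 1]`.
#' @export
ray_cast <- function(plan, origin, angle) {
  if (!points_inside(plan, origin[1], origin[2])) {
    stopf("ray origin (%g, %g) is not strictly inside the enclosure",
          origin[1], origin[2])
  }
  r <- ray_cast_many(plan, origin, angle)
  if (!is.finite(r$distance)) {
    stopf("ray from (%g, %g) at %.1f deg hits no wall: open floor plan?",
          origin[1], origin[2], rad2deg(angle))
  }
  list(distance = r$distance, segment = r$segment, u = r$u)
}
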