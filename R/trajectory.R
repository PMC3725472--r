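#' Movement statistics of the virtual rat
#'
#' The rat is not controlled directly; its path is drawn from a statistical
#' model. Each step the candidate heading is perturbed by a uniform turn
#' `u ~ U(-arc, +arc)` and blended with the previous direction vector with
#' weight `momentum`, so higher momentum gives straighter paths while the
#' per-step turn never exceeds `arc`.
#'
#' @param speed Base speed in world units per time step.
#' @param momentum Path straightness in `[0, 1]`; 1 = never turns.
#' @param arc Maximal rotation per time step, degrees.
#' @param min_wall_dist Nearest distance the rat can approach a wall
#'   (world units).
#' @param path_noise Standard deviation (world units) of the positional
#'   noise added in waypoint-following mode.
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(speed = 0.2, momentum = 0.6, arc = 60,
                          min_wall_dist = 0.2, path_noise = 0.5) {
  if (speed <= 0) stopf("speed must be positive")
  if (momentum < 0 || momentum > 1) stopf("momentum must lie in [0, 1]")
  if (arc < 0) stopf("arc must be non-negative")
  if (min_wall_dist < 0 || path_noise < 0) {
    stopf("min_wall_dist and path_noise must be non-negative")
  }
  structure(list(speed = speed, momentum = momentum, arc = arc,
                 min_wall_dist = min_wall_dist, path_noise = path_noise),
            class = "motion_params")
}

#' Waypoint path
#'
#' @param waypoints Two-column matrix or data frame of `(x, y)` waypoints
#'   (at least 2).
#' @param loop If `TRUE` the rat continues from the last waypoint back to
#'   the first and runs a continuous loop; if `FALSE` its position is reset
#'   to the first waypoint upon reaching the final one.
#' @export
make_path <- function(waypoints, loop = FALSE) {
  wp <- as.matrix(as.data.frame(waypoints)[, 1:2])
  if (nrow(wp) < 2) stopf("a path needs at least 2 waypoints")
  structure(list(waypoints = unname(wp), loop = isTRUE(loop), target = 1L),
            class = "rat_path")
}

# pick the first valid candidate move; candidates keep |turn| <= arc and
# back off on speed near walls (displacement <= speed by contract).
resolve_move <- function(x, y, heading, turn, params, plan) {
  arc <- deg2rad(params$arc)
  turn <- max(-arc, min(arc, turn))
  h1 <- heading + turn
  nx <- x + params$speed * cos(h1)
  ny <- y + params$speed * sin(h1)
  if (is_valid_position(plan, nx, ny, params$min_wall_dist)) {
    return(list(x = nx, y = ny, heading = h1, moved = TRUE))
  }
  offs <- c(0, arc / 4, -arc / 4, arc / 2, -arc / 2, 3 * arc / 4,
            -3 * arc / 4, arc, -arc)
  for (sp in params$speed * c(1, 0.5, 0.25)) {
    hs <- heading + pmax(-arc, pmin(arc, turn + offs))
    cx <- x + sp * cos(hs)
    cy <- y + sp * sin(hs)
    ok <- is_valid_position(plan, cx, cy, params$min_wall_dist)
    if (any(ok)) {
      i <- which(ok)[1]
      return(list(x = cx[i], y = cy[i], heading = hs[i], moved = TRUE))
    }
  }
  # boxed in: stay put and rotate by the full arc (counter-clockwise
  # tie-break) so the full circle is swept within a few steps
  list(x = x, y = y, heading = heading + max(arc, abs(turn)), moved = FALSE)
}

#' One random-foraging step
#'
#' Draws a turn `u ~ U(-arc, +arc)`, blends the turned direction with the
#' previous one using `momentum`, and advances by `speed`. If the proposed
#' position violates the wall margin, nearby candidate headings within the
#' same `arc` bound are tried with reduced speed (wall avoidance).
#'
#' @param state List with `x`, `y`, `heading` (radians).
#' @param params A [motion_params()] object.
#' @param plan A `floorplan`.
#' @return Updated state list (uses the current RNG stream).
#' @export
step_random <- function(state, params, plan) {
  arc <- deg2rad(params$arc)
  u <- stats::runif(1, -arc, arc)
  d0 <- c(cos(state$heading), sin(state$heading))
  d1 <- c(cos(state$heading + u), sin(state$heading + u))
  v <- params$momentum * d0 + (1 - params$momentum) * d1
  turn <- wrap_angle(atan2(v[2], v[1]) - state$heading)
  resolve_move(state$x, state$y, state$heading, turn, params, plan)
}

#' One waypoint-following step
#'
#' The heading is steered toward the current waypoint with the turn clipped
#' to `arc`; positional noise of standard deviation `path_noise` makes the
#' movement along the path irregular. Within a capture radius of
#' `2 * speed` the target advances; after the final waypoint the target
#' wraps to the first when `loop = TRUE`, otherwise the rat is reset to the
#' first waypoint.
#'
#' @param state List with `x`, `y`, `heading`.
#' @param path A [make_path()] object (carries the current target index).
#' @inheritParams step_random
#' @return List with updated `state` and `path`.
#' @export
step_path <- function(state, path, params, plan) {
  arc <- deg2rad(params$arc)
  wp <- path$waypoints[path$target, ]
  desired <- atan2(wp[2] - state$y, wp[1] - state$x)
  turn <- max(-arc, min(arc, wrap_angle(desired - state$heading)))
  noise <- stats::rnorm(2) * params$path_noise
  h1 <- state$heading + turn
  nx <- state$x + params$speed * cos(h1) + noise[1]
  ny <- state$y + params$speed * sin(h1) + noise[2]
  if (is_valid_position(plan, nx, ny, params$min_wall_dist)) {
    new <- list(x = nx, y = ny, heading = h1, moved = TRUE)
  } else {
    new <- resolve_move(state$x, state$y, state$heading, turn, params, plan)
  }
  if (sqrt((new$x - wp[1])^2 + (new$y - wp[2])^2) <= 2 * params$speed) {
    if (path$target < nrow(path$waypoints)) {
      path$target <- path$target + 1L
    } else if (path$loop) {
      path$target <- 1L
    } else {
      # reset to the first waypoint and head for the second
      new$x <- path$waypoints[1, 1]
      new$y <- path$waypoints[1, 2]
      path$target <- 2L
    }
  }
  list(state = new, path = path)
}

#' Generate a pose sequence for the virtual rat
#'
#' Runs the movement model for `n_steps` time steps, starting from a
#' uniformly drawn valid position with uniform heading. The sequence is
#' fully determined by `seed`.
#'
#' @param plan A `floorplan`.
#' @param params A [motion_params()] object.
#' @param n_steps Number of poses to emit (>= 1).
#' @param mode `"random"` foraging or `"path"` waypoint following.
#' @param path A [make_path()] (required for `mode = "path"`); all
#'   waypoints must be valid positions.
#' @param seed Integer seed controlling the whole trajectory.
#' @param start Optional `(x, y, heading_rad)` start state overriding the
#'   random draw.
#' @return A tibble of class `rat_trajectory` with columns `step`, `x`,
#'   `y`, `heading` (radians).
#' @export
generate_trajectory <- function(plan, params = motion_params(), n_steps,
                                mode = c("random", "path"), path = NULL,
                                seed = 1, start = NULL) {
  mode <- match.arg(mode)
  if (n_steps < 1) stopf("n_steps must be >= 1")
  if (mode == "path") {
    if (is.null(path)) stopf("mode 'path' requires a waypoint path")
    ok <- is_valid_position(plan, path$waypoints[, 1], path$waypoints[, 2],
                            params$min_wall_dist)
    if (!all(ok)) {
      stopf("waypoint %d at (%g, %g) is not a valid position",
            which(!ok)[1], path$waypoints[which(!ok)[1], 1],
            path$waypoints[which(!ok)[1], 2])
    }
  }
  b <- plan$bounds
  xs <- ys <- hs <- numeric(n_steps)
  withr::with_seed(derive_seed(seed, 101L), {
    if (is.null(start)) {
      state <- NULL
      for (i in 1:10000) {
        px <- stats::runif(1, b["xmin"], b["xmax"])
        py <- stats::runif(1, b["ymin"], b["ymax"])
        if (is_valid_position(plan, px, py, params$min_wall_dist)) {
          state <- list(x = px, y = py,
                        heading = stats::runif(1, 0, 2 * pi), moved = TRUE)
          break
        }
      }
      if (is.null(state)) stopf("could not find a valid start position")
    } else {
      if (!is_valid_position(plan, start[1], start[2], params$min_wall_dist)) {
        stopf("start position (%g, %g) is not valid", start[1], start[2])
      }
      state <- list(x = start[1], y = start[2], heading = start[3], moved = TRUE)
    }
    xs[1] <- state$x; ys[1] <- state$y; hs[1] <- state$heading
    stuck <- 0L
    if (n_steps > 1) {
      for (t in 2:n_steps) {
        if (mode == "random") {
          state <- step_random(state, params, plan)
        } else {
          res <- step_path(state, path, params, plan)
          state <- res$state
          path <- res$path
        }
        stuck <- if (state$moved) 0L else stuck + 1L
        if (stuck >= 50L) {
          stopf("agent made no progress for 50 consecutive steps at (%g, %g): malformed floor plan or unreachable waypoint",
                state$x, state$y)
        }
        xs[t] <- state$x; ys[t] <- state$y; hs[t] <- state$heading
      }
    }
  })
  out <- tibble::tibble(step = seq_len(n_steps), x = xs, y = ys, heading = hs)
  class(out) <- c("rat_trajectory", class(out))
  attr(out, "params") <- params
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  out
}

#' @export
autoplot.rat_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(linewidth = 0.2, alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Agent trajectory", x = "x (world units)",
                  y = "y (world units)")
}
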