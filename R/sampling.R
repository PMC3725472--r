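#' Sample place-field rate maps over an enclosure
#'
#' Probes the trained network on a regular grid of positions: at every
#' valid grid position the view is rendered while looking in each of 8
#' compass directions (0, 45, ..., 315 degrees), the network responds, and
#' each output signal is recorded, giving one rate map per signal per
#' direction plus a direction-averaged map (the pointwise mean of the 8).
#'
#' @param network A trained `sfa_network`.
#' @param plan A `floorplan`.
#' @param view A [view_params()] matching the network input.
#' @param spacing Grid spacing in world units (default: 1/20 of the larger
#'   enclosure extent).
#' @param margin Wall margin used for the validity mask (world units);
#'   matches the movement model's `min_wall_dist` by default.
#' @param directions Number of equally spaced sampling headings (default 8).
#' @return An object of class `rate_maps`: arrays `values`
#'   (`ny x nx x n_signals x directions`, `NA` outside the valid mask),
#'   `average`, the logical `mask`, grid coordinates, and the sampled
#'   directions in degrees.
#' @export
sample_place <- function(network, plan, view, spacing = NULL, margin = 0.2,
                         directions = 8) {
  assert_trained(network)
  b <- plan$bounds
  ext <- max(b["xmax"] - b["xmin"], b["ymax"] - b["ymin"])
  spacing <- spacing %||% (ext / 20)
  if (spacing <= 0) stopf("spacing must be positive")
  xc <- seq(b["xmin"] + spacing / 2, b["xmax"] - spacing / 2 + 1e-9, by = spacing)
  yc <- seq(b["ymin"] + spacing / 2, b["ymax"] - spacing / 2 + 1e-9, by = spacing)
  grid <- expand.grid(x = xc, y = yc)
  valid <- is_valid_position(plan, grid$x, grid$y, margin)
  mask <- matrix(valid, length(yc), length(xc), byrow = TRUE) # [iy, ix]
  dirs <- seq(0, 360, length.out = directions + 1)[seq_len(directions)]
  vx <- grid$x[valid]; vy <- grid$y[valid]
  nv <- sum(valid)
  nsig <- network_output_dim(network)
  vals <- array(NA_real_, dim = c(length(yc), length(xc), nsig, directions))
  idx <- which(valid)                       # expand.grid order: x fastest
  ix <- ((idx - 1L) %% length(xc)) + 1L
  iy <- ((idx - 1L) %/% length(xc)) + 1L
  for (d in seq_along(dirs)) {
    h <- deg2rad(dirs[d])
    arr <- array(0, dim = c(view$height, view$width, nv))
    for (p in seq_len(nv)) {
      arr[, , p] <- render_view_internal(plan, vx[p], vy[p], h, view,
                                         plan$registry, color = FALSE)
    }
    Y <- forward_many(network, arr)
    for (p in seq_len(nv)) vals[iy[p], ix[p], , d] <- Y[p, ]
  }
  avg <- array(0, dim = c(length(yc), length(xc), nsig))
  for (s in seq_len(nsig)) {
    acc <- matrix(0, length(yc), length(xc))
    for (d in seq_len(directions)) acc <- acc + vals[, , s, d]
    avg[, , s] <- acc / directions
  }
  structure(list(values = vals, average = avg, mask = mask,
                 x = xc, y = yc, directions = dirs, spacing = spacing,
                 n_signals = nsig),
            class = "rate_maps")
}

network_output_dim <- function(network) {
  L <- network$layers[[length(network$layers)]]
  as.integer(L$per_node_out * prod(L$grid))
}

#' @export
print.rate_maps <- function(x, ...) {
  cat(sprintf("<rate_maps> %d signals x %d directions (+average) on a %d x %d grid (%d valid cells)\n",
              x$n_signals, length(x$directions), length(x$x), length(x$y),
              sum(x$mask)))
  invisible(x)
}

#' @export
as_tibble.rate_maps <- function(x, ...) {
  dir_labels <- c(sprintf("%d", round(x$directions)), "average")
  purrr::map_dfr(seq_along(dir_labels), function(d) {
    m <- if (d <= length(x$directions)) x$values[, , , d, drop = FALSE] else x$average
    xs <- rep(x$x, each = length(x$y))
    ys <- rep(x$y, length(x$x))
    purrr::map_dfr(seq_len(x$n_signals), function(s) {
      mm <- if (d <= length(x$directions)) m[, , s, 1] else m[, , s]
      tibble::tibble(direction = dir_labels[d], signal = s,
                     x = xs, y = ys, value = as.vector(mm))
    })
  })
}

#' Sample head-direction tuning curves
#'
#' For each of `n_angles` equally spaced headings, each output signal's
#' response is averaged over `n_positions` randomly drawn valid positions,
#' giving one tuning curve per signal.
#'
#' @inheritParams sample_place
#' @param n_angles Number of headings covering `[0, 360)` (>= 8).
#' @param n_positions Valid positions averaged per heading.
#' @param seed Seed for the position sample.
#' @return An object of class `tuning_curves` with `angles` (degrees) and
#'   a `n_angles x n_signals` `response` matrix.
#' @export
sample_head_direction <- function(network, plan, view, n_angles = 24,
                                  n_positions = 50, margin = 0.2, seed = 1) {
  assert_trained(network)
  if (n_angles < 8) stopf("n_angles must be >= 8")
  b <- plan$bounds
  pts <- withr::with_seed(derive_seed(seed, 31L), {
    out <- matrix(0, n_positions, 2)
    got <- 0L
    for (i in seq_len(100000)) {
      px <- stats::runif(1, b["xmin"], b["xmax"])
      py <- stats::runif(1, b["ymin"], b["ymax"])
      if (is_valid_position(plan, px, py, margin)) {
        got <- got + 1L
        out[got, ] <- c(px, py)
        if (got == n_positions) break
      }
    }
    if (got < n_positions) stopf("could not sample %d valid positions", n_positions)
    out
  })
  angles <- seq(0, 360, length.out = n_angles + 1)[seq_len(n_angles)]
  nsig <- network_output_dim(network)
  resp <- matrix(0, n_angles, nsig)
  for (a in seq_along(angles)) {
    h <- deg2rad(angles[a])
    arr <- array(0, dim = c(view$height, view$width, n_positions))
    for (p in seq_len(n_positions)) {
      arr[, , p] <- render_view_internal(plan, pts[p, 1], pts[p, 2], h, view,
                                         plan$registry, color = FALSE)
    }
    resp[a, ] <- colMeans(forward_many(network, arr))
  }
  structure(list(angles = angles, response = resp, n_signals = nsig,
                 n_positions = n_positions),
            class = "tuning_curves")
}

#' @export
print.tuning_curves <- function(x, ...) {
  cat(sprintf("<tuning_curves> %d signals at %d headings (mean over %d positions)\n",
              x$n_signals, length(x$angles), x$n_positions))
  invisible(x)
}

#' @export
as_tibble.tuning_curves <- function(x, ...) {
  tibble::tibble(
    signal = rep(seq_len(x$n_signals), each = length(x$angles)),
    angle = rep(x$angles, x$n_signals),
    response = as.vector(x$response)
  )
}

#' Directional dependence of a place field
#'
#' Compares each directional rate map with the direction-averaged map:
#' `1 - min_d cor(map_d, average)` over valid cells, clamped to `[0, 1]`.
#' A perfectly direction-invariant field scores 0; fields firing only when
#' traversed in a particular direction (as after stereotyped path running)
#' score high.
#'
#' @param maps A `rate_maps` object.
#' @param signal Signal index.
#' @return Scalar in `[0, 1]`.
#' @export
directionality_score <- function(maps, signal) {
  m <- maps$mask
  avg <- maps$average[, , signal][m]
  if (stats::sd(avg) == 0) {
    stopf("average map of signal %d is constant; correlation undefined", signal)
  }
  rs <- vapply(seq_along(maps$directions), function(d) {
    v <- maps$values[, , signal, d][m]
    if (stats::sd(v) == 0) {
      stopf("directional map (%g deg) of signal %d is constant; correlation undefined",
            maps$directions[d], signal)
    }
    stats::cor(v, avg)
  }, 0)
  max(0, min(1, 1 - min(rs)))
}

#' Place-field statistics per signal
#'
#' For each signal's direction-averaged map (sign-flipped so the spatial
#' peak is positive, resolving the ICA sign ambiguity) the cells above
#' `threshold` of the maximum are labelled into 4-connected regions.
#' A localised place field is a single region covering less than a quarter
#' of the valid area.
#'
#' @param maps A `rate_maps` object.
#' @param signals Signal indices (default: all).
#' @param threshold Fraction of the peak response (default 0.5).
#' @param max_area_frac Area fraction below which a field counts as
#'   localised (default 0.25).
#' @return A tibble with one row per signal: `n_regions`, `area_frac`
#'   (super-threshold fraction of valid cells), `peak`, and `localized`.
#' @export
place_field_stats <- function(maps, signals = NULL, threshold = 0.5,
                              max_area_frac = 0.25) {
  signals <- signals %||% seq_len(maps$n_signals)
  m <- maps$mask
  nvalid <- sum(m)
  purrr::map_dfr(signals, function(s) {
    a <- maps$average[, , s]
    vals <- a[m]
    if (abs(min(vals)) > max(vals)) { a <- -a; vals <- -vals } # sign flip
    thr <- threshold * max(vals)
    binary <- matrix(0, nrow(a), ncol(a))
    binary[m & !is.na(a) & a >= thr] <- 1
    lab <- EBImage::bwlabel(binary)
    n_regions <- max(lab)
    area <- sum(binary)
    tibble::tibble(signal = s, n_regions = as.integer(n_regions),
                   area_frac = area / nvalid, peak = max(vals),
                   localized = n_regions == 1L & area / nvalid < max_area_frac)
  })
}

#' Concentration of a head-direction tuning curve
#'
#' Circular concentration (1 - circular variance) of a signal's tuning
#' curve, using the min-shifted response as a non-negative weight; 1 means
#' all mass at one heading, 0 a flat curve.
#'
#' @param curves A `tuning_curves` object.
#' @param signal Signal index.
#' @export
tuning_concentration <- function(curves, signal) {
  r <- curves$response[, signal]
  w <- r - min(r)
  if (sum(w) == 0) return(0)
  th <- deg2rad(curves$angles)
  sqrt(sum(w * cos(th))^2 + sum(w * sin(th))^2) / sum(w)
}

# ---- plotting ---------------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.rate_maps <- function(object, signals = 1:min(8, object$n_signals),
                               direction = "average", ...) {
  df <- as_tibble.rate_maps(object)
  df <- df[df$direction == direction & df$signal %in% signals, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~signal) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(title = sprintf("Rate maps (%s direction)", direction),
                  fill = "response")
}

#' @export
autoplot.tuning_curves <- function(object,
                                   signals = 1:min(8, object$n_signals), ...) {
  df <- as_tibble.tuning_curves(object)
  df <- df[df$signal %in% signals, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data$response)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, scales = "free_y") +
    ggplot2::labs(title = "Head-direction tuning curves",
                  x = "heading (deg)", y = "mean response")
}

# viridis-like ramp without requiring a graphics device
map_to_colors <- function(m) {
  anchors <- rbind(c(0.267, 0.005, 0.329), c(0.283, 0.141, 0.458),
                   c(0.254, 0.265, 0.530), c(0.207, 0.372, 0.553),
                   c(0.164, 0.471, 0.558), c(0.128, 0.567, 0.551),
                   c(0.135, 0.659, 0.518), c(0.267, 0.749, 0.441),
                   c(0.478, 0.821, 0.318), c(0.741, 0.873, 0.150),
                   c(0.993, 0.906, 0.144))
  rng <- range(m, na.rm = TRUE)
  v <- if (diff(rng) == 0) m * 0 else (m - rng[1]) / diff(rng)
  out <- array(1, dim = c(nrow(m), ncol(m), 3))
  ok <- which(!is.na(v))
  pos <- v[ok] * (nrow(anchors) - 1)
  i0 <- pmin(floor(pos) + 1, nrow(anchors) - 1)
  frac <- pos - (i0 - 1)
  for (k in 1:3) {
    page <- out[, , k]
    page[ok] <- anchors[i0, k] * (1 - frac) + anchors[i0 + 1, k] * frac
    out[, , k] <- page
  }
  out
}

upscale <- function(img, f) {
  d <- dim(img)
  out <- array(0, dim = c(d[1] * f, d[2] * f, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- img[, , k][rep(seq_len(d[1]), each = f),
                                                    rep(seq_len(d[2]), each = f)]
  out
}

#' Write labelled plot files for rate maps or tuning curves
#'
#' One PNG per map or curve, under `<out_dir>/place/<direction>/sig_<k>.png`
#' and `<out_dir>/hd/sig_<k>.png`; re-running with the same inputs
#' overwrites the same file names. Map colours are min-max normalised per
#' map; invalid cells are white.
#'
#' @param maps A `rate_maps` or `tuning_curves` object.
#' @param out_dir Output directory (created if missing).
#' @param signals Signal indices to plot (default: all).
#' @return A tibble manifest with one row per written file.
#' @export
plot_maps <- function(maps, out_dir, signals = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (inherits(maps, "rate_maps")) {
    signals <- signals %||% seq_len(maps$n_signals)
    dir_labels <- c(sprintf("%03d", round(maps$directions)), "average")
    for (d in seq_along(dir_labels)) {
      sub <- file.path(out_dir, "place", dir_labels[d])
      dir.create(sub, showWarnings = FALSE, recursive = TRUE)
      for (s in signals) {
        m <- if (d <= length(maps$directions)) maps$values[, , s, d] else maps$average[, , s]
        img <- upscale(map_to_colors(m[rev(seq_len(nrow(m))), , drop = FALSE]), 8L)
        f <- file.path(sub, sprintf("sig_%02d.png", s))
        png::writePNG(img, f)
        files <- c(files, f)
      }
    }
  } else if (inherits(maps, "tuning_curves")) {
    signals <- signals %||% seq_len(maps$n_signals)
    sub <- file.path(out_dir, "hd")
    dir.create(sub, showWarnings = FALSE, recursive = TRUE)
    for (s in signals) {
      f <- file.path(sub, sprintf("sig_%02d.png", s))
      png::writePNG(curve_image(maps$angles, maps$response[, s]), f)
      files <- c(files, f)
    }
  } else {
    stopf("plot_maps expects a rate_maps or tuning_curves object")
  }
  tibble::tibble(file = files)
}

# rasterized polar-free line plot of a tuning curve
curve_image <- function(angles, response, h = 160L, w = 240L) {
  img <- rl_canvas(h, w)
  rng <- range(response)
  if (diff(rng) == 0) rng <- rng + c(-1, 1)
  px <- 10 + (angles / 360) * (w - 20)
  py <- h - 10 - (response - rng[1]) / diff(rng) * (h - 20)
  img <- rl_draw_line(img, h - 10, 10, h - 10, w - 10, c(0.6, 0.6, 0.6))
  img <- rl_draw_line(img, 10, 10, h - 10, 10, c(0.6, 0.6, 0.6))
  for (i in seq_len(length(angles) - 1)) {
    img <- rl_draw_line(img, py[i], px[i], py[i + 1], px[i + 1], c(0.1, 0.2, 0.7))
  }
  img
}
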