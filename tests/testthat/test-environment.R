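test_that("box preset builds a closed rectangle with the stated bounds", {
  plan <- make_box(10, 10)
  expect_equal(nrow(plan$segments), 4)
  expect_equal(unname(plan$bounds), c(0, 10, 0, 10))
  expect_true(check_closed(plan)$ok)
  expect_error(make_box(5, 0), "positive")
  expect_error(make_box(-1, 5), "positive")
})

test_that("valid region of a box with margin is the shrunk rectangle", {
  plan <- make_box(10, 10)
  set.seed(11)
  px <- runif(500, 0.01, 9.99)
  py <- runif(500, 0.01, 9.99)
  expect_identical(is_valid_position(plan, px, py, margin = 1),
                   px > 1 & px < 9 & py > 1 & py < 9)
})

test_that("circle preset is a regular polygon with the chord-length segments", {
  for (n in c(3, 7, 12, 33, 60)) {
    r <- 5
    plan <- make_circle(r, n)
    expect_equal(nrow(plan$segments), n)
    expect_true(check_closed(plan)$ok)
    s <- plan$segments
    len <- sqrt((s$x2 - s$x1)^2 + (s$y2 - s$y1)^2)
    expect_equal(len, rep(2 * r * sin(pi / n), n), tolerance = 1e-12)
  }
  # n = 4 special case: vertices at distance r from the center
  plan <- make_circle(3, 4)
  ctr <- c(mean(range(plan$segments$x1)), mean(range(plan$segments$y1)))
  d <- sqrt((plan$segments$x1 - ctr[1])^2 + (plan$segments$y1 - ctr[2])^2)
  expect_equal(d, rep(3, 4), tolerance = 1e-12)
  expect_error(make_circle(5, 2), "at least 3")
})

test_that("star maze has 4 segments per arm, closes, and is rotation symmetric", {
  plan <- make_star_maze(5, 20, 80, 40)
  expect_equal(nrow(plan$segments), 20)
  expect_true(check_closed(plan)$ok)
  # 5-fold rotational symmetry of the vertex set about the centroid
  v <- cbind(plan$segments$x1, plan$segments$y1)
  ctr <- colMeans(v)
  th <- 2 * pi / 5
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  vr <- sweep(sweep(v, 2, ctr) %*% t(R), 2, ctr, `+`)
  dist_to_set <- apply(vr, 1, function(p) min(sqrt(colSums((t(v) - p)^2))))
  expect_lt(max(dist_to_set), 1e-9)

  plan3 <- make_star_maze(3, 4, 10, 6)
  expect_equal(nrow(plan3$segments), 12)
  expect_true(check_closed(plan3)$ok)

  expect_error(make_star_maze(2, 5, 10, 10), "at least 3 arms")
  expect_error(make_star_maze(8, 30, 10, 16), "overlap")
})

test_that("floor-plan files round-trip and report malformed input precisely", {
  plan <- make_box(6, 4)
  f <- withr::local_tempfile(fileext = ".txt")
  write_floorplan(plan, f)
  plan2 <- load_floorplan(f)
  expect_equal(plan2$segments[, 1:4], plan$segments[, 1:4])

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 1 0", "1 0 1 one"), bad)
  expect_error(load_floorplan(bad), "line 2")

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines("# only a comment", empty)
  expect_error(load_floorplan(empty), "no wall segments")

  gappy <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 4 0", "4 0 4 4", "4 4 0 4", "0 4 0 0.01"), gappy)
  expect_warning(plan3 <- load_floorplan(gappy), "dangling")
  expect_false(check_closed(plan3)$ok)
})

test_that("ray casting matches closed-form cases and the per-segment oracle", {
  plan <- make_box(10, 10)
  expect_equal(ray_cast(plan, c(5, 5), 0)$distance, 5)
  expect_equal(ray_cast(plan, c(5, 5), pi / 4)$distance, 5 * sqrt(2))
  expect_error(ray_cast(plan, c(11, 5), 0), "inside")

  presets <- list(make_box(10, 10), make_circle(5, 24),
                  make_star_maze(5, 2, 8, 4),
                  add_obstacle(make_box(10, 10), 4, 4, 2, 2))
  set.seed(99)
  for (plan in presets) {
    b <- plan$bounds
    tried <- 0L
    while (tried < 250L) {
      p <- c(runif(1, b["xmin"], b["xmax"]), runif(1, b["ymin"], b["ymax"]))
      if (!is_valid_position(plan, p[1], p[2], 1e-3)) next
      tried <- tried + 1L
      a <- runif(1, 0, 2 * pi)
      got <- ray_cast(plan, p, a)
      want <- oracle_raycast(plan, p, a)
      expect_equal(got$distance, want$distance, tolerance = 1e-9)
      expect_equal(got$u, want$u, tolerance = 1e-6)
    }
  }
})

test_that("position validity is monotone in the wall margin", {
  plan <- add_obstacle(make_box(10, 8), 2, 2, 2, 2)
  set.seed(7)
  px <- runif(300, 0, 10); py <- runif(300, 0, 8)
  margins <- c(0, 0.2, 0.5, 1, 2)
  ok <- sapply(margins, function(m) is_valid_position(plan, px, py, m))
  for (k in seq_len(length(margins) - 1)) {
    expect_true(all(ok[, k] | !ok[, k + 1])) # valid at larger margin => valid at smaller
  }
  # obstacle interior is invalid at any margin
  expect_false(is_valid_position(plan, 3, 3, 0))
  # point closer than the margin to a wall is invalid
  expect_false(is_valid_position(plan, 0.25, 4, 0.5))
  expect_true(is_valid_position(plan, 5, 4, 0.5))
})

test_that("wallcheck overview draws the grid without touching wall pixels", {
  plan <- make_box(10, 10)
  on_img <- render_wallcheck(plan, raster_overlay = TRUE, grid_spacing = 2)
  off_img <- render_wallcheck(plan, raster_overlay = FALSE)
  expect_equal(attr(on_img, "grid_x"), seq(0, 10, by = 2))
  expect_gt(sum(on_img != off_img), 0) # the grid is actually drawn
  walls <- off_img[, , 1] == 0 & off_img[, , 2] == 0 & off_img[, , 3] == 0
  for (k in 1:3) {
    expect_true(all(on_img[, , k][walls] == 0)) # identical wall pixels
  }
  # dangling endpoints are marked in red
  gap <- suppressWarnings(new_plan <- local({
    f <- tempfile(fileext = ".txt")
    writeLines(c("0 0 4 0", "4 0 4 4", "4 4 0 4", "0 4 0 0.5"), f)
    suppressWarnings(load_floorplan(f))
  }))
  img <- render_wallcheck(gap, raster_overlay = FALSE)
  reds <- img[, , 1] == 1 & img[, , 2] == 0 & img[, , 3] == 0
  expect_gt(sum(reds), 0)
})
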