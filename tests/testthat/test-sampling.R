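sampled_fixture <- function() {
  if (is.null(study_cache$sampling_fx)) {
    fx <- test_frames(700, seed = 13, box = c(6, 6))
    net <- train(reduced_architecture(), fx$frames, batch_size = 700,
                 with_ica = TRUE, noise_sigma = 1e-4, seed = 13)
    maps <- sample_place(net, fx$plan, tiny_view(), spacing = 0.75,
                         margin = 0.2)
    study_cache$sampling_fx <- list(fx = fx, net = net, maps = maps)
  }
  study_cache$sampling_fx
}

test_that("place sampling emits 32 signals x (8 + average) maps with a validity mask", {
  sf <- sampled_fixture()
  maps <- sf$maps
  expect_equal(maps$n_signals, 32)
  expect_equal(length(maps$directions), 8)
  expect_equal(maps$directions, seq(0, 315, by = 45))
  expect_equal(dim(maps$values)[3:4], c(32, 8))
  # every map: valid cells finite, invalid cells NA
  for (d in c(1, 5)) {
    expect_true(all(is.finite(maps$values[, , 1, d][maps$mask])))
    expect_true(all(is.na(maps$values[, , 1, d][!maps$mask])))
  }
  # the mask is the complement of the validity grid
  grid <- expand.grid(x = maps$x, y = maps$y)
  v <- is_valid_position(sf$fx$plan, grid$x, grid$y, 0.2)
  expect_identical(as.vector(t(maps$mask)), v)
})

test_that("the averaged map is exactly the pointwise mean of the directional maps", {
  maps <- sampled_fixture()$maps
  for (s in c(1, 9, 32)) {
    man <- apply(maps$values[, , s, ], c(1, 2), mean)
    expect_lt(max(abs(man - maps$average[, , s]), na.rm = TRUE), 1e-12)
  }
})

test_that("sampling leaves the network parameters untouched", {
  sf <- sampled_fixture()
  before <- serialize(sf$net, NULL)
  invisible(sample_place(sf$net, sf$fx$plan, tiny_view(), spacing = 1.5,
                         margin = 0.2))
  invisible(sample_head_direction(sf$net, sf$fx$plan, tiny_view(),
                                  n_angles = 8, n_positions = 5, seed = 1))
  expect_identical(serialize(sf$net, NULL), before)
})

test_that("directionality score is 0 for identical maps and clamps the toy extreme", {
  maps <- sampled_fixture()$maps
  # construct maps whose 8 directional copies are all the average
  toy <- maps
  for (d in 1:8) toy$values[, , , d] <- maps$average
  expect_equal(directionality_score(toy, 1), 0, tolerance = 1e-12)
  # one direction equal to the negated average: raw score 2, clamped to 1
  toy$values[, , 1, 3] <- -maps$average[, , 1]
  expect_equal(directionality_score(toy, 1), 1)
  # constant map: correlation undefined
  toy2 <- maps
  toy2$average[, , 2][toy2$mask] <- 1
  expect_error(directionality_score(toy2, 2), "constant")
})

test_that("head-direction curves have one response per heading rendered at that heading", {
  sf <- sampled_fixture()
  curves <- sample_head_direction(sf$net, sf$fx$plan, tiny_view(),
                                  n_angles = 12, n_positions = 8, seed = 4)
  expect_equal(dim(curves$response), c(12, 32))
  expect_equal(curves$angles, seq(0, 330, by = 30))
  expect_error(sample_head_direction(sf$net, sf$fx$plan, tiny_view(),
                                     n_angles = 4), ">= 8")
  # reproducibility of the position sample
  curves2 <- sample_head_direction(sf$net, sf$fx$plan, tiny_view(),
                                   n_angles = 12, n_positions = 8, seed = 4)
  expect_identical(curves$response, curves2$response)
  tb <- as_tibble(curves)
  expect_equal(nrow(tb), 12 * 32)
})

test_that("plot files are written once per map with deterministic names", {
  sf <- sampled_fixture()
  out <- withr::local_tempdir()
  man <- plot_maps(sf$maps, out, signals = 1:3)
  expect_equal(nrow(man), 3 * 9)
  expect_true(all(file.exists(man$file)))
  expect_equal(sum(grepl("/place/average/", man$file)), 3)
  man2 <- plot_maps(sf$maps, out, signals = 1:3)
  expect_identical(man$file, man2$file)
  curves <- sample_head_direction(sf$net, sf$fx$plan, tiny_view(),
                                  n_angles = 8, n_positions = 5, seed = 1)
  man_hd <- plot_maps(curves, out, signals = 1:4)
  expect_equal(nrow(man_hd), 4)
  expect_true(all(grepl("/hd/sig_", man_hd$file)))
})

test_that("a heading-dominated movement regime sharpens head-direction tuning", {
  open <- study_run_open()
  # fast, straight running: heading becomes the slowest behavioural variable
  plan <- make_box(10, 10)
  traj <- generate_trajectory(plan,
                              motion_params(speed = 1, momentum = 0.9,
                                            arc = 10),
                              n_steps = 10000, seed = 44)
  frames <- render_frames(plan, traj, tiny_view())
  net_hd <- train(reduced_architecture(), frames, batch_size = 5000,
                  with_ica = TRUE, noise_sigma = 1e-4, seed = 44)
  curves_hd <- sample_head_direction(net_hd, plan, tiny_view(),
                                     n_angles = 24, n_positions = 40,
                                     seed = 7)
  curves_pos <- sample_head_direction(open$net, open$plan, tiny_view(),
                                      n_angles = 24, n_positions = 40,
                                      seed = 7)
  conc_hd <- max(vapply(1:32, function(s) tuning_concentration(curves_hd, s), 0))
  conc_pos <- max(vapply(1:32, function(s) tuning_concentration(curves_pos, s), 0))
  # lower circular variance (higher concentration) for the peak signal
  expect_gt(conc_hd, conc_pos)
})

test_that("rate maps and curves tidy into plottable tables", {
  sf <- sampled_fixture()
  tb <- as_tibble(sf$maps)
  expect_equal(nrow(tb), 9 * 32 * length(sf$maps$x) * length(sf$maps$y))
  expect_setequal(unique(tb$direction), c(as.character(seq(0, 315, by = 45)),
                                          "average"))
  p <- ggplot2::autoplot(sf$maps, signals = 1:2)
  expect_s3_class(p, "ggplot")
})
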