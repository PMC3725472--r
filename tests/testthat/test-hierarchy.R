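test_that("tiling arithmetic matches the closed form and rejects inexact tilings", {
  expect_equal(unname(tile(320, 40, c(10, 8), c(5, 4))), c(63, 9))
  expect_equal(unname(tile(63, 9, c(14, 5), c(7, 4))), c(8, 2))
  expect_equal(unname(tile(10, 10, c(4, 4), c(3, 3))), c(3, 3))
  expect_error(tile(10, 10, c(4, 4), c(4, 4)), "residue")
})

test_that("standard architectures reproduce the layer grids and tiling identities", {
  net <- default_architecture()
  expect_equal(unname(net$layers[[1]]$grid), c(63, 9))
  expect_equal(unname(net$layers[[2]]$grid), c(8, 2))
  expect_equal(prod(net$layers[[2]]$grid), 16)
  expect_equal(unname(net$layers[[3]]$grid), c(1, 1))
  expect_equal((63 - 1) * 5 + 10, 320)
  expect_equal((9 - 1) * 4 + 8, 40)
  expect_equal(net$layers[[1]]$per_node_out, 32L)
  red <- reduced_architecture()
  expect_equal(unname(red$layers[[1]]$grid), c(12, 3))
  expect_equal(unname(red$layers[[2]]$grid), c(3, 1))
  for (net2 in list(net, red)) {
    for (l in net2$layers) {
      expect_equal(unname((l$grid[1] - 1) * l$stride[1] + l$rf[1]), l$in_w)
      expect_equal(unname((l$grid[2] - 1) * l$stride[2] + l$rf[2]), l$in_h)
    }
  }
})

test_that("batched training is exactly equivalent to single-batch training", {
  fx <- test_frames(600)
  n1 <- train(reduced_architecture(), fx$frames, batch_size = 600,
              with_ica = TRUE, noise_sigma = 1e-4, seed = 9)
  n2 <- train(reduced_architecture(), fx$frames, batch_size = 60,
              with_ica = TRUE, noise_sigma = 1e-4, seed = 9)
  probe <- fx$frames$frames[, , 1:40]
  expect_lt(max(abs(forward_many(n1, probe) - forward_many(n2, probe))), 1e-6)
  # moment accumulation is chunk-aligned, so parameters agree to rounding
  expect_equal(n1$layers, n2$layers, tolerance = 1e-9)
  expect_equal(n1$meta$n_batches, 1)
  expect_equal(n2$meta$n_batches, 10)
})

test_that("training is reproducible and the top node satisfies the SFA constraints", {
  fx <- test_frames(600)
  n1 <- train(reduced_architecture(), fx$frames, batch_size = 300,
              with_ica = TRUE, noise_sigma = 1e-4, seed = 7)
  n2 <- train(reduced_architecture(), fx$frames, batch_size = 300,
              with_ica = TRUE, noise_sigma = 1e-4, seed = 7)
  expect_identical(n1$layers, n2$layers)
  expect_identical(n1$ica$rotation, n2$ica$rotation)
  # constraints on the top node's training ensemble (noise-free propagation
  # of the training frames; tolerances widened only by the 1e-4 fit noise)
  n0 <- train(reduced_architecture(), fx$frames, batch_size = 300,
              with_ica = FALSE, noise_sigma = 0, seed = 7)
  Y <- forward_many(n0, fx$frames)
  expect_lt(max(abs(colMeans(Y))), 1e-8)
  expect_lt(max(abs(colMeans(Y^2) - 1)), 1e-6)
  C <- crossprod(Y) / nrow(Y)
  expect_lt(max(abs(C[upper.tri(C)])), 1e-6)
  deltas <- n0$layers[[3]]$nodes[[1]]$stage2$delta_values
  expect_true(all(diff(deltas) >= 0))
})

test_that("forward pass equals a hand-rolled composition of per-node SFA maps", {
  fx <- test_frames(500)
  net <- train(sfa_network(64, 16, list(list(rf = c(24, 16), stride = c(20, 1))),
                           per_node_out = 8, reduce_dim = 6),
               fx$frames, batch_size = 500, with_ica = FALSE,
               noise_sigma = 1e-4, seed = 5)
  frame <- fx$frames$frames[, , 17] / 255
  lay <- net$layers[[1]]
  manual <- unlist(lapply(1:3, function(i) {
    patch <- frame[1:16, ((i - 1) * 20 + 1):((i - 1) * 20 + 24)]
    z <- apply_sfa(lay$nodes[[i]]$stage1, as.vector(patch))
    apply_sfa(lay$nodes[[i]]$stage2, z)
  }))
  expect_equal(unname(forward(net, fx$frames$frames[, , 17])),
               unname(manual), tolerance = 1e-12)
})

test_that("output dimension and determinism of the forward pass", {
  fx <- test_frames(500)
  net <- train(reduced_architecture(), fx$frames, batch_size = 500,
               with_ica = TRUE, noise_sigma = 1e-4, seed = 2)
  fr <- fx$frames$frames[, , 3]
  y <- forward(net, fr)
  expect_length(y, 32)
  expect_identical(forward(net, fr), y)
  expect_error(forward(reduced_architecture(), fr), "untrained")
  expect_error(train(reduced_architecture(),
                     array(0, dim = c(10, 10, 20)), batch_size = 10),
               "expects")
})

test_that("generic lower-layer training freezes layers 1-2; train_top leaves them intact", {
  fx <- test_frames(500)
  # scrambled frame order stands in for a generic natural-image stream
  nat <- fx$frames
  nat$frames <- nat$frames[, , seq(dim(nat$frames)[3], 1)]
  ng <- train_generic(reduced_architecture(), nat, batch_size = 250, seed = 5)
  expect_true(ng$layers[[1]]$frozen && ng$layers[[2]]$frozen)
  expect_error(forward_many(ng, fx$frames), "untrained")
  lower <- ng$layers[1:2]
  nt <- train_top(ng, fx$frames, batch_size = 250, with_ica = TRUE, seed = 5)
  expect_identical(nt$layers[1:2], lower)
  expect_equal(ncol(forward_many(nt, fx$frames)), 32)
  # same environment frames twice give identical top layers
  nt2 <- train_top(ng, fx$frames, batch_size = 250, with_ica = TRUE, seed = 5)
  expect_identical(nt$layers[[3]], nt2$layers[[3]])
  expect_error(train_top(reduced_architecture(), fx$frames), "lower layers")
})

test_that("a place code learned in one enclosure is lost after retraining in another", {
  fx_a <- test_frames(1500, seed = 31, box = c(8, 8))
  net <- train(reduced_architecture(), fx_a$frames, batch_size = 750,
               with_ica = TRUE, noise_sigma = 1e-4, seed = 11)
  maps_a <- sample_place(net, fx_a$plan, tiny_view(), spacing = 0.8,
                         margin = 0.2)
  # freeze the lower layers, retrain the top in a different enclosure
  net$layers[[1]]$frozen <- TRUE
  net$layers[[2]]$frozen <- TRUE
  plan_b <- make_circle(5, 24)
  traj_b <- generate_trajectory(plan_b, motion_params(), n_steps = 1500,
                                seed = 32)
  frames_b <- render_frames(plan_b, traj_b, tiny_view())
  net_b <- train_top(net, frames_b, batch_size = 750, with_ica = TRUE,
                     seed = 12)
  maps_a2 <- sample_place(net_b, fx_a$plan, tiny_view(), spacing = 0.8,
                          margin = 0.2)
  m <- maps_a$mask
  rs <- vapply(1:32, function(s) {
    abs(cor(maps_a$average[, , s][m], maps_a2$average[, , s][m]))
  }, 0)
  expect_lt(median(rs), 0.5)
})

test_that("add_ica attaches the rotation without touching the SFA layers", {
  fx <- test_frames(500)
  base <- train(reduced_architecture(), fx$frames, batch_size = 500,
                with_ica = FALSE, noise_sigma = 1e-4, seed = 9)
  with_ica <- train(reduced_architecture(), fx$frames, batch_size = 500,
                    with_ica = TRUE, noise_sigma = 1e-4, seed = 9)
  added <- add_ica(base, fx$frames)
  expect_identical(added$layers, base$layers)
  expect_identical(added$ica$rotation, with_ica$ica$rotation)
  expect_length(forward(added, fx$frames$frames[, , 1]), 32)
  expect_error(add_ica(added, fx$frames), "already")
})
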