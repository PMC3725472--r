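#' Exact receptive-field tiling
#'
#' Number of nodes that tile an input of `input_w x input_h` units with
#' receptive fields of size `rf` and strides `stride`. The tiling must be
#' exact: `(cols - 1) * stride_x + rf_w == input_w` (and likewise
#' vertically), otherwise a configuration error reports the residue.
#'
#' @param input_w,input_h Input extent (pixels for layer 1, node-grid units
#'   above).
#' @param rf `(width, height)` of each node's receptive field.
#' @param stride `(horizontal, vertical)` stride between neighbouring nodes.
#' @return `c(cols, rows)` of the resulting node grid.
#' @export
tile <- function(input_w, input_h, rf, stride) {
  res_w <- (input_w - rf[1]) %% stride[1]
  res_h <- (input_h - rf[2]) %% stride[2]
  if (res_w != 0 || res_h != 0) {
    stopf(paste0("receptive fields do not tile the input exactly: ",
                 "width residue %d, height residue %d ",
                 "(input %d x %d, rf %d x %d, stride %d x %d)"),
          res_w, res_h, input_w, input_h, rf[1], rf[2], stride[1], stride[2])
  }
  c(cols = (input_w - rf[1]) %/% stride[1] + 1L,
    rows = (input_h - rf[2]) %/% stride[2] + 1L)
}

new_layer <- function(in_w, in_h, in_channels, rf, stride, per_node_out,
                      reduce_dim) {
  grid <- tile(in_w, in_h, rf, stride)
  in_dim <- in_channels * rf[1] * rf[2]
  red <- min(reduce_dim, in_dim)
  out <- min(per_node_out, expanded_dim(red, "quadratic"))
  list(rf = as.integer(rf), stride = as.integer(stride),
       grid = as.integer(grid), in_w = as.integer(in_w),
       in_h = as.integer(in_h), in_channels = as.integer(in_channels),
       in_dim = as.integer(in_dim), reduce_dim = as.integer(red),
       per_node_out = as.integer(out),
       nodes = NULL, trained = FALSE, frozen = FALSE)
}

#' Construct an untrained hierarchical SFA network
#'
#' Each layer is a 2-D grid of SFA nodes with overlapping receptive fields
#' that tile the layer input exactly. A node internally reduces its input
#' to `reduce_dim` signals by linear SFA, expands them quadratically, and
#' extracts `per_node_out` slow signals, keeping every per-node
#' eigenproblem small (the reason for using a hierarchy at all).
#'
#' @param input_w,input_h Frame size in pixels the network consumes.
#' @param layer_defs List of `list(rf = c(w, h), stride = c(x, y))`, one
#'   per layer, bottom to top.
#' @param per_node_out Slow signals each node emits (default 32).
#' @param reduce_dim Linear pre-reduction inside each node (default 16).
#' @return An object of class `sfa_network` (untrained).
#' @export
sfa_network <- function(input_w, input_h, layer_defs, per_node_out = 32,
                        reduce_dim = 16) {
  layers <- list()
  in_w <- input_w; in_h <- input_h; in_ch <- 1L
  for (ld in layer_defs) {
    lay <- new_layer(in_w, in_h, in_ch, ld$rf, ld$stride, per_node_out,
                     reduce_dim)
    layers[[length(layers) + 1L]] <- lay
    in_w <- lay$grid[1]; in_h <- lay$grid[2]; in_ch <- lay$per_node_out
  }
  structure(list(input_w = as.integer(input_w), input_h = as.integer(input_h),
                 layers = layers, ica = NULL, meta = list()),
            class = "sfa_network")
}

#' Default network architecture (320 x 40 panoramic input)
#'
#' Three SFA layers: a 63 x 9 grid over the pixels (receptive fields
#' 10 x 8, stride 5 x 4), an 8 x 2 grid over the node outputs (fields
#' 14 x 5 nodes, stride 7 x 4), and a single top node integrating all 16
#' second-layer nodes; an ICA sparse-coding node can sit on the final 32
#' signals.
#'
#' @param input_w,input_h Input frame size (default 320 x 40).
#' @inheritParams sfa_network
#' @export
default_architecture <- function(input_w = 320, input_h = 40,
                                 per_node_out = 32, reduce_dim = 16) {
  net <- sfa_network(input_w, input_h, list(
    list(rf = c(10, 8), stride = c(5, 4)),
    list(rf = c(14, 5), stride = c(7, 4))
  ), per_node_out = per_node_out, reduce_dim = reduce_dim)
  g <- net$layers[[length(net$layers)]]$grid
  net$layers[[3]] <- new_layer(g[1], g[2], per_node_out,
                               rf = g, stride = c(1, 1),
                               per_node_out = per_node_out,
                               reduce_dim = reduce_dim)
  net
}

#' Reduced network architecture (64 x 16 input)
#'
#' A smaller first-class configuration with the same node internals and
#' ~50% receptive-field overlap: grids 12 x 3 and 3 x 1 plus a single top
#' node. Used for fast end-to-end runs.
#'
#' @inheritParams default_architecture
#' @export
reduced_architecture <- function(input_w = 64, input_h = 16,
                                 per_node_out = 32, reduce_dim = 16) {
  net <- sfa_network(input_w, input_h, list(
    list(rf = c(9, 8), stride = c(5, 4)),
    list(rf = c(6, 3), stride = c(3, 1))
  ), per_node_out = per_node_out, reduce_dim = reduce_dim)
  g <- net$layers[[length(net$layers)]]$grid
  net$layers[[3]] <- new_layer(g[1], g[2], per_node_out,
                               rf = g, stride = c(1, 1),
                               per_node_out = per_node_out,
                               reduce_dim = reduce_dim)
  net
}

#' @export
print.sfa_network <- function(x, ...) {
  cat(sprintf("<sfa_network> input %d x %d, %d layers%s\n",
              x$input_w, x$input_h, length(x$layers),
              if (!is.null(x$ica)) " + ICA" else ""))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  layer %d: grid %d x %d (%d nodes), rf %d x %d, stride %d x %d, out %d%s%s\n",
                i, l$grid[1], l$grid[2], prod(l$grid), l$rf[1], l$rf[2],
                l$stride[1], l$stride[2], l$per_node_out,
                if (l$trained) ", trained" else "",
                if (l$frozen) ", frozen" else ""))
  }
  invisible(x)
}

# ---- receptive-field gathering ---------------------------------------------
# Layer-1 streams are pixel arrays (H, W, T); upper-layer streams are node
# output arrays (nsig, cols, rows, T). Within a receptive field the input
# vector is ordered rows-fastest (layer 1) / signals-fastest (upper layers);
# the order is fixed but arbitrary.

gather_node <- function(layer, stream, i, j, tsel = NULL) {
  c0 <- (i - 1L) * layer$stride[1]
  r0 <- (j - 1L) * layer$stride[2]
  if (length(dim(stream)) == 3L) {
    sub <- stream[r0 + seq_len(layer$rf[2]), c0 + seq_len(layer$rf[1]),
                  tsel %||% TRUE, drop = FALSE]
  } else {
    sub <- stream[, c0 + seq_len(layer$rf[1]), r0 + seq_len(layer$rf[2]),
                  tsel %||% TRUE, drop = FALSE]
  }
  nt <- dim(sub)[length(dim(sub))]
  dim(sub) <- c(length(sub) / nt, nt)
  t(sub)
}

node_forward <- function(node, X) {
  apply_sfa(node$stage2, apply_sfa(node$stage1, X))
}

# training noise drawn sample-major, so that the draw stream is identical
# whatever the batch size: concatenating batches reproduces one long batch
sample_major_noise <- function(n, d) {
  t(matrix(stats::rnorm(n * d), d, n))
}

train_layer <- function(layer, stream, batches, noise_sigma, seed, lindex) {
  n_nodes <- prod(layer$grid)
  nodes <- vector("list", n_nodes)
  for (j in seq_len(layer$grid[2])) {
    for (i in seq_len(layer$grid[1])) {
      n <- (j - 1L) * layer$grid[1] + i
      node_seed <- derive_seed(seed, lindex, n)
      # stage 1: linear reduction
      acc <- moments_new(layer$in_dim)
      withr::with_seed(node_seed, {
        for (b in batches) {
          X <- gather_node(layer, stream, i, j, b)
          if (noise_sigma > 0) {
            X <- X + sample_major_noise(nrow(X), ncol(X)) * noise_sigma
          }
          acc <- moments_update(acc, X)
        }
      })
      mom1 <- moments_finalize(acc)
      s1 <- sfa_from_moments(mom1, layer$reduce_dim)
      stage1 <- new_sfa_model(input_mean = mom1$mean, expansion = "none",
                              exp_mean = numeric(layer$in_dim),
                              proj = s1$proj, delta = s1$delta,
                              rank = s1$rank, noise_sigma = noise_sigma,
                              seed = node_seed, n_train = mom1$n)
      # stage 2: quadratic SFA on the reduced signals (same noise stream)
      acc <- moments_new(expanded_dim(layer$reduce_dim, "quadratic"))
      withr::with_seed(node_seed, {
        for (b in batches) {
          X <- gather_node(layer, stream, i, j, b)
          if (noise_sigma > 0) {
            X <- X + sample_major_noise(nrow(X), ncol(X)) * noise_sigma
          }
          acc <- moments_update(acc, quadratic_expand(apply_sfa(stage1, X)))
        }
      })
      mom2 <- moments_finalize(acc)
      s2 <- sfa_from_moments(mom2, layer$per_node_out)
      stage2 <- new_sfa_model(input_mean = numeric(layer$reduce_dim),
                              expansion = "quadratic", exp_mean = mom2$mean,
                              proj = s2$proj, delta = s2$delta,
                              rank = s2$rank, noise_sigma = 0,
                              seed = node_seed, n_train = mom2$n)
      nodes[[n]] <- list(stage1 = stage1, stage2 = stage2)
    }
  }
  layer$nodes <- nodes
  layer$trained <- TRUE
  layer
}

propagate_layer <- function(layer, stream) {
  nd <- length(dim(stream))
  T_ <- dim(stream)[nd]
  out <- array(0, dim = c(layer$per_node_out, layer$grid[1], layer$grid[2], T_))
  for (j in seq_len(layer$grid[2])) {
    for (i in seq_len(layer$grid[1])) {
      n <- (j - 1L) * layer$grid[1] + i
      Y <- node_forward(layer$nodes[[n]], gather_node(layer, stream, i, j))
      out[, i, j, ] <- t(Y)
    }
  }
  out
}

# coerce input frames to the network's pixel stream in [0, 1]
as_pixel_stream <- function(network, frames) {
  if (inherits(frames, "frame_sequence")) {
    frames <- to_grayscale(frames)$frames
  }
  d <- dim(frames)
  if (length(d) == 2L) dim(frames) <- c(d, 1L)
  d <- dim(frames)
  if (d[1] != network$input_h || d[2] != network$input_w) {
    stopf("frames are %d x %d but the network expects %d x %d (crop_center may help)",
          d[2], d[1], network$input_w, network$input_h)
  }
  frames / 255
}

make_batches <- function(T_, batch_size) {
  if (batch_size < 2) stopf("batch_size must be >= 2")
  split(seq_len(T_), ceiling(seq_len(T_) / batch_size))
}

#' Train the hierarchical SFA network
#'
#' Layers are trained strictly bottom-up. Within a layer the second-moment
#' and difference-moment statistics are accumulated over batches of
#' `batch_size` frames (the last sample of each batch is carried over, so
#' batched accumulation is exactly equivalent to a single pass); after a
#' layer is fitted the whole sequence is propagated through it to form the
#' next layer's input. Seeded Gaussian noise of standard deviation
#' `noise_sigma` is added to every node's input during fitting only, which
#' regularises near-degenerate input statistics.
#'
#' @param network An untrained (or re-trainable) [sfa_network()].
#' @param frames A `frame_sequence` (color frames are converted to
#'   grayscale) or an `H x W x T` array with intensities 0-255.
#' @param batch_size Frames per accumulation batch.
#' @param with_ica Fit the ICA sparse-coding rotation on the top-node
#'   outputs after the SFA layers.
#' @param noise_sigma Training noise standard deviation (on inputs scaled
#'   to `[0, 1]`).
#' @param seed Master seed for all training randomness.
#' @param verbose Log per-layer timing and batch counts.
#' @return The trained network.
#' @export
train <- function(network, frames, batch_size = 10000, with_ica = TRUE,
                  noise_sigma = 1e-4, seed = 1, verbose = FALSE) {
  stream <- as_pixel_stream(network, frames)
  T_ <- dim(stream)[3]
  batches <- make_batches(T_, batch_size)
  for (l in seq_along(network$layers)) {
    t0 <- Sys.time()
    if (!(network$layers[[l]]$frozen && network$layers[[l]]$trained)) {
      network$layers[[l]] <- train_layer(network$layers[[l]], stream, batches,
                                         noise_sigma, seed, l)
    }
    stream <- propagate_layer(network$layers[[l]], stream)
    if (verbose) {
      message(sprintf("layer %d: trained %d nodes in %d batches (%.1f s)",
                      l, prod(network$layers[[l]]$grid), length(batches),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  top <- top_outputs_from_stream(stream)
  if (with_ica) {
    network$ica <- fit_ica(top, seed = derive_seed(seed, 99L))
  }
  network$meta <- list(frames_seen = T_, batch_size = batch_size,
                       n_batches = length(batches), seed = seed,
                       noise_sigma = noise_sigma)
  network
}

top_outputs_from_stream <- function(stream) {
  d <- dim(stream)
  out <- stream
  dim(out) <- c(prod(d[-length(d)]), d[length(d)])
  t(out)
}

#' Generic (natural-image) training of the lower layers
#'
#' Trains all layers except the top one on an arbitrary image sequence
#' (e.g. natural movies, or frames pooled over several enclosures) and
#' freezes them. The frozen layers extract generic low-level features;
#' afterwards only the top layer has to be trained per environment with
#' [train_top()].
#'
#' @inheritParams train
#' @param natural_frames Image sequence matching the input size (use
#'   [crop_center()] to conform).
#' @export
train_generic <- function(network, natural_frames, batch_size = 10000,
                          noise_sigma = 1e-4, seed = 1, verbose = FALSE) {
  stream <- as_pixel_stream(network, natural_frames)
  batches <- make_batches(dim(stream)[3], batch_size)
  lower <- seq_len(length(network$layers) - 1L)
  for (l in lower) {
    network$layers[[l]] <- train_layer(network$layers[[l]], stream, batches,
                                       noise_sigma, seed, l)
    network$layers[[l]]$frozen <- TRUE
    stream <- propagate_layer(network$layers[[l]], stream)
    if (verbose) message(sprintf("layer %d: trained and frozen", l))
  }
  network$meta$generic_frames <- dim(stream)[length(dim(stream))]
  network
}

#' Train the top layer within one environment
#'
#' Requires the lower layers to be trained (typically frozen after
#' [train_generic()]); fits the top SFA layer (and optionally ICA) on
#' frames from a single environment, leaving the lower layers bit-identical.
#'
#' @inheritParams train
#' @param env_frames Frames recorded in the target environment.
#' @export
train_top <- function(network, env_frames, batch_size = 10000,
                      with_ica = TRUE, noise_sigma = 1e-4, seed = 1) {
  L <- length(network$layers)
  if (!all(vapply(network$layers[-L], `[[`, TRUE, "trained"))) {
    stopf("train_top requires all lower layers to be trained (run train_generic first)")
  }
  stream <- as_pixel_stream(network, env_frames)
  T_ <- dim(stream)[3]
  batches <- make_batches(T_, batch_size)
  for (l in seq_len(L - 1L)) {
    stream <- propagate_layer(network$layers[[l]], stream)
  }
  network$layers[[L]] <- train_layer(network$layers[[L]], stream, batches,
                                     noise_sigma, seed, L)
  network$layers[[L]]$frozen <- FALSE
  stream <- propagate_layer(network$layers[[L]], stream)
  network$ica <- NULL
  if (with_ica) {
    network$ica <- fit_ica(top_outputs_from_stream(stream),
                           seed = derive_seed(seed, 99L))
  }
  network$meta <- utils::modifyList(network$meta %||% list(),
                                    list(frames_seen = T_,
                                         batch_size = batch_size,
                                         n_batches = length(batches),
                                         seed = seed,
                                         noise_sigma = noise_sigma))
  network
}

#' Attach the ICA sparse-coding node to a trained network
#'
#' Fits the ICA rotation on the top-node outputs over the given frames; the
#' SFA layers are left bit-identical. Errors if an ICA node is already
#' present.
#'
#' @inheritParams train
#' @export
add_ica <- function(network, frames, seed = NULL) {
  if (!is.null(network$ica)) stopf("network already has an ICA node")
  assert_trained(network, ica_needed = FALSE)
  seed <- seed %||% network$meta$seed %||% 1L
  top <- forward_many(network, frames)
  network$ica <- fit_ica(top, seed = derive_seed(seed, 99L))
  network
}

assert_trained <- function(network, ica_needed = FALSE) {
  tr <- vapply(network$layers, `[[`, TRUE, "trained")
  if (!all(tr)) {
    stopf("network layer %d is untrained; train the network first", which(!tr)[1])
  }
  if (ica_needed && is.null(network$ica)) stopf("network has no ICA node")
  invisible(network)
}

#' Forward pass through the trained network
#'
#' Per node: gather the receptive field, apply the node's SFA stages,
#' concatenate, move up a layer; finally apply the ICA rotation when
#' present. Deterministic; no noise at application time.
#'
#' @param network A trained `sfa_network`.
#' @param frame A single frame (matrix or color array).
#' @return Numeric vector of the network's output signals (length 32 for
#'   the standard architectures).
#' @export
forward <- function(network, frame) {
  if (!is.matrix(frame) && length(dim(frame)) == 3L) frame <- to_grayscale(frame)
  drop(forward_many(network, array(frame, dim = c(dim(frame), 1L))))
}

#' Forward pass for a whole frame sequence
#'
#' @param network A trained `sfa_network`.
#' @param frames A `frame_sequence` or `H x W x T` array (0-255).
#' @return `T x k` matrix of output signals.
#' @export
forward_many <- function(network, frames) {
  assert_trained(network)
  stream <- as_pixel_stream(network, frames)
  for (l in seq_along(network$layers)) {
    stream <- propagate_layer(network$layers[[l]], stream)
  }
  out <- top_outputs_from_stream(stream)
  if (!is.null(network$ica)) out <- apply_ica(network$ica, out)
  out
}

#' @export
tidy.sfa_network <- function(x, ...) {
  purrr::map_dfr(seq_along(x$layers), function(l) {
    lay <- x$layers[[l]]
    if (!lay$trained) return(NULL)
    purrr::map_dfr(seq_along(lay$nodes), function(n) {
      tibble::tibble(layer = l, node = n,
                     component = seq_along(lay$nodes[[n]]$stage2$delta_values),
                     delta = lay$nodes[[n]]$stage2$delta_values)
    })
  })
}

#' @export
glance.sfa_network <- function(x, ...) {
  tibble::tibble(
    input_w = x$input_w, input_h = x$input_h,
    n_layers = length(x$layers),
    n_nodes = sum(vapply(x$layers, function(l) prod(l$grid), 0)),
    trained = all(vapply(x$layers, `[[`, TRUE, "trained")),
    has_ica = !is.null(x$ica),
    frames_seen = x$meta$frames_seen %||% NA_integer_,
    n_batches = x$meta$n_batches %||% NA_integer_
  )
}
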