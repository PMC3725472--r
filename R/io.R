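# On-disk formats. Both binary formats are bespoke but documented so that
# implementations in other languages can read them; all multi-byte values
# are little-endian.
#
# Frame container (.rlf):
#   bytes 0-3   magic "RLFC"
#   int32 x 6   version (1), T, width, height, channels (1|3), color tag
#               (0 = grayscale, 1 = color)
#   payload     T frames, each channel-major / column-major within a
#               channel (R array order H x W [x C]), one byte per pixel
# A plain-text pose sidecar "<path>.pose.txt" holds one "x y heading" line
# per frame (heading in radians).
#
# Network file (.rnet):
#   line 1      "SFANET 1"
#   line 2      JSON header (architecture, color mode, seeds, metadata)
#   line 3      "@BINARY"
#   blobs       for each layer, node, stage: input_mean, exp_mean, proj,
#               delta as (int32 ndim, int32 dims..., float64 data...), in a
#               fixed traversal order; then the ICA rotation when present.

FRAME_MAGIC <- "RLFC"
NET_MAGIC <- "SFANET"
NET_VERSION <- 1L

#' Write a frame sequence to a single binary container
#'
#' @param frames A `frame_sequence`.
#' @param path Output file path (a pose sidecar `<path>.pose.txt` is
#'   written when pose data is present).
#' @return `path`, invisibly.
#' @export
write_frame_container <- function(frames, path) {
  stopifnot(inherits(frames, "frame_sequence"))
  a <- frames$frames
  d <- dim(a)
  color <- frames$color_mode == "color"
  T_ <- d[length(d)]
  ch <- if (color) 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(FRAME_MAGIC, con, nchars = 4, eos = NULL)
  writeBin(c(1L, T_, d[2], d[1], ch, as.integer(color)), con,
           size = 4, endian = "little")
  # array order is already (H, W [, C], T) column-major
  writeBin(as.raw(pmax(0, pmin(255, round(as.vector(a))))), con)
  if (!is.null(frames$pose)) {
    writeLines(sprintf("%.17g %.17g %.17g", frames$pose$x, frames$pose$y,
                       frames$pose$heading),
               paste0(path, ".pose.txt"))
  }
  invisible(path)
}

#' Read a frame container
#'
#' @param path Container file path.
#' @return A `frame_sequence` (with pose data when the sidecar exists).
#' @export
read_frame_container <- function(path) {
  if (!file.exists(path)) stopf("frame container not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, FRAME_MAGIC)) {
    stopf("%s is not a frame container (bad magic '%s')", path, magic)
  }
  hd <- readBin(con, "integer", 6, size = 4, endian = "little")
  if (hd[1] != 1L) stopf("unsupported frame-container version %d", hd[1])
  T_ <- hd[2]; w <- hd[3]; h <- hd[4]; ch <- hd[5]
  expect <- as.double(T_) * w * h * ch
  payload <- as.integer(readBin(con, "raw", expect))
  if (length(payload) != expect) {
    stopf("frame container %s is truncated: expected %.0f pixel bytes, found %d (first bad frame index %d)",
          path, expect, length(payload),
          floor(length(payload) / (w * h * ch)) + 1)
  }
  if (length(readBin(con, "raw", 1)) != 0) {
    stopf("frame container %s has trailing bytes beyond the declared payload", path)
  }
  dims <- if (ch == 3L) c(h, w, 3L, T_) else c(h, w, T_)
  arr <- array(as.double(payload), dim = dims)
  pose <- NULL
  pose_path <- paste0(path, ".pose.txt")
  if (file.exists(pose_path)) {
    tab <- utils::read.table(pose_path, col.names = c("x", "y", "heading"))
    if (nrow(tab) != T_) {
      stopf("pose sidecar has %d lines for %d frames", nrow(tab), T_)
    }
    pose <- tibble::as_tibble(tab)
  }
  frame_sequence(arr, pose = pose)
}

# ---- network serialization --------------------------------------------------

# read one newline-terminated line from a binary connection without
# read-ahead buffering (readLines would desynchronise subsequent readBin)
read_line_bin <- function(con, max_bytes = 16777216L) {
  pos <- seek(con, where = NA)
  buf <- readBin(con, "raw", max_bytes)
  nl <- which(buf == as.raw(10L))[1]
  if (is.na(nl)) stopf("corrupt file: unterminated header line")
  seek(con, where = pos + nl)
  rawToChar(buf[seq_len(nl - 1L)])
}

write_blob <- function(con, x) {
  d <- dim(x) %||% length(x)
  writeBin(length(d), con, size = 4, endian = "little")
  writeBin(as.integer(d), con, size = 4, endian = "little")
  writeBin(as.double(x), con, size = 8, endian = "little")
}

read_blob <- function(con) {
  nd <- readBin(con, "integer", 1, size = 4, endian = "little")
  d <- readBin(con, "integer", nd, size = 4, endian = "little")
  x <- readBin(con, "double", prod(d), size = 8, endian = "little")
  if (length(x) != prod(d)) stopf("network file is truncated")
  if (nd > 1) dim(x) <- d
  x
}

sfa_model_blobs <- function(m) {
  list(input_mean = m$input_mean, exp_mean = m$exp_mean,
       proj = m$proj, delta = m$delta_values)
}

#' Save a trained network to a versioned binary file
#'
#' The format is a documented, language-neutral container (text header with
#' the architecture and seeds, followed by all model matrices as raw
#' doubles); a load/save round trip is bit-identical.
#'
#' @param network A trained `sfa_network`.
#' @param path Output file path.
#' @export
save_network <- function(network, path) {
  assert_trained(network)
  header <- list(
    format = NET_MAGIC, version = NET_VERSION,
    input_w = network$input_w, input_h = network$input_h,
    layers = lapply(network$layers, function(l) {
      list(rf = l$rf, stride = l$stride, grid = l$grid,
           in_channels = l$in_channels, reduce_dim = l$reduce_dim,
           per_node_out = l$per_node_out, frozen = l$frozen,
           stage_meta = lapply(l$nodes, function(nd) {
             list(s1 = c(nd$stage1$rank, nd$stage1$n_train),
                  s2 = c(nd$stage2$rank, nd$stage2$n_train),
                  seeds = c(nd$stage1$seed),
                  noise = nd$stage1$noise_sigma)
           }))
    }),
    has_ica = !is.null(network$ica),
    ica_meta = if (!is.null(network$ica)) {
      list(converged = network$ica$converged,
           iterations = network$ica$iterations, seed = network$ica$seed)
    },
    meta = network$meta
  )
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(c(sprintf("%s %d", NET_MAGIC, NET_VERSION),
                  as.character(jsonlite::toJSON(header, auto_unbox = TRUE,
                                                digits = NA, null = "null")),
                  "@BINARY"), "\n", collapse = "")
  writeChar(hdr, con, eos = NULL)
  for (l in network$layers) {
    for (nd in l$nodes) {
      for (b in c(sfa_model_blobs(nd$stage1), sfa_model_blobs(nd$stage2))) {
        write_blob(con, b)
      }
    }
  }
  if (!is.null(network$ica)) write_blob(con, network$ica$rotation)
  invisible(path)
}

#' Load a network file
#'
#' @param path Network file path.
#' @return A trained `sfa_network`; forward outputs are identical to the
#'   saved network's.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stopf("network file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  tag <- read_line_bin(con)
  parts <- strsplit(tag, " ")[[1]]
  if (length(parts) != 2 || parts[1] != NET_MAGIC) {
    stopf("%s is not a network file (bad format tag '%s')", path, tag)
  }
  if (is.na(suppressWarnings(as.integer(parts[2]))) ||
      as.integer(parts[2]) != NET_VERSION) {
    stopf("network file version %s is incompatible with this reader (version %d)",
          parts[2], NET_VERSION)
  }
  header <- tryCatch(
    jsonlite::fromJSON(read_line_bin(con), simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    error = function(e) stopf("network file %s has a corrupt header: %s",
                              path, conditionMessage(e)))
  if (!identical(read_line_bin(con), "@BINARY")) {
    stopf("network file %s has a corrupt header (missing @BINARY marker)", path)
  }
  layers <- list()
  for (li in seq_along(header$layers)) {
    hl <- header$layers[[li]]
    lay <- list(rf = as.integer(unlist(hl$rf)),
                stride = as.integer(unlist(hl$stride)),
                grid = as.integer(unlist(hl$grid)),
                in_channels = hl$in_channels,
                reduce_dim = hl$reduce_dim, per_node_out = hl$per_node_out,
                trained = TRUE, frozen = isTRUE(hl$frozen))
    nodes <- vector("list", prod(lay$grid))
    for (n in seq_len(prod(lay$grid))) {
      sm <- hl$stage_meta[[n]]
      read_model <- function(expansion, rankn) {
        im <- read_blob(con); em <- read_blob(con)
        pj <- read_blob(con); dl <- read_blob(con)
        new_sfa_model(input_mean = im, expansion = expansion, exp_mean = em,
                      proj = pj, delta = dl, rank = rankn[1],
                      noise_sigma = sm$noise, seed = sm$seeds[1],
                      n_train = rankn[2])
      }
      s1 <- read_model("none", unlist(sm$s1))
      s2 <- read_model("quadratic", unlist(sm$s2))
      nodes[[n]] <- list(stage1 = s1, stage2 = s2)
    }
    lay$nodes <- nodes
    lay$in_dim <- length(nodes[[1]]$stage1$input_mean)
    layers[[li]] <- lay
  }
  ica <- NULL
  if (isTRUE(header$has_ica)) {
    rot <- read_blob(con)
    ica <- structure(list(rotation = rot,
                          converged = isTRUE(header$ica_meta$converged),
                          iterations = header$ica_meta$iterations,
                          seed = header$ica_meta$seed, k = nrow(rot)),
                     class = "ica_model")
  }
  structure(list(input_w = header$input_w, input_h = header$input_h,
                 layers = layers, ica = ica, meta = header$meta),
            class = "sfa_network")
}

# ---- experiment configuration ----------------------------------------------

config_schema <- function() {
  num <- function(lo = -Inf, hi = Inf) {
    function(v) {
      x <- suppressWarnings(as.numeric(v))
      if (is.na(x) || x < lo || x > hi) stopf("value '%s' out of range [%g, %g]", v, lo, hi)
      x
    }
  }
  choice <- function(...) {
    opts <- c(...)
    function(v) {
      if (!v %in% opts) stopf("value '%s' not one of: %s", v, paste(opts, collapse = ", "))
      v
    }
  }
  list(
    speed = num(1e-9), momentum = num(0, 1), arc = num(0, 360),
    min_wall_dist = num(0), path_noise = num(0),
    fov = num(1e-9, 360), frame_width = num(4), frame_height = num(2),
    wall_scale = num(1e-9), color_mode = choice("grayscale", "color", "both"),
    sample_spacing = num(1e-9), sample_margin = num(0),
    batch_size = num(2), noise_sigma = num(0), seed = num(0, 2^31 - 1),
    texture_mode = choice("cycle", "same")
  )
}

#' Default experiment configuration
#'
#' The technical parameters that typically stay fixed across experiments:
#' movement statistics, view geometry, sampling and training settings.
#' @export
default_config <- function() {
  structure(list(
    speed = 0.2, momentum = 0.6, arc = 60, min_wall_dist = 0.2,
    path_noise = 0.5, fov = 320, frame_width = 320, frame_height = 40,
    wall_scale = 2, color_mode = "grayscale", sample_spacing = NA_real_,
    sample_margin = 0.2, batch_size = 10000, noise_sigma = 1e-4, seed = 1,
    texture_mode = "cycle"
  ), class = "experiment_config")
}

#' Read a key=value configuration file
#'
#' Plain-text `key = value` lines, `#` comments. Every key is validated
#' against the configuration schema; unknown keys are errors.
#'
#' @param path Config file path.
#' @param base Configuration to override (default [default_config()]).
#' @export
read_config <- function(path, base = default_config()) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  schema <- config_schema()
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(ln)) next
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stopf("line %d of %s: expected 'key = value'", i, path)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(schema)) {
      stopf("line %d of %s: unknown configuration key '%s'", i, path, key)
    }
    base[[key]] <- schema[[key]](val)
  }
  base
}

#' Write a configuration file
#' @param config An `experiment_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  keep <- !vapply(config, function(v) is.numeric(v) && is.na(v), TRUE)
  config <- config[keep]
  writeLines(c("# experiment configuration",
               sprintf("%s = %s", names(config),
                       vapply(config, function(v) format(v, digits = 17), ""))),
             path)
  invisible(path)
}
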