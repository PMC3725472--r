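#' Wall texture registry
#'
#' Holds the raster images painted onto wall segments by the renderer.
#' A set of procedural textures (stripes, checker, noise, gradient) at
#' distinct mean luminances is always available, so enclosures render with
#' zero bundled image assets; user PNG files layered on top override or
#' extend the set.
#'
#' @param dir Optional directory of PNG files; each `<name>.png` is added
#'   under `<name>` (values rescaled to 0-255).
#' @param cycle If `TRUE` (default) segments cycle through the available
#'   textures in order; if `FALSE` every segment uses the first texture.
#' @param tile_width World-unit width covered by one horizontal repeat of a
#'   texture when painted along a wall.
#' @return An object of class `texture_registry`.
#' @export
texture_registry <- function(dir = NULL, cycle = TRUE, tile_width = 2) {
  tex <- default_textures()
  if (!is.null(dir)) {
    if (!dir.exists(dir)) stopf("texture directory not found: %s", dir)
    files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
    for (f in files) {
      img <- png::readPNG(f) * 255
      name <- sub("\\.png$", "", basename(f))
      tex[[name]] <- as_texture(img)
    }
  }
  structure(
    list(textures = tex, cycle = isTRUE(cycle), tile_width = tile_width),
    class = "texture_registry"
  )
}

# normalize an image array into list(col = HxWx3, gray = HxW), 0..255
as_texture <- function(img) {
  if (is.matrix(img)) {
    col <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (length(dim(img)) == 3L) {
    col <- img[, , 1:3, drop = FALSE] # drop alpha if present
  } else {
    stopf("texture must be a matrix or H x W x C array")
  }
  gray <- 0.299 * col[, , 1] + 0.587 * col[, , 2] + 0.114 * col[, , 3]
  list(col = col, gray = round(gray))
}

# Procedural fallback textures. Distinct mean luminances and tints so the
# lowest network layer sees wall identity even in grayscale.
default_textures <- function() {
  n <- 32L
  stripe_v <- matrix(rep(c(30, 170), each = 4, length.out = n), n, n, byrow = TRUE)
  stripe_h <- matrix(rep(c(220, 90), each = 4, length.out = n), n, n, byrow = FALSE)
  checker <- 255 * outer(seq_len(n) %/% 8, seq_len(n) %/% 8,
                         function(i, j) (i + j) %% 2)
  # fixed congruential noise: a constant asset, not a random draw
  idx <- outer(seq_len(n), seq_len(n), function(i, j) (i * 73 + j * 151) %% 97)
  noise <- 60 + round(idx / 96 * 180)
  grad <- matrix(rep(round(seq(10, 245, length.out = n)), each = n), n, n)

  tint <- function(m, rgb) {
    a <- array(0, dim = c(nrow(m), ncol(m), 3L))
    for (k in 1:3) a[, , k] <- pmin(255, m * rgb[k])
    as_texture(a)
  }
  list(
    stripes_v = tint(stripe_v, c(1.00, 0.55, 0.45)),
    stripes_h = tint(stripe_h, c(0.45, 0.60, 1.00)),
    checker   = tint(checker,  c(0.55, 1.00, 0.55)),
    noise     = tint(noise,    c(0.95, 0.90, 0.80)),
    gradient  = tint(grad,     c(1.00, 0.95, 0.50))
  )
}

#' @export
print.texture_registry <- function(x, ...) {
  cat("<texture_registry> ", length(x$textures), " textures: ",
      paste(names(x$textures), collapse = ", "),
      "; mode: ", if (x$cycle) "cycle" else "same", "\n", sep = "")
  invisible(x)
}

# resolve a texture id; unknown ids fall back to the first texture
get_texture <- function(registry, id) {
  registry$textures[[id]] %||% registry$textures[[1L]]
}

# texture name for the i-th wall segment under the registry's cycling mode
texture_for_index <- function(registry, i) {
  nm <- names(registry$textures)
  if (registry$cycle) nm[[(i - 1L) %% length(nm) + 1L]] else nm[[1L]]
}
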