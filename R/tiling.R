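#' Tessellate an image into non-overlapping square tiles
#'
#' Cuts a raster into a dense grid of non-overlapping `tile_size`-pixel
#' squares (default 299 px, i.e. a 273-um square at the default scanner
#' scale) and records, for every grid cell, the minimum gray value and
#' whether the tile passes the tissue pixel threshold. Partial strips at the
#' right/bottom edge are dropped: non-overlapping squares cannot cover a
#' remainder and padding would fabricate tissue.
#'
#' Grid indices are 0-based and row-major; pixel offsets are half-open, so
#' tile (row, col) covers rows `y0 + 1 .. y0 + tile_size` of the matrix with
#' `x0 = col * tile_size`, `y0 = row * tile_size`.
#'
#' @param image gray matrix or RGB array (see [as_gray8()]).
#' @param tile_size tile edge in pixels (default 299).
#' @param threshold gray threshold passed to [passes_pixel_threshold()].
#' @param slide_id identifier recorded in the manifest.
#' @param um_per_px physical scale; default 273/299 um per pixel.
#' @return a `tile_manifest`: data.frame with columns `slide_id`, `row`,
#'   `col`, `x0`, `y0`, `min_gray`, `kept`, and attributes `tile_size`,
#'   `image_dim`, `um_per_px`.
#' @export
tessellate <- function(image, tile_size = 299L, threshold = 110,
                       slide_id = "slide", um_per_px = 273 / 299) {
  g <- as_gray8(image)
  h <- nrow(g); w <- ncol(g)
  if (h < tile_size || w < tile_size) {
    stop_tf("image (%d x %d) smaller than one %d-px tile: empty manifest", w, h, tile_size)
  }
  n_rows <- h %/% tile_size
  n_cols <- w %/% tile_size
  grid <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  grid <- grid[order(grid$row, grid$col), , drop = FALSE]
  min_gray <- mapply(function(r, cc) {
    min(g[r * tile_size + seq_len(tile_size), cc * tile_size + seq_len(tile_size)])
  }, grid$row, grid$col)
  man <- data.frame(
    slide_id = slide_id,
    row = grid$row, col = grid$col,
    x0 = grid$col * tile_size, y0 = grid$row * tile_size,
    min_gray = as.numeric(min_gray),
    kept = as.numeric(min_gray) <= threshold,
    stringsAsFactors = FALSE
  )
  rownames(man) <- NULL
  attr(man, "tile_size") <- as.integer(tile_size)
  attr(man, "image_dim") <- c(height = h, width = w)
  attr(man, "um_per_px") <- um_per_px
  attr(man, "threshold") <- threshold
  class(man) <- c("tile_manifest", "data.frame")
  man
}

#' Tissue pixel-threshold filter for a single tile
#'
#' A tile is kept when the minimum gray value of its 8-bit gray-scale
#' conversion is at most `threshold` (default 110): at least one
#' sufficiently dark pixel is the proxy for at least one nucleated cell.
#' The boundary is inclusive — a tile whose darkest pixel is exactly 110
#' passes.
#'
#' @param tile gray matrix or RGB array.
#' @param threshold gray level in [0, 255]; default 110.
#' @return logical scalar.
#' @export
passes_pixel_threshold <- function(tile, threshold = 110) {
  min(as_gray8(tile)) <= threshold
}

#' Extract one tile's pixel block from an image
#'
#' @param image image accepted by [as_gray8()].
#' @param manifest a `tile_manifest` row source.
#' @param i row index into the manifest.
#' @return gray matrix of the tile.
#' @export
extract_tile <- function(image, manifest, i) {
  g <- as_gray8(image)
  ts <- attr(manifest, "tile_size")
  g[manifest$y0[i] + seq_len(ts), manifest$x0[i] + seq_len(ts), drop = FALSE]
}

#' Write a tile manifest as CSV
#'
#' @param manifest a `tile_manifest`.
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}
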