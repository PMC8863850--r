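#' Render the whole-slide tile-probability color map
#'
#' One colored cell per manifest tile: cancer tiles predicted metastatic
#' (`p_met` > 0.5) on a red ramp scaled by `p_met`, non-metastatic tiles on
#' a green ramp scaled by the non-metastatic probability, non-cancer tiles
#' fixed gray, and threshold-rejected tiles left at the background color.
#' Within each ramp brightness is linear in probability, with probability
#' 0.5 mapped to the darkest visible shade (not black) so direction stays
#' readable. Output is deterministic.
#'
#' @param manifest a `tile_manifest` from [tessellate()].
#' @param records data.frame with `row`, `col`, `p_met`, and optionally
#'   `predicted_label` (tiles not labeled "cancer" are drawn gray). Must
#'   reference only manifest tiles.
#' @param cell_size output pixels per tile cell (default 8).
#' @param min_brightness ramp value at probability 0.5 (default 0.25).
#' @param gray gray level for non-cancer tiles (default 0.5).
#' @param background background RGB for rejected tiles (default white).
#' @return RGB array (rows x cols x 3) in [0, 1], suitable for
#'   [png::writePNG()]; grid dimensions times `cell_size`.
#' @export
render_map <- function(manifest, records, cell_size = 8L,
                       min_brightness = 0.25, gray = 0.5,
                       background = c(1, 1, 1)) {
  key <- function(r, cc) paste(r, cc, sep = "_")
  man_keys <- key(manifest$row, manifest$col)
  rec_keys <- key(records$row, records$col)
  if (!all(rec_keys %in% man_keys)) {
    stop_tf("records reference tiles absent from the manifest")
  }
  n_rows <- max(manifest$row) + 1L
  n_cols <- max(manifest$col) + 1L
  img <- array(rep(background, each = n_rows * n_cols),
               dim = c(n_rows, n_cols, 3L))
  kept <- manifest$kept
  ## kept but unclassified (or non-cancer) tiles: fixed gray
  for (ch in 1:3) {
    m <- img[, , ch]
    m[cbind(manifest$row + 1L, manifest$col + 1L)[kept, , drop = FALSE]] <- gray
    img[, , ch] <- m
  }
  is_cancer <- if ("predicted_label" %in% names(records)) {
    records$predicted_label == "cancer"
  } else rep(TRUE, nrow(records))
  ramp <- function(p) min_brightness + (1 - min_brightness) * pmin(pmax(2 * (p - 0.5), 0), 1)
  for (i in which(is_cancer)) {
    r <- records$row[i] + 1L; cc <- records$col[i] + 1L
    p <- records$p_met[i]
    rgb <- if (p > 0.5) c(ramp(p), 0, 0) else c(0, ramp(1 - p), 0)
    img[r, cc, ] <- rgb
  }
  ## expand grid cells to cell_size x cell_size pixels
  big <- img[rep(seq_len(n_rows), each = cell_size),
             rep(seq_len(n_cols), each = cell_size), , drop = FALSE]
  attr(big, "um_per_cell") <- (attr(manifest, "um_per_px") %||% (273 / 299)) *
    (attr(manifest, "tile_size") %||% 299L)
  big
}

#' Write a slide map PNG plus a legend JSON
#'
#' @param map RGB array from [render_map()].
#' @param path output PNG path.
#' @export
write_map <- function(map, path) {
  png::writePNG(map, path)
  legend <- list(
    red = "metastatic-predicted cancer tile, brightness linear in p_met",
    green = "non-metastatic-predicted cancer tile, brightness linear in 1 - p_met",
    gray = "tile classified as non-tumor",
    background = "tile rejected by the tissue pixel threshold",
    um_per_cell = attr(map, "um_per_cell"))
  jsonlite::write_json(legend, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
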