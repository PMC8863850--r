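#' @importFrom stats rnorm rbeta rbinom rlnorm runif sd aggregate predict
#' @importFrom utils head write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.datatable.aware <- TRUE

utils::globalVariables(c("p_met", "p_cancer", "met", "case_id",
                         "isA", "isB", "isC", "isD", "isE"))

stop_tf <- function(...) stop(sprintf(...), call. = FALSE)

#' Convert a raster image to an 8-bit gray matrix
#'
#' Accepts a numeric matrix (gray) or a 3-dimensional array (RGB or RGBA, as
#' returned by [png::readPNG()]). RGB is collapsed with the standard
#' luminance weights 0.299 R + 0.587 G + 0.114 B so results are bit-stable
#' across readers. Values are returned on the 0--255 scale; inputs whose
#' maximum does not exceed 1 are assumed to be on [0, 1] and rescaled.
#'
#' @param img numeric matrix or 3-d numeric array.
#' @return numeric matrix of gray values in [0, 255].
#' @export
as_gray8 <- function(img) {
  if (is.array(img) && length(dim(img)) == 3L) {
    if (dim(img)[3] < 3L) {
      img <- img[, , 1L]
    } else {
      img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    }
  }
  if (!is.matrix(img) || !is.numeric(img)) {
    stop_tf("image is not convertible to a gray matrix")
  }
  if (max(img) <= 1) img <- img * 255
  if (min(img) < 0 || max(img) > 255) {
    stop_tf("gray values outside [0, 255] after conversion")
  }
  img
}

## Block-mean downscale of a gray matrix to out_px x out_px. Non-integer
## ratios are handled by assigning source rows/cols to output cells by index
## interval, so any input size is accepted.
downscale_gray <- function(mat, out_px) {
  if (nrow(mat) == out_px && ncol(mat) == out_px) return(mat)
  ri <- ceiling(seq_len(nrow(mat)) / nrow(mat) * out_px)
  ci <- ceiling(seq_len(ncol(mat)) / ncol(mat) * out_px)
  sums <- rowsum(mat, ri)
  sums <- t(rowsum(t(sums), ci))
  cnt <- tabulate(ri, out_px) %o% tabulate(ci, out_px)
  sums / cnt
}

## Truncated-normal draws by resampling (rejection), vectorised over mean.
rtruncnorm_resample <- function(n, mean, sd, lower = 0, upper = 1,
                                max_rounds = 1000L) {
  x <- rnorm(n, mean = mean, sd = sd)
  bad <- which(x < lower | x > upper)
  rounds <- 0L
  mean <- rep_len(mean, n)
  while (length(bad) > 0L) {
    rounds <- rounds + 1L
    if (rounds > max_rounds) stop_tf("truncated-normal resampling did not converge")
    x[bad] <- rnorm(length(bad), mean = mean[bad], sd = sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

## Draw a child seed stream from a master seed without exhausting the 32-bit
## integer range.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(master_seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}
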