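# Image feature backbones. Tile models pass each 299x299 standardized
# tile through a convolutional feature extractor, and trainable dense
# layers sit on top of the extracted features. Backbones are pluggable by
# name so a large pretrained network can be registered where available;
# the bundled "small-test" backbone is a fixed, randomly initialized
# two-layer CNN (random convolutional features) sized for CPU use.

.pdxmm_env <- new.env(parent = emptyenv())

#' Register an image feature backbone
#'
#' A backbone is a function taking a list of tiles (or pixel arrays) and
#' returning a numeric feature matrix with one row per tile. The
#' `"small-test"` backbone ships with the package; `"pretrained-large"` is
#' a plugin slot for an externally supplied pretrained extractor.
#'
#' @param name backbone identifier.
#' @param fn feature-extractor function `(tiles) -> matrix`.
#' @return `fn`, invisibly.
#' @export
register_backbone <- function(name, fn) {
  if (is.null(.pdxmm_env$backbones)) .pdxmm_env$backbones <- list()
  .pdxmm_env$backbones[[name]] <- fn
  invisible(fn)
}

get_backbone <- function(name) {
  fn <- .pdxmm_env$backbones[[name]]
  if (is.null(fn))
    abort_validation(sprintf(paste0(
      "backbone '%s' is not registered; supply a feature extractor with ",
      "register_backbone(\"%s\", fn)"), name, name))
  fn
}

# 2D average pooling by integer factor (crops to a multiple of the factor).
pool_mean <- function(x, f) {
  if (f <= 1L) return(x)
  pool_rows <- function(a) {
    h2 <- floor(dim(a)[1] / f)
    a <- a[seq_len(h2 * f), , , drop = FALSE]
    d <- dim(a)
    m <- colMeans(matrix(a, nrow = f))
    array(m, dim = c(h2, d[2], d[3]))
  }
  x <- pool_rows(x)
  x <- aperm(pool_rows(aperm(x, c(2, 1, 3))), c(2, 1, 3))
  x
}

# im2col convolution: k x k patches at the given stride, flattened so the
# convolution becomes one matrix product.
conv2d <- function(x, w, k = 3L, stride = 2L) {
  h <- dim(x)[1]; wd <- dim(x)[2]; ch <- dim(x)[3]
  rows <- seq(1L, h - k + 1L, by = stride)
  cols <- seq(1L, wd - k + 1L, by = stride)
  patches <- matrix(0, length(rows) * length(cols), k * k * ch)
  p <- 0L
  for (c0 in seq_len(ch)) for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    p <- p + 1L
    patches[, p] <- as.vector(x[rows + dy, cols + dx, c0])
  }
  out <- pmax(patches %*% w, 0)
  array(out, dim = c(length(rows), length(cols), ncol(w)))
}

small_test_weights <- function() {
  if (is.null(.pdxmm_env$small_test_w)) {
    .pdxmm_env$small_test_w <- with_seed(180451L, list(
      w1 = matrix(stats::rnorm(27 * 8, sd = sqrt(2 / 27)), 27, 8),
      w2 = matrix(stats::rnorm(72 * 16, sd = sqrt(2 / 72)), 72, 16)))
  }
  .pdxmm_env$small_test_w
}

small_test_features_one <- function(px) {
  w <- small_test_weights()
  f <- max(1L, floor(dim(px)[1] / 60))
  x <- pool_mean(px, f)
  c1 <- conv2d(x, w$w1)
  c2 <- conv2d(c1, w$w2)
  chan_stats <- function(a) {
    m <- apply(a, 3, mean)
    s <- apply(a, 3, stats::sd)
    c(m, s)
  }
  c(chan_stats(x), chan_stats(c1), chan_stats(c2))
}

#' Extract backbone features for a list of tiles
#'
#' @param tiles list of `pdx_tile`s or pixel arrays (standardized tiles).
#' @param backbone backbone name (default `"small-test"`).
#' @return numeric matrix, one row per tile.
#' @export
backbone_features <- function(tiles, backbone = "small-test") {
  fn <- get_backbone(backbone)
  fn(tiles)
}

# feature width: 2 x (3 input + 8 conv1 + 16 conv2) channel moments
register_backbone("small-test", function(tiles) {
  t(vapply(tiles, function(tl) small_test_features_one(tile_pixels(tl)),
           numeric(54)))
})
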