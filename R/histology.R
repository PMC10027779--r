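#' Read a whole-slide image (flat PNG/TIFF or multi-page TIFF)
#'
#' Returns the pixel array together with the microns-per-pixel (mpp)
#' resolution, which drives tile geometry. Multi-page (pyramidal) TIFFs are
#' supported through the `page` argument; `page = 1` is the full-resolution
#' level and the supplied `microns_per_pixel` must describe the chosen page.
#'
#' @param path PNG or TIFF file.
#' @param microns_per_pixel physical resolution of the chosen page (um/px);
#'   required, as neither format reliably carries it.
#' @param page page index for multi-page TIFF; ignored for PNG.
#' @return an object of class `pdx_slide`: list with `pixels`
#'   (rows x cols x 3 array in \[0, 1\], row = y downward, col = x
#'   rightward), `microns_per_pixel`, and `specimen_id` (file stem).
#' @export
read_slide <- function(path, microns_per_pixel, page = 1L) {
  if (missing(microns_per_pixel) || !is.numeric(microns_per_pixel) ||
      is.na(microns_per_pixel) || microns_per_pixel <= 0)
    abort_validation("`microns_per_pixel` is required and must be > 0")
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (page > length(pages))
      abort_validation(sprintf("TIFF has %d page(s); page %d requested",
                               length(pages), page))
    pages[[page]]
  } else abort_validation("slide must be a .png, .tif or .tiff file")
  img <- ensure_rgb(img)
  structure(list(pixels = img,
                 microns_per_pixel = as.numeric(microns_per_pixel),
                 specimen_id = tools::file_path_sans_ext(basename(path))),
            class = "pdx_slide")
}

# Coerce grayscale / RGBA pixel data to a rows x cols x 3 array in [0, 1].
ensure_rgb <- function(img) {
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Read ROI polygon annotations from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features in pixel coordinates
#' (top-left origin, x rightward, y downward). Only the outer ring of each
#' polygon is used.
#'
#' @param path GeoJSON file.
#' @return object of class `pdx_roi`: list with `specimen_id` and
#'   `polygons`, a list of closed n x 2 matrices (columns x, y).
#' @export
read_roi_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  polys <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    close_ring(m)
  })
  structure(list(specimen_id = tools::file_path_sans_ext(basename(path)),
                 polygons = polys),
            class = "pdx_roi")
}

#' Write ROI polygons as GeoJSON
#'
#' @param polygons list of n x 2 matrices (pixel coordinates).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roi_geojson <- function(polygons, path) {
  features <- lapply(polygons, function(p) {
    p <- close_ring(p)
    list(type = "Feature", properties = list(),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(p)),
                                                   function(i) as.numeric(p[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

close_ring <- function(m) {
  if (nrow(m) < 3L) abort_validation("ROI polygon needs at least 3 vertices")
  if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

points_in_polygons <- function(pts, polygons) {
  inside <- rep(FALSE, nrow(pts))
  for (p in polygons) inside <- inside | mgcv::in.out(close_ring(p), pts)
  inside
}

#' Extract raw tiles from a slide on a non-overlapping grid
#'
#' Tiles of `tile_um` x `tile_um` physical size are laid on a
#' non-overlapping grid of stride `round(tile_um / mpp)` source pixels,
#' anchored at the top-left of the ROI bounding box. A grid cell is kept
#' iff its center lies inside at least one ROI polygon; kept windows are
#' resized (bilinear) to `tile_px` x `tile_px`. At 0.5 um/px (a 20x scan)
#' the 302 um window spans 604 px and the resize to 299 px yields an
#' effective magnification of ~10x.
#'
#' @param slide a [read_slide()] object (or list with `pixels` and
#'   `microns_per_pixel`).
#' @param rois a [read_roi_geojson()] object or list of polygons.
#' @param tile_um physical tile side in microns (default 302).
#' @param tile_px output tile side in pixels (default 299).
#' @return list of raw tiles (class `pdx_tile`), each with `pixels`
#'   (`tile_px` x `tile_px` x 3), `specimen_id`, `grid_index` = c(row, col)
#'   and `stage = "raw"`. Empty list when no grid cell qualifies.
#' @export
extract_tiles <- function(slide, rois, tile_um = 302, tile_px = 299L) {
  mpp <- slide$microns_per_pixel
  if (is.null(mpp) || !is.finite(mpp) || mpp <= 0)
    abort_validation("slide has no valid microns-per-pixel metadata")
  stride <- as.integer(round_half_up(tile_um / mpp))
  if (stride < 1L) abort_validation("tile_um / microns_per_pixel must be >= 1")
  polygons <- if (inherits(rois, "pdx_roi")) rois$polygons else rois
  img <- slide$pixels
  h <- dim(img)[1]; w <- dim(img)[2]
  allv <- do.call(rbind, polygons)
  x0 <- max(floor(min(allv[, 1])), 0)
  y0 <- max(floor(min(allv[, 2])), 0)
  x1 <- min(ceiling(max(allv[, 1])), w)
  y1 <- min(ceiling(max(allv[, 2])), h)
  n_cols <- floor((x1 - x0) / stride)
  n_rows <- floor((y1 - y0) / stride)
  if (n_cols < 1L || n_rows < 1L) return(list())
  grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  centers <- cbind(x0 + (grid$col - 0.5) * stride,
                   y0 + (grid$row - 0.5) * stride)
  keep <- points_in_polygons(centers, polygons)
  tiles <- vector("list", sum(keep))
  k <- 0L
  for (g in which(keep)) {
    i <- grid$row[g]; j <- grid$col[g]
    rows <- (y0 + (i - 1L) * stride + 1L):(y0 + i * stride)
    cols <- (x0 + (j - 1L) * stride + 1L):(x0 + j * stride)
    window <- img[rows, cols, , drop = FALSE]
    k <- k + 1L
    tiles[[k]] <- structure(list(pixels = resize_bilinear(window, tile_px),
                                 specimen_id = slide$specimen_id,
                                 grid_index = c(row = i, col = j),
                                 stage = "raw"),
                            class = "pdx_tile")
  }
  tiles
}

resize_bilinear <- function(img, side) {
  if (dim(img)[1] == side && dim(img)[2] == side) return(unname(img))
  out <- EBImage::resize(EBImage::Image(img, colormode = "Color"),
                         w = side, h = side, filter = "bilinear")
  array(pmin(pmax(EBImage::imageData(out), 0), 1), dim = c(side, side, 3))
}

#' Flag background tiles by HSV hue
#'
#' Converts the tile to HSV (hue normalized to \[0, 1); achromatic pixels,
#' including pure white background, have hue 0 under the standard
#' conversion) and flags the tile as background iff strictly more than
#' `pixel_fraction` of its pixels have hue below `hue_threshold`.
#'
#' @param tile raw `pdx_tile` or an RGB array.
#' @param hue_threshold hue cutoff (default 0.05).
#' @param pixel_fraction fraction of qualifying pixels above which the tile
#'   is background (default 0.60, strict inequality).
#' @return logical flag.
#' @export
is_background <- function(tile, hue_threshold = 0.05, pixel_fraction = 0.60) {
  px <- tile_pixels(tile)
  rgbm <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hue <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)[1, ]
  mean(hue < hue_threshold) > pixel_fraction
}

tile_pixels <- function(tile) if (inherits(tile, "pdx_tile")) tile$pixels else tile

# Ruderman l-alpha-beta opponent color space via log-LMS, the space in
# which Reinhard color transfer matches per-channel moments.
.lms_from_rgb <- matrix(c(0.3811, 0.5783, 0.0402,
                          0.1967, 0.7244, 0.0782,
                          0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
.rgb_from_lms <- solve(.lms_from_rgb)
.lab_from_loglms <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
.loglms_from_lab <- solve(.lab_from_loglms)

#' Convert RGB pixels to Ruderman lab space (and back)
#'
#' @param px rows x cols x 3 RGB array in \[0, 1\], or n x 3 matrix.
#' @return `rgb_to_lab()`: n x 3 matrix of l, alpha, beta values;
#'   `lab_to_rgb()`: n x 3 RGB matrix clipped to \[0, 1\].
#' @keywords internal
#' @export
rgb_to_lab <- function(px) {
  m <- if (length(dim(px)) == 3L)
    cbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  else px
  lms <- pmax(m %*% t(.lms_from_rgb), 1e-6)
  log10(lms) %*% t(.lab_from_loglms)
}

#' @rdname rgb_to_lab
#' @export
lab_to_rgb <- function(lab) {
  lms <- 10^(lab %*% t(.loglms_from_lab))
  pmin(pmax(lms %*% t(.rgb_from_lms), 0), 1)
}

#' Per-channel lab statistics of a tile
#'
#' @param tile `pdx_tile` or RGB array.
#' @return list with numeric length-3 `mean` and `sd` (population SD) of
#'   the l, alpha, beta channels.
#' @export
reinhard_stats <- function(tile) {
  lab <- rgb_to_lab(tile_pixels(tile))
  n <- nrow(lab)
  mu <- colMeans(lab)
  list(mean = mu, sd = sqrt(colSums(sweep(lab, 2, mu)^2) / n))
}

#' Reinhard stain normalization of a tile
#'
#' Maps each lab channel v to `(v - mu_src) * sd_tgt / sd_src + mu_tgt`,
#' so the tile's per-channel lab moments match `target_stats`, then
#' converts back to RGB (clipped to gamut). Harmonizes H&E staining
#' variation across slides against a common reference.
#'
#' @param tile raw `pdx_tile` or RGB array.
#' @param target_stats list with `mean` and `sd` (length 3 each), e.g.
#'   [reinhard_stats()] of a reference tile.
#' @return the normalized tile (`stage = "normalized"`); a constant
#'   channel (zero source SD) is shifted to the target mean with a
#'   warning.
#' @export
reinhard_normalize <- function(tile, target_stats) {
  if (any(!is.finite(c(target_stats$mean, target_stats$sd))) ||
      any(target_stats$sd <= 0))
    abort_validation("target stats must be finite with positive SDs")
  px <- tile_pixels(tile)
  src <- reinhard_stats(px)
  zero <- src$sd == 0
  if (any(zero))
    warning(sprintf("%d constant lab channel(s) shifted to target mean", sum(zero)))
  gain <- ifelse(zero, 1, target_stats$sd / ifelse(zero, 1, src$sd))
  lab <- rgb_to_lab(px)
  lab <- sweep(sweep(lab, 2, src$mean), 2, gain, "*")
  lab <- sweep(lab, 2, target_stats$mean, "+")
  out <- lab_to_rgb(lab)
  d <- dim(px)
  res <- array(out, dim = d)
  if (inherits(tile, "pdx_tile")) {
    tile$pixels <- res
    tile$stage <- "normalized"
    tile
  } else res
}

#' Standardize a tile to zero mean and unit variance
#'
#' Standardizes jointly over all pixels and channels (population SD), the
#' usual final step before feeding tiles to a convolutional network.
#'
#' @param tile normalized `pdx_tile` or numeric array.
#' @return the standardized tile (`stage = "standardized"`); an exactly
#'   constant tile maps to all zeros with a warning.
#' @export
standardize_tile <- function(tile) {
  px <- tile_pixels(tile)
  mu <- mean(px)
  s <- sqrt(mean((px - mu)^2))
  res <- if (s == 0) {
    warning("zero-variance tile standardized to all zeros")
    array(0, dim = dim(px))
  } else (px - mu) / s
  if (inherits(tile, "pdx_tile")) {
    tile$pixels <- res
    tile$stage <- "standardized"
    tile
  } else res
}

#' Full slide-to-tiles preprocessing pipeline
#'
#' Runs extract -> background filter -> Reinhard normalization ->
#' per-tile standardization, in that order (filters never see normalized
#' or standardized tiles).
#'
#' @param slide a `pdx_slide`.
#' @param rois a `pdx_roi` or list of polygons.
#' @param target_stats Reinhard target; default (`NULL`) uses the stats of
#'   the first non-background tile of this slide as reference.
#' @param tile_um,tile_px grid geometry, see [extract_tiles()].
#' @return list with `tiles` (standardized `pdx_tile`s) and `index`
#'   (data.frame: specimen_id, row, col, background flag for every grid
#'   tile extracted).
#' @export
tile_slide <- function(slide, rois, target_stats = NULL,
                       tile_um = 302, tile_px = 299L) {
  raw <- extract_tiles(slide, rois, tile_um, tile_px)
  if (length(raw) == 0L)
    return(list(tiles = list(),
                index = data.frame(specimen_id = character(), row = integer(),
                                   col = integer(), background = logical())))
  bg <- vapply(raw, is_background, logical(1))
  index <- data.frame(
    specimen_id = vapply(raw, function(t) t$specimen_id, character(1)),
    row = vapply(raw, function(t) t$grid_index[["row"]], numeric(1)),
    col = vapply(raw, function(t) t$grid_index[["col"]], numeric(1)),
    background = bg)
  fg <- raw[!bg]
  if (length(fg) == 0L) return(list(tiles = list(), index = index))
  if (is.null(target_stats)) target_stats <- reinhard_stats(fg[[1]])
  tiles <- lapply(fg, function(t) standardize_tile(reinhard_normalize(t, target_stats)))
  list(tiles = tiles, index = index)
}
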