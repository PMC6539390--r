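# Rendering of synthetic sensor-array image pairs.  Images are integer arrays
# (rows = y, cols = x, 3 channels) with 8-bit gray levels 0..255; the render
# is the inverse of the extraction path so the imaging stage can be tested
# round-trip.

#' Geometry of the 4x3 sensor array in an image
#'
#' @param grid_rows,grid_cols grid dimensions (4 x 3 = 12 spots).
#' @param spacing center-to-center spot distance, pixels.
#' @param margin distance from image edge to first spot center, pixels.
#' @param spot_radius_render radius of the rendered dye disc, pixels; must
#'   exceed the 15 px analysis ROI so ROI means sample the disc interior.
#' @return object of class `sensor_layout`: dye names, 12 spot centers
#'   (columns `x`, `y`, row-major grid order), render radius and image size
#'   `c(width, height)`.
#' @export
#' @examples
#' sensor_layout()$image_size
sensor_layout <- function(grid_rows = 4, grid_cols = 3, spacing = 60,
                          margin = 30, spot_radius_render = 20) {
  if (grid_rows * grid_cols != 12L)
    stop("the sensor array has 12 spots: grid_rows * grid_cols must be 12")
  if (2 * spot_radius_render >= spacing) stop("spot discs would overlap")
  x <- margin + spacing * (seq_len(grid_cols) - 1L)
  y <- margin + spacing * (seq_len(grid_rows) - 1L)
  centers <- cbind(x = rep(x, times = grid_rows), y = rep(y, each = grid_cols))
  size <- c(width = max(x) + margin, height = max(y) + margin)
  if (margin <= spot_radius_render) stop("spot discs would touch the image border")
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 dye_names = sensor_dyes(), spot_centers = centers,
                 spot_radius_render = spot_radius_render, image_size = size),
            class = "sensor_layout")
}

# Fixed pre-reaction palette, one mid-range RGB color per dye.  Mid-range
# values leave headroom for signed gray-level responses on either side.
dye_palette <- function() {
  matrix(c(150, 110, 120,   # TPP
           140, 120,  95,   # TPPMnCl
           120,  95, 150,   # FTPPFeCl
           155, 130, 100,   # TPPFeCl
           110, 145, 125,   # TPPCu
           130, 150,  95,   # FTPPCo
            95, 130, 155,   # TPPZn
           145,  95, 135,   # MTPPTE
           125, 125, 125,   # MTPPNiCl
           160, 115, 110,   # OEPPNi
           105, 155, 140,   # MTPP
           120, 140, 160),  # BTB
         ncol = 3L, byrow = TRUE,
         dimnames = list(sensor_dyes(), c("R", "G", "B")))
}

new_image <- function(width, height, value = 18L) {
  array(as.integer(value), dim = c(height, width, 3L))
}

# Logical matrix marking pixels with (x-cx)^2 + (y-cy)^2 <= r^2 for an image
# of the given height x width; integer pixel-center convention.
disc_mask <- function(cx, cy, r, width, height) {
  xs <- seq_len(width); ys <- seq_len(height)
  outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
}

paint_disc <- function(img, cx, cy, r, color) {
  m <- disc_mask(cx, cy, r, dim(img)[2L], dim(img)[1L])
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[m] <- as.integer(color[ch])
    img[, , ch] <- plane
  }
  img
}

#' Render a before/after sensor-array image pair
#'
#' Paints each dye spot with its palette color (plus small per-sample jitter)
#' on a dark background, then adds the rounded signed gray-level response of
#' each component to the corresponding spot and channel in the after image.
#' Extraction of the rendered pair recovers the injected vector to within
#' +/- 1 gray level per component.
#'
#' @param features numeric 36-vector of signed component responses
#'   (dye-major, channels R, G, B).
#' @param layout a [sensor_layout()].
#' @param base_jitter_sd per-sample gray-level jitter of the pre-reaction spot
#'   colors (applied identically to both images).
#' @param seed optional integer seed for the jitter.
#' @return object of class `image_pair`: integer arrays `before` and `after`
#'   (height x width x 3, 0..255) and the `layout`.
#' @export
#' @examples
#' pair <- render_image_pair(rep(0, 36), seed = 1)
#' identical(pair$before, pair$after)
render_image_pair <- function(features, layout = sensor_layout(),
                              base_jitter_sd = 2, seed = NULL) {
  if (length(features) != 36L) stop("'features' must have length 36")
  stopifnot_finite(features, "features")
  pal <- dye_palette()
  with_seed(seed, {
    w <- layout$image_size[["width"]]; h <- layout$image_size[["height"]]
    before <- new_image(w, h)
    after <- NULL
    base <- pal + matrix(round(rnorm(36L, 0, base_jitter_sd)), 12L, 3L)
    delta <- matrix(round(features), nrow = 12L, ncol = 3L, byrow = TRUE)
    post <- base + delta
    bad <- which(post < 0 | post > 255 | base < 0 | base > 255, arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      i <- bad[1L, ]
      stop(sprintf("rendered color out of 8-bit range for component %s",
                   paste0(sensor_dyes()[i[1L]], ":", c("R", "G", "B")[i[2L]])))
    }
    for (s in seq_len(12L)) {
      cx <- layout$spot_centers[s, "x"]; cy <- layout$spot_centers[s, "y"]
      before <- paint_disc(before, cx, cy, layout$spot_radius_render, base[s, ])
    }
    after <- before
    for (s in seq_len(12L)) {
      cx <- layout$spot_centers[s, "x"]; cy <- layout$spot_centers[s, "y"]
      after <- paint_disc(after, cx, cy, layout$spot_radius_render, post[s, ])
    }
    structure(list(before = before, after = after, layout = layout),
              class = "image_pair")
  })
}

#' Write an image pair to PNG files with a JSON layout sidecar
#'
#' @param pair an [render_image_pair()] result.
#' @param dir output directory.
#' @param sample_id basename stem; files are `<sample_id>_pre.png`,
#'   `<sample_id>_post.png` and `<sample_id>_layout.json`.
#' @return invisibly, the paths written.
#' @export
write_image_pair <- function(pair, dir, sample_id) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write images")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(sample_id, c("_pre.png", "_post.png",
                                              "_layout.json")))
  png::writePNG(pair$before / 255, paths[1L])
  png::writePNG(pair$after / 255, paths[2L])
  lay <- pair$layout
  jsonlite::write_json(list(grid_rows = lay$grid_rows,
                            grid_cols = lay$grid_cols,
                            dye_names = lay$dye_names,
                            spot_centers = lay$spot_centers,
                            spot_radius_render = lay$spot_radius_render,
                            image_size = unname(lay$image_size)),
                       paths[3L], auto_unbox = TRUE)
  invisible(paths)
}

#' Read an image pair from PNG files
#'
#' @param pre_path,post_path PNG paths.
#' @param layout optional [sensor_layout()] used as a localization hint.
#' @return an `image_pair`.
#' @export
read_image_pair <- function(pre_path, post_path, layout = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to read images")
  to_int <- function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) != 3L) stop("expected an RGB image: ", p)
    array(as.integer(round(a[, , 1:3] * 255)), dim = c(dim(a)[1:2], 3L))
  }
  structure(list(before = to_int(pre_path), after = to_int(post_path),
                 layout = layout),
            class = "image_pair")
}
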