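# Feature extraction from before/after sensor images: preprocessing to a
# spot mask, spot localization, circular-ROI channel means, and the 36
# signed Delta-R/G/B color components.

#' Preprocess a sensor image into a binary spot mask
#'
#' Channel-max grayscale conversion, median filtering, Otsu global
#' thresholding, then morphological opening and closing with a disc
#' structuring element.
#'
#' @param image integer array height x width x 3, gray levels 0..255.
#' @param median_radius radius of the median filter window (1 gives 3x3).
#' @param morph_radius radius of the disc structuring element.
#' @return logical matrix (height x width), `TRUE` on spot foreground.  If no
#'   foreground survives, an empty mask is returned with a warning of class
#'   `odsensor_no_spots`.
#' @export
preprocess <- function(image, median_radius = 1, morph_radius = 3) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("'image' must be a height x width x 3 array")
  gray <- pmax(image[, , 1L], image[, , 2L], image[, , 3L]) / 255
  no_spots <- function(msg) {
    w <- simpleWarning(msg)
    class(w) <- c("odsensor_no_spots", class(w))
    warning(w)
    matrix(FALSE, nrow(gray), ncol(gray))
  }
  if (diff(range(gray)) == 0)
    return(no_spots("uniform image: no spots found"))
  # EBImage images are x-major; transpose in and out.
  g <- EBImage::medianFilter(t(gray), size = median_radius)
  thr <- EBImage::otsu(EBImage::Image(g, colormode = "Grayscale"))
  mask <- g > thr
  kern <- EBImage::makeBrush(2L * morph_radius + 1L, shape = "disc")
  mask <- EBImage::closing(EBImage::opening(mask, kern), kern)
  mask <- t(as.array(mask) > 0)
  if (!any(mask)) return(no_spots("no foreground after preprocessing"))
  mask
}

#' Locate the 12 sensor spots in a binary mask
#'
#' Connected components are labelled and their centroids taken as spot
#' centers, ordered row-major by grid position (top row left-to-right first)
#' and labelled with the dye names.  If the component count is not 12, each
#' found centroid is registered to the nearest layout-hint position and
#' missing spots fall back to their hinted centers; without a hint this is an
#' error reporting the count found.
#'
#' @param mask logical matrix from [preprocess()].
#' @param layout_hint optional [sensor_layout()].
#' @param radius analysis ROI radius assigned to each spot, pixels.
#' @return data.frame with columns `dye`, `x`, `y`, `radius` (12 rows,
#'   row-major order).
#' @export
locate_spots <- function(mask, layout_hint = NULL, radius = 15) {
  lab <- EBImage::bwlabel(t(mask))          # x-major labels
  n <- max(lab)
  cents <- NULL
  if (n > 0L) {
    mom <- EBImage::computeFeatures.moment(lab)
    cents <- cbind(x = mom[, "m.cx"], y = mom[, "m.cy"])
  }
  dyes <- sensor_dyes()
  if (n == 12L) {
    rows <- if (!is.null(layout_hint)) layout_hint$grid_rows else 4L
    cols <- 12L %/% rows
    ord <- order(cents[, "y"])
    out <- matrix(NA_real_, 12L, 2L)
    for (r in seq_len(rows)) {
      idx <- ord[(r - 1L) * cols + seq_len(cols)]
      idx <- idx[order(cents[idx, "x"])]
      out[(r - 1L) * cols + seq_len(cols), ] <- cents[idx, , drop = FALSE]
    }
    return(data.frame(dye = dyes, x = out[, 1L], y = out[, 2L], radius = radius))
  }
  if (is.null(layout_hint))
    stop(sprintf("found %d spot(s), expected 12, and no layout hint supplied", n))
  hint <- layout_hint$spot_centers
  out <- cbind(x = hint[, "x"], y = hint[, "y"])
  if (n > 0L) {
    # register each centroid to its nearest free hint position
    d <- outer(cents[, "x"], hint[, "x"], `-`)^2 +
      outer(cents[, "y"], hint[, "y"], `-`)^2
    for (k in seq_len(min(n, 12L))) {
      i <- which(d == min(d), arr.ind = TRUE)[1L, ]
      out[i[2L], ] <- cents[i[1L], ]
      d[i[1L], ] <- Inf; d[, i[2L]] <- Inf
    }
  }
  data.frame(dye = dyes, x = out[, "x"], y = out[, "y"], radius = radius)
}

#' Mean R, G, B gray levels over a circular ROI
#'
#' The ROI is the set of integer pixel centers at distance `<= radius` from
#' the center (inclusive boundary); means are exact arithmetic means over
#' those pixels.
#'
#' @param image integer array height x width x 3.
#' @param x,y ROI center, pixel coordinates (x = column, y = row).
#' @param radius ROI radius, pixels (default 15).
#' @return named numeric vector `c(R =, G =, B =)`.
#' @export
roi_mean_rgb <- function(image, x, y, radius = 15) {
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (radius <= 0) stop("'radius' must be > 0")
  if (x - radius < 1 || x + radius > w || y - radius < 1 || y + radius > h)
    stop("ROI disc is clipped by the image border")
  m <- disc_mask(x, y, radius, w, h)
  c(R = mean(image[, , 1L][m]),
    G = mean(image[, , 2L][m]),
    B = mean(image[, , 3L][m]))
}

#' Extract the 36 color components from an image pair
#'
#' Spots are located on the before image (falling back to the layout hint
#' when thresholding does not yield 12 components), then for every spot and
#' channel the component is `mean(after ROI) - mean(before ROI)`, a signed
#' gray-level difference, ordered dye-major with channels R, G, B.
#'
#' @param pair an `image_pair` (see [render_image_pair()] /
#'   [read_image_pair()]).
#' @param radius ROI radius, pixels.
#' @param median_radius,morph_radius preprocessing parameters, see
#'   [preprocess()].
#' @return named numeric 36-vector with attribute `spots` (the ROI table).
#' @export
extract_features <- function(pair, radius = 15, median_radius = 1,
                             morph_radius = 3) {
  if (!identical(dim(pair$before), dim(pair$after)))
    stop("before and after images must have identical dimensions")
  mask <- withCallingHandlers(
    preprocess(pair$before, median_radius, morph_radius),
    odsensor_no_spots = function(w)
      if (!is.null(pair$layout)) invokeRestart("muffleWarning"))
  spots <- locate_spots(mask, layout_hint = pair$layout, radius = radius)
  pre <- t(vapply(seq_len(12L), function(i)
    roi_mean_rgb(pair$before, spots$x[i], spots$y[i], radius), numeric(3L)))
  post <- t(vapply(seq_len(12L), function(i)
    roi_mean_rgb(pair$after, spots$x[i], spots$y[i], radius), numeric(3L)))
  v <- as.vector(t(post - pre))
  names(v) <- feature_names()
  attr(v, "spots") <- spots
  v
}

#' Normalized difference map of an image pair
#'
#' Display artifact summarizing the array response: the absolute component
#' differences are min--max normalized to 0..255 across all 36 components and
#' painted into the spot discs on a black background.  The map is for
#' visualization only; models always consume the raw signed components.
#'
#' @inheritParams extract_features
#' @return integer array height x width x 3.
#' @export
difference_map <- function(pair, radius = 15, median_radius = 1,
                           morph_radius = 3) {
  v <- extract_features(pair, radius, median_radius, morph_radius)
  spots <- attr(v, "spots")
  a <- abs(unname(v))
  rng <- range(a)
  norm <- if (diff(rng) == 0) rep(0, 36L) else (a - rng[1L]) / diff(rng) * 255
  img <- new_image(dim(pair$before)[2L], dim(pair$before)[1L], value = 0L)
  cols <- matrix(round(norm), nrow = 12L, ncol = 3L, byrow = TRUE)
  for (s in seq_len(12L))
    img <- paint_disc(img, spots$x[s], spots$y[s], radius, cols[s, ])
  img
}
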