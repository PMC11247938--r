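#' @title Nuclei counting on image patches
#' @name nuclei
#' @description
#' Particle-style counting of DAPI-stained nuclei in 2D grayscale
#' patches: global threshold, connected-component labelling (8-connected
#' by default), and a minimum-area filter, reported in physical units via
#' the pixel size. Used by the cell-density stage of the morphometry
#' pipeline.
NULL

#' Construct a nuclei image
#'
#' @param pixels numeric matrix of intensities in `[0, 1]`; rows are image
#'   rows (y), columns are x.
#' @param pixel_size physical size of one pixel in um (default 1).
#' @return object of class `nuclei_image`.
#' @export
nuclei_image <- function(pixels, pixel_size = 1) {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop("empty image")
  if (!is.numeric(pixels)) stop("pixel intensities must be numeric")
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("pixel intensities must lie in [0, 1]")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be positive")
  }
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "nuclei_image")
}

#' Read a grayscale image as a nuclei image
#'
#' Reads TIFF or PNG; multi-channel images are averaged to grayscale.
#'
#' @param path image path (.tif/.tiff/.png).
#' @param pixel_size um per pixel.
#' @return a `nuclei_image`.
#' @export
read_nuclei_image <- function(path, pixel_size = 1) {
  if (!file.exists(path)) stop("image not found: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  nuclei_image(img, pixel_size = pixel_size)
}

#' Write a binary mask image
#'
#' @param mask logical or 0/1 matrix.
#' @param path output path (.tif/.tiff/.png).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- matrix(as.numeric(mask), nrow = nrow(mask))
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(m, path),
    png = png::writePNG(m, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Otsu threshold of an image
#'
#' Between-class variance maximization on a 256-bin histogram; offered as
#' an alternative to the fixed global threshold.
#'
#' @param image a `nuclei_image`.
#' @return threshold intensity in (0, 1).
#' @export
otsu_threshold <- function(image) {
  stopifnot(inherits(image, "nuclei_image"))
  h <- tabulate(pmin(255L, as.integer(image$pixels * 256)) + 1L, 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 1))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  (which.max(sigma_b) - 0.5) / 256
}

## label connected foreground components of a logical matrix; returns an
## integer matrix of labels (0 = background)
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(labels)
  vid <- matrix(0L, nr, nc)
  vid[fg] <- seq_along(fg)
  row <- ((fg - 1L) %% nr) + 1L
  col <- ((fg - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))                # down, right
  if (connectivity == 8L) {
    offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))    # diagonals
  }
  edges <- lapply(offs, function(o) {
    r2 <- row + o[1]; c2 <- col + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (!any(ok)) return(NULL)
    cbind(vid[cbind(row[ok], col[ok])], vid[cbind(r2[ok], c2[ok])])
  })
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(el)) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)$membership
  labels[fg] <- as.integer(comp)
  labels
}

#' Count nuclei by threshold + connected components + area filter
#'
#' Binarizes the image at `intensity >= threshold`, labels connected
#' components under the chosen pixel connectivity, discards components
#' smaller than `min_area`, and reports counts, centroids and areas in
#' physical units. Pixel centers are at `(col - 0.5, row - 0.5) *
#' pixel_size`, so the image spans `[0, width) x [0, height)` um.
#'
#' @param image a `nuclei_image`.
#' @param threshold global intensity threshold in (0, 1).
#' @param min_area minimum component area in um^2 (default 0).
#' @param connectivity 4 or 8 (default 8, the usual particle-analysis
#'   convention).
#' @return object of class `particle_result`: `count`, `centroids`
#'   (data.frame x, y in um), `areas` (um^2), `mask` (logical matrix),
#'   `labels` (integer matrix).
#' @export
count_nuclei <- function(image, threshold, min_area = 0,
                         connectivity = 8L) {
  stopifnot(inherits(image, "nuclei_image"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly between 0 and 1")
  }
  if (min_area < 0) stop("min_area must be non-negative")
  px <- image$pixels
  mask <- px >= threshold
  if (all(mask)) {
    warning("image is saturated at this threshold: one component spans ",
            "the whole frame")
  }
  labels <- label_components(mask, connectivity = as.integer(connectivity))
  ncomp <- max(labels)
  ps <- image$pixel_size
  if (ncomp == 0L) {
    return(structure(list(count = 0L,
                          centroids = data.frame(x = numeric(0),
                                                 y = numeric(0)),
                          areas = numeric(0), mask = mask, labels = labels),
                     class = "particle_result"))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  row <- ((idx - 1L) %% nrow(px)) + 1L
  col <- ((idx - 1L) %/% nrow(px)) + 1L
  npix <- tabulate(lab, ncomp)
  areas <- npix * ps^2
  cx <- (tapply(col, lab, mean) - 0.5) * ps
  cy <- (tapply(row, lab, mean) - 0.5) * ps
  keep <- which(areas >= min_area)
  ## relabel surviving components 1..k in the label image
  remap <- integer(ncomp)
  remap[keep] <- seq_along(keep)
  labels[idx] <- remap[lab]
  structure(
    list(count = length(keep),
         centroids = data.frame(x = as.numeric(cx[keep]),
                                y = as.numeric(cy[keep])),
         areas = areas[keep], mask = labels > 0L, labels = labels),
    class = "particle_result"
  )
}

#' @export
print.particle_result <- function(x, ...) {
  cat("<particle_result>", x$count, "particles\n")
  if (x$count > 0) {
    cat("  areas (um^2):", paste(format(x$areas, digits = 4),
                                 collapse = ", "), "\n")
  }
  invisible(x)
}

#' Nuclei density within a rectangle
#'
#' Counts the particles whose centroid falls in the half-open rectangle
#' `[x0, x1) x [y0, y1)` (um) and divides by the rectangle area, giving
#' nuclei per um^2. Centroid membership makes counting deterministic for
#' particles touching the rectangle border and avoids double counting
#' across adjacent rectangles.
#'
#' @param image a `nuclei_image`.
#' @param rect numeric `c(x0, y0, x1, y1)` in um, within the image bounds.
#' @param threshold,min_area,connectivity passed to [count_nuclei()].
#' @return density in nuclei per um^2.
#' @export
density_from_image <- function(image, rect, threshold, min_area = 0,
                               connectivity = 8L) {
  stopifnot(inherits(image, "nuclei_image"), length(rect) == 4L)
  ps <- image$pixel_size
  w <- ncol(image$pixels) * ps
  h <- nrow(image$pixels) * ps
  x0 <- rect[1]; y0 <- rect[2]; x1 <- rect[3]; y1 <- rect[4]
  if (x1 <= x0 || y1 <= y0) stop("rectangle has non-positive extent")
  if (x0 < 0 || y0 < 0 || x1 > w || y1 > h) {
    stop("rectangle [", x0, ",", x1, ") x [", y0, ",", y1,
         ") exceeds the image bounds ", w, " x ", h, " um")
  }
  res <- count_nuclei(image, threshold, min_area = min_area,
                      connectivity = connectivity)
  inside <- res$centroids$x >= x0 & res$centroids$x < x1 &
    res$centroids$y >= y0 & res$centroids$y < y1
  sum(inside) / ((x1 - x0) * (y1 - y0))
}
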