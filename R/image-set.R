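#' Bundle fields of view into an image set
#'
#' An `image_set` is the unit the brightfield pipeline works on: all fields of
#' view acquired for one sample condition, with pixel-size metadata. It is a
#' list of numeric matrices (rows = y, columns = x) of identical shape.
#'
#' @param images A list of numeric matrices, one per field of view.
#' @param pixel_size_nm Physical pixel size in nanometres.
#' @return An object of class `image_set`.
#' @export
image_set <- function(images, pixel_size_nm = 108) {
  if (is.matrix(images)) images <- list(images)
  if (!length(images) || !all(vapply(images, is.matrix, logical(1)))) {
    abort("`images` must be a non-empty list of matrices.")
  }
  shp <- vapply(images, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
    abort("all fields of view in an image set must share one shape.")
  }
  structure(images, pixel_size_nm = pixel_size_nm, class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<image_set> %d field(s) of %d x %d px, pixel size %.3g nm\n",
              length(x), d[1], d[2], attr(x, "pixel_size_nm")))
  invisible(x)
}

#' @export
`[.image_set` <- function(x, i) {
  image_set(unclass(x)[i], pixel_size_nm = attr(x, "pixel_size_nm"))
}

#' Read and write image sets as multi-page TIFF
#'
#' Fields of view are stored as pages of one TIFF file. Because baseline TIFF
#' writing in R stores intensities on \[0, 1\], values are scaled by a single
#' per-file factor recorded (with the pixel size) in a JSON sidecar
#' (`<path>.json`); [read_image_set()] inverts the scaling.
#'
#' @param x An [image_set()].
#' @param path Path of the `.tif` file.
#' @param bits Bits per sample (8, 16 or 32).
#' @return `write_image_set()` returns `path` invisibly; `read_image_set()`
#'   returns an [image_set()].
#' @export
write_image_set <- function(x, path, bits = 16L) {
  stopifnot(inherits(x, "image_set"))
  hi <- max(vapply(x, max, numeric(1)), 1e-12)
  lo <- min(vapply(x, min, numeric(1)), 0)
  scale <- hi - lo
  pages <- lapply(x, function(m) (m - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  meta <- list(scale = scale, offset = lo,
               pixel_size_nm = attr(x, "pixel_size_nm"))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_set
#' @export
read_image_set <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  scale <- 1; lo <- 0; px <- 108
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    scale <- meta$scale %||% 1
    lo <- meta$offset %||% 0
    px <- meta$pixel_size_nm %||% 108
  }
  image_set(lapply(pages, function(m) m * scale + lo), pixel_size_nm = px)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
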