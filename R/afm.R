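# AFM height-map processing: first-order plane (tilt) correction and
# per-pixel median projection of multi-frame captures.

#' Level an AFM height map by plane subtraction
#'
#' Fits a first-order plane `a*x + b*y + c` to all pixels by least squares
#' and subtracts it. Optionally subtracts the per-scanline median afterwards
#' (`line_level = TRUE`), for stripe artifacts. Idempotent up to numerical
#' tolerance.
#'
#' @param frame A numeric height matrix (nm).
#' @param line_level If `TRUE`, also subtract each row's median after plane
#'   removal.
#' @return The leveled frame.
#' @export
plane_level <- function(frame, line_level = FALSE) {
  assert_image(frame, arg = "frame")
  nr <- nrow(frame); nc <- ncol(frame)
  x <- rep(0:(nc - 1), each = nr)
  y <- rep(0:(nr - 1), nc)
  X <- cbind(1, x, y)
  beta <- stats::lm.fit(X, as.vector(frame))$coefficients
  out <- frame - matrix(X %*% beta, nr, nc)
  if (line_level) out <- out - apply(out, 1, median)
  out
}

#' Median projection of a frame stack
#'
#' Per-pixel median across frames; the even-frame median uses the midpoint
#' convention. With fewer than half the frames corrupted, the projection
#' equals the clean frame exactly for odd, noise-free stacks.
#'
#' @param stack A `rows x cols x n_frames` array (or list of matrices).
#' @return A 2-D matrix.
#' @export
median_project <- function(stack) {
  if (is.list(stack)) {
    stack <- array(unlist(stack), c(dim(stack[[1]]), length(stack)))
  }
  if (length(dim(stack)) != 3 || dim(stack)[3] < 1) {
    abort("`stack` must be a rows x cols x n_frames array with >= 1 frame.")
  }
  if (dim(stack)[3] == 1) return(stack[, , 1])
  apply(stack, c(1, 2), median)
}

#' Level every frame, then median-project
#'
#' Composition of [plane_level()] (per frame) followed by [median_project()],
#' in that order: tilt is removed before the median so frame-to-frame tilt
#' drift does not bias the projection.
#'
#' @inheritParams median_project
#' @inheritParams plane_level
#' @return A 2-D leveled, projected height map.
#' @export
level_and_project <- function(stack, line_level = FALSE) {
  if (is.list(stack)) {
    stack <- array(unlist(stack), c(dim(stack[[1]]), length(stack)))
  }
  lev <- stack
  for (f in seq_len(dim(stack)[3])) {
    lev[, , f] <- plane_level(stack[, , f], line_level = line_level)
  }
  median_project(lev)
}

#' Read and write AFM stacks as plain-matrix text
#'
#' Frames are written as whitespace-separated matrices separated by lines
#' starting with `# frame`.
#'
#' @param stack A `rows x cols x n_frames` array.
#' @param path Text file path.
#' @return `write_afm_text()` returns `path` invisibly; `read_afm_text()`
#'   returns the array.
#' @export
write_afm_text <- function(stack, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(stack)[3])) {
    writeLines(sprintf("# frame %d", f), con)
    utils::write.table(stack[, , f], con, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_afm_text
#' @export
read_afm_text <- function(path) {
  lines <- readLines(path)
  breaks <- grep("^# frame", lines)
  if (!length(breaks)) abort("no '# frame' markers found.")
  bounds <- c(breaks, length(lines) + 1L)
  frames <- lapply(seq_along(breaks), function(k) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    as.matrix(utils::read.table(text = block))
  })
  arr <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
  dimnames(arr) <- NULL
  arr
}
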