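# Plain-text and PNG I/O for height maps, landmarks and feature tables.

#' Read / write a height map as a plain CSV matrix
#'
#' The CSV is a bare numeric matrix (no header, no row names) — the lossless
#' interchange format for supraorbital height maps. `spacing` is not stored
#' in the CSV; supply it on read if it differs from the synthetic default.
#'
#' @param path file path.
#' @param spacing physical grid spacing per pixel.
#' @return `read_height_map_csv()` returns a [height_map()].
#' @export
read_height_map_csv <- function(path, spacing = 2.5e-5) {
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  height_map(m, spacing)
}

#' @param hm a [height_map()].
#' @rdname read_height_map_csv
#' @export
write_height_map_csv <- function(hm, path) {
  stopifnot(inherits(hm, "height_map"))
  # %.17g round-trips doubles exactly, so readers recover identical features
  lines <- apply(hm$heights, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a height map as a grayscale PNG for inspection
#'
#' Heights are min-max normalised to \[0, 1\] before writing, so the PNG is a
#' visual aid only; use the CSV writer for lossless storage.
#'
#' @param hm a [height_map()].
#' @param path output file.
#' @export
write_height_map_png <- function(hm, path) {
  stopifnot(inherits(hm, "height_map"))
  z <- hm$heights
  rng <- range(z)
  z <- if (diff(rng) > 0) (z - rng[1L]) / diff(rng) else z * 0
  png::writePNG(z, path)
  invisible(path)
}

#' Read a grayscale (or RGB) PNG as a height map
#'
#' RGB images are converted to luminance with [to_grayscale()] first.
#' Intensities in \[0, 1\] are used directly as heights.
#'
#' @inheritParams read_height_map_csv
#' @export
read_height_map_png <- function(path, spacing = 2.5e-5) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- to_grayscale(img[, , 1:3, drop = FALSE])
  height_map(img, spacing)
}

#' Read / write frontal landmarks as CSV
#'
#' Columns `x`, `y`, `z`; one ordered landmark per row.
#'
#' @param path file path.
#' @return `read_landmarks_csv()` returns an n x 3 numeric matrix.
#' @export
read_landmarks_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("x", "y", "z") %in% names(d)))
  as.matrix(d[, c("x", "y", "z")])
}

#' @param landmarks n x 3 matrix with columns x, y, z.
#' @rdname read_landmarks_csv
#' @export
write_landmarks_csv <- function(landmarks, path) {
  d <- as.data.frame(landmarks)
  names(d) <- c("x", "y", "z")
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
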