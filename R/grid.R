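#' Image grids
#'
#' A `pa_grid` is a square-pixel 2D absorption image with physical units.
#' The coordinate convention, used everywhere in the package, is: physical
#' millimetres, origin at the image centre, x rightward, y upward. Pixel
#' values are stored as an `ny` x `nx` matrix whose first row is the *top*
#' of the image (largest y) and first column the left edge (smallest x), so
#' the row index runs along -y. Images are vectorised column-major
#' (R's native order) wherever a pixel vector is needed.
#'
#' @param values numeric `ny` x `nx` matrix of absorption values.
#' @param pixel_size pixel edge length in mm.
#' @param extent optional physical width in mm; exactly one of `pixel_size`
#'   and `extent` must be given.
#' @return A `pa_grid` object.
#' @export
pa_grid <- function(values, pixel_size = NULL, extent = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("grid must be at least 2 x 2 pixels")
  if (!all(is.finite(values)))
    stop("grid values must be finite")
  if (is.null(pixel_size) == is.null(extent))
    stop("give exactly one of `pixel_size` and `extent`")
  if (is.null(pixel_size)) pixel_size <- extent / ncol(values)
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(
    list(values = values, nx = ncol(values), ny = nrow(values),
         pixel_size = pixel_size),
    class = "pa_grid")
}

#' @exportS3Method
print.pa_grid <- function(x, ...) {
  cat(sprintf("<pa_grid> %d x %d pixels, %.4g mm/pixel (%.4g x %.4g mm)\n",
              x$nx, x$ny, x$pixel_size,
              x$nx * x$pixel_size, x$ny * x$pixel_size))
  cat(sprintf("  values in [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @exportS3Method
dim.pa_grid <- function(x) dim(x$values)

#' @exportS3Method
as.matrix.pa_grid <- function(x, ...) x$values

# physical x of every column centre / y of every row centre
grid_x_centers <- function(grid) {
  w <- grid$nx * grid$pixel_size
  -w / 2 + (seq_len(grid$nx) - 0.5) * grid$pixel_size
}

grid_y_centers <- function(grid) {
  h <- grid$ny * grid$pixel_size
  h / 2 - (seq_len(grid$ny) - 0.5) * grid$pixel_size
}

grid_extent <- function(grid) {
  c(x = grid$nx * grid$pixel_size, y = grid$ny * grid$pixel_size)
}

grid_vec <- function(grid) as.vector(grid$values)

grid_with_values <- function(grid, v) {
  grid$values <- matrix(v, grid$ny, grid$nx)
  grid
}

#' Read / write image grids as plain text
#'
#' Grids are stored as tab-separated values with a one-line header comment
#' carrying the pixel size, so files round-trip exactly at full precision.
#'
#' @param grid a [pa_grid()].
#' @param path file path.
#' @return `read_image_tsv` returns a `pa_grid`; the writer returns `path`
#'   invisibly.
#' @export
write_image_tsv <- function(grid, path) {
  stopifnot(inherits(grid, "pa_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pa_grid pixel_size_mm=%.17g", grid$pixel_size), con)
  write.table(format(grid$values, digits = 17, trim = TRUE, scientific = TRUE),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_image_tsv
#' @export
read_image_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  px <- as.numeric(sub(".*pixel_size_mm=", "", header))
  if (!is.finite(px)) stop("not a pa_grid TSV file: ", path)
  vals <- as.matrix(read.table(path, skip = 1L, sep = "\t"))
  dimnames(vals) <- NULL
  pa_grid(vals, pixel_size = px)
}

#' Write an image grid as an 8-bit PNG (display only)
#'
#' Values are affinely mapped to \[0, 1\] before quantisation; the PNG is for
#' inspection, never for further computation.
#'
#' @inheritParams write_image_tsv
#' @export
write_image_png <- function(grid, path) {
  stopifnot(inherits(grid, "pa_grid"))
  v <- grid$values
  rng <- range(v)
  img <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  png::writePNG(img, path)
  invisible(path)
}

#' @export
autoplot.pa_grid <- function(object, ...) {
  df <- expand.grid(y = grid_y_centers(object), x = grid_x_centers(object))
  df$value <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "A")
}

#' @importFrom ggplot2 .data
NULL
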