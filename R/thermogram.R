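# Thermogram container, temperature-matrix I/O, foot segmentation and
# network-ready encodings.

#' Create a plantar thermogram
#'
#' A thermogram stores one foot's per-pixel surface temperatures in degrees
#' Celsius together with acquisition metadata. The coordinate convention is
#' row 1 at the toes (anterior) and, for a right foot, column 1 on the medial
#' side; left feet are mirrored.
#'
#' @param temperatures numeric matrix of temperatures in degrees Celsius,
#'   all values finite. Background pixels hold the ambient temperature (not
#'   `NA`); foot/background is distinguished by a mask (see
#'   [segment_foot()]). Any size is storable; angiosome partitioning needs
#'   a foot at least 2 pixels long and wide (see
#'   [partition_angiosomes()]).
#' @param subject_id opaque subject identifier.
#' @param side `"left"` or `"right"`.
#' @param group `"control"` or `"diabetic"`.
#' @return an object of class `thermogram`: a list with elements
#'   `temperatures`, `subject_id`, `side`, `group`, `height`, `width`.
#' @examples
#' t <- thermogram(matrix(25, 10, 5), subject_id = "S1",
#'                 side = "right", group = "control")
#' t$height
#' @export
thermogram <- function(temperatures, subject_id = "unknown",
                       side = c("right", "left"),
                       group = c("diabetic", "control")) {
  side <- match.arg(side)
  group <- match.arg(group)
  if (!is.matrix(temperatures) || !is.numeric(temperatures))
    stop("`temperatures` must be a numeric matrix")
  if (!all(is.finite(temperatures)))
    stop("all temperature values must be finite")
  structure(
    list(temperatures = temperatures, subject_id = as.character(subject_id),
         side = side, group = group,
         height = nrow(temperatures), width = ncol(temperatures)),
    class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %s (%s foot, %s) %dx%d px, %.1f-%.1f degC\n",
              x$subject_id, x$side, x$group, x$height, x$width,
              min(x$temperatures), max(x$temperatures)))
  invisible(x)
}

#' Read a temperature matrix from CSV
#'
#' The file format is a headerless rectangular grid of comma-separated
#' temperatures in degrees Celsius, one image row per line.
#'
#' @param path path to the CSV file.
#' @param sep field separator (default comma).
#' @inheritParams thermogram
#' @return a [thermogram()].
#' @export
read_temperature_matrix <- function(path, sep = ",", subject_id = "unknown",
                                    side = c("right", "left"),
                                    group = c("diabetic", "control")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty temperature matrix: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("format error: row %d has %d fields; expected %d",
                 bad, widths[bad], widths[1]))
  }
  vals <- suppressWarnings(lapply(fields, as.numeric))
  for (i in seq_along(vals)) {
    nai <- which(is.na(vals[[i]]) & trimws(fields[[i]]) != "NA")
    if (length(nai) > 0)
      stop(sprintf("parse error: non-numeric value %s at row %d, column %d",
                   dQuote(trimws(fields[[i]][nai[1]])), i, nai[1]))
  }
  thermogram(do.call(rbind, vals), subject_id = subject_id,
             side = side, group = group)
}

#' Write a temperature matrix to CSV
#'
#' Values are written at full double precision so that a read/write round
#' trip is bit-identical.
#'
#' @param t a [thermogram()] or numeric matrix.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_temperature_matrix <- function(t, path) {
  m <- if (inherits(t, "thermogram")) t$temperatures else t
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, con)
  invisible(path)
}

#' Map temperatures to 8-bit gray levels
#'
#' Affine map of a temperature window onto 0..255 with clipping; used by the
#' PNG export. `round()` follows R semantics (half to even does not arise for
#' the 0..255 grid in practice).
#'
#' @param x numeric vector/matrix of temperatures, degrees Celsius.
#' @param window length-2 numeric, `c(low, high)` of the display window.
#' @return integer gray levels with the shape of `x`.
#' @export
temperature_to_gray <- function(x, window = c(18, 40)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  g <- round(255 * (clamp(x, window[1], window[2]) - window[1]) /
               (window[2] - window[1]))
  storage.mode(g) <- "integer"
  g
}

#' Export a thermogram as a grayscale PNG
#'
#' Writes an 8-bit grayscale PNG whose intensities map the configured
#' temperature window linearly to 0..255. The window is recorded in the file
#' (tEXt chunk) and, by convention, in the filename.
#'
#' @inheritParams write_temperature_matrix
#' @param window temperature window in degrees Celsius, `c(low, high)`.
#' @return the path written, invisibly.
#' @export
export_thermogram_png <- function(t, path, window = c(18, 40)) {
  m <- if (inherits(t, "thermogram")) t$temperatures else t
  gray <- temperature_to_gray(m, window)
  write_png_gray(gray, path,
                 text = c(temperature_window = sprintf("%g-%g degC",
                                                       window[1], window[2])))
}

#' Segment the foot from the ambient background
#'
#' Thresholds at `ambient_ceiling` (foot pixels are warmer than the ambient
#' background), keeps the largest 4-connected component and fills interior
#' holes. If no pixel exceeds the ceiling an all-`FALSE` mask is returned
#' with a warning.
#'
#' @param t a [thermogram()].
#' @param ambient_ceiling temperature in degrees Celsius above which a pixel
#'   is considered foot rather than background.
#' @return logical matrix of the thermogram's shape; `TRUE` = foot pixel.
#' @export
segment_foot <- function(t, ambient_ceiling = 22) {
  stopifnot(is.finite(ambient_ceiling))
  m <- if (inherits(t, "thermogram")) t$temperatures else t
  raw <- m > ambient_ceiling
  if (!any(raw)) {
    warning("no pixel above ambient ceiling; returning empty mask")
    return(raw)
  }
  fill_holes(largest_component(raw))
}

#' Encode a thermogram for network input
#'
#' Clips temperatures to `window`, maps them affinely to `[0, 1]`, and brings
#' the result to one of the three supported network geometries:
#' \describe{
#'   \item{`rectangular`}{bilinear resample to 180 x 80, the native
#'     aspect-preserving input of the compact CNN.}
#'   \item{`resized`}{bilinear resample to 227 x 227 (square-input models).}
#'   \item{`padded`}{the foot's bounding box at native scale, centered on a
#'     227 x 227 canvas; padding value is intensity 0 (coldest). If the box
#'     exceeds the canvas it is downscaled to fit, with a warning.}
#' }
#'
#' @param t a [thermogram()].
#' @param mask optional logical foot mask (from [segment_foot()]); used by
#'   `padded` mode to locate the foot. Default: the full frame.
#' @param mode one of `"rectangular"`, `"resized"`, `"padded"`.
#' @param window temperature window in degrees Celsius mapped onto `[0, 1]`.
#' @return an object of class `encoded_input`: list with `values` (numeric
#'   matrix in `[0, 1]`), `mode`, `window`, `source_dim`.
#' @export
encode_for_network <- function(t, mask = NULL,
                               mode = c("rectangular", "resized", "padded"),
                               window = c(18, 40)) {
  mode <- match.arg(mode)
  stopifnot(length(window) == 2, window[1] < window[2])
  m <- if (inherits(t, "thermogram")) t$temperatures else t
  norm <- (clamp(m, window[1], window[2]) - window[1]) / (window[2] - window[1])
  vals <- switch(mode,
    rectangular = resize_bilinear(norm, 180L, 80L),
    resized = resize_bilinear(norm, 227L, 227L),
    padded = {
      if (is.null(mask)) mask <- matrix(TRUE, nrow(norm), ncol(norm))
      if (!any(mask)) stop("padded mode requires a non-empty foot mask")
      rr <- range(which(rowSums(mask) > 0))
      cc <- range(which(colSums(mask) > 0))
      block <- norm[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
      if (nrow(block) > 227 || ncol(block) > 227) {
        warning("foot bounding box exceeds 227x227; downscaling to fit")
        s <- min(227 / nrow(block), 227 / ncol(block))
        block <- resize_bilinear(block, max(1L, floor(nrow(block) * s)),
                                 max(1L, floor(ncol(block) * s)))
      }
      canvas <- matrix(0, 227, 227)
      r0 <- (227 - nrow(block)) %/% 2
      c0 <- (227 - ncol(block)) %/% 2
      canvas[r0 + seq_len(nrow(block)), c0 + seq_len(ncol(block))] <- block
      canvas
    })
  structure(list(values = vals, mode = mode, window = window,
                 source_dim = dim(m)),
            class = "encoded_input")
}

#' @export
print.encoded_input <- function(x, ...) {
  cat(sprintf("<encoded_input> %s %dx%d, window %g-%g degC\n", x$mode,
              nrow(x$values), ncol(x$values), x$window[1], x$window[2]))
  invisible(x)
}
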