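#' Multi-channel image stack
#'
#' The unit of input for the whole pipeline: a set of named 2D intensity
#' channels sharing one shape, plus the physical pixel size.  Intensities
#' are stored as doubles on the `[0, 1]` scale (integer images are rescaled
#' by their dtype range at read time), with `(row, col)` coordinates,
#' 0-based origin at the top-left corner.
#'
#' @param channels Named list of numeric matrices, all with the same
#'   dimensions.  Conventional channel names are `"nuclear"` (Hoechst),
#'   `"wfa"` (Wisteria floribunda agglutinin, the PNN marker), `"comparison"`
#'   (e.g. a myc- or his-tag channel) and `"pv"` (parvalbumin).
#' @param pixel_size Pixel edge length in micrometres.
#' @param source Optional path the stack was read from.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size = 1, source = NULL) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    abort("`channels` must be a non-empty named list of matrices.")
  }
  if (anyDuplicated(names(channels))) {
    abort("duplicate channel names in `channels`.")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(x) !is.matrix(x) || !is.numeric(x),
                 logical(1)))) {
    abort("every channel must be a numeric matrix.")
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    abort("all channels must share one shape.")
  }
  bad <- vapply(channels, function(x) any(!is.finite(x)) || any(x < 0),
                logical(1))
  if (any(bad)) {
    abort(paste0("non-finite or negative intensities in channel(s): ",
                 paste(names(channels)[bad], collapse = ", ")))
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number (micrometres/pixel).")
  }
  structure(
    list(channels = lapply(channels, unclass),
         pixel_size = as.numeric(pixel_size),
         source = source),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<image_stack> %d x %d px, %.4g um/px\n", d[1L], d[2L],
              x$pixel_size))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1L]])

#' Extract one channel of an image stack
#'
#' @param stack An [image_stack()].
#' @param channel Channel name.
#' @return The channel matrix.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (!channel %in% names(stack$channels)) {
    abort(sprintf("unknown channel '%s'; stack has: %s", channel,
                  paste(names(stack$channels), collapse = ", ")))
  }
  stack$channels[[channel]]
}

#' Write an image stack as a multi-page TIFF
#'
#' One grayscale page per channel, 16-bit, values clipped to `[0, 1]`.
#' Channel names and the pixel size go to a JSON sidecar
#' (`<path>.channels.json`) so that [read_stack()] can restore them.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @param bits_per_sample Bit depth to write (8 or 16; default 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits_per_sample = 16L) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(stack$channels, clamp01)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits_per_sample),
                  compression = "none", reduce = TRUE)
  sidecar <- paste0(path, ".channels.json")
  jsonlite::write_json(
    list(channels = names(stack$channels), pixel_size = stack$pixel_size),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF (or a directory of per-channel TIFFs) as a stack
#'
#' Integer pixel values are rescaled to `[0, 1]` by the file's bit depth
#' (the `tiff` package already returns that scale).  A channel map gives the
#' channel name of each page; when omitted, the JSON sidecar written by
#' [write_stack()] is consulted.
#'
#' @param path A multi-page TIFF file, or a directory containing one
#'   single-page TIFF per channel (file names become channel names).
#' @param channel_map Named integer vector or list mapping channel name to
#'   0-based page index, e.g. `c(nuclear = 0, wfa = 1, comparison = 2, pv = 3)`.
#'   Ignored for directory input.
#' @param pixel_size Micrometres per pixel; defaults to the sidecar value,
#'   else 1.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_map = NULL, pixel_size = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file or directory: %s", path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) abort(sprintf("no TIFF files in directory %s", path))
    channels <- lapply(files, function(f) as_gray_matrix(tiff::readTIFF(f)))
    names(channels) <- sub("\\.tiff?$", "", basename(files), ignore.case = TRUE)
    return(image_stack(channels, pixel_size %||% 1, source = path))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, as_gray_matrix)
  sidecar <- paste0(path, ".channels.json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  if (is.null(channel_map)) {
    if (is.null(meta)) {
      abort("no `channel_map` given and no channel sidecar found.")
    }
    channel_map <- stats::setNames(seq_along(meta$channels) - 1L,
                                   meta$channels)
  }
  channel_map <- unlist(channel_map)
  if (is.null(names(channel_map)) || anyDuplicated(names(channel_map))) {
    abort("`channel_map` must have unique channel names.")
  }
  idx <- as.integer(channel_map)
  if (any(idx < 0L) || any(idx >= length(pages))) {
    abort(sprintf("channel_map names page %d but the file has %d page(s).",
                  max(idx), length(pages)))
  }
  channels <- stats::setNames(pages[idx + 1L], names(channel_map))
  image_stack(channels,
              pixel_size %||% meta$pixel_size %||% 1,
              source = path)
}

# Collapse RGB(A) pages to grayscale; tiff::readTIFF already rescales
# integer data to [0, 1].
as_gray_matrix <- function(x) {
  if (length(dim(x)) == 3L) x <- apply(x[, , 1:min(3L, dim(x)[3L]),
                                         drop = FALSE], c(1L, 2L), mean)
  pmax(unclass(x), 0)
}

#' Write a per-PNN measurement table
#'
#' One row per PNN object, stable column order, full-precision CSV.
#'
#' @param records A measurement tibble (see [measure_pnns()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  stopifnot(is.data.frame(records))
  readr::write_csv(drop_list_columns(records), path)
  invisible(path)
}

#' Read a measurement table written by [write_measurements()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_measurements <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

drop_list_columns <- function(df) {
  df[, !vapply(df, is.list, logical(1)), drop = FALSE]
}
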