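#' Multi-channel fluorescence image container
#'
#' Bundles registered 2D intensity grids (one matrix per channel, all the same
#' shape) with the physical pixel size and sample annotation. Intensities are
#' stored on a \[0, 1\] scale compatible with 16-bit TIFF round-tripping.
#'
#' @param channels Named list of numeric matrices, all with identical
#'   dimensions; values must be finite and non-negative.
#' @param pixel_size Physical pixel size in micrometres per pixel.
#' @param sample_id Sample identifier.
#' @param group Experimental group label (e.g. `"control"` or `"stress"`).
#'
#' @return An object of class `multichannel_image`: a list with elements
#'   `channels`, `pixel_size`, `sample_id` and `group`.
#' @export
#' @examples
#' img <- multichannel_image(
#'   channels = list(er = matrix(0, 8, 8), mito = matrix(0, 8, 8)),
#'   pixel_size = 0.07)
multichannel_image <- function(channels, pixel_size, sample_id = "sample",
                               group = "control") {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(names(channels) == ""))
    stop_param("channels must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  if (any(!vapply(channels, is.matrix, logical(1))))
    stop_param("every channel must be a matrix")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop_param("all channels must share one shape")
  for (ch in names(channels)) {
    v <- channels[[ch]]
    if (!all(is.finite(v)) || any(v < 0))
      stop_param("channel '", ch, "' has non-finite or negative intensities")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop_param("pixel_size must be a single positive number")
  structure(list(channels = channels, pixel_size = pixel_size,
                 sample_id = sample_id, group = group),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multichannel_image> %dx%d px, %.3f um/px, sample '%s' (%s)\n",
              d[1], d[2], x$pixel_size, x$sample_id, x$group))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Labeled binary mask with preprocessing provenance
#'
#' A binary foreground mask together with its 8-connected component labels and
#' a record of how it was produced (threshold, minimum object size, any
#' contrast adjustment). Produced by [binarize_and_filter()].
#'
#' @param mask Logical matrix of foreground pixels.
#' @param labels Integer matrix of the same shape; 0 = background, k > 0 =
#'   component id.
#' @param provenance Named list recording the preprocessing parameters.
#'
#' @return An object of class `labeled_mask` with elements `mask`, `labels`,
#'   `n_objects` and `provenance`.
#' @export
labeled_mask <- function(mask, labels, provenance = list()) {
  mask <- as_binary_matrix(mask)
  if (!identical(dim(mask), dim(labels)))
    stop_param("mask and labels must share one shape")
  structure(list(mask = mask, labels = labels,
                 n_objects = max(0L, max(labels)),
                 provenance = provenance),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %dx%d px, %d object(s), %d foreground px\n",
              nrow(x$mask), ncol(x$mask), x$n_objects, sum(x$mask)))
  invisible(x)
}
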