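# TIFF and sidecar I/O. Images travel as 16-bit multi-page TIFF (one page
# per channel) plus a JSON sidecar with channel names, pixel size and sample
# annotation, so a written image round-trips into a multichannel_image.

#' Write a multi-channel image as 16-bit multi-page TIFF with JSON sidecar
#'
#' @param image A [multichannel_image] (intensities in \[0, 1\]).
#' @param path Output TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param truth Optional ground-truth list; serializable components (data
#'   frames, scalars) are stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, truth = NULL) {
  if (!inherits(image, "multichannel_image"))
    stop_param("image must be a multichannel_image")
  tiff::writeTIFF(unname(image$channels), path, bits.per.sample = 16)
  side <- list(channels = names(image$channels),
               pixel_size = image$pixel_size,
               sample_id = image$sample_id, group = image$group)
  if (!is.null(truth)) {
    keep <- Filter(function(x) is.data.frame(x) ||
                     (is.atomic(x) && length(x) <= 16), truth)
    side$truth <- keep
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_image_tiff()]
#'
#' @param path TIFF path with an accompanying `<path>.json` sidecar.
#' @return A [multichannel_image].
#' @export
read_image_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- setNames(pages, side$channels)
  multichannel_image(channels, side$pixel_size, side$sample_id, side$group)
}
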